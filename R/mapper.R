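#' Build a seed index over a reference genome
#'
#' The index supports exact k-mer seed lookups on both strands of the
#' reference; k-mers containing `N` never match. Lookups are served by exact
#' string matching over the stored reference, so rebuilding from the same
#' input always yields identical results.
#'
#' @param reference A named `DNAStringSet`, a named character vector of
#'   chromosome sequences, a `genome_bundle`, or a FASTA path.
#' @param k Seed length (default 21).
#' @return An object of class `seed_index`.
#' @export
build_index <- function(reference, k = 21L) {
  seqs <- if (inherits(reference, "genome_bundle")) {
    reference$sequences
  } else if (methods::is(reference, "DNAStringSet")) {
    reference
  } else if (is.character(reference) && length(reference) == 1L &&
             file.exists(reference)) {
    Biostrings::readDNAStringSet(reference)
  } else {
    Biostrings::DNAStringSet(reference)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  k <- as.integer(k)
  if (k < 2L) ts_stop("seed length k must be >= 2", "invalid_argument")
  if (k > min(Biostrings::width(seqs))) {
    ts_stop("seed length k exceeds the shortest chromosome", "invalid_argument")
  }
  structure(list(seqs = seqs, k = k), class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> k=%d over %d chromosome(s), %s bp\n",
              x$k, length(x$seqs),
              format(sum(Biostrings::width(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' Number of indexed forward seed positions
#'
#' Counts the forward-strand k-mer windows of the reference, excluding any
#' window containing `N`.
#'
#' @param index A `seed_index`.
#' @return Integer count.
#' @export
n_seeds <- function(index) {
  k <- index$k
  total <- 0L
  for (i in seq_along(index$seqs)) {
    s <- index$seqs[[i]]
    L <- length(s)
    if (L < k) next
    nwin <- L - k + 1L
    npos <- Biostrings::start(Biostrings::matchPattern("N", s, fixed = TRUE))
    if (length(npos)) {
      bad <- unique(unlist(lapply(npos, function(p) {
        max(1L, p - k + 1L):min(nwin, p)
      })))
      nwin <- nwin - length(bad)
    }
    total <- total + nwin
  }
  total
}

#' Look up a seed k-mer on both strands
#'
#' @param index A `seed_index`.
#' @param kmer Seed sequence of length `k`.
#' @return Data frame with `chrom`, `pos` (1-based start of the forward-
#'   strand window) and `strand`.
#' @export
seed_positions <- function(index, kmer) {
  if (nchar(kmer) != index$k) {
    ts_stop("kmer length must equal the index's k", "invalid_argument")
  }
  out <- list()
  for (q in c("+", "-")) {
    pat <- if (q == "+") kmer else revcomp(kmer)
    if (grepl("N", pat, fixed = TRUE)) next
    for (i in seq_along(index$seqs)) {
      m <- Biostrings::matchPattern(pat, index$seqs[[i]], fixed = TRUE)
      if (length(m)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = names(index$seqs)[i], pos = Biostrings::start(m),
          strand = q, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
}

## Candidate full-length alignments of `query` against the forward strand,
## found by pigeonhole seeding (mm+1 non-overlapping seeds: any alignment with
## <= mm mismatches matches at least one seed exactly).
scan_query <- function(query, index, mm) {
  k <- index$k
  L <- nchar(query)
  nseg <- mm + 1L
  seed_starts <- unique(pmin(L - k + 1L, 1L + (seq_len(nseg) - 1L) * k))
  hits <- list()
  for (ci in seq_along(index$seqs)) {
    chrom <- names(index$seqs)[ci]
    subject <- index$seqs[[ci]]
    subj_len <- length(subject)
    cand <- integer(0)
    for (ss in seed_starts) {
      pat <- substr(query, ss, ss + k - 1L)
      if (grepl("N", pat, fixed = TRUE)) next
      m <- Biostrings::start(Biostrings::matchPattern(pat, subject, fixed = TRUE))
      cand <- c(cand, m - ss + 1L)
    }
    cand <- unique(cand)
    cand <- cand[cand >= 1L & cand + L - 1L <= subj_len]
    for (s in cand) {
      ref_piece <- as.character(Biostrings::subseq(subject, s, s + L - 1L))
      d <- count_mismatches(ref_piece, query)
      if (d <= mm) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = s, end = s + L - 1L, mismatches = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
}

#' Map a validated flanking sequence to the reference
#'
#' Seed-and-extend exact mapping (optionally tolerating up to
#' `max_mismatches` substitutions) of a junction flank on both strands. A
#' unique best full-length hit yields an insertion site reported as a 1-based
#' adjacent coordinate pair: the element sits between `left` and
#' `left + 1`, on the junction side of the flank. Multiple equally good hits
#' give `mapping_status = "multi"` (no coordinate); none give `"unmapped"`.
#'
#' The caller states which end of the supplied sequence abuts the element via
#' `junction_end`: flanks produced by [extract_and_validate_flank()] read
#' away from the element, so their junction is at the 5' end (the default).
#' Mapping a flank and its reverse complement (with the flag flipped) yields
#' the same coordinate pair on opposite strands.
#'
#' @param flank Flank sequence (character scalar); attributes are preserved
#'   in the result where present.
#' @param index A [build_index()] result.
#' @param junction_end Which end of `flank` abuts the element: `"5p"`
#'   (default) or `"3p"`.
#' @param max_mismatches Maximum substitutions tolerated in a full-length
#'   match (default 0, exact).
#' @param mutant_id Optional mutant label carried into the result.
#' @return One-row data frame: `mutant_id`, `chromosome`, `left`, `right`,
#'   `strand`, `mapping_status`, `mismatches`.
#' @export
map_flank <- function(flank, index, junction_end = c("5p", "3p"),
                      max_mismatches = 0L, mutant_id = NA_character_) {
  junction_end <- match.arg(junction_end)
  query <- toupper(as.character(flank))
  if (nchar(query) < index$k) {
    ts_stop(sprintf("flank (%d bp) shorter than seed length k=%d",
                    nchar(query), index$k),
            "flank_too_short")
  }
  res <- function(chromosome, left, strand, status, mism) {
    data.frame(mutant_id = mutant_id, chromosome = chromosome,
               left = left, right = if (is.na(left)) NA_real_ else left + 1,
               strand = strand, mapping_status = status,
               mismatches = mism, stringsAsFactors = FALSE)
  }
  fwd <- scan_query(query, index, max_mismatches)
  rev <- scan_query(revcomp(query), index, max_mismatches)
  if (nrow(fwd)) fwd$strand <- "+"
  if (nrow(rev)) rev$strand <- "-"
  hits <- rbind(fwd, rev)
  if (nrow(hits) == 0L) {
    return(res(NA_character_, NA_real_, NA_character_, "unmapped", NA_integer_))
  }
  best <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  if (nrow(best) > 1L) {
    return(res(NA_character_, NA_real_, NA_character_, "multi", min(hits$mismatches)))
  }
  h <- best[1L, ]
  elem_before_match <- (h$strand == "+") == (junction_end == "5p")
  left <- if (elem_before_match) h$start - 1 else h$end
  if (left < 1) {
    return(res(NA_character_, NA_real_, NA_character_, "unmapped", h$mismatches))
  }
  res(h$chrom, left, h$strand, "unique", h$mismatches)
}

#' Summarise mapping outcomes over a mutant cohort
#'
#' @param sites Data frame of [map_flank()] rows (one per mutant; mutants
#'   with no recoverable flank should appear with
#'   `mapping_status = "unmapped"`).
#' @return An object of class `mapping_report` with `n`, `unique`, `multi`,
#'   `unmapped` counts and the unique-site table under `sites`.
#' @export
summarize_mapping <- function(sites) {
  status <- if (nrow(sites)) sites$mapping_status else character(0)
  structure(
    list(n = nrow(sites),
         unique = sum(status == "unique"),
         multi = sum(status == "multi"),
         unmapped = sum(status == "unmapped"),
         sites = sites[status == "unique", , drop = FALSE]),
    class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("<mapping_report> %d mutant(s): %d unique, %d multi, %d unmapped\n",
              x$n, x$unique, x$multi, x$unmapped))
  invisible(x)
}
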