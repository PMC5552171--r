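#' Blunt-cutting restriction enzymes
#'
#' `restriction_enzyme()` describes one blunt cutter; `restriction_enzymes()`
#' returns the default panel used by the display protocol: DraI (TTT^AAA),
#' EcoRV (GAT^ATC), PvuII (CAG^CTG) and StuI (AGG^CCT).
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (A/C/G/T only; `N` in the subject
#'   never matches).
#' @param cut_offset Cut position, in bases from the recognition-site start
#'   (the cut falls after that many bases; blunt ends assumed).
#' @return A `restriction_enzyme`, or for `restriction_enzymes()` a named
#'   list of them.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (grepl("[^ACGT]", recognition)) {
    ts_stop("recognition sequence must be over {A,C,G,T}", "invalid_enzyme")
  }
  if (cut_offset <= 0 || cut_offset >= nchar(recognition)) {
    ts_stop("cut_offset must satisfy 0 < cut_offset < recognition length",
            "invalid_enzyme")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @param names Which of the default enzymes to return.
#' @export
restriction_enzymes <- function(names = c("DraI", "EcoRV", "PvuII", "StuI")) {
  defaults <- list(
    DraI = restriction_enzyme("DraI", "TTTAAA", 3L),
    EcoRV = restriction_enzyme("EcoRV", "GATATC", 3L),
    PvuII = restriction_enzyme("PvuII", "CAGCTG", 3L),
    StuI = restriction_enzyme("StuI", "AGGCCT", 3L))
  defaults[names]
}

## Positions p such that the enzyme cuts between bases p and p+1.
## Overlapping recognition-site occurrences are all honoured.
cut_positions <- function(sequence, enzyme) {
  if (!methods::is(sequence, "DNAString")) {
    sequence <- Biostrings::DNAString(sequence)
  }
  L <- length(sequence)
  if (L == 0L) return(integer(0))
  m <- Biostrings::matchPattern(enzyme$recognition, sequence, fixed = TRUE)
  p <- Biostrings::start(m) + enzyme$cut_offset - 1L
  sort(unique(p[p >= 1L & p < L]))
}

#' Digest a sequence with a blunt-cutting enzyme
#'
#' Scans left to right for every (possibly overlapping) occurrence of the
#' recognition sequence and cuts after `cut_offset` bases of each. The
#' returned fragments tile the input exactly.
#'
#' @param sequence Nucleotide string or `DNAString` over `{A,C,G,T,N}`; `N`
#'   never matches a recognition site.
#' @param enzyme A [restriction_enzyme()].
#' @return Data frame with `start`, `end` (1-based inclusive on the input)
#'   and `sequence` per fragment; zero rows for an empty input.
#' @examples
#' digest("AAATTTAAACCC", restriction_enzymes()[["DraI"]])
#' @export
digest <- function(sequence, enzyme) {
  seq_chr <- if (methods::is(sequence, "DNAString")) as.character(sequence)
             else toupper(as.character(sequence))
  L <- nchar(seq_chr)
  if (L == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  cuts <- cut_positions(seq_chr, enzyme)
  bounds <- c(0L, cuts, L)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  data.frame(start = starts, end = ends,
             sequence = substring(seq_chr, starts, ends),
             stringsAsFactors = FALSE)
}

#' Predict nested-PCR display bands for a mutant genome
#'
#' Simulates the genome-walking display readout for every tracked element
#' copy: the copy's primer-bearing terminus must sit on a digestion fragment
#' that still contains the complete outer (R1) and nested (R2) primer sites
#' and ends in an adaptor-ligated genomic cut. The observable nested product
#' runs from the R2 site through the element terminus to the fragment's
#' genomic cut end, plus the nested adaptor-primer tail. Copies whose
#' primer-bearing end is truncated or fractured yield no band; fragments
#' outside the amplifiable size window are dropped.
#'
#' @param mutant A `mutant_genome` from [implant_element()], or a list with
#'   `sequences` (`DNAStringSet`) and a `copies` data frame
#'   (`chrom`, `start`, `end`, `orientation`, `source`).
#' @param element An [element_spec()]; defaults to the mutant's element.
#' @param enzymes List of [restriction_enzyme()]s (default: the four-enzyme
#'   panel).
#' @param adaptor_length Length contributed by the nested adaptor primer
#'   tail, bp.
#' @param size_range Amplifiable product-length window, bp.
#' @param sample_id Sample label attached to each band.
#' @return Data frame of class `display_bands`: `sample_id`, `enzyme`,
#'   `product_length`, `chrom`, `junction` (mutant coordinate of the
#'   element/genome boundary), `source`, `orientation`, `flank_seq`,
#'   `product_seq`.
#' @export
predict_display_products <- function(mutant,
                                     element = NULL,
                                     enzymes = restriction_enzymes(),
                                     adaptor_length = 25L,
                                     size_range = c(100L, 6000L),
                                     sample_id = NULL) {
  element <- element %||% mutant$element
  if (is.null(element)) {
    ts_stop("an element_spec is required to locate primer sites",
            "invalid_argument")
  }
  sample_id <- sample_id %||% mutant$mutant_id %||% "S1"
  copies <- mutant$copies
  dist_r1 <- element$primer_sites$R1$dist
  dist_r2 <- element$primer_sites$R2$dist
  term_r1 <- element_terminal_seq(element, dist_r1)

  out <- list()
  needed_chroms <- unique(copies$chrom)
  for (en in enzymes) {
    cuts_by_chrom <- lapply(
      setNames(needed_chroms, needed_chroms),
      function(ch) cut_positions(mutant$sequences[[ch]], en))
    for (i in seq_len(nrow(copies))) {
      cp <- copies[i, ]
      seq_i <- mutant$sequences[[cp$chrom]]
      L <- length(seq_i)
      cuts <- cuts_by_chrom[[cp$chrom]]
      ## does the flank extend rightwards of the assayed terminus?
      flank_right <- (cp$orientation == "+") == (element$primer_terminus == "3p")
      if (flank_right) {
        term <- cp$end
        if (term - dist_r1 + 1L < 1L) next
        idx <- findInterval(term, cuts)
        frag_lo <- if (idx >= 1L) cuts[idx] + 1L else 1L
        frag_hi_cut <- if (idx < length(cuts)) cuts[idx + 1L] else NA
        if (frag_lo > term - dist_r1 + 1L) next     # primer sites cut away
        if (is.na(frag_hi_cut) || frag_hi_cut <= term) next  # no genomic cut
        f <- frag_hi_cut - term
        elem_part <- as.character(Biostrings::subseq(seq_i, term - dist_r2 + 1L, term))
        flank <- as.character(Biostrings::subseq(seq_i, term + 1L, frag_hi_cut))
      } else {
        term <- cp$start
        if (term + dist_r1 - 1L > L) next
        idx <- findInterval(term - 1L, cuts)
        frag_hi <- if (idx < length(cuts)) cuts[idx + 1L] else L
        frag_lo_cut <- if (idx >= 1L) cuts[idx] else NA
        if (frag_hi < term + dist_r1 - 1L) next
        if (is.na(frag_lo_cut) || frag_lo_cut >= term - 1L) next
        f <- (term - 1L) - frag_lo_cut
        elem_part <- revcomp(as.character(
          Biostrings::subseq(seq_i, term, term + dist_r2 - 1L)))
        flank <- revcomp(as.character(
          Biostrings::subseq(seq_i, frag_lo_cut + 1L, term - 1L)))
      }
      ## exact-match primer check: the terminal dist_r1 bases must equal the
      ## element's terminus (fails for fractured/over-truncated copies)
      elem_r1 <- if (flank_right) {
        as.character(Biostrings::subseq(seq_i, term - dist_r1 + 1L, term))
      } else {
        revcomp(as.character(Biostrings::subseq(seq_i, term, term + dist_r1 - 1L)))
      }
      if (elem_r1 != term_r1) next
      product_length <- dist_r2 + f + adaptor_length
      if (product_length < size_range[1] || product_length > size_range[2]) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, enzyme = en$name,
        product_length = product_length,
        chrom = cp$chrom,
        junction = term,
        source = cp$source, orientation = cp$orientation,
        flank_seq = flank,
        product_seq = paste0(elem_part, flank),
        stringsAsFactors = FALSE)
    }
  }
  bands <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), enzyme = character(0),
               product_length = numeric(0), chrom = character(0),
               junction = numeric(0), source = character(0),
               orientation = character(0), flank_seq = character(0),
               product_seq = character(0), stringsAsFactors = FALSE)
  class(bands) <- c("display_bands", class(bands))
  bands
}

#' Flag bands as common or unique across samples
#'
#' A band is common when every sample in the comparison shows a band of the
#' same enzyme within `length_tolerance` bp; otherwise it is unique to its
#' sample. The residual element copies shared by all samples surface as
#' common bands; fresh insertions surface as unique bands.
#'
#' @param bands A `display_bands` data frame covering two or more samples
#'   (one sample triggers a warning and all-unique flags).
#' @param length_tolerance Band-length matching tolerance, bp. The in-silico
#'   default is 0 (exact); a small positive "gel mode" tolerance emulates gel
#'   resolution.
#' @return The input with a logical `unique` column added.
#' @export
compare_band_sets <- function(bands, length_tolerance = 0) {
  samples <- unique(bands$sample_id)
  if (length(samples) < 2L) {
    ts_warn("band comparison needs >= 2 samples; flagging all bands unique",
            "single_sample_comparison")
    bands$unique <- rep(TRUE, nrow(bands))
    return(bands)
  }
  uniq <- logical(nrow(bands))
  for (i in seq_len(nrow(bands))) {
    others <- setdiff(samples, bands$sample_id[i])
    present <- vapply(others, function(s) {
      any(bands$sample_id == s & bands$enzyme == bands$enzyme[i] &
            abs(bands$product_length - bands$product_length[i]) <= length_tolerance)
    }, logical(1))
    uniq[i] <- !all(present)
  }
  bands$unique <- uniq
  bands
}

#' Validate a band's element-end evidence and extract the genomic flank
#'
#' Mirrors the screening step of the wet protocol: a sequenced product is
#' accepted only if it carries more than `min_element_evidence` bases exactly
#' matching the element terminus adjacent to the junction; the genomic-side
#' sequence beyond the junction is returned for mapping.
#'
#' @param band One row of a `display_bands` table (with `product_seq` and
#'   `flank_seq`).
#' @param element The [element_spec()] the product should derive from.
#' @param min_element_evidence Minimum element-end evidence, bp (exclusive
#'   bound; default 100).
#' @return The genomic flank sequence (character scalar) with the band's
#'   `chrom` and `junction` attached as attributes.
#' @export
extract_and_validate_flank <- function(band, element,
                                       min_element_evidence = 100L) {
  product <- band$product_seq
  flank <- band$flank_seq
  elem_len <- nchar(product) - nchar(flank)
  if (nchar(flank) == 0L) {
    ts_stop("product contains no genomic sequence beyond the element terminus",
            "no_genomic_flank")
  }
  ## contiguous exact match to the element terminus, counted from the junction
  term <- element_terminal_seq(element, elem_len)
  elem_part <- substr(product, 1L, elem_len)
  a <- rev(charToRaw(elem_part))
  b <- rev(charToRaw(term))
  n <- min(length(a), length(b))
  mism <- which(a[seq_len(n)] != b[seq_len(n)])
  evidence <- if (length(mism)) mism[1L] - 1L else n
  if (evidence <= min_element_evidence) {
    ts_stop(sprintf(
      "only %d bp of element-end evidence (need > %d); band rejected",
      evidence, min_element_evidence),
      "insufficient_element_evidence")
  }
  structure(flank, chrom = band$chrom, junction = band$junction,
            sample_id = band$sample_id, enzyme = band$enzyme)
}
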