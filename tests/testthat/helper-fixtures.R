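## Shared in-code fixtures: everything is generated, nothing is read from disk.

## A minimal genome_bundle around explicit chromosome sequences.
toy_bundle <- function(seqs, genes = list(),
                       residual_copies = NULL, element = NULL) {
  if (is.null(residual_copies)) {
    residual_copies <- data.frame(
      chrom = character(0), start = numeric(0), end = numeric(0),
      length = integer(0), orientation = character(0),
      stringsAsFactors = FALSE)
  }
  structure(
    list(sequences = Biostrings::DNAStringSet(seqs),
         genes = genes,
         pericentromeres = data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0)),
         residual_copies = residual_copies,
         element = element,
         spec = NULL),
    class = "genome_bundle")
}

## Deterministic nucleotide string free of all four default recognition sites.
safe_dna <- function(n) {
  substr(strrep("ACGG", ceiling(n / 4)), 1, n)
}

## Deterministic non-periodic sequence free of the default recognition sites
## (periodic sequences make truncated element ends look like intact ones).
random_safe_dna <- function(n, seed) {
  forbidden <- c("TTTAAA", "GATATC", "CAGCTG", "AGGCCT")
  set.seed(seed)
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    if (!any(vapply(forbidden, grepl, logical(1), x = s, fixed = TRUE))) {
      return(s)
    }
  }
}

## The worked two-exon plus-strand transcript used across partition tests.
two_exon_tx <- function(strand = "+") {
  transcript_model("t1", "g1", "Chr01", strand,
                   exons = rbind(c(101, 200), c(301, 400)),
                   cds = rbind(c(151, 200), c(301, 350)))
}

## Small synthetic spec for fast end-to-end pipeline tests.
small_spec <- function(seed = 42L) {
  synthetic_genome_spec(n_chromosomes = 2L, chromosome_length = 3e5,
                        seed = seed)
}

## Brute-force digestion oracle: naive left-to-right sliding-window scan.
oracle_digest <- function(sequence, enzyme) {
  s <- as.character(sequence)
  L <- nchar(s)
  rec <- enzyme$recognition
  m <- nchar(rec)
  cuts <- integer(0)
  for (p in seq_len(max(0L, L - m + 1L))) {
    if (substr(s, p, p + m - 1L) == rec) {
      cp <- p + enzyme$cut_offset - 1L
      if (cp >= 1L && cp < L) cuts <- c(cuts, cp)
    }
  }
  cuts <- sort(unique(cuts))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, L)
  data.frame(start = starts, end = ends,
             sequence = substring(s, starts, ends),
             stringsAsFactors = FALSE)
}

## Independent hotspot oracle: qualifying index windows reduced with IRanges.
oracle_hotspots <- function(sites, window = 1e6, min_count = 3L) {
  out <- list()
  for (ch in sort(unique(sites$chromosome))) {
    pos <- sort(sites$left[sites$chromosome == ch])
    m <- length(pos)
    qi <- list()
    for (i in seq_len(m)) {
      for (j in i:m) {
        if (pos[j] - pos[i] + 1 <= window && j - i + 1L >= min_count) {
          qi[[length(qi) + 1L]] <- c(i, j)
        }
      }
    }
    if (!length(qi)) next
    q <- do.call(rbind, qi)
    ## merge only index runs that truly share a member (overlap), not runs
    ## that are merely adjacent
    red <- IRanges::reduce(IRanges::IRanges(q[, 1], q[, 2]),
                           min.gapwidth = 0L)
    for (r in seq_along(red)) {
      i <- IRanges::start(red)[r]; j <- IRanges::end(red)[r]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch, start = pos[i], end = pos[j],
        insertion_count = j - i + 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chromosome = character(0), start = numeric(0),
               end = numeric(0), insertion_count = integer(0),
               stringsAsFactors = FALSE)
}

## Per-base label array oracle for the classifier (toy genomes only).
## Labels each base of one chromosome from the longest variants, then reads
## the label of base `left`; gene bodies take precedence, then the nearer of
## the upstream/downstream windows, ties to the smaller gene_id.
oracle_classify <- function(left, genes, chrom, chrom_len, window = 2000L) {
  label <- rep("intergenic", chrom_len)
  owner <- rep(NA_character_, chrom_len)
  for (g in genes[order(vapply(genes, `[[`, character(1), "gene_id"),
                        decreasing = TRUE)]) {
    if (g$chromosome != chrom) next
    t <- select_longest_variant(g)
    span <- c(min(t$exons[, 1]), max(t$exons[, 2]))
    body <- span[1]:span[2]
    label[body] <- "intron"
    for (i in seq_len(nrow(t$exons))) {
      label[t$exons[i, 1]:t$exons[i, 2]] <- "exon"
    }
    owner[body] <- g$gene_id
  }
  if (label[left] %in% c("exon", "intron")) {
    return(list(category = label[left], gene_id = owner[left]))
  }
  best <- NULL
  for (g in genes) {
    if (g$chromosome != chrom) next
    t <- select_longest_variant(g)
    span <- c(min(t$exons[, 1]), max(t$exons[, 2]))
    if (left < span[1] && span[1] - left <= window) {
      kind <- if (g$strand == "+") "upstream" else "downstream"
      d <- span[1] - left
    } else if (left > span[2] && left - span[2] <= window) {
      kind <- if (g$strand == "+") "downstream" else "upstream"
      d <- left - span[2]
    } else next
    if (is.null(best) || d < best$distance ||
        (d == best$distance && g$gene_id < best$gene_id)) {
      best <- list(category = kind, gene_id = g$gene_id, distance = d)
    }
  }
  if (is.null(best)) list(category = "intergenic", gene_id = NA_character_)
  else best
}
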