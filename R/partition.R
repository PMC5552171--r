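#' Select a gene's longest splice variant
#'
#' "Longest" means the greatest transcribed span (distance from the first to
#' the last exonic base), the region transcribed being the gene's full
#' length for partition purposes. Ties are broken by the lexicographically
#' smallest transcript identifier. An alternative rule (greatest summed
#' exonic length) is available via `by = "exonic"`.
#'
#' @param gene A [gene_model()] with at least one transcript.
#' @param by `"span"` (default) or `"exonic"`.
#' @return The selected [transcript_model()].
#' @export
select_longest_variant <- function(gene, by = c("span", "exonic")) {
  by <- match.arg(by)
  if (length(gene$transcripts) == 0L) {
    ts_stop(sprintf("gene %s has no transcripts", gene$gene_id),
            "malformed_annotation")
  }
  key <- vapply(gene$transcripts, function(t) {
    if (by == "span") transcript_span(t) else sum(t$exons[, 2] - t$exons[, 1] + 1)
  }, numeric(1))
  ids <- vapply(gene$transcripts, `[[`, character(1), "transcript_id")
  best <- which(key == max(key))
  gene$transcripts[[best[order(ids[best])[1L]]]]
}

#' Partition a transcript into UTR, CDS and intron lengths
#'
#' Decomposes the transcribed span into the 5' UTR, CDS, 3' UTR and combined
#' intron lengths (strand-aware), satisfying the identity
#' `full = utr5 + cds + utr3 + intron`. For a non-coding transcript (no CDS)
#' the whole exonic length is reported in the `cds_length` slot with
#' `noncoding = TRUE`, keeping the identity intact.
#'
#' @param t A [transcript_model()].
#' @return A one-row data frame with `gene_id`, `transcript_id`,
#'   `full_length`, `cds_length`, `utr5_length`, `utr3_length`,
#'   `intron_length`, `noncoding`.
#' @examples
#' t <- transcript_model("t1", "g1", "Chr01", "+",
#'                       exons = rbind(c(101, 200), c(301, 400)),
#'                       cds = rbind(c(151, 200), c(301, 350)))
#' partition_transcript(t)
#' @export
partition_transcript <- function(t) {
  exon_len <- sum(t$exons[, 2] - t$exons[, 1] + 1)
  full <- transcript_span(t)
  intron <- full - exon_len
  if (nrow(t$cds) == 0L) {
    return(data.frame(
      gene_id = t$gene_id, transcript_id = t$transcript_id,
      full_length = full, cds_length = exon_len,
      utr5_length = 0, utr3_length = 0, intron_length = intron,
      noncoding = TRUE, stringsAsFactors = FALSE))
  }
  cds_len <- sum(t$cds[, 2] - t$cds[, 1] + 1)
  cds_gmin <- min(t$cds[, 1])
  cds_gmax <- max(t$cds[, 2])
  ## exonic bases genomically before the first / after the last CDS base
  b5 <- sum(pmax(0, pmin(t$exons[, 2], cds_gmin - 1) - t$exons[, 1] + 1))
  b3 <- sum(pmax(0, t$exons[, 2] - pmax(t$exons[, 1], cds_gmax + 1) + 1))
  utr5 <- if (t$strand == "+") b5 else b3
  utr3 <- if (t$strand == "+") b3 else b5
  data.frame(
    gene_id = t$gene_id, transcript_id = t$transcript_id,
    full_length = full, cds_length = cds_len,
    utr5_length = utr5, utr3_length = utr3, intron_length = intron,
    noncoding = FALSE, stringsAsFactors = FALSE)
}

#' Per-gene partition table over longest splice variants
#'
#' @param genes List of [gene_model()] objects.
#' @inheritParams select_longest_variant
#' @return Data frame with one row per gene (its longest variant's
#'   partition).
#' @export
gene_partition_table <- function(genes, by = "span") {
  if (length(genes) == 0L) {
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      full_length = numeric(0), cds_length = numeric(0),
                      utr5_length = numeric(0), utr3_length = numeric(0),
                      intron_length = numeric(0), noncoding = logical(0)))
  }
  do.call(rbind, lapply(genes, function(g) {
    partition_transcript(select_longest_variant(g, by = by))
  }))
}

#' Genome-wide exon/intron partition totals
#'
#' Sums the longest-variant partitions of all genes and divides by the summed
#' chromosome lengths to give the exon, intron and genic fractions expected
#' under random insertion. Only chromosome-mapped sequence enters the
#' denominator: a gene on a chromosome absent from `chrom_lengths` raises an
#' error (naming the gene) rather than silently distorting the fractions.
#'
#' In the default `count_mode = "per_gene"` every gene contributes its own
#' lengths independently, so bases shared by overlapping gene models are
#' counted once per gene. `count_mode = "deduplicated"` instead measures the
#' union of longest-variant exon and gene-body intervals, so each base counts
#' at most once.
#'
#' @param genes List of [gene_model()] objects.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param count_mode `"per_gene"` (default) or `"deduplicated"`.
#' @inheritParams select_longest_variant
#' @return An object of class `partition_totals` with `total_exon`,
#'   `total_intron`, `genome_length`, `exon_fraction`, `intron_fraction`,
#'   `genic_fraction`, `n_genes`, `n_noncoding` and the per-gene `table`.
#' @export
genome_partition <- function(genes, chrom_lengths,
                             count_mode = c("per_gene", "deduplicated"),
                             by = "span") {
  count_mode <- match.arg(count_mode)
  for (g in genes) {
    if (!g$chromosome %in% names(chrom_lengths)) {
      ts_stop(sprintf("gene %s lies on unknown chromosome '%s'",
                      g$gene_id, g$chromosome),
              "unknown_chromosome")
    }
  }
  genome_length <- sum(as.numeric(chrom_lengths))
  tab <- gene_partition_table(genes, by = by)
  if (count_mode == "per_gene") {
    total_exon <- sum(tab$utr5_length + tab$cds_length + tab$utr3_length)
    total_intron <- sum(tab$intron_length)
  } else {
    longest <- lapply(genes, select_longest_variant, by = by)
    by_chrom <- split(longest, vapply(longest, `[[`, character(1), "chromosome"))
    total_exon <- 0
    total_genic <- 0
    for (txs in by_chrom) {
      ex <- do.call(rbind, lapply(txs, `[[`, "exons"))
      exon_union <- IRanges::reduce(IRanges::IRanges(ex[, 1], ex[, 2]))
      spans <- t(vapply(txs, function(t) range(t$exons), numeric(2)))
      span_union <- IRanges::reduce(IRanges::IRanges(spans[, 1], spans[, 2]))
      total_exon <- total_exon + sum(IRanges::width(exon_union))
      total_genic <- total_genic + sum(IRanges::width(span_union))
    }
    total_intron <- total_genic - total_exon
  }
  structure(
    list(total_exon = total_exon,
         total_intron = total_intron,
         genome_length = genome_length,
         exon_fraction = if (genome_length > 0) total_exon / genome_length else 0,
         intron_fraction = if (genome_length > 0) total_intron / genome_length else 0,
         genic_fraction = if (genome_length > 0)
           (total_exon + total_intron) / genome_length else 0,
         n_genes = length(genes),
         n_noncoding = sum(tab$noncoding),
         count_mode = count_mode,
         table = tab),
    class = "partition_totals")
}

#' @export
print.partition_totals <- function(x, ...) {
  cat(sprintf(paste0(
    "<partition_totals> %d gene(s) on %s bp (%s)\n",
    "  exon %.3f  intron %.3f  genic %.3f"),
    x$n_genes, format(x$genome_length, big.mark = ","), x$count_mode,
    x$exon_fraction, x$intron_fraction, x$genic_fraction))
  if (x$n_noncoding > 0) {
    cat(sprintf("  (%d non-coding model(s): exonic length counted as exon)",
                x$n_noncoding))
  }
  cat("\n")
  invisible(x)
}

#' Read chromosome lengths from a FASTA or two-column TSV
#'
#' @param path FASTA (`.fa`, `.fasta`, `.fna`) or a TSV with columns
#'   `chrom`, `length`.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chromosome_lengths <- function(path) {
  if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)) {
    Biostrings::fasta.seqlengths(path)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    setNames(as.numeric(df[[2]]), df[[1]])
  }
}

#' Write partition totals (and the per-gene table) to disk
#'
#' @param totals A `partition_totals` object.
#' @param json_path Path for the totals JSON.
#' @param table_path Optional path for the per-gene partition TSV.
#' @return Invisibly, `json_path`.
#' @export
write_partition_totals <- function(totals, json_path, table_path = NULL) {
  out <- totals[c("total_exon", "total_intron", "genome_length",
                  "exon_fraction", "intron_fraction", "genic_fraction",
                  "n_genes", "n_noncoding", "count_mode")]
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(table_path)) {
    write.table(totals$table, table_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(json_path)
}
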