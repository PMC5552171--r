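#' Construct a transcript model
#'
#' A transcript is an ordered set of 1-based inclusive exon intervals plus the
#' CDS segments they contain. Coordinates are genomic (GFF3 convention);
#' transcription order is derived from `strand`.
#'
#' @param transcript_id,gene_id Feature identifiers.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of exon intervals.
#' @param cds Two-column matrix (start, end) of CDS segments; may have zero
#'   rows for a non-coding transcript.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chromosome, strand,
                             exons, cds = matrix(numeric(0), ncol = 2)) {
  exons <- matrix(as.numeric(exons), ncol = 2)
  cds <- matrix(as.numeric(cds), ncol = 2)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(cds)) cds <- cds[order(cds[, 1]), , drop = FALSE]
  if (!strand %in% c("+", "-")) {
    ts_stop("strand must be '+' or '-'", "malformed_annotation")
  }
  if (nrow(exons) == 0L) {
    ts_stop(sprintf("transcript %s has no exons", transcript_id),
            "malformed_annotation")
  }
  if (any(exons[, 2] < exons[, 1]) || (nrow(cds) && any(cds[, 2] < cds[, 1]))) {
    ts_stop(sprintf("transcript %s has reversed intervals", transcript_id),
            "malformed_annotation")
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1] <= exons[-nrow(exons), 2])) {
    ts_stop(sprintf("transcript %s has overlapping exons", transcript_id),
            "malformed_annotation")
  }
  ## every CDS segment must lie within some exon
  if (nrow(cds)) {
    for (i in seq_len(nrow(cds))) {
      inside <- any(exons[, 1] <= cds[i, 1] & exons[, 2] >= cds[i, 2])
      if (!inside) {
        ts_stop(sprintf("transcript %s: CDS segment outside exons",
                        transcript_id),
                "malformed_annotation")
      }
    }
  }
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chromosome = as.character(chromosome),
         strand = strand,
         exons = exons,
         cds = cds),
    class = "transcript_model"
  )
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts List of [transcript_model()] objects (at least one).
#' @return An object of class `gene_model` whose span covers all transcripts.
#' @export
gene_model <- function(gene_id, chromosome, strand, transcripts) {
  if (length(transcripts) == 0L) {
    ts_stop(sprintf("gene %s has no transcripts", gene_id),
            "malformed_annotation")
  }
  starts <- vapply(transcripts, function(t) min(t$exons[, 1]), numeric(1))
  ends <- vapply(transcripts, function(t) max(t$exons[, 2]), numeric(1))
  structure(
    list(gene_id = as.character(gene_id),
         chromosome = as.character(chromosome),
         strand = strand,
         start = min(starts),
         end = max(ends),
         transcripts = transcripts),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%s-%s (%s), %d transcript(s)\n",
              x$gene_id, x$chromosome,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$strand, length(x$transcripts)))
  invisible(x)
}

transcript_span <- function(t) max(t$exons[, 2]) - min(t$exons[, 1]) + 1

## ---- GFF3 interchange -----------------------------------------------------

#' Convert gene models to a GFF3-style GRanges
#'
#' Emits the gene/mRNA/exon/CDS feature hierarchy plus derived
#' five_prime_UTR/three_prime_UTR features, suitable for
#' `rtracklayer::export` as GFF3.
#'
#' @param genes List of [gene_model()] objects.
#' @return A `GRanges` with `type`, `ID` and `Parent` metadata columns.
#' @export
gene_models_to_granges <- function(genes) {
  rows <- list()
  add <- function(chrom, start, end, strand, type, id, parent,
                  phase = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, strand = strand,
      type = type, ID = id, Parent = parent, phase = phase,
      stringsAsFactors = FALSE)
  }
  for (g in genes) {
    add(g$chromosome, g$start, g$end, g$strand, "gene", g$gene_id, NA)
    for (t in g$transcripts) {
      add(t$chromosome, min(t$exons[, 1]), max(t$exons[, 2]), t$strand,
          "mRNA", t$transcript_id, g$gene_id)
      for (i in seq_len(nrow(t$exons))) {
        add(t$chromosome, t$exons[i, 1], t$exons[i, 2], t$strand,
            "exon", NA, t$transcript_id)
      }
      if (nrow(t$cds)) {
        ## phase of each CDS segment in transcription order
        ord <- if (t$strand == "+") seq_len(nrow(t$cds)) else rev(seq_len(nrow(t$cds)))
        lens <- t$cds[ord, 2] - t$cds[ord, 1] + 1
        phase <- (3 - c(0, cumsum(lens)[-length(lens)]) %% 3) %% 3
        for (i in seq_along(ord)) {
          add(t$chromosome, t$cds[ord[i], 1], t$cds[ord[i], 2], t$strand,
              "CDS", NA, t$transcript_id, phase = as.integer(phase[i]))
        }
      }
      for (u in transcript_utrs(t)) {
        for (i in seq_len(nrow(u$intervals))) {
          add(t$chromosome, u$intervals[i, 1], u$intervals[i, 2], t$strand,
              u$type, NA, t$transcript_id)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(GenomicRanges::GRanges())
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  gr
}

## UTR intervals derived from exons minus CDS, split strand-aware into 5'/3'.
transcript_utrs <- function(t) {
  if (nrow(t$cds) == 0L) return(list())
  cds_min <- min(t$cds[, 1]); cds_max <- max(t$cds[, 2])
  clip <- function(lo, hi) {
    s <- pmax(t$exons[, 1], lo); e <- pmin(t$exons[, 2], hi)
    keep <- s <= e
    matrix(c(s[keep], e[keep]), ncol = 2)
  }
  left <- clip(-Inf, cds_min - 1)
  right <- clip(cds_max + 1, Inf)
  out <- list()
  if (t$strand == "+") {
    if (nrow(left)) out <- c(out, list(list(type = "five_prime_UTR", intervals = left)))
    if (nrow(right)) out <- c(out, list(list(type = "three_prime_UTR", intervals = right)))
  } else {
    if (nrow(right)) out <- c(out, list(list(type = "five_prime_UTR", intervals = right)))
    if (nrow(left)) out <- c(out, list(list(type = "three_prime_UTR", intervals = left)))
  }
  out
}

#' Read gene models from a GFF3 file
#'
#' Parses the gene/mRNA/exon/CDS hierarchy (1-based inclusive coordinates)
#' into a list of [gene_model()] objects. UTR features, if present, are
#' ignored: UTR lengths are always derived from exons and CDS so that the
#' partition arithmetic is self-consistent.
#'
#' @param path Path to a GFF3 file.
#' @return List of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  granges_to_gene_models(gr)
}

#' @rdname read_gene_models
#' @param gr A `GRanges` with `type`, `ID`, `Parent` columns as produced by
#'   `rtracklayer::import` on a GFF3 file.
#' @export
granges_to_gene_models <- function(gr) {
  type <- as.character(S4Vectors::mcols(gr)$type)
  id <- as.character(S4Vectors::mcols(gr)$ID)
  parent <- S4Vectors::mcols(gr)$Parent
  parent1 <- vapply(as.list(parent), function(p) {
    if (length(p)) as.character(p[[1]]) else NA_character_
  }, character(1))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))

  is_mrna <- type %in% c("mRNA", "transcript")
  mrna_ids <- id[is_mrna]
  mrna_gene <- parent1[is_mrna]
  mrna_chrom <- chrom[is_mrna]
  mrna_strand <- strand[is_mrna]

  pick <- function(what) {
    sel <- type == what & parent1 %in% mrna_ids
    split(data.frame(start = start[sel], end = end[sel]), parent1[sel])
  }
  exon_by_tx <- pick("exon")
  cds_by_tx <- pick("CDS")

  genes <- list()
  gene_ids <- unique(mrna_gene)
  for (gid in gene_ids) {
    tx_idx <- which(mrna_gene == gid)
    txs <- list()
    for (j in tx_idx) {
      tid <- mrna_ids[j]
      ex <- exon_by_tx[[tid]]
      if (is.null(ex)) next
      cd <- cds_by_tx[[tid]]
      txs[[length(txs) + 1L]] <- transcript_model(
        tid, gid, mrna_chrom[j], mrna_strand[j],
        as.matrix(ex),
        if (is.null(cd)) matrix(numeric(0), ncol = 2) else as.matrix(cd))
    }
    if (length(txs)) {
      genes[[length(genes) + 1L]] <- gene_model(
        gid, txs[[1]]$chromosome, txs[[1]]$strand, txs)
    }
  }
  genes
}
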