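## Structural constants of the gene builder. Exon/intron sizes are drawn in
## ranges typical of compact plant gene models; the final gene on each
## chromosome is built to land the summed exon and intron lengths on the
## requested totals (to within the minimum feature sizes).
.MIN_EXON <- 90L
.MAX_EXON <- 400L
.MIN_INTRON <- 60L
.MIN_GAP <- 200L

## Split `total` into k parts of at least `min_each`, randomly but exactly.
split_total <- function(total, k, min_each) {
  if (k == 1L) return(total)
  spare <- total - k * min_each
  u <- runif(k)
  lens <- min_each + floor(spare * u / sum(u))
  lens[1L] <- lens[1L] + total - sum(lens)
  lens
}

## Map exonic trims (transcription order) back to genomic CDS intervals.
trim_exons <- function(exons, strand, trim5, trim3) {
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  lens <- exons[, 2] - exons[, 1] + 1
  total <- sum(lens)
  keep_start <- trim5 + 1
  keep_end <- total - trim3
  out <- list()
  pos <- 0
  for (i in ord) {
    s <- pos + 1
    e <- pos + lens[i]
    pos <- e
    lo <- max(s, keep_start)
    hi <- min(e, keep_end)
    if (lo <= hi) {
      if (strand == "+") {
        out[[length(out) + 1L]] <- c(exons[i, 1] + (lo - s), exons[i, 1] + (hi - s))
      } else {
        out[[length(out) + 1L]] <- c(exons[i, 2] - (hi - s), exons[i, 2] - (lo - s))
      }
    }
  }
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

## Draw gene structures (relative layout) until the exon/intron budgets for
## one chromosome are spent. Returns a list of lists with exon_lens,
## intron_lens, strand, utr5, utr3.
draw_gene_structures <- function(target_exon, target_intron, mean_exons) {
  ratio <- if (target_exon > 0) target_intron / target_exon else 0
  bespoke_threshold <- 2600
  structures <- list()
  exon_sum <- 0
  intron_sum <- 0
  repeat {
    exon_rem <- target_exon - exon_sum
    intron_rem <- target_intron - intron_sum
    if (exon_rem < .MIN_EXON) break
    if (exon_rem <= bespoke_threshold) {
      ## final gene absorbs the remainders as exactly as feature minima allow
      n_ex <- max(1L, min(round(exon_rem / 300),
                          floor(exon_rem / .MIN_EXON),
                          floor(max(0, intron_rem) / .MIN_INTRON) + 1L))
      exon_lens <- split_total(round(exon_rem), n_ex, .MIN_EXON)
      intron_lens <- if (n_ex > 1L) {
        split_total(round(max(intron_rem, (n_ex - 1L) * .MIN_INTRON)),
                    n_ex - 1L, .MIN_INTRON)
      } else numeric(0)
      final <- TRUE
    } else {
      n_ex <- max(2L, 1L + rpois(1L, mean_exons - 1))
      exon_lens <- sample(seq(.MIN_EXON, .MAX_EXON), n_ex, replace = TRUE)
      while (sum(exon_lens) > exon_rem && n_ex > 2L) {
        exon_lens <- exon_lens[-n_ex]
        n_ex <- n_ex - 1L
      }
      intron_total <- max(round(ratio * sum(exon_lens)),
                          (n_ex - 1L) * .MIN_INTRON)
      intron_lens <- if (n_ex > 1L) {
        split_total(intron_total, n_ex - 1L, .MIN_INTRON)
      } else numeric(0)
      final <- FALSE
    }
    exon_total <- sum(exon_lens)
    utr5 <- max(0L, min(sample(20:150, 1L), floor(exon_total * 0.2)))
    utr3 <- max(0L, min(sample(20:150, 1L), floor(exon_total * 0.2)))
    if (exon_total - utr5 - utr3 < 30L) {
      utr5 <- utr3 <- max(0L, floor((exon_total - 30L) / 2))
    }
    structures[[length(structures) + 1L]] <- list(
      exon_lens = exon_lens, intron_lens = intron_lens,
      strand = sample(c("+", "-"), 1L), utr5 = utr5, utr3 = utr3)
    exon_sum <- exon_sum + exon_total
    intron_sum <- intron_sum + sum(intron_lens)
    if (final) break
  }
  structures
}

## Turn a structure at an absolute start position into a gene_model,
## optionally with a second (shorter or exon-skipping) splice variant.
build_gene <- function(struct, gene_id, chrom, gene_start, make_isoform) {
  n_ex <- length(struct$exon_lens)
  starts <- numeric(n_ex)
  ends <- numeric(n_ex)
  pos <- gene_start
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    ends[i] <- pos + struct$exon_lens[i] - 1
    pos <- ends[i] + 1 + if (i < n_ex) struct$intron_lens[i] else 0
  }
  exons <- cbind(starts, ends)
  cds <- trim_exons(exons, struct$strand, struct$utr5, struct$utr3)
  txs <- list(transcript_model(paste0(gene_id, ".1"), gene_id, chrom,
                               struct$strand, exons, cds))
  if (make_isoform && n_ex >= 2L) {
    if (n_ex >= 3L && runif(1) < 0.5) {
      ## skip one internal exon: span unchanged, exonic length reduced
      drop <- sample(2:(n_ex - 1L), 1L)
      exons2 <- exons[-drop, , drop = FALSE]
    } else {
      ## truncate the 3'-terminal exon: transcribed span shortened
      exons2 <- exons
      i3 <- if (struct$strand == "+") n_ex else 1L
      len <- exons2[i3, 2] - exons2[i3, 1] + 1
      cut <- max(1L, floor(len / 2))
      if (len - cut < 30L) cut <- len - 30L
      if (cut > 0L) {
        if (struct$strand == "+") {
          exons2[i3, 2] <- exons2[i3, 2] - cut
        } else {
          exons2[i3, 1] <- exons2[i3, 1] + cut
        }
      }
    }
    total2 <- sum(exons2[, 2] - exons2[, 1] + 1)
    u5 <- min(struct$utr5, max(0L, total2 - 30L))
    u3 <- min(struct$utr3, max(0L, total2 - u5 - 3L))
    cds2 <- trim_exons(exons2, struct$strand, u5, u3)
    txs[[2L]] <- transcript_model(paste0(gene_id, ".2"), gene_id, chrom,
                                  struct$strand, exons2, cds2)
  }
  gene_model(gene_id, chrom, struct$strand, txs)
}

#' Generate a reproducible synthetic genome bundle
#'
#' Builds random chromosome sequences, a non-overlapping gene annotation whose
#' realised exon and intron fractions hit the spec's targets, one contiguous
#' central pericentromeric block per chromosome, and planted truncated copies
#' of the transposable element in intergenic space. Identical spec + seed
#' gives byte-identical output files.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param element An [element_spec()]; its truncated, primer-bearing terminus
#'   is used for the residual copies.
#' @return An object of class `genome_bundle` with components `sequences`
#'   (a named `DNAStringSet`), `genes` (list of [gene_model()]),
#'   `pericentromeres` (data frame, 1-based inclusive), `residual_copies`
#'   (data frame), `element`, and `spec`.
#' @examples
#' b <- generate_genome(synthetic_genome_spec(n_chromosomes = 1,
#'                                            chromosome_length = 2e5))
#' b
#' @export
generate_genome <- function(spec = synthetic_genome_spec(),
                            element = element_spec()) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  with_seed(spec$seed, {
    L <- spec$chromosome_length
    chroms <- sprintf("Chr%02d", seq_len(spec$n_chromosomes))
    genes <- list()
    seqs <- character(spec$n_chromosomes)
    gaps_by_chrom <- list()
    gene_counter <- 0L

    for (ci in seq_along(chroms)) {
      structs <- draw_gene_structures(
        target_exon = spec$target_exon_fraction * L,
        target_intron = spec$target_intron_fraction * L,
        mean_exons = spec$mean_exons_per_gene)
      spans <- vapply(structs, function(s) sum(s$exon_lens) + sum(s$intron_lens),
                      numeric(1))
      ng <- length(structs)
      if (ng > 0) {
        intergenic <- L - sum(spans)
        if (intergenic < (ng + 1L) * .MIN_GAP) {
          ts_stop(sprintf(
            "requested gene content does not fit: %d genes spanning %s bp on a %s bp chromosome",
            ng, format(sum(spans), big.mark = ","), format(L, big.mark = ",")),
            "infeasible_spec")
        }
        gaps <- split_total(intergenic, ng + 1L, .MIN_GAP)
      } else {
        gaps <- L
      }
      pos <- 0
      gap_rec <- list()
      for (gi in seq_len(ng)) {
        gap_rec[[length(gap_rec) + 1L]] <- c(pos + 1, pos + gaps[gi])
        gstart <- pos + gaps[gi] + 1
        gene_counter <- gene_counter + 1L
        gid <- sprintf("SynGene.%s.%04d", sub("Chr", "", chroms[ci]), gene_counter)
        make_iso <- runif(1) < spec$multi_isoform_gene_fraction
        genes[[length(genes) + 1L]] <-
          build_gene(structs[[gi]], gid, chroms[ci], gstart, make_iso)
        pos <- gstart + spans[gi] - 1
      }
      gap_rec[[length(gap_rec) + 1L]] <- c(pos + 1, L)
      gaps_by_chrom[[chroms[ci]]] <- do.call(rbind, gap_rec)
      seqs[ci] <- random_dna(L, spec$gc_content)
    }

    ## residual, immobile truncated element copies in the widest gaps
    residual <- data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), length = integer(0),
                           orientation = character(0))
    if (spec$n_residual_copies > 0L) {
      res_seq <- element_residual_seq(element, spec$residual_copy_length)
      res_len <- nchar(res_seq)
      for (j in seq_len(spec$n_residual_copies)) {
        ci <- ((j - 1L) %% spec$n_chromosomes) + 1L
        g <- gaps_by_chrom[[chroms[ci]]]
        widths <- g[, 2] - g[, 1] + 1
        k <- which.max(widths)
        if (widths[k] < res_len + 2 * .MIN_GAP) {
          ts_stop("no intergenic gap wide enough for a residual element copy",
                  "infeasible_spec")
        }
        s <- g[k, 1] + floor((widths[k] - res_len) / 2)
        substr(seqs[ci], s, s + res_len - 1) <- res_seq
        ## shrink the used gap so a second copy on this chromosome moves on
        gaps_by_chrom[[chroms[ci]]][k, ] <- c(g[k, 1], s - 1)
        residual <- rbind(residual, data.frame(
          chrom = chroms[ci], start = s, end = s + res_len - 1,
          length = res_len, orientation = "+"))
      }
    }

    peri_len <- round(spec$pericentromere_fraction * L)
    peri <- data.frame(
      chrom = chroms,
      start = floor((L - peri_len) / 2) + 1,
      end = floor((L - peri_len) / 2) + peri_len)
    if (peri_len == 0) peri <- peri[0, ]

    sequences <- Biostrings::DNAStringSet(setNames(seqs, chroms))
    structure(
      list(sequences = sequences,
           genes = genes,
           pericentromeres = peri,
           residual_copies = residual,
           element = element,
           spec = spec),
      class = "genome_bundle")
  })
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf(
    "<genome_bundle> %d chromosome(s), %s bp total, %d gene(s), %d residual element cop%s\n",
    length(x$sequences),
    format(sum(Biostrings::width(x$sequences)), big.mark = ","),
    length(x$genes), nrow(x$residual_copies),
    if (nrow(x$residual_copies) == 1) "y" else "ies"))
  invisible(x)
}

#' Chromosome lengths of a genome bundle
#' @param bundle A `genome_bundle`.
#' @return Named numeric vector of chromosome lengths.
#' @export
chromosome_lengths <- function(bundle) {
  setNames(as.numeric(Biostrings::width(bundle$sequences)),
           names(bundle$sequences))
}

#' Write a genome bundle to standard-format files
#'
#' Writes the reference FASTA, the gene annotation as GFF3 (1-based
#' inclusive, with derived UTR features), the pericentromere track as BED
#' (0-based half-open) and the residual-copy table as TSV.
#'
#' @param bundle A `genome_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    reference = file.path(dir, "reference.fa"),
    annotation = file.path(dir, "annotation.gff3"),
    pericentromeres = file.path(dir, "pericentromeres.bed"),
    residual_copies = file.path(dir, "residual_copies.tsv"))
  Biostrings::writeXStringSet(bundle$sequences, paths$reference)
  gr <- gene_models_to_granges(bundle$genes)
  rtracklayer::export(gr, paths$annotation, format = "gff3")
  if (nrow(bundle$pericentromeres)) {
    peri_gr <- GenomicRanges::GRanges(
      seqnames = bundle$pericentromeres$chrom,
      ranges = IRanges::IRanges(bundle$pericentromeres$start,
                                bundle$pericentromeres$end))
    rtracklayer::export(peri_gr, paths$pericentromeres, format = "bed")
  } else {
    writeLines(character(0), paths$pericentromeres)
  }
  write.table(bundle$residual_copies, paths$residual_copies,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
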