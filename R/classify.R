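#' Precompute classification tables from gene models
#'
#' Reduces each gene to its longest splice variant and builds the interval
#' tables the classifier overlaps against: transcribed spans, exons and
#' introns (with strand-aware ordinals counted from the gene's 5' end).
#'
#' @param genes List of [gene_model()] objects (or an existing
#'   `annotation_db`, returned unchanged).
#' @return An object of class `annotation_db`.
#' @export
annotation_db <- function(genes) {
  if (inherits(genes, "annotation_db")) return(genes)
  longest <- lapply(genes, select_longest_variant)
  spans <- exons <- introns <- list()
  for (t in longest) {
    s <- min(t$exons[, 1]); e <- max(t$exons[, 2])
    spans[[length(spans) + 1L]] <- data.frame(
      chrom = t$chromosome, start = s, end = e, strand = t$strand,
      gene_id = t$gene_id, stringsAsFactors = FALSE)
    n_ex <- nrow(t$exons)
    ord_ex <- if (t$strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    exons[[length(exons) + 1L]] <- data.frame(
      chrom = t$chromosome, start = t$exons[, 1], end = t$exons[, 2],
      gene_id = t$gene_id, ordinal = ord_ex, stringsAsFactors = FALSE)
    if (n_ex > 1L) {
      is_ <- t$exons[-n_ex, 2] + 1
      ie_ <- t$exons[-1L, 1] - 1
      ord_in <- if (t$strand == "+") seq_len(n_ex - 1L) else rev(seq_len(n_ex - 1L))
      introns[[length(introns) + 1L]] <- data.frame(
        chrom = t$chromosome, start = is_, end = ie_,
        gene_id = t$gene_id, ordinal = ord_in, stringsAsFactors = FALSE)
    }
  }
  bindgr <- function(lst) {
    if (!length(lst)) {
      return(list(df = data.frame(), gr = GenomicRanges::GRanges()))
    }
    df <- do.call(rbind, lst)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    list(df = df, gr = gr)
  }
  structure(
    list(spans = bindgr(spans), exons = bindgr(exons), introns = bindgr(introns)),
    class = "annotation_db")
}

## select, per query point, the subject hit minimising (key1, key2)
pick_best <- function(qh, sh, key1, key2) {
  o <- order(qh, key1, key2)
  keep <- o[!duplicated(qh[o])]
  list(q = qh[keep], s = sh[keep])
}

#' Classify insertion sites against the annotation
#'
#' Assigns every uniquely mapped site exactly one category. The inter-base
#' junction between `left` and `left + 1` is attributed to the feature
#' containing base `left` (so a junction falling exactly on an exon/intron
#' boundary goes to the lower-coordinate feature). A junction inside a gene's
#' longest-variant span is exonic or intronic, with the ordinal counted from
#' the gene's 5' end; UTR bases count as exon. Outside gene bodies, a
#' junction within `window` bp of a transcription start is upstream (distance
#' `gene_start - left` on the plus strand, mirrored on the minus strand) and
#' within `window` bp past the gene end is downstream; the nearest gene wins,
#' ties go to the smaller `gene_id`. Everything else is intergenic.
#'
#' @param sites Data frame with `mutant_id`, `chromosome`, `left` (and
#'   optionally `mapping_status`; non-`"unique"` rows are passed through
#'   unclassified).
#' @param genes List of [gene_model()]s or an [annotation_db()].
#' @param window Upstream/downstream window, bp (default 2000).
#' @param pericentromeres Optional pericentromere table (see
#'   [chromatin_context()]); when supplied a `chromatin` column is added.
#' @return Data frame with `category` (`exon`, `intron`, `upstream`,
#'   `downstream`, `intergenic`), `gene_id`, `ordinal`, `distance` and
#'   optionally `chromatin` columns appended to `sites`.
#' @export
classify_sites <- function(sites, genes, window = 2000L,
                           pericentromeres = NULL) {
  db <- annotation_db(genes)
  n <- nrow(sites)
  out <- sites
  out$category <- rep(NA_character_, n)
  out$gene_id <- rep(NA_character_, n)
  out$ordinal <- rep(NA_integer_, n)
  out$distance <- rep(NA_real_, n)
  ok <- if ("mapping_status" %in% names(sites)) {
    sites$mapping_status == "unique"
  } else rep(TRUE, n)
  ok <- ok & !is.na(sites$left)
  idx <- which(ok)
  if (length(idx)) {
    pts <- GenomicRanges::GRanges(
      sites$chromosome[idx],
      IRanges::IRanges(sites$left[idx], width = 1L))

    ## --- gene bodies ------------------------------------------------------
    ## sites on chromosomes with no annotated features are legitimate
    ## (intergenic), so seqlevel-mismatch warnings from overlaps are noise
    if (length(db$spans$gr)) {
      ov <- suppressWarnings(GenomicRanges::findOverlaps(pts, db$spans$gr))
      if (length(ov)) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        best <- pick_best(qh, sh, db$spans$df$gene_id[sh], sh)
        gene_of <- setNames(db$spans$df$gene_id[best$s], best$q)
        body_q <- best$q
        ## exon hits restricted to the assigned gene
        if (length(db$exons$gr)) {
          ove <- suppressWarnings(
            GenomicRanges::findOverlaps(pts[body_q], db$exons$gr))
          if (length(ove)) {
            qe <- body_q[S4Vectors::queryHits(ove)]
            se <- S4Vectors::subjectHits(ove)
            same <- db$exons$df$gene_id[se] == gene_of[as.character(qe)]
            qe <- qe[same]; se <- se[same]
            if (length(qe)) {
              b <- pick_best(qe, se, db$exons$df$ordinal[se], se)
              ii <- idx[b$q]
              out$category[ii] <- "exon"
              out$gene_id[ii] <- db$exons$df$gene_id[b$s]
              out$ordinal[ii] <- db$exons$df$ordinal[b$s]
            }
          }
        }
        ## remaining gene-body points are intronic
        rest <- body_q[is.na(out$category[idx[body_q]])]
        if (length(rest) && length(db$introns$gr)) {
          ovi <- suppressWarnings(
            GenomicRanges::findOverlaps(pts[rest], db$introns$gr))
          if (length(ovi)) {
            qi <- rest[S4Vectors::queryHits(ovi)]
            si <- S4Vectors::subjectHits(ovi)
            same <- db$introns$df$gene_id[si] == gene_of[as.character(qi)]
            qi <- qi[same]; si <- si[same]
            if (length(qi)) {
              b <- pick_best(qi, si, db$introns$df$ordinal[si], si)
              ii <- idx[b$q]
              out$category[ii] <- "intron"
              out$gene_id[ii] <- db$introns$df$gene_id[b$s]
              out$ordinal[ii] <- db$introns$df$ordinal[b$s]
            }
          }
        }
      }
    }

    ## --- upstream / downstream windows ------------------------------------
    open_q <- which(is.na(out$category[idx]))
    if (length(open_q) && length(db$spans$gr)) {
      sp <- db$spans$df
      ## before_gene: the window [start - window, start - 1] of base `left`,
      ## i.e. junctions strictly before the gene body; after_gene mirrors it.
      ## Upstream of a + gene (and downstream of a - gene) is before_gene.
      win_of <- function(kind) {
        before <- (kind == "upstream") == (sp$strand == "+")
        s <- ifelse(before, sp$start - window, sp$end + 1)
        e <- ifelse(before, sp$start - 1, sp$end + window)
        keep <- which(pmax(s, 1) <= e)
        if (!length(keep)) return(NULL)
        list(gr = GenomicRanges::GRanges(
               sp$chrom[keep], IRanges::IRanges(pmax(s[keep], 1), e[keep])),
             gene = sp$gene_id[keep], row = keep)
      }
      cand <- list()
      for (kind in c("upstream", "downstream")) {
        w <- win_of(kind)
        if (is.null(w)) next
        ov <- suppressWarnings(GenomicRanges::findOverlaps(pts[open_q], w$gr))
        if (!length(ov)) next
        q <- open_q[S4Vectors::queryHits(ov)]
        r <- w$row[S4Vectors::subjectHits(ov)]
        left <- sites$left[idx[q]]
        before <- (kind == "upstream") == (sp$strand[r] == "+")
        dist <- ifelse(before, sp$start[r] - left, left - sp$end[r])
        cand[[kind]] <- data.frame(q = q, gene = sp$gene_id[r],
                                   kind = kind, dist = dist,
                                   stringsAsFactors = FALSE)
      }
      if (length(cand)) {
        cd <- do.call(rbind, cand)
        o <- order(cd$q, cd$dist, cd$gene)
        cd <- cd[o[!duplicated(cd$q[o])], , drop = FALSE]
        ii <- idx[cd$q]
        out$category[ii] <- cd$kind
        out$gene_id[ii] <- cd$gene
        out$distance[ii] <- cd$dist
      }
    }
    out$category[idx][is.na(out$category[idx])] <- "intergenic"
  }
  if (!is.null(pericentromeres)) {
    out$chromatin <- chromatin_context(out, pericentromeres)
  }
  out
}

#' Classify a single insertion site
#'
#' Scalar wrapper around [classify_sites()]; refuses sites whose mapping is
#' not unique.
#'
#' @param site One-row data frame (or list) with `chromosome` and `left`
#'   (optionally `mutant_id`, `mapping_status`).
#' @inheritParams classify_sites
#' @return A one-row classification data frame.
#' @export
classify_site <- function(site, genes, window = 2000L,
                          pericentromeres = NULL) {
  site <- as.data.frame(site, stringsAsFactors = FALSE)
  if ("mapping_status" %in% names(site) &&
      !identical(site$mapping_status, "unique")) {
    ts_stop(sprintf("refusing to classify a site with mapping_status '%s'",
                    site$mapping_status),
            "unclassifiable_site")
  }
  classify_sites(site, genes, window = window,
                 pericentromeres = pericentromeres)
}

#' Chromatin context of insertion sites
#'
#' A site is pericentromeric when its `left` coordinate lies inside any
#' pericentromere interval (1-based inclusive), euchromatic otherwise. Sites
#' on chromosomes absent from the pericentromere table are called euchromatic
#' with a warning.
#'
#' @param sites Data frame with `chromosome` and `left`.
#' @param pericentromeres Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. a bundle's `pericentromeres` or
#'   [read_pericentromeres()] output.
#' @return Character vector, `"euchromatic"` or `"pericentromeric"`.
#' @export
chromatin_context <- function(sites, pericentromeres) {
  n <- nrow(sites)
  res <- rep("euchromatic", n)
  if (n == 0L || is.null(pericentromeres) || nrow(pericentromeres) == 0L) {
    return(res)
  }
  missing_chr <- setdiff(unique(sites$chromosome),
                         unique(pericentromeres$chrom))
  if (length(missing_chr)) {
    ts_warn(sprintf(
      "chromosome(s) %s absent from the pericentromere track; sites there called euchromatic",
      paste(missing_chr, collapse = ", ")),
      "missing_pericentromere_chrom")
  }
  ok <- !is.na(sites$left)
  if (!any(ok)) return(res)
  pts <- GenomicRanges::GRanges(sites$chromosome[ok],
                                IRanges::IRanges(sites$left[ok], width = 1L))
  peri <- GenomicRanges::GRanges(
    pericentromeres$chrom,
    IRanges::IRanges(pericentromeres$start, pericentromeres$end))
  hit <- suppressWarnings(GenomicRanges::countOverlaps(pts, peri)) > 0
  res[which(ok)[hit]] <- "pericentromeric"
  res
}

#' Read a pericentromere BED track
#'
#' @param path BED file (0-based half-open); returned 1-based inclusive.
#' @return Data frame with `chrom`, `start`, `end`.
#' @export
read_pericentromeres <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Summarise a classified cohort
#'
#' @param annotations Output of [classify_sites()].
#' @return An object of class `cohort_summary`: per-category counts and
#'   percentages (1 decimal), per-chromosome counts, the genic percentage
#'   (exon + intron) and, when present, the euchromatic percentage.
#' @export
cohort_summary <- function(annotations) {
  cats <- c("exon", "intron", "upstream", "downstream", "intergenic")
  n <- nrow(annotations)
  counts <- setNames(vapply(cats, function(k) {
    sum(annotations$category == k, na.rm = TRUE)
  }, numeric(1)), cats)
  pct <- if (n > 0) round(100 * counts / n, 1) else counts * 0
  by_chrom <- if (n > 0) table(annotations$chromosome) else table(character(0))
  euch_pct <- if ("chromatin" %in% names(annotations) && n > 0) {
    round(100 * sum(annotations$chromatin == "euchromatic", na.rm = TRUE) / n, 1)
  } else NA_real_
  structure(
    list(n = n, counts = counts, percentages = pct,
         genic_percentage = if (n > 0) round(100 * (counts[["exon"]] + counts[["intron"]]) / n, 1) else 0,
         by_chromosome = by_chrom,
         euchromatic_percentage = euch_pct),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d site(s)\n", x$n))
  for (k in names(x$counts)) {
    cat(sprintf("  %-11s %4d  (%.1f%%)\n", k, x$counts[[k]], x$percentages[[k]]))
  }
  cat(sprintf("  genic %.1f%%", x$genic_percentage))
  if (!is.na(x$euchromatic_percentage)) {
    cat(sprintf(", euchromatic %.1f%%", x$euchromatic_percentage))
  }
  cat("\n")
  invisible(x)
}
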