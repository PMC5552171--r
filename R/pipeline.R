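## Commented provenance header written at the top of every tabular output.
ts_header <- function(config_hash, seed) {
  c(sprintf("# transposcan %s",
            as.character(utils::packageVersion("transposcan"))),
    sprintf("# seed=%s config=%s", seed, config_hash))
}

write_tsv <- function(df, path, config_hash = "none", seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ts_header(config_hash, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an insertion-site table
#'
#' @param path TSV with columns `mutant_id`, `chromosome`, `left` (and
#'   optionally more); commented `#` headers are skipped.
#' @return Data frame with a `mapping_status` column (defaulting to
#'   `"unique"` when absent).
#' @export
read_insertion_sites <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!"mapping_status" %in% names(df)) df$mapping_status <- "unique"
  df
}

#' Assemble and validate a pipeline configuration
#'
#' Two modes are supported. Synthetic mode (default) generates the genome
#' with `genome_spec` and simulates, displays, maps and classifies a mutant
#' cohort end to end. File mode is selected by supplying `reference`,
#' `annotation` and `sites` paths (plus optionally `pericentromeres`): the
#' same partition, classification and statistics stages then run unmodified
#' on the externally supplied data.
#'
#' @param out_dir Output directory for all stage outputs and the manifest.
#' @param genome_spec A [synthetic_genome_spec()] (synthetic mode).
#' @param element An [element_spec()].
#' @param reference,annotation,pericentromeres,sites Paths to a reference
#'   FASTA (or chromosome-length TSV), GFF3 annotation, pericentromere BED
#'   and insertion-site TSV (file mode). All supplied paths must exist.
#' @param n_mutants Cohort size (synthetic mode).
#' @param n_unrecoverable Number of mutants implanted with a fractured
#'   element end, making their junction unrecoverable by the display.
#' @param insertion_model [uniform_model()] or [hotspot_model()].
#' @param enzymes Restriction-enzyme panel for the display.
#' @param adaptor_length,size_range,min_element_evidence,length_tolerance
#'   Display parameters (see [predict_display_products()],
#'   [compare_band_sets()], [extract_and_validate_flank()]).
#' @param k,max_mismatches Mapper parameters (see [build_index()],
#'   [map_flank()]).
#' @param classifier_window Upstream/downstream window, bp.
#' @param hotspot_window,hotspot_min_count Hotspot sweep parameters.
#' @param count_mode Partition counting mode (see [genome_partition()]).
#' @param seed Integer seed driving all stochastic stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            genome_spec = synthetic_genome_spec(),
                            element = element_spec(),
                            reference = NULL, annotation = NULL,
                            pericentromeres = NULL, sites = NULL,
                            n_mutants = 124L, n_unrecoverable = 0L,
                            insertion_model = uniform_model(),
                            enzymes = restriction_enzymes(),
                            adaptor_length = 25L,
                            size_range = c(100L, 6000L),
                            min_element_evidence = 100L,
                            length_tolerance = 0,
                            k = 21L, max_mismatches = 0L,
                            classifier_window = 2000L,
                            hotspot_window = 1e6, hotspot_min_count = 3L,
                            count_mode = "per_gene",
                            seed = 1L) {
  file_mode <- !is.null(reference) || !is.null(annotation) || !is.null(sites)
  if (file_mode) {
    needed <- c(reference = reference, annotation = annotation, sites = sites)
    if (any(vapply(list(reference, annotation, sites), is.null, logical(1)))) {
      ts_stop("file mode needs reference, annotation and sites paths",
              "config_error")
    }
    paths <- c(needed, pericentromeres = pericentromeres)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      ts_stop(paste("missing input file(s):",
                    paste(missing, collapse = ", ")),
              "config_error")
    }
  }
  if (n_unrecoverable > n_mutants) {
    ts_stop("n_unrecoverable cannot exceed n_mutants", "config_error")
  }
  structure(
    list(out_dir = out_dir, genome_spec = genome_spec, element = element,
         reference = reference, annotation = annotation,
         pericentromeres = pericentromeres, sites = sites,
         file_mode = file_mode,
         n_mutants = as.integer(n_mutants),
         n_unrecoverable = as.integer(n_unrecoverable),
         insertion_model = insertion_model, enzymes = enzymes,
         adaptor_length = adaptor_length, size_range = size_range,
         min_element_evidence = min_element_evidence,
         length_tolerance = length_tolerance,
         k = as.integer(k), max_mismatches = as.integer(max_mismatches),
         classifier_window = classifier_window,
         hotspot_window = hotspot_window,
         hotspot_min_count = hotspot_min_count,
         count_mode = count_mode,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("pipeline_stage_error", "transposcan_error")))
  })
}

## Synthetic cohort: implant, display, band-compare, validate, map.
run_synthetic_cohort <- function(config, bundle) {
  truth <- simulate_insertions(bundle, config$n_mutants,
                               model = config$insertion_model,
                               seed = config$seed)
  ## insertions inside a planted residual copy cannot be implanted; redraw
  ## deterministically until clear of them
  redraw_seed <- config$seed
  repeat {
    rc <- bundle$residual_copies
    bad <- rep(FALSE, nrow(truth))
    if (nrow(rc)) {
      for (i in seq_len(nrow(rc))) {
        bad <- bad | (truth$chromosome == rc$chrom[i] &
                        truth$left >= rc$start[i] & truth$left < rc$end[i])
      }
    }
    if (!any(bad)) break
    redraw_seed <- redraw_seed + 1000L
    repl <- simulate_insertions(bundle, sum(bad),
                                model = config$insertion_model,
                                seed = redraw_seed)
    truth$chromosome[bad] <- repl$chromosome
    truth$left[bad] <- repl$left
    truth$orientation[bad] <- repl$orientation
  }
  fractured <- with_seed(config$seed + 7L, {
    sort(sample(seq_len(config$n_mutants), config$n_unrecoverable))
  })
  truth$fractured <- seq_len(config$n_mutants) %in% fractured

  element <- bundle$element
  fracture_bp <- element$primer_sites$R1$dist + 50L
  bands <- vector("list", config$n_mutants)
  for (i in seq_len(config$n_mutants)) {
    mut <- implant_element(bundle, truth[i, ],
                           fracture = if (truth$fractured[i]) fracture_bp else 0L)
    bands[[i]] <- predict_display_products(
      mut, element = element, enzymes = config$enzymes,
      adaptor_length = config$adaptor_length,
      size_range = config$size_range,
      sample_id = truth$mutant_id[i])
  }
  bands <- do.call(rbind, bands)
  bands <- compare_band_sets(bands, length_tolerance = config$length_tolerance)

  index <- build_index(bundle, k = config$k)
  rc <- bundle$residual_copies
  tsd <- element$tsd_length
  near_residual <- function(chrom, left) {
    if (nrow(rc) == 0L || is.na(left)) return(FALSE)
    any(rc$chrom == chrom &
          (abs(left - rc$end) <= tsd | abs(left - (rc$start - 1)) <= tsd))
  }

  sites <- vector("list", config$n_mutants)
  flank_fa <- character(0)
  for (i in seq_len(config$n_mutants)) {
    mid <- truth$mutant_id[i]
    cand <- bands[bands$sample_id == mid & bands$unique, , drop = FALSE]
    mapped <- list()
    for (j in seq_len(nrow(cand))) {
      flank <- tryCatch(
        extract_and_validate_flank(cand[j, ], element,
                                   min_element_evidence = config$min_element_evidence),
        transposcan_error = function(e) NULL)
      if (is.null(flank) || nchar(flank) < config$k) next
      m <- map_flank(flank, index, junction_end = "5p",
                     max_mismatches = config$max_mismatches, mutant_id = mid)
      if (m$mapping_status == "unique" &&
          near_residual(m$chromosome, m$left)) next  # residual-derived band
      m$flank_length <- nchar(flank)
      m$enzyme <- cand$enzyme[j]
      mapped[[length(mapped) + 1L]] <- m
      flank_fa <- c(flank_fa,
                    sprintf(">%s %s %dbp", mid, cand$enzyme[j], nchar(flank)),
                    as.character(flank))
    }
    if (!length(mapped)) {
      sites[[i]] <- data.frame(
        mutant_id = mid, chromosome = NA_character_, left = NA_real_,
        right = NA_real_, strand = NA_character_,
        mapping_status = "unmapped", mismatches = NA_integer_,
        flank_length = NA_integer_, enzyme = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    md <- do.call(rbind, mapped)
    uq <- md[md$mapping_status == "unique", , drop = FALSE]
    if (nrow(uq)) {
      ## one junction per mutant: the coordinate supported by most enzymes,
      ## ties to the longest flank
      key <- paste(uq$chromosome, uq$left)
      support <- table(key)
      uq$support <- as.integer(support[key])
      uq <- uq[order(-uq$support, -uq$flank_length), , drop = FALSE]
      sites[[i]] <- uq[1L, setdiff(names(uq), "support"), drop = FALSE]
    } else {
      sites[[i]] <- md[1L, , drop = FALSE]
    }
  }
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL
  list(truth = truth, bands = bands, sites = sites, flank_fa = flank_fa)
}

#' Run the full insertion-analysis pipeline
#'
#' Executes the configured stages in order — genome (generate or load),
#' partition, simulate/display/map (synthetic mode), classify, statistics —
#' writes every stage output plus a JSON manifest to `out_dir`, and returns
#' the manifest. Identical configuration and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list, invisibly classed `pipeline_manifest`)
#'   with per-stage record counts, the statistics, and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_json <- config[c("file_mode", "n_mutants", "n_unrecoverable",
                       "adaptor_length", "size_range", "min_element_evidence",
                       "length_tolerance", "k", "max_mismatches",
                       "classifier_window", "hotspot_window",
                       "hotspot_min_count", "count_mode", "seed")]
  cfg_json$genome_spec <- unclass(config$genome_spec)
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA)
  config_hash <- unname(tools::md5sum(cfg_path))
  seed <- config$seed
  paths <- list(config = cfg_path)

  ## ---- genome ------------------------------------------------------------
  if (config$file_mode) {
    genes <- run_stage("annotation", read_gene_models(config$annotation))
    chrom_lengths <- run_stage("reference",
                               read_chromosome_lengths(config$reference))
    peri <- if (!is.null(config$pericentromeres)) {
      run_stage("pericentromeres", read_pericentromeres(config$pericentromeres))
    } else NULL
    bundle <- NULL
  } else {
    bundle <- run_stage("genome",
                        generate_genome(config$genome_spec, config$element))
    paths <- c(paths, run_stage("genome_io",
                                write_genome_bundle(bundle, config$out_dir)))
    genes <- bundle$genes
    chrom_lengths <- chromosome_lengths(bundle)
    peri <- bundle$pericentromeres
  }

  ## ---- partition ---------------------------------------------------------
  totals <- run_stage("partition",
                      genome_partition(genes, chrom_lengths,
                                       count_mode = config$count_mode))
  paths$partition <- file.path(config$out_dir, "partition_totals.json")
  write_partition_totals(totals, paths$partition,
                         file.path(config$out_dir, "gene_partitions.tsv"))

  ## ---- cohort ------------------------------------------------------------
  if (config$file_mode) {
    sites <- run_stage("sites", read_insertion_sites(config$sites))
    truth <- NULL
    bands <- NULL
  } else {
    cohort <- run_stage("display_map", run_synthetic_cohort(config, bundle))
    truth <- cohort$truth
    bands <- cohort$bands
    sites <- cohort$sites
    paths$truth <- file.path(config$out_dir, "truth_insertions.tsv")
    write_tsv(truth, paths$truth, config_hash, seed)
    paths$bands <- file.path(config$out_dir, "band_report.tsv")
    write_tsv(bands[, setdiff(names(bands), c("flank_seq", "product_seq"))],
              paths$bands, config_hash, seed)
    paths$flanks <- file.path(config$out_dir, "validated_flanks.fa")
    writeLines(cohort$flank_fa, paths$flanks)
  }
  report <- summarize_mapping(sites)

  ## ---- classification ----------------------------------------------------
  ann <- run_stage("classify",
                   classify_sites(report$sites, genes,
                                  window = config$classifier_window,
                                  pericentromeres = peri))
  paths$sites <- file.path(config$out_dir, "insertion_sites.tsv")
  write_tsv(sites, paths$sites, config_hash, seed)
  paths$annotations <- file.path(config$out_dir, "insertion_annotations.tsv")
  write_tsv(ann, paths$annotations, config_hash, seed)
  paths$browser_gff3 <- file.path(config$out_dir, "insertions.gff3")
  paths$browser_bed <- file.path(config$out_dir, "insertions.bed")
  export_browser_tracks(ann, paths$browser_gff3, paths$browser_bed)

  ## ---- statistics --------------------------------------------------------
  summ <- cohort_summary(ann)
  stats <- run_stage("stats", {
    if (summ$n > 0) {
      obs_pct <- c(summ$percentages[["exon"]], summ$percentages[["intron"]])
      exp_pct <- c(100 * totals$exon_fraction, 100 * totals$intron_fraction)
      paper <- if (all(exp_pct > 0)) chisq_paper(obs_pct, exp_pct) else NULL
      counts <- chisq_counts(
        c(summ$counts[["exon"]], summ$counts[["intron"]],
          summ$n - summ$counts[["exon"]] - summ$counts[["intron"]]),
        summ$n,
        c(totals$exon_fraction, totals$intron_fraction,
          1 - totals$genic_fraction))
      list(paper_faithful = paper, count_based = counts)
    } else list(paper_faithful = NULL, count_based = NULL)
  })
  hotspots <- detect_hotspots(ann, window = config$hotspot_window,
                              min_count = config$hotspot_min_count)
  paths$hotspots <- file.path(config$out_dir, "hotspots.tsv")
  write_tsv(hotspots, paths$hotspots, config_hash, seed)
  euch <- euchromatic_fraction(ann)

  stats_out <- list(
    cohort = list(n = summ$n, counts = as.list(summ$counts),
                  percentages = as.list(summ$percentages),
                  genic_percentage = summ$genic_percentage,
                  euchromatic_percentage = euch),
    expected = list(exon_fraction = totals$exon_fraction,
                    intron_fraction = totals$intron_fraction,
                    genic_fraction = totals$genic_fraction),
    chisq = lapply(stats, function(x) if (is.null(x)) NULL else
      x[c("mode", "statistic", "df", "p_value")]),
    hotspots = hotspots)
  paths$stats <- file.path(config$out_dir, "stats.json")
  jsonlite::write_json(stats_out, paths$stats, auto_unbox = TRUE, digits = NA,
                       null = "null")

  ## ---- truth accounting (synthetic mode) ---------------------------------
  truth_recovered <- NA_integer_
  if (!config$file_mode && report$unique > 0) {
    tsd <- config$element$tsd_length
    terminus <- config$element$primer_terminus
    tt <- truth[match(report$sites$mutant_id, truth$mutant_id), ]
    flank_right <- (tt$orientation == "+") == (terminus == "3p")
    expected_left <- tt$left + ifelse(flank_right, 0, tsd)
    truth_recovered <- sum(report$sites$chromosome == tt$chromosome &
                             report$sites$left == expected_left)
  }

  manifest <- structure(list(
    version = as.character(utils::packageVersion("transposcan")),
    seed = seed,
    config_hash = config_hash,
    mode = if (config$file_mode) "file" else "synthetic",
    counts = list(
      genes = length(genes),
      mutants = nrow(sites),
      bands = if (is.null(bands)) NA_integer_ else nrow(bands),
      unique_bands = if (is.null(bands)) NA_integer_ else sum(bands$unique),
      mapped_unique = report$unique,
      mapped_multi = report$multi,
      unmapped = report$unmapped,
      classified = nrow(ann),
      hotspot_regions = nrow(hotspots),
      truth_recovered = truth_recovered),
    partition = list(exon_fraction = totals$exon_fraction,
                     intron_fraction = totals$intron_fraction,
                     genic_fraction = totals$genic_fraction),
    stats = stats_out[c("cohort", "chisq")],
    paths = paths),
    class = "pipeline_manifest")
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "paths")],
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(manifest)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> transposcan %s, %s mode, seed %d\n",
              x$version, x$mode, x$seed))
  cat(sprintf("  mutants %s | mapped %s unique / %s multi / %s unmapped | classified %s\n",
              x$counts$mutants, x$counts$mapped_unique, x$counts$mapped_multi,
              x$counts$unmapped, x$counts$classified))
  invisible(x)
}

#' Export classified insertions as genome-browser tracks
#'
#' Writes one feature per mutant: a GFF3 record spanning the adjacent
#' coordinate pair (`left`, `left + 1`) with the mutant label as `ID` and the
#' category and gene in the attributes, plus a BED mirror covering the
#' single base `left` (0-based half-open `[left - 1, left)`).
#'
#' @param annotations Output of [classify_sites()].
#' @param gff3_path,bed_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
export_browser_tracks <- function(annotations, gff3_path, bed_path) {
  ann <- annotations[!is.na(annotations$left), , drop = FALSE]
  if (nrow(ann) == 0L) {
    writeLines("##gff-version 3", gff3_path)
    writeLines(character(0), bed_path)
    return(invisible(list(gff3 = gff3_path, bed = bed_path)))
  }
  gr <- GenomicRanges::GRanges(
    ann$chromosome, IRanges::IRanges(ann$left, ann$left + 1))
  S4Vectors::mcols(gr)$type <- "transposable_element_insertion_site"
  S4Vectors::mcols(gr)$ID <- ann$mutant_id
  S4Vectors::mcols(gr)$category <- ann$category
  S4Vectors::mcols(gr)$gene_id <- ifelse(is.na(ann$gene_id), "NA", ann$gene_id)
  rtracklayer::export(gr, gff3_path, format = "gff3")
  bed <- GenomicRanges::GRanges(
    ann$chromosome, IRanges::IRanges(ann$left, width = 1L))
  S4Vectors::mcols(bed)$name <- ann$mutant_id
  rtracklayer::export(bed, bed_path, format = "bed")
  invisible(list(gff3 = gff3_path, bed = bed_path))
}
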