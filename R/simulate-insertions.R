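#' Insertion-site sampling models
#'
#' `uniform_model()` draws each insertion uniformly over the summed
#' chromosome lengths (the randomness null). `hotspot_model()` draws with
#' probability `weight` from the union of the supplied hotspot intervals and
#' uniformly otherwise, emulating region-preferential transposition.
#'
#' @param weight Probability of drawing from a hotspot interval.
#' @param intervals Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive) hotspot intervals.
#' @return A model descriptor for [simulate_insertions()].
#' @export
uniform_model <- function() {
  structure(list(type = "uniform"), class = "insertion_model")
}

#' @rdname uniform_model
#' @export
hotspot_model <- function(weight, intervals) {
  if (weight < 0 || weight > 1) {
    ts_stop("hotspot weight must lie in [0, 1]", "invalid_argument")
  }
  structure(list(type = "hotspot", weight = weight, intervals = intervals),
            class = "insertion_model")
}

#' Simulate a cohort of single-insertion mutants
#'
#' Each simulated mutant carries exactly one new element insertion, stored as
#' the 1-based coordinate `left` of the reference base immediately before the
#' insertion point (the element sits between `left` and `left + 1`).
#'
#' @param bundle A `genome_bundle`.
#' @param n Number of mutants (>= 0).
#' @param model [uniform_model()] (default) or [hotspot_model()].
#' @param seed Integer seed; draws are reproducible.
#' @param id_prefix Prefix for mutant identifiers.
#' @return Data frame with `mutant_id`, `chromosome`, `left`, `orientation`.
#' @export
simulate_insertions <- function(bundle, n, model = uniform_model(),
                                seed = 1L, id_prefix = "T9") {
  if (n < 0) ts_stop("n must be >= 0", "invalid_argument")
  lens <- chromosome_lengths(bundle)
  empty <- data.frame(mutant_id = character(0), chromosome = character(0),
                      left = numeric(0), orientation = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  if (model$type == "hotspot") {
    iv <- model$intervals
    if (any(!iv$chrom %in% names(lens)) ||
        any(iv$start < 1 | iv$end > lens[iv$chrom])) {
      ts_stop("hotspot intervals must lie within genome bounds",
              "invalid_argument")
    }
  }
  with_seed(seed, {
    chrom <- character(n)
    left <- numeric(n)
    draw_uniform <- function(k) {
      ci <- sample(seq_along(lens), k, replace = TRUE, prob = lens)
      list(chrom = names(lens)[ci],
           left = 1 + floor(runif(k) * (lens[ci] - 1)))
    }
    if (model$type == "uniform") {
      d <- draw_uniform(n)
      chrom <- d$chrom
      left <- d$left
    } else {
      in_hot <- runif(n) < model$weight
      if (any(!in_hot)) {
        d <- draw_uniform(sum(!in_hot))
        chrom[!in_hot] <- d$chrom
        left[!in_hot] <- d$left
      }
      if (any(in_hot)) {
        iv <- model$intervals
        w <- iv$end - iv$start + 1
        ii <- sample(seq_len(nrow(iv)), sum(in_hot), replace = TRUE, prob = w)
        chrom[in_hot] <- iv$chrom[ii]
        left[in_hot] <- iv$start[ii] +
          floor(runif(sum(in_hot)) * pmin(w[ii], lens[iv$chrom[ii]] - iv$start[ii]))
      }
    }
    data.frame(
      mutant_id = sprintf("%s%04d", id_prefix, seq_len(n)),
      chromosome = unname(chrom),
      left = unname(left),
      orientation = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Implant the element into the reference to build a mutant genome
#'
#' Inserts the element between reference bases `left` and `left + 1`,
#' duplicating the `tsd_length` target-site bases on both sides of the
#' element (total mutant length = reference + element + duplication). The
#' planted residual copies are present identically in every mutant.
#'
#' @param bundle A `genome_bundle`.
#' @param insertion One row of a [simulate_insertions()] table (or a list
#'   with `mutant_id`, `chromosome`, `left`, `orientation`).
#' @param element An [element_spec()], or a plain nucleotide string (no
#'   primer geometry; useful for toy constructions). Defaults to the
#'   bundle's element.
#' @param tsd_length Target-site duplication length; defaults to the element
#'   spec's value (0 for a plain string element).
#' @param fracture Number of bases to delete from the element's
#'   primer-bearing terminus before implanting, emulating elements fractured
#'   during transposition; a fracture past the primer sites makes the
#'   junction unrecoverable by the display.
#' @return An object of class `mutant_genome`: the full mutant `sequences`
#'   (`DNAStringSet`), the element-copy registry `copies` in mutant
#'   coordinates, and bookkeeping fields.
#' @export
implant_element <- function(bundle, insertion, element = bundle$element,
                            tsd_length = NULL, fracture = 0L) {
  chrom <- as.character(insertion$chromosome)
  left <- as.numeric(insertion$left)
  orient <- as.character(insertion$orientation %||% "+")
  lens <- chromosome_lengths(bundle)
  if (!chrom %in% names(lens)) {
    ts_stop(sprintf("unknown chromosome '%s'", chrom), "invalid_argument")
  }
  L <- lens[[chrom]]
  if (left < 1 || left >= L) {
    ts_stop("insertion coordinate out of bounds (need 1 <= left < length)",
            "invalid_argument")
  }
  rc <- bundle$residual_copies
  if (nrow(rc)) {
    hit <- rc$chrom == chrom & left >= rc$start & left < rc$end
    if (any(hit)) {
      ts_stop(sprintf("insertion at %s:%s lies inside a residual element copy",
                      chrom, format(left, big.mark = ",")),
              "residual_overlap")
    }
  }
  if (is.character(element)) {
    el_seq <- toupper(element)
    d <- as.integer(tsd_length %||% 0L)
    terminus <- "3p"
  } else {
    el_seq <- element$sequence
    d <- as.integer(tsd_length %||% element$tsd_length)
    terminus <- element$primer_terminus
  }
  fracture <- as.integer(fracture)
  if (fracture > 0L) {
    keep <- nchar(el_seq) - fracture
    if (keep < 0L) keep <- 0L
    el_seq <- if (terminus == "3p") substr(el_seq, 1L, keep) else
      substr(el_seq, fracture + 1L, nchar(el_seq))
  }
  el_oriented <- if (orient == "-" && nchar(el_seq) > 0) revcomp(el_seq) else el_seq
  d_eff <- min(d, L - left)
  ref <- bundle$sequences[[chrom]]
  parts <- list(Biostrings::subseq(ref, 1L, left + d_eff))
  if (nchar(el_oriented) > 0) {
    parts[[2L]] <- Biostrings::DNAString(el_oriented)
  }
  parts[[length(parts) + 1L]] <- Biostrings::subseq(ref, left + 1L, L)
  mutant_chrom <- do.call(Biostrings::xscat, parts)

  sequences <- bundle$sequences
  sequences[[chrom]] <- mutant_chrom
  shift <- nchar(el_oriented) + d_eff
  el_len <- nchar(el_oriented)

  copies <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), orientation = character(0),
                       source = character(0), trunc_len = integer(0),
                       fractured = logical(0), junction_ref = numeric(0))
  if (el_len > 0) {
    copies <- rbind(copies, data.frame(
      chrom = chrom, start = left + d_eff + 1,
      end = left + d_eff + el_len, orientation = orient,
      source = "new", trunc_len = el_len,
      fractured = fracture > 0L, junction_ref = left))
  }
  if (nrow(rc)) {
    rs <- rc$start + ifelse(rc$chrom == chrom & rc$start > left, shift, 0)
    copies <- rbind(copies, data.frame(
      chrom = rc$chrom, start = rs, end = rs + rc$length - 1,
      orientation = rc$orientation, source = "residual",
      trunc_len = rc$length, fractured = FALSE, junction_ref = NA))
  }
  structure(
    list(mutant_id = as.character(insertion$mutant_id %||% NA),
         sequences = sequences,
         copies = copies,
         element = if (is.character(element)) NULL else element,
         tsd = d_eff,
         insertion = as.list(insertion)),
    class = "mutant_genome")
}

#' @export
print.mutant_genome <- function(x, ...) {
  cat(sprintf("<mutant_genome> %s: insertion at %s:%s (%s), %d element cop%s tracked\n",
              x$mutant_id, x$insertion$chromosome,
              format(x$insertion$left, big.mark = ","),
              x$insertion$orientation %||% "+",
              nrow(x$copies), if (nrow(x$copies) == 1) "y" else "ies"))
  invisible(x)
}
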