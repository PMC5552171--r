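#' Percentage-scale chi-squared comparison of exon/intron insertion rates
#'
#' Reproduction-oriented form of the randomness check: the statistic is
#' computed directly on the observed and expected percentages of the two
#' insertion classes, `sum((obs - exp)^2 / exp)` over {exon, intron}, with 1
#' degree of freedom and an upper-tail p-value. With observed (16.2, 9.5)
#' against expected (11.6, 10.5) this gives 1.92. Note this form is
#' scale-dependent (percentages, not counts) and is provided for
#' reproduction; [chisq_counts()] is the statistically standard companion.
#'
#' @param observed_pct Numeric length-2 vector: observed (exon, intron)
#'   percentages.
#' @param expected_pct Numeric length-2 vector: expected (exon, intron)
#'   percentages; must be positive.
#' @return An object of class `chisq_result`.
#' @examples
#' chisq_paper(c(16.2, 9.5), c(11.6, 10.5))
#' @export
chisq_paper <- function(observed_pct, expected_pct) {
  if (length(observed_pct) != 2L || length(expected_pct) != 2L) {
    ts_stop("observed and expected must each have two classes (exon, intron)",
            "invalid_argument")
  }
  if (any(observed_pct < 0)) {
    ts_stop("observed percentages must be >= 0", "invalid_argument")
  }
  if (any(expected_pct <= 0)) {
    ts_stop("expected percentage of zero leaves the statistic undefined",
            "undefined_statistic")
  }
  stat <- sum((observed_pct - expected_pct)^2 / expected_pct)
  structure(
    list(mode = "paper_faithful",
         observed = setNames(observed_pct, c("exon", "intron")),
         expected = setNames(expected_pct, c("exon", "intron")),
         statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1L, lower.tail = FALSE)),
    class = "chisq_result")
}

#' Multinomial goodness-of-fit test of insertion counts
#'
#' Classic count-based chi-squared test of the observed (exon, intron, other)
#' insertion counts against the genomic expectation, with
#' `df = classes - 1`. Expected counts below 1 in any class trigger a
#' validity warning but the statistic is still computed.
#'
#' @param observed Integer vector of class counts (typically exon, intron,
#'   other), summing to `n`.
#' @param n Cohort size.
#' @param expected_fractions Expected class fractions summing to 1.
#' @return An object of class `chisq_result`.
#' @examples
#' chisq_counts(c(17, 10, 78), 105, c(0.116, 0.105, 0.779))
#' @export
chisq_counts <- function(observed, n = sum(observed), expected_fractions) {
  if (length(observed) != length(expected_fractions)) {
    ts_stop("observed and expected_fractions must have equal length",
            "invalid_argument")
  }
  if (abs(sum(observed) - n) > 1e-8) {
    ts_stop("observed counts must sum to n", "invalid_argument")
  }
  if (abs(sum(expected_fractions) - 1) > 1e-6) {
    ts_stop("expected fractions must sum to 1", "invalid_argument")
  }
  expected <- n * expected_fractions
  if (any(expected < 1)) {
    ts_warn("expected count below 1 in at least one class; test validity is doubtful",
            "low_expected_count")
  }
  ht <- suppressWarnings(chisq.test(observed, p = expected_fractions))
  nm <- if (length(observed) == 3L) c("exon", "intron", "other") else
    paste0("class", seq_along(observed))
  structure(
    list(mode = "count_based",
         observed = setNames(observed, nm),
         expected = setNames(expected, nm),
         statistic = unname(ht$statistic),
         df = as.integer(unname(ht$parameter)),
         p_value = unname(ht$p.value)),
    class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("<chisq_result> mode=%s  X^2 = %.4f, df = %d, p = %.4g\n",
              x$mode, x$statistic, x$df, x$p_value))
  cat("  observed:", paste(sprintf("%s=%g", names(x$observed), x$observed),
                           collapse = ", "), "\n")
  cat("  expected:", paste(sprintf("%s=%g", names(x$expected),
                                   round(x$expected, 3)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Detect insertion hotspot regions by a windowed sweep
#'
#' Per chromosome, finds maximal sets of at least `min_count` insertions
#' whose footprint (`max(left) - min(left) + 1`) does not exceed `window`
#' bp, via a two-pointer sweep; overlapping qualifying windows (sharing a
#' member site) are merged into one region reporting the tight span of its
#' member sites. The result equals exhaustive enumeration of all windows on
#' small inputs.
#'
#' @param sites Data frame with `chromosome`, `left` and optionally
#'   `mutant_id`.
#' @param window Maximum region footprint, bp (default 1 Mb).
#' @param min_count Minimum insertions per region (default 3).
#' @return Data frame with `chromosome`, `start`, `end` (1-based inclusive
#'   tight span), `insertion_count` and comma-separated `mutant_ids`.
#' @export
detect_hotspots <- function(sites, window = 1e6, min_count = 3L) {
  empty <- data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), insertion_count = integer(0),
                      mutant_ids = character(0), stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) return(empty)
  ids <- if ("mutant_id" %in% names(sites)) sites$mutant_id else
    as.character(seq_len(nrow(sites)))
  out <- list()
  for (ch in sort(unique(sites$chromosome))) {
    sel <- sites$chromosome == ch
    o <- order(sites$left[sel])
    pos <- sites$left[sel][o]
    id_c <- ids[sel][o]
    m <- length(pos)
    runs <- list()
    j <- 1L
    for (i in seq_len(m)) {
      if (j < i) j <- i
      while (j < m && pos[j + 1L] - pos[i] + 1 <= window) j <- j + 1L
      if (j - i + 1L >= min_count) runs[[length(runs) + 1L]] <- c(i, j)
    }
    if (!length(runs)) next
    ## merge runs sharing members
    merged <- list(runs[[1L]])
    for (r in runs[-1L]) {
      last <- merged[[length(merged)]]
      if (r[1L] <= last[2L]) {
        merged[[length(merged)]] <- c(last[1L], max(last[2L], r[2L]))
      } else {
        merged[[length(merged) + 1L]] <- r
      }
    }
    for (r in merged) {
      members <- r[1L]:r[2L]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch, start = pos[r[1L]], end = pos[r[2L]],
        insertion_count = length(members),
        mutant_ids = paste(id_c[members], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Euchromatic insertion fraction of a classified cohort
#'
#' @param annotations Classification table with a `chromatin` column.
#' @return Percentage of euchromatic insertions (1 decimal); `NA` for an
#'   empty cohort.
#' @export
euchromatic_fraction <- function(annotations) {
  if (nrow(annotations) == 0L) return(NA_real_)
  round(100 * mean(annotations$chromatin == "euchromatic", na.rm = TRUE), 1)
}
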