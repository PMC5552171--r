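#' Describe the transposable element assayed by the display
#'
#' An `element_spec` holds the element sequence together with the geometry the
#' in-silico display needs: terminal inverted repeats, the element terminus the
#' nested primers read out of, the primer annealing sites (as distances from
#' that terminus), and the length of the target-site duplication created on
#' insertion.
#'
#' By default a 20,548 bp CACTA-style element is generated deterministically:
#' the sequence starts with `CACTA`, ends with its reverse complement, and
#' carries short terminal inverted repeats. The nested display primers are
#' placed near the assayed terminus, with the nested primer (`R2`) closer to
#' the terminus than the outer primer (`R1`), as required for nested PCR.
#'
#' @param sequence Element nucleotide sequence. `NULL` (default) generates a
#'   deterministic CACTA-style sequence of `length` bp.
#' @param length Length of the generated default sequence, in bp.
#' @param tir_length Terminal inverted repeat length, in bp.
#' @param primer_terminus Which element terminus the display primers read
#'   through: `"3p"` (default) or `"5p"`. Residual, 5'-truncated copies retain
#'   a 3' terminus, so the default makes them visible as common bands.
#' @param primer_sites Named list of primer sites. Each entry is a list with
#'   `dist` (bp from the assayed terminus to the primer's terminus-distal end)
#'   and `len` (annealing length, bp). Must contain `R1` (outer) and `R2`
#'   (nested), with `R2$dist < R1$dist`.
#' @param tsd_length Target-site duplication length created on insertion, in
#'   bp (default 3; a CACTA-family convention, configurable).
#' @param seed Seed for the generated default sequence.
#'
#' @return An object of class `element_spec`.
#' @examples
#' el <- element_spec(length = 2000)
#' nchar(el$sequence)
#' @export
element_spec <- function(sequence = NULL,
                         length = 20548L,
                         tir_length = 13L,
                         primer_terminus = c("3p", "5p"),
                         primer_sites = list(
                           R1 = list(dist = 250L, len = 24L),
                           R2 = list(dist = 150L, len = 24L)
                         ),
                         tsd_length = 3L,
                         seed = 101L) {
  primer_terminus <- match.arg(primer_terminus)
  if (is.null(sequence)) {
    if (length < 2L * tir_length + 10L) {
      ts_stop("element length too short for the requested terminal repeats",
              "invalid_element")
    }
    sequence <- with_seed(seed, {
      core <- random_dna(length - 10L, gc_content = 0.4)
      head5 <- paste0("CACTA", substr(core, 1, tir_length - 5L))
      paste0(head5,
             substr(core, tir_length - 4L, nchar(core)),
             revcomp(head5))
    })
    sequence <- substr(sequence, 1, length)
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n > 0 && grepl("[^ACGTN]", sequence)) {
    ts_stop("element sequence must be over {A,C,G,T,N}", "invalid_element")
  }
  if (!all(c("R1", "R2") %in% names(primer_sites))) {
    ts_stop("primer_sites must define R1 (outer) and R2 (nested)",
            "invalid_element")
  }
  for (nm in names(primer_sites)) {
    ps <- primer_sites[[nm]]
    if (ps$dist > n) {
      ts_stop(sprintf("primer site %s does not lie within the element", nm),
              "invalid_element")
    }
    if (ps$len > ps$dist) {
      ts_stop(sprintf("primer site %s extends past the element terminus", nm),
              "invalid_element")
    }
  }
  if (primer_sites$R2$dist >= primer_sites$R1$dist) {
    ts_stop("nested primer R2 must be closer to the element terminus than R1",
            "invalid_element")
  }
  if (tsd_length < 0) ts_stop("tsd_length must be >= 0", "invalid_element")
  structure(
    list(sequence = sequence,
         length = n,
         tir_length = as.integer(tir_length),
         primer_terminus = primer_terminus,
         primer_sites = primer_sites,
         tsd_length = as.integer(tsd_length)),
    class = "element_spec"
  )
}

#' @export
print.element_spec <- function(x, ...) {
  cat(sprintf("<element_spec> %d bp, primers at %s terminus (R1 %d bp, R2 %d bp), TSD %d bp\n",
              x$length, x$primer_terminus,
              x$primer_sites$R1$dist, x$primer_sites$R2$dist, x$tsd_length))
  invisible(x)
}

## Terminal sequence of the assayed end, reading outward so that position 1 is
## the base adjacent to the junction. Used for primer-presence checks and for
## validating element-end evidence in display products.
element_terminal_seq <- function(element, nbases) {
  nbases <- min(nbases, element$length)
  if (element$primer_terminus == "3p") {
    substr(element$sequence, element$length - nbases + 1L, element$length)
  } else {
    ## 5' terminus: read outward means reverse complement of the leading bases
    revcomp(substr(element$sequence, 1L, nbases))
  }
}

## The truncated residual-copy sequence of `len` bp retaining the assayed
## (primer-bearing) terminus; returned in element orientation.
element_residual_seq <- function(element, len) {
  len <- min(len, element$length)
  if (element$primer_terminus == "3p") {
    substr(element$sequence, element$length - len + 1L, element$length)
  } else {
    substr(element$sequence, 1L, len)
  }
}
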