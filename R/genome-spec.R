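#' Parameters of the synthetic genome generator
#'
#' Describes a multi-chromosome genome whose composition emulates a
#' gene-sparse plant genome: by default ~11.6% exon and ~10.5% intron content
#' with a single contiguous pericentromeric block covering 57% of each
#' chromosome, matching the composition used to build the random-insertion
#' expectation.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome, bp.
#' @param target_exon_fraction Genome-wide exon (5' UTR + CDS + 3' UTR)
#'   fraction to realise.
#' @param target_intron_fraction Genome-wide intron fraction to realise.
#' @param pericentromere_fraction Fraction of each chromosome covered by its
#'   central pericentromeric block.
#' @param mean_exons_per_gene Mean exon count per gene (Poisson-like).
#' @param multi_isoform_gene_fraction Fraction of genes given a second,
#'   shorter splice variant (exercises longest-variant selection).
#' @param gc_content GC content of the random background sequence.
#' @param n_residual_copies Number of truncated, immobile element copies
#'   planted in intergenic space (they produce the display's common bands).
#' @param residual_copy_length Length of each planted residual copy, bp.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   outputs.
#'
#' @return An object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_chromosomes = 4L,
                                  chromosome_length = 2e6,
                                  target_exon_fraction = 0.116,
                                  target_intron_fraction = 0.105,
                                  pericentromere_fraction = 0.57,
                                  mean_exons_per_gene = 6,
                                  multi_isoform_gene_fraction = 0.3,
                                  gc_content = 0.35,
                                  n_residual_copies = 2L,
                                  residual_copy_length = 1200L,
                                  seed = 42L) {
  fracs <- c(target_exon_fraction, target_intron_fraction,
             pericentromere_fraction, multi_isoform_gene_fraction, gc_content)
  if (any(fracs < 0 | fracs > 1)) {
    ts_stop("all proportions must lie in [0, 1]", "invalid_spec")
  }
  if (target_exon_fraction + target_intron_fraction >= 1) {
    ts_stop("exon + intron fractions must be < 1", "invalid_spec")
  }
  if (n_chromosomes < 1 || chromosome_length < 1 || mean_exons_per_gene < 1 ||
      n_residual_copies < 0 || residual_copy_length < 1) {
    ts_stop("lengths and counts must be positive", "invalid_spec")
  }
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         chromosome_length = as.numeric(chromosome_length),
         target_exon_fraction = target_exon_fraction,
         target_intron_fraction = target_intron_fraction,
         pericentromere_fraction = pericentromere_fraction,
         mean_exons_per_gene = mean_exons_per_gene,
         multi_isoform_gene_fraction = multi_isoform_gene_fraction,
         gc_content = gc_content,
         n_residual_copies = as.integer(n_residual_copies),
         residual_copy_length = as.integer(residual_copy_length),
         seed = as.integer(seed)),
    class = "synthetic_genome_spec"
  )
}

#' @export
print.synthetic_genome_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_genome_spec> %d chromosome(s) x %s bp\n",
    "  exon %.3f / intron %.3f targets, pericentromere %.2f, GC %.2f, seed %d\n"),
    x$n_chromosomes, format(x$chromosome_length, big.mark = ","),
    x$target_exon_fraction, x$target_intron_fraction,
    x$pericentromere_fraction, x$gc_content, x$seed))
  invisible(x)
}
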