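test_that("element_spec validates primer geometry", {
  el <- element_spec()
  expect_s3_class(el, "element_spec")
  expect_identical(nchar(el$sequence), el$length)
  expect_lt(el$primer_sites$R2$dist, el$primer_sites$R1$dist)
  expect_error(
    element_spec(primer_sites = list(R1 = list(dist = 100L, len = 24L),
                                     R2 = list(dist = 150L, len = 24L))),
    class = "transposcan_error")
  expect_error(
    element_spec(length = 100L,
                 primer_sites = list(R1 = list(dist = 120L, len = 24L),
                                     R2 = list(dist = 50L, len = 24L))),
    class = "transposcan_error")
})

test_that("generated genome hits partition targets and is deterministic", {
  spec <- synthetic_genome_spec()
  bundle <- generate_genome(spec, element_spec())
  totals <- genome_partition(bundle$genes, chromosome_lengths(bundle))
  expect_lt(abs(totals$exon_fraction - spec$target_exon_fraction), 0.01)
  expect_lt(abs(totals$intron_fraction - spec$target_intron_fraction), 0.01)
  expect_equal(sum(Biostrings::width(bundle$sequences)),
               spec$n_chromosomes * spec$chromosome_length)
  ## pericentromeres: one contiguous central block per chromosome
  expect_identical(nrow(bundle$pericentromeres), spec$n_chromosomes)
  expect_gte(nrow(bundle$residual_copies), 1L)

  ## determinism: same spec + seed twice => byte-identical FASTA and GFF3
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  write_genome_bundle(bundle, d1)
  write_genome_bundle(generate_genome(spec, element_spec()), d2)
  for (f in c("reference.fa", "annotation.gff3")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero-gene spec yields an empty annotation", {
  spec <- synthetic_genome_spec(n_chromosomes = 1L, chromosome_length = 1e5,
                                target_exon_fraction = 0,
                                target_intron_fraction = 0,
                                n_residual_copies = 0L)
  bundle <- generate_genome(spec, element_spec())
  expect_length(bundle$genes, 0)
  totals <- genome_partition(bundle$genes, chromosome_lengths(bundle))
  expect_identical(totals$exon_fraction, 0)
  expect_identical(totals$intron_fraction, 0)
})

test_that("infeasible spec raises an explicit error", {
  expect_error(
    generate_genome(synthetic_genome_spec(n_chromosomes = 1L,
                                          chromosome_length = 5e4,
                                          target_exon_fraction = 0.6,
                                          target_intron_fraction = 0.39),
                    element_spec()),
    class = "infeasible_spec")
})

test_that("simulate_insertions respects n, bounds and the hotspot model", {
  bundle <- generate_genome(small_spec(), element_spec())
  expect_identical(nrow(simulate_insertions(bundle, 0)), 0L)
  expect_error(simulate_insertions(bundle, -1), class = "transposcan_error")

  ins <- simulate_insertions(bundle, 500, seed = 3)
  lens <- chromosome_lengths(bundle)
  expect_true(all(ins$left >= 1 & ins$left < lens[ins$chromosome]))
  expect_identical(ins, simulate_insertions(bundle, 500, seed = 3))

  hs <- data.frame(chrom = "Chr01", start = 1e4, end = 2e4)
  hot <- simulate_insertions(bundle, 200, model = hotspot_model(1, hs),
                             seed = 4)
  expect_true(all(hot$chromosome == "Chr01" &
                    hot$left >= 1e4 & hot$left <= 2e4))
  expect_error(
    simulate_insertions(bundle, 10,
                        model = hotspot_model(1, data.frame(
                          chrom = "Chr01", start = 1, end = 9e9))),
    class = "transposcan_error")
})

test_that("implant_element splices by hand-checkable arithmetic", {
  b <- toy_bundle(c(Chr01 = "ACGTACGT"))
  ins <- list(mutant_id = "m1", chromosome = "Chr01", left = 4,
              orientation = "+")
  mut <- implant_element(b, ins, element = "TTTT", tsd_length = 0)
  expect_identical(as.character(mut$sequences[["Chr01"]]), "ACGTTTTTACGT")

  ## zero-length element, zero duplication: identity
  mut0 <- implant_element(b, ins, element = "", tsd_length = 0)
  expect_identical(as.character(mut0$sequences[["Chr01"]]), "ACGTACGT")

  ## length bookkeeping with a target-site duplication
  mut2 <- implant_element(b, ins, element = "TTTT", tsd_length = 3)
  expect_identical(nchar(as.character(mut2$sequences[["Chr01"]])),
                   8L + 4L + 3L)
  ## duplicated target bases ACG flank the element on both sides
  expect_identical(as.character(mut2$sequences[["Chr01"]]), "ACGTACGTTTTACGT")
})

test_that("implanting inside a residual copy is an explicit overlap error", {
  rc <- data.frame(chrom = "Chr01", start = 10, end = 20, length = 11L,
                   orientation = "+", stringsAsFactors = FALSE)
  b <- toy_bundle(c(Chr01 = safe_dna(100)), residual_copies = rc)
  expect_error(
    implant_element(b, list(mutant_id = "m1", chromosome = "Chr01",
                            left = 15, orientation = "+"),
                    element = "TTTT", tsd_length = 0),
    class = "residual_overlap")
  expect_error(
    implant_element(b, list(mutant_id = "m1", chromosome = "Chr01",
                            left = 200, orientation = "+"),
                    element = "TTTT", tsd_length = 0),
    class = "invalid_argument")
})
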