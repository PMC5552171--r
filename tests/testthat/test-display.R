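test_that("digest reproduces the manual DraI scan and conserves sequence", {
  dra <- restriction_enzyme("DraI", "TTTAAA", 3L)
  fr <- digest("AAATTTAAACCC", dra)
  expect_identical(fr$sequence, c("AAATTT", "AAACCC"))

  none <- digest("ACGTACGT", dra)
  expect_identical(none$sequence, "ACGTACGT")

  with_seed <- function(seed, code) { set.seed(seed); code }
  for (i in 1:25) {
    s <- with_seed(i, paste(sample(c("A", "C", "G", "T", "N"), 400,
                                   replace = TRUE,
                                   prob = c(.3, .2, .2, .28, .02)),
                            collapse = ""))
    fr <- digest(s, dra)
    expect_identical(paste(fr$sequence, collapse = ""), s)
    expect_equal(fr, oracle_digest(s, dra))
  }
})

test_that("overlapping recognition occurrences are all honored", {
  en <- restriction_enzyme("toy", "AAA", 1L)
  fr <- digest("CAAAAC", en)
  expect_equal(fr, oracle_digest("CAAAAC", en))
  expect_identical(fr$sequence, c("CA", "A", "AAC"))
})

test_that("the default enzyme panel matches the published assay", {
  panel <- restriction_enzymes()
  expect_setequal(vapply(panel, `[[`, character(1), "name"),
                  c("DraI", "EcoRV", "PvuII", "StuI"))
  recog <- vapply(panel, `[[`, character(1), "recognition")
  expect_setequal(recog, c("TTTAAA", "GATATC", "CAGCTG", "AGGCCT"))
  expect_true(all(vapply(panel, `[[`, integer(1), "cut_offset") == 3L))
  expect_error(restriction_enzyme("bad", "TTTAAA", 6L),
               class = "transposcan_error")
})

## Toy geometry from the worked example: R2 site 60 bp from the assayed
## terminus, flank-side cut 140 bp past the junction, 25 bp adaptor tail.
toy_display <- function() {
  el <- element_spec(sequence = random_safe_dna(500, seed = 77), length = 500L,
                     primer_sites = list(R1 = list(dist = 80L, len = 10L),
                                         R2 = list(dist = 60L, len = 10L)),
                     tsd_length = 0L)
  ref <- paste0(safe_dna(300), safe_dna(137), "TTTAAA",
                safe_dna(50), "GATATC", safe_dna(50))
  bundle <- toy_bundle(c(Chr01 = ref), element = el)
  list(bundle = bundle, el = el,
       ins = list(mutant_id = "m1", chromosome = "Chr01", left = 300,
                  orientation = "+"))
}

test_that("product length = R2 distance + flank + adaptor tail", {
  fx <- toy_display()
  mut <- implant_element(fx$bundle, fx$ins, element = fx$el)
  bands <- predict_display_products(mut, element = fx$el,
                                    enzymes = restriction_enzymes("DraI"),
                                    adaptor_length = 25L,
                                    sample_id = "m1")
  expect_identical(nrow(bands), 1L)
  expect_equal(bands$product_length, 60 + 140 + 25)
  expect_identical(bands$source, "new")
  expect_identical(nchar(bands$flank_seq), 140L)
})

test_that("junctions agree across enzymes while lengths differ", {
  fx <- toy_display()
  mut <- implant_element(fx$bundle, fx$ins, element = fx$el)
  bands <- predict_display_products(
    mut, element = fx$el,
    enzymes = restriction_enzymes(c("DraI", "EcoRV")),
    adaptor_length = 25L, sample_id = "m1")
  expect_identical(nrow(bands), 2L)
  expect_identical(length(unique(bands$junction)), 1L)
  expect_identical(length(unique(bands$product_length)), 2L)
})

test_that("a fractured primer-bearing end yields no band", {
  fx <- toy_display()
  mut <- implant_element(fx$bundle, fx$ins, element = fx$el, fracture = 100L)
  bands <- predict_display_products(mut, element = fx$el,
                                    enzymes = restriction_enzymes("DraI"),
                                    sample_id = "m1")
  expect_identical(nrow(bands), 0L)
})

test_that("band comparison separates common from unique bands", {
  mk <- function(sample, enzyme, len) {
    data.frame(sample_id = sample, enzyme = enzyme, product_length = len,
               stringsAsFactors = FALSE)
  }
  bands <- rbind(mk("s1", "DraI", 300), mk("s2", "DraI", 300),
                 mk("s1", "DraI", 410), mk("s2", "DraI", 525))
  flagged <- compare_band_sets(bands)
  expect_identical(flagged$unique, c(FALSE, FALSE, TRUE, TRUE))

  same <- rbind(mk("s1", "DraI", 300), mk("s2", "DraI", 300))
  expect_identical(sum(compare_band_sets(same)$unique), 0L)

  ## tolerance boundary: 300 vs 304 shared under tolerance 5
  tol <- rbind(mk("s1", "DraI", 300), mk("s2", "DraI", 304))
  expect_identical(sum(compare_band_sets(tol, length_tolerance = 5)$unique), 0L)
  expect_identical(sum(compare_band_sets(tol)$unique), 2L)

  expect_warning(one <- compare_band_sets(mk("s1", "DraI", 300)),
                 class = "single_sample_comparison")
  expect_true(all(one$unique))
})

test_that("flank validation enforces the >100 bp element-evidence rule", {
  el <- element_spec(sequence = safe_dna(500), length = 500L,
                     primer_sites = list(R1 = list(dist = 80L, len = 10L),
                                         R2 = list(dist = 60L, len = 10L)),
                     tsd_length = 0L)
  term150 <- substr(el$sequence, 351, 500)
  flank <- paste(rep("T", 200), collapse = "")
  band <- function(product, fl) {
    data.frame(sample_id = "s1", enzyme = "DraI", chrom = "Chr01",
               junction = 800, product_length = nchar(product),
               product_seq = product, flank_seq = fl,
               stringsAsFactors = FALSE)
  }
  good <- extract_and_validate_flank(band(paste0(term150, flank), flank), el)
  expect_identical(nchar(good), 200L)
  expect_identical(as.character(attr(good, "chrom")), "Chr01")

  ## only 80 bp of true element end next to the junction: rejected
  spoiled <- paste0(chartr("ACGT", "TGCA", substr(el$sequence, 351, 420)),
                    substr(el$sequence, 421, 500))
  expect_error(extract_and_validate_flank(band(paste0(spoiled, flank), flank), el),
               class = "insufficient_element_evidence")

  ## pure element product: distinct error
  expect_error(extract_and_validate_flank(band(term150, ""), el),
               class = "no_genomic_flank")
})

test_that("display round trip recovers the implanted junction", {
  bundle <- generate_genome(small_spec(), element_spec())
  ins <- simulate_insertions(bundle, 4, seed = 9)
  idx <- build_index(bundle)
  el <- bundle$element
  for (i in seq_len(nrow(ins))) {
    mut <- implant_element(bundle, ins[i, ])
    bands <- predict_display_products(mut, sample_id = ins$mutant_id[i])
    nb <- bands[bands$source == "new", , drop = FALSE]
    expect_gt(nrow(nb), 0L)
    fl <- extract_and_validate_flank(nb[1, ], el)
    m <- map_flank(fl, idx, mutant_id = ins$mutant_id[i])
    exp_left <- ins$left[i] +
      if (ins$orientation[i] == "-") el$tsd_length else 0
    expect_identical(m$mapping_status, "unique")
    expect_identical(m$chromosome, ins$chromosome[i])
    expect_equal(m$left, exp_left)
  }
})
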