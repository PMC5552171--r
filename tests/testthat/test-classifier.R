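## A two-gene toy annotation exercised throughout.
toy_genes <- function() {
  t1 <- transcript_model("g1.1", "g1", "Chr01", "+",
                         exons = rbind(c(101, 200), c(301, 400)),
                         cds = rbind(c(151, 200), c(301, 350)))
  t2 <- transcript_model("g2.1", "g2", "Chr01", "-",
                         exons = rbind(c(5000, 5199), c(5400, 5599)),
                         cds = rbind(c(5100, 5199), c(5400, 5499)))
  list(gene_model("g1", "Chr01", "+", list(t1)),
       gene_model("g2", "Chr01", "-", list(t2)))
}

site <- function(left, chrom = "Chr01", id = "m1") {
  data.frame(mutant_id = id, chromosome = chrom, left = left,
             mapping_status = "unique", stringsAsFactors = FALSE)
}

test_that("gene-body junctions get exon/intron with strand-aware ordinals", {
  genes <- toy_genes()
  a <- classify_site(site(250), genes)
  expect_identical(a$category, "intron")
  expect_identical(a$gene_id, "g1")
  expect_identical(a$ordinal, 1L)

  b <- classify_site(site(320), genes)
  expect_identical(b$category, "exon")
  expect_identical(b$ordinal, 2L)

  ## minus-strand gene: genomically last exon is the 1st from the 5' end
  c1 <- classify_site(site(5500), genes)
  expect_identical(c1$category, "exon")
  expect_identical(c1$gene_id, "g2")
  expect_identical(c1$ordinal, 1L)
  c2 <- classify_site(site(5100), genes)
  expect_identical(c2$ordinal, 2L)
})

test_that("exact feature boundaries go to the lower-coordinate feature", {
  genes <- toy_genes()
  ## base 200 is the last base of exon 1: junction 200/201 -> exon
  expect_identical(classify_site(site(200), genes)$category, "exon")
  ## base 300 is the last intron base: junction 300/301 -> intron
  expect_identical(classify_site(site(300), genes)$category, "intron")
  ## base 400 is the gene's last base; 401 is outside -> exon
  expect_identical(classify_site(site(400), genes)$category, "exon")
})

test_that("upstream/downstream distances follow the printed convention", {
  genes <- toy_genes()
  up <- classify_site(site(29), genes, window = 2000)
  expect_identical(up$category, "upstream")
  expect_equal(up$distance, 101 - 29)

  dn <- classify_site(site(640), genes, window = 2000)
  expect_identical(dn$category, "downstream")
  expect_equal(dn$distance, 640 - 400)

  ## minus-strand gene: upstream lies at higher coordinates
  upm <- classify_site(site(5799), genes, window = 2000)
  expect_identical(upm$category, "upstream")
  expect_identical(upm$gene_id, "g2")
  expect_equal(upm$distance, 5799 - 5599)
  dnm <- classify_site(site(4900), genes, window = 2000)
  expect_identical(dnm$category, "downstream")
  expect_equal(dnm$distance, 5000 - 4900)

  ## outside every window, and on a geneless chromosome: intergenic
  expect_identical(classify_site(site(2800), genes)$category, "intergenic")
  expect_identical(classify_site(site(50, chrom = "Chr09"), genes)$category,
                   "intergenic")
})

test_that("nearest gene wins window ties, then the smaller gene_id", {
  mk <- function(gid, s, e, strand) {
    gene_model(gid, "Chr01", strand,
               list(transcript_model(paste0(gid, ".1"), gid, "Chr01", strand,
                                     exons = rbind(c(s, e)),
                                     cds = rbind(c(s, e)))))
  }
  genes <- list(mk("gA", 3000, 3500, "+"), mk("gB", 1000, 2000, "+"))
  ## 2500: 500 bp past gB, 500 bp before gA -> tie, smaller id gA
  tie <- classify_site(site(2500), genes, window = 2000)
  expect_identical(tie$gene_id, "gA")
  ## 2200: 200 past gB beats 800 before gA
  near <- classify_site(site(2200), genes, window = 2000)
  expect_identical(near$gene_id, "gB")
  expect_identical(near$category, "downstream")
})

test_that("non-unique sites are refused or passed through unclassified", {
  genes <- toy_genes()
  bad <- site(250)
  bad$mapping_status <- "multi"
  expect_error(classify_site(bad, genes), class = "unclassifiable_site")
  mixed <- rbind(site(250, id = "a"), bad)
  ann <- classify_sites(mixed, genes)
  expect_identical(ann$category, c("intron", NA))
})

test_that("chromatin context uses 1-based inclusive containment", {
  peri <- data.frame(chrom = "Chr01", start = 5000001, end = 15000000)
  sites <- data.frame(chromosome = "Chr01",
                      left = c(7e6, 5e6, 5000001, 15000000, 15000001))
  ctx <- chromatin_context(sites, peri)
  expect_identical(ctx, c("pericentromeric", "euchromatic", "pericentromeric",
                          "pericentromeric", "euchromatic"))

  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  expect_identical(unique(chromatin_context(sites, empty)), "euchromatic")

  off <- data.frame(chromosome = "Chr07", left = 5)
  expect_warning(ctx2 <- chromatin_context(off, peri),
                 class = "missing_pericentromere_chrom")
  expect_identical(ctx2, "euchromatic")
})

test_that("cohort summaries reproduce the 17/10-of-105 arithmetic", {
  ann <- data.frame(
    mutant_id = sprintf("m%03d", 1:105),
    chromosome = "Chr01",
    category = rep(c("exon", "intron", "intergenic", "upstream", "downstream"),
                   c(17, 10, 40, 20, 18)),
    chromatin = rep(c("euchromatic", "pericentromeric"), c(81, 24)),
    stringsAsFactors = FALSE)
  s <- cohort_summary(ann)
  expect_identical(s$n, 105L)
  expect_equal(s$percentages[["exon"]], 16.2)
  expect_equal(s$percentages[["intron"]], 9.5)
  expect_equal(s$genic_percentage, 25.7)
  expect_equal(s$euchromatic_percentage, 77.1)
  expect_equal(euchromatic_fraction(ann), 77.1)

  e <- cohort_summary(ann[0, ])
  expect_identical(e$n, 0L)
  expect_true(all(e$counts == 0))
  expect_true(is.na(euchromatic_fraction(ann[0, ])))
})

test_that("classifier agrees with a per-base label oracle", {
  genes <- toy_genes()
  chrom_len <- 8000L
  set.seed(61)
  lefts <- sort(sample(chrom_len - 1L, 400))
  ann <- classify_sites(
    data.frame(mutant_id = as.character(seq_along(lefts)),
               chromosome = "Chr01", left = lefts,
               mapping_status = "unique", stringsAsFactors = FALSE),
    genes)
  for (i in seq_along(lefts)) {
    o <- oracle_classify(lefts[i], genes, "Chr01", chrom_len)
    expect_identical(ann$category[i], o$category)
    if (!is.na(o$gene_id)) expect_identical(ann$gene_id[i], o$gene_id)
  }
})

test_that("uniform cohorts converge to the partition fractions", {
  bundle <- generate_genome(small_spec(), element_spec())
  totals <- genome_partition(bundle$genes, chromosome_lengths(bundle))
  sites <- simulate_insertions(bundle, 10000, seed = 8)
  sites$mapping_status <- "unique"
  ann <- classify_sites(sites, bundle$genes)
  genic <- mean(ann$category %in% c("exon", "intron"))
  se <- sqrt(totals$genic_fraction * (1 - totals$genic_fraction) / 10000)
  expect_lt(abs(genic - totals$genic_fraction), 3 * se)
  ## every classified site gets exactly one category
  expect_false(anyNA(ann$category))
  expect_identical(nrow(ann), 10000L)
})
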