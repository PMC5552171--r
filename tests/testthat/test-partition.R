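test_that("longest-variant selection maximizes span with documented tie-break", {
  tx <- function(id, s, e) transcript_model(id, "g1", "Chr01", "+",
                                            exons = rbind(c(s, e)))
  g <- gene_model("g1", "Chr01", "+", list(tx("a", 1, 2400), tx("b", 1, 3000)))
  expect_identical(select_longest_variant(g)$transcript_id, "b")
  g1 <- gene_model("g1", "Chr01", "+", list(tx("only", 10, 20)))
  expect_identical(select_longest_variant(g1)$transcript_id, "only")
  ## equal spans: lexicographically smallest id, in either input order
  for (ord in list(c("m2", "m1"), c("m1", "m2"))) {
    g2 <- gene_model("g1", "Chr01", "+",
                     list(tx(ord[1], 1, 500), tx(ord[2], 1, 500)))
    expect_identical(select_longest_variant(g2)$transcript_id, "m1")
  }
  expect_error(gene_model("g0", "Chr01", "+", list()),
               class = "malformed_annotation")
})

test_that("partition_transcript does the worked interval arithmetic", {
  p <- partition_transcript(two_exon_tx("+"))
  expect_identical(p$full_length, 300)
  expect_identical(p$cds_length, 100)
  expect_identical(p$utr5_length, 50)
  expect_identical(p$utr3_length, 50)
  expect_identical(p$intron_length, 100)

  ## single fully coding exon
  t1 <- transcript_model("t", "g", "Chr01", "+", exons = rbind(c(1, 90)),
                         cds = rbind(c(1, 90)))
  p1 <- partition_transcript(t1)
  expect_identical(unname(unlist(p1[c("full_length", "cds_length",
                                      "utr5_length", "utr3_length",
                                      "intron_length")])),
                   c(90, 90, 0, 0, 0))

  ## minus strand: same values by symmetry (UTRs swap ends)
  pm <- partition_transcript(two_exon_tx("-"))
  expect_identical(pm$utr5_length, 50)
  expect_identical(pm$utr3_length, 50)
  expect_identical(pm$cds_length, p$cds_length)

  ## asymmetric UTRs flip on the minus strand
  ta <- function(strand) transcript_model("t", "g", "Chr01", strand,
                                          exons = rbind(c(1, 100)),
                                          cds = rbind(c(31, 90)))
  expect_identical(partition_transcript(ta("+"))$utr5_length, 30)
  expect_identical(partition_transcript(ta("-"))$utr5_length, 10)
})

test_that("malformed transcripts are rejected with classed errors", {
  expect_error(transcript_model("t", "g", "Chr01", "+",
                                exons = rbind(c(10, 5))),
               class = "malformed_annotation")
  expect_error(transcript_model("t", "g", "Chr01", "+",
                                exons = rbind(c(1, 50), c(40, 90))),
               class = "malformed_annotation")
  expect_error(transcript_model("t", "g", "Chr01", "+",
                                exons = rbind(c(1, 50)),
                                cds = rbind(c(40, 60))),
               class = "malformed_annotation")
})

test_that("non-coding transcripts keep the conservation identity", {
  t <- transcript_model("t", "g", "Chr01", "+",
                        exons = rbind(c(1, 100), c(201, 300)))
  p <- partition_transcript(t)
  expect_true(p$noncoding)
  expect_identical(p$utr5_length + p$cds_length + p$utr3_length +
                     p$intron_length, p$full_length)
})

test_that("genome_partition sums genes and polices the denominator", {
  g <- gene_model("g1", "Chr01", "+", list(two_exon_tx("+")))
  totals <- genome_partition(list(g), c(Chr01 = 1000))
  expect_identical(totals$total_exon, 200)
  expect_identical(totals$total_intron, 100)
  expect_identical(totals$exon_fraction, 0.2)
  expect_identical(totals$genic_fraction, 0.3)

  empty <- genome_partition(list(), c(Chr01 = 1000))
  expect_identical(empty$exon_fraction, 0)
  expect_identical(empty$intron_fraction, 0)

  expect_error(genome_partition(list(g), c(Chr02 = 1000)),
               class = "unknown_chromosome")
  expect_error(genome_partition(list(g), c(Chr02 = 1000)),
               regexp = "g1")
})

test_that("conservation identity holds across a generated annotation", {
  bundle <- generate_genome(small_spec(), element_spec())
  tab <- gene_partition_table(bundle$genes)
  expect_equal(tab$utr5_length + tab$cds_length + tab$utr3_length +
                 tab$intron_length, tab$full_length)
  expect_true(all(tab[c("cds_length", "utr5_length", "utr3_length",
                        "intron_length")] >= 0))
})

test_that("interval arithmetic agrees with per-base labeling", {
  g1 <- gene_model("g1", "Chr01", "+", list(two_exon_tx("+")))
  t2 <- transcript_model("t2", "g2", "Chr01", "-",
                         exons = rbind(c(501, 600), c(651, 700), c(801, 900)),
                         cds = rbind(c(551, 600), c(651, 700), c(801, 850)))
  g2 <- gene_model("g2", "Chr01", "-", list(t2))
  genes <- list(g1, g2)
  chrom_len <- 1200

  label <- rep("intergenic", chrom_len)
  for (g in genes) {
    t <- select_longest_variant(g)
    label[min(t$exons[, 1]):max(t$exons[, 2])] <- "intron"
    for (i in seq_len(nrow(t$exons))) label[t$exons[i, 1]:t$exons[i, 2]] <- "exon"
  }
  totals <- genome_partition(genes, c(Chr01 = chrom_len))
  expect_equal(totals$total_exon, sum(label == "exon"))
  expect_equal(totals$total_intron, sum(label == "intron"))
})

test_that("deduplicated mode counts overlapping gene bases once", {
  tx <- function(id, gid) transcript_model(id, gid, "Chr01", "+",
                                           exons = rbind(c(101, 300)),
                                           cds = rbind(c(101, 300)))
  genes <- list(gene_model("g1", "Chr01", "+", list(tx("t1", "g1"))),
                gene_model("g2", "Chr01", "+", list(tx("t2", "g2"))))
  per_gene <- genome_partition(genes, c(Chr01 = 1000))
  dedup <- genome_partition(genes, c(Chr01 = 1000),
                            count_mode = "deduplicated")
  expect_identical(per_gene$total_exon, 400)
  expect_identical(dedup$total_exon, 200)
})

test_that("partition totals round-trip through JSON", {
  g <- gene_model("g1", "Chr01", "+", list(two_exon_tx("+")))
  totals <- genome_partition(list(g), c(Chr01 = 1000))
  jp <- tempfile(fileext = ".json")
  write_partition_totals(totals, jp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$exon_fraction, totals$exon_fraction)
  expect_equal(back$total_intron, totals$total_intron)
  unlink(jp)
})
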