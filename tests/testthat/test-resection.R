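one_gene_ann <- function() {
  make_annotation("chr1", 10000, 11000, "geneA", "+", c(chr1 = 100000))
}

test_that("annotation parsing handles BED, GFF3 and bad input", {
  cs_path <- tempfile(fileext = ".chrom.sizes")
  writeLines("chrII\t50000\nchrIII\t30000", cs_path)
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrII\t100\t200\tgeneA\t0\t+",
               "chrIII\t0\t500\tgeneB\t0\t-"), bed)
  ann <- parse_annotation(bed, cs_path)
  expect_identical(GenomicRanges::start(ann), c(101L, 1L))  # 0-based half-open in
  expect_identical(GenomicRanges::end(ann), c(200L, 500L))
  expect_identical(ann$gene_id, c("geneA", "geneB"))
  expect_identical(as.character(GenomicRanges::strand(ann)), c("+", "-"))

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrII\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneA"), gff)
  ann2 <- parse_annotation(gff, cs_path)
  # 1-based closed GFF3 feature 101..200 is the same interval as BED 100..200
  expect_identical(GenomicRanges::start(ann2), 101L)
  expect_identical(GenomicRanges::end(ann2), 200L)

  bad <- tempfile(fileext = ".bed")
  writeLines("chrII\t300\t200\tgeneX\t0\t+", bad)
  expect_error(parse_annotation(bad, cs_path))
  unk <- tempfile(fileext = ".bed")
  writeLines("chrVII\t100\t200\tgeneY\t0\t+", unk)
  expect_error(parse_annotation(unk, cs_path), "chrVII")
  expect_error(make_annotation("chrII", 100, 100, "g", "+",
                               c(chrII = 1000)), "end <= start")
})

test_that("exposure intervals follow the closed form", {
  # long repeat: the two arms coalesce into one interval
  gr <- exposure_intervals(one_gene_ann(), L = 4000, min_exposure = 300)
  expect_identical(length(gr), 1L)
  expect_identical(GenomicRanges::start(gr), 6301L)   # 0-based 6300
  expect_identical(GenomicRanges::end(gr), 14700L)
  # short repeat (< 2*E_min): central band excluded
  ann2 <- make_annotation("chr1", 1000, 1400, "g", "+", c(chr1 = 5000))
  gr2 <- exposure_intervals(ann2, L = 1000, min_exposure = 300)
  expect_identical(GenomicRanges::start(gr2), c(301L, 1301L))
  expect_identical(GenomicRanges::end(gr2), c(1100L, 2100L))
  # tract below the minimum exposure: nothing at risk
  expect_identical(length(exposure_intervals(one_gene_ann(), 200, 300)), 0L)
  # repeat shorter than the minimum exposure: nothing at risk
  tiny <- make_annotation("chr1", 1000, 1200, "g", "+", c(chr1 = 5000))
  expect_identical(length(exposure_intervals(tiny, 4000, 300)), 0L)
  # clipping at chromosome bounds
  edge <- make_annotation("chr1", 0, 1000, "g", "+", c(chr1 = 2000))
  gr3 <- exposure_intervals(edge, 4000, 300)
  expect_identical(GenomicRanges::start(gr3), 1L)
  expect_identical(GenomicRanges::end(gr3), 2000L)
})

test_that("risk fractions match the worked examples", {
  ann <- one_gene_ann()
  expect_equal(resection_risk_fraction(ann, t = 1), 0.084)
  expect_equal(resection_risk_fraction(ann, t = 0), 0)
  co_ann <- make_annotation("chr1", 4000, 5000, "g", "+", c(chr1 = 10000))
  expect_equal(co_risk_fraction(co_ann, margin = 300), 0.04)
  # repeat not longer than twice the margin contributes nothing
  short <- make_annotation("chr1", 1000, 1600, "g", "+", c(chr1 = 10000))
  expect_equal(co_risk_fraction(short, margin = 300), 0)
  expect_equal(co_risk_fraction(short[0], margin = 300), 0)
})

test_that("interval merging has position-set union semantics", {
  cs <- c(chrA = 100, chrB = 100)
  gr <- make_annotation(c("chrA", "chrA", "chrA", "chrB"),
                        c(0, 5, 10, 0), c(10, 15, 20, 10),
                        c("a", "b", "c", "d"), "*", cs)
  m <- merge_intervals(gr)
  expect_identical(length(m), 2L)  # chrA merges (incl. adjacency), chrB apart
  expect_identical(GenomicRanges::start(m), c(1L, 1L))
  expect_identical(GenomicRanges::end(m), c(20L, 10L))
  expect_identical(sum(GenomicRanges::width(m)), position_set_union_bp(gr))
})

test_that("risk profile is monotone and reports static coverage", {
  ann <- one_gene_ann()
  prof <- risk_profile(ann, resection_params(times = seq(0, 4, 0.25)))
  expect_identical(nrow(prof), 17L)
  expect_true(all(diff(prof$genome_fraction) >= 0))
  expect_equal(attr(prof, "static_coverage"), 1000 / 100000)
  expect_equal(prof$at_risk_bp / 100000, prof$genome_fraction)
  # empty annotation: all fractions zero
  prof0 <- risk_profile(ann[0])
  expect_true(all(prof0$genome_fraction == 0))
  # single interval: coalesced arms span [s-(L-E), e+(L-E)) clipped to the
  # chromosome, once L >= E_min
  E <- 300; v <- 4000
  expected <- vapply(prof$t_hours, function(t) {
    L <- v * t
    if (L < E) return(0)
    (min(100000, 11000 + (L - E)) - max(0, 10000 - (L - E))) / 100000
  }, numeric(1))
  expect_equal(prof$genome_fraction, expected)
})

test_that("naive extension and both-end strictness bracket the default rule", {
  ann <- one_gene_ann()
  p <- resection_params()
  f_exp <- resection_risk_fraction(ann, 1, p)
  f_naive <- resection_risk_fraction(ann, 1, p, mode = "naive")
  f_both <- resection_risk_fraction(ann, 1, p, both_ends = TRUE)
  expect_gt(f_naive, f_exp)       # extends by L instead of L - E_min
  expect_lt(f_both, f_exp)        # two usable ends is stricter than one
  expect_equal(f_naive, (1000 + 2 * 4000) / 100000)
  # naive mode at t = 0 degenerates to repeat coverage
  expect_equal(resection_risk_fraction(ann, 0, p, mode = "naive"),
               1000 / 100000)
})

test_that("per-base oracle reproduces the closed form on hand cases", {
  ann <- one_gene_ann()
  expect_equal(per_base_oracle(ann, L = 4000), 0.084)
  expect_equal(per_base_oracle(ann, L = 0), 0)
  # saturating case: repeat covers a whole chromosome
  cs <- c(chrA = 2000, chrB = 3000)
  full <- make_annotation("chrA", 0, 2000, "g", "+", cs)
  expect_equal(per_base_oracle(full, L = 500), 2000 / 5000)
  expect_error(per_base_oracle(make_annotation("c", 0, 10, "g", "+",
                                               c(c = 2e7)), 100),
               "too large")
})

test_that("closed form equals the per-base oracle across random genomes", {
  # the deep 200-genome sweep lives in the acceptance suite; this is the
  # fast regression version with awkward geometries
  for (seed in 1:25) {
    ann <- random_annotation(seed)
    set.seed(seed * 13)
    L <- sample(c(0, 150, 400, 1000, 4000, 16000), 1)
    E <- sample(c(100, 300, 450), 1)
    p <- resection_params(min_exposure = E, speed = 1)
    expect_equal(resection_risk_fraction(ann, t = L, p),
                 per_base_oracle(ann, L, E), tolerance = 0,
                 info = sprintf("seed %d L %d E %d", seed, L, E))
    expect_equal(resection_risk_fraction(ann, t = L, p, both_ends = TRUE),
                 per_base_oracle(ann, L, E, both_ends = TRUE), tolerance = 0,
                 info = sprintf("both-ends seed %d", seed))
  }
})

test_that("risk ordering: CO subset of coverage subset of resection space", {
  for (seed in 26:40) {
    ann <- random_annotation(seed)
    cover <- sum(GenomicRanges::width(merge_intervals(ann))) /
      genome_length(ann)
    expect_lte(co_risk_fraction(ann, 300), cover)
    # exposure sets contain the repeat body once length >= 2*E_min and
    # v*t >= 2*E_min; repeats below 2*E_min keep an uncovered central band,
    # so the coverage <= resection inequality is asserted on the long ones
    long <- ann[GenomicRanges::width(ann) >= 600]
    if (length(long) == 0L) next
    cover_long <- sum(GenomicRanges::width(merge_intervals(long))) /
      genome_length(long)
    f <- resection_risk_fraction(long, t = 1, resection_params(speed = 4000))
    expect_lte(cover_long, f)
  }
})
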