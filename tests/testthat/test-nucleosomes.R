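# Peak calling, width filtering, positioning classification, dyads,
# shared nucleosomes and annotation filters.

test_that("fragment length filter is exclusive at both bounds", {
  fr <- data.frame(chrom = "chr1", start = 0L,
                   end = c(120L, 121L, 179L, 180L))
  kept <- filter_fragments(fr)
  expect_equal(kept$end, c(121L, 179L))
  expect_equal(nrow(filter_fragments(fr[integer(0), ])), 0)
})

test_that("peak caller resolves delta and two-cluster inputs", {
  expect_error(call_peaks(delta_fragments(500), bandwidth = 0), "bandwidth")
  pk <- call_peaks(delta_fragments(500))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$summit, 500)
  expect_lte(pk$end - pk$start, 140)

  two <- rbind(delta_fragments(400), delta_fragments(600))
  pk2 <- call_peaks(two, bandwidth = 20)
  expect_equal(nrow(pk2), 2)
  expect_lte(max(abs(sort(pk2$summit) - c(400, 600))), 2)

  expect_equal(nrow(call_peaks(delta_fragments(500)[integer(0), ])), 0)
})

test_that("width filter removes peaks wider than 140 bp only", {
  pk <- data.frame(chrom = "chr1", start = 0L, end = c(140L, 141L),
                   summit = 70L, height = 1)
  expect_equal(filter_peak_width(pk)$end, 140L)
  expect_equal(nrow(filter_peak_width(pk[integer(0), ])), 0)
})

test_that("reciprocal overlap follows interval arithmetic and is symmetric", {
  a <- list(chrom = "chr1", start = 100, end = 240)
  b <- list(chrom = "chr1", start = 110, end = 250)
  expect_equal(reciprocal_overlap(a, a), c(1, 1))
  expect_equal(reciprocal_overlap(a, b), c(130 / 140, 130 / 140))
  expect_equal(reciprocal_overlap(a, list(chrom = "chr1", start = 300,
                                          end = 400)), c(0, 0))
  expect_error(reciprocal_overlap(a, list(chrom = "chr2", start = 100,
                                          end = 240)), "chromosome")
  set.seed(42)
  for (i in 1:25) {
    x <- list(chrom = "chr1", start = sample(1000, 1))
    x$end <- x$start + sample(140, 1)
    y <- list(chrom = "chr1", start = sample(1000, 1))
    y$end <- y$start + sample(140, 1)
    expect_equal(reciprocal_overlap(x, y), rev(reciprocal_overlap(y, x)))
  }
})

test_that("dyads are the midpoint of the union span of member peaks", {
  one <- data.frame(chrom = "chr1", start = 100, end = 240)
  expect_equal(compute_dyad(one), 170L)
  two <- rbind(one, data.frame(chrom = "chr1", start = 110, end = 250))
  expect_equal(compute_dyad(two), 175L)
  three <- data.frame(chrom = "chr1", start = rep(0, 3), end = rep(140, 3))
  expect_equal(compute_dyad(three), 70L)
  expect_error(compute_dyad(one[integer(0), ]), "empty")
  # endpoint-mean alternative differs for asymmetric overlaps
  expect_equal(compute_dyad(two, method = "endpoint_mean"), 175L)
})

test_that("positioning groups follow the 25% reciprocal-overlap increments", {
  rep1 <- data.frame(chrom = "chr1",
                     start = c(100L, 1000L, 2000L, 3000L),
                     end = c(240L, 1100L, 2100L, 3100L))
  rep2 <- data.frame(chrom = "chr1",
                     start = c(110L, 1025L, 2060L, 5000L),
                     end = c(250L, 1125L, 2160L, 5100L))
  calls <- classify_positioning(rep1, rep2)
  # 130/140 ~ 0.93 -> group 1; exactly 0.75 -> group 2 (boundary to the
  # lower group); 40/100 -> group 3; no overlap -> other
  expect_equal(calls$group, c("1", "2", "3", "other"))
  expect_equal(calls$dyad[1], 175L)
  expect_equal(calls$dyad[4], 3050L)
  # partition: every peak in exactly one group
  expect_equal(nrow(calls), nrow(rep1))
  # dyads lie strictly inside their union spans
  expect_true(all(calls$dyad > calls$start & calls$dyad < calls$end))
})

test_that("positioning classification partitions random replicate peaks", {
  set.seed(7)
  mk <- function() {
    s <- sort(sample(0:5000, 40))
    data.frame(chrom = "chr1", start = s, end = s + sample(60:140, 40,
                                                           replace = TRUE))
  }
  r1 <- mk()
  r2 <- mk()
  calls <- classify_positioning(r1, r2)
  expect_equal(nrow(calls), nrow(r1))
  expect_true(all(calls$group %in% c("1", "2", "3", "4", "other")))
  expect_true(all(calls$dyad >= calls$start & calls$dyad <= calls$end))
})

test_that("shared nucleosomes use the inclusive 20 bp dyad rule", {
  a <- data.frame(chrom = "chr1", dyad = c(100L, 500L, 900L))
  b <- data.frame(chrom = "chr1", dyad = c(120L, 521L, 900L))
  m <- shared_nucleosomes(a, b)
  # 100/120 (dist 20, inclusive) and 900/900 match; 500/521 (dist 21) do not
  expect_equal(sort(m$dyad_a), c(100L, 900L))
  expect_equal(sort(m$dist), c(0L, 20L))
  expect_equal(anyDuplicated(m$idx_a), 0)
  expect_equal(anyDuplicated(m$idx_b), 0)
})

test_that("genic nucleosomes are labelled exonic by any exon overlap", {
  parts <- data.frame(chrom = "chr1",
                      start = c(0L, 200L, 500L),
                      end = c(200L, 500L, 700L),
                      type = c("exon", "intron", "exon"),
                      gene_id = "g1")
  calls <- data.frame(chrom = "chr1", dyad = c(272L, 300L, 480L, 1000L))
  lab <- classify_genic_nucleosomes(calls, parts)
  # span [199,346) overlaps the first exon by 1 bp -> exonic
  # span [227,374) sits entirely inside the intron -> intronic
  # span [407,554) crosses the intron/exon junction -> exonic
  expect_equal(lab, c("exonic", "intronic", "exonic", NA))
})

test_that("heterochromatic TE filter applies all three criteria", {
  tes <- data.frame(chrom = "chr1", start = 0L,
                    end = c(100L, 30L, 100L, 100L),
                    feature_id = paste0("te", 1:4))
  scores <- c(10, 9, 8, 1)   # quintiles of 4 values: 5, 5, 4 (?), ...
  tes10 <- data.frame(chrom = "chr1", start = 0L,
                      end = c(rep(100L, 8), 30L, 100L),
                      feature_id = paste0("te", 1:10))
  mcg <- c(rep(0.06, 8), 0.06, 0.04)
  h3k <- 1:10                 # te9, te10 in the top two quintiles
  kept <- filter_heterochromatic_tes(tes10, mcg, h3k)
  # te7, te8 pass all criteria; te9 is exactly 30 bp (excluded); te10 has
  # mCG of 4% (excluded)
  expect_equal(kept$feature_id, c("te7", "te8"))
  expect_error(filter_heterochromatic_tes(tes10, mcg, c(h3k[-10], NA)),
               "te10")
  expect_error(filter_heterochromatic_tes(tes, c(0.06, 0.06), scores),
               "every TE")
})
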