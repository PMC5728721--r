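# CX parsing, weighted methylation, metaprofiles, difference profiles and
# RPM coverage tracks.

test_that("CX reader converts the 1-based dialect and rejects bad lines", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t100\t+\t3\t1\tCG", path)
  rec <- read_cx_report(path)
  expect_equal(rec$pos, 99L)
  expect_equal(rec$count_meth / rec$count_total, 0.75)

  writeLines(c("chr1\t100\t+\t3\t1\tCG", "chr1\t101\t-\t1\t0\tCNN"), path)
  expect_error(read_cx_report(path), "line\\(s\\): 2")
  writeLines("chr1\t100\t+\t-3\t1\tCG", path)
  expect_error(read_cx_report(path), "malformed")
  file.create(path)
  expect_equal(nrow(read_cx_report(path)), 0)
})

test_that("weighted methylation pools counts within the interval", {
  rec <- make_records(pos = c(10, 20, 30), meth = c(2, 1, 5),
                      total = c(4, 1, 5))
  expect_equal(weighted_methylation(rec, "chr1", 0, 25), 3 / 5)
  expect_equal(weighted_methylation(rec, "chr1", 25, 40), 1)
  expect_true(is.na(weighted_methylation(rec, "chr1", 100, 200)))
  expect_error(weighted_methylation(rec, "chr1", 10, 10), "non-empty")
})

test_that("anchored profiles pool counts into offset bins", {
  rec <- make_records(pos = 1005, meth = 3, total = 4)
  anchors <- data.frame(chrom = "chr1", pos = 1000L)
  pr <- profile_around_anchors(rec, anchors, flank = 50, bin = 10)
  expect_equal(pr$fraction[pr$offset == 0], 0.75)
  expect_true(all(is.na(pr$fraction[pr$offset != 0])))
  expect_error(profile_around_anchors(rec, anchors, flank = 50, bin = 0),
               "bin")
  # minus-strand anchor mirrors the offset when oriented
  anchors_m <- data.frame(chrom = "chr1", pos = 1000L, strand = "-")
  pr_m <- profile_around_anchors(rec, anchors_m, flank = 50, bin = 10,
                                 oriented = TRUE)
  expect_equal(pr_m$fraction[pr_m$offset == -10], 0.75)
  expect_true(is.na(pr_m$fraction[pr_m$offset == 0]))
})

test_that("profiles pool count-wise across anchor subsets", {
  set.seed(11)
  rec <- make_records(pos = sort(sample(0:4000, 300)),
                      meth = rbinom(300, 10, 0.4), total = 10)
  a <- data.frame(chrom = "chr1", pos = c(500L, 1500L))
  b <- data.frame(chrom = "chr1", pos = c(2500L, 3500L))
  pa <- profile_around_anchors(rec, a, flank = 200, bin = 20)
  pb <- profile_around_anchors(rec, b, flank = 200, bin = 20)
  pab <- profile_around_anchors(rec, rbind(a, b), flank = 200, bin = 20)
  expect_equal(pab$n_meth, pa$n_meth + pb$n_meth)
  expect_equal(pab$n_total, pa$n_total + pb$n_total)
  # count conservation: profile totals equal in-flank record totals
  in_flank <- outer(rec$pos, rbind(a, b)$pos, function(p, q) {
    o <- p - q
    o >= -200 & o < 200
  })
  expect_equal(sum(pab$n_total),
               sum(rec$count_total * rowSums(in_flank)))
})

test_that("simulated core/linker structure is recovered around dyads", {
  cfg <- sim_config(seed = 9, chrom_sizes = c(chr1 = 2e5))
  lay <- generate_layout(cfg)
  map <- simulate_true_nucleosomes(lay, cfg)
  rec <- simulate_methylome(lay, map, "h1ddm1", cfg)
  anchors <- data.frame(chrom = map$chrom, pos = map$dyad)
  pr <- profile_around_anchors(rec, anchors, flank = 100, bin = 10,
                               context = "CG")
  core <- pr$fraction[abs(pr$offset + 5) <= 60]
  linker <- pr$fraction[abs(pr$offset + 5) >= 84 & abs(pr$offset + 5) <= 96]
  expect_true(all(core < min(linker)))           # cores depleted vs linkers
  expect_lt(abs(pr$offset[which.min(pr$fraction)] + 5), 74)  # minimum in core
})

test_that("difference profiles subtract per bin and propagate missingness", {
  mk <- function(fr) {
    p <- data.frame(offset = c(-10, 0), n_meth = 1, n_total = 2,
                    fraction = fr)
    attr(p, "context") <- "CHH"
    p
  }
  expect_equal(difference_profile(mk(c(0.5, 0.5)), mk(c(0.5, 0.5)))$delta,
               c(0, 0))
  expect_equal(difference_profile(mk(c(0.2, 0.2)), mk(c(0.9, 0.9)))$delta,
               c(-0.7, -0.7), tolerance = 1e-12)
  d <- difference_profile(mk(c(0.2, NA)), mk(c(NA, 0.9)))
  expect_true(all(is.na(d$delta)))
  other <- mk(c(0.5, 0.5))
  other$offset <- c(0, 10)
  expect_error(difference_profile(mk(c(0.5, 0.5)), other), "mismatched bins")
})

test_that("RPM tracks scale by library size and conserve counts", {
  fr <- data.frame(chrom = "chr1", start = rep(100L, 10), end = rep(200L, 10))
  tr <- rpm_normalize(fr, total_mapped = 2e6, bin = 10)
  expect_equal(tr$rpm[tr$start == 150], 5.0)
  tr2 <- rpm_normalize(fr, total_mapped = 4e6, bin = 10)
  expect_equal(tr2$rpm, tr$rpm / 2)
  # zero-count bins inside the covered span report 0 RPM
  fr2 <- data.frame(chrom = "chr1", start = c(100L, 300L), end = c(110L, 310L))
  tr3 <- rpm_normalize(fr2, total_mapped = 1e6, bin = 10)
  expect_equal(tr3$rpm[tr3$start == 200], 0)
  expect_equal(sum(tr3$rpm * 1e6 / 1e6), sum(tr3$count) * 1)
  expect_error(rpm_normalize(fr, total_mapped = 0), "total_mapped")
})

test_that("decile-stratified profiles partition anchors by expression", {
  set.seed(3)
  rec <- make_records(pos = sort(sample(0:5000, 400)),
                      meth = rbinom(400, 10, 0.5), total = 10)
  anchors <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                        pos = c(500L, 1500L, 2500L, 3500L))
  one_decile <- data.frame(gene_id = paste0("g", 1:4), decile = 5L)
  out <- profile_by_expression_decile(rec, anchors, one_decile,
                                      flank = 200, bin = 20)
  expect_named(out, "5")
  plain <- profile_around_anchors(rec, anchors[, c("chrom", "pos")],
                                  flank = 200, bin = 20)
  expect_equal(out[["5"]]$n_meth, plain$n_meth)
  # missing genes are excluded with a warning
  expect_warning(
    out2 <- profile_by_expression_decile(rec, anchors, one_decile[1:3, ],
                                         flank = 200, bin = 20),
    "missing")
  expect_lt(sum(out2[["5"]]$n_total), sum(plain$n_total))
})

test_that("a planted decile-specific methylation loss is recovered", {
  # decile-1 gene loses methylation in the mutant; decile-10 gene does not
  pos1 <- seq(400, 600, by = 10)
  pos10 <- seq(2400, 2600, by = 10)
  mut <- rbind(make_records(pos1, meth = 1, total = 10),
               make_records(pos10, meth = 8, total = 10))
  anchors <- data.frame(gene_id = c("lo", "hi"), chrom = "chr1",
                        pos = c(500L, 2500L))
  dec <- data.frame(gene_id = c("lo", "hi"), decile = c(1L, 10L))
  out <- profile_by_expression_decile(mut, anchors, dec,
                                      flank = 100, bin = 100)
  m <- function(p) sum(p$n_meth) / sum(p$n_total)
  expect_lt(m(out[["1"]]), m(out[["10"]]))
})
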