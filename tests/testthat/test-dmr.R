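# Windowed DMR calling: pooling, the one-sided exact test, loss and
# exclusivity criteria, merging, and anchoring.

test_that("window counts pool per genotype on the fixed 50 bp grid", {
  wt <- make_records(pos = 60, meth = 5, total = 10, context = "CHH")
  win <- window_counts(list(WT = wt))
  expect_equal(win$start, 50L)
  expect_equal(win$meth_WT / win$total_WT, 0.5)

  two <- make_records(pos = c(60, 70), meth = c(1, 3), total = c(2, 4),
                      context = "CHH")
  win2 <- window_counts(list(WT = two))
  expect_equal(win2$meth_WT / win2$total_WT, 4 / 6)

  cg_only <- make_records(pos = 60, meth = 5, total = 10, context = "CG")
  expect_equal(nrow(window_counts(list(WT = cg_only))), 0)
  expect_error(window_counts(list(WT = wt), window = 0), "window")
  expect_error(window_counts(list(wt)), "named")
})

test_that("one-sided exact p-values match hand-enumerated tables", {
  expect_equal(fisher_exact_one_sided(5, 0, 0, 5), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_gt(fisher_exact_one_sided(3, 3, 3, 3), 0.5)
  # a mutant *gain* can never look like a significant loss
  expect_gte(fisher_exact_one_sided(2, 8, 8, 2), 0.5)
  expect_error(fisher_exact_one_sided(0, 0, 0, 0), "zero grand total")
  expect_error(fisher_exact_one_sided(-1, 2, 3, 4), "non-negative")
})

test_that("exact test equals hypergeometric enumeration on small tables", {
  set.seed(5)
  for (i in 1:200) {
    tab <- as.integer(sample(0:6, 4, replace = TRUE))
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_one_sided(tab[1], tab[2], tab[3], tab[4]),
                 enum_one_sided_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
})

test_that("DMR windows require WT floor, relative loss and significance", {
  win <- rbind(
    make_window(0, wt = 40, mut = 10, other = 38),    # passes everything
    make_window(100, wt = 5, mut = 0, other = 5),     # WT below the 10% floor
    make_window(200, wt = 40, mut = 32, other = 40),  # loss 20% <= 30%
    make_window(300, wt = 10, mut = 6, other = 10))   # loss ok, p too weak
  dmrs <- call_dmrs(win, wt_label = "WT", mut_label = "mut",
                    other_mut_label = "other")
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 0L)
  expect_equal(dmrs$dependency, "mut")
  expect_lt(dmrs$min_p, 0.01)
})

test_that("book-ended DMR windows merge; separated windows do not", {
  win <- rbind(make_window(0, wt = 40, mut = 5, other = 38),
               make_window(50, wt = 40, mut = 5, other = 38),
               make_window(200, wt = 40, mut = 5, other = 38))
  dmrs <- call_dmrs(win, wt_label = "WT", mut_label = "mut",
                    other_mut_label = "other")
  expect_equal(dmrs$start, c(0L, 200L))
  expect_equal(dmrs$end, c(100L, 250L))
  expect_equal(dmrs$n_windows, c(2L, 1L))
  # member windows reconstruct their DMRs exactly
  wt_tab <- attr(dmrs, "window_table")
  for (i in seq_len(nrow(dmrs))) {
    mem <- wt_tab[wt_tab$dmr == i, ]
    expect_equal(min(mem$start), dmrs$start[i])
    expect_equal(max(mem$end), dmrs$end[i])
    expect_true(all(sort(mem$start)[-1] == sort(mem$end)[-nrow(mem)]))
  }
})

test_that("shared losses are rejected by the exclusivity filter", {
  shared <- make_window(0, wt = 40, mut = 5, other = 6)
  excl <- make_window(100, wt = 40, mut = 5, other = 39)
  dmrs <- call_dmrs(rbind(shared, excl), wt_label = "WT",
                    mut_label = "mut", other_mut_label = "other")
  expect_equal(dmrs$start, 100L)
  # significance-only exclusivity is stricter here too
  dmrs2 <- call_dmrs(rbind(shared, excl), wt_label = "WT",
                     mut_label = "mut", other_mut_label = "other",
                     exclusivity = "significance")
  expect_equal(dmrs2$start, 100L)
  no_other <- make_window(0, wt = 40, mut = 5, other = 38)
  no_other$meth_other <- NULL
  no_other$total_other <- NULL
  expect_error(call_dmrs(no_other, wt_label = "WT", mut_label = "mut",
                         other_mut_label = "other"), "exclusivity")
})

test_that("raising alpha never reduces the number of DMR windows", {
  set.seed(8)
  win <- do.call(rbind, lapply(seq(0, 5000, by = 50), function(s) {
    make_window(s, wt = rbinom(1, 100, 0.3), mut = rbinom(1, 100, 0.15),
                other = rbinom(1, 100, 0.3))
  }))
  n_at <- vapply(c(0.001, 0.01, 0.05, 0.2), function(a) {
    d <- call_dmrs(win, wt_label = "WT", mut_label = "mut",
                   other_mut_label = "other", alpha = a)
    nrow(attr(d, "window_table"))
  }, numeric(1))
  expect_true(all(diff(n_at) >= 0))
})

test_that("DMRs must overlap an annotated TE", {
  dmrs <- data.frame(chrom = "chr1", start = c(0L, 500L), end = c(100L, 600L),
                     dependency = "mut", n_windows = 2L, min_p = 1e-5)
  tes <- data.frame(chrom = "chr1", start = 50L, end = 200L)
  kept <- require_te_overlap(dmrs, tes)
  expect_equal(kept$start, 0L)
  expect_true(all(kept$te_overlap))
  expect_warning(none <- require_te_overlap(dmrs, tes[integer(0), ]),
                 "empty TE annotation")
  expect_equal(nrow(none), 0)
})

test_that("DMR anchoring separates nucleosome dyads from free DMR centers", {
  calls <- data.frame(chrom = "chr1",
                      dyad = c(100L, 1000L, 2000L),
                      group = c("1", "3", "1"))
  dmrs <- data.frame(chrom = "chr1",
                     start = c(173L, 995L, 5000L),
                     end = c(223L, 1045L, 5100L))
  out <- anchor_dmr_analysis(dmrs, calls)
  # group-1 dyad at 100 overlaps DMR [173,223) by exactly 1 bp (span ends 174)
  expect_equal(out$nucleosome_anchors$pos, 100L)
  # DMR at 995 overlaps only a group-3 nucleosome: in neither set
  # DMR at 5000 overlaps nothing: its centre goes to set B
  expect_equal(out$dmr_center_anchors$pos, 5050L)
})
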