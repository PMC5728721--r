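# Shared fixtures and small oracles for the test suite. All data are built
# in code; nothing is read from disk except files the tests write themselves.

# Compact config for fast unit tests.
small_config <- function(seed = 1, size = 5e4, ...) {
  sim_config(seed = seed, chrom_sizes = c(chr1 = size), ...)
}

# Adjusted Rand index between two labelings (closed-form from the pair
# contingency table); independent of any clustering code under test.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Brute-force one-sided (mutant-lower) exact test by enumeration of the
# hypergeometric pmf from choose() ratios; oracle for the phyper-based
# implementation.
enum_one_sided_p <- function(meth_wt, unmeth_wt, meth_mut, unmeth_mut) {
  white <- meth_wt + meth_mut      # methylated reads
  black <- unmeth_wt + unmeth_mut  # unmethylated reads
  k <- meth_mut + unmeth_mut       # mutant column total
  x <- 0:meth_mut
  sum(choose(white, x) * choose(black, k - x)) / choose(white + black, k)
}

# Fragment set with every fragment length 147 and midpoint at `mid`.
delta_fragments <- function(mid, n = 1000, chrom = "chr1") {
  data.frame(chrom = chrom, start = mid - 73L, end = mid + 74L)[rep(1, n), ]
}

# Cytosine records from a compact spec: data.frame(pos, meth, total, ...).
make_records <- function(pos, meth, total, context = "CG", strand = "+",
                         chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = context, count_meth = as.integer(meth),
             count_total = as.integer(total), stringsAsFactors = FALSE)
}

# Window-count row in the layout call_dmrs() expects.
make_window <- function(start, wt, mut, other, total = 100L, chrom = "chr1",
                        window = 50L) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + window),
             meth_WT = wt, total_WT = total,
             meth_mut = mut, total_mut = total,
             meth_other = other, total_other = total,
             stringsAsFactors = FALSE)
}
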