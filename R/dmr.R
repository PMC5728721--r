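# Windowed differentially-methylated-region calling with a one-sided exact
# test and a mutant-exclusivity filter.

#' Pool methylation counts into fixed windows
#'
#' Tiles each chromosome with non-overlapping windows (step = width, phase
#' anchored at position 0) and pools methylated/total counts of one context
#' per genotype. Only windows covered in at least one genotype are returned;
#' genotypes without coverage in a window get zero counts there.
#'
#' @param records_list Named list of cytosine record data frames, one per
#'   genotype.
#' @param window Window width in bp.
#' @param context Context to pool (default CHH, the context in which the
#'   DRM1/2- and CMT2-dependent regions are defined).
#' @return Data frame: chrom, start, end, then `meth_<genotype>` and
#'   `total_<genotype>` columns; attributes `window`, `context`.
#' @export
window_counts <- function(records_list, window = 50L, context = "CHH") {
  if (window <= 0) stop("invalid parameter: window must be > 0")
  if (is.null(names(records_list)) || any(names(records_list) == "")) {
    stop("records_list must be a named list (one element per genotype)")
  }
  per_geno <- lapply(records_list, function(rec) {
    .check_records(rec)
    rec <- rec[rec$context == context, , drop = FALSE]
    if (nrow(rec) == 0) {
      return(data.frame(chrom = character(0), start = integer(0),
                        meth = numeric(0), total = numeric(0),
                        stringsAsFactors = FALSE))
    }
    w <- rec$pos %/% window
    key <- paste(rec$chrom, w, sep = "\r")
    m <- rowsum(cbind(rec$count_meth, rec$count_total), key)
    parts <- strsplit(rownames(m), "\r", fixed = TRUE)
    data.frame(chrom = vapply(parts, `[[`, character(1), 1),
               start = as.integer(vapply(parts, `[[`, character(1), 2)) *
                 window,
               meth = m[, 1], total = m[, 2], stringsAsFactors = FALSE)
  })
  keys <- unique(do.call(rbind, lapply(per_geno, function(d) {
    d[, c("chrom", "start")]
  })))
  keys <- keys[order(keys$chrom, keys$start), , drop = FALSE]
  out <- data.frame(chrom = keys$chrom, start = keys$start,
                    end = keys$start + window, stringsAsFactors = FALSE)
  for (g in names(per_geno)) {
    d <- per_geno[[g]]
    i <- match(paste(keys$chrom, keys$start), paste(d$chrom, d$start))
    out[[paste0("meth_", g)]] <- ifelse(is.na(i), 0, d$meth[i])
    out[[paste0("total_", g)]] <- ifelse(is.na(i), 0, d$total[i])
  }
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "context") <- context
  out
}

#' One-sided exact test for methylation loss
#'
#' Exact hypergeometric tail probability that the mutant methylated count is
#' as low as or lower than observed, conditional on the margins of the 2x2
#' table (methylated/unmethylated x WT/mutant). This is the one-sided
#' (mutant-lower) Fisher exact test, computed via the log-gamma
#' hypergeometric CDF, numerically stable for large counts. Vectorised.
#'
#' @param meth_wt,unmeth_wt,meth_mut,unmeth_mut Non-negative counts.
#' @return P-value(s) in `[0, 1]`.
#' @examples
#' fisher_exact_one_sided(5, 0, 0, 5)  # 1/choose(10, 5)
#' @export
fisher_exact_one_sided <- function(meth_wt, unmeth_wt, meth_mut, unmeth_mut) {
  n <- max(length(meth_wt), length(unmeth_wt), length(meth_mut),
           length(unmeth_mut))
  meth_wt <- rep_len(meth_wt, n)
  unmeth_wt <- rep_len(unmeth_wt, n)
  meth_mut <- rep_len(meth_mut, n)
  unmeth_mut <- rep_len(unmeth_mut, n)
  if (any(c(meth_wt, unmeth_wt, meth_mut, unmeth_mut) < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  grand <- meth_wt + unmeth_wt + meth_mut + unmeth_mut
  if (any(grand == 0, na.rm = TRUE)) {
    stop("exact test undefined for a zero grand total")
  }
  # X ~ Hypergeometric(white = all methylated, black = all unmethylated,
  # drawn = mutant column); p = P(X <= observed mutant methylated).
  phyper(meth_mut, meth_wt + meth_mut, unmeth_wt + unmeth_mut,
         meth_mut + unmeth_mut)
}

#' Call genotype-exclusive hypomethylated DMRs
#'
#' Implements the windowed DMR definition: a window is a candidate iff its
#' WT methylation is at least `min_wt`, its *relative* loss in the focal
#' mutant `(f_wt - f_mut)/f_wt` exceeds `min_loss`, and the one-sided exact
#' test for a decrease is significant at `alpha`. Windows that also satisfy
#' the loss criteria against the other mutant are discarded, keeping only
#' regions exclusive to the focal genotype. Surviving book-ended windows
#' (gap exactly 0) are merged into DMRs.
#'
#' @param windows Window count table from [window_counts()].
#' @param wt_label,mut_label,other_mut_label Genotype column labels; counts
#'   for all three must be present (exclusivity cannot be evaluated
#'   otherwise).
#' @param min_wt Minimum WT methylation fraction (inclusive).
#' @param min_loss Minimum relative loss (exclusive).
#' @param alpha Significance threshold on the raw one-sided p-value.
#' @param exclusivity `"full"` (default) applies all three criteria against
#'   the other mutant; `"significance"` discards on the other mutant's
#'   p-value alone.
#' @param p_adjust `"none"` (default, raw p-values) or `"BH"`.
#' @return Data frame of merged DMRs: chrom, start, end, dependency
#'   (`mut_label`), n_windows, min_p; the per-window diagnostics (with the
#'   DMR index of each passing window) are attached as attribute
#'   `window_table`.
#' @export
call_dmrs <- function(windows, wt_label = "WT", mut_label,
                      other_mut_label, min_wt = 0.10, min_loss = 0.30,
                      alpha = 0.01,
                      exclusivity = c("full", "significance"),
                      p_adjust = c("none", "BH")) {
  exclusivity <- match.arg(exclusivity)
  p_adjust <- match.arg(p_adjust)
  need <- c(paste0(c("meth_", "total_"), rep(c(wt_label, mut_label,
                                               other_mut_label), each = 2)))
  miss <- setdiff(need, names(windows))
  if (length(miss) > 0) {
    stop("window table lacks counts required for exclusivity: ",
         paste(miss, collapse = ", "))
  }
  col <- function(kind, g) windows[[paste0(kind, "_", g)]]
  f <- function(g) {
    tot <- col("total", g)
    ifelse(tot > 0, col("meth", g) / tot, NA_real_)
  }
  f_wt <- f(wt_label)
  loss_pass <- function(g) {
    f_g <- f(g)
    ok <- !is.na(f_wt) & !is.na(f_g) & f_wt >= min_wt &
      (f_wt - f_g) / f_wt > min_loss
    ok & col("total", g) > 0
  }
  pval <- function(g) {
    tot_wt <- col("total", wt_label)
    tot_g <- col("total", g)
    p <- rep(NA_real_, nrow(windows))
    ok <- tot_wt + tot_g > 0
    p[ok] <- fisher_exact_one_sided(
      col("meth", wt_label)[ok], tot_wt[ok] - col("meth", wt_label)[ok],
      col("meth", g)[ok], tot_g[ok] - col("meth", g)[ok])
    if (p_adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    p
  }
  p_mut <- pval(mut_label)
  p_other <- pval(other_mut_label)
  pass_mut <- loss_pass(mut_label) & !is.na(p_mut) & p_mut < alpha
  pass_other <- if (exclusivity == "full") {
    loss_pass(other_mut_label) & !is.na(p_other) & p_other < alpha
  } else {
    !is.na(p_other) & p_other < alpha
  }
  keep <- pass_mut & !pass_other
  kept <- windows[keep, c("chrom", "start", "end"), drop = FALSE]
  kept$p <- p_mut[keep]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), dependency = character(0),
                      n_windows = integer(0), min_p = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(kept) == 0) {
    attr(empty, "window_table") <- kept
    return(empty)
  }
  kept <- kept[order(kept$chrom, kept$start), , drop = FALSE]
  new_run <- c(TRUE, kept$chrom[-1] != kept$chrom[-nrow(kept)] |
                 kept$start[-1] != kept$end[-nrow(kept)])
  kept$dmr <- cumsum(new_run)
  dmrs <- data.frame(
    chrom = tapply(kept$chrom, kept$dmr, `[`, 1),
    start = as.integer(tapply(kept$start, kept$dmr, min)),
    end = as.integer(tapply(kept$end, kept$dmr, max)),
    dependency = mut_label,
    n_windows = as.integer(tapply(kept$dmr, kept$dmr, length)),
    min_p = as.numeric(tapply(kept$p, kept$dmr, min)),
    stringsAsFactors = FALSE
  )
  rownames(dmrs) <- NULL
  attr(dmrs, "window_table") <- kept
  dmrs
}

#' Require DMRs to overlap an annotated TE
#'
#' Retains DMRs overlapping at least one TE interval by >= 1 bp and flags
#' them. An empty TE annotation yields an empty result with a warning.
#'
#' @param dmrs DMR data frame from [call_dmrs()].
#' @param te_annotation Data frame of TE intervals (chrom, start, end).
#' @return The retained DMRs with a `te_overlap` column.
#' @export
require_te_overlap <- function(dmrs, te_annotation) {
  if (nrow(te_annotation) == 0) {
    warning("empty TE annotation: no DMR can satisfy the TE-overlap filter")
    out <- dmrs[integer(0), , drop = FALSE]
    out$te_overlap <- logical(0)
    return(out)
  }
  if (nrow(dmrs) == 0) {
    dmrs$te_overlap <- logical(0)
    return(dmrs)
  }
  hits <- GenomicRanges::findOverlaps(
    .gr0(dmrs$chrom, dmrs$start, dmrs$end),
    .gr0(te_annotation$chrom, te_annotation$start, te_annotation$end))
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- dmrs[keep, , drop = FALSE]
  out$te_overlap <- TRUE
  rownames(out) <- NULL
  out
}

#' Anchor sets for DMR-centred methylation analysis
#'
#' Splits a DMR set into the two anchor sets used for nucleosome-aware DMR
#' profiles: (A) dyads of group-1 (well-positioned) nucleosomes whose 147 bp
#' span overlaps a DMR by at least 1 bp, and (B) arithmetic centres of DMRs
#' that do not overlap any group 1--4 nucleosome span.
#'
#' @param dmrs DMR data frame.
#' @param calls Genotype-specific nucleosome calls from
#'   [classify_positioning()].
#' @param nucleosome_length Span used around each dyad (bp).
#' @return List with `nucleosome_anchors` and `dmr_center_anchors`, both
#'   data frames with chrom, pos.
#' @export
anchor_dmr_analysis <- function(dmrs, calls, nucleosome_length = 147L) {
  half <- (nucleosome_length - 1L) %/% 2L
  gr_dmr <- if (nrow(dmrs) > 0) .gr0(dmrs$chrom, dmrs$start, dmrs$end)
  g1 <- calls[calls$group == "1", , drop = FALSE]
  set_a <- data.frame(chrom = character(0), pos = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(g1) > 0 && nrow(dmrs) > 0) {
    gr_g1 <- .gr0(g1$chrom, g1$dyad - half, g1$dyad - half + nucleosome_length)
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr_g1, gr_dmr)))
    set_a <- data.frame(chrom = g1$chrom[hit], pos = g1$dyad[hit],
                        stringsAsFactors = FALSE)
  }
  set_b <- data.frame(chrom = character(0), pos = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(dmrs) > 0) {
    g14 <- calls[calls$group %in% c("1", "2", "3", "4"), , drop = FALSE]
    disjoint <- rep(TRUE, nrow(dmrs))
    if (nrow(g14) > 0) {
      gr_g14 <- .gr0(g14$chrom, g14$dyad - half,
                     g14$dyad - half + nucleosome_length)
      hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr_dmr, gr_g14)))
      disjoint[hit] <- FALSE
    }
    set_b <- data.frame(chrom = dmrs$chrom[disjoint],
                        pos = (dmrs$start[disjoint] + dmrs$end[disjoint]) %/%
                          2L,
                        stringsAsFactors = FALSE)
  }
  list(nucleosome_anchors = set_a, dmr_center_anchors = set_b)
}
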