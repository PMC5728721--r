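# Nucleosome peak calling, width filtering, replicate-based positioning
# reliability classification, dyad computation and cross-genotype matching.

#' Filter MNase fragments by length
#'
#' Retains mononucleosome-sized fragments with
#' `min_exclusive < length < max_exclusive` (both bounds exclusive, matching
#' the 120--180 bp, not inclusive, mononucleosome selection).
#'
#' @param fragments Data frame with chrom, start, end (0-based half-open).
#' @param min_exclusive,max_exclusive Exclusive length bounds in bp.
#' @return The retained fragments.
#' @export
filter_fragments <- function(fragments, min_exclusive = 120L,
                             max_exclusive = 180L) {
  len <- fragments$end - fragments$start
  fragments[len > min_exclusive & len < max_exclusive, , drop = FALSE]
}

#' Call nucleosome peaks from fragment midpoint density
#'
#' A deliberately simple kernel-density peak caller standing in for external
#' nucleosome-position software: fragment midpoints are smoothed with a
#' Gaussian kernel, local maxima of the smoothed density become peak summits,
#' and peak bounds are placed at the half-maximum crossing or the flanking
#' minimum, whichever is encountered first walking out from the summit.
#' Externally called peak BED files can be substituted anywhere a peak set is
#' consumed (see [read_bed()]).
#'
#' @param fragments Fragment data frame (one replicate).
#' @param bandwidth Gaussian kernel sd in bp.
#' @param min_fragments Minimum local fragment support for a summit; summits
#'   whose smoothed density falls below
#'   `min_fragments * dnorm(0, sd = bandwidth) / 2` are discarded.
#' @return Peak data frame: chrom, start, end (0-based half-open), summit
#'   (bp), height (smoothed density at the summit).
#' @export
call_peaks <- function(fragments, bandwidth = 15, min_fragments = 3) {
  if (bandwidth <= 0) stop("invalid parameter: bandwidth must be > 0")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      height = numeric(0), stringsAsFactors = FALSE)
  if (is.null(fragments) || nrow(fragments) == 0) return(empty)
  h <- as.integer(ceiling(4 * bandwidth))
  kern <- dnorm(seq(-h, h), sd = bandwidth)
  thr <- min_fragments * dnorm(0, sd = bandwidth) / 2
  out <- lapply(split(fragments, fragments$chrom), function(fr) {
    mids <- (fr$start + fr$end) %/% 2L
    lo <- min(mids)
    hi <- max(mids)
    counts <- tabulate(mids - lo + 1L, nbins = hi - lo + 1L)
    # extend the domain by one kernel half-width so peaks at the range
    # edges keep their full Gaussian footprint; dens[i] is the smoothed
    # density at position lo - h + i - 1
    padded <- c(numeric(2L * h), counts, numeric(2L * h))
    dens <- convolve(padded, kern, type = "filter")
    lo <- lo - h
    n <- length(dens)
    if (n < 3) return(NULL)
    up <- c(FALSE, dens[-1] > dens[-n])
    down <- c(dens[-n] >= dens[-1], FALSE)
    summits <- which(up & down & dens >= thr)
    if (length(summits) == 0) return(NULL)
    peaks <- lapply(summits, function(s) {
      half <- dens[s] / 2
      jl <- s
      while (jl > 1 && dens[jl - 1] <= dens[jl] && dens[jl - 1] >= half) {
        jl <- jl - 1L
      }
      jr <- s
      while (jr < n && dens[jr + 1] <= dens[jr] && dens[jr + 1] >= half) {
        jr <- jr + 1L
      }
      c(jl, jr, s)
    })
    pk <- do.call(rbind, peaks)
    data.frame(chrom = fr$chrom[1],
               start = lo + pk[, 1] - 1L,
               end = lo + pk[, 2],            # half-open right bound
               summit = lo + pk[, 3] - 1L,
               height = dens[pk[, 3]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Remove peaks wider than a maximum width
#'
#' Retains peaks with width `<= max_width` bp ("wider than 140 bp" removed,
#' so a 140 bp peak is kept).
#'
#' @param peaks Peak data frame.
#' @param max_width Maximum retained width in bp.
#' @return The retained peaks.
#' @export
filter_peak_width <- function(peaks, max_width = 140L) {
  peaks[(peaks$end - peaks$start) <= max_width, , drop = FALSE]
}

#' Reciprocal overlap of two intervals
#'
#' For two intervals on the same chromosome, returns the pair of fractional
#' overlaps `(overlap/width(a), overlap/width(b))`. The reciprocal overlap
#' used for positioning classification is the minimum of the pair: both
#' directions must pass a threshold for the peaks to "overlap reciprocally".
#'
#' @param a,b Lists or single-row data frames with chrom, start, end.
#' @return Numeric length-2 vector of fractional overlaps.
#' @export
reciprocal_overlap <- function(a, b) {
  if (a$chrom != b$chrom) {
    stop("reciprocal overlap is undefined across chromosomes")
  }
  ovl <- max(0, min(a$end, b$end) - max(a$start, b$start))
  c(ovl / (a$end - a$start), ovl / (b$end - b$start))
}

# Group from the best reciprocal-overlap fraction; half-open at the top:
# (0.75, 1] -> 1, (0.50, 0.75] -> 2, (0.25, 0.50] -> 3, (0, 0.25] -> 4,
# 0 -> other. Boundary values go to the lower (less well-positioned) group,
# reading "more than 75%" strictly.
.overlap_group <- function(ro) {
  ifelse(ro > 0.75, "1",
         ifelse(ro > 0.50, "2",
                ifelse(ro > 0.25, "3",
                       ifelse(ro > 0, "4", "other"))))
}

#' Compute a presumptive dyad from overlapping peaks
#'
#' The dyad is the arithmetic mean of the combined 5'- and 3'-most ends of
#' the member peaks, i.e. the midpoint of their union span, rounded half-up.
#' `method = "endpoint_mean"` instead averages all member endpoints, the
#' alternative reading for asymmetric overlaps.
#'
#' @param members Data frame of member peaks (chrom, start, end).
#' @param method `"union_span"` (default) or `"endpoint_mean"`.
#' @return Integer dyad position (bp, 0-based).
#' @export
compute_dyad <- function(members, method = c("union_span", "endpoint_mean")) {
  method <- match.arg(method)
  if (is.null(members) || nrow(members) == 0) {
    stop("cannot compute a dyad from an empty member set")
  }
  if (method == "union_span") {
    .round_half_up((min(members$start) + max(members$end)) / 2)
  } else {
    .round_half_up(mean(c(members$start, members$end)))
  }
}

#' Classify nucleosome positioning reliability between two replicates
#'
#' Each width-filtered replicate-1 peak is assigned its best reciprocal
#' overlap (minimum of the two fractional overlaps, maximised over
#' replicate-2 peaks) and classified in 25% increments: group 1 for
#' reciprocal overlap > 0.75 (well-positioned), then 2, 3, 4, and "other"
#' for peaks with no replicate-2 overlap. The presumptive dyad of each call
#' is computed from the replicate-1 peak together with *all* replicate-2
#' peaks it overlaps (multiple overlaps allowed).
#'
#' @param peaks_rep1,peaks_rep2 Width-filtered peak data frames.
#' @param dyad_method Passed to [compute_dyad()].
#' @return Data frame of nucleosome calls: chrom, dyad, group (character,
#'   "1".."4"/"other"), start, end (union span), best_ro, n_members.
#' @export
classify_positioning <- function(peaks_rep1, peaks_rep2,
                                 dyad_method = c("union_span",
                                                 "endpoint_mean")) {
  dyad_method <- match.arg(dyad_method)
  if (nrow(peaks_rep1) == 0) {
    return(data.frame(chrom = character(0), dyad = integer(0),
                      group = character(0), start = integer(0),
                      end = integer(0), best_ro = numeric(0),
                      n_members = integer(0), stringsAsFactors = FALSE))
  }
  if (is.unsorted(order(peaks_rep1$chrom, peaks_rep1$start))) {
    message("classify_positioning: sorting replicate-1 peaks")
  }
  peaks_rep1 <- peaks_rep1[order(peaks_rep1$chrom, peaks_rep1$start), ,
                           drop = FALSE]
  gr1 <- .gr0(peaks_rep1$chrom, peaks_rep1$start, peaks_rep1$end)
  w1 <- peaks_rep1$end - peaks_rep1$start
  best_ro <- numeric(nrow(peaks_rep1))
  span_start <- peaks_rep1$start
  span_end <- peaks_rep1$end
  n_members <- rep(1L, nrow(peaks_rep1))
  if (nrow(peaks_rep2) > 0) {
    gr2 <- .gr0(peaks_rep2$chrom, peaks_rep2$start, peaks_rep2$end)
    w2 <- peaks_rep2$end - peaks_rep2$start
    hits <- GenomicRanges::findOverlaps(gr1, gr2)
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ovl <- pmin(peaks_rep1$end[q], peaks_rep2$end[s]) -
        pmax(peaks_rep1$start[q], peaks_rep2$start[s])
      ro <- pmin(ovl / w1[q], ovl / w2[s])
      best_ro[] <- 0
      agg <- tapply(ro, q, max)
      best_ro[as.integer(names(agg))] <- agg
      mn <- tapply(peaks_rep2$start[s], q, min)
      mx <- tapply(peaks_rep2$end[s], q, max)
      idx <- as.integer(names(mn))
      span_start[idx] <- pmin(span_start[idx], as.integer(mn))
      span_end[idx] <- pmax(span_end[idx], as.integer(mx))
      cnt <- tapply(s, q, length)
      n_members[as.integer(names(cnt))] <- 1L + as.integer(cnt)
    }
  }
  dyad <- if (dyad_method == "union_span") {
    .round_half_up((span_start + span_end) / 2)
  } else {
    # endpoint mean needs the full member endpoint multiset; recompute per call
    vapply(seq_len(nrow(peaks_rep1)), function(i) {
      mem <- peaks_rep1[i, c("chrom", "start", "end")]
      if (nrow(peaks_rep2) > 0) {
        sel <- peaks_rep2$chrom == peaks_rep1$chrom[i] &
          peaks_rep2$start < peaks_rep1$end[i] &
          peaks_rep2$end > peaks_rep1$start[i]
        mem <- rbind(mem, peaks_rep2[sel, c("chrom", "start", "end")])
      }
      compute_dyad(mem, method = "endpoint_mean")
    }, integer(1))
  }
  data.frame(chrom = peaks_rep1$chrom, dyad = dyad,
             group = .overlap_group(best_ro),
             start = span_start, end = span_end,
             best_ro = best_ro, n_members = n_members,
             stringsAsFactors = FALSE)
}

#' Match nucleosomes shared between two genotypes
#'
#' Pairs calls whose dyads lie within `max_dist` bp (inclusive) of each
#' other. Matching is greedy by increasing dyad distance (ties broken toward
#' the leftmost dyad), and each call is matched at most once.
#'
#' @param calls_a,calls_b Nucleosome call data frames (chrom, dyad).
#' @param max_dist Maximum dyad distance in bp (inclusive).
#' @return Data frame of matched pairs: chrom, idx_a, idx_b (row indices into
#'   the inputs), dyad_a, dyad_b, dist.
#' @export
shared_nucleosomes <- function(calls_a, calls_b, max_dist = 20L) {
  empty <- data.frame(chrom = character(0), idx_a = integer(0),
                      idx_b = integer(0), dyad_a = integer(0),
                      dyad_b = integer(0), dist = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(calls_a) == 0 || nrow(calls_b) == 0) return(empty)
  gr_a <- .gr0(calls_a$chrom, calls_a$dyad, calls_a$dyad + 1L)
  gr_b <- .gr0(calls_b$chrom, calls_b$dyad - max_dist,
               calls_b$dyad + max_dist + 1L)
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b)
  if (length(hits) == 0) return(empty)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  d <- abs(calls_a$dyad[q] - calls_b$dyad[s])
  ord <- order(d, calls_a$dyad[q], calls_b$dyad[s])
  used_a <- logical(nrow(calls_a))
  used_b <- logical(nrow(calls_b))
  keep <- logical(length(ord))
  for (i in ord) {
    if (!used_a[q[i]] && !used_b[s[i]]) {
      used_a[q[i]] <- TRUE
      used_b[s[i]] <- TRUE
      keep[i] <- TRUE
    }
  }
  data.frame(chrom = calls_a$chrom[q[keep]], idx_a = q[keep],
             idx_b = s[keep], dyad_a = calls_a$dyad[q[keep]],
             dyad_b = calls_b$dyad[s[keep]], dist = d[keep],
             stringsAsFactors = FALSE)
}

#' Label genic nucleosomes as exonic or intronic
#'
#' A nucleosome (147 bp span centred on the dyad) is exonic if it overlaps
#' any exon by at least 1 bp, and intronic only if it lies entirely inside a
#' single intron. Nucleosomes matching neither rule are left unlabelled (NA).
#'
#' @param calls Nucleosome call data frame (chrom, dyad).
#' @param gene_parts Data frame of exon/intron segments (chrom, start, end,
#'   type), e.g. the `gene_parts` element of a [generate_layout()] result.
#' @param nucleosome_length Span used around each dyad (bp).
#' @return Character vector of labels ("exonic", "intronic", NA) parallel to
#'   `calls`.
#' @export
classify_genic_nucleosomes <- function(calls, gene_parts,
                                       nucleosome_length = 147L) {
  half <- (nucleosome_length - 1L) %/% 2L
  start <- calls$dyad - half
  end <- start + nucleosome_length
  lab <- rep(NA_character_, nrow(calls))
  if (nrow(calls) == 0 || nrow(gene_parts) == 0) return(lab)
  gr_n <- .gr0(calls$chrom, start, end)
  ex <- gene_parts[gene_parts$type == "exon", , drop = FALSE]
  if (nrow(ex) > 0) {
    hits <- GenomicRanges::findOverlaps(gr_n, .gr0(ex$chrom, ex$start, ex$end))
    lab[unique(S4Vectors::queryHits(hits))] <- "exonic"
  }
  intr <- gene_parts[gene_parts$type == "intron", , drop = FALSE]
  if (nrow(intr) > 0) {
    hits <- GenomicRanges::findOverlaps(
      gr_n, .gr0(intr$chrom, intr$start, intr$end), type = "within")
    within <- unique(S4Vectors::queryHits(hits))
    lab[setdiff(within, which(lab == "exonic"))] <- "intronic"
  }
  lab
}

#' Filter TEs to the heterochromatic compartment
#'
#' Retains transposable elements with CG methylation above 5%, an H3K9me2
#' enrichment in the upper two quintiles of the supplied scores, and length
#' strictly greater than `min_len` bp.
#'
#' @param te_intervals Data frame of TEs (chrom, start, end, optionally
#'   feature_id).
#' @param mcg_fraction Numeric vector of per-TE CG methylation fractions.
#' @param h3k9me2_score Numeric vector of per-TE H3K9me2 enrichment scores.
#' @param min_len Minimum length in bp (exclusive).
#' @param min_mcg Minimum CG methylation fraction (exclusive).
#' @return The retained TE intervals.
#' @export
filter_heterochromatic_tes <- function(te_intervals, mcg_fraction,
                                       h3k9me2_score, min_len = 30L,
                                       min_mcg = 0.05) {
  n <- nrow(te_intervals)
  if (length(mcg_fraction) != n || length(h3k9me2_score) != n) {
    stop("scores must be supplied for every TE")
  }
  bad <- which(is.na(mcg_fraction) | is.na(h3k9me2_score))
  if (length(bad) > 0) {
    ids <- if ("feature_id" %in% names(te_intervals)) {
      te_intervals$feature_id[bad]
    } else {
      as.character(bad)
    }
    stop("missing mCG or H3K9me2 score for TE(s): ",
         paste(head(ids, 5), collapse = ", "))
  }
  quint <- ceiling(5 * rank(h3k9me2_score, ties.method = "average") / n)
  keep <- mcg_fraction > min_mcg & quint >= 4 &
    (te_intervals$end - te_intervals$start) > min_len
  te_intervals[keep, , drop = FALSE]
}
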