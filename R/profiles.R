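# Anchor-centred methylation metaprofiles, difference profiles and
# RPM-normalised coverage tracks.

#' Coverage-weighted methylation over an interval
#'
#' Pooled methylation fraction `sum(count_meth) / sum(count_total)` over the
#' records of one context falling in `[start, end)`. Returns `NA` when no
#' covered cytosine lies in the interval.
#'
#' @param records Cytosine record data frame.
#' @param chrom Chromosome name.
#' @param start,end Interval bounds, 0-based half-open.
#' @param context Optional context filter (`"CG"`, `"CHG"`, `"CHH"`).
#' @return A single methylation fraction, or `NA_real_`.
#' @export
weighted_methylation <- function(records, chrom, start, end, context = NULL) {
  .check_records(records)
  if (end <= start) stop("interval must be non-empty")
  sel <- records$chrom == chrom & records$pos >= start & records$pos < end
  if (!is.null(context)) sel <- sel & records$context == context
  tot <- sum(records$count_total[sel])
  if (tot == 0) return(NA_real_)
  sum(records$count_meth[sel]) / tot
}

# Map (record, anchor) pairs within +-flank to relative offsets. Returns a
# data.frame with record index, anchor index and offset, or NULL.
.anchor_offsets <- function(records, anchors, flank, oriented) {
  pieces <- lapply(unique(anchors$chrom), function(ch) {
    ri <- which(records$chrom == ch)
    ai <- which(anchors$chrom == ch)
    if (length(ri) == 0 || length(ai) == 0) return(NULL)
    ir_r <- IRanges::IRanges(records$pos[ri] + 1L, width = 1L)
    ir_a <- IRanges::IRanges(anchors$pos[ai] - flank + 1L,
                             anchors$pos[ai] + flank)
    hits <- IRanges::findOverlaps(ir_r, ir_a)
    if (length(hits) == 0) return(NULL)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    off <- records$pos[ri][q] - anchors$pos[ai][s]
    if (oriented && "strand" %in% names(anchors)) {
      neg <- anchors$strand[ai][s] == "-"
      off[neg] <- -off[neg]
    }
    data.frame(rec = ri[q], anc = ai[s], off = off)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) return(NULL)
  out <- do.call(rbind, pieces)
  out[out$off >= -flank & out$off < flank, , drop = FALSE]
}

#' Methylation metaprofile around a set of anchors
#'
#' Pools methylated/total counts of one context into fixed-width bins of
#' offsets relative to each anchor (dyads, TSSs, binding sites, ...), then
#' returns the pooled per-bin fraction. With `oriented = TRUE`, offsets are
#' mirrored for anchors on the minus strand so that profiles are in the
#' feature's own 5'->3' frame. The default weighting pools raw counts across
#' cytosines and anchors (coverage-weighted); `weighting = "per_cytosine"`
#' averages per-cytosine fractions instead.
#'
#' @param records Cytosine record data frame.
#' @param anchors Data frame with chrom, pos (anchor point, 0-based) and
#'   optionally strand.
#' @param flank Half-width of the profiled window in bp; a multiple of `bin`.
#' @param bin Bin width in bp.
#' @param context Context to profile (`"CG"`, `"CHG"`, `"CHH"`).
#' @param oriented Mirror offsets for minus-strand anchors.
#' @param weighting `"pooled"` (default) or `"per_cytosine"`.
#' @return Data frame of class `methylation_profile`: offset (bin left edge,
#'   bp relative to anchor), n_meth, n_total, fraction (`NA` where
#'   uncovered); attributes `context`, `bin`, `flank`, `n_anchors`.
#' @export
profile_around_anchors <- function(records, anchors, flank = 500L, bin = 1L,
                                   context = "CG", oriented = FALSE,
                                   weighting = c("pooled", "per_cytosine")) {
  weighting <- match.arg(weighting)
  .check_records(records)
  if (bin <= 0) stop("invalid parameter: bin must be > 0")
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  records <- records[records$context == context, , drop = FALSE]
  offsets <- seq(-flank, flank - bin, by = bin)
  prof <- data.frame(offset = offsets,
                     n_meth = 0, n_total = 0,
                     fraction = NA_real_)
  pairs <- if (nrow(anchors) > 0) {
    .anchor_offsets(records, anchors, flank, oriented)
  } else {
    NULL
  }
  if (!is.null(pairs) && nrow(pairs) > 0) {
    b <- pairs$off %/% bin
    key <- factor(b, levels = offsets %/% bin)
    prof$n_meth <- as.numeric(tapply(records$count_meth[pairs$rec], key, sum,
                                     default = 0))
    prof$n_total <- as.numeric(tapply(records$count_total[pairs$rec], key,
                                      sum, default = 0))
    if (weighting == "pooled") {
      prof$fraction <- ifelse(prof$n_total > 0,
                              prof$n_meth / prof$n_total, NA_real_)
    } else {
      fr <- records$count_meth[pairs$rec] / records$count_total[pairs$rec]
      prof$fraction <- as.numeric(tapply(fr, key, mean, default = NA_real_))
    }
  }
  attr(prof, "context") <- context
  attr(prof, "bin") <- bin
  attr(prof, "flank") <- flank
  attr(prof, "n_anchors") <- nrow(anchors)
  class(prof) <- c("methylation_profile", "data.frame")
  prof
}

#' Difference between two methylation profiles
#'
#' Per-bin `fraction_mut - fraction_wt`; bins where either profile is
#' uncovered are `NA`. The profiles must share bins and context.
#'
#' @param profile_mut,profile_wt Profiles from [profile_around_anchors()].
#' @return Data frame: offset, delta.
#' @export
difference_profile <- function(profile_mut, profile_wt) {
  if (!identical(profile_mut$offset, profile_wt$offset)) {
    stop("profiles have mismatched bins")
  }
  cm <- attr(profile_mut, "context")
  cw <- attr(profile_wt, "context")
  if (!is.null(cm) && !is.null(cw) && !identical(cm, cw)) {
    stop("profiles have mismatched contexts: ", cm, " vs ", cw)
  }
  data.frame(offset = profile_mut$offset,
             delta = profile_mut$fraction - profile_wt$fraction)
}

#' RPM-normalised fragment coverage track
#'
#' Bins fragment midpoints and scales counts to reads per million mapped:
#' `count * 1e6 / total_mapped`.
#'
#' @param fragments Fragment data frame.
#' @param total_mapped Total mapped read (fragment) count of the library.
#' @param bin Bin width in bp.
#' @return Data frame: chrom, start, end, count, rpm.
#' @export
rpm_normalize <- function(fragments, total_mapped, bin = 10L) {
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  if (bin <= 0) stop("invalid parameter: bin must be > 0")
  if (nrow(fragments) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), count = integer(0),
                      rpm = numeric(0), stringsAsFactors = FALSE))
  }
  mids <- (fragments$start + fragments$end) %/% 2L
  out <- lapply(split(mids, fragments$chrom), function(m) {
    b <- m %/% bin
    lo <- min(b)
    cnt <- tabulate(b - lo + 1L, nbins = max(b) - lo + 1L)
    data.frame(start = (lo + seq_along(cnt) - 1L) * bin,
               count = cnt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Map(function(ch, d) {
    data.frame(chrom = ch, start = d$start, end = d$start + bin,
               count = d$count, rpm = d$count * 1e6 / total_mapped,
               stringsAsFactors = FALSE)
  }, names(out), out))
  rownames(out) <- NULL
  out
}

#' Metaprofiles stratified by gene-expression decile
#'
#' Partitions gene anchors by their expression decile and computes one
#' profile per decile. Genes missing from the decile table are excluded with
#' a warning reporting how many were dropped; empty deciles are absent from
#' the output.
#'
#' @param records Cytosine record data frame.
#' @param gene_anchors Data frame with gene_id, chrom, pos and optionally
#'   strand.
#' @param decile_table Data frame with gene_id and decile (1--10).
#' @param ... Passed to [profile_around_anchors()].
#' @return Named list of profiles, one per non-empty decile.
#' @export
profile_by_expression_decile <- function(records, gene_anchors, decile_table,
                                         ...) {
  dec <- decile_table$decile[match(gene_anchors$gene_id,
                                   decile_table$gene_id)]
  missing <- is.na(dec)
  if (any(missing)) {
    warning(sum(missing), " gene(s) missing from the decile table; excluded")
  }
  anchors <- gene_anchors[!missing, , drop = FALSE]
  dec <- dec[!missing]
  out <- lapply(split(anchors, dec), profile_around_anchors,
                records = records, ...)
  if (length(out) < 10) {
    message("deciles absent from output: ",
            paste(setdiff(as.character(1:10), names(out)), collapse = ", "))
  }
  out
}
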