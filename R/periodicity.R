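# Rotational (~10 bp) methylation periodicity: per-base methylation vectors
# anchored on 147 bp nucleosome-core fragments and their raw FFT periodogram.

#' Select nucleosome-core-sized anchor fragments
#'
#' Retains fragments with length exactly `length` bp (147 by default, one
#' full nucleosome core) and, when a feature mask is given, whose span lies
#' entirely within a mask interval (e.g. heterochromatic TEs or genes).
#'
#' @param fragments Fragment data frame.
#' @param mask Optional data frame of mask intervals (chrom, start, end).
#' @param length Required fragment length in bp.
#' @return The retained anchor fragments.
#' @export
select_147bp <- function(fragments, mask = NULL, length = 147L) {
  keep <- (fragments$end - fragments$start) == length
  anchors <- fragments[keep, , drop = FALSE]
  if (!is.null(mask) && nrow(anchors) > 0) {
    if (nrow(mask) == 0) return(anchors[integer(0), , drop = FALSE])
    hits <- GenomicRanges::findOverlaps(
      .gr0(anchors$chrom, anchors$start, anchors$end),
      .gr0(mask$chrom, mask$start, mask$end), type = "within")
    anchors <- anchors[sort(unique(S4Vectors::queryHits(hits))), ,
                       drop = FALSE]
  }
  rownames(anchors) <- NULL
  anchors
}

#' Per-base methylation vector across anchor fragments
#'
#' For offsets 1..`length` from each fragment's 5'-most end, pools
#' methylated/total counts of one context at `start + offset - 1` across all
#' anchors, and returns the pooled per-offset fraction. With
#' `symmetrize = TRUE` the counts are averaged with their reverse, pooling
#' the two fragment orientations.
#'
#' @param anchors Anchor fragments from [select_147bp()].
#' @param records Cytosine record data frame.
#' @param context Context to profile.
#' @param length Fragment length (vector length).
#' @param symmetrize Average the vector with its reverse.
#' @return Data frame of class `per_base_vector`: offset (1..length),
#'   n_meth, n_total, fraction (`NA` where uncovered).
#' @export
per_base_vector <- function(anchors, records, context = "CG",
                            length = 147L, symmetrize = FALSE) {
  if (is.null(anchors) || nrow(anchors) == 0) {
    stop("per_base_vector requires at least one anchor fragment")
  }
  .check_records(records)
  records <- records[records$context == context, , drop = FALSE]
  n_meth <- numeric(length)
  n_total <- numeric(length)
  for (ch in unique(anchors$chrom)) {
    starts <- anchors$start[anchors$chrom == ch]
    rec <- records[records$chrom == ch, , drop = FALSE]
    if (nrow(rec) == 0) next
    size <- max(rec$pos, starts + length) + 2L
    mv <- numeric(size)
    tv <- numeric(size)
    acc <- rowsum(cbind(rec$count_meth, rec$count_total), rec$pos)
    at <- as.integer(rownames(acc)) + 1L
    mv[at] <- acc[, 1]
    tv[at] <- acc[, 2]
    for (i in seq_len(length)) {
      idx <- starts + i          # 1-based index of 0-based position start+i-1
      n_meth[i] <- n_meth[i] + sum(mv[idx])
      n_total[i] <- n_total[i] + sum(tv[idx])
    }
  }
  if (symmetrize) {
    n_meth <- (n_meth + rev(n_meth)) / 2
    n_total <- (n_total + rev(n_total)) / 2
  }
  out <- data.frame(offset = seq_len(length), n_meth = n_meth,
                    n_total = n_total,
                    fraction = ifelse(n_total > 0, n_meth / n_total,
                                      NA_real_))
  attr(out, "context") <- context
  attr(out, "n_anchors") <- nrow(anchors)
  class(out) <- c("per_base_vector", "data.frame")
  out
}

#' Raw FFT periodogram of a methylation vector
#'
#' Mean-centres the vector (missing offsets imputed by the vector mean, which
#' adds no spectral component) and computes the raw periodogram
#' `power(k) = |DFT_k|^2 / n` for `k = 1..floor(n/2)`, reported against the
#' period `n/k` in bp. No taper or detrending beyond mean removal is applied.
#'
#' @param x A `per_base_vector`, or a numeric vector of methylation
#'   fractions.
#' @param max_period Maximum period (bp) retained when the periodogram is
#'   written or printed; the full spectrum is kept in the object.
#' @return Data frame of class `periodogram_result`: period (bp), power;
#'   attributes `n`, `max_period`, `n_imputed`.
#' @export
periodogram <- function(x, max_period = 30) {
  if (is.data.frame(x)) x <- x$fraction
  n <- length(x)
  if (n < 16) stop("periodogram requires a vector of length >= 16")
  miss <- is.na(x)
  if (all(miss)) stop("periodogram undefined for an all-missing vector")
  if (any(miss)) {
    message("periodogram: imputing ", sum(miss),
            " missing offset(s) with the vector mean")
    x[miss] <- mean(x[!miss])
  }
  xc <- x - mean(x)
  ft <- fft(xc)
  k <- seq_len(n %/% 2)
  out <- data.frame(period = n / k, power = Mod(ft[k + 1])^2 / n)
  attr(out, "n") <- n
  attr(out, "max_period") <- max_period
  attr(out, "n_imputed") <- sum(miss)
  class(out) <- c("periodogram_result", "data.frame")
  out
}

#' Period of maximal spectral power
#'
#' Returns the Fourier period `n/k` with the highest periodogram power
#' within `range`; exact power ties are broken toward the smaller period.
#'
#' @param result A `periodogram_result`.
#' @param range Period search range in bp (inclusive).
#' @return The peak period in bp.
#' @export
peak_period <- function(result, range = c(5, 30)) {
  sel <- result$period >= range[1] & result$period <= range[2]
  if (!any(sel)) stop("no Fourier period falls inside the requested range")
  p <- result[sel, , drop = FALSE]
  mx <- max(p$power)
  min(p$period[p$power == mx])
}
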