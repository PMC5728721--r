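# Self-organizing-map clustering of dyad-centred methylation matrices, used
# to isolate loci with phased nucleosome arrays.

#' Per-locus methylation matrix around anchors
#'
#' One row per anchor, one column per offset bin across `+-flank`; each cell
#' is the pooled methylation fraction of the context in that (anchor, bin)
#' cell, `NA` where uncovered. Pooling all rows count-wise reproduces
#' [profile_around_anchors()].
#'
#' @param anchors Data frame with chrom, pos (dyads).
#' @param records Cytosine record data frame.
#' @param flank Half-width in bp (multiple of `bin`).
#' @param bin Bin width in bp.
#' @param context Context to profile.
#' @return Object of class `locus_matrix`: list with `fraction`, `n_meth`,
#'   `n_total` (anchors x bins matrices), `offsets` (bin left edges) and
#'   `anchors`.
#' @export
build_locus_matrix <- function(anchors, records, flank = 350L, bin = 10L,
                               context = "CG") {
  if (nrow(anchors) == 0) stop("anchors must be non-empty")
  if (bin <= 0) stop("invalid parameter: bin must be > 0")
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  .check_records(records)
  records <- records[records$context == context, , drop = FALSE]
  offsets <- seq(-flank, flank - bin, by = bin)
  nb <- length(offsets)
  na <- nrow(anchors)
  n_meth <- matrix(0, na, nb)
  n_total <- matrix(0, na, nb)
  pairs <- .anchor_offsets(records, anchors, flank, oriented = FALSE)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    bcol <- (pairs$off %/% bin) - (-flank %/% bin) + 1L
    cell <- (pairs$anc - 1L) * nb + bcol
    acc <- rowsum(cbind(records$count_meth[pairs$rec],
                        records$count_total[pairs$rec]), cell)
    at <- as.integer(rownames(acc))
    n_meth[cbind(((at - 1L) %/% nb) + 1L, ((at - 1L) %% nb) + 1L)] <- acc[, 1]
    n_total[cbind(((at - 1L) %/% nb) + 1L, ((at - 1L) %% nb) + 1L)] <-
      acc[, 2]
  }
  fraction <- ifelse(n_total > 0, n_meth / n_total, NA_real_)
  empty_rows <- sum(rowSums(n_total) == 0)
  if (empty_rows > 0) {
    message("build_locus_matrix: ", empty_rows,
            " anchor(s) with no covered cytosine (all-missing rows retained)")
  }
  out <- list(fraction = fraction, n_meth = n_meth, n_total = n_total,
              offsets = offsets, anchors = anchors, context = context,
              bin = bin, flank = flank)
  class(out) <- "locus_matrix"
  out
}

#' Cluster locus rows with a 1-D self-organizing map
#'
#' Trains a 1 x k Kohonen map by the standard online update: each row is
#' assigned to its best-matching unit (Euclidean distance) and the codebook
#' is pulled toward it under a Gaussian neighbourhood whose width and
#' learning rate decay linearly over epochs. Missing cells are imputed by
#' column means for training; original missingness is untouched in the
#' input. Deterministic given `seed`.
#'
#' @param x A `locus_matrix` or a numeric matrix (rows = loci).
#' @param k Number of map units (clusters).
#' @param epochs Training epochs.
#' @param learning_rate Initial learning rate (decays to 0.01).
#' @param seed Integer seed for codebook initialisation and row order.
#' @return Object of class `som_fit`: list with `cluster` (per-row labels
#'   1..k), `codebook` (k x bins), and the training metadata.
#' @export
som_cluster <- function(x, k = 5L, epochs = 100L, learning_rate = 0.5,
                        seed = 1L) {
  if (inherits(x, "locus_matrix")) x <- x$fraction
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of rows")
  if (k < 1) stop("k must be >= 1")
  cm <- colMeans(x, na.rm = TRUE)
  cm[is.nan(cm)] <- mean(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- cm[j]
  }
  .with_seed(.substream(seed, "som"), {
    codebook <- x[sample.int(n, k), , drop = FALSE]
    alphas <- seq(learning_rate, 0.01, length.out = epochs)
    sigmas <- seq(max(k / 2, 0.5), 0.3, length.out = epochs)
    units <- seq_len(k)
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      a <- alphas[e]
      s2 <- 2 * sigmas[e]^2
      for (i in ord) {
        xi <- x[i, ]
        d <- rowSums((codebook - matrix(xi, k, ncol(x), byrow = TRUE))^2)
        bmu <- which.min(d)
        h <- a * exp(-(units - bmu)^2 / s2)
        codebook <- codebook +
          h * (matrix(xi, k, ncol(x), byrow = TRUE) - codebook)
      }
    }
    d2 <- vapply(seq_len(k), function(j) {
      rowSums((x - matrix(codebook[j, ], n, ncol(x), byrow = TRUE))^2)
    }, numeric(n))
    cluster <- max.col(-matrix(d2, n, k), ties.method = "first")
    out <- list(cluster = cluster, codebook = codebook, k = k,
                epochs = epochs, learning_rate = learning_rate, seed = seed)
    class(out) <- "som_fit"
    out
  })
}

#' Identify the phased-array cluster
#'
#' Cluster labels from a SOM are arbitrary, so the cluster carrying the
#' phased (linker-high / core-low alternating) methylation signal is found
#' post hoc: for each mean-centred codebook vector, the squared amplitude of
#' its cosine/sine component at the nucleosome repeat length is computed,
#' and the cluster maximising it is returned.
#'
#' @param fit A `som_fit`.
#' @param offsets Bin left-edge offsets (bp) of the matrix columns, e.g. the
#'   `offsets` element of a [build_locus_matrix()] result.
#' @param repeat_length Nucleosome repeat length in bp (core + mean linker).
#' @return Integer cluster label.
#' @export
phased_cluster <- function(fit, offsets, repeat_length = 177) {
  bin <- if (length(offsets) > 1) diff(offsets[1:2]) else 1
  t <- offsets + bin / 2
  scores <- vapply(seq_len(fit$k), function(j) {
    v <- fit$codebook[j, ] - mean(fit$codebook[j, ])
    a <- mean(v * cos(2 * pi * t / repeat_length)) * 2
    b <- mean(v * sin(2 * pi * t / repeat_length)) * 2
    a^2 + b^2
  }, numeric(1))
  which.max(scores)
}

#' Per-genotype metaprofiles restricted to one cluster
#'
#' Restricts the anchor set to the rows assigned to `cluster` and computes
#' one pooled metaprofile per genotype record set.
#'
#' @param matrix A `locus_matrix` (supplies anchors and binning).
#' @param fit The `som_fit` for that matrix.
#' @param cluster Cluster label (1..k).
#' @param records_by_genotype Named list of cytosine record data frames.
#' @param context Context to profile (defaults to the matrix context).
#' @return Named list of `methylation_profile` objects, one per genotype.
#' @export
cluster_profiles <- function(matrix, fit, cluster, records_by_genotype,
                             context = NULL) {
  if (!cluster %in% seq_len(fit$k)) {
    stop("unknown cluster id: ", cluster)
  }
  sel <- fit$cluster == cluster
  if (!any(sel)) stop("cluster ", cluster, " is empty")
  anchors <- matrix$anchors[sel, , drop = FALSE]
  if (is.null(context)) context <- matrix$context
  lapply(records_by_genotype, function(rec) {
    profile_around_anchors(rec, anchors, flank = matrix$flank,
                           bin = matrix$bin, context = context)
  })
}
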