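# End-to-end orchestration: simulate -> nucleosomes -> profiles -> DMRs ->
# FFT -> clusters, with a machine-readable run manifest.

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed, propagated to every stochastic stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "nucleosomes", "profile", "dmr", "fft", "cluster")`;
#'   later stages depend on earlier ones.
#' @param sim A [sim_config()]; defaults to a compact 200 kb genome so a
#'   full run stays light.
#' @param genotypes Genotypes to simulate and profile.
#' @param profile_flank,profile_bin Metaprofile window and bin (bp).
#' @param cluster_k,cluster_epochs SOM size and training epochs.
#' @param max_cluster_rows Cap on rows entering the SOM stage.
#' @param inputs Optional named list of pre-existing inputs (paths) for
#'   partial runs without the simulate stage: `fragments` (character vector
#'   of >= 2 replicate BED paths) and `cx_reports` (named list
#'   genotype -> CX TSV path).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate", "nucleosomes", "profile",
                                  "dmr", "fft", "cluster"),
                       sim = NULL,
                       genotypes = c("WT", "h1", "ddm1", "h1ddm1"),
                       profile_flank = 300L, profile_bin = 5L,
                       cluster_k = 5L, cluster_epochs = 50L,
                       max_cluster_rows = 1000L,
                       inputs = list()) {
  if (is.null(sim)) {
    sim <- sim_config(seed = seed, chrom_sizes = c(chr1 = 2e5))
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
              sim = sim, genotypes = genotypes,
              profile_flank = profile_flank, profile_bin = profile_bin,
              cluster_k = cluster_k, cluster_epochs = cluster_epochs,
              max_cluster_rows = max_cluster_rows, inputs = inputs)
  class(cfg) <- "run_config"
  cfg
}

.stage_log <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

.manifest_files <- function(paths) {
  lapply(stats::setNames(paths, basename(paths)), function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the selected stages in dependency order on synthetic (or
#' supplied) inputs, writes all genomic outputs as BED/TSV under
#' `config$out_dir`, and returns a manifest recording parameters, output
#' checksums and headline numbers. Rerunning with the same config and seed
#' reproduces byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return The manifest (named list), invisibly; also written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "nucleosomes", "profile", "dmr", "fft",
                  "cluster")
  stages <- intersect(all_stages, config$stages)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "nucmeth", seed = config$seed, stages = list())
  state <- list()

  if ("simulate" %in% stages) {
    .stage_log("simulate", "generating layout, nucleosomes, fragments, ",
               "methylomes (seed ", config$sim$seed, ")")
    layout <- generate_layout(config$sim)
    map <- simulate_true_nucleosomes(layout, config$sim)
    frags <- simulate_fragments(map, config$sim, n_replicates = 2L)
    meth <- lapply(stats::setNames(config$genotypes, config$genotypes),
                   function(g) simulate_methylome(layout, map, g, config$sim))
    paths <- character(0)
    for (r in seq_along(frags)) {
      p <- file.path(config$out_dir, sprintf("fragments_rep%d.bed", r))
      write_bed(frags[[r]], p)
      paths <- c(paths, p)
    }
    for (g in config$genotypes) {
      p <- file.path(config$out_dir, paste0(g, "_cx_report.tsv"))
      write_cx_report(meth[[g]], p)
      paths <- c(paths, p)
    }
    p <- file.path(config$out_dir, "true_dyads.bed")
    write_bed(data.frame(chrom = map$chrom, start = map$dyad,
                         end = map$dyad + 1L, name = map$class), p)
    paths <- c(paths, p)
    state$layout <- layout
    state$map <- map
    state$fragments <- frags
    state$methylomes <- meth
    manifest$stages$simulate <- list(
      n_nucleosomes = nrow(map),
      n_fragments = vapply(frags, nrow, integer(1)),
      n_cytosines = vapply(meth, nrow, integer(1)),
      outputs = .manifest_files(paths))
  } else if (length(setdiff(stages, "simulate")) > 0) {
    if (!is.null(config$inputs$fragments)) {
      state$fragments <- lapply(config$inputs$fragments, read_bed)
    }
    if (!is.null(config$inputs$cx_reports)) {
      state$methylomes <- lapply(config$inputs$cx_reports, read_cx_report)
    }
  }

  need <- function(stage, what, dep) {
    if (is.null(state[[what]])) {
      stop("stage '", stage, "' requires outputs of stage '", dep,
           "' (or explicit inputs); none available")
    }
    state[[what]]
  }

  if ("nucleosomes" %in% stages) {
    frags <- need("nucleosomes", "fragments", "simulate")
    if (length(frags) < 2) {
      stop("stage 'nucleosomes' requires two fragment replicates")
    }
    .stage_log("nucleosomes", "calling and classifying peaks")
    peaks <- lapply(frags[1:2], function(fr) {
      filter_peak_width(call_peaks(filter_fragments(fr)))
    })
    calls <- classify_positioning(peaks[[1]], peaks[[2]])
    state$calls <- calls
    p_calls <- file.path(config$out_dir, "nucleosome_calls.tsv")
    write.table(calls, p_calls, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p_dyads <- file.path(config$out_dir, "group1_dyads.bed")
    g1 <- calls[calls$group == "1", , drop = FALSE]
    write_bed(data.frame(chrom = g1$chrom, start = g1$dyad,
                         end = g1$dyad + 1L, name = "group1",
                         score = round(g1$best_ro * 1000)), p_dyads)
    manifest$stages$nucleosomes <- list(
      group_sizes = as.list(table(calls$group)),
      outputs = .manifest_files(c(p_calls, p_dyads)))
  }

  het_anchors <- function() {
    calls <- need("profile/fft/cluster", "calls", "nucleosomes")
    g1 <- calls[calls$group == "1", , drop = FALSE]
    anchors <- data.frame(chrom = g1$chrom, pos = g1$dyad,
                          stringsAsFactors = FALSE)
    if (!is.null(state$layout)) {
      het <- state$layout$features[
        state$layout$features$class == "het_TE", , drop = FALSE]
      if (nrow(het) > 0 && nrow(anchors) > 0) {
        hit <- GenomicRanges::findOverlaps(
          .gr0(anchors$chrom, anchors$pos, anchors$pos + 1L),
          .gr0(het$chrom, het$start, het$end))
        anchors <- anchors[sort(unique(S4Vectors::queryHits(hit))), ,
                           drop = FALSE]
      }
    }
    anchors
  }

  if ("profile" %in% stages) {
    meth <- need("profile", "methylomes", "simulate")
    anchors <- het_anchors()
    .stage_log("profile", nrow(anchors),
               " heterochromatic group-1 dyad anchors")
    paths <- character(0)
    for (g in names(meth)) {
      prof <- profile_around_anchors(meth[[g]], anchors,
                                     flank = config$profile_flank,
                                     bin = config$profile_bin,
                                     context = "CG")
      p <- file.path(config$out_dir, paste0("profile_CG_", g, ".tsv"))
      write_profile_tsv(prof, p)
      paths <- c(paths, p)
    }
    manifest$stages$profile <- list(
      n_anchors = nrow(anchors), flank = config$profile_flank,
      bin = config$profile_bin, outputs = .manifest_files(paths))
  }

  if ("dmr" %in% stages) {
    meth <- need("dmr", "methylomes", "simulate")
    gts <- names(meth)
    if (length(gts) < 3) stop("stage 'dmr' requires three genotypes")
    wt <- gts[1]; mut <- gts[which(gts != wt)[2]]; other <- gts[gts != wt][1]
    .stage_log("dmr", "CHH windows, ", mut, " vs ", wt,
               " (exclusive against ", other, ")")
    win <- window_counts(meth[c(wt, mut, other)])
    dmrs <- call_dmrs(win, wt_label = wt, mut_label = mut,
                      other_mut_label = other)
    state$dmrs <- dmrs
    p <- file.path(config$out_dir, "dmrs.bed")
    if (nrow(dmrs) > 0) {
      write_bed(data.frame(chrom = dmrs$chrom, start = dmrs$start,
                           end = dmrs$end, name = dmrs$dependency,
                           score = pmin(1000, round(-10 * log10(
                             pmax(dmrs$min_p, 1e-100))))), p)
    } else {
      file.create(p)
      message("no DMRs called; wrote empty ", p)
    }
    manifest$stages$dmr <- list(
      focal = mut, other = other, n_windows = nrow(win),
      n_dmrs = nrow(dmrs), outputs = .manifest_files(p))
  }

  if ("fft" %in% stages) {
    frags <- need("fft", "fragments", "simulate")
    meth <- need("fft", "methylomes", "simulate")
    mask <- if (!is.null(state$layout)) {
      fe <- state$layout$features
      fe[fe$class == "het_TE", , drop = FALSE]
    } else {
      NULL
    }
    anchors <- select_147bp(frags[[1]], mask = mask)
    .stage_log("fft", nrow(anchors), " core-sized anchor fragments")
    vec <- per_base_vector(anchors, meth[[1]], context = "CG")
    pg <- periodogram(vec)
    pk <- peak_period(pg)
    p <- file.path(config$out_dir, "periodogram_CG.tsv")
    write_periodogram_tsv(pg, p)
    manifest$stages$fft <- list(
      n_anchors = nrow(anchors), peak_period_bp = pk,
      outputs = .manifest_files(p))
  }

  if ("cluster" %in% stages) {
    meth <- need("cluster", "methylomes", "simulate")
    anchors <- het_anchors()
    if (nrow(anchors) > config$max_cluster_rows) {
      anchors <- anchors[seq_len(config$max_cluster_rows), , drop = FALSE]
    }
    if (nrow(anchors) < config$cluster_k) {
      stop("stage 'cluster': fewer anchors than clusters")
    }
    gclust <- if ("h1ddm1" %in% names(meth)) "h1ddm1" else names(meth)[1]
    .stage_log("cluster", "SOM on ", nrow(anchors), " ", gclust,
               " CG rows, k = ", config$cluster_k)
    lm <- build_locus_matrix(anchors, meth[[gclust]],
                             flank = config$profile_flank,
                             bin = config$profile_bin, context = "CG")
    fit <- som_cluster(lm, k = config$cluster_k,
                       epochs = config$cluster_epochs, seed = config$seed)
    pc <- phased_cluster(fit, lm$offsets)
    p <- file.path(config$out_dir, "cluster_assignments.tsv")
    write.table(data.frame(chrom = anchors$chrom, pos = anchors$pos,
                           cluster = fit$cluster),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$cluster <- list(
      genotype = gclust, k = config$cluster_k,
      cluster_sizes = as.list(table(fit$cluster)), phased_cluster = pc,
      outputs = .manifest_files(p))
  }

  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .stage_log("run", "completed stages: ", paste(stages, collapse = ", "))
  invisible(manifest)
}
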