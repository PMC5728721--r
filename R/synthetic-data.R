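# Synthetic genome / nucleosome / methylome generator.
#
# The generator emulates the statistical structure the downstream analyses
# assume: chromosomes tiled by heterochromatic TEs, euchromatic TEs, genes
# (with exon/intron structure) and intergenic gaps; regular nucleosome arrays
# (147 bp cores, sampled linkers); paired-end MNase fragments whose midpoints
# jitter around true dyads; and per-cytosine binomial methylation counts with
# genotype/context-specific core and linker rates plus a ~10 bp cosine
# modulation of core methylation phased to the dyad.

#' Generate a synthetic genome layout
#'
#' Tiles each chromosome with feature blocks (heterochromatic TEs,
#' euchromatic TEs, genes, intergenic gaps) drawn according to
#' `feature_props`. Genes receive alternating exon/intron segments that tile
#' the gene body exactly, plus a strand.
#'
#' @param config A [sim_config()].
#' @return A list of class `genome_layout` with elements `chrom_sizes`,
#'   `features` (data.frame: chrom, start, end, class, strand, feature_id;
#'   0-based half-open) and `gene_parts` (data.frame: chrom, start, end,
#'   type in exon/intron, gene_id).
#' @examples
#' lay <- generate_layout(sim_config(seed = 1, chrom_sizes = c(chr1 = 5e4)))
#' table(lay$features$class)
#' @export
generate_layout <- function(config) {
  config <- validate_sim_config(config)
  cs <- config$chrom_sizes
  if (length(cs) == 0) stop("invalid config: no chromosomes defined")
  if (any(cs < 1e4)) stop("invalid config: chromosome sizes must be >= 10 kb")
  props <- config$feature_props
  len_rng <- list(het_TE = c(2000, 8000), eu_TE = c(200, 1000),
                  gene = c(1000, 4000), intergenic = c(200, 2000))
  classes <- c("het_TE", "eu_TE", "gene", "intergenic")
  p <- c(props[["het_TE"]], props[["eu_TE"]], props[["gene"]],
         max(1 - sum(props), 0.05))
  .with_seed(.substream(config$seed, "layout"), {
    feats <- vector("list", 0L)
    parts <- vector("list", 0L)
    id <- 0L
    for (chrom in names(cs)) {
      L <- as.integer(cs[[chrom]])
      pos <- 0L
      while (pos < L) {
        cls <- sample(classes, 1L, prob = p)
        r <- len_rng[[cls]]
        len <- r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
        end <- min(pos + len, L)
        if (cls != "intergenic" && end - pos >= 200L) {
          id <- id + 1L
          fid <- sprintf("f%05d", id)
          strand <- if (cls == "gene") sample(c("+", "-"), 1L) else "*"
          feats[[length(feats) + 1L]] <- data.frame(
            chrom = chrom, start = pos, end = end, class = cls,
            strand = strand, feature_id = fid, stringsAsFactors = FALSE)
          if (cls == "gene") {
            parts[[length(parts) + 1L]] <-
              .gene_structure(chrom, pos, end, fid)
          }
        }
        pos <- end
      }
    }
    layout <- list(
      chrom_sizes = cs,
      features = if (length(feats)) do.call(rbind, feats) else
        data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   class = character(0), strand = character(0),
                   feature_id = character(0), stringsAsFactors = FALSE),
      gene_parts = if (length(parts)) do.call(rbind, parts) else
        data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   type = character(0), gene_id = character(0),
                   stringsAsFactors = FALSE)
    )
    class(layout) <- "genome_layout"
    layout
  })
}

# Alternating exon/intron segments (odd count, exon first and last) tiling
# [start, end) exactly.
.gene_structure <- function(chrom, start, end, gene_id) {
  glen <- end - start
  n_ex <- sample(1:5, 1L)
  nseg <- 2L * n_ex - 1L
  if (glen < nseg * 60L) {
    n_ex <- 1L
    nseg <- 1L
  }
  w <- rgamma(nseg, shape = 2)
  lens <- pmax(20L, as.integer(floor(glen * w / sum(w))))
  lens[nseg] <- glen - sum(lens[-nseg])
  if (lens[nseg] < 20L) {          # degenerate partition: single exon
    nseg <- 1L
    lens <- glen
  }
  starts <- start + c(0L, cumsum(lens[-nseg]))
  data.frame(
    chrom = chrom,
    start = starts,
    end = starts + lens,
    type = rep_len(c("exon", "intron"), nseg),
    gene_id = gene_id,
    stringsAsFactors = FALSE
  )
}

#' Place true nucleosome dyads along the genome
#'
#' Walks each chromosome alternating 147 bp cores with linkers drawn from
#' `Normal(linker_length_mean, linker_length_sd)` (rounded, clamped at 0), so
#' consecutive dyads are separated by at least one nucleosome length. Each
#' dyad is labelled with the feature class it falls in.
#'
#' @param layout A `genome_layout` from [generate_layout()].
#' @param config A [sim_config()].
#' @return Data frame of class `true_nucleosome_map`: chrom, dyad (0-based
#'   bp), class; with the chromosome sizes kept as an attribute.
#' @examples
#' cfg <- sim_config(seed = 1, chrom_sizes = c(chr1 = 5e4),
#'                   linker_length_sd = 0)
#' map <- simulate_true_nucleosomes(generate_layout(cfg), cfg)
#' unique(diff(map$dyad))  # 177 bp everywhere when linker sd is 0
#' @export
simulate_true_nucleosomes <- function(layout, config) {
  config <- validate_sim_config(config)
  if (config$linker_length_mean <= 0) {
    stop("invalid config: linker_length_mean must be > 0")
  }
  nl <- config$nucleosome_length
  half <- (nl - 1L) %/% 2L
  .with_seed(.substream(config$seed, "nucleosomes"), {
    out <- lapply(names(layout$chrom_sizes), function(chrom) {
      L <- as.integer(layout$chrom_sizes[[chrom]])
      n_max <- ceiling(L / nl) + 1L
      linkers <- pmax(0, round(rnorm(n_max, config$linker_length_mean,
                                     config$linker_length_sd)))
      offset <- sample.int(50L, 1L) - 1L
      spacing <- nl + as.integer(linkers)
      starts <- offset + c(0L, cumsum(spacing[-n_max]))
      keep <- (starts + nl) <= L
      starts <- starts[keep]
      dyads <- starts + half
      fe <- layout$features[layout$features$chrom == chrom, , drop = FALSE]
      cls <- rep("intergenic", length(dyads))
      if (nrow(fe) > 0) {
        idx <- findInterval(dyads, fe$start)
        hit <- idx > 0 & dyads < fe$end[pmax(idx, 1L)]
        cls[hit] <- fe$class[idx[hit]]
      }
      data.frame(chrom = chrom, dyad = dyads, class = cls,
                 stringsAsFactors = FALSE)
    })
    map <- do.call(rbind, out)
    attr(map, "chrom_sizes") <- layout$chrom_sizes
    class(map) <- c("true_nucleosome_map", "data.frame")
    map
  })
}

#' Simulate MNase-seq fragments around true dyads
#'
#' For each nucleosome, draws `Poisson(fragment_depth)` fragments per
#' replicate. Fragment midpoints are the true dyad plus rounded
#' `Normal(0, positioning_sd)` jitter (sd resolved per feature class);
#' lengths are drawn from `fragment_length_dist`. Replicates use independent
#' RNG substreams, so two replicates from the same seed differ.
#'
#' @param map A `true_nucleosome_map`.
#' @param config A [sim_config()].
#' @param n_replicates Number of biological replicates to simulate.
#' @return List of `n_replicates` data frames (chrom, start, end; 0-based
#'   half-open), each sorted by chrom and start.
#' @export
simulate_fragments <- function(map, config, n_replicates = 1L) {
  config <- validate_sim_config(config)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  cs <- attr(map, "chrom_sizes")
  lens <- as.integer(names(config$fragment_length_dist))
  lapply(seq_len(n_replicates), function(r) {
    if (nrow(map) == 0) return(.empty_fragments())
    .with_seed(.substream(config$seed, paste0("fragments-rep", r)), {
      counts <- rpois(nrow(map), config$fragment_depth)
      dyad <- rep(map$dyad, counts)
      chrom <- rep(map$chrom, counts)
      cls <- rep(map$class, counts)
      n <- length(dyad)
      if (n == 0) return(.empty_fragments())
      sdv <- .positioning_sd_for(config, cls)
      mids <- dyad + as.integer(round(rnorm(n, 0, sdv)))
      flen <- lens[sample.int(length(lens), n, replace = TRUE,
                              prob = config$fragment_length_dist)]
      start <- mids - flen %/% 2L
      end <- start + flen
      ok <- start >= 0L
      if (!is.null(cs)) ok <- ok & end <= as.integer(cs[chrom])
      fr <- data.frame(chrom = chrom[ok], start = start[ok], end = end[ok],
                       stringsAsFactors = FALSE)
      fr[order(fr$chrom, fr$start, fr$end), , drop = FALSE]
    })
  })
}

# Cytosine site positions/strands/contexts; shared by all genotypes so that
# genotype comparisons are made at identical sites (seeded from the master
# seed only).
.simulate_sites <- function(layout, config) {
  .with_seed(.substream(config$seed, "sites"), {
    out <- lapply(names(layout$chrom_sizes), function(chrom) {
      L <- as.integer(layout$chrom_sizes[[chrom]])
      per_strand <- lapply(c("+", "-"), function(strand) {
        pos <- which(runif(L) < config$cytosine_density) - 1L
        data.frame(chrom = chrom, pos = pos, strand = strand,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_strand)
    })
    sites <- do.call(rbind, out)
    sites$context <- sample(names(config$context_probs), nrow(sites),
                            replace = TRUE, prob = config$context_probs)
    sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  })
}

# Signed distance from each position to its nearest dyad on the same chrom.
.dist_to_nearest_dyad <- function(chrom, pos, map) {
  delta <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    dy <- sort(map$dyad[map$chrom == ch])
    if (length(dy) == 0) next
    i <- findInterval(pos[sel], dy)
    left <- dy[pmax(i, 1L)]
    right <- dy[pmin(i + 1L, length(dy))]
    dl <- pos[sel] - left
    dr <- pos[sel] - right
    dl[i == 0] <- Inf
    d <- ifelse(abs(dl) <= abs(dr), dl, dr)
    delta[sel] <- d
  }
  delta
}

#' Simulate a bisulfite methylome for one genotype
#'
#' Generates per-cytosine methylation counts: cytosines within +-73 bp of a
#' true dyad use the genotype/context core rate modulated by
#' `rotational_amplitude * cos(2*pi*(pos - dyad)/rotational_period)` (cosine
#' maximum at the dyad); linker cytosines use the linker rate. Read totals
#' are `Poisson(coverage_mean)` and methylated counts `Binomial(total, rate)`.
#' Cytosine site positions are shared across genotypes (same substream), so
#' genotypes are compared at identical sites.
#'
#' @param layout A `genome_layout`.
#' @param map A `true_nucleosome_map`.
#' @param genotype One of the names of `config$genotype_params`.
#' @param config A [sim_config()].
#' @return Cytosine record data frame: chrom, pos (0-based), strand, context,
#'   count_meth, count_total; rows with zero coverage are dropped.
#' @export
simulate_methylome <- function(layout, map, genotype, config) {
  config <- validate_sim_config(config)
  gp <- config$genotype_params[[genotype]]
  if (is.null(gp)) {
    stop("unknown genotype '", genotype, "'; available: ",
         paste(names(config$genotype_params), collapse = ", "))
  }
  if (config$coverage_mean == 0) return(.empty_records())
  sites <- .simulate_sites(layout, config)
  half <- (config$nucleosome_length - 1L) %/% 2L
  delta <- .dist_to_nearest_dyad(sites$chrom, sites$pos, map)
  core <- !is.na(delta) & abs(delta) <= half
  cr <- vapply(gp, function(x) x$core_rate, numeric(1))[sites$context]
  lr <- vapply(gp, function(x) x$linker_rate, numeric(1))[sites$context]
  am <- vapply(gp, function(x) x$rotational_amplitude,
               numeric(1))[sites$context]
  rate <- ifelse(core,
                 cr + am * cos(2 * pi * delta / config$rotational_period),
                 lr)
  rate[is.na(rate)] <- lr[is.na(rate)]
  rate <- pmin(pmax(rate, 0), 1)
  .with_seed(.substream(config$seed, paste0("methylome-", genotype)), {
    total <- rpois(nrow(sites), config$coverage_mean)
    meth <- rbinom(nrow(sites), total, rate)
    keep <- total > 0
    out <- data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                      strand = sites$strand[keep],
                      context = sites$context[keep],
                      count_meth = meth[keep], count_total = total[keep],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Simulate CHH methylomes with planted differentially methylated regions
#'
#' Builds a three-genotype CHH count set for evaluating the DMR caller:
#' `n_planted` regions hypomethylated exclusively in the focal mutant
#' (`wt_rate` in WT, `lost_rate` in the mutant, WT-like in the other mutant)
#' and `n_decoy` shared-loss regions hypomethylated in *both* mutants, which
#' a correct exclusivity filter must reject. Background methylation is
#' `wt_rate` in all genotypes. Regions are `region_width` bp wide, aligned to
#' the 50 bp window grid, and separated by `spacing` bp.
#'
#' @param seed Integer seed.
#' @param n_planted,n_decoy Numbers of mutant-exclusive and shared-loss
#'   regions.
#' @param region_width Region width in bp (multiple of 50).
#' @param wt_rate,lost_rate WT/background and hypomethylated CHH rates.
#' @param coverage Mean read depth per cytosine (Poisson).
#' @param site_density Per-strand CHH site density per bp.
#' @param spacing Distance between consecutive region starts (bp).
#' @param mut,other Genotype labels for the focal and the other mutant.
#' @return List with `records` (named list of cytosine record data frames for
#'   WT, `mut`, `other`), `planted` and `decoys` (region data frames), and
#'   `chrom_size`.
#' @export
simulate_dmr_methylomes <- function(seed = 1L, n_planted = 100L,
                                    n_decoy = 100L, region_width = 150L,
                                    wt_rate = 0.25, lost_rate = 0.05,
                                    coverage = 20, site_density = 0.1,
                                    spacing = 600L, mut = "drm12",
                                    other = "cmt2") {
  if (region_width %% 50L != 0L) stop("region_width must be a multiple of 50")
  n_reg <- n_planted + n_decoy
  starts <- (seq_len(n_reg) - 1L) * spacing + 100L
  starts <- (starts %/% 50L) * 50L                  # align to the window grid
  planted <- data.frame(chrom = "chr1", start = starts[seq_len(n_planted)],
                        end = starts[seq_len(n_planted)] + region_width,
                        stringsAsFactors = FALSE)
  decoys <- data.frame(chrom = "chr1",
                       start = starts[n_planted + seq_len(n_decoy)],
                       end = starts[n_planted + seq_len(n_decoy)] +
                         region_width,
                       stringsAsFactors = FALSE)
  L <- max(starts) + region_width + 500L
  in_region <- function(pos, reg) {
    if (nrow(reg) == 0) return(rep(FALSE, length(pos)))
    idx <- findInterval(pos, reg$start)
    idx > 0 & pos < reg$end[pmax(idx, 1L)]
  }
  .with_seed(.substream(seed, "dmr-sites"), {
    sites <- do.call(rbind, lapply(c("+", "-"), function(strand) {
      pos <- which(runif(L) < site_density) - 1L
      data.frame(chrom = "chr1", pos = pos, strand = strand,
                 stringsAsFactors = FALSE)
    }))
    sites <- sites[order(sites$pos, sites$strand), , drop = FALSE]
  })
  lost_in <- list()
  lost_in[["WT"]] <- rep(FALSE, nrow(sites))
  lost_in[[mut]] <- in_region(sites$pos, planted) |
    in_region(sites$pos, decoys)
  lost_in[[other]] <- in_region(sites$pos, decoys)
  records <- lapply(names(lost_in), function(g) {
    rate <- ifelse(lost_in[[g]], lost_rate, wt_rate)
    .with_seed(.substream(seed, paste0("dmr-meth-", g)), {
      total <- rpois(nrow(sites), coverage)
      meth <- rbinom(nrow(sites), total, rate)
      keep <- total > 0
      data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                 strand = sites$strand[keep], context = "CHH",
                 count_meth = meth[keep], count_total = total[keep],
                 stringsAsFactors = FALSE)
    })
  })
  names(records) <- names(lost_in)
  list(records = records, planted = planted, decoys = decoys, chrom_size = L)
}
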