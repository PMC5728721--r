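#' Default per-genotype methylation parameters
#'
#' Core/linker methylation rates and rotational-modulation amplitudes for the
#' four simulated genotypes (`WT`, `h1`, `ddm1`, `h1ddm1`) in each cytosine
#' context. The values are simulation defaults that reproduce the qualitative
#' structure of heterochromatic methylation in these genotypes: wild type
#' methylates both cores and linkers efficiently (with a mild core dip),
#' `ddm1` loses methylation everywhere but retains a core/linker differential,
#' and the `h1ddm1` double mutant shows linker methylation near wild-type
#' levels juxtaposed with `ddm1`-like core depletion. Rotational amplitude is
#' the size of the ~10 bp cosine modulation of core methylation; it is zero in
#' `ddm1`, where remodeler loss abolishes the rotational signal.
#'
#' Each genotype maps context (`CG`, `CHG`, `CHH`) to a list with
#' `core_rate`, `linker_rate` and `rotational_amplitude`, all in `[0, 1]`
#' with `rotational_amplitude <= min(core_rate, 1 - core_rate)`.
#'
#' @return Nested named list: genotype -> context -> parameter list.
#' @export
default_genotype_params <- function() {
  gp <- function(core, linker, amp) {
    list(core_rate = core, linker_rate = linker, rotational_amplitude = amp)
  }
  list(
    WT = list(
      CG  = gp(0.86, 0.92, 0.08),
      CHG = gp(0.55, 0.70, 0.08),
      CHH = gp(0.12, 0.20, 0.06)
    ),
    h1 = list(
      CG  = gp(0.92, 0.95, 0.04),
      CHG = gp(0.65, 0.80, 0.08),
      CHH = gp(0.18, 0.30, 0.06)
    ),
    ddm1 = list(
      CG  = gp(0.25, 0.45, 0.00),
      CHG = gp(0.10, 0.25, 0.00),
      CHH = gp(0.03, 0.08, 0.00)
    ),
    h1ddm1 = list(
      CG  = gp(0.20, 0.85, 0.08),
      CHG = gp(0.10, 0.60, 0.08),
      CHH = gp(0.05, 0.25, 0.04)
    )
  )
}

#' Simulation configuration
#'
#' Collects every free parameter of the synthetic-data generator: genome
#' layout proportions, nucleosome array geometry, MNase fragment sampling,
#' bisulfite coverage, and per-genotype methylation rates. All downstream
#' simulation functions are deterministic given `seed`.
#'
#' @param seed Integer master seed; every stochastic stage derives an
#'   independent substream from it.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param nucleosome_length Core particle length in bp (147).
#' @param linker_length_mean,linker_length_sd Normal parameters for linker
#'   lengths (bp); sampled linkers are rounded and clamped at 0.
#' @param positioning_sd Positioning jitter (bp sd of observed fragment
#'   midpoints around the true dyad). Either a single number or a named
#'   vector per feature class (`het_TE`, `eu_TE`, `gene`, `intergenic`).
#'   Heterochromatic arrays are modelled as well-positioned (small sd).
#' @param fragment_length_dist Named numeric vector mapping fragment length
#'   (bp) to sampling weight. Default: triangular weights on 137--157 bp
#'   peaked at 147 bp, so mononucleosome-sized fragments dominate.
#' @param fragment_depth Mean number of MNase fragments per nucleosome per
#'   replicate (Poisson).
#' @param coverage_mean Mean bisulfite read depth per cytosine (Poisson).
#' @param cytosine_density Per-strand probability that a position carries a
#'   cytosine.
#' @param context_probs Named probabilities that a cytosine is CG/CHG/CHH.
#' @param feature_props Genome fraction targets for `het_TE`, `eu_TE`,
#'   `gene` feature classes (the remainder is intergenic). Must sum to <= 1.
#' @param rotational_period Period (bp) of the rotational methylation
#'   modulation; 10 bp, the helical repeat of nucleosomal DNA.
#' @param genotype_params Per-genotype, per-context rate parameters; see
#'   [default_genotype_params()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, chrom_sizes = c(chr1 = 5e4))
#' cfg$nucleosome_length
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = c(chr1 = 1e6),
                       nucleosome_length = 147L,
                       linker_length_mean = 30,
                       linker_length_sd = 5,
                       positioning_sd = c(het_TE = 2, eu_TE = 5,
                                          gene = 10, intergenic = 20),
                       fragment_length_dist = NULL,
                       fragment_depth = 20,
                       coverage_mean = 10,
                       cytosine_density = 0.18,
                       context_probs = c(CG = 0.17, CHG = 0.20, CHH = 0.63),
                       feature_props = c(het_TE = 0.35, eu_TE = 0.10,
                                         gene = 0.30),
                       rotational_period = 10,
                       genotype_params = default_genotype_params()) {
  if (is.null(fragment_length_dist)) {
    lens <- 137:157
    w <- 11 - abs(lens - 147)
    fragment_length_dist <- stats::setNames(w / sum(w), lens)
  }
  cfg <- list(
    seed = as.integer(seed),
    chrom_sizes = chrom_sizes,
    nucleosome_length = as.integer(nucleosome_length),
    linker_length_mean = linker_length_mean,
    linker_length_sd = linker_length_sd,
    positioning_sd = positioning_sd,
    fragment_length_dist = fragment_length_dist,
    fragment_depth = fragment_depth,
    coverage_mean = coverage_mean,
    cytosine_density = cytosine_density,
    context_probs = context_probs,
    feature_props = feature_props,
    rotational_period = rotational_period,
    genotype_params = genotype_params
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sim_config()]: rates in `[0, 1]`,
#' rotational amplitudes compatible with their core rates, non-negative
#' jitter, and feature proportions summing to at most 1.
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly unchanged, or an error describing the violation.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop("invalid config: seed must be a single integer")
  }
  if (any(cfg$positioning_sd < 0)) {
    stop("invalid config: positioning_sd must be >= 0")
  }
  if (any(cfg$chrom_sizes <= 0)) {
    stop("invalid config: chromosome sizes must be positive")
  }
  if (sum(cfg$feature_props) > 1 + 1e-9) {
    stop("invalid config: feature class proportions sum to > 1")
  }
  if (any(cfg$fragment_length_dist < 0) ||
      abs(sum(cfg$fragment_length_dist) - 1) > 1e-6) {
    stop("invalid config: fragment_length_dist must be a probability vector")
  }
  for (g in names(cfg$genotype_params)) {
    for (ctx in names(cfg$genotype_params[[g]])) {
      p <- cfg$genotype_params[[g]][[ctx]]
      rates <- c(p$core_rate, p$linker_rate, p$rotational_amplitude)
      if (any(rates < 0) || any(c(p$core_rate, p$linker_rate) > 1)) {
        stop("invalid config: rates for ", g, "/", ctx, " outside [0, 1]")
      }
      if (p$rotational_amplitude >
          min(p$core_rate, 1 - p$core_rate) + 1e-9) {
        stop("invalid config: rotational_amplitude for ", g, "/", ctx,
             " exceeds min(core_rate, 1 - core_rate)")
      }
    }
  }
  cfg
}

# Per-fragment positioning sd, resolved from a scalar or per-class vector.
.positioning_sd_for <- function(cfg, classes) {
  sdv <- cfg$positioning_sd
  if (length(sdv) == 1 && is.null(names(sdv))) {
    return(rep(as.numeric(sdv), length(classes)))
  }
  out <- unname(sdv[classes])
  out[is.na(out)] <- if ("intergenic" %in% names(sdv)) {
    sdv[["intergenic"]]
  } else {
    mean(sdv)
  }
  as.numeric(out)
}
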