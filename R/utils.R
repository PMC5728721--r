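# Internal helpers shared across modules.

# Derive an independent substream seed (< 2^31) from a master seed and a tag,
# so the simulator's stages draw from non-overlapping, reproducible streams.
.substream <- function(seed, tag) {
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v) * 131)
  as.integer((as.numeric(seed) * 100003 + h * 7919) %% 2147483629)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# 0-based half-open [start, end) -> IRanges (1-based closed).
.ir0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = as.integer(end))

# 0-based half-open intervals -> GRanges.
.gr0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(seqnames = chrom, ranges = .ir0(start, end))
}

# Midpoint of the union span [mn, mx): mean of the two endpoints, rounded
# half-up so the result is a single deterministic base position.
.round_half_up <- function(x) as.integer(floor(x + 0.5))

.empty_fragments <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

.empty_records <- function() {
  data.frame(chrom = character(0), pos = integer(0), strand = character(0),
             context = character(0), count_meth = integer(0),
             count_total = integer(0), stringsAsFactors = FALSE)
}

.check_records <- function(records) {
  need <- c("chrom", "pos", "context", "count_meth", "count_total")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("cytosine records lack required columns: ", paste(miss, collapse = ", "))
  }
  invisible(records)
}

.contexts <- c("CG", "CHG", "CHH")
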