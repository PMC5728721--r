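# Readers and writers for the plain-text formats at the package boundary.
# Internal coordinates are 0-based half-open throughout; BED I/O goes through
# rtracklayer, which handles the BED coordinate convention.

#' Read a BED file of intervals
#'
#' @param path Path to a BED file (BED3/BED6).
#' @return Data frame with chrom, start, end (0-based half-open) and, when
#'   present in the file, name, score, strand.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  md <- S4Vectors::mcols(gr)
  if ("name" %in% names(md)) out$name <- as.character(md$name)
  if ("score" %in% names(md)) out$score <- as.numeric(md$score)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write intervals to a BED file
#'
#' @param x Data frame with chrom, start, end (0-based half-open) and
#'   optionally name, score, strand.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  gr <- .gr0(x$chrom, x$start, x$end)
  if ("strand" %in% names(x)) {
    GenomicRanges::strand(gr) <- x$strand
  }
  md <- list()
  if ("name" %in% names(x)) md$name <- x$name
  if ("score" %in% names(x)) md$score <- x$score
  if (length(md) > 0) S4Vectors::mcols(gr) <- S4Vectors::DataFrame(md)
  rtracklayer::export(gr, path, format = "BED")
  message("wrote ", length(gr), " intervals to ", path)
  invisible(path)
}

#' Read a BEDPE file and collapse mate pairs to fragments
#'
#' Mate intervals on the same chromosome are collapsed to the fragment
#' spanning both (min start to max end). rtracklayer has no BEDPE parser, so
#' the six leading columns are read directly.
#'
#' @param path Path to a BEDPE file.
#' @return Fragment data frame (chrom, start, end; 0-based half-open).
#' @export
read_bedpe <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 6) stop("BEDPE requires at least 6 columns")
  if (any(d[[1]] != d[[4]])) {
    stop("interchromosomal BEDPE pairs cannot be collapsed to fragments")
  }
  data.frame(chrom = as.character(d[[1]]),
             start = pmin(as.integer(d[[2]]), as.integer(d[[5]])),
             end = pmax(as.integer(d[[3]]), as.integer(d[[6]])),
             stringsAsFactors = FALSE)
}

#' Read a CX-report-style methylation TSV
#'
#' Parses the per-cytosine dialect written by [write_cx_report()] (and by
#' common bisulfite callers): tab-separated chrom, position (1-based),
#' strand, methylated count, unmethylated count, context. Positions are
#' converted to 0-based; malformed lines are rejected with their line
#' numbers.
#'
#' @param path Path to the TSV.
#' @return Cytosine record data frame: chrom, pos (0-based), strand, context,
#'   count_meth, count_total.
#' @export
read_cx_report <- function(path) {
  if (file.size(path) == 0) return(.empty_records())
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chrom", "pos", "strand",
                                       "count_meth", "count_unmeth",
                                       "context"))
  bad <- which(!(d$context %in% .contexts))
  if (length(bad) > 0) {
    stop("unknown context token at line(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(is.na(d$pos) | is.na(d$count_meth) | is.na(d$count_unmeth) |
                 d$count_meth < 0 | d$count_unmeth < 0)
  if (length(bad) > 0) {
    stop("malformed counts or positions at line(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  data.frame(chrom = as.character(d$chrom),
             pos = as.integer(d$pos) - 1L,
             strand = as.character(d$strand),
             context = as.character(d$context),
             count_meth = as.integer(d$count_meth),
             count_total = as.integer(d$count_meth + d$count_unmeth),
             stringsAsFactors = FALSE)
}

#' Write cytosine records as a CX-report-style TSV
#'
#' Inverse of [read_cx_report()]: positions written 1-based, counts split
#' into methylated and unmethylated.
#'
#' @param records Cytosine record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(records, path) {
  .check_records(records)
  out <- data.frame(records$chrom, records$pos + 1L, records$strand,
                    records$count_meth,
                    records$count_total - records$count_meth,
                    records$context)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  message("wrote ", nrow(out), " cytosine records to ", path)
  invisible(path)
}

#' Write a methylation profile as TSV
#'
#' @param profile A profile data frame from [profile_around_anchors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", nrow(profile), " profile bins to ", path)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' @param track Coverage track data frame from [rpm_normalize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- .gr0(track$chrom, track$start, track$end)
  S4Vectors::mcols(gr)$score <- track$rpm
  rtracklayer::export(gr, path, format = "bedGraph")
  message("wrote ", nrow(track), " bins to ", path)
  invisible(path)
}

#' Write a periodogram as TSV
#'
#' Periods are truncated to the stored maximum reporting period.
#'
#' @param pg A periodogram result from [periodogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_periodogram_tsv <- function(pg, path) {
  maxp <- attr(pg, "max_period")
  out <- pg[pg$period <= maxp, c("period", "power"), drop = FALSE]
  names(out) <- c("period_bp", "power")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", nrow(out), " periodogram rows to ", path)
  invisible(path)
}
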