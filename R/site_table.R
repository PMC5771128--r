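#' Construct a per-site NOME-seq measurement table
#'
#' A site table holds one row per measured cytosine: its chromosome, 0-based
#' position, sequence context (`"CpG"` for endogenous methylation, `"GpC"` for
#' the accessibility readout), and methylated / total read counts. The
#' methylation level of a site is methylated reads divided by total reads;
#' sites with zero coverage are retained but yield a missing level.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based positions.
#' @param context Character vector, each `"CpG"` or `"GpC"`.
#' @param meth_reads Numeric vector of methylated read counts.
#' @param total_reads Numeric vector of total read counts.
#' @return A data.frame of class `site_table`, sorted by (chrom, pos, context).
#' @export
site_table <- function(chrom, pos, context, meth_reads, total_reads) {
  x <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  context = as.character(context),
                  meth_reads = meth_reads, total_reads = total_reads,
                  stringsAsFactors = FALSE)
  x <- x[order(x$chrom, x$pos, x$context), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("site_table", "data.frame")
  validate_site_table(x)
}

validate_site_table <- function(x) {
  need <- c("chrom", "pos", "context", "meth_reads", "total_reads")
  if (!all(need %in% names(x))) {
    stop("site table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(x$context %in% c("CpG", "GpC"))) {
    stop("context must be 'CpG' or 'GpC'", call. = FALSE)
  }
  if (any(x$meth_reads < 0) || any(x$total_reads < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (any(x$meth_reads > x$total_reads)) {
    bad <- which(x$meth_reads > x$total_reads)
    stop("methylated reads exceed total reads at ", length(bad),
         " site(s), first at row ", bad[1], call. = FALSE)
  }
  key <- paste(x$chrom, x$pos, x$context)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos, context) records in site table", call. = FALSE)
  }
  invisible(x)
}

#' Read a site table from TSV
#'
#' Dialect: tab-separated with a header line
#' `chrom pos context meth_reads total_reads`; `pos` is 0-based; lines starting
#' with `#` are skipped.
#'
#' @param path Input path.
#' @return A `site_table`.
#' @export
read_site_table <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  site_table(x$chrom, x$pos, x$context, x$meth_reads, x$total_reads)
}

#' Write a site table to TSV
#'
#' @param x A `site_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path) {
  validate_site_table(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import pre-computed levels from a bedGraph file
#'
#' Accepts a 4-column bedGraph (`chrom`, `start`, `end`, `value` in `[0,1]`)
#' of single-base intervals as pre-computed methylation levels. Total read
#' count is unknown; it is recorded as 1 (unknown-but-positive) with
#' `meth_reads = value`, so levels round-trip but counts are not meaningful.
#'
#' @param path Input bedGraph path.
#' @param context `"CpG"` or `"GpC"` to assign to all records.
#' @return A `site_table`.
#' @export
import_bedgraph <- function(path, context = c("CpG", "GpC")) {
  context <- match.arg(context)
  x <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = c("chrom", "start", "end", "value"),
                         stringsAsFactors = FALSE)
  if (any(x$value < 0 | x$value > 1)) {
    stop("bedGraph values must lie in [0,1] to be used as levels", call. = FALSE)
  }
  site_table(x$chrom, x$start, rep(context, nrow(x)),
             meth_reads = x$value, total_reads = rep(1, nrow(x)))
}

#' Per-site methylation level
#'
#' Level = methylated reads / total reads; `NA` where total is zero.
#'
#' @param meth_reads Numeric vector of methylated read counts.
#' @param total_reads Numeric vector of total read counts.
#' @return Numeric vector of levels in `[0,1]`, `NA` at zero coverage.
#' @examples
#' methylation_level(3, 10)  # 0.3
#' methylation_level(0, 0)   # NA
#' @export
methylation_level <- function(meth_reads, total_reads) {
  if (any(meth_reads < 0) || any(total_reads < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (any(meth_reads > total_reads)) {
    stop("methylated reads exceed total reads", call. = FALSE)
  }
  ifelse(total_reads > 0, meth_reads / total_reads, NA_real_)
}

#' Nucleosome occupancy from GpC methylation
#'
#' In NOME-seq the exogenous methyltransferase only reaches GpC cytosines that
#' are not wrapped in a nucleosome, so occupancy is one minus the GpC
#' methylation level. Missing levels propagate.
#'
#' @param gpc_level Numeric vector of GpC methylation levels in `[0,1]` or `NA`.
#' @return Numeric vector of occupancies.
#' @export
occupancy_from_gpc <- function(gpc_level) {
  ok <- is.na(gpc_level) | (gpc_level >= 0 & gpc_level <= 1)
  if (!all(ok)) {
    stop("GpC level outside [0,1]", call. = FALSE)
  }
  1 - gpc_level
}

#' Per-position levels for one context
#'
#' Extracts positions and levels for one context on one chromosome, applying an
#' optional minimum-coverage filter (sites below it get a missing level but are
#' kept, so density computations still see their positions).
#'
#' @param sites A `site_table`.
#' @param chrom Chromosome name.
#' @param context `"CpG"` or `"GpC"`.
#' @param min_total Minimum total reads for a defined level (default 1).
#' @return data.frame with `pos` (sorted) and `level` (`NA` below `min_total`).
#' @export
site_levels <- function(sites, chrom, context = c("CpG", "GpC"), min_total = 1) {
  context <- match.arg(context)
  s <- sites[sites$chrom == chrom & sites$context == context, , drop = FALSE]
  s <- s[order(s$pos), , drop = FALSE]
  level <- methylation_level(s$meth_reads, s$total_reads)
  level[s$total_reads < min_total] <- NA_real_
  data.frame(pos = s$pos, level = level)
}
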