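#' Select promoters by expression quantile
#'
#' Returns the `floor(q * N)` promoters with the highest (or lowest)
#' expression. Ties are broken by genomic order (chromosome, then position),
#' which makes the selection deterministic.
#'
#' @param promoters Anchor data.frame with `id`, `chrom`, `pos`, `expression`.
#' @param q Quantile fraction in (0, 0.5].
#' @param which `"top"` or `"bottom"`.
#' @return The selected subset of `promoters`, in selection order.
#' @export
select_by_expression <- function(promoters, q = 0.05, which = c("top", "bottom")) {
  which <- match.arg(which)
  if (!(q > 0 && q <= 0.5)) stop("q must lie in (0, 0.5]", call. = FALSE)
  if (anyNA(promoters$expression)) {
    bad <- promoters$id[is.na(promoters$expression)]
    stop("promoters without expression values: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  n_sel <- floor(q * nrow(promoters))
  key <- if (which == "top") -promoters$expression else promoters$expression
  ord <- order(key, promoters$chrom, promoters$pos)
  promoters[ord[seq_len(n_sel)], , drop = FALSE]
}

#' Mean CpG density of anchor windows
#'
#' Number of CpG sites (no dedup) in `pos +/- halfwidth` divided by the window
#' length `2*halfwidth + 1`. Out-of-bounds anchors are flagged and get `NA`.
#'
#' @param anchors Anchor data.frame with `chrom`, `pos`.
#' @param cpg_sites data.frame with `chrom`, `pos` of CpG sites.
#' @param halfwidth Half-width in bp.
#' @param chrom_len Optional named vector of chromosome lengths.
#' @return Numeric vector of densities per bp.
#' @export
mean_region_density <- function(anchors, cpg_sites, halfwidth = 1000L,
                                chrom_len = NULL) {
  out <- rep(NA_real_, nrow(anchors))
  ok <- anchors$pos - halfwidth >= 0
  if (!is.null(chrom_len)) ok <- ok & anchors$pos + halfwidth < chrom_len[anchors$chrom]
  if (any(!ok)) message(sum(!ok), " anchor(s) out of bounds; flagged with NA density")
  for (ch in unique(anchors$chrom)) {
    rows <- which(anchors$chrom == ch & ok)
    pos <- sort(cpg_sites$pos[cpg_sites$chrom == ch])
    cnt <- findInterval(anchors$pos[rows] + halfwidth, pos) -
      findInterval(anchors$pos[rows] - halfwidth - 1L, pos)
    out[rows] <- cnt / (2 * halfwidth + 1)
  }
  out
}

#' Mean CpG methylation of anchor windows
#'
#' Unweighted mean of per-CpG methylation levels over the covered CpG sites in
#' `pos +/- halfwidth`; `NA` when no covered CpG falls in the window.
#'
#' @param anchors Anchor data.frame with `chrom`, `pos`.
#' @param sites A `site_table`.
#' @param halfwidth Half-width in bp.
#' @param min_total Minimum coverage for a site to count (default 1).
#' @return Numeric vector of mean levels in `[0,1]` or `NA`.
#' @export
mean_region_methylation <- function(anchors, sites, halfwidth = 1000L,
                                    min_total = 1) {
  out <- rep(NA_real_, nrow(anchors))
  for (ch in unique(anchors$chrom)) {
    rows <- which(anchors$chrom == ch)
    lv <- site_levels(sites, ch, "CpG", min_total = min_total)
    cov <- !is.na(lv$level)
    pos <- lv$pos
    cs_l <- c(0, cumsum(ifelse(cov, lv$level, 0)))
    cs_n <- c(0, cumsum(cov))
    hi <- findInterval(anchors$pos[rows] + halfwidth, pos)
    lo <- findInterval(anchors$pos[rows] - halfwidth - 1L, pos)
    s <- cs_l[hi + 1L] - cs_l[lo + 1L]
    k <- cs_n[hi + 1L] - cs_n[lo + 1L]
    out[rows] <- ifelse(k > 0, s / k, NA_real_)
  }
  out
}

#' Select ids with values strictly below a threshold
#'
#' Strict `<`, with missing values excluded -- used to pick low-density
#' promoters or low-methylation regions relative to a grand mean computed
#' upstream.
#'
#' @param ids Vector of identifiers.
#' @param values Numeric vector, parallel to `ids`.
#' @param threshold Threshold value.
#' @return The subset of `ids` with `values < threshold`.
#' @export
select_below_threshold <- function(ids, values, threshold) {
  stopifnot(length(ids) == length(values))
  ids[!is.na(values) & values < threshold]
}

#' Summarize a profile into single mean values
#'
#' Per-track mean over the defined positions of a profile: occupancy and
#' methylation means are weighted by the number of contributing windows at
#' each position (consistent with how the per-position means were built);
#' CpG density is an unweighted positional mean. All-undefined tracks give
#' `NA`.
#'
#' @param profile A `nome_profile`.
#' @param label Label for the summary row.
#' @return One-row data.frame with `label`, `mean_density`, `mean_methylation`,
#'   `mean_occupancy`, `n_regions`.
#' @export
summarize_profile <- function(profile, label = "profile") {
  wmean <- function(x, w) {
    ok <- !is.na(x) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  data.frame(label = label,
             mean_density = mean(profile$cpg_density, na.rm = TRUE),
             mean_methylation = wmean(profile$meth_mean, profile$meth_n),
             mean_occupancy = wmean(profile$occ_mean, profile$occ_n),
             n_regions = profile$n_windows[1],
             stringsAsFactors = FALSE)
}
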