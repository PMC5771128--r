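#' Anchor-aligned signal windows
#'
#' `extract_windows()` builds, for a set of oriented anchors (TSSs or control
#' region centers), per-relative-position tracks over `-halfwidth..+halfwidth`:
#' nucleosome occupancy (1 - GpC methylation level), CpG methylation level, and
#' a CpG-site indicator. With `orient = TRUE` (default) windows from
#' minus-strand anchors are flipped so that positive relative positions always
#' mean downstream of the TSS; this is what makes the phased-nucleosome pattern
#' after the TSS visible in an average. Positions without a measured site, or
#' with zero coverage, are missing and later disregarded by the averaging.
#'
#' Anchors whose window would leave the chromosome are not silently dropped:
#' they are flagged, reported via a message, and listed in the `skipped`
#' attribute of the result.
#'
#' @param sites A `site_table` of measurements.
#' @param cpg_sites data.frame with `chrom`, `pos` of all CpG sites (from
#'   [genome_sites()]); used for the density indicator.
#' @param anchors data.frame with `id`, `chrom`, `pos` (0-based anchor
#'   coordinate), `strand` (`"+"`, `"-"` or `"*"`) and optionally `expression`.
#' @param halfwidth Window half-width in bp (default 1000, i.e. 2001 positions).
#' @param chrom_len Named vector of chromosome lengths (for bounds checking);
#'   if `NULL`, only the lower bound is checked.
#' @param orient Flip minus-strand windows so +r is downstream (default TRUE).
#' @param min_total Minimum coverage for a defined level (see [site_levels()]).
#' @return An object of class `window_set`: a list with `rel` (relative
#'   positions), matrices `occ`, `meth` (levels, `NA` = missing) and `cpg`
#'   (1/0 indicator, `NA` once excluded by dedup), the `anchors` used, and the
#'   window orientation sign `dir` per anchor.
#' @export
extract_windows <- function(sites, cpg_sites, anchors, halfwidth = 1000L,
                            chrom_len = NULL, orient = TRUE, min_total = 1) {
  stopifnot(halfwidth >= 1)
  rel <- seq.int(-halfwidth, halfwidth)
  strand <- if ("strand" %in% names(anchors)) anchors$strand else rep("*", nrow(anchors))
  dir <- ifelse(orient & strand == "-", -1L, 1L)

  lo_ok <- anchors$pos - halfwidth >= 0
  hi_ok <- if (is.null(chrom_len)) rep(TRUE, nrow(anchors)) else {
    anchors$pos + halfwidth < chrom_len[anchors$chrom]
  }
  usable <- lo_ok & hi_ok & !is.na(lo_ok) & !is.na(hi_ok)
  skipped <- anchors[!usable, , drop = FALSE]
  if (nrow(skipped) > 0) {
    message(nrow(skipped), " anchor(s) out of chromosome bounds; flagged and skipped")
  }
  anchors <- anchors[usable, , drop = FALSE]
  dir <- dir[usable]
  n <- nrow(anchors)
  p <- length(rel)
  occ <- matrix(NA_real_, n, p)
  meth <- matrix(NA_real_, n, p)
  cpg <- matrix(0L, n, p)

  for (ch in unique(anchors$chrom)) {
    rows <- which(anchors$chrom == ch)
    cl <- site_levels(sites, ch, "CpG", min_total = min_total)
    gl <- site_levels(sites, ch, "GpC", min_total = min_total)
    gl$occ <- occupancy_from_gpc(gl$level)
    cpos <- sort(cpg_sites$pos[cpg_sites$chrom == ch])
    for (w in rows) {
      g <- anchors$pos[w] + dir[w] * rel
      occ[w, ] <- lookup_values(g, gl$pos, gl$occ)
      meth[w, ] <- lookup_values(g, cl$pos, cl$level)
      cpg[w, ] <- as.integer(!is.na(lookup_values(g, cpos, rep(1, length(cpos)))))
    }
  }
  structure(list(rel = rel, occ = occ, meth = meth, cpg = cpg,
                 anchors = anchors, dir = dir, halfwidth = as.integer(halfwidth)),
            skipped = skipped, class = "window_set")
}

# value at each query position, NA where no site; positions must be sorted
lookup_values <- function(query, pos, values) {
  if (length(pos) == 0L) return(rep(NA_real_, length(query)))
  idx <- findInterval(query, pos)
  hit <- idx >= 1L & pos[pmax(idx, 1L)] == query
  out <- rep(NA_real_, length(query))
  out[hit] <- values[idx[hit]]
  out
}

#' Extract a single anchor window
#'
#' Convenience wrapper around [extract_windows()] for one anchor; returns a
#' list with vectors `rel`, `gpos` (genomic coordinate of each relative
#' position), `occ`, `meth`, `cpg`, or a flagged-skip result (`skipped = TRUE`)
#' when the window leaves the chromosome.
#'
#' @inheritParams extract_windows
#' @param anchor A one-row data.frame (or list) with `chrom`, `pos`, `strand`.
#' @export
extract_window <- function(sites, cpg_sites, anchor, halfwidth = 1000L,
                           chrom_len = NULL, orient = TRUE, min_total = 1) {
  a <- data.frame(id = if (!is.null(anchor$id)) anchor$id else "anchor",
                  chrom = anchor$chrom, pos = anchor$pos,
                  strand = if (!is.null(anchor$strand)) anchor$strand else "*",
                  stringsAsFactors = FALSE)
  ws <- extract_windows(sites, cpg_sites, a, halfwidth, chrom_len, orient, min_total)
  if (nrow(ws$anchors) == 0L) {
    return(list(skipped = TRUE, anchor = a))
  }
  list(skipped = FALSE, rel = ws$rel,
       gpos = a$pos + ws$dir[1] * ws$rel,
       occ = ws$occ[1, ], meth = ws$meth[1, ], cpg = ws$cpg[1, ])
}

#' Exclude double-counted CpG indicators across overlapping windows
#'
#' When windows overlap, the same genomic CpG would be counted into the density
#' of several windows. Iterating windows in ascending (chromosome, anchor)
#' order, each genomic CpG keeps its indicator in the first window containing
#' it and is marked excluded (`NA`) in every later window. Excluded positions
#' count as zero in density numerators while the window stays in the
#' denominator. Only the density track is affected; occupancy and methylation
#' are averaged in every window that measures them.
#'
#' @param ws A `window_set`.
#' @return The `window_set` with deduplicated `cpg` indicators.
#' @export
dedup_cpg_indicators <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  ord <- order(ws$anchors$chrom, ws$anchors$pos)
  for (ch in unique(ws$anchors$chrom)) {
    rows <- ord[ws$anchors$chrom[ord] == ch]
    if (length(rows) == 0L) next
    wlist <- lapply(rows, function(w) {
      cols <- which(ws$cpg[w, ] == 1L)
      if (length(cols) == 0L) return(NULL)
      data.frame(w = w, col = cols,
                 gpos = ws$anchors$pos[w] + ws$dir[w] * ws$rel[cols])
    })
    tab <- do.call(rbind, wlist)
    if (is.null(tab)) next
    dup <- duplicated(tab$gpos)
    if (any(dup)) {
      ws$cpg[cbind(tab$w[dup], tab$col[dup])] <- NA_integer_
    }
  }
  ws
}

#' Average windows into a profile
#'
#' At each relative position, occupancy and methylation means are taken over
#' the windows with a measurement there (windows without one are disregarded),
#' and the number of contributing windows is recorded. CpG density is the
#' number of indicator-1 windows divided by the total number of windows in the
#' set -- the denominator does not depend on coverage, and dedup-excluded
#' positions count as zero.
#'
#' @param ws A `window_set`.
#' @return data.frame of class `nome_profile` with columns `rel_pos`,
#'   `occ_mean`, `occ_n`, `meth_mean`, `meth_n`, `cpg_density`, `n_windows`.
#' @export
average_profiles <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  n <- nrow(ws$occ)
  if (n == 0L) stop("no usable windows to average", call. = FALSE)
  occ_n <- colSums(!is.na(ws$occ))
  meth_n <- colSums(!is.na(ws$meth))
  occ_mean <- ifelse(occ_n > 0, colSums(ws$occ, na.rm = TRUE) / occ_n, NA_real_)
  meth_mean <- ifelse(meth_n > 0, colSums(ws$meth, na.rm = TRUE) / meth_n, NA_real_)
  dens <- colSums(ws$cpg == 1L, na.rm = TRUE) / n
  out <- data.frame(rel_pos = ws$rel, occ_mean = occ_mean, occ_n = occ_n,
                    meth_mean = meth_mean, meth_n = meth_n,
                    cpg_density = dens, n_windows = n)
  class(out) <- c("nome_profile", "data.frame")
  out
}

# centered moving average, truncated at the edges, NA-excluded
moving_mean <- function(x, w) {
  stopifnot(w >= 1)
  left <- floor(w / 2)
  right <- w - 1L - left
  n <- length(x)
  ok <- !is.na(x)
  xv <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xv))
  cn <- c(0, cumsum(ok))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  s <- cs[hi + 1L] - cs[lo]
  k <- cn[hi + 1L] - cn[lo]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Smooth a profile with a moving window
#'
#' Replaces the occupancy, methylation and density tracks by a centered moving
#' average over `window_bp` positions (for the default even width of 30 the
#' window at position i covers i-15..i+14). The window is truncated, not
#' padded, at the profile edges, and undefined positions are excluded from each
#' local mean. Count tracks are not smoothed.
#'
#' @param profile A `nome_profile`.
#' @param window_bp Moving window width in bp (default 30).
#' @return The smoothed `nome_profile`.
#' @export
smooth_profile <- function(profile, window_bp = 30L) {
  stopifnot(window_bp >= 1)
  profile$occ_mean <- moving_mean(profile$occ_mean, window_bp)
  profile$meth_mean <- moving_mean(profile$meth_mean, window_bp)
  profile$cpg_density <- moving_mean(profile$cpg_density, window_bp)
  profile
}

#' Write / read a profile TSV
#'
#' Columns `rel_pos, occ_mean, occ_n, meth_mean, meth_n, cpg_density,
#' n_windows`; missing values serialized as `NA`.
#'
#' @param profile A `nome_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("nome_profile", "data.frame")
  out
}

#' Dominant oscillation period of the downstream occupancy track
#'
#' Estimates the phasing period of the downstream nucleosome oscillation from
#' the discrete power spectrum of the detrended occupancy profile on relative
#' positions `from..to`. The trend is removed with a wide moving average so
#' that the NDR shoulder does not dominate the low frequencies; missing values
#' are replaced by the trend before the FFT.
#'
#' @param profile A (typically smoothed) `nome_profile`.
#' @param from,to Relative-position range to analyze (default 1..1000,
#'   downstream of the anchor).
#' @param period_range Periods (bp) searched for the spectral peak.
#' @param trend_bp Width of the detrending moving average.
#' @return List with `period` (bp), `freq_index` (cycles over the analyzed
#'   span) and `power` (spectrum over the searched indices).
#' @export
phasing_period <- function(profile, from = 1L, to = 1000L,
                           period_range = c(50, 500), trend_bp = 301L) {
  sel <- profile$rel_pos >= from & profile$rel_pos <= to
  y <- profile$occ_mean[sel]
  n <- length(y)
  if (n < 16L) stop("too few positions for a spectrum", call. = FALSE)
  trend <- moving_mean(y, trend_bp)
  y <- ifelse(is.na(y), 0, y - trend)
  pw <- Mod(stats::fft(y))^2
  k <- seq_len(n) - 1L                      # cycles over the span
  period <- ifelse(k > 0, n / k, Inf)
  cand <- which(k >= 1 & period >= period_range[1] & period <= period_range[2])
  best <- cand[which.max(pw[cand])]
  list(period = n / k[best], freq_index = k[best], power = pw[cand])
}

#' Plot a profile
#'
#' Simple base-graphics line plot of the three tracks of a profile, with the
#' density track on its own axis scale.
#'
#' @param x A `nome_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nome_profile <- function(x, ...) {
  graphics::plot(x$rel_pos, x$occ_mean, type = "l", col = "blue",
                 ylim = c(0, 1), xlab = "position relative to anchor (bp)",
                 ylab = "occupancy / methylation", ...)
  graphics::lines(x$rel_pos, x$meth_mean, col = "darkgreen")
  dmax <- max(x$cpg_density, na.rm = TRUE)
  if (dmax > 0) graphics::lines(x$rel_pos, x$cpg_density / dmax, col = "magenta", lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 1, 2),
                   col = c("blue", "darkgreen", "magenta"),
                   legend = c("occupancy", "methylation", "CpG density (scaled)"))
  invisible(x)
}
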