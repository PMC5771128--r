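#' Detect CpG clusters
#'
#' A CpG cluster is a maximal run of CpG sites in which successive inter-site
#' distances are below `max_intra_gap` (default 20 bp). Singleton sites form
#' singleton clusters.
#'
#' @param pos Sorted integer vector of CpG positions on one chromosome.
#' @param max_intra_gap Gap threshold in bp; a gap of exactly this size splits.
#' @return data.frame with `start`, `end` (first/last member CpG, 0-based
#'   inclusive) and `n_sites`.
#' @export
detect_clusters <- function(pos, max_intra_gap = 20L) {
  if (length(pos) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), n_sites = integer(0)))
  }
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  grp <- cumsum(c(1L, as.integer(diff(pos) >= max_intra_gap)))
  data.frame(start = as.integer(tapply(pos, grp, min)),
             end = as.integer(tapply(pos, grp, max)),
             n_sites = as.integer(tapply(pos, grp, length)),
             row.names = NULL)
}

#' Merge nearby CpG clusters
#'
#' Adjacent clusters closer than `max_inter_gap` (start of the next minus end
#' of the previous, default 50 bp) are merged transitively; member counts are
#' summed.
#'
#' @param clusters data.frame from [detect_clusters()], sorted, non-overlapping.
#' @param max_inter_gap Gap threshold in bp.
#' @return data.frame of merged clusters.
#' @export
merge_clusters <- function(clusters, max_inter_gap = 50L) {
  n <- nrow(clusters)
  if (n <= 1L) return(clusters)
  if (is.unsorted(clusters$start)) stop("clusters must be sorted", call. = FALSE)
  gap <- clusters$start[-1L] - clusters$end[-n]
  grp <- cumsum(c(1L, as.integer(gap >= max_inter_gap)))
  data.frame(start = as.integer(tapply(clusters$start, grp, min)[as.character(unique(grp))]),
             end = as.integer(tapply(clusters$end, grp, max)[as.character(unique(grp))]),
             n_sites = as.integer(tapply(clusters$n_sites, grp, sum)[as.character(unique(grp))]),
             row.names = NULL)
}

#' Candidate control regions from clusters
#'
#' One candidate region per merged cluster, centered on the midpoint of the
#' cluster span (rounded down), spanning `center +/- halfwidth`. Clusters whose
#' region would leave the chromosome are flagged and skipped.
#'
#' @param clusters Merged clusters (one chromosome).
#' @param halfwidth Region half-width in bp (default 1000).
#' @param chrom_len Chromosome length in bp, or `NULL` to skip the upper check.
#' @return data.frame with `cluster_id`, `center`, `n_sites`.
#' @export
candidate_regions <- function(clusters, halfwidth = 1000L, chrom_len = NULL) {
  center <- as.integer(floor((clusters$start + clusters$end) / 2))
  ok <- center - halfwidth >= 0
  if (!is.null(chrom_len)) ok <- ok & (center + halfwidth < chrom_len)
  if (any(!ok)) {
    message(sum(!ok), " cluster(s) too close to a chromosome end; flagged and skipped")
  }
  data.frame(cluster_id = which(ok), center = center[ok],
             n_sites = clusters$n_sites[ok])
}

#' Promoter exclusion zones
#'
#' Merged intervals of `tss +/- halfwidth` around every promoter, per
#' chromosome; control regions may not intersect them.
#'
#' @param promoters Anchor data.frame with `chrom` and `pos`.
#' @param halfwidth Half-width in bp (default 1000).
#' @return data.frame with `chrom`, `start`, `end` (0-based inclusive), sorted
#'   and non-overlapping within each chromosome.
#' @export
build_exclusion <- function(promoters, halfwidth = 1000L) {
  if (nrow(promoters) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  res <- lapply(unique(promoters$chrom), function(ch) {
    p <- promoters$pos[promoters$chrom == ch]
    ir <- IRanges::reduce(IRanges::IRanges(start = p - halfwidth, end = p + halfwidth))
    data.frame(chrom = ch, start = IRanges::start(ir), end = IRanges::end(ir))
  })
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# counts of sites strictly left/right of each center within halfwidth;
# a site exactly at the center belongs to neither side
count_sides <- function(centers, pos, halfwidth) {
  left <- findInterval(centers - 1, pos) - findInterval(centers - halfwidth - 1, pos)
  right <- findInterval(centers + halfwidth, pos) - findInterval(centers, pos)
  cbind(left = left, right = right)
}

# TRUE where [center-halfwidth, center+halfwidth] misses every zone
zone_free <- function(centers, halfwidth, zstart, zend) {
  if (length(zstart) == 0L) return(rep(TRUE, length(centers)))
  idx <- findInterval(centers + halfwidth, zstart)
  free <- idx < 1L
  some <- which(!free)
  free[some] <- zend[idx[some]] < centers[some] - halfwidth
  free
}

#' Per-side CpG counts around promoters
#'
#' Counts CpG sites strictly upstream ("left") and downstream ("right") of each
#' TSS within `halfwidth`, in the promoter's orientation: for a minus-strand
#' promoter the genomic sides are swapped. A site exactly at the TSS belongs to
#' neither side.
#'
#' @param promoters Anchor data.frame with `chrom`, `pos`, `strand`.
#' @param cpg_sites data.frame with `chrom`, `pos` of CpG sites.
#' @param halfwidth Half-width in bp.
#' @return Matrix with columns `left`, `right`, one row per promoter.
#' @export
promoter_side_counts <- function(promoters, cpg_sites, halfwidth = 1000L) {
  out <- matrix(0L, nrow(promoters), 2, dimnames = list(NULL, c("left", "right")))
  for (ch in unique(promoters$chrom)) {
    rows <- which(promoters$chrom == ch)
    pos <- sort(cpg_sites$pos[cpg_sites$chrom == ch])
    sc <- count_sides(promoters$pos[rows], pos, halfwidth)
    minus <- promoters$strand[rows] == "-"
    out[rows, "left"] <- ifelse(minus, sc[, "right"], sc[, "left"])
    out[rows, "right"] <- ifelse(minus, sc[, "left"], sc[, "right"])
  }
  out
}

#' Match one promoter to one candidate region
#'
#' Scans shifted centers `candidate center + offset` in order of increasing
#' `|offset|` (ties: negative first) for a center whose per-side CpG counts
#' equal the promoter's and whose full window avoids every exclusion zone.
#' The center may shift at most `max_shift` (default `halfwidth`) so the region
#' stays attached to its cluster. No-match is a value (`NULL`), not an error.
#'
#' @param side_counts Length-2 vector `(left, right)` of the promoter's counts.
#' @param center Candidate region center.
#' @param pos Sorted CpG positions on the candidate's chromosome.
#' @param zones Exclusion zones for that chromosome (`start`, `end`), sorted.
#' @param halfwidth Region half-width in bp.
#' @param max_shift Maximum |offset| in bp.
#' @return List with `center`, `left_n`, `right_n`, `offset`, or `NULL`.
#' @export
match_one <- function(side_counts, center, pos, zones, halfwidth = 1000L,
                      max_shift = halfwidth) {
  off <- seq.int(-max_shift, max_shift)
  off <- off[order(abs(off), off)]
  centers <- center + off
  sc <- count_sides(centers, pos, halfwidth)
  ok <- sc[, "left"] == side_counts[1] & sc[, "right"] == side_counts[2] &
    zone_free(centers, halfwidth, zones$start, zones$end)
  k <- which(ok)[1]
  if (is.na(k)) return(NULL)
  list(center = centers[k], left_n = unname(sc[k, "left"]),
       right_n = unname(sc[k, "right"]), offset = off[k])
}

#' Match all promoters to control regions
#'
#' Promoters are processed in ascending genomic order; each is matched to the
#' first (by genomic order) not-yet-used candidate for which [match_one()]
#' succeeds. Candidates are used at most once, so matched control regions never
#' share a source cluster (they may still overlap unless `disjoint = TRUE`).
#' Unmatched promoters are reported in the `unmatched` attribute, not as
#' errors.
#'
#' @param promoters Anchor data.frame with `id`, `chrom`, `pos`, `strand`.
#' @param candidates data.frame per [candidate_regions()], with a `chrom`
#'   column when multiple chromosomes are present (otherwise `chrom` is taken
#'   from the promoters' single chromosome).
#' @param cpg_sites data.frame with `chrom`, `pos` of CpG sites.
#' @param zones Exclusion zones from [build_exclusion()].
#' @param halfwidth Region half-width in bp.
#' @param disjoint Also forbid overlap between accepted control regions.
#' @return data.frame of class `match_result` with `promoter_id`, `chrom`,
#'   `center`, `left_n`, `right_n`, `prom_left_n`, `prom_right_n`,
#'   `cluster_id`, `offset`; attribute `unmatched` lists promoter ids without
#'   a match.
#' @export
match_all <- function(promoters, candidates, cpg_sites, zones,
                      halfwidth = 1000L, disjoint = FALSE) {
  if (!"chrom" %in% names(candidates)) {
    stopifnot(length(unique(promoters$chrom)) <= 1L)
    candidates$chrom <- if (nrow(promoters)) promoters$chrom[1] else character(0)
  }
  promoters <- promoters[order(promoters$chrom, promoters$pos), , drop = FALSE]
  candidates <- candidates[order(candidates$chrom, candidates$center), , drop = FALSE]
  side <- promoter_side_counts(promoters, cpg_sites, halfwidth)
  used <- rep(FALSE, nrow(candidates))
  res <- vector("list", nrow(promoters))
  unmatched <- character(0)
  # with disjoint = TRUE, accepted control intervals join the exclusion zones
  # so the offset scan itself avoids them
  merge_zones <- function(z) {
    if (nrow(z) <= 1L) return(z)
    z <- z[order(z$start), , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(z$start, z$end))
    data.frame(chrom = z$chrom[1], start = IRanges::start(ir), end = IRanges::end(ir))
  }
  zones_by_chrom <- split(zones, zones$chrom)

  by_chrom_pos <- lapply(split(cpg_sites$pos, cpg_sites$chrom), sort)
  # candidates can only host a window of n sites if their +/-2*halfwidth span holds n
  span_n <- integer(nrow(candidates))
  for (ch in unique(candidates$chrom)) {
    rows <- which(candidates$chrom == ch)
    pos <- by_chrom_pos[[ch]]
    if (is.null(pos)) pos <- integer(0)
    span_n[rows] <- findInterval(candidates$center[rows] + 2L * halfwidth, pos) -
      findInterval(candidates$center[rows] - 2L * halfwidth - 1L, pos)
  }

  # precomputed side counts for every candidate at every offset, in the same
  # preference order match_one scans (|offset| ascending, negative first),
  # encoded as left * KEY_BASE + right -- one integer comparison per offset
  KEY_BASE <- 4096L
  off <- seq.int(-halfwidth, halfwidth)
  off <- off[order(abs(off), off)]
  key_rows <- integer(nrow(candidates))  # row of this candidate in its chrom's matrix
  K_by_chrom <- list()
  for (ch in unique(candidates$chrom)) {
    rows <- which(candidates$chrom == ch)
    key_rows[rows] <- seq_along(rows)
    pos <- by_chrom_pos[[ch]]
    if (is.null(pos)) pos <- integer(0)
    K <- matrix(0L, length(rows), length(off))
    for (r in seq_along(rows)) {
      sc <- count_sides(candidates$center[rows[r]] + off, pos, halfwidth)
      K[r, ] <- sc[, "left"] * KEY_BASE + sc[, "right"]
    }
    K_by_chrom[[ch]] <- K
  }
  if (any(side >= KEY_BASE)) stop("side counts exceed key base", call. = FALSE)

  for (i in seq_len(nrow(promoters))) {
    ch <- promoters$chrom[i]
    pos <- by_chrom_pos[[ch]]
    if (is.null(pos)) pos <- integer(0)
    zch <- zones_by_chrom[[ch]]
    if (is.null(zch)) zch <- data.frame(chrom = character(0), start = integer(0),
                                        end = integer(0))
    need <- side[i, "left"] + side[i, "right"]
    q <- side[i, "left"] * KEY_BASE + side[i, "right"]
    cand_rows <- which(!used & candidates$chrom == ch & span_n >= need)
    K <- K_by_chrom[[ch]]
    hit <- NULL
    for (j in cand_rows) {
      ts <- which(K[key_rows[j], ] == q)
      if (length(ts) == 0L) next
      centers <- candidates$center[j] + off[ts]
      t1 <- which(zone_free(centers, halfwidth, zch$start, zch$end))[1]
      if (!is.na(t1)) {
        hit <- list(center = centers[t1], left_n = unname(side[i, "left"]),
                    right_n = unname(side[i, "right"]), offset = off[ts[t1]],
                    j = j)
        break
      }
    }
    if (is.null(hit)) {
      unmatched <- c(unmatched, promoters$id[i])
    } else {
      used[hit$j] <- TRUE
      if (disjoint) {
        zones_by_chrom[[ch]] <- merge_zones(rbind(
          zch, data.frame(chrom = ch, start = hit$center - halfwidth,
                          end = hit$center + halfwidth)))
      }
      res[[i]] <- data.frame(promoter_id = promoters$id[i], chrom = ch,
                             center = hit$center, left_n = hit$left_n,
                             right_n = hit$right_n,
                             prom_left_n = unname(side[i, "left"]),
                             prom_right_n = unname(side[i, "right"]),
                             cluster_id = candidates$cluster_id[hit$j],
                             offset = hit$offset, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(promoter_id = character(0), chrom = character(0),
                      center = integer(0), left_n = integer(0), right_n = integer(0),
                      prom_left_n = integer(0), prom_right_n = integer(0),
                      cluster_id = integer(0), offset = integer(0))
  }
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  class(out) <- c("match_result", "data.frame")
  out
}

#' Export clusters or matched regions as BED
#'
#' 0-based half-open BED with the site count in the score column.
#'
#' @param clusters data.frame with `start`, `end`, `n_sites` (and optionally
#'   `chrom`).
#' @param path Output path.
#' @param chrom Chromosome name used when `clusters` has no `chrom` column.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path, chrom = "chr") {
  ch <- if ("chrom" %in% names(clusters)) clusters$chrom else rep(chrom, nrow(clusters))
  bed <- data.frame(chrom = ch, start = clusters$start, end = clusters$end + 1L,
                    name = sprintf("cluster_%d", seq_len(nrow(clusters))),
                    score = clusters$n_sites)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a match table as TSV
#'
#' @param matches A `match_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
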