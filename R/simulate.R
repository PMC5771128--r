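#' Configuration for the synthetic NOME-seq generator
#'
#' Bundles and validates every parameter of the simulator. The generator
#' emulates the statistical structure the promoter analysis assumes: a genome
#' whose CpG dinucleotides are under-represented relative to the C+G content
#' while GpC dinucleotides are not; CpG islands around each TSS over a sparse
#' background; additional unannotated ("decoy") CpG islands between promoters,
#' standing in for the genome's many non-promoter CpG clusters that the control
#' matcher draws from; CpG methylation that decreases with local CpG density;
#' nucleosome occupancy with an expression-scaled nucleosome-decreased region
#' (NDR) upstream of each TSS and exponentially damped phased nucleosomes
#' downstream; and binomial read sampling at Poisson coverage.
#'
#' @param seed Integer random seed.
#' @param chrom_name Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param gc_fraction Genome G+C fraction. The default 0.37 makes the expected
#'   CpG frequency `f(C)*f(G)` about 3.4% while planted CpGs sit near 0.9% of
#'   background positions, i.e. a strongly CpG-under-represented genome.
#' @param n_promoters Number of promoters.
#' @param min_tss_spacing Minimum spacing between consecutive TSSs (bp).
#' @param island_halfwidth CpG island half-width around a TSS / decoy center.
#' @param island_cpg_rate Island CpG planting rate (sites/bp) at expression
#'   weight 1 (see `expr_density_coupling`).
#' @param background_cpg_rate Background CpG planting rate (sites/bp).
#' @param background_gpc_rate Uniform GpC planting rate (sites/bp); GpC content
#'   matches what the C+G content predicts, so the default equals
#'   `(gc_fraction/2)^2` rounded to 0.034.
#' @param expr_density_coupling If `TRUE` (default), a promoter's island rate
#'   scales with its expression weight `e`:
#'   `rate = bg + (island_cpg_rate - bg) * (floor + (1-floor)*e)`, emulating
#'   the higher CpG density of highly expressed promoters. If `FALSE`, every
#'   island uses `island_cpg_rate`.
#' @param island_rate_floor Floor of the coupling factor (default 0.15).
#' @param m_max,m_min Methylation plateau at low / high CpG density.
#' @param rho0 Density midpoint of the methylation response (sites/bp).
#' @param rho_slope Logistic slope of the methylation response (sites/bp).
#' @param density_halfwidth Half-width (bp) of the local-density window used by
#'   the methylation response.
#' @param o_bg Baseline nucleosome occupancy away from active TSSs.
#' @param a_ndr NDR amplitude at expression weight 1.
#' @param x_ndr NDR center, bp relative to the TSS (negative = upstream).
#' @param sigma_ndr NDR Gaussian width (bp).
#' @param a_ph Phasing amplitude at expression weight 1.
#' @param period Nucleosome phasing period (bp).
#' @param tau Phasing decay length (bp).
#' @param expr_meanlog,expr_sdlog Log-normal expression distribution.
#' @param expr_half Expression half-saturation: weight `e = x / (x + expr_half)`.
#' @param coverage Mean reads per site (Poisson).
#' @param halfwidth Analysis window half-width (bp).
#' @param decoy_clearance Minimum distance (bp) between a decoy island center
#'   and any TSS; large enough that a shifted control window can never touch a
#'   promoter exclusion zone.
#' @param decoy_spacing Spacing (bp) between decoy centers within a gap.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, chrom_name = "chrS", chrom_length = 2e6,
                       gc_fraction = 0.37,
                       n_promoters = 200L, min_tss_spacing = 5000L,
                       island_halfwidth = 500L,
                       island_cpg_rate = 0.08, background_cpg_rate = 0.009,
                       background_gpc_rate = 0.034,
                       expr_density_coupling = TRUE, island_rate_floor = 0.15,
                       m_max = 0.85, m_min = 0.10, rho0 = 0.04,
                       rho_slope = 0.008, density_halfwidth = 100L,
                       o_bg = 0.75, a_ndr = 0.4, x_ndr = -150L, sigma_ndr = 80,
                       a_ph = 0.12, period = 200, tau = 600,
                       expr_meanlog = log(5), expr_sdlog = 1.5, expr_half = 5,
                       coverage = 20, halfwidth = 1000L,
                       decoy_clearance = 3100L, decoy_spacing = 1700L) {
  cfg <- as.list(environment())
  rates <- c(island_cpg_rate, background_cpg_rate, background_gpc_rate)
  if (any(rates < 0)) stop("planting rates must be non-negative", call. = FALSE)
  if (island_cpg_rate + background_gpc_rate > 1 / 3) {
    stop("combined planting rates exceed the 1-site-per-3-bp packing limit",
         call. = FALSE)
  }
  if (!(m_min <= m_max && m_min >= 0 && m_max <= 1)) {
    stop("need 0 <= m_min <= m_max <= 1", call. = FALSE)
  }
  if (o_bg - a_ndr < 0 || o_bg + a_ph > 1) {
    stop("occupancy model leaves [0,1]: need o_bg - a_ndr >= 0 and o_bg + a_ph <= 1",
         call. = FALSE)
  }
  if (abs(x_ndr) > halfwidth) stop("x_ndr must lie within the window", call. = FALSE)
  if (coverage < 0) stop("coverage must be non-negative", call. = FALSE)
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction in (0,1)", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Density-dependent true methylation probability
#'
#' `m(rho) = m_max - (m_max - m_min) * logistic((rho - rho0) / rho_slope)`:
#' strictly decreasing in local CpG density, saturating at `m_max` in sparse
#' background and at `m_min` inside dense islands.
#'
#' @param local_density Local CpG density (sites/bp).
#' @param config A `sim_config`.
#' @return Methylation probabilities in `[m_min, m_max]`.
#' @export
true_methylation <- function(local_density, config) {
  config$m_max - (config$m_max - config$m_min) *
    stats::plogis((local_density - config$rho0) / config$rho_slope)
}

#' True nucleosome occupancy around a TSS
#'
#' With `x` the strand-oriented offset from the TSS and `e` the expression
#' weight in `[0,1]`:
#' `O(x) = o_bg - e*a_ndr*exp(-(x - x_ndr)^2 / (2*sigma_ndr^2))
#'         + e*a_ph*cos(2*pi*x/period)*exp(-x/tau)*[x > 0]`,
#' clamped to `[0,1]`. Positions with no TSS within the window half-width get
#' `o_bg` (use `has_tss = FALSE`).
#'
#' @param x Oriented offsets from the TSS (bp).
#' @param e Expression weights in `[0,1]` (recycled).
#' @param config A `sim_config`.
#' @param has_tss Logical (recycled): `FALSE` forces the flat background value.
#' @return Occupancies in `[0,1]`.
#' @export
true_occupancy <- function(x, e, config, has_tss = TRUE) {
  n <- max(length(x), length(e), length(has_tss))
  x <- rep_len(x, n)
  e <- rep_len(e, n)
  has_tss <- rep_len(has_tss, n)
  ndr <- e * config$a_ndr * exp(-(x - config$x_ndr)^2 / (2 * config$sigma_ndr^2))
  ph <- e * config$a_ph * cos(2 * pi * x / config$period) *
    exp(-x / config$tau) * (x > 0)
  occ <- config$o_bg - ndr + ph
  occ[!has_tss] <- config$o_bg
  pmin(pmax(occ, 0), 1)
}

# sample n positions in [lo, hi] (0-based starts), uniform without replacement
sample_segment <- function(lo, hi, n) {
  width <- hi - lo + 1L
  n <- min(n, width)
  if (n <= 0L) return(integer(0))
  lo + sample.int(width, n) - 1L
}

# enforce a minimum gap of 3 bp between all planted dinucleotide starts by
# re-drawing violators inside their own segment; count is preserved unless the
# packing is infeasible (then leftovers are dropped with a message)
resolve_collisions <- function(df, min_gap = 3L, max_iter = 500L) {
  for (it in seq_len(max_iter)) {
    ord <- order(df$pos, df$seg_lo)
    d <- diff(df$pos[ord])
    bad <- ord[which(d < min_gap) + 1L]
    if (length(bad) == 0L) return(df)
    for (b in bad) {
      df$pos[b] <- sample_segment(df$seg_lo[b], df$seg_hi[b], 1L)
    }
  }
  ord <- order(df$pos, df$seg_lo)
  d <- diff(df$pos[ord])
  bad <- ord[which(d < min_gap) + 1L]
  if (length(bad) > 0L) {
    message("dropping ", length(bad), " unplaceable planted site(s)")
    df <- df[-bad, , drop = FALSE]
  }
  df
}

#' Simulate a genome, promoter annotation and ground truth
#'
#' Generates an iid base sequence at the configured GC fraction, strips every
#' native CpG and GpC dinucleotide (randomly replacing one of the two bases),
#' then plants `CG` dinucleotides at the background rate genome-wide and at the
#' island rate within `+/- island_halfwidth` of each TSS and each decoy center,
#' and `GC` dinucleotides at a uniform background rate. Planted sites keep a
#' minimum 3 bp spacing and flanking bases are adjusted so that no unplanned
#' CpG/GpC arises -- the planted coordinates are therefore exactly the
#' dinucleotide sites of the emitted sequence, which pins down the ground
#' truth. TSS strands are assigned +/- with equal probability and expression is
#' drawn per promoter. Deterministic under `config$seed`.
#'
#' @param config A `sim_config`.
#' @return List with `genome` (named character vector), `anchors` (promoter
#'   data.frame: `id`, `chrom`, `pos`, `strand`, `expression`) and `truth`
#'   (list: per-CpG `local_density` and `true_meth`, per-GpC `true_occ`,
#'   promoter table with expression weights and island rates, decoy table,
#'   and the config).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- as.integer(config$chrom_length)
  n <- as.integer(config$n_promoters)
  H <- config$halfwidth
  ihw <- config$island_halfwidth

  # --- stage 1: anchors -----------------------------------------------------
  tss <- integer(0); strand <- character(0); expr <- numeric(0); e <- numeric(0)
  decoy <- integer(0); de <- numeric(0)
  if (n > 0L) {
    slot <- floor(L / n)
    if (slot < config$min_tss_spacing) {
      stop("promoters do not fit: ", n, " promoters need spacing >= ",
           config$min_tss_spacing, " in ", L, " bp", call. = FALSE)
    }
    tss_offset <- H + ihw + 100L
    jit <- sample.int(301L, n, replace = TRUE) - 151L
    tss <- as.integer((seq_len(n) - 1L) * slot + tss_offset + jit)
    if (tss[n] + H + ihw >= L) {
      stop("promoters do not fit near the chromosome end", call. = FALSE)
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    expr <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
    e <- expr / (expr + config$expr_half)

    # decoy islands in the gaps between consecutive TSSs (and after the last)
    gap_hi <- c(tss[-1L], L - tss_offset) - config$decoy_clearance
    gap_lo <- tss + config$decoy_clearance
    for (i in seq_len(n)) {
      if (gap_hi[i] < gap_lo[i]) next
      centers <- seq.int(gap_lo[i], gap_hi[i], by = config$decoy_spacing)
      centers <- centers + sample.int(201L, length(centers), replace = TRUE) - 101L
      decoy <- c(decoy, pmin(pmax(centers, gap_lo[i]), gap_hi[i]))
    }
    decoy <- as.integer(decoy)
    dx <- stats::rlnorm(length(decoy), config$expr_meanlog, config$expr_sdlog)
    de <- dx / (dx + config$expr_half)
  }

  island_rate <- function(ew) {
    if (config$expr_density_coupling) {
      config$background_cpg_rate +
        (config$island_cpg_rate - config$background_cpg_rate) *
        (config$island_rate_floor + (1 - config$island_rate_floor) * ew)
    } else {
      rep(config$island_cpg_rate, length(ew))
    }
  }
  prom_rate <- island_rate(e)
  decoy_rate <- island_rate(de)

  # --- stage 2: base sequence ----------------------------------------------
  gc <- config$gc_fraction
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  # --- stage 3: strip native CG and GC dinucleotides ------------------------
  for (pass in 1:5) {
    i <- which(base[-L] == "C" & base[-1L] == "G")
    j <- which(base[-L] == "G" & base[-1L] == "C")
    if (length(i) == 0L && length(j) == 0L) break
    if (length(i)) {
      pick <- sample(c(0L, 1L), length(i), replace = TRUE)
      base[i + pick] <- sample(c("A", "T"), length(i), replace = TRUE)
    }
    j <- which(base[-L] == "G" & base[-1L] == "C")
    if (length(j)) {
      pick <- sample(c(0L, 1L), length(j), replace = TRUE)
      base[j + pick] <- sample(c("A", "T"), length(j), replace = TRUE)
    }
  }

  # --- stage 4: plant CpG and GpC positions ---------------------------------
  # island intervals (0-based starts of the C of each CpG)
  isl <- data.frame(lo = c(tss - ihw, decoy - ihw),
                    hi = c(tss + ihw, decoy + ihw),
                    rate = c(prom_rate, decoy_rate))
  if (nrow(isl)) {
    isl$lo <- pmax(isl$lo, 0L)
    isl$hi <- pmin(isl$hi, L - 2L)
    isl <- isl[order(isl$lo), , drop = FALSE]
  }
  # background = complement of the islands over [0, L-2]
  bg <- list()
  cur <- 0L
  if (nrow(isl)) {
    for (k in seq_len(nrow(isl))) {
      if (isl$lo[k] > cur) bg[[length(bg) + 1L]] <- c(cur, isl$lo[k] - 1L)
      cur <- max(cur, isl$hi[k] + 1L)
    }
  }
  if (cur <= L - 2L) bg[[length(bg) + 1L]] <- c(cur, L - 2L)

  plant_one <- function(lo, hi, rate, type) {
    width <- hi - lo + 1L
    if (width <= 0L || rate <= 0) return(NULL)
    n_k <- stats::rbinom(1L, width, min(rate, 1))
    if (n_k == 0L) return(NULL)
    data.frame(pos = sample_segment(lo, hi, n_k), type = type,
               seg_lo = lo, seg_hi = hi)
  }
  plants <- list()
  if (nrow(isl)) {
    for (k in seq_len(nrow(isl))) {
      plants[[length(plants) + 1L]] <- plant_one(isl$lo[k], isl$hi[k],
                                                 isl$rate[k], "CpG")
    }
  }
  for (sg in bg) {
    plants[[length(plants) + 1L]] <- plant_one(sg[1], sg[2],
                                               config$background_cpg_rate, "CpG")
  }
  plants[[length(plants) + 1L]] <- plant_one(0L, L - 2L,
                                             config$background_gpc_rate, "GpC")
  plants <- do.call(rbind, plants)
  if (is.null(plants)) {
    plants <- data.frame(pos = integer(0), type = character(0),
                         seg_lo = integer(0), seg_hi = integer(0))
  }
  plants <- resolve_collisions(plants)

  # --- stage 5: write planted dinucleotides, guard the flanks ---------------
  cp <- plants$pos[plants$type == "CpG"]
  gp <- plants$pos[plants$type == "GpC"]
  base[cp + 1L] <- "C"; base[cp + 2L] <- "G"
  base[gp + 1L] <- "G"; base[gp + 2L] <- "C"
  fix <- function(idx) {
    idx <- idx[idx >= 1L & idx <= L]
    base[idx] <<- sample(c("A", "T"), length(idx), replace = TRUE)
  }
  fix(cp[cp >= 1L & base[pmax(cp, 1L)] == "G"])            # G|CG -> GpC
  fix((cp + 3L)[cp + 3L <= L & base[pmin(cp + 3L, L)] == "C"])  # CG|C -> GpC
  fix(gp[gp >= 1L & base[pmax(gp, 1L)] == "C"])            # C|GC -> CpG
  fix((gp + 3L)[gp + 3L <= L & base[pmin(gp + 3L, L)] == "G"])  # GC|G -> CpG

  genome <- stats::setNames(paste(base, collapse = ""), config$chrom_name)

  # --- ground truth ---------------------------------------------------------
  # site coordinate convention: the cytosine of the dinucleotide, i.e. the
  # planted start for CpG and the second base for GpC
  cp <- sort(cp); gp <- sort(gp) + 1L
  dh <- config$density_halfwidth
  local_density <- (findInterval(cp + dh, cp) - findInterval(cp - dh - 1L, cp)) /
    (2 * dh + 1)
  cpg_truth <- data.frame(chrom = config$chrom_name, pos = cp,
                          local_density = local_density,
                          true_meth = true_methylation(local_density, config))
  if (n > 0L && length(gp)) {
    k <- findInterval(gp, tss)
    lo_tss <- pmax(k, 1L); hi_tss <- pmin(k + 1L, n)
    near <- ifelse(abs(gp - tss[lo_tss]) <= abs(gp - tss[hi_tss]), lo_tss, hi_tss)
    dist <- gp - tss[near]
    in_win <- abs(dist) <= H
    dirn <- ifelse(strand[near] == "-", -1L, 1L)
    occ <- true_occupancy(dirn * dist, e[near], config, has_tss = in_win)
  } else {
    occ <- rep(config$o_bg, length(gp))
  }
  gpc_truth <- data.frame(chrom = config$chrom_name, pos = gp, true_occ = occ)

  anchors <- data.frame(id = sprintf("P%04d", seq_len(n)),
                        chrom = rep(config$chrom_name, n), pos = tss,
                        strand = strand, expression = expr,
                        stringsAsFactors = FALSE)
  truth <- list(cpg = cpg_truth, gpc = gpc_truth,
                promoters = cbind(anchors,
                                  data.frame(e_weight = e, island_rate = prom_rate)),
                decoys = data.frame(center = decoy, e_weight = de,
                                    island_rate = decoy_rate),
                config = config)
  list(genome = genome, anchors = anchors, truth = truth)
}

#' Sample NOME-seq reads from the ground truth
#'
#' Per site, total reads are Poisson at the configured mean coverage and
#' methylated reads are binomial with success probability equal to the true
#' methylation for CpG sites and `1 - true occupancy` for GpC sites (the
#' exogenous methyltransferase only reaches unprotected GpCs). Deterministic
#' under `config$seed` (its own stream, offset from the genome stage).
#'
#' @param truth Ground-truth list from [simulate_genome()].
#' @param config A `sim_config`.
#' @return A `site_table` covering every planted CpG and GpC site.
#' @export
sample_reads <- function(truth, config) {
  set.seed(config$seed + 1L)
  p <- c(truth$cpg$true_meth, 1 - truth$gpc$true_occ)
  chrom <- c(truth$cpg$chrom, truth$gpc$chrom)
  pos <- c(truth$cpg$pos, truth$gpc$pos)
  context <- c(rep("CpG", nrow(truth$cpg)), rep("GpC", nrow(truth$gpc)))
  total <- stats::rpois(length(p), config$coverage)
  meth <- stats::rbinom(length(p), total, p)
  site_table(chrom, pos, context, meth, total)
}

#' Run the full synthetic experiment
#'
#' [simulate_genome()] followed by [sample_reads()].
#'
#' @param config A `sim_config`.
#' @return List with `genome`, `anchors`, `sites` (a `site_table`) and `truth`.
#' @export
simulate_nome <- function(config = sim_config()) {
  g <- simulate_genome(config)
  sites <- sample_reads(g$truth, config)
  c(g, list(sites = sites))
}

#' Write promoter anchors as BED6 + expression
#'
#' Columns: chrom, start, end (start+1), name, score (0), strand, expression.
#'
#' @param anchors Promoter data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters_bed <- function(anchors, path) {
  bed <- data.frame(chrom = anchors$chrom, start = anchors$pos,
                    end = anchors$pos + 1L, name = anchors$id,
                    score = rep(0L, nrow(anchors)),
                    strand = anchors$strand, expression = anchors$expression)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read promoter anchors from BED6 + expression
#'
#' @param path Input path.
#' @return Promoter data.frame with `id`, `chrom`, `pos`, `strand`,
#'   `expression`.
#' @export
read_promoters_bed <- function(path) {
  empty <- data.frame(id = character(0), chrom = character(0), pos = integer(0),
                      strand = character(0), expression = numeric(0))
  if (file.size(path) == 0L) return(empty)
  x <- utils::read.table(path, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 7) stop("expected BED6 + expression column", call. = FALSE)
  names(x)[1:7] <- c("chrom", "start", "end", "name", "score", "strand", "expression")
  data.frame(id = x$name, chrom = x$chrom, pos = x$start, strand = x$strand,
             expression = x$expression, stringsAsFactors = FALSE)
}
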