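#' Run configuration for the pipeline commands
#'
#' The pipeline is driven by a flat key-value configuration (YAML on disk).
#' Defaults are the analysis constants: 1000 bp window half-width, 30 bp
#' smoothing, 20/50 bp cluster gaps, 5% expression strata. Every default that
#' fills an unspecified field is logged, and each command writes a resolved
#' copy of its configuration next to its outputs.
#'
#' @param out_dir Output directory.
#' @param genome,sites,promoters Input paths (FASTA / site TSV / BED6+expr);
#'   default to the files `cmd_simulate()` writes into `out_dir`.
#' @param halfwidth Window half-width (bp).
#' @param smooth_bp Smoothing window (bp).
#' @param intra_gap,inter_gap Cluster detection / merging gaps (bp).
#' @param expr_q Expression stratum quantile fraction.
#' @param orient Orient windows by strand.
#' @param seed Seed for the simulate command.
#' @param sim Optional list of overrides passed to [sim_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = "nome_out",
                       genome = file.path(out_dir, "genome.fa"),
                       sites = file.path(out_dir, "sites.tsv"),
                       promoters = file.path(out_dir, "promoters.bed"),
                       halfwidth = 1000L, smooth_bp = 30L,
                       intra_gap = 20L, inter_gap = 50L,
                       expr_q = 0.05, orient = TRUE, seed = 1L,
                       sim = list()) {
  cfg <- as.list(environment())
  if (!(expr_q > 0 && expr_q <= 0.5)) {
    stop_config("expr_q must lie in (0, 0.5]")
  }
  if (halfwidth < 1 || smooth_bp < 1 || intra_gap < 1 || inter_gap < 1) {
    stop_config("halfwidth, smooth_bp and cluster gaps must be >= 1")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Unknown keys are a configuration error; omitted keys fall back to the
#' defaults of [run_config()] and each fallback is logged via `message()`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_config("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (k in setdiff(known, names(vals))) {
    if (!(k %in% c("genome", "sites", "promoters"))) {
      message("config: using default for '", k, "'")
    }
  }
  do.call(run_config, vals)
}

write_resolved_config <- function(cfg, out_dir) {
  x <- unclass(cfg)
  x$sim <- if (length(x$sim)) x$sim else NULL
  yaml::write_yaml(x, file.path(out_dir, "resolved_config.yaml"))
}

# condition helpers mapped to CLI exit codes 2/3/4
stop_config <- function(...) {
  stop(structure(class = c("nome_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
stop_input <- function(...) {
  stop(structure(class = c("nome_input_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
stop_empty <- function(...) {
  stop(structure(class = c("nome_empty_result", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

need_file <- function(path, what) {
  if (!file.exists(path)) stop_input(what, " not found: ", path)
  path
}

#' Simulate a synthetic NOME-seq data set to disk
#'
#' Writes `genome.fa`, `promoters.bed` (BED6 + expression), `sites.tsv`,
#' ground-truth TSVs (`truth_cpg.tsv`, `truth_gpc.tsv`, `truth_promoters.tsv`)
#' and the resolved configuration into `cfg$out_dir`.
#'
#' @param cfg A `run_config`.
#' @return The simulation list from [simulate_nome()], invisibly.
#' @export
cmd_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- do.call(sim_config, c(list(seed = cfg$seed, halfwidth = cfg$halfwidth),
                              cfg$sim))
  sim <- simulate_nome(sc)
  write_genome(sim$genome, file.path(cfg$out_dir, "genome.fa"))
  write_promoters_bed(sim$anchors, file.path(cfg$out_dir, "promoters.bed"))
  write_site_table(sim$sites, file.path(cfg$out_dir, "sites.tsv"))
  utils::write.table(sim$truth$cpg, file.path(cfg$out_dir, "truth_cpg.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$gpc, file.path(cfg$out_dir, "truth_gpc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$promoters,
                     file.path(cfg$out_dir, "truth_promoters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_resolved_config(cfg, cfg$out_dir)
  invisible(sim)
}

#' Locate dinucleotide sites and composition statistics
#'
#' Reads the genome, writes CpG and GpC sites as BED and a composition table
#' (observed, expected, ratio per motif).
#'
#' @param cfg A `run_config`.
#' @return data.frame of composition statistics, invisibly.
#' @export
cmd_sites <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome(need_file(cfg$genome, "genome FASTA"))
  for (m in c("CG", "GC")) {
    sites <- genome_sites(genome, m)
    write_sites_bed(sites, file.path(cfg$out_dir,
                                     sprintf("sites_%s.bed", sites$context[1] %||% m)))
  }
  comp <- do.call(rbind, lapply(c("CG", "GC"), function(m) {
    r <- dinucleotide_representation(genome, m)
    data.frame(motif = m, observed = r$observed, expected = r$expected,
               ratio = r$ratio)
  }))
  utils::write.table(comp, file.path(cfg$out_dir, "composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_resolved_config(cfg, cfg$out_dir)
  invisible(comp)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

# shared input loading for profile/match/stratify
load_inputs <- function(cfg) {
  genome <- read_genome(need_file(cfg$genome, "genome FASTA"))
  sites <- read_site_table(need_file(cfg$sites, "site table"))
  promoters <- read_promoters_bed(need_file(cfg$promoters, "promoter BED"))
  list(genome = genome, sites = sites, promoters = promoters,
       cpg = genome_sites(genome, "CG"), clen = chrom_lengths(genome))
}

profile_anchors <- function(inp, anchors, cfg, dedup = TRUE) {
  ws <- extract_windows(inp$sites, inp$cpg, anchors, cfg$halfwidth,
                        chrom_len = inp$clen, orient = cfg$orient)
  if (nrow(ws$anchors) == 0L) stop_empty("no usable anchors")
  if (dedup) ws <- dedup_cpg_indicators(ws)
  average_profiles(ws)
}

#' Promoter profile command
#'
#' Builds the anchor-aligned average profile over all promoters (or a supplied
#' anchor set) and writes the raw and smoothed profile TSVs.
#'
#' @param cfg A `run_config`.
#' @param anchors Optional anchor data.frame overriding the promoter file.
#' @param label Output file label.
#' @return The smoothed profile, invisibly.
#' @export
cmd_profile <- function(cfg, anchors = NULL, label = "promoters") {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(cfg)
  if (is.null(anchors)) anchors <- inp$promoters
  prof <- profile_anchors(inp, anchors, cfg)
  write_profile(prof, file.path(cfg$out_dir, sprintf("profile_%s_raw.tsv", label)))
  sm <- smooth_profile(prof, cfg$smooth_bp)
  write_profile(sm, file.path(cfg$out_dir, sprintf("profile_%s.tsv", label)))
  write_resolved_config(cfg, cfg$out_dir)
  invisible(sm)
}

#' Control-region matching command
#'
#' Detects and merges CpG clusters, builds promoter exclusion zones, matches
#' every promoter to a shifted non-promoter cluster region with identical
#' per-side CpG counts, and writes `clusters.bed`, `controls.bed` and
#' `matches.tsv`.
#'
#' @param cfg A `run_config`.
#' @param disjoint Forbid overlap between accepted control regions.
#' @return The `match_result`, invisibly.
#' @export
cmd_match <- function(cfg, disjoint = FALSE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(cfg)
  zones <- build_exclusion(inp$promoters, cfg$halfwidth)
  cand_all <- list(); clus_all <- list()
  for (ch in names(inp$genome)) {
    pos <- sort(inp$cpg$pos[inp$cpg$chrom == ch])
    cl <- merge_clusters(detect_clusters(pos, cfg$intra_gap), cfg$inter_gap)
    if (nrow(cl) == 0L) next
    cl$chrom <- ch
    clus_all[[ch]] <- cl
    cand <- candidate_regions(cl, cfg$halfwidth, chrom_len = inp$clen[ch])
    if (nrow(cand)) {
      cand$chrom <- ch
      cand_all[[ch]] <- cand
    }
  }
  clusters <- do.call(rbind, clus_all)
  candidates <- do.call(rbind, cand_all)
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop_empty("no candidate cluster regions found")
  }
  matches <- match_all(inp$promoters, candidates, inp$cpg, zones, cfg$halfwidth,
                       disjoint = disjoint)
  write_clusters_bed(clusters, file.path(cfg$out_dir, "clusters.bed"))
  ctrl <- data.frame(chrom = matches$chrom, start = matches$center - cfg$halfwidth,
                     end = matches$center + cfg$halfwidth + 1L,
                     name = matches$promoter_id,
                     score = matches$left_n + matches$right_n)
  utils::write.table(ctrl, file.path(cfg$out_dir, "controls.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_matches(matches, file.path(cfg$out_dir, "matches.tsv"))
  write_resolved_config(cfg, cfg$out_dir)
  invisible(matches)
}

match_controls_as_anchors <- function(matches) {
  data.frame(id = paste0("C_", matches$promoter_id), chrom = matches$chrom,
             pos = matches$center, strand = "+",
             stringsAsFactors = FALSE)
}

#' Stratification command
#'
#' Selects the expression strata (top/bottom `expr_q`), the low-CpG-density
#' promoters (density below the all-promoter mean), and -- when a match table
#' is available -- the matched controls per stratum plus low-methylation
#' controls (below the all-control mean), profiles each stratum, and writes
#' per-stratum anchor lists, profiles, and a summary table of per-profile
#' means.
#'
#' @param cfg A `run_config`.
#' @param matches Optional `match_result` from [cmd_match()]; when `NULL`,
#'   `matches.tsv` in `out_dir` is used if present.
#' @return The summary table, invisibly.
#' @export
cmd_stratify <- function(cfg, matches = NULL) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_inputs(cfg)
  prom <- inp$promoters
  if (anyNA(prom$expression)) {
    stop_input("expression stratification requested but expression is missing")
  }
  strata <- list(
    all = prom,
    high_expr = select_by_expression(prom, cfg$expr_q, "top"),
    low_expr = select_by_expression(prom, cfg$expr_q, "bottom")
  )
  dens <- mean_region_density(prom, inp$cpg, cfg$halfwidth, inp$clen)
  low_ids <- select_below_threshold(prom$id, dens, mean(dens, na.rm = TRUE))
  strata$low_density <- prom[prom$id %in% low_ids, , drop = FALSE]

  if (is.null(matches) && file.exists(file.path(cfg$out_dir, "matches.tsv"))) {
    matches <- utils::read.delim(file.path(cfg$out_dir, "matches.tsv"),
                                 stringsAsFactors = FALSE)
  }
  if (!is.null(matches) && nrow(matches) > 0) {
    ctrl <- match_controls_as_anchors(matches)
    strata$controls_all <- ctrl
    for (s in c("high_expr", "low_expr")) {
      sel <- matches$promoter_id %in% strata[[s]]$id
      strata[[paste0("controls_", s)]] <-
        match_controls_as_anchors(matches[sel, , drop = FALSE])
    }
    cm <- mean_region_methylation(ctrl, inp$sites, cfg$halfwidth)
    keep <- ctrl$id %in% select_below_threshold(ctrl$id, cm, mean(cm, na.rm = TRUE))
    strata$controls_low_meth <- ctrl[keep, , drop = FALSE]
  }

  summaries <- list()
  for (s in names(strata)) {
    a <- strata[[s]]
    utils::write.table(a, file.path(cfg$out_dir, sprintf("stratum_%s.tsv", s)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(a) == 0L) {
      warning("stratum '", s, "' is empty; no profile written", call. = FALSE)
      next
    }
    prof <- smooth_profile(profile_anchors(inp, a, cfg), cfg$smooth_bp)
    write_profile(prof, file.path(cfg$out_dir, sprintf("profile_%s.tsv", s)))
    summaries[[s]] <- summarize_profile(prof, s)
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  utils::write.table(summary, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_resolved_config(cfg, cfg$out_dir)
  invisible(summary)
}

#' Summarize existing profile files
#'
#' Reads every `profile_<label>.tsv` in the output directory and writes the
#' per-profile mean table.
#'
#' @param cfg A `run_config`.
#' @return The summary table, invisibly.
#' @export
cmd_summarize <- function(cfg) {
  files <- list.files(cfg$out_dir, pattern = "^profile_.*\\.tsv$", full.names = TRUE)
  files <- files[!grepl("_raw\\.tsv$", files)]
  if (length(files) == 0L) stop_empty("no profile files in ", cfg$out_dir)
  summary <- do.call(rbind, lapply(files, function(f) {
    label <- sub("^profile_(.*)\\.tsv$", "\\1", basename(f))
    summarize_profile(read_profile(f), label)
  }))
  utils::write.table(summary, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}
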