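# shared fixtures: small in-code genomes, window sets, and memoized simulations

random_seq <- function(n, alphabet = c("A", "C", "G", "T"), p_n = 0) {
  letters <- sample(alphabet, n, replace = TRUE)
  if (p_n > 0) {
    mask <- stats::runif(n) < p_n
    letters[mask] <- "N"
  }
  paste(letters, collapse = "")
}

reverse_complement <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# naive character-by-character dinucleotide scan (independent oracle)
naive_find_sites <- function(seq, motif) {
  s <- strsplit(toupper(seq), "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  hits <- integer(0)
  if (length(s) >= 2) {
    for (i in seq_len(length(s) - 1)) {
      if (s[i] == m[1] && s[i + 1] == m[2]) hits <- c(hits, i - 1L)
    }
  }
  offset <- if (m[2] == "C" && m[1] != "C") 1L else 0L
  hits + offset
}

# linear-scan oracle for cluster detection
naive_clusters <- function(pos, gap) {
  if (length(pos) == 0) return(list())
  runs <- list(pos[1])
  for (p in pos[-1]) {
    last <- runs[[length(runs)]]
    if (p - last[length(last)] < gap) {
      runs[[length(runs)]] <- c(last, p)
    } else {
      runs[[length(runs) + 1]] <- p
    }
  }
  runs
}

# a small window_set built directly from matrices (bypasses extraction)
make_window_set <- function(occ, meth, cpg, anchors = NULL, halfwidth = NULL) {
  n <- nrow(occ)
  p <- ncol(occ)
  if (is.null(halfwidth)) halfwidth <- (p - 1L) / 2L
  if (is.null(anchors)) {
    anchors <- data.frame(id = sprintf("A%03d", seq_len(n)), chrom = "chrT",
                          pos = seq_len(n) * 10000L, strand = "+",
                          stringsAsFactors = FALSE)
  }
  structure(list(rel = seq.int(-halfwidth, halfwidth), occ = occ, meth = meth,
                 cpg = cpg, anchors = anchors, dir = rep(1L, n),
                 halfwidth = as.integer(halfwidth)),
            class = "window_set")
}

# small, fast simulation for unit tests (memoized per seed)
.sim_cache <- new.env(parent = emptyenv())

tiny_sim <- function(seed = 42, ...) {
  extra <- list(...)
  key <- paste0("tiny_", seed, "_",
                paste(names(extra), unlist(extra), sep = "=", collapse = ","))
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  args <- utils::modifyList(list(seed = seed, chrom_length = 150000,
                                 n_promoters = 12, min_tss_spacing = 8000),
                            extra)
  .sim_cache[[key]] <- simulate_nome(do.call(sim_config, args))
  .sim_cache[[key]]
}

# full-scale simulations shared by the acceptance tests
acc_sim <- function(seed, n_promoters = 200) {
  key <- paste0("acc_", seed, "_", n_promoters)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  cfg <- sim_config(seed = seed, n_promoters = n_promoters)
  .sim_cache[[key]] <- simulate_nome(cfg)
  .sim_cache[[key]]
}

cpg_df_of <- function(sim) {
  data.frame(chrom = sim$anchors$chrom[1] %||% names(sim$genome)[1],
             pos = sort(sim$truth$cpg$pos), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

# matched controls on the default full-scale simulation (memoized)
acc_match <- function(seed, disjoint = TRUE) {
  key <- paste0("match_", seed, "_", disjoint)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  sim <- acc_sim(seed)
  cpg <- cpg_df_of(sim)
  cl <- merge_clusters(detect_clusters(cpg$pos, 20), 50)
  cand <- suppressMessages(
    candidate_regions(cl, 1000, chrom_len = unname(chrom_lengths(sim$genome)[1])))
  cand$chrom <- names(sim$genome)[1]
  zones <- build_exclusion(sim$anchors, 1000)
  .sim_cache[[key]] <- match_all(sim$anchors, cand, cpg, zones, 1000,
                                 disjoint = disjoint)
  .sim_cache[[key]]
}

# shared profiling shortcut: extract, dedup, average, smooth
smoothed_profile <- function(sim, anchors, smooth_bp = 30, orient = TRUE) {
  cpg <- cpg_df_of(sim)
  ws <- extract_windows(sim$sites, cpg, anchors, 1000,
                        chrom_len = chrom_lengths(sim$genome), orient = orient)
  ws <- dedup_cpg_indicators(ws)
  smooth_profile(average_profiles(ws), smooth_bp)
}

controls_as_anchors <- function(matches) {
  data.frame(id = paste0("C_", matches$promoter_id), chrom = matches$chrom,
             pos = matches$center, strand = "+", stringsAsFactors = FALSE)
}
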