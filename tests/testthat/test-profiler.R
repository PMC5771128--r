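# a small measured fixture: one chromosome, hand-placed sites
fixture_sites <- function() {
  site_table(chrom = rep("chrT", 4),
             pos = c(4997L, 5003L, 5010L, 5003L),
             context = c("GpC", "CpG", "GpC", "GpC"),
             meth_reads = c(2, 1, 0, 8),
             total_reads = c(10, 4, 0, 10))
}

test_that("window extraction maps genomic to relative coordinates by strand", {
  cpg <- data.frame(chrom = "chrT", pos = 5003L)
  anchor_plus <- list(chrom = "chrT", pos = 5000L, strand = "+")
  w <- extract_window(fixture_sites(), cpg, anchor_plus, halfwidth = 10)
  expect_false(w$skipped)
  expect_equal(w$cpg[w$rel == 3], 1L)
  expect_equal(sum(w$cpg), 1L)
  # occupancy = 1 - GpC level at rel -3 (site 4997: 2/10 methylated)
  expect_equal(w$occ[w$rel == -3], 0.8)
  # zero-coverage GpC at 5010 stays missing
  expect_true(is.na(w$occ[w$rel == 10]))
  # CpG methylation level at +3
  expect_equal(w$meth[w$rel == 3], 0.25)

  anchor_minus <- list(chrom = "chrT", pos = 5000L, strand = "-")
  w2 <- extract_window(fixture_sites(), cpg, anchor_minus, halfwidth = 10)
  expect_equal(w2$cpg[w2$rel == -3], 1L)
  expect_equal(w2$occ[w2$rel == 3], 0.8)
  # with orientation off, the minus window looks like the plus window
  w3 <- extract_window(fixture_sites(), cpg, anchor_minus, halfwidth = 10,
                       orient = FALSE)
  expect_equal(w3$cpg, w$cpg)
})

test_that("empty site tables give all-missing tracks and zero indicators", {
  empty <- site_table(character(0), integer(0), character(0), numeric(0), numeric(0))
  cpg0 <- data.frame(chrom = character(0), pos = integer(0))
  w <- extract_window(empty, cpg0, list(chrom = "chrT", pos = 5000L, strand = "+"),
                      halfwidth = 50)
  expect_true(all(is.na(w$occ)))
  expect_true(all(is.na(w$meth)))
  expect_true(all(w$cpg == 0L))
})

test_that("out-of-bounds anchors are flagged, not dropped silently", {
  cpg <- data.frame(chrom = "chrT", pos = 5003L)
  anchors <- data.frame(id = c("a", "b"), chrom = "chrT", pos = c(5L, 5000L),
                        strand = "+")
  expect_message(
    ws <- extract_windows(fixture_sites(), cpg, anchors, halfwidth = 100),
    "out of chromosome bounds")
  expect_equal(nrow(ws$anchors), 1)
  expect_equal(attr(ws, "skipped")$id, "a")
  w <- suppressMessages(
    extract_window(fixture_sites(), cpg, list(chrom = "chrT", pos = 5L),
                   halfwidth = 100))
  expect_true(w$skipped)
})

test_that("dedup excludes shared CpGs from later windows only", {
  cpg <- data.frame(chrom = "chrT", pos = c(5003L, 5400L))
  empty <- site_table(character(0), integer(0), character(0), numeric(0), numeric(0))
  # two windows overlapping by 500 bp share the CpG at 5400
  anchors <- data.frame(id = c("w1", "w2"), chrom = "chrT",
                        pos = c(5000L, 5500L), strand = "+")
  ws <- dedup_cpg_indicators(extract_windows(empty, cpg, anchors, halfwidth = 500))
  expect_equal(ws$cpg[1, ws$rel == 3], 1L)       # 5003 only in w1
  expect_equal(ws$cpg[1, ws$rel == 400], 1L)     # 5400 first seen in w1
  expect_true(is.na(ws$cpg[2, ws$rel == -100]))  # 5400 excluded in w2

  # non-overlapping windows are untouched
  far <- data.frame(id = c("w1", "w2"), chrom = "chrT",
                    pos = c(5000L, 9000L), strand = "+")
  ws2 <- extract_windows(empty, cpg, far, halfwidth = 500)
  expect_identical(dedup_cpg_indicators(ws2)$cpg, ws2$cpg)

  # a duplicated window loses all its indicators
  dup <- data.frame(id = c("w1", "w1b"), chrom = "chrT",
                    pos = c(5000L, 5000L), strand = "+")
  ws3 <- dedup_cpg_indicators(extract_windows(empty, cpg, dup, halfwidth = 500))
  expect_equal(sum(ws3$cpg[2, ] == 1L, na.rm = TRUE), 0)
})

test_that("dedup conserves the count of distinct genomic CpGs", {
  set.seed(77)
  cpg <- data.frame(chrom = "chrT", pos = sort(sample(1000:20000, 300)))
  empty <- site_table(character(0), integer(0), character(0), numeric(0), numeric(0))
  anchors <- data.frame(id = sprintf("w%d", 1:40), chrom = "chrT",
                        pos = sort(sample(2000:18000, 40)), strand = "+")
  ws <- dedup_cpg_indicators(extract_windows(empty, cpg, anchors, halfwidth = 800))
  prof <- average_profiles(ws)
  counted <- sum(prof$cpg_density * prof$n_windows)
  covered <- unique(unlist(lapply(seq_len(nrow(ws$anchors)), function(w) {
    g <- ws$anchors$pos[w] + ws$dir[w] * ws$rel
    intersect(g, cpg$pos)
  })))
  expect_equal(counted, length(covered))
})

test_that("averaging masks missing measurements and matches a brute-force loop", {
  # forced example: {0.2, missing} averages to 0.2 with count 1
  occ <- rbind(rep(0.6, 5), rep(NA, 5))
  meth <- rbind(c(0.2, NA, 0.5, NA, 1), rep(NA, 5))
  cpg <- rbind(c(1L, 0L, 1L, 0L, 0L), c(0L, 1L, NA, 0L, 0L))
  ws <- make_window_set(occ, meth, cpg)
  prof <- average_profiles(ws)
  expect_equal(prof$occ_mean, rep(0.6, 5))
  expect_equal(prof$occ_n, rep(1, 5))
  expect_equal(prof$meth_mean[1], 0.2)
  expect_equal(prof$meth_n[2], 0)
  expect_true(is.na(prof$meth_mean[2]))
  # excluded indicator counts as 0 in the numerator, window stays in denominator
  expect_equal(prof$cpg_density, c(0.5, 0.5, 0.5, 0, 0))

  # brute-force double-loop oracle on a random fixture
  set.seed(55)
  n <- 50; p <- 41
  occ <- matrix(ifelse(runif(n * p) < 0.3, NA, runif(n * p)), n, p)
  meth <- matrix(ifelse(runif(n * p) < 0.5, NA, runif(n * p)), n, p)
  cpg <- matrix(sample(c(0L, 1L, NA), n * p, TRUE, c(.7, .2, .1)), n, p)
  prof <- average_profiles(make_window_set(occ, meth, cpg))
  for (j in seq_len(p)) {
    vals <- occ[, j][!is.na(occ[, j])]
    expect_equal(prof$occ_n[j], length(vals))
    if (length(vals)) expect_equal(prof$occ_mean[j], mean(vals))
    expect_equal(prof$cpg_density[j], sum(cpg[, j] == 1L, na.rm = TRUE) / n)
  }
  expect_error(average_profiles(make_window_set(occ[0, , drop = FALSE],
                                                meth[0, , drop = FALSE],
                                                cpg[0, , drop = FALSE],
                                                anchors = data.frame())),
               "no usable windows")
})

test_that("smoothing is a truncated centered moving average that skips NAs", {
  p0 <- data.frame(rel_pos = 1:100, occ_mean = rep(0.4, 100), occ_n = 1,
                   meth_mean = rep(0.7, 100), meth_n = 1,
                   cpg_density = rep(0.1, 100), n_windows = 1)
  class(p0) <- c("nome_profile", "data.frame")
  # constant tracks are invariant; window 1 is the identity
  expect_equal(smooth_profile(p0, 30)$occ_mean, p0$occ_mean)
  expect_equal(smooth_profile(p0, 1), p0)

  # single spike: direct convolution oracle (window i-15..i+14, truncated)
  spike <- p0
  spike$occ_mean <- c(rep(0, 49), 1, rep(0, 50))
  sm <- smooth_profile(spike, 30)$occ_mean
  oracle <- vapply(1:100, function(i) {
    idx <- max(1, i - 15):min(100, i + 14)
    mean(spike$occ_mean[idx])
  }, numeric(1))
  expect_equal(sm, oracle)
  expect_equal(sm[50], 1 / 30)

  # NAs are excluded from each local mean, not imputed
  gap <- p0
  gap$meth_mean[30:60] <- NA
  gap$meth_mean[1:29] <- 0.2
  sm2 <- smooth_profile(gap, 30)$meth_mean
  expect_equal(sm2[31], 0.2)           # window 16..45: only 16..29 defined
  expect_true(is.na(sm2[45]))          # window 30..59: fully undefined
  expect_false(anyNA(sm2[1:29]))
})

test_that("random-track smoothing equals the direct windowed-mean oracle", {
  set.seed(66)
  x <- ifelse(runif(200) < 0.2, NA, runif(200))
  for (w in c(2, 7, 30)) {
    got <- nomeprofiler:::moving_mean(x, w)
    left <- floor(w / 2); right <- w - 1 - left
    want <- vapply(seq_along(x), function(i) {
      idx <- max(1, i - left):min(length(x), i + right)
      v <- x[idx][!is.na(x[idx])]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    expect_equal(got, want)
  }
})

test_that("minus-strand profiles mirror plus-strand profiles on the reverse complement", {
  set.seed(88)
  seq <- random_seq(4000)
  g1 <- c(chrT = seq)
  g2 <- c(chrT = reverse_complement(seq))
  L <- nchar(seq)
  empty <- site_table(character(0), integer(0), character(0), numeric(0), numeric(0))
  a1 <- data.frame(id = "a", chrom = "chrT", pos = 2000L, strand = "-")
  # a CpG at p maps to a CpG at L - 2 - p on the reverse complement; the
  # mirrored anchor of TSS t is L - 1 - t on the + strand
  a2 <- data.frame(id = "a", chrom = "chrT", pos = L - 1L - 2000L, strand = "+")
  p1 <- average_profiles(extract_windows(empty, genome_sites(g1, "CG"), a1, 300))
  p2 <- average_profiles(extract_windows(empty, genome_sites(g2, "CG"), a2, 300))
  # CpG site coordinate is the C, which mirrors to the G side: shift by one
  expect_equal(p1$cpg_density[-1], p2$cpg_density[-length(p2$cpg_density)])
})

test_that("profiles round-trip through the TSV writer", {
  prof <- average_profiles(make_window_set(
    occ = matrix(c(0.5, NA), 1, 2), meth = matrix(c(NA, 0.25), 1, 2),
    cpg = matrix(c(1L, 0L), 1, 2), halfwidth = 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(as.data.frame(back), as.data.frame(prof))
})
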