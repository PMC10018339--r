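test_that("cleavage probability is monotone and respects orientation", {
  lib <- build_library(n_background = 4L, seed = 1L)
  model <- digestion_model()
  rev <- library_members(lib, "reverse_target")
  rev <- rev[order(rev$pam_center_offset), ]
  p <- cleavage_probability(rev, model)
  # monotone non-decreasing in distance from the dyad (positive side)
  pos <- rev$pam_center_offset >= 0
  expect_true(all(diff(p[pos]) >= -1e-12))
  # deep-core member sits at the nontarget baseline
  deep <- rev[which.min(abs(rev$pam_center_offset)), ]
  expect_lt(cleavage_probability(deep, model),
            model$nontarget_cleavage + 0.01)
  # far-linker member (largest |offset|, upstream end) approaches max cleavage
  far <- rev[which.max(abs(rev$pam_center_offset)), ]
  expect_gt(cleavage_probability(far, model), 0.9 * model$max_cleavage)
  # forward members are protected for extra bp: p_fwd <= p_rev at equal offset
  fwd <- library_members(lib, "forward_target")
  joint <- merge(fwd, rev, by = "pam_center_offset",
                 suffixes = c(".f", ".r"))
  pf <- cleavage_probability(
    data.frame(role = "forward_target",
               pam_center_offset = joint$pam_center_offset), model)
  pr <- cleavage_probability(
    data.frame(role = "reverse_target",
               pam_center_offset = joint$pam_center_offset), model)
  expect_true(all(pf <= pr + 1e-12))
  # nontarget/control/background members take the baseline
  expect_equal(cleavage_probability(
    data.frame(role = "background", pam_center_offset = NA), model),
    model$nontarget_cleavage)
  # mismatch penalties scale cleavage down
  edge <- data.frame(role = "forward_target", pam_center_offset = 90L)
  p_on <- cleavage_probability(edge, model)
  p_mm20 <- cleavage_probability(edge, model, mismatch = 20)
  p_mm19 <- cleavage_probability(edge, model, mismatch = 19)
  expect_true(p_mm19 < p_mm20 && p_mm20 < p_on)
  expect_error(cleavage_probability(edge, model, mismatch = 7),
               "no penalty")
})

test_that("simulated counts follow the thinning model", {
  lib <- toy_library()
  model <- digestion_model(nontarget_cleavage = 0)
  cfg <- sim_config(n_reads = 5e4, seed = 77, n_replicates = 1)
  ct <- simulate_counts(lib, model, cfg)
  truth <- attr(ct, "truth")
  expect_identical(nrow(truth), nrow(lib$members))
  u <- ct[ct$sample == "undigested", ]
  d <- ct[ct$sample == "digested", ]
  expect_identical(sum(u$count), 50000L)
  # null model: all-zero cleavage keeps digested ~ undigested
  ct0 <- simulate_counts(lib, digestion_model(max_cleavage = 0,
                                              nontarget_cleavage = 0),
                         cfg)
  pr0 <- compute_protection(ct0, lib,
                            pseudocount = 1)
  targ0 <- pr0$raw[pr0$member_id %in%
                     library_members(lib, "reverse_target")$member_id]
  expect_true(all(abs(targ0) < 0.25))
  # certain cleavage empties the digested pool for target members
  lib1 <- lib
  model1 <- digestion_model(max_cleavage = 1, steepness = 10,
                            nontarget_cleavage = 0)
  ct1 <- simulate_counts(lib1, model1, cfg)
  t1 <- attr(ct1, "truth")
  sure <- t1$member_id[t1$cleavage_probability > 0.999]
  expect_gt(length(sure), 0)
  d1 <- ct1[ct1$sample == "digested" & ct1$member_id %in% sure, ]
  expect_true(all(d1$count == 0L))
  # determinism under the seed
  ct_again <- simulate_counts(lib, model, cfg)
  expect_identical(ct, ct_again)
})

test_that("protection of thinned counts matches log2(1 - p) at depth", {
  lib <- toy_library()
  model <- digestion_model(nontarget_cleavage = 0)
  cfg <- sim_config(n_reads = 1e5, seed = 5, n_replicates = 1)
  ct <- simulate_counts(lib, model, cfg)
  truth <- attr(ct, "truth")
  pr <- compute_protection(ct, lib, pseudocount = 0)
  n <- 1e5
  q <- 1 / nrow(lib$members)
  for (i in seq_len(nrow(truth))) {
    id <- truth$member_id[i]
    p <- truth$cleavage_probability[i]
    expected <- log2(1 - p)  # control cleavage is 0
    s <- 1 - p
    # delta-method variance of the log2 ratio: binomial terms for the
    # four counts plus the negative multinomial covariance between the
    # member and control counts within each pool (-1/n per pair)
    se <- sqrt((1 - q * s) / (n * q * s) + 3 * (1 - q) / (n * q) +
               4 / n) / log(2)
    expect_lt(abs(pr$raw[pr$member_id == id] - expected), 3 * se)
  }
})

test_that("read simulation is seed-deterministic down to the FASTQ bytes", {
  lib <- toy_library()
  cfg <- sim_config(n_reads = 40, seed = 13, error_rate = 0.01,
                    n_replicates = 1)
  cnt <- data.frame(member_id = lib$members$member_id[1:4], count = 10L)
  p1 <- simulate_reads(cnt, lib, cfg)
  p2 <- simulate_reads(cnt, lib, cfg)
  f <- c(withr::local_tempfile(fileext = ".fastq"),
         withr::local_tempfile(fileext = ".fastq"),
         withr::local_tempfile(fileext = ".fastq"),
         withr::local_tempfile(fileext = ".fastq"))
  write_fastq_pairs(p1, f[1], f[2])
  write_fastq_pairs(p2, f[3], f[4])
  expect_identical(readLines(f[1]), readLines(f[3]))
  expect_identical(readLines(f[2]), readLines(f[4]))
  # different stream -> different reads
  p3 <- simulate_reads(cnt, lib, cfg, stream = 1L)
  expect_false(identical(vapply(p1, function(x) x$r1$seq, ""),
                         vapply(p3, function(x) x$r1$seq, "")))
  # empty count table -> no reads
  expect_identical(simulate_reads(cnt[0, ], lib, cfg), list())
})

test_that("error-free reads reconstruct their member after merging", {
  lib <- toy_library()
  cfg <- sim_config(n_reads = 4, seed = 9, error_rate = 0,
                    n_replicates = 1)
  cnt <- data.frame(member_id = lib$members$member_id[1], count = 2L)
  pairs <- simulate_reads(cnt, lib, cfg)
  m <- merge_pair(pairs[[1]]$r1, pairs[[1]]$r2)
  expect_true(m$merged)
  expect_identical(m$seq, lib$members$sequence[1])
  expect_identical(m$overlap_len, 2L * cfg$read_length - 230L)
})

test_that("tail error profile encodes errors in low-quality 3' bases", {
  cfg <- sim_config(n_reads = 10, seed = 2, error_rate = 0.01,
                    read_length = 150L, n_replicates = 1)
  em <- nuctile:::.read_error_model(cfg)
  expect_identical(length(em$qual), 150L)
  t <- sum(em$qual == 2L)
  expect_identical(t, 3L)  # 150 * 0.01 / 0.5
  expect_true(all(em$qual[1:(150 - t)] == 38L))
  expect_equal(mean(em$perr), 0.01, tolerance = 0.01)
  # uniform profile: flat qualities, flat errors
  cfg_u <- sim_config(n_reads = 10, seed = 2, error_rate = 0.01,
                      error_profile = "uniform", n_replicates = 1)
  em_u <- nuctile:::.read_error_model(cfg_u)
  expect_true(all(em_u$qual == 40L))
  expect_true(all(em_u$perr == 0.01))
})

test_that("MNase fragment simulation respects cut sites and size selection", {
  # cuts only at the molecule ends: every fragment is the whole molecule
  L <- 150L
  frs <- simulate_mnase_fragments(rep(0, L + 1), 30L, seed = 1,
                                  min_len = 0L)
  expect_true(all(frs$start == 0L & frs$end == L))
  # fragment ends only where cutting is possible
  cp <- rep(0, L + 1)
  cp[c(31L, 121L) + 1L] <- 1  # boundaries 30 and 121... cut sites 31,121
  frs2 <- simulate_mnase_fragments(cp, 50L, seed = 2, min_len = 0L)
  expect_true(all(frs2$start %in% c(0L, which(cp > 0) - 1L)))
  expect_true(all(frs2$end %in% c(L, which(cp > 0) - 1L)))
  # uniform cut probability: higher probability -> shorter fragments
  mean_len <- vapply(c(0.01, 0.05, 0.2), function(p) {
    f <- simulate_mnase_fragments(rep(p, 201), 400L, seed = 3,
                                  min_len = 0L)
    mean(f$end - f$start)
  }, numeric(1))
  expect_true(all(diff(mean_len) < 0))
  # protected core: zero interior cut probability across the core plus
  # size selection gives an exact protection plateau of 1
  lib_frame <- default_frame()
  lims <- core_limits(lib_frame)
  cp3 <- rep(0.08, 231)
  cp3[(lims[1] + 1):(lims[2] + 1)] <- 0  # boundaries inside the core
  frs3 <- simulate_mnase_fragments(cp3, 200L, seed = 4, min_len = 100L)
  tr <- mnase_track(frs3, 230L)
  core_bp <- seq(lims[1], lims[2] - 1)
  expect_true(all(tr$protection[tr$bp %in% core_bp] == 1))
})

test_that("longer digestion lowers protection outside the core", {
  lims <- core_limits(default_frame())
  mk <- function(p, seed) {
    cp <- rep(p, 231)
    cp[(lims[1] + 1):(lims[2] + 1)] <- 0
    frs <- simulate_mnase_fragments(cp, 500L, seed = seed, min_len = 100L)
    mnase_track(frs, 230L)$protection
  }
  short <- mk(0.02, 11)
  long <- mk(0.15, 11)
  flank <- c(seq(0, lims[1] - 1), seq(lims[2], 229))
  expect_lt(mean(long[flank + 1]), mean(short[flank + 1]))
})

test_that("grid search recovers the generating edge offset", {
  lib <- build_library(n_background = 30L, seed = 6L)
  model <- digestion_model(edge_offset = 73)
  cfg <- sim_config(n_reads = 1e5, seed = 19, n_replicates = 3)
  ct <- simulate_counts(lib, model, cfg)
  pr <- compute_protection(ct, lib)
  prof <- profile_by_position(pr, lib, "reverse_target")
  fit <- fit_edge_offset(prof, lib, model)
  expect_lte(abs(fit$edge_offset - 73), 2)
})
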