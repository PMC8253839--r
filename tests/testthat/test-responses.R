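test_that("within-run z-scoring standardizes each voxel-run slice", {
  emb <- random_embedding(n_cat = 18, dim = 3, seed = 2)
  g <- generate_responses(emb, n_voxels = 10, noise_sd = 0.5,
                          n_runs_per_fold = 2, seed = 3)
  z <- zscore_within_run(g$data)
  for (r in seq_along(z$run_fold)) {
    slice <- z$betas[, , r]
    slice <- slice[, !is.na(slice[1, ])]
    expect_equal(unname(rowMeans(slice)), rep(0, nrow(slice)),
                 tolerance = 1e-12)
    expect_equal(unname(apply(slice, 1, sd)), rep(1, nrow(slice)),
                 tolerance = 1e-12)
  }
  # elementwise (x - mean) / sd oracle on one slice
  raw <- g$data$betas[3, , 1]
  raw <- raw[!is.na(raw)]
  expect_equal(z$betas[3, names(raw), 1], (raw - mean(raw)) / sd(raw),
               tolerance = 1e-12)
  # idempotence up to numerical noise
  z2 <- zscore_within_run(z)
  expect_lt(max(abs(z2$betas - z$betas), na.rm = TRUE), 1e-12)
})

test_that("constant voxel-run slices are flagged and excluded", {
  emb <- random_embedding(n_cat = 12, dim = 3, seed = 5)
  g <- generate_responses(emb, n_voxels = 6, noise_sd = 1,
                          n_runs_per_fold = 2, seed = 8)
  b <- g$data$betas
  b[2, !is.na(b[2, , 1]), 1] <- 7  # constant slice for voxel 2, run 1
  data <- response_data(b, g$data$run_fold, g$data$folds)
  expect_warning(z <- zscore_within_run(data), "constant")
  expect_identical(attr(z, "flagged"), "v0002")
  expect_identical(dim(z$betas)[1], 5L)
})

test_that("run averaging matches a loop-based oracle and checks coverage", {
  emb <- random_embedding(n_cat = 12, dim = 3, seed = 6)
  g <- generate_responses(emb, n_voxels = 5, noise_sd = 1,
                          n_runs_per_fold = 3, seed = 9)
  avg <- average_runs(g$data)
  b <- g$data$betas
  oracle <- matrix(NA_real_, dim(b)[1], dim(b)[2], dimnames = dimnames(b)[1:2])
  for (v in seq_len(dim(b)[1])) for (ct in seq_len(dim(b)[2]))
    oracle[v, ct] <- mean(b[v, ct, ], na.rm = TRUE)
  expect_equal(avg, oracle, tolerance = 1e-12)
  # odd-run subset oracle
  odd <- seq(1, dim(b)[3], 2)
  avg_odd <- average_runs(g$data, odd)
  for (v in 1:2) for (ct in seq_len(dim(b)[2]))
    expect_equal(avg_odd[v, ct], mean(b[v, ct, odd], na.rm = TRUE),
                 tolerance = 1e-12)
  # a subset that misses a fold's categories is a coverage error
  expect_error(average_runs(g$data, 1:2),
               class = "voxembed_coverage_error")
})

test_that("split-half reliability behaves at the exact and noisy extremes", {
  emb <- random_embedding(n_cat = 12, dim = 3, seed = 7)
  g <- generate_responses(emb, n_voxels = 8, noise_sd = 0,
                          n_runs_per_fold = 2, seed = 4)
  # noiseless runs duplicate each other: reliability is exactly 1
  expect_equal(unname(split_half_reliability(g$data)), rep(1, 8),
               tolerance = 1e-12)
  # even half = negated odd half gives -1
  b <- g$data$betas
  for (f in seq_along(g$data$folds)) {
    runs <- which(g$data$run_fold == f)
    b[, , runs[2]] <- -b[, , runs[2]]
  }
  neg <- response_data(b, g$data$run_fold, g$data$folds)
  expect_equal(unname(split_half_reliability(neg)), rep(-1, 8),
               tolerance = 1e-12)
  # invariance to a common category re-ordering
  noisy <- generate_responses(emb, n_voxels = 8, noise_sd = 1,
                              n_runs_per_fold = 2, seed = 5)
  perm <- sample(dim(noisy$data$betas)[2])
  permuted <- response_data(noisy$data$betas[, perm, , drop = FALSE],
                            noisy$data$run_fold, noisy$data$folds)
  expect_equal(split_half_reliability(permuted),
               split_half_reliability(noisy$data), tolerance = 1e-12)
})

test_that("noisy reliability matches the closed-form attenuation oracle", {
  set.seed(11)
  emb <- random_embedding(n_cat = 24, dim = 4, seed = 12)
  n_half <- 2  # runs averaged per half
  # per-voxel expected reliability: s / (s + sigma^2 / n_half), with s the
  # empirical signal variance of the voxel's noiseless profile
  sigma <- 1.2
  g <- generate_responses(emb, n_voxels = 200, noise_sd = sigma,
                          n_runs_per_fold = 2 * n_half, seed = 13)
  r <- split_half_reliability(g$data)
  s <- apply(g$truth$noiseless, 1, var)
  rho <- s / (s + sigma^2 / n_half)
  se <- sd(r - rho) / sqrt(length(r))
  expect_lt(abs(mean(r) - mean(rho)), 2 * se + 0.02)
})

test_that("critical_r inverts the one-sided t test for a correlation", {
  expect_equal(round(critical_r(81, 0.05), 4), 0.1841)
  expect_equal(critical_r(200, 0.5), 0, tolerance = 1e-12)
  # t-quantile oracle at n = 12
  t10 <- qt(0.95, 10)
  expect_equal(critical_r(12, 0.05), t10 / sqrt(t10^2 + 10),
               tolerance = 1e-12)
  # strictly decreasing in n and in alpha
  rs <- sapply(4:60, critical_r, alpha = 0.05)
  expect_true(all(diff(rs) < 0))
  as <- sapply(c(0.01, 0.05, 0.1, 0.25), function(a) critical_r(30, a))
  expect_true(all(diff(as) < 0))
  expect_error(critical_r(2, 0.05), class = "voxembed_domain_error")
  expect_error(critical_r(30, 1.2), class = "voxembed_domain_error")
})

test_that("reliability masks retain voxels by cross-subject mean threshold", {
  set.seed(14)
  rel <- matrix(runif(300, -0.2, 0.9), 100, 3,
                dimnames = list(sprintf("v%03d", 1:100), NULL))
  mask <- reliability_mask(rel, threshold = 0.3)
  oracle <- rownames(rel)[rowMeans(rel) >= 0.3]
  expect_identical(mask$voxels, oracle)
  # threshold 0 keeps every voxel with defined reliability
  expect_length(reliability_mask(rel, threshold = -1)$voxels, 100L)
  # threshold above the maximum empties the mask
  expect_length(reliability_mask(rel, threshold = 1)$voxels, 0L)
  # analytic threshold path
  m2 <- reliability_mask(rel, alpha = 0.05, n = 81)
  expect_equal(m2$threshold, critical_r(81, 0.05))
  # NA reliability in any subject excludes the voxel
  rel[1, 2] <- NA
  expect_false("v001" %in% reliability_mask(rel, threshold = -1)$voxels)
  # misaligned subject vectors
  a <- setNames(runif(5), paste0("v", 1:5))
  b <- setNames(runif(5), paste0("w", 1:5))
  expect_error(reliability_mask(list(a, b), threshold = 0),
               class = "voxembed_alignment_error")
})

test_that("betas round-trip through long CSV and masks serialize", {
  emb <- random_embedding(n_cat = 12, dim = 3, seed = 15)
  g <- generate_responses(emb, n_voxels = 4, noise_sd = 1,
                          n_runs_per_fold = 2, seed = 16)
  path <- withr::local_tempfile(fileext = ".csv")
  write_betas(g$data, path)
  back <- read_betas(path, g$folds)
  expect_equal(back$betas, g$data$betas, tolerance = 1e-12)
  expect_identical(back$run_fold, g$data$run_fold)
  mask <- reliability_mask(
    matrix(runif(8), 4, 2, dimnames = list(rownames(g$truth$noiseless)[1:4],
                                           NULL)),
    threshold = 0.2)
  mpath <- withr::local_tempfile(fileext = ".txt")
  write_voxel_mask(mask, mpath)
  expect_identical(readLines(mpath), mask$voxels)
  side <- jsonlite::read_json(paste0(mpath, ".json"))
  expect_equal(side$threshold, 0.2)
})

test_that("response_data rejects runs whose categories mismatch their fold", {
  emb <- random_embedding(n_cat = 12, dim = 3, seed = 17)
  g <- generate_responses(emb, n_voxels = 3, noise_sd = 1,
                          n_runs_per_fold = 2, seed = 18)
  bad_fold <- g$data$run_fold
  bad_fold[1] <- bad_fold[1] %% length(g$folds) + 1L
  expect_error(response_data(g$data$betas, bad_fold, g$folds),
               class = "voxembed_domain_error")
})
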