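test_that("noiseless linear responses are recovered exactly", {
  fx <- encoding_fixture(noise_sd = 0)
  res <- fit_predict_cv(fx$model, fx$Y, fx$folds)
  expect_true(all(abs(1 - res$accuracy) < 1e-10))
  expect_equal(res$predicted, fx$Y, tolerance = 1e-8)
  # a zero-column nuisance matrix is the same as no nuisance
  nn <- matrix(numeric(0), nrow(fx$model), 0,
               dimnames = list(rownames(fx$model), NULL))
  res0 <- fit_predict_cv(fx$model, fx$Y, fx$folds, nuisance = nn)
  expect_equal(res0$predicted, res$predicted, tolerance = 1e-12)
  expect_equal(res0$weights, res$weights, tolerance = 1e-12)
})

test_that("tiny fold-wise fit matches normal equations solved directly", {
  cats <- paste0("c", 1:6)
  M <- matrix(c(0.2, -1, 0.5, 2, -0.3, 1.4), 6, 1,
              dimnames = list(cats, "f1"))
  set.seed(2)
  Y <- matrix(rnorm(12), 2, 6, dimnames = list(c("v1", "v2"), cats))
  folds <- structure(list(cats[1:3], cats[4:6]), class = "fold_design")
  res <- fit_predict_cv(M, Y, folds)
  for (f in 1:2) {
    test <- folds[[f]]; train <- setdiff(cats, test)
    X <- cbind(1, M[train, ])
    for (v in 1:2) {
      beta <- solve(t(X) %*% X, t(X) %*% Y[v, train])
      expect_equal(unname(res$predicted[v, test]),
                   unname(as.vector(cbind(1, M[test, ]) %*% beta)),
                   tolerance = 1e-10)
      expect_equal(unname(res$weights[v, , f]), unname(as.vector(beta)),
                   tolerance = 1e-10)
    }
  }
})

test_that("nuisance regressors are fit in training but never predict", {
  # responses driven solely by nuisance features orthogonal to the model:
  # accuracy must be centred on zero
  set.seed(4)
  n_cat <- 24; n_vox <- 200
  cats <- sprintf("c%02d", seq_len(n_cat))
  M <- matrix(rnorm(n_cat * 3), n_cat, 3, dimnames = list(cats, NULL))
  N <- qr.Q(qr(cbind(M, matrix(rnorm(n_cat * 4), n_cat, 4))))[, 4:7]
  rownames(N) <- cats
  Y <- t(N %*% matrix(rnorm(4 * n_vox), 4, n_vox)) +
    matrix(rnorm(n_vox * n_cat, sd = 0.1), n_vox, n_cat)
  dimnames(Y) <- list(sprintf("v%03d", seq_len(n_vox)), cats)
  folds <- make_folds(cats, 4)
  res <- fit_predict_cv(M, Y, folds, nuisance = N)
  expect_lt(abs(mean(res$accuracy)), 0.06)
  # with the nuisance absorbed in training, model weights shrink toward 0
  expect_lt(mean(abs(average_weights(res))), 1)
})

test_that("rank-deficient or undersized training designs are refused", {
  fx <- encoding_fixture(n_cat = 12, n_vox = 4, p = 2, n_folds = 2)
  M_bad <- cbind(fx$model, fx$model[, 1] * 2)  # collinear column
  expect_error(fit_predict_cv(M_bad, fx$Y, fx$folds),
               class = "voxembed_singular_design")
  # too many regressors for the training size
  M_wide <- matrix(rnorm(12 * 7), 12, 7,
                   dimnames = list(rownames(fx$model), NULL))
  expect_error(fit_predict_cv(M_wide, fx$Y, fx$folds),
               class = "voxembed_singular_design")
  Y_un <- fx$Y; rownames(Y_un) <- NULL
  expect_error(fit_predict_cv(fx$model, Y_un, fx$folds),
               class = "voxembed_alignment_error")
})

test_that("prediction accuracy is rowwise Pearson with affine invariance", {
  fx <- encoding_fixture(n_cat = 12, n_vox = 6, noise_sd = 0.5, seed = 5,
                         n_folds = 3)
  res <- fit_predict_cv(fx$model, fx$Y, fx$folds)
  expect_equal(unname(prediction_accuracy(fx$Y, fx$Y)), rep(1, 6))
  expect_equal(unname(prediction_accuracy(-fx$Y + 2, fx$Y)), rep(-1, 6))
  # covariance-formula oracle per voxel
  oracle <- sapply(seq_len(6), function(v)
    cor(res$predicted[v, ], fx$Y[v, ]))
  expect_equal(unname(res$accuracy), oracle, tolerance = 1e-12)
  # invariance to positive affine transforms of the actual responses
  Y2 <- fx$Y * 3.7 + 11
  expect_equal(prediction_accuracy(res$predicted, Y2), res$accuracy,
               tolerance = 1e-12)
  # constant voxel flagged
  Yc <- fx$Y; Yc[2, ] <- 5
  expect_warning(acc <- prediction_accuracy(res$predicted, Yc), "constant")
  expect_true(is.na(acc[2]))
})

test_that("permutation p-values match an explicit enumeration oracle", {
  fx <- encoding_fixture(n_cat = 12, n_vox = 8, noise_sd = 1, seed = 6,
                         n_folds = 3)
  res <- fit_predict_cv(fx$model, fx$Y, fx$folds)
  perms <- make_fold_permutations(fx$folds, colnames(fx$Y), n_perm = 10,
                                  seed = 3)
  pr <- permutation_null(res, fx$Y, perms = perms)
  # loop-based oracle with the same permutation stream
  for (v in seq_len(8)) {
    null_v <- sapply(seq_len(10), function(k)
      cor(res$predicted[v, perms[, k]], fx$Y[v, ]))
    expect_equal(unname(pr$null_accuracy[, v]), null_v, tolerance = 1e-12)
    expect_equal(unname(pr$p_values[v]),
                 (1 + sum(null_v >= res$accuracy[v])) / 11,
                 tolerance = 1e-12)
  }
  # permutations only shuffle within folds
  for (k in 1:10) for (f in fx$folds) {
    pos <- which(colnames(fx$Y) %in% f)
    expect_setequal(perms[pos, k], pos)
  }
})

test_that("permutation p spans its floor and ceiling", {
  fx <- encoding_fixture(n_cat = 12, n_vox = 5, noise_sd = 0, seed = 7,
                         n_folds = 3)
  res <- fit_predict_cv(fx$model, fx$Y, fx$folds)
  pr <- permutation_null(res, fx$Y, n_perm = 200, seed = 8)
  # perfect prediction beats every permuted profile
  expect_equal(unname(pr$p_values), rep(1 / 201, 5), tolerance = 1e-12)
  # an anti-predictor is beaten by every permutation replicate
  anti <- -res$predicted
  pr2 <- permutation_null(anti, fx$Y, n_perm = 200, seed = 8,
                          folds = fx$folds)
  expect_equal(unname(pr2$p_values), rep(1, 5), tolerance = 1e-12)
})

test_that("fdr_adjust reproduces brute-force Benjamini-Hochberg", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(9)
  for (i in 1:25) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "voxembed_domain_error")
  q <- fdr_adjust(c(0.2, NA, 0.01))
  expect_true(is.na(q[2]))
})

test_that("bootstrap SE resamples within folds, pairing actual and predicted", {
  fx <- encoding_fixture(n_cat = 12, n_vox = 6, noise_sd = 0.8, seed = 10,
                         n_folds = 3)
  res <- fit_predict_cv(fx$model, fx$Y, fx$folds)
  se <- bootstrap_se(res$predicted, fx$Y, fx$folds, n_boot = 50, seed = 4)
  expect_gte(se, 0)
  # index-sharing oracle: replay the same RNG stream
  cats <- colnames(fx$Y)
  pos <- lapply(fx$folds, function(f) which(cats %in% f))
  set.seed(4)
  oracle <- sapply(1:50, function(b) {
    idx <- unlist(lapply(pos, function(p)
      p[sample.int(length(p), length(p), replace = TRUE)]))
    mean(sapply(seq_len(6), function(v)
      cor(res$predicted[v, idx], fx$Y[v, idx])))
  })
  expect_equal(unname(attr(se, "replicates")), oracle, tolerance = 1e-12)
  expect_equal(as.numeric(se), sd(oracle), tolerance = 1e-12)
  # zero-noise data with perfect accuracy has zero SE
  fx0 <- encoding_fixture(n_cat = 12, n_vox = 4, noise_sd = 0, seed = 11,
                          n_folds = 3)
  res0 <- fit_predict_cv(fx0$model, fx0$Y, fx0$folds)
  se0 <- bootstrap_se(res0$predicted, fx0$Y, fx0$folds, n_boot = 30,
                      seed = 5)
  expect_lt(as.numeric(se0), 1e-10)
})

test_that("ROI tests average voxels across subjects and reuse the null", {
  fx <- encoding_fixture(n_cat = 12, n_vox = 3, noise_sd = 1, seed = 12,
                         n_folds = 3)
  res <- fit_predict_cv(fx$model, fx$Y, fx$folds)
  perms <- make_fold_permutations(fx$folds, colnames(fx$Y), 100, seed = 6)
  pr <- permutation_null(res, fx$Y, perms = perms)
  # single voxel, single subject reduces to that voxel's permutation p
  one <- roi_test(res$accuracy, pr$null_accuracy, roi = "v001")
  expect_equal(one$p, unname(pr$p_values["v001"]), tolerance = 1e-12)
  # flat-average oracle over 3 voxels x 2 subjects
  acc2 <- res$accuracy + 0.05
  both <- roi_test(list(res$accuracy, acc2),
                   list(pr$null_accuracy, pr$null_accuracy),
                   roi = rownames(fx$Y))
  expect_equal(both$mean_accuracy,
               mean(c(res$accuracy, acc2)), tolerance = 1e-12)
  # observed above every null replicate gives the floor p
  null_low <- pr$null_accuracy * 0 - 1
  top <- roi_test(res$accuracy, null_low, roi = rownames(fx$Y))
  expect_equal(top$p, 1 / 101, tolerance = 1e-12)
  expect_error(roi_test(res$accuracy, pr$null_accuracy, roi = character(0)),
               class = "voxembed_domain_error")
})

test_that("interaction statistic contrasts accuracy differences across ROIs", {
  mk_null <- function(vals, seed = 1) {
    m <- matrix(rep(vals, each = 10), 10, length(vals),
                dimnames = list(NULL, names(vals)))
    attr(m, "perm_seed") <- seed
    m
  }
  acc_a <- c(r1 = 0.3, r2 = 0.2)
  acc_b <- c(r1 = 0.1, r2 = 0.15)
  na <- mk_null(c(r1 = 0, r2 = 0)); nb <- mk_null(c(r1 = 0, r2 = 0))
  out <- interaction_test(acc_a, acc_b, na, nb, "r1", "r2")
  expect_equal(out$statistic, (0.3 - 0.1) - (0.2 - 0.15), tolerance = 1e-12)
  # identical models give a zero statistic
  same <- interaction_test(acc_a, acc_a, na, nb, "r1", "r2")
  expect_equal(same$statistic, 0)
  # different permutation streams are a contract violation
  nb2 <- mk_null(c(r1 = 0, r2 = 0), seed = 2)
  expect_error(interaction_test(acc_a, acc_b, na, nb2, "r1", "r2"),
               class = "voxembed_contract_error")
})

test_that("preference maps floor negative accuracies before differencing", {
  mk_null <- function(n_vox, seed = 1) {
    m <- matrix(rnorm(20 * n_vox, sd = 0.1), 20, n_vox,
                dimnames = list(NULL, paste0("v", seq_len(n_vox))))
    attr(m, "perm_seed") <- seed
    m
  }
  acc_a <- c(v1 = 0.3, v2 = -0.1)
  acc_b <- c(v1 = 0.1, v2 = 0.2)
  pm <- preference_map(acc_a, acc_b, mk_null(2), mk_null(2))
  expect_equal(unname(pm$difference), c(0.2, -0.2), tolerance = 1e-12)
  # antisymmetry of the difference field under argument swap
  pm_rev <- preference_map(acc_b, acc_a, mk_null(2), mk_null(2))
  expect_equal(pm$difference, -pm_rev$difference, tolerance = 1e-12)
  expect_true(all(pm$q_a >= pm$p_a, na.rm = TRUE))
})

test_that("weight PCA recovers a planted direction across voxels", {
  set.seed(13)
  p <- 6; n_vox <- 120
  base <- rnorm(p)
  dir <- rnorm(p); dir <- dir / sqrt(sum(dir^2))
  W <- matrix(rep(base, each = n_vox), n_vox, p) +
    outer(rnorm(n_vox, sd = 2), dir) +
    matrix(rnorm(n_vox * p, sd = 0.05), n_vox, p)
  rownames(W) <- sprintf("v%03d", seq_len(n_vox))
  cats <- sprintf("c%02d", 1:15)
  M <- matrix(rnorm(15 * p), 15, p, dimnames = list(cats, NULL))
  out <- weights_pca(W, model = M, n_components = 2)
  expect_gt(abs(sum(out$loadings[, 1] * dir)), 0.99)
  # category scores are the regressors projected on the loadings
  expect_equal(out$scores, M %*% out$loadings, tolerance = 1e-12)
  # sign convention
  for (j in 1:2) {
    l <- out$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # full-rank components carry all the variance
  full <- weights_pca(W, model = M, n_components = p)
  expect_equal(sum(full$explained), 1, tolerance = 1e-10)
  expect_error(weights_pca(W[1:3, ], model = M, n_components = 4),
               class = "voxembed_rank_error")
})
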