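## tiny feature tensor built directly (trials x features x freqs x times)
mk_ft <- function(data, labels, freqs = NULL, times = NULL) {
  structure(list(data = data, labels = labels,
                 freqs = if (is.null(freqs)) seq_len(dim(data)[3]) else freqs,
                 times = if (is.null(times)) seq_len(dim(data)[4]) else times,
                 feature_labels = paste0("f", seq_len(dim(data)[2]))),
            class = "feature_tensor")
}

test_that("undersampling balances classes, keeps balanced sets intact, and is seeded", {
  labels <- rep(c("a", "b", "c", "d"), c(20, 20, 20, 18))
  k1 <- balance_by_undersampling(labels, seed = 5)
  expect_true(all(table(labels[k1]) == 18))
  k2 <- balance_by_undersampling(labels, seed = 5)
  expect_identical(k1, k2)
  k3 <- balance_by_undersampling(labels, seed = 6)
  expect_false(identical(k1, k3))
  balanced <- rep(c("a", "b"), each = 10)
  expect_identical(balance_by_undersampling(balanced, 1), 1:20)
  expect_error(balance_by_undersampling(rep("a", 5), 1), "2 non-empty")
})

test_that("tf features have the documented shape and track evoked band power", {
  rec <- generate_recording(small_config(seed = 50, n_trials_per_class = 3))
  rec <- lowpass_downsample(rec, 50, 3, 200)
  ep <- epoch(rec, c(-3, 8), c(-3, 0))
  ft <- tf_features(ep, freqs = seq(2, 20, by = 2), window = c(0, 8),
                    time_decim = 20)
  expect_equal(dim(ft$data)[1:3], c(9, 3, 10))
  ft1 <- tf_features(ep, freqs = seq(2, 20, by = 2), window = c(0, 8),
                     time_decim = 20, channels = "OB")
  expect_equal(dim(ft1$data)[2], 1)
  ## evoked trials put their maximal power in the evoked band
  odor <- which(ep$labels == "AA")
  pw <- apply(ft$data[odor, 1, , , drop = FALSE], 3, mean)
  expect_true(ft$freqs[which.max(pw)] >= 5 && ft$freqs[which.max(pw)] <= 12)
  expect_error(tf_features(ep, window = c(0, 20)), "exceeds")
})

test_that("shrinkage LDA matches MASS::lda class assignments on well-conditioned data", {
  skip_if_not_installed("MASS")
  set.seed(51)
  X <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 1.2), 50))
  y <- rep(c("a", "b"), each = 50)
  fit <- olfconn:::lda_fit(X, y, lambda = 0)
  sc <- olfconn:::lda_scores(fit, X)
  mine <- fit$classes[max.col(sc)]
  ref <- as.character(predict(MASS::lda(X, grouping = y))$class)
  expect_gt(mean(mine == ref), 0.98)
  ## singular pixel features do not break the shrunk fit
  Xs <- cbind(X[, 1], X[, 1])
  expect_no_error(olfconn:::lda_fit(Xs, y, lambda = 0.05))
})

test_that("rank AUC agrees with pROC and is invariant to monotone score maps", {
  skip_if_not_installed("pROC")
  set.seed(52)
  sc <- rnorm(60)
  pos <- rep(c(TRUE, FALSE), 30)
  mine <- olfconn:::auc_rank(sc, pos)
  ref <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = sc,
                                        quiet = TRUE, direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
  expect_identical(olfconn:::auc_rank(3 * sc + 7, pos), mine)
  expect_identical(olfconn:::auc_rank(exp(sc), pos), mine)
})

test_that("decoding of separable classes saturates while permuted labels sit at chance", {
  set.seed(53)
  n_per <- 20
  y <- rep(c("a", "b", "c", "d"), each = n_per)
  mu <- rep(c(0, 4, 8, 12), each = n_per)
  data <- array(rnorm(80 * 2 * 2 * 3, sd = 0.4), dim = c(80, 2, 2, 3))
  data[, 1, 2, ] <- data[, 1, 2, ] + mu     # informative pixel row 2
  ft <- mk_ft(data, y)
  dm <- decode_multiclass(ft, folds = 10, seed = 3)
  expect_true(all(dm$auc[2, ] > 0.95))
  expect_true(all(abs(dm$auc[1, ] - 0.5) < 0.15))
  ## label permutation kills the information
  ft_perm <- ft
  set.seed(54)
  ft_perm$labels <- sample(y)
  dm_perm <- decode_multiclass(ft_perm, folds = 10, seed = 3)
  expect_lt(abs(mean(dm_perm$auc) - 0.5), 0.06)
  expect_error(decode_multiclass(mk_ft(data[1:16, , , , drop = FALSE],
                                       y[c(1:4, 21:24, 41:44, 61:64)]),
                                 folds = 10), "folds")
})

test_that("cross-validation is hygienic: no test trial influences its own fold's training", {
  y <- rep(c("a", "b"), each = 20)
  folds <- 10
  fid <- olfconn:::stratified_folds(y, folds, seed = 9)
  expect_true(all(table(fid) == 4))
  for (k in seq_len(folds))
    expect_length(intersect(which(fid == k), which(fid != k)), 0)
  ## fold assignment is stratified within class
  expect_true(all(table(fid[y == "a"]) == 2))
})

test_that("multivariate decoding beats the best univariate on redundant encodings", {
  set.seed(55)
  n_per <- 24
  y <- rep(c("a", "b"), each = n_per)
  s <- rep(c(-1, 1), each = n_per)
  n_pix <- 6
  data <- array(0, dim = c(2 * n_per, 3, 1, n_pix))
  for (r in 1:3) data[, r, 1, ] <- s + rnorm(2 * n_per * n_pix, sd = 2.2)
  ft_multi <- mk_ft(data, y)
  auc_multi <- mean(decode_multiclass(ft_multi, folds = 8, seed = 4)$auc)
  auc_uni <- vapply(1:3, function(r) {
    mean(decode_multiclass(mk_ft(data[, r, , , drop = FALSE], y),
                           folds = 8, seed = 4)$auc)
  }, numeric(1))
  expect_gt(auc_multi, max(auc_uni))
})

test_that("cluster labelling matches a brute-force transitive closure on random masks", {
  set.seed(56)
  brute_components <- function(mask) {
    idx <- which(mask)
    if (!length(idx)) return(0L)
    nr <- nrow(mask)
    comp <- seq_along(idx)
    pos <- cbind(((idx - 1) %% nr) + 1, ((idx - 1) %/% nr) + 1)
    repeat {
      changed <- FALSE
      for (i in seq_along(idx)) for (j in seq_along(idx)) {
        if (comp[i] != comp[j] &&
            sum(abs(pos[i, ] - pos[j, ])) == 1) {
          comp[pmin(comp[i], comp[j]) == comp | comp == pmax(comp[i], comp[j])] <-
            min(comp[i], comp[j])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    length(unique(comp))
  }
  for (rep in 1:8) {
    mask <- matrix(runif(48) < 0.35, 6, 8)
    lab <- olfconn:::label_clusters(mask)
    expect_equal(max(lab), brute_components(mask))
    ## labelled pixels are exactly the masked ones
    expect_identical(lab > 0, mask)
  }
})

test_that("the cluster permutation test recovers a planted block and rejects noise", {
  set.seed(57)
  n_sub <- 8
  mk_map <- function(signal) {
    m <- matrix(0.5 + rnorm(10 * 40, sd = 0.02), 10, 40)
    if (signal) m[4:7, 10:30] <- m[4:7, 10:30] + 0.12
    m
  }
  maps <- replicate(n_sub, mk_map(TRUE), simplify = FALSE)
  ct <- cluster_permutation_test(maps, n_perm = 300, seed = 2)
  expect_gte(nrow(ct$clusters), 1)
  top <- ct$clusters[1, ]
  expect_lt(top$p, 0.05)
  ## the significant cluster covers the planted block
  expect_gt(mean(ct$sig_mask[4:7, 10:30]), 0.9)
  expect_lt(mean(ct$sig_mask[-(4:7), ]), 0.1)
  ## pure noise: no significant cluster at this seed
  null_maps <- replicate(n_sub, mk_map(FALSE), simplify = FALSE)
  ct0 <- cluster_permutation_test(null_maps, n_perm = 300, seed = 3)
  expect_true(nrow(ct0$clusters) == 0 || min(ct0$clusters$p) > 0.05)
  expect_error(cluster_permutation_test(maps[1:2]), ">= 3 subjects")
  expect_warning(cluster_permutation_test(maps, n_perm = 10, seed = 1),
                 "resolution")
})
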