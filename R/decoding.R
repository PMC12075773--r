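## Spectral decoding of stimulus class: single-trial time-frequency power
## features, balanced multiclass LDA under stratified cross-validation with
## AUC scoring, and group-level cluster-based permutation inference.

#' Single-trial time-frequency features for decoding
#'
#' Morlet scaleogram power per trial and region over a frequency grid
#' (default 1--40 Hz) and a post-stimulus window (default 0--10 s), decimated
#' in time for tractability.
#'
#' @param ep an `epoch_set`.
#' @param freqs Hz grid.
#' @param window seconds pair relative to onset.
#' @param time_decim keep every `time_decim`-th sample inside `window`.
#' @param sigma Morlet parameter.
#' @param channels channel indices/labels to use as features (default all —
#'   the multivariate case; pass one channel for univariate decoding).
#' @return A `feature_tensor`: list with `data` (trials x features x freqs x
#'   times), `labels`, `freqs`, `times`, `feature_labels`.
#' @export
tf_features <- function(ep, freqs = 1:40, window = c(0, 10), time_decim = 10,
                        sigma = 5, channels = NULL) {
  validate_epochs(ep)
  if (is.null(channels)) channels <- seq_len(dim(ep$data)[2])
  if (is.character(channels)) channels <- match(channels, ep$channel_labels)
  tt <- epoch_times(ep)
  if (window[1] < tt[1] - 1e-9 || window[2] > tt[length(tt)] + 1 / ep$fs + 1e-9)
    stopf("window [%g, %g] s exceeds the epoch", window[1], window[2])
  keep <- which(tt >= window[1] & tt < window[2])
  keep <- keep[seq(1, length(keep), by = max(1L, as.integer(time_decim)))]
  d <- dim(ep$data)
  out <- array(0, dim = c(d[1], length(channels), length(freqs), length(keep)))
  for (i in seq_len(d[1]))
    for (jj in seq_along(channels)) {
      m <- cwt_scaleogram(ep$data[i, channels[jj], ], ep$fs, freqs, sigma,
                          t0 = ep$t0)
      out[i, jj, , ] <- m$values[, keep]
    }
  ft <- list(data = out, labels = ep$labels, freqs = freqs, times = tt[keep],
             feature_labels = ep$channel_labels[channels])
  class(ft) <- "feature_tensor"
  ft
}

#' Balance classes by random undersampling
#'
#' Reduces every class to the size of the smallest one by uniform random
#' selection, so the classifier and the AUC metric see balanced designs.
#'
#' @param labels class label per trial.
#' @param seed integer seed making the kept set reproducible.
#' @return Sorted integer indices of the kept trials.
#' @export
balance_by_undersampling <- function(labels, seed = 1L) {
  cnt <- table(labels)
  if (any(cnt == 0) || length(cnt) < 2) stopf("need >= 2 non-empty classes")
  m <- min(cnt)
  with_seed(seed, {
    keep <- unlist(lapply(names(cnt), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > m) sample(idx, m) else idx
    }))
    sort(keep)
  })
}

## --- shrinkage LDA -------------------------------------------------------
## Gaussian LDA with a shrunk pooled covariance
## S_lambda = (1 - lambda) S + lambda * mean(diag(S)) * I  (plus a tiny
## ridge), so 1-3 feature pixels with collinear or within-class-constant
## power never produce a singular fit.
lda_fit <- function(X, y, lambda = 0.05) {
  X <- as.matrix(X); y <- as.factor(y)
  d <- ncol(X); n <- nrow(X)
  cls <- levels(y)
  mu <- matrix(0, length(cls), d)
  Sw <- matrix(0, d, d)
  for (i in seq_along(cls)) {
    Xi <- X[y == cls[i], , drop = FALSE]
    mu[i, ] <- colMeans(Xi)
    xc <- sweep(Xi, 2, mu[i, ])
    Sw <- Sw + crossprod(xc)
  }
  Sw <- Sw / (n - length(cls))
  nu <- mean(diag(Sw))
  if (nu == 0) nu <- 1e-12
  S <- (1 - lambda) * Sw + lambda * nu * diag(d) + 1e-10 * nu * diag(d)
  Sinv <- solve(S)
  W <- Sinv %*% t(mu)                       # d x n_classes
  b <- -0.5 * colSums(t(mu) * W) + log(as.numeric(table(y)[cls]) / n)
  list(W = W, b = b, classes = cls)
}

lda_scores <- function(fit, X) {
  sweep(as.matrix(X) %*% fit$W, 2, fit$b, `+`)
}

## softmax posteriors of the discriminant scores; used for one-vs-rest AUC
## (raw linear scores share a monotone trend across ordered classes, which
## would corrupt the ranking for middle classes)
lda_posterior <- function(fit, X) {
  sc <- lda_scores(fit, X)
  sc <- sc - apply(sc, 1, max)
  e <- exp(sc)
  e / rowSums(e)
}

## Mann-Whitney AUC of scores for positives vs negatives (tie-aware)
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## macro one-vs-rest AUC from a score matrix (trials x classes)
macro_auc <- function(scores, y, classes) {
  a <- vapply(seq_along(classes), function(ci)
    auc_rank(scores[, ci], y == classes[ci]), numeric(1))
  mean(a, na.rm = TRUE)
}

stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
}

#' Cross-validated multiclass decoding of a feature tensor
#'
#' At every (frequency, time) pixel, trains a shrinkage-regularized linear
#' discriminant on the per-region power features under stratified k-fold
#' cross-validation (default 10-fold: train on 90%, test on the held-out
#' 10%), and scores performance as the macro-averaged one-vs-rest AUC of the
#' test-set discriminant scores, averaged across folds.  Labels must be
#' balanced first ([balance_by_undersampling()]).
#'
#' @param ft a `feature_tensor`.
#' @param folds number of CV folds.
#' @param seed seed for the fold assignment.
#' @param lambda covariance shrinkage of the LDA.
#' @return A `decoding_map`: list with `auc` (freqs x times), `freqs`,
#'   `times`, `n_trials`, `folds`.
#' @export
decode_multiclass <- function(ft, folds = 10, seed = 1L, lambda = 0.05) {
  stopifnot(inherits(ft, "feature_tensor"))
  y <- as.factor(ft$labels)
  cls <- levels(y)
  cnt <- table(y)
  if (length(unique(cnt)) != 1)
    stopf("labels are unbalanced (%s); undersample first",
          paste(cnt, collapse = "/"))
  if (min(cnt) < folds)
    stopf("need >= %d trials per class for %d folds", folds, folds)
  dm <- dim(ft$data)
  fold_id <- stratified_folds(y, folds, seed)
  auc <- matrix(NA_real_, dm[3], dm[4])
  for (fi in seq_len(dm[3])) {
    for (ti in seq_len(dm[4])) {
      X <- matrix(ft$data[, , fi, ti], dm[1], dm[2])
      fold_auc <- vapply(seq_len(folds), function(k) {
        tr <- fold_id != k; te <- !tr
        fit <- lda_fit(X[tr, , drop = FALSE], y[tr], lambda)
        sc <- lda_posterior(fit, X[te, , drop = FALSE])
        macro_auc(sc, as.character(y[te]), fit$classes)
      }, numeric(1))
      auc[fi, ti] <- mean(fold_auc, na.rm = TRUE)
    }
  }
  out <- list(auc = auc, freqs = ft$freqs, times = ft$times,
              n_trials = dm[1], folds = folds,
              feature_labels = ft$feature_labels)
  class(out) <- "decoding_map"
  out
}

#' @export
print.decoding_map <- function(x, ...) {
  cat(sprintf("<decoding_map> %d freqs x %d times, %d trials, %d-fold CV, mean AUC %.3f\n",
              length(x$freqs), length(x$times), x$n_trials, x$folds,
              mean(x$auc)))
  invisible(x)
}

## 4-connected component labelling of a logical matrix (BFS flood fill)
label_clusters <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (p in which(mask)) {
    if (lab[p]) next
    cur <- cur + 1L
    stack <- p
    lab[p] <- cur
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((q - 1L) %% nr) + 1L
      cc <- ((q - 1L) %/% nr) + 1L
      nb <- c(if (r > 1L) q - 1L, if (r < nr) q + 1L,
              if (cc > 1L) q - nr, if (cc < nc) q + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

max_cluster_mass <- function(tvec, nr, nc, thr) {
  tm <- matrix(tvec, nr, nc)
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- (sgn * tm) > thr
    if (!any(mask)) next
    lab <- label_clusters(mask)
    if (max(lab) > 0) {
      masses <- vapply(seq_len(max(lab)), function(l) sum(tm[lab == l]),
                       numeric(1))
      best <- max(best, max(abs(masses)))
    }
  }
  best
}

#' Group-level cluster-based permutation test on AUC maps
#'
#' Tests per-subject AUC maps against chance with pixel-wise two-sided
#' t-tests, forms clusters of contiguous supra-threshold pixels
#' (4-connectivity in the time-frequency plane, positive and negative
#' excursions separately) scored by their summed t, and assesses them
#' against the null distribution of the maximum cluster mass obtained by
#' random sign-flipping of each subject's deviation map
#' (`n_perm` iterations).  Family-wise error is controlled at the cluster
#' `alpha`.
#'
#' @param maps list of subject AUC matrices (freqs x times) or a 3-D array
#'   subjects x freqs x times (e.g. stacked `decoding_map$auc`).
#' @param chance chance level subtracted from the maps (default 0.5).
#' @param n_perm permutation iterations (default 1000).
#' @param alpha cluster-level significance cutoff.
#' @param cluster_alpha pixel-level two-sided p forming clusters
#'   (default 0.05, i.e. |t| above the t quantile with n_subjects - 1 df).
#' @param seed seed for the sign flips.
#' @return A `cluster_test`: list with `t_map`, `cluster_labels` (signed
#'   integer matrix), `clusters` (data.frame: id, sign, n_pixels, mass, p),
#'   `sig_mask`, `n_perm`, `alpha`.
#' @export
cluster_permutation_test <- function(maps, chance = 0.5, n_perm = 1000,
                                     alpha = 0.05, cluster_alpha = 0.05,
                                     seed = 1L) {
  if (is.array(maps) && length(dim(maps)) == 3)
    maps <- lapply(seq_len(dim(maps)[1]), function(i) maps[i, , ])
  n_sub <- length(maps)
  if (n_sub < 3) stopf("need >= 3 subjects for an across-subject t-test")
  if (n_perm < 1 / alpha)
    warning(sprintf("n_perm = %d gives p-value resolution coarser than alpha = %g",
                    n_perm, alpha))
  nr <- nrow(maps[[1]]); nc <- ncol(maps[[1]])
  D <- t(vapply(maps, function(m) as.numeric(m) - chance, numeric(nr * nc)))
  ss <- colSums(D^2)
  thr <- stats::qt(1 - cluster_alpha / 2, df = n_sub - 1)
  t_of <- function(eps) {
    m <- as.numeric(eps %*% D) / n_sub
    v <- (ss - n_sub * m^2) / (n_sub - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n_sub)
  }
  t_obs <- t_of(rep(1, n_sub))
  tm <- matrix(t_obs, nr, nc)
  ## observed clusters, both signs
  clusters <- NULL
  lab_signed <- matrix(0L, nr, nc)
  next_id <- 0L
  for (sgn in c(1L, -1L)) {
    mask <- (sgn * tm) > thr
    if (!any(mask)) next
    lab <- label_clusters(mask)
    for (l in seq_len(max(lab))) {
      next_id <- next_id + 1L
      sel <- lab == l
      lab_signed[sel] <- next_id * sgn
      clusters <- rbind(clusters,
                        data.frame(id = next_id, sign = sgn,
                                   n_pixels = sum(sel),
                                   mass = sum(tm[sel])))
    }
  }
  ## permutation null of the max cluster mass
  null_max <- with_seed(seed, {
    E <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE), n_perm, n_sub)
    vapply(seq_len(n_perm),
           function(i) max_cluster_mass(t_of(E[i, ]), nr, nc, thr),
           numeric(1))
  })
  if (!is.null(clusters)) {
    clusters$p <- vapply(clusters$mass, function(m)
      (1 + sum(null_max >= abs(m))) / (n_perm + 1), numeric(1))
    clusters <- clusters[order(clusters$p, -abs(clusters$mass)), ]
  } else {
    clusters <- data.frame(id = integer(0), sign = integer(0),
                           n_pixels = integer(0), mass = numeric(0),
                           p = numeric(0))
  }
  sig_ids <- clusters$id[clusters$p < alpha]
  out <- list(t_map = tm, cluster_labels = lab_signed, clusters = clusters,
              sig_mask = matrix(abs(lab_signed) %in% sig_ids, nr, nc),
              null_max = null_max, n_perm = n_perm, alpha = alpha,
              n_subjects = n_sub)
  class(out) <- "cluster_test"
  out
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d subjects, %d permutations, %d cluster(s), %d significant at alpha = %g\n",
              x$n_subjects, x$n_perm, nrow(x$clusters),
              sum(x$clusters$p < x$alpha), x$alpha))
  if (nrow(x$clusters)) print(utils::head(x$clusters, 5), row.names = FALSE)
  invisible(x)
}
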