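## Gaussian-copula mutual information between band power and stimulus class,
## and co-information (redundancy / synergy) between region pairs.

## rank -> standard normal quantile (copula normalization); average ranks for
## ties, then the deterministic quantile map r/(n+1)
copnorm <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, copnorm))
  stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

## Gaussian entropy (nats) of an n x d matrix with small-sample bias
## correction (psi-function terms for the covariance estimate).
ent_g <- function(x, bias = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < d + 2) stopf("too few samples (%d) for a %d-dim Gaussian entropy", n, d)
  xc <- sweep(x, 2, colMeans(x))
  C <- crossprod(xc) / (n - 1)
  ch <- tryCatch(chol(C), error = function(e) {
    chol(C + diag(1e-10 * max(diag(C), 1), d))   # rank-degenerate: tiny ridge
  })
  h <- sum(log(diag(ch))) + 0.5 * d * (log(2 * pi) + 1)
  if (bias) {
    psiterms <- digamma((n - seq_len(d)) / 2) / 2
    dterm <- (log(2) - log(n - 1)) / 2
    h <- h - (d * dterm + sum(psiterms))
  }
  h
}

#' Gaussian-copula mutual information with a discrete class
#'
#' Rank-normalizes each continuous variable to standard normal quantiles
#' (copula transform), then computes the parametric mutual information
#' between the Gaussianized variables and the discrete class from
#' class-conditional Gaussian entropies,
#' `I = H(X) - sum_c p_c H(X | c)`, with analytic small-sample bias
#' correction of each entropy.  The copula step makes the estimate invariant
#' under any strictly monotone transform of each variable.
#'
#' @param values numeric vector (one variable) or trials x d matrix.
#' @param labels class label per trial (>= 2 classes, >= 4 trials each so
#'   the class-conditional covariances are estimable).
#' @param bias apply the small-sample bias correction (default TRUE).
#' @param floor clip the estimate at 0 (residual negative values are
#'   estimator noise); the co-information combination uses unfloored terms.
#' @return Mutual information in bits.
#' @export
gcmi_discrete <- function(values, labels, bias = TRUE, floor = TRUE) {
  x <- as.matrix(values)
  n <- nrow(x)
  if (length(labels) != n) stopf("labels length must match trial count")
  labels <- as.factor(labels)
  cnt <- table(labels)
  if (length(cnt) < 2) stopf("need >= 2 classes")
  if (any(cnt < ncol(x) + 2))
    stopf("every class needs more than d + 1 trials (smallest has %d)", min(cnt))
  cx <- as.matrix(copnorm(x))
  ## exactly collinear columns (e.g. a duplicated region) carry no extra
  ## information: keep an independent column basis
  if (ncol(cx) > 1) {
    qd <- qr(cx)
    if (qd$rank < ncol(cx))
      cx <- cx[, qd$pivot[seq_len(qd$rank)], drop = FALSE]
  }
  h_unc <- ent_g(cx, bias)
  h_cond <- 0
  for (cl in levels(labels)) {
    sel <- labels == cl
    h_cond <- h_cond + (sum(sel) / n) * ent_g(cx[sel, , drop = FALSE], bias)
  }
  i <- (h_unc - h_cond) / log(2)
  if (floor) max(0, i) else i
}

#' Co-information between two regions about the stimulus class
#'
#' For each time point computes `I(X;S)`, `I(Y;S)`, `I(X,Y;S)` by
#' Gaussian-copula MI ([gcmi_discrete()]) and combines them as
#' `co-I(X;Y;S) = I(X;S) + I(Y;S) - I(X,Y;S)`.
#' Positive co-I: the two regions carry redundant (overlapping) information
#' about the class; negative co-I: synergy — the pair jointly carries more
#' than the sum of its parts.  The MI terms enter unfloored so the sign of
#' co-I is unbiased.
#'
#' @param x,y trials x times matrices (e.g. band power) from two regions,
#'   same trials in the same order.
#' @param labels class per trial (exactly 2 classes is the usual contrast).
#' @param times optional time axis for the result.
#' @return A `coinfo_result`: list with `times`, `I_xs`, `I_ys`, `I_xys`,
#'   `coI` (bits per time point).
#' @export
coinformation <- function(x, y, labels, times = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stopf("x and y must have matching trials x times")
  if (length(labels) != nrow(x)) stopf("labels length must equal trial count")
  nt <- ncol(x)
  I_xs <- I_ys <- I_xys <- numeric(nt)
  for (t in seq_len(nt)) {
    I_xs[t] <- gcmi_discrete(x[, t], labels, floor = FALSE)
    I_ys[t] <- gcmi_discrete(y[, t], labels, floor = FALSE)
    I_xys[t] <- gcmi_discrete(cbind(x[, t], y[, t]), labels, floor = FALSE)
  }
  out <- list(times = if (is.null(times)) seq_len(nt) else times,
              I_xs = I_xs, I_ys = I_ys, I_xys = I_xys,
              coI = I_xs + I_ys - I_xys)
  class(out) <- "coinfo_result"
  out
}

#' @export
print.coinfo_result <- function(x, ...) {
  cat(sprintf("<coinfo_result> %d time points, mean coI %.4f bits (%s)\n",
              length(x$times), mean(x$coI),
              if (mean(x$coI) >= 0) "redundancy-leaning" else "synergy-leaning"))
  invisible(x)
}

#' Band-power co-information pipeline for one region pair and class pair
#'
#' Chains the co-information analysis end to end: band-pass the epochs
#' (default 6--10 Hz, zero-phase FIR), Hilbert analytic signal, squared
#' envelope (time-resolved band power), optional temporal smoothing and
#' decimation, then [coinformation()] between the selected pair of classes.
#' Also reports the post- vs pre-stimulus contrast of the mean co-I.
#'
#' @param ep a broadband `epoch_set`.
#' @param pair two channel indices or labels.
#' @param classes two class labels to contrast.
#' @param band Hz pair for the power band.
#' @param smooth_s width (s) of a moving-average smoother applied to the
#'   power time course per trial (0 to disable; default 0.5 — single-sample
#'   MI at ~20 trials per class is high-variance).
#' @param decimate keep every `decimate`-th time point (default 10).
#' @param post,pre seconds pairs for the contrast windows.
#' @return A `coinfo_result` with extra fields `pair`, `classes`,
#'   `post_mean`, `pre_mean`, `contrast` (bits).
#' @export
coinfo_pipeline <- function(ep, pair = c(1, 2), classes, band = c(6, 10),
                            smooth_s = 0.5, decimate = 10,
                            post = c(1, 5), pre = NULL) {
  validate_epochs(ep)
  if (is.character(pair)) pair <- match(pair, ep$channel_labels)
  if (length(classes) != 2) stopf("classes must name exactly two classes")
  keep <- ep$labels %in% classes
  if (sum(keep) < 8) stopf("too few trials in the selected classes")
  cnt <- table(ep$labels[keep])
  if (min(cnt) / max(cnt) < 0.5)
    warning("class counts are imbalanced: ", paste(cnt, collapse = " vs "))
  sub <- ep
  sub$data <- ep$data[keep, , , drop = FALSE]
  sub$labels <- ep$labels[keep]
  bp <- bandpass_zero_phase(sub, band[1], band[2])
  as <- analytic_signal(bp)
  pow_x <- Mod(as$xi[, pair[1], ])^2
  pow_y <- Mod(as$xi[, pair[2], ])^2
  if (smooth_s > 0) {
    wdt <- max(1L, round(smooth_s * ep$fs))
    pow_x <- t(apply(pow_x, 1, moving_average, width = wdt))
    pow_y <- t(apply(pow_y, 1, moving_average, width = wdt))
  }
  tt <- epoch_times(ep)
  sel <- seq(1, length(tt), by = max(1L, as.integer(decimate)))
  res <- coinformation(pow_x[, sel], pow_y[, sel], sub$labels, times = tt[sel])
  res$pair <- ep$channel_labels[pair]
  res$classes <- classes
  if (is.null(pre)) pre <- c(ep$t0, min(0, ep$t0 + diff(post)))
  post_i <- res$times >= post[1] & res$times < post[2]
  pre_i <- res$times >= pre[1] & res$times < pre[2]
  if (!any(post_i) || !any(pre_i)) stopf("contrast windows outside the epoch")
  res$post_mean <- mean(res$coI[post_i])
  res$pre_mean <- mean(res$coI[pre_i])
  res$contrast <- res$post_mean - res$pre_mean
  res
}
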