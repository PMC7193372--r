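#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: the reference spectrum is the feature-wise
#' median across samples; each sample's dilution factor is the median, over
#' features positive in both the sample and the reference, of
#' `value / reference`; the whole sample row is divided by its factor.
#'
#' @param X Numeric matrix, samples x features (no missing values).
#' @return Normalized matrix with attribute `pqn_factors` (per-sample
#'   dilution factors).
#' @export
pqn_normalize <- function(X) {
  stopifnot(is.matrix(X))
  if (anyNA(X)) stop("missing values in metabolite matrix")
  ref <- apply(X, 2, median)
  factors <- vapply(seq_len(nrow(X)), function(s) {
    elig <- X[s, ] > 0 & ref > 0
    if (!any(elig)) {
      stop("sample ", rownames(X)[s] %||% s,
           " has no positive features eligible for quotient computation")
    }
    median(X[s, elig] / ref[elig])
  }, numeric(1))
  out <- X / factors
  attr(out, "pqn_factors") <- setNames(factors, rownames(X))
  out
}

#' Unit-variance scaling
#'
#' Centers every feature to mean zero and scales to unit standard deviation
#' (denominator n - 1). The means and SDs are retained so the transform can
#' be applied to new data or inverted.
#'
#' @param X Numeric matrix, samples x features.
#' @return List with `X` (scaled matrix), `means`, `sds`.
#' @export
uv_scale <- function(X) {
  stopifnot(is.matrix(X))
  sds <- apply(X, 2, sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    stop("zero-variance feature(s): ",
         paste(colnames(X)[zero] %||% which(zero), collapse = ", "))
  }
  means <- colMeans(X)
  list(X = sweep(sweep(X, 2, means), 2, sds, "/"), means = means, sds = sds)
}

# Apply stored scaling parameters to new data.
uv_apply <- function(Xnew, means, sds) {
  sweep(sweep(Xnew, 2, means), 2, sds, "/")
}

#' Fit an orthogonal projection to latent structures (O-PLS) model
#'
#' One predictive component plus `n_ortho` response-orthogonal components.
#' The predictive weight is `w = X'y` normalized to unit length; each
#' orthogonal component takes the part of the current loading orthogonal to
#' `w` (`w_o = p - (w'p) w`, normalized), scores `t_o = X w_o`, and deflates
#' `X <- X - t_o p_o'`. The final predictive score is `t = X w` on the
#' deflated matrix, with the inner regression `b = t'y / t't`.
#'
#' @param X Scaled descriptor matrix (samples x features); see [uv_scale()].
#' @param y Centered response vector.
#' @param n_ortho Number of orthogonal components.
#' @return Object of class `opls_model`: `w`, `p`, `t`, `W_o`, `P_o`, `T_o`,
#'   `b`, `r2y`, `n_ortho`.
#' @export
fit_opls <- function(X, y, n_ortho = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) > n_ortho + 1)
  if (sd(y) == 0) stop("response has zero variance")
  if (all(X == 0)) stop("degenerate all-zero descriptor matrix")
  w <- drop(crossprod(X, y))
  w <- w / sqrt(sum(w^2))
  W_o <- matrix(0, ncol(X), 0)
  P_o <- matrix(0, ncol(X), 0)
  T_o <- matrix(0, nrow(X), 0)
  Xd <- X
  for (k in seq_len(n_ortho)) {
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    w_o <- p - sum(w * p) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break  # no y-orthogonal structure left
    w_o <- w_o / nrm
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
  }
  t <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t)) / sum(t^2)
  b <- sum(t * y) / sum(t^2)
  r2y <- 1 - sum((y - b * t)^2) / sum((y - mean(y))^2)
  structure(
    list(w = w, p = p, t = t, W_o = W_o, P_o = P_o, T_o = T_o, b = b,
         r2y = r2y, n_ortho = ncol(T_o)),
    class = "opls_model"
  )
}

#' Predict from an O-PLS model
#'
#' Removes the orthogonal components from the new descriptor rows in fit
#' order, then projects on the predictive weight.
#'
#' @param object An `opls_model`.
#' @param newdata Matrix on the same scaling as the training `X`.
#' @param ... Unused.
#' @return List with `yhat` (centered-scale predictions) and scores `t`.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xn <- newdata
  for (k in seq_len(object$n_ortho)) {
    t_o <- drop(Xn %*% object$W_o[, k])
    Xn <- Xn - tcrossprod(t_o, object$P_o[, k])
  }
  t <- drop(Xn %*% object$w)
  list(yhat = object$b * t, t = t)
}

#' Cross-validated predictive performance Q2Y
#'
#' Seven-fold (by default) cross-validation of an O-PLS model:
#' `Q2Y = 1 - PRESS / TSS` with TSS taken on the centered response. Fold
#' membership is a seeded shuffle; unit-variance scaling of `X` and centering
#' of `y` are re-estimated inside each training fold only.
#'
#' @param X Raw (unscaled) descriptor matrix.
#' @param y Response vector.
#' @param k Number of folds (default 7).
#' @param n_ortho Orthogonal components per fold model.
#' @param seed Seed for the fold shuffle.
#' @return Q2Y (scalar, at most 1).
#' @export
q2_cross_validate <- function(X, y, k = 7L, n_ortho = 1L, seed = 1L) {
  n <- nrow(X)
  stopifnot(k >= 2, n >= 2 * k, length(y) == n)
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  if (min(table(fold)) < 2) stop("a fold has fewer than 2 samples")
  press <- 0
  for (f in seq_len(k)) {
    tr <- fold != f
    sc <- uv_scale(X[tr, , drop = FALSE])
    ym <- mean(y[tr])
    fit <- fit_opls(sc$X, y[tr] - ym, n_ortho = n_ortho)
    Xv <- uv_apply(X[!tr, , drop = FALSE], sc$means, sc$sds)
    pred <- predict(fit, Xv)
    press <- press + sum((y[!tr] - (pred$yhat + ym))^2)
  }
  tss <- sum((y - mean(y))^2)
  1 - press / tss
}

#' Permutation validation of an O-PLS model
#'
#' Recomputes the cross-validated Q2Y under `n_perm` random permutations of
#' the response; `p = (1 + #\{Q2_perm >= Q2_obs\}) / (n_perm + 1)`.
#'
#' @param X Raw descriptor matrix.
#' @param y Response vector.
#' @param n_perm Number of permutations (the reference analysis uses 1000).
#' @param seed Integer seed driving both fold shuffles and permutations.
#' @param k,n_ortho Passed to [q2_cross_validate()].
#' @return List with `p`, `observed_q2`, `permuted_q2`.
#' @export
permutation_validate <- function(X, y, n_perm = 1000L, seed = 1L, k = 7L,
                                 n_ortho = 1L) {
  stopifnot(n_perm >= 1)
  withr::with_seed(seed, {
    fold_seeds <- sample.int(.Machine$integer.max - 1L, n_perm + 1L)
    obs <- q2_cross_validate(X, y, k = k, n_ortho = n_ortho,
                             seed = fold_seeds[1])
    perm <- vapply(seq_len(n_perm), function(b) {
      q2_cross_validate(X, sample(y), k = k, n_ortho = n_ortho,
                        seed = fold_seeds[b + 1L])
    }, numeric(1))
    list(p = (1 + sum(perm >= obs)) / (n_perm + 1),
         observed_q2 = obs, permuted_q2 = perm)
  })
}

#' Feature-level correlations with the model driver
#'
#' Pearson correlation of every feature with a driver vector (by default the
#' model's predictive scores; the raw response may be used instead), with
#' t-distribution p-values and Benjamini-Hochberg q-values. Constant
#' features get `r = 0`, `p = 1` with a warning.
#'
#' @param X Feature matrix (samples x features).
#' @param driver Numeric vector of length `nrow(X)` (predictive scores `t`
#'   or the response `y`).
#' @return data.frame `feature`, `r`, `p`, `q`.
#' @export
feature_correlations <- function(X, driver) {
  stopifnot(nrow(X) == length(driver))
  n <- nrow(X)
  sds <- apply(X, 2, sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s); reported as r = 0, p = 1")
  }
  r <- rep(0, ncol(X))
  r[!const] <- drop(cor(X[, !const, drop = FALSE], driver))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[const] <- 1
  data.frame(feature = colnames(X) %||% paste0("feat", seq_len(ncol(X))),
             r = r, p = p, q = bh_adjust(p), stringsAsFactors = FALSE)
}
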