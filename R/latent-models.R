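#' Fit a single-response partial least squares regression
#'
#' Classical PLS1 by sequential deflation (NIPALS, exact for one response):
#' each component's unit-norm weight vector maximizes the covariance of its
#' X-score with the response; X is deflated by the loading projection after
#' each round. Predictions are reconstructed in the original variable space
#' via \eqn{B = W (P'W)^{-1} q}.
#'
#' The predictor matrix is expected centred and scaled (see [preprocess()]);
#' columns are re-centred internally for numerical safety but never rescaled.
#' The response is centred internally and its training mean stored.
#'
#' @param X numeric matrix (n x p) of standardized predictors, with column
#'   names.
#' @param y numeric response vector of length n, no missing values.
#' @param A number of components, \code{1 <= A <= min(n-1, p)}.
#' @return A \code{latent_model} with weights \code{W} (p x A), X-loadings
#'   \code{P}, scores \code{scores} (n x A), response loadings \code{q},
#'   per-component shares of training response variance \code{SS},
#'   coefficients \code{coef} in predictor space, \code{y_mean},
#'   \code{x_center}, \code{r2_train}.
#' @export
fit_pls <- function(X, y, A) {
  prep <- check_xy(X, y, A)
  X0 <- prep$X; yc <- prep$y
  n <- nrow(X0); p <- ncol(X0)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xd <- X0
  yd <- yc
  ss_tot <- sum(yc^2)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(ss_tot))) break  # no covariance left
    w <- w / nw
    tvec <- drop(Xd %*% w)
    tt <- sum(tvec^2)
    if (tt < 1e-24) break
    pvec <- drop(crossprod(Xd, tvec)) / tt
    qa <- sum(yd * tvec) / tt
    Xd <- Xd - tcrossprod(tvec, pvec)
    yd <- yd - qa * tvec
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- tvec; q[a] <- qa
    a_used <- a
  }
  if (a_used == 0L) stopf("response has no covariance with the predictors")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  sgn <- component_signs(P)
  W <- sweep(W, 2, sgn, "*"); P <- sweep(P, 2, sgn, "*")
  Tm <- sweep(Tm, 2, sgn, "*"); q <- q * sgn
  SS <- q^2 * colSums(Tm^2) / ss_tot
  coef <- drop(W %*% solve(crossprod(P, W), q))
  new_latent_model("PLS", a_used, W, P, Tm, q, SS, coef, prep, sum(SS))
}

#' Fit a principal-components regression
#'
#' The components are the leading principal axes of the predictor matrix
#' (right singular vectors, i.e. eigenvectors of its covariance in descending
#' eigenvalue order); the centred response is regressed on the A component
#' scores, which are mutually orthogonal, so each component's share of
#' training response variance is additive.
#'
#' @inheritParams fit_pls
#' @return A \code{latent_model} (no weight matrix \code{W}; the orthonormal
#'   loadings \code{P} play that role).
#' @export
fit_pcr <- function(X, y, A) {
  prep <- check_xy(X, y, A)
  X0 <- prep$X; yc <- prep$y
  sv <- svd(X0, nu = 0, nv = A)
  pos <- sv$d[seq_len(A)] > 1e-10 * sv$d[1]
  a_used <- max(1L, sum(pos))
  P <- sv$v[, seq_len(a_used), drop = FALSE]
  sgn <- component_signs(P)
  P <- sweep(P, 2, sgn, "*")
  Tm <- X0 %*% P
  tt <- colSums(Tm^2)
  q <- drop(crossprod(Tm, yc)) / tt
  SS <- q^2 * tt / sum(yc^2)
  coef <- drop(P %*% q)
  rownames(P) <- colnames(X0)
  new_latent_model("PCR", a_used, NULL, P, Tm, q, SS, coef, prep, sum(SS))
}

# shared input validation / centring for the latent models
check_xy <- function(X, y, A) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stopf("X has %d rows but y has length %d",
                                  nrow(X), length(y))
  if (anyNA(X) || anyNA(y)) stopf("X and y must be complete (impute first)")
  sds <- apply(X, 2, stats::sd)
  if (any(sds <= 1e-12))
    stopf("zero-variance column(s): %s (preprocess them out)",
          paste(colnames(X)[sds <= 1e-12], collapse = ", "))
  A <- as.integer(A)
  if (A < 1) stopf("A must be >= 1")
  if (A > min(nrow(X) - 1L, ncol(X)))
    stopf("A = %d exceeds the rank bound min(n-1, p) = %d",
          A, min(nrow(X) - 1L, ncol(X)))
  xc <- colMeans(X)
  ym <- mean(y)
  list(X = sweep(X, 2, xc, "-"), y = y - ym, x_center = xc, y_mean = ym,
       var_names = colnames(X))
}

# deterministic sign convention: largest-|loading| entry positive
component_signs <- function(P) {
  apply(P, 2, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
}

new_latent_model <- function(method, A, W, P, Tm, q, SS, coef, prep, r2) {
  if (!is.null(W)) rownames(W) <- prep$var_names
  rownames(P) <- prep$var_names
  structure(list(method = method, A = A, W = W, P = P, scores = Tm, q = q,
                 SS = SS, coef = stats::setNames(coef, prep$var_names),
                 x_center = prep$x_center, y_mean = prep$y_mean,
                 var_names = prep$var_names, r2_train = r2),
            class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("%s model: %d component(s), %d variables, training R^2 = %.4f\n",
              x$method, x$A, length(x$var_names), x$r2_train))
  invisible(x)
}

#' Predict from a fitted latent model
#'
#' \eqn{\hat y = \bar y_{train} + X_{new} B}. New data must carry the model's
#' variables; if column names are present they are aligned by name, so column
#' order does not matter. \code{newdata} must already be transformed with the
#' training preprocessing statistics (see [apply_preprocess()]).
#'
#' @param object latent_model.
#' @param newdata numeric matrix of predictors.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.latent_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    missing_v <- setdiff(object$var_names, colnames(X))
    extra_v <- setdiff(colnames(X), object$var_names)
    if (length(missing_v) || length(extra_v))
      stopf("column mismatch: missing [%s], extra [%s]",
            paste(missing_v, collapse = ", "), paste(extra_v, collapse = ", "))
    X <- X[, object$var_names, drop = FALSE]
  } else if (ncol(X) != length(object$var_names)) {
    stopf("newdata has %d columns, model expects %d", ncol(X),
          length(object$var_names))
  }
  drop(object$y_mean + sweep(X, 2, object$x_center, "-") %*% object$coef)
}

#' Holdout fit metrics: RMSE and variance explained
#'
#' \code{rmse} is the root mean squared prediction error;
#' \code{variance_explained} is the pseudo-R^2
#' \eqn{1 - MSE(Y, \hat Y) / \mathrm{variance}(Y)} with the population (1/n)
#' variance in the denominator, so predicting the mean scores exactly 0 and
#' worse-than-mean predictors score negative.
#'
#' @param y observed response values.
#' @param y_hat predictions of the same length (>= 2).
#' @return object of class \code{fit_metrics}: list with \code{rmse} and
#'   \code{variance_explained}.
#' @export
score_predictions <- function(y, y_hat) {
  if (length(y) != length(y_hat))
    stopf("length mismatch: y has %d, y_hat has %d", length(y), length(y_hat))
  if (length(y) < 2) stopf("need at least 2 observations")
  mse <- mean((y - y_hat)^2)
  structure(list(rmse = sqrt(mse),
                 variance_explained = 1 - mse / pop_var(y)),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("rmse = %.4f, variance explained = %.4f\n",
              x$rmse, x$variance_explained))
  invisible(x)
}

#' Cross-validated component selection by the one-standard-error rule
#'
#' Estimates the root mean squared error of prediction RMSEP(A) for
#' \code{A = 0, ..., max_A} (A = 0 is the intercept-only model) by k-fold
#' cross-validation with folds formed as contiguous blocks of a seeded
#' permutation, then picks the smallest A whose RMSEP is within one standard
#' error of the minimum — the simplest model statistically indistinguishable
#' from the best, guarding against overfitting the component count.
#'
#' @param X standardized predictor matrix with column names.
#' @param y complete response vector.
#' @param max_A largest component count evaluated; default
#'   \code{min(n - ceiling(n/n_folds) - 1, p, 100)}.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed for the fold permutation.
#' @param method \code{"pls"} or \code{"pcr"}.
#' @return A \code{component_selection}: RMSEP and SE per component count,
#'   the selected A, fold count and seed.
#' @export
select_components <- function(X, y, max_A = NULL, n_folds = 10L, seed = 1L,
                              method = c("pls", "pcr")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_folds) stopf("n = %d is smaller than n_folds = %d", n, n_folds)
  cap <- min(n - ceiling(n / n_folds) - 1L, ncol(X), 100L)
  max_A <- as.integer(max_A %||% cap)
  if (max_A < 1) stopf("max_A must be >= 1")
  max_A <- min(max_A, cap)
  set.seed(seed)
  perm <- sample.int(n)
  # folds are contiguous blocks of the seeded permutation
  fold_of <- integer(n)
  bounds <- floor(seq(0, n, length.out = n_folds + 1))
  for (f in seq_len(n_folds)) fold_of[perm[(bounds[f] + 1):bounds[f + 1]]] <- f
  err2 <- matrix(NA_real_, n, max_A + 1L)  # per-observation CV squared error
  for (f in seq_len(n_folds)) {
    tr <- fold_of != f
    Bs <- nested_coefs(X[tr, , drop = FALSE], y[tr], max_A, method)
    Xte <- sweep(X[!tr, , drop = FALSE], 2, Bs$x_center, "-")
    preds <- Xte %*% Bs$B + rep(Bs$y_mean, each = sum(!tr))
    preds <- cbind(Bs$y_mean, preds)  # A = 0 column first
    err2[!tr, ] <- (y[!tr] - preds)^2
  }
  rmsep <- sqrt(colMeans(err2))
  fold_rmse <- t(vapply(seq_len(n_folds), function(f)
    sqrt(colMeans(err2[fold_of == f, , drop = FALSE])), numeric(max_A + 1L)))
  se <- apply(fold_rmse, 2, stats::sd) / sqrt(n_folds)
  names(rmsep) <- names(se) <- as.character(0:max_A)
  sel <- select_one_se(rmsep, se)
  structure(list(rmsep = rmsep, se = se, selected_A = sel,
                 n_folds = n_folds, seed = seed, method = method),
            class = "component_selection")
}

#' One-standard-error rule on an RMSEP curve
#'
#' Given cross-validated errors for component counts \code{0, 1, ...} and
#' their standard errors, returns the smallest count whose error does not
#' exceed the minimum error plus the standard error at the minimizer.
#'
#' @param rmsep numeric vector of CV errors for A = 0, 1, ... (names, if
#'   present, give the component counts).
#' @param se standard errors of the same length (or a single SE applied at
#'   the minimizer).
#' @return integer: the selected component count.
#' @export
select_one_se <- function(rmsep, se) {
  if (length(se) == 1) se <- rep(se, length(rmsep))
  if (length(se) != length(rmsep)) stopf("rmsep and se lengths differ")
  amin <- which.min(rmsep)
  thr <- rmsep[amin] + se[amin]
  counts <- if (!is.null(names(rmsep))) as.integer(names(rmsep))
            else seq_along(rmsep) - 1L
  counts[which(rmsep <= thr)[1]]
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("component_selection (%s, %d-fold CV): selected A = %d (of 0..%d)\n",
              x$method, x$n_folds, x$selected_A, length(x$rmsep) - 1L))
  invisible(x)
}

# Coefficient paths B (p x max_A) for nested component counts, fit on (X, y).
nested_coefs <- function(X, y, max_A, method) {
  xc <- colMeans(X)
  ym <- mean(y)
  X0 <- sweep(X, 2, xc, "-")
  yc <- y - ym
  p <- ncol(X)
  max_A <- min(max_A, nrow(X) - 1L, p)
  B <- matrix(0, p, max_A)
  if (method == "pcr") {
    sv <- svd(X0, nu = 0, nv = max_A)
    keep <- sv$d[seq_len(max_A)] > 1e-10 * max(sv$d[1], 1e-300)
    V <- sv$v
    b <- numeric(p)
    for (a in seq_len(max_A)) {
      if (keep[a]) {
        tvec <- X0 %*% V[, a]
        b <- b + V[, a] * sum(tvec * yc) / sum(tvec^2)
      }
      B[, a] <- b
    }
  } else {
    W <- P <- matrix(0, p, max_A)
    q <- numeric(max_A)
    Xd <- X0; yd <- yc
    a_used <- 0L
    for (a in seq_len(max_A)) {
      w <- drop(crossprod(Xd, yd))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      tvec <- drop(Xd %*% w)
      tt <- sum(tvec^2)
      if (tt < 1e-24) break
      pv <- drop(crossprod(Xd, tvec)) / tt
      qa <- sum(yd * tvec) / tt
      Xd <- Xd - tcrossprod(tvec, pv)
      yd <- yd - qa * tvec
      W[, a] <- w; P[, a] <- pv; q[a] <- qa
      a_used <- a
      B[, a] <- W[, 1:a, drop = FALSE] %*%
        solve(crossprod(P[, 1:a, drop = FALSE], W[, 1:a, drop = FALSE]),
              q[1:a])
    }
    if (a_used < max_A && a_used > 0L)
      for (a in (a_used + 1L):max_A) B[, a] <- B[, a_used]
  }
  list(B = B, x_center = xc, y_mean = ym)
}

#' Variable importance in projection (VIP) scores
#'
#' For a fitted PLS model,
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}}
#' where \eqn{SS_a} is component a's share of training response variance and
#' \eqn{w_a} its weight vector. The mean of squared VIP over variables is 1
#' by construction, so variables scoring below 1 contribute less than an
#' average variable and are conventionally removable.
#'
#' @param model a \code{latent_model} with \code{method == "PLS"} and at
#'   least one component.
#' @return named numeric vector of VIP scores (>= 0), one per variable.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "latent_model") || model$method != "PLS")
    stopf("VIP scores are defined for PLS models")
  if (model$A < 1) stopf("model has no components")
  W <- model$W
  wn2 <- sweep(W, 2, sqrt(colSums(W^2)), "/")^2
  ss <- model$SS
  vip <- sqrt(nrow(W) * drop(wn2 %*% ss) / sum(ss))
  stats::setNames(vip, model$var_names)
}

#' Per-variable percent of response variance explained (PCR decomposition)
#'
#' Each variable's squared influence on every retained principal component,
#' scaled by the share of training response variance that component explains:
#' \deqn{c_j = \sum_a p_{ja}^2 SS_a} (in percent). Because loading columns
#' are orthonormal, the contributions sum exactly to the model's training
#' R^2.
#'
#' @param model a \code{latent_model} with \code{method == "PCR"}.
#' @return named numeric vector: percent of response variance per variable.
#' @export
pcr_variance_decomposition <- function(model) {
  if (!inherits(model, "latent_model") || model$method != "PCR")
    stopf("the variance decomposition is defined for PCR models")
  if (model$A < 1) stopf("model has no components")
  P <- model$P
  G <- crossprod(P)
  if (max(abs(G - diag(ncol(P)))) > 1e-6)
    stopf("PCR loadings are not orthonormal; model state is corrupted")
  contrib <- drop(P^2 %*% model$SS) * 100
  stats::setNames(contrib, model$var_names)
}
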