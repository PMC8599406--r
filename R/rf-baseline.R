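#' Random-forest regression baseline
#'
#' A comparison model for the latent-variable regressions: an ensemble of
#' regression trees on bootstrap resamples with random variable subsetting at
#' each split (delegated to \pkg{ranger}), at the conventional defaults of
#' 500 trees and \code{mtry = max(1, floor(p/3))}. The out-of-bag pseudo-R^2
#' uses the same variance-explained formula as [score_predictions()]
#' (population variance in the denominator), computed from out-of-bag
#' predictions on the training side.
#'
#' @param X_train numeric predictor matrix (preprocessed) with column names.
#' @param y_train complete numeric response.
#' @param n_trees number of trees (default 500).
#' @param mtry_fraction fraction of variables available per split
#'   (default 1/3).
#' @param seed integer seed; fits are deterministic under it (single thread).
#' @return An \code{rf_baseline}: list with the ranger \code{fit},
#'   \code{oob_r2}, \code{oob_rmse}, \code{mtry}, \code{n_trees},
#'   \code{seed}.
#' @export
fit_rf_baseline <- function(X_train, y_train, n_trees = 500L,
                            mtry_fraction = 1 / 3, seed = 1L) {
  X_train <- as.matrix(X_train)
  p <- ncol(X_train)
  if (p == 0) stopf("no predictor variables")
  if (anyNA(X_train) || anyNA(y_train)) stopf("training data must be complete")
  mtry <- max(1L, floor(p * mtry_fraction))
  fit <- ranger::ranger(x = X_train, y = as.numeric(y_train),
                        num.trees = n_trees, mtry = mtry, seed = seed,
                        num.threads = 1, verbose = FALSE)
  oob <- fit$predictions
  ok <- is.finite(oob)
  oob_mse <- mean((y_train[ok] - oob[ok])^2)
  structure(list(fit = fit, mtry = mtry, n_trees = n_trees, seed = seed,
                 oob_rmse = sqrt(oob_mse),
                 oob_r2 = 1 - oob_mse / pop_var(y_train[ok])),
            class = "rf_baseline")
}

#' @export
predict.rf_baseline <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  vn <- object$fit$forest$independent.variable.names
  if (!is.null(colnames(X)) && all(vn %in% colnames(X)))
    X <- X[, vn, drop = FALSE]
  as.numeric(stats::predict(object$fit, data = X,
                            num.threads = 1)$predictions)
}

#' @export
print.rf_baseline <- function(x, ...) {
  cat(sprintf("rf_baseline: %d trees, mtry = %d, OOB pseudo-R^2 = %.4f\n",
              x$n_trees, x$mtry, x$oob_r2))
  invisible(x)
}
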