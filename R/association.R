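#' Spearman partial correlation
#'
#' Nonparametric partial association between \code{x} and \code{y} given a
#' covariate matrix \code{Z}: all columns are rank-transformed (average ranks
#' for ties), the ranked \code{x} and \code{y} are residualized by least
#' squares on the ranked covariates plus an intercept, and the partial
#' correlation is the Pearson correlation of the two residual vectors. With
#' no covariates this is the ordinary Spearman correlation. The p-value comes
#' from \eqn{t = r\sqrt{(n-2-k)/(1-r^2)}} on \eqn{n-2-k} degrees of freedom,
#' with \eqn{k} covariates. Rows with any missing value across
#' \code{x}, \code{y}, \code{Z} are dropped (complete-case analysis).
#'
#' @param x,y numeric vectors.
#' @param Z optional numeric covariate matrix (or NULL for none).
#' @return list with \code{rho}, \code{p_value}, \code{n_used}, \code{df}.
#' @export
spearman_partial <- function(x, y, Z = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != length(x)) stopf("Z has %d rows, expected %d", nrow(Z),
                                    length(x))
  }
  k <- if (is.null(Z)) 0L else ncol(Z)
  cc <- !is.na(x) & !is.na(y)
  if (k > 0) cc <- cc & !apply(is.na(Z), 1, any)
  n <- sum(cc)
  if (n < k + 3) stopf("only %d complete observations for %d covariates", n, k)
  rx <- rank(x[cc]); ry <- rank(y[cc])
  if (stats::sd(rx) == 0) stopf("x is constant after ranking")
  if (stats::sd(ry) == 0) stopf("y is constant after ranking")
  rx <- rx - mean(rx)
  ry <- ry - mean(ry)
  if (k > 0) {
    RZ <- apply(Z[cc, , drop = FALSE], 2, rank)
    qr_z <- qr(cbind(1, RZ))
    rx <- qr.resid(qr_z, rx)
    ry <- qr.resid(qr_z, ry)
    if (sum(rx^2) < 1e-12 || sum(ry^2) < 1e-12)
      stopf("x or y is fully explained by the covariates")
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  r <- max(-1, min(1, r))
  df <- n - 2L - k
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tstat), df)
  }
  list(rho = r, p_value = p, n_used = n, df = df)
}

#' Grouped partial correlations of every variable with a response
#'
#' For each predictor variable, computes the Spearman partial correlation
#' with the response using as covariates all variables in the \emph{other}
#' variable groups — variables in the tested variable's own group are not
#' adjusted for, so within-group redundancy does not cancel a group's shared
#' signal. p-values are Bonferroni-adjusted with family size equal to the
#' number of variables tested for this response.
#'
#' @param table feature_table with all-numeric predictors.
#' @param response response column name.
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @return data.frame with one row per variable: \code{variable},
#'   \code{group}, \code{response}, \code{rho}, \code{p}, \code{p_adj},
#'   \code{n}, \code{covariates}, \code{significant}.
#' @export
grouped_partial_correlations <- function(table, response, alpha = 0.05) {
  if (!response %in% colnames(table$responses))
    stopf("no such response: %s", response)
  X <- as.matrix(table)
  y <- table$responses[[response]]
  vn <- colnames(X)
  grp <- table$group[vn]
  if (length(unique(grp)) > 1) {
    full <- names(which(table(grp) == length(vn)))
    if (length(full))
      stopf("group '%s' contains all variables; no covariates available", full)
  }
  m <- length(vn)
  res <- vector("list", m)
  complete_X <- !anyNA(X)
  for (g in unique(grp)) {
    members <- vn[grp == g]
    covars <- vn[grp != g]
    if (complete_X) {
      # predictors complete: one projection per group serves all members
      cc <- !is.na(y)
      n <- sum(cc)
      k <- length(covars)
      if (n < k + 3)
        stopf("only %d complete observations for %d covariates (group %s)",
              n, k, g)
      ry <- rank(y[cc])
      if (k > 0) {
        RZ <- apply(X[cc, covars, drop = FALSE], 2, rank)
        qr_z <- qr(cbind(1, RZ))
        ry_r <- qr.resid(qr_z, ry)
      } else ry_r <- ry - mean(ry)
      for (v in members) {
        rx <- rank(X[cc, v])
        rec <- if (stats::sd(rx) == 0) {
          list(rho = NA_real_, p_value = NA_real_, n_used = n)
        } else {
          rx_r <- if (k > 0) qr.resid(qr_z, rx) else rx - mean(rx)
          r <- sum(rx_r * ry_r) / sqrt(sum(rx_r^2) * sum(ry_r^2))
          r <- max(-1, min(1, r))
          df <- n - 2L - k
          p <- if (abs(r) >= 1) 0 else
            2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
          list(rho = r, p_value = p, n_used = n)
        }
        res[[match(v, vn)]] <- data.frame(
          variable = v, group = g, response = response, rho = rec$rho,
          p = rec$p_value, n = rec$n_used, covariates = k,
          stringsAsFactors = FALSE)
      }
    } else {
      for (v in members) {
        rec <- tryCatch(spearman_partial(X[, v], y, X[, covars, drop = FALSE]),
                        error = function(e) list(rho = NA_real_,
                                                 p_value = NA_real_,
                                                 n_used = NA_integer_))
        res[[match(v, vn)]] <- data.frame(
          variable = v, group = g, response = response, rho = rec$rho,
          p = rec$p_value, n = rec$n_used, covariates = length(covars),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p * m)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out[c("variable", "group", "response", "rho", "p", "p_adj", "n",
        "covariates", "significant")]
}
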