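# Standardized random regression fixture with a linear signal.
random_xy <- function(n, p, seed, noise = 1) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  colnames(X) <- paste0("v", seq_len(p))
  beta <- rnorm(p)
  list(X = X, y = drop(X %*% beta) + noise * rnorm(n))
}

test_that("a one-component, one-predictor PLS recovers the least-squares slope", {
  set.seed(10)
  x <- scale(rnorm(60))[, 1]
  y <- 0.7 * x + rnorm(60)
  m <- fit_pls(matrix(x, dimnames = list(NULL, "x")), y, 1)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(unname(m$coef), slope, tolerance = 1e-12)
  expect_equal(unname(vip_scores(m)), 1)   # p = 1 forces VIP = 1
})

test_that("full-rank PLS and PCR reproduce ordinary least squares", {
  d <- random_xy(200, 10, seed = 1)
  ols <- unname(drop(cbind(1, d$X) %*% coef(lm(d$y ~ d$X))))
  for (fit in list(fit_pls(d$X, d$y, 10), fit_pcr(d$X, d$y, 10)))
    expect_equal(unname(predict(fit, d$X)), ols, tolerance = 1e-6)
})

test_that("an exactly linear response is interpolated at full rank", {
  set.seed(3)
  X <- scale(matrix(rnorm(100 * 5), 100, 5))
  colnames(X) <- paste0("v", 1:5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3))
  for (m in list(fit_pls(X, y, 5), fit_pcr(X, y, 5)))
    expect_lt(sqrt(mean((predict(m, X) - y)^2)), 1e-8)
})

test_that("duplicated predictors share the first PLS weight symmetrically", {
  set.seed(4)
  x <- scale(rnorm(80))[, 1]
  X <- cbind(a = x, b = x) + 0  # two identical columns
  X <- X + matrix(rnorm(160, sd = 1e-8), 80, 2)  # break exact singularity
  colnames(X) <- c("a", "b")
  y <- x + rnorm(80)
  m <- fit_pls(X, y, 1)
  expect_equal(unname(abs(m$W[1, 1])), unname(abs(m$W[2, 1])),
               tolerance = 1e-4)
})

test_that("model structure invariants hold on random fits", {
  for (seed in 1:5) {
    d <- random_xy(120, 8, seed = seed)
    pls <- fit_pls(d$X, d$y, 4)
    pcr <- fit_pcr(d$X, d$y, 4)
    # unit-norm PLS weights, orthonormal PCR loadings
    expect_equal(unname(colSums(pls$W^2)), rep(1, 4), tolerance = 1e-10)
    expect_equal(crossprod(pcr$P), diag(4), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # score columns mutually orthogonal
    for (m in list(pls, pcr)) {
      G <- crossprod(m$scores)
      expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
      expect_true(all(m$SS >= 0))
    }
    # PLS training R^2 non-decreasing in A
    r2s <- vapply(1:4, function(a) fit_pls(d$X, d$y, a)$r2_train, numeric(1))
    expect_true(all(diff(r2s) >= -1e-12))
  }
})

test_that("sign flips of a component leave predictions, VIP and decomposition unchanged", {
  d <- random_xy(100, 6, seed = 9)
  pls <- fit_pls(d$X, d$y, 3)
  flip <- function(m, a) {
    if (!is.null(m$W)) m$W[, a] <- -m$W[, a]
    m$P[, a] <- -m$P[, a]
    m$scores[, a] <- -m$scores[, a]
    m$q[a] <- -m$q[a]
    m
  }
  flipped <- flip(pls, 2)
  expect_equal(vip_scores(flipped), vip_scores(pls), tolerance = 1e-12)
  pcr <- fit_pcr(d$X, d$y, 3)
  expect_equal(pcr_variance_decomposition(flip(pcr, 1)),
               pcr_variance_decomposition(pcr), tolerance = 1e-12)
  # coefficients (hence predictions) are invariant as reconstructed
  b_flip <- drop(flipped$W %*% solve(crossprod(flipped$P, flipped$W), flipped$q))
  expect_equal(unname(b_flip), unname(pls$coef), tolerance = 1e-10)
})

test_that("PCR components align with orthogonal columns of descending variance", {
  set.seed(12)
  n <- 300
  # mean-zero, exactly orthogonal columns with descending variance
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  X <- Q %*% diag(c(3, 2, 1)) * sqrt(n)
  colnames(X) <- c("a", "b", "c")
  y <- rnorm(n)
  m <- fit_pcr(X, y, 3)
  expect_equal(abs(m$P), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("prediction aligns new data by column name and validates mismatches", {
  d <- random_xy(50, 4, seed = 2)
  m <- fit_pls(d$X, d$y, 2)
  perm <- d$X[, c(3, 1, 4, 2)]
  expect_equal(predict(m, perm), predict(m, d$X))
  expect_equal(unname(predict(m, matrix(m$x_center, 1,
                                        dimnames = list(NULL, colnames(d$X))))),
               m$y_mean)
  bad <- d$X[, 1:3]
  expect_error(predict(m, bad), "v4")
})

test_that("degenerate inputs are rejected", {
  d <- random_xy(30, 3, seed = 5)
  expect_error(fit_pls(d$X, d$y, 4), "rank bound")
  Xz <- cbind(d$X, z = rep(2, 30))
  expect_error(fit_pls(Xz, d$y, 2), "zero-variance")
  expect_error(fit_pcr(Xz, d$y, 2), "zero-variance")
})

test_that("holdout scoring follows the printed pseudo-R^2 formula", {
  expect_equal(unclass(score_predictions(c(0, 2), c(1, 1))),
               list(rmse = 1, variance_explained = 0))
  y <- c(1, 3, 5, 7)
  perfect <- score_predictions(y, y)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$variance_explained, 1)
  expect_equal(score_predictions(y, rep(mean(y), 4))$variance_explained, 0)
  # worse-than-mean predictions go negative
  expect_lt(score_predictions(y, rev(y))$variance_explained, 0)
  expect_error(score_predictions(1:3, 1:4), "length")
})

test_that("VIP matches direct formula evaluation and its mean-square identity", {
  # worked two-variable case: one component, weights (0.8, 0.6)
  m <- structure(list(method = "PLS", A = 1L,
                      W = matrix(c(0.8, 0.6), 2, 1), SS = 0.4,
                      var_names = c("a", "b")),
                 class = "latent_model")
  expect_equal(unname(vip_scores(m)), c(sqrt(1.28), sqrt(0.72)),
               tolerance = 1e-10)
  for (seed in 1:10) {
    d <- random_xy(80, sample(3:12, 1), seed = 100 + seed)
    m <- fit_pls(d$X, d$y, sample(2:3, 1))
    expect_equal(mean(vip_scores(m)^2), 1, tolerance = 1e-8)
    expect_true(all(vip_scores(m) >= 0))
  }
  pcrm <- fit_pcr(random_xy(50, 4, 1)$X, random_xy(50, 4, 1)$y, 2)
  expect_error(vip_scores(pcrm), "PLS")
})

test_that("the PCR decomposition is exact for symmetric loadings and sums to training R^2", {
  # one component, loadings (1/sqrt(2), 1/sqrt(2)), 40% of response variance
  m <- structure(list(method = "PCR", A = 1L,
                      P = matrix(1 / sqrt(2), 2, 1), SS = 0.4,
                      var_names = c("a", "b")),
                 class = "latent_model")
  expect_equal(unname(pcr_variance_decomposition(m)), c(20, 20),
               tolerance = 1e-10)
  for (seed in 1:10) {
    d <- random_xy(90, sample(4:10, 1), seed = 200 + seed)
    m <- fit_pcr(d$X, d$y, sample(2:4, 1))
    dec <- pcr_variance_decomposition(m)
    expect_equal(sum(dec) / 100, m$r2_train, tolerance = 1e-8)
    expect_true(all(dec >= 0))
  }
})

test_that("the one-SE rule traces the textbook example and degenerates to the minimum", {
  rmsep <- stats::setNames(c(3.0, 2.0, 1.95, 1.96), 0:3)
  expect_equal(select_one_se(rmsep, rep(0.10, 4)), 1L)
  expect_equal(select_one_se(rmsep, rep(1e-9, 4)), 2L)  # SE -> 0: argmin
  decreasing <- stats::setNames(c(3, 2.5, 2, 1), 0:3)
  expect_equal(select_one_se(decreasing, rep(1e-12, 4)), 3L)
})

test_that("cross-validated selection finds structure and is seed-deterministic", {
  set.seed(77)
  X <- scale(matrix(rnorm(300 * 8), 300, 8))
  colnames(X) <- paste0("v", 1:8)
  y <- drop(X[, 1:2] %*% c(2, -2)) + rnorm(300, sd = 0.5)
  sel <- select_components(X, y, max_A = 6, seed = 5)
  expect_gte(sel$selected_A, 1)
  expect_true(all(sel$rmsep >= 0))
  sel2 <- select_components(X, y, max_A = 6, seed = 5)
  expect_identical(sel$rmsep, sel2$rmsep)
  expect_error(select_components(X, y, max_A = 0, seed = 1), "max_A")
})

test_that("pure-noise responses select the intercept-only model most often", {
  picks <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    X <- scale(matrix(rnorm(300 * 10), 300, 10))
    colnames(X) <- paste0("v", 1:10)
    y <- rnorm(300)
    select_components(X, y, max_A = 8, seed = s)$selected_A
  }, integer(1))
  tab <- table(picks)
  expect_equal(names(tab)[which.max(tab)], "0")
})

test_that("a planted-null response yields near-zero test R^2 for PCR", {
  set.seed(404)
  X <- scale(matrix(rnorm(500 * 10), 500, 10))
  colnames(X) <- paste0("v", 1:10)
  y <- rnorm(500)
  tr <- 1:350
  m <- fit_pcr(X[tr, ], y[tr], 5)
  expect_lt(m$r2_train, 0.08)
  te <- score_predictions(y[-tr], predict(m, X[-tr, ]))
  expect_lt(abs(te$variance_explained), 0.1)
})

test_that("PLS predictions and VIP agree with an independent implementation", {
  set.seed(42)
  X <- scale(matrix(rnorm(100 * 8), 100, 8))
  colnames(X) <- paste0("v", 1:8)
  y <- drop(X %*% rnorm(8)) + rnorm(100)
  m <- fit_pls(X, y, 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  expect_equal(unname(predict(m, X)),
               unname(predict(ref, X)$predict[, , 3]), tolerance = 1e-10)
  ref_vip <- mixOmics::vip(ref)[, 3]
  expect_equal(vip_scores(m), ref_vip[names(vip_scores(m))],
               tolerance = 1e-10)
})
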