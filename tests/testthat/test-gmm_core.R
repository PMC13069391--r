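test_that("free-parameter counts follow the eigen-decomposition enumeration", {
  expect_equal(gmm_n_params("EII", 2, 3), 1 + 6 + 1)
  expect_equal(gmm_n_params("VVV", 2, 2), 1 + 4 + 2 * 3)
  expect_equal(gmm_n_params("EEE", 3, 2), 2 + 6 + 3)
  expect_error(gmm_n_params("XYZ", 2, 2), "unknown")
  # cross-check the whole table against the reference implementation
  for (fam in gmm_families())
    for (G in 1:3)
      expect_equal(gmm_n_params(fam, G, 4),
                   mclust::nMclustParams(fam, d = 4, G = G),
                   info = paste(fam, G))
})

test_that("a single-component fit equals the closed-form Gaussian MLE", {
  X <- two_cluster_data(seed = 3, n1 = 25, n2 = 15, d = 3)
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / nrow(X)     # ML (1/n) covariance
  ll_closed <- sum(apply(X, 1, function(x)
    -0.5 * (3 * log(2 * pi) + as.numeric(determinant(S)$modulus) +
              t(x - mu) %*% solve(S) %*% (x - mu))))
  for (fam in c("EEE", "VVV")) {
    f <- fit_gmm(X, 1, fam)
    expect_equal(unname(f$means[1, ]), unname(mu), tolerance = 1e-10)
    expect_equal(f$covariances[[1]], S, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(f$loglik, ll_closed, tolerance = 1e-8)
  }
})

test_that("BIC follows the maximize convention on a hand-computable case", {
  X <- matrix(c(0, 0, 1, 1), ncol = 1)
  f <- fit_gmm(X, 1, "EII")
  sigma2 <- 0.25
  ll <- sum(dnorm(X, 0.5, sqrt(sigma2), log = TRUE))
  expect_equal(f$loglik, ll, tolerance = 1e-10)
  expect_equal(f$n_params, 2)
  expect_equal(f$bic, 2 * ll - 2 * log(4), tolerance = 1e-10)
  expect_equal(bic_of(f), f$bic)
})

test_that("BIC is invariant to specimen order", {
  X <- two_cluster_data(seed = 5)
  perm <- withr::with_seed(6, sample(nrow(X)))
  f1 <- fit_gmm(X, 2, "VVI")
  f2 <- fit_gmm(X[perm, ], 2, "VVI")
  expect_equal(f1$bic, f2$bic, tolerance = 1e-6)
})

test_that("EM log-likelihood is monotone for every family at every iteration", {
  X <- two_cluster_data(seed = 7)
  for (fam in gmm_families()) {
    f <- fit_gmm(X, 2, fam)
    expect_true(all(diff(f$loglik_trace) >= -1e-9), info = fam)
    expect_true(f$converged, info = fam)
  }
})

test_that("the unconstrained fit matches an independent EM oracle from the same start", {
  X <- two_cluster_data(seed = 11)
  z0 <- withr::with_seed(12, {
    z <- matrix(runif(nrow(X) * 2), ncol = 2); z / rowSums(z)
  })
  f <- fit_gmm(X, 2, "VVV", z_init = z0, tol = 1e-12, max_iter = 2000)
  o <- oracle_em_vvv(X, z0)
  expect_equal(f$loglik, o$loglik, tolerance = 1e-6)
})

test_that("the spherical family recovers the mean within-cluster variance", {
  X <- two_cluster_data(seed = 13)
  f <- fit_gmm(X, 2, "EII", tol = 1e-12)
  z <- f$responsibilities
  lam_direct <- sum(vapply(1:2, function(k) {
    Xc <- sweep(X, 2, f$means[k, ])
    sum(z[, k] * rowSums(Xc^2))
  }, 0)) / (nrow(X) * ncol(X))
  expect_equal(f$details$lambda[1], lam_direct, tolerance = 1e-6)
  expect_equal(f$covariances[[1]][1, 1], lam_direct, tolerance = 1e-6)
})

test_that("richer families never fit worse from a shared start (nesting)", {
  for (seed in 1:5) {
    X <- two_cluster_data(seed = seed, sep = 3)
    # shared deterministic Ward start keeps every family in one basin
    ll <- vapply(c("EEE", "VEE", "VVV", "EEI", "VVI"), function(fam)
      fit_gmm(X, 2, fam)$loglik, 0)
    eps <- 1e-4
    expect_gte(ll["VVV"], ll["VEE"] - eps)
    expect_gte(ll["VEE"], ll["EEE"] - eps)
    expect_gte(ll["VVI"], ll["EEI"] - eps)
  }
})

test_that("shared entities of E-letter families are bitwise identical across components", {
  X <- two_cluster_data(seed = 17)
  for (fam in gmm_families()) {
    f <- fit_gmm(X, 2, fam)
    letters3 <- strsplit(fam, "")[[1]]
    if (letters3[1] == "E")
      expect_identical(f$details$lambda[1], f$details$lambda[2], info = fam)
    if (letters3[2] %in% c("E", "I"))
      expect_identical(f$details$shape[, 1], f$details$shape[, 2], info = fam)
    if (letters3[3] %in% c("E", "I"))
      expect_identical(f$details$orientation[[1]], f$details$orientation[[2]],
                       info = fam)
  }
})

test_that("fitted parameters agree with the reference implementation", {
  suppressMessages(library(mclust))
  X <- two_cluster_data(seed = 19)
  for (fam in c("EII", "VEI", "EEE", "VVE", "VEV", "VVV")) {
    f <- fit_gmm(X, 2, fam)
    m <- mclust::Mclust(X, G = 2, modelNames = fam, verbose = FALSE)
    expect_equal(f$loglik, m$loglik, tolerance = 5e-3, info = fam,
                 ignore_attr = TRUE)
  }
})

test_that("parameter recovery on structured two-component data", {
  # VEE-type truth: shared correlated shape/orientation, distinct volumes,
  # centroids exactly 6 sigma apart (Mahalanobis, wrt the larger component)
  C <- matrix(0.3, 4, 4); diag(C) <- 1
  C <- C / det(C)^(1 / 4)
  S1 <- 0.6 * C; S2 <- 1.0 * C
  ones <- rep(1, 4)
  mu1 <- rep(0, 4)
  mu2 <- ones * 6 / sqrt(drop(crossprod(ones, solve(S2, ones))))
  sim <- simulate_gaussian_groups(
    list(list(name = "a", n = 400, mean = mu1, sigma = S1),
         list(name = "b", n = 400, mean = mu2, sigma = S2)),
    seed = 23)
  f <- fit_gmm(sim$X, 2, "VEE")
  ord <- order(f$means[, 1])
  expect_lt(sqrt(sum((f$means[ord[1], ] - mu1)^2)), 0.15)
  expect_lt(sqrt(sum((f$means[ord[2], ] - mu2)^2)), 0.15)
  truth <- rep(1:2, each = 400)
  pred <- f$classification
  acc <- max(mean(pred == truth), mean(3 - pred == truth))
  expect_gte(acc, 0.99)
})

test_that("degenerate fits raise a typed error and restarts are attempted", {
  X <- matrix(c(1, 1, 1, 1, 1, 2), ncol = 1)  # nearly all identical
  expect_error(fit_gmm(X, 3, "VVV", seed = 1, n_restarts = 1),
               class = "morphodelim_degenerate")
})
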