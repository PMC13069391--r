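fam_small <- c("EII", "EEI", "EEE", "VVV")

test_that("a fully lumped EDDA fit reduces to the single-Gaussian mixture fit", {
  X <- two_cluster_data(seed = 41, n1 = 25, n2 = 20)
  e <- fit_edda(X, rep("all", nrow(X)), "VVV")
  g <- fit_gmm(X, 1, "VVV")
  expect_equal(e$loglik, g$loglik, tolerance = 1e-8)
  # proportions term vanishes (pi = 1) but the parameter count drops by
  # the absent mixing proportion, so BICs agree after that adjustment
  expect_equal(e$n_params, g$n_params)
})

test_that("unconstrained EDDA equals groupwise plug-in estimates", {
  X <- two_cluster_data(seed = 43, n1 = 30, n2 = 25)
  lab <- rep(c("A", "B"), c(30, 25))
  e <- fit_edda(X, lab, "VVV")
  ll_oracle <- 0
  for (g in c("A", "B")) {
    Xg <- X[lab == g, ]
    mu <- colMeans(Xg)
    S <- crossprod(sweep(Xg, 2, mu)) / nrow(Xg)
    expect_equal(e$means[which(e$groups == g), ], mu, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(e$covariances[[which(e$groups == g)]], S, tolerance = 1e-10,
                 ignore_attr = TRUE)
    ll_oracle <- ll_oracle + sum(apply(Xg, 1, function(x)
      -0.5 * (ncol(X) * log(2 * pi) + as.numeric(determinant(S)$modulus) +
                t(x - mu) %*% solve(S) %*% (x - mu)))) +
      nrow(Xg) * log(nrow(Xg) / nrow(X))
  }
  expect_equal(e$loglik, ll_oracle, tolerance = 1e-8)
})

test_that("the shared-covariance family uses the pooled within-group ML covariance", {
  X <- two_cluster_data(seed = 45, n1 = 30, n2 = 25)
  lab <- rep(c("A", "B"), c(30, 25))
  e <- fit_edda(X, lab, "EEE")
  W <- Reduce(`+`, lapply(c("A", "B"), function(g) {
    Xg <- X[lab == g, ]
    crossprod(sweep(Xg, 2, colMeans(Xg)))
  }))
  expect_equal(e$covariances[[1]], W / nrow(X), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(e$covariances[[1]], e$covariances[[2]])
})

test_that("tiny groups are refused by name", {
  X <- two_cluster_data(seed = 47, n1 = 10, n2 = 10)
  lab <- c(rep("A", 19), "lonely")
  expect_error(fit_edda(X, lab, "EII"), "lonely")
})

test_that("scheme ranking arithmetic: deltas, Bayes factors, posteriors", {
  rk <- rank_schemes(c(6681, 6670, 6394))
  expect_equal(rk$delta_bic, c(0, 11, 287))
  expect_equal(rk$bf[1], 1)
  expect_equal(round(rk$pp[1], 3), 0.996)
  expect_equal(round(rk$pp[2], 3), 0.004)
  expect_lt(rk$pp[3], 1e-60)
  expect_equal(rk$bf[2], exp(11 / 2), tolerance = 1e-12)
  expect_match(rk$bf_label[3], "E\\+62")
  # single scheme and exact ties
  expect_equal(rank_schemes(5)$pp, 1)
  expect_equal(rank_schemes(c(7, 7))$pp, c(0.5, 0.5))
  expect_error(rank_schemes(numeric(0)), "no BIC")
})

test_that("posterior probabilities normalize and Bayes factors track deltas", {
  withr::with_seed(49, {
    for (i in 1:10) {
      b <- rnorm(6, 1000, 50)
      rk <- rank_schemes(b)
      expect_equal(sum(rk$pp), 1, tolerance = 1e-12)
      expect_equal(rk$bf[which.max(b)], 1)
      expect_equal(order(rk$bf), order(rk$delta_bic))
      expect_true(all(rk$bf >= 1))
    }
  })
})

test_that("a two-OTU merge path has exactly the two possible schemes", {
  X <- two_cluster_data(seed = 51, n1 = 20, n2 = 20)
  lab <- rep(c("A", "B"), each = 20)
  mp <- merge_path(X, lab, families = fam_small)
  expect_equal(nrow(mp$table), 2)
  expect_equal(mp$table$K, c(2, 1))
  expect_equal(mp$table$scheme[2], "A-B")
})

test_that("the merge path lumps the two identically distributed groups first", {
  sim <- withr::with_seed(53, {
    A <- MASS::mvrnorm(30, c(8, 8), diag(2))
    B <- MASS::mvrnorm(25, c(0, 0), diag(2))
    C <- MASS::mvrnorm(25, c(0, 0), diag(2))
    list(X = rbind(A, B, C), lab = rep(c("A", "B", "C"), c(30, 25, 25)))
  })
  mp <- merge_path(sim$X, sim$lab, families = fam_small)
  expect_equal(mp$table$merged[2], "B-C")
  expect_equal(mp$table$K[mp$best], 2)
  # each level coarsens the previous one
  for (t in 2:length(mp$assignments)) {
    prev <- mp$assignments[[t - 1]]
    cur <- mp$assignments[[t]]
    expect_true(all(tapply(cur, prev, function(v) length(unique(v))) == 1))
  }
})

test_that("compare_schemes agrees with the merge path on the same hypotheses", {
  sim <- withr::with_seed(55, {
    A <- MASS::mvrnorm(20, c(6, 0), diag(2))
    B <- MASS::mvrnorm(20, c(0, 0), diag(2))
    C <- MASS::mvrnorm(20, c(0, 1), diag(2))
    list(X = rbind(A, B, C), lab = rep(c("A", "B", "C"), each = 20))
  })
  mp <- merge_path(sim$X, sim$lab, families = fam_small)
  schemes <- setNames(mp$assignments, paste0("level", seq_along(mp$assignments)))
  cmp <- compare_schemes(sim$X, schemes, families = fam_small)
  expect_equal(sort(cmp$table$bic), sort(mp$table$bic), tolerance = 1e-10)
  expect_error(compare_schemes(sim$X, schemes[c(1, 1)], families = fam_small),
               "duplicate")
  dup <- compare_schemes(sim$X,
                         list(s1 = sim$lab, s2 = sim$lab),
                         families = fam_small)
  expect_equal(dup$table$pp, c(0.5, 0.5))
})

test_that("splitting a homogeneous OTU at random loses to keeping it whole", {
  X <- withr::with_seed(57, MASS::mvrnorm(40, c(0, 0), diag(2)))
  halves <- withr::with_seed(58, sample(rep(c("A1", "A2"), each = 20)))
  cmp <- compare_schemes(X, list(whole = rep("A", 40), split = halves),
                         families = fam_small)
  expect_equal(cmp$table$scheme[1], "whole")
})

test_that("true labels fit no worse than permuted labels on separated groups", {
  X <- two_cluster_data(seed = 59, sep = 6)
  lab <- rep(c("A", "B"), c(60, 50))
  perm <- withr::with_seed(60, sample(lab))
  expect_gt(fit_edda(X, lab, "EEE")$loglik,
            fit_edda(X, perm, "EEE")$loglik)
})

test_that("greedy first merge equals the brute-force best pair; path is near-optimal", {
  fams <- c("EII", "EEI", "EEE")
  n_rep <- 50
  agree_best <- 0
  for (s in seq_len(n_rep)) {
    sim <- withr::with_seed(600 + s, {
      mus <- list(c(0, 0), c(0.8, 0), c(4, 4), c(4.2, 3.5))
      X <- do.call(rbind, lapply(mus, function(m) MASS::mvrnorm(12, m, diag(2) * 0.6)))
      list(X = X, lab = rep(c("A", "B", "C", "D"), each = 12))
    })
    mp <- merge_path(sim$X, sim$lab, families = fams)
    # oracle: score every pairwise merge of the original four groups
    pair_bics <- sapply(utils::combn(c("A", "B", "C", "D"), 2, simplify = FALSE),
                        function(p) {
      cand <- sim$lab
      cand[cand %in% p] <- paste(sort(p), collapse = "-")
      max(vapply(fams, function(f)
        tryCatch(fit_edda(sim$X, cand, f)$bic, error = function(e) -Inf), 0))
    })
    best_pair_bic <- max(pair_bics)
    expect_equal(mp$table$bic[2], best_pair_bic, tolerance = 1e-9)
    # oracle: exhaustive search over every merge-reachable partition
    parts <- all_partitions(c("A", "B", "C", "D"))
    part_bics <- vapply(parts, function(p) {
      cand <- sim$lab
      for (i in seq_along(p)) cand[sim$lab %in% p[[i]]] <- paste0("g", i)
      max(vapply(fams, function(f)
        tryCatch(fit_edda(sim$X, cand, f)$bic, error = function(e) -Inf), 0))
    }, 0)
    if (max(mp$table$bic) >= max(part_bics) - 1e-9) agree_best <- agree_best + 1
  }
  # greedy is not guaranteed globally optimal; it should match the
  # exhaustive optimum in the vast majority of replicates
  expect_gte(agree_best / n_rep, 0.9)
})
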