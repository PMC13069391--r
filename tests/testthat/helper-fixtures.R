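# Shared fixtures and independent oracles for the test suite.

# Small well-formed morphometric CSV on disk; returns the path.
write_fixture_csv <- function(df, dir = tempdir()) {
  path <- tempfile("morpho", tmpdir = dir, fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

tiny_dataset <- function() {
  morpho_dataset(
    otu = c("A", "A", "A", "B", "B", "B"),
    body_size = c(10, 12, 14, 20, 22, 24),
    characters = cbind(HL = c(2.0, 2.2, 2.5, 4.0, 4.2, 4.4),
                       HW = c(1.0, 1.1, 1.2, 2.0, 2.1, 2.2)),
    warn_singletons = FALSE)
}

# Two well-separated Gaussian clusters, fixed seed.
two_cluster_data <- function(seed = 1, n1 = 60, n2 = 50, d = 3, sep = 4) {
  withr::with_seed(seed, {
    rbind(MASS::mvrnorm(n1, rep(0, d), diag(d)),
          MASS::mvrnorm(n2, c(sep, sep, rep(0, d - 2)),
                        diag(d) * 0.8 + 0.2))
  })
}

# Independent unconstrained (VVV) EM oracle: plain textbook implementation,
# no shared code with the package's engine.
oracle_em_vvv <- function(X, z, tol = 1e-10, max_iter = 1000) {
  n <- nrow(X); d <- ncol(X); G <- ncol(z)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    nk <- colSums(z)
    pi_k <- nk / n
    mu <- lapply(seq_len(G), function(k) colSums(X * z[, k]) / nk[k])
    S <- lapply(seq_len(G), function(k) {
      Xc <- sweep(X, 2, mu[[k]])
      t(Xc * z[, k]) %*% Xc / nk[k]
    })
    dens <- sapply(seq_len(G), function(k) {
      Si <- solve(S[[k]])
      Xc <- sweep(X, 2, mu[[k]])
      q <- rowSums((Xc %*% Si) * Xc)
      pi_k[k] * (2 * pi)^(-d / 2) * det(S[[k]])^(-0.5) * exp(-q / 2)
    })
    tot <- rowSums(dens)
    ll <- sum(log(tot))
    z <- dens / tot
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(loglik = ll, z = z)
}

# Closed-form Welch t statistic, df and p (independent of stats::t.test).
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Two-group selection fixture: a few mean-shifted characters plus pure noise.
make_boruta_data <- function(seed, n = 50, shift = 3, n_info = 3, n_noise = 5) {
  withr::with_seed(seed, {
    X <- cbind(
      matrix(rnorm(2 * n * n_info), ncol = n_info,
             dimnames = list(NULL, paste0("info", seq_len(n_info)))),
      matrix(rnorm(2 * n * n_noise), ncol = n_noise,
             dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
    X[seq_len(n), seq_len(n_info)] <- X[seq_len(n), seq_len(n_info)] + shift
    list(X = X, lab = rep(c("g1", "g2"), each = n))
  })
}

# All partitions of a set of group labels (for the exhaustive merge oracle).
all_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  first <- items[1]
  rest <- all_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(first), p)
  }
  out
}
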