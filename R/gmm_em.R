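# Gaussian mixture EM under eigen-decomposed covariance constraints.

# log N(x; mu, Sigma) for all rows of X, via the Cholesky factor.
mvn_logdens <- function(X, mu, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Xc <- sweep(X, 2, mu)
  z <- backsolve(R, t(Xc), transpose = TRUE)
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(z^2))
}

# E-step quantities from component log-densities and log-proportions.
estep <- function(logdens, logpro) {
  lpr <- sweep(logdens, 2, logpro, `+`)
  m <- apply(lpr, 1, max)
  ll_i <- m + log(rowSums(exp(lpr - m)))
  list(z = exp(lpr - ll_i), loglik = sum(ll_i))
}

hclust_init <- function(X, G) {
  sds <- apply(X, 2, stats::sd)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, pmax(sds, .Machine$double.eps), `/`)
  cl <- stats::cutree(stats::hclust(stats::dist(Xs), method = "ward.D2"), k = G)
  z <- matrix(0, nrow(X), G)
  z[cbind(seq_len(nrow(X)), cl)] <- 1
  z
}

degenerate_error <- function(msg) {
  stop(structure(class = c("morphodelim_degenerate", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Fit a constrained-covariance Gaussian mixture by EM
#'
#' Maximum-likelihood fit of a `G`-component multivariate Gaussian mixture
#' whose component covariances obey one of the 14 eigen-decomposition
#' families ([gmm_families()]). The default initialization is
#' deterministic: Ward agglomeration on standardized data cut at `G`
#' groups. Iterative covariance families (VEI, VEE, VEV, EVE, VVE) use
#' inner fixed-point / majorize-minimize updates warm-started from the
#' previous EM iteration, so the observed-data log-likelihood is
#' non-decreasing across iterations.
#'
#' Components whose covariance update fails or whose smallest eigenvalue
#' drops below the regularization floor (`1e-10` times the mean diagonal
#' of the total covariance) abort the fit; with `init = "hclust"` up to
#' `n_restarts` random re-initializations are attempted before a
#' degenerate-fit error (condition class `morphodelim_degenerate`) is
#' signalled.
#'
#' @param X numeric matrix, specimens x characters.
#' @param G number of mixture components (`n > G` required).
#' @param family covariance family code.
#' @param init `"hclust"` (deterministic Ward start) or `"random"`
#'   (seeded random responsibilities).
#' @param z_init optional n x G responsibility matrix overriding `init`
#'   (used e.g. to share an initialization across families).
#' @param seed integer seed for random initializations and restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param n_restarts perturbed re-initializations tried after a degenerate
#'   fit.
#' @param inner_tol,inner_max tolerance and cap for the inner covariance
#'   updates of the iterative families.
#' @return An object of class `gmm_fit`: means (G x d), `covariances`
#'   (list of d x d), `proportions`, `loglik`, `loglik_trace`, `n_params`,
#'   `bic` (= `2*loglik - n_params*log(n)`), `responsibilities` (n x G),
#'   `classification`, `converged`, `iterations`, and the volume / shape /
#'   orientation decomposition in `details`.
#' @export
fit_gmm <- function(X, G, family = "VVV", init = c("hclust", "random"),
                    z_init = NULL, seed = NULL, tol = 1e-8, max_iter = 500,
                    n_restarts = 3, inner_tol = 1e-8, inner_max = 100) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  init <- match.arg(init)
  n <- nrow(X); d <- ncol(X)
  if (!all(is.finite(X))) stop("X must be finite")
  if (n <= G) stop("need more specimens than components (n > G)")
  family <- match.arg(family, gmm_families())
  floor_ <- 1e-10 * mean(diag(stats::cov(X)))
  if (!is.null(seed)) set.seed(seed)

  run_em <- function(z) {
    prev <- NULL
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    res <- NULL
    for (iter in seq_len(max_iter)) {
      nk <- colSums(z)
      if (any(nk < 1e-8)) return(list(fail = "component collapsed"))
      mu <- crossprod(z, X) / nk
      W <- lapply(seq_len(G), function(k) {
        Xc <- sweep(X, 2, mu[k, ])
        crossprod(Xc * sqrt(z[, k]))
      })
      cs <- mstep_cov(W, nk, family, prev = prev,
                      inner_tol = inner_tol, inner_max = inner_max)
      if (is.null(cs)) return(list(fail = "covariance update not estimable"))
      for (k in seq_len(G)) {
        ev <- eigen(cs$Sigma[[k]], symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < floor_)
          return(list(fail = "covariance hit the eigenvalue floor"))
      }
      prev <- cs
      pro <- nk / n
      logdens <- matrix(0, n, G)
      for (k in seq_len(G)) {
        ld <- mvn_logdens(X, mu[k, ], cs$Sigma[[k]])
        if (is.null(ld)) return(list(fail = "non-PD covariance"))
        logdens[, k] <- ld
      }
      e <- estep(logdens, log(pro))
      if (!is.finite(e$loglik)) return(list(fail = "non-finite log-likelihood"))
      ll_trace <- c(ll_trace, e$loglik)
      res <- list(mu = mu, cs = cs, pro = pro, z = e$z, loglik = e$loglik)
      if (is.finite(ll_old) &&
          abs(e$loglik - ll_old) < tol * (1 + abs(e$loglik))) {
        converged <- TRUE
        break
      }
      ll_old <- e$loglik
      z <- e$z
    }
    c(res, list(ll_trace = ll_trace, converged = converged,
                iterations = length(ll_trace)))
  }

  z0 <- if (!is.null(z_init)) {
    stopifnot(nrow(z_init) == n, ncol(z_init) == G)
    z_init / rowSums(z_init)
  } else if (init == "hclust") hclust_init(X, G) else {
    z <- matrix(stats::runif(n * G), n, G); z / rowSums(z)
  }
  fit <- run_em(z0)
  attempt <- 0
  while (!is.null(fit$fail) && attempt < n_restarts) {
    attempt <- attempt + 1
    z <- matrix(stats::runif(n * G), n, G)
    fit <- run_em(z / rowSums(z))
  }
  if (!is.null(fit$fail))
    degenerate_error(paste0("EM for family ", family, ", G = ", G,
                            " failed after ", n_restarts,
                            " restarts: ", fit$fail))
  np <- gmm_n_params(family, G, d)
  structure(list(
    G = G, family = family, means = fit$mu, covariances = fit$cs$Sigma,
    proportions = fit$pro, loglik = fit$loglik, loglik_trace = fit$ll_trace,
    n_params = np, bic = 2 * fit$loglik - np * log(n), n = n, d = d,
    responsibilities = fit$z,
    classification = max.col(fit$z, ties.method = "first"),
    converged = fit$converged, iterations = fit$iterations,
    details = list(lambda = fit$cs$lambda, shape = fit$cs$shape,
                   orientation = fit$cs$orientation)),
    class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: G = %d, family %s, n = %d, d = %d\n",
              x$G, x$family, x$n, x$d))
  cat(sprintf("  loglik = %.4f, params = %d, BIC = %.4f (%sconverged, %d iter)\n",
              x$loglik, x$n_params, x$bic,
              if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Bayesian Information Criterion of a fitted model
#'
#' Follows the maximize-BIC sign convention,
#' `BIC = 2*loglik - n_params*log(n)`: larger values indicate better
#' models. Works for [fit_gmm()] and [fit_edda()] objects.
#'
#' @param fit a `gmm_fit` or `edda_fit`.
#' @return Numeric BIC.
#' @export
bic_of <- function(fit) {
  stopifnot(inherits(fit, c("gmm_fit", "edda_fit")))
  2 * fit$loglik - fit$n_params * log(fit$n)
}

#' Serialize a fit to JSON
#'
#' @param fit a `gmm_fit` or `edda_fit`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  x <- unclass(fit)
  x$responsibilities <- NULL
  x$details <- NULL
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
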