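#' The fourteen eigen-decomposed covariance families
#'
#' Component covariances are parameterized as
#' \eqn{\Sigma_k = \lambda_k D_k A_k D_k^T}, with \eqn{\lambda_k} the
#' volume, \eqn{A_k} the shape (diagonal, determinant 1) and \eqn{D_k} the
#' orientation (orthogonal). The three letters of a family code state
#' whether volume, shape and orientation are Equal across components,
#' Variable, or (for shape/orientation) the Identity. `"EII"` is the
#' spherical equal-volume family; `"VVV"` is fully unconstrained.
#'
#' @return Character vector of the 14 family codes.
#' @export
gmm_families <- function() {
  c("EII", "VII", "EEI", "VEI", "EVI", "VVI",
    "EEE", "VEE", "EVE", "VVE", "EEV", "VEV", "EVV", "VVV")
}

#' Free-parameter count of a constrained Gaussian mixture
#'
#' Total free parameters: `(G - 1)` mixing proportions, `G * d` means,
#' plus the family-specific covariance count from the standard
#' eigen-decomposition enumeration. Used in the BIC penalty
#' `2*loglik - n_params*log(n)`.
#'
#' @param family a code from [gmm_families()].
#' @param G number of components (>= 1).
#' @param d data dimensionality (>= 1).
#' @param proportions count the `G - 1` mixing proportions (set `FALSE`
#'   for a fixed-weight model).
#' @return Integer parameter count.
#' @export
gmm_n_params <- function(family, G, d, proportions = TRUE) {
  stopifnot(G >= 1, d >= 1)
  cov_p <- switch(family,
    EII = 1,
    VII = G,
    EEI = d,
    VEI = G + (d - 1),
    EVI = 1 + G * (d - 1),
    VVI = G * d,
    EEE = d * (d + 1) / 2,
    VEE = G + (d - 1) + d * (d - 1) / 2,
    EVE = 1 + G * (d - 1) + d * (d - 1) / 2,
    VVE = G + G * (d - 1) + d * (d - 1) / 2,
    EEV = 1 + (d - 1) + G * d * (d - 1) / 2,
    VEV = G + (d - 1) + G * d * (d - 1) / 2,
    EVV = 1 + G * (d - 1) + G * d * (d - 1) / 2,
    VVV = G * d * (d + 1) / 2,
    stop("unknown covariance family code: ", family))
  as.integer((if (proportions) G - 1 else 0) + G * d + cov_p)
}

# --- internal covariance M-steps ------------------------------------------
#
# Input: W = list of G scatter matrices W_k = sum_i z_ik (x_i - mu_k)(.)^T,
# nk = component weights. Output: list(Sigma = list of G SPD matrices,
# lambda = length-G volumes, shape = d x G matrix, orientation = list of G
# orthogonal matrices) or NULL when the family is not estimable from these
# scatters. `prev` carries the previous EM iteration's decomposition so the
# iterative families (VEI, VEE, VEV, EVE, VVE) warm-start and the M-step
# objective can only improve, keeping EM monotone.

tr_ <- function(m) sum(diag(m))

safe_det_chol <- function(m) {
  R <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  prod(diag(R))^2
}

mstep_cov <- function(W, nk, family, prev = NULL,
                      inner_tol = 1e-8, inner_max = 100) {
  G <- length(W)
  d <- nrow(W[[1]])
  n <- sum(nk)
  Id <- diag(d)
  rep_list <- function(x) rep(list(x), G)
  out <- function(Sigma, lambda, shape, orientation)
    list(Sigma = Sigma, lambda = lambda, shape = shape,
         orientation = orientation)
  geo_mean_pow <- function(v) prod(v)^(1 / d)

  if (family == "EII") {
    lam <- sum(vapply(W, tr_, 0)) / (n * d)
    if (lam <= 0) return(NULL)
    return(out(rep_list(lam * Id), rep(lam, G),
               matrix(1, d, G), rep_list(Id)))
  }
  if (family == "VII") {
    lam <- vapply(W, tr_, 0) / (nk * d)
    if (any(lam <= 0)) return(NULL)
    return(out(lapply(lam, function(l) l * Id), lam,
               matrix(1, d, G), rep_list(Id)))
  }
  if (family == "EEI") {
    b <- diag(Reduce(`+`, W)) / n
    if (any(b <= 0)) return(NULL)
    lam <- geo_mean_pow(b)
    return(out(rep_list(diag(b, d)), rep(lam, G),
               matrix(b / lam, d, G), rep_list(Id)))
  }
  if (family == "EVI") {
    B <- vapply(W, diag, numeric(d))            # d x G
    if (any(B <= 0)) return(NULL)
    detk <- apply(B, 2, geo_mean_pow)
    A <- sweep(B, 2, detk, `/`)
    lam <- sum(detk) / n
    Sigma <- lapply(seq_len(G), function(k) diag(lam * A[, k], d))
    return(out(Sigma, rep(lam, G), A, rep_list(Id)))
  }
  if (family == "VVI") {
    B <- vapply(W, diag, numeric(d))
    if (any(B <= 0)) return(NULL)
    B <- sweep(B, 2, nk, `/`)
    lam <- apply(B, 2, geo_mean_pow)
    return(out(lapply(seq_len(G), function(k) diag(B[, k], d)),
               lam, sweep(B, 2, lam, `/`), rep_list(Id)))
  }
  if (family == "VEI") {
    B <- vapply(W, diag, numeric(d))            # diag scatters
    lam <- if (!is.null(prev$lambda)) prev$lambda else colSums(B) / (nk * d)
    if (any(lam <= 0)) return(NULL)
    obj_old <- Inf
    for (it in seq_len(inner_max)) {
      a <- rowSums(sweep(B, 2, lam, `/`))
      if (any(a <= 0)) return(NULL)
      A <- a / geo_mean_pow(a)
      lam <- colSums(B / A) / (nk * d)
      obj <- sum(colSums(B / A) / lam) + d * sum(nk * log(lam))
      if (is.finite(obj_old) && abs(obj_old - obj) < inner_tol * (1 + abs(obj)))
        break
      obj_old <- obj
    }
    Sigma <- lapply(lam, function(l) diag(l * A, d))
    return(out(Sigma, lam, matrix(A, d, G), rep_list(Id)))
  }
  if (family == "EEE") {
    S <- Reduce(`+`, W) / n
    if (is.null(safe_det_chol(S))) return(NULL)
    e <- eigen(S, symmetric = TRUE)
    lam <- geo_mean_pow(e$values)
    return(out(rep_list(S), rep(lam, G), matrix(e$values / lam, d, G),
               rep_list(e$vectors)))
  }
  if (family == "VVV") {
    Sigma <- lapply(seq_len(G), function(k) W[[k]] / nk[k])
    lam <- numeric(G); A <- matrix(0, d, G); Dk <- vector("list", G)
    for (k in seq_len(G)) {
      if (is.null(safe_det_chol(Sigma[[k]]))) return(NULL)
      e <- eigen(Sigma[[k]], symmetric = TRUE)
      lam[k] <- geo_mean_pow(e$values)
      A[, k] <- e$values / lam[k]
      Dk[[k]] <- e$vectors
    }
    return(out(Sigma, lam, A, Dk))
  }
  if (family == "EVV") {
    detk <- vapply(W, function(w) {
      dt <- safe_det_chol(w); if (is.null(dt)) NA_real_ else dt^(1 / d)
    }, 0)
    if (anyNA(detk) || any(detk <= 0)) return(NULL)
    lam <- sum(detk) / n
    Sigma <- lapply(seq_len(G), function(k) lam * W[[k]] / detk[k])
    A <- matrix(0, d, G); Dk <- vector("list", G)
    for (k in seq_len(G)) {
      e <- eigen(W[[k]] / detk[k], symmetric = TRUE)
      A[, k] <- e$values
      Dk[[k]] <- e$vectors
    }
    return(out(Sigma, rep(lam, G), A, Dk))
  }
  if (family == "VEE") {
    lam <- if (!is.null(prev$lambda)) prev$lambda else
      vapply(W, tr_, 0) / (nk * d)
    if (any(lam <= 0)) return(NULL)
    obj_old <- Inf; C <- NULL
    for (it in seq_len(inner_max)) {
      M <- Reduce(`+`, Map(`/`, W, as.list(lam)))
      dtM <- safe_det_chol(M)
      if (is.null(dtM) || dtM <= 0) return(NULL)
      C <- M / dtM^(1 / d)
      Cinv <- chol2inv(chol(C))
      lam <- vapply(W, function(w) tr_(w %*% Cinv), 0) / (nk * d)
      if (any(lam <= 0)) return(NULL)
      obj <- sum(vapply(W, function(w) tr_(w %*% Cinv), 0) / lam) +
        d * sum(nk * log(lam))
      if (is.finite(obj_old) && abs(obj_old - obj) < inner_tol * (1 + abs(obj)))
        break
      obj_old <- obj
    }
    e <- eigen(C, symmetric = TRUE)
    Sigma <- lapply(lam, function(l) l * C)
    return(out(Sigma, lam, matrix(e$values, d, G), rep_list(e$vectors)))
  }
  if (family %in% c("EEV", "VEV")) {
    eW <- lapply(W, function(w) eigen(w, symmetric = TRUE))  # values descending
    Om <- vapply(eW, `[[`, numeric(d), "values")             # d x G
    if (any(Om < 0)) Om[Om < 0] <- 0
    Dk <- lapply(eW, `[[`, "vectors")
    if (family == "EEV") {
      avec <- rowSums(Om) / n
      if (any(avec <= 0)) return(NULL)
      lam <- geo_mean_pow(avec)
      A <- avec / lam
      Sigma <- lapply(seq_len(G), function(k)
        Dk[[k]] %*% (avec * t(Dk[[k]])))
      return(out(Sigma, rep(lam, G), matrix(A, d, G), Dk))
    }
    lam <- if (!is.null(prev$lambda)) prev$lambda else colSums(Om) / (nk * d)
    if (any(lam <= 0)) return(NULL)
    obj_old <- Inf; A <- NULL
    for (it in seq_len(inner_max)) {
      a <- rowSums(sweep(Om, 2, lam, `/`))
      if (any(a <= 0)) return(NULL)
      A <- a / geo_mean_pow(a)
      lam <- colSums(Om / A) / (nk * d)
      obj <- sum(colSums(Om / A) / lam) + d * sum(nk * log(lam))
      if (is.finite(obj_old) && abs(obj_old - obj) < inner_tol * (1 + abs(obj)))
        break
      obj_old <- obj
    }
    Sigma <- lapply(seq_len(G), function(k)
      Dk[[k]] %*% ((lam[k] * A) * t(Dk[[k]])))
    return(out(Sigma, lam, matrix(A, d, G), Dk))
  }
  if (family %in% c("EVE", "VVE")) {
    # shared orientation D, varying shapes; minimize
    # f(D) = sum_k tr(A_k^{-1} D' W_k D) / lambda_k by a linear
    # majorize-minimize update over the orthogonal group, alternated with
    # closed-form shape/volume updates ("flip-flop").
    D <- if (!is.null(prev$orientation)) prev$orientation[[1]] else
      eigen(Reduce(`+`, W), symmetric = TRUE)$vectors
    omega <- vapply(W, function(w) max(eigen(w, symmetric = TRUE,
                                             only.values = TRUE)$values), 0)
    lam <- rep(1, G); A <- matrix(1, d, G)
    # diag(D' W_k D) without forming the full product
    bdiag <- function(D) vapply(W, function(w) colSums((w %*% D) * D),
                                numeric(d))
    fval <- function(B, A, wt) sum(colSums(B / A) * wt)
    obj_old <- Inf
    for (it in seq_len(inner_max)) {
      B <- bdiag(D)                                       # d x G
      if (any(B <= 0)) return(NULL)
      detk <- apply(B, 2, geo_mean_pow)
      A <- sweep(B, 2, detk, `/`)
      if (family == "EVE") {
        lam_s <- sum(colSums(B / A)) / (n * d)
        if (lam_s <= 0) return(NULL)
        lam <- rep(lam_s, G)
      } else {
        lam <- colSums(B / A) / (nk * d)
        if (any(lam <= 0)) return(NULL)
      }
      wt <- 1 / lam
      # one MM step for D per sweep (reject non-improving steps so the
      # M-step objective, and hence EM, stays monotone)
      f0 <- fval(B, A, wt)
      Fm <- Reduce(`+`, lapply(seq_len(G), function(k)
        wt[k] * ((W[[k]] %*% D - omega[k] * D) * rep(1 / A[, k],
                                                     each = d))))
      sv <- svd(Fm)
      Dn <- -sv$u %*% t(sv$v)
      fn <- fval(bdiag(Dn), A, wt)
      if (fn < f0 - 1e-12 * (1 + abs(f0))) { D <- Dn; f0 <- fn }
      obj <- f0 + d * sum(nk * log(lam))
      if (is.finite(obj_old) && abs(obj_old - obj) < inner_tol * (1 + abs(obj)))
        break
      obj_old <- obj
    }
    Sigma <- lapply(seq_len(G), function(k)
      D %*% ((lam[k] * A[, k]) * t(D)))
    return(out(Sigma, lam, A, rep_list(D)))
  }
  stop("unknown covariance family code: ", family)
}
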