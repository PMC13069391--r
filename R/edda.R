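# Supervised (EDDA) discriminant fitting, greedy merge path over
# delimitation schemes, and Bayes-factor hypothesis ranking.

#' Fit an EDDA (eigenvalue-decomposition discriminant) model
#'
#' One Gaussian per known group with covariances constrained by a family
#' code shared across groups (the letters state what is Equal/Variable
#' across groups). Labels are fixed, so there is no EM over memberships:
#' means and scatters are the groupwise maximum-likelihood values and only
#' the constrained covariance estimation iterates where the family
#' requires. The log-likelihood is the complete-data value
#' \eqn{\sum_i \log[\pi_{z_i}\,\phi(x_i \mid \mu_{z_i}, \Sigma_{z_i})]}
#' with proportions estimated as group frequencies (counted as `K - 1`
#' free parameters).
#'
#' @param X numeric matrix, specimens x characters.
#' @param labels group label per specimen (a delimitation scheme).
#' @param family covariance family code from [gmm_families()].
#' @param inner_tol,inner_max control the iterative covariance families.
#' @return An object of class `edda_fit` with `groups`, `means`,
#'   `covariances`, `proportions`, `loglik`, `n_params`, `bic`, `n`, `d`.
#' @export
fit_edda <- function(X, labels, family = "VVV",
                     inner_tol = 1e-8, inner_max = 100) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  family <- match.arg(family, gmm_families())
  groups <- sort(unique(labels))
  K <- length(groups)
  n <- nrow(X); d <- ncol(X)
  if (n <= K) stop("need more specimens than groups (n > K)")
  nk <- vapply(groups, function(g) sum(labels == g), 0)
  small <- groups[nk < 2]
  if (length(small))
    stop("group(s) with fewer than 2 specimens: ",
         paste(small, collapse = ", "))
  mu <- t(vapply(groups, function(g)
    colMeans(X[labels == g, , drop = FALSE]), numeric(d)))
  W <- lapply(seq_len(K), function(k) {
    Xc <- sweep(X[labels == groups[k], , drop = FALSE], 2, mu[k, ])
    crossprod(Xc)
  })
  cs <- mstep_cov(W, nk, family, inner_tol = inner_tol, inner_max = inner_max)
  if (is.null(cs))
    degenerate_error(paste0("family ", family,
                            " is not estimable for this grouping"))
  floor_ <- 1e-10 * mean(diag(stats::cov(X)))
  pro <- nk / n
  ll <- 0
  for (k in seq_len(K)) {
    ev <- eigen(cs$Sigma[[k]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < floor_)
      degenerate_error(paste0("family ", family,
                              ": covariance at the eigenvalue floor"))
    idx <- labels == groups[k]
    ld <- mvn_logdens(X[idx, , drop = FALSE], mu[k, ], cs$Sigma[[k]])
    if (is.null(ld)) degenerate_error("non-PD covariance")
    ll <- ll + sum(ld) + sum(idx) * log(pro[[k]])
  }
  np <- gmm_n_params(family, K, d)
  structure(list(groups = groups, K = K, family = family, means = mu,
                 covariances = cs$Sigma, proportions = pro, loglik = ll,
                 n_params = np, bic = 2 * ll - np * log(n), n = n, d = d,
                 details = list(lambda = cs$lambda, shape = cs$shape,
                                orientation = cs$orientation)),
            class = "edda_fit")
}

#' @export
print.edda_fit <- function(x, ...) {
  cat(sprintf("EDDA fit: K = %d groups, family %s, n = %d, d = %d\n",
              x$K, x$family, x$n, x$d))
  cat(sprintf("  loglik = %.4f, params = %d, BIC = %.4f\n",
              x$loglik, x$n_params, x$bic))
  invisible(x)
}

# Best-over-families EDDA fit; non-estimable families are skipped.
# Ties: fewer parameters, then alphabetical family code.
best_edda <- function(X, labels, families = gmm_families(), ...) {
  best <- NULL
  skipped <- character(0)
  for (fam in families) {
    fit <- tryCatch(fit_edda(X, labels, fam, ...),
                    morphodelim_degenerate = function(e) NULL)
    if (is.null(fit)) { skipped <- c(skipped, fam); next }
    if (is.null(best) || fit$bic > best$bic ||
        (fit$bic == best$bic && (fit$n_params < best$n_params ||
          (fit$n_params == best$n_params && fit$family < best$family))))
      best <- fit
  }
  if (is.null(best))
    stop("no covariance family was estimable for this grouping")
  attr(best, "skipped_families") <- skipped
  best
}

#' Rank delimitation schemes by BIC
#'
#' Given the best BIC of each scheme, computes the BIC deficit
#' \eqn{\Delta BIC_i = BIC_{best} - BIC_i}, the Bayes factor against each
#' scheme \eqn{BF_i = \exp(\Delta BIC_i / 2)} and the flat-prior posterior
#' model probability
#' \eqn{PP_i = \exp(-\Delta BIC_i/2) / \sum_j \exp(-\Delta BIC_j/2)}.
#' Bayes factors are also returned on the log scale and preformatted
#' (scientific notation with 4 significant digits beyond 1e6) so extreme
#' deficits remain reportable.
#'
#' @param bics numeric vector of BIC values (maximize-BIC convention);
#'   `NA` entries are carried through with `PP = 0`.
#' @return Data frame with columns `bic`, `delta_bic`, `bf`, `log_bf`,
#'   `bf_label`, `pp`, in input order.
#' @export
rank_schemes <- function(bics) {
  bics <- as.numeric(bics)
  if (!length(bics)) stop("no BIC values supplied")
  if (!any(is.finite(bics))) stop("need at least one finite BIC")
  best <- max(bics, na.rm = TRUE)
  delta <- best - bics
  log_bf <- delta / 2
  bf <- exp(log_bf)
  w <- exp(-log_bf)
  w[!is.finite(bics)] <- 0
  pp <- w / sum(w, na.rm = TRUE)
  bf_label <- ifelse(is.na(bf), NA_character_,
                     ifelse(bf > 1e6, formatC(bf, format = "E", digits = 3),
                            formatC(bf, format = "f", digits = 3)))
  data.frame(bic = bics, delta_bic = delta, bf = bf, log_bf = log_bf,
             bf_label = bf_label, pp = pp, stringsAsFactors = FALSE)
}

scheme_display_name <- function(labels) {
  paste(sort(unique(labels)), collapse = " | ")
}

#' Greedy BIC-guided merge path over OTU lumping schemes
#'
#' Starting from the original OTU assignment (maximum splitting), every
#' unordered pair of current groups is tentatively merged and scored by
#' its best-over-families EDDA BIC; the merge with the highest BIC is
#' committed, and the process repeats until all groups are lumped
#' (maximum lumping). The result is a hierarchical sequence of `K0`
#' delimitation schemes, ranked against each other by
#' [rank_schemes()]. Greedy: a single optimal merging path is followed
#' rather than an exhaustive search over all partitions.
#'
#' Equal-BIC merges are broken lexicographically by merged-pair name;
#' merged groups are named `"A-B"` with the two names in lexicographic
#' order.
#'
#' @param X numeric matrix (size-corrected characters), or a
#'   `morpho_corrected` / `morpho_dataset`.
#' @param otu_labels group label per specimen; defaults to the dataset's
#'   OTU labels when `X` is a dataset object.
#' @param families covariance families searched per scheme.
#' @param ... passed to [fit_edda()].
#' @return An object of class `merge_path`: `table` (one row per scheme:
#'   `scheme`, `K`, `family`, `bic`, `delta_bic`, `bf`, `bf_label`, `pp`,
#'   `merged`), `assignments` (list of label vectors per level) and
#'   `best` (index of the BIC-best scheme).
#' @export
merge_path <- function(X, otu_labels = NULL, families = gmm_families(), ...) {
  if (inherits(X, c("morpho_dataset", "morpho_corrected"))) {
    if (is.null(otu_labels)) otu_labels <- X$otu
    X <- X$characters
  }
  X <- as.matrix(X)
  labels <- as.character(otu_labels)
  K0 <- length(unique(labels))
  if (K0 < 2) stop("need at least 2 OTUs to build a merge path")
  levels_ <- list()
  fit <- best_edda(X, labels, families, ...)
  levels_[[1]] <- list(labels = labels, fit = fit, merged = NA_character_)
  current <- labels
  while (length(unique(current)) > 1) {
    groups <- sort(unique(current))
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    best_pair <- NULL
    for (p in pairs) {
      cand <- current
      newname <- paste(sort(p), collapse = "-")
      cand[cand %in% p] <- newname
      f <- tryCatch(best_edda(X, cand, families, ...),
                    error = function(e) NULL)
      if (is.null(f)) next
      pname <- paste(sort(p), collapse = "|")
      if (is.null(best_pair) || f$bic > best_pair$fit$bic ||
          (f$bic == best_pair$fit$bic && pname < best_pair$pname))
        best_pair <- list(labels = cand, fit = f, pname = pname,
                          merged = newname)
    }
    if (is.null(best_pair))
      stop("no estimable merge at K = ", length(groups))
    levels_[[length(levels_) + 1]] <- best_pair[c("labels", "fit", "merged")]
    current <- best_pair$labels
  }
  tab <- data.frame(
    scheme = vapply(levels_, function(l) scheme_display_name(l$labels), ""),
    K = vapply(levels_, function(l) length(unique(l$labels)), 0),
    family = vapply(levels_, function(l) l$fit$family, ""),
    merged = vapply(levels_, function(l) l$merged, ""),
    stringsAsFactors = FALSE)
  tab <- cbind(tab, rank_schemes(vapply(levels_, function(l) l$fit$bic, 0)))
  structure(list(table = tab,
                 assignments = lapply(levels_, `[[`, "labels"),
                 fits = lapply(levels_, `[[`, "fit"),
                 best = which.max(tab$bic)),
            class = "merge_path")
}

#' @export
print.merge_path <- function(x, ...) {
  cat("Greedy merge path (", nrow(x$table), " schemes):\n", sep = "")
  tab <- x$table[, c("scheme", "K", "family", "bic", "delta_bic",
                     "bf_label", "pp")]
  tab$bic <- round(tab$bic, 3); tab$delta_bic <- round(tab$delta_bic, 3)
  tab$pp <- round(tab$pp, 3)
  print(tab, row.names = FALSE)
  cat("Best-supported scheme:", x$table$scheme[x$best], "\n")
  invisible(x)
}

#' Compare explicit taxonomic hypotheses
#'
#' Each scheme (a named assignment of every specimen to a group; schemes
#' may lump OTUs or split them) is scored by its best-over-families EDDA
#' BIC, and schemes are ranked jointly by [rank_schemes()] — BIC deficit,
#' Bayes factor and flat-prior posterior probability. Because this uses
#' the same model framework as [merge_path()], identical hypotheses yield
#' identical scores.
#'
#' @param X numeric matrix (size-corrected characters), or a
#'   `morpho_corrected` / `morpho_dataset`.
#' @param schemes named list of label vectors (or a `scheme_set` from
#'   [read_schemes()]); names must be unique.
#' @param families covariance families searched per scheme.
#' @param prior optional prior weight per scheme (default flat); weights
#'   are normalized and fold into the posterior probabilities.
#' @param ... passed to [fit_edda()].
#' @return An object of class `scheme_comparison`: a data frame with one
#'   row per scheme (`scheme`, `K`, `family`, `bic`, `delta_bic`, `bf`,
#'   `bf_label`, `pp`), sorted by decreasing BIC.
#' @export
compare_schemes <- function(X, schemes, families = gmm_families(),
                            prior = NULL, ...) {
  if (inherits(X, c("morpho_dataset", "morpho_corrected"))) X <- X$characters
  X <- as.matrix(X)
  schemes <- unclass(schemes)
  if (is.null(names(schemes)) || any(names(schemes) == ""))
    stop("schemes must be named")
  if (anyDuplicated(names(schemes)))
    stop("duplicate scheme names: ",
         paste(unique(names(schemes)[duplicated(names(schemes))]),
               collapse = ", "))
  if (length(schemes) < 1) stop("no schemes supplied")
  fits <- lapply(schemes, function(s) best_edda(X, s, families, ...))
  rk <- rank_schemes(vapply(fits, bic_of, 0))
  if (!is.null(prior)) {
    stopifnot(length(prior) == length(schemes), all(prior > 0))
    w <- exp(-rk$delta_bic / 2) * (prior / sum(prior))
    rk$pp <- w / sum(w)
  }
  tab <- data.frame(scheme = names(schemes),
                    K = vapply(fits, function(f) f$K, 0),
                    family = vapply(fits, function(f) f$family, ""),
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, rk)
  tab <- tab[order(-tab$bic, tab$K), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "scheme_comparison")
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat("Taxonomic hypothesis comparison:\n")
  tab <- x$table[, c("scheme", "K", "family", "bic", "delta_bic",
                     "bf_label", "pp")]
  tab$bic <- round(tab$bic, 3); tab$delta_bic <- round(tab$delta_bic, 3)
  tab$pp <- round(tab$pp, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
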