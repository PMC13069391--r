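# PCA, DAPC and permutational MANOVA on size-corrected characters.

#' Principal component analysis with a deterministic sign convention
#'
#' Eigen-decomposition of the covariance (or, with `scale = TRUE`,
#' correlation) matrix via [stats::prcomp()]. Axis signs are fixed so the
#' largest-magnitude loading on every component is positive, making scores
#' reproducible across platforms.
#'
#' @param X numeric matrix, or a `morpho_corrected` / `morpho_dataset`.
#' @param scale scale characters to unit variance (correlation PCA).
#' @return An object of class `morpho_pca`: `scores` (n x d), `loadings`
#'   (d x d), `explained` (variance proportions, summing to 1), `center`,
#'   `scale`.
#' @export
morpho_pca <- function(X, scale = FALSE) {
  if (inherits(X, c("morpho_dataset", "morpho_corrected"))) X <- X$characters
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 specimens")
  if (scale && any(apply(X, 2, stats::sd) == 0))
    stop("constant character(s) cannot be scaled to unit variance")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 sdev = pc$sdev, center = pc$center,
                 scale = if (scale) pc$scale else FALSE),
            class = "morpho_pca")
}

#' @export
print.morpho_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "specimens,", ncol(x$scores), "components\n")
  ev <- round(100 * x$explained[seq_len(min(5, length(x$explained)))], 1)
  cat("explained (%):", paste(ev, collapse = ", "),
      if (length(x$explained) > 5) "...", "\n")
  invisible(x)
}

#' Discriminant analysis of principal components
#'
#' Reduces the data to `n_pcs` principal components, then fits linear
#' discriminant axes maximizing between-group relative to within-group
#' variance on the retained scores (via [MASS::lda()]). The number of
#' discriminant axes is `min(K - 1, n_pcs)`. With `n_pcs = "auto"` the
#' smallest number of components explaining at least 90% of the variance
#' is retained, capped at `n/3` (an overfitting guard).
#'
#' @param X numeric matrix, or a `morpho_corrected` / `morpho_dataset`.
#' @param labels group label per specimen.
#' @param n_pcs number of retained components, or `"auto"`.
#' @return An object of class `morpho_dapc`: `ld_scores` (n x axes),
#'   `n_pcs`, `n_axes`, `assignment` (training prediction), `accuracy`
#'   (training assignment accuracy), `lda` (the underlying fit), `pca`.
#' @export
morpho_dapc <- function(X, labels = NULL, n_pcs = "auto") {
  if (inherits(X, c("morpho_dataset", "morpho_corrected"))) {
    if (is.null(labels)) labels <- X$otu
    X <- X$characters
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  K <- length(unique(labels))
  n <- nrow(X)
  if (K < 2) stop("DAPC needs at least 2 groups")
  pca <- morpho_pca(X)
  if (identical(n_pcs, "auto")) {
    n_pcs <- which(cumsum(pca$explained) >= 0.9)[1]
    n_pcs <- max(1L, min(n_pcs, floor(n / 3), n - K - 1L))
  }
  if (n_pcs >= n - K)
    stop("n_pcs must be smaller than n - K (overfit guard); got ", n_pcs)
  scores <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  fit <- MASS::lda(scores, grouping = factor(labels))
  pred <- stats::predict(fit, scores)
  structure(list(ld_scores = pred$x, n_pcs = n_pcs,
                 n_axes = min(K - 1, n_pcs),
                 assignment = as.character(pred$class),
                 accuracy = mean(as.character(pred$class) == labels),
                 lda = fit, pca = pca),
            class = "morpho_dapc")
}

#' @export
print.morpho_dapc <- function(x, ...) {
  cat(sprintf("DAPC: %d retained PCs, %d discriminant axes, training accuracy %.3f\n",
              x$n_pcs, x$n_axes, x$accuracy))
  invisible(x)
}

# Between-group sum of squares from group sums (Euclidean geometry);
# cheap enough to recompute for every permutation.
ss_between <- function(X, lab_int, ng, total_sq_over_n) {
  S <- rowsum(X, lab_int)
  sum(rowSums(S^2) / ng) - total_sq_over_n
}

#' Permutational multivariate analysis of variance
#'
#' One-way PERMANOVA with Euclidean distances, computed directly from
#' sums of squares: pseudo-F = `[SSb/(K-1)] / [SSw/(n-K)]`,
#' `R^2 = SSb/SStot`, and a permutation p-value under the add-one
#' convention `p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1)` — so the
#' smallest attainable p is `1/(n_perm + 1)`. Group labels are permuted
#' with a seeded stream; when specimen ids are supplied, rows are first
#' sorted by id so the result is invariant to input ordering.
#'
#' Euclidean distances on all PCA scores are identical to Euclidean
#' distances on the input characters, so this can be run on either.
#'
#' @param X numeric matrix (characters or PCA scores), or a
#'   `morpho_corrected` / `morpho_dataset`.
#' @param labels group label per specimen.
#' @param n_perm number of label permutations (the example workflow uses
#'   50,000; default 999).
#' @param seed integer seed for the permutation stream.
#' @param ids optional specimen ids used to canonicalize row order.
#' @return An object of class `permanova_result`: data frame `table` with
#'   `F`, `R2`, `p`, plus `n_perm`, `seed`, `df`.
#' @export
permanova <- function(X, labels = NULL, n_perm = 999, seed = 1, ids = NULL) {
  if (inherits(X, c("morpho_dataset", "morpho_corrected"))) {
    if (is.null(labels)) labels <- X$otu
    if (is.null(ids)) ids <- X$specimen_ids
    X <- X$characters
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels), n_perm >= 1)
  if (!is.null(ids)) {
    ord <- order(ids)
    X <- X[ord, , drop = FALSE]
    labels <- labels[ord]
  }
  K <- length(unique(labels))
  if (K < 2) stop("PERMANOVA needs at least 2 groups")
  tab <- table(labels)
  if (any(tab < 2))
    stop("group(s) of size 1: ", paste(names(tab)[tab < 2], collapse = ", "))
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  ss_tot <- sum(Xc^2)
  lab_f <- factor(labels)
  lab_int <- as.integer(lab_f)
  ng <- as.numeric(table(lab_int))
  tso <- sum(colSums(Xc)^2) / n  # 0 after centering; kept for clarity
  ssb_obs <- ss_between(Xc, lab_int, ng, tso)
  f_of <- function(ssb) (ssb / (K - 1)) / ((ss_tot - ssb) / (n - K))
  F_obs <- f_of(ssb_obs)
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(n)
      f_of(ss_between(Xc, lab_int[perm], ng, tso))
    }, 0) >= F_obs)
  })
  structure(list(table = data.frame(
    comparison = paste(levels(lab_f), collapse = " vs "),
    F = F_obs, R2 = ssb_obs / ss_tot,
    p = (hits + 1) / (n_perm + 1), stringsAsFactors = FALSE),
    df = c(K - 1, n - K), n_perm = n_perm, seed = seed),
    class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (Euclidean, %d permutations, seed %d):\n",
              x$n_perm, x$seed))
  tab <- x$table
  tab$F <- round(tab$F, 6); tab$R2 <- round(tab$R2, 6)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pairwise PERMANOVA with multiplicity adjustment
#'
#' Runs [permanova()] on every unordered pair of groups and adjusts the
#' p-values across the `K(K-1)/2` comparisons (Bonferroni by default,
#' matching the convention of reporting an adjusted column alongside the
#' raw permutation p).
#'
#' @inheritParams permanova
#' @param adjust `"bonferroni"`, `"holm"` or `"bh"`.
#' @return A `permanova_result` whose `table` has one row per pair with
#'   `F`, `R2`, `p` and `p_adjusted`.
#' @export
pairwise_permanova <- function(X, labels = NULL, n_perm = 999, seed = 1,
                               adjust = c("bonferroni", "holm", "bh"),
                               ids = NULL) {
  if (inherits(X, c("morpho_dataset", "morpho_corrected"))) {
    if (is.null(labels)) labels <- X$otu
    if (is.null(ids)) ids <- X$specimen_ids
    X <- X$characters
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  adjust <- match.arg(adjust)
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    keep <- labels %in% p
    permanova(X[keep, , drop = FALSE], labels[keep], n_perm = n_perm,
              seed = seed, ids = if (!is.null(ids)) ids[keep])$table
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- stats::p.adjust(tab$p, method = switch(adjust,
    bonferroni = "bonferroni", holm = "holm", bh = "BH"))
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 adjust = adjust),
            class = "permanova_result")
}
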