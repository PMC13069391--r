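# Unsupervised inference of the number of morphological clusters.

# Tie-breaking used in every BIC comparison: higher BIC wins; ties go to
# fewer parameters, then fewer components, then alphabetical family code.
pick_best_cell <- function(df) {
  df <- df[is.finite(df$bic), , drop = FALSE]
  if (!nrow(df)) return(NULL)
  df <- df[order(-df$bic, df$n_params, df$G, df$family), , drop = FALSE]
  df[1, , drop = FALSE]
}

#' Infer the number of morphological clusters without OTU labels
#'
#' Fits every (G, family) cell for `G = 1 .. Gmax` and the requested
#' covariance families, selects the cell maximizing BIC, and — when OTU
#' labels are supplied — cross-tabulates the best model's classification
#' against the labels.
#'
#' Cells whose EM fit degenerates (component collapse, covariance at the
#' eigenvalue floor, non-estimable family) are recorded as `NA` and
#' excluded from model selection.
#'
#' @param X numeric matrix of (size-corrected) characters, or a
#'   `morpho_corrected` / `morpho_dataset` object.
#' @param Gmax largest number of clusters considered (default 9).
#' @param families subset of [gmm_families()] (default: all 14).
#' @param seed integer seed (restarts of degenerate cells).
#' @param otu_labels optional character vector of OTU labels.
#' @param ... passed to [fit_gmm()].
#' @return An object of class `model_selection`: `bic_table` (Gmax x
#'   families matrix, `NA` = non-converged cell), `best` (the winning
#'   `gmm_fit`), `best_G`, `best_family`, and — with labels —
#'   `correspondence` (see [classify_correspondence()]).
#' @export
unsupervised_cluster <- function(X, Gmax = 9, families = gmm_families(),
                                 seed = NULL, otu_labels = NULL, ...) {
  if (inherits(X, c("morpho_dataset", "morpho_corrected"))) {
    if (is.null(otu_labels)) otu_labels <- X$otu
    X <- X$characters
  }
  X <- as.matrix(X)
  stopifnot(Gmax >= 1)
  families <- match.arg(families, gmm_families(), several.ok = TRUE)
  bic_table <- matrix(NA_real_, Gmax, length(families),
                      dimnames = list(G = seq_len(Gmax), family = families))
  fits <- list()
  cells <- data.frame(G = integer(), family = character(),
                      n_params = integer(), bic = numeric())
  for (G in seq_len(Gmax)) {
    for (fam in families) {
      fit <- tryCatch(
        fit_gmm(X, G = G, family = fam, seed = seed, ...),
        morphodelim_degenerate = function(e) NULL,
        error = function(e) NULL)
      if (!is.null(fit)) {
        bic_table[G, fam] <- fit$bic
        fits[[paste(fam, G)]] <- fit
        cells <- rbind(cells, data.frame(G = G, family = fam,
                                         n_params = fit$n_params,
                                         bic = fit$bic))
      }
    }
  }
  best <- pick_best_cell(cells)
  if (is.null(best))
    stop("no (G, family) cell converged; cannot select a model")
  best_fit <- fits[[paste(best$family, best$G)]]
  corr <- if (!is.null(otu_labels))
    classify_correspondence(best_fit, otu_labels) else NULL
  structure(list(bic_table = bic_table, best = best_fit,
                 best_G = best$G, best_family = best$family,
                 correspondence = corr),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("Model selection over %d x %d (G, family) cells\n",
              nrow(x$bic_table), ncol(x$bic_table)))
  cat(sprintf("Best model: G = %d, family %s, BIC = %.3f\n",
              x$best_G, x$best_family, x$best$bic))
  if (!is.null(x$correspondence)) print(x$correspondence)
  invisible(x)
}

#' BIC profile plot
#'
#' BIC against the number of clusters, one line per covariance family.
#' @param x a `model_selection`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.model_selection <- function(x, ...) {
  graphics::matplot(seq_len(nrow(x$bic_table)), x$bic_table, type = "b",
                    pch = seq_len(ncol(x$bic_table)), lty = 1,
                    xlab = "Number of clusters (G)", ylab = "BIC", ...)
  graphics::legend("bottomright", colnames(x$bic_table), bty = "n",
                   pch = seq_len(ncol(x$bic_table)),
                   col = seq_len(ncol(x$bic_table)), cex = 0.7)
  invisible(x)
}

#' Cross-tabulate inferred clusters against OTU labels
#'
#' Counts specimens per (OTU, inferred cluster) and diagnoses the
#' qualitative pattern: *perfect correspondence* (each cluster holds one
#' OTU and each OTU one cluster), *mixed clusters* (a cluster to which two
#' or more OTUs each contribute at least 2 specimens), and/or *split OTUs*
#' (an OTU with at least 2 specimens in each of two or more clusters).
#' Single stragglers are reported but do not change the diagnosis.
#'
#' @param fit a `gmm_fit` (or an integer classification vector).
#' @param otu_labels character vector aligned to the fitted specimens.
#' @return An object of class `correspondence`: `table` (OTU x cluster
#'   counts), `pattern` (character vector of tags) and `stragglers`.
#' @export
classify_correspondence <- function(fit, otu_labels) {
  cl <- if (inherits(fit, "gmm_fit")) fit$classification else as.integer(fit)
  stopifnot(length(cl) == length(otu_labels))
  tab <- table(OTU = otu_labels, cluster = cl)
  mixed <- any(colSums(tab >= 2) >= 2)
  split <- any(rowSums(tab >= 2) >= 2)
  pattern <- c(if (mixed) "mixed clusters", if (split) "split OTUs")
  if (is.null(pattern)) pattern <- "perfect correspondence"
  stragglers <- which(tab == 1 & rowSums(tab >= 2) >= 1, arr.ind = TRUE)
  structure(list(table = tab, pattern = pattern, stragglers = stragglers),
            class = "correspondence")
}

#' @export
print.correspondence <- function(x, ...) {
  cat("Cluster-OTU correspondence (", paste(x$pattern, collapse = " + "),
      "):\n", sep = "")
  print(x$table)
  invisible(x)
}
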