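#' Thorpe allometric size correction
#'
#' Removes proportional, body-size-related variation from each character
#' before multivariate analysis. Each raw value X is adjusted on the
#' base-10 log scale:
#'
#' \deqn{X_{adj} = \log_{10} X - \beta\,(\log_{10} SVL - \overline{\log_{10} SVL})}
#'
#' where the reference size is the grand mean of log10 body size over all
#' specimens, and the allometric slope \eqn{\beta} of log-character on
#' log-size is estimated either once from group-mean-centered data pooled
#' across OTUs (`mode = "pooled"`, the standard multispecies variant) or
#' separately within each OTU (`mode = "per-otu"`). With `mode = "none"`
#' no slope term is subtracted and the log10-transformed values are
#' returned as-is (set `log = FALSE` for a raw passthrough).
#'
#' @param ds a [morpho_dataset()].
#' @param mode `"pooled"`, `"per-otu"` or `"none"`.
#' @param log with `mode = "none"` only: log10-transform (default) or
#'   return raw values untouched.
#' @return An object of class `thorpe_corrected`: list with `corrected`
#'   (n x d matrix, same dimnames as the input characters), `slopes`
#'   (per character; a matrix OTU x character in per-otu mode), `ref_log_size`
#'   (grand mean log10 body size) and `mode`.
#' @export
thorpe_correct <- function(ds, mode = c("pooled", "per-otu", "none"), log = TRUE) {
  stopifnot(inherits(ds, "morpho_dataset"))
  mode <- match.arg(mode)
  X <- log10(ds$characters)
  s <- log10(ds$body_size)
  ref <- mean(s)
  if (mode == "none") {
    corrected <- if (log) X else ds$characters
    return(structure(list(corrected = corrected, slopes = NULL,
                          ref_log_size = ref, mode = mode, log = log),
                     class = "thorpe_corrected"))
  }
  otu <- ds$otu
  if (mode == "pooled") {
    sc <- s - stats::ave(s, otu)            # group-mean-centered log size
    if (sum(sc^2) == 0) {
      if (stats::var(s) == 0) {
        # every specimen at the reference size: the correction term is zero
        # for any slope, so the log-transformed values are returned as-is
        beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
        return(structure(list(corrected = X, slopes = beta,
                              ref_log_size = ref, mode = mode, log = TRUE),
                         class = "thorpe_corrected"))
      }
      stop("body size is constant within every OTU; the pooled allometric ",
           "slope is undefined. Use mode = \"none\".")
    }
    Xc <- X - apply(X, 2, function(col) stats::ave(col, otu))
    beta <- colSums(sc * Xc) / sum(sc^2)    # common within-group OLS slope
    corrected <- X - outer(s - ref, beta)
  } else {
    otus <- sort(unique(otu))
    beta <- matrix(NA_real_, length(otus), ncol(X),
                   dimnames = list(otus, colnames(X)))
    corrected <- X
    for (g in otus) {
      idx <- which(otu == g)
      if (length(idx) < 2 || stats::var(s[idx]) == 0)
        stop("OTU '", g, "' needs >= 2 specimens with non-constant body ",
             "size to estimate a per-OTU slope")
      sc <- s[idx] - mean(s[idx])
      b <- colSums(sc * scale(X[idx, , drop = FALSE], scale = FALSE)) / sum(sc^2)
      beta[g, ] <- b
      corrected[idx, ] <- X[idx, , drop = FALSE] - outer(s[idx] - ref, b)
    }
  }
  structure(list(corrected = corrected, slopes = beta, ref_log_size = ref,
                 mode = mode, log = TRUE),
            class = "thorpe_corrected")
}

#' @export
print.thorpe_corrected <- function(x, ...) {
  cat("Thorpe-corrected matrix:", nrow(x$corrected), "specimens x",
      ncol(x$corrected), "characters (mode:", x$mode, ")\n")
  if (!is.null(x$slopes) && is.null(dim(x$slopes))) {
    cat("pooled slopes:\n"); print(round(x$slopes, 4))
  }
  invisible(x)
}

#' Size-corrected dataset for downstream analysis
#'
#' Wraps [thorpe_correct()] and returns a dataset-shaped object whose
#' character matrix holds the size-adjusted log-scale values. The
#' body-size column is either dropped (default) or carried along as
#' log10(size) in the first column. The result is tagged as corrected;
#' feeding it to a second round of correction is refused.
#'
#' @param ds a [morpho_dataset()] (not already corrected).
#' @param mode passed to [thorpe_correct()].
#' @param keep_body_size carry log10 body size as an extra first column.
#' @param log passed to [thorpe_correct()] (mode `"none"` only).
#' @return A `morpho_corrected` object: list with `specimen_ids`, `otu`,
#'   `characters` (corrected matrix), and the `thorpe_corrected` fit as
#'   `correction`.
#' @export
corrected_dataset <- function(ds, mode = c("pooled", "per-otu", "none"),
                              keep_body_size = FALSE, log = TRUE) {
  if (inherits(ds, "morpho_corrected") || isTRUE(attr(ds, "corrected")))
    stop("dataset is already size-corrected; refusing to correct twice")
  fit <- thorpe_correct(ds, mode, log = log)
  chars <- fit$corrected
  if (keep_body_size) {
    chars <- cbind(log10(ds$body_size), chars)
    colnames(chars)[1] <- paste0("log10_", ds$body_size_name)
  }
  structure(list(specimen_ids = ds$specimen_ids, otu = ds$otu,
                 characters = chars, character_names = colnames(chars),
                 correction = fit),
            class = "morpho_corrected", corrected = TRUE)
}
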