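#' Construct a morphometric dataset
#'
#' A `morpho_dataset` holds one row per specimen: an OTU label, a body-size
#' measurement (e.g. snout--vent length) and one or more continuous
#' morphometric characters. All measurements must be strictly positive so
#' that a base-10 log transform (required by the allometric correction) is
#' defined.
#'
#' @param otu character vector of OTU labels, one per specimen.
#' @param body_size numeric vector of body-size measurements (> 0), in the
#'   units measured (typically mm).
#' @param characters numeric matrix (specimens x characters) of strictly
#'   positive measurements, with column names.
#' @param specimen_ids optional character vector of unique specimen
#'   identifiers; generated as `s001, s002, ...` when missing.
#' @param body_size_name name of the body-size character (default `"SVL"`).
#' @param warn_singletons emit a warning listing OTUs represented by a
#'   single specimen (these cannot contribute variance estimates and are
#'   usually removed during data quality control).
#'
#' @return An object of class `morpho_dataset`: a list with elements
#'   `specimen_ids`, `otu`, `body_size`, `characters` (matrix),
#'   `character_names` and `body_size_name`.
#' @export
morpho_dataset <- function(otu, body_size, characters, specimen_ids = NULL,
                           body_size_name = "SVL", warn_singletons = TRUE) {
  characters <- as.matrix(characters)
  if (is.null(colnames(characters)))
    colnames(characters) <- paste0("char", seq_len(ncol(characters)))
  n <- length(otu)
  if (n < 2) stop("a morphometric dataset needs at least 2 specimens")
  if (ncol(characters) < 1) stop("at least one morphometric character is required")
  if (length(body_size) != n || nrow(characters) != n)
    stop("otu, body_size and characters must describe the same specimens")
  if (is.null(specimen_ids))
    specimen_ids <- sprintf("s%03d", seq_len(n))
  specimen_ids <- as.character(specimen_ids)
  if (anyDuplicated(specimen_ids))
    stop("duplicate specimen id(s): ",
         paste(unique(specimen_ids[duplicated(specimen_ids)]), collapse = ", "))
  if (!is.numeric(body_size) || !is.numeric(characters))
    stop("body size and characters must be numeric")
  if (anyNA(body_size) || anyNA(characters))
    stop("missing values are not allowed; remove or impute them before analysis")
  if (any(body_size <= 0) || any(characters <= 0))
    stop("all body-size and character values must be > 0 ",
         "(the log10 transform used by allometric correction requires it)")
  if (anyDuplicated(colnames(characters)))
    stop("duplicate character names")
  otu <- as.character(otu)
  tab <- table(otu)
  if (warn_singletons && any(tab == 1))
    warning("singleton OTU(s) (one specimen): ",
            paste(names(tab)[tab == 1], collapse = ", "),
            ". Consider removing them during data quality control.")
  structure(list(specimen_ids = specimen_ids, otu = otu,
                 body_size = as.numeric(body_size), characters = characters,
                 character_names = colnames(characters),
                 body_size_name = body_size_name),
            class = "morpho_dataset")
}

#' @export
print.morpho_dataset <- function(x, ...) {
  cat("Morphometric dataset:", length(x$otu), "specimens,",
      length(x$character_names), "characters + body size (", x$body_size_name, ")\n")
  tab <- table(x$otu)
  cat("OTUs:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of specimens and characters
#' @param x a `morpho_dataset`.
#' @export
dim.morpho_dataset <- function(x) c(length(x$otu), ncol(x$characters))

#' Read a morphometric table from CSV
#'
#' Expected layout: a header row; column 1 = OTU label, column 2 = body
#' size, remaining columns = morphometric characters. An optional leading
#' column named `specimen`, `specimen_id` or `id` (case-insensitive)
#' supplies specimen identifiers; otherwise identifiers `s001, s002, ...`
#' are generated in file order. Values are comma-separated with `.` as
#' decimal point.
#'
#' @param path path to the CSV file.
#' @param drop_singletons drop OTUs represented by a single specimen
#'   instead of merely warning about them.
#' @return A validated [morpho_dataset()].
#' @export
read_morphometrics <- function(path, drop_singletons = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 3)
    stop("need at least 3 columns (OTU, body size, >= 1 character)")
  ids <- NULL
  if (tolower(names(raw)[1]) %in% c("specimen", "specimen_id", "id")) {
    ids <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
    if (ncol(raw) < 3)
      stop("need at least 3 columns after the id column (OTU, body size, >= 1 character)")
  }
  otu <- as.character(raw[[1]])
  num <- raw[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     v[bad[1]], bad[1], names(num)[j]))
      v <- conv
    }
    na <- which(is.na(v))
    if (length(na))
      stop(sprintf("missing value at row %d, column '%s'", na[1], names(num)[j]))
    nonpos <- which(v <= 0)
    if (length(nonpos))
      stop(sprintf(paste0("value <= 0 at row %d, column '%s': the log10 ",
                          "transform used by allometric correction requires ",
                          "strictly positive measurements"),
                   nonpos[1], names(num)[j]))
    num[[j]] <- v
  }
  if (drop_singletons) {
    tab <- table(otu)
    keep <- otu %in% names(tab)[tab > 1]
    if (!all(keep)) {
      message("dropped singleton OTU(s): ",
              paste(names(tab)[tab == 1], collapse = ", "))
      otu <- otu[keep]; num <- num[keep, , drop = FALSE]
      if (!is.null(ids)) ids <- ids[keep]
    }
  }
  morpho_dataset(otu = otu, body_size = num[[1]],
                 characters = as.matrix(num[, -1, drop = FALSE]),
                 specimen_ids = ids, body_size_name = names(num)[1],
                 warn_singletons = !drop_singletons)
}

#' Write a morphometric dataset to CSV
#'
#' Inverse of [read_morphometrics()]: values round-trip at full double
#' precision.
#'
#' @param ds a `morpho_dataset`.
#' @param path output path.
#' @param ids write the specimen-id column.
#' @export
write_morphometrics <- function(ds, path, ids = FALSE) {
  df <- data.frame(OTU = ds$otu, check.names = FALSE)
  df[[ds$body_size_name]] <- ds$body_size
  df <- cbind(df, as.data.frame(ds$characters, check.names = FALSE))
  if (ids) df <- cbind(data.frame(specimen = ds$specimen_ids), df)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-OTU summary statistics
#'
#' One row per (OTU, character) combination — body size included — with
#' N, mean, standard deviation (n-1 denominator), minimum and maximum:
#' the "N; Mean +/- SD; Min--Max" table conventionally reported in
#' taxonomic descriptions. For single-specimen OTUs the SD is undefined
#' and reported as `NA`.
#'
#' @param ds a `morpho_dataset`.
#' @return A data frame of class `morpho_summary` with columns `otu`,
#'   `character`, `n`, `mean`, `sd`, `min`, `max` and a preformatted
#'   `formatted` column (`"N; mean +/- sd; min--max"`).
#' @export
morpho_summary <- function(ds) {
  stopifnot(inherits(ds, "morpho_dataset"))
  mat <- cbind(stats::setNames(data.frame(ds$body_size), ds$body_size_name),
               as.data.frame(ds$characters))
  otus <- sort(unique(ds$otu))
  out <- do.call(rbind, lapply(otus, function(g) {
    sub <- mat[ds$otu == g, , drop = FALSE]
    do.call(rbind, lapply(names(sub), function(ch) {
      v <- sub[[ch]]
      data.frame(otu = g, character = ch, n = length(v), mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                 min = min(v), max = max(v), stringsAsFactors = FALSE)
    }))
  }))
  out$formatted <- sprintf("%d; %.2f ± %s; %.2f–%.2f", out$n, out$mean,
                           ifelse(is.na(out$sd), "NA", sprintf("%.2f", out$sd)),
                           out$min, out$max)
  rownames(out) <- NULL
  class(out) <- c("morpho_summary", "data.frame")
  out
}

#' Flag potential outliers by robust z-score
#'
#' Within each OTU and character, computes the robust score
#' `|x - median| / MAD` where the MAD carries the usual 1.4826 consistency
#' constant, and returns entries whose score exceeds `threshold`, sorted by
#' decreasing score. Groups with fewer than 3 specimens, or with zero
#' spread (MAD = 0 and all values equal), are skipped with a warning. When
#' MAD = 0 but some values differ from the median, those values are flagged
#' with an infinite score.
#'
#' @param ds a `morpho_dataset`.
#' @param threshold positive robust-z cutoff (default 3.5).
#' @param include_body_size also screen the body-size column.
#' @return Data frame with columns `specimen_id`, `otu`, `character`,
#'   `value`, `score`.
#' @export
flag_outliers <- function(ds, threshold = 3.5, include_body_size = TRUE) {
  stopifnot(inherits(ds, "morpho_dataset"), threshold > 0)
  cols <- as.data.frame(ds$characters)
  if (include_body_size)
    cols <- cbind(stats::setNames(data.frame(ds$body_size), ds$body_size_name), cols)
  res <- list()
  for (g in sort(unique(ds$otu))) {
    idx <- which(ds$otu == g)
    if (length(idx) < 3) {
      warning("OTU '", g, "' has fewer than 3 specimens; outlier screen skipped")
      next
    }
    for (ch in names(cols)) {
      v <- cols[[ch]][idx]
      med <- stats::median(v)
      m <- stats::mad(v)          # 1.4826 * median(|x - med|)
      if (m == 0) {
        if (all(v == med)) {
          warning("OTU '", g, "', character '", ch,
                  "': zero spread, outlier screen skipped")
          next
        }
        score <- ifelse(v == med, 0, Inf)
      } else {
        score <- abs(v - med) / m
      }
      hit <- which(score > threshold)
      if (length(hit))
        res[[length(res) + 1L]] <- data.frame(
          specimen_id = ds$specimen_ids[idx[hit]], otu = g, character = ch,
          value = v[hit], score = score[hit], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(specimen_id = character(), otu = character(),
               character = character(), value = numeric(), score = numeric())
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read taxonomic delimitation schemes
#'
#' A scheme file maps every specimen to a group label under one or more
#' named taxonomic hypotheses: column 1 = specimen id, columns 2+ = one
#' column per scheme. Group labels are taken verbatim, so a scheme may
#' lump several OTUs under one label or split an OTU across labels. The
#' id set must match the dataset exactly; rows are re-aligned to dataset
#' order.
#'
#' @param path path to the scheme CSV.
#' @param ds the `morpho_dataset` the schemes refer to.
#' @return A named list of class `scheme_set`; each element is a character
#'   vector of group labels aligned to `ds$specimen_ids`.
#' @export
read_schemes <- function(path, ds) {
  stopifnot(inherits(ds, "morpho_dataset"))
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 2) stop("scheme file needs an id column plus >= 1 scheme column")
  ids <- as.character(raw[[1]])
  missing_ids <- setdiff(ds$specimen_ids, ids)
  extra_ids <- setdiff(ids, ds$specimen_ids)
  if (length(missing_ids) || length(extra_ids))
    stop("scheme file ids do not match the dataset.",
         if (length(missing_ids)) paste0(" Missing: ",
                                         paste(missing_ids, collapse = ", "), "."),
         if (length(extra_ids)) paste0(" Unknown: ",
                                       paste(extra_ids, collapse = ", "), "."))
  if (anyDuplicated(ids))
    stop("duplicate specimen id(s) in scheme file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- match(ds$specimen_ids, ids)
  schemes <- lapply(raw[, -1, drop = FALSE], function(col) {
    col <- as.character(col)[ord]
    if (anyNA(col) || any(col == ""))
      stop("empty group label in scheme file")
    col
  })
  structure(schemes, class = "scheme_set", specimen_ids = ds$specimen_ids)
}
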