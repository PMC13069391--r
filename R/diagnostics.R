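# Diagnostic character identification: shadow-feature random-forest
# selection plus univariate tests.

#' Identify diagnostic characters by shadow-feature selection
#'
#' Iterative random-forest wrapper in the Boruta style. Each run appends
#' one shuffled "shadow" copy of every still-undecided character, trains a
#' random forest on the augmented matrix and computes out-of-bag
#' permutation importances (how much accuracy drops when a character's
#' values are scrambled across groups). A character scores a *hit* when
#' its importance exceeds the maximum importance among the shadows. After
#' every run, one-sided binomial tests on the hit counts (success
#' probability 0.5, Bonferroni-corrected across the full character set)
#' promote characters to **Confirmed** (significantly more important
#' than the best shadow — candidate diagnostic characters) or demote them
#' to **Rejected** (no better than random noise); rejected characters and
#' their shadows are removed from subsequent runs. Characters still
#' undecided after `max_runs` are **Tentative**.
#'
#' @param X numeric matrix, specimens x characters, or a
#'   `morpho_corrected` / `morpho_dataset`.
#' @param labels group label per specimen.
#' @param groups subset of labels to compare (default: all groups).
#' @param n_trees trees per forest (default 500).
#' @param max_runs maximum shadow runs (default 100).
#' @param alpha significance level of the binomial decisions (default
#'   0.01, Bonferroni-corrected internally).
#' @param seed integer seed; decisions are fully reproducible given the
#'   seed.
#' @return An object of class `boruta_result`: data frame `decision`
#'   (per-character decision, hits, runs, binomial p-values) and
#'   `importance_history` (per run: each character's importance and the
#'   shadow maximum; `NA` once a character has left the game).
#' @export
boruta_select <- function(X, labels, groups = NULL, n_trees = 500,
                          max_runs = 100, alpha = 0.01, seed = 1) {
  if (inherits(X, c("morpho_dataset", "morpho_corrected"))) {
    if (is.null(labels)) labels <- X$otu
    X <- X$characters
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  if (!is.null(groups)) {
    keep <- labels %in% groups
    X <- X[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2)
    stop("need at least 2 groups to identify diagnostic characters")
  if (min(table(labels)) < 2) stop("every group needs at least 2 specimens")
  if (nrow(X) < 5)
    stop("fewer than 5 specimens; a random forest cannot be trained meaningfully")
  chars <- colnames(X)
  if (is.null(chars)) chars <- colnames(X) <- paste0("char", seq_len(ncol(X)))
  d <- length(chars)
  withr::with_seed(seed, {
    decision <- stats::setNames(rep("Tentative", d), chars)
    hits <- stats::setNames(integer(d), chars)
    runs <- stats::setNames(integer(d), chars)
    p_conf <- p_rej <- stats::setNames(rep(NA_real_, d), chars)
    hist_imp <- matrix(NA_real_, 0, d, dimnames = list(NULL, chars))
    hist_shadow <- numeric(0)
    y <- factor(labels)
    for (run in seq_len(max_runs)) {
      active <- chars[decision == "Tentative"]
      if (!length(active)) break
      Xa <- X[, active, drop = FALSE]
      Sh <- apply(Xa, 2, sample)
      # keep at least 5 shadows so the best-shadow bar stays meaningful
      # when few characters remain in play
      while (ncol(Sh) < 5) Sh <- cbind(Sh, apply(Xa, 2, sample))
      colnames(Sh) <- paste0(".shadow.", seq_len(ncol(Sh)))
      df <- data.frame(Xa, Sh, check.names = FALSE)
      df$.group <- y
      rf <- ranger::ranger(dependent.variable.name = ".group", data = df,
                           num.trees = n_trees, importance = "permutation",
                           num.threads = 1,
                           seed = sample.int(.Machine$integer.max, 1))
      imp <- rf$variable.importance
      shadow_max <- max(imp[startsWith(names(imp), ".shadow.")])
      real_imp <- imp[active]
      hit <- real_imp > shadow_max
      hits[active] <- hits[active] + hit
      runs[active] <- runs[active] + 1L
      row <- rep(NA_real_, d); names(row) <- chars
      row[active] <- real_imp
      hist_imp <- rbind(hist_imp, row)
      hist_shadow <- c(hist_shadow, shadow_max)
      # binomial decisions; Bonferroni over the full original character
      # set, so the familywise bar does not weaken as characters leave
      # the game
      pc <- stats::pbinom(hits[active] - 1L, runs[active], 0.5,
                          lower.tail = FALSE)
      pr <- stats::pbinom(hits[active], runs[active], 0.5)
      p_conf[active] <- pmin(pc * d, 1)
      p_rej[active] <- pmin(pr * d, 1)
      decision[active][p_conf[active] < alpha] <- "Confirmed"
      decision[active][p_rej[active] < alpha] <- "Rejected"
    }
    structure(list(
      decision = data.frame(character = chars, decision = unname(decision),
                            hits = unname(hits), runs = unname(runs),
                            p_confirm = unname(p_conf),
                            p_reject = unname(p_rej),
                            stringsAsFactors = FALSE),
      importance_history = hist_imp, shadow_max_history = hist_shadow,
      groups = levels(y), alpha = alpha, n_trees = n_trees, seed = seed),
      class = "boruta_result")
  })
}

#' @export
print.boruta_result <- function(x, ...) {
  cat("Shadow-feature character selection (groups:",
      paste(x$groups, collapse = ", "), ")\n")
  for (dec in c("Confirmed", "Tentative", "Rejected")) {
    ch <- x$decision$character[x$decision$decision == dec]
    if (length(ch)) cat(sprintf("  %-9s %s\n", paste0(dec, ":"),
                                paste(ch, collapse = ", ")))
  }
  invisible(x)
}

#' Univariate tests of character differences between groups
#'
#' Per-character two-sample tests (Welch's t by default, Student's t, or
#' one-way ANOVA for more than two groups), with a multiplicity
#' adjustment across the characters. Characters with zero variance in all
#' compared groups are reported with `NA` statistics.
#'
#' @param X numeric matrix, specimens x characters, or a
#'   `morpho_corrected` / `morpho_dataset`.
#' @param labels group label per specimen.
#' @param groups the two groups to compare (required for the t-tests;
#'   `anova` accepts more).
#' @param test `"welch-t"`, `"student-t"` or `"anova"`.
#' @param adjust `"none"`, `"bonferroni"`, `"holm"` or `"bh"`.
#' @param alpha significance level for the `significant` flag (applied to
#'   the raw p by default, mirroring common figure annotation; the
#'   adjusted column is always reported alongside).
#' @param flag_on flag significance on `"raw"` or `"adjusted"` p.
#' @return A data frame of class `univariate_table`: per character the
#'   statistic, df, raw and adjusted p, and significance flag.
#' @export
univariate_tests <- function(X, labels, groups = NULL,
                             test = c("welch-t", "student-t", "anova"),
                             adjust = c("none", "bonferroni", "holm", "bh"),
                             alpha = 0.05, flag_on = c("raw", "adjusted")) {
  if (inherits(X, c("morpho_dataset", "morpho_corrected"))) {
    if (is.null(labels)) labels <- X$otu
    X <- X$characters
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  flag_on <- match.arg(flag_on)
  if (is.null(groups)) groups <- sort(unique(labels))
  if (test != "anova" && length(groups) != 2)
    stop("t-tests compare exactly two groups; use test = \"anova\" for more")
  keep <- labels %in% groups
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  if (min(table(labels)) < 2) stop("every compared group needs >= 2 specimens")
  res <- do.call(rbind, lapply(colnames(X), function(ch) {
    v <- X[, ch]
    row <- function(statistic, df, p)
      data.frame(character = ch, statistic = statistic, df = df, p = p,
                 stringsAsFactors = FALSE)
    if (test == "anova") {
      return(tryCatch({
        s <- summary(stats::aov(v ~ factor(labels)))[[1]]
        row(s$`F value`[1], s$Df[1], s$`Pr(>F)`[1])
      }, error = function(e) row(NA_real_, NA_real_, NA_real_)))
    }
    v1 <- v[labels == groups[1]]
    v2 <- v[labels == groups[2]]
    if (stats::var(v1) == 0 && stats::var(v2) == 0) {
      # statistic undefined when spreads vanish; identical groups get t = 0
      if (mean(v1) == mean(v2)) return(row(0, NA_real_, 1))
      return(row(NA_real_, NA_real_, NA_real_))
    }
    tt <- stats::t.test(v1, v2, var.equal = (test == "student-t"))
    row(unname(tt$statistic), unname(tt$parameter), tt$p.value)
  }))
  res$p_adjusted <- stats::p.adjust(res$p, method = switch(adjust,
    none = "none", bonferroni = "bonferroni", holm = "holm", bh = "BH"))
  pflag <- if (flag_on == "raw") res$p else res$p_adjusted
  res$significant <- !is.na(pflag) & pflag < alpha
  attr(res, "groups") <- groups
  attr(res, "test") <- test
  attr(res, "alpha") <- alpha
  class(res) <- c("univariate_table", "data.frame")
  res
}

#' Cross-classify diagnostic power against mean differences
#'
#' Merges a shadow-feature selection result with a univariate test table
#' and labels each character by the agreement between the two views: a
#' character may be diagnostic (high discriminatory power) without a
#' significant mean shift, and vice versa.
#'
#' @param boruta a [boruta_select()] result.
#' @param uni a [univariate_tests()] table over the same characters.
#' @return Data frame with the Boruta decision, the significance flag and
#'   an `agreement` label: `"concordant diagnostic"` (Confirmed +
#'   significant), `"discriminatory, not mean-shifted"` (Confirmed +
#'   non-significant), `"mean-shifted, weak classifier"` (Rejected +
#'   significant), `"concordant non-diagnostic"` (Rejected +
#'   non-significant); Tentative characters are labelled
#'   `"undecided"`.
#' @export
diagnostic_report <- function(boruta, uni) {
  stopifnot(inherits(boruta, "boruta_result"),
            inherits(uni, "univariate_table"))
  b <- boruta$decision
  if (!setequal(b$character, uni$character))
    stop("character sets differ between the selection and the test table")
  m <- merge(b[, c("character", "decision")],
             uni[, c("character", "p", "p_adjusted", "significant")],
             by = "character")
  m$agreement <- ifelse(m$decision == "Tentative", "undecided",
    ifelse(m$decision == "Confirmed",
           ifelse(m$significant, "concordant diagnostic",
                  "discriminatory, not mean-shifted"),
           ifelse(m$significant, "mean-shifted, weak classifier",
                  "concordant non-diagnostic")))
  m
}
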