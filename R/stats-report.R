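## Group-comparison wrappers with the study's nested mixed-model contract,
## contingency tests and report assembly. Standard tests are delegated to
## stats::wilcox.test / t.test / fisher.test; this module owns the
## contracts, the nesting design and the reporting.

.test_result <- function(test, statistic, p, nPerGroup, effect) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  list(test = test, statistic = unname(statistic), p_value = unname(p),
       n_per_group = nPerGroup, effect = effect)
}

#' Two-group comparison
#'
#' \code{rank_sum}: two-sided Wilcoxon rank-sum test, exact when the pooled
#' sample is at most 20 and tie-free, midranks with normal approximation
#' and continuity correction otherwise. \code{t_two_sample}: Welch
#' two-sample t test. Swapping the groups flips the effect sign and leaves
#' the p value unchanged.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param method "rank_sum" or "t_two_sample".
#' @return A TestResult list: test, statistic, p_value, n_per_group,
#'   effect (difference of medians for rank_sum, of means for the t test).
#' @export
compareGroups <- function(a, b, method = c("rank_sum", "t_two_sample")) {
  method <- match.arg(method)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (method == "rank_sum") {
    pooled <- c(a, b)
    if (stats::sd(pooled) == 0) {
      warning("constant pooled data: rank-sum p fixed at 1")
      return(.test_result("rank_sum", NA_real_, 1,
                          c(length(a), length(b)), 0))
    }
    exact <- (length(pooled) <= 20L) && !anyDuplicated(pooled)
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    .test_result("rank_sum", wt$statistic, wt$p.value,
                 c(length(a), length(b)),
                 stats::median(a) - stats::median(b))
  } else {
    tt <- stats::t.test(a, b)
    .test_result("t_two_sample", tt$statistic, tt$p.value,
                 c(length(a), length(b)), mean(a) - mean(b))
  }
}

#' One-sample t test against a reference constant
#'
#' @param values numeric sample (n >= 2, non-degenerate).
#' @param reference reference value, e.g. the tutor playback's syllable
#'   rate.
#' @return A TestResult list; zero-variance input yields a degenerate
#'   flagged result (p = 0 when off the reference, p = 1 on it) rather than
#'   an error.
#' @export
oneSampleTest <- function(values, reference) {
  stopifnot(length(values) >= 2L)
  if (stats::sd(values) == 0) {
    on_ref <- isTRUE(all.equal(values[1], reference))
    res <- .test_result("one_sample_t", if (on_ref) 0 else Inf,
                        if (on_ref) 1 else 0, length(values),
                        mean(values) - reference)
    res$degenerate <- TRUE
    return(res)
  }
  tt <- stats::t.test(values, mu = reference)
  res <- .test_result("one_sample_t", tt$statistic, tt$p.value,
                      length(values), mean(values) - reference)
  res$degenerate <- FALSE
  res
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p value by summing hypergeometric probabilities no
#' larger than the observed table's.
#'
#' @param counts 2x2 matrix (or length-4 vector, filled column-wise) of
#'   non-negative integer counts.
#' @return A TestResult list (statistic = odds-ratio estimate). A table
#'   with an all-zero margin gives p = 1.
#' @export
fisher2x2 <- function(counts) {
  m <- matrix(as.numeric(counts), 2, 2)
  stopifnot(all(m >= 0), all(m == round(m)))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(.test_result("fisher_exact", NA_real_, 1, rowSums(m), NA_real_))
  ft <- stats::fisher.test(m)
  .test_result("fisher_exact", ft$estimate, ft$p.value, rowSums(m),
               unname(ft$estimate))
}

#' Nested mixed-model comparison
#'
#' Fits \code{response ~ 1 + condition + (1 | outer) + (1 | outer:inner)}
#' by maximum likelihood (the study design: neurons nested in birds for
#' neural metrics, birds nested in fathers for behavioral ones) and
#' reports the condition fixed effect with a two-sided Wald p value.
#'
#' When the nesting is singular in the strong sense — one inner group per
#' observation — the inner random intercept is dropped with a warning and
#' an outer-only model is fitted instead.
#'
#' @param data data.frame containing the model columns.
#' @param response,condition,outer,inner column names (condition may be a
#'   factor or numeric; the reported effect is for its second level or unit
#'   change).
#' @return list with \code{estimate}, \code{se}, \code{z}, \code{p_value},
#'   \code{varcomp} (named variance components), \code{fallback} (TRUE when
#'   the inner term was dropped) and the fitted \code{model}.
#' @export
fitNestedLmm <- function(data, response, condition, outer, inner) {
  stopifnot(all(c(response, condition, outer, inner) %in% names(data)))
  if (length(unique(data[[outer]])) < 2L)
    stop("fitNestedLmm needs at least 2 outer groups")
  data <- as.data.frame(data)
  if (stats::var(data[[response]]) == 0) {
    # constant response: every effect is exactly zero and the mixed model
    # is degenerate; report the trivial fit directly
    return(list(estimate = 0, se = 0, z = NA_real_, p_value = 1,
                varcomp = c(Residual = 0), fallback = FALSE, model = NULL))
  }
  data$.inner_nested <- interaction(data[[outer]], data[[inner]], drop = TRUE)
  fallback <- length(levels(data$.inner_nested)) >= nrow(data)
  f_full <- stats::as.formula(sprintf(
    "%s ~ 1 + %s + (1 | %s) + (1 | .inner_nested)", response, condition, outer))
  f_outer <- stats::as.formula(sprintf(
    "%s ~ 1 + %s + (1 | %s)", response, condition, outer))
  if (fallback) {
    warning("one inner group per observation: dropping the nested ",
            "intercept and fitting the outer-only model")
    fit <- lme4::lmer(f_outer, data = data, REML = FALSE)
  } else {
    fit <- lme4::lmer(f_full, data = data, REML = FALSE)
  }
  cf <- summary(fit)$coefficients
  # the condition effect is the first non-intercept coefficient
  row <- setdiff(rownames(cf), "(Intercept)")[1]
  est <- cf[row, "Estimate"]
  se <- cf[row, "Std. Error"]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  list(estimate = unname(est), se = unname(se), z = unname(z),
       p_value = unname(p), varcomp = varcomp, fallback = fallback,
       model = fit)
}

#' Assemble a Markdown report of pipeline outputs
#'
#' Collects whatever stage outputs are supplied (session summaries, trend
#' results, per-cell intracellular tables, population unit tables,
#' perturbation results, ad-hoc test results) into one human-readable
#' Markdown document with a config echo and the seed. Missing stages are
#' marked absent; with \code{strict = TRUE} a missing stage is an error.
#' The body is deterministic for identical inputs (no timestamps).
#'
#' @param stages named list; recognised names: \code{session_summaries},
#'   \code{trend}, \code{intracellular}, \code{population},
#'   \code{perturbation}, \code{tests}.
#' @param cfg the [runConfig()] used for the run.
#' @param path optional output file; when NULL the lines are returned.
#' @param strict error on missing stages.
#' @return character vector of Markdown lines (invisibly when written).
#' @export
buildReport <- function(stages = list(), cfg = runConfig(), path = NULL,
                        strict = FALSE) {
  expected <- c("session_summaries", "trend", "intracellular",
                "population", "perturbation", "tests")
  fmt_df <- function(df) {
    if (!nrow(df)) return("(empty table)")
    hdr <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    body <- apply(df, 1, function(r)
      paste(vapply(r, function(x) {
        xx <- suppressWarnings(as.numeric(x))
        if (!is.na(xx)) format(xx, digits = 4) else as.character(x)
      }, character(1)), collapse = " | "))
    c(paste("|", hdr, "|"), paste("|", sep, "|"), paste("|", body, "|"))
  }
  lines <- c("# finchvocal run report", "",
             "## Configuration", "",
             paste0("- ", names(unclass(cfg)), ": ",
                    vapply(unclass(cfg), format, character(1))), "")
  for (s in expected) {
    lines <- c(lines, sprintf("## %s", s), "")
    x <- stages[[s]]
    if (is.null(x)) {
      if (strict) stop("missing stage output: ", s)
      lines <- c(lines, "_absent_", "")
    } else if (is.data.frame(x)) {
      lines <- c(lines, fmt_df(x), "")
    } else {
      flat <- unlist(x)
      lines <- c(lines, paste0("- ", names(flat), ": ",
                               vapply(flat, format, character(1))), "")
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
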