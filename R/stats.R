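#' Rank-based ordered-quantile normalizing transform
#'
#' Maps values to normal quantiles by rank: `qnorm((rank - 0.5) / n)`, with
#' ties sharing the average rank. The output is approximately standard
#' normal for any continuous input and preserves order exactly; it is the
#' deterministic default of the ordered-quantile family of normalizing
#' transforms and is applied to PTE and power values before mixed-effects
#' modelling (both are strongly right-skewed).
#'
#' @param x numeric vector, `n >= 3`, not all equal.
#' @return transformed vector of the same length.
#' @export
normalize_orq <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) abort("need at least 3 values to normalize.")
  if (!all(is.finite(x))) abort("values must be finite.")
  if (max(x) == min(x)) abort("all values identical; normalization undefined.")
  qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Two-condition contrast with subject random intercepts
#'
#' Fits `value ~ condition + (1 | subject)` (REML, Satterthwaite df) on an
#' observation table and reports the condition F test, effect direction and
#' Cohen's d (`2 * sqrt(F) / sqrt(df2)`, signed by direction). Observations
#' are one value per subject x pair x condition; average across trials
#' before building the table. With a single subject (or a singular
#' random-effect fit) the model falls back to a fixed-effects ANOVA with a
#' warning.
#'
#' @param table tibble with columns `value`, `condition` (exactly 2 levels),
#'   `subject`, and optionally `pair`.
#' @param normalize apply [normalize_orq()] to `value` first (default TRUE).
#' @return a `cond_contrast` object: list with `f`, `df1`, `df2`, `p`, `d`,
#'   `direction` (the condition level with the larger mean), `levels`,
#'   `method`, and the underlying `fit`. Has [tidy()]/[glance()] methods.
#' @export
condition_contrast <- function(table, normalize = TRUE) {
  table <- as_tibble(table)
  need <- c("value", "condition", "subject")
  if (!all(need %in% names(table))) {
    abort(paste0("observation table needs columns: ", paste(need, collapse = ", ")))
  }
  levs <- sort(unique(as.character(table$condition)))
  if (length(levs) != 2L) abort("`condition` must have exactly 2 levels.")
  df <- table
  if (normalize) df$value <- normalize_orq(df$value)
  df$condition <- factor(df$condition, levels = levs)
  df$subject <- factor(df$subject)

  means <- tapply(df$value, df$condition, mean)
  direction <- names(means)[which.max(means)]

  single_subject <- length(unique(df$subject)) < 2L
  fit <- NULL
  method <- "lmm"
  if (!single_subject) {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(value ~ condition + (1 | subject), data = df)),
      error = function(e) NULL
    )
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-4)) {
      warn("singular random-effect fit; falling back to fixed-effects ANOVA.")
      fit <- NULL
    }
  } else {
    warn("single subject; falling back to fixed-effects ANOVA.")
  }
  if (is.null(fit)) {
    method <- "anova"
    fit <- stats::lm(value ~ condition, data = df)
    an <- stats::anova(fit)
    f <- an[["F value"]][1]; df1 <- an$Df[1]; df2 <- an$Df[2]
    p <- an[["Pr(>F)"]][1]
  } else {
    an <- stats::anova(fit)   # lmerTest: Satterthwaite F test
    f <- an[["F value"]][1]; df1 <- an$NumDF[1]; df2 <- an$DenDF[1]
    p <- an[["Pr(>F)"]][1]
  }
  f <- max(f, 0)
  d <- 2 * sqrt(f) / sqrt(df2)
  structure(
    list(
      f = f, df1 = df1, df2 = df2, p = p, d = d,
      direction = direction, levels = levs, method = method, fit = fit,
      n = nrow(df)
    ),
    class = "cond_contrast"
  )
}

#' @export
print.cond_contrast <- function(x, ...) {
  cat(sprintf(
    "<cond_contrast> F(%g, %.1f) = %.3f, p = %.3g, Cohen's d = %.3f (higher: %s)%s\n",
    x$df1, x$df2, x$f, x$p, x$d, x$direction,
    if (x$method == "anova") " [fixed-effects fallback]" else ""
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cond_contrast <- function(x, ...) {
  tibble(
    term = "condition", statistic = x$f, df1 = x$df1, df2 = x$df2,
    p.value = x$p, cohens_d = x$d, direction = x$direction
  )
}

#' @exportS3Method generics::glance
glance.cond_contrast <- function(x, ...) {
  tibble(nobs = x$n, method = x$method, df2 = x$df2, p.value = x$p)
}

#' Cohen's d from a t statistic
#'
#' `d = 2 * t / sqrt(df)` for a two-condition contrast.
#'
#' @param t t statistic.
#' @param df degrees of freedom (> 0).
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, df) {
  if (df <= 0) abort("`df` must be positive.")
  2 * t / sqrt(df)
}

#' Cohen's d from a 1-df F statistic
#'
#' For a condition effect with 1 numerator df, `t = sqrt(F)` and
#' `d = 2 * sqrt(F) / sqrt(df2)`.
#'
#' @param f F statistic (>= 0).
#' @param df2 denominator degrees of freedom (> 0).
#' @return Cohen's d (unsigned).
#' @export
cohens_d_from_f <- function(f, df2) {
  if (df2 <= 0) abort("`df2` must be positive.")
  if (f < 0) abort("`f` must be non-negative.")
  cohens_d_from_t(sqrt(f), df2)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate control: returns BH-adjusted p-values and
#' the rejection mask at level `alpha`.
#'
#' @param pvals p-values in `[0, 1]` (may be empty).
#' @param alpha FDR level (default 0.05).
#' @return tibble with columns `p`, `p_adj`, `reject`.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) {
    return(tibble(p = numeric(), p_adj = numeric(), reject = logical()))
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  adj <- p.adjust(pvals, method = "BH")
  tibble(p = pvals, p_adj = adj, reject = adj <= alpha)
}

# ML fits for the BIC Bayes-factor approximation; fixed-effects fallback
# mirrors condition_contrast.
bf10_from_table <- function(df) {
  single_subject <- length(unique(df$subject)) < 2L
  if (!single_subject) {
    fit1 <- tryCatch(
      suppressMessages(lme4::lmer(value ~ condition + (1 | subject), data = df, REML = FALSE)),
      error = function(e) NULL
    )
    fit0 <- tryCatch(
      suppressMessages(lme4::lmer(value ~ 1 + (1 | subject), data = df, REML = FALSE)),
      error = function(e) NULL
    )
    if (!is.null(fit1) && !is.null(fit0)) {
      return(exp((BIC(fit0) - BIC(fit1)) / 2))
    }
  }
  fit1 <- stats::lm(value ~ condition, data = df)
  fit0 <- stats::lm(value ~ 1, data = df)
  exp((BIC(fit0) - BIC(fit1)) / 2)
}

#' Bayes factor for the condition effect
#'
#' Evidence for `value ~ condition + (1 | subject)` against the null
#' `value ~ 1 + (1 | subject)` (both with subject intercepts, fitted by
#' maximum likelihood), via the BIC approximation to the marginal-likelihood
#' ratio: `BF10 = exp((BIC0 - BIC1) / 2)`. Strictly positive; values > 1
#' favour a condition effect.
#'
#' @inheritParams condition_contrast
#' @return BF10 (scalar, > 0).
#' @export
bayes_factor_condition <- function(table, normalize = TRUE) {
  table <- as_tibble(table)
  levs <- sort(unique(as.character(table$condition)))
  if (length(levs) != 2L) abort("`condition` must have exactly 2 levels.")
  df <- table
  if (normalize) df$value <- normalize_orq(df$value)
  df$condition <- factor(df$condition, levels = levs)
  df$subject <- factor(df$subject)
  bf <- bf10_from_table(df)
  if (!is.finite(bf) || bf <= 0) abort("degenerate Bayes-factor fit.")
  bf
}

#' Replication Bayes factor ratio
#'
#' Quantifies how much a replication dataset strengthens the evidence for a
#' condition effect established in an original dataset:
#' `ratio = BF10(original + replication) / BF10(original)`, each BF from
#' [bayes_factor_condition()]. A ratio of at least 3 is taken as evidence
#' for replication, at least 100 as decisive.
#'
#' @param original,replication observation tables with identical condition
#'   coding (`value`, `condition`, `subject`; subjects may overlap —
#'   replication subjects are suffixed to keep grouping distinct).
#' @param normalize normalize values within each fitted table (default TRUE).
#' @return a `replication_bf`: list with `bf_original`, `bf_joint`, `ratio`,
#'   `verdict` (`"not replicated"`, `"replicated"` or `"decisive"`).
#' @export
replication_bf <- function(original, replication, normalize = TRUE) {
  original <- as_tibble(original)
  replication <- as_tibble(replication)
  if (!nrow(replication)) abort("replication table is empty.")
  if (!setequal(unique(original$condition), unique(replication$condition))) {
    abort("original and replication must use the same condition coding.")
  }
  joint <- bind_rows(
    original |> mutate(subject = paste0("orig_", .data$subject)),
    replication |> mutate(subject = paste0("repl_", .data$subject))
  )
  bf_orig <- bayes_factor_condition(original, normalize = normalize)
  bf_joint <- bayes_factor_condition(joint, normalize = normalize)
  ratio <- bf_joint / bf_orig
  verdict <- if (ratio >= 100) "decisive" else if (ratio >= 3) "replicated" else "not replicated"
  structure(
    list(
      bf_original = bf_orig, bf_joint = bf_joint,
      ratio = ratio, verdict = verdict
    ),
    class = "replication_bf"
  )
}

#' @export
print.replication_bf <- function(x, ...) {
  cat(sprintf(
    "<replication_bf> BF10(original) = %.3g, BF10(joint) = %.3g, ratio = %.3g -> %s\n",
    x$bf_original, x$bf_joint, x$ratio, x$verdict
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.replication_bf <- function(x, ...) {
  tibble(
    bf_original = x$bf_original, bf_joint = x$bf_joint,
    ratio = x$ratio, verdict = x$verdict
  )
}

#' Build a direction-contrast observation table from PTE results
#'
#' Extracts, for a region pair (A, B), the trial-averaged PTE of the two
#' directions A->B and B->A as a two-condition observation table ready for
#' [condition_contrast()] / [bayes_factor_condition()]. Each electrode pair
#' contributes one value per direction; condition labels are `"A->B"` and
#' `"B->A"`.
#'
#' @param result a `pte_result` (possibly row-bound across subjects).
#' @param region_a,region_b region labels.
#' @return observation tibble: `value`, `condition`, `subject`, `pair`,
#'   `task`.
#' @export
direction_table <- function(result, region_a, region_b) {
  fwd <- result |>
    filter(.data$source_region == region_a, .data$target_region == region_b) |>
    mutate(condition = paste0(region_a, "->", region_b))
  rev <- result |>
    filter(.data$source_region == region_b, .data$target_region == region_a) |>
    mutate(condition = paste0(region_b, "->", region_a))
  out <- bind_rows(fwd, rev)
  if (!nrow(out)) abort("no pairs link the requested regions.")
  out |>
    mutate(
      value = .data$pte_mean,
      pair = paste(
        pmin(.data$source_channel, .data$target_channel),
        pmax(.data$source_channel, .data$target_channel),
        sep = "|"
      )
    ) |>
    select("value", "condition", "subject", "pair", "task")
}

#' Build a task-vs-rest observation table from PTE results
#'
#' Combines task-condition and rest-condition PTE results for the same
#' directed pairs into a two-condition table (`"task"` vs `"rest"`).
#'
#' @param task_result,rest_result `pte_result` tibbles.
#' @return observation tibble: `value`, `condition`, `subject`, `pair`,
#'   `task`.
#' @export
task_rest_table <- function(task_result, rest_result) {
  mk <- function(res, lab) {
    res |>
      mutate(
        value = .data$pte_mean, condition = lab,
        pair = paste(.data$source_channel, .data$target_channel, sep = ">")
      ) |>
      select("value", "condition", "subject", "pair", "task")
  }
  bind_rows(mk(task_result, "task"), mk(rest_result, "rest"))
}
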