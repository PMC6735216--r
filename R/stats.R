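strategy_cols <- c("sm1_4", "sm1_5", "erd")

#' Published per-subject classification accuracies
#'
#' The per-subject offline accuracies (in percent) of the three
#' channel-selection strategies for the ten subjects with detectable
#' paretic-hand ERD, together with their topography group and the channels
#' each strategy selected. Shipped as a plain-text fixture so the statistics
#' stage runs without any external data.
#'
#' @return A tibble of class `accuracy_table` with columns `subject`,
#'   `group` (`"proliferation"`, `"SM1"`, `"others"`), `sm1_4`, `sm1_5`,
#'   `erd` (accuracies in percent) and the `*_channels` strings.
#' @examples
#' published_accuracies()
#' @export
published_accuracies <- function() {
  path <- system.file("extdata", "strategy_accuracies.csv", package = "erdtopo",
                      mustWork = TRUE)
  as_accuracy_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Validate and classify a strategy-accuracy table
#'
#' @param x A data frame with columns `subject`, `group`, `sm1_4`, `sm1_5`
#'   and `erd` (accuracies in percent).
#' @return A tibble of class `accuracy_table`.
#' @export
as_accuracy_table <- function(x) {
  x <- as_tibble(x)
  needed <- c("subject", "group", strategy_cols)
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("accuracy table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  acc <- as.matrix(x[strategy_cols])
  if (anyNA(acc)) abort("accuracy table has missing cells.")
  if (any(acc < 0 | acc > 100)) {
    abort("accuracies must be percentages in [0, 100].")
  }
  structure(x, class = c("accuracy_table", class(as_tibble(x))))
}

#' Mean and standard deviation of accuracy per strategy
#'
#' Per-strategy mean and sample standard deviation (n - 1 denominator),
#' overall and within each topography group. A single-subject scope reports
#' an SD of 0 flagged as undefined.
#'
#' @param table An [as_accuracy_table()] (e.g. [published_accuracies()]).
#' @return A tibble with columns `scope` (`"overall"` or a group label),
#'   `strategy`, `n`, `mean`, `sd` and `sd_defined`.
#' @export
group_summary <- function(table) {
  table <- as_accuracy_table(table)
  if (nrow(table) == 0L) abort("empty accuracy table.")
  long <- tidyr::pivot_longer(
    as_tibble(table)[c("subject", "group", strategy_cols)],
    dplyr::all_of(strategy_cols),
    names_to = "strategy", values_to = "accuracy"
  )
  summarize_scope <- function(df, scope) {
    dplyr::summarise(
      dplyr::group_by(df, .data$strategy),
      n = dplyr::n(),
      mean = mean(.data$accuracy),
      sd = if (dplyr::n() > 1) sd(.data$accuracy) else 0,
      .groups = "drop"
    ) |>
      dplyr::mutate(scope = scope, sd_defined = .data$n > 1)
  }
  out <- dplyr::bind_rows(
    summarize_scope(long, "overall"),
    dplyr::bind_rows(lapply(
      split(long, long$group),
      function(df) summarize_scope(df, df$group[1])
    ))
  )
  out$strategy <- factor(out$strategy, levels = strategy_cols)
  dplyr::arrange(
    dplyr::select(out, "scope", "strategy", "n", "mean", "sd", "sd_defined"),
    .data$scope != "overall", .data$scope, .data$strategy
  )
}

#' One-way repeated-measures ANOVA across strategies
#'
#' Partitions the total sum of squares of the subject x strategy accuracy
#' matrix into subject, strategy and residual (subject x strategy) terms and
#' tests the strategy effect with
#' `F = MS_strategy / MS_error` on `(s - 1, (s - 1)(n - 1))` degrees of
#' freedom -- the within-subject design in which every subject contributes
#' one accuracy per strategy.
#'
#' @param table An [as_accuracy_table()].
#' @return An object of class `rm_anova` with the SS partition, `statistic`
#'   (F), `df_effect`, `df_error` and `p_value`.
#' @export
rm_anova <- function(table) {
  table <- as_accuracy_table(table)
  acc <- as.matrix(as_tibble(table)[strategy_cols])
  n <- nrow(acc)
  s <- ncol(acc)
  if (n < 2L) abort("repeated-measures ANOVA needs at least 2 subjects.")
  gm <- mean(acc)
  ss_subject <- s * sum((rowMeans(acc) - gm)^2)
  ss_strategy <- n * sum((colMeans(acc) - gm)^2)
  ss_total <- sum((acc - gm)^2)
  ss_error <- ss_total - ss_subject - ss_strategy
  df_effect <- s - 1L
  df_error <- (s - 1L) * (n - 1L)
  ms_strategy <- ss_strategy / df_effect
  ms_error <- ss_error / df_error
  statistic <- if (ms_error > 0) ms_strategy / ms_error else {
    if (ms_strategy == 0) 0 else Inf
  }
  structure(
    list(
      statistic = statistic,
      df_effect = df_effect,
      df_error = df_error,
      p_value = stats::pf(statistic, df_effect, df_error, lower.tail = FALSE),
      ss = tibble(
        term = c("subject", "strategy", "error"),
        df = c(n - 1L, df_effect, df_error),
        sumsq = c(ss_subject, ss_strategy, ss_error)
      ),
      n_subjects = n,
      n_strategies = s
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.4g (%d subjects, %d strategies)\n",
    x$df_effect, x$df_error, x$statistic, x$p_value, x$n_subjects,
    x$n_strategies
  ))
  invisible(x)
}

#' Tidy the repeated-measures ANOVA partition
#'
#' @param x An [rm_anova()] result.
#' @param ... Unused.
#' @return A tibble with one row per term (`subject`, `strategy`, `error`)
#'   giving `df`, `sumsq`, `meansq` and, for the strategy term, `statistic`
#'   and `p.value`.
#' @exportS3Method generics::tidy
#' @export
tidy.rm_anova <- function(x, ...) {
  out <- dplyr::mutate(x$ss, meansq = .data$sumsq / .data$df)
  out$statistic <- ifelse(out$term == "strategy", x$statistic, NA_real_)
  out$p.value <- ifelse(out$term == "strategy", x$p_value, NA_real_)
  out
}

#' One-row summary of the repeated-measures ANOVA
#'
#' @param x An [rm_anova()] result.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df_effect`, `df_error`,
#'   `p.value` and the design size.
#' @exportS3Method generics::glance
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    df_effect = x$df_effect,
    df_error = x$df_error,
    p.value = x$p_value,
    n_subjects = x$n_subjects
  )
}

#' Bonferroni-corrected paired post-hoc comparisons
#'
#' Two-sided paired t tests between every pair of strategies with the
#' Bonferroni correction (p multiplied by the number of pairs, capped at 1).
#' A zero-variance difference vector is a degenerate case: it is flagged,
#' with p = 1 when the two strategies are identical and p = 0 when they
#' differ by a nonzero constant.
#'
#' @param table An [as_accuracy_table()].
#' @return A tibble with columns `pair`, `estimate` (mean difference),
#'   `statistic`, `df`, `p_value`, `p_adjusted` and `degenerate`.
#' @export
bonferroni_paired <- function(table) {
  table <- as_accuracy_table(table)
  acc <- as.matrix(as_tibble(table)[strategy_cols])
  if (nrow(acc) < 2L) abort("paired tests need at least 2 subjects.")
  pairs <- utils::combn(strategy_cols, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    d <- acc[, pr[1]] - acc[, pr[2]]
    if (sd(d) == 0) {
      return(tibble(
        pair = paste(pr, collapse = " vs "),
        estimate = mean(d), statistic = NA_real_,
        df = length(d) - 1L,
        p_value = if (mean(d) == 0) 1 else 0,
        degenerate = TRUE
      ))
    }
    ht <- stats::t.test(acc[, pr[1]], acc[, pr[2]], paired = TRUE)
    tibble(
      pair = paste(pr, collapse = " vs "),
      estimate = unname(ht$estimate), statistic = unname(ht$statistic),
      df = unname(ht$parameter), p_value = ht$p.value,
      degenerate = FALSE
    )
  })
  rows$p_adjusted <- pmin(1, rows$p_value * length(pairs))
  rows[c("pair", "estimate", "statistic", "df", "p_value", "p_adjusted",
         "degenerate")]
}
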