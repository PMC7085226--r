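#' Summarize one metric for one treatment group
#'
#' Group results are reported as mean +/- sample standard deviation
#' (`n - 1` denominator), the convention of the published study table.
#'
#' @param values Numeric vector of per-sample values (>= 2 finite values).
#' @param group `"pre"` or `"post"`.
#' @param metric `"nuclear_area_px2"` or `"collagen_content_pct"` (any other
#'   label is accepted but these two are the study's endpoints).
#' @return A one-row tibble of class `group_summary`: `group`, `metric`, `n`,
#'   `mean`, `sd`.
#' @examples
#' summarize_metric(c(1, 3), "pre", "nuclear_area_px2")
#' @export
summarize_metric <- function(values, group = c("pre", "post"),
                             metric = "nuclear_area_px2") {
  group <- match.arg(group)
  values <- values[!is.na(values)]
  if (length(values) < 2L || any(!is.finite(values))) {
    stop("at least 2 finite values are required to summarize a group", call. = FALSE)
  }
  structure(
    tibble::tibble(
      group = group, metric = metric,
      n = length(values), mean = mean(values), sd = sd(values)
    ),
    class = c("group_summary", class(tibble::tibble()))
  )
}

new_group_summary <- function(n, mean, sd, group = "pre", metric = "metric") {
  stopifnot(n >= 2L, sd >= 0)
  structure(
    tibble::tibble(group = group, metric = metric, n = as.integer(n), mean = mean, sd = sd),
    class = c("group_summary", class(tibble::tibble()))
  )
}

#' Two-sample t-test from group summaries
#'
#' Computes the two-sided two-sample t-test directly from per-group
#' `(n, mean, sd)`, which is how the published group table can be re-tested
#' without per-sample data. The pooled (Student) variant uses
#' `t = (mean_b - mean_a) / (s_p * sqrt(1/n_a + 1/n_b))` with the pooled SD
#' `s_p` and `df = n_a + n_b - 2`; the Welch variant uses the unpooled
#' standard error with Satterthwaite degrees of freedom. With equal group
#' sizes the two t statistics coincide (the df differ).
#'
#' Degenerate inputs follow a documented convention: zero pooled SD with
#' equal means gives `t = 0, p = 1`; zero SD with unequal means gives an
#' infinite t, a p-value reported at the smallest positive double, and
#' `degenerate = TRUE`.
#'
#' @param a,b Group summaries from [summarize_metric()] (or any one-row data
#'   frame with `n`, `mean`, `sd`). `a` is conventionally the pre-treatment
#'   group; positive `t` means `b` exceeds `a`.
#' @param variant `"pooled"` (default, classic Student) or `"welch"`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `mpm_ttest`.
#' @examples
#' pre <- summarize_metric(c(590, 600, 610), "pre")
#' post <- summarize_metric(c(850, 860, 870), "post")
#' t_test_from_summary(pre, post)
#' @export
t_test_from_summary <- function(a, b, variant = c("pooled", "welch"),
                                alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(a$n >= 2L, b$n >= 2L, a$sd >= 0, b$sd >= 0)
  diff <- b$mean - a$mean
  if (variant == "pooled") {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2) * sqrt(1 / a$n + 1 / b$n)
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- if (se > 0) {
      (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    } else {
      a$n + b$n - 2
    }
  }
  degenerate <- FALSE
  if (se == 0) {
    if (diff == 0) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(diff) * Inf
      p <- .Machine$double.xmin # below any attainable p; flagged
      degenerate <- TRUE
    }
  } else {
    t_stat <- diff / se
    p <- 2 * pt(-abs(t_stat), df)
  }
  structure(
    list(
      t_statistic = t_stat,
      degrees_of_freedom = df,
      p_value = p,
      significant = p < alpha,
      alpha = alpha,
      variant = variant,
      degenerate = degenerate,
      summary_a = a,
      summary_b = b
    ),
    class = "mpm_ttest"
  )
}

#' Two-sample t-test from raw per-sample values
#'
#' Summarizes each group with [summarize_metric()]'s conventions and then
#' delegates to [t_test_from_summary()], so the two entry points agree
#' exactly.
#'
#' @param a,b Numeric vectors of per-sample values (>= 2 finite each).
#' @inheritParams t_test_from_summary
#' @return An `mpm_ttest`.
#' @export
t_test_from_values <- function(a, b, variant = c("pooled", "welch"),
                               alpha = 0.05) {
  t_test_from_summary(
    summarize_metric(a, "pre"), summarize_metric(b, "post"),
    variant = variant, alpha = alpha
  )
}

#' @export
print.mpm_ttest <- function(x, ...) {
  p_shown <- if (x$degenerate) "< machine precision" else format_pvalue(x$p_value)
  cat(sprintf(
    "Two-sample t-test (%s): t = %.4f, df = %.4g, p %s%s\n",
    x$variant, x$t_statistic, x$degrees_of_freedom,
    if (grepl("^<", p_shown)) p_shown else paste("=", p_shown),
    if (x$significant) sprintf(" (significant at alpha = %g)", x$alpha) else ""
  ))
  invisible(x)
}

format_pvalue <- function(p) {
  if (p < 1e-4) sprintf("%.3g", p) else sprintf("%.4f", p)
}

bin_pvalue <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "<0.001",
    p < 0.01 ~ "<0.01",
    p < 0.05 ~ "<0.05",
    TRUE ~ "ns"
  )
}

#' @rdname t_test_from_summary
#' @param x An `mpm_ttest`.
#' @param ... Unused.
#' @method tidy mpm_ttest
#' @export
tidy.mpm_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$summary_b$mean - x$summary_a$mean,
    t_statistic = x$t_statistic,
    degrees_of_freedom = x$degrees_of_freedom,
    p_value = x$p_value,
    p_bin = bin_pvalue(x$p_value),
    significant = x$significant,
    variant = x$variant,
    degenerate = x$degenerate
  )
}

#' @rdname t_test_from_summary
#' @method glance mpm_ttest
#' @export
glance.mpm_ttest <- function(x, ...) {
  tidy(x)
}

#' Compare pre- and post-treatment metric tables
#'
#' Builds the study-style comparison: per metric, both group summaries (mean
#' +/- SD, n) and the two-sample t-test with its significance bin. One sample
#' contributes one value per metric — per-sample aggregation happens before
#' testing, so nuclei within an image are never treated as independent
#' replicates.
#'
#' @param pre_metrics,post_metrics Data frames with one row per sample and
#'   one numeric column per metric (any non-numeric columns, e.g.
#'   `sample_id`, are ignored). Both tables must share their metric columns.
#' @param alpha Significance level (default 0.05).
#' @inheritParams t_test_from_summary
#' @return A tibble of class `mpm_comparison`, one row per metric: group
#'   `n`/`mean`/`sd`, `t_statistic`, `degrees_of_freedom`, `p_value`,
#'   `p_bin`, `significant`.
#' @examples
#' pre <- tibble::tibble(nuclear_area_px2 = rnorm(30, 596, 209))
#' post <- tibble::tibble(nuclear_area_px2 = rnorm(30, 856, 256))
#' compare_groups(pre, post)
#' @export
compare_groups <- function(pre_metrics, post_metrics, alpha = 0.05,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  metric_cols <- function(df) {
    names(df)[vapply(df, is.numeric, logical(1)) & names(df) != "seed"]
  }
  metrics <- intersect(metric_cols(pre_metrics), metric_cols(post_metrics))
  if (length(metrics) == 0L) {
    stop("no shared numeric metric columns between the two tables", call. = FALSE)
  }
  rows <- purrr::map(metrics, function(m) {
    a <- summarize_metric(pre_metrics[[m]], "pre", m)
    b <- summarize_metric(post_metrics[[m]], "post", m)
    tt <- t_test_from_summary(a, b, variant = variant, alpha = alpha)
    tibble::tibble(
      metric = m,
      n_pre = a$n, mean_pre = a$mean, sd_pre = a$sd,
      n_post = b$n, mean_post = b$mean, sd_post = b$sd,
      t_statistic = tt$t_statistic,
      degrees_of_freedom = tt$degrees_of_freedom,
      p_value = tt$p_value,
      p_bin = bin_pvalue(tt$p_value),
      significant = tt$significant,
      variant = variant
    )
  })
  structure(dplyr::bind_rows(rows),
    class = c("mpm_comparison", class(tibble::tibble()))
  )
}
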