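test_that("group summaries use the sample SD and reject tiny samples", {
  s <- summarize_metric(c(1, 3), "pre")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$n, 2L)
  flat <- summarize_metric(c(5, 5, 5), "post")
  expect_equal(flat$sd, 0)
  expect_error(summarize_metric(7, "pre"), "at least 2")
  expect_error(summarize_metric(c(1, Inf), "pre"), "finite")
})

test_that("pooled t from the published summaries matches the closed form", {
  t1s <- table1_summaries()
  # independent oracle: pooled formula evaluated directly in this test
  oracle <- function(a, b) {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    (b$mean - a$mean) / (sqrt(sp2) * sqrt(1 / a$n + 1 / b$n))
  }
  nuc <- t_test_from_summary(
    summary_row(t1s$nuclear$pre), summary_row(t1s$nuclear$post, "post")
  )
  col <- t_test_from_summary(
    summary_row(t1s$collagen$pre), summary_row(t1s$collagen$post, "post")
  )
  expect_equal(nuc$t_statistic, oracle(t1s$nuclear$pre, t1s$nuclear$post),
    tolerance = 1e-12
  )
  expect_equal(col$t_statistic, oracle(t1s$collagen$pre, t1s$collagen$post),
    tolerance = 1e-12
  )
  # frozen high-precision values of the closed form
  expect_equal(nuc$t_statistic, 4.308669341225, tolerance = 1e-9)
  expect_equal(col$t_statistic, 4.523887361238, tolerance = 1e-9)
  expect_equal(nuc$degrees_of_freedom, 58)
  expect_equal(col$degrees_of_freedom, 58)
  expect_lt(nuc$p_value, 0.001)
  expect_lt(col$p_value, 0.001)
})

test_that("value- and summary-based tests agree to 12 significant digits", {
  withr::with_seed(101L, {
    for (rep in 1:5) {
      a <- rnorm(17, 10, 3)
      b <- rnorm(23, 12, 4)
      for (variant in c("pooled", "welch")) {
        tv <- t_test_from_values(a, b, variant = variant)
        ts <- t_test_from_summary(
          summary_row(list(n = length(a), mean = mean(a), sd = sd(a))),
          summary_row(list(n = length(b), mean = mean(b), sd = sd(b)), "post"),
          variant = variant
        )
        expect_equal(tv$t_statistic, ts$t_statistic, tolerance = 1e-12)
        expect_equal(tv$p_value, ts$p_value, tolerance = 1e-12)
        # cross-check against the reference implementation
        ref <- stats::t.test(b, a, var.equal = variant == "pooled")
        expect_equal(tv$t_statistic, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(tv$p_value, ref$p.value, tolerance = 1e-10)
        expect_equal(tv$degrees_of_freedom, unname(ref$parameter),
          tolerance = 1e-8
        )
      }
    }
  })
})

test_that("degenerate variance cases follow the documented conventions", {
  same <- t_test_from_values(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  zero_var <- t_test_from_values(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(is.infinite(zero_var$t_statistic))
  expect_true(zero_var$degenerate)
  expect_lt(zero_var$p_value, 1e-300)
  expect_true(zero_var$significant)

  id <- t_test_from_summary(
    summary_row(list(n = 10L, mean = 5, sd = 2)),
    summary_row(list(n = 10L, mean = 5, sd = 2), "post")
  )
  expect_equal(id$t_statistic, 0)
  expect_equal(id$p_value, 1)
})

test_that("t is antisymmetric and p invariant under group swap", {
  withr::with_seed(7L, {
    a <- rnorm(12, 0, 1)
    b <- rnorm(15, 0.8, 1.3)
  })
  for (variant in c("pooled", "welch")) {
    ab <- t_test_from_values(a, b, variant = variant)
    ba <- t_test_from_values(b, a, variant = variant)
    expect_equal(ab$t_statistic, -ba$t_statistic, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  }
  # equal n: pooled and Welch t coincide, dfs differ
  withr::with_seed(8L, {
    x <- rnorm(20, 0, 1)
    y <- rnorm(20, 1, 2)
  })
  expect_equal(
    t_test_from_values(x, y, "pooled")$t_statistic,
    t_test_from_values(x, y, "welch")$t_statistic,
    tolerance = 1e-12
  )
})

test_that("type-I error of the pooled test sits near the nominal level", {
  withr::with_seed(1234L, {
    hits <- replicate(1000, {
      a <- rnorm(30, 22.81, 10.23)
      b <- rnorm(30, 22.81, 10.23)
      t_test_from_values(a, b)$significant
    })
  })
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("compare_groups reproduces the study-table layout", {
  withr::with_seed(55L, {
    pre <- tibble::tibble(
      nuclear_area_px2 = rnorm(30, 596.56, 208.69),
      collagen_content_pct = rnorm(30, 22.81, 10.23)
    )
    post <- tibble::tibble(
      nuclear_area_px2 = rnorm(30, 856.22, 255.74),
      collagen_content_pct = rnorm(30, 36.10, 12.42)
    )
  })
  cmp <- compare_groups(pre, post)
  expect_equal(cmp$metric, c("nuclear_area_px2", "collagen_content_pct"))
  expect_equal(cmp$n_pre, c(30L, 30L))
  expect_equal(cmp$degrees_of_freedom, c(58, 58))
  expect_true(all(cmp$p_bin %in% c("<0.001", "<0.01", "<0.05", "ns")))
  # row-by-row agreement with the direct tests
  for (i in 1:2) {
    tt <- t_test_from_values(pre[[cmp$metric[i]]], post[[cmp$metric[i]]])
    expect_equal(cmp$t_statistic[i], tt$t_statistic, tolerance = 1e-12)
  }
  expect_error(compare_groups(pre[0, ], post), "at least 2")
  expect_error(
    compare_groups(tibble::tibble(id = c("a", "b")), post),
    "no shared numeric"
  )
})

test_that("tidy on a t-test result is a one-row broom-style frame", {
  tt <- t_test_from_values(c(1, 2, 3, 4), c(3, 4, 5, 6))
  td <- tidy(tt)
  expect_equal(nrow(td), 1L)
  expect_named(td, c(
    "estimate", "t_statistic", "degrees_of_freedom", "p_value",
    "p_bin", "significant", "variant", "degenerate"
  ))
  expect_equal(td$estimate, 2)
})
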