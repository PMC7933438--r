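test_that("percent change follows the baseline-denominator definition", {
  expect_equal(percent_change(40, 50), 25)
  expect_equal(percent_change(7, 7), 0)
  expect_equal(percent_change(50, 40), -20)
  expect_error(percent_change(0, 10), "zero")
  # follow-up-denominator variant
  expect_equal(percent_change(40, 50, denominator = "followup"), 20)
  # documented asymmetry of ratio changes
  expect_false(isTRUE(all.equal(abs(percent_change(40, 50)),
                                abs(percent_change(50, 40)))))
})

test_that("group comparisons match a first-principles ANOVA/Tukey oracle", {
  set.seed(101)
  df <- data.frame(
    value = c(rnorm(8, 10, 2), rnorm(12, 12, 2), rnorm(10, 9, 2)),
    group = rep(c("sham", "vehicle", "treated"), c(8, 12, 10)))
  gc <- group_compare(df, "value", "group")
  oracle <- anova_oracle(df$value, df$group)
  expect_equal(gc$anova_f, oracle$f, tolerance = 1e-6)
  expect_equal(gc$anova_p, oracle$p, tolerance = 1e-6)
  td <- tidy(gc)
  for (j in seq_len(ncol(oracle$pairs))) {
    pr <- oracle$pairs[, j]
    row <- td[(td$group1 == pr[1] & td$group2 == pr[2]) |
                (td$group1 == pr[2] & td$group2 == pr[1]), ]
    expect_equal(unname(row$adj_p_value), unname(oracle$tukey_p[j]),
                 tolerance = 1e-6)
  }
  gl <- glance(gc)
  expect_equal(gl$n, 30)
  expect_equal(gl$n_groups, 3)
  # summaries report sem = sd / sqrt(n)
  expect_equal(gc$summary$sem, gc$summary$sd / sqrt(gc$summary$n))
})

test_that("extreme group separation gives adjusted p below 0.001", {
  set.seed(7)
  df <- data.frame(value = c(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1),
                             rnorm(10, 5, 0.1)),
                   group = rep(c("a", "b", "c"), each = 10))
  td <- tidy(group_compare(df, "value", "group"))
  involving_c <- td[td$group1 == "c" | td$group2 == "c", ]
  expect_true(all(involving_c$adj_p_value < 0.001))
  expect_gt(td$adj_p_value[td$group1 != "c" & td$group2 != "c"], 0.05)
})

test_that("Tukey-Kramer adjusted p never undercuts the pooled pairwise t p", {
  # the comparable unadjusted p uses the same pooled scale (ANOVA MSE and
  # residual df); the studentized range of k groups dominates the pair range,
  # so the adjusted p is always at least this t-test's p
  pooled_t_p <- function(df, g1, g2) {
    fit <- stats::aov(value ~ group, data = df)
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    m <- tapply(df$value, df$group, mean)
    n <- tapply(df$value, df$group, length)
    tt <- (m[[g1]] - m[[g2]]) / sqrt(mse * (1 / n[[g1]] + 1 / n[[g2]]))
    2 * stats::pt(-abs(tt), fit$df.residual)
  }
  set.seed(42)
  for (rep in 1:25) {
    ns <- sample(4:9, 3, replace = TRUE)
    df <- data.frame(value = rnorm(sum(ns), rep(c(0, 0.5, 1), ns)),
                     group = rep(c("a", "b", "c"), ns))
    td <- tidy(group_compare(df, "value", "group"))
    for (j in seq_len(nrow(td))) {
      praw <- pooled_t_p(df, td$group1[j], td$group2[j])
      expect_gte(td$adj_p_value[j] + 1e-12, praw)
    }
  }
})

test_that("group comparison input contracts are enforced", {
  expect_error(group_compare(data.frame(value = 1:4,
                                        group = rep("a", 4)),
                             "value", "group"), "two groups")
  expect_error(group_compare(data.frame(value = 1:3,
                                        group = c("a", "a", "b")),
                             "value", "group"), "two observations")
})

test_that("Pearson correlation handles exact, null and degenerate inputs", {
  x <- seq_len(20)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  set.seed(3)
  res <- pearson_cor(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(res$r), 0.03)
  expect_gt(res$p_value, 1e-4)
  expect_error(pearson_cor(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_cor(1:2, 2:3), "3 complete")
})

test_that("study reports are complete and round-trip through CSV", {
  ell <- ellipsoid_mask(c(1400, 800, 800), spacing_um = 50)
  mr <- lv_morphometry(ell)
  dens <- tibble::tibble(zone = c("infarct", "border", "remote", "whole_wall"),
                         zone_volume_mm3 = c(1, 2, 3, 6),
                         vessel_volume_mm3 = c(.07, .3, .6, .97),
                         density_pct = c(7, 15, 20, 16.17))
  dir <- withr::local_tempdir()
  long <- build_report(list(m1 = mr, m2 = dens,
                            m3 = c(ef_change_pct = -12.5)),
                       groups = c(m1 = "sham", m2 = "vehicle", m3 = "vehicle"),
                       dir = dir)
  expect_setequal(unique(long$subject), c("m1", "m2", "m3"))
  expect_true("conicity_index" %in% long$endpoint)
  expect_true(file.exists(file.path(dir, "study_summary.json")))
  csvs <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  expect_gt(length(csvs), 4)
  back <- utils::read.csv(csvs[1])
  orig <- long[long$endpoint == back$endpoint[1], ]
  expect_equal(back$value, orig$value) # full-precision round trip
  expect_error(build_report(list()), "no results")
  expect_error(build_report(list(tibble::tibble(x = 1))), "named")
})
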