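#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Percent change of an echocardiographic endpoint
#'
#' `100 * (week4 - week0) / week0` — the study-period change of LVID or EF
#' relative to baseline. The alternative follow-up denominator
#' (`/ week4 * 100`) that appears in some figure legends is available via
#' `denominator = "followup"`; the baseline form is the default. Note the
#' documented asymmetry of ratio changes: a gain and an equal-magnitude loss
#' are only antisymmetric on the same baseline.
#'
#' @param week0 baseline value(s); must be nonzero.
#' @param week4 follow-up value(s).
#' @param denominator `"baseline"` (default) or `"followup"`.
#' @return percent change (vectorised).
#' @export
percent_change <- function(week0, week4,
                           denominator = c("baseline", "followup")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "baseline") week0 else week4
  if (any(den == 0)) stop("percent change undefined for a zero denominator")
  100 * (week4 - week0) / den
}

#' Compare an endpoint across study groups
#'
#' One-way ANOVA followed by Tukey-Kramer honestly-significant-difference
#' pairwise comparisons (the unequal-n form, via the studentized range
#' distribution), plus optional pre-specified two-tailed t-tests. Group
#' summaries are reported as mean ± s.e.m.
#'
#' @param data data frame in long format.
#' @param value column name (string) of the endpoint values.
#' @param group column name (string) of the group labels.
#' @param t_test_pairs optional list of length-2 character vectors naming
#'   group pairs for two-tailed t-tests.
#' @return a `group_comparison` object; see [tidy.group_comparison()] and
#'   [glance.group_comparison()].
#' @export
group_compare <- function(data, value, group, t_test_pairs = NULL) {
  stopifnot(value %in% names(data), group %in% names(data))
  df <- data.frame(value = as.numeric(data[[value]]),
                   group = factor(data[[group]]))
  df <- df[complete.cases(df), ]
  if (nlevels(droplevels(df$group)) < 2L)
    stop("need at least two groups")
  df$group <- droplevels(df$group)
  ns <- table(df$group)
  if (any(ns < 2L)) stop("each group needs at least two observations")
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  summ <- dplyr::summarise(dplyr::group_by(df, group),
                           n = dplyr::n(), mean = mean(value),
                           sd = sd(value), sem = sd(value) / sqrt(dplyr::n()),
                           .groups = "drop")
  tt <- NULL
  if (!is.null(t_test_pairs)) {
    tt <- dplyr::bind_rows(lapply(t_test_pairs, function(p) {
      x <- df$value[df$group == p[1]]
      y <- df$value[df$group == p[2]]
      ht <- t.test(x, y, alternative = "two.sided")
      tibble::tibble(group1 = p[1], group2 = p[2],
                     estimate = mean(x) - mean(y),
                     statistic = unname(ht$statistic),
                     p_value = ht$p.value)
    }))
  }
  structure(list(endpoint = value, fit = fit,
                 anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 df_between = an[["Df"]][1], df_within = an[["Df"]][2],
                 tukey = tk, summary = summ, t_tests = tt),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$endpoint, x$df_between, x$df_within, x$anova_f, x$anova_p))
  print(tidy(x))
  invisible(x)
}

#' Tidy and glance methods for group comparisons
#'
#' `tidy()` returns one row per group pair with the mean difference and the
#' Tukey-Kramer adjusted p-value; `glance()` returns the one-row ANOVA
#' summary.
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @rdname tidy_group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  pairs <- rownames(x$tukey)
  parts <- strsplit(pairs, "-", fixed = TRUE)
  tibble::tibble(endpoint = x$endpoint,
                 group1 = vapply(parts, `[`, "", 1L),
                 group2 = vapply(parts, `[`, "", 2L),
                 estimate = x$tukey[, "diff"],
                 conf_low = x$tukey[, "lwr"],
                 conf_high = x$tukey[, "upr"],
                 adj_p_value = x$tukey[, "p adj"])
}

#' @rdname tidy_group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(endpoint = x$endpoint, statistic = x$anova_f,
                 p_value = x$anova_p, df = x$df_between,
                 df_residual = x$df_within,
                 n = sum(x$summary$n), n_groups = nrow(x$summary))
}

#' Pearson correlation with two-tailed p-value
#'
#' Sample Pearson correlation with significance from the t-distribution on
#' n - 2 degrees of freedom (as used for the echocardiography versus
#' light-sheet volume comparison and the conicity-EF relation).
#'
#' @param x,y numeric vectors of equal length (n >= 3, nonconstant).
#' @return one-row tibble with `r`, `statistic`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input has no correlation")
  ht <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ht$estimate), statistic = unname(ht$statistic),
                 p_value = ht$p.value, n = length(x))
}

#' Assemble a study report from per-subject results
#'
#' Writes one CSV per endpoint (subject, group, value, units), a single JSON
#' study summary keyed by subject, and returns the long endpoint table. The
#' CSVs round-trip through [utils::read.csv()] at full precision.
#'
#' @param results named list (by subject id) of result objects —
#'   `morphometry_result`s, [zone_vascular_density()] tibbles, or named
#'   numeric vectors of scalar endpoints.
#' @param groups optional named character vector mapping subject id to group.
#' @param dir output directory; `NULL` skips writing.
#' @return the long endpoint tibble, invisibly when `dir` is given.
#' @export
build_report <- function(results, groups = NULL, dir = NULL) {
  if (length(results) == 0L) stop("no results to report")
  if (is.null(names(results)) || any(names(results) == ""))
    stop("results must be named by subject id")
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    tab <- if (inherits(r, "morphometry_result")) {
      tidy(r)
    } else if (is.data.frame(r) && "density_pct" %in% names(r)) {
      tibble::tibble(endpoint = paste0("vascular_density_", r$zone),
                     value = r$density_pct, units = "%")
    } else if (is.numeric(r) && !is.null(names(r))) {
      tibble::tibble(endpoint = names(r), value = unname(r), units = "")
    } else {
      stop("unsupported result type for subject ", id)
    }
    tab$subject <- id
    tab
  })
  long <- dplyr::bind_rows(rows)
  long$group <- if (is.null(groups)) NA_character_ else
    unname(groups[long$subject])
  long <- long[, c("subject", "group", "endpoint", "value", "units")]
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (ep in unique(long$endpoint)) {
      sub <- long[long$endpoint == ep, ]
      write.csv(sub, file.path(dir, paste0(gsub("[^A-Za-z0-9_]", "_", ep),
                                           ".csv")), row.names = FALSE)
    }
    by_subject <- split(long[, c("endpoint", "value", "units")], long$subject)
    jsonlite::write_json(lapply(by_subject, function(d)
      setNames(as.list(d$value), d$endpoint)),
      file.path(dir, "study_summary.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(long))
  }
  long
}
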