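#' Two-sided unpaired t-test between two condition groups
#'
#' Welch's variant (unequal variances, Welch-Satterthwaite degrees of
#' freedom) is the default; the classical pooled-variance variant is
#' available. The two agree exactly when group variances and sizes are
#' equal. Two identical constant groups are reported as t = 0, p = 1.
#'
#' @param group_a,group_b Numeric value vectors (each n >= 2).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param labels Optional two group labels for the report.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `conf_low`, `conf_high`, `variant`, `group_a`, `group_b`.
#' @export
ttest_unpaired <- function(group_a, group_b, variant = c("welch", "pooled"),
                           labels = c("A", "B")) {
  variant <- match.arg(variant)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2)
    abort("each group needs at least two values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) != mean(b))
      abort("degenerate groups: both constant with different means")
    return(tibble::tibble(
      statistic = 0, df = length(a) + length(b) - 2, p_value = 1,
      mean_a = mean(a), mean_b = mean(b),
      conf_low = 0, conf_high = 0, variant = variant,
      group_a = labels[1], group_b = labels[2]))
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"),
                      alternative = "two.sided")
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(a), mean_b = mean(b),
    conf_low = ht$conf.int[1], conf_high = ht$conf.int[2],
    variant = variant,
    group_a = labels[1], group_b = labels[2]
  )
}

#' Fit the linear dose-response of bead uptake
#'
#' Ordinary least squares of bead-pixels-per-cell on exposure concentration,
#' with 95% confidence intervals from the t distribution on n - 2 degrees of
#' freedom and a mean-response confidence band over the concentration range.
#'
#' @param data Data frame with columns `concentration` and `value` (or a
#'   column named `bead_px_per_cell`, used as the value when `value` is
#'   absent).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `dose_fit` (see [tidy.dose_fit()],
#'   [glance.dose_fit()], [autoplot.dose_fit()]).
#' @export
fit_dose_response <- function(data, conf_level = 0.95) {
  stopifnot(is.data.frame(data))
  if (!"value" %in% names(data) && "bead_px_per_cell" %in% names(data))
    data$value <- data$bead_px_per_cell
  if (!all(c("concentration", "value") %in% names(data)))
    abort("data must have columns 'concentration' and 'value'")
  data <- data[stats::complete.cases(data[c("concentration", "value")]), ]
  if (nrow(data) < 3) abort("at least three points are required")
  if (length(unique(data$concentration)) < 2)
    abort("at least two distinct concentrations are required")
  model <- stats::lm(value ~ concentration, data = data)
  sm <- suppressWarnings(summary(model))
  ci <- suppressWarnings(stats::confint(model, level = conf_level))
  grid <- tibble::tibble(concentration = sort(unique(data$concentration)))
  band <- suppressWarnings(
    stats::predict(model, newdata = grid, interval = "confidence",
                   level = conf_level))
  structure(list(
    model = model,
    data = tibble::as_tibble(data),
    slope = unname(coef(model)[2]),
    intercept = unname(coef(model)[1]),
    slope_se = sm$coefficients[2, 2],
    ci95_slope = unname(ci[2, ]),
    ci95_intercept = unname(ci[1, ]),
    r_squared = sm$r.squared,
    conf_level = conf_level,
    confidence_band = dplyr::bind_cols(grid, tibble::as_tibble(band))
  ), class = "dose_fit")
}

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_fit> slope %.4g [%.4g, %.4g] bead px per cell per (ug/cm^2), R^2 = %.3f\n",
    x$slope, x$ci95_slope[1], x$ci95_slope[2], x$r_squared))
  invisible(x)
}

#' Tidy a dose-response fit
#'
#' @param x A `dose_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.dose_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$model))$coefficients
  ci <- suppressWarnings(stats::confint(x$model, level = x$conf_level))
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4],
    conf.low = ci[, 1], conf.high = ci[, 2]
  )
}

#' Glance at a dose-response fit
#'
#' @param x A `dose_fit`.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `sigma`, `df.residual`, `nobs`,
#'   `p.value` (slope test).
#' @export
glance.dose_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$model))
  tibble::tibble(
    r.squared = sm$r.squared,
    sigma = sm$sigma,
    df.residual = x$model$df.residual,
    nobs = nrow(x$data),
    p.value = sm$coefficients[2, 4]
  )
}

#' Summarize uptake records by condition with tests and regressions
#'
#' Groups records by cell line, concentration and exposure time; reports per
#' group n, mean and sd of bead-pixels-per-cell; runs pairwise two-sided
#' unpaired t-tests between concentrations within each cell line and time
#' (raw p-values, flagged at p <= 0.05; Holm adjustment optional); and fits
#' the linear dose-response per cell line and time.
#'
#' @param records Tibble of uptake records (as returned by [quantify_fov()]
#'   or [make_dose_response_set()]).
#' @param variant t-test variant, `"welch"` or `"pooled"`.
#' @param holm Also report Holm-adjusted p-values (default FALSE).
#' @return A list of class `uptake_summary` with tibbles `groups`, `tests`
#'   and `fits`.
#' @export
summarize_uptake <- function(records, variant = "welch", holm = FALSE) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) abort("no records to summarize")
  if (!"bead_px_per_cell" %in% names(records))
    abort("records must carry a 'bead_px_per_cell' column")
  if ("valid" %in% names(records)) records <- records[records$valid, ]
  groups <- records %>%
    dplyr::group_by(.data$cell_line, .data$concentration, .data$time_h) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$bead_px_per_cell),
                     sd = stats::sd(.data$bead_px_per_cell),
                     .groups = "drop")

  tests <- records %>%
    dplyr::group_by(.data$cell_line, .data$time_h) %>%
    dplyr::group_modify(function(df, key) {
      concs <- sort(unique(df$concentration))
      if (length(concs) < 2) return(tibble::tibble())
      pairs <- utils::combn(concs, 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(p) {
        a <- df$bead_px_per_cell[df$concentration == p[1]]
        b <- df$bead_px_per_cell[df$concentration == p[2]]
        if (length(a) < 2 || length(b) < 2) return(tibble::tibble())
        res <- tryCatch(
          ttest_unpaired(a, b, variant = variant,
                         labels = as.character(p)),
          error = function(e) NULL)
        if (is.null(res)) return(tibble::tibble())
        res
      })
    }) %>% dplyr::ungroup()
  if (nrow(tests)) {
    tests$significant <- tests$p_value <= 0.05
    if (holm) tests$p_holm <- stats::p.adjust(tests$p_value, "holm")
  }

  fits <- records %>%
    dplyr::group_by(.data$cell_line, .data$time_h) %>%
    dplyr::group_modify(function(df, key) {
      if (length(unique(df$concentration)) < 2 || nrow(df) < 3)
        return(tibble::tibble())
      fit <- fit_dose_response(
        tibble::tibble(concentration = df$concentration,
                       value = df$bead_px_per_cell))
      tibble::tibble(slope = fit$slope, intercept = fit$intercept,
                     slope_se = fit$slope_se,
                     ci_low = fit$ci95_slope[1], ci_high = fit$ci95_slope[2],
                     r_squared = fit$r_squared, n = nrow(df))
    }) %>% dplyr::ungroup()

  structure(list(groups = groups, tests = tests, fits = fits),
            class = "uptake_summary")
}

#' @export
print.uptake_summary <- function(x, ...) {
  cat("<uptake_summary>\nGroup means:\n")
  print(x$groups)
  if (nrow(x$tests)) { cat("Pairwise t-tests:\n"); print(x$tests) }
  if (nrow(x$fits)) { cat("Dose-response fits:\n"); print(x$fits) }
  invisible(x)
}
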