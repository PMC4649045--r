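#' Mean sensitivity of an annual series
#'
#' The dendrochronological mean sensitivity: the average absolute relative
#' change between consecutive annual values, with the mean of the two
#' values as denominator,
#' `MS = 100 * mean(|2 * (x_t - x_(t-1)) / (x_t + x_(t-1))|)`.
#'
#' @param series A numeric vector of annual values (> 0), or a tibble with
#'   a `value` column such as [assemble_time_series()] returns.
#' @return Mean sensitivity in percent.
#' @examples
#' mean_sensitivity(c(1, 3)) # 100
#' @export
mean_sensitivity <- function(series) {
  x <- if (is.data.frame(series)) series$value else series
  if (!is.numeric(x) || length(x) < 2) abort_field("series", "needs at least 2 numeric values")
  if (any(!is.finite(x) | x <= 0)) {
    abort_field("series", "all values must be positive and finite")
  }
  d <- diff(x)
  100 * mean(abs(2 * d / (x[-1] + x[-length(x)])))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#'
#' @param x Numeric vector (n >= 2) or a tibble with a `value` column.
#' @return Dimensionless CV.
#' @export
coefficient_of_variation <- function(x) {
  v <- if (is.data.frame(x)) x$value else x
  if (!is.numeric(v) || length(v) < 2) abort_field("x", "needs at least 2 numeric values")
  if (any(!is.finite(v))) abort_field("x", "values must be finite")
  m <- mean(v)
  if (m == 0) abort_field("x", "mean is zero; CV undefined")
  stats::sd(v) / m
}

#' Expected mean sensitivity of i.i.d. lognormal annual values
#'
#' For annual values `x_t = c * g_t` with i.i.d. lognormal year factors of
#' log-standard-deviation `sigma_log`, the step ratio is lognormal with
#' log-sd `sigma_log * sqrt(2)` and the expected mean sensitivity has the
#' closed form `E[MS] = 200 * E[ tanh(|N(0, 1)| * sigma_log / sqrt(2)) ]`,
#' evaluated here by Gaussian quadrature.
#'
#' @param sigma_log Log-scale standard deviation of the year factor
#'   (>= 0).
#' @return Expected mean sensitivity in percent.
#' @export
expected_mean_sensitivity <- function(sigma_log) {
  check_number(sigma_log, "sigma_log", min = 0)
  if (sigma_log == 0) return(0)
  stats::integrate(
    function(z) 2 * stats::dnorm(z) * 200 * tanh(sigma_log * z / sqrt(2)),
    0, Inf
  )$value
}

# Expected mean sensitivity of the *measured* annual PERPAR series, whose
# values pass through the saturating Boolean coverage transform: evaluated
# by midpoint quadrature in probability space over a pair of consecutive
# year factors.
expected_ms_measured <- function(config, sigma_log, thickness_um = 15, nq = 48) {
  if (sigma_log == 0) return(0)
  q <- list(z = stats::qnorm((seq_len(nq) - 0.5) / nq), w = rep(1 / nq, nq))
  f <- vapply(
    exp(-sigma_log^2 / 2 + sigma_log * q$z),
    function(g) expected_perpar(config, "cross", thickness_um, width_factor = g),
    numeric(1)
  )
  w2 <- outer(q$w, q$w)
  ms <- abs(2 * outer(f, f, "-") / outer(f, f, "+"))
  100 * sum(w2 * ms)
}

#' Calibrate the inter-annual modulation to a target mean sensitivity
#'
#' Finds the inter-annual coefficient of variation of the year factor such
#' that the expected mean sensitivity of the measured annual PERPAR series
#' equals `target_ms`, accounting for the mildly saturating coverage
#' transform between ray intensity and measured areal fraction.
#'
#' @param config A [wood_config()].
#' @param target_ms Target mean sensitivity, percent (> 0).
#' @param thickness_um Assumed section thickness.
#' @return The configuration with `interannual_cv` set.
#' @export
calibrate_interannual_cv <- function(config, target_ms, thickness_um = 15) {
  check_number(target_ms, "target_ms", min = 0, strict_min = TRUE, max = 150)
  root <- stats::uniroot(
    function(s) expected_ms_measured(config, s, thickness_um) - target_ms,
    lower = 1e-6, upper = 2, tol = 1e-8
  )
  config$interannual_cv <- sqrt(exp(root$root^2) - 1)
  validate_wood_config(config)
}

#' Pearson correlation matrix with significance
#'
#' Pairwise Pearson correlations between the numeric columns of a metric
#' table, with two-sided p-values from the t distribution on n - 2 degrees
#' of freedom.  Zero-variance columns yield `NA` correlations and a
#' warning rather than a silent zero.
#'
#' @param data A data frame of per-section (or per-ring) metrics; only
#'   numeric columns enter, and only complete rows are used.
#' @return A `pearson_matrix` object: list with matrices `r` and `p`,
#'   sample size `n` and variable names.  Use [generics::tidy()] for a
#'   long tibble.
#' @export
pearson_matrix <- function(data) {
  num <- data[vapply(data, is.numeric, logical(1))]
  num <- num[stats::complete.cases(num), , drop = FALSE]
  n <- nrow(num)
  if (n < 3) rlang::abort("need at least 3 complete rows for correlations")
  if (ncol(num) < 2) rlang::abort("need at least 2 numeric columns")
  degenerate <- vapply(num, function(x) stats::sd(x) == 0, logical(1))
  if (any(degenerate)) {
    rlang::warn(sprintf(
      "zero-variance column(s): %s; correlations set to NA",
      paste(names(num)[degenerate], collapse = ", ")
    ))
  }
  r <- suppressWarnings(stats::cor(num))
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  diag(r) <- ifelse(degenerate, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  structure(
    list(r = r, p = p, n = n, variables = colnames(num)),
    class = "pearson_matrix"
  )
}

significance_marks <- function(p) {
  cut(p,
    breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
    labels = c("***", "**", "*", ".", "ns")
  )
}

#' @export
print.pearson_matrix <- function(x, ...) {
  cat(sprintf("<pearson_matrix> %d variables, n = %d\n", length(x$variables), x$n))
  print(round(x$r, 3))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname pearson_matrix
#' @param x A `pearson_matrix`.
#' @param ... Ignored.
#' @export
tidy.pearson_matrix <- function(x, ...) {
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = x$variables[pairs[, 1]],
    var2 = x$variables[pairs[, 2]],
    r = x$r[pairs],
    p = x$p[pairs],
    n = x$n,
    signif = as.character(significance_marks(x$p[pairs]))
  )
}

#' @rdname pearson_matrix
#' @param object A `pearson_matrix`.
#' @export
autoplot.pearson_matrix <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(df, dplyr::rename(df, var1 = "var2", var2 = "var1"))
  ggplot2::ggplot(df2, ggplot2::aes(.data$var1, .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$r, ifelse(.data$signif == "ns", "", .data$signif))
    ), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Paired (or two-sample) comparison of two metric samples
#'
#' Student's t comparison of two samples, paired by default (e.g. the same
#' tree rings measured in two zones or planes).  The sign convention is
#' `t > 0` when `mean(a) > mean(b)`.
#'
#' @param a,b Numeric samples; equal lengths when `paired`.
#' @param paired Pair observations (default) or fall back to Welch's
#'   two-sample comparison.
#' @return A `ray_ttest` object; see [tidy.ray_ttest()].
#' @export
paired_t_test <- function(a, b, paired = TRUE) {
  if (!is.numeric(a) || !is.numeric(b)) abort_field("a", "samples must be numeric")
  if (paired && length(a) != length(b)) {
    abort_field("b", "paired samples must have equal length")
  }
  if (length(a) < 2) abort_field("a", "need at least 2 observations")
  if (paired && stats::sd(a - b) == 0) {
    rlang::abort("differences have zero variance; the paired t statistic is undefined")
  }
  ht <- stats::t.test(a, b, paired = paired)
  structure(
    list(
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      df = unname(ht$parameter),
      n = length(a),
      mean_a = mean(a),
      mean_b = mean(b),
      paired = paired,
      method = ht$method
    ),
    class = "ray_ttest"
  )
}

#' @export
print.ray_ttest <- function(x, ...) {
  cat(sprintf(
    "<ray_ttest> %s: t = %.3f, df = %.1f, p = %.4g (means %.4g vs %.4g, n = %d)\n",
    x$method, x$statistic, x$df, x$p_value, x$mean_a, x$mean_b, x$n
  ))
  invisible(x)
}

#' Tidiers for comparison results
#'
#' @param x,object A `ray_ttest`.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @export
tidy.ray_ttest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p_value, df = x$df, n = x$n,
    mean_a = x$mean_a, mean_b = x$mean_b,
    method = x$method,
    signif = as.character(significance_marks(x$p_value))
  )
}

#' @rdname tidy.ray_ttest
#' @export
glance.ray_ttest <- function(x, ...) tidy(x, ...)

#' Allometric regression between two ray dimensions
#'
#' Ordinary least squares of `y` on `x` -- e.g. individual ray area
#' against ray length (cross-sections) or ray height (tangential
#' sections), relationships strong enough to estimate area from a single
#' measured dimension.
#'
#' @param data Optional data frame; `x` and `y` are then column names
#'   (tidy evaluation).  Alternatively pass numeric vectors directly.
#' @param x,y Predictor and response.
#' @return An `allometry_fit` with the underlying `lm` fit, `slope`,
#'   `intercept`, `r_squared` and `n`; see [tidy.allometry_fit()].
#' @examples
#' fit <- fit_allometry(data.frame(l = 1:10, a = 2 * (1:10) + rnorm(10, 0, .1)), l, a)
#' fit$r_squared
#' @export
fit_allometry <- function(data = NULL, x, y) {
  if (is.data.frame(data)) {
    xv <- rlang::eval_tidy(rlang::enquo(x), data)
    yv <- rlang::eval_tidy(rlang::enquo(y), data)
  } else {
    xv <- if (is.null(data)) x else data
    yv <- y
  }
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 3) rlang::abort("need at least 3 complete observations")
  if (stats::sd(xv) == 0) rlang::abort("predictor is constant; slope undefined")
  fit <- stats::lm(yv ~ xv)
  s <- summary(fit)
  structure(
    list(
      fit = fit,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = s$r.squared,
      p_value = unname(s$coefficients[2, 4]),
      n = length(xv)
    ),
    class = "allometry_fit"
  )
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf(
    "<allometry_fit> y = %.4g + %.4g x, R2 = %.3f, p = %.3g, n = %d\n",
    x$intercept, x$slope, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

#' Tidiers for allometric fits
#'
#' @param x,object An `allometry_fit`.
#' @param ... Ignored.
#' @return `tidy()`: one row per coefficient; `glance()`: one-row model
#'   summary.
#' @export
tidy.allometry_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 3],
    p.value = s[, 4]
  )
}

#' @rdname tidy.allometry_fit
#' @export
glance.allometry_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
    p.value = x$p_value, n = x$n
  )
}
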