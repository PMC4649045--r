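#' Randomly placed measurement windows on a section
#'
#' Places `count` axis-aligned windows uniformly at random, fully inside
#' the image (overlaps permitted), and records the percentage of ray
#' surface in each -- the sampling design behind window-based accuracy
#' assessment.  On tangential sections the windows are squares of
#' `window` mm2; on cross-sections they are full-height strips of `window`
#' mm tangential width, so that a 1-mm strip on rings about 1 mm wide
#' measures a comparable surface to a 1-mm2 tangential window.
#'
#' @param image A [cut_section()] image.
#' @param window Window size: mm2 (tangential, square windows) or mm width
#'   (cross, full-height strips).
#' @param count Number of windows.
#' @param seed Integer seed for the placement stream.
#' @return A `window_pool`: a tibble (`window`, `x_mm`, `y_mm`, `perpar`)
#'   with attributes `window_size`, `plane` and `seed`.  The `perpar`
#'   column is the data pool downstream bootstrap analyses resample.
#' @export
sample_windows <- function(image, window = 1, count = 1000, seed = 1L) {
  stopifnot(inherits(image, "section_image"))
  check_number(window, "window", min = 0, strict_min = TRUE)
  check_number(count, "count", min = 0, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  px_mm <- um_to_mm(image$pixel_size_um)
  strip <- image$plane == "cross"
  wx_px <- as.integer(round((if (strip) window else sqrt(window)) / px_mm))
  wy_px <- if (strip) image$ny else wx_px
  if (wx_px < 1 || wx_px > image$nx || wy_px > image$ny) {
    rlang::abort(sprintf(
      "window of %g %s does not fit the %g x %g mm image",
      window, if (strip) "mm width" else "mm2",
      image$nx * px_mm, image$ny * px_mm
    ))
  }
  empty <- tibble::tibble(
    window = integer(0), x_mm = numeric(0), y_mm = numeric(0), perpar = numeric(0)
  )
  out <- if (count == 0) {
    empty
  } else {
    with_seed(seed, {
      x_px <- sample.int(image$nx - wx_px + 1L, count, replace = TRUE)
      y_px <- if (wy_px == image$ny) {
        rep(1L, count)
      } else {
        sample.int(image$ny - wy_px + 1L, count, replace = TRUE)
      }
      if (wy_px == image$ny) {
        # full-height strips: cumulative per-column counts suffice
        idx <- nonzero_indices(image$labels)
        col_counts <- tabulate((idx - 1L) %/% image$ny + 1L, nbins = image$nx)
        cum <- c(0, cumsum(col_counts))
        npos <- cum[x_px + wx_px] - cum[x_px]
      } else {
        # summed-area table -> O(1) ray-pixel count per window
        a <- matrix(0, image$ny + 1L, image$nx + 1L)
        a[-1, -1] <- image$labels != 0L
        a <- apply(a, 2, cumsum)
        a <- t(apply(a, 1, cumsum))
        i2 <- y_px + wy_px
        j2 <- x_px + wx_px
        npos <- a[cbind(i2, j2)] - a[cbind(y_px, j2)] -
          a[cbind(i2, x_px)] + a[cbind(y_px, x_px)]
      }
      tibble::tibble(
        window = seq_len(count),
        x_mm = image$x0 + (x_px - 1L) * px_mm,
        y_mm = image$y0 + (y_px - 1L) * px_mm,
        perpar = 100 * npos / (wx_px * wy_px)
      )
    })
  }
  structure(out,
    window_size = window, plane = image$plane, seed = seed,
    class = c("window_pool", class(out))
  )
}

pool_values <- function(pool) {
  v <- if (is.numeric(pool)) pool else if (is.data.frame(pool)) pool$perpar else NULL
  if (is.null(v)) rlang::abort("`pool` must be a window_pool tibble (or numeric vector of PERPAR values)")
  if (any(!is.finite(v) | v < 0 | v > 100)) {
    rlang::abort("pool values must be finite percentages in [0, 100]")
  }
  v
}

#' Bootstrap accuracy of a window data pool
#'
#' Simulates the measurement of increasing wood surface: for each size `s`,
#' draws `reps` bootstrap estimates, each the mean of `s` window values
#' resampled with replacement from the pool, and records the mean and the
#' coefficient of variation (sd/mean, n-1 denominator) of those estimates.
#' The resulting CV-versus-surface curve, combined with [ci95()], yields
#' sampling-design guidance.
#'
#' @param pool A [sample_windows()] pool (several sections' pools may be
#'   row-bound first), or a numeric vector of PERPAR values.
#' @param sizes Integer vector of pool-draw counts (measured surface in
#'   window units), default 1 to 15.
#' @param reps Bootstrap replications (>= 2), default 1000.
#' @param seed Integer seed for the resampling stream.
#' @return An `accuracy_curve`: tibble (`size`, `mean`, `cv`) with
#'   attributes `reps` and `seed`.
#' @export
bootstrap_accuracy <- function(pool, sizes = 1:15, reps = 1000, seed = 1L) {
  v <- pool_values(pool)
  check_number(reps, "reps", min = 2, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (any(sizes < 1 | sizes != round(sizes))) abort_field("sizes", "must be positive integers")
  if (length(v) < max(sizes)) {
    rlang::abort(sprintf(
      "pool of %d values is smaller than the largest size %d", length(v), max(sizes)
    ))
  }
  if (mean(v) == 0) rlang::abort("pool mean is zero; CV undefined")
  out <- with_seed(seed, {
    purrr::map_dfr(sort(unique(as.integer(sizes))), function(s) {
      est <- rowMeans(matrix(v[sample.int(length(v), s * reps, replace = TRUE)], nrow = reps))
      tibble::tibble(size = s, mean = mean(est), cv = stats::sd(est) / mean(est))
    })
  })
  structure(out, reps = reps, seed = seed, class = c("accuracy_curve", class(out)))
}

#' Relative 95% confidence interval of a mean estimate
#'
#' For a per-sample coefficient of variation `cv` and `n` samples, the
#' relative 95% confidence interval, as a percentage of the mean, is
#' `CI95 = 100 * 2 * cv / sqrt(n)`: CI95 is about twice the standard
#' error, the standard error is the standard deviation over `sqrt(n)`, and
#' the standard deviation is `cv` times the mean.
#'
#' @param cv Coefficient of variation of a single sample (dimensionless,
#'   >= 0); vectorized.
#' @param n Number of samples (>= 1); vectorized.
#' @return CI95 in percent of the mean.
#' @examples
#' ci95(0.10, 4) # 10%
#' @export
ci95 <- function(cv, n) {
  if (any(!is.finite(cv) | cv < 0)) abort_field("cv", "must be >= 0")
  if (any(!is.finite(n) | n < 1)) abort_field("n", "must be >= 1")
  100 * 2 * cv / sqrt(n)
}

#' Samples needed for a target accuracy
#'
#' Inverts [ci95()]: the smallest integer `n` such that
#' `ci95(cv, n) <= target_ci95`.  Rounds up -- conservative for sampling
#' design.
#'
#' @param cv Per-sample coefficient of variation (> 0).
#' @param target_ci95 Target relative 95% confidence interval, percent of
#'   the mean (> 0).
#' @return Integer sample count (>= 1).
#' @examples
#' required_samples(0.2, 10) # 16 one-unit samples for a +/-10% CI95
#' @export
required_samples <- function(cv, target_ci95) {
  check_number(cv, "cv", min = 0, strict_min = TRUE)
  check_number(target_ci95, "target_ci95", min = 0, strict_min = TRUE)
  n <- max(1L, as.integer(ceiling((200 * cv / target_ci95)^2 - 1e-9)))
  while (ci95(cv, n) > target_ci95) n <- n + 1L
  while (n > 1L && ci95(cv, n - 1L) <= target_ci95) n <- n - 1L
  n
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an accuracy curve as CI95 versus measured surface
#'
#' Draws the relative 95% confidence interval as a function of the
#' measured surface (or width) for several sample counts, the standard
#' sampling-design display.
#'
#' @param object An [bootstrap_accuracy()] curve.
#' @param n_samples Sample counts to draw, one line each.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.accuracy_curve <- function(object, n_samples = c(5, 10, 15, 20), ...) {
  df <- tidyr::crossing(tibble::as_tibble(object), n = n_samples)
  df$ci95 <- ci95(df$cv, df$n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$size, y = .data$ci95,
    colour = factor(.data$n), group = .data$n
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "measured surface per sample (window units)",
      y = "CI95 (% of mean PERPAR)", colour = "samples"
    ) +
    ggplot2::theme_minimal()
}
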