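#' Run the full virtual quantification pipeline
#'
#' Executes simulate -> section -> quantify -> accuracy -> stats and
#' writes every intermediate artifact under `out_dir`: the model (ray CSV
#' + JSON sidecar), one PNG + JSON label map per section, the outline
#' table, per-ring metrics for cross-sections, the window pool and
#' bootstrap accuracy curve, a tidy statistics table, and a manifest with
#' an MD5 content hash per file.  All randomness derives from `seed`
#' through named sub-streams (generation, window placement, bootstrap), so
#' identical calls produce byte-identical artifacts and manifest hashes.
#' A failing stage aborts with the stage name; artifacts of completed
#' stages are retained.
#'
#' @param out_dir Output directory (created).
#' @param config A [wood_config()]; its `rng_seed` is replaced by the
#'   pipeline's generation sub-stream.
#' @param sections Named list of [section_spec()]s; the default cuts one
#'   cross-section and one tangential section at 15 um.
#' @param window,window_count Window size (mm2 tangential / mm cross) and
#'   number of windows per section for the accuracy stage.
#' @param sizes,reps Bootstrap sizes and replications, see
#'   [bootstrap_accuracy()].
#' @param seed Global integer seed.
#' @param verbose Emit one log line per stage.
#' @return A tibble manifest (`file`, `stage`, `md5`), invisibly.
#' @export
run_pipeline <- function(out_dir,
                         config = wood_config(),
                         sections = list(
                           cross = section_spec("cross"),
                           tangential = section_spec("tangential")
                         ),
                         window = 1,
                         window_count = 1000,
                         sizes = 1:15,
                         reps = 1000,
                         seed = 1L,
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, files) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      file = unname(files), stage = stage, md5 = unname(tools::md5sum(files))
    )
    if (verbose) {
      message(sprintf(
        "[%s] %s", stage,
        paste(sprintf("%s %s", basename(files), substr(tools::md5sum(files), 1, 8)),
          collapse = "  "
        )
      ))
    }
  }
  run_stage <- function(stage, input, code) {
    tryCatch(code, error = function(e) {
      rlang::abort(
        sprintf("pipeline stage '%s' failed (input: %s): %s", stage, input, conditionMessage(e)),
        parent = e
      )
    })
  }

  # simulate
  model <- run_stage("simulate", "config", {
    config$rng_seed <- sub_seed(seed, "generate")
    generate_wood(config)
  })
  note("simulate", write_wood_model(model, file.path(out_dir, "model")))

  # section
  images <- list()
  for (nm in names(sections)) {
    images[[nm]] <- run_stage("section", nm, cut_section(model, sections[[nm]]))
    paths <- write_section_image(
      images[[nm]],
      file.path(out_dir, sprintf("section_%s.png", nm))
    )
    note("section", paths)
  }

  # quantify
  outlines <- run_stage("quantify", "sections", {
    dplyr::bind_rows(purrr::imap(images, ~ extract_outlines(.x, section_id = .y)))
  })
  out_csv <- file.path(out_dir, "outlines.csv")
  write_outlines(outlines, out_csv)
  note("quantify", out_csv)
  cross_names <- names(images)[purrr::map_chr(images, "plane") == "cross"]
  metrics <- NULL
  if (length(cross_names)) {
    metrics <- run_stage("quantify", cross_names[1], {
      ring_metrics(
        images[[cross_names[1]]],
        outlines = outlines[outlines$section_id == cross_names[1], , drop = FALSE]
      )
    })
    met_csv <- file.path(out_dir, "ring_metrics.csv")
    write_ring_metrics(metrics, met_csv)
    note("quantify", met_csv)
  }

  # accuracy (window sampling on non-cross sections, or strips on cross)
  acc_names <- names(images)[purrr::map_chr(images, "plane") == "tangential"]
  if (!length(acc_names)) acc_names <- names(images)[1]
  pools <- purrr::imap(images[acc_names], function(img, nm) {
    run_stage(
      "accuracy", nm,
      sample_windows(img, window, window_count,
        seed = sub_seed(seed, "windows", match(nm, acc_names))
      )
    )
  })
  pool <- dplyr::bind_rows(pools, .id = "section_id")
  pool_csv <- file.path(out_dir, "window_pool.csv")
  write_window_pool(pool, pool_csv)
  curve <- run_stage("accuracy", "pool", {
    bootstrap_accuracy(pool, sizes = sizes, reps = reps, seed = sub_seed(seed, "bootstrap"))
  })
  acc_csv <- file.path(out_dir, "accuracy.csv")
  write_accuracy_curve(curve, acc_csv)
  note("accuracy", c(pool_csv, acc_csv))

  # stats
  stats_tbl <- run_stage("stats", "metrics", {
    rows <- list()
    if (!is.null(metrics) && nrow(metrics) >= 2) {
      series <- assemble_time_series(metrics, "perpar")
      rows$cv <- tibble::tibble(
        analysis = "interannual", statistic = "cv",
        value = coefficient_of_variation(series), p_value = NA_real_,
        n = nrow(series)
      )
      rows$ms <- tibble::tibble(
        analysis = "interannual", statistic = "mean_sensitivity",
        value = mean_sensitivity(series), p_value = NA_real_, n = nrow(series)
      )
      zones_ok <- stats::complete.cases(metrics[, c("perpar_early", "perpar_late")])
      if (sum(zones_ok) >= 3 &&
        stats::sd(metrics$perpar_late[zones_ok] - metrics$perpar_early[zones_ok]) > 0) {
        tt <- paired_t_test(metrics$perpar_late[zones_ok], metrics$perpar_early[zones_ok])
        rows$tt <- tibble::tibble(
          analysis = "latewood_vs_earlywood_perpar", statistic = "t",
          value = tt$statistic, p_value = tt$p_value, n = tt$n
        )
      }
    }
    cross_out <- outlines[outlines$plane == "cross" & !outlines$edge_flag, , drop = FALSE]
    if (nrow(cross_out) >= 3 && stats::sd(cross_out$length_um) > 0) {
      fit <- fit_allometry(cross_out, length_um, area_um2)
      rows$allo <- tibble::tibble(
        analysis = "area_vs_length", statistic = "r_squared",
        value = fit$r_squared, p_value = fit$p_value, n = fit$n
      )
    }
    dplyr::bind_rows(rows)
  })
  stats_csv <- file.path(out_dir, "stats.csv")
  readr::write_csv(stats_tbl, stats_csv)
  note("stats", stats_csv)

  manifest <- dplyr::bind_rows(manifest)
  manifest$file <- sub(paste0("^", out_dir, "/?"), "", manifest$file)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  write_json_file(
    purrr::pmap(manifest, function(file, stage, md5) list(file = file, stage = stage, md5 = md5)),
    file.path(out_dir, "manifest.json")
  )
  invisible(manifest)
}

#' Plot a section label map
#'
#' @param object A [cut_section()] image.
#' @param max_pixels Downsample the raster to at most this many pixels.
#' @param ... Ignored.
#' @return A ggplot showing ray tissue and ring borders.
#' @export
autoplot.section_image <- function(object, max_pixels = 1e6, ...) {
  step <- max(1L, ceiling(sqrt(object$nx * object$ny / max_pixels)))
  rows <- seq(1L, object$ny, by = step)
  cols <- seq(1L, object$nx, by = step)
  px_mm <- um_to_mm(object$pixel_size_um)
  df <- expand.grid(
    y = object$y0 + (rows - 0.5) * px_mm,
    x = object$x0 + (cols - 0.5) * px_mm
  )
  df$ray <- as.vector(object$labels[rows, cols] > 0L)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$ray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95", `TRUE` = "firebrick4")) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = switch(object$plane, radial = "radial (mm)", "tangential (mm)"),
      y = switch(object$plane, cross = "radial (mm)", "axial (mm)"),
      fill = "ray"
    ) +
    ggplot2::theme_minimal()
  if (object$plane %in% c("cross", "radial") && !is.null(object$ring_borders)) {
    borders <- object$ring_borders
    gg <- gg + if (object$plane == "cross") {
      ggplot2::geom_hline(yintercept = borders, linewidth = 0.2, colour = "grey40")
    } else {
      ggplot2::geom_vline(xintercept = borders, linewidth = 0.2, colour = "grey40")
    }
  }
  gg
}
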