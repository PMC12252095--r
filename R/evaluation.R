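## Accuracy metrics and cohort experiments: dimension measurement along the
## symmetry system, the direct ellipsoid-fitting baseline, regression
## metrics (R^2, RMSE, relative RMSE), paired signed-rank tests, and the
## cohort runner that produces a completion-accuracy table per occlusion
## level.

#' Measure fruit dimensions along a symmetry system
#'
#' The extent (max minus min signed projection) along each of the three
#' system normals, sorted descending into length, width and height. The
#' same largest-first convention is used by the generator's ground truth,
#' so errors are directly comparable.
#'
#' @param cloud A non-empty point cloud (typically a completed fruit).
#' @param system A `symmetry_system`.
#' @return A one-row tibble: `length`, `width`, `height` (mm).
#' @export
measure_dimensions <- function(cloud, system) {
  stopifnot(inherits(system, "symmetry_system"))
  m <- as_xyz(cloud)
  if (nrow(m) == 0) stop("cannot measure an empty cloud", call. = FALSE)
  ext <- vapply(system$planes, function(p) {
    d <- signed_projection(m, p)
    max(d) - min(d)
  }, numeric(1))
  ext <- sort(ext, decreasing = TRUE)
  tibble::tibble(length = ext[1], width = ext[2], height = ext[3])
}

#' Baseline dimensions from direct ellipsoid fitting
#'
#' The conventional approach: fit an ellipsoid to the raw (occluded) cloud
#' with [fit_ellipsoid_ransac()] and report twice the semi-axes, sorted
#' descending. Serves as the comparison method for the completion pipeline.
#'
#' @param cloud The occluded fruit cloud, N >= 30.
#' @param config A [pipeline_config()].
#' @return A one-row tibble: `length`, `width`, `height` (mm).
#' @export
ellipsoid_baseline_dimensions <- function(cloud, config = pipeline_config()) {
  fit <- fit_ellipsoid_ransac(cloud, iters = config$ransac_iters,
                              inlier_tol = config$ransac_inlier_tol,
                              seed = stage_seed(config$seed, "baseline-ellipsoid"))
  d <- sort(2 * fit$semi_axes, decreasing = TRUE)
  tibble::tibble(length = d[1], width = d[2], height = d[3])
}

#' Regression metrics between predicted and true values
#'
#' `R^2 = 1 - SS_res / SS_tot`, `RMSE = sqrt(mean((pred - truth)^2))`,
#' `rRMSE = RMSE / mean(truth)`.
#'
#' @param predicted,truth Equal-length numeric vectors, length >= 2.
#' @return A one-row tibble: `r_squared`, `rmse`, `rrmse`.
#' @export
regression_metrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) >= 2)
  if (stats::sd(truth) == 0) {
    stop("R^2 is undefined for constant truth values", call. = FALSE)
  }
  res <- predicted - truth
  rmse <- sqrt(mean(res^2))
  tibble::tibble(r_squared = 1 - sum(res^2) / sum((truth - mean(truth))^2),
                 rmse = rmse,
                 rrmse = rmse / mean(truth))
}

#' Two-sided Wilcoxon signed-rank test on paired errors
#'
#' Zero differences are dropped first. The p-value is exact for n <= 25
#' remaining pairs without ties, and uses the normal approximation with tie
#' correction otherwise.
#'
#' @param errors_a,errors_b Equal-length numeric vectors of paired errors;
#'   at least 6 non-zero differences are required.
#' @return The two-sided p-value.
#' @examples
#' paired_signed_rank(1:8, (1:8) + 1) # 2 / 2^8
#' @export
paired_signed_rank <- function(errors_a, errors_b) {
  stopifnot(length(errors_a) == length(errors_b))
  d <- errors_a - errors_b
  d <- d[d != 0]
  if (length(d) == 0) stop("all paired differences are zero", call. = FALSE)
  if (length(d) < 6) stop("need at least 6 non-zero differences", call. = FALSE)
  ties <- any(duplicated(abs(d)))
  exact <- length(d) <= 25 && !ties
  res <- stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                            exact = exact, correct = TRUE)
  unname(res$p.value)
}

#' Run a completion-accuracy experiment over a cohort
#'
#' For every fruit in a [generate_cohort()] tibble, runs the requested
#' methods (symmetry completion and/or the ellipsoid baseline), measures
#' dimensions, and compares them to the generator's ground truth. Metrics
#' are aggregated per occlusion level and per dimension; paired
#' signed-rank p-values compare the two methods' absolute errors when both
#' ran.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param methods Character subset of `c("assm", "ellipsoid")`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory to write `per_fruit.csv`,
#'   `metrics.csv` and `report.json` into.
#' @return An `assm_experiment` list: `per_fruit` (one row per fruit and
#'   method), `metrics` (per level, method, dimension), `p_values`,
#'   `n_skipped`.
#' @export
run_experiment <- function(cohort, methods = c("assm", "ellipsoid"),
                           config = pipeline_config(), out_dir = NULL) {
  stopifnot(nrow(cohort) >= 1)
  methods <- match.arg(methods, c("assm", "ellipsoid"), several.ok = TRUE)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(cohort))) {
    truth <- cohort$truth[[i]]
    cl <- cohort$cloud[[i]]
    td <- truth$dimensions
    for (meth in methods) {
      dims <- tryCatch({
        if (meth == "assm") {
          comp <- assm_complete(cl, config, report = FALSE)
          measure_dimensions(comp$cloud, comp$system)
        } else {
          ellipsoid_baseline_dimensions(cl, config)
        }
      }, error = function(e) {
        message(sprintf("fruit %d (%s) skipped: %s", cohort$id[i], meth,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(dims)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = cohort$id[i], method = meth, level = cohort$level[i],
        occlusion = cohort$achieved_rate[i],
        dimension = c("length", "width", "height"),
        predicted = as.numeric(dims[1, ]),
        truth = td)
    }
  }
  per_fruit <- dplyr::bind_rows(rows)
  if (nrow(per_fruit) == 0) stop("every fruit failed in every method", call. = FALSE)

  metrics <- per_fruit |>
    dplyr::group_by(.data$level, .data$method, .data$dimension) |>
    dplyr::summarise(n = dplyr::n(),
                     metrics = list(regression_metrics(.data$predicted, .data$truth)),
                     .groups = "drop") |>
    tidyr::unnest("metrics")

  p_values <- NULL
  if (all(c("assm", "ellipsoid") %in% methods)) {
    wide <- per_fruit |>
      dplyr::mutate(abs_err = abs(.data$predicted - .data$truth)) |>
      dplyr::select("id", "level", "method", "dimension", "abs_err") |>
      tidyr::pivot_wider(names_from = "method", values_from = "abs_err")
    p_values <- wide |>
      dplyr::filter(!is.na(.data$assm), !is.na(.data$ellipsoid)) |>
      dplyr::group_by(.data$level, .data$dimension) |>
      dplyr::summarise(n = dplyr::n(),
                       p_value = tryCatch(
                         paired_signed_rank(.data$assm, .data$ellipsoid),
                         error = function(e) NA_real_),
                       .groups = "drop")
  }

  out <- structure(list(per_fruit = per_fruit, metrics = metrics,
                        p_values = p_values, n_skipped = skipped),
                   class = "assm_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_fruit, file.path(out_dir, "per_fruit.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(metrics = metrics, p_values = p_values, n_skipped = skipped),
      file.path(out_dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.assm_experiment <- function(x, ...) {
  cat("Completion-accuracy experiment:",
      dplyr::n_distinct(x$per_fruit$id), "fruits,",
      x$n_skipped, "method runs skipped\n")
  print(x$metrics, n = Inf)
  if (!is.null(x$p_values)) {
    cat("\nPaired signed-rank (|error| assm vs ellipsoid):\n")
    print(x$p_values, n = Inf)
  }
  invisible(x)
}
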