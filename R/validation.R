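# Template validation: agreement of the template's gross geometry with
# the population means (relative-deviation criterion) and k-fold
# cross-validation of template stability.

#' Deviation of template descriptors from population means
#'
#' For each gross parameter x in (V, A_surf, L_CL, D_med):
#' `dev = (x_template - mean(x_population)) / mean(x_population) * 100 %`.
#' The overall deviation is the arithmetic mean of the absolute
#' per-parameter deviations; a template below 5 % overall is considered a
#' good approximation of the population mean shape.
#'
#' @param template_desc named list/vector with the template's descriptors
#'   (a [compute_descriptors()] result works).
#' @param population_desc data frame (one row per subject) or named list
#'   of population means, containing the same parameters.
#' @param parameters which descriptors enter the criterion
#'   (default `c("V", "A_surf", "L_CL", "D_med")`).
#' @param threshold pass threshold on the overall deviation \[%\]
#'   (default 5).
#' @return a `deviation_report`: `deviation` (signed, %),
#'   `abs_deviation` (%), `total` (%), `pass`, `template_values`,
#'   `population_means`.
#' @export
template_deviation <- function(template_desc, population_desc,
                               parameters = c("V", "A_surf", "L_CL", "D_med"),
                               threshold = 5) {
  tv <- vapply(parameters, function(p) {
    x <- template_desc[[p]]
    if (is.null(x)) NA_real_ else as.numeric(x)
  }, numeric(1))
  if (is.data.frame(population_desc)) {
    pm <- vapply(parameters, function(p) mean(population_desc[[p]]), numeric(1))
  } else {
    pm <- vapply(parameters, function(p) {
      x <- population_desc[[p]]
      if (is.null(x)) NA_real_ else mean(as.numeric(x))
    }, numeric(1))
  }
  if (any(!is.finite(tv)) || any(!is.finite(pm))) {
    stop("descriptors incomplete for: ",
         paste(parameters[!is.finite(tv) | !is.finite(pm)], collapse = ", "))
  }
  if (any(pm == 0)) stop("zero population mean")
  dev <- (tv - pm) / pm * 100
  total <- mean(abs(dev))
  structure(list(deviation = dev, abs_deviation = abs(dev), total = total,
                 pass = total < threshold, threshold = threshold,
                 template_values = tv, population_means = pm),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("deviation_report (template vs population means):\n")
  for (p in names(x$deviation)) {
    cat(sprintf("  %-8s template %10.1f  mean %10.1f  deviation %5.1f %%\n",
                p, x$template_values[[p]], x$population_means[[p]],
                x$abs_deviation[[p]]))
  }
  cat(sprintf("  overall deviation %.1f %% -> %s (threshold %g %%)\n",
              x$total, if (x$pass) "pass" else "FAIL", x$threshold))
  invisible(x)
}

#' K-fold cross-validation of template stability
#'
#' Subjects are partitioned into `k` seeded random folds (sizes differing
#' by at most one); the template is recomputed `k` times, each time
#' leaving one fold out, with the identical kernel/configuration. Each
#' fold template is compared to the full-cohort template by symmetric
#' surface distance and (when descriptors are computable) by the
#' overall descriptor deviation. Alignment is reused from the full
#' cohort; only the template is recomputed per fold.
#'
#' @param surfaces list of aligned [triangle_surface()] objects.
#' @param kernel a [kernel_params()].
#' @param k number of folds (default 10; `k = length(surfaces)` gives
#'   leave-one-out).
#' @param seed fold-assignment seed.
#' @param full_template optional precomputed full-cohort `ssm_template`
#'   (computed here if missing).
#' @param atlas_args list of extra arguments for [compute_template()].
#' @param descriptor_fun function(surface) returning a named list with
#'   V, A_surf, L_CL, D_med; `"auto"` (default) uses
#'   [compute_descriptors()]; `NULL` skips the descriptor deviations.
#' @return a `crossval_report`: `k`, `folds` (assignment), `seed`,
#'   per-fold `max_distance`, `mean_distance` \[mm\], `deviation_total`
#'   \[%\], `failed` flags, and the `full_template`.
#' @export
kfold_validate <- function(surfaces, kernel, k = 10L, seed = 1L,
                           full_template = NULL, atlas_args = list(),
                           descriptor_fun = "auto") {
  n <- length(surfaces)
  if (n < 4L) stop("need at least 4 subjects")
  if (k > n) stop("k must not exceed the number of subjects")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  if (is.null(full_template)) {
    full_template <- do.call(compute_template,
                             c(list(surfaces = surfaces, kernel = kernel),
                               atlas_args))
  }
  if (identical(descriptor_fun, "auto")) {
    descriptor_fun <- function(s) {
      tryCatch(suppressWarnings(compute_descriptors(s)),
               error = function(e) NULL)
    }
  }
  full_desc <- if (is.function(descriptor_fun)) descriptor_fun(full_template$surface) else NULL
  max_d <- mean_d <- dev_tot <- rep(NA_real_, k)
  failed <- rep(FALSE, k)
  for (f in seq_len(k)) {
    keep <- which(folds != f)
    tmpl_f <- tryCatch(
      do.call(compute_template,
              c(list(surfaces = surfaces[keep], kernel = kernel),
                atlas_args)),
      error = function(e) NULL)
    if (is.null(tmpl_f)) {
      failed[f] <- TRUE
      next
    }
    sd_ <- surface_distance(tmpl_f$surface, full_template$surface)
    max_d[f] <- sd_$max
    mean_d[f] <- sd_$mean
    if (!is.null(full_desc)) {
      df <- descriptor_fun(tmpl_f$surface)
      if (!is.null(df)) {
        dev_tot[f] <- tryCatch(
          template_deviation(df, full_desc)$total, error = function(e) NA_real_)
      }
    }
  }
  structure(list(k = k, folds = folds, seed = seed,
                 max_distance = max_d, mean_distance = mean_d,
                 deviation_total = dev_tot, failed = failed,
                 full_template = full_template),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("crossval_report: k = %d (seed %d)\n", x$k, x$seed))
  ok <- !x$failed & is.finite(x$max_distance)
  if (any(ok)) {
    cat(sprintf("  fold-template max surface distance: %.3f-%.3f mm (mean of means %.3f mm)\n",
                min(x$max_distance[ok]), max(x$max_distance[ok]),
                mean(x$mean_distance[ok])))
  }
  if (any(is.finite(x$deviation_total))) {
    cat(sprintf("  fold descriptor deviation vs full template: %.1f-%.1f %%\n",
                min(x$deviation_total, na.rm = TRUE),
                max(x$deviation_total, na.rm = TRUE)))
  }
  if (any(x$failed)) cat("  failed folds:", which(x$failed), "\n")
  invisible(x)
}

#' Write validation reports to disk
#'
#' @param deviation a `deviation_report` (or `NULL`).
#' @param crossval a `crossval_report` (or `NULL`).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(deviation = NULL, crossval = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  if (!is.null(deviation)) {
    out$template_deviation <- list(
      deviation_percent = as.list(deviation$deviation),
      total_percent = deviation$total,
      pass = deviation$pass)
  }
  if (!is.null(crossval)) {
    out$cross_validation <- list(
      k = crossval$k, seed = crossval$seed, folds = crossval$folds,
      max_distance_mm = crossval$max_distance,
      mean_distance_mm = crossval$mean_distance,
      deviation_total_percent = crossval$deviation_total,
      failed = crossval$failed)
  }
  jsonlite::write_json(out, file.path(dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(crossval)) {
    utils::write.csv(
      data.frame(fold = seq_len(crossval$k),
                 max_distance_mm = crossval$max_distance,
                 mean_distance_mm = crossval$mean_distance,
                 deviation_total_percent = crossval$deviation_total,
                 failed = crossval$failed),
      file.path(dir, "crossval.csv"), row.names = FALSE)
  }
  invisible(dir)
}
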