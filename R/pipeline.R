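# End-to-end orchestration: alignment -> kernel estimation -> template ->
# moment matrix -> size (BSA) PLS -> residualization -> function (EF) PLS
# -> Cook screening. Used by the command-line interface, the validation
# studies and the worked examples.

#' Run the full shape-analysis pipeline on a cohort
#'
#' @param surfaces list of [triangle_surface()] objects (one per subject).
#' @param covariates data frame with one row per subject; columns `BSA`
#'   \[m^2\] and optionally `EF` \[%\] (plus anything else).
#' @param kernel a [kernel_params()]; if `NULL`, estimated from the
#'   smallest cohort surface area via the probed-fraction rule
#'   (p_W = 2.5 %, p_V = 25 %).
#' @param align `"icp"` (rigid ICP to the picked reference, default),
#'   `"gpa"` (full Procrustes loop) or `"none"` (surfaces already aligned).
#' @param atlas_args extra arguments for [compute_template()]
#'   (e.g. `outer_iter`, `inner_iter`, `n_time_steps`, `gamma`).
#' @param n_components PLS components per response (default 1).
#' @param cook_screen drop subjects flagged by [cooks_flag()] on the BSA
#'   fit before the final PLS fits (default TRUE, mirroring the outlier
#'   handling of the analysis protocol).
#' @return an `ssm_pipeline` list: `kernel`, `reference`, `aligned`,
#'   `template`, `moments`, `cook`, `kept` (indices after screening),
#'   `pls_bsa`, `sv_bsa`, `cor_bsa`, `moments_resid`, `pls_ef`, `sv_ef`,
#'   `cor_ef` (EF entries `NULL` when `covariates$EF` is absent).
#' @export
ssm_pipeline <- function(surfaces, covariates, kernel = NULL,
                         align = c("icp", "gpa", "none"),
                         atlas_args = list(), n_components = 1L,
                         cook_screen = TRUE) {
  align <- match.arg(align)
  n <- length(surfaces)
  stopifnot(nrow(covariates) == n, "BSA" %in% names(covariates))
  areas <- vapply(surfaces, function(s) surface_measures(s)$area, numeric(1))
  if (is.null(kernel)) kernel <- estimate_initial_lambdas(min(areas))
  # reference: subject closest to the population centre in gross geometry
  desc <- t(vapply(surfaces, function(s) {
    bb <- apply(s$vertices, 2L, range)
    ctr <- colMeans(s$vertices)
    c(a_surf = surface_measures(s)$area,
      bbox_diag = sqrt(sum((bb[2, ] - bb[1, ])^2)),
      mean_radius = mean(sqrt(rowSums(sweep(s$vertices, 2L, ctr)^2))))
  }, numeric(3)))
  reference <- pick_initial_reference(desc)
  if (align == "icp") {
    aligned <- lapply(surfaces, function(s)
      icp_rigid(s, surfaces[[reference]])$aligned)
    tmpl <- do.call(compute_template,
                    c(list(surfaces = aligned, kernel = kernel,
                           init = aligned[[reference]]), atlas_args))
  } else if (align == "gpa") {
    g <- gpa_align(surfaces, atlas_config = c(list(kernel = kernel), atlas_args),
                   reference = reference)
    aligned <- g$aligned
    tmpl <- g$template
  } else {
    aligned <- surfaces
    tmpl <- do.call(compute_template,
                    c(list(surfaces = aligned, kernel = kernel,
                           init = aligned[[reference]]), atlas_args))
  }
  mm <- moment_matrix(tmpl)
  bsa <- covariates$BSA
  cook <- cooks_flag(mm, bsa, n_components)
  kept <- seq_len(n)
  if (cook_screen && length(cook$flagged) > 0L) {
    kept <- setdiff(kept, cook$flagged)
  }
  mm_kept <- mm
  mm_kept$rows <- mm$rows[kept, , drop = FALSE]
  mm_kept$subject_ids <- mm$subject_ids[kept]
  pls_bsa <- pls_fit(mm_kept, bsa[kept], n_components)
  sv_bsa <- shape_vector(pls_bsa, mm_kept, response_name = "BSA")
  cor_bsa <- correlate(sv_bsa$values, bsa[kept])
  out <- list(kernel = kernel, reference = reference, aligned = aligned,
              template = tmpl, moments = mm, cook = cook, kept = kept,
              pls_bsa = pls_bsa, sv_bsa = sv_bsa, cor_bsa = cor_bsa,
              moments_resid = NULL, pls_ef = NULL, sv_ef = NULL,
              cor_ef = NULL)
  if ("EF" %in% names(covariates)) {
    mm_resid <- residualize(mm_kept, pls_bsa)
    pls_ef <- pls_fit(mm_resid, covariates$EF[kept], n_components)
    sv_ef <- shape_vector(pls_ef, mm_resid, response_name = "EF")
    out$moments_resid <- mm_resid
    out$pls_ef <- pls_ef
    out$sv_ef <- sv_ef
    out$cor_ef <- correlate(sv_ef$values, covariates$EF[kept])
  }
  class(out) <- "ssm_pipeline"
  out
}

#' @export
print.ssm_pipeline <- function(x, ...) {
  cat(sprintf("ssm_pipeline: %d subjects (%d kept after Cook screening)\n",
              length(x$aligned), length(x$kept)))
  print(x$kernel)
  cat(sprintf("  BSA shape vector vs BSA: %s = %.3f (p = %.3g)\n",
              if (x$cor_bsa$method == "pearson") "r" else "tau",
              x$cor_bsa$coefficient, x$cor_bsa$p_value))
  if (!is.null(x$cor_ef)) {
    cat(sprintf("  EF shape vector vs EF (size-residualized): %s = %.3f (p = %.3g)\n",
                if (x$cor_ef$method == "pearson") "r" else "tau",
                x$cor_ef$coefficient, x$cor_ef$p_value))
  }
  invisible(x)
}

# Read a cohort manifest CSV (subject_id, mesh_path, BSA, EF, ...) and the
# meshes it points to. Relative mesh paths resolve against the manifest's
# directory.
read_manifest <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "mesh_path") %in% names(rec))) {
    stop("manifest must have subject_id and mesh_path columns")
  }
  base <- dirname(path)
  surfaces <- lapply(seq_len(nrow(rec)), function(i) {
    p <- rec$mesh_path[i]
    if (!file.exists(p)) p <- file.path(base, basename(rec$mesh_path[i]))
    read_surface(p, subject_id = rec$subject_id[i])
  })
  attr(rec, "surfaces") <- surfaces
  rec
}
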