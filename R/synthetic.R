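# Seeded generator of aortic-arch-like tube meshes with analytic ground
# truth. The centreline is an ascending limb, a planar semi-elliptic arch
# (semi-axes T/2 and A) and a descending limb with a small sinusoidal
# lateral perturbation; circular cross-sections are swept along it with a
# radius profile carrying Gaussian narrowing/dilation bumps (root,
# transverse arch, isthmus) and an ascending-to-descending taper. Every
# quantity the morphometry module measures has a closed-form target here.

#' Parameters of one synthetic arch
#'
#' @param base_radius vessel radius \[mm\] before bumps/taper.
#' @param arch_height_A,arch_width_T semi-elliptic arch height and width
#'   \[mm\] (semi-axes A and T/2).
#' @param limb_asc,limb_desc straight limb lengths \[mm\].
#' @param multipliers named radius multipliers at `positions` (arc-length
#'   fractions); values in (0, 1.5]. Defaults: slightly dilated root,
#'   narrowed transverse arch and isthmus -- the repaired-coarctation
#'   pattern.
#' @param positions arc-length fractions of the bumps.
#' @param bump_width Gaussian bump width as arc-length fraction.
#' @param taper ascending-to-descending taper coefficient: the radius is
#'   multiplied by `1 + taper * (0.5 - s)` for arc fraction `s` (positive
#'   taper: wider ascending, slimmer descending aorta).
#' @param tortuosity_amp lateral sinusoidal perturbation amplitude \[mm\].
#' @param n_section points per cross-section ring.
#' @param axial_step spacing of rings along the centreline \[mm\].
#' @param noise_sd isotropic vertex jitter standard deviation \[mm\].
#' @param scale global similarity scale applied to all lengths.
#' @param seed RNG seed for the jitter (`NULL`: use current RNG state).
#' @return an `arch_params` object.
#' @export
arch_params <- function(base_radius = 8.5, arch_height_A = 45,
                        arch_width_T = 60, limb_asc = 40, limb_desc = 80,
                        multipliers = c(root = 1.15, trans = 0.85, isth = 0.78),
                        positions = c(root = 0.08, trans = 0.47, isth = 0.60),
                        bump_width = 0.035, taper = 0,
                        tortuosity_amp = 1.5, n_section = 16L,
                        axial_step = 3, noise_sd = 0.1, scale = 1,
                        seed = NULL) {
  stopifnot(length(multipliers) == length(positions))
  if (any(multipliers <= 0 | multipliers > 1.5)) {
    stop("multipliers must lie in (0, 1.5]")
  }
  structure(list(base_radius = base_radius, arch_height_A = arch_height_A,
                 arch_width_T = arch_width_T, limb_asc = limb_asc,
                 limb_desc = limb_desc, multipliers = multipliers,
                 positions = positions, bump_width = bump_width,
                 taper = taper, tortuosity_amp = tortuosity_amp,
                 n_section = as.integer(n_section), axial_step = axial_step,
                 noise_sd = noise_sd, scale = scale, seed = seed),
            class = "arch_params")
}

# Analytic centreline of the arch (before lateral perturbation), sampled
# at `ds` spacing; returns points, tangents and total length.
arch_centreline <- function(p, ds) {
  a <- p$arch_width_T / 2
  b <- p$arch_height_A
  # densely sample the ellipse to get an arc-length table
  th <- seq(0, pi, length.out = 2000L)
  ex <- a * cos(th)
  ez <- b * sin(th)
  seg <- sqrt(diff(ex)^2 + diff(ez)^2)
  arc <- c(0, cumsum(seg))
  L_arch <- arc[length(arc)]
  L_tot <- p$limb_asc + L_arch + p$limb_desc
  s <- seq(0, L_tot, by = ds)
  if (s[length(s)] < L_tot) s <- c(s, L_tot)
  pt <- matrix(0, length(s), 3L)
  for (i in seq_along(s)) {
    si <- s[i]
    if (si <= p$limb_asc) {
      pt[i, ] <- c(a, 0, -(p$limb_asc - si))
    } else if (si <= p$limb_asc + L_arch) {
      u <- si - p$limb_asc
      thi <- stats::approx(arc, th, xout = u)$y
      pt[i, ] <- c(a * cos(thi), 0, b * sin(thi))
    } else {
      u <- si - p$limb_asc - L_arch
      pt[i, ] <- c(-a, 0, -u)
    }
  }
  list(points = pt, s = s, L_tot = L_tot, L_arch = L_arch)
}

arch_radius_profile <- function(p, sfrac) {
  r <- rep(p$base_radius, length(sfrac))
  for (j in seq_along(p$multipliers)) {
    r <- r * (1 + (p$multipliers[[j]] - 1) *
                exp(-(sfrac - p$positions[[j]])^2 / (2 * p$bump_width^2)))
  }
  r * (1 + p$taper * (0.5 - sfrac))
}

#' Generate one synthetic arch mesh
#'
#' @param p an [arch_params()].
#' @param subject_id id attached to the mesh.
#' @return a [triangle_surface()] (open tube, 2 boundary loops) with the
#'   ground-truth parameters attached as attribute `ground_truth`.
#' @export
generate_arch <- function(p, subject_id = NULL) {
  stopifnot(inherits(p, "arch_params"))
  if (!is.null(p$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(p$seed)
  }
  cl <- arch_centreline(p, p$axial_step)
  P <- cl$points
  sfrac <- cl$s / cl$L_tot
  # lateral sinusoidal perturbation, zero at both ends
  P[, 2] <- P[, 2] + p$tortuosity_amp * sin(2 * pi * sfrac)
  r <- arch_radius_profile(p, sfrac)
  # parallel-transport frames along the polyline
  n <- nrow(P)
  tang <- rbind(P[2L, ] - P[1L, ],
                P[3:n, , drop = FALSE] - P[1:(n - 2L), , drop = FALSE],
                P[n, ] - P[n - 1L, ])
  tang <- tang / rownorm(tang)
  e1 <- c(0, 1, 0)
  e1 <- e1 - sum(e1 * tang[1L, ]) * tang[1L, ]
  e1 <- e1 / sqrt(sum(e1^2))
  th <- seq(0, 2 * pi, length.out = p$n_section + 1L)[-(p$n_section + 1L)]
  V <- matrix(0, n * p$n_section, 3L)
  for (i in seq_len(n)) {
    if (i > 1L) {
      # transport e1 to the new tangent
      t_prev <- tang[i - 1L, ]; t_cur <- tang[i, ]
      ax <- c(t_prev[2] * t_cur[3] - t_prev[3] * t_cur[2],
              t_prev[3] * t_cur[1] - t_prev[1] * t_cur[3],
              t_prev[1] * t_cur[2] - t_prev[2] * t_cur[1])
      sa <- sqrt(sum(ax^2))
      ca <- sum(t_prev * t_cur)
      if (sa > 1e-12) {
        ax <- ax / sa
        kxv <- c(ax[2] * e1[3] - ax[3] * e1[2],
                 ax[3] * e1[1] - ax[1] * e1[3],
                 ax[1] * e1[2] - ax[2] * e1[1])
        # Rodrigues: v cos + (k x v) sin + k (k.v)(1 - cos)
        e1 <- e1 * ca + kxv * sa + ax * sum(ax * e1) * (1 - ca)
        e1 <- e1 / sqrt(sum(e1^2))
      }
      e1 <- e1 - sum(e1 * t_cur) * t_cur
      e1 <- e1 / sqrt(sum(e1^2))
    }
    e2 <- c(tang[i, 2] * e1[3] - tang[i, 3] * e1[2],
            tang[i, 3] * e1[1] - tang[i, 1] * e1[3],
            tang[i, 1] * e1[2] - tang[i, 2] * e1[1])
    ring <- outer(cos(th), e1) + outer(sin(th), e2)
    V[(i - 1L) * p$n_section + seq_len(p$n_section), ] <-
      sweep(r[i] * ring, 2L, -P[i, ])
  }
  f <- NULL
  ns <- p$n_section
  idx <- function(i, j) (i - 1L) * ns + ((j - 1L) %% ns) + 1L
  i_all <- rep(seq_len(n - 1L), each = ns)
  j_all <- rep(seq_len(ns), n - 1L)
  a_ <- idx(i_all, j_all); b_ <- idx(i_all, j_all + 1L)
  c_ <- idx(i_all + 1L, j_all); d_ <- idx(i_all + 1L, j_all + 1L)
  f <- rbind(cbind(a_, b_, d_), cbind(a_, d_, c_))
  V <- V * p$scale
  if (p$noise_sd > 0) {
    V <- V + matrix(stats::rnorm(length(V), sd = p$noise_sd), ncol = 3L)
  }
  s <- triangle_surface(V, f, subject_id = subject_id)
  attr(s, "ground_truth") <- list(
    A = p$arch_height_A * p$scale, T = p$arch_width_T * p$scale,
    base_radius = p$base_radius * p$scale,
    D_base = 2 * p$base_radius * p$scale,
    L_tot = cl$L_tot * p$scale, L_arch = cl$L_arch * p$scale,
    limb_asc = p$limb_asc * p$scale, limb_desc = p$limb_desc * p$scale,
    radius_at = function(sf) arch_radius_profile(p, sf) * p$scale,
    params = p)
  s
}

#' Cohort specification for the synthetic population
#'
#' Emulates the statistical structure the shape analyses assume: vessel
#' size scales with a body-surface-area covariate, and ventricular
#' function (ejection fraction) is linked to the ascending-to-descending
#' taper and to the arch roundness (high EF: rounder, more tapered arch).
#'
#' @param n number of subjects.
#' @param bsa_mean,bsa_sd BSA distribution \[m^2\] (default 1.6 +/- 0.2,
#'   an adolescent post-repair cohort).
#' @param bsa_slope global scale change per m^2 of BSA.
#' @param ef_mean,ef_sd EF distribution \[%\] (default 60 +/- 8).
#' @param k_taper taper units per EF standard deviation.
#' @param k_round relative A (down) / T (up) change per EF standard
#'   deviation.
#' @param coupling_noise_sd additive noise on the coupled shape parameters
#'   (taper and relative A/T change), default 0.03; 0 gives a noiseless
#'   covariate-to-shape map.
#' @param noise_sd vertex jitter \[mm\] passed to each arch.
#' @param outlier plant one influential subject (the last): an oversized,
#'   extreme-A/T arch whose covariates do not follow the cohort maps.
#' @param mesh mesh resolution arguments forwarded to [arch_params()]
#'   (`n_section`, `axial_step`).
#' @param seed cohort RNG seed.
#' @return a `population_spec` object.
#' @export
population_spec <- function(n = 12L, bsa_mean = 1.6, bsa_sd = 0.2,
                            bsa_slope = 0.45, ef_mean = 60, ef_sd = 8,
                            k_taper = 0.12, k_round = 0.10,
                            coupling_noise_sd = 0.03, noise_sd = 0.1,
                            outlier = FALSE,
                            mesh = list(n_section = 8L, axial_step = 10),
                            seed = 1L) {
  if (n < 2L) stop("need n >= 2")
  structure(list(n = as.integer(n), bsa_mean = bsa_mean, bsa_sd = bsa_sd,
                 bsa_slope = bsa_slope, ef_mean = ef_mean, ef_sd = ef_sd,
                 k_taper = k_taper, k_round = k_round,
                 coupling_noise_sd = coupling_noise_sd, noise_sd = noise_sd,
                 outlier = outlier, mesh = mesh, seed = seed),
            class = "population_spec")
}

#' Generate a synthetic cohort
#'
#' Draws covariates, maps them to per-subject arch parameters through the
#' linear models of the [population_spec()], builds the meshes and (when
#' `out_dir` is given) writes them plus a manifest CSV with columns
#' `subject_id, mesh_path, BSA, EF, age, height` and ground-truth columns
#' prefixed `gt_`.
#'
#' @param spec a [population_spec()].
#' @param out_dir optional output directory for meshes (VTK) and manifest.
#' @return data frame of subject records; the meshes are attached as
#'   attribute `surfaces` (a list of [triangle_surface()]).
#' @export
generate_population <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n
  BSA <- stats::rnorm(n, spec$bsa_mean, spec$bsa_sd)
  EF <- stats::rnorm(n, spec$ef_mean, spec$ef_sd)
  z_bsa <- (BSA - spec$bsa_mean) / spec$bsa_sd
  z_ef <- (EF - spec$ef_mean) / spec$ef_sd
  height <- 1500 + 220 * z_bsa + stats::rnorm(n, 0, 40)      # mm
  age <- 16 + 2.5 * z_bsa + stats::rnorm(n, 0, 1.2)          # years
  cns <- spec$coupling_noise_sd
  scale <- 1 + spec$bsa_slope * (BSA - spec$bsa_mean)
  taper <- spec$k_taper * z_ef + stats::rnorm(n, 0, cns)
  round_fac <- spec$k_round * z_ef + stats::rnorm(n, 0, cns)
  A0 <- 45; T0 <- 60
  A_ <- A0 * (1 - round_fac)
  T_ <- T0 * (1 + round_fac)
  if (spec$outlier) {
    # emulates an influential subject: considerably larger than the rest
    # of the cohort and extremely gothic (high A, narrow T), while its
    # recorded covariates stay at their drawn values
    scale[n] <- 1.5
    A_[n] <- A0 * 1.45
    T_[n] <- T0 * 0.70
    taper[n] <- -0.15
  }
  subject_seeds <- spec$seed + 1000L + seq_len(n)
  surfaces <- vector("list", n)
  ids <- sprintf("SYN%02d", seq_len(n))
  for (i in seq_len(n)) {
    p <- arch_params(arch_height_A = A_[i], arch_width_T = T_[i],
                     taper = taper[i], noise_sd = spec$noise_sd,
                     scale = scale[i], seed = subject_seeds[i],
                     n_section = spec$mesh$n_section %||% 8L,
                     axial_step = spec$mesh$axial_step %||% 10)
    surfaces[[i]] <- generate_arch(p, subject_id = ids[i])
  }
  mesh_path <- rep(NA_character_, n)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      mesh_path[i] <- file.path(out_dir, paste0(ids[i], ".vtk"))
      write_surface(surfaces[[i]], mesh_path[i])
    }
  }
  rec <- data.frame(subject_id = ids, mesh_path = mesh_path,
                    BSA = BSA, EF = EF, age = age, height = height,
                    gt_scale = scale, gt_taper = taper,
                    gt_A = A_, gt_T = T_,
                    gt_is_outlier = spec$outlier & seq_len(n) == n)
  if (!is.null(out_dir)) {
    utils::write.csv(rec, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  attr(rec, "surfaces") <- surfaces
  rec
}
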