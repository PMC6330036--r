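#' Phantom parameters for a synthetic vertebral CT study
#'
#' Bundles the geometry, densitometry, imaging and longitudinal-dynamics
#' parameters of the elliptical-shell vertebra phantom. The phantom is a
#' high-density cortical shell of constant true thickness (an inward-offset
#' ring of the outer ellipse) around a lower-density cancellous interior with
#' smooth stochastic texture, imaged as calibrated density maps (mg/cm^3)
#' with Gaussian partial-volume blur and additive noise.
#'
#' Defaults describe a young rat lumbar vertebral body: outer semi-axes
#' 0.22 x 0.16 cm, 0.04 cm cortical shell, 0.6 cm body height sliced at
#' 0.1 cm intervals (6 slices per vertebra, 18 over L2-L4), cortical
#' 900 mg/cm^3, cancellous 300 mg/cm^3. Growth is multiplicative per day;
#' the fasting intervention halts geometric growth and turns density accrual
#' into loss while it lasts, then lets density catch up at a boosted rate
#' (capped at the control trajectory), while a persistent mineral
#' redistribution spreads the cortical shell inward at constant total mineral
#' (a thicker but less dense shell), which lowers the density-weighted
#' moments at matched BMD.
#'
#' @param outer_semiaxes half-width and half-depth of the vertebral body
#'   cross-section, cm.
#' @param cortical_thickness cortical shell thickness, cm; must be smaller
#'   than the shell's minimum radius of curvature.
#' @param body_height vertebral body extent along the axis, cm.
#' @param cortical_density,cancellous_density_mean compartment densities,
#'   mg/cm^3; cortical must exceed cancellous.
#' @param cancellous_texture_sd standard deviation of the smoothed cancellous
#'   density fluctuation, mg/cm^3.
#' @param texture_corr_px Gaussian correlation length of the texture, pixels.
#' @param pixel_spacing isotropic in-plane pixel spacing, cm.
#' @param slice_interval_d inter-slice interval d, cm (default 0.1 cm = 1 mm).
#' @param blur_sigma partial-volume blur, pixels.
#' @param noise_sd additive imaging noise, mg/cm^3.
#' @param growth_rates list with per-day fractional increases `semiaxes`,
#'   `thickness`, `height`, `density`.
#' @param fasting_effect list with `geometry_during_fast` and
#'   `density_during_fast` (multipliers on the respective growth rates while
#'   the fast lasts; 1 = no effect), `density_recovery` (multiplier after the
#'   fast until the control trajectory is reached), and
#'   `redistribution_rate` (per-day increment of the persistent shell-spread
#'   fraction; 0 = no effect).
#' @param subject_sd list with lognormal between-subject standard deviations
#'   `geometry` and `density`.
#' @param vertebra_factors named size multipliers for the vertebrae (L2-L4).
#' @param calibration list with the 16-bit TIFF `slope` and `intercept`
#'   (density = slope * pixel value + intercept).
#' @param fov_margin background margin around the largest vertebra, cm.
#' @param seed master seed; the same seed and parameters regenerate the study
#'   bit-identically.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(outer_semiaxes = c(0.22, 0.16),
                           cortical_thickness = 0.04,
                           body_height = 0.60,
                           cortical_density = 900,
                           cancellous_density_mean = 300,
                           cancellous_texture_sd = 30,
                           texture_corr_px = 2,
                           pixel_spacing = 0.005,
                           slice_interval_d = 0.1,
                           blur_sigma = 0.8,
                           noise_sd = 20,
                           growth_rates = list(semiaxes = 0.006,
                                               thickness = 0.006,
                                               height = 0.010,
                                               density = 0.015),
                           fasting_effect = list(geometry_during_fast = -1,
                                                 density_during_fast = -3,
                                                 density_recovery = 5,
                                                 redistribution_rate = 0.08),
                           subject_sd = list(geometry = 0.02, density = 0.03),
                           vertebra_factors = c(L2 = 0.97, L3 = 1.00,
                                                L4 = 1.03),
                           calibration = list(slope = 0.05, intercept = 0),
                           fov_margin = 0.10,
                           seed = 1L) {
  p <- list(outer_semiaxes = as.numeric(outer_semiaxes),
            cortical_thickness = cortical_thickness,
            body_height = body_height,
            cortical_density = cortical_density,
            cancellous_density_mean = cancellous_density_mean,
            cancellous_texture_sd = cancellous_texture_sd,
            texture_corr_px = texture_corr_px,
            pixel_spacing = pixel_spacing,
            slice_interval_d = slice_interval_d,
            blur_sigma = blur_sigma,
            noise_sd = noise_sd,
            growth_rates = growth_rates,
            fasting_effect = fasting_effect,
            subject_sd = subject_sd,
            vertebra_factors = vertebra_factors,
            calibration = calibration,
            fov_margin = fov_margin,
            seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  lens <- c(p$outer_semiaxes, p$cortical_thickness, p$body_height,
            p$pixel_spacing, p$slice_interval_d)
  if (length(p$outer_semiaxes) != 2L || any(lens <= 0)) {
    stop("all lengths (semiaxes, thickness, height, spacing, interval) ",
         "must be positive")
  }
  if (p$cortical_thickness >= min(p$outer_semiaxes)) {
    stop("cortical_thickness must be smaller than the smallest semi-axis")
  }
  if (!(p$cortical_density > p$cancellous_density_mean) ||
      p$cancellous_density_mean < 0) {
    stop("require cortical_density > cancellous_density_mean >= 0")
  }
  if (p$cancellous_texture_sd < 0 || p$noise_sd < 0 || p$blur_sigma < 0) {
    stop("texture/noise/blur parameters must be non-negative")
  }
  need <- c("semiaxes", "thickness", "height", "density")
  if (!all(need %in% names(p$growth_rates))) {
    stop("growth_rates must name: ", paste(need, collapse = ", "))
  }
  need <- c("geometry_during_fast", "density_during_fast",
            "density_recovery", "redistribution_rate")
  if (!all(need %in% names(p$fasting_effect))) {
    stop("fasting_effect must name: ", paste(need, collapse = ", "))
  }
  invisible(p)
}

#' Neutral fasting effect (null generator)
#'
#' Fasting-effect multipliers that make the fasting arm statistically
#' exchangeable with the control arm: all growth multipliers 1, no
#' redistribution. Used for type-I-error calibration.
#'
#' @return a list suitable for the `fasting_effect` field of
#'   [phantom_params()].
#' @export
fasting_effect_null <- function() {
  list(geometry_during_fast = 1, density_during_fast = 1,
       density_recovery = 1, redistribution_rate = 0)
}

#' Longitudinal study design
#'
#' Two-arm design mirroring a fasting experiment: a control arm fed ad
#' libitum and a fasting arm fasted from `fast_start_day` to `fast_end_day`,
#' imaged on `imaging_days`. Defaults follow a 14-day study with a 4-day
#' fast, 5 control and 6 fasting subjects, imaging every other day.
#'
#' @param n_control,n_fasting subjects per arm (each >= 1).
#' @param total_days study length, days.
#' @param fast_start_day,fast_end_day fasting window, days;
#'   `0 <= start < end <= total_days`.
#' @param imaging_days sorted unique imaging days within `[0, total_days]`.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_control = 5L, n_fasting = 6L, total_days = 14L,
                         fast_start_day = 0L, fast_end_day = 4L,
                         imaging_days = seq(0L, 14L, by = 2L)) {
  d <- list(n_control = as.integer(n_control),
            n_fasting = as.integer(n_fasting),
            total_days = as.integer(total_days),
            fast_start_day = as.integer(fast_start_day),
            fast_end_day = as.integer(fast_end_day),
            imaging_days = as.integer(imaging_days))
  if (d$n_control < 1L || d$n_fasting < 1L) {
    stop("both groups need at least one subject ",
         "(n_control = ", d$n_control, ", n_fasting = ", d$n_fasting, ")")
  }
  if (!(0L <= d$fast_start_day && d$fast_start_day < d$fast_end_day &&
        d$fast_end_day <= d$total_days)) {
    stop("require 0 <= fast_start_day < fast_end_day <= total_days")
  }
  if (is.unsorted(d$imaging_days, strictly = TRUE) ||
      any(d$imaging_days < 0L) || any(d$imaging_days > d$total_days)) {
    stop("imaging_days must be sorted, unique and within [0, total_days]")
  }
  structure(d, class = "study_design")
}

# Per-day multiplicative state of a unit (factor-1) subject: cumulative
# geometry/thickness/height/density factors and the shell-spread fraction.
# Density in the fasting arm is capped at the control trajectory once the
# boosted post-fast accrual has caught up.
growth_schedule <- function(params, design, group) {
  days <- 0:design$total_days
  fasted <- identical(group, "fasting")
  g <- params$growth_rates
  fe <- params$fasting_effect
  n <- length(days)
  geom <- thick <- height <- dens <- dens_ctrl <- rep.int(1, n)
  spread <- numeric(n)
  for (k in seq_len(n)[-1L]) {
    d <- days[k]
    in_fast <- fasted && d > design$fast_start_day && d <= design$fast_end_day
    post_fast <- fasted && d > design$fast_end_day
    gm <- if (in_fast) fe$geometry_during_fast else 1
    dm <- if (in_fast) {
      fe$density_during_fast
    } else if (post_fast) {
      fe$density_recovery
    } else 1
    geom[k] <- geom[k - 1L] * (1 + g$semiaxes * gm)
    thick[k] <- thick[k - 1L] * (1 + g$thickness * gm)
    height[k] <- height[k - 1L] * (1 + g$height * gm)
    dens_ctrl[k] <- dens_ctrl[k - 1L] * (1 + g$density)
    dens[k] <- dens[k - 1L] * (1 + g$density * dm)
    if (fasted && dens[k] > dens_ctrl[k]) dens[k] <- dens_ctrl[k]
    spread[k] <- if (fasted && d > design$fast_start_day) {
      spread[k - 1L] + fe$redistribution_rate
    } else 0
  }
  data.frame(day = days, geom = geom, thick = thick, height = height,
             dens = dens, spread = spread)
}

# Analytic state of a unit subject / unit vertebra on one day. The
# redistribution dilutes the cortical shell at constant total mineral:
# the shell thickens by (1 + spread) and its density is rescaled so that
# shell mineral plus displaced cancellous mineral is conserved, leaving BMD
# untouched while the mineral moves inward.
day_state <- function(params, srow) {
  a <- params$outer_semiaxes[1] * srow$geom
  b <- params$outer_semiaxes[2] * srow$geom
  t_nom <- params$cortical_thickness * srow$thick
  t_eff <- t_nom * (1 + srow$spread)
  pr_nom <- offset_region_props(a, b, t_nom)
  pr_eff <- if (srow$spread > 0) offset_region_props(a, b, t_eff) else pr_nom
  area_out <- pi * a * b
  rho_t <- params$cancellous_density_mean * srow$dens
  rho_c_nom <- params$cortical_density * srow$dens
  rho_c <- (rho_c_nom * (area_out - pr_nom$area) +
              rho_t * (pr_nom$area - pr_eff$area)) / (area_out - pr_eff$area)
  list(a = a, b = b, t_eff = t_eff, rho_c = rho_c, rho_t = rho_t,
       area_out = area_out, area_in = pr_eff$area,
       ixx_in = pr_eff$Ixx, iyy_in = pr_eff$Iyy,
       height = params$body_height * srow$height)
}

# Apply the subject geometry/density factors and the vertebra size factor.
# The offset geometry scales exactly under uniform scaling (k^2 for areas,
# k^4 for second moments), so the boundary quadrature runs once per
# (group, day) and is reused across subjects and vertebrae.
scale_state <- function(st, k_geom, k_dens, vfac) {
  kk <- k_geom * vfac
  list(a = st$a * kk, b = st$b * kk, t_eff = st$t_eff * kk,
       rho_c = st$rho_c * k_dens, rho_t = st$rho_t * k_dens,
       area_out = st$area_out * kk^2, area_in = st$area_in * kk^2,
       ixx_in = st$ixx_in * kk^4, iyy_in = st$iyy_in * kk^4,
       height = st$height * kk)
}

state_n_slices <- function(state, d) {
  max(2L, as.integer(round(state$height / d)))
}

# True morphometry of one subject on one day from the analytic states of its
# vertebrae (closed-form outer ellipse + offset-region quadrature); matches
# the conventions of the measurement pipeline (L2-L4 aggregation, lengths in
# mm, moments averaged per slice).
truth_from_states <- function(states, d) {
  per_v <- lapply(states, function(s) {
    n <- state_n_slices(s, d)
    ring <- s$area_out - s$area_in
    mineral_slice <- s$rho_c * ring + s$rho_t * s$area_in
    ix_out <- pi * s$a * s$b^3 / 4
    iy_out <- pi * s$a^3 * s$b / 4
    ix <- s$rho_c * (ix_out - s$ixx_in) + s$rho_t * s$ixx_in
    iy <- s$rho_c * (iy_out - s$iyy_in) + s$rho_t * s$iyy_in
    list(n = n, area = s$area_out, mineral = mineral_slice,
         i_min = min(ix, iy), j = ix + iy, width = 2 * s$a, t = s$t_eff)
  })
  n <- vapply(per_v, `[[`, integer(1), "n")
  volume <- sum(n * vapply(per_v, `[[`, numeric(1), "area")) * d
  mineral <- sum(n * vapply(per_v, `[[`, numeric(1), "mineral")) * d
  data.frame(bmd = mineral / volume,
             mineral_content = mineral,
             volume = volume,
             cortical_thickness = mean(vapply(per_v, `[[`, numeric(1), "t")) * 10,
             body_height = mean(n) * d * 10,
             body_width = mean(vapply(per_v, `[[`, numeric(1), "width")) * 10,
             min_moment = sum(n * vapply(per_v, `[[`, numeric(1), "i_min")) / sum(n),
             polar_moment = sum(n * vapply(per_v, `[[`, numeric(1), "j")) / sum(n))
}

# Field of view wide enough for the largest vertebra of the largest subject
# on the last day, plus the background margin; fixed per study.
study_fov <- function(params, design) {
  gmax <- (1 + params$growth_rates$semiaxes)^design$total_days
  amax <- max(params$outer_semiaxes) * gmax * max(params$vertebra_factors) *
    exp(4 * params$subject_sd$geometry)
  2 * amax + 2 * params$fov_margin
}

render_slice <- function(params, state, dim_px, center, rotation) {
  h <- params$pixel_spacing
  xs <- (seq_len(dim_px[2]) - 0.5) * h - center[1]
  ys <- (seq_len(dim_px[1]) - 0.5) * h - center[2]
  gx <- matrix(xs, nrow = dim_px[1], ncol = dim_px[2], byrow = TRUE)
  gy <- matrix(ys, nrow = dim_px[1], ncol = dim_px[2])
  u <- cos(rotation) * gx + sin(rotation) * gy
  v <- -sin(rotation) * gx + cos(rotation) * gy
  sd_map <- matrix(ellipse_signed_distance(as.vector(u), as.vector(v),
                                           state$a, state$b),
                   nrow = dim_px[1])
  dens <- matrix(0, dim_px[1], dim_px[2])
  cortical <- sd_map < 0 & sd_map >= -state$t_eff
  cancellous <- sd_map < -state$t_eff
  dens[cortical] <- state$rho_c
  if (any(cancellous)) {
    if (params$cancellous_texture_sd > 0 && sum(cancellous) > 1L) {
      z <- matrix(stats::rnorm(prod(dim_px)), dim_px[1], dim_px[2])
      if (params$texture_corr_px > 0) {
        z <- EBImage::gblur(z, sigma = params$texture_corr_px)
      }
      zc <- z[cancellous]
      zc <- (zc - mean(zc)) / stats::sd(zc) * params$cancellous_texture_sd
      dens[cancellous] <- state$rho_t + zc
    } else {
      dens[cancellous] <- state$rho_t
    }
  }
  if (params$blur_sigma > 0) {
    dens <- EBImage::gblur(dens, sigma = params$blur_sigma)
  }
  if (params$noise_sd > 0) {
    dens <- dens + matrix(stats::rnorm(prod(dim_px), sd = params$noise_sd),
                          dim_px[1], dim_px[2])
  }
  dens
}

#' Generate one phantom cross-section
#'
#' Renders a single calibrated density map (mg/cm^3): an elliptical cortical
#' ring around a textured cancellous interior, optionally blurred and with
#' additive noise. The background is exactly zero before noise. A
#' `slice_index` outside the body extent returns an all-zero map flagged with
#' attribute `out_of_extent`.
#'
#' @param params a [phantom_params()] object.
#' @param subject_state analytic slice state as produced internally by the
#'   study generator; defaults to the day-0 unit subject (L3) of `params`.
#' @param slice_index 1-based slice position along the body axis.
#' @param seed integer seed for the texture/noise stream (`NULL` continues
#'   the current RNG stream).
#' @param dim_px image dimensions `c(rows, cols)`; default sized from the
#'   field of view.
#' @param center phantom centre in cm; default the image centre.
#' @param rotation in-plane rotation of the phantom, radians.
#' @return density matrix (mg/cm^3), attribute `out_of_extent` if flagged.
#' @export
generate_slice <- function(params, subject_state = NULL, slice_index = 1L,
                           seed = NULL, dim_px = NULL, center = NULL,
                           rotation = 0) {
  if (is.null(subject_state)) {
    sched <- growth_schedule(params, study_design(), "control")
    subject_state <- day_state(params, sched[1L, ])
  }
  if (is.null(dim_px)) {
    n <- as.integer(ceiling((2 * max(subject_state$a, subject_state$b) +
                               2 * params$fov_margin) /
                              params$pixel_spacing))
    dim_px <- c(n, n)
  }
  if (is.null(center)) {
    center <- c(dim_px[2], dim_px[1]) * params$pixel_spacing / 2
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_sl <- state_n_slices(subject_state, params$slice_interval_d)
  if (slice_index < 1L || slice_index > n_sl) {
    out <- matrix(0, dim_px[1], dim_px[2])
    attr(out, "out_of_extent") <- TRUE
    return(out)
  }
  render_slice(params, subject_state, dim_px, center, rotation)
}

render_subject_stack <- function(params, states, seed, dim_px, center,
                                 rotation = 0) {
  set.seed(as.integer(seed))
  slices <- list()
  labels <- list()
  idx <- 0L
  d <- params$slice_interval_d
  for (v in names(states)) {
    n_sl <- state_n_slices(states[[v]], d)
    first <- idx + 1L
    for (i in seq_len(n_sl)) {
      idx <- idx + 1L
      slices[[idx]] <- render_slice(params, states[[v]], dim_px, center,
                                    rotation)
    }
    labels[[v]] <- c(first, idx)
  }
  calibrated_stack(slices, pixel_spacing = params$pixel_spacing,
                   slice_interval_d = d, vertebra_labels = labels)
}

#' Generate a longitudinal two-arm phantom study
#'
#' Simulates every subject of a two-arm fasting study at every imaging day.
#' Between-subject variability enters as lognormal size and density factors;
#' within a subject the trajectory follows the multiplicative growth model of
#' [phantom_params()]. Ground truth records, per subject and imaging day,
#' the analytically exact values of every quantity the measurement pipeline
#' estimates.
#'
#' Reproducibility: subject factors and per-(subject, day) rendering seeds
#' are all drawn up front from the master seed, so regeneration is
#' bit-identical and independent of evaluation order.
#'
#' @param params a [phantom_params()] object.
#' @param design a [study_design()] object.
#' @param render if `FALSE`, skip image rendering and return ground truth
#'   only (used for generator-level calibration at many replicates).
#' @return list with `subjects` (data frame: subject_id, group, factors,
#'   seed), `ground_truth` (data frame, one row per subject x imaging day),
#'   and if `render = TRUE` a `stacks` list of lists
#'   (`stacks[[subject_id]][[as.character(day)]]`, each a
#'   [calibrated_stack()]).
#' @export
generate_study <- function(params, design, render = TRUE) {
  stopifnot(inherits(params, "phantom_params"),
            inherits(design, "study_design"))
  n_tot <- design$n_control + design$n_fasting
  set.seed(params$seed)
  subjects <- data.frame(
    subject_id = c(sprintf("C%02d", seq_len(design$n_control)),
                   sprintf("F%02d", seq_len(design$n_fasting))),
    group = rep(c("control", "fasting"),
                c(design$n_control, design$n_fasting)),
    stringsAsFactors = FALSE)
  subjects$k_geom <- exp(stats::rnorm(n_tot, 0, params$subject_sd$geometry))
  subjects$k_dens <- exp(stats::rnorm(n_tot, 0, params$subject_sd$density))
  n_days <- length(design$imaging_days)
  day_seed <- matrix(sample.int(.Machine$integer.max - 1L, n_tot * n_days),
                     nrow = n_tot)

  sched <- list(control = growth_schedule(params, design, "control"),
                fasting = growth_schedule(params, design, "fasting"))
  unit_states <- lapply(sched, function(s) {
    lapply(design$imaging_days, function(dday) {
      day_state(params, s[s$day == dday, ])
    })
  })

  fov <- study_fov(params, design)
  dim_px <- rep(as.integer(ceiling(fov / params$pixel_spacing)), 2L)
  center <- c(dim_px[2], dim_px[1]) * params$pixel_spacing / 2

  gt <- vector("list", n_tot * n_days)
  stacks <- if (render) stats::setNames(vector("list", n_tot),
                                        subjects$subject_id)
  row <- 0L
  for (i in seq_len(n_tot)) {
    grp <- subjects$group[i]
    if (render) stacks[[i]] <- list()
    for (j in seq_len(n_days)) {
      row <- row + 1L
      ust <- unit_states[[grp]][[j]]
      states <- lapply(params$vertebra_factors, function(vf) {
        scale_state(ust, subjects$k_geom[i], subjects$k_dens[i], vf)
      })
      names(states) <- names(params$vertebra_factors)
      gt[[row]] <- cbind(
        data.frame(subject_id = subjects$subject_id[i], group = grp,
                   day = design$imaging_days[j], stringsAsFactors = FALSE),
        truth_from_states(states, params$slice_interval_d))
      if (render) {
        stacks[[i]][[as.character(design$imaging_days[j])]] <-
          render_subject_stack(params, states, day_seed[i, j], dim_px, center)
      }
    }
  }
  out <- list(subjects = subjects, ground_truth = do.call(rbind, gt),
              design = design, params = params)
  if (render) out$stacks <- stacks
  out
}
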