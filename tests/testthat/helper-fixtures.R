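# Fixture builders shared across the suite. Everything is generated in code
# at test time; no binary fixtures.

# noiseless, blur-free phantom parameter set (texture optional)
quiet_params <- function(spacing = 0.005, texture_sd = 0, ...) {
  phantom_params(pixel_spacing = spacing, noise_sd = 0, blur_sigma = 0,
                 cancellous_texture_sd = texture_sd, ...)
}

# analytic slice state for a standalone shell phantom (circular when b = a)
ring_state <- function(a, b = a, t, rho_c = 300, rho_t = 0, height = 0.3) {
  list(a = a, b = b, t_eff = t, rho_c = rho_c, rho_t = rho_t,
       height = height)
}

# small random sparse slice + mask for oracle tests
random_mask_slice <- function(n_pix = 50, dim = 20L, spacing = 0.1,
                              density_range = c(50, 400)) {
  slice <- matrix(0, dim, dim)
  mask <- matrix(0L, dim, dim)
  idx <- sample.int(dim * dim, n_pix)
  slice[idx] <- stats::runif(n_pix, density_range[1], density_range[2])
  mask[idx] <- 1L
  list(slice = slice, mask = mask, spacing = spacing)
}

# brute-force minimum over a dense theta grid (independent oracle for the
# eigen-decomposition route)
grid_min_moment <- function(slice, mask, centroid, spacing,
                            n_theta = 3600L) {
  thetas <- seq(0, pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  vals <- vapply(thetas,
                 function(th) moment_about_axis(slice, mask, centroid, th,
                                                spacing),
                 numeric(1))
  list(i_min = min(vals), theta_star = thetas[which.min(vals)])
}

# tiny two-pixel configuration: densities 100 at (+-0.5, 0) cm around the
# centroid, pixel area 1 cm^2
two_pixel_case <- function() {
  slice <- matrix(c(100, 100), nrow = 1)   # centres (0.5, 0.5), (1.5, 0.5)
  mask <- matrix(1L, nrow = 1, ncol = 2)
  list(slice = slice, mask = mask, spacing = 1)
}

# study table with a known per-day group difference, for stats tests
synthetic_table <- function(delta = 0, n1 = 5L, n2 = 6L, days = c(0L, 2L),
                            sd = 1, seed = 42L) {
  set.seed(seed)
  rows <- list()
  for (d in days) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = c(sprintf("C%02d", seq_len(n1)),
                     sprintf("F%02d", seq_len(n2))),
      group = rep(c("control", "fasting"), c(n1, n2)),
      day = d,
      bmd = c(stats::rnorm(n1, 100, sd), stats::rnorm(n2, 100 + delta, sd)))
  }
  do.call(rbind, rows)
}
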