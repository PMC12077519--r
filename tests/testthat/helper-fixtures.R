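# Shared synthetic fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

constant_field <- function(t0 = 2)
  thickness_field_spec(t0 = t0, axial_amp = 0, dorsal_amp = 0, ridge_amp = 0)

# straight circular tube, outer r = 5, t = 2 mm
constant_tube <- function(res = c(160L, 120L), L = 40, r = 5, t = 2,
                          angle = 0, aspect = 1) {
  generate_phalanx(phalanx_spec(
    L = L, base_radius = r, mid_radius = r, troch_radius = r, aspect = aspect,
    included_angle_deg = angle, thickness_field = constant_field(t),
    mesh_resolution = res, noise_sd = 0, seed = 1L))
}

# curved phalanx with ridges + dorsal band, flared ends
ridged_phalanx <- function(res = c(200L, 100L), seed = 1L, noise_sd = 0) {
  generate_phalanx(phalanx_spec(
    included_angle_deg = 30,
    thickness_field = thickness_field_spec(
      t0 = 1.2, axial_profile = "monotone_increase", axial_amp = 0.8,
      dorsal_amp = 0.5, ridge_amp = 1.5),
    mesh_resolution = res, noise_sd = noise_sd, seed = seed))
}

# a synthetic cross_section with analytic circular contours
circle_section <- function(r_out = 5, c_out = c(0, 0), r_in = 3,
                           c_in = c(0, 0), n = 2000L, level = 0.5) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  outer_c <- cbind(c_out[1L] + r_out * cos(th), c_out[2L] + r_out * sin(th))
  inner_c <- if (is.null(r_in)) NULL else
    cbind(c_in[1L] + r_in * cos(th), c_in[2L] + r_in * sin(th))
  structure(list(level_frac = level, level_x = NA_real_,
                 outer_contour = outer_c, inner_contour = inner_c,
                 centroid = c_out),
            class = "cross_section")
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

rigid_transform_pair <- function(pair, R, tr) {
  p <- pair
  p$outer <- transform_surface(pair$outer, R, tr)
  p$inner <- transform_surface(pair$inner, R, tr)
  p$oriented <- FALSE
  p$frame <- NULL
  p
}
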