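#' Parametric cortical-thickness field
#'
#' Describes the ground-truth cortical thickness t(s, theta) of a
#' synthetic phalanx, where s is the axial fraction (0 proximal, 1
#' distal) of bone length and theta the circumferential angle measured
#' from mid-dorsal (radians, counterclockwise viewed from distal).
#' The field is a sum of a baseline, an axial profile, a dorsal-shaft
#' band and paired palmar flexor-sheath ridges:
#'
#' t = t0 + axial_amp * ax(s) + dorsal_amp * dors(theta)
#'        + ridge_amp * win(s) * sum_k exp(-(theta - theta_k)^2 / 2 sd^2)
#'
#' `ax` is either a smooth monotone proximodistal increase (ape-like) or
#' a Gaussian mid-shaft peak (human-like); `dors` is a raised cosine over
#' mid-dorsal +/- 60 degrees; `win` is a smooth axial window for the
#' ridges.
#'
#' @param t0 baseline thickness (mm).
#' @param axial_profile `"monotone_increase"` or `"mid_peak"`.
#' @param axial_amp amplitude of the axial profile (mm).
#' @param peak_frac,fall_frac mid-peak location and Gaussian width
#'   (fractions of bone length); used only for `"mid_peak"`.
#' @param dorsal_amp dorsal band amplitude (mm).
#' @param ridge_amp flexor-ridge amplitude (mm).
#' @param ridge_angles angular centers of the two ridges (radians from
#'   mid-dorsal); defaults flank the palmar midline.
#' @param ridge_angular_sd angular width of each ridge (radians).
#' @param ridge_axial_window axial extent (start, end fractions) of the
#'   ridges.
#' @return object of class `thickness_field_spec`.
#' @export
thickness_field_spec <- function(t0 = 1.2,
                                 axial_profile = c("monotone_increase", "mid_peak"),
                                 axial_amp = 0.8,
                                 peak_frac = 0.65, fall_frac = 0.18,
                                 dorsal_amp = 0,
                                 ridge_amp = 0,
                                 ridge_angles = c(pi - 1.0, pi + 1.0),
                                 ridge_angular_sd = 0.35,
                                 ridge_axial_window = c(0.25, 0.95)) {
  axial_profile <- match.arg(axial_profile)
  stopifnot(t0 > 0, axial_amp >= 0, dorsal_amp >= 0, ridge_amp >= 0,
            length(ridge_angles) == 2L, ridge_angular_sd > 0,
            peak_frac > 0, peak_frac < 1, fall_frac > 0)
  structure(list(t0 = t0, axial_profile = axial_profile, axial_amp = axial_amp,
                 peak_frac = peak_frac, fall_frac = fall_frac,
                 dorsal_amp = dorsal_amp, ridge_amp = ridge_amp,
                 ridge_angles = as.numeric(ridge_angles),
                 ridge_angular_sd = ridge_angular_sd,
                 ridge_axial_window = as.numeric(ridge_axial_window)),
            class = "thickness_field_spec")
}

# wrap an angle difference into (-pi, pi]
.wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

# smoothstep from 0 to 1 over [a, b]
.smoothstep <- function(x, a, b) {
  t <- pmin(pmax((x - a) / (b - a), 0), 1)
  t * t * (3 - 2 * t)
}

#' Weighted mixture of thickness fields
#'
#' Represents a cortical field that is a convex combination of component
#' fields -- used e.g. to build an "intermediate" specimen blending two
#' group morphotypes.
#'
#' @param fields list of [thickness_field_spec()]s.
#' @param weights nonnegative weights, one per field (normalized to 1).
#' @return object of class `thickness_field_mixture`.
#' @export
thickness_field_mixture <- function(fields, weights) {
  stopifnot(length(fields) == length(weights), all(weights >= 0), sum(weights) > 0)
  structure(list(fields = fields, weights = weights / sum(weights)),
            class = "thickness_field_mixture")
}

#' Evaluate a thickness field
#'
#' @param field a [thickness_field_spec()] or [thickness_field_mixture()].
#' @param s axial fractions in `[0, 1]` (recycled against `theta`).
#' @param theta angles in radians from mid-dorsal.
#' @return thickness values (mm), same length as the recycled inputs.
#' @export
eval_thickness_field <- function(field, s, theta) {
  if (inherits(field, "thickness_field_mixture")) {
    out <- 0
    for (i in seq_along(field$fields))
      out <- out + field$weights[i] * eval_thickness_field(field$fields[[i]], s, theta)
    return(out)
  }
  ax <- switch(field$axial_profile,
    monotone_increase = .smoothstep(s, 0, 1),
    mid_peak = exp(-0.5 * ((s - field$peak_frac) / field$fall_frac)^2))
  th <- .wrap_angle(theta)
  dors <- ifelse(abs(th) <= pi / 3, 0.5 * (1 + cos(3 * th)), 0)
  w <- field$ridge_axial_window
  taper <- 0.05
  win <- .smoothstep(s, w[1L], w[1L] + taper) * (1 - .smoothstep(s, w[2L] - taper, w[2L]))
  ridge <- 0
  for (a in field$ridge_angles)
    ridge <- ridge + exp(-0.5 * (.wrap_angle(theta - a) / field$ridge_angular_sd)^2)
  field$t0 + field$axial_amp * ax + field$dorsal_amp * dors +
    field$ridge_amp * win * ridge
}

#' Specification of one synthetic phalanx
#'
#' The outer surface is a longitudinally curved elliptical tube: a
#' circular-arc centerline in the sagittal plane (bowing palmarly, i.e.
#' toward -v) swept with elliptical cross sections whose size
#' interpolates base, midshaft and trochlear radii (a quadratic through
#' the three, giving flared metaphyses). The inner surface is the outer
#' surface offset inward by the thickness field along in-plane rays from
#' the section center.
#'
#' @param L maximum length (mm); also the chord extent along u.
#' @param base_radius,mid_radius,troch_radius radioulnar semi-axes at the
#'   proximal end, midshaft and distal end (mm).
#' @param aspect dorsopalmar/radioulnar semi-axis ratio of the sections.
#' @param included_angle_deg longitudinal arc of the centerline (degrees).
#' @param thickness_field a [thickness_field_spec()].
#' @param mesh_resolution integer `(n_axial, n_circumferential)`.
#' @param noise_sd i.i.d. radial vertex jitter (mm), applied to both
#'   surfaces independently.
#' @param seed RNG seed for the jitter.
#' @return object of class `phalanx_spec`.
#' @export
phalanx_spec <- function(L = 40, base_radius = 6, mid_radius = 4.5,
                         troch_radius = 5, aspect = 0.8,
                         included_angle_deg = 30,
                         thickness_field = thickness_field_spec(),
                         mesh_resolution = c(200L, 100L),
                         noise_sd = 0, seed = 1L) {
  stopifnot(L > 0, base_radius > 0, mid_radius > 0, troch_radius > 0,
            aspect > 0, included_angle_deg >= 0, noise_sd >= 0,
            length(mesh_resolution) == 2L, all(mesh_resolution >= 8L))
  if (!inherits(thickness_field, c("thickness_field_spec", "thickness_field_mixture")))
    stop("thickness_field must be a thickness_field_spec or mixture")
  structure(list(L = L, base_radius = base_radius, mid_radius = mid_radius,
                 troch_radius = troch_radius, aspect = aspect,
                 included_angle_deg = included_angle_deg,
                 thickness_field = thickness_field,
                 mesh_resolution = as.integer(mesh_resolution),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phalanx_spec")
}

# quadratic radius profile through (0, base), (0.5, mid), (1, troch)
.radius_profile <- function(spec, s) {
  b <- spec$base_radius; m <- spec$mid_radius; tr <- spec$troch_radius
  # Lagrange quadratic
  b * (2 * (s - 0.5) * (s - 1)) + m * (-4 * s * (s - 1)) + tr * (2 * s * (s - 0.5))
}

# palmar sag of the arc centerline below its chord, at axial fraction s
.centerline_sag <- function(L, angle_deg, s) {
  if (angle_deg <= 0) return(rep(0, length(s)))
  phi <- angle_deg * pi / 180
  R <- L / (2 * sin(phi / 2))
  sqrt(pmax(R^2 - (L * (s - 0.5))^2, 0)) - R * cos(phi / 2)
}

# elliptical boundary radius at angle theta (from the v axis) for
# semi-axes a (v, dorsopalmar) and b (w, radioulnar)
.ellipse_radius <- function(a, b, theta) {
  1 / sqrt((cos(theta) / a)^2 + (sin(theta) / b)^2)
}

#' Generate a synthetic phalanx with known ground truth
#'
#' @param spec a [phalanx_spec()].
#' @param label,element,digit,id specimen metadata for the returned pair.
#' @param truth_window shaft window (fractions of bone length) on which
#'   the ground-truth matrix is sampled; matches the default analysis
#'   window.
#' @return list with `pair` (an oriented [bone_pair()] in canonical
#'   coordinates) and `truth` (the field spec, a callable `fun(s, theta)`
#'   and a 97 x 50 matrix `values` on the analysis grid, levels being
#'   fractions 0.02..0.98 of the shaft window).
#' @export
generate_phalanx <- function(spec, label = "synthetic", element = "PP",
                             digit = 3L, id = "synth-1",
                             truth_window = c(0.2, 0.8)) {
  n_ax <- spec$mesh_resolution[1L]
  n_ci <- spec$mesh_resolution[2L]
  s <- seq(0, 1, length.out = n_ax)
  theta <- seq(0, 2 * pi, length.out = n_ci + 1L)[-(n_ci + 1L)]
  r <- .radius_profile(spec, s)
  if (any(r <= 0)) stop("generation error: radius profile nonpositive")
  sag <- .centerline_sag(spec$L, spec$included_angle_deg, s)

  S <- rep(s, each = n_ci)
  TH <- rep(theta, times = n_ax)
  A <- rep(r * spec$aspect, each = n_ci)   # dorsopalmar semi-axis (v)
  B <- rep(r, each = n_ci)                 # radioulnar semi-axis (w)
  rho <- .ellipse_radius(A, B, TH)
  t_field <- eval_thickness_field(spec$thickness_field, S, TH)
  bad <- which(t_field >= rho - 1e-9)
  if (length(bad) > 0L)
    stop(sprintf("generation error: thickness %.3f >= local radius %.3f at (s = %.3f, theta = %.3f)",
                 t_field[bad[1L]], rho[bad[1L]], S[bad[1L]], TH[bad[1L]]))
  if (spec$noise_sd > 0) {
    jit <- withr_seed(spec$seed, list(
      outer = stats::rnorm(length(rho), 0, spec$noise_sd),
      inner = stats::rnorm(length(rho), 0, spec$noise_sd)))
    rho_out <- rho + jit$outer
    rho_in <- pmin(rho - t_field + jit$inner, rho_out - 0.05 * t_field)
    rho_in <- pmax(rho_in, 1e-3)
  } else {
    rho_out <- rho
    rho_in <- rho - t_field
  }
  cx <- rep(s * spec$L, each = n_ci)
  cy <- rep(-sag, each = n_ci)
  vx <- cx
  vy_out <- cy + rho_out * cos(TH)
  vz_out <- rho_out * sin(TH)
  vy_in <- cy + rho_in * cos(TH)
  vz_in <- rho_in * sin(TH)

  faces <- .tube_faces(n_ax, n_ci)
  outer <- tri_surface(cbind(vx, vy_out, vz_out), faces, clean = FALSE)
  inner <- tri_surface(cbind(vx, vy_in, vz_in), faces, clean = FALSE)
  pair <- bone_pair(outer, inner, side = "right", label = label,
                    element = element, digit = digit,
                    frame = anatomical_frame(), oriented = TRUE, id = id)

  levels <- seq(0.02, 0.98, by = 0.01)
  angles <- theta_grid(50L)
  s_abs <- truth_window[1L] + diff(truth_window) * levels
  tf <- spec$thickness_field
  fun <- function(s, theta) eval_thickness_field(tf, s, theta)
  values <- outer(s_abs, angles, fun)
  list(pair = pair,
       truth = list(field = tf, fun = fun, values = values,
                    levels = levels, angles = angles, window = truth_window,
                    spec = spec))
}

# triangulated closed tube over an n_ax x n_ci vertex grid
.tube_faces <- function(n_ax, n_ci) {
  i <- rep(seq_len(n_ax - 1L), each = n_ci)
  j <- rep(seq_len(n_ci), times = n_ax - 1L)
  jn <- j %% n_ci + 1L
  v00 <- (i - 1L) * n_ci + j
  v01 <- (i - 1L) * n_ci + jn
  v10 <- i * n_ci + j
  v11 <- i * n_ci + jn
  rbind(cbind(v00, v01, v11), cbind(v00, v11, v10))
}

#' The 50 equiangular map ray directions
#' @param k number of rays (default 50).
#' @return angles in radians from mid-dorsal, counterclockwise viewed
#'   from distal.
#' @export
theta_grid <- function(k = 50L) seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]

#' Generate a group-structured cohort of synthetic phalanges
#'
#' Each individual's spec perturbs its group's base spec: amplitude-like
#' parameters (lengths, radii, thickness amplitudes) get multiplicative
#' log-normal perturbations with the given relative sd; positional
#' parameters (angles, peak location) get additive normal perturbations.
#' Invalid draws are resampled up to 100 times.
#'
#' @param group_specs named list: each element a list with `spec` (a
#'   [phalanx_spec()]) and `sd` (named list of perturbation sds; relative
#'   for amplitude-like, absolute for positional parameters).
#' @param n_per_group individuals per group (>= 2).
#' @param seed cohort RNG seed.
#' @param element element type tag for all individuals.
#' @return list of individuals, each a list with `pair`, `truth`, `label`,
#'   `id`.
#' @export
generate_cohort <- function(group_specs, n_per_group, seed = 1L, element = "PP") {
  stopifnot(n_per_group >= 2L, length(group_specs) >= 1L)
  labels <- names(group_specs)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("group_specs must be a named list (names are group labels)")
  amplitude_pars <- c("L", "base_radius", "mid_radius", "troch_radius", "aspect",
                      "t0", "axial_amp", "dorsal_amp", "ridge_amp")
  positional_pars <- c("included_angle_deg", "peak_frac", "fall_frac",
                       "ridge_angles", "ridge_angular_sd")
  out <- list()
  withr_seed(seed, {
    for (g in labels) {
      base <- group_specs[[g]]$spec
      sds <- group_specs[[g]]$sd
      if (is.null(sds)) sds <- list()
      bad_par <- setdiff(names(sds), c(amplitude_pars, positional_pars))
      if (length(bad_par)) stop("unknown perturbation parameter: ", bad_par[1L])
      for (i in seq_len(n_per_group)) {
        sp <- NULL
        for (try in seq_len(100L)) {
          cand <- .perturb_spec(base, sds, amplitude_pars)
          cand$seed <- sample.int(.Machine$integer.max - 1L, 1L)
          ok <- tryCatch({ .validate_field(cand); TRUE }, error = function(e) FALSE)
          if (ok) { sp <- cand; break }
        }
        if (is.null(sp))
          stop("could not draw a valid spec for group '", g, "' in 100 tries")
        id <- sprintf("%s-%02d", g, i)
        gen <- generate_phalanx(sp, label = g, element = element, id = id)
        out[[length(out) + 1L]] <- list(pair = gen$pair, truth = gen$truth,
                                        label = g, id = id)
      }
    }
  })
  out
}

.perturb_spec <- function(base, sds, amplitude_pars) {
  sp <- unclass(base)
  is_mix <- inherits(base$thickness_field, "thickness_field_mixture")
  tf <- if (is_mix) list() else unclass(sp$thickness_field)
  for (p in names(sds)) {
    sd <- sds[[p]]
    if (sd == 0) next
    tgt <- if (p %in% names(tf)) "tf" else "sp"
    if (is_mix && !p %in% names(sp)) next
    val <- if (tgt == "tf") tf[[p]] else sp[[p]]
    if (p %in% amplitude_pars) {
      val <- val * exp(stats::rnorm(length(val), 0, sd))
    } else {
      val <- val + stats::rnorm(length(val), 0, sd)
    }
    if (tgt == "tf") tf[[p]] <- val else sp[[p]] <- val
  }
  if (!is_mix) {
    tf$axial_profile <- base$thickness_field$axial_profile
    sp$thickness_field <- structure(tf, class = "thickness_field_spec")
  }
  structure(sp, class = "phalanx_spec")
}

#' Canonical reference morphotypes for simulation studies
#'
#' Two group definitions emulating the qualitative contrast seen between
#' great apes and humans in phalangeal cortical bone: the "ape-like"
#' morphotype carries pronounced palmar flexor-sheath ridges
#' (ridge amplitude 1.5 mm), a monotone proximodistal thickness increase
#' and stronger longitudinal curvature (40 degrees); the "human-like"
#' morphotype carries dorsal-shaft thickening (1.0 mm), a mid-shaft peak
#' at 65 percent of bone length and milder curvature (20 degrees).
#' Between-individual variation defaults to a 10 percent (log-normal)
#' relative sd on amplitudes, a 0.05 additive sd on the peak location, a
#' 5 percent sd on length, and 3 degrees on curvature.
#'
#' @param mesh_resolution mesh resolution for every individual.
#' @param noise_sd radial vertex jitter in mm.
#' @return named list of group definitions suitable for
#'   [generate_cohort()] (each with `spec` and `sd`).
#' @export
reference_group_specs <- function(mesh_resolution = c(200L, 100L),
                                  noise_sd = 0.02) {
  ape_field <- thickness_field_spec(
    t0 = 1.2, axial_profile = "monotone_increase", axial_amp = 0.8,
    dorsal_amp = 0, ridge_amp = 1.5)
  human_field <- thickness_field_spec(
    t0 = 1.2, axial_profile = "mid_peak", axial_amp = 0.8,
    peak_frac = 0.65, fall_frac = 0.18, dorsal_amp = 1.0, ridge_amp = 0)
  sds <- list(t0 = 0.10, axial_amp = 0.10, dorsal_amp = 0.10, ridge_amp = 0.10,
              L = 0.05, peak_frac = 0.05, included_angle_deg = 3)
  list(
    ape_like = list(
      spec = phalanx_spec(L = 42, included_angle_deg = 40,
                          thickness_field = ape_field,
                          mesh_resolution = mesh_resolution,
                          noise_sd = noise_sd),
      sd = sds),
    human_like = list(
      spec = phalanx_spec(L = 40, included_angle_deg = 20,
                          thickness_field = human_field,
                          mesh_resolution = mesh_resolution,
                          noise_sd = noise_sd),
      sd = sds))
}

#' Parameter-blend of two phalanx specs
#'
#' Averages the geometric parameters of two specs with weight `w` on the
#' first, and blends their thickness fields as a
#' [thickness_field_mixture()] -- the synthetic analog of a specimen of
#' intermediate morphology.
#'
#' @param spec_a,spec_b [phalanx_spec()]s.
#' @param w weight on `spec_a` in `[0, 1]` (default 0.5).
#' @param seed seed for the blended spec.
#' @return a [phalanx_spec()].
#' @export
blend_phalanx_spec <- function(spec_a, spec_b, w = 0.5, seed = 1L) {
  stopifnot(w >= 0, w <= 1)
  num <- function(p) w * spec_a[[p]] + (1 - w) * spec_b[[p]]
  phalanx_spec(
    L = num("L"), base_radius = num("base_radius"),
    mid_radius = num("mid_radius"), troch_radius = num("troch_radius"),
    aspect = num("aspect"), included_angle_deg = num("included_angle_deg"),
    thickness_field = thickness_field_mixture(
      list(spec_a$thickness_field, spec_b$thickness_field), c(w, 1 - w)),
    mesh_resolution = spec_a$mesh_resolution,
    noise_sd = num("noise_sd"), seed = seed)
}

# check positivity and non-self-intersection of the field on a dense grid
.validate_field <- function(spec) {
  s <- seq(0, 1, length.out = 97L)
  th <- theta_grid(72L)
  S <- rep(s, each = length(th)); TH <- rep(th, times = length(s))
  t <- eval_thickness_field(spec$thickness_field, S, TH)
  if (any(t <= 0)) stop("thickness field nonpositive")
  r <- .radius_profile(spec, S)
  if (any(r <= 0)) stop("radius profile nonpositive")
  rho <- .ellipse_radius(r * spec$aspect, r, TH)
  if (any(t >= rho - 3 * spec$noise_sd))
    stop("thickness reaches local radius")
  if (spec$included_angle_deg < 0) stop("negative included angle")
  invisible(TRUE)
}
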