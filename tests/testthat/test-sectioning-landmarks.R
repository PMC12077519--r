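test_that("shaft cropping obeys the window arithmetic", {
  gen <- fixture("tube", function() constant_tube(res = c(100L, 60L)))
  sh <- define_shaft(gen$pair, shaft_window(0.2, 0.8))
  ext <- diff(range(sh$pair$outer$vertices[, 1L]))
  expect_equal(ext, 24, tolerance = 0.1 / 24)
  expect_equal(sh$shaft_length, 24)

  full <- define_shaft(gen$pair, shaft_window(0, 1))
  expect_equal(nrow(full$pair$outer$vertices), nrow(gen$pair$outer$vertices))
  expect_error(shaft_window(0.8, 0.2), "precondition")
})

test_that("sectioning produces exactly 97 levels with 50 landmark pairs each", {
  gen <- fixture("ridged", function() ridged_phalanx(res = c(120L, 72L)))
  sh <- define_shaft(gen$pair)
  secs <- extract_sections(sh)
  expect_length(secs, 97L)
  expect_equal(secs[[1L]]$level_frac, 0.02)
  expect_equal(secs[[97L]]$level_frac, 0.98)
  expect_equal(diff(vapply(secs, `[[`, 0, "level_frac"))[1L], 0.01)
  lm <- place_landmarks(secs[[50L]])
  expect_length(lm$thickness, 50L)
  expect_identical(nrow(lm$outer_pts), 50L)
})

test_that("cylinder slices are circles of the construction radius", {
  gen <- fixture("tube200", function() constant_tube(res = c(60L, 200L)))
  sh <- define_shaft(gen$pair)
  secs <- extract_sections(sh, n_levels = 5L)
  for (s in secs) {
    r <- sqrt(rowSums(s$outer_contour^2))
    expect_lt(max(abs(r - 5)), 0.02)
  }
})

test_that("solid distal half yields absent inner contours and flagged cells", {
  # cavity only in the proximal half: truncate the inner tube
  gen <- constant_tube(res = c(100L, 60L))
  keep <- gen$pair$inner$vertices[, 1L] <= 20
  vkeep <- which(keep)
  fkeep <- apply(matrix(gen$pair$inner$faces %in% vkeep,
                        ncol = 3L), 1L, all)
  remap <- integer(nrow(gen$pair$inner$vertices))
  remap[vkeep] <- seq_along(vkeep)
  inner_half <- tri_surface(gen$pair$inner$vertices[vkeep, , drop = FALSE],
                            matrix(remap[gen$pair$inner$faces[fkeep, ]], ncol = 3L),
                            clean = FALSE)
  pair <- bone_pair(gen$pair$outer, inner_half, side = "right",
                    frame = anatomical_frame(), oriented = TRUE, id = "halfcav")
  sh <- define_shaft(pair, shaft_window(0.2, 0.8))
  secs <- extract_sections(sh)
  has_inner <- !vapply(secs, function(s) is.null(s$inner_contour), TRUE)
  lv <- vapply(secs, `[[`, 0, "level_frac")
  # distal-of-cavity sections (bone fraction > 0.5 <=> shaft fraction > 0.5)
  expect_true(all(!has_inner[lv > 0.52]))
  expect_true(all(has_inner[lv < 0.48]))
  m <- compute_thickness_map(pair)
  expect_true(all(m$mask[m$levels > 0.52, ]))
  expect_true(all(!m$mask[m$levels < 0.48, ]))
  # flagged cells fall back to full-radius (centroid) thickness
  expect_equal(mean(m$values[m$levels > 0.55, ]), 5, tolerance = 0.01)
})

test_that("landmark thickness matches the dense ray oracle on offset circles", {
  sec <- circle_section(r_out = 5, c_out = c(0, 0), r_in = 1, c_in = c(1, 0))
  lm <- place_landmarks(sec)
  # oracle: distance to outer minus distance to inner along each ray
  d_out <- dense_circle_ray_distance(c(0, 0), lm$angles, c(0, 0), 5)
  d_in <- dense_circle_ray_distance(c(0, 0), lm$angles, c(1, 0), 1)
  expect_lt(max(abs(lm$thickness - (d_out - d_in))), 0.02)
  # spot values: the ray toward +v (theta 0 points dorsal, the inner circle
  # is offset along +v) passes through the cavity; the opposite ray misses it
  expect_equal(lm$thickness[1L], 3, tolerance = 0.02)
  expect_equal(lm$thickness[26L], 5, tolerance = 0.02)
})

test_that("concentric annulus gives uniform thickness", {
  sec <- circle_section(r_out = 5, r_in = 3)
  lm <- place_landmarks(sec)
  expect_lt(max(abs(lm$thickness - 2)), 0.02)
  expect_true(all(!lm$flagged))
})

test_that("map assembly enforces the grid contract", {
  gen <- fixture("tube", function() constant_tube(res = c(100L, 60L)))
  sh <- define_shaft(gen$pair)
  secs <- extract_sections(sh)
  lms <- lapply(secs, place_landmarks)
  expect_error(build_thickness_map(lms[1:96], bone_length = 40), "shape error")
  m <- build_thickness_map(lms, bone_length = 40)
  expect_identical(dim(m$values), c(97L, 50L))
  expect_lt(max(abs(m$values - 2)), 0.05)
})

test_that("map rows index shaft levels proximal to distal (marker bump)", {
  # a mid_peak field with a tight peak acts as a single-level marker
  sp <- phalanx_spec(
    included_angle_deg = 0,
    thickness_field = thickness_field_spec(
      t0 = 1, axial_profile = "mid_peak", axial_amp = 1.5,
      peak_frac = 0.62, fall_frac = 0.04),
    mesh_resolution = c(300L, 60L))
  gen <- generate_phalanx(sp)
  m <- compute_thickness_map(gen$pair)
  peak_row <- which.max(rowMeans(m$values))
  # bone fraction 0.62 maps to shaft fraction (0.62 - 0.2) / 0.6 = 0.70
  expect_equal(m$levels[peak_row], 0.70, tolerance = 0.015)
  expect_equal(peak_row, which.min(abs(m$levels - 0.70)))
})

test_that("thickness maps are invariant to rigid transforms of the bone", {
  gen <- fixture("ridged", function() ridged_phalanx(res = c(120L, 72L)))
  m0 <- fixture("ridged_map", function() compute_thickness_map(
    fixture("ridged", function() ridged_phalanx(res = c(120L, 72L)))$pair))
  withr::with_seed(5, {
    moved <- rigid_transform_pair(gen$pair, random_rotation(), c(-7, 2, 13))
  })
  m1 <- compute_thickness_map(orient_anatomical(moved))
  expect_lt(max(abs(m1$values - m0$values)), 0.05)
})

test_that("mirrored left bones unroll to angle-reversed maps", {
  gen <- fixture("ridged", function() ridged_phalanx(res = c(120L, 72L)))
  m0 <- fixture("ridged_map", function() compute_thickness_map(
    fixture("ridged", function() ridged_phalanx(res = c(120L, 72L)))$pair))
  left <- gen$pair
  left$side <- "left"
  refl <- left
  refl$outer$vertices[, 3L] <- -refl$outer$vertices[, 3L]
  refl$inner$vertices[, 3L] <- -refl$inner$vertices[, 3L]
  refl$outer$faces <- refl$outer$faces[, c(1L, 3L, 2L)]
  refl$inner$faces <- refl$inner$faces[, c(1L, 3L, 2L)]
  m2 <- compute_thickness_map(mirror_to_right(refl))
  # double reflection recovers the original bone, hence the original map
  expect_lt(max(abs(m2$values - m0$values)), 1e-9)
  # the raw (unmirrored) left-bone map is the angular reversal about the
  # mid-dorsal column: column j <-> column 52 - j
  m_raw <- compute_thickness_map(refl)
  expect_lt(max(abs(m_raw$values[, c(1L, 50:2)] - m2$values)), 0.05)
})
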