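sp_aniso <- c(0.2, 0.06, 0.06)
sp_iso <- c(0.06, 0.06, 0.06)

test_that("volume is voxel count times voxel volume", {
  m <- box_mask(10L, 10L, 10L)
  expect_equal(measure_volume(m, sp_aniso), 1000 * 0.2 * 0.06 * 0.06)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(measure_volume(one, sp_aniso), prod(sp_aniso))
  expect_error(measure_volume(array(FALSE, c(3, 3, 3)), sp_aniso),
               "empty")
})

test_that("digitized sphere volume matches the analytic value", {
  m <- digitized_sphere(1, sp_iso)
  expect_lt(abs(measure_volume(m, sp_iso) / (4 / 3 * pi) - 1), 0.05)
})

test_that("surface factor closed forms and errors", {
  expect_equal(surface_factor(4 / 3 * pi, 4 * pi), 1, tolerance = 1e-12)
  expect_equal(surface_factor(1, 6), (pi / 6)^(1 / 3), tolerance = 1e-12)
  expect_equal(surface_factor(4, 18), pi^(1 / 3) * 24^(2 / 3) / 18,
               tolerance = 1e-12)
  expect_error(surface_factor(0, 6), "positive")
  expect_error(surface_factor(1, -1), "positive")
})

test_that("surface factor is invariant under k^3 / k^2 rescaling", {
  base <- surface_factor(2.5, 11)
  for (k in c(0.1, 0.5, 2, 10))
    expect_equal(surface_factor(2.5 * k^3, 11 * k^2), base,
                 tolerance = 1e-9)
})

test_that("voxel-face area is the exact face sum for boxes", {
  m <- box_mask(5L, 7L, 9L)
  sz <- sp_aniso[1]; sy <- sp_aniso[2]; sx <- sp_aniso[3]
  expected <- 2 * (7 * 9 * sy * sx + 5 * 9 * sz * sx + 5 * 7 * sz * sy)
  expect_equal(measure_surface_area(m, sp_aniso, "voxel_faces"), expected)
})

test_that("mesh area of a digitized sphere is accurate on both grids", {
  m_iso <- digitized_sphere(1, sp_iso)
  expect_lt(abs(measure_surface_area(m_iso, sp_iso) / (4 * pi) - 1), 0.03)
  m_aniso <- digitized_sphere(1, sp_aniso)
  expect_lt(abs(measure_surface_area(m_aniso, sp_aniso) / (4 * pi) - 1),
            0.05)
})

test_that("voxel faces overestimate relative to the mesh; boxes agree to 12%", {
  m <- digitized_sphere(1, sp_iso)
  expect_gte(measure_surface_area(m, sp_iso, "voxel_faces"),
             measure_surface_area(m, sp_iso, "marching_cubes"))
  for (dims in list(c(15L, 20L, 25L), c(16L, 40L, 40L))) {
    b <- box_mask(dims[1], dims[2], dims[3])
    vf <- measure_surface_area(b, sp_aniso, "voxel_faces")
    mc <- measure_surface_area(b, sp_aniso, "marching_cubes")
    expect_gte(vf, mc)
    expect_lt(vf / mc - 1, 0.12)
  }
})

test_that("no generated shape beats the sphere's surface factor", {
  sf_sphere <- local({
    m <- digitized_sphere(1, sp_aniso)
    surface_factor(measure_volume(m, sp_aniso),
                   measure_surface_area(m, sp_aniso))
  })
  shapes <- list(box_mask(5L, 17L, 17L), box_mask(10L, 12L, 60L))
  for (m in shapes) {
    sf <- surface_factor(measure_volume(m, sp_aniso),
                         measure_surface_area(m, sp_aniso))
    expect_lte(sf, sf_sphere + 0.02)
  }
})

test_that("segmentation keeps the largest sufficient component", {
  # two blobs of very different volume: only the large one survives
  vox <- array(0, c(20, 40, 40))
  vox[5:15, 5:25, 5:25] <- 100      # large blob
  vox[17:18, 30:33, 30:33] <- 100   # small blob
  st <- image_stack3d(vox, c(0.2, 0.2, 0.2))
  mask <- segment_array(st, "ch1", smoothing_sigma = 0,
                        min_volume = 0.05,
                        nucleus_mask = array(TRUE, dim(vox)))
  expect_true(all(mask[5:15, 5:25, 5:25]))
  expect_false(any(mask[17:18, 30:33, 30:33]))
  expect_error(segment_array(image_stack3d(array(0, c(4, 4, 4)),
                                           c(0.2, 0.06, 0.06)), "ch1"),
               "degenerate")
})

test_that("segmentation recovers the true sphere mask (Jaccard >= 0.9)", {
  g <- generate_array_stack(scene_spec("sphere", seed = 7L))
  mask <- segment_array(g$stack)
  jac <- sum(mask & g$truth$true_mask) / sum(mask | g$truth$true_mask)
  expect_gte(jac, 0.9)
})

test_that("array intensity totals, means and calibration", {
  vox <- array(0, c(4, 4, 4))
  mask <- array(FALSE, c(4, 4, 4))
  mask[seq_len(10)] <- TRUE  # 10 voxels
  vox[mask] <- 5
  st <- image_stack3d(vox, c(0.2, 0.06, 0.06))
  int <- array_intensity(st, mask, "ch1")
  expect_equal(int$total, 50)
  expect_equal(int$mean, 5)
  expect_equal(int$normalized, int$total)   # identity calibration
  expect_equal(array_intensity(st, mask, "ch1", 2.5)$normalized, 125)
  expect_error(array_intensity(st, mask, "nope"), "unknown channel")
})

test_that("enrichment ratio is 1 on a uniform nucleus", {
  vox <- array(10, c(10, 10, 10))
  st <- image_stack3d(vox, c(0.2, 0.06, 0.06))
  mask <- array(FALSE, c(10, 10, 10)); mask[4:6, 4:6, 4:6] <- TRUE
  expect_equal(enrichment_ratio(st, mask, "ch1",
                                nucleus_mask = array(TRUE, dim(vox))), 1)
})

test_that("decondensation classification follows the control quantile", {
  set.seed(1)
  ctrl <- rnorm(30, 0.8, 0.05)
  # identical cohorts: about the quantile itself gets labelled
  cls <- classify_decondensed(ctrl, ctrl, 0.20)
  expect_lt(abs(cls$percent_decondensed - 20), 4)
  # strongly shifted test cohort: nearly all decondensed
  test <- rnorm(30, 0.6, 0.05)
  cls2 <- classify_decondensed(test, ctrl, 0.20)
  expect_gte(cls2$percent_decondensed, 90)
  # all test values above the control maximum: none decondensed
  cls3 <- classify_decondensed(ctrl + 1, ctrl)
  expect_equal(cls3$percent_decondensed, 0)
  # ties at the threshold count as condensed
  thr <- unname(quantile(ctrl, 0.2))
  cls4 <- classify_decondensed(rep(thr, 12), ctrl)
  expect_equal(cls4$percent_decondensed, 0)
  expect_error(classify_decondensed(test, ctrl[1:5]), "at least 10")
})
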