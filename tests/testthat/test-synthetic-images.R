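test_that("scene specs validate geometry and units", {
  expect_error(scene_spec("sphere", sphere_radius = 3, nucleus_radius = 2),
               "does not fit inside nucleus")
  expect_error(scene_spec("sphere", voxel_spacing = c(0.2, -0.06, 0.06)),
               "strictly positive")
  expect_error(scene_spec("sphere", fiber_persistence = 1.5), "\\[0, 1\\]")
  expect_error(scene_spec("sphere",
                          channel_enrichments = c(HP1g = Inf)), "finite")
  sp <- scene_spec("sphere")
  expect_identical(sp$voxel_spacing, c(0.2, 0.06, 0.06))
})

test_that("default fibre and sphere specs have equal nominal volume", {
  sph <- scene_spec("sphere")
  fib <- scene_spec("fiber")
  expect_lt(abs(nominal_volume_of(fib) / nominal_volume_of(sph) - 1), 0.05)
})

test_that("ground truth surface factor: sphere ~1, fibre lower", {
  gs <- generate_array_stack(scene_spec("sphere", gaussian_noise_sigma = 0))
  expect_lt(abs(gs$truth$true_surface_factor - 1), 0.02)
  gf <- generate_array_stack(scene_spec("fiber", gaussian_noise_sigma = 0,
                                        seed = 3L))
  expect_lt(gf$truth$true_surface_factor, gs$truth$true_surface_factor)
  expect_gt(gf$truth$true_surface_factor, 0)
})

test_that("fibre ground-truth volume is conserved within 5% of nominal", {
  nom <- nominal_volume_of(scene_spec("fiber"))
  for (s in c(2L, 11L, 23L)) {
    g <- generate_array_stack(scene_spec("fiber", seed = s,
                                         gaussian_noise_sigma = 0))
    expect_lt(abs(g$truth$true_volume / nom - 1), 0.05)
  }
})

test_that("equal spec and seed give bitwise-identical stacks", {
  sc <- scene_spec("sphere", nucleus_radius = 1.5, sphere_radius = 0.5,
                   voxel_spacing = c(0.2, 0.12, 0.12), seed = 9L)
  a <- generate_array_stack(sc)
  b <- generate_array_stack(sc)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$true_mask, b$truth$true_mask)
  sc$seed <- 10L
  expect_false(identical(generate_array_stack(sc)$stack$voxels,
                         a$stack$voxels))
})

test_that("cohort generation counts cells and reproduces manifests", {
  specs <- list(ctrl = scene_spec("sphere", nucleus_radius = 1.5,
                                  sphere_radius = 0.5,
                                  voxel_spacing = c(0.2, 0.12, 0.12)),
                test = scene_spec("sphere", nucleus_radius = 1.5,
                                  sphere_radius = 0.7,
                                  voxel_spacing = c(0.2, 0.12, 0.12)))
  co <- generate_cohort(specs, n_per_spec = 3L, master_seed = 5L)
  expect_length(co$stacks, 6L)
  expect_equal(nrow(co$manifest), 6L)
  expect_setequal(unique(co$manifest$construct_label), c("ctrl", "test"))
  expect_false(anyDuplicated(co$manifest$cell_id) > 0)
  co2 <- generate_cohort(specs, n_per_spec = 3L, master_seed = 5L)
  expect_identical(co$manifest, co2$manifest)
  expect_error(generate_cohort(list(), 3L), "at least one")
})

test_that("extra channels carry the requested enrichment", {
  sc <- scene_spec("sphere", sphere_radius = 0.8, nucleus_radius = 2,
                   channel_enrichments = c(HP1g = 3, lost = 1),
                   gaussian_noise_sigma = 0, seed = 2L)
  g <- generate_array_stack(sc)
  expect_identical(g$stack$channel_names, c("array", "HP1g", "lost"))
  er <- enrichment_ratio(g$stack, g$truth$true_mask, "HP1g",
                         buffer = 0.2)
  expect_lt(abs(er - 3), 0.15)
  er1 <- enrichment_ratio(g$stack, g$truth$true_mask, "lost",
                          buffer = 0.2)
  expect_lt(abs(er1 - 1), 0.05)
})
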