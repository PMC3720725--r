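# shared fixtures, built in code

# digitize a solid sphere of radius r on a (z, y, x) grid of the given
# spacing, voxel centres symmetric about the origin
digitized_sphere <- function(r, spacing, margin = 0.4) {
  ax <- function(half, s) {
    n <- 2L * ceiling(half / s) + 1L
    (seq_len(n) - (n + 1) / 2) * s
  }
  z <- ax(r + margin, spacing[1])
  y <- ax(r + margin, spacing[2])
  x <- ax(r + margin, spacing[3])
  d <- c(length(z), length(y), length(x))
  array(z^2, d) + array(rep(y^2, each = d[1]), d) +
    array(rep(x^2, each = d[1] * d[2]), d) <= r^2
}

# a solid axis-aligned box mask of nz x ny x nx voxels inside padding
box_mask <- function(nz, ny, nx, pad = 2L) {
  m <- array(FALSE, c(nz + 2L * pad, ny + 2L * pad, nx + 2L * pad))
  m[pad + seq_len(nz), pad + seq_len(ny), pad + seq_len(nx)] <- TRUE
  m
}

# expensive sphere-vs-fibre cohort, built once per test run
.cohort_cache <- new.env(parent = emptyenv())

pair_cohort_report <- function() {
  if (is.null(.cohort_cache$report)) {
    cfg <- list(
      cohorts = list(control = list(shape_kind = "sphere"),
                     unfolded = list(shape_kind = "fiber")),
      control_label = "control", n_per_spec = 30L, master_seed = 1L,
      analysis = list(m = 7, alpha = 0.05))
    .cohort_cache$report <- run_morphology_experiment(cfg)
  }
  .cohort_cache$report
}

# nominal analytic volume of a scene spec, recomputed independently
nominal_volume_of <- function(spec) {
  if (spec$shape_kind == "sphere") 4 / 3 * pi * spec$sphere_radius^3
  else spec$fiber_length * pi * spec$fiber_thickness^2
}

# brute-force two-sided rank-sum p-value by full enumeration of all
# assignments of the pooled ranks to the test group
wilcoxon_enum_p <- function(test, control) {
  m <- length(test)
  pooled <- c(test, control)
  stopifnot(!any(duplicated(pooled)))
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(length(pooled), m)
  ud <- apply(sets, 2, function(ix) sum(rank(pooled)[ix]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(ud <= u_obs), mean(ud >= u_obs)))
}
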