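# Synthetic confocal stack generation with known ground truth.

# centred voxel-centre coordinates for one axis
axis_coords <- function(half_extent, s) {
  n <- 2L * ceiling(half_extent / s) + 1L
  (seq_len(n) - (n + 1) / 2) * s
}

# minimum distance from every voxel centre to a polyline, computed locally
# around each segment; cells farther than 'maxd' keep the sentinel value
polyline_distance <- function(z, y, x, pts, maxd, sentinel = 1e3) {
  d <- array(sentinel, c(length(z), length(y), length(x)))
  for (s in seq_len(nrow(pts) - 1L)) {
    p <- pts[s, ]; q <- pts[s + 1L, ]
    lo <- pmin(p, q) - maxd; hi <- pmax(p, q) + maxd
    zi <- which(z >= lo[1] & z <= hi[1])
    yi <- which(y >= lo[2] & y <= hi[2])
    xi <- which(x >= lo[3] & x <= hi[3])
    if (!length(zi) || !length(yi) || !length(xi)) next
    nzb <- length(zi); nyb <- length(yi); nxb <- length(xi)
    Z <- array(z[zi], c(nzb, nyb, nxb))
    Y <- array(rep(y[yi], each = nzb), c(nzb, nyb, nxb))
    X <- array(rep(x[xi], each = nzb * nyb), c(nzb, nyb, nxb))
    v <- q - p
    vv <- sum(v * v)
    tt <- ((Z - p[1]) * v[1] + (Y - p[2]) * v[2] + (X - p[3]) * v[3]) / vv
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    dd <- sqrt((Z - p[1] - tt * v[1])^2 + (Y - p[2] - tt * v[2])^2 +
               (X - p[3] - tt * v[3])^2)
    sub <- d[zi, yi, xi]
    d[zi, yi, xi] <- pmin(sub, dd)
  }
  d
}

# persistent, self-avoiding random walk confined to a sphere of radius rc;
# consumes the current RNG stream
fiber_centerline <- function(length_um, step, persistence, rc) {
  n <- max(2L, ceiling(length_um / step)) + 1L
  pts <- matrix(0, n, 3L)
  dir <- random_unit()
  min_sep <- 2 * step          # self-avoidance between non-adjacent beads
  for (i in 2:n) {
    placed <- FALSE
    for (try in 1:60) {
      u <- random_unit()
      prop <- persistence * dir + sqrt(max(0, 1 - persistence^2)) * u
      prop <- prop / sqrt(sum(prop^2))
      cand <- pts[i - 1L, ] + step * prop
      ok_in <- sqrt(sum(cand^2)) <= rc
      ok_sa <- TRUE
      if (i > 3L) {
        prev <- pts[1:(i - 3L), , drop = FALSE]
        dmin <- min(sqrt(rowSums((prev - matrix(cand, nrow(prev), 3L,
                                                byrow = TRUE))^2)))
        ok_sa <- dmin >= min_sep
      }
      if (ok_in && ok_sa) {
        pts[i, ] <- cand; dir <- prop; placed <- TRUE; break
      }
      # relax persistence progressively when boxed in
      if (try > 20) persistence <- persistence * 0.95
    }
    if (!placed) {             # turn back toward the centre as a last resort
      inward <- -pts[i - 1L, ]
      nrm <- sqrt(sum(inward^2))
      dir <- if (nrm > 0) inward / nrm else random_unit()
      pts[i, ] <- pts[i - 1L, ] + step * dir
    }
  }
  pts
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v * v))
    if (n > 1e-12) return(v / n)
  }
}

# ground truth for a fibre: voxelize the analytic tube on a fine isotropic
# grid and mesh the analytic signed field (fine-mesh oracle; no closed form
# exists for a confined random tube)
fiber_truth <- function(pts, thickness, h) {
  lo <- apply(pts, 2, min) - thickness - 4 * h
  hi <- apply(pts, 2, max) + thickness + 4 * h
  z <- seq(lo[1], hi[1], by = h)
  y <- seq(lo[2], hi[2], by = h)
  x <- seq(lo[3], hi[3], by = h)
  d <- polyline_distance(z, y, x, pts, thickness + 3 * h)
  vol <- sum(d <= thickness) * h^3
  area <- mt_surface_area(thickness - d, 0, c(h, h, h))
  list(volume = vol, area = area)
}

#' Generate a synthetic nucleus stack with ground truth
#'
#' Renders the scene described by a \code{\link{scene_spec}}: the array
#' channel is \code{nucleoplasm_level} inside the nucleus,
#' \code{array_amplitude} inside the domain and 0 outside, convolved with a
#' separable anisotropic Gaussian PSF, with additive Gaussian noise
#' (clamped at zero). Extra channels listed in \code{channel_enrichments}
#' have nucleoplasm level \code{nucleoplasm_level} and in-domain level
#' scaled by their enrichment factor. Ground truth (pre-blur geometry) is
#' returned alongside: the binary domain mask on the stack grid, the true
#' volume, surface area and surface factor (closed form for the sphere; a
#' fine-mesh oracle on an isotropic grid at the finest spacing for the
#' fibre).
#'
#' @param spec a \code{\link{scene_spec}}.
#' @return list with elements \code{stack} (an
#'   \code{\link{image_stack3d}}) and \code{truth} (class
#'   \code{"ground_truth"}: \code{true_mask}, \code{true_volume},
#'   \code{true_surface_area}, \code{true_surface_factor},
#'   \code{channel_enrichments}).
#' @examples
#' sc <- scene_spec("sphere", sphere_radius = 0.5, nucleus_radius = 1.5,
#'                  voxel_spacing = c(0.2, 0.12, 0.12))
#' gs <- generate_array_stack(sc)
#' gs$truth$true_surface_factor
#' @export
generate_array_stack <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  sp <- spec$voxel_spacing
  sig <- c(spec$psf_sigma_axial, spec$psf_sigma_lateral,
           spec$psf_sigma_lateral)
  pad <- 4 * sp + 3 * sig
  z <- axis_coords(spec$nucleus_radius + pad[1], sp[1])
  y <- axis_coords(spec$nucleus_radius + pad[2], sp[2])
  x <- axis_coords(spec$nucleus_radius + pad[3], sp[3])
  d <- c(length(z), length(y), length(x))
  Z2 <- array(z^2, d)
  Y2 <- array(rep(y^2, each = d[1]), d)
  X2 <- array(rep(x^2, each = d[1] * d[2]), d)
  r2 <- Z2 + Y2 + X2
  nucleus <- r2 <= spec$nucleus_radius^2

  with_seed(spec$seed, {
    if (spec$shape_kind == "sphere") {
      domain <- r2 <= spec$sphere_radius^2
      truth_v <- 4 / 3 * pi * spec$sphere_radius^3
      truth_s <- 4 * pi * spec$sphere_radius^2
    } else {
      # the dilated tube gains two hemispherical end caps; shorten the
      # centreline so the capsule volume matches the nominal L*pi*t^2
      len_eff <- max(spec$fiber_thickness,
                     spec$fiber_length - 4 / 3 * spec$fiber_thickness)
      pts <- fiber_centerline(len_eff, spec$fiber_thickness,
                              spec$fiber_persistence,
                              spec$nucleus_radius - spec$fiber_thickness)
      dist <- polyline_distance(z, y, x, pts,
                                spec$fiber_thickness + 2 * max(sp))
      domain <- dist <= spec$fiber_thickness
      ft <- fiber_truth(pts, spec$fiber_thickness, min(sp))
      truth_v <- ft$volume
      truth_s <- ft$area
    }
    if (any(domain & !nucleus))
      stop(sprintf(
        "domain not fully inside nucleus (%s protrudes beyond radius %.3g um)",
        spec$shape_kind, spec$nucleus_radius), call. = FALSE)

    ch_names <- c("array", names(spec$channel_enrichments))
    vox <- array(0, c(d, length(ch_names)))
    sig_vox <- sig / sp
    for (ci in seq_along(ch_names)) {
      e <- if (ci == 1L) spec$array_amplitude / spec$nucleoplasm_level
           else spec$channel_enrichments[[ci - 1L]]
      img <- array(0, d)
      img[nucleus] <- spec$nucleoplasm_level
      img[domain] <- spec$nucleoplasm_level * e
      img <- gauss_blur3d(img, sig_vox)
      if (spec$gaussian_noise_sigma > 0)
        img <- img + stats::rnorm(length(img),
                                  sd = spec$gaussian_noise_sigma)
      img[img < 0] <- 0
      vox[, , , ci] <- img
    }
  })

  sf <- surface_factor(truth_v, truth_s)
  truth <- structure(list(
    true_mask = domain, true_volume = truth_v, true_surface_area = truth_s,
    true_surface_factor = sf,
    channel_enrichments = spec$channel_enrichments),
    class = "ground_truth")
  list(stack = image_stack3d(vox, sp, ch_names), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: V %.3g um^3, S %.3g um^2, surface factor %.3f (%d voxels)\n",
    x$true_volume, x$true_surface_area, x$true_surface_factor,
    sum(x$true_mask)))
  invisible(x)
}

#' Generate a cohort of synthetic nuclei
#'
#' Renders \code{n_per_spec} cells per scene specification with per-cell
#' seeds derived deterministically from \code{master_seed}, so a fixed
#' master seed reproduces the whole cohort. Mirrors the usual experimental
#' design of roughly 30 nuclei imaged per construct.
#'
#' Cell-to-cell expression variability: transfected cells express the
#' tagged construct at widely different levels, and the downstream
#' correlation analysis (intensity versus surface factor) relies on that
#' variation existing independently of domain shape. Each cell therefore
#' draws a lognormal expression factor (mean 1, coefficient of variation
#' \code{amplitude_cv}) that scales the array channel's amplitude and
#' nucleoplasm level together; set \code{amplitude_cv = 0} for identical
#' expression.
#'
#' @param spec_list list of \code{\link{scene_spec}} objects (optionally
#'   named; names become construct labels).
#' @param n_per_spec number of cells per spec (default 30).
#' @param master_seed integer master seed.
#' @param amplitude_cv coefficient of variation of the per-cell expression
#'   factor (default 0.3).
#' @return list with \code{stacks} (list of \code{image_stack3d}),
#'   \code{truths} (list of \code{ground_truth}) and \code{manifest}
#'   (data.frame: cell_id, construct_label, seed, expression factor and
#'   true morphometry).
#' @export
generate_cohort <- function(spec_list, n_per_spec = 30L, master_seed = 1L,
                            amplitude_cv = 0.3) {
  if (length(spec_list) == 0L)
    stop("'spec_list' must contain at least one scene_spec", call. = FALSE)
  if (!all(vapply(spec_list, inherits, logical(1), "scene_spec")))
    stop("all elements of 'spec_list' must be scene_spec objects",
         call. = FALSE)
  if (n_per_spec < 1L) stop("'n_per_spec' must be >= 1", call. = FALSE)
  labels <- names(spec_list) %||%
    paste0(vapply(spec_list, `[[`, "", "shape_kind"),
           seq_along(spec_list))
  if (is.null(names(spec_list))) names(spec_list) <- labels
  stacks <- list(); truths <- list(); rows <- list()
  cell <- 0L
  for (si in seq_along(spec_list)) {
    for (j in seq_len(n_per_spec)) {
      cell <- cell + 1L
      spec <- spec_list[[si]]
      spec$seed <- derive_seed(master_seed, cell)
      expr_factor <- 1
      if (amplitude_cv > 0) {
        sdlog <- sqrt(log(1 + amplitude_cv^2))
        expr_factor <- with_seed(derive_seed(master_seed + 1L, cell),
                                 stats::rlnorm(1, -sdlog^2 / 2, sdlog))
        spec$array_amplitude <- spec$array_amplitude * expr_factor
        spec$nucleoplasm_level <- spec$nucleoplasm_level * expr_factor
        # detector noise is largely signal-dependent; keep per-cell SNR
        # constant so measurement quality does not track expression
        spec$gaussian_noise_sigma <- spec$gaussian_noise_sigma * expr_factor
      }
      g <- generate_array_stack(spec)
      id <- sprintf("%s_%03d", labels[si], j)
      stacks[[id]] <- g$stack
      truths[[id]] <- g$truth
      rows[[cell]] <- data.frame(
        cell_id = id, construct_label = labels[si], seed = spec$seed,
        expression_factor = expr_factor,
        shape_kind = spec$shape_kind,
        true_volume = g$truth$true_volume,
        true_surface_area = g$truth$true_surface_area,
        true_surface_factor = g$truth$true_surface_factor,
        stringsAsFactors = FALSE)
    }
  }
  list(stacks = stacks, truths = truths,
       manifest = do.call(rbind, rows))
}
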