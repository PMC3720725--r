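# 3D morphometry of the segmented lacO-array domain.

#' Surface factor (sphericity) of a 3D object
#'
#' The shape statistic used throughout: the surface of a sphere with the
#' same volume divided by the measured surface,
#' \deqn{\mathrm{SF} = \pi^{1/3} (6V)^{2/3} / S.}
#' A perfect sphere gives 1; elongated or furrowed objects (an unfolded,
#' fibrillar chromatin domain) give lower values.
#'
#' @param volume volume in um^3 (> 0). Vectorized.
#' @param surface_area surface area in um^2 (> 0). Vectorized.
#' @return dimensionless surface factor.
#' @examples
#' surface_factor(4 / 3 * pi, 4 * pi)   # sphere: 1
#' surface_factor(1, 6)                 # unit cube: (pi/6)^(1/3) ~ 0.806
#' @export
surface_factor <- function(volume, surface_area) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("'volume' must be positive and finite", call. = FALSE)
  if (any(!is.finite(surface_area)) || any(surface_area <= 0))
    stop("'surface_area' must be positive and finite", call. = FALSE)
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface_area
}

#' Volume of a binary voxel mask
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing (z, y, x) in um.
#' @return volume in um^3 (voxel count times voxel volume).
#' @export
measure_volume <- function(mask, spacing) {
  check_mask(mask)
  n <- sum(mask)
  if (n == 0L) stop("mask is empty", call. = FALSE)
  n * prod(spacing)
}

#' Surface area of a binary voxel mask
#'
#' Two estimators are provided. \code{"marching_cubes"} extracts a
#' triangulated iso-surface at level 0.5 from the zero-padded mask after a
#' one-voxel-per-axis Gaussian smoothing (which restores sub-voxel surface
#' placement that is lost when interpolating raw binary data) and returns
#' the total triangle area in physical units. \code{"voxel_faces"} sums the
#' areas of exposed voxel faces -- the brute-force oracle, exact for
#' axis-aligned boxes but a systematic overestimate for oblique or curved
#' surfaces (up to +50\% for a sphere).
#'
#' Masks touching the grid boundary are handled by the one-voxel zero
#' padding; no error is raised.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing (z, y, x) in um.
#' @param method "marching_cubes" (default) or "voxel_faces".
#' @return surface area in um^2.
#' @export
measure_surface_area <- function(mask, spacing,
                                 method = c("marching_cubes",
                                            "voxel_faces")) {
  method <- match.arg(method)
  check_mask(mask)
  if (sum(mask) == 0L) stop("mask is empty", call. = FALSE)
  d <- dim(mask)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- as.numeric(mask)
  if (method == "voxel_faces") {
    sz <- spacing[1]; sy <- spacing[2]; sx <- spacing[3]
    nz <- sum(abs(pad[-1, , ] - pad[-nrow(pad), , ]))
    dp <- dim(pad)
    ny <- sum(abs(pad[, -1, ] - pad[, -dp[2], ]))
    nx <- sum(abs(pad[, , -1] - pad[, , -dp[3]]))
    return(nz * sy * sx + ny * sz * sx + nx * sz * sy)
  }
  sm <- gauss_blur3d(pad, c(1, 1, 1))
  mt_surface_area(sm, 0.5, spacing)
}

check_mask <- function(mask) {
  if (!(is.logical(mask) || all(mask %in% c(0, 1))) ||
      length(dim(mask)) != 3L)
    stop("'mask' must be a logical 3D array", call. = FALSE)
  invisible(TRUE)
}

# --- segmentation -----------------------------------------------------------

# Otsu threshold on a plain numeric vector (maximal between-class variance);
# needed because the threshold must be computed within an arbitrary voxel
# subset (the nucleus support), not per image frame
otsu_threshold <- function(v, levels = 256L) {
  r <- range(v)
  if (diff(r) <= 0) stop("cannot threshold a constant sample", call. = FALSE)
  br <- seq(r[1], r[2], length.out = levels + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  bc <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  bc[!is.finite(bc)] <- -Inf
  mids[which.max(bc)]
}

# connected components of a logical 3D mask at 26-connectivity, via an
# igraph over the voxel adjacency
label_components <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list(membership = integer(0), ids = fg))
  rank <- array(0L, d)
  rank[fg] <- seq_along(fg)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
               (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    o <- as.integer(offs[k, ])
    z1 <- max(1L, 1L - o[1]):min(d[1], d[1] - o[1])
    y1 <- max(1L, 1L - o[2]):min(d[2], d[2] - o[2])
    x1 <- max(1L, 1L - o[3]):min(d[3], d[3] - o[3])
    a <- rank[z1, y1, x1, drop = FALSE]
    b <- rank[z1 + o[1], y1 + o[2], x1 + o[3], drop = FALSE]
    both <- a > 0L & b > 0L
    if (any(both)) edges[[length(edges) + 1L]] <- rbind(a[both], b[both])
  }
  if (length(edges) == 0L) {
    membership <- seq_along(fg)
  } else {
    e <- do.call(cbind, edges)
    g <- igraph::make_graph(as.vector(e), n = length(fg), directed = FALSE)
    membership <- igraph::components(g)$membership
  }
  list(membership = membership, ids = fg)
}

#' Segment the array domain from a stack
#'
#' Gaussian pre-smoothing at a physical-unit sigma (anisotropy-aware),
#' Otsu threshold computed within the nucleus support, 26-connected
#' components, removal of components below \code{min_volume}, and return of
#' the largest remaining component. When no nucleus mask is supplied the
#' support is itself estimated by a first Otsu pass separating nucleus from
#' background.
#'
#' @param stack an \code{\link{image_stack3d}}.
#' @param channel channel to segment (default "array").
#' @param smoothing_sigma pre-smoothing sigma in um (default 0.1).
#' @param min_volume minimum component volume in um^3 (default 0.05).
#' @param nucleus_mask optional logical array restricting the threshold
#'   computation.
#' @return logical 3D mask of the selected component.
#' @export
segment_array <- function(stack, channel = "array", smoothing_sigma = 0.1,
                          min_volume = 0.05, nucleus_mask = NULL) {
  stopifnot(inherits(stack, "image_stack3d"))
  img <- stack_channel(stack, channel)
  if (diff(range(img)) <= 0)
    stop("degenerate input: channel is constant and cannot be segmented",
         call. = FALSE)
  sp <- stack$spacing
  if (smoothing_sigma > 0)
    img <- gauss_blur3d(img, smoothing_sigma / sp)
  if (is.null(nucleus_mask)) {
    th0 <- otsu_threshold(as.vector(img))
    nucleus_mask <- img > th0
  }
  if (!any(nucleus_mask))
    stop("nucleus support is empty", call. = FALSE)
  th <- otsu_threshold(img[nucleus_mask])
  fgmask <- nucleus_mask & img > th
  lab <- label_components(fgmask)
  if (length(lab$ids) == 0L)
    stop(sprintf(
      "empty segmentation: no voxels above Otsu threshold %.4g (min_volume %.3g um^3)",
      th, min_volume), call. = FALSE)
  sizes <- tabulate(lab$membership)
  voxvol <- prod(sp)
  keep <- which(sizes * voxvol >= min_volume)
  if (length(keep) == 0L)
    stop(sprintf(
      "empty segmentation: all %d component(s) below min_volume %.3g um^3 (threshold %.4g)",
      length(sizes), min_volume, th), call. = FALSE)
  best <- keep[which.max(sizes[keep])]
  out <- array(FALSE, dim(img))
  out[lab$ids[lab$membership == best]] <- TRUE
  out
}

# --- intensity --------------------------------------------------------------

#' Array intensity within a mask
#'
#' Total and mean channel intensity over the mask, plus a calibrated total
#' (\code{normalized = total * calibration_factor}); the linear calibration
#' factor stands in for a detector (PMT gain/offset) standard curve and
#' maps acquisitions taken at different settings onto a common scale.
#'
#' @param stack an \code{\link{image_stack3d}}.
#' @param mask logical 3D mask.
#' @param channel channel name.
#' @param calibration_factor linear calibration factor (default 1).
#' @return list with \code{total}, \code{mean}, \code{normalized}.
#' @export
array_intensity <- function(stack, mask, channel = "array",
                            calibration_factor = 1) {
  stopifnot(inherits(stack, "image_stack3d"))
  check_mask(mask)
  img <- stack_channel(stack, channel)
  if (!all(dim(mask) == dim(img)))
    stop("mask dimensions do not match the stack", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  v <- img[mask]
  total <- sum(v)
  list(total = total, mean = mean(v),
       normalized = total * calibration_factor)
}

# dilate/erode a mask by an ellipsoidal ball of physical radius r (um)
morph_ball <- function(mask, r, spacing, op = c("dilate", "erode")) {
  op <- match.arg(op)
  if (r <= 0) return(mask)
  if (op == "erode") return(!morph_ball(!mask, r, spacing, "dilate"))
  d <- dim(mask)
  rad <- floor(r / spacing)
  out <- mask
  for (dz in -rad[1]:rad[1]) for (dy in -rad[2]:rad[2])
    for (dx in -rad[3]:rad[3]) {
      if ((dz * spacing[1])^2 + (dy * spacing[2])^2 +
          (dx * spacing[3])^2 > r^2) next
      if (dz == 0 && dy == 0 && dx == 0) next
      z1 <- max(1L, 1L + dz):min(d[1], d[1] + dz)
      y1 <- max(1L, 1L + dy):min(d[2], d[2] + dy)
      x1 <- max(1L, 1L + dx):min(d[3], d[3] + dx)
      out[z1, y1, x1] <- out[z1, y1, x1] |
        mask[z1 - dz, y1 - dy, x1 - dx]
    }
  out
}

#' In-array versus nucleoplasm enrichment of a channel
#'
#' Mean channel intensity inside the domain mask divided by the mean in the
#' nucleoplasm (nucleus outside the mask): a quantitative surrogate for
#' presence/absence scoring of factor accumulation at the array. A value
#' near 1 means no accumulation (loss), larger values mean enrichment.
#'
#' To make the ratio robust to PSF blur at the domain boundary, the inside
#' region can be eroded and the excluded region dilated by \code{buffer}
#' micrometres (set it to about one PSF sigma).
#'
#' @param stack an \code{\link{image_stack3d}}.
#' @param mask logical domain mask.
#' @param channel channel name.
#' @param nucleus_mask optional logical nucleus mask; estimated by an Otsu
#'   pass on the channel when absent.
#' @param buffer erosion/exclusion radius in um (default 0).
#' @return dimensionless enrichment ratio.
#' @export
enrichment_ratio <- function(stack, mask, channel, nucleus_mask = NULL,
                             buffer = 0) {
  stopifnot(inherits(stack, "image_stack3d"))
  check_mask(mask)
  img <- stack_channel(stack, channel)
  if (is.null(nucleus_mask)) {
    th0 <- otsu_threshold(as.vector(img))
    nucleus_mask <- img > th0
  }
  inner <- if (buffer > 0) morph_ball(mask, buffer, stack$spacing, "erode")
           else mask
  excl <- if (buffer > 0) morph_ball(mask, buffer, stack$spacing, "dilate")
          else mask
  # keep the nucleoplasm sample away from the PSF-attenuated nuclear rim
  core <- if (buffer > 0) morph_ball(nucleus_mask, buffer, stack$spacing,
                                     "erode") else nucleus_mask
  outer <- core & !excl
  if (!any(inner) || !any(outer))
    stop("mask interior or nucleoplasm region is empty", call. = FALSE)
  denom <- mean(img[outer])
  if (denom <= 0) stop("nucleoplasm mean is zero", call. = FALSE)
  mean(img[inner]) / denom
}

#' Measure the domain morphometry of one cell
#'
#' Convenience wrapper: segment the array channel and compute volume, mesh
#' surface area, surface factor and intensities in one record.
#'
#' @inheritParams segment_array
#' @param calibration_factor linear intensity calibration factor.
#' @return object of class \code{"domain_morphology"}: a list with
#'   \code{mask}, \code{volume}, \code{surface_area}, \code{surface_factor},
#'   \code{total_intensity}, \code{mean_intensity},
#'   \code{normalized_intensity}.
#' @export
measure_domain <- function(stack, channel = "array", smoothing_sigma = 0.1,
                           min_volume = 0.05, calibration_factor = 1,
                           nucleus_mask = NULL) {
  mask <- segment_array(stack, channel, smoothing_sigma, min_volume,
                        nucleus_mask)
  v <- measure_volume(mask, stack$spacing)
  s <- measure_surface_area(mask, stack$spacing, "marching_cubes")
  int <- array_intensity(stack, mask, channel, calibration_factor)
  structure(list(mask = mask, volume = v, surface_area = s,
                 surface_factor = surface_factor(v, s),
                 total_intensity = int$total, mean_intensity = int$mean,
                 normalized_intensity = int$normalized),
            class = "domain_morphology")
}

#' @export
print.domain_morphology <- function(x, ...) {
  cat(sprintf(
    "domain_morphology: V %.3g um^3, S %.3g um^2, surface factor %.3f\n",
    x$volume, x$surface_area, x$surface_factor))
  cat(sprintf("  intensity: total %.4g, mean %.4g, normalized %.4g\n",
              x$total_intensity, x$mean_intensity, x$normalized_intensity))
  invisible(x)
}

# --- condensation classification -------------------------------------------

#' Classify decondensed arrays against a control quantile
#'
#' The decondensation threshold is the \code{control_quantile} quantile
#' (linear interpolation) of the control cohort's surface factors --
#' i.e. the fraction of control cells regarded as mildly decondensed
#' defines the cut. Cells with surface factor strictly below the threshold
#' are labelled "decondensed"; ties count as condensed (conservative toward
#' the null).
#'
#' @param test surface factors of the test cohort: a numeric vector or a
#'   cohort data.frame with a \code{surface_factor} column.
#' @param control surface factors of the control cohort (>= 10 cells).
#' @param control_quantile quantile defining the threshold (default 0.20).
#' @return object of class \code{"decondensation"}: list with
#'   \code{threshold}, \code{labels} (per test cell), and
#'   \code{percent_decondensed} for the test and control cohorts.
#' @export
classify_decondensed <- function(test, control, control_quantile = 0.20) {
  sf_test <- extract_sf(test)
  sf_ctrl <- extract_sf(control)
  if (length(sf_test) == 0L || length(sf_ctrl) == 0L)
    stop("cohorts must be non-empty", call. = FALSE)
  if (length(sf_ctrl) < 10L)
    stop("control cohort must contain at least 10 cells", call. = FALSE)
  thr <- unname(stats::quantile(sf_ctrl, control_quantile, type = 7))
  labels <- ifelse(sf_test < thr, "decondensed", "condensed")
  names(labels) <- names(sf_test)
  structure(list(
    threshold = thr, control_quantile = control_quantile, labels = labels,
    percent_decondensed = 100 * mean(sf_test < thr),
    control_percent_decondensed = 100 * mean(sf_ctrl < thr)),
    class = "decondensation")
}

extract_sf <- function(x) {
  if (is.data.frame(x)) {
    if (!"surface_factor" %in% names(x))
      stop("cohort table lacks a 'surface_factor' column", call. = FALSE)
    v <- x$surface_factor
    if (!is.null(x$cell_id)) names(v) <- x$cell_id
    v
  } else as.numeric(x)
}

#' @export
print.decondensation <- function(x, ...) {
  cat(sprintf(
    "decondensation: threshold %.4f (control %.0f%% quantile)\n",
    x$threshold, 100 * x$control_quantile))
  cat(sprintf("  test cohort: %.1f%% decondensed (n = %d); control: %.1f%%\n",
              x$percent_decondensed, length(x$labels),
              x$control_percent_decondensed))
  invisible(x)
}
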