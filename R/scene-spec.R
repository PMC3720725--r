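#' Specify a synthetic nucleus scene
#'
#' Describes a single-nucleus scene for the stack generator: a nucleus of
#' uniform nucleoplasmic signal containing a bright lacO-array domain that
#' is either a compact spheroid (condensed array) or a dilated persistent
#' random walk (unfolded, fibrillar array). Lengths are micrometres,
#' intensities arbitrary units.
#'
#' When \code{fiber_thickness} is \code{NULL} it is derived so that the
#' nominal fibre volume (length x pi x thickness^2) equals the nominal
#' volume of a sphere of \code{sphere_radius}, which makes sphere and fibre
#' cohorts comparable at fixed volume.
#'
#' @param shape_kind "sphere" or "fiber".
#' @param sphere_radius radius of the condensed domain (um).
#' @param fiber_length contour length of the fibrillar domain (um).
#' @param fiber_persistence step-direction correlation in [0, 1]; higher
#'   values give straighter fibres.
#' @param fiber_thickness tube (dilation) radius of the fibre (um), or
#'   \code{NULL} to match the sphere volume.
#' @param nucleus_radius nucleus radius (um); the domain must fit inside.
#' @param array_amplitude expected array-channel intensity inside the
#'   domain (a.u.).
#' @param nucleoplasm_level expected array-channel intensity in the
#'   nucleoplasm (a.u.).
#' @param channel_enrichments named numeric vector mapping extra channel
#'   names to their in-array / nucleoplasm enrichment factor (>= 0); for
#'   example \code{c(HP1g = 3)} adds an HP1-gamma-like channel accumulating
#'   3-fold at the array.
#' @param psf_sigma_lateral,psf_sigma_axial Gaussian PSF sigmas (um); the
#'   defaults emulate deconvolved confocal data.
#' @param gaussian_noise_sigma additive Gaussian noise sd (a.u.).
#' @param voxel_spacing (axial, lateral, lateral) spacing in um; default
#'   \code{c(0.2, 0.06, 0.06)}.
#' @param seed integer RNG seed; equal specs with equal seeds generate
#'   bitwise-identical stacks.
#' @return An object of class \code{"scene_spec"}.
#' @export
scene_spec <- function(shape_kind = c("sphere", "fiber"),
                       sphere_radius = 1,
                       fiber_length = 10,
                       fiber_persistence = 0.9,
                       fiber_thickness = NULL,
                       nucleus_radius = 3,
                       array_amplitude = 100,
                       nucleoplasm_level = 20,
                       channel_enrichments = NULL,
                       psf_sigma_lateral = 0.08,
                       psf_sigma_axial = 0.2,
                       gaussian_noise_sigma = 5,
                       voxel_spacing = c(0.2, 0.06, 0.06),
                       seed = 1L) {
  shape_kind <- match.arg(shape_kind)
  for (nm in c("sphere_radius", "fiber_length", "fiber_persistence",
               "nucleus_radius", "array_amplitude", "nucleoplasm_level",
               "psf_sigma_lateral", "psf_sigma_axial"))
    if (nm != "fiber_persistence")
      stop_if_not_scalar_pos(get(nm), nm)
  if (!is.numeric(fiber_persistence) || fiber_persistence < 0 ||
      fiber_persistence > 1)
    stop("'fiber_persistence' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(voxel_spacing) || length(voxel_spacing) != 3L ||
      any(voxel_spacing <= 0))
    stop("'voxel_spacing' must be three strictly positive lengths (um)",
         call. = FALSE)
  if (gaussian_noise_sigma < 0)
    stop("'gaussian_noise_sigma' must be >= 0", call. = FALSE)
  if (is.null(fiber_thickness))
    fiber_thickness <- sqrt(4 * sphere_radius^3 / (3 * fiber_length))
  stop_if_not_scalar_pos(fiber_thickness, "fiber_thickness")
  if (!is.null(channel_enrichments)) {
    if (is.null(names(channel_enrichments)) ||
        any(!nzchar(names(channel_enrichments))))
      stop("'channel_enrichments' must be a named numeric vector",
           call. = FALSE)
    if (any(!is.finite(channel_enrichments)) || any(channel_enrichments < 0))
      stop("enrichment factors must be finite and >= 0", call. = FALSE)
  }
  if (shape_kind == "sphere" && sphere_radius >= nucleus_radius)
    stop(sprintf(
      "domain does not fit inside nucleus: sphere_radius %.3g um >= nucleus_radius %.3g um",
      sphere_radius, nucleus_radius), call. = FALSE)
  if (shape_kind == "fiber" && fiber_thickness >= nucleus_radius)
    stop(sprintf(
      "domain does not fit inside nucleus: fiber_thickness %.3g um >= nucleus_radius %.3g um",
      fiber_thickness, nucleus_radius), call. = FALSE)
  structure(list(
    shape_kind = shape_kind, sphere_radius = sphere_radius,
    fiber_length = fiber_length, fiber_persistence = fiber_persistence,
    fiber_thickness = fiber_thickness, nucleus_radius = nucleus_radius,
    array_amplitude = array_amplitude, nucleoplasm_level = nucleoplasm_level,
    channel_enrichments = channel_enrichments,
    psf_sigma_lateral = psf_sigma_lateral, psf_sigma_axial = psf_sigma_axial,
    gaussian_noise_sigma = gaussian_noise_sigma,
    voxel_spacing = as.numeric(voxel_spacing), seed = as.integer(seed)),
    class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("scene_spec: %s domain in %.2g um nucleus\n",
              x$shape_kind, x$nucleus_radius))
  if (x$shape_kind == "sphere")
    cat(sprintf("  sphere radius %.3g um (nominal V %.3g um^3)\n",
                x$sphere_radius, 4 / 3 * pi * x$sphere_radius^3))
  else
    cat(sprintf(
      "  fibre length %.3g um, thickness %.3g um, persistence %.2f (nominal V %.3g um^3)\n",
      x$fiber_length, x$fiber_thickness, x$fiber_persistence,
      x$fiber_length * pi * x$fiber_thickness^2))
  cat(sprintf("  amplitude %.3g, nucleoplasm %.3g, noise sd %.3g, seed %d\n",
              x$array_amplitude, x$nucleoplasm_level,
              x$gaussian_noise_sigma, x$seed))
  invisible(x)
}

# nominal analytic volume of the generating geometry (um^3)
nominal_volume <- function(spec) {
  if (spec$shape_kind == "sphere") 4 / 3 * pi * spec$sphere_radius^3
  else spec$fiber_length * pi * spec$fiber_thickness^2
}
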