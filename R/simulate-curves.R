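# Simulation of FLIP/FRAP intensity time series from a two-population
# (freely diffusing + transiently chromatin-bound) exchange model. The
# simulation operates at ROI-intensity level: the bi-exponential expected
# value plus additive Gaussian noise, which keeps the generating parameters
# exactly known for parameter-recovery studies.

#' Specify a two-pool photobleaching kinetics scenario
#'
#' The model has a fast component (freely diffusing molecules, half-time
#' \code{thalf_fast}) and a slow component (transiently chromatin-bound
#' molecules, half-time \code{thalf_slow}) with bound fraction
#' \code{f_bound}.
#'
#' @param f_bound chromatin-bound (slow pool) fraction in [0, 1].
#' @param thalf_fast,thalf_slow half-times in seconds
#'   (\code{thalf_fast < thalf_slow}).
#' @param sampling_interval frame interval in s (default 2, the usual
#'   live-imaging cadence).
#' @param n_frames post-bleach frames (default 80, typical for FLIP; use 60
#'   for FRAP).
#' @param n_prebleach pre-bleach frames (default 10).
#' @param background_level,prebleach_level raw ROI intensities (a.u.).
#' @param noise_sigma additive Gaussian noise sd as a fraction of the
#'   pre-bleach amplitude (prebleach - background).
#' @param seed integer RNG seed.
#' @return object of class \code{"kinetics_spec"}.
#' @export
kinetics_spec <- function(f_bound, thalf_fast, thalf_slow,
                          sampling_interval = 2, n_frames = 80L,
                          n_prebleach = 10L, background_level = 10,
                          prebleach_level = 110, noise_sigma = 0.02,
                          seed = 1L) {
  if (!is.numeric(f_bound) || f_bound < 0 || f_bound > 1)
    stop("'f_bound' must lie in [0, 1]", call. = FALSE)
  stop_if_not_scalar_pos(thalf_fast, "thalf_fast")
  if (!(is.numeric(thalf_slow) && (is.infinite(thalf_slow) ||
                                    thalf_slow > 0)))
    stop("'thalf_slow' must be positive (Inf allowed)", call. = FALSE)
  if (thalf_fast >= thalf_slow)
    stop("'thalf_fast' must be smaller than 'thalf_slow'", call. = FALSE)
  stop_if_not_scalar_pos(sampling_interval, "sampling_interval")
  if (n_frames < 1L || n_prebleach < 1L)
    stop("'n_frames' and 'n_prebleach' must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  if (prebleach_level <= background_level)
    stop("'prebleach_level' must exceed 'background_level'", call. = FALSE)
  structure(list(
    f_bound = f_bound, thalf_fast = thalf_fast, thalf_slow = thalf_slow,
    sampling_interval = sampling_interval, n_frames = as.integer(n_frames),
    n_prebleach = as.integer(n_prebleach),
    background_level = background_level, prebleach_level = prebleach_level,
    noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "kinetics_spec")
}

#' @export
print.kinetics_spec <- function(x, ...) {
  cat(sprintf(
    "kinetics_spec: bound %.1f%% (t1/2 %.3g s), free %.1f%% (t1/2 %.3g s)\n",
    100 * x$f_bound, x$thalf_slow, 100 * (1 - x$f_bound), x$thalf_fast))
  cat(sprintf("  %d pre + %d post frames at %.3g s, noise sd %.3g, seed %d\n",
              x$n_prebleach, x$n_frames, x$sampling_interval,
              x$noise_sigma, x$seed))
  invisible(x)
}

# two-pool decay kernel, value 1 at t = 0
biexp_kernel <- function(t, f_bound, thalf_fast, thalf_slow) {
  slow <- if (is.infinite(thalf_slow)) rep(1, length(t))
          else exp(-log(2) * t / thalf_slow)
  (1 - f_bound) * exp(-log(2) * t / thalf_fast) + f_bound * slow
}

#' Simulate a photobleaching time series
#'
#' For FLIP, the expected post-bleach spot signal is
#' \code{background + A * [(1 - f_bound) exp(-ln2 t / thalf_fast) +
#' f_bound exp(-ln2 t / thalf_slow)]} with
#' \code{A = prebleach_level - background_level}; pre-bleach frames sit at
#' \code{prebleach_level}. For FRAP the expected signal recovers as
#' \code{background + A * (1 - kernel(t))} toward the pre-bleach plateau.
#' Additive Gaussian noise of sd \code{noise_sigma * A} is applied to the
#' spot series; the background series is constant.
#'
#' @param spec a \code{\link{kinetics_spec}}.
#' @param mode "FLIP" or "FRAP".
#' @return object of class \code{"bleach_series"}: list with \code{times}
#'   (s, 0 at the last pre-bleach frame), \code{spot}, \code{background},
#'   \code{n_prebleach}, \code{mode} and the generating \code{spec}.
#' @export
simulate_bleach_curve <- function(spec, mode = c("FLIP", "FRAP")) {
  stopifnot(inherits(spec, "kinetics_spec"))
  mode <- match.arg(mode)
  dt <- spec$sampling_interval
  npre <- spec$n_prebleach
  tpre <- -((npre - 1L):0) * dt
  tpost <- seq_len(spec$n_frames) * dt
  A <- spec$prebleach_level - spec$background_level
  kern <- biexp_kernel(tpost, spec$f_bound, spec$thalf_fast,
                       spec$thalf_slow)
  expected_post <- if (mode == "FLIP") spec$background_level + A * kern
                   else spec$background_level + A * (1 - kern)
  spot <- with_seed(spec$seed, {
    c(rep(spec$prebleach_level, npre), expected_post) +
      stats::rnorm(npre + spec$n_frames, sd = spec$noise_sigma * A)
  })
  structure(list(
    times = c(tpre, tpost), spot = spot,
    background = rep(spec$background_level, npre + spec$n_frames),
    n_prebleach = npre, mode = mode, spec = spec),
    class = "bleach_series")
}

#' @export
print.bleach_series <- function(x, ...) {
  cat(sprintf("bleach_series (%s): %d pre + %d post frames, dt %.3g s\n",
              x$mode, x$n_prebleach, length(x$times) - x$n_prebleach,
              diff(x$times)[1]))
  invisible(x)
}

#' Construct a bleach series from raw data
#'
#' @param times acquisition times in s (strictly increasing, uniform grid).
#' @param spot raw spot/strip ROI means.
#' @param background raw background ROI means.
#' @param n_prebleach number of frames preceding the bleach (>= 1).
#' @param mode "FLIP" or "FRAP".
#' @return object of class \code{"bleach_series"}.
#' @export
bleach_series <- function(times, spot, background,
                          n_prebleach = 10L, mode = c("FLIP", "FRAP")) {
  mode <- match.arg(mode)
  if (length(times) != length(spot) || length(spot) != length(background))
    stop("'times', 'spot' and 'background' must have equal length",
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (n_prebleach < 1L || n_prebleach >= length(times))
    stop("'n_prebleach' must be >= 1 and leave post-bleach frames",
         call. = FALSE)
  structure(list(times = as.numeric(times), spot = as.numeric(spot),
                 background = as.numeric(background),
                 n_prebleach = as.integer(n_prebleach), mode = mode),
            class = "bleach_series")
}
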