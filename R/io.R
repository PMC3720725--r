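# File conventions: multi-page TIFF per channel with a JSON sidecar for
# stacks; CSV for bleach curves and cohort tables.

#' Write an image stack as TIFF files plus a JSON sidecar
#'
#' One multi-page 32-bit TIFF per channel (pages are z slices; intensities
#' are rescaled to [0, 1] with the scale factor recorded in the sidecar)
#' and a \code{<prefix>.json} sidecar carrying voxel spacing, channel
#' names, intensity scales, the seed and, if given, the scalar ground
#' truth (volume, surface area, surface factor, enrichments; the voxel
#' mask itself is not serialized).
#'
#' @param stack an \code{\link{image_stack3d}}.
#' @param prefix output path prefix (files \code{<prefix>_<channel>.tif}).
#' @param truth optional \code{ground_truth}.
#' @param seed optional integer recorded in the sidecar.
#' @return invisibly, the sidecar path.
#' @export
write_array_stack <- function(stack, prefix, truth = NULL, seed = NULL) {
  stopifnot(inherits(stack, "image_stack3d"))
  d <- dim(stack$voxels)
  scales <- numeric(d[4])
  files <- character(d[4])
  for (ci in seq_len(d[4])) {
    ch <- stack$voxels[, , , ci, drop = TRUE]
    scales[ci] <- max(ch, 1e-12)
    pages <- lapply(seq_len(d[1]), function(z) ch[z, , ] / scales[ci])
    files[ci] <- paste0(prefix, "_", stack$channel_names[ci], ".tif")
    tiff::writeTIFF(pages, files[ci], bits.per.sample = 32L)
  }
  side <- list(spacing = stack$spacing,
               channel_names = stack$channel_names,
               intensity_scales = scales, files = basename(files),
               seed = seed)
  if (!is.null(truth))
    side$ground_truth <- list(
      true_volume = truth$true_volume,
      true_surface_area = truth$true_surface_area,
      true_surface_factor = truth$true_surface_factor,
      channel_enrichments = as.list(truth$channel_enrichments))
  path <- paste0(prefix, ".json")
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an image stack written by \code{write_array_stack}
#'
#' @param prefix the path prefix used at write time.
#' @return list with \code{stack} (an \code{image_stack3d}) and
#'   \code{truth} (scalar ground truth list, or NULL).
#' @export
read_array_stack <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  dirn <- dirname(prefix)
  chs <- lapply(seq_along(side$files), function(ci) {
    pages <- tiff::readTIFF(file.path(dirn, side$files[ci]), all = TRUE)
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    arr * side$intensity_scales[ci]
  })
  vox <- array(0, c(dim(chs[[1]]), length(chs)))
  for (ci in seq_along(chs)) vox[, , , ci] <- chs[[ci]]
  list(stack = image_stack3d(vox, side$spacing, side$channel_names),
       truth = side$ground_truth)
}

#' Write a bleach series to CSV
#'
#' Columns: \code{frame}, \code{time_s}, \code{spot_mean},
#' \code{background_mean}. Pre-bleach frames are those with
#' \code{time_s <= 0}.
#'
#' @param series a \code{\link{bleach_series}}.
#' @param path output path.
#' @export
write_bleach_csv <- function(series, path) {
  stopifnot(inherits(series, "bleach_series"))
  utils::write.csv(data.frame(
    frame = seq_along(series$times), time_s = series$times,
    spot_mean = series$spot, background_mean = series$background),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a bleach series from CSV
#'
#' @param path CSV with columns \code{frame}, \code{time_s},
#'   \code{spot_mean}, \code{background_mean}.
#' @param mode "FLIP" or "FRAP".
#' @return a \code{\link{bleach_series}} (pre-bleach frame count inferred
#'   from non-positive times).
#' @export
read_bleach_csv <- function(path, mode = c("FLIP", "FRAP")) {
  mode <- match.arg(mode)
  d <- utils::read.csv(path)
  need <- c("time_s", "spot_mean", "background_mean")
  if (!all(need %in% names(d)))
    stop("CSV must have columns time_s, spot_mean, background_mean",
         call. = FALSE)
  bleach_series(d$time_s, d$spot_mean, d$background_mean,
                n_prebleach = sum(d$time_s <= 0), mode = mode)
}

#' Validate and write/read cohort tables
#'
#' A cohort table has one row per cell with at least \code{cell_id}
#' (unique) and \code{construct_label}, plus the morphometric columns.
#'
#' @param table cohort data.frame.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(table, path) {
  validate_cohort_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  validate_cohort_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

validate_cohort_table <- function(table) {
  if (!is.data.frame(table))
    stop("cohort table must be a data.frame", call. = FALSE)
  if (!all(c("cell_id", "construct_label") %in% names(table)))
    stop("cohort table needs 'cell_id' and 'construct_label' columns",
         call. = FALSE)
  if (anyDuplicated(table$cell_id))
    stop("cell_ids must be unique", call. = FALSE)
  if (any(is.na(table$construct_label) | !nzchar(table$construct_label)))
    stop("every row must carry a construct_label", call. = FALSE)
  table
}
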