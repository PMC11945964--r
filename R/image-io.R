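#' Read an image frame from PNG
#'
#' Frames are held in memory as numeric arrays of 8-bit values in `[0, 255]`:
#' `H x W x 3` for RGB, `H x W` for gray-scale. Pixel coordinates throughout
#' the package are 0-based `(row, col)` with half-open ranges, matching the
#' manifest convention.
#'
#' @param path path to a PNG file.
#' @return numeric array of values in `[0, 255]`.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) abort_io(paste0("frame not found: ", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  round_half_up(img * 255)
}

#' Write an image frame to PNG
#'
#' @param img numeric array in `[0, 255]` (`H x W` or `H x W x 3`).
#' @param path output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_frame <- function(img, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

manifest_cols <- c("case_id", "label", "frame_path", "frame_index",
                   "probe_row", "probe_col", "pixels_per_cm")

#' Read / write a cohort manifest
#'
#' The manifest is the package's hand-off format for a cohort: one CSV row per
#' frame with columns `case_id, label, frame_path, frame_index, probe_row,
#' probe_col, pixels_per_cm`. `label` is `"benign"` or `"malignant"`;
#' `probe_row`/`probe_col` are the 0-based pixel coordinates of the probe
#' center; `pixels_per_cm` is the scale calibration that replaces on-screen
#' scale-mark detection.
#'
#' @param path CSV path.
#' @return a tibble with one row per frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_io(paste0("manifest not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_cols, names(df))
  if (length(missing))
    abort_data(paste0("manifest is missing columns: ", paste(missing, collapse = ", ")))
  validate_manifest(tibble::as_tibble(df))
}

#' @rdname read_manifest
#' @param manifest tibble of frame records.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(manifest[, manifest_cols]), path, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(manifest) {
  if (!all(manifest$label %in% c("benign", "malignant")))
    abort_data("manifest labels must be 'benign' or 'malignant'")
  lab_per_case <- tapply(manifest$label, manifest$case_id, function(l) length(unique(l)))
  if (any(lab_per_case != 1))
    abort_data("a case's label must be constant across its frames")
  if (any(manifest$pixels_per_cm <= 0))
    abort_data("pixels_per_cm must be positive")
  manifest
}

#' Summarize a manifest at case level
#'
#' @param manifest frame-level manifest tibble.
#' @return tibble with one row per case: `case_id`, `label`, `n_frames`.
#' @export
cohort_cases <- function(manifest) {
  manifest |>
    dplyr::group_by(.data$case_id, .data$label) |>
    dplyr::summarise(n_frames = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$case_id)
}

#' @importFrom rlang .data
NULL
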