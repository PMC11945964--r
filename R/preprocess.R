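#' Probe-centered crop specifications (Types 1-4)
#'
#' Radial EBUS frames are cropped to square fields of view centered on the
#' ultrasound probe. Four fixed physical sizes are defined: 4 x 4 cm (Type 1),
#' 3 x 3 cm (Type 2), 2 x 2 cm (Type 3) and 1 x 1 cm (Type 4). Calibration
#' (pixels per cm) travels in the manifest rather than being detected from
#' on-screen scale marks.
#'
#' @param type_id crop type, one of 1, 2, 3, 4.
#' @return a `crop_spec` list with `type_id` and `side_cm`.
#' @export
crop_spec <- function(type_id) {
  sides <- c(`1` = 4.0, `2` = 3.0, `3` = 2.0, `4` = 1.0)
  if (!is_count(type_id) || !as.character(type_id) %in% names(sides))
    abort_argument("type_id must be 1, 2, 3 or 4")
  structure(list(type_id = as.integer(type_id), side_cm = unname(sides[as.character(type_id)])),
            class = "crop_spec")
}

#' Crop a square probe-centered field of view
#'
#' Returns the axis-aligned square sub-image of side
#' `round(side_cm * pixels_per_cm)` pixels centered on the probe. No
#' resampling is performed: the result is exactly a sub-array of the input.
#' Pixel ranges are half-open and 0-based; for even side lengths the probe
#' pixel sits at offset `side/2` inside the crop (rows
#' `[center - side/2, center + side/2)`).
#'
#' @param frame image array (`H x W` or `H x W x C`), values untouched.
#' @param probe_center_px 0-based `(row, col)` of the probe center.
#' @param pixels_per_cm scale calibration.
#' @param spec a [crop_spec()] or a bare type id.
#' @return the cropped image array.
#' @export
slbic_crop <- function(frame, probe_center_px, pixels_per_cm, spec) {
  if (!inherits(spec, "crop_spec")) spec <- crop_spec(spec)
  d <- dim(frame)
  if (is.null(d) || length(d) < 2) abort_shape("frame must be a 2-D or 3-D array")
  side <- as.integer(round_half_up(spec$side_cm * pixels_per_cm))
  if (side < 1) abort_geometry("crop side rounds to zero pixels")
  r0 <- as.integer(probe_center_px[1]) - side %/% 2L
  c0 <- as.integer(probe_center_px[2]) - side %/% 2L
  over <- c(top = max(0L, -r0), left = max(0L, -c0),
            bottom = max(0L, r0 + side - d[1]), right = max(0L, c0 + side - d[2]))
  if (any(over > 0)) {
    bad <- over[over > 0]
    abort_geometry(paste0(
      "crop of side ", side, " px exceeds the frame by ",
      paste(sprintf("%d px (%s)", bad, names(bad)), collapse = ", ")))
  }
  rows <- (r0 + 1L):(r0 + side)
  cols <- (c0 + 1L):(c0 + side)
  if (length(d) == 2) frame[rows, cols, drop = FALSE] else frame[rows, cols, , drop = FALSE]
}

#' Polar resampling specification
#'
#' @param n_radius,n_angle output grid (rows = radius, cols = angle).
#' @param r_max_px outermost sampled radius in input pixels; must not exceed
#'   the distance from the probe center to the nearest image edge.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return a `polar_spec` list.
#' @export
polar_spec <- function(n_radius = 224L, n_angle = 224L, r_max_px,
                       interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (n_radius < 1 || n_angle < 1) abort_argument("output grid must be positive")
  if (r_max_px <= 0) abort_argument("r_max_px must be positive")
  structure(list(n_radius = as.integer(n_radius), n_angle = as.integer(n_angle),
                 r_max_px = r_max_px, interpolation = interpolation),
            class = "polar_spec")
}

# Distance (px) from a 0-based pixel-center coordinate to the nearest image
# edge, with the image occupying [-0.5, n - 0.5] along each axis.
center_edge_distance <- function(center, hw) {
  min(center[1] + 0.5, hw[1] - 0.5 - center[1],
      center[2] + 0.5, hw[2] - 0.5 - center[2])
}

#' Unwrap a radial image to polar coordinates
#'
#' Output pixel `(i, j)` (0-based) samples the input at radius
#' `r = (i + 0.5) / n_radius * r_max_px` and angle
#' `theta = (j + 0.5) / n_angle * 2 * pi` about the probe center, so rows
#' index radius (increasing outward) and columns index angle
#' (counter-clockwise from the +col direction, i.e. sample position
#' `row = center_row - r sin(theta)`, `col = center_col + r cos(theta)`).
#' Continuous sample coordinates are clamped to the pixel-center range before
#' interpolation; the precondition on `r_max_px` keeps every sample inside
#' the image so clamping only touches the half-pixel border.
#'
#' @inheritParams slbic_crop
#' @param image input array (`H x W` or `H x W x C`).
#' @param spec a [polar_spec()].
#' @return array of dim `(n_radius, n_angle[, C])`.
#' @export
polar_transform <- function(image, probe_center_px, spec) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2) abort_shape("image must be a 2-D or 3-D array")
  if (spec$r_max_px > center_edge_distance(probe_center_px, d[1:2]) + 1e-9)
    abort_geometry("r_max_px exceeds the distance from the probe center to the nearest edge")
  i <- (seq_len(spec$n_radius) - 0.5) / spec$n_radius * spec$r_max_px
  j <- (seq_len(spec$n_angle) - 0.5) / spec$n_angle * 2 * pi
  rr <- outer(i, -sin(j))                 # n_radius x n_angle offsets
  cc <- outer(i, cos(j))
  row_f <- clamp(probe_center_px[1] + rr, 0, d[1] - 1)
  col_f <- clamp(probe_center_px[2] + cc, 0, d[2] - 1)

  sample_plane <- function(plane) {
    if (spec$interpolation == "nearest") {
      ri <- clamp(round_half_up(row_f), 0, d[1] - 1)
      ci <- clamp(round_half_up(col_f), 0, d[2] - 1)
      out <- plane[cbind(as.vector(ri) + 1, as.vector(ci) + 1)]
    } else {
      r0 <- floor(row_f); c0 <- floor(col_f)
      fr <- row_f - r0;   fc <- col_f - c0
      r1 <- pmin(r0 + 1, d[1] - 1); c1 <- pmin(c0 + 1, d[2] - 1)
      g <- function(ri, ci) plane[cbind(as.vector(ri) + 1, as.vector(ci) + 1)]
      out <- g(r0, c0) * as.vector((1 - fr) * (1 - fc)) +
             g(r0, c1) * as.vector((1 - fr) * fc) +
             g(r1, c0) * as.vector(fr * (1 - fc)) +
             g(r1, c1) * as.vector(fr * fc)
      out <- round_half_up(out)
    }
    matrix(out, spec$n_radius, spec$n_angle)
  }

  if (length(d) == 2) return(sample_plane(image))
  out <- array(0, dim = c(spec$n_radius, spec$n_angle, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- sample_plane(image[, , ch])
  out
}

#' Convert an RGB image to gray-scale (BT.601 luma)
#'
#' `Y = 0.299 R + 0.587 G + 0.114 B`, rounded half-up to 8-bit.
#'
#' @param image `H x W x 3` array of values in `[0, 255]`.
#' @return `H x W` matrix.
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    abort_shape("to_grayscale expects an H x W x 3 array")
  round_half_up(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

#' Resize an image
#'
#' Bilinear (default) or nearest-neighbor resampling with half-pixel center
#' alignment: destination pixel `d` samples source coordinate
#' `(d + 0.5) * S / D - 0.5`, clamped to the source pixel-center range.
#' Identity when the input already has the target size. Values are rounded
#' half-up back to the 8-bit grid.
#'
#' @param image `H x W` or `H x W x C` array.
#' @param size target `(h, w)`.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return resized array.
#' @export
resize_to <- function(image, size, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(image)
  if (is.null(d) || length(d) < 2) abort_shape("image must be a 2-D or 3-D array")
  size <- as.integer(size)
  if (length(size) != 2 || any(size < 1)) abort_argument("target size must be two positive integers")
  if (all(d[1:2] == size)) return(image)

  src <- function(n_dst, n_src) clamp((seq_len(n_dst) - 0.5) * n_src / n_dst - 0.5, 0, n_src - 1)
  ys <- src(size[1], d[1]); xs <- src(size[2], d[2])

  resize_plane <- function(plane) {
    if (interpolation == "nearest") {
      yi <- clamp(round_half_up(ys), 0, d[1] - 1) + 1
      xi <- clamp(round_half_up(xs), 0, d[2] - 1) + 1
      return(plane[yi, xi, drop = FALSE])
    }
    y0 <- floor(ys); fy <- ys - y0; y1 <- pmin(y0 + 1, d[1] - 1)
    x0 <- floor(xs); fx <- xs - x0; x1 <- pmin(x0 + 1, d[2] - 1)
    # separable: interpolate rows, then columns
    a <- plane[y0 + 1, , drop = FALSE] * (1 - fy) + plane[y1 + 1, , drop = FALSE] * fy
    out <- a[, x0 + 1, drop = FALSE] * rep(1 - fx, each = size[1]) +
           a[, x1 + 1, drop = FALSE] * rep(fx, each = size[1])
    round_half_up(out)
  }

  if (length(d) == 2) return(resize_plane(image))
  out <- array(0, dim = c(size, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- resize_plane(image[, , ch])
  out
}
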