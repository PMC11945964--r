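#' Enumerate the six multi-scale composite specifications
#'
#' Three composites are built from the probe-centered crops (MS 1-2-3,
#' MS 1-2-4, MS 2-3-4) and three from their polar-unwrapped counterparts
#' (PMS 1-2-3, PMS 1-2-4, PMS 2-3-4). Each composite merges the gray-scale
#' versions of three crop types into one RGB image: the R channel holds the
#' smallest type id (largest physical field of view), B the largest.
#'
#' @return a tibble with columns `name`, `polar`, `type_r`, `type_g`, `type_b`.
#' @export
multiscale_specs <- function() {
  triples <- list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(2L, 3L, 4L))
  dplyr::bind_rows(lapply(c(FALSE, TRUE), function(p) {
    dplyr::bind_rows(lapply(triples, function(tr) {
      tibble::tibble(
        name = paste0(if (p) "PMS " else "MS ", paste(tr, collapse = "-")),
        polar = p, type_r = tr[1], type_g = tr[2], type_b = tr[3])
    }))
  }))
}

#' Look up one multi-scale specification by name
#'
#' Accepts the canonical names (`"MS 1-2-3"`, `"PMS 2-3-4"`, ...) as well as
#' hyphen/underscore forms such as `"MS-2-3-4"` or `"pms_1_2_4"`.
#'
#' @param name composite name.
#' @return a `multiscale_spec` list with `name`, `source_types`, `polar`.
#' @export
multiscale_spec <- function(name) {
  norm <- toupper(gsub("[ _-]+", "", name))
  specs <- multiscale_specs()
  key <- toupper(gsub("[ _-]+", "", specs$name))
  hit <- match(norm, key)
  if (is.na(hit))
    abort_key(paste0("unknown multi-scale spec '", name, "'; expected one of: ",
                     paste(specs$name, collapse = ", ")))
  row <- specs[hit, ]
  structure(list(name = row$name,
                 source_types = c(row$type_r, row$type_g, row$type_b),
                 polar = row$polar),
            class = "multiscale_spec")
}

#' Merge three gray-scale crops into one multi-scale RGB composite
#'
#' Channels are copied unmodified: R takes the smallest source type id,
#' G the middle, B the largest. Extracting the channels of the result
#' recovers the three inputs bit-exactly.
#'
#' @param gray_images named list of `H x W` gray matrices keyed by type id
#'   (`"1"` .. `"4"`); extra entries are ignored, the order is irrelevant.
#' @param spec a [multiscale_spec()] or a spec name.
#' @param provenance optional `(case_id, frame_index)` tag attached to the
#'   result.
#' @return `H x W x 3` array with attributes `spec` and `provenance`.
#' @export
generate_multiscale <- function(gray_images, spec, provenance = NULL) {
  if (!inherits(spec, "multiscale_spec")) spec <- multiscale_spec(spec)
  keys <- as.character(spec$source_types)
  missing <- setdiff(keys, names(gray_images))
  if (length(missing))
    abort_key(paste0("gray_images is missing type(s): ", paste(missing, collapse = ", ")))
  planes <- gray_images[keys]
  dims <- lapply(planes, dim)
  if (any(vapply(planes, function(p) is.null(dim(p)) || length(dim(p)) != 2, logical(1))))
    abort_shape("each gray image must be a 2-D matrix")
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    abort_shape(paste0("gray images disagree in size: ",
                       paste(vapply(dims, paste, character(1), collapse = "x"), collapse = " vs ")))
  out <- array(0, dim = c(dims[[1]], 3))
  for (k in 1:3) out[, , k] <- planes[[k]]
  attr(out, "spec") <- spec
  attr(out, "provenance") <- provenance
  out
}

#' Build branch input images from a raw frame
#'
#' One call takes a raw frame plus its probe geometry and produces the image
#' a given branch consumes: a resized crop (`"type3"`), a polar-unwrapped
#' crop (`"polar3"`), or a multi-scale composite (`"MS 2-3-4"`,
#' `"PMS 1-2-3"`, ...). All outputs are `size x size x 3` arrays in
#' `[0, 255]`.
#'
#' @param frame `H x W x 3` array.
#' @param probe_center_px 0-based `(row, col)` probe center.
#' @param pixels_per_cm calibration.
#' @param image_type branch name: `"type1"` .. `"type4"`, `"polar1"` ..
#'   `"polar4"`, or a multi-scale spec name.
#' @param size output side in pixels (224 matches the trained input size).
#' @param interpolation passed to the polar transform and resizing.
#' @return `size x size x 3` array.
#' @export
preprocess_frame <- function(frame, probe_center_px, pixels_per_cm, image_type,
                             size = 224L, interpolation = "bilinear") {
  ty <- parse_image_type(image_type)
  crop_one <- function(type_id, polar) {
    cr <- slbic_crop(frame, probe_center_px, pixels_per_cm, crop_spec(type_id))
    if (polar) {
      ctr <- c(dim(cr)[1] %/% 2L, dim(cr)[2] %/% 2L)
      sp <- polar_spec(size, size, r_max_px = center_edge_distance(ctr, dim(cr)[1:2]),
                       interpolation = interpolation)
      polar_transform(cr, ctr, sp)
    } else {
      resize_to(cr, c(size, size), interpolation)
    }
  }
  if (ty$kind == "single") {
    crop_one(ty$types, ty$polar)
  } else {
    grays <- lapply(ty$types, function(t) to_grayscale(crop_one(t, ty$polar)))
    names(grays) <- as.character(ty$types)
    generate_multiscale(grays, ty$spec)
  }
}

parse_image_type <- function(image_type) {
  if (inherits(image_type, "multiscale_spec"))
    return(list(kind = "ms", types = image_type$source_types,
                polar = image_type$polar, spec = image_type))
  s <- tolower(gsub("[ _-]+", "", image_type))
  if (grepl("^type[1-4]$", s))
    return(list(kind = "single", types = as.integer(substr(s, 5, 5)), polar = FALSE))
  if (grepl("^polar(type)?[1-4]$", s))
    return(list(kind = "single", types = as.integer(substr(s, nchar(s), nchar(s))), polar = TRUE))
  spec <- multiscale_spec(image_type)
  list(kind = "ms", types = spec$source_types, polar = spec$polar, spec = spec)
}

#' Preprocess every frame of a manifest to disk
#'
#' Writes `\{case\}_f\{frame\}_\{type\}.png` files for the requested image types,
#' mirroring the on-disk layout the training functions consume.
#'
#' @param manifest frame-level manifest tibble (paths relative to `root`).
#' @param root directory the manifest's `frame_path` entries are relative to.
#' @param image_types character vector of branch names (see
#'   [preprocess_frame()]).
#' @param out_dir output directory.
#' @param size output image side in pixels.
#' @return tibble of written files (`case_id`, `frame_index`, `image_type`,
#'   `path`), invisibly.
#' @export
preprocess_manifest <- function(manifest, root, image_types, out_dir, size = 224L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    frame <- read_frame(file.path(root, m$frame_path))
    for (ty in image_types) {
      img <- preprocess_frame(frame, c(m$probe_row, m$probe_col), m$pixels_per_cm,
                              ty, size = size)
      fn <- sprintf("%s_f%02d_%s.png", m$case_id, m$frame_index,
                    gsub("[ ]+", "", tolower(ty)))
      write_frame(img, file.path(out_dir, fn))
      rows[[length(rows) + 1]] <- tibble::tibble(
        case_id = m$case_id, frame_index = m$frame_index,
        image_type = ty, path = file.path(out_dir, fn))
    }
  }
  invisible(dplyr::bind_rows(rows))
}
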