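#' Configure the synthetic radial-EBUS phantom
#'
#' The phantom emulates what a 20 MHz radial ultrasound probe sees from inside
#' an airway: a dark central probe disk, multiplicative speckle, and a single
#' peribronchial lesion surrounding the probe whose appearance is conditioned
#' on the case label. Benign lesions render as homogeneous hypoechoic disks
#' with smooth circular boundaries; malignant lesions carry heterogeneous
#' internal texture and a radially perturbed (irregular) boundary. Defaults
#' reproduce the clinical cohort structure this package targets: 13 benign vs
#' 82 malignant cases, roughly 12 retained frames per case video, and a field
#' of view large enough for a probe-centered 4 x 4 cm crop.
#'
#' @param image_size_px side of the square frame in pixels.
#' @param pixels_per_cm scale calibration (replaces on-screen scale marks).
#' @param probe_radius_cm radius of the rendered probe disk.
#' @param n_cases_benign,n_cases_malignant case counts per class.
#' @param frames_per_case consecutive-frame stack length per case.
#' @param speckle_scale multiplicative log-normal speckle strength (sigma of
#'   log intensity); 0 disables noise and yields piecewise-constant frames.
#' @param lesion_radius_range_cm `(low, high)` bounds for the lesion radius.
#' @param class_separation in `[0, 1]`; scales the malignant texture amplitude
#'   and boundary irregularity. 1 gives a clearly separable cohort, smaller
#'   values weaken the malignant appearance cues.
#' @param p_ambiguous probability that a case is sonographically ambiguous:
#'   its rendered appearance is drawn from the *other* class's renderer while
#'   its biopsy label is unchanged. 0 (default) gives fully faithful
#'   appearance; positive values create genuinely overlapping classes, the
#'   regime where loss weighting matters.
#' @param seed top-level cohort seed; per-case and per-frame streams are
#'   derived from it with [derive_seed()].
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(image_size_px = 256L,
                           pixels_per_cm = 50,
                           probe_radius_cm = 0.25,
                           n_cases_benign = 13L,
                           n_cases_malignant = 82L,
                           frames_per_case = 12L,
                           speckle_scale = 0.3,
                           lesion_radius_range_cm = c(0.8, 1.4),
                           class_separation = 1,
                           p_ambiguous = 0,
                           seed = 1L) {
  cfg <- list(
    image_size_px = as.integer(image_size_px),
    pixels_per_cm = pixels_per_cm,
    probe_radius_cm = probe_radius_cm,
    n_cases_benign = as.integer(n_cases_benign),
    n_cases_malignant = as.integer(n_cases_malignant),
    frames_per_case = as.integer(frames_per_case),
    speckle_scale = speckle_scale,
    lesion_radius_range_cm = lesion_radius_range_cm,
    class_separation = class_separation,
    p_ambiguous = p_ambiguous,
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
}

validate_phantom_config <- function(cfg) {
  if (cfg$image_size_px < 2 * 2 * cfg$pixels_per_cm)
    abort_config("image_size_px must be at least 2 * 2 cm * pixels_per_cm so a 4 x 4 cm crop fits")
  if (cfg$pixels_per_cm <= 0) abort_config("pixels_per_cm must be positive")
  if (cfg$probe_radius_cm <= 0) abort_config("probe_radius_cm must be positive")
  r <- cfg$lesion_radius_range_cm
  if (length(r) != 2 || r[1] > r[2] || r[1] <= 0)
    abort_config("lesion_radius_range_cm must be positive with low <= high")
  if (cfg$probe_radius_cm >= r[1])
    abort_config("probe_radius_cm must be smaller than the minimum lesion radius")
  if (cfg$frames_per_case < 1) abort_config("frames_per_case must be positive")
  if (cfg$n_cases_benign < 0 || cfg$n_cases_malignant < 0)
    abort_config("case counts must be non-negative")
  if (cfg$speckle_scale < 0) abort_config("speckle_scale must be non-negative")
  if (cfg$class_separation < 0 || cfg$class_separation > 1)
    abort_config("class_separation must lie in [0, 1]")
  if (is.null(cfg$p_ambiguous)) cfg$p_ambiguous <- 0
  if (cfg$p_ambiguous < 0 || cfg$p_ambiguous > 1)
    abort_config("p_ambiguous must lie in [0, 1]")
  cfg
}

# Probe sits at the (integer) center pixel of the square frame, 0-based.
phantom_probe_center <- function(cfg) {
  c(cfg$image_size_px %/% 2L, cfg$image_size_px %/% 2L)
}

# Speckle in B-mode imagery is spatially correlated (the transducer's finite
# resolution cell), so the log-noise field is band-limited with a separable
# (1,2,1)/4 kernel and rescaled to keep unit marginal variance.
smooth_field <- function(Z) {
  S <- nrow(Z)
  k <- function(M) {
    up <- M[c(1, 1:(S - 1)), , drop = FALSE]
    dn <- M[c(2:S, S), , drop = FALSE]
    (up + 2 * M + dn) / 4
  }
  Z <- k(t(k(t(k(t(k(t(Z))))))))
  Z / sqrt(mean(Z^2))
}

# Case-level appearance parameters, a pure function of the case seed and
# label. An ambiguous case keeps its label but renders with the other
# class's appearance model.
phantom_case_params <- function(cfg, label, case_seed) {
  if (cfg$p_ambiguous > 0) {
    flip <- withr::with_seed(derive_seed(case_seed, 303),
                             runif(1) < cfg$p_ambiguous)
    if (flip) label <- if (label == "benign") "malignant" else "benign"
  }
  withr::with_seed(derive_seed(case_seed, 101), {
    sep <- cfg$class_separation
    p <- list(
      appearance = label,
      lesion_radius = runif(1, cfg$lesion_radius_range_cm[1], cfg$lesion_radius_range_cm[2]),
      offset_d = runif(1, 0, 0.2),
      offset_a = runif(1, 0, 2 * pi)
    )
    if (label == "malignant") {
      amps <- runif(3, 0.3, 1)
      p$irr_orders <- sample(3:7, 3)
      p$irr_amps   <- 0.16 * sep * amps / sum(amps)
      p$irr_phases <- runif(3, 0, 2 * pi)
      p$tex_freq   <- runif(3, 1.5, 3.5)
      p$tex_phase  <- runif(3, 0, 2 * pi)
      p$tex_amp    <- c(0.10, 0.06) * sep
    }
    p
  })
}

#' Render one synthetic EBUS frame
#'
#' A deterministic function of `(config, label, case_seed, frame_index)`:
#' regenerating with the same arguments yields a bit-identical image.
#' Lesion geometry and texture are drawn from the case stream; frame-to-frame
#' pose jitter and the speckle field come from a per-frame stream, mimicking
#' consecutive frames of one probe video.
#'
#' @param config a [phantom_config()].
#' @param label `"benign"` or `"malignant"`.
#' @param case_seed integer seed identifying the case.
#' @param frame_index 0-based frame number within the case.
#' @return `H x W x 3` array of 8-bit values (gray content replicated to RGB).
#' @export
generate_phantom_frame <- function(config, label, case_seed, frame_index = 0L) {
  config <- validate_phantom_config(config)
  if (!label %in% c("benign", "malignant"))
    abort_label("label must be 'benign' or 'malignant'")
  S <- config$image_size_px
  ctr <- phantom_probe_center(config)
  p <- phantom_case_params(config, label, case_seed)

  withr::with_seed(derive_seed(case_seed, 202, frame_index), {
    jit <- runif(2, -0.05, 0.05)           # cm, lesion pose jitter per frame
    rot <- runif(1, -0.15, 0.15)           # rad, texture/boundary phase drift
    rsc <- 1 + runif(1, -0.02, 0.02)       # lesion radius breathing
    Z <- if (config$speckle_scale > 0) smooth_field(matrix(rnorm(S * S), S, S))
         else matrix(0, S, S)
  })

  # cm coordinates relative to the probe center; rows increase downward
  dr <- matrix((0:(S - 1) - ctr[1]) / config$pixels_per_cm, S, S)
  dc <- matrix((0:(S - 1) - ctr[2]) / config$pixels_per_cm, S, S, byrow = TRUE)
  r_probe <- sqrt(dr^2 + dc^2)

  ox <- p$offset_d * cos(p$offset_a) + jit[1]
  oy <- p$offset_d * sin(p$offset_a) + jit[2]
  lx <- dc - ox
  ly <- dr - oy
  dl <- sqrt(lx^2 + ly^2)
  al <- atan2(ly, lx)

  R0 <- p$lesion_radius * rsc
  if (p$appearance == "malignant") {
    pert <- p$irr_amps[1] * sin(p$irr_orders[1] * (al + rot) + p$irr_phases[1]) +
            p$irr_amps[2] * sin(p$irr_orders[2] * (al + rot) + p$irr_phases[2]) +
            p$irr_amps[3] * sin(p$irr_orders[3] * (al + rot) + p$irr_phases[3])
    rb <- R0 * (1 + pert)
  } else {
    rb <- R0
  }

  tmpl <- matrix(0.45, S, S)               # surrounding parenchyma echo
  inside <- dl <= rb
  tmpl[inside] <- 0.22                     # hypoechoic lesion
  if (p$appearance == "malignant") {
    tex <- p$tex_amp[1] * sin(2 * pi * p$tex_freq[1] * lx + p$tex_phase[1] + rot) *
                          sin(2 * pi * p$tex_freq[2] * ly + p$tex_phase[2]) +
           p$tex_amp[2] * sin(2 * pi * p$tex_freq[3] * (lx + ly) + p$tex_phase[3])
    tmpl[inside] <- tmpl[inside] + tex[inside]
  }
  tmpl[r_probe <= config$probe_radius_cm] <- 0.06

  s <- config$speckle_scale
  img <- if (s > 0) tmpl * exp(s * Z - s^2 / 2) else tmpl
  q <- round_half_up(clamp(img, 0, 1) * 255)
  array(q, dim = c(S, S, 3))
}

#' Generate a reproducible phantom cohort on disk
#'
#' Writes one 8-bit RGB PNG per frame plus a frame-level CSV manifest
#' (`manifest.csv`) under `out_dir`. Per-case seeds are derived from the
#' config seed, so two runs with the same config are byte-identical.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest tibble, invisibly carrying `out_dir` as an attribute.
#' @export
generate_cohort <- function(config, out_dir) {
  config <- validate_phantom_config(config)
  dir.create(file.path(out_dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_io(paste0("cannot create output directory: ", out_dir))
  ctr <- phantom_probe_center(config)

  labels <- c(rep("benign", config$n_cases_benign),
              rep("malignant", config$n_cases_malignant))
  ids <- c(sprintf("B%03d", seq_len(config$n_cases_benign)),
           sprintf("M%03d", seq_len(config$n_cases_malignant)))

  rows <- vector("list", length(ids) * config$frames_per_case)
  k <- 0L
  for (i in seq_along(ids)) {
    case_seed <- derive_seed(config$seed, i)
    for (fi in seq_len(config$frames_per_case) - 1L) {
      img <- generate_phantom_frame(config, labels[i], case_seed, fi)
      rel <- file.path("frames", sprintf("%s_f%02d.png", ids[i], fi))
      write_frame(img, file.path(out_dir, rel))
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        case_id = ids[i], label = labels[i], frame_path = rel, frame_index = fi,
        probe_row = ctr[1], probe_col = ctr[2], pixels_per_cm = config$pixels_per_cm
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "out_dir") <- out_dir
  invisible(manifest)
}
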