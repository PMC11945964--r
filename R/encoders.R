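# Known backbone catalogue. The final-conv channel widths are architecture
# constants (what the backbone emits at 224 x 224 before global pooling).
backbone_catalogue <- c(
  resnet18 = 512L, resnet50 = 2048L, resnet101 = 2048L,
  resnext50 = 2048L, resnext101 = 2048L,
  densenet121 = 1024L, densenet169 = 1664L, densenet201 = 1920L,
  mobilenet_v2 = 1280L, shufflenet_v2 = 1024L,
  efficientnet_b0 = 1280L, efficientnet_v2 = 1280L,
  tiny_cnn = 32L
)

#' Configure a per-branch encoder
#'
#' An encoder is a convolutional backbone whose original classifier is
#' replaced by a three-layer head: `FC(d -> h1) -> BatchNorm -> ReLU ->
#' Dropout -> FC(h1 -> h2) -> BatchNorm -> ReLU -> Dropout -> FC(h2 -> 2)`.
#' `tiny_cnn` is a three-stage stride-2 CNN (~90k parameters) that trains on
#' a CPU in minutes and is the backbone used by every bundled experiment; the
#' twelve ImageNet backbone names are accepted for configuration but require
#' an external pretrained-vision library that this package does not bundle,
#' so [build_encoder()] refuses them with a configuration error.
#'
#' @param backbone_name one of `names(ebusfusion:::backbone_catalogue)`.
#' @param pretrained logical; `tiny_cnn` never claims pretraining.
#' @param head_dims integer vector `(d, h1, h2, 2)`; defaults to
#'   `(d, 512, 128, 2)` where `d` is the backbone's feature width.
#' @param dropout_p head dropout probability.
#' @param feature_stage `"last_conv"` (feature maps handed to fusion) or
#'   `"penultimate_fc"` (the width-`h2` head activation).
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(backbone_name = "tiny_cnn", pretrained = FALSE,
                           head_dims = NULL, dropout_p = 0.5,
                           feature_stage = c("last_conv", "penultimate_fc")) {
  feature_stage <- match.arg(feature_stage)
  if (!backbone_name %in% names(backbone_catalogue))
    abort_config(paste0("unknown backbone '", backbone_name, "'"))
  d <- backbone_catalogue[[backbone_name]]
  if (is.null(head_dims)) head_dims <- c(d, 512L, 128L, 2L)
  head_dims <- as.integer(head_dims)
  if (length(head_dims) != 4 || tail(head_dims, 1) != 2L)
    abort_config("head_dims must be (d, h1, h2, 2): the output width is the two classes")
  if (head_dims[1] != d)
    abort_config(paste0("head input width must equal the backbone feature width (", d, ")"))
  if (backbone_name == "tiny_cnn" && isTRUE(pretrained))
    abort_config("tiny_cnn has no pretrained weights")
  if (dropout_p < 0 || dropout_p > 1) abort_config("dropout_p must lie in [0, 1]")
  structure(list(backbone_name = backbone_name, pretrained = isTRUE(pretrained),
                 head_dims = head_dims, dropout_p = dropout_p,
                 feature_stage = feature_stage),
            class = "encoder_config")
}

build_tiny_backbone <- function() {
  nn_sequential(
    nn_conv2d(3, 8, k = 3, stride = 2, pad = 1), nn_batchnorm(8), nn_relu(),
    nn_conv2d(8, 16, k = 3, stride = 2, pad = 1), nn_batchnorm(16), nn_relu(),
    nn_conv2d(16, 32, k = 3, stride = 2, pad = 1), nn_batchnorm(32), nn_relu()
  )
}

#' Build an encoder from a configuration
#'
#' With `pretrained = FALSE` all parameters are drawn from a generator seeded
#' by `seed`, so two builds with the same seed are parameter-identical.
#'
#' @param config an [encoder_config()].
#' @param seed integer initialization seed.
#' @return an `ebus_encoder` object.
#' @export
build_encoder <- function(config, seed = 0L) {
  if (!inherits(config, "encoder_config")) abort_config("config must be an encoder_config")
  if (config$backbone_name != "tiny_cnn")
    abort_config(paste0(
      "backbone '", config$backbone_name, "' needs an external pretrained ",
      "vision library that is not bundled; use backbone_name = 'tiny_cnn'"))
  hd <- config$head_dims
  enc <- withr::with_seed(seed, {
    list(
      backbone = build_tiny_backbone(),
      pool = nn_global_avg_pool(),
      head = nn_sequential(
        nn_linear(hd[1], hd[2]), nn_batchnorm(hd[2]), nn_relu(), nn_dropout(config$dropout_p),
        nn_linear(hd[2], hd[3]), nn_batchnorm(hd[3]), nn_relu(), nn_dropout(config$dropout_p),
        nn_linear(hd[3], hd[4])
      )
    )
  })
  enc$config <- config
  enc$seed <- as.integer(seed)
  class(enc) <- "ebus_encoder"
  enc
}

encoder_modules <- function(encoder) {
  c(collect_modules(encoder$backbone), collect_modules(encoder$pool),
    collect_modules(encoder$head))
}

#' Encoder parameter and buffer state
#'
#' Deep copy of every parameter and running statistic; `identical()` on two
#' states is the bit-exact frozen-encoder check.
#'
#' @param encoder an `ebus_encoder`.
#' @return nested list of arrays.
#' @export
encoder_parameters <- function(encoder) {
  list(backbone = module_state(encoder$backbone),
       pool = module_state(encoder$pool),
       head = module_state(encoder$head))
}

restore_encoder_parameters <- function(encoder, state) {
  restore_module_state(encoder$backbone, state$backbone)
  restore_module_state(encoder$pool, state$pool)
  restore_module_state(encoder$head, state$head)
  invisible(encoder)
}

check_image_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 3) {
    if (!is.null(d) && length(d) == 3) { dim(x) <- c(d, 1L); d <- dim(x) }
  }
  if (length(dim(x)) != 4 || dim(x)[3] != 3)
    abort_shape("expected an (H, W, 3, N) image batch")
  x
}

#' Full forward pass of an encoder (logits)
#'
#' @param encoder an `ebus_encoder`.
#' @param x image batch `(H, W, 3, N)`, values already scaled to `[0, 1]`.
#' @param training logical; enables dropout and batch statistics.
#' @return `N x 2` logit matrix (columns: benign, malignant).
#' @export
encoder_logits <- function(encoder, x, training = FALSE) {
  x <- check_image_batch(x)
  h <- encoder$backbone$fwd(x, training)
  v <- encoder$pool$fwd(h, training)
  encoder$head$fwd(v, training)
}

#' Extract frozen convolutional feature maps
#'
#' Runs the backbone in evaluation mode (dropout off, fixed normalization
#' statistics) and returns the final convolutional block's activations.
#' Never mutates encoder parameters; repeated calls are identical.
#'
#' @inheritParams encoder_logits
#' @return feature maps `(H', W', C, N)`.
#' @export
extract_feature_map <- function(encoder, x) {
  x <- check_image_batch(x)
  encoder$backbone$fwd(x, training = FALSE)
}

#' Extract frozen FC-layer features
#'
#' Evaluation-mode activations after the second head block (width `h2`);
#' non-negative because the block ends in a ReLU.
#'
#' @inheritParams encoder_logits
#' @return `N x h2` matrix.
#' @export
extract_fc_feature <- function(encoder, x) {
  x <- check_image_batch(x)
  h <- encoder$backbone$fwd(x, training = FALSE)
  v <- encoder$pool$fwd(h, training = FALSE)
  for (i in 1:8) v <- encoder$head$submodules[[i]]$fwd(v, training = FALSE)
  v
}

#' Malignancy probability per image from a single encoder
#'
#' @inheritParams encoder_logits
#' @return numeric vector of `P(malignant)` per image.
#' @export
predict_encoder <- function(encoder, x) {
  lg <- encoder_logits(encoder, x, training = FALSE)
  softmax_rows(lg)[, 2]
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
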