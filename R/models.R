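# Encoder architectures (variants A, B, C for each modality), pretext and
# downstream heads. All encoders map one trial matrix (as a 1 x H x W tensor)
# to a 64-dimensional embedding.
#
# Variant A is the spatial-then-temporal separable design: the first layer's
# kernels span the full spatial axis (all 17 AUs, or all 62 channels), later
# layers filter along time only, with depthwise/separable temporal
# convolutions compressing the feature maps. Variants B and C are plain
# 3 x 3 conv stacks with max pooling; C adds one extra 64-kernel conv per
# branch.

#' Encoder configuration
#'
#' @param variant architecture variant, "A", "B" or "C"
#' @param modality "AU" or "EEG"
#' @param embedding_dim embedding dimensionality (64 for all variants)
#' @return list of class `ssml_encoder_config`
#' @export
encoder_config <- function(variant = c("A", "B", "C"),
                           modality = c("AU", "EEG"),
                           embedding_dim = 64L) {
  variant <- match.arg(variant)
  modality <- match.arg(modality)
  stopifnot(embedding_dim == 64L)
  structure(list(variant = variant, modality = modality,
                 embedding_dim = as.integer(embedding_dim)),
            class = "ssml_encoder_config")
}

#' Build an encoder network
#'
#' Maps a single-modality trial matrix (17 x 87 AU or 62 x 192 EEG, fed as a
#' `1 x H x W x n` tensor) to a finite 64-vector per trial. Weight
#' initialisation uses the current RNG state; seed upstream for
#' reproducibility. Batch normalization follows each convolution and the
#' embedding layer (the latter pins the embedding scale, which keeps the
#' cross-modal alignment loss from collapsing the representation), and a 50%
#' dropout precedes the embedding layer.
#'
#' @param config an [encoder_config()]
#' @return an `ssml_network` with `config` attached
#' @export
build_encoder <- function(config) {
  stopifnot(inherits(config, "ssml_encoder_config"))
  in_shape <- if (config$modality == "AU") c(1L, N_AU_ROWS, N_AU_FRAMES)
              else c(1L, N_EEG_CHANNELS, N_EEG_SAMPLES)
  layers <- switch(paste0(config$variant, "_", config$modality),
    A_AU = list(
      nn_conv2d(16, N_AU_ROWS, 1),            # full-height spatial filters
      nn_batchnorm(), nn_relu(),
      nn_conv2d(32, 1, 17, pad = c(0, 8)),    # temporal convs along frames
      nn_batchnorm(), nn_relu(),
      nn_avgpool(1, 2),
      nn_conv2d(64, 1, 17, pad = c(0, 8)),
      nn_batchnorm(), nn_relu(),
      nn_conv2d(64, 1, 17, pad = c(0, 8)),
      nn_batchnorm(), nn_relu(),
      nn_avgpool(1, 2),
      nn_depthwise(2, 1, 9, pad = c(0, 4)),   # 64 -> 128 depthwise temporal
      nn_batchnorm(), nn_relu(),
      nn_depthwise(1, 1, 9, pad = c(0, 4)),   # separable: depthwise ...
      nn_conv2d(16, 1, 1),                    # ... + pointwise to 16 maps
      nn_batchnorm(), nn_relu(),
      nn_dropout(0.5), nn_flatten(), nn_dense(EMBED_DIM), nn_batchnorm()),
    A_EEG = list(
      nn_conv2d(16, N_EEG_CHANNELS, 1),       # full-height spatial filters
      nn_batchnorm(), nn_relu(),
      nn_depthwise(2, 1, 9, pad = c(0, 4)),   # 16 kernels, depth factor 2
      nn_batchnorm(), nn_relu(),
      nn_avgpool(1, 4),
      nn_depthwise(1, 1, 9, pad = c(0, 4)),   # separable: depthwise ...
      nn_conv2d(16, 1, 1),                    # ... + pointwise, 16 kernels
      nn_batchnorm(), nn_relu(),
      nn_avgpool(1, 4),
      nn_dropout(0.5), nn_flatten(), nn_dense(EMBED_DIM), nn_batchnorm()),
    B_AU = bc_layers(pools = list(c(2, 2), c(2, 2), c(2, 2)), extra = FALSE),
    B_EEG = bc_layers(pools = list(c(2, 4), c(2, 4), c(2, 2)), extra = FALSE),
    C_AU = bc_layers(pools = list(c(2, 2), c(2, 2), c(2, 2)), extra = TRUE),
    C_EEG = bc_layers(pools = list(c(2, 4), c(2, 4), c(2, 2)), extra = TRUE))
  net <- nn_network(in_shape, layers)
  net$config <- config
  net
}

bc_layers <- function(pools, extra) {
  kernels <- c(16, 32, 64)
  layers <- list()
  for (i in 1:3) {
    layers <- c(layers, list(nn_conv2d(kernels[i], 3, 3, pad = c(1, 1)),
                             nn_batchnorm(), nn_relu(),
                             nn_maxpool(pools[[i]][1], pools[[i]][2])))
  }
  if (extra)
    layers <- c(layers, list(nn_conv2d(64, 3, 3, pad = c(1, 1)),
                             nn_batchnorm(), nn_relu()))
  c(layers, list(nn_dropout(0.5), nn_flatten(), nn_dense(EMBED_DIM),
                 nn_batchnorm()))
}

#' Build a classification or regression head
#'
#' Pretext heads are a single dense layer from the 64-dim embedding to the
#' class count (4 paradigms for EEG; 11 transformation classes and 15 window
#' classes for AU). The downstream head is 3 dense layers ending in one
#' logit. The `fusion` head takes the concatenated 128-dim embedding.
#'
#' @param purpose one of "pretext_eeg", "pretext_au_st", "pretext_au_win",
#'   "downstream", "fusion"
#' @return an `ssml_network`
#' @export
build_heads <- function(purpose = c("pretext_eeg", "pretext_au_st",
                                    "pretext_au_win", "downstream", "fusion")) {
  purpose <- match.arg(purpose)
  switch(purpose,
    pretext_eeg = nn_network(EMBED_DIM, list(nn_dense(4))),
    pretext_au_st = nn_network(EMBED_DIM, list(nn_dense(N_ST_CLASSES))),
    pretext_au_win = nn_network(EMBED_DIM, list(nn_dense(N_WIN_CLASSES))),
    downstream = nn_network(EMBED_DIM, list(nn_dense(32), nn_relu(),
                                            nn_dropout(0.5),
                                            nn_dense(16), nn_relu(),
                                            nn_dense(1))),
    fusion = nn_network(2L * EMBED_DIM, list(nn_dense(32), nn_relu(),
                                             nn_dropout(0.5),
                                             nn_dense(16), nn_relu(),
                                             nn_dense(1))))
}

# count conv layers of a network (used in tests and `model describe`)
n_conv_layers <- function(net) {
  sum(vapply(net$layers, function(l) l$type %in% c("conv2d", "depthwise"),
             logical(1)))
}

#' Compute embeddings for a batch of trials
#'
#' @param encoder an encoder network
#' @param x input tensor `1 x H x W x n`
#' @return `embedding_dim x n` matrix (inference mode, deterministic)
#' @export
encode <- function(encoder, x) {
  nn_forward(encoder, x, training = FALSE)$out
}
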