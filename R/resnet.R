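# ResNet-50 encoder contract: a 2048-dimensional embedding from a
# single-channel image, with the final prediction layer removed. Built on
# the same layer kit as the small test encoder. Weights are He-initialized
# (untrained); the object serves frozen-encoder paths (linear probing,
# confusion estimation) and the embedding-dimension contract — gradient
# training at full scale is outside this package's test envelope, and
# externally pretrained weights can be loaded into `params` by name.

res_bottleneck <- function(c_in, c_mid, c_out, stride) {
  list(conv1 = nn_conv(c_in, c_mid, 1L),
       bn1 = nn_bn(c_mid, "2d"),
       conv2 = nn_conv(c_mid, c_mid, 3L, stride = stride, pad = 1L),
       bn2 = nn_bn(c_mid, "2d"),
       conv3 = nn_conv(c_mid, c_out, 1L),
       bn3 = nn_bn(c_out, "2d"),
       down = if (c_in != c_out || stride != 1L)
         list(conv = nn_conv(c_in, c_out, 1L, stride = stride),
              bn = nn_bn(c_out, "2d")))
}

#' Untrained ResNet-50 single-channel encoder
#'
#' Standard ResNet-50 topology (7x7/2 stem, 3x3/2 max pool, bottleneck
#' stages of 3/4/6/3 blocks with 256/512/1024/2048 output channels,
#' global average pooling) taking one grayscale channel and emitting a
#' 2048-dimensional embedding; the classification layer is removed.
#'
#' @param seed seed for the He weight initialization.
#' @return a `resnet50_encoder` object.
#' @export
resnet50_encoder <- function(seed = 1L) {
  set.seed(seed)
  stage <- function(n, c_in, c_mid, c_out, stride) {
    blocks <- vector("list", n)
    blocks[[1L]] <- res_bottleneck(c_in, c_mid, c_out, stride)
    for (i in seq_len(n - 1L))
      blocks[[i + 1L]] <- res_bottleneck(c_out, c_mid, c_out, 1L)
    blocks
  }
  structure(list(
    stem_conv = nn_conv(1L, 64L, 7L, stride = 2L, pad = 3L),
    stem_bn = nn_bn(64L, "2d"),
    stem_pool = nn_maxpool(3L, 2L, pad = 1L),
    stages = list(stage(3L, 64L, 64L, 256L, 1L),
                  stage(4L, 256L, 128L, 512L, 2L),
                  stage(6L, 512L, 256L, 1024L, 2L),
                  stage(3L, 1024L, 512L, 2048L, 2L)),
    embedding_dim = 2048L), class = "resnet50_encoder")
}

#' @export
print.resnet50_encoder <- function(x, ...) {
  cat("<resnet50_encoder> untrained, single-channel input,",
      x$embedding_dim, "dim embedding\n")
  invisible(x)
}

fwd <- function(layer, x) layer_forward(layer, x, train = FALSE)$out

bottleneck_forward <- function(blk, x) {
  h <- fwd(blk$bn1, fwd(blk$conv1, x))
  h <- h * (h > 0)
  h <- fwd(blk$bn2, fwd(blk$conv2, h))
  h <- h * (h > 0)
  h <- fwd(blk$bn3, fwd(blk$conv3, h))
  skip <- if (is.null(blk$down)) x
          else fwd(blk$down$bn, fwd(blk$down$conv, x))
  h <- h + skip
  h * (h > 0)
}

#' Embed images with the ResNet-50 encoder
#'
#' @param encoder a [resnet50_encoder].
#' @param x an `(H, W)` matrix (one image, e.g. 512 x 512 from
#'   [preprocess_cxr]) or an `(H, W, 1, B)` array.
#' @return embedding matrix `2048 x B`.
#' @export
resnet50_embed <- function(encoder, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  h <- fwd(encoder$stem_bn, fwd(encoder$stem_conv, x))
  h <- h * (h > 0)
  h <- fwd(encoder$stem_pool, h)
  for (stg in encoder$stages)
    for (blk in stg) h <- bottleneck_forward(blk, h)
  fwd(nn_gap(), h)
}
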