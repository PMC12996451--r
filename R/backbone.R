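# Convolutional feature backbone.
#
# The packaged "toy" backbone is a small frozen conv stack (3 blocks,
# seeded He-normal init, 64 output channels) standing where a pretrained
# ImageNet backbone would in production: it is never trained, it only
# provides fixed visual features, exactly like a frozen transfer-learning
# backbone. The registry keeps the spec open for heavier backbones.

#' Model specification
#'
#' The classification head is fixed by design: global average pooling,
#' dense(F -> 1024, ReLU), dropout 0.5, dense(1024 -> 512, ReLU),
#' dense(512 -> 3, softmax). Only the head is trainable; the backbone is
#' frozen.
#'
#' @param backbone_id registry key; "toy" is the packaged conv stack.
#' @param input_px model input side in pixels.
#' @param seed seed for backbone and head initialisation.
#' @param channels conv channels per block for the toy backbone.
#' @export
model_spec <- function(backbone_id = "toy", input_px = 64, seed = 1234,
                       channels = c(16, 32, 64)) {
  if (!backbone_id %in% c("toy"))
    stop("registry error: unknown backbone '", backbone_id, "'", call. = FALSE)
  if (input_px %% 4 != 0) stop("input_px must be a multiple of 4", call. = FALSE)
  structure(list(backbone_id = backbone_id, input_px = as.integer(input_px),
                 feature_dim = as.integer(channels[length(channels)]),
                 channels = as.integer(channels),
                 head_dims = c(1024L, 512L, 3L), dropout = 0.5,
                 backbone_frozen = TRUE, seed = as.integer(seed)),
            class = "model_spec")
}

#' Trainable head parameter count
#' @param feature_dim backbone output channels F.
#' @return total parameters of the dense head (weights + biases).
#' @export
head_param_count <- function(feature_dim) {
  feature_dim * 1024 + 1024 + 1024 * 512 + 512 + 512 * 3 + 3
}

# 3x3 same-padding convolution via patch-matrix multiplication
conv2d_same <- function(x, Wmat, b) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  xp <- array(0, c(h + 2, w + 2, cin))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  cols <- vector("list", 9)
  idx <- 1L
  for (dx in 0:2) for (dy in 0:2) {
    cols[[idx]] <- matrix(xp[dy + seq_len(h), dx + seq_len(w), ], h * w, cin)
    idx <- idx + 1L
  }
  out <- do.call(cbind, cols) %*% Wmat
  out <- sweep(out, 2, b, "+")
  array(out, c(h, w, ncol(Wmat)))
}

maxpool2 <- function(x) {
  h2 <- dim(x)[1] %/% 2L; w2 <- dim(x)[2] %/% 2L
  i1 <- seq(1, 2 * h2, 2); i2 <- seq(2, 2 * h2, 2)
  j1 <- seq(1, 2 * w2, 2); j2 <- seq(2, 2 * w2, 2)
  pmax(x[i1, j1, , drop = FALSE], x[i2, j1, , drop = FALSE],
       x[i1, j2, , drop = FALSE], x[i2, j2, , drop = FALSE])
}

relu <- function(x) { x[x < 0] <- 0; x }

init_backbone <- function(spec) {
  with_seed(sub_seed(spec$seed, 1), {
    cin <- 3L
    layers <- list()
    for (cout in spec$channels) {
      fan_in <- 9 * cin
      layers[[length(layers) + 1]] <- list(
        W = matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
        b = rep(0, cout))
      cin <- cout
    }
    layers
  })
}

# forward pass through the frozen backbone: blocks 1..(n-1) are
# conv/ReLU/pool, the final block is conv/ReLU (its activation map is the
# "final convolutional layer" used by CAM and Grad-CAM); GAP follows.
backbone_forward <- function(model, img) {
  x <- img / 255 - 0.5
  nl <- length(model$backbone)
  for (li in seq_len(nl)) {
    x <- relu(conv2d_same(x, model$backbone[[li]]$W, model$backbone[[li]]$b))
    if (li < nl) x <- maxpool2(x)
  }
  f <- apply(x, 3, mean)
  list(conv = x, gap = f)
}

# exact scalar fingerprint of the frozen weights
backbone_checksum <- function(model) {
  sum(vapply(model$backbone, function(l) sum(l$W) + sum(l$b), numeric(1)))
}
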