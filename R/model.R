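# Classifier assembly, head training, inference and explainability.
#
# Architecture: frozen backbone -> global average pooling -> dense(F->1024,
# ReLU) -> dropout(0.5) -> dense(1024->512, ReLU) -> dense(512->3, softmax).
# Only the head trains (Xavier-normal init, Adam, categorical cross-entropy);
# the best epoch is selected by validation accuracy.

#' Training configuration
#'
#' Defaults are the reference protocol: categorical cross-entropy, Adam at
#' learning rate 1e-5, batch size 16, 50 epochs, Xavier-normal head init.
#' Small-scale runs on synthetic data typically override learning_rate and
#' epochs.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed seed for shuffling and dropout.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 16, epochs = 50, seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(loss = "categorical_crossentropy", optimizer = "adam",
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), init = "xavier_normal",
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Augmentation configuration
#'
#' Exactly six techniques: horizontal flip, rotation in (-40, 40) degrees,
#' shifts, shear, zoom, and additive channel shifts in \[0, 10\] intensity
#' levels. Ranges not fixed by the protocol default to flip p = 0.5,
#' shift +/-10 percent of the side, shear +/-10 degrees, zoom \[0.9, 1.1\],
#' reflect fill.
#' @export
augment_config <- function(horizontal_flip = 0.5, rotation_range = c(-40, 40),
                           shift_fraction = 0.1, shear_range = c(-10, 10),
                           zoom_range = c(0.9, 1.1), channel_shift_range = c(0, 10),
                           fill = "reflect") {
  stopifnot(rotation_range[1] <= rotation_range[2],
            shear_range[1] <= shear_range[2],
            zoom_range[1] <= zoom_range[2], zoom_range[1] > 0,
            channel_shift_range[1] <= channel_shift_range[2])
  structure(list(horizontal_flip = horizontal_flip, rotation_range = rotation_range,
                 shift_fraction = shift_fraction, shear_range = shear_range,
                 zoom_range = zoom_range, channel_shift_range = channel_shift_range,
                 fill = fill),
            class = "augment_config")
}

xavier_normal <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / (fan_in + fan_out))), fan_in, fan_out)
}

#' Build an (untrained) classifier
#'
#' @param spec a model_spec.
#' @return object of class "nbt_model": frozen backbone weights, head
#'   weights, training history slot.
#' @export
build_model <- function(spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  F <- spec$feature_dim
  head <- with_seed(sub_seed(spec$seed, 2), list(
    W1 = xavier_normal(F, 1024), b1 = rep(0, 1024),
    W2 = xavier_normal(1024, 512), b2 = rep(0, 512),
    W3 = xavier_normal(512, 3), b3 = rep(0, 3)))
  F_dim <- spec$feature_dim
  structure(list(spec = spec, backbone = init_backbone(spec), head = head,
                 # frozen per-channel feature standardisation; constants are
                 # fixed from the training set when training starts and are
                 # part of the frozen feature extractor thereafter
                 feat_norm = list(mean = rep(0, F_dim), sd = rep(1, F_dim)),
                 history = NULL, best_epoch = NULL, trained = FALSE),
            class = "nbt_model")
}

#' @export
print.nbt_model <- function(x, ...) {
  cat(sprintf("nbt_model: %s backbone (frozen, F=%d), head %d->1024->512->3%s\n",
              x$spec$backbone_id, x$spec$feature_dim, x$spec$feature_dim,
              if (x$trained) sprintf(", trained (best epoch %d)", x$best_epoch)
              else ", untrained"))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# head forward; dropout (inverted, between the two dense layers) only when
# a mask is supplied
head_forward <- function(head, X, drop_mask = NULL) {
  z1 <- sweep(X %*% head$W1, 2, head$b1, "+")
  h1 <- relu(z1)
  h1d <- if (is.null(drop_mask)) h1 else h1 * drop_mask
  z2 <- sweep(h1d %*% head$W2, 2, head$b2, "+")
  h2 <- relu(z2)
  logits <- sweep(h2 %*% head$W3, 2, head$b3, "+")
  list(z1 = z1, h1 = h1, h1d = h1d, z2 = z2, h2 = h2,
       logits = logits, probs = softmax_rows(logits))
}

head_backward <- function(head, X, fw, Y, drop_mask) {
  n <- nrow(X)
  dlog <- (fw$probs - Y) / n
  gW3 <- crossprod(fw$h2, dlog); gb3 <- colSums(dlog)
  dh2 <- dlog %*% t(head$W3)
  dz2 <- dh2 * (fw$z2 > 0)
  gW2 <- crossprod(fw$h1d, dz2); gb2 <- colSums(dz2)
  dh1d <- dz2 %*% t(head$W2)
  dh1 <- if (is.null(drop_mask)) dh1d else dh1d * drop_mask
  dz1 <- dh1 * (fw$z1 > 0)
  gW1 <- crossprod(X, dz1); gb1 <- colSums(dz1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

adam_init <- function(head) {
  lapply(head, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(head, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(head)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    head[[nm]] <- head[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(head = head, state = state)
}

patch_image <- function(p) if (is.list(p) && !is.null(p$pixels)) p$pixels else p

as_image_list <- function(x) {
  if (inherits(x, "patch_set")) lapply(x$patches, patch_image)
  else if (is.list(x) && !is.array(x)) lapply(x, patch_image)
  else list(patch_image(x))
}

prep_image <- function(img, input_px) {
  assert_rgb(img)
  if (nrow(img) != input_px || ncol(img) != input_px)
    img <- resize_image(img, input_px, input_px, "bilinear")
  img
}

# backbone GAP features for a list of images (rows = images)
backbone_features <- function(model, images) {
  t(vapply(images, function(im)
    backbone_forward(model, prep_image(im, model$spec$input_px))$gap,
    numeric(model$spec$feature_dim)))
}

# standardised features as seen by the head
model_features <- function(model, images) {
  X <- backbone_features(model, images)
  sweep(sweep(X, 2, model$feat_norm$mean), 2, model$feat_norm$sd, "/")
}

#' Best-epoch selection rule
#' @param val_accuracy per-epoch validation accuracies.
#' @return 1-based index of the first maximum.
#' @export
select_best_epoch <- function(val_accuracy) which.max(val_accuracy)

#' Train the classification head
#'
#' The backbone stays frozen (weights bit-identical before and after);
#' only the dense head is updated, by Adam on categorical cross-entropy.
#' When an augment_config is supplied, training features are recomputed
#' each epoch from freshly augmented patches; validation features are
#' never augmented. The returned model carries the weights of the epoch
#' with the highest validation accuracy.
#'
#' @param model an nbt_model from \code{build_model}.
#' @param train_set,val_set labelled patch_sets; all three classes must be
#'   present in train_set.
#' @param cfg a train_config.
#' @param aug optional augment_config for online training augmentation.
#' @return the trained nbt_model with `history` and `best_epoch`.
#' @export
train <- function(model, train_set, val_set, cfg = train_config(), aug = NULL) {
  stopifnot(inherits(model, "nbt_model"), inherits(cfg, "train_config"))
  if (!inherits(train_set, "patch_set") || length(train_set) == 0)
    stop("data error: empty training set", call. = FALSE)
  if (!inherits(val_set, "patch_set") || length(val_set) == 0)
    stop("config error: empty validation set", call. = FALSE)
  y_tr <- patch_labels(train_set)
  y_va <- patch_labels(val_set)
  if (!all(0:2 %in% y_tr))
    stop("data error: all three classes must be present in the training set", call. = FALSE)
  checksum_before <- backbone_checksum(model)
  imgs_tr <- as_image_list(train_set)
  imgs_va <- as_image_list(val_set)
  # fix the frozen feature standardisation from the (un-augmented)
  # training features before any head update
  X_tr_raw <- backbone_features(model, imgs_tr)
  if (!model$trained) {
    sds <- apply(X_tr_raw, 2, stats::sd)
    model$feat_norm <- list(mean = colMeans(X_tr_raw), sd = pmax(sds, 1e-8))
  }
  std <- function(X) sweep(sweep(X, 2, model$feat_norm$mean), 2, model$feat_norm$sd, "/")
  X_va <- std(backbone_features(model, imgs_va))
  X_tr_static <- if (is.null(aug)) std(X_tr_raw) else NULL
  n <- length(imgs_tr)
  Y <- matrix(0, n, 3); Y[cbind(seq_len(n), y_tr + 1L)] <- 1
  head <- model$head
  state <- adam_init(head)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_accuracy = numeric(0), val_loss = numeric(0),
                     val_accuracy = numeric(0))
  best <- list(acc = -Inf, head = head, epoch = 1L)
  t_step <- 0L
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      X <- if (is.null(aug)) X_tr_static else {
        aug_imgs <- lapply(seq_len(n), function(i)
          augment(imgs_tr[[i]], aug, seed = sub_seed(cfg$seed, ep * 100000L + i)))
        std(backbone_features(model, aug_imgs))
      }
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        mask <- matrix(rbinom(length(idx) * 1024, 1, 1 - model$spec$dropout),
                       length(idx), 1024) / (1 - model$spec$dropout)
        fw <- head_forward(head, Xb, drop_mask = mask)
        gr <- head_backward(head, Xb, fw, Yb, mask)
        t_step <- t_step + 1L
        upd <- adam_step(head, gr, state, cfg$learning_rate, t_step)
        head <- upd$head; state <- upd$state
        p <- pmax(fw$probs[cbind(seq_len(nrow(Yb)), max.col(Yb))], 1e-12)
        ep_loss <- ep_loss - sum(log(p))
        ep_correct <- ep_correct + sum(max.col(fw$probs, ties.method = "first") == max.col(Yb))
      }
      fw_va <- head_forward(head, X_va)
      pv <- pmax(fw_va$probs[cbind(seq_along(y_va), y_va + 1L)], 1e-12)
      val_loss <- -mean(log(pv))
      val_acc <- mean(max.col(fw_va$probs, ties.method = "first") - 1L == y_va)
      hist[ep, ] <- list(ep, ep_loss / n, ep_correct / n, val_loss, val_acc)
      if (val_acc > best$acc) best <- list(acc = val_acc, head = head, epoch = ep)
    }
  })
  model$head <- best$head
  model$history <- hist
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  stopifnot(identical(checksum_before, backbone_checksum(model)))
  model
}

#' Predict class probabilities
#'
#' @param model an nbt_model.
#' @param patches a patch_set, list of images, or single H x W x 3 array;
#'   images are resized to the model input size if needed.
#' @return data.frame with p_epithelium, p_stroma, p_adipocyte, pred
#'   (argmax, lowest index on ties) and confidence (probability of the
#'   predicted class). Dropout is inactive.
#' @export
predict_probs <- function(model, patches) {
  imgs <- as_image_list(patches)
  X <- model_features(model, imgs)
  fw <- head_forward(model$head, X)
  pred <- max.col(fw$probs, ties.method = "first") - 1L
  data.frame(p_epithelium = fw$probs[, 1], p_stroma = fw$probs[, 2],
             p_adipocyte = fw$probs[, 3], pred = pred,
             confidence = fw$probs[cbind(seq_len(nrow(fw$probs)), pred + 1L)])
}

#' Penultimate-layer features
#'
#' @inheritParams predict_probs
#' @return n x 512 matrix: the post-ReLU output of the second dense layer
#'   (dropout inactive). Applying the stored final dense layer + softmax
#'   to these rows reproduces \code{predict_probs}.
#' @export
extract_features <- function(model, patches) {
  imgs <- as_image_list(patches)
  X <- model_features(model, imgs)
  head_forward(model$head, X)$h2
}

# min-max normalisation to [0, 1]; constant maps become all zeros
minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] < 1e-300) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Class activation map via the linearised head
#'
#' The two-hidden-layer head has no single class weight vector, so the
#' channel importance w(class) is defined as the corresponding column of
#' the product W1 W2 W3 of the dense weight matrices (ReLU and dropout
#' dropped). The heatmap is sum_k w_k A_k over the final conv activations,
#' min-max normalised to \[0, 1\], and optionally bicubically resized.
#'
#' @param model an nbt_model.
#' @param patch image or patch record.
#' @param class_id target class 0/1/2.
#' @param resize_to optional output side in pixels (bicubic).
#' @return heatmap matrix in \[0, 1\].
#' @export
cam <- function(model, patch, class_id, resize_to = NULL) {
  if (!class_id %in% 0:2) stop("class_id must be 0, 1 or 2", call. = FALSE)
  img <- prep_image(patch_image(patch), model$spec$input_px)
  A <- backbone_forward(model, img)$conv
  # the frozen feature standardisation folds into the channel weights
  W1s <- model$head$W1 / model$feat_norm$sd
  Wlin <- W1s %*% model$head$W2 %*% model$head$W3
  h <- dim(A)[1]; w <- dim(A)[2]
  heat <- matrix(matrix(A, h * w, dim(A)[3]) %*% Wlin[, class_id + 1L], h, w)
  heat <- minmax01(heat)
  if (!is.null(resize_to)) heat <- resize_image(heat, resize_to, resize_to, "bicubic")
  heat
}

#' Grad-CAM
#'
#' Channel weights are the spatial mean of the gradient of the
#' pre-softmax class logit with respect to the final conv activations
#' (computed analytically through the frozen GAP + head); the heatmap is
#' ReLU of the weighted activation sum, min-max normalised, optionally
#' bicubically resized.
#'
#' @inheritParams cam
#' @export
grad_cam <- function(model, patch, class_id, resize_to = NULL) {
  if (!class_id %in% 0:2) stop("class_id must be 0, 1 or 2", call. = FALSE)
  img <- prep_image(patch_image(patch), model$spec$input_px)
  bf <- backbone_forward(model, img)
  A <- bf$conv
  h <- dim(A)[1]; w <- dim(A)[2]
  f_std <- (bf$gap - model$feat_norm$mean) / model$feat_norm$sd
  fw <- head_forward(model$head, matrix(f_std, 1))
  # d logit / d f through the ReLU masks active at this input
  dh2 <- model$head$W3[, class_id + 1L]
  dz2 <- dh2 * as.numeric(fw$z2 > 0)
  dh1 <- as.vector(model$head$W2 %*% dz2)
  dz1 <- dh1 * as.numeric(fw$z1 > 0)
  df <- as.vector(model$head$W1 %*% dz1) / model$feat_norm$sd
  wk <- df / (h * w)   # spatial mean of d logit / d A_k
  heat <- matrix(matrix(A, h * w, dim(A)[3]) %*% wk, h, w)
  heat <- relu(heat)
  heat <- minmax01(heat)
  if (!is.null(resize_to)) heat <- resize_image(heat, resize_to, resize_to, "bicubic")
  heat
}

#' Apply the six-technique augmentation to one patch
#'
#' Draws flip / rotation / shift / shear / zoom parameters from the
#' configured ranges under the given seed, applies them as a single
#' bilinear affine warp with reflect fill, then adds per-channel offsets
#' drawn from the channel-shift range, clipping to \[0, 255\].
#'
#' @param patch H x W x 3 array or patch record.
#' @param cfg an augment_config.
#' @param seed integer seed.
#' @return augmented image array (same dimensions, integer-valued).
#' @export
augment <- function(patch, cfg = augment_config(), seed = 1) {
  img <- patch_image(patch)
  assert_rgb(img)
  S <- nrow(img)
  stopifnot(ncol(img) == S)
  with_seed(seed, {
    do_flip <- runif(1) < cfg$horizontal_flip
    angle <- runif(1, cfg$rotation_range[1], cfg$rotation_range[2]) * pi / 180
    shift <- runif(2, -cfg$shift_fraction, cfg$shift_fraction) * S
    shear <- tan(runif(1, cfg$shear_range[1], cfg$shear_range[2]) * pi / 180)
    zoom <- runif(1, cfg$zoom_range[1], cfg$zoom_range[2])
    chshift <- runif(3, cfg$channel_shift_range[1], cfg$channel_shift_range[2])
    out <- warp_affine(img, do_flip, angle, shift, shear, zoom)
    for (k in 1:3) out[, , k] <- clip255(out[, , k] + chshift[k])
    round(out)
  })
}

# single combined affine warp about the image centre, reflect fill
warp_affine <- function(img, do_flip, angle, shift, shear, zoom) {
  S <- nrow(img)
  identity_tf <- !do_flip && angle == 0 && all(shift == 0) && shear == 0 && zoom == 1
  if (identity_tf) return(img)
  ctr <- (S + 1) / 2
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2, byrow = TRUE)
  Sh <- matrix(c(1, shear, 0, 1), 2, 2, byrow = TRUE)
  M <- R %*% Sh * zoom
  if (do_flip) M <- M %*% diag(c(-1, 1))
  Minv <- solve(M)
  xs <- rep(seq_len(S), each = S) - ctr - shift[1]   # output x (col)
  ys <- rep(seq_len(S), times = S) - ctr - shift[2]  # output y (row)
  in_x <- Minv[1, 1] * xs + Minv[1, 2] * ys + ctr
  in_y <- Minv[2, 1] * xs + Minv[2, 2] * ys + ctr
  # reflect coordinates into [1, S]
  reflect <- function(v) {
    if (S == 1) return(rep(1, length(v)))
    period <- 2 * (S - 1)
    t <- abs((v - 1) %% period)
    pmin(t, period - t) + 1
  }
  in_x <- reflect(in_x); in_y <- reflect(in_y)
  out <- array(0, dim(img))
  for (k in 1:3) out[, , k] <- matrix(sample_bilinear(img[, , k], in_y, in_x), S, S)
  out
}

#' Save a trained model
#'
#' Writes the model as a single RDS file plus a JSON sidecar describing
#' the spec, training configuration echo, and class names.
#' @param model an nbt_model.
#' @param path output .rds path; the sidecar gets ".json" appended.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(spec = unclass(model$spec), classes = CLASS_NAMES,
                  trained = model$trained, best_epoch = model$best_epoch)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by \code{save_model}
#' @param path .rds path.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "nbt_model"))
  model
}
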