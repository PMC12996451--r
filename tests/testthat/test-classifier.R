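# Classifier assembly, training mechanics, inference contracts,
# augmentation semantics, CAM/Grad-CAM.

test_that("head layout and parameter counts follow the architecture", {
  expect_identical(head_param_count(1280), 1280 * 1024 + 1024 + 1024 * 512 + 512 + 512 * 3 + 3)
  expect_identical(head_param_count(1280), 1838083)

  m <- build_model(model_spec(input_px = 64, seed = 5))
  expect_identical(dim(m$head$W1), c(m$spec$feature_dim, 1024L))
  expect_identical(dim(m$head$W2), c(1024L, 512L))
  expect_identical(dim(m$head$W3), c(512L, 3L))
  expect_identical(m$spec$dropout, 0.5)
  expect_true(m$spec$backbone_frozen)

  m2 <- build_model(model_spec(input_px = 64, seed = 5))
  expect_identical(m$head, m2$head)
  expect_identical(m$backbone, m2$backbone)
  expect_error(model_spec("resnet50"), "registry error")
})

test_that("probability records sit on the simplex with first-index ties", {
  m <- quick_trained_model()
  ps <- tile_patchset(3, 31)
  pr <- predict_probs(m, ps)
  expect_true(all(abs(pr$p_epithelium + pr$p_stroma + pr$p_adipocyte - 1) < 1e-6))
  expect_true(all(pr$confidence == pmax(pr$p_epithelium, pr$p_stroma, pr$p_adipocyte)))

  # hand-pinned two-feature head: softmax against direct computation
  head <- list(W1 = matrix(c(1, -1, 0.5, 0.2), 2, 2), b1 = c(0.1, -0.2),
               W2 = matrix(c(0.3, 0.7, -0.4, 0.5), 2, 2), b2 = c(0, 0.1),
               W3 = matrix(c(0.2, -0.1, 0.4, 0.3, -0.2, 0.6), 2, 3), b3 = c(0.05, 0, -0.05))
  x <- matrix(c(0.4, 0.9), 1, 2)
  fw <- nbtclassify:::head_forward(head, x)
  z1 <- as.vector(x %*% head$W1) + head$b1
  h1 <- pmax(z1, 0)
  z2 <- as.vector(h1 %*% head$W2) + head$b2
  h2 <- pmax(z2, 0)
  lg <- as.vector(h2 %*% head$W3) + head$b3
  expect_equal(as.vector(fw$probs), exp(lg) / sum(exp(lg)), tolerance = 1e-12)

  # uniform probabilities resolve to the lowest class index
  expect_identical(max.col(matrix(1 / 3, 1, 3), ties.method = "first") - 1L, 0L)
})

test_that("penultimate features are 512-d, non-negative and consistent", {
  m <- quick_trained_model()
  ps <- tile_patchset(2, 57)
  ft <- extract_features(m, ps)
  expect_identical(dim(ft), c(6L, 512L))
  expect_true(all(ft >= 0))
  logits <- sweep(ft %*% m$head$W3, 2, m$head$b3, "+")
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)
  pr <- predict_probs(m, ps)
  expect_equal(unname(cbind(pr$p_epithelium, pr$p_stroma, pr$p_adipocyte)),
               unname(probs), tolerance = 1e-6)
  expect_identical(ft, extract_features(m, ps))
})

test_that("training selects the best epoch and never touches the backbone", {
  expect_identical(select_best_epoch(c(0.5, 0.9, 0.7)), 2L)

  m0 <- build_model(model_spec(input_px = 64, seed = 11))
  before <- nbtclassify:::backbone_checksum(m0)
  tr <- tile_patchset(20, 201)
  va <- tile_patchset(6, 301)
  cfg <- train_config(learning_rate = 1e-3, epochs = 4, seed = 1)
  tm <- train(m0, tr, va, cfg)
  expect_identical(nbtclassify:::backbone_checksum(tm), before)
  expect_identical(tm$backbone, m0$backbone)
  expect_identical(nrow(tm$history), 4L)
  expect_identical(tm$best_epoch, select_best_epoch(tm$history$val_accuracy))

  # missing class / empty validation are rejected
  two_cls <- patch_set(Filter(function(p) p$label != 2, tr$patches))
  expect_error(train(m0, two_cls, va, cfg), "data error")
  expect_error(train(m0, tr, patch_set(list()), cfg), "config error")
})

test_that("a toy model fits the synthetic task", {
  tm <- quick_trained_model()
  expect_gte(utils::tail(tm$history$train_accuracy, 1), 0.95)
})

test_that("training defaults encode the reference protocol", {
  cfg <- train_config()
  expect_identical(cfg$optimizer, "adam")
  expect_identical(cfg$loss, "categorical_crossentropy")
  expect_identical(cfg$learning_rate, 1e-5)
  expect_identical(cfg$batch_size, 16L)
  expect_identical(cfg$epochs, 50L)
  expect_identical(cfg$init, "xavier_normal")
})

test_that("augmentation honours neutral draws, channel shifts and symmetry", {
  img <- make_tile(1, 64, mpp = 2, seed = 4)$image
  neutral <- augment_config(horizontal_flip = 0, rotation_range = c(0, 0),
                            shift_fraction = 0, shear_range = c(0, 0),
                            zoom_range = c(1, 1), channel_shift_range = c(0, 0))
  expect_identical(augment(img, neutral, seed = 1), img)

  shift10 <- augment_config(horizontal_flip = 0, rotation_range = c(0, 0),
                            shift_fraction = 0, shear_range = c(0, 0),
                            zoom_range = c(1, 1), channel_shift_range = c(10, 10))
  const <- array(100, c(32, 32, 3))
  expect_identical(augment(const, shift10, seed = 1), array(110, c(32, 32, 3)))
  # clipping at the top of the 8-bit range
  bright <- array(250, c(32, 32, 3))
  expect_identical(augment(bright, shift10, seed = 1), array(255, c(32, 32, 3)))

  # rotation by 180 degrees of a symmetric fixture is the identity
  sym <- array(0, c(33, 33, 3))
  d2 <- outer((1:33 - 17)^2, (1:33 - 17)^2, "+")
  for (k in 1:3) sym[, , k] <- 100 + 80 * (d2 <= 100)
  rot180 <- augment_config(horizontal_flip = 0, rotation_range = c(180, 180),
                           shift_fraction = 0, shear_range = c(0, 0),
                           zoom_range = c(1, 1), channel_shift_range = c(0, 0))
  expect_identical(augment(sym, rot180, seed = 1), sym)

  # draws stay in [0, 255] and the shape is preserved
  out <- augment(img, augment_config(), seed = 9)
  expect_identical(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 255))

  # online augmentation pathway runs end to end
  m0 <- build_model(model_spec(input_px = 64, seed = 2))
  tm <- train(m0, tile_patchset(8, 801), tile_patchset(4, 901),
              train_config(learning_rate = 1e-3, epochs = 2, seed = 1),
              aug = augment_config())
  expect_identical(nrow(tm$history), 2L)
})

test_that("CAM is proportional to a single positive activation channel", {
  m <- build_model(model_spec(input_px = 8, seed = 3, channels = c(4, 4, 1)))
  # force a positive linearised weight for class 0
  m$head$W1 <- abs(m$head$W1); m$head$W2 <- abs(m$head$W2); m$head$W3 <- abs(m$head$W3)
  img <- make_tile(0, 32, mpp = 2, seed = 1)$image
  img8 <- resize_image(img, 8, 8)
  A <- nbtclassify:::backbone_forward(m, img8)$conv[, , 1]
  hm <- cam(m, img8, 0)
  if (sd(A) > 0) expect_gt(cor(as.vector(hm), as.vector(A)), 0.9999)

  # two-channel hand arithmetic
  m2 <- build_model(model_spec(input_px = 8, seed = 4, channels = c(4, 4, 2)))
  A2 <- nbtclassify:::backbone_forward(m2, img8)$conv
  Wlin <- m2$head$W1 %*% m2$head$W2 %*% m2$head$W3
  raw <- A2[, , 1] * Wlin[1, 2] + A2[, , 2] * Wlin[2, 2]
  want <- (raw - min(raw)) / (max(raw) - min(raw))
  expect_equal(cam(m2, img8, 1), want, tolerance = 1e-12)

  expect_error(cam(m2, img8, 7), "class_id")
})

test_that("Grad-CAM reduces to CAM for an effectively linear head", {
  m <- build_model(model_spec(input_px = 64, seed = 6))
  # all-positive weights + non-negative activations keep every ReLU active
  # and the weighted sum non-negative: the head is linear on this input
  m$head$W1 <- abs(m$head$W1); m$head$W2 <- abs(m$head$W2); m$head$W3 <- abs(m$head$W3)
  img <- make_tile(1, 64, mpp = 2, seed = 2)$image
  expect_lt(max(abs(grad_cam(m, img, 0) - cam(m, img, 0))), 1e-5)

  hm <- grad_cam(m, img, 2)
  expect_gte(min(hm), 0)
  expect_equal(max(hm), 1)

  # resized heatmaps match the patch dimensions
  expect_identical(dim(grad_cam(m, img, 0, resize_to = 64)), c(64L, 64L))
  expect_identical(dim(cam(m, img, 0, resize_to = 64)), c(64L, 64L))
})

test_that("Grad-CAM localises an epithelium island inside stroma", {
  hits <- vapply(c(11, 22, 33), function(sd_) {
    m <- quick_trained_model(sd_, normalize = FALSE)
    comp <- make_tile(1, 256, mpp = 0.5, seed = sd_)$image
    comp[65:192, 65:192, ] <- make_tile(0, 128, mpp = 0.5, seed = sd_ + 1)$image
    comp <- round(resize_image(comp, 64, 64))
    hm <- grad_cam(m, comp, 0)
    mask <- matrix(FALSE, nrow(hm), ncol(hm))
    scale <- nrow(hm) / 64
    mask[(16 * scale + 1):(48 * scale), (16 * scale + 1):(48 * scale)] <- TRUE
    top <- hm >= stats::quantile(hm, 0.9)
    sum(hm[top & mask]) / sum(hm[top])
  }, numeric(1))
  expect_gte(sum(hits >= 0.7), 2)
})

test_that("models round-trip through disk with a JSON sidecar", {
  m <- quick_trained_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  ps <- tile_patchset(1, 71)
  expect_equal(predict_probs(back, ps), predict_probs(m, ps))
  side <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_identical(side$classes, c("Epithelium", "Stroma", "Adipocytes"))
  expect_identical(side$spec$head_dims, c(1024L, 512L, 3L))
})
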