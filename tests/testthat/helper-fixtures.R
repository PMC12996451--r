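# Shared fixtures and independent oracles. Everything is generated in
# code; heavyweight objects (trained models, pseudo-slides) are memoised
# so multiple test files can reuse them within one session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# balanced patch set of single-class synthetic tiles: 256 px at 0.5 mpp
# (the 128-micron field of view at slide resolution), resized to the toy
# model input and Reinhard-normalised — the same path tessellated slide
# patches take before inference
tile_patchset <- function(n_per_class, seed0, size = 256, mpp = 0.5,
                          out_px = 64, normalize = TRUE, source = "synth") {
  ref <- if (normalize) cached("stain_ref", default_stain_reference)
  patches <- vector("list", 3 * n_per_class)
  k <- 0
  for (cl in 0:2) for (i in seq_len(n_per_class)) {
    img <- make_tile(cl, size, mpp = mpp, seed = seed0 + cl * 10000 + i)$image
    if (!is.null(out_px) && out_px != size)
      img <- round(resize_image(img, out_px, out_px))
    if (normalize) img <- reinhard_normalize(img, ref)
    k <- k + 1
    patches[[k]] <- list(pixels = img, origin = c(i * size, cl * size),
                         patch_px = nrow(img), mpp = mpp * size / nrow(img),
                         label = cl, source_id = source)
  }
  patch_set(patches)
}

# small toy training run shared across test files; normalize = FALSE
# trains on raw generator tiles (no stain transfer in the patch path)
quick_trained_model <- function(seed = 11, normalize = TRUE) {
  cached(paste0("model_", seed, "_", normalize), function() {
    tr <- tile_patchset(50, seed, normalize = normalize)
    va <- tile_patchset(15, seed + 400, normalize = normalize)
    train(build_model(model_spec(input_px = 64, seed = seed)), tr, va,
          train_config(learning_rate = 1e-3, epochs = 10, seed = seed))
  })
}

small_slide <- function() cached("slide_2560", function() make_slide(1, 2560, mpp = 0.5, seed = 3))

# ---- independent oracles ----------------------------------------------

# scalar ray-casting point-in-polygon with inclusive boundary (independent
# of the vectorised implementation under test)
oracle_point_in_rings <- function(x, y, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  crossings <- 0L
  for (ring in rings) {
    xs <- ring[, 1]; ys <- ring[, 2]
    n <- length(xs)
    if (xs[1] == xs[n] && ys[1] == ys[n]) { xs <- xs[-n]; ys <- ys[-n]; n <- n - 1 }
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      x1 <- xs[k]; y1 <- ys[k]; x2 <- xs[k2]; y2 <- ys[k2]
      # boundary?
      d <- abs((x - x1) * (y2 - y1) - (y - y1) * (x2 - x1))
      len2 <- (x2 - x1)^2 + (y2 - y1)^2
      if (len2 > 0) {
        tp <- ((x - x1) * (x2 - x1) + (y - y1) * (y2 - y1)) / len2
        if (tp >= 0 && tp <= 1 && d / sqrt(len2) < 1e-9) return(TRUE)
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
        if (x < xint) crossings <- crossings + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

# random simple (star-convex) polygon
random_polygon <- function(cx, cy, rmin, rmax, n_vert = 5) {
  ang <- sort(runif(n_vert, 0, 2 * pi))
  r <- runif(n_vert, rmin, rmax)
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# stack-based flood fill labelling, deliberately different from the
# frontier-expansion implementation in the package
oracle_flood_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- if (connectivity == 8)
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (o in offs) {
        q <- p + o
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  lab
}

# full lobule-detection oracle: label, size-filter, fill enclosed small
# holes, return canonical cell-index sets and areas
oracle_detect <- function(epi, native_px, min_object_px, max_hole_px, connectivity = 8) {
  s2 <- native_px^2
  lab <- oracle_flood_label(epi, connectivity)
  comps <- list()
  for (ci in seq_len(max(lab, 0))) {
    cells <- lab == ci
    if (sum(cells) * s2 < min_object_px) next
    inv <- oracle_flood_label(!cells, if (connectivity == 8) 4 else 8)
    nr <- nrow(cells); nc <- ncol(cells)
    border <- unique(c(inv[1, ], inv[nr, ], inv[, 1], inv[, nc]))
    for (hi in setdiff(seq_len(max(inv, 0)), border)) {
      hole <- inv == hi
      # enclosed by this component?
      ok <- TRUE
      hidx <- which(hole, arr.ind = TRUE)
      for (r in seq_len(nrow(hidx))) {
        for (o in list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))) {
          q <- hidx[r, ] + o
          if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
          if (!hole[q[1], q[2]] && !cells[q[1], q[2]]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok && sum(hole) * s2 < max_hole_px) cells <- cells | hole
    }
    idx <- which(cells, arr.ind = TRUE)
    comps[[length(comps) + 1]] <- list(
      cells = idx[order(idx[, 1], idx[, 2]), , drop = FALSE],
      n_cells = nrow(idx), area = nrow(idx) * s2)
  }
  comps
}

canonical_cells <- function(idx) paste(idx[order(idx[, 1], idx[, 2]), 1],
                                       idx[order(idx[, 1], idx[, 2]), 2],
                                       sep = ",", collapse = ";")

# brute-force tie-corrected AUC by pair counting
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force DeLong structural components and covariance
oracle_delong <- function(labels, sa, sb) {
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  comp <- function(s) {
    pos <- s[labels == 1]; neg <- s[labels == 0]
    m <- length(pos); n <- length(neg)
    v10 <- vapply(pos, function(x) mean(vapply(neg, function(y) psi(x, y), numeric(1))), numeric(1))
    v01 <- vapply(neg, function(y) mean(vapply(pos, function(x) psi(x, y), numeric(1))), numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  ca <- comp(sa); cb <- comp(sb)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  list(auc_a = ca$auc, auc_b = cb$auc, S = S,
       var_diff = S[1, 1] + S[2, 2] - 2 * S[1, 2])
}
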