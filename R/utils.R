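#' @keywords internal
#' @import stats
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators never perturb user randomness.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-object sub-seed so each drawn object owns its stream and
# layout edits do not cascade into unrelated objects. Kept < 2^31.
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

is_rgb_image <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L && all(is.finite(img))
}

assert_rgb <- function(img, what = "image") {
  if (!is_rgb_image(img)) stop(what, " must be an H x W x 3 numeric array", call. = FALSE)
  invisible(img)
}

# ---- resampling --------------------------------------------------------

# Bilinear sampling of a single channel at fractional (row, col) positions.
# Coordinates are 1-based pixel centres; out-of-range samples are clamped.
sample_bilinear <- function(ch, rr, cc) {
  h <- nrow(ch); w <- ncol(ch)
  rr <- pmin(pmax(rr, 1), h); cc <- pmin(pmax(cc, 1), w)
  r0 <- floor(rr); c0 <- floor(cc)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- rr - r0; fc <- cc - c0
  ch[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    ch[cbind(r1, c0)] * fr * (1 - fc) +
    ch[cbind(r0, c1)] * (1 - fr) * fc +
    ch[cbind(r1, c1)] * fr * fc
}

#' Resize an RGB image or matrix
#'
#' Bilinear (default) or bicubic resampling with pixel-centre alignment.
#' Bilinear is used for tessellated patches; bicubic (Catmull-Rom kernel)
#' is reserved for upscaling explainability heatmaps to patch size.
#'
#' @param img numeric matrix or H x W x 3 array.
#' @param out_h,out_w output dimensions in pixels.
#' @param method "bilinear" or "bicubic".
#' @return resized matrix or array of the same arity as the input.
#' @export
resize_image <- function(img, out_h, out_w, method = c("bilinear", "bicubic")) {
  method <- match.arg(method)
  dims <- dim(img)
  in_h <- dims[1]; in_w <- dims[2]
  if (in_h == out_h && in_w == out_w) return(img)
  # pixel-centre mapping: output centre u maps to input (u - 0.5) * scale + 0.5
  rr <- (seq_len(out_h) - 0.5) * (in_h / out_h) + 0.5
  cc <- (seq_len(out_w) - 0.5) * (in_w / out_w) + 0.5
  grid_r <- rep(rr, times = out_w)
  grid_c <- rep(cc, each = out_h)
  sample_one <- function(ch) {
    v <- if (method == "bilinear") sample_bilinear(ch, grid_r, grid_c)
         else sample_bicubic(ch, grid_r, grid_c)
    matrix(v, out_h, out_w)
  }
  if (length(dims) == 2L) return(sample_one(img))
  out <- array(0, c(out_h, out_w, dims[3]))
  for (k in seq_len(dims[3])) out[, , k] <- sample_one(img[, , k])
  out
}

# Catmull-Rom (Keys, a = -0.5) cubic kernel, separable sampling.
cubic_kernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

sample_bicubic <- function(ch, rr, cc) {
  h <- nrow(ch); w <- ncol(ch)
  rr <- pmin(pmax(rr, 1), h); cc <- pmin(pmax(cc, 1), w)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  acc <- numeric(length(rr)); wacc <- numeric(length(rr))
  for (dy in -1:2) {
    ry <- pmin(pmax(r0 + dy, 1), h)
    ky <- cubic_kernel(fr - dy)
    for (dx in -1:2) {
      cx <- pmin(pmax(c0 + dx, 1), w)
      k <- ky * cubic_kernel(fc - dx)
      acc <- acc + ch[cbind(ry, cx)] * k
      wacc <- wacc + k
    }
  }
  acc / wacc
}

# ---- point in polygon --------------------------------------------------

# Even-odd (crossing number) membership test with inclusive boundaries,
# vectorised over query points. `rings` is a list of n x 2 vertex matrices
# (x, y), implicitly closed; interior rings toggle parity (holes).
points_in_polygon <- function(px, py, rings, eps = 1e-9) {
  if (is.matrix(rings)) rings <- list(rings)
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  for (ring in rings) {
    n <- nrow(ring)
    if (n < 3) next
    xs <- ring[, 1]; ys <- ring[, 2]
    # drop an explicit closing vertex
    if (xs[1] == xs[n] && ys[1] == ys[n]) { xs <- xs[-n]; ys <- ys[-n]; n <- n - 1 }
    j <- c(n, seq_len(n - 1))
    for (k in seq_len(n)) {
      x1 <- xs[j[k]]; y1 <- ys[j[k]]; x2 <- xs[k]; y2 <- ys[k]
      crosses <- ((y1 > py) != (y2 > py))
      if (any(crosses)) {
        xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        hit <- crosses & (px < xint)
        inside[hit] <- !inside[hit]
      }
      # boundary: point within segment bounding box and collinear
      dx <- x2 - x1; dy <- y2 - y1
      seg_len2 <- dx * dx + dy * dy
      if (seg_len2 > 0) {
        tproj <- ((px - x1) * dx + (py - y1) * dy) / seg_len2
        on_seg <- tproj >= -eps & tproj <= 1 + eps
        cross <- abs((px - x1) * dy - (py - y1) * dx)
        boundary <- boundary | (on_seg & cross <= eps * sqrt(seg_len2) * 1e3)
      } else {
        boundary <- boundary | (abs(px - x1) <= eps & abs(py - y1) <= eps)
      }
    }
  }
  inside | boundary
}

shoelace_area <- function(ring) {
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- length(xs)
  if (xs[1] == xs[n] && ys[1] == ys[n]) { xs <- xs[-n]; ys <- ys[-n]; n <- n - 1 }
  j <- c(2:n, 1)
  sum(xs * ys[j] - xs[j] * ys) / 2
}

# ---- connected components on a cell grid -------------------------------

# Label TRUE cells of a logical matrix. Frontier-expansion flood fill;
# grids here are class-map sized (tens of cells per side), not pixels.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    off <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    off <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
    off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  }
  next_lab <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    seed_cell <- todo[1]
    next_lab <- next_lab + 1L
    frontier <- seed_cell
    lab[seed_cell] <- next_lab
    while (length(frontier)) {
      fi <- ((frontier - 1L) %% nr) + 1L
      fj <- ((frontier - 1L) %/% nr) + 1L
      cand_i <- rep(fi, each = nrow(off)) + off[, 1]
      cand_j <- rep(fj, each = nrow(off)) + off[, 2]
      ok <- cand_i >= 1L & cand_i <= nr & cand_j >= 1L & cand_j <= nc
      idx <- unique(cand_i[ok] + (cand_j[ok] - 1L) * nr)
      idx <- idx[mask[idx] & lab[idx] == 0L]
      lab[idx] <- next_lab
      frontier <- idx
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

# md5 of a file, used by the pipeline manifest
file_md5 <- function(path) unname(tools::md5sum(path))
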