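# Whole-slide processing: foreground detection, physical-size tessellation,
# slide classification into a class map, probability heatmaps, confidence
# filtering.

#' Class-probability map over a slide
#'
#' Cell (i, j) (1-based) covers full-resolution pixels
#' \[ (j-1) * native_px, j * native_px ) x \[ (i-1) * native_px, i * native_px ).
#' Background cells carry NA probabilities.
#'
#' @param probs rows x cols x 3 array of class probabilities (NA = background).
#' @param native_px cell edge in full-resolution pixels.
#' @param mpp microns per pixel.
#' @export
class_map <- function(probs, native_px, mpp) {
  stopifnot(is.array(probs), length(dim(probs)) == 3L, dim(probs)[3] == 3L,
            native_px >= 1, mpp > 0)
  ok <- !is.na(probs[, , 1])
  if (any(ok)) {
    s <- probs[, , 1] + probs[, , 2] + probs[, , 3]
    stopifnot(all(abs(s[ok] - 1) < 1e-5))   # 1e-5 admits CSV round-trips
  }
  structure(list(probs = probs, rows = dim(probs)[1], cols = dim(probs)[2],
                 native_px = as.integer(native_px), mpp = mpp),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  n_bg <- sum(is.na(x$probs[, , 1]))
  cat(sprintf("class_map: %d x %d cells of %d px (%.3g mpp), %d background\n",
              x$rows, x$cols, x$native_px, x$mpp, n_bg))
  invisible(x)
}

#' Predicted class per cell (argmax, lowest index on ties; 255 background)
#' @param map a class_map.
#' @export
class_map_pred <- function(map) {
  pred <- matrix(255L, map$rows, map$cols)
  for (i in seq_len(map$rows)) for (j in seq_len(map$cols)) {
    p <- map$probs[i, j, ]
    if (!is.na(p[1])) pred[i, j] <- which.max(p) - 1L
  }
  pred
}

#' Cell index to full-resolution pixel origin
#' @param map a class_map.
#' @param i,j 1-based cell indices.
#' @return c(x0, y0) 0-based pixel origin of the cell.
#' @export
cell_origin <- function(map, i, j) c((j - 1L) * map$native_px, (i - 1L) * map$native_px)

#' Full-resolution pixel to cell index
#' @param map a class_map.
#' @param x,y 0-based pixel coordinates.
#' @return c(i, j) 1-based cell indices.
#' @export
origin_cell <- function(map, x, y) c(as.integer(y %/% map$native_px) + 1L,
                                     as.integer(x %/% map$native_px) + 1L)

#' Detect foreground tissue
#'
#' Simple saturation/intensity rule standing in for a dedicated QC tool:
#' tissue = (HSV saturation > sat_min) OR (grey intensity < intensity_max).
#' Components smaller than min_area_um2 are removed and interior holes
#' smaller than min_area_um2 are filled.
#'
#' @param slide_image H x W x 3 array (0-255) or synthetic_slide.
#' @param mpp microns per pixel (defaults from the slide object).
#' @param sat_min minimum HSV saturation for tissue.
#' @param intensity_max grey level below which a pixel is tissue.
#' @param min_area_um2 area threshold for speckle removal / hole filling.
#' @param downsample integer stride at which the mask is computed.
#' @return object of class "foreground_mask": logical matrix `mask` at the
#'   stated downsample, plus downsample and mpp.
#' @export
detect_foreground <- function(slide_image, mpp = NULL, sat_min = 0.05,
                              intensity_max = 220, min_area_um2 = 5000,
                              downsample = 4) {
  if (inherits(slide_image, "synthetic_slide")) {
    if (is.null(mpp)) mpp <- slide_image$mpp
    slide_image <- slide_image$image
  }
  assert_rgb(slide_image)
  stopifnot(!is.null(mpp))
  idx_r <- seq(1, nrow(slide_image), by = downsample)
  idx_c <- seq(1, ncol(slide_image), by = downsample)
  thumb <- slide_image[idx_r, idx_c, , drop = FALSE]
  mx <- pmax(thumb[, , 1], thumb[, , 2], thumb[, , 3])
  mn <- pmin(thumb[, , 1], thumb[, , 2], thumb[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  grey <- (thumb[, , 1] + thumb[, , 2] + thumb[, , 3]) / 3
  mask <- sat > sat_min | grey < intensity_max
  px_area_um2 <- (mpp * downsample)^2
  min_px <- max(1L, round(min_area_um2 / px_area_um2))
  # speckle removal
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    pos <- lab > 0
    small <- pos
    small[pos] <- sizes[lab[pos]] < min_px
    mask[small] <- FALSE
  }
  # fill interior holes below threshold
  inv <- EBImage::bwlabel(!mask)
  if (max(inv) > 0) {
    border_labs <- unique(c(inv[1, ], inv[nrow(inv), ], inv[, 1], inv[, ncol(inv)]))
    sizes <- tabulate(inv[inv > 0])
    fill <- setdiff(which(sizes < min_px), border_labs)
    if (length(fill)) {
      hit <- matrix(inv %in% fill, nrow(mask), ncol(mask))
      mask[hit] <- TRUE
    }
  }
  structure(list(mask = mask, downsample = as.integer(downsample), mpp = mpp),
            class = "foreground_mask")
}

#' Tessellation specification
#'
#' Patches have a fixed physical edge (microns) so tessellation adapts to
#' the scanner resolution: at 0.25 mpp a 128-micron target gives native
#' 512-px cells fed to the 512-px model without resize; at 0.5 mpp the
#' native cell is 256 px and is resized up.
#'
#' @param target_um patch edge in microns (128 for the 512-px model,
#'   256 for the 1024-px model).
#' @param mpp microns per pixel of the slide.
#' @param model_input_px model input side the patches are resized to.
#' @param resize resampling method for the patch resize.
#' @export
tessellation_spec <- function(target_um = 128, mpp = 0.25, model_input_px = 512,
                              resize = "bilinear") {
  if (is.null(mpp) || is.na(mpp)) stop("metadata error: mpp is required", call. = FALSE)
  native_px <- round(target_um / mpp)
  stopifnot(native_px >= 1)
  structure(list(target_um = target_um, mpp = mpp, native_px = as.integer(native_px),
                 model_input_px = as.integer(model_input_px), resize = resize),
            class = "tessellation_spec")
}

#' Tessellate a slide into grid patches
#'
#' The slide is cut into floor(W / native_px) x floor(H / native_px)
#' non-overlapping cells anchored at the origin (edge remainders dropped).
#' A cell yields a patch iff its foreground fraction reaches
#' min_fg_fraction; emitted patches are resized to model_input_px.
#'
#' @param slide_image H x W x 3 array or synthetic_slide.
#' @param fg a foreground_mask (or NULL to treat everything as tissue).
#' @param spec a tessellation_spec.
#' @param min_fg_fraction minimum tissue fraction per cell (default 0.5).
#' @return object of class "patch_grid": list of resized patches, their
#'   grid indices/origins, grid dimensions and the spec.
#' @export
tessellate <- function(slide_image, fg = NULL, spec, min_fg_fraction = 0.5) {
  if (inherits(slide_image, "synthetic_slide")) slide_image <- slide_image$image
  assert_rgb(slide_image)
  stopifnot(inherits(spec, "tessellation_spec"))
  s <- spec$native_px
  H <- nrow(slide_image); W <- ncol(slide_image)
  rows <- as.integer(H %/% s); cols <- as.integer(W %/% s)
  patches <- list(); idx <- list()
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    y0 <- (i - 1L) * s; x0 <- (j - 1L) * s
    frac <- 1
    if (!is.null(fg)) {
      d <- fg$downsample
      rr <- floor(y0 / d) + seq_len(max(1L, floor(s / d)))
      cc <- floor(x0 / d) + seq_len(max(1L, floor(s / d)))
      rr <- rr[rr <= nrow(fg$mask)]; cc <- cc[cc <= ncol(fg$mask)]
      frac <- mean(fg$mask[rr, cc])
    }
    if (frac < min_fg_fraction) next
    patch <- slide_image[(y0 + 1):(y0 + s), (x0 + 1):(x0 + s), , drop = FALSE]
    if (s != spec$model_input_px)
      patch <- round(resize_image(patch, spec$model_input_px, spec$model_input_px,
                                  spec$resize))
    patches[[length(patches) + 1L]] <- patch
    idx[[length(idx) + 1L]] <- c(i = i, j = j, x0 = x0, y0 = y0)
  }
  structure(list(patches = patches,
                 index = if (length(idx)) as.data.frame(do.call(rbind, idx))
                         else data.frame(i = integer(0), j = integer(0),
                                         x0 = integer(0), y0 = integer(0)),
                 rows = rows, cols = cols, spec = spec),
            class = "patch_grid")
}

#' Classify a tessellated slide into a class map
#'
#' Each emitted patch is stain-normalised (when reference statistics are
#' given) and classified; its probability triple is stored at its grid
#' index. Cells without a patch stay background.
#'
#' @param model a trained nbt_model.
#' @param grid a patch_grid from \code{tessellate}.
#' @param normalizer optional stain_stats reference for Reinhard
#'   normalisation before inference.
#' @return a class_map.
#' @export
classify_slide <- function(model, grid, normalizer = NULL) {
  stopifnot(inherits(grid, "patch_grid"))
  probs <- array(NA_real_, c(grid$rows, grid$cols, 3))
  if (length(grid$patches)) {
    imgs <- grid$patches
    if (!is.null(normalizer))
      imgs <- lapply(imgs, reinhard_normalize, ref = normalizer)
    pr <- predict_probs(model, imgs)
    for (k in seq_len(nrow(pr))) {
      i <- grid$index$i[k]; j <- grid$index$j[k]
      probs[i, j, ] <- c(pr$p_epithelium[k], pr$p_stroma[k], pr$p_adipocyte[k])
    }
  }
  class_map(probs, native_px = grid$spec$native_px, mpp = grid$spec$mpp)
}

#' RGB probability heatmap of a class map
#'
#' Epithelium, stroma and adipocyte probabilities map to the red, green
#' and blue channels (255 * p); background cells render white. With
#' smooth = TRUE the probability grid is bilinearly upscaled
#' (corner-aligned) before mapping, giving the smoothed heatmap; otherwise
#' cells are replicated as solid blocks.
#'
#' @param map a class_map.
#' @param upscale integer pixel replication / interpolation factor.
#' @param smooth logical; interpolate instead of block replication.
#' @return (rows * upscale) x (cols * upscale) x 3 array, 0-255.
#' @export
probability_heatmap <- function(map, upscale = 1, smooth = FALSE) {
  stopifnot(inherits(map, "class_map"), upscale >= 1)
  p <- map$probs
  bg <- is.na(p[, , 1])
  rgb0 <- array(0, dim(p))
  for (k in 1:3) {
    ch <- p[, , k]
    ch[bg] <- 1   # background renders white
    rgb0[, , k] <- ch * 255
  }
  if (upscale == 1) return(round(rgb0))
  out_h <- map$rows * upscale; out_w <- map$cols * upscale
  if (!smooth) {
    out <- array(0, c(out_h, out_w, 3))
    ones <- matrix(1, upscale, upscale)
    for (k in 1:3) out[, , k] <- kronecker(rgb0[, , k], ones)
    return(round(out))
  }
  # corner-aligned bilinear interpolation of the probability grid
  out <- array(0, c(out_h, out_w, 3))
  rr <- seq(1, map$rows, length.out = out_h)
  cc <- seq(1, map$cols, length.out = out_w)
  grid_r <- rep(rr, times = out_w); grid_c <- rep(cc, each = out_h)
  for (k in 1:3) out[, , k] <- matrix(sample_bilinear(rgb0[, , k], grid_r, grid_c),
                                      out_h, out_w)
  round(out)
}

#' Confidence filtering of a class map
#'
#' Confidence is the maximum class probability per non-background cell.
#' Returns the exact fraction of cells with confidence strictly greater
#' than tau, and their indices.
#'
#' @param map a class_map.
#' @param tau threshold in \[0, 1\] (typical operating points 0.7, 0.99).
#' @return list(fraction, cells): `cells` is a data.frame (i, j, confidence)
#'   of the selected cells.
#' @export
confidence_filter <- function(map, tau) {
  stopifnot(inherits(map, "class_map"), tau >= 0, tau <= 1)
  conf <- apply(map$probs, c(1, 2), function(v) if (is.na(v[1])) NA_real_ else max(v))
  fg <- which(!is.na(conf), arr.ind = TRUE)
  if (!nrow(fg)) return(list(fraction = NA_real_, cells = data.frame()))
  cv <- conf[fg]
  sel <- cv > tau
  list(fraction = mean(sel),
       cells = data.frame(i = fg[sel, 1], j = fg[sel, 2], confidence = cv[sel]))
}

#' Serialise a class map as CSV
#'
#' Columns: row, col (0-based), x0, y0, p_epithelium, p_stroma,
#' p_adipocyte, pred, confidence. Probabilities are written at fixed
#' 6-decimal precision so reruns are byte-identical.
#' @param map a class_map.
#' @param path output CSV.
#' @export
write_class_map_csv <- function(map, path) {
  pred <- class_map_pred(map)
  rows <- list()
  for (i in seq_len(map$rows)) for (j in seq_len(map$cols)) {
    p <- map$probs[i, j, ]
    if (is.na(p[1])) next
    o <- cell_origin(map, i, j)
    rows[[length(rows) + 1L]] <- sprintf("%d,%d,%d,%d,%.6f,%.6f,%.6f,%d,%.6f",
      i - 1L, j - 1L, o[1], o[2], p[1], p[2], p[3], pred[i, j], max(p))
  }
  writeLines(c("row,col,x0,y0,p_epithelium,p_stroma,p_adipocyte,pred,confidence",
               unlist(rows)), path)
  invisible(path)
}

#' Read a class map CSV written by \code{write_class_map_csv}
#' @param path CSV path.
#' @param rows,cols grid dimensions.
#' @param native_px,mpp cell geometry.
#' @export
read_class_map_csv <- function(path, rows, cols, native_px, mpp) {
  df <- utils::read.csv(path)
  probs <- array(NA_real_, c(rows, cols, 3))
  for (k in seq_len(nrow(df))) {
    probs[df$row[k] + 1L, df$col[k] + 1L, ] <-
      c(df$p_epithelium[k], df$p_stroma[k], df$p_adipocyte[k])
  }
  class_map(probs, native_px, mpp)
}
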