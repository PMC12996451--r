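# Reinhard colour-statistics transfer in the decorrelated log lab space.
#
# RGB -> LMS -> log10 -> l-alpha-beta; per-channel means/sds are matched to
# a reference and the mapping inverted. This is colour-statistics transfer,
# not stain deconvolution: it removes global staining/scanner shifts while
# leaving morphology untouched. All pixels enter the statistics (no
# background masking).

RGB2LMS <- matrix(c(0.3811, 0.5783, 0.0402,
                    0.1967, 0.7244, 0.0782,
                    0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
# exact inverses keep the self-normalisation round trip within one
# quantisation level (published rounded inverses add ~1 level of error)
LMS2RGB <- solve(RGB2LMS)
LMS2LAB <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
LAB2LMS <- solve(LMS2LAB)

rgb_to_lab_pixels <- function(img) {
  pix <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3])) / 255
  pix[pix < 1 / 255] <- 1 / 255       # floor zeros before the logarithm
  lms <- pix %*% t(RGB2LMS)
  lms[lms < 1e-12] <- 1e-12
  log10(lms) %*% t(LMS2LAB)
}

lab_pixels_to_rgb <- function(lab, h, w) {
  lms <- 10^(lab %*% t(LAB2LMS))
  rgb <- lms %*% t(LMS2RGB) * 255
  out <- array(0, c(h, w, 3))
  for (k in 1:3) out[, , k] <- matrix(clip255(rgb[, k]), h, w)
  round(out)
}

#' Colour-space moments of an image in decorrelated log space
#'
#' @param image H x W x 3 RGB array on the 8-bit scale, or an object with
#'   an `$image` field (e.g. a synthetic tile).
#' @return object of class "stain_stats": means and standard deviations of
#'   the l, alpha, beta channels over all pixels.
#' @export
lab_stats <- function(image) {
  if (is.list(image) && !is.null(image$image)) image <- image$image
  assert_rgb(image)
  if (length(image) == 0) stop("empty image", call. = FALSE)
  lab <- rgb_to_lab_pixels(image)
  structure(list(
    mean_l = mean(lab[, 1]), mean_a = mean(lab[, 2]), mean_b = mean(lab[, 3]),
    std_l = stats::sd(lab[, 1]), std_a = stats::sd(lab[, 2]), std_b = stats::sd(lab[, 3])
  ), class = "stain_stats")
}

#' @export
print.stain_stats <- function(x, ...) {
  cat(sprintf("stain_stats: mean(l,a,b) = (%.4f, %.4f, %.4f), sd = (%.4f, %.4f, %.4f)\n",
              x$mean_l, x$mean_a, x$mean_b, x$std_l, x$std_a, x$std_b))
  invisible(x)
}

#' Reinhard normalisation of an image to reference colour statistics
#'
#' Each log-space channel x is mapped to
#' (x - mean_src) * (std_ref / std_src) + mean_ref and inverted back to
#' 8-bit RGB with clipping. A degenerate source channel (std 0) maps the
#' whole channel onto the reference mean.
#'
#' @param image H x W x 3 RGB array (0-255) or object with `$image`.
#' @param ref stain_stats of the reference image.
#' @return normalised H x W x 3 array, integer-valued 0-255.
#' @export
reinhard_normalize <- function(image, ref) {
  if (is.list(image) && !is.null(image$image)) image <- image$image
  assert_rgb(image)
  stopifnot(inherits(ref, "stain_stats"))
  src <- lab_stats(image)
  lab <- rgb_to_lab_pixels(image)
  mu_s <- c(src$mean_l, src$mean_a, src$mean_b)
  sd_s <- c(src$std_l, src$std_a, src$std_b)
  mu_r <- c(ref$mean_l, ref$mean_a, ref$mean_b)
  sd_r <- c(ref$std_l, ref$std_a, ref$std_b)
  for (k in 1:3) {
    scale <- if (sd_s[k] < 1e-12) 0 else sd_r[k] / sd_s[k]
    lab[, k] <- (lab[, k] - mu_s[k]) * scale + mu_r[k]
  }
  lab_pixels_to_rgb(lab, nrow(image), ncol(image))
}

#' Packaged default reference stain statistics
#'
#' Computed at call time from a fixed synthetic H&E-like reference tile
#' (stroma texture, seed 42). A real reference image can be substituted by
#' computing \code{lab_stats} on it and passing the result around instead.
#' @return a stain_stats object.
#' @export
default_stain_reference <- function() {
  ref_tile <- make_tile(1, 128, mpp = 1, seed = 42)
  lab_stats(ref_tile$image)
}

#' Serialise stain statistics to JSON
#' @param stats a stain_stats object.
#' @param path output JSON file.
#' @export
write_stain_stats <- function(stats, path) {
  stopifnot(inherits(stats, "stain_stats"))
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read stain statistics from JSON
#' @param path JSON file written by \code{write_stain_stats}.
#' @export
read_stain_stats <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(x[c("mean_l", "mean_a", "mean_b", "std_l", "std_a", "std_b")],
            class = "stain_stats")
}
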