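# QuPath-compatible polygon annotations: GeoJSON I/O, centre-rule patch
# extraction, and class-balanced sampling.
#
# Conventions: 0-based pixel coordinates at full resolution, x rightward,
# y downward. Grid cells are half-open [x0, x0+S) x [y0, y0+S). The class
# vocabulary is fixed: 0 epithelium, 1 stroma, 2 adipocytes.

LABEL_COLORS <- list(`0` = c(255L, 0L, 0L), `1` = c(0L, 255L, 0L), `2` = c(0L, 0L, 255L))

label_from_name <- function(name, remap = NULL) {
  key <- tolower(trimws(name))
  std <- c(epithelium = 0L, stroma = 1L, adipocyte = 2L, adipocytes = 2L)
  if (key %in% names(std)) return(unname(std[key]))
  if (!is.null(remap) && name %in% names(remap)) return(as.integer(remap[[name]]))
  stop("label error: unknown classification name '", name, "' and no remap given",
       call. = FALSE)
}

#' Construct an annotation set
#'
#' @param features list of features, each a list with `polygon` (a list of
#'   n x 2 vertex matrices: exterior ring first, optional holes after),
#'   `label` (0/1/2) and `id` (string).
#' @param mpp slide microns per pixel.
#' @param dims slide dimensions c(W, H) in pixels.
#' @export
annotation_set <- function(features = list(), mpp = NA_real_, dims = c(NA_real_, NA_real_)) {
  for (f in features) {
    stopifnot(is.list(f$polygon), f$label %in% 0:2)
    for (ring in f$polygon) stopifnot(is.matrix(ring), ncol(ring) == 2)
  }
  structure(list(features = features, mpp = mpp, dims = dims),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  labs <- vapply(x$features, function(f) f$label, integer(1))
  cat("annotation_set:", length(x$features), "features (",
      paste(sprintf("%s=%d", CLASS_NAMES, tabulate(labs + 1L, 3)), collapse = ", "),
      ") on", x$dims[1], "x", x$dims[2], "px at", x$mpp, "mpp\n")
  invisible(x)
}

#' Read QuPath-dialect GeoJSON annotations
#'
#' Accepts a FeatureCollection whose features carry Polygon geometry and a
#' `properties.classification.name`. Ring closure (first vertex repeated
#' last) is normalised away. Vertices are validated against the slide
#' bounds; out-of-bounds vertices either abort or are clipped.
#'
#' @param path GeoJSON file.
#' @param mpp slide microns per pixel (stored on the result).
#' @param slide_dims c(W, H) in pixels.
#' @param remap optional named list mapping non-standard class names to 0/1/2.
#' @param oob "error" (default) or "clip" for out-of-bounds vertices.
#' @return an annotation_set.
#' @export
read_annotations <- function(path, mpp = NA_real_, slide_dims = c(NA, NA),
                             remap = NULL, oob = c("error", "clip")) {
  oob <- match.arg(oob)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("parse error: ", conditionMessage(e), call. = FALSE))
  if (is.null(doc$type) || doc$type != "FeatureCollection")
    stop("parse error: not a GeoJSON FeatureCollection", call. = FALSE)
  feats <- list()
  for (ft in doc$features) {
    if (is.null(ft$geometry) || ft$geometry$type != "Polygon")
      stop("parse error: only Polygon geometries are supported", call. = FALSE)
    cls <- ft$properties$classification$name
    if (is.null(cls)) stop("label error: feature without classification name", call. = FALSE)
    label <- label_from_name(cls, remap)
    rings <- lapply(ft$geometry$coordinates, function(ring) {
      m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
      n <- nrow(m)
      if (n > 1 && m[1, 1] == m[n, 1] && m[1, 2] == m[n, 2]) m <- m[-n, , drop = FALSE]
      colnames(m) <- c("x", "y")
      m
    })
    if (!any(is.na(slide_dims))) {
      for (ri in seq_along(rings)) {
        m <- rings[[ri]]
        bad <- m[, 1] < 0 | m[, 1] > slide_dims[1] | m[, 2] < 0 | m[, 2] > slide_dims[2]
        if (any(bad)) {
          if (oob == "error")
            stop("bounds error: vertex outside slide dimensions", call. = FALSE)
          m[, 1] <- pmin(pmax(m[, 1], 0), slide_dims[1])
          m[, 2] <- pmin(pmax(m[, 2], 0), slide_dims[2])
          rings[[ri]] <- m
        }
      }
    }
    id <- if (!is.null(ft$id)) as.character(ft$id)
          else if (!is.null(ft$properties$name)) as.character(ft$properties$name)
          else sprintf("annotation_%d", length(feats) + 1L)
    feats[[length(feats) + 1L]] <- list(polygon = rings, label = label, id = id)
  }
  annotation_set(feats, mpp = mpp, dims = slide_dims)
}

qupath_feature <- function(rings, label, id, name = CLASS_NAMES[label + 1L],
                           color = LABEL_COLORS[[as.character(label)]]) {
  closed <- lapply(rings, function(m) {
    m <- unname(m)
    rbind(m, m[1, , drop = FALSE])
  })
  list(
    type = "Feature",
    id = id,
    geometry = list(type = "Polygon", coordinates = closed),
    properties = list(
      objectType = "annotation",
      classification = list(name = name, color = color)
    )
  )
}

#' Write objects as QuPath-compatible GeoJSON
#'
#' Annotation sets are written feature by feature; class maps become one
#' axis-aligned square polygon per non-background cell; lobule detections
#' become their traced component polygons. Classification colours follow
#' the red/green/blue convention for epithelium/stroma/adipocytes.
#'
#' @param objects an annotation_set, class_map, or lobule_detection.
#' @param path output file.
#' @export
write_qupath_geojson <- function(objects, path) {
  feats <- list()
  if (inherits(objects, "annotation_set")) {
    for (f in objects$features)
      feats[[length(feats) + 1L]] <- qupath_feature(f$polygon, f$label, f$id)
  } else if (inherits(objects, "class_map")) {
    pred <- class_map_pred(objects)
    s <- objects$native_px
    for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 255L) next
      x0 <- (j - 1) * s; y0 <- (i - 1) * s
      ring <- cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))
      feats[[length(feats) + 1L]] <-
        qupath_feature(list(ring), pred[i, j], sprintf("cell_%d_%d", i - 1L, j - 1L))
    }
  } else if (inherits(objects, "lobule_detection")) {
    for (comp in objects$components)
      feats[[length(feats) + 1L]] <-
        qupath_feature(comp$polygon, 0L, sprintf("lobule_%d", comp$id))
  } else stop("unsupported object type for GeoJSON export", call. = FALSE)
  doc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract labelled patches by the centre-in-annotation rule
#'
#' The image is tessellated into a non-overlapping grid of patch_px cells
#' anchored at the origin. A patch is emitted iff its centre point lies
#' inside at least one annotation (boundary-inclusive even-odd test) and
#' all annotations containing the centre agree on the label; centres in
#' overlapping annotations of conflicting labels are dropped.
#'
#' @param image H x W x 3 array, or a synthetic_slide.
#' @param annotations an annotation_set.
#' @param patch_px patch side in pixels (>= 32).
#' @param mpp microns per pixel (defaults to the annotation set's).
#' @param source_id provenance string.
#' @param keep_pixels if FALSE only origins/labels are recorded (cheap for
#'   geometry checks on large slides).
#' @return a patch_set.
#' @export
extract_labeled_patches <- function(image, annotations, patch_px, mpp = NULL,
                                    source_id = "slide", keep_pixels = TRUE) {
  if (inherits(image, "synthetic_slide")) {
    if (is.null(mpp)) mpp <- image$mpp
    image <- image$image
  }
  assert_rgb(image)
  stopifnot(patch_px >= 32, nrow(image) >= patch_px, ncol(image) >= patch_px)
  if (is.null(mpp)) mpp <- annotations$mpp
  H <- nrow(image); W <- ncol(image)
  nx <- floor(W / patch_px); ny <- floor(H / patch_px)
  ox <- rep((seq_len(nx) - 1L) * patch_px, each = ny)
  oy <- rep((seq_len(ny) - 1L) * patch_px, times = nx)
  cx <- ox + patch_px / 2; cy <- oy + patch_px / 2
  hit_label <- rep(NA_integer_, length(cx))
  conflict <- rep(FALSE, length(cx))
  for (f in annotations$features) {
    inside <- points_in_polygon(cx, cy, f$polygon)
    newhit <- inside & is.na(hit_label)
    hit_label[newhit] <- f$label
    conflict <- conflict | (inside & !is.na(hit_label) & hit_label != f$label)
  }
  keep <- !is.na(hit_label) & !conflict
  patches <- lapply(which(keep), function(k) {
    px <- NULL
    if (keep_pixels)
      px <- image[(oy[k] + 1):(oy[k] + patch_px), (ox[k] + 1):(ox[k] + patch_px), , drop = FALSE]
    list(pixels = px, origin = c(ox[k], oy[k]), patch_px = patch_px,
         mpp = mpp, label = hit_label[k], source_id = source_id)
  })
  patch_set(patches, provenance = list(source_ids = source_id, patch_px = patch_px, mpp = mpp))
}

#' Bundle patches into a patch set
#' @param patches list of patch records (pixels, origin, patch_px, mpp,
#'   label, source_id).
#' @param provenance free-form provenance list.
#' @export
patch_set <- function(patches = list(), provenance = list()) {
  keys <- vapply(patches, function(p)
    paste(p$source_id, p$origin[1], p$origin[2], sep = "_"), character(1))
  if (anyDuplicated(keys)) stop("duplicate (source_id, origin) patch", call. = FALSE)
  labs <- vapply(patches, function(p) if (is.null(p$label)) NA_integer_ else p$label, integer(1))
  structure(list(patches = patches,
                 counts = tabulate(labs + 1L, 3),
                 provenance = provenance),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("patch_set:", length(x$patches), "patches (",
      paste(sprintf("%s=%d", CLASS_NAMES, x$counts), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
length.patch_set <- function(x) length(x$patches)

patch_labels <- function(ps) vapply(ps$patches, function(p) p$label, integer(1))

#' Class-balanced patch sampling
#'
#' For every (source, class) stratum with m available patches, keeps
#' exactly min(m, n) chosen by seeded sampling without replacement,
#' warning when a stratum is short.
#'
#' @param patches a patch_set.
#' @param n_per_class_per_source requested patches per class per source.
#' @param seed integer seed.
#' @return a patch_set.
#' @export
balanced_sample <- function(patches, n_per_class_per_source, seed = 1) {
  stopifnot(n_per_class_per_source >= 1)
  src <- vapply(patches$patches, function(p) p$source_id, character(1))
  lab <- patch_labels(patches)
  key <- paste(src, lab, sep = "\r")
  sel <- integer(0)
  for (k in sort(unique(key))) {
    idx <- which(key == k)
    m <- length(idx)
    if (m < n_per_class_per_source)
      warning(sprintf("stratum %s has %d < %d patches; keeping all",
                      gsub("\r", "/", k), m, n_per_class_per_source), call. = FALSE)
    take <- min(m, n_per_class_per_source)
    pick <- with_seed(sub_seed(seed, which(sort(unique(key)) == k)),
                      sample(idx, take))
    sel <- c(sel, sort(pick))
  }
  patch_set(patches$patches[sel], provenance = c(patches$provenance,
            list(balanced_n = n_per_class_per_source, seed = seed)))
}

#' Write a patch-set manifest CSV
#' @param patches a patch_set.
#' @param path output CSV (source_id, x0, y0, patch_px, mpp, label).
#' @export
write_patch_manifest <- function(patches, path) {
  df <- data.frame(
    source_id = vapply(patches$patches, function(p) p$source_id, character(1)),
    x0 = vapply(patches$patches, function(p) p$origin[1], numeric(1)),
    y0 = vapply(patches$patches, function(p) p$origin[2], numeric(1)),
    patch_px = vapply(patches$patches, function(p) p$patch_px, numeric(1)),
    mpp = vapply(patches$patches, function(p) p$mpp, numeric(1)),
    label = patch_labels(patches))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
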