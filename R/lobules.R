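# Lobule detection on a whole-slide class map.
#
# The epithelium layer of the class map is extracted, connected components
# are identified, small objects are removed, small interior holes are
# filled, and each surviving component is rendered as an enlarged binary
# mask and a traced polygon with its peri-lobular ring. Area thresholds
# are counted in full-resolution-equivalent pixels (cells x native_px^2),
# which is the unit under which a two-patch lobule at 512-px cells
# (~520,000 px) clears the 400,000-px cutoff; the x32 enlargement is a
# rendering device for smooth masks and polygons, not a measuring scale.

#' Lobule detection parameters
#'
#' @param min_object_px minimum object area in full-resolution pixels;
#'   default 400,000 at 40x (mpp <= 0.3) and 250,000 at 20x.
#' @param max_hole_px interior holes below this area are filled (default
#'   400,000).
#' @param enlargement_factor rendering upscale for the output mask.
#' @param connectivity 4 or 8 (default 8: diagonal acinar continuity).
#' @param perilobular_width_um default ring width in microns.
#' @param mpp microns per pixel, used only to pick the 40x/20x default.
#' @export
lobule_params <- function(min_object_px = NULL, max_hole_px = 400000,
                          enlargement_factor = 32, connectivity = 8,
                          perilobular_width_um = 250, mpp = 0.25) {
  if (is.null(min_object_px))
    min_object_px <- if (!is.na(mpp) && mpp > 0.3) 250000 else 400000
  stopifnot(min_object_px > 0, max_hole_px > 0, enlargement_factor >= 1,
            connectivity %in% c(4, 8), perilobular_width_um >= 0)
  structure(list(min_object_px = min_object_px, max_hole_px = max_hole_px,
                 enlargement_factor = as.integer(enlargement_factor),
                 connectivity = connectivity,
                 perilobular_width_um = perilobular_width_um),
            class = "lobule_params")
}

# trace boundary rings of a cell set (logical matrix); returns a list of
# vertex matrices in cell-corner coordinates (0-based), exterior first.
trace_cell_boundary <- function(cells) {
  nr <- nrow(cells); nc <- ncol(cells)
  # directed boundary edges: top->right, right->down, bottom->left, left->up
  edges <- list()
  at <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && cells[i, j]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!cells[i, j]) next
    x0 <- j - 1; y0 <- i - 1
    if (!at(i - 1, j)) edges[[length(edges) + 1]] <- c(x0, y0, x0 + 1, y0)
    if (!at(i, j + 1)) edges[[length(edges) + 1]] <- c(x0 + 1, y0, x0 + 1, y0 + 1)
    if (!at(i + 1, j)) edges[[length(edges) + 1]] <- c(x0 + 1, y0 + 1, x0, y0 + 1)
    if (!at(i, j - 1)) edges[[length(edges) + 1]] <- c(x0, y0 + 1, x0, y0)
  }
  if (!length(edges)) return(list())
  em <- do.call(rbind, edges)
  used <- rep(FALSE, nrow(em))
  key <- paste(em[, 1], em[, 2])
  rings <- list()
  for (start in seq_len(nrow(em))) {
    if (used[start]) next
    ring <- list(em[start, 1:2])
    cur <- start; used[start] <- TRUE
    repeat {
      nx <- em[cur, 3]; ny <- em[cur, 4]
      cand <- which(!used & em[, 1] == nx & em[, 2] == ny)
      if (!length(cand)) break
      if (length(cand) > 1) {
        # pinch vertex (diagonally touching cells): prefer the sharpest
        # left turn relative to the incoming direction to keep rings simple
        din <- c(em[cur, 3] - em[cur, 1], em[cur, 4] - em[cur, 2])
        angle_of <- function(e) {
          dout <- c(em[e, 3] - em[e, 1], em[e, 4] - em[e, 2])
          atan2(din[1] * dout[2] - din[2] * dout[1],
                din[1] * dout[1] + din[2] * dout[2])
        }
        cand <- cand[order(vapply(cand, angle_of, numeric(1)))][1]
      }
      ring[[length(ring) + 1]] <- em[cand, 1:2]
      used[cand] <- TRUE
      cur <- cand
      if (em[cur, 3] == em[start, 1] && em[cur, 4] == em[start, 2]) break
    }
    m <- do.call(rbind, ring)
    # drop collinear intermediate vertices
    keep <- rep(TRUE, nrow(m))
    n <- nrow(m)
    for (k in seq_len(n)) {
      p <- m[if (k == 1) n else k - 1, ]; q <- m[k, ]; r <- m[if (k == n) 1 else k + 1, ]
      if ((q[1] - p[1]) * (r[2] - q[2]) == (q[2] - p[2]) * (r[1] - q[1])) keep[k] <- FALSE
    }
    rings[[length(rings) + 1]] <- m[keep, , drop = FALSE]
  }
  if (length(rings) > 1) {
    areas <- vapply(rings, function(r) abs(shoelace_area(r)), numeric(1))
    rings <- rings[order(-areas)]
  }
  rings
}

#' Detect lobules in a class map
#'
#' Pipeline: extract the epithelium layer (cells whose predicted class is
#' epithelium), find connected components at the configured connectivity,
#' remove components below min_object_px (full-resolution-equivalent
#' area), fill interior holes below max_hole_px (filled cells join the
#' component and count toward its area), then render the enlarged mask
#' and trace component polygons in full-resolution pixel coordinates.
#'
#' @param map a class_map.
#' @param params a lobule_params.
#' @return object of class "lobule_detection": `components` (each with id,
#'   cells, n_cells, area_px_fullres, area_um2, bbox, polygon), `mask`
#'   (cell grid), `mask_enlarged`, `params`, and the map geometry.
#' @export
detect_lobules <- function(map, params = lobule_params(mpp = map$mpp)) {
  stopifnot(inherits(map, "class_map"), inherits(params, "lobule_params"))
  pred <- class_map_pred(map)
  epi <- pred == 0L
  s2 <- as.numeric(map$native_px)^2
  lab <- label_components(epi, params$connectivity)
  keep_mask <- matrix(FALSE, map$rows, map$cols)
  comps <- list()
  if (max(lab) > 0) {
    for (ci in seq_len(max(lab))) {
      cells <- lab == ci
      if (sum(cells) * s2 < params$min_object_px) next
      keep_mask <- keep_mask | cells
      comps[[length(comps) + 1]] <- cells
    }
  }
  # fill small interior holes per surviving component
  filled <- list()
  for (cells in comps) {
    # holes: complement components (4-connected for 8-connected foreground)
    inv_conn <- if (params$connectivity == 8) 4 else 8
    inv <- label_components(!cells, inv_conn)
    border_labs <- unique(c(inv[1, ], inv[map$rows, ], inv[, 1], inv[, map$cols]))
    border_labs <- border_labs[border_labs > 0]
    for (hi in setdiff(seq_len(max(inv)), border_labs)) {
      hole <- inv == hi
      # a hole belongs to this component only if it is enclosed by it:
      # all cells bordering the hole are component cells
      ring <- neighbors_of(hole, map$rows, map$cols) & !hole
      if (!all(cells[ring])) next
      if (sum(hole) * s2 < params$max_hole_px) cells <- cells | hole
    }
    filled[[length(filled) + 1]] <- cells
  }
  components <- lapply(seq_along(filled), function(ci) {
    cells <- filled[[ci]]
    idx <- which(cells, arr.ind = TRUE)
    n_cells <- nrow(idx)
    s <- map$native_px
    x0 <- (min(idx[, 2]) - 1L) * s; x1 <- max(idx[, 2]) * s
    y0 <- (min(idx[, 1]) - 1L) * s; y1 <- max(idx[, 1]) * s
    rings <- trace_cell_boundary(cells)
    rings <- lapply(rings, function(r) r * s)   # cell corners -> pixels
    list(id = ci, cells = idx, n_cells = n_cells,
         area_px_fullres = n_cells * s2,
         area_um2 = n_cells * s2 * map$mpp^2,
         bbox = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
         polygon = rings)
  })
  full_mask <- Reduce(`|`, filled, matrix(FALSE, map$rows, map$cols))
  f <- params$enlargement_factor
  structure(list(components = components, mask = full_mask,
                 mask_enlarged = kronecker(full_mask + 0L, matrix(1L, f, f)) > 0,
                 params = params, native_px = map$native_px, mpp = map$mpp,
                 rows = map$rows, cols = map$cols),
            class = "lobule_detection")
}

# cells 8-adjacent to any TRUE cell (including the cells themselves)
neighbors_of <- function(mask, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  idx <- which(mask, arr.ind = TRUE)
  for (di in -1:1) for (dj in -1:1) {
    ii <- idx[, 1] + di; jj <- idx[, 2] + dj
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    out[cbind(ii[ok], jj[ok])] <- TRUE
  }
  out
}

#' @export
print.lobule_detection <- function(x, ...) {
  cat(sprintf("lobule_detection: %d lobules on a %d x %d cell grid (min %g px)\n",
              length(x$components), x$rows, x$cols, x$params$min_object_px))
  invisible(x)
}

#' Peri-lobular region of one lobule
#'
#' Mode "bbox" (the default, matching the two-box visualisation): the
#' lobule bounding box expanded by width_um on each side, minus the lobule
#' itself. Mode "dilation": a morphological dilation ring of the same
#' radius around the lobule mask. Both are clipped to the slide bounds.
#'
#' @param lobule one component from \code{detect_lobules}.
#' @param width_um ring width in microns (>= 0).
#' @param mpp microns per pixel.
#' @param mode "bbox" or "dilation".
#' @param slide_dims c(W, H) full-resolution bounds for clipping.
#' @param detection the parent lobule_detection (required for mode
#'   "dilation", which works on the cell grid).
#' @return list with `outer_bbox` (x0, y0, x1, y1), `polygon` (ring
#'   geometry: outer boundary plus the lobule as hole, pixel coords) and,
#'   for mode "dilation", the ring cell mask.
#' @export
perilobular_region <- function(lobule, width_um, mpp, mode = c("bbox", "dilation"),
                               slide_dims = NULL, detection = NULL) {
  mode <- match.arg(mode)
  if (width_um < 0) stop("width_um must be >= 0", call. = FALSE)
  w_px <- width_um / mpp
  bb <- lobule$bbox
  outer <- c(x0 = bb[["x0"]] - w_px, y0 = bb[["y0"]] - w_px,
             x1 = bb[["x1"]] + w_px, y1 = bb[["y1"]] + w_px)
  if (!is.null(slide_dims)) {
    outer["x0"] <- max(outer["x0"], 0); outer["y0"] <- max(outer["y0"], 0)
    outer["x1"] <- min(outer["x1"], slide_dims[1])
    outer["y1"] <- min(outer["y1"], slide_dims[2])
  }
  if (mode == "bbox") {
    if (width_um == 0) {
      return(list(outer_bbox = outer, polygon = list(), empty = TRUE))
    }
    outer_ring <- cbind(c(outer["x0"], outer["x1"], outer["x1"], outer["x0"]),
                        c(outer["y0"], outer["y0"], outer["y1"], outer["y1"]))
    list(outer_bbox = outer,
         polygon = c(list(outer_ring), lobule$polygon),
         empty = FALSE)
  } else {
    stopifnot(inherits(detection, "lobule_detection"))
    cells <- matrix(FALSE, detection$rows, detection$cols)
    cells[lobule$cells] <- TRUE
    # dilate on the enlarged grid so sub-cell widths are representable
    f <- detection$params$enlargement_factor
    big <- kronecker(cells + 0L, matrix(1L, f, f)) > 0
    px_per_unit <- detection$native_px / f
    r_units <- max(1L, round(w_px / px_per_unit))
    brush <- EBImage::makeBrush(2L * r_units + 1L, shape = "disc")
    dil <- EBImage::dilate(big + 0, brush) > 0
    ring <- dil & !big
    list(outer_bbox = outer, ring_mask_enlarged = ring,
         ring_area_px_fullres = sum(ring) * px_per_unit^2, empty = !any(ring))
  }
}

#' Write lobules (and optional peri-lobular rings) as QuPath GeoJSON
#'
#' Lobule polygons are exported red; when a ring width is given, each
#' lobule additionally gets its bbox-mode peri-lobular ring in yellow.
#'
#' @param detection a lobule_detection.
#' @param path output GeoJSON file.
#' @param perilobular_width_um optional ring width in microns.
#' @param slide_dims optional c(W, H) bounds for ring clipping.
#' @export
write_lobule_geojson <- function(detection, path, perilobular_width_um = NULL,
                                 slide_dims = NULL) {
  stopifnot(inherits(detection, "lobule_detection"))
  feats <- list()
  for (comp in detection$components) {
    feats[[length(feats) + 1L]] <-
      qupath_feature(comp$polygon, 0L, sprintf("lobule_%d", comp$id))
    if (!is.null(perilobular_width_um) && perilobular_width_um > 0) {
      reg <- perilobular_region(comp, perilobular_width_um, detection$mpp,
                                mode = "bbox", slide_dims = slide_dims)
      feats[[length(feats) + 1L]] <-
        qupath_feature(reg$polygon, 1L, sprintf("perilobular_%d", comp$id),
                       name = "Perilobular", color = c(255L, 255L, 0L))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the lobule component table as CSV
#' @param detection a lobule_detection.
#' @param path output CSV (id, n_cells, area_px, area_um2, bbox).
#' @export
write_lobule_table <- function(detection, path) {
  comps <- detection$components
  df <- data.frame(
    id = vapply(comps, function(c) c$id, numeric(1)),
    n_cells = vapply(comps, function(c) c$n_cells, numeric(1)),
    area_px = vapply(comps, function(c) c$area_px_fullres, numeric(1)),
    area_um2 = vapply(comps, function(c) c$area_um2, numeric(1)),
    x0 = vapply(comps, function(c) c$bbox[["x0"]], numeric(1)),
    y0 = vapply(comps, function(c) c$bbox[["y0"]], numeric(1)),
    x1 = vapply(comps, function(c) c$bbox[["x1"]], numeric(1)),
    y1 = vapply(comps, function(c) c$bbox[["y1"]], numeric(1)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
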