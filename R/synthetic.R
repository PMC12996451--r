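# Synthetic H&E-like data generator.
#
# Produces deterministic tiles, pseudo-slides and abstract class maps with
# ground truth, so that stain normalisation, patch extraction, training,
# whole-slide classification and lobule detection are all testable without
# downloading any real whole-slide image. Textures are schematic, not
# photorealistic: each tissue class gets a distinct palette and morphology
# (dark nuclear clusters on purple for epithelium, oriented pink fibres for
# stroma, white cells with membranes for adipocytes).

CLASS_NAMES <- c("Epithelium", "Stroma", "Adipocytes")

#' Texture parameters for one synthetic tissue class
#'
#' Morphology is specified in microns so that rendering adapts to the
#' requested microns-per-pixel: nucleus radius/density for epithelium,
#' fibre wavelength/amplitude for stroma, cell diameter and membrane
#' thickness for adipocytes. Palettes are chosen pairwise distinguishable
#' (mean-RGB distance > 20 on the 8-bit scale).
#'
#' @param class_id 0 epithelium, 1 stroma, 2 adipocytes.
#' @return list of class "texture_params".
#' @export
texture_params <- function(class_id) {
  if (!class_id %in% 0:2) stop("class_id must be 0, 1 or 2", call. = FALSE)
  p <- switch(as.character(class_id),
    "0" = list(
      base = c(198, 162, 212),          # pale purple cytoplasm
      nucleus_col = c(88, 52, 132),     # haematoxylin-dark nuclei
      nucleus_radius_um = 3.5,
      nucleus_density_per_um2 = 0.016,  # dense acinar packing
      cluster_diameter_um = 45
    ),
    "1" = list(
      base = c(236, 184, 202),          # eosin pink
      fibre_wavelength_um = 24,
      fibre_amplitude = 0.16,           # multiplicative depth of fibre bands
      fibre_col_scale = c(0.92, 0.55, 0.75) # fibres darken G most (deep pink)
    ),
    "2" = list(
      base = c(222, 196, 210),          # membrane / interstitial colour
      lumen_col = c(250, 248, 250),     # optically empty fat vacuole
      cell_diameter_um = 45,
      membrane_thickness_um = 2.5
    ))
  p$class_id <- as.integer(class_id)
  structure(p, class = "texture_params")
}

# draw filled disks (cx, cy in 1-based pixel-centre coords) into an
# h x w x 3 canvas; vectorised per disk over its bounding box
draw_disks <- function(canvas, cx, cy, r, col) {
  h <- dim(canvas)[1]; w <- dim(canvas)[2]
  for (i in seq_along(cx)) {
    x0 <- max(1L, floor(cx[i] - r[i])); x1 <- min(w, ceiling(cx[i] + r[i]))
    y0 <- max(1L, floor(cy[i] - r[i])); y1 <- min(h, ceiling(cy[i] + r[i]))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((ys - cy[i])^2, (xs - cx[i])^2, "+")
    hit <- d2 <= r[i]^2
    if (!any(hit)) next
    for (k in 1:3) {
      block <- canvas[ys, xs, k, drop = FALSE]
      block[hit] <- col[k]
      canvas[ys, xs, k] <- block
    }
  }
  canvas
}

# Render one tissue texture on an h x w canvas. Deterministic per seed.
render_texture <- function(class_id, h, w, mpp, seed, params = texture_params(class_id)) {
  with_seed(seed, {
    canvas <- array(0, c(h, w, 3))
    for (k in 1:3) canvas[, , k] <- params$base[k]
    if (class_id == 0L) {
      # nuclei scattered around acinar cluster centres
      area_um2 <- h * w * mpp^2
      n_nuc <- max(8L, round(params$nucleus_density_per_um2 * area_um2))
      n_clu <- max(1L, round(sqrt(area_um2) / params$cluster_diameter_um)^2)
      clu_x <- runif(n_clu, 1, w); clu_y <- runif(n_clu, 1, h)
      pick <- sample.int(n_clu, n_nuc, replace = TRUE)
      spread <- params$cluster_diameter_um / mpp / 2
      cx <- clu_x[pick] + rnorm(n_nuc, 0, spread)
      cy <- clu_y[pick] + rnorm(n_nuc, 0, spread)
      r <- pmax(0.8, rnorm(n_nuc, params$nucleus_radius_um / mpp,
                           0.15 * params$nucleus_radius_um / mpp))
      canvas <- draw_disks(canvas, cx, cy, r, params$nucleus_col)
    } else if (class_id == 1L) {
      theta <- runif(1, 0, pi)
      lambda_px <- params$fibre_wavelength_um / mpp
      xs <- matrix(rep(seq_len(w), each = h), h, w)
      ys <- matrix(rep(seq_len(h), times = w), h, w)
      proj <- xs * cos(theta) + ys * sin(theta)
      perp <- -xs * sin(theta) + ys * cos(theta)
      wave <- sin(2 * pi * proj / lambda_px + 1.2 * sin(2 * pi * perp / (4 * lambda_px) + runif(1, 0, 2 * pi)))
      depth <- params$fibre_amplitude * (wave + 1) / 2   # 0..amplitude
      for (k in 1:3) {
        fade <- 1 - depth * (1 - params$fibre_col_scale[k])
        canvas[, , k] <- canvas[, , k] * fade
      }
    } else {
      # jittered hex packing of fat vacuoles with membrane rings
      d_px <- params$cell_diameter_um / mpp
      t_px <- max(1, params$membrane_thickness_um / mpp)
      step <- d_px * 0.95
      gx <- seq(step / 2, w + step / 2, by = step)
      gy <- seq(step / 2, h + step / 2, by = step * 0.87)
      centers <- expand.grid(cx = gx, cy = gy)
      odd_row <- (match(centers$cy, gy) %% 2) == 1
      centers$cx <- centers$cx + ifelse(odd_row, 0, step / 2)
      n <- nrow(centers)
      centers$cx <- centers$cx + runif(n, -0.08, 0.08) * d_px
      centers$cy <- centers$cy + runif(n, -0.08, 0.08) * d_px
      rr <- d_px / 2 * runif(n, 0.85, 1.05)
      canvas <- draw_disks(canvas, centers$cx, centers$cy, rr, params$base * 0.92)
      canvas <- draw_disks(canvas, centers$cx, centers$cy, pmax(rr - t_px, 1), params$lumen_col)
    }
    noise <- array(rnorm(h * w * 3, 0, 2.5), c(h, w, 3))
    clip255(canvas + noise)
  })
}

#' Generate one synthetic single-class H&E-like tile
#'
#' @param class_id 0 epithelium, 1 stroma, 2 adipocytes.
#' @param size_px tile side in pixels (>= 32).
#' @param mpp microns per pixel.
#' @param stain_shift additive per-channel RGB offset (length 3), applied
#'   after rendering with clipping at \[0, 255\] — a controllable stand-in
#'   for cohort-level stain variation.
#' @param seed integer seed; identical arguments reproduce identical bytes.
#' @return object of class "synthetic_tile" with fields image (size_px x
#'   size_px x 3, integer-valued 0-255), mask (uniformly class_id), mpp,
#'   seed, stain_shift, class_id.
#' @export
make_tile <- function(class_id, size_px, mpp = 0.25, stain_shift = c(0, 0, 0), seed = 1) {
  if (!length(class_id) == 1 || !class_id %in% 0:2)
    stop("class_id must be 0, 1 or 2", call. = FALSE)
  if (size_px < 32) stop("size_px must be >= 32", call. = FALSE)
  stopifnot(mpp > 0, length(stain_shift) == 3)
  img <- round(render_texture(as.integer(class_id), size_px, size_px, mpp,
                              sub_seed(seed, class_id + 1L)))
  for (k in 1:3) img[, , k] <- clip255(img[, , k] + stain_shift[k])
  structure(list(
    image = img,
    mask = matrix(as.integer(class_id), size_px, size_px),
    mpp = mpp, seed = seed, stain_shift = stain_shift,
    class_id = as.integer(class_id)
  ), class = "synthetic_tile")
}

# rasterise polygon rings (x, y 0-based pixel coords) onto an h x w pixel
# grid, testing pixel centres; returns logical matrix
rasterize_rings <- function(rings, h, w) {
  if (is.matrix(rings)) rings <- list(rings)
  allx <- unlist(lapply(rings, function(r) r[, 1]))
  ally <- unlist(lapply(rings, function(r) r[, 2]))
  j0 <- max(1L, floor(min(allx)) + 1L); j1 <- min(w, ceiling(max(allx)))
  i0 <- max(1L, floor(min(ally)) + 1L); i1 <- min(h, ceiling(max(ally)))
  out <- matrix(FALSE, h, w)
  if (j0 > j1 || i0 > i1) return(out)
  js <- j0:j1; is <- i0:i1
  px <- rep(js - 0.5, each = length(is))
  py <- rep(is - 0.5, times = length(js))
  hit <- points_in_polygon(px, py, rings)
  out[is, js] <- matrix(hit, length(is), length(js))
  out
}

# blobby circle polygon: radius modulated by low-order harmonics
blob_polygon <- function(cx, cy, r_px, seed, n_vert = 48) {
  with_seed(seed, {
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    a1 <- runif(1, 0.06, 0.13); a2 <- runif(1, 0.04, 0.09)
    phi <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
    r <- r_px * (1 + a1 * sin(3 * phi + ph1) + a2 * sin(5 * phi + ph2))
    cbind(x = round(cx + r * cos(phi), 2), y = round(cy + r * sin(phi), 2))
  })
}

#' Generate a synthetic pseudo-slide with ground truth
#'
#' Lays out a stroma matrix with a white glass margin, one adipocyte field,
#' and `n_lobules` epithelium blobs (each at least two 128-micron patch
#' cells across), then renders class textures, polygon annotations, and a
#' patch-grid truth map, all mutually consistent: the truth labels are
#' rasterised from the very polygons returned as annotations.
#'
#' @param n_lobules number of epithelium blobs (>= 0).
#' @param canvas_px canvas side in pixels (>= 1024).
#' @param mpp microns per pixel.
#' @param seed integer seed.
#' @param stain_shift optional additive RGB offset applied post-render.
#' @param target_um patch-cell edge for the truth map (microns).
#' @return object of class "synthetic_slide" with image, annotations
#'   (an annotation_set), truth_map (labels grid + geometry), mpp, seed.
#' @export
make_slide <- function(n_lobules, canvas_px, mpp = 0.25, seed = 1,
                       stain_shift = c(0, 0, 0), target_um = 128,
                       lobule_radius_um = 220) {
  stopifnot(n_lobules >= 0, canvas_px >= 1024, mpp > 0)
  native_px <- round(target_um / mpp)
  margin <- max(round(64 / mpp), round(canvas_px * 0.05))
  x0 <- margin; x1 <- canvas_px - margin   # tissue rect, 0-based coords
  um <- function(u) u / mpp                # microns -> pixels

  # adipocyte field: circle in the lower-right tissue quadrant
  r_adi <- max(um(140), canvas_px * 0.07)
  adi_c <- c(x1 - r_adi - um(40), x1 - r_adi - um(40))
  adi_poly <- blob_polygon(adi_c[1], adi_c[2], r_adi, sub_seed(seed, 900))

  # epithelium lobules: jittered-grid placement with guaranteed clearance;
  # greedy placement is restarted over shuffled candidate orders so any
  # admissible layout is found deterministically per seed
  r_lob <- um(lobule_radius_um)             # diameter ~3.4 patch cells
  sep <- um(2.1 * target_um)                # >= 2 full cells between blobs
  lob_centers <- NULL
  if (n_lobules > 0) {
    pad <- r_lob * 1.35 + um(20)
    lo <- x0 + pad; hi <- x1 - pad
    if (hi <= lo) stop("layout error: canvas too small for requested lobules", call. = FALSE)
    k <- max(ceiling(sqrt(n_lobules * 2)), 2)
    gxy <- seq(lo, hi, length.out = k)
    cand0 <- as.matrix(expand.grid(x = gxy, y = gxy))
    chosen <- matrix(numeric(0), 0, 2)
    for (restart in seq_len(80)) {
      cand <- with_seed(sub_seed(seed, 500 + restart),
                        cand0[sample.int(nrow(cand0)), , drop = FALSE])
      chosen <- matrix(numeric(0), 0, 2)
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, ] + with_seed(sub_seed(seed, 600 + restart * 97 + i),
                                   runif(2, -um(15), um(15)))
        if (sqrt(sum((p - adi_c)^2)) < r_lob + r_adi + sep) next
        if (nrow(chosen) &&
            any(sqrt(rowSums(sweep(chosen, 2, p)^2)) < 2 * r_lob * 1.3 + sep)) next
        chosen <- rbind(chosen, p)
        if (nrow(chosen) == n_lobules) break
      }
      if (nrow(chosen) == n_lobules) break
    }
    if (nrow(chosen) < n_lobules)
      stop("layout error: cannot place ", n_lobules, " lobules on this canvas", call. = FALSE)
    lob_centers <- chosen
  }
  lob_polys <- lapply(seq_len(n_lobules), function(i)
    blob_polygon(lob_centers[i, 1], lob_centers[i, 2], r_lob, sub_seed(seed, 700 + i)))

  stroma_rect <- cbind(x = c(x0, x1, x1, x0), y = c(x0, x0, x1, x1))

  # label canvas: 255 background, then stroma, adipocytes, epithelium
  lab <- matrix(255L, canvas_px, canvas_px)
  lab[(x0 + 1):x1, (x0 + 1):x1] <- 1L
  adi_mask <- rasterize_rings(adi_poly, canvas_px, canvas_px)
  lab[adi_mask] <- 2L
  lob_masks <- lapply(lob_polys, rasterize_rings, h = canvas_px, w = canvas_px)
  for (m in lob_masks) lab[m] <- 0L

  # render textures region by region
  img <- array(248, c(canvas_px, canvas_px, 3))
  str_tex <- render_texture(1L, x1 - x0, x1 - x0, mpp, sub_seed(seed, 11))
  for (k in 1:3) {
    block <- img[(x0 + 1):x1, (x0 + 1):x1, k]
    sel <- lab[(x0 + 1):x1, (x0 + 1):x1] == 1L
    block[sel] <- str_tex[, , k][sel]
    img[(x0 + 1):x1, (x0 + 1):x1, k] <- block
  }
  paint_region <- function(img, mask, class_id, obj_seed) {
    idx <- which(mask, arr.ind = TRUE)
    if (!nrow(idx)) return(img)
    i0 <- min(idx[, 1]); i1 <- max(idx[, 1]); j0 <- min(idx[, 2]); j1 <- max(idx[, 2])
    tex <- render_texture(class_id, i1 - i0 + 1, j1 - j0 + 1, mpp, obj_seed)
    sub <- mask[i0:i1, j0:j1]
    for (k in 1:3) {
      block <- img[i0:i1, j0:j1, k]
      block[sub] <- tex[, , k][sub]
      img[i0:i1, j0:j1, k] <- block
    }
    img
  }
  img <- paint_region(img, adi_mask & lab == 2L, 2L, sub_seed(seed, 12))
  for (i in seq_len(n_lobules))
    img <- paint_region(img, lob_masks[[i]], 0L, sub_seed(seed, 20 + i))
  img <- round(img)
  for (k in 1:3) img[, , k] <- clip255(img[, , k] + stain_shift[k])

  # annotations: epithelium blobs, adipocyte field, stroma rect with holes
  feats <- list()
  for (i in seq_len(n_lobules))
    feats[[length(feats) + 1]] <- list(polygon = list(lob_polys[[i]]),
                                       label = 0L, id = sprintf("lobule_%d", i))
  feats[[length(feats) + 1]] <- list(polygon = list(adi_poly), label = 2L, id = "adipose_1")
  feats[[length(feats) + 1]] <- list(polygon = c(list(stroma_rect), lob_polys, list(adi_poly)),
                                     label = 1L, id = "stroma_1")
  ann <- annotation_set(feats, mpp = mpp, dims = c(canvas_px, canvas_px))

  # truth map: majority label per patch cell, background when tissue < 50%
  rows <- floor(canvas_px / native_px); cols <- rows
  counts <- array(0L, c(rows, cols, 4))
  cell_sum <- function(binmat) {
    m <- binmat[seq_len(rows * native_px), seq_len(cols * native_px), drop = FALSE]
    m <- rowsum(m + 0L, rep(seq_len(rows), each = native_px))
    t(rowsum(t(m), rep(seq_len(cols), each = native_px)))
  }
  for (cl in 0:2) counts[, , cl + 1] <- cell_sum(lab == cl)
  counts[, , 4] <- cell_sum(lab == 255L)
  tissue <- counts[, , 1] + counts[, , 2] + counts[, , 3]
  truth <- matrix(255L, rows, cols)
  maj <- apply(counts[, , 1:3, drop = FALSE], c(1, 2), which.max) - 1L
  keep <- tissue >= native_px^2 / 2
  truth[keep] <- maj[keep]

  structure(list(
    image = img,
    annotations = ann,
    truth_map = list(labels = truth, native_px = native_px, mpp = mpp,
                     rows = rows, cols = cols),
    label_image = lab,
    mpp = mpp, seed = seed, n_lobules = as.integer(n_lobules)
  ), class = "synthetic_slide")
}

#' Generate an abstract class map with known epithelium components
#'
#' Direct fixture generator for lobule detection: places the requested
#' epithelium components (cell footprints, optionally with a one-cell
#' interior hole) disjointly on a rows x cols probability grid; remaining
#' cells are split between stroma and adipocytes.
#'
#' For `has_hole = TRUE` the footprint count includes the hole cell (e.g.
#' a count of 9 gives a 3 x 3 ring of 8 epithelium cells around a 1-cell
#' hole); such counts must be >= 9.
#'
#' @param rows,cols grid dimensions.
#' @param components list of c(cell_count, has_hole) pairs (has_hole 0/1).
#' @param seed integer seed.
#' @param native_px,mpp cell geometry attached to the returned map.
#' @return list with `map` (a class_map) and `components` (ground truth:
#'   per component the epithelium cells, hole cells, and counts).
#' @export
make_class_map <- function(rows, cols, components = list(), seed = 1,
                           native_px = 512, mpp = 0.25) {
  occupied <- matrix(FALSE, rows, cols)   # cells + 1-cell margin
  epi <- matrix(FALSE, rows, cols)
  truth <- list()
  shape_cells <- function(n, has_hole, sseed) {
    if (!has_hole) {
      # random-walk blob of n cells, 4-connected
      with_seed(sseed, {
        cells <- matrix(c(0L, 0L), 1, 2)
        while (nrow(cells) < n) {
          base <- cells[sample.int(nrow(cells), 1), ]
          step <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[sample.int(4, 1), ]
          cand <- base + step
          if (!any(cells[, 1] == cand[1] & cells[, 2] == cand[2]))
            cells <- rbind(cells, cand)
        }
        list(epi = cells, hole = matrix(integer(0), 0, 2))
      })
    } else {
      if (n < 9) stop("a component with a hole needs footprint >= 9 cells", call. = FALSE)
      m <- ceiling(n / 3)
      grid <- as.matrix(expand.grid(r = 1:3, c = 1:m))
      drop_n <- 3 * m - n
      if (drop_n > 0) {
        drop_rows <- c(3, 1)[seq_len(drop_n)]   # trim far column, keep ring
        keep <- !(grid[, 2] == m & grid[, 1] %in% drop_rows)
        grid <- grid[keep, , drop = FALSE]
      }
      hole <- matrix(c(2L, 2L), 1, 2)
      epi_cells <- grid[!(grid[, 1] == 2 & grid[, 2] == 2), , drop = FALSE]
      list(epi = epi_cells - 1L, hole = hole - 1L)   # 0-based offsets
    }
  }
  for (ci in seq_along(components)) {
    comp <- components[[ci]]
    n <- comp[1]; has_hole <- as.logical(comp[2])
    sh <- shape_cells(n, has_hole, sub_seed(seed, 100 + ci))
    foot <- rbind(sh$epi, sh$hole)
    placed <- FALSE
    for (attempt in seq_len(400)) {
      off <- with_seed(sub_seed(seed, 1000 + ci * 500 + attempt), {
        c(sample.int(rows, 1), sample.int(cols, 1))
      })
      cand <- cbind(foot[, 1] + off[1], foot[, 2] + off[2])
      if (any(cand < 1) || any(cand[, 1] > rows) || any(cand[, 2] > cols)) next
      # require a clear 1-cell margin so components never touch (8-conn)
      clash <- FALSE
      for (i in seq_len(nrow(cand))) {
        r0 <- max(1, cand[i, 1] - 1); r1 <- min(rows, cand[i, 1] + 1)
        c0 <- max(1, cand[i, 2] - 1); c1 <- min(cols, cand[i, 2] + 1)
        if (any(occupied[r0:r1, c0:c1])) { clash <- TRUE; break }
      }
      if (clash) next
      epi_cells <- cbind(sh$epi[, 1] + off[1], sh$epi[, 2] + off[2])
      hole_cells <- if (nrow(sh$hole)) cbind(sh$hole[, 1] + off[1], sh$hole[, 2] + off[2])
                    else matrix(integer(0), 0, 2)
      epi[epi_cells] <- TRUE
      occupied[cand] <- TRUE
      truth[[ci]] <- list(id = ci, epi_cells = epi_cells, hole_cells = hole_cells,
                          n_epi = nrow(epi_cells), n_footprint = n,
                          has_hole = has_hole)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("placement error: cannot place component ", ci, " disjointly", call. = FALSE)
  }
  probs <- with_seed(sub_seed(seed, 7), {
    p <- array(0, c(rows, cols, 3))
    n_cells <- rows * cols
    # non-epithelium cells: random stroma/adipocyte split
    other <- matrix(sample(c(1L, 2L), n_cells, replace = TRUE), rows, cols)
    lead <- matrix(runif(n_cells, 0.75, 0.98), rows, cols)
    rest1 <- matrix(runif(n_cells), rows, cols)
    for (i in seq_len(rows)) for (j in seq_len(cols)) {
      main <- if (epi[i, j]) 0L else other[i, j]
      pr <- numeric(3)
      pr[main + 1] <- lead[i, j]
      left <- 1 - lead[i, j]
      split <- rest1[i, j]
      pr[setdiff(1:3, main + 1)] <- left * c(split, 1 - split)
      p[i, j, ] <- pr
    }
    p
  })
  list(map = class_map(probs, native_px = native_px, mpp = mpp),
       components = truth)
}

#' Write a tile or slide image to PNG
#' @param x synthetic_tile, synthetic_slide, or H x W x 3 array (0-255).
#' @param path output file.
#' @export
write_image_png <- function(x, path) {
  img <- if (is.list(x) && !is.null(x$image)) x$image else x
  assert_rgb(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read an RGB PNG as a 0-255 array
#' @param path PNG file.
#' @return H x W x 3 numeric array on the 8-bit scale.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4L) img <- img[, , 1:3]
  round(img * 255)
}

#' Write a truth map or class-map label grid as CSV (row, col, label)
#' @param labels matrix of labels (0/1/2/255) or a truth_map list.
#' @param path output CSV.
#' @export
write_label_csv <- function(labels, path) {
  if (is.list(labels)) labels <- labels$labels
  df <- data.frame(row = rep(seq_len(nrow(labels)), ncol(labels)) - 1L,
                   col = rep(seq_len(ncol(labels)), each = nrow(labels)) - 1L,
                   label = as.vector(labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
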