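# Lobule detection: area filtering, hole filling, oracle equivalence,
# peri-lobular geometry.

test_that("area thresholds act in full-resolution-equivalent pixels", {
  # all-stroma map: nothing to detect
  empty <- make_class_map(10, 10, list(), seed = 1)$map
  det <- detect_lobules(empty, lobule_params(mpp = 0.25))
  expect_length(det$components, 0)
  expect_false(any(det$mask))

  # one isolated 512-px cell: 262,144 px < 400,000 -> removed
  one <- make_class_map(10, 10, list(c(1, 0)), seed = 2, native_px = 512)$map
  expect_length(detect_lobules(one, lobule_params(mpp = 0.25))$components, 0)

  # two connected cells: 524,288 px >= 400,000 -> survives
  two <- make_class_map(10, 10, list(c(2, 0)), seed = 2, native_px = 512)$map
  det2 <- detect_lobules(two, lobule_params(mpp = 0.25))
  expect_length(det2$components, 1)
  expect_identical(det2$components[[1]]$n_cells, 2L)
  expect_identical(det2$components[[1]]$area_px_fullres, 2 * 512^2)

  # 20x default threshold drops to 250,000
  expect_identical(lobule_params(mpp = 0.5)$min_object_px, 250000)
  expect_identical(lobule_params(mpp = 0.25)$min_object_px, 400000)
})

test_that("small interior holes are filled and join the component", {
  ring <- make_class_map(20, 20, list(c(9, 1)), seed = 3, native_px = 512)$map
  det <- detect_lobules(ring, lobule_params(mpp = 0.25))
  expect_length(det$components, 1)
  # 8 ring cells + 1 filled hole (262,144 px < 400,000)
  expect_identical(det$components[[1]]$n_cells, 9L)
  expect_identical(det$components[[1]]$area_px_fullres, 9 * 512^2)
  # polygon has a single exterior ring once the hole is filled
  expect_length(det$components[[1]]$polygon, 1)
})

test_that("detection matches the flood-fill oracle on random fixtures", {
  set.seed(99)
  for (fx in seq_len(50)) {
    spec_comps <- list()
    n_comp <- sample(0:4, 1)
    for (k in seq_len(n_comp)) {
      if (runif(1) < 0.25) spec_comps[[k]] <- c(sample(9:12, 1), 1)
      else spec_comps[[k]] <- c(sample(1:6, 1), 0)
    }
    cm <- make_class_map(22, 22, spec_comps, seed = 4000 + fx, native_px = 512)
    params <- lobule_params(mpp = 0.25)
    det <- detect_lobules(cm$map, params)

    epi <- class_map_pred(cm$map) == 0L
    want <- oracle_detect(epi, 512, params$min_object_px, params$max_hole_px, 8)

    expect_identical(length(det$components), length(want))
    got_keys <- sort(vapply(det$components, function(c) canonical_cells(c$cells), character(1)))
    want_keys <- sort(vapply(want, function(c) canonical_cells(c$cells), character(1)))
    expect_identical(got_keys, want_keys)
    expect_setequal(vapply(det$components, function(c) c$area_px_fullres, numeric(1)),
                    vapply(want, function(c) c$area, numeric(1)))
  }
})

test_that("raising the object threshold never adds lobules", {
  cm <- make_class_map(22, 22, list(c(2, 0), c(4, 0), c(9, 1), c(1, 0)),
                       seed = 5, native_px = 512)$map
  counts <- vapply(c(1, 250000, 400000, 800000, 3e6), function(thr)
    length(detect_lobules(cm, lobule_params(min_object_px = thr))$components),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  # every survivor satisfies the threshold it was filtered at
  det <- detect_lobules(cm, lobule_params(min_object_px = 400000))
  for (comp in det$components)
    expect_gte(comp$area_px_fullres, 400000)
})

test_that("component polygons enclose exactly their member cells", {
  cm <- make_class_map(15, 15, list(c(5, 0)), seed = 8, native_px = 512)$map
  det <- detect_lobules(cm, lobule_params(mpp = 0.25))
  comp <- det$components[[1]]
  # polygon area equals the cell-union area
  area <- sum(vapply(comp$polygon, function(r) nbtclassify:::shoelace_area(r), numeric(1)))
  expect_equal(abs(area), comp$area_px_fullres)
  # cell centres are inside, non-member centres outside
  for (i in seq_len(15)) for (j in seq_len(15)) {
    cx <- (j - 0.5) * 512; cy <- (i - 0.5) * 512
    member <- any(comp$cells[, 1] == i & comp$cells[, 2] == j)
    expect_identical(oracle_point_in_rings(cx, cy, comp$polygon), member)
  }
  # enlarged mask is the x32 rendering of the cell mask
  expect_identical(dim(det$mask_enlarged), dim(det$mask) * 32L)
})

test_that("peri-lobular rings expand the bounding box by the physical width", {
  lob <- list(id = 1L, cells = cbind(3:4, 3:4), n_cells = 2L,
              area_px_fullres = 2 * 512^2, area_um2 = 2 * 128^2,
              bbox = c(x0 = 1000, y0 = 1000, x1 = 2000, y1 = 2000),
              polygon = list(cbind(c(1000, 2000, 2000, 1000), c(1000, 1000, 2000, 2000))))
  reg <- perilobular_region(lob, 250, mpp = 0.25, mode = "bbox")
  expect_equal(unname(reg$outer_bbox), c(0, 0, 3000, 3000))
  # clipping to slide bounds
  reg2 <- perilobular_region(lob, 250, mpp = 0.25, mode = "bbox", slide_dims = c(2500, 2500))
  expect_equal(unname(reg2$outer_bbox), c(0, 0, 2500, 2500))
  # zero width -> empty ring
  expect_true(perilobular_region(lob, 0, mpp = 0.25)$empty)
  expect_error(perilobular_region(lob, -5, mpp = 0.25), "width_um")

  # ring + lobule partition the expanded region (even-odd on the rings)
  pts <- expand.grid(x = seq(100, 2900, by = 280), y = seq(100, 2900, by = 280))
  reg <- perilobular_region(lob, 250, mpp = 0.25, mode = "bbox")
  for (k in seq_len(nrow(pts))) {
    in_ring <- oracle_point_in_rings(pts$x[k], pts$y[k], reg$polygon)
    in_lob <- oracle_point_in_rings(pts$x[k], pts$y[k], lob$polygon)
    in_outer <- pts$x[k] >= 0 && pts$x[k] <= 3000 && pts$y[k] >= 0 && pts$y[k] <= 3000
    if (in_lob) expect_false(in_ring)
    expect_identical(in_outer, in_ring || in_lob)
  }
})

test_that("dilation-mode rings surround the lobule and exclude it", {
  cm <- make_class_map(12, 12, list(c(4, 0)), seed = 6, native_px = 512)$map
  det <- detect_lobules(cm, lobule_params(mpp = 0.25))
  comp <- det$components[[1]]
  reg <- perilobular_region(comp, 250, mpp = 0.25, mode = "dilation", detection = det)
  expect_false(reg$empty)
  lob_big <- matrix(FALSE, det$rows, det$cols)
  lob_big[comp$cells] <- TRUE
  f <- det$params$enlargement_factor
  big <- kronecker(lob_big + 0L, matrix(1L, f, f)) > 0
  expect_false(any(reg$ring_mask_enlarged & big))
  expect_gt(reg$ring_area_px_fullres, 0)
})

test_that("lobule exports carry tables and GeoJSON features", {
  cm <- make_class_map(15, 15, list(c(4, 0), c(2, 0)), seed = 10, native_px = 512)$map
  det <- detect_lobules(cm, lobule_params(mpp = 0.25))
  f <- withr::local_tempfile(fileext = ".csv")
  write_lobule_table(det, f)
  tab <- utils::read.csv(f)
  expect_identical(nrow(tab), length(det$components))
  expect_true(all(tab$area_px >= 400000))

  g <- withr::local_tempfile(fileext = ".geojson")
  write_qupath_geojson(det, g)
  doc <- jsonlite::fromJSON(g, simplifyVector = FALSE)
  expect_length(doc$features, length(det$components))
  expect_identical(doc$features[[1]]$properties$classification$name, "Epithelium")

  # combined export: red lobules plus yellow peri-lobular rings
  g2 <- withr::local_tempfile(fileext = ".geojson")
  write_lobule_geojson(det, g2, perilobular_width_um = 250)
  doc2 <- jsonlite::fromJSON(g2, simplifyVector = FALSE)
  expect_length(doc2$features, 2 * length(det$components))
  expect_identical(doc2$features[[2]]$properties$classification$name, "Perilobular")
  expect_identical(unlist(doc2$features[[2]]$properties$classification$color),
                   c(255L, 255L, 0L))
})
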