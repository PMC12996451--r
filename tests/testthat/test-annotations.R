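# GeoJSON I/O, centre-rule patch extraction, balanced sampling.

test_that("GeoJSON reading handles empty, simple and malformed inputs", {
  f <- withr::local_tempfile(fileext = ".geojson")
  writeLines('{"type": "FeatureCollection", "features": []}', f)
  ann <- read_annotations(f, mpp = 0.25, slide_dims = c(100, 100))
  expect_length(ann$features, 0)

  square <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", id = "sq1",
    geometry = list(type = "Polygon",
      coordinates = list(list(c(0, 0), c(100, 0), c(100, 100), c(0, 100), c(0, 0)))),
    properties = list(objectType = "annotation",
                      classification = list(name = "Epithelium", color = c(255, 0, 0))))))
  jsonlite::write_json(square, f, auto_unbox = TRUE, digits = NA)
  ann <- read_annotations(f, mpp = 0.25, slide_dims = c(200, 200))
  expect_length(ann$features, 1)
  expect_identical(ann$features[[1]]$label, 0L)
  expect_equal(abs(nbtclassify:::shoelace_area(ann$features[[1]]$polygon[[1]])), 10000)

  writeLines("{not json", f)
  expect_error(read_annotations(f), "parse error")

  # unknown label without remap errors; with remap it maps
  bad <- square
  bad$features[[1]]$properties$classification$name <- "Tumour"
  jsonlite::write_json(bad, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_annotations(f, slide_dims = c(200, 200)), "label error")
  ann <- read_annotations(f, slide_dims = c(200, 200), remap = list(Tumour = 1))
  expect_identical(ann$features[[1]]$label, 1L)

  # out-of-bounds vertex: error by default, clip on request
  oob <- square
  oob$features[[1]]$geometry$coordinates[[1]][[2]] <- c(500, 0)
  jsonlite::write_json(oob, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_annotations(f, slide_dims = c(200, 200)), "bounds error")
  ann <- read_annotations(f, slide_dims = c(200, 200), oob = "clip")
  expect_lte(max(ann$features[[1]]$polygon[[1]][, 1]), 200)
})

test_that("GeoJSON write -> read is the identity on annotation sets", {
  ring_out <- cbind(x = c(10, 90, 90, 10), y = c(10, 10, 90, 90))
  hole <- cbind(x = c(40, 60, 60, 40), y = c(40, 40, 60, 60))
  tri <- cbind(x = c(120, 180, 150), y = c(20, 30, 80))
  ann <- annotation_set(list(
    list(polygon = list(ring_out, hole), label = 1L, id = "stroma_hole"),
    list(polygon = list(tri), label = 0L, id = "epi_tri"),
    list(polygon = list(tri + 50), label = 2L, id = "adi_tri")),
    mpp = 0.25, dims = c(400, 400))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_qupath_geojson(ann, f)
  back <- read_annotations(f, mpp = 0.25, slide_dims = c(400, 400))
  expect_equal(back, ann)

  # QuPath dialect fields present with the red/green/blue convention
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_identical(doc$features[[2]]$properties$objectType, "annotation")
  expect_identical(doc$features[[2]]$properties$classification$name, "Epithelium")
  expect_identical(unlist(doc$features[[2]]$properties$classification$color), c(255L, 0L, 0L))
  expect_identical(unlist(doc$features[[1]]$properties$classification$color), c(0L, 255L, 0L))
  expect_identical(unlist(doc$features[[3]]$properties$classification$color), c(0L, 0L, 255L))
})

test_that("class-map cells export as axis-aligned squares", {
  probs <- array(NA_real_, c(1, 1, 3))
  probs[1, 1, ] <- c(0.8, 0.1, 0.1)
  map <- class_map(probs, native_px = 512, mpp = 0.25)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_qupath_geojson(map, f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_length(doc$features, 1)
  coords <- do.call(rbind, lapply(doc$features[[1]]$geometry$coordinates[[1]], unlist))
  expect_equal(coords[1:4, ], cbind(c(0, 512, 512, 0), c(0, 0, 512, 512)))
  expect_identical(unlist(doc$features[[1]]$properties$classification$color), c(255L, 0L, 0L))
})

test_that("centre-rule extraction matches full cover, empty and conflicts", {
  img <- array(200, c(1024, 1024, 3))
  full <- annotation_set(list(list(
    polygon = list(cbind(c(0, 1024, 1024, 0), c(0, 0, 1024, 1024))),
    label = 1L, id = "all")), mpp = 0.25, dims = c(1024, 1024))
  ps <- extract_labeled_patches(img, full, 512, keep_pixels = FALSE)
  expect_length(ps, 4)
  expect_true(all(nbtclassify:::patch_labels(ps) == 1L))

  none <- annotation_set(list(), mpp = 0.25, dims = c(1024, 1024))
  expect_length(extract_labeled_patches(img, none, 512), 0)

  # conflicting overlap drops the centre; same-label overlap keeps it
  sq <- cbind(c(0, 1024, 1024, 0), c(0, 0, 1024, 1024))
  conflict <- annotation_set(list(
    list(polygon = list(sq), label = 0L, id = "a"),
    list(polygon = list(sq), label = 1L, id = "b")), dims = c(1024, 1024))
  expect_length(extract_labeled_patches(img, conflict, 512), 0)
  agree <- annotation_set(list(
    list(polygon = list(sq), label = 0L, id = "a"),
    list(polygon = list(sq), label = 0L, id = "b")), dims = c(1024, 1024))
  expect_length(extract_labeled_patches(img, agree, 512), 4)
})

test_that("centre rule equals the brute-force point-in-polygon oracle", {
  img <- array(200, c(320, 320, 3))
  patch <- 32
  set.seed(77)
  for (fx in seq_len(50)) {
    feats <- lapply(seq_len(6), function(i) {
      poly <- random_polygon(runif(1, 20, 300), runif(1, 20, 300),
                             rmin = 15, rmax = 70, n_vert = sample(3:7, 1))
      list(polygon = list(poly), label = sample(0:2, 1), id = paste0("p", i))
    })
    ann <- annotation_set(feats, mpp = 1, dims = c(320, 320))
    ps <- extract_labeled_patches(img, ann, patch, keep_pixels = FALSE)
    got <- sort(vapply(ps$patches, function(p)
      sprintf("%d_%d_%d", p$origin[1], p$origin[2], p$label), character(1)))

    want <- character(0)
    for (gx in 0:9) for (gy in 0:9) {
      cx <- gx * patch + patch / 2; cy <- gy * patch + patch / 2
      labs <- integer(0)
      for (f in feats)
        if (oracle_point_in_rings(cx, cy, f$polygon)) labs <- c(labs, f$label)
      if (length(labs) >= 1 && length(unique(labs)) == 1)
        want <- c(want, sprintf("%d_%d_%d", gx * patch, gy * patch, labs[1]))
    }
    expect_identical(got, sort(want))
  }
})

test_that("balanced sampling honours the min rule, determinism and uniqueness", {
  make_ps <- function(n_by_class, source = "w1") {
    patches <- list(); k <- 0
    for (cl in 0:2) for (i in seq_len(n_by_class[cl + 1])) {
      k <- k + 1
      patches[[k]] <- list(pixels = NULL, origin = c(i * 32, cl * 32),
                           patch_px = 32, mpp = 1, label = cl, source_id = source)
    }
    patch_set(patches)
  }
  ps <- make_ps(c(300, 280, 260))
  sel <- balanced_sample(ps, 250, seed = 5)
  expect_identical(sel$counts, c(250L, 250L, 250L))

  short <- make_ps(c(4, 20, 20))
  expect_warning(sel2 <- balanced_sample(short, 10, seed = 5), "keeping all")
  expect_identical(sel2$counts, c(4L, 10L, 10L))

  keys <- function(s) vapply(s$patches, function(p)
    paste(p$source_id, p$origin[1], p$origin[2]), character(1))
  expect_false(anyDuplicated(keys(sel)) > 0)

  big <- make_ps(c(1000, 1000, 1000))
  a <- balanced_sample(big, 100, seed = 1)
  b <- balanced_sample(big, 100, seed = 1)
  c <- balanced_sample(big, 100, seed = 2)
  expect_identical(keys(a), keys(b))
  expect_false(identical(keys(a), keys(c)))
})
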