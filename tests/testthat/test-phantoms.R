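# Synthetic lesion phantoms: determinism, geometry, contrast behaviour,
# dataset splitting and disk round-trips.

test_that("a fixed seed gives bit-identical phantoms", {
  sp <- phantom_spec(image_size = 64, radius_range = c(3, 12),
                     background_texture_scale = 3, seed = 77)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
})

test_that("an undeformed disc has the expected rasterized area", {
  sp <- phantom_spec(image_size = 64, n_lesions = c(1, 1),
                     radius_range = c(10, 10), deform = 0,
                     background_texture_scale = 3, seed = 5)
  for (s in 1:5) {
    sp$seed <- s
    ph <- generate_phantom(sp)
    area <- sum(ph$mask)
    expect_gte(area, pi * 9^2)
    expect_lte(area, pi * 11^2)
  }
})

test_that("zero contrast renders lesions invisible", {
  # mean intensity inside vs outside the mask differs by < 3 standard errors
  diffs <- vapply(1:60, function(s) {
    sp <- phantom_spec(image_size = 64, radius_range = c(5, 14), contrast = 0,
                       background_texture_scale = 3, seed = 1000 + s)
    ph <- generate_phantom(sp)
    mean(ph$image[ph$mask == 1]) - mean(ph$image[ph$mask == 0])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-3)
})

test_that("lesion sizes span a wide range across seeds", {
  areas <- vapply(1:200, function(s) {
    sp <- phantom_spec(seed = 3000 + s)    # default 256 px, radii 4-60
    sum(generate_phantom(sp)$mask)
  }, numeric(1))
  q <- quantile(areas, c(0.05, 0.95))
  expect_gte(q[[2]] / q[[1]], 50)
})

test_that("radii too large for the canvas are rejected", {
  expect_error(generate_phantom(phantom_spec(image_size = 64)), "too large")
})

test_that("dataset generation splits, persists and round-trips exactly", {
  sp <- phantom_spec(image_size = 32, radius_range = c(3, 8),
                     background_texture_scale = 3, seed = 21)
  out <- file.path(tempdir(), "phantoms-a")
  man <- generate_dataset(10, sp, 0.8, out)
  j <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_length(j$train, 8)
  expect_length(j$test, 2)
  # ceiling rule
  out2 <- file.path(tempdir(), "phantoms-b")
  generate_dataset(5, sp, 0.8, out2)
  j2 <- jsonlite::read_json(file.path(out2, "manifest.json"))
  expect_length(j2$train, 4)
  expect_length(j2$test, 1)
  expect_error(generate_dataset(1, sp, 0.8, tempdir()), "at least 2")
  # masks survive the 8-bit round trip exactly; images within quantization
  items <- load_manifest(file.path(out, "manifest.json"), "all")
  expect_length(items, 10)
  id1 <- which(vapply(j$train, function(x) x$id, "") == "phantom_0001")
  s1 <- sp; s1$seed <- sp$seed + 1
  ph <- generate_phantom(s1)
  stored <- c(lapply(j$train, function(x) x$id), lapply(j$test, function(x) x$id))
  all_items <- load_manifest(file.path(out, "manifest.json"), "all")
  pos <- which(vapply(all_items, function(x) x$id, "") == "phantom_0001")
  expect_identical(all_items[[pos]]$mask, ph$mask + 0L)
  expect_lte(max(abs(all_items[[pos]]$image - ph$image)), 1 / 255)
  # re-running with the same master seed reproduces the manifest
  out3 <- file.path(tempdir(), "phantoms-c")
  generate_dataset(10, sp, 0.8, out3)
  j3 <- jsonlite::read_json(file.path(out3, "manifest.json"))
  expect_identical(lapply(j$train, function(x) x$id),
                   lapply(j3$train, function(x) x$id))
})
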