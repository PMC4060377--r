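test_that("RGB images are reduced to the green channel and scaled to [0,1]", {
  arr <- array(0, dim = c(70, 70, 3))
  arr[1, 1, ] <- c(10, 200, 30) / 255
  p <- tempfile(fileext = ".png")
  png::writePNG(arr, p)
  img <- load_image(p)
  expect_equal(img$pixels[1, 1], 200 / 255)
  expect_equal(img$pixels[2, 2], 0)
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
})

test_that("an all-black image canonicalizes to exactly zero", {
  p <- tempfile(fileext = ".png")
  png::writePNG(matrix(0, 64, 64), p)
  expect_true(all(load_image(p)$pixels == 0))
})

test_that("16-bit intensities are scaled by the bit-depth maximum", {
  p <- tempfile(fileext = ".tif")
  m <- matrix(0.5, 64, 64); m[1, 1] <- 1  # 65535 -> 1.0
  tiff::writeTIFF(m, p, bits.per.sample = 16L)
  img <- load_image(p)
  expect_equal(img$pixels[1, 1], 1.0)   # 65535 -> exactly 1.0
  expect_lte(abs(img$pixels[2, 2] - 0.5), 1 / 65535)
})

test_that("canonicalization is idempotent on grayscale [0,1] images", {
  set.seed(4)
  m <- round(matrix(runif(64 * 64), 64, 64) * 255) / 255
  p <- tempfile(fileext = ".png")
  png::writePNG(m, p)
  expect_equal(load_image(p)$pixels, m, ignore_attr = TRUE)
})

test_that("image loading errors name the path and class", {
  expect_error(load_image("no/such/file.png"), "no/such/file.png",
               class = "cliftcad_io_error")
  expect_error(well_image(matrix(0.5, 10, 10)), class = "cliftcad_validation_error")
  expect_error(well_image(matrix(2, 64, 64)), class = "cliftcad_validation_error")
  expect_error(well_image(matrix(0.5, 64, 64), magnification_scale = 0),
               class = "cliftcad_validation_error")
})

make_records <- function(n_wells = 2, per_well = 5) {
  do.call(rbind, lapply(seq_len(n_wells), function(w) {
    data.frame(well_id = sprintf("W%02d", w),
               image_path = sprintf("img/W%02d_%d.png", w, seq_len(per_well)),
               magnification_scale = 1,
               image_label = ifelse(w == 1, "positive", "negative"),
               well_label = ifelse(w == 1, "positive", "negative"))
  }))
}

test_that("manifest validates structure and groups wells", {
  m <- clift_manifest(make_records())
  expect_s3_class(m, "clift_manifest")
  expect_equal(nrow(m$records), 10)
  expect_equal(length(unique(m$records$well_id)), 2)

  dup <- make_records(); dup$image_path[2] <- dup$image_path[1]
  expect_error(clift_manifest(dup), "duplicate", class = "cliftcad_validation_error")

  bad <- make_records(); bad$image_label[1] <- "POS"
  expect_error(clift_manifest(bad), "positive, negative",
               class = "cliftcad_validation_error")

  con <- make_records(); con$image_label[1] <- "negative"
  expect_error(clift_manifest(con), "conflict", class = "cliftcad_validation_error")

  noid <- make_records(); noid$well_id[3] <- ""
  expect_error(clift_manifest(noid), class = "cliftcad_validation_error")
})

test_that("manifest write/load round-trips records and annotations", {
  rec <- make_records()
  rec$width <- 512; rec$height <- 384
  cells <- list()
  cells[[rec$image_path[1]]] <- data.frame(x = c(10.5, 100), y = c(20, 30.25),
                                           label = c("positive", "negative"))
  m <- clift_manifest(rec, cells)
  pj <- tempfile(fileext = ".json")
  write_manifest(m, pj, "json")
  m2 <- load_manifest(pj)
  expect_equal(m2$records$well_id, m$records$well_id)
  expect_equal(m2$records$image_path, m$records$image_path)
  expect_equal(m2$records$image_label, m$records$image_label)
  expect_equal(m2$cells[[rec$image_path[1]]]$x, cells[[rec$image_path[1]]]$x)
  expect_equal(m2$cells[[rec$image_path[1]]]$label,
               cells[[rec$image_path[1]]]$label)

  pc <- tempfile(fileext = ".csv")
  write_manifest(m, pc, "csv")
  m3 <- load_manifest(pc)
  expect_equal(m3$records$image_path, m$records$image_path)
  expect_equal(m3$records$well_label, m$records$well_label)

  # annotations outside image bounds are rejected when bounds are known
  bad <- cells
  bad[[rec$image_path[1]]]$x[1] <- 600
  expect_error(clift_manifest(rec, bad), "bounds",
               class = "cliftcad_validation_error")
})

test_that("dataset_summary reproduces class percentages from counts", {
  # 74 positives of 342 images and 928 of 1487 cells, as in a typical
  # annotated CLIFT cohort
  rec <- data.frame(well_id = "W1", image_path = sprintf("i%d.png", 1:342),
                    magnification_scale = 1,
                    image_label = rep(c("positive", "negative"), c(74, 268)))
  s <- dataset_summary(clift_manifest(rec), "images")
  expect_equal(s$n, 342); expect_equal(s$n_positive, 74)
  expect_equal(s$pct_positive, 21.6)
  expect_equal(s$pct_negative, 78.4)

  cells <- list("i1.png" = data.frame(
    x = 0, y = 0, label = rep(c("positive", "negative"), c(928, 559))))
  rec2 <- data.frame(well_id = "W1", image_path = "i1.png",
                     magnification_scale = 1)
  s2 <- dataset_summary(clift_manifest(rec2, cells), "cells")
  expect_equal(s2$pct_positive, 62.4)
  expect_equal(s2$pct_negative, 37.6)

  rec3 <- data.frame(well_id = "W1", image_path = sprintf("j%d.png", 1:10),
                     magnification_scale = 1, image_label = "negative")
  s3 <- dataset_summary(clift_manifest(rec3), "images")
  expect_equal(s3$pct_positive, 0.0)

  expect_error(dataset_summary(clift_manifest(rec3), "wells"),
               class = "cliftcad_validation_error")
})

test_that("summary percentages at each level sum to ~100", {
  set.seed(9)
  for (np in c(1, 3, 7, 333)) {
    rec <- data.frame(well_id = "W1",
                      image_path = sprintf("k%d.png", 1:(np + 11)),
                      magnification_scale = 1,
                      image_label = rep(c("positive", "negative"), c(np, 11)))
    s <- dataset_summary(clift_manifest(rec), "images")
    expect_lte(abs(s$pct_positive + s$pct_negative - 100), 0.1)
  }
})

test_that("half-up rounding matches reporting convention on ties", {
  expect_equal(round_half_up(21.65, 1), 21.7)
  expect_equal(round_half_up(17.55, 1), 17.6)
  expect_equal(round_half_up(98.45, 1), 98.5)
  expect_equal(round_half_up(2.5, 0), 3)
})
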