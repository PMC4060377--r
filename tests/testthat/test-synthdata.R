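test_that("generation is deterministic: same seed, identical bytes", {
  cfg <- synth_config(seed = 7, n_wells = 2, images_per_well = 2,
                      image_size = c(192, 160))
  d1 <- tempfile(); d2 <- tempfile()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
})

test_that("a fully negative dataset has only negative labels", {
  d <- generate_dataset(synth_config(seed = 3, n_wells = 3,
                                     fraction_positive_wells = 0,
                                     images_per_well = 2,
                                     image_size = c(192, 160)), tempfile())
  expect_true(all(d$manifest$records$image_label == "negative"))
  labs <- unlist(lapply(d$manifest$cells, function(a) a$label))
  expect_true(all(labs == "negative"))
})

test_that("image labels inherit the well label and cell labels track the kinetoplast", {
  d <- generate_dataset(synth_config(seed = 8, n_wells = 4,
                                     fraction_positive_wells = 0.5,
                                     images_per_well = 3,
                                     image_size = c(192, 160)), tempfile())
  r <- d$manifest$records
  for (w in unique(r$well_id)) {
    expect_equal(length(unique(r$image_label[r$well_id == w])), 1)
  }
  for (id in names(d$truth)) {
    tr <- d$truth[[id]]
    expect_equal(tr$image_label, tr$well_label)
    for (cl in tr$cells) {
      has_k <- any(vapply(cl$components, function(cm) cm$type == "kinetoplast",
                          TRUE))
      expect_equal(cl$label, if (has_k) "positive" else "negative")
    }
  }
})

test_that("per-image cell counts are truncated-Poisson with the configured mean", {
  d <- generate_dataset(synth_config(seed = 13, n_wells = 20,
                                     images_per_well = 5,
                                     mean_cells_per_image = 8), tempfile())
  counts <- vapply(d$truth, function(tr) length(tr$cells), 0)
  expect_equal(length(counts), 100)
  expect_true(all(counts >= 1))
  expect_gte(mean(counts), 7.2)  # 99% band of a Poisson(8) mean over n=100
  expect_lte(mean(counts), 8.8)
})

test_that("well prevalence converges to the configured fraction", {
  d <- generate_dataset(synth_config(seed = 5, n_wells = 200,
                                     fraction_positive_wells = 0.25,
                                     images_per_well = 1,
                                     mean_cells_per_image = 2,
                                     image_size = c(128, 96)), tempfile())
  r <- d$manifest$records
  frac <- mean(r$well_label[!duplicated(r$well_id)] == "positive")
  expect_gte(frac, 0.25 - 3 * sqrt(0.25 * 0.75 / 200))
  expect_lte(frac, 0.25 + 3 * sqrt(0.25 * 0.75 / 200))
})

test_that("in positive wells the kinetoplast rate per cell matches the config", {
  d <- generate_dataset(synth_config(seed = 17, n_wells = 6,
                                     fraction_positive_wells = 1,
                                     images_per_well = 3,
                                     image_size = c(256, 192)), tempfile())
  cells <- unlist(lapply(d$truth, `[[`, "cells"), recursive = FALSE)
  frac <- mean(vapply(cells, function(cl) cl$label == "positive", TRUE))
  n <- length(cells)
  expect_gte(frac, 0.9 - 3 * sqrt(0.9 * 0.1 / n))
  expect_lte(frac, min(1, 0.9 + 3 * sqrt(0.9 * 0.1 / n)))
})

test_that("render_cell puts the global maximum at the kinetoplast", {
  cell <- list(x = 60, y = 50, orientation = 0.8, length = 40,
               cytoplasm = 0.2,
               components = list(list(type = "kinetoplast",
                                      x = 60 + 0.35 * 40 * cos(0.8),
                                      y = 50 + 0.35 * 40 * sin(0.8),
                                      sigma = 2.5, peak = 0.9)))
  rc <- render_cell(cell, matrix(0, 120, 120))
  am <- which(rc$canvas == max(rc$canvas), arr.ind = TRUE)  # argmax scan oracle
  k <- cell$components[[1]]
  d <- sqrt((am[, 2] - 1 - k$x)^2 + (am[, 1] - 1 - k$y)^2)
  expect_lte(min(d), 1.5 * 2.5)
  expect_equal(rc$components$type, "kinetoplast")
})

test_that("render_cell respects intensity bounds and additivity", {
  plain <- list(x = 40, y = 40, orientation = 0, length = 30, cytoplasm = 0.2,
                components = list())
  rc <- render_cell(plain, matrix(0, 80, 80))
  expect_lte(max(rc$canvas), 0.2 + 1e-9)

  other <- list(x = 120, y = 120, orientation = 1, length = 30,
                cytoplasm = 0.15, components = list())
  canvas <- matrix(0, 160, 160)
  both <- render_cell(other, render_cell(
    modifyList(plain, list(x = 40, y = 40)), canvas)$canvas)$canvas
  alone1 <- render_cell(modifyList(plain, list(x = 40, y = 40)),
                        matrix(0, 160, 160))$canvas
  alone2 <- render_cell(other, matrix(0, 160, 160))$canvas
  expect_equal(both, alone1 + alone2)  # disjoint, below saturation

  expect_error(render_cell(modifyList(plain, list(x = 5)), matrix(0, 80, 80)),
               class = "cliftcad_validation_error")
})

test_that("kinetoplast rendered area scales ~4x between magnifications", {
  area_at <- function(scale) {
    k <- list(type = "kinetoplast", x = 80, y = 80, sigma = 2.5 * scale,
              peak = 0.9)
    cell <- list(x = 80, y = 80, orientation = 0, length = 40 * scale,
                 cytoplasm = 0, components = list(k))
    rc <- render_cell(cell, matrix(0, 160, 160))
    sum(rc$canvas > 0.15)   # fixed-level area oracle on the noiseless render
  }
  ratio <- area_at(1) / area_at(0.5)
  expect_gte(ratio, 3); expect_lte(ratio, 5)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(n_wells = 0), class = "cliftcad_validation_error")
  expect_error(synth_config(images_per_well = 0), class = "cliftcad_validation_error")
  expect_error(synth_config(fraction_positive_wells = 1.2),
               class = "cliftcad_validation_error")
  expect_error(synth_config(kinetoplast_peak = 0.04, background_level = 0.05),
               class = "cliftcad_validation_error")
})
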