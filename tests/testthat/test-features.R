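# build a minimal cell_crop by hand for block-level tests
fake_cell <- function(crop, mask = NULL, candidates = NULL,
                      body_area = sum(mask), body_mean = mean(crop[mask]),
                      major = 40) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(crop), ncol(crop))
  structure(list(well_id = "W01", image_id = "W01_I01", cell_id = "W01_I01_C01",
                 crop = crop, body_mask = mask, candidates = candidates,
                 cell_centroid = c(x = (ncol(crop) - 1) / 2,
                                   y = (nrow(crop) - 1) / 2),
                 major_axis_len = major, orientation = 0,
                 body_area_px = body_area, body_mean = body_mean,
                 mask_img = mask, mask_offset = c(row = 1L, col = 1L),
                 crop_origin = c(row = 1L, col = 1L), crop_factor = 1,
                 magnification_scale = 1, true_label = NULL),
            class = "cell_crop")
}

disk_coords <- function(cx, cy, r) {
  g <- expand.grid(row = seq_len(cy + r + 2), col = seq_len(cx + r + 2))
  as.matrix(g[(g$row - cy)^2 + (g$col - cx)^2 <= r^2, c("row", "col")])
}

test_that("histogram features on degenerate crops", {
  m <- matrix(0.2, 20, 20)
  h <- histogram_features(m, matrix(TRUE, 20, 20))
  expect_equal(unname(h), c(0, 0.2, 0.2, 0, 0))

  m2 <- matrix(0, 10, 10); m2[5, 5] <- 1
  h2 <- histogram_features(m2, matrix(TRUE, 10, 10))
  expect_equal(h2[["hist_high_frac"]], 0.01)
  expect_equal(h2[["hist_max"]], 1)

  set.seed(1)
  h3 <- histogram_features(matrix(runif(400), 20, 20), matrix(TRUE, 20, 20))
  expect_lte(h3[["hist_entropy"]], log2(32))
  expect_error(histogram_features(m, matrix(FALSE, 20, 20)),
               class = "cliftcad_validation_error")
})

test_that("GLCM of a constant crop is a single-cell matrix", {
  g <- glcm_features(matrix(0.5, 16, 16), matrix(TRUE, 16, 16))
  for (d in 1:2) {
    expect_equal(g[[paste0("glcm_energy_d", d)]], 1)
    expect_equal(g[[paste0("glcm_contrast_d", d)]], 0)
    expect_equal(g[[paste0("glcm_homogeneity_d", d)]], 1)
    expect_equal(g[[paste0("glcm_entropy_d", d)]], 0)
  }
})

test_that("checkerboard contrast at distance 1, angle 0 equals 31^2", {
  n <- 16
  chk <- outer(1:n, 1:n, function(i, j) ifelse((i + j) %% 2 == 0, 31 / 32, 0))
  P <- glcm_matrix(chk, matrix(TRUE, n, n), drow = 0, dcol = 1)
  st <- cliftcad:::glcm_stats(P)
  expect_equal(st[["contrast"]], 31^2)
  expect_equal(st[["homogeneity"]], 1 / (1 + 31^2))
})

test_that("GLCM matches direct pair enumeration on small random crops", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    crop <- matrix(runif(n * n), n, n)
    mask <- matrix(runif(n * n) > 0.25, n, n)
    drow <- sample(c(-2, -1, 0), 1); dcol <- sample(0:2, 1)
    if (drow == 0 && dcol == 0) dcol <- 1
    got <- glcm_matrix(crop, mask, drow, dcol)
    # oracle: enumerate every pixel pair explicitly
    q <- pmin(floor(crop * 32), 31)
    want <- matrix(0, 32, 32)
    for (r in seq_len(n)) for (c in seq_len(n)) {
      r2 <- r + drow; c2 <- c + dcol
      if (r2 < 1 || c2 < 1 || r2 > n || c2 > n) next
      if (!mask[r, c] || !mask[r2, c2]) next
      i <- q[r, c] + 1; j <- q[r2, c2] + 1
      want[i, j] <- want[i, j] + 1
      want[j, i] <- want[j, i] + 1
    }
    if (sum(want) > 0) want <- want / sum(want)
    expect_equal(got, want, label = sprintf("rep %d", rep))
  }
})

test_that("Fourier features: conventions, normalization, monotonicity", {
  expect_equal(unname(fourier_features(matrix(0, 30, 30))), numeric(9))

  set.seed(2)
  f <- fourier_features(matrix(runif(40 * 40), 40, 40))
  expect_equal(sum(f[1:8]), 1, tolerance = 1e-9)

  # more fluorescent objects -> more high-frequency energy
  one <- spot_image(list(list(x = 32, y = 32, sigma = 3, peak = 1)),
                    w = 64, h = 64, background = 0)$pixels
  four_spots <- list(list(x = 20, y = 20, sigma = 3, peak = 0.25),
                     list(x = 44, y = 20, sigma = 3, peak = 0.25),
                     list(x = 20, y = 44, sigma = 3, peak = 0.25),
                     list(x = 44, y = 44, sigma = 3, peak = 0.25))
  four <- spot_image(four_spots, w = 64, h = 64, background = 0)$pixels
  expect_gt(fourier_features(four)[["ft_centroid_radius"]],
            fourier_features(one)[["ft_centroid_radius"]])
})

test_that("LBP histograms are normalized and flat on constant crops", {
  l <- lbp_features(matrix(0.3, 24, 24), matrix(TRUE, 24, 24))
  expect_equal(sum(l[1:10]), 1, tolerance = 1e-9)
  expect_equal(sum(l[11:28]), 1, tolerance = 1e-9)
  # all-neighbors-equal -> all bits set -> "all ones" uniform bin
  expect_equal(l[["lbp_p8r1_b8"]], 1)
  expect_equal(l[["lbp_p16r2_b16"]], 1)
})

test_that("LBP histograms are invariant to right-angle rotations", {
  set.seed(21)
  crop <- matrix(runif(28 * 28), 28, 28)
  mask <- matrix(TRUE, 28, 28)
  base <- lbp_features(crop, mask)
  r90 <- lbp_features(rot90(crop), rot90(mask))
  r180 <- lbp_features(rot90(rot90(crop)), rot90(rot90(mask)))
  expect_equal(base, r90, tolerance = 1e-9)
  expect_equal(base, r180, tolerance = 1e-9)
})

test_that("morphology features follow the brightest candidate", {
  corrected <- matrix(0.9, 40, 40)
  disk <- disk_coords(20, 20, 4)
  cand <- cliftcad:::make_candidate(disk, corrected)
  expect_gte(cand$compactness, 0.85)      # rasterized-circle perimeter oracle
  expect_lte(cand$compactness, 1.2)

  dim_cand <- cliftcad:::make_candidate(disk_coords(10, 10, 3),
                                        matrix(0.5, 40, 40))
  cell <- fake_cell(matrix(0.3, 40, 40), matrix(TRUE, 40, 40),
                    candidates = list(dim_cand, cand),
                    body_area = 400, body_mean = 0.3)
  mf <- morphology_features(cell)
  expect_equal(mf[["morph_n_candidates"]], 2)
  expect_equal(mf[["morph_max_intensity"]], 0.9)  # brightest drives the block
  expect_equal(mf[["morph_area_frac"]], nrow(disk) / 400)
  expect_lte(mf[["morph_eccentricity"]], 0.35)    # near-circular
  # discretization keeps a radius-4 disk's solidity below 1 (the reference
  # regionprops convention gives 0.86 for the same pixel set)
  expect_gte(mf[["morph_solidity"]], 0.80)

  # candidate spanning the whole body -> area fraction 1
  whole <- fake_cell(matrix(0.8, 20, 20), matrix(TRUE, 20, 20),
                     candidates = list(cliftcad:::make_candidate(
                       which(matrix(TRUE, 20, 20), arr.ind = TRUE),
                       matrix(0.8, 20, 20))),
                     body_area = 400, body_mean = 0.8)
  expect_equal(morphology_features(whole)[["morph_area_frac"]], 1)

  expect_error(morphology_features(fake_cell(matrix(0.1, 9, 9))),
               class = "cliftcad_validation_error")
})

test_that("the full feature vector is deterministic, finite and bounded", {
  sc <- single_cell_image(positive = TRUE, seed = 12)
  cells <- extract_cells(sc$image, prescreen_image(sc$image)$candidates)
  v1 <- extract_features(cells[[1]])
  v2 <- extract_features(cells[[1]])
  expect_identical(v1, v2)
  expect_length(v1, 60)
  expect_equal(names(v1), feature_names())
  expect_true(all(is.finite(v1)))
  expect_gte(v1[["hist_high_frac"]], 0); expect_lte(v1[["hist_high_frac"]], 1)
  expect_gte(v1[["morph_area_frac"]], 0); expect_lte(v1[["morph_area_frac"]], 1)
  expect_equal(sum(v1[paste0("ft_band_", 1:8)]), 1, tolerance = 1e-9)
  expect_equal(sum(v1[paste0("lbp_p8r1_b", 0:9)]), 1, tolerance = 1e-9)
  expect_equal(sum(v1[paste0("lbp_p16r2_b", 0:17)]), 1, tolerance = 1e-9)
})

test_that("positive and negative cell populations separate on key features", {
  # positive cells (kinetoplast) vs hard negatives (basal body only)
  feats <- function(positive, n) {
    out <- NULL
    for (i in seq_len(n)) {
      sc <- single_cell_image(positive = positive, basal = !positive,
                              nucleus = (i %% 2 == 0), seed = 100 + i,
                              orientation = i * 0.37)
      cells <- extract_cells(sc$image, prescreen_image(sc$image)$candidates)
      if (!length(cells)) next
      out <- rbind(out, extract_features(cells[[1]]))
    }
    out
  }
  fp <- feats(TRUE, 30); fn <- feats(FALSE, 30)
  expect_gte(nrow(fp), 20); expect_gte(nrow(fn), 10)
  auc <- auc_oracle(fp[, "hist_high_frac"], fn[, "hist_high_frac"])
  expect_gt(auc, 0.9)
})

test_that("features are stable across magnification for the same cell", {
  v <- list()
  for (s in c(1, 0.5)) {
    sc <- single_cell_image(positive = TRUE, scale = s, seed = 33, noise = 0,
                            w = 128, h = 128)
    cells <- extract_cells(sc$image, prescreen_image(sc$image)$candidates)
    v[[as.character(s)]] <- extract_features(cells[[1]])
  }
  scn <- single_cell_image(positive = FALSE, basal = TRUE, seed = 33,
                           noise = 0, w = 128, h = 128)
  cn <- extract_cells(scn$image, prescreen_image(scn$image)$candidates)
  vneg <- extract_features(cn[[1]])
  d_scale <- sqrt(sum((v[["1"]] - v[["0.5"]])^2))
  d_class <- sqrt(sum((v[["1"]] - vneg)^2))
  expect_lt(d_scale, d_class)
})
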