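#' Feature vector layout
#'
#' Names of the 60 per-cell features, in the fixed order used by training and
#' prediction: intensity-histogram block (5), gray-level co-occurrence block
#' (10), Fourier block (9), circular local-binary-pattern block (28) and
#' morphology block (8).
#'
#' @return character vector of length 60.
#' @export
feature_names <- function() {
  c("hist_high_frac", "hist_max", "hist_mean", "hist_std", "hist_entropy",
    paste0("glcm_", rep(c("contrast", "correlation", "energy",
                          "homogeneity", "entropy"), 2),
           "_d", rep(1:2, each = 5)),
    paste0("ft_band_", 1:8), "ft_centroid_radius",
    paste0("lbp_p8r1_b", 0:9), paste0("lbp_p16r2_b", 0:17),
    "morph_area_frac", "morph_eccentricity", "morph_solidity",
    "morph_compactness", "morph_mean_ratio", "morph_max_intensity",
    "morph_centroid_offset", "morph_n_candidates")
}

# -- histogram block ----------------------------------------------------------

#' Intensity-histogram features of a cell crop
#'
#' Five statistics over the body pixels: fraction of highly fluorescent
#' pixels (intensity > `theta_hf`), maximum, mean, standard deviation and
#' Shannon entropy (bits) of a 32-bin histogram on `[0, 1]` (empty bins
#' contribute 0).
#'
#' @param crop numeric matrix of intensities in `[0, 1]`.
#' @param body_mask logical matrix, same size, marking body pixels.
#' @param theta_hf high-fluorescence threshold.
#' @return named numeric vector of length 5.
#' @export
histogram_features <- function(crop, body_mask, theta_hf = 0.7) {
  if (!any(body_mask)) stop_validation("empty body mask")
  v <- crop[body_mask]
  counts <- tabulate(pmin(floor(v * 32), 31) + 1L, 32L)
  p <- counts / sum(counts)
  p <- p[p > 0]
  c(hist_high_frac = mean(v > theta_hf),
    hist_max = max(v), hist_mean = mean(v),
    hist_std = if (length(v) > 1) stats::sd(v) else 0,
    hist_entropy = -sum(p * log2(p)))
}

# -- GLCM block ---------------------------------------------------------------

#' Gray-level co-occurrence matrix at one offset
#'
#' Symmetric, normalized co-occurrence matrix of the 32-level quantized crop,
#' restricted to pixel pairs that both lie inside the body mask. Exposed so
#' the texture statistics can be verified against direct pair enumeration.
#'
#' @inheritParams histogram_features
#' @param drow,dcol offset in rows/columns (e.g. `drow = 0, dcol = 1` is
#'   distance 1 at angle 0).
#' @param levels number of gray levels.
#' @return `levels x levels` matrix summing to 1, or all zeros if the mask
#'   admits no pair at this offset.
#' @export
glcm_matrix <- function(crop, body_mask, drow, dcol, levels = 32L) {
  q <- pmin(floor(crop * levels), levels - 1L)
  h <- nrow(crop); w <- ncol(crop)
  r1 <- seq_len(h - abs(drow)) + max(0L, -drow)
  c1 <- seq_len(w - abs(dcol)) + max(0L, -dcol)
  r2 <- r1 + drow; c2 <- c1 + dcol
  a <- q[r1, c1, drop = FALSE]; b <- q[r2, c2, drop = FALSE]
  ok <- body_mask[r1, c1, drop = FALSE] & body_mask[r2, c2, drop = FALSE]
  if (!any(ok)) return(matrix(0, levels, levels))
  i <- a[ok] + 1L; j <- b[ok] + 1L
  counts <- tabulate((i - 1L) * levels + j, levels * levels) +
            tabulate((j - 1L) * levels + i, levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P / sum(P)
}

glcm_stats <- function(P) {
  if (sum(P) == 0) {
    return(c(contrast = 0, correlation = 0, energy = 0,
             homogeneity = 0, entropy = 0))
  }
  lv <- nrow(P)
  i <- matrix(seq_len(lv) - 1L, lv, lv)
  j <- t(i)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  } else 0
  nz <- P[P > 0]
  c(contrast = sum((i - j)^2 * P),
    correlation = corr,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + (i - j)^2)),
    entropy = -sum(nz * log2(nz)))
}

#' GLCM texture features of a cell crop
#'
#' The five co-occurrence statistics (contrast, correlation, energy,
#' homogeneity, entropy) at distances 1 and 2, each averaged over the four
#' angles 0/45/90/135 degrees, on a 32-level quantization restricted to body
#' pixels. Angles with no valid pair are skipped; a distance with no valid
#' pairs at any angle contributes zeros.
#'
#' @inheritParams histogram_features
#' @return named numeric vector of length 10.
#' @export
glcm_features <- function(crop, body_mask) {
  out <- numeric(0)
  for (d in 1:2) {
    offs <- list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
    acc <- NULL; n <- 0L
    for (o in offs) {
      P <- glcm_matrix(crop, body_mask, o[1], o[2])
      if (sum(P) == 0) next
      st <- glcm_stats(P)
      acc <- if (is.null(acc)) st else acc + st
      n <- n + 1L
    }
    st <- if (n > 0L) acc / n else glcm_stats(matrix(0, 32, 32))
    names(st) <- paste0("glcm_", names(glcm_stats(matrix(0, 2, 2))), "_d", d)
    out <- c(out, st)
  }
  out
}

# -- Fourier block ------------------------------------------------------------

#' Fourier spectrum features of a cell crop
#'
#' The crop is centered on a 64 x 64 zero canvas (larger crops are
#' center-cropped), the power spectrum `|FFT|^2` is computed, the DC term is
#' excluded, and the energy fractions in 8 equal-width radial annuli between
#' radius 1 and 32 are reported together with the spectral centroid radius
#' `sum(r * E) / sum(E)`. The more fluorescent objects a cell contains, the
#' more spectral energy sits at high radii and the larger the centroid.
#' An (effectively) empty crop yields nine zeros by convention.
#'
#' @param crop numeric matrix of intensities.
#' @return named numeric vector of length 9.
#' @export
fourier_features <- function(crop) {
  n <- 64L
  canvas <- matrix(0, n, n)
  h <- min(nrow(crop), n); w <- min(ncol(crop), n)
  rs <- floor((nrow(crop) - h) / 2); cs <- floor((ncol(crop) - w) / 2)
  r0 <- floor((n - h) / 2); c0 <- floor((n - w) / 2)
  canvas[r0 + seq_len(h), c0 + seq_len(w)] <-
    crop[rs + seq_len(h), cs + seq_len(w)]
  P <- Mod(stats::fft(canvas))^2
  u <- c(0:(n / 2 - 1), -(n / 2):-1)
  r <- sqrt(outer(u^2, u^2, "+"))
  keep <- r >= 1 & r <= n / 2
  total <- sum(P[keep])
  nm <- c(paste0("ft_band_", 1:8), "ft_centroid_radius")
  if (total < 1e-12) return(stats::setNames(numeric(9), nm))
  edges <- seq(1, n / 2, length.out = 9)
  bands <- vapply(1:8, function(k) {
    inb <- r >= edges[k] & (if (k < 8) r < edges[k + 1] else r <= edges[9])
    sum(P[inb])
  }, 0)
  stats::setNames(c(bands / total, sum((r * P)[keep]) / total), nm)
}

# -- LBP block ----------------------------------------------------------------

# Rotation-invariant uniform circular LBP histogram for one (P, R) config,
# over body pixels at least ceil(R)+1 from the crop border and surviving a
# 2-px erosion of the body mask. Bilinear interpolation at the P sampling
# points; rotation-invariant uniform coding: patterns with at most two 0/1
# circular transitions map to their number of set bits (0..P), all others to
# the "non-uniform" bin P+1.
lbp_histogram <- function(crop, body_mask, P, R) {
  er <- EBImage::imageData(EBImage::erode(
    EBImage::Image(body_mask * 1), EBImage::makeBrush(5, "disc"))) > 0.5
  h <- nrow(crop); w <- ncol(crop)
  mrg <- ceiling(R) + 1L
  if (h <= 2 * mrg || w <= 2 * mrg) return(rep(0, P + 2L))
  ok <- er
  ok[c(1:mrg, (h - mrg + 1L):h), ] <- FALSE
  ok[, c(1:mrg, (w - mrg + 1L):w)] <- FALSE
  centers <- which(ok, arr.ind = TRUE)
  if (!nrow(centers)) return(rep(0, P + 2L))
  gc <- crop[centers]
  bits <- matrix(FALSE, nrow(centers), P)
  for (p in seq_len(P)) {
    ang <- 2 * pi * (p - 1) / P
    dc <- R * cos(ang); dr <- -R * sin(ang)
    rr <- centers[, 1] + dr; cc <- centers[, 2] + dc
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    # snap near-integer offsets so right-angle symmetries are exact
    fr[abs(fr) < 1e-9] <- 0; fc[abs(fc) < 1e-9] <- 0
    fr[abs(fr - 1) < 1e-9] <- 1; fc[abs(fc - 1) < 1e-9] <- 1
    idx <- function(r, c) crop[(pmin(pmax(c, 1L), w) - 1L) * h + pmin(pmax(r, 1L), h)]
    gp <- (1 - fr) * (1 - fc) * idx(r0, c0) +
          (1 - fr) * fc       * idx(r0, c0 + 1L) +
          fr       * (1 - fc) * idx(r0 + 1L, c0) +
          fr       * fc       * idx(r0 + 1L, c0 + 1L)
    # tolerance absorbs bilinear round-off when neighbor equals center
    bits[, p] <- gp >= gc - 1e-9
  }
  trans <- rowSums(bits != bits[, c(2:P, 1), drop = FALSE])
  ones <- rowSums(bits)
  lab <- ifelse(trans <= 2, ones, P + 1L)
  histc <- tabulate(lab + 1L, P + 2L)
  histc / sum(histc)
}

#' Circular local-binary-pattern features of a cell crop
#'
#' Rotation-invariant uniform LBP histograms for the (P = 8, R = 1)
#' configuration (10 bins) and the (P = 16, R = 2) configuration (18 bins),
#' computed over body-interior pixels (2-px erosion) and each normalized to
#' sum 1. Rotation invariance removes the cell-orientation nuisance. If the
#' interior is empty, 28 zeros are returned.
#'
#' @inheritParams histogram_features
#' @return named numeric vector of length 28.
#' @export
lbp_features <- function(crop, body_mask) {
  h1 <- lbp_histogram(crop, body_mask, 8L, 1)
  h2 <- lbp_histogram(crop, body_mask, 16L, 2)
  stats::setNames(c(h1, h2),
                  c(paste0("lbp_p8r1_b", 0:9), paste0("lbp_p16r2_b", 0:17)))
}

# -- morphology block ---------------------------------------------------------

#' Morphological features of the brightest candidate in a cell
#'
#' Shape and intensity descriptors of the presumed kinetoplast, computed on
#' the candidate with the greatest maximum intensity (in original image
#' coordinates, so all ratios are magnification-free): candidate/body area
#' fraction, eccentricity, solidity (area over convex hull area), compactness,
#' candidate/body mean-intensity ratio, candidate maximum intensity, centroid
#' offset relative to the major axis, and the number of candidates in the
#' cell.
#'
#' @param cell a `cell_crop`.
#' @return named numeric vector of length 8.
#' @export
morphology_features <- function(cell) {
  if (!length(cell$candidates)) {
    stop_validation("cell has no candidate region")
  }
  mx <- vapply(cell$candidates, function(cc) cc$max_intensity, 0)
  cand <- cell$candidates[[which.max(mx)]]
  coords <- cand$pixels
  mom <- moments_of(coords)
  hull <- hull_area_of(coords)
  off <- sqrt((cand$centroid[["x"]] - cell$cell_centroid[["x"]])^2 +
              (cand$centroid[["y"]] - cell$cell_centroid[["y"]])^2)
  c(morph_area_frac = min(cand$area_px / max(cell$body_area_px, 1), 1),
    morph_eccentricity = mom$eccentricity,
    morph_solidity = min(cand$area_px / max(hull, cand$area_px), 1),
    morph_compactness = cand$compactness,
    morph_mean_ratio = cand$mean_intensity / max(cell$body_mean, 1e-6),
    morph_max_intensity = cand$max_intensity,
    morph_centroid_offset = off / max(cell$major_axis_len, 1e-6),
    morph_n_candidates = length(cell$candidates))
}

#' Extract the full feature vector of a cell
#'
#' Concatenates the histogram, GLCM, Fourier, LBP and morphology blocks in
#' the fixed order of [feature_names()]. The order never changes between
#' training and prediction.
#'
#' @param cell a `cell_crop` from [extract_cells()].
#' @return named numeric vector of length 60, all finite.
#' @export
extract_features <- function(cell) {
  stopifnot(inherits(cell, "cell_crop"))
  crop <- cell$crop; mask <- cell$body_mask
  v <- c(histogram_features(crop, mask),
         glcm_features(crop, mask),
         fourier_features(crop * mask),
         lbp_features(crop, mask),
         morphology_features(cell))
  names(v) <- feature_names()
  if (any(!is.finite(v))) {
    stop_state("non-finite feature(s): %s",
               paste(feature_names()[!is.finite(v)], collapse = ", "))
  }
  v
}

#' Build a feature table for a set of cells
#'
#' One row per cell with identifiers, label (if any) and the 60 features.
#'
#' @param cells list of `cell_crop`.
#' @return data.frame with columns `well_id`, `image_id`, `cell_id`, `label`
#'   and the feature columns.
#' @export
features_table <- function(cells) {
  if (!length(cells)) {
    out <- data.frame(well_id = character(0), image_id = character(0),
                      cell_id = character(0), label = character(0))
    for (nm in feature_names()) out[[nm]] <- numeric(0)
    return(out)
  }
  feats <- t(vapply(cells, extract_features, numeric(60)))
  meta <- data.frame(
    well_id = vapply(cells, `[[`, "", "well_id"),
    image_id = vapply(cells, `[[`, "", "image_id"),
    cell_id = vapply(cells, `[[`, "", "cell_id"),
    label = vapply(cells, function(cl) cl$true_label %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(feats))
}
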