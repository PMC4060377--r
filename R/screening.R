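#' Screening parameters
#'
#' Parameters of the threshold-based kinetoplast candidate detector. The
#' threshold is `mean + k_sigma * sd` of the median-subtracted intensities,
#' computed per image so the detector adapts to exposure and equipment. The
#' area gate is expressed in units of the nominal kinetoplast area
#' `pi * (2.5 * magnification_scale)^2`, so both magnifications behave
#' identically. `k_sigma` is calibrated so that the threshold sits above the
#' cytoplasm + nucleus pedestal of a stained cell but well below the
#' kinetoplast peak (see the methods vignette for the calibration).
#'
#' @param k_sigma multiplier of the per-image SD.
#' @param max_fraction floor of the threshold as a fraction of the image's
#'   maximum corrected intensity; keeps the threshold above broad pedestal
#'   structures (nucleus over cytoplasm) in sparse, low-variance images.
#' @param min_area_scale,max_area_scale candidate area gate, in units of the
#'   nominal kinetoplast area at the image's magnification scale. A candidate
#'   additionally always spans at least 2 pixels (single hot pixels are
#'   sensor noise, not organelles).
#' @param min_compactness minimum `4*pi*area/perimeter^2` of a candidate.
#' @return an object of class `screening_params`.
#' @export
screening_params <- function(k_sigma = 8, max_fraction = 0.78,
                             min_area_scale = 0.15,
                             max_area_scale = 4.0, min_compactness = 0.4) {
  if (k_sigma <= 0) stop_validation("k_sigma must be > 0")
  if (max_fraction < 0 || max_fraction >= 1) {
    stop_validation("max_fraction must lie in [0, 1)")
  }
  if (min_area_scale >= max_area_scale) {
    stop_validation("min_area_scale must be < max_area_scale")
  }
  structure(list(k_sigma = k_sigma, max_fraction = max_fraction,
                 min_area_scale = min_area_scale,
                 max_area_scale = max_area_scale,
                 min_compactness = min_compactness),
            class = "screening_params")
}

nominal_kinetoplast_area <- function(scale) pi * (2.5 * scale)^2

# Build a candidate_region from its pixel coordinates and the corrected image.
make_candidate <- function(coords, corrected) {
  vals <- corrected[coords]
  area <- nrow(coords)
  mask <- matrix(FALSE, nrow(corrected), ncol(corrected))
  mask[coords] <- TRUE
  # crop to the bounding box before estimating the perimeter
  rr <- range(coords[, 1]); cr <- range(coords[, 2])
  per <- perimeter_estimate(mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE])
  structure(list(
    pixels = coords,                                   # (row, col), 1-based
    area_px = area,
    centroid = c(x = mean(coords[, 2]) - 1, y = mean(coords[, 1]) - 1),
    max_intensity = max(vals),
    mean_intensity = mean(vals),
    perimeter_px = per,
    compactness = compactness_of(area, per)),
    class = "candidate_region")
}

#' Detect candidate kinetoplast regions
#'
#' Step 1 of the pipeline: find compact sets of pixels distinctly more
#' fluorescent than the rest of the image. The image is background-corrected
#' by subtracting its median (clipped at 0), thresholded at
#' `max(mean + k_sigma * sd, max_fraction * max)` of the corrected
#' intensities (the second term keeps sparse images with few cells from
#' thresholding below broad pedestal structures), and 8-connected
#' components are kept if their area lies within the scale-normalized gate
#' and their compactness is at least `min_compactness`. Candidates are
#' returned sorted by decreasing maximum intensity, ties broken by centroid
#' `(y, x)`. A constant image yields an empty list.
#'
#' @param image a [well_image].
#' @param params a [screening_params].
#' @return list of `candidate_region` objects.
#' @export
detect_candidates <- function(image, params = screening_params()) {
  stopifnot(inherits(image, "well_image"))
  px <- image$pixels
  corrected <- px - stats::median(px)
  corrected[corrected < 0] <- 0
  sdv <- stats::sd(corrected)
  if (!is.finite(sdv) || sdv == 0) return(list())
  thr <- max(mean(corrected) + params$k_sigma * sdv,
             params$max_fraction * max(corrected))
  mask <- corrected > thr
  if (!any(mask)) return(list())
  lab <- label_components(mask)
  nominal <- nominal_kinetoplast_area(image$magnification_scale)
  out <- list()
  for (k in seq_len(max(lab))) {
    coords <- which(lab == k, arr.ind = TRUE)
    area <- nrow(coords)
    if (area < max(params$min_area_scale * nominal, 2) ||
        area > params$max_area_scale * nominal) next
    cand <- make_candidate(coords, corrected)
    if (cand$compactness < params$min_compactness) next
    out[[length(out) + 1L]] <- cand
  }
  if (length(out) > 1L) {
    mx <- vapply(out, function(cc) cc$max_intensity, 0)
    cy <- vapply(out, function(cc) cc$centroid[["y"]], 0)
    cx <- vapply(out, function(cc) cc$centroid[["x"]], 0)
    out <- out[order(-mx, cy, cx)]
  }
  out
}

#' Pre-screen an image by candidate presence
#'
#' An image with no candidate region is presumed negative and never reaches
#' the cell classifier (this is what makes the first step fast and keeps
#' false negatives rare); otherwise it is only *candidate* positive and the
#' final label is decided by the cell classifier and majority voting.
#'
#' @inheritParams detect_candidates
#' @return list with `status` (`"candidate_positive"` or
#'   `"presumed_negative"`) and `candidates`.
#' @export
prescreen_image <- function(image, params = screening_params()) {
  cands <- detect_candidates(image, params)
  list(status = if (length(cands)) "candidate_positive" else "presumed_negative",
       candidates = cands)
}
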