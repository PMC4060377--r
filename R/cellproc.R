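#' Cell localization parameters
#'
#' @param expected_cell_length nominal cell body length in pixels at the
#'   reference magnification (scale 1). Windows, body-area gates and the
#'   artifact-rejection rule are expressed relative to this length times the
#'   image's magnification scale.
#' @param max_candidate_distance maximum distance (px) from a candidate
#'   centroid to the nearest segmented body pixel before the candidate is
#'   discarded as an extracellular artifact.
#' @param min_body_fraction,max_body_fraction allowed segmented body area as
#'   a fraction of the nominal ellipse body area `pi * (L/2) * (L/5)`. The
#'   lower gate rejects bright speckles that Otsu segmentation would
#'   otherwise promote to "bodies"; the upper gate rejects background
#'   over-segmentation.
#' @param crop_axis_px target major-axis length of the scale-normalized crop.
#' @return an object of class `cell_params`.
#' @export
cell_params <- function(expected_cell_length = 40,
                        max_candidate_distance = 5,
                        min_body_fraction = 0.25,
                        max_body_fraction = 3,
                        crop_axis_px = 64) {
  if (expected_cell_length <= 0) stop_validation("expected_cell_length must be > 0")
  if (min_body_fraction >= max_body_fraction) {
    stop_validation("min_body_fraction must be < max_body_fraction")
  }
  structure(list(expected_cell_length = expected_cell_length,
                 max_candidate_distance = max_candidate_distance,
                 min_body_fraction = min_body_fraction,
                 max_body_fraction = max_body_fraction,
                 crop_axis_px = crop_axis_px),
            class = "cell_params")
}

# distance from a point (row, col) to the nearest TRUE pixel of a mask
min_dist_to_mask <- function(mask, r, c) {
  coords <- which(mask, arr.ind = TRUE)
  if (!nrow(coords)) return(Inf)
  sqrt(min((coords[, 1] - r)^2 + (coords[, 2] - c)^2))
}

#' Locate cells around candidate regions
#'
#' For each candidate: a window of side 3 x expected cell length (scale-aware)
#' centered on the candidate is segmented by Otsu's threshold on the
#' median-subtracted window, followed by morphological closing (disc radius
#' 2). The connected body component containing (or nearest to, within
#' `max_candidate_distance` px) the candidate is taken as the cell body;
#' candidates with no body nearby, or whose "body" is smaller than a quarter
#' of the nominal cell area (bright extracellular speckles), are discarded as
#' artifacts. Bodies claiming multiple candidates produce one crop holding
#' all of them. Each crop is resampled (bilinear) so the body major axis is
#' about `crop_axis_px` pixels, making downstream texture features
#' magnification-independent.
#'
#' @param image a [well_image].
#' @param candidates list of `candidate_region` from [detect_candidates()].
#' @param params a [cell_params].
#' @return list of `cell_crop` objects (possibly empty).
#' @export
extract_cells <- function(image, candidates, params = cell_params()) {
  stopifnot(inherits(image, "well_image"))
  if (!length(candidates)) return(list())
  s <- image$magnification_scale
  L <- params$expected_cell_length * s
  half <- round(1.5 * L)
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  min_body_area <- params$min_body_fraction * pi * (L / 2) * (L / 5)
  max_body_area <- params$max_body_fraction * pi * (L / 2) * (L / 5)
  claimed <- matrix(0L, h, w)          # image pixels -> crop index
  crops <- list()

  for (cand in candidates) {
    cr <- min(max(round(cand$centroid[["y"]]) + 1L, 1L), h)   # 1-based row
    cc <- min(max(round(cand$centroid[["x"]]) + 1L, 1L), w)
    if (claimed[cr, cc] > 0L) {
      k <- claimed[cr, cc]
      crops[[k]]$candidates <- c(crops[[k]]$candidates, list(cand))
      next
    }
    r0 <- max(1L, cr - half); r1 <- min(h, cr + half)
    c0 <- max(1L, cc - half); c1 <- min(w, cc + half)
    win <- px[r0:r1, c0:c1]
    winc <- win - stats::median(win)
    winc[winc < 0] <- 0
    wr <- cr - r0 + 1L; wc <- cc - c0 + 1L
    # the component containing (or nearest to) the candidate, subject to the
    # body-area gates; NULL when the segmentation holds no acceptable body
    find_body <- function(thr) {
      mask <- winc > thr
      mask <- EBImage::imageData(EBImage::closing(
        EBImage::Image(mask * 1), EBImage::makeBrush(5, "disc"))) > 0.5
      lab <- label_components(mask)
      if (max(lab) == 0L) return(NULL)
      comp <- lab[wr, wc]
      if (comp == 0L) {
        dists <- vapply(seq_len(max(lab)), function(k)
          min_dist_to_mask(lab == k, wr, wc), 0)
        if (min(dists) > params$max_candidate_distance) return(NULL)
        comp <- which.min(dists)
      }
      body <- lab == comp
      if (sum(body) < min_body_area ||
          sum(body) > max_body_area) return(NULL)
      body
    }
    t1 <- EBImage::otsu(EBImage::Image(winc), range = c(0, 1))
    body <- find_body(t1)
    if (is.null(body)) {
      # a dominant bright organelle can pull Otsu above the cytoplasm level;
      # re-threshold the sub-organelle population (two-level Otsu)
      low <- winc[winc <= t1]
      if (length(low) > 64 && stats::sd(low) > 0) {
        t2 <- EBImage::otsu(EBImage::Image(matrix(low, 1)), range = c(0, 1))
        if (t2 < t1) body <- find_body(t2)
      }
    }
    if (is.null(body)) next                      # artifact or unsegmentable
    # overlap with an already-claimed body -> same cell, attach
    bidx <- which(body, arr.ind = TRUE)
    bimg <- cbind(bidx[, 1] + r0 - 1L, bidx[, 2] + c0 - 1L)
    owners <- claimed[bimg]
    if (any(owners > 0L)) {
      k <- as.integer(names(which.max(table(owners[owners > 0L]))))
      crops[[k]]$candidates <- c(crops[[k]]$candidates, list(cand))
      next
    }
    mom <- moments_of(bidx)
    if (mom$major <= 0) next
    f <- params$crop_axis_px / mom$major
    rr <- range(bidx[, 1]); crng <- range(bidx[, 2])
    m <- 3L
    br0 <- max(1L, rr[1] - m); br1 <- min(nrow(win), rr[2] + m)
    bc0 <- max(1L, crng[1] - m); bc1 <- min(ncol(win), crng[2] + m)
    sub <- winc[br0:br1, bc0:bc1]
    subm <- body[br0:br1, bc0:bc1]
    nw <- max(8L, round(ncol(sub) * f)); nh <- max(8L, round(nrow(sub) * f))
    crop <- t(EBImage::imageData(EBImage::resize(
      EBImage::Image(t(sub)), w = nw, h = nh, filter = "bilinear")))
    cmask <- t(EBImage::imageData(EBImage::resize(
      EBImage::Image(t(subm * 1)), w = nw, h = nh, filter = "none"))) > 0.5
    crop[crop < 0] <- 0; crop[crop > 1] <- 1
    k <- length(crops) + 1L
    claimed[(bimg[, 2] - 1L) * h + bimg[, 1]] <- k
    crops[[k]] <- structure(list(
      well_id = image$well_id, image_id = image$image_id,
      cell_id = sprintf("%s_C%02d", image$image_id, k),
      crop = crop, body_mask = cmask,
      candidates = list(cand),
      cell_centroid = c(x = unname(mom$centroid[2]) + c0 - 2,
                        y = unname(mom$centroid[1]) + r0 - 2),
      major_axis_len = mom$major, orientation = mom$orientation,
      body_area_px = sum(body), body_mean = mean(winc[body]),
      mask_img = body[rr[1]:rr[2], crng[1]:crng[2], drop = FALSE],
      mask_offset = c(row = rr[1] + r0 - 1L, col = crng[1] + c0 - 1L),
      # transform image coords -> crop coords: subtract bbox origin, scale by f
      crop_origin = c(row = br0 + r0 - 1L, col = bc0 + c0 - 1L), crop_factor = f,
      magnification_scale = s, true_label = NULL),
      class = "cell_crop")
  }
  crops
}

#' @export
print.cell_crop <- function(x, ...) {
  cat(sprintf("<cell_crop> %s  %d candidate(s)  body %d px  label %s\n",
              x$cell_id, length(x$candidates), x$body_area_px,
              x$true_label %||% "<none>"))
  invisible(x)
}

# TRUE if 0-based image point (x, y) falls inside the cell's body mask.
point_in_body <- function(cell, x, y) {
  r <- round(y) + 1L - cell$mask_offset[["row"]] + 1L
  c <- round(x) + 1L - cell$mask_offset[["col"]] + 1L
  if (r < 1L || c < 1L || r > nrow(cell$mask_img) || c > ncol(cell$mask_img)) {
    return(FALSE)
  }
  cell$mask_img[r, c]
}

#' Attach ground-truth labels to cell crops
#'
#' Each annotation (0-based image coordinates) labels the crop whose body
#' mask contains it; if it falls inside several (overlapping) bodies the
#' nearest cell centroid wins, ties broken by distance then (y, x).
#' Annotations matching no body are counted and reported via a warning and
#' the `n_unmatched` attribute. A crop that receives several annotations
#' takes the label of the annotation nearest its centroid.
#'
#' @param cells list of `cell_crop` from [extract_cells()].
#' @param annotations data.frame with columns `x`, `y`, `label`.
#' @return `cells`, with `true_label` set on matched crops;
#'   attribute `n_unmatched` counts annotations matching nothing.
#' @export
match_annotations <- function(cells, annotations) {
  if (is.null(annotations) || !nrow(annotations)) {
    attr(cells, "n_unmatched") <- 0L
    return(cells)
  }
  annotations$label <- parse_label(annotations$label, "cell label")
  n_unmatched <- 0L
  assigned <- vector("list", length(cells))
  for (i in seq_len(nrow(annotations))) {
    ax <- annotations$x[i]; ay <- annotations$y[i]
    inside <- which(vapply(cells, point_in_body, TRUE, x = ax, y = ay))
    if (!length(inside)) {
      n_unmatched <- n_unmatched + 1L
      next
    }
    if (length(inside) > 1L) {
      d <- vapply(cells[inside], function(cl)
        sqrt((cl$cell_centroid[["x"]] - ax)^2 + (cl$cell_centroid[["y"]] - ay)^2), 0)
      cy <- vapply(cells[inside], function(cl) cl$cell_centroid[["y"]], 0)
      cx <- vapply(cells[inside], function(cl) cl$cell_centroid[["x"]], 0)
      inside <- inside[order(d, cy, cx)][1]
      warn_cliftcad("annotation %d lies inside several bodies; nearest wins", i)
    }
    k <- inside[1]
    d <- sqrt((cells[[k]]$cell_centroid[["x"]] - ax)^2 +
              (cells[[k]]$cell_centroid[["y"]] - ay)^2)
    assigned[[k]] <- rbind(assigned[[k]],
                           data.frame(d = d, label = annotations$label[i]))
  }
  for (k in seq_along(cells)) {
    if (!is.null(assigned[[k]])) {
      cells[[k]]$true_label <- assigned[[k]]$label[which.min(assigned[[k]]$d)]
    }
  }
  if (n_unmatched > 0L) {
    warn_cliftcad("%d annotation(s) matched no cell body", n_unmatched)
  }
  attr(cells, "n_unmatched") <- n_unmatched
  cells
}
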