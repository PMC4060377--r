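# Fixtures and independent oracles used across the suite. Oracles are kept
# deliberately naive (queue-based flood fill, direct pair enumeration,
# explicit vote counting) and independent of the package's implementations.

# uniform background + Gaussian spots, as a well_image
spot_image <- function(spots, w = 96, h = 96, background = 0.05, scale = 1,
                       noise = 0, seed = NULL) {
  m <- matrix(background, h, w)
  for (sp in spots) {
    for (r in seq_len(h)) {
      # vectorized over columns
      m[r, ] <- m[r, ] + sp$peak *
        exp(-(((seq_len(w) - 1) - sp$x)^2 + ((r - 1) - sp$y)^2) / (2 * sp$sigma^2))
    }
  }
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    m <- m + matrix(rnorm(h * w, 0, noise), h, w)
  }
  m[m < 0] <- 0; m[m > 1] <- 1
  well_image(m, magnification_scale = scale)
}

# breadth-first flood-fill 8-connected labeling (oracle for label_components)
bfs_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextlab <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- ((cur - 1L) %% nrow(mask)) + 1L
      c <- ((cur - 1L) %/% nrow(mask)) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || c2 < 1 || r2 > nrow(mask) || c2 > ncol(mask)) next
        i2 <- (c2 - 1L) * nrow(mask) + r2
        if (mask[i2] && lab[i2] == 0L) {
          lab[i2] <- nextlab
          queue <- c(queue, i2)
        }
      }
    }
  }
  lab
}

# full screening oracle: reimplements thresholding + gating from the
# documented rules, with BFS labeling, returning candidate pixel index sets
# in the documented sort order
screening_oracle <- function(image, params = screening_params()) {
  px <- image$pixels
  corr <- px - median(px); corr[corr < 0] <- 0
  sdv <- sd(corr)
  if (!is.finite(sdv) || sdv == 0) return(list())
  thr <- max(mean(corr) + params$k_sigma * sdv,
             params$max_fraction * max(corr))
  mask <- corr > thr
  lab <- bfs_label(mask)
  nominal <- pi * (2.5 * image$magnification_scale)^2
  cands <- list()
  for (k in seq_len(max(lab))) {
    coords <- which(lab == k, arr.ind = TRUE)
    a <- nrow(coords)
    if (a < max(params$min_area_scale * nominal, 2) ||
        a > params$max_area_scale * nominal) next
    sub <- matrix(FALSE, nrow(px), ncol(px)); sub[coords] <- TRUE
    rr <- range(coords[, 1]); cr <- range(coords[, 2])
    per <- cliftcad:::perimeter_estimate(sub[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE])
    comp <- cliftcad:::compactness_of(a, per)
    if (comp < params$min_compactness) next
    cands[[length(cands) + 1L]] <- list(
      coords = coords, max = max(corr[coords]),
      cy = mean(coords[, 1]) - 1, cx = mean(coords[, 2]) - 1)
  }
  if (length(cands) > 1L) {
    mx <- sapply(cands, `[[`, "max")
    cands <- cands[order(-mx, sapply(cands, `[[`, "cy"),
                         sapply(cands, `[[`, "cx"))]
  }
  cands
}

# canonical pixel-set key for comparing candidate regions
pixel_key <- function(coords) paste(sort(coords[, 1] * 1e5 + coords[, 2]),
                                    collapse = ",")

# explicit vote counters (oracles for classify_image / classify_well)
vote_image_oracle <- function(labels, prescreen) {
  if (prescreen == "presumed_negative") return("negative")
  if (length(labels) == 0) return("negative")
  np <- sum(labels == "positive"); nn <- sum(labels == "negative")
  if (np > nn) "positive" else if (nn > np) "negative" else "positive"
}

vote_well_oracle <- function(labels) {
  np <- sum(labels == "positive"); nn <- sum(labels == "negative")
  if (np > nn) "positive" else if (nn > np) "negative" else "suspended"
}

# rank-sum AUC of score separating two groups (oracle for feature separation)
auc_oracle <- function(pos_scores, neg_scores) {
  r <- rank(c(pos_scores, neg_scores))
  np <- length(pos_scores); nn <- length(neg_scores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# 90-degree counter-clockwise rotation of a matrix
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# draw a single synthetic cell as a well_image; returns image + geometry
single_cell_image <- function(positive = TRUE, scale = 1, cytoplasm = 0.22,
                              nucleus = FALSE, basal = FALSE,
                              w = 160, h = 160, background = 0.05,
                              noise = 0.02, seed = 1, orientation = 0.5,
                              extra_spots = list()) {
  set.seed(seed)
  len <- 40 * scale
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  sigk <- 2.5 * scale
  kx <- cx + 0.35 * len * cos(orientation)
  ky <- cy + 0.35 * len * sin(orientation)
  comps <- list()
  if (positive) comps <- c(comps, list(list(type = "kinetoplast", x = kx,
                                            y = ky, sigma = sigk, peak = 0.9)))
  if (nucleus) comps <- c(comps, list(list(type = "nucleus", x = cx, y = cy,
                                           sigma = 4 * sigk, peak = 0.45)))
  if (basal) comps <- c(comps, list(list(
    type = "basal_body", x = kx + 2 * sigk * cos(orientation),
    y = ky + 2 * sigk * sin(orientation), sigma = 0.6 * sigk, peak = 0.65)))
  cell <- list(x = cx, y = cy, orientation = orientation, length = len,
               cytoplasm = cytoplasm, components = comps)
  canvas <- matrix(background, h, w)
  rc <- render_cell(cell, canvas)
  canvas <- rc$canvas
  for (sp in extra_spots) {
    canvas <- cliftcad:::add_spot(canvas, sp$x, sp$y, sp$sigma, sp$peak)
  }
  canvas[canvas > 1] <- 1
  if (noise > 0) canvas <- canvas + matrix(rnorm(h * w, 0, noise), h, w)
  canvas[canvas < 0] <- 0; canvas[canvas > 1] <- 1
  list(image = well_image(canvas, magnification_scale = scale),
       cell = cell, kineto = if (positive) c(kx, ky) else NULL)
}
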