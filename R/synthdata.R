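#' Synthetic dataset configuration
#'
#' Parameters of the synthetic CLIFT image generator. Defaults emulate the
#' statistical structure of a routine acquisition: about five fields per well,
#' about eight Crithidia luciliae cells per field, elongated cell bodies with
#' a small bright kinetoplast spot in positive cells, distractor fluorescence
#' (nucleus, basal body, extracellular artifacts) and additive sensor noise.
#' Intensities are on the canonical `[0, 1]` scale; lengths are pixels at the
#' reference 50-fold magnification (`magnification_scale = 1`).
#'
#' @param seed integer seed; the single RNG stream of the dataset.
#' @param n_wells number of wells (sera).
#' @param fraction_positive_wells probability a well is positive.
#' @param images_per_well fields acquired per well.
#' @param mean_cells_per_image Poisson mean of the per-field cell count
#'   (truncated at >= 1).
#' @param image_size `c(width, height)` in pixels.
#' @param magnification_scale 1.0 (50-fold reference) or 0.5 (25-fold).
#' @param cell_length_px mean cell body length at scale 1.
#' @param kinetoplast_sigma_px Gaussian sigma of the kinetoplast spot at scale 1.
#' @param kinetoplast_peak peak intensity added by the kinetoplast.
#' @param p_cell_positive_given_well_positive probability a cell of a positive
#'   well carries a stained kinetoplast.
#' @param p_nucleus,p_basal_body per-cell probabilities of the distractors.
#' @param artifacts_per_image Poisson mean of extracellular bright speckles.
#' @param noise_sigma additive Gaussian sensor noise SD.
#' @param background_level constant background fluorescence.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_wells = 8L,
                         fraction_positive_wells = 0.25,
                         images_per_well = 5L,
                         mean_cells_per_image = 8,
                         image_size = c(512L, 384L),
                         magnification_scale = 1.0,
                         cell_length_px = 40,
                         kinetoplast_sigma_px = 2.5,
                         kinetoplast_peak = 0.9,
                         p_cell_positive_given_well_positive = 0.9,
                         p_nucleus = 0.6,
                         p_basal_body = 0.3,
                         artifacts_per_image = 1.0,
                         noise_sigma = 0.02,
                         background_level = 0.05) {
  cfg <- list(seed = as.integer(seed), n_wells = as.integer(n_wells),
              fraction_positive_wells = fraction_positive_wells,
              images_per_well = as.integer(images_per_well),
              mean_cells_per_image = mean_cells_per_image,
              image_size = as.integer(image_size),
              magnification_scale = magnification_scale,
              cell_length_px = cell_length_px,
              kinetoplast_sigma_px = kinetoplast_sigma_px,
              kinetoplast_peak = kinetoplast_peak,
              p_cell_positive_given_well_positive = p_cell_positive_given_well_positive,
              p_nucleus = p_nucleus, p_basal_body = p_basal_body,
              artifacts_per_image = artifacts_per_image,
              noise_sigma = noise_sigma, background_level = background_level)
  probs <- c(cfg$fraction_positive_wells,
             cfg$p_cell_positive_given_well_positive, cfg$p_nucleus,
             cfg$p_basal_body)
  if (any(probs < 0 | probs > 1)) stop_validation("probabilities must lie in [0, 1]")
  pos <- c(cfg$cell_length_px, cfg$kinetoplast_sigma_px, cfg$kinetoplast_peak,
           cfg$magnification_scale, cfg$mean_cells_per_image)
  if (any(pos <= 0)) stop_validation("sizes, sigmas and peaks must be positive")
  if (cfg$n_wells < 1L) stop_validation("n_wells must be >= 1")
  if (cfg$images_per_well < 1L) stop_validation("images_per_well must be >= 1")
  if (cfg$kinetoplast_peak <= cfg$background_level) {
    stop_validation("kinetoplast_peak must exceed background_level")
  }
  if (cfg$noise_sigma < 0 || cfg$background_level < 0) {
    stop_validation("noise_sigma and background_level must be >= 0")
  }
  if (any(cfg$image_size < 64L)) stop_validation("image_size must be >= 64 px")
  structure(cfg, class = "synth_config")
}

# -- low-level rendering ------------------------------------------------------

# Additive filled rotated ellipse. Coordinates 0-based (x = col, y = row).
add_ellipse <- function(canvas, x, y, a, b, theta, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  r0 <- max(1L, floor(y - a) + 1L); r1 <- min(h, ceiling(y + a) + 1L)
  c0 <- max(1L, floor(x - a) + 1L); c1 <- min(w, ceiling(x + a) + 1L)
  rows <- r0:r1; cols <- c0:c1
  yy <- matrix(rows - 1, length(rows), length(cols)) - y
  xx <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE) - x
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  canvas[rows, cols] <- canvas[rows, cols] + value * inside
  canvas
}

# Logical mask of the same ellipse, used for overlap tests / artifact placement.
ellipse_mask <- function(h, w, x, y, a, b, theta) {
  m <- matrix(0, h, w)
  add_ellipse(m, x, y, a, b, theta, 1) > 0
}

# Additive isotropic Gaussian spot, truncated at 4 sigma.
add_spot <- function(canvas, x, y, sigma, peak) {
  h <- nrow(canvas); w <- ncol(canvas)
  e <- ceiling(4 * sigma)
  r0 <- max(1L, floor(y - e) + 1L); r1 <- min(h, ceiling(y + e) + 1L)
  c0 <- max(1L, floor(x - e) + 1L); c1 <- min(w, ceiling(x + e) + 1L)
  rows <- r0:r1; cols <- c0:c1
  yy <- matrix(rows - 1, length(rows), length(cols)) - y
  xx <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE) - x
  canvas[rows, cols] <- canvas[rows, cols] +
    peak * exp(-(xx^2 + yy^2) / (2 * sigma^2))
  canvas
}

#' Render one synthetic cell onto a canvas
#'
#' Draws the elongated cell body (filled rotated ellipse, aspect ratio 2.5)
#' additively, then each listed component (Gaussian spots: kinetoplast,
#' nucleus, basal body), and clips at the saturation level 1. Rendering is
#' additive, so two disjoint cells drawn on the same canvas sum pixel-wise.
#'
#' @param cell list with `x`, `y` (0-based centroid), `orientation` (radians),
#'   `length` (major axis, px), `cytoplasm` (body intensity), and `components`:
#'   a list of `list(type, x, y, sigma, peak)`.
#' @param canvas numeric matrix to draw on.
#' @return list with `canvas` (updated matrix) and `components`
#'   (data.frame of rendered component type and centroid).
#' @export
render_cell <- function(cell, canvas) {
  a <- cell$length / 2
  if (cell$x - a < 0 || cell$x + a > ncol(canvas) - 1 ||
      cell$y - a < 0 || cell$y + a > nrow(canvas) - 1) {
    stop_validation("cell bounding box outside canvas")
  }
  b <- cell$length / 5                    # aspect ratio 2.5
  canvas <- add_ellipse(canvas, cell$x, cell$y, a, b, cell$orientation,
                        cell$cytoplasm)
  comp <- data.frame(type = character(0), x = numeric(0), y = numeric(0))
  for (cm in cell$components) {
    canvas <- add_spot(canvas, cm$x, cm$y, cm$sigma, cm$peak)
    comp <- rbind(comp, data.frame(type = cm$type, x = cm$x, y = cm$y))
  }
  canvas[canvas > 1] <- 1
  list(canvas = canvas, components = comp)
}

# Sample the geometry and components of one cell. `well_positive` gates the
# kinetoplast; distractors are drawn for positive and negative cells alike.
sample_cell <- function(cfg, w, h, occupied) {
  s <- cfg$magnification_scale
  len_mean <- cfg$cell_length_px * s
  len <- stats::rnorm(1, len_mean, 0.15 * len_mean)
  len <- min(max(len, 0.5 * len_mean), 1.5 * len_mean)
  theta <- stats::runif(1, 0, pi)
  margin <- len / 2 + 2
  for (try in 1:100) {
    x <- stats::runif(1, margin, w - 1 - margin)
    y <- stats::runif(1, margin, h - 1 - margin)
    bodym <- ellipse_mask(h, w, x, y, len / 2, len / 5, theta)
    if (!any(bodym & occupied)) break
  }
  list(x = x, y = y, orientation = theta, length = len, mask = bodym)
}

#' Generate a synthetic CLIFT dataset
#'
#' Writes 8-bit grayscale PNG images and a JSON manifest (with cell-level
#' ground-truth annotations) to `out_dir`. Deterministic given `config$seed`:
#' re-running with the same configuration reproduces identical bytes.
#'
#' Wells are drawn positive with probability `fraction_positive_wells`; images
#' inherit their well's label (serum status is a property of the well). Each
#' image holds `Poisson(mean_cells_per_image)` cells (truncated at >= 1),
#' placed without body overlap by rejection sampling. In a positive well each
#' cell carries a kinetoplast with probability
#' `p_cell_positive_given_well_positive`; a cell is labeled positive iff a
#' kinetoplast was rendered in it. Distractors: a dim nuclear blob at the cell
#' center, a small bright basal-body spot adjacent to the kinetoplast pole,
#' and extracellular bright speckles ("artifacts") placed outside all cell
#' bodies. Additive Gaussian noise is applied last and clipped to `[0, 1]`.
#'
#' @param config a [synth_config].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the [clift_manifest] (`manifest`) and the
#'   full ground truth (`truth`): one entry per image with cell geometry and
#'   rendered components.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- config$image_size[1]; h <- config$image_size[2]
  s <- config$magnification_scale
  sig_k <- config$kinetoplast_sigma_px * s

  with_seed(config$seed, {
    well_ids <- sprintf("W%02d", seq_len(config$n_wells))
    well_pos <- stats::runif(config$n_wells) < config$fraction_positive_wells
    records <- list(); cells_ann <- list(); truth <- list()

    for (wi in seq_len(config$n_wells)) {
      wlab <- if (well_pos[wi]) "positive" else "negative"
      for (ii in seq_len(config$images_per_well)) {
        image_id <- sprintf("%s_I%02d", well_ids[wi], ii)
        repeat {
          n_cells <- stats::rpois(1, config$mean_cells_per_image)
          if (n_cells >= 1L) break
        }
        canvas <- matrix(config$background_level, h, w)
        occupied <- matrix(FALSE, h, w)
        img_cells <- list()
        for (ci in seq_len(n_cells)) {
          g <- sample_cell(config, w, h, occupied)
          occupied <- occupied | g$mask
          pole <- sample(c(-1, 1), 1)
          dirx <- cos(g$orientation) * pole
          diry <- sin(g$orientation) * pole
          comps <- list()
          has_kineto <- well_pos[wi] &&
            stats::runif(1) < config$p_cell_positive_given_well_positive
          kx <- g$x + 0.35 * g$length * dirx
          ky <- g$y + 0.35 * g$length * diry
          if (has_kineto) {
            comps <- c(comps, list(list(type = "kinetoplast", x = kx, y = ky,
                                        sigma = sig_k,
                                        peak = config$kinetoplast_peak)))
          }
          if (stats::runif(1) < config$p_nucleus) {
            comps <- c(comps, list(list(type = "nucleus", x = g$x, y = g$y,
                                        sigma = 4 * sig_k,
                                        peak = stats::runif(1, 0.35, 0.50))))
          }
          if (stats::runif(1) < config$p_basal_body) {
            comps <- c(comps, list(list(
              type = "basal_body",
              x = kx + 2 * sig_k * dirx, y = ky + 2 * sig_k * diry,
              sigma = 0.6 * sig_k, peak = stats::runif(1, 0.5, 0.7))))
          }
          cell <- list(x = g$x, y = g$y, orientation = g$orientation,
                       length = g$length,
                       cytoplasm = stats::runif(1, 0.15, 0.30),
                       components = comps)
          rc <- render_cell(cell, canvas)
          canvas <- rc$canvas
          cell$mask <- NULL
          cell$label <- if (has_kineto) "positive" else "negative"
          img_cells[[ci]] <- cell
        }
        # extracellular artifacts
        n_art <- stats::rpois(1, config$artifacts_per_image)
        arts <- list()
        for (ai in seq_len(n_art)) {
          for (try in 1:100) {
            ax <- stats::runif(1, 4, w - 5); ay <- stats::runif(1, 4, h - 5)
            if (!occupied[round(ay) + 1L, round(ax) + 1L]) break
          }
          asig <- stats::runif(1, 1, 3); apk <- stats::runif(1, 0.6, 1.0)
          canvas <- add_spot(canvas, ax, ay, asig, apk)
          arts[[ai]] <- list(x = ax, y = ay, sigma = asig, peak = apk)
        }
        canvas[canvas > 1] <- 1
        if (config$noise_sigma > 0) {
          canvas <- canvas + matrix(stats::rnorm(h * w, 0, config$noise_sigma), h, w)
        }
        canvas[canvas < 0] <- 0; canvas[canvas > 1] <- 1
        fname <- paste0(image_id, ".png")
        png::writePNG(canvas, file.path(out_dir, fname))

        records[[image_id]] <- data.frame(
          well_id = well_ids[wi], image_path = file.path(out_dir, fname),
          magnification_scale = s, image_label = wlab, well_label = wlab,
          image_id = image_id, width = w, height = h, stringsAsFactors = FALSE)
        cells_ann[[file.path(out_dir, fname)]] <- do.call(rbind, lapply(
          img_cells, function(cl) data.frame(x = cl$x, y = cl$y,
                                             label = cl$label,
                                             stringsAsFactors = FALSE)))
        truth[[image_id]] <- list(well_id = well_ids[wi], well_label = wlab,
                                  image_label = wlab, cells = img_cells,
                                  artifacts = arts)
      }
    }
    records <- do.call(rbind, records)
    rownames(records) <- NULL
    manifest <- clift_manifest(records, cells_ann)
    # the on-disk manifest uses paths relative to its own directory so a
    # regenerated dataset is byte-identical wherever it lives
    rel <- records
    rel$image_path <- basename(rel$image_path)
    rel_cells <- cells_ann
    names(rel_cells) <- basename(names(rel_cells))
    write_manifest(clift_manifest(rel, rel_cells),
                   file.path(out_dir, "manifest.json"), "json")
    invisible(list(manifest = manifest, truth = truth,
                   manifest_path = file.path(out_dir, "manifest.json")))
  })
}
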