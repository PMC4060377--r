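#' Construct a well image
#'
#' The canonical pixel container of the pipeline: a single acquired field of a
#' CLIFT well as a numeric matrix of intensities in `[0, 1]`, row = image row
#' (y), column = image column (x). Coordinates elsewhere in the package are
#' 0-based `(x = column, y = row)` with pixel centers at integers.
#'
#' @param pixels numeric matrix with values in `[0, 1]`, at least 64 x 64.
#' @param well_id,image_id identifiers (non-empty strings).
#' @param magnification_scale positive scale factor; 1.0 is the reference
#'   50-fold magnification, 0.5 emulates 25-fold.
#' @param true_label optional ground-truth image label, `"positive"` or
#'   `"negative"`.
#' @return an object of class `well_image`.
#' @export
well_image <- function(pixels, well_id = "W00", image_id = "I00",
                       magnification_scale = 1.0, true_label = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_validation("pixels must be a numeric matrix")
  }
  if (nrow(pixels) < 64L || ncol(pixels) < 64L) {
    stop_validation("image must be at least 64 x 64 pixels, got %d x %d",
                    ncol(pixels), nrow(pixels))
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop_validation("pixel intensities must lie in [0, 1]")
  }
  if (!is.character(well_id) || !nzchar(well_id)) {
    stop_validation("well_id must be a non-empty string")
  }
  if (!is.numeric(magnification_scale) || magnification_scale <= 0) {
    stop_validation("magnification_scale must be > 0")
  }
  if (!is.null(true_label)) true_label <- parse_label(true_label)
  structure(list(pixels = pixels,
                 well_id = well_id,
                 image_id = image_id,
                 width = ncol(pixels),
                 height = nrow(pixels),
                 magnification_scale = magnification_scale,
                 true_label = true_label),
            class = "well_image")
}

#' @export
print.well_image <- function(x, ...) {
  cat(sprintf("<well_image> %s/%s  %d x %d px  scale %.2f  label %s\n",
              x$well_id, x$image_id, x$width, x$height,
              x$magnification_scale, x$true_label %||% "<none>"))
  invisible(x)
}

#' Load an image into canonical form
#'
#' Reads a PNG, JPEG or TIFF image and normalizes it for the pipeline:
#' RGB images are reduced to the green channel (FITC emission is captured
#' there; luminance mixing would dilute the fluorescence signal), and
#' intensities are scaled by the bit-depth maximum into `[0, 1]`.
#' Canonicalization is idempotent: a grayscale `[0, 1]` image is unchanged.
#'
#' @inheritParams well_image
#' @param path path to the image file.
#' @return a [well_image].
#' @export
load_image <- function(path, magnification_scale = 1.0,
                       well_id = "W00", image_id = NULL, true_label = NULL) {
  if (!file.exists(path)) stop_io("cannot read image file '%s'", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop_io(
                    "cannot decode image file '%s': %s", path, conditionMessage(e)))
  dat <- EBImage::imageData(img)
  if (length(dat) == 0L) stop_validation("zero-sized image in '%s'", path)
  if (length(dim(dat)) == 3L) {
    dat <- if (dim(dat)[3] >= 2L) dat[, , 2L] else dat[, , 1L]  # green channel
  }
  # EBImage stores [x, y]; the canonical matrix is [row = y, col = x]
  px <- t(dat)
  px[px < 0] <- 0; px[px > 1] <- 1
  well_image(px, well_id = well_id,
             image_id = image_id %||% tools::file_path_sans_ext(basename(path)),
             magnification_scale = magnification_scale, true_label = true_label)
}

# Manifest ---------------------------------------------------------------------

#' Construct a dataset manifest
#'
#' A manifest groups images into wells and carries ground-truth labels at the
#' well/image level and, optionally, cell-level annotations
#' (`data.frame(x, y, label)` in 0-based image coordinates).
#'
#' @param records data.frame with columns `well_id`, `image_path`,
#'   `magnification_scale` and optional `image_label`, `well_label`,
#'   `image_id`, `width`, `height`.
#' @param cells optional named list (by `image_path`) of cell annotation
#'   data.frames with columns `x`, `y`, `label`.
#' @return an object of class `clift_manifest`.
#' @export
clift_manifest <- function(records, cells = list()) {
  req <- c("well_id", "image_path", "magnification_scale")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop_validation("manifest records need columns: %s", paste(req, collapse = ", "))
  }
  records$well_id <- as.character(records$well_id)
  records$image_path <- as.character(records$image_path)
  records$magnification_scale <- as.numeric(records$magnification_scale)
  for (col in c("image_label", "well_label")) {
    records[[col]] <- if (col %in% names(records)) {
      parse_label(records[[col]], col)
    } else NA_character_
  }
  if (!"image_id" %in% names(records)) {
    records$image_id <- tools::file_path_sans_ext(basename(records$image_path))
  }
  if (anyDuplicated(records$image_path)) {
    stop_validation("duplicate image_path in manifest: '%s'",
                    records$image_path[duplicated(records$image_path)][1])
  }
  if (any(!nzchar(records$well_id) | is.na(records$well_id))) {
    stop_validation("every record must carry a non-empty well_id")
  }
  if (any(records$magnification_scale <= 0, na.rm = TRUE)) {
    stop_validation("magnification_scale must be > 0")
  }
  for (w in unique(records$well_id)) {
    rows <- records[records$well_id == w, ]
    wl <- unique(rows$well_label[!is.na(rows$well_label)])
    if (length(wl) > 1L) {
      stop_validation("well '%s' carries conflicting well_label values", w)
    }
    il <- rows$image_label[!is.na(rows$image_label)]
    if (length(wl) == 1L && length(il) > 0L && any(il != wl)) {
      stop_validation("well '%s': image labels conflict with well_label '%s'", w, wl)
    }
  }
  # cell centroids must lie inside their image bounds when bounds are known
  if (length(cells)) {
    for (p in names(cells)) {
      an <- cells[[p]]
      if (is.null(an) || !nrow(an)) next
      an$label <- parse_label(an$label, "cell label")
      cells[[p]] <- an
      r <- records[records$image_path == p, , drop = FALSE]
      if (nrow(r) == 1L && !is.null(r$width) && !is.na(r$width)) {
        if (any(an$x < 0 | an$x > r$width - 1 | an$y < 0 | an$y > r$height - 1)) {
          stop_validation("cell annotation outside image bounds for '%s'", p)
        }
      }
    }
  }
  structure(list(records = records, cells = cells), class = "clift_manifest")
}

#' @export
print.clift_manifest <- function(x, ...) {
  cat(sprintf("<clift_manifest> %d images in %d wells, %d annotated images\n",
              nrow(x$records), length(unique(x$records$well_id)),
              sum(vapply(x$cells, function(a) !is.null(a) && nrow(a) > 0, TRUE))))
  invisible(x)
}

#' Load a dataset manifest from CSV or JSON
#'
#' The CSV dialect is flat with header
#' `well_id,image_path,magnification_scale,image_label,well_label`.
#' The JSON dialect is `{"images": [...]}` where each element carries the same
#' fields plus optional `image_id`, `width`, `height` and
#' `cells: [{x, y, label}]`. Labels are parsed case-insensitively from
#' positive/negative.
#'
#' @param path manifest file; format chosen by extension (`.json` vs other).
#' @return a [clift_manifest].
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop_io("cannot read manifest file '%s'", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    imgs <- doc$images %||% doc
    grab <- function(el, f) el[[f]] %||% NA
    records <- do.call(rbind, lapply(imgs, function(el) {
      data.frame(well_id = as.character(grab(el, "well_id")),
                 image_path = as.character(grab(el, "image_path")),
                 magnification_scale = as.numeric(grab(el, "magnification_scale")),
                 image_label = as.character(grab(el, "image_label")),
                 well_label = as.character(grab(el, "well_label")),
                 image_id = as.character(grab(el, "image_id")),
                 width = as.numeric(grab(el, "width")),
                 height = as.numeric(grab(el, "height")),
                 stringsAsFactors = FALSE)
    }))
    records$image_id[is.na(records$image_id)] <-
      tools::file_path_sans_ext(basename(records$image_path[is.na(records$image_id)]))
    cells <- list()
    for (el in imgs) {
      if (!is.null(el$cells) && length(el$cells)) {
        cells[[el$image_path]] <- do.call(rbind, lapply(el$cells, function(cc) {
          data.frame(x = as.numeric(cc$x), y = as.numeric(cc$y),
                     label = as.character(cc$label), stringsAsFactors = FALSE)
        }))
      }
    }
    # resolve paths relative to the manifest's own directory
    base <- dirname(normalizePath(path))
    resolve <- vapply(records$image_path, function(p) {
      if (!file.exists(p) && file.exists(file.path(base, p))) {
        file.path(base, p)
      } else p
    }, "")
    names(cells) <- vapply(names(cells), function(p) {
      if (!file.exists(p) && file.exists(file.path(base, p))) {
        file.path(base, p)
      } else p
    }, "")
    records$image_path <- unname(resolve)
    clift_manifest(records, cells)
  } else {
    records <- utils::read.csv(path, stringsAsFactors = FALSE,
                               colClasses = "character")
    clift_manifest(records)
  }
}

#' Write a dataset manifest
#'
#' Inverse of [load_manifest()]; `load_manifest(write_manifest(m, p))` is the
#' identity on records and cell annotations.
#'
#' @param manifest a [clift_manifest].
#' @param path output file.
#' @param format `"json"` (supports cell annotations) or `"csv"` (flat).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(manifest, "clift_manifest"))
  r <- manifest$records
  if (format == "csv") {
    cols <- c("well_id", "image_path", "magnification_scale",
              "image_label", "well_label")
    utils::write.csv(r[, cols], path, row.names = FALSE, na = "")
  } else {
    imgs <- lapply(seq_len(nrow(r)), function(i) {
      el <- list(well_id = r$well_id[i],
                 image_id = r$image_id[i],
                 image_path = r$image_path[i],
                 magnification_scale = r$magnification_scale[i])
      for (f in c("image_label", "well_label", "width", "height")) {
        if (!is.null(r[[f]]) && !is.na(r[[f]][i])) el[[f]] <- r[[f]][i]
      }
      an <- manifest$cells[[r$image_path[i]]]
      if (!is.null(an) && nrow(an)) {
        el$cells <- lapply(seq_len(nrow(an)), function(j) as.list(an[j, ]))
      }
      el
    })
    jsonlite::write_json(list(images = imgs), path,
                         auto_unbox = TRUE, digits = 8, pretty = TRUE)
  }
  invisible(path)
}

#' Summarize a labeled dataset
#'
#' Counts and class percentages at one level of the hierarchy. Percentages are
#' computed from the integer counts and rounded half-up to one decimal.
#'
#' @param manifest a [clift_manifest].
#' @param level `"wells"`, `"images"` or `"cells"`.
#' @return list with `n`, `n_positive`, `n_negative`, `pct_positive`,
#'   `pct_negative`.
#' @export
dataset_summary <- function(manifest, level = c("images", "wells", "cells")) {
  level <- match.arg(level)
  stopifnot(inherits(manifest, "clift_manifest"))
  r <- manifest$records
  labels <- switch(level,
    images = r$image_label,
    wells = {
      w <- r[!duplicated(r$well_id), ]
      w$well_label
    },
    cells = {
      if (!length(manifest$cells)) character(0)
      else unlist(lapply(manifest$cells, function(a) a$label), use.names = FALSE)
    })
  if (length(labels) == 0L || all(is.na(labels))) {
    stop_validation("no labels available at level '%s'", level)
  }
  if (anyNA(labels)) stop_validation("missing labels at level '%s'", level)
  n <- length(labels)
  np <- sum(labels == "positive")
  list(n = n, n_positive = np, n_negative = n - np,
       pct_positive = round_half_up(100 * np / n, 1),
       pct_negative = round_half_up(100 * (n - np) / n, 1))
}
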