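#' Classify an image from its cell labels
#'
#' Majority vote over the classified cells of the image. An image pre-screened
#' as presumed-negative is negative without any cell ever being classified.
#' A candidate-positive image whose every candidate was discarded as an
#' extracellular artifact has no cells to vote and is negative (a kinetoplast
#' is an organelle and must lie inside a cell). A tied cell vote goes to
#' positive: at image level a false positive is recoverable by the well vote,
#' while a false negative at the first steps is what the screening design
#' tries hardest to avoid.
#'
#' @param cell_labels character vector of per-cell labels
#'   (positive/negative); may be empty.
#' @param prescreen `"candidate_positive"` or `"presumed_negative"`.
#' @return `"positive"` or `"negative"`.
#' @export
classify_image <- function(cell_labels, prescreen = "candidate_positive") {
  if (!prescreen %in% c("candidate_positive", "presumed_negative")) {
    stop_validation("invalid prescreen status '%s'", prescreen)
  }
  if (prescreen == "presumed_negative") return("negative")
  if (!length(cell_labels)) return("negative")
  cell_labels <- parse_label(cell_labels, "cell label")
  npos <- sum(cell_labels == "positive")
  nneg <- length(cell_labels) - npos
  if (npos >= nneg) "positive" else "negative"
}

#' Classify a well from its image labels
#'
#' Majority vote over the images of the well; when exactly as many images
#' are positive as negative the decision is suspended (reject option) and
#' deferred to the physician. Suspended wells are always surfaced, never
#' silently resolved.
#'
#' @param image_labels non-empty character vector of per-image labels.
#' @return an object of class `well_decision`: list with `decision`
#'   (positive/negative/suspended), `n_pos_images`, `n_neg_images` and
#'   `image_labels`.
#' @export
classify_well <- function(image_labels) {
  if (!length(image_labels)) {
    stop_validation("a well needs at least one image label")
  }
  image_labels <- parse_label(image_labels, "image label")
  npos <- sum(image_labels == "positive")
  nneg <- length(image_labels) - npos
  decision <- if (npos > nneg) "positive" else if (nneg > npos) "negative"
              else "suspended"
  structure(list(decision = decision, n_pos_images = npos,
                 n_neg_images = nneg, image_labels = image_labels),
            class = "well_decision")
}

#' @export
print.well_decision <- function(x, ...) {
  cat(sprintf("<well_decision> %s (%d positive vs %d negative images)\n",
              x$decision, x$n_pos_images, x$n_neg_images))
  invisible(x)
}

# Process one image end to end with a trained model; returns the per-cell
# rows and the image-level outcome.
process_image <- function(image, model, screening = screening_params(),
                          cell = cell_params()) {
  ps <- prescreen_image(image, screening)
  cells <- list(); pred <- character(0)
  if (ps$status == "candidate_positive") {
    cells <- extract_cells(image, ps$candidates, cell)
    if (length(cells)) {
      feats <- t(vapply(cells, extract_features, numeric(60)))
      pred <- predict(model, feats)
    }
  }
  label <- classify_image(pred, ps$status)
  cell_rows <- if (length(cells)) {
    data.frame(well_id = image$well_id, image_id = image$image_id,
               cell_id = vapply(cells, `[[`, "", "cell_id"),
               x = vapply(cells, function(cl) cl$cell_centroid[["x"]], 0),
               y = vapply(cells, function(cl) cl$cell_centroid[["y"]], 0),
               prediction = pred, stringsAsFactors = FALSE)
  } else {
    data.frame(well_id = character(0), image_id = character(0),
               cell_id = character(0), x = numeric(0), y = numeric(0),
               prediction = character(0))
  }
  list(cells = cell_rows, prescreen = ps$status,
       n_candidates = length(ps$candidates), label = label)
}

#' Run the full classification pipeline over a dataset
#'
#' Executes screening, cell localization, feature extraction, cell
#' classification and the two majority votes for every image of every well
#' in the manifest, and returns the full audit trail. Any unreadable image
#' aborts the run with an error naming it (no silent skips).
#'
#' @param manifest a [clift_manifest()].
#' @param model a trained `clift_model`.
#' @param screening a [screening_params()].
#' @param cell a [cell_params()].
#' @return list of data.frames: `cells` (per-cell predictions), `images`
#'   (per-image prescreen status, candidate count, label and truth when
#'   known) and `wells` (per-well decision, image counts and truth).
#' @export
run_pipeline <- function(manifest, model, screening = screening_params(),
                         cell = cell_params()) {
  stopifnot(inherits(manifest, "clift_manifest"),
            inherits(model, "clift_model"))
  r <- manifest$records
  cell_rows <- list(); img_rows <- list()
  for (i in seq_len(nrow(r))) {
    img <- load_image(r$image_path[i], r$magnification_scale[i],
                      well_id = r$well_id[i], image_id = r$image_id[i])
    res <- process_image(img, model, screening, cell)
    cell_rows[[i]] <- res$cells
    img_rows[[i]] <- data.frame(
      well_id = r$well_id[i], image_id = r$image_id[i],
      prescreen = res$prescreen, n_candidates = res$n_candidates,
      n_cells = nrow(res$cells), label = res$label,
      truth = r$image_label[i] %||% NA_character_, stringsAsFactors = FALSE)
  }
  images <- do.call(rbind, img_rows)
  wells <- do.call(rbind, lapply(split(images, images$well_id), function(g) {
    wd <- classify_well(g$label)
    data.frame(well_id = g$well_id[1], decision = wd$decision,
               n_pos_images = wd$n_pos_images, n_neg_images = wd$n_neg_images,
               truth = r$well_label[match(g$well_id[1], r$well_id)] %||%
                 NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(wells) <- NULL
  list(cells = do.call(rbind, cell_rows), images = images, wells = wells)
}

#' End-to-end one-well-out cross-validated evaluation
#'
#' The complete assessment loop on a labeled dataset: every image is screened
#' and its cells localized and labeled from the manifest's ground-truth
#' annotations once; then, for each well in turn, a classifier is trained on
#' the cells of all other wells and applied to the held-out well, its image
#' labels are derived by cell majority voting (with the pre-screen shortcut)
#' and its well decision by image majority voting with the tie-suspension
#' rule. Returns pooled contingency tables and metrics at cell, image and
#' well level.
#'
#' @param manifest a labeled [clift_manifest()] with cell annotations.
#' @param seed integer seed (drives per-fold classifier training).
#' @param screening a [screening_params()].
#' @param cell a [cell_params()].
#' @param progress print per-fold progress lines.
#' @return list with `cells`, `images`, `wells` data.frames,
#'   `tables` (cell/image/well [contingency_table()]s) and
#'   `metrics` (cell/image/well [metrics_report()]s).
#' @export
crossval_pipeline <- function(manifest, seed = 1L,
                              screening = screening_params(),
                              cell = cell_params(), progress = FALSE) {
  stopifnot(inherits(manifest, "clift_manifest"))
  r <- manifest$records
  if (any(is.na(r$image_label))) {
    stop_validation("cross-validated evaluation needs image labels")
  }
  # pass 1: screening + cell localization + features, once per image
  per_image <- vector("list", nrow(r))
  for (i in seq_len(nrow(r))) {
    img <- load_image(r$image_path[i], r$magnification_scale[i],
                      well_id = r$well_id[i], image_id = r$image_id[i],
                      true_label = r$image_label[i])
    ps <- prescreen_image(img, screening)
    cells <- list()
    if (ps$status == "candidate_positive") {
      cells <- extract_cells(img, ps$candidates, cell)
      cells <- suppressWarnings(
        match_annotations(cells, manifest$cells[[r$image_path[i]]]))
    }
    per_image[[i]] <- list(status = ps$status,
                           n_candidates = length(ps$candidates),
                           features = features_table(cells))
  }
  feats <- do.call(rbind, lapply(per_image, `[[`, "features"))
  labeled <- !is.na(feats$label)
  fx <- as.matrix(feats[labeled, feature_names()])
  fy <- feats$label[labeled]
  fw <- feats$well_id[labeled]

  uw <- sort(unique(r$well_id))
  if (length(uw) < 3L) stop_validation("need >= 3 wells for one-well-out CV")
  cell_pred <- rep(NA_character_, nrow(feats))
  img_label <- rep(NA_character_, nrow(r))
  for (k in seq_along(uw)) {
    w <- uw[k]
    tr <- fw != w
    if (length(unique(fy[tr])) < 2L || min(table(fy[tr])) < 10L) {
      warn_cliftcad("fold '%s' skipped: insufficient training classes", w)
      next
    }
    model <- train_cell_classifier(fx[tr, , drop = FALSE], fy[tr], fw[tr],
                                   seed = seed + k)
    if (progress) message(sprintf("fold %s: C=%g gamma=%.4g", w,
                                  model$best$cost, model$best$gamma))
    in_well <- which(r$well_id == w)
    for (i in in_well) {
      pi <- per_image[[i]]
      pred <- character(0)
      if (nrow(pi$features)) {
        idx <- which(feats$image_id == r$image_id[i])
        pred <- predict(model, as.matrix(feats[idx, feature_names()]))
        cell_pred[idx] <- pred
      }
      img_label[i] <- classify_image(pred, pi$status)
    }
  }
  images <- data.frame(well_id = r$well_id, image_id = r$image_id,
                       prescreen = vapply(per_image, `[[`, "", "status"),
                       n_candidates = vapply(per_image, `[[`, 0L, "n_candidates"),
                       label = img_label, truth = r$image_label,
                       stringsAsFactors = FALSE)
  done <- !is.na(images$label)
  wells <- do.call(rbind, lapply(split(images[done, ], images$well_id[done]),
                                 function(g) {
    wd <- classify_well(g$label)
    data.frame(well_id = g$well_id[1], decision = wd$decision,
               n_pos_images = wd$n_pos_images, n_neg_images = wd$n_neg_images,
               truth = r$well_label[match(g$well_id[1], r$well_id)],
               stringsAsFactors = FALSE)
  }))
  rownames(wells) <- NULL
  cells_out <- cbind(feats[, c("well_id", "image_id", "cell_id", "label")],
                     prediction = cell_pred)
  okc <- !is.na(cells_out$prediction) & !is.na(cells_out$label)
  tables <- list(
    cell = tabulate_decisions(cells_out$label[okc], cells_out$prediction[okc]),
    image = tabulate_decisions(images$truth[done], images$label[done]),
    well = tabulate_decisions(wells$truth, wells$decision))
  list(cells = cells_out, images = images, wells = wells, tables = tables,
       metrics = lapply(tables, metrics_report))
}
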