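#' Train the cell classifier
#'
#' Fits a radial-kernel support vector machine on standardized features with
#' class weights inverse to class frequency. Hyperparameters (cost `C` in
#' \{0.1, 1, 10, 100\}, kernel width `gamma` in \{0.25, 0.5, 1, 2, 4\} /
#' n_features) are chosen by stratified inner 5-fold cross-validation
#' maximizing balanced accuracy; ties prefer the smallest `C`, then the
#' smallest `gamma`. Standardization statistics come from the training data
#' only; zero-variance features get scale 1 and are flagged. Deterministic
#' given `seed`.
#'
#' @param x numeric feature matrix (n cells x 60), columns in
#'   [feature_names()] order.
#' @param y character/factor labels, values positive/negative, >= 10 cells
#'   per class.
#' @param wells character well id per cell; >= 2 distinct wells required.
#' @param seed integer seed driving the inner-CV fold assignment.
#' @param cost_grid,gamma_grid hyperparameter grids.
#' @return an object of class `clift_model` with elements `center`, `scale`,
#'   `fit` (the svm object), `best` (chosen hyperparameters), `inner_cv`
#'   (grid search results) and `meta`.
#' @export
train_cell_classifier <- function(x, y, wells, seed = 1L,
                                  cost_grid = c(0.1, 1, 10, 100),
                                  gamma_grid = c(0.25, 0.5, 1, 2, 4) / ncol(x)) {
  x <- as.matrix(x)
  y <- parse_label(y)
  if (anyNA(y)) stop_validation("all training cells must be labeled")
  if (length(unique(y)) < 2L) {
    stop_validation("training data contains a single class")
  }
  if (min(table(y)) < 10L) {
    stop_validation("need >= 10 cells per class, got %s",
                    paste(table(y), collapse = "/"))
  }
  if (length(unique(wells)) < 2L) {
    stop_validation("need cells from >= 2 distinct wells")
  }
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  flat <- !is.finite(scl) | scl == 0
  scl[flat] <- 1
  xs <- scale(x, center = center, scale = scl)
  yf <- factor(y, levels = .clift_labels)
  wts <- as.numeric(length(y) / (2 * table(yf)[.clift_labels]))
  names(wts) <- .clift_labels

  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cl in .clift_labels) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(1:5, length(idx))
    }
    f
  })
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  grid$balanced_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    pred <- rep(NA_character_, length(y))
    for (k in 1:5) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2L) next
      fit <- e1071::svm(xs[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        class.weights = wts, scale = FALSE)
      pred[!tr] <- as.character(predict(fit, xs[!tr, , drop = FALSE]))
    }
    ok <- !is.na(pred)
    sens <- mean(pred[ok & y == "positive"] == "positive")
    spec <- mean(pred[ok & y == "negative"] == "negative")
    grid$balanced_accuracy[g] <- (sens + spec) / 2
  }
  best <- grid[order(-grid$balanced_accuracy, grid$cost, grid$gamma), ][1, ]
  fit <- e1071::svm(xs, yf, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, class.weights = wts, scale = FALSE)
  structure(list(center = center, scale = scl, flat_features = which(flat),
                 fit = fit,
                 best = list(cost = best$cost, gamma = best$gamma,
                             balanced_accuracy = best$balanced_accuracy),
                 inner_cv = grid,
                 meta = list(n = length(y), class_counts = table(y),
                             wells = sort(unique(wells)), seed = seed,
                             feature_names = colnames(x) %||% feature_names())),
            class = "clift_model")
}

#' @export
print.clift_model <- function(x, ...) {
  cat(sprintf(paste0("<clift_model> svm radial C=%g gamma=%.4g ",
                     "(inner-CV balanced accuracy %.3f)\n  trained on %d cells ",
                     "(%s) from %d wells\n"),
              x$best$cost, x$best$gamma, x$best$balanced_accuracy,
              x$meta$n, paste(names(x$meta$class_counts),
                              x$meta$class_counts, collapse = ", "),
              length(x$meta$wells)))
  invisible(x)
}

#' Predict cell labels
#'
#' Applies the stored standardization and the trained decision rule.
#'
#' @param object a `clift_model`.
#' @param newdata numeric feature matrix (n x 60).
#' @param ... unused.
#' @return character vector of positive/negative labels.
#' @export
predict.clift_model <- function(object, newdata, ...) {
  if (is.null(object$fit)) stop_state("model has not been trained")
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(character(0))
  if (ncol(newdata) != length(object$center)) {
    stop_validation("feature matrix has %d columns, model expects %d",
                    ncol(newdata), length(object$center))
  }
  xs <- scale(newdata, center = object$center, scale = object$scale)
  as.character(predict(object$fit, xs))
}

#' One-well-out cross-validation of the cell classifier
#'
#' One fold per well: the cells of the held-out well form the test set, all
#' other wells the training set, so no cell-level information leaks between
#' training and test of the same serum. Standardization and hyperparameter
#' selection are redone inside every fold from its training cells only.
#' Folds whose training set degenerates to a single class are skipped with a
#' warning and reported.
#'
#' @inheritParams train_cell_classifier
#' @return list with `predictions` (data.frame: well_id, cell index, truth,
#'   prediction), `table` (pooled [contingency_table()]), `per_well`
#'   (data.frame of per-well accuracy) and `skipped_wells`.
#' @export
one_well_out_cv <- function(x, y, wells, seed = 1L) {
  x <- as.matrix(x)
  y <- parse_label(y)
  wells <- as.character(wells)
  uw <- sort(unique(wells))
  if (length(uw) < 3L) stop_validation("need >= 3 wells for one-well-out CV")
  if (anyNA(y)) stop_validation("every cell must be labeled")
  pred <- rep(NA_character_, length(y))
  skipped <- character(0)
  for (k in seq_along(uw)) {
    te <- wells == uw[k]
    if (length(unique(y[!te])) < 2L || min(table(y[!te])) < 10L) {
      warn_cliftcad("fold '%s' skipped: training set lacks both classes", uw[k])
      skipped <- c(skipped, uw[k])
      next
    }
    model <- train_cell_classifier(x[!te, , drop = FALSE], y[!te],
                                   wells[!te], seed = seed + k)
    pred[te] <- predict(model, x[te, , drop = FALSE])
  }
  ok <- !is.na(pred)
  tab <- tabulate_decisions(y[ok], pred[ok])
  per_well <- do.call(rbind, lapply(uw, function(w) {
    i <- wells == w & ok
    data.frame(well_id = w, n = sum(i),
               accuracy = if (any(i)) mean(pred[i] == y[i]) else NA_real_)
  }))
  list(predictions = data.frame(well_id = wells, index = seq_along(y),
                                truth = y, prediction = pred,
                                stringsAsFactors = FALSE),
       table = tab, per_well = per_well, skipped_wells = skipped)
}
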