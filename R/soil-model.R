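#' Fit a weighted-feature soil-differentiation model
#'
#' Projects the per-strike features onto a single differentiation level
#' `L = sum(W_i * F_i)` (features standardized first) and learns the
#' weights `W` that best separate the soil classes along that axis.  The
#' objective is the minimum over class pairs of the Fisher-like ratio
#' `|mean_L(c1) - mean_L(c2)| / (sd_L(c1) + sd_L(c2) + 1e-6)`, maximized
#' by seeded multi-restart Nelder-Mead over unit-norm weight vectors
#' (deterministic given `seed`).  Weights below `sparsity` of the norm are
#' zeroed after the fit, approximating feature-subset selection.  Classes
#' are ordered by their mean level and decision thresholds placed at the
#' midpoints of adjacent class means.  An outlier-exclusion rectangle in
#' centroid space is calibrated from the training centroids (1.25 x their
#' maxima) unless explicit bounds are supplied.
#'
#' @param features Tibble with one row per strike: the feature columns
#'   plus a class-label column.
#' @param class_col Name of the label column (default `"soil"`).
#' @param feature_cols Feature columns to weight.  The default uses all
#'   six; `c("sx", "sy")` gives the centroid-only model.
#' @param seed Integer seed for the restart draws.
#' @param n_restarts Random restarts on top of the per-feature basis
#'   starts.
#' @param sparsity Weights with `|w| < sparsity` (of the unit norm) are
#'   zeroed post-fit.
#' @param exclusion Optional `c(x_max, y_max)` outlier rectangle in
#'   centroid units; `NULL` calibrates it from the training data.
#' @return A `soil_model` object: classes (ordered by mean level),
#'   unit-norm `weights`, the standardization (`center`, `scale`),
#'   `thresholds`, per-class level statistics, the exclusion rectangle,
#'   the achieved objective, and a `separable` flag (adjacent classes
#'   farther apart than their summed level spreads).
#' @export
fit_soil_model <- function(features, class_col = "soil",
                           feature_cols = SOIL_FEATURES,
                           seed = 1L, n_restarts = 20L, sparsity = 0.05,
                           exclusion = NULL) {
  if (!class_col %in% names(features)) {
    stop_solegait(paste0("no class column '", class_col, "'"), "fit")
  }
  missing_cols <- setdiff(feature_cols, names(features))
  if (length(missing_cols) > 0) {
    stop_solegait(
      paste0("missing feature column(s): ", paste(missing_cols, collapse = ", ")),
      "fit"
    )
  }
  y <- as.character(features[[class_col]])
  counts <- table(y)
  if (length(counts) < 2) {
    stop_solegait("need at least 2 classes", "fit")
  }
  if (any(counts < 3)) {
    stop_solegait(
      paste0(
        "every class needs at least 3 strikes; short: ",
        paste(names(counts)[counts < 3], collapse = ", ")
      ),
      "fit"
    )
  }
  X <- as.matrix(features[feature_cols])
  if (any(!is.finite(X))) {
    stop_solegait("features contain non-finite values", "fit")
  }
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  yf <- factor(y)

  nc <- as.integer(table(yf))
  k <- length(nc)
  lt <- lower.tri(diag(k))

  # Separation of class levels for a matrix of candidate directions
  # (columns): min over class pairs of |mean difference| / (sd sum + eps).
  batch_objective <- function(W) {
    norms <- sqrt(colSums(W^2))
    W <- sweep(W, 2, pmax(norms, 1e-12), "/")
    L <- Xs %*% W
    mu <- rowsum(L, yf) / nc
    ss <- rowsum(L^2, yf)
    s <- sqrt(pmax((ss - nc * mu^2) / (nc - 1), 0))
    vapply(seq_len(ncol(W)), function(j) {
      min(abs(outer(mu[, j], mu[, j], "-"))[lt] /
        (outer(s[, j], s[, j], "+")[lt] + 1e-6))
    }, numeric(1))
  }
  objective <- function(w) batch_objective(matrix(w, ncol = 1))

  # The objective is non-smooth (a min of ratios), so Nelder-Mead alone
  # stalls in local basins: screen a large seeded set of random directions
  # first, then polish the leaders.
  p <- length(feature_cols)
  set.seed(seed)
  screen <- cbind(diag(p), matrix(rnorm(200 * n_restarts * p), nrow = p))
  vals <- batch_objective(screen)
  leaders <- screen[, order(vals, decreasing = TRUE)[seq_len(n_restarts)], drop = FALSE]
  best_w <- leaders[, 1]
  best_val <- vals[order(vals, decreasing = TRUE)[1]]
  for (i in seq_len(ncol(leaders))) {
    fit <- optim(leaders[, i], objective,
      method = "Nelder-Mead",
      control = list(fnscale = -1, maxit = 1000, reltol = 1e-12)
    )
    if (fit$value > best_val) {
      best_val <- fit$value
      best_w <- fit$par
    }
  }
  w <- best_w / sqrt(sum(best_w^2))
  w[abs(w) < sparsity] <- 0
  if (all(w == 0)) w <- best_w / sqrt(sum(best_w^2))
  w <- w / sqrt(sum(w^2))
  if (w[which.max(abs(w))] < 0) w <- -w
  final_obj <- objective(w)

  L <- drop(Xs %*% w)
  stats <- tibble::tibble(
    class = levels(yf),
    n = as.integer(table(yf)),
    mean_level = as.numeric(tapply(L, yf, mean)),
    sd_level = as.numeric(tapply(L, yf, sd))
  ) |>
    dplyr::arrange(.data$mean_level)
  thresholds <- (head(stats$mean_level, -1) + tail(stats$mean_level, -1)) / 2

  if (is.null(exclusion)) {
    exclusion <- c(
      x_max = 1.25 * max(features$sx),
      y_max = 1.25 * max(features$sy)
    )
  } else {
    exclusion <- c(x_max = exclusion[[1]], y_max = exclusion[[2]])
  }

  structure(
    list(
      classes = stats$class,
      weights = setNames(w, feature_cols),
      center = setNames(as.numeric(center), feature_cols),
      scale = setNames(as.numeric(scale), feature_cols),
      feature_cols = feature_cols,
      thresholds = thresholds,
      class_stats = stats,
      exclusion = exclusion,
      objective = final_obj,
      separable = final_obj >= 1,
      seed = as.integer(seed)
    ),
    class = "soil_model"
  )
}

#' @export
print.soil_model <- function(x, ...) {
  cat("<soil_model>", length(x$classes), "classes:",
    paste(x$classes, collapse = " < "), "\n")
  cat("  objective (min pairwise separation):", format(x$objective, digits = 4),
    if (x$separable) "(separable)" else "(NOT separable)", "\n")
  nz <- x$weights[x$weights != 0]
  cat("  weights:", paste(names(nz), format(nz, digits = 3), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Differentiation level of feature vectors under a fitted model
#'
#' `L = sum(W_i * scaled(F_i))`, with the model's stored standardization
#' applied first.
#'
#' @param features Tibble with the model's feature columns.
#' @param model A [fit_soil_model()] object.
#' @return Numeric vector of levels, one per row.
#' @export
differentiation_level <- function(features, model) {
  if (!inherits(model, "soil_model")) {
    stop_solegait("model must be a fitted soil_model", "state")
  }
  X <- as.matrix(features[model$feature_cols])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  drop(Xs %*% model$weights)
}

#' Classify strikes by soil type
#'
#' Assigns each feature row the class whose level interval (bounded by the
#' model thresholds) contains its differentiation level; a level exactly at
#' a threshold goes to the lower-level class.  A strike whose spectral
#' centroid falls outside the exclusion rectangle `[0, x_max] x [0, y_max]`
#' is flagged an outlier (the class is still reported).
#'
#' @param features Tibble with feature columns (and `sx`, `sy`).
#' @param model A [fit_soil_model()] object.
#' @return `features` with `level`, `pred_class` and `outlier` columns.
#' @export
classify_soil <- function(features, model) {
  L <- differentiation_level(features, model)
  idx <- vapply(L, function(l) 1L + sum(model$thresholds < l), integer(1))
  features |>
    dplyr::mutate(
      level = L,
      pred_class = model$classes[idx],
      outlier = .data$sx < 0 | .data$sx > model$exclusion[["x_max"]] |
        .data$sy < 0 | .data$sy > model$exclusion[["y_max"]]
    )
}

#' Detection rate of a fitted model on labelled strikes
#'
#' Fraction of non-outlier strikes whose predicted class equals the label.
#'
#' @param features Labelled feature tibble (class column as in the fit).
#' @param model A [fit_soil_model()] object.
#' @param class_col Name of the label column.
#' @return A fraction in `[0, 1]`; `NA` (with a warning) if every strike
#'   is an outlier.
#' @export
detection_rate <- function(features, model, class_col = "soil") {
  if (nrow(features) == 0) {
    stop_solegait("detection rate undefined on an empty set", "parameter")
  }
  scored <- classify_soil(features, model)
  kept <- scored[!scored$outlier, ]
  if (nrow(kept) == 0) {
    warn_solegait("all strikes fell in the exclusion region", "all_outliers")
    return(NA_real_)
  }
  mean(kept$pred_class == as.character(kept[[class_col]]))
}

#' @describeIn fit_soil_model Tidy the fitted weights: one row per feature
#'   with its weight and standardization.
#' @param x A `soil_model`.
#' @param ... Unused.
#' @export
tidy.soil_model <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_cols,
    weight = as.numeric(x$weights),
    center = as.numeric(x$center),
    scale = as.numeric(x$scale)
  )
}

#' @describeIn fit_soil_model One-row model summary (classes, objective,
#'   separability, exclusion bounds).
#' @export
glance.soil_model <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    objective = x$objective,
    separable = x$separable,
    exclusion_x = x$exclusion[["x_max"]],
    exclusion_y = x$exclusion[["y_max"]],
    seed = x$seed
  )
}

#' Plot differentiation levels by class
#'
#' Strip plot of per-strike levels under the model, one column per soil,
#' with the decision thresholds as horizontal lines.
#'
#' @param object A `soil_model`.
#' @param features Labelled feature tibble to score.
#' @param class_col Name of the label column.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.soil_model <- function(object, features, class_col = "soil", ...) {
  scored <- classify_soil(features, object)
  scored$label <- factor(as.character(scored[[class_col]]), levels = object$classes)
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$label, y = .data$level)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$outlier), width = 0.15, height = 0) +
    ggplot2::geom_hline(yintercept = object$thresholds, linetype = "dashed") +
    ggplot2::labs(x = "soil", y = "differentiation level L", colour = "outlier")
}

#' Serialize / restore a soil model
#'
#' The model (classes, weights, scaling, thresholds, exclusion region,
#' seed) round-trips through YAML or JSON so a fitted model can ship with
#' a device configuration.
#'
#' @param model A `soil_model`.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly (`write_soil_model`); a `soil_model`
#'   (`read_soil_model`).
#' @export
write_soil_model <- function(model, path) {
  payload <- list(
    classes = model$classes,
    weights = as.list(model$weights),
    center = as.list(model$center),
    scale = as.list(model$scale),
    feature_cols = model$feature_cols,
    thresholds = model$thresholds,
    class_stats = as.data.frame(model$class_stats),
    exclusion = as.list(model$exclusion),
    objective = model$objective,
    separable = model$separable,
    seed = model$seed
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_soil_model
#' @export
read_soil_model <- function(path) {
  payload <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  structure(
    list(
      classes = as.character(payload$classes),
      weights = setNames(as.numeric(unlist(payload$weights)), payload$feature_cols),
      center = setNames(as.numeric(unlist(payload$center)), payload$feature_cols),
      scale = setNames(as.numeric(unlist(payload$scale)), payload$feature_cols),
      feature_cols = as.character(payload$feature_cols),
      thresholds = as.numeric(unlist(payload$thresholds)),
      class_stats = tibble::as_tibble(payload$class_stats),
      exclusion = c(
        x_max = as.numeric(payload$exclusion$x_max),
        y_max = as.numeric(payload$exclusion$y_max)
      ),
      objective = as.numeric(payload$objective),
      separable = as.logical(payload$separable),
      seed = as.integer(payload$seed)
    ),
    class = "soil_model"
  )
}
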