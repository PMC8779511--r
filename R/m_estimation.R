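activity_levels <- c("low", "moderate", "high")

#' Activity-level classification probabilities
#'
#' @param p_low,p_moderate,p_high Probabilities of the low, moderate and
#'   high standing activity levels; each in `[0, 1]`, summing to 1.
#' @return A list of class `activity_probabilities`.
#' @export
activity_probabilities <- function(p_low, p_moderate, p_high) {
  p <- c(low = unname(p_low), moderate = unname(p_moderate),
         high = unname(p_high))
  if (any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("probabilities must sum to 1 (got ", format(sum(p), digits = 12),
         ")", call. = FALSE)
  structure(as.list(p), class = "activity_probabilities")
}

#' Metabolic rate from posture and activity-level probabilities
#'
#' A sitting person's metabolic rate varies so little that a single
#' representative constant is used (default 72.5 W/m^2). A standing person's
#' rate is the probability-weighted sum of the three level boundaries:
#' `M = Pl*Ml + Pm*Mm + Ph*Mh` (defaults 75, 125, 174 W/m^2), a convex
#' combination that always lies between `Ml` and `Mh`.
#'
#' @param posture `"Sit"` or `"Stand"`.
#' @param probabilities An [activity_probabilities()]; required for
#'   standing, ignored for sitting.
#' @param config A [pipeline_config()] supplying `m_sitting` and `m_levels`.
#' @param features Optional `activity_features` to attach to the result.
#' @return A list of class `metabolic_result` with fields `m` (W/m^2),
#'   `posture`, `probabilities` and `features`.
#' @export
estimate_m <- function(posture, probabilities = NULL,
                       config = pipeline_config(), features = NULL) {
  if (!posture %in% c("Sit", "Stand"))
    stop("posture must be Sit or Stand", call. = FALSE)
  if (posture == "Sit") {
    m <- config$m_sitting
    probabilities <- NULL
    features <- NULL
  } else {
    if (is.null(probabilities))
      stop("standing posture requires activity probabilities", call. = FALSE)
    if (!inherits(probabilities, "activity_probabilities"))
      probabilities <- activity_probabilities(probabilities[[1]],
                                              probabilities[[2]],
                                              probabilities[[3]])
    p <- unlist(probabilities[activity_levels])
    m <- sum(p * config$m_levels[activity_levels])
  }
  structure(list(m = unname(m), posture = posture,
                 probabilities = probabilities, features = features),
            class = "metabolic_result")
}

#' @export
print.metabolic_result <- function(x, ...) {
  cat(sprintf("M = %.1f W/m^2 (%s", x$m, x$posture))
  if (!is.null(x$probabilities))
    cat(sprintf("; P = %.2f/%.2f/%.2f", x$probabilities$low,
                x$probabilities$moderate, x$probabilities$high))
  cat(")\n")
  invisible(x)
}

z_fit <- function(x) list(mean = colMeans(x), sd = pmax(apply(x, 2,
                                                              stats::sd),
                                                        1e-12))
z_apply <- function(x, sc) sweep(sweep(as.matrix(x), 2, sc$mean), 2, sc$sd,
                                 "/")

feature_cols <- c("center_spread", "scale_spread", "flow_intensity")

as_feature_df <- function(features) {
  if (inherits(features, "activity_features"))
    features <- as.data.frame(features[feature_cols])
  stopifnot(all(feature_cols %in% names(features)))
  features[, feature_cols, drop = FALSE]
}

#' Fit the standing activity-level classifier
#'
#' Trains a three-class (low/moderate/high) classifier on activity-intensity
#' features. The default model is a random forest with shallow trees
#' (`max_depth = 2`), the configuration found to classify standing office
#' activity best; k-nearest-neighbour and SVM alternatives are available.
#' Rows labelled `"ambiguous"` (mixed-intensity windows that are difficult
#' to label) are dropped before fitting. Training rows are put into a
#' canonical order first so the fit does not depend on input order; together
#' with `seed` this makes training deterministic.
#'
#' @param training Data frame with columns `center_spread`, `scale_spread`,
#'   `flow_intensity` and `label` in `c("low", "moderate", "high",
#'   "ambiguous")`.
#' @param model_kind `"random_forest"` (default), `"knn"` or `"svm"`.
#' @param hyperparameters Named list overriding model defaults
#'   (`random_forest`: `max_depth = 2`, `num_trees = 500`; `knn`: `k = 5`;
#'   `svm`: passed to [e1071::svm()]).
#' @param seed Integer seed controlling all training randomness.
#' @return A list of class `activity_classifier`.
#' @export
fit_activity_classifier <- function(training,
                                    model_kind = c("random_forest", "knn",
                                                   "svm"),
                                    hyperparameters = list(), seed = 0L) {
  model_kind <- match.arg(model_kind)
  stopifnot(is.data.frame(training),
            all(c(feature_cols, "label") %in% names(training)))
  training <- training[training$label != "ambiguous", , drop = FALSE]
  missing <- setdiff(activity_levels, unique(as.character(training$label)))
  if (length(missing) > 0)
    stop("training data lacks class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  # canonical internal ordering: invariance to training-set permutation
  ord <- order(as.character(training$label), training$center_spread,
               training$scale_spread, training$flow_intensity)
  training <- training[ord, , drop = FALSE]
  x <- as.matrix(training[, feature_cols])
  y <- factor(as.character(training$label), levels = activity_levels)

  scaling <- NULL
  model <- switch(model_kind,
    random_forest = {
      hp <- utils::modifyList(list(max_depth = 2, num_trees = 500),
                              hyperparameters)
      ranger::ranger(x = x, y = y, probability = TRUE,
                     max.depth = hp$max_depth, num.trees = hp$num_trees,
                     seed = as.integer(seed))
    },
    knn = {
      hp <- utils::modifyList(list(k = 5), hyperparameters)
      scaling <- z_fit(x)
      list(x = z_apply(x, scaling), y = y, k = hp$k)
    },
    svm = {
      scaling <- z_fit(x)
      args <- utils::modifyList(
        list(x = z_apply(x, scaling), y = y, probability = TRUE),
        hyperparameters)
      set.seed(as.integer(seed))
      do.call(e1071::svm, args)
    })
  structure(list(model_kind = model_kind, model = model, scaling = scaling,
                 levels = activity_levels, hyperparameters = hyperparameters,
                 seed = as.integer(seed),
                 version = as.character(utils::packageVersion("thermotrack"))),
            class = "activity_classifier")
}

#' Predict activity-level probabilities
#'
#' @param classifier An [fit_activity_classifier()] model.
#' @param features An `activity_features` object, or a data frame of feature
#'   rows.
#' @return For a single feature set, an [activity_probabilities()]; for a
#'   data frame, a data frame with columns `p_low`, `p_moderate`, `p_high`
#'   (rows on the probability simplex, in this fixed order).
#' @export
predict_probabilities <- function(classifier, features) {
  if (!inherits(classifier, "activity_classifier"))
    stop("classifier must be fitted with fit_activity_classifier()",
         call. = FALSE)
  single <- inherits(features, "activity_features")
  x <- as.matrix(as_feature_df(features))
  p <- switch(classifier$model_kind,
    random_forest = {
      pr <- stats::predict(classifier$model, data = as.data.frame(x))
      pr$predictions[, activity_levels, drop = FALSE]
    },
    knn = {
      m <- classifier$model
      xz <- z_apply(x, classifier$scaling)
      t(apply(xz, 1, function(row) {
        d <- sqrt(colSums((t(m$x) - row)^2))
        nn <- order(d)[seq_len(min(m$k, length(d)))]
        tab <- table(factor(m$y[nn], levels = activity_levels))
        as.numeric(tab) / sum(tab)
      }))
    },
    svm = {
      xz <- z_apply(x, classifier$scaling)
      pr <- attr(stats::predict(classifier$model, xz, probability = TRUE),
                 "probabilities")
      pr[, activity_levels, drop = FALSE]
    })
  p <- matrix(p, ncol = 3, dimnames = list(NULL, activity_levels))
  p <- p / rowSums(p)
  if (single)
    return(activity_probabilities(p[1, "low"], p[1, "moderate"],
                                  p[1, "high"]))
  data.frame(p_low = p[, "low"], p_moderate = p[, "moderate"],
             p_high = p[, "high"])
}

#' Persist / restore a fitted activity classifier
#'
#' The file embeds the model kind, hyperparameters, training seed and the
#' package version that produced it.
#'
#' @param classifier An `activity_classifier`.
#' @param path Destination file.
#' @return `load_classifier` returns the restored `activity_classifier`.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "activity_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "activity_classifier"))
    stop("file does not contain an activity classifier", call. = FALSE)
  obj
}
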