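# The behavrec model: multidomain feature bank -> firefly feature
# selection -> LSTM classifier, as one fitting function with the usual
# S3 surface.

#' Fit a behavioral-effect classifier
#'
#' Fits the full modelling chain on a behavioral dataset: the
#' multidomain Behavioral Feature Vector is extracted per record
#' ([build_bfv()]), features are selected by the firefly optimizer
#' ([ffo_select()]), the selected columns are z-scored, and an LSTM
#' recurrence with softmax head is trained by gradient descent through
#' the unrolled recurrence ([train_classifier()]). Predicted classes are
#' quantized into low/medium/high effect levels.
#'
#' @param dataset A `behavior_dataset` (e.g. from [generate_dataset()]
#'   or [read_dataset()]) whose records carry `true_class` labels.
#' @param features A [feature_config()].
#' @param selection An [ffo_config()].
#' @param hidden_dim,n_steps,learning_rate,epochs,weight_decay Passed to
#'   [train_classifier()].
#' @param effect_map Class-to-effect map (see [train_classifier()]).
#' @param seed Integer seed fixing feature selection and training
#'   initialisation.
#' @return An object of class `"behavrec"` with elements
#'   `feature_config`, `selection` (an `"ffo_selection"`), `center` and
#'   `scale` (training standardisation), `model` (an `"lstm_model"`),
#'   `categories`, `n_classes`, `train_accuracy` and `call`.
#' @examples
#' cfg <- synth_config(n_subjects = 12, n_samples = 64, corr_spec = list())
#' ds <- generate_dataset(cfg, seed = 1)
#' fit <- behavrec(ds, selection = ffo_config(n_fireflies = 5, n_iterations = 5),
#'                 epochs = 20, seed = 1)
#' predict(fit, ds)$class
#' @export
behavrec <- function(dataset,
                     features = feature_config(),
                     selection = ffo_config(),
                     hidden_dim = 8L, n_steps = 3L,
                     learning_rate = 0.2, epochs = 300L,
                     weight_decay = 0.05,
                     effect_map = NULL, seed = 1L) {
  stopifnot(length(dataset) >= 2L)
  labels <- vapply(dataset, `[[`, 0L, "true_class")
  if (anyNA(labels)) stop_fmt("behavrec: records must carry true_class labels")
  x <- bfv_matrix(dataset, features)
  sel <- ffo_select(x, selection, seed = seed)
  xs <- x[, sel$indices, drop = FALSE]
  ctr <- colMeans(xs)
  scl <- apply(xs, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(xs, 2L, ctr), 2L, scl, "/")
  model <- train_classifier(
    xs, labels,
    hidden_dim = hidden_dim, n_steps = n_steps,
    learning_rate = learning_rate, epochs = epochs,
    weight_decay = weight_decay,
    n_classes = max(labels), effect_map = effect_map, seed = seed
  )
  train_pred <- predict_classes(model, xs)
  structure(
    list(
      feature_config = features, selection = sel,
      center = ctr, scale = scl, model = model,
      categories = names(dataset[[1]]$series),
      n_classes = model$n_classes,
      train_accuracy = mean(train_pred$class == labels),
      call = match.call()
    ),
    class = "behavrec"
  )
}

# shared feature path for new data
.behavrec_features <- function(object, dataset) {
  x <- bfv_matrix(dataset, object$feature_config)
  xs <- x[, object$selection$indices, drop = FALSE]
  sweep(sweep(xs, 2L, object$center), 2L, object$scale, "/")
}

#' Predict classes and effect levels for new records
#'
#' @param object A fitted `"behavrec"` model.
#' @param newdata A `behavior_dataset`.
#' @param ... Unused.
#' @return The [predict_classes()] data frame: posterior columns,
#'   `class`, `effect`, `effect_label`.
#' @export
predict.behavrec <- function(object, newdata, ...) {
  predict_classes(object$model, .behavrec_features(object, newdata))
}

#' @export
print.behavrec <- function(x, ...) {
  cat("Behavioral-effect classifier (firefly-selected multidomain features + LSTM)\n")
  cat(sprintf(
    "  categories: %s\n  selected features: %d\n  classes: %d  hidden dim: %d\n",
    paste(x$categories, collapse = ", "),
    length(x$selection$indices), x$n_classes, x$model$params$hidden_dim
  ))
  cat(sprintf(
    "  training: %d epochs, final loss %.4f, accuracy %.3f\n",
    length(x$model$history),
    x$model$history[length(x$model$history)], x$train_accuracy
  ))
  invisible(x)
}

#' @export
summary.behavrec <- function(object, ...) {
  s <- object$selection
  print(object)
  cat(sprintf(
    "\n  brightness threshold fth: %s\n  firefly population: %d, mean-brightness trace length: %d\n",
    format(s$fth, digits = 4), length(s$population), length(s$brightness_trace)
  ))
  h <- object$model$history
  cat(sprintf(
    "  training loss: %s -> %s over %d epochs\n",
    format(h[1], digits = 4), format(h[length(h)], digits = 4), length(h)
  ))
  invisible(object)
}

#' @export
coef.behavrec <- function(object, ...) {
  list(w = object$model$head$w, b = object$model$head$b)
}

#' @export
plot.behavrec <- function(x, ...) {
  opar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(opar))
  plot(x$model$history,
    type = "l", xlab = "epoch", ylab = "cross-entropy loss",
    main = "Training loss", ...
  )
  plot(x$selection$brightness_trace,
    type = "l", xlab = "iteration", ylab = "mean brightness",
    main = "Firefly brightness", ...
  )
  invisible(x)
}

#' Derive corrective-behavior recommendations
#'
#' Generic; the `"behavrec"` method builds the category linkage map,
#' clusters the correlation values with fuzzy c-means, derives the
#' automatic minimum support, mines frequent itemsets with Apriori, and
#' flags red (health-affecting) vs blue categories with per-subject
#' templated suggestions (see [flag_and_recommend()]).
#'
#' @param object A fitted model.
#' @param ... Method arguments.
#' @export
recommend <- function(object, ...) UseMethod("recommend")

#' @rdname recommend
#' @param dataset A `behavior_dataset` to recommend for.
#' @param predictions Optional precomputed [predict.behavrec()] output
#'   for `dataset`.
#' @param fcm_k Number of fuzzy clusters (2 separates affecting from
#'   non-affecting).
#' @param fuzziness FCM fuzziness exponent.
#' @param seed Seed for the FCM initialisation.
#' @return A `"recommendation_report"` (see [flag_and_recommend()]),
#'   with the FCM result and support parameters attached as elements
#'   `fcm` and `support`.
#' @export
recommend.behavrec <- function(object, dataset, predictions = NULL,
                               fcm_k = 2L, fuzziness = 2, seed = 1L, ...) {
  linkage <- build_linkage_map(dataset)
  rvals <- linkage$r[upper.tri(linkage$r)]
  rvals <- rvals[is.finite(rvals)]
  if (length(rvals) < fcm_k) stop_fmt("recommend: too few correlation values to cluster")
  cl <- fcm(rvals, k = fcm_k, fuzziness = fuzziness, seed = seed)
  sup <- support_params(cl, rvals)
  summaries <- category_summaries(dataset)
  tx <- build_transactions(summaries, linkage, sup$Minsup)
  its <- apriori(tx, sup$Minsup)
  preds <- predictions %||% predict(object, dataset)
  rep <- flag_and_recommend(linkage, its, preds, tx, summaries, minsup = sup$Minsup)
  rep$fcm <- cl
  rep$support <- sup
  rep
}
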