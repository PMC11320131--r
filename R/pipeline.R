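# End-to-end pipeline orchestration, artifact writing and the
# hyperparameter sweep harness.

.config_key <- function(...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(...), tmp, version = 2)
  # md5 of a canonical serialization; stable across sessions
  unname(tools::md5sum(tmp))
}

.stage_time <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- expr
  list(value = value, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full pipeline
#'
#' simulate (or load) -> extract -> select -> train -> predict ->
#' recommend -> evaluate, with per-stage timing and a run manifest. The
#' cohort is split into a training head and a held-out tail (classes are
#' assigned round-robin by the generator, so the split is stratified).
#' Recommendation confusion is scored against the generator's planted
#' effect-driving categories: a red flag on a planted category is a true
#' positive, on an unplanted one a false positive; planted-but-blue is a
#' false negative and unplanted-and-blue a true negative.
#'
#' @param synth A [synth_config()]; the dataset is generated from it.
#'   Alternatively pass a pre-built `behavior_dataset` as `dataset`.
#' @param dataset Optional `behavior_dataset` overriding `synth`.
#' @param n_test Number of held-out records (tail of the cohort).
#' @param features,selection,hidden_dim,n_steps,learning_rate,epochs,weight_decay
#'   Passed to [behavrec()].
#' @param seed Integer seed fixing generation, selection and training.
#' @param out_dir Optional directory; when given, `report.json` (fully
#'   deterministic given config + seed) and `metrics.json` (including
#'   the hardware-dependent delay and stage timings) are written there.
#' @param cache_dir Optional feature-cache directory: the extracted
#'   feature matrix is stored under a hash of the data/feature
#'   configuration and reused when the hash matches.
#' @return An object of class `"behavrec_run"`: list with `fit`,
#'   `predictions` (held-out), `holdout_accuracy`, `report`
#'   (recommendation report), `outcome` (confusion row), `metrics`
#'   (from [rec_metrics()]), `timings`, `manifest` and
#'   `cache_hit` (logical).
#' @export
run_pipeline <- function(synth = synth_config(), dataset = NULL,
                         n_test = 100L,
                         features = feature_config(),
                         selection = ffo_config(),
                         hidden_dim = 8L, n_steps = 3L,
                         learning_rate = 0.2, epochs = 300L,
                         weight_decay = 0.05,
                         seed = 1L, out_dir = NULL, cache_dir = NULL) {
  timings <- list()
  st <- .stage_time(dataset %||% generate_dataset(synth, seed = seed))
  dataset <- st$value
  timings$simulate <- st$seconds
  n <- length(dataset)
  n_test <- min(as.integer(n_test), n - 2L)
  if (n_test < 1L) stop_fmt("run_pipeline: cohort too small for a held-out split")
  train_idx <- seq_len(n - n_test)
  test_idx <- setdiff(seq_len(n), train_idx)
  train <- structure(dataset[train_idx],
    class = "behavior_dataset",
    config = attr(dataset, "config"), effect_driving = attr(dataset, "effect_driving")
  )
  test <- structure(dataset[test_idx],
    class = "behavior_dataset",
    config = attr(dataset, "config"), effect_driving = attr(dataset, "effect_driving")
  )

  # feature extraction, cached by configuration hash when requested
  key <- .config_key(attr(dataset, "config"), features, seed, n)
  cache_file <- if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    file.path(cache_dir, paste0("bfv-", key, ".rds"))
  }
  cache_hit <- !is.null(cache_file) && file.exists(cache_file)
  st <- .stage_time({
    if (cache_hit) {
      readRDS(cache_file)
    } else {
      m <- bfv_matrix(dataset, features)
      if (!is.null(cache_file)) saveRDS(m, cache_file, version = 2)
      m
    }
  })
  x_all <- st$value
  timings$extract <- st$seconds

  st <- .stage_time(ffo_select(x_all[train_idx, , drop = FALSE], selection, seed = seed))
  sel <- st$value
  timings$select <- st$seconds

  st <- .stage_time({
    xs <- x_all[train_idx, sel$indices, drop = FALSE]
    ctr <- colMeans(xs)
    scl <- apply(xs, 2L, stats::sd)
    scl[scl == 0] <- 1
    xs <- sweep(sweep(xs, 2L, ctr), 2L, scl, "/")
    labels <- vapply(train, `[[`, 0L, "true_class")
    model <- train_classifier(
      xs, labels,
      hidden_dim = hidden_dim, n_steps = n_steps,
      learning_rate = learning_rate, epochs = epochs,
      weight_decay = weight_decay,
      n_classes = attr(dataset, "config")$n_classes %||% max(labels),
      effect_map = attr(dataset, "config")$effect_map, seed = seed
    )
    tp <- predict_classes(model, xs)
    fit <- structure(
      list(
        feature_config = features, selection = sel, center = ctr, scale = scl,
        model = model, categories = names(dataset[[1]]$series),
        n_classes = model$n_classes,
        train_accuracy = mean(tp$class == labels), call = match.call()
      ),
      class = "behavrec"
    )
    fit
  })
  fit <- st$value
  timings$train <- st$seconds

  st <- .stage_time({
    xt <- x_all[test_idx, sel$indices, drop = FALSE]
    xt <- sweep(sweep(xt, 2L, fit$center), 2L, fit$scale, "/")
    predict_classes(fit$model, xt)
  })
  preds <- st$value
  timings$predict <- st$seconds
  truth <- vapply(test, `[[`, 0L, "true_class")
  holdout_accuracy <- mean(preds$class == truth)

  ts0 <- proc.time()[["elapsed"]]
  report <- recommend(fit, test, predictions = preds, seed = seed)
  ts1 <- proc.time()[["elapsed"]]
  timings$recommend <- ts1 - ts0

  planted <- attr(dataset, "effect_driving") %||% character(0)
  cats <- fit$categories
  outcome <- data.frame(
    tp = length(intersect(report$red, planted)),
    fp = length(setdiff(report$red, planted)),
    fn = length(setdiff(planted, report$red)),
    tn = length(setdiff(cats, union(report$red, planted))),
    ts_start = ts0, ts_complete = ts1
  )
  metrics <- rec_metrics(outcome)

  manifest <- list(
    config_key = key, seed = as.integer(seed), n_subjects = n,
    n_test = n_test, package_version = as.character(utils::packageVersion("behavrec")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  run <- structure(
    list(
      fit = fit, predictions = preds, holdout_accuracy = holdout_accuracy,
      report = report, outcome = outcome, metrics = metrics,
      timings = timings, manifest = manifest, cache_hit = cache_hit
    ),
    class = "behavrec_run"
  )
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

#' @export
print.behavrec_run <- function(x, ...) {
  cat("<behavrec_run>\n")
  cat(sprintf("  held-out accuracy: %.3f\n", x$holdout_accuracy))
  cat(sprintf(
    "  recommendation metrics: A=%.3f P=%.3f R_paper=%.3f R_standard=%.3f d=%.3fs\n",
    x$metrics$A, x$metrics$P, x$metrics$R_paper, x$metrics$R_standard, x$metrics$d
  ))
  cat("  red:", if (length(x$report$red)) paste(x$report$red, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write run artifacts
#'
#' `report.json` carries only deterministic content (linkage, minimum
#' support, itemsets, red/blue flags, suggestions, per-subject
#' predictions, held-out accuracy) so identical config + seed produce
#' byte-identical files; `metrics.json` carries the recommendation
#' metrics including the hardware-dependent delay, plus stage timings
#' and the manifest.
#'
#' @param run A `"behavrec_run"`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- run$report
  report_doc <- list(
    linkage = list(
      categories = rep$linkage$categories,
      r = unname(apply(rep$linkage$r, 1L, as.numeric, simplify = FALSE))
    ),
    minsup = rep$minsup,
    itemsets = if (nrow(rep$itemsets)) {
      lapply(seq_len(nrow(rep$itemsets)), function(i) {
        list(items = rep$itemsets$items[[i]], support = rep$itemsets$support[i])
      })
    } else {
      list()
    },
    red = rep$red, blue = rep$blue,
    suggestions = rep$suggestions,
    predictions = data.frame(
      subject_id = rownames(run$predictions) %||% seq_len(nrow(run$predictions)),
      class = run$predictions$class, effect = run$predictions$effect
    ),
    holdout_accuracy = run$holdout_accuracy,
    disclaimer = rep$disclaimer
  )
  jsonlite::write_json(report_doc, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(
    list(metrics = run$metrics, timings = run$timings, manifest = run$manifest),
    file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' Hyperparameter sweep harness
#'
#' Re-runs the full pipeline over a grid of one firefly hyperparameter
#' (`n_fireflies`, `learning_rate` or `n_iterations`) x replicate seeds
#' and tabulates the recommendation metrics and held-out accuracy. Any
#' per-cell failure is recorded and the sweep continues.
#'
#' @param param One of `"n_fireflies"`, `"learning_rate"`,
#'   `"n_iterations"`.
#' @param values Grid values.
#' @param seeds Integer vector of replicate seeds.
#' @param synth A [synth_config()] for the data generated per cell.
#' @param ... Further arguments to [run_pipeline()].
#' @return A data frame with columns `param`, `value`, `seed`,
#'   `holdout_accuracy`, `A`, `P`, `R_paper`, `R_standard`, `d`,
#'   `error`; the attribute `"argmax"` holds the row with the highest
#'   mean accuracy per value.
#' @export
sweep_ffo <- function(param = c("n_fireflies", "learning_rate", "n_iterations"),
                      values, seeds = 1L, synth = synth_config(), ...) {
  param <- match.arg(param)
  rows <- list()
  for (v in values) {
    for (s in seeds) {
      sel <- ffo_config()
      sel[[param]] <- if (param == "learning_rate") v else as.integer(v)
      res <- tryCatch(
        run_pipeline(synth = synth, selection = sel, seed = s, ...),
        error = function(e) e
      )
      rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
        data.frame(
          param = param, value = v, seed = s, holdout_accuracy = NA_real_,
          A = NA_real_, P = NA_real_, R_paper = NA_real_, R_standard = NA_real_,
          d = NA_real_, error = conditionMessage(res), stringsAsFactors = FALSE
        )
      } else {
        data.frame(
          param = param, value = v, seed = s,
          holdout_accuracy = res$holdout_accuracy,
          A = res$metrics$A, P = res$metrics$P,
          R_paper = res$metrics$R_paper, R_standard = res$metrics$R_standard,
          d = res$metrics$d, error = NA_character_, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  ok <- out[!is.na(out$A), , drop = FALSE]
  if (nrow(ok)) {
    by_val <- stats::aggregate(A ~ value, data = ok, FUN = mean)
    attr(out, "argmax") <- by_val[which.max(by_val$A), , drop = FALSE]
  }
  out
}
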