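#' Configuration for the synthetic behavioral-data generator
#'
#' Builds the configuration object for [generate_dataset()]. The generator
#' emulates a multimodal wearable/clinical corpus: each subject contributes
#' one uniformly sampled series per behavioral category. Designated
#' *signal categories* carry a class-dependent sinusoid (frequency
#' `class_freqs[class]`), so the health-condition class is encoded
#' spectrally; the remaining categories oscillate at class-independent
#' base frequencies. Additive Gaussian noise is applied everywhere, and
#' cross-category correlations can be planted via a shared latent noise
#' component with an analytically computed mixing weight.
#'
#' All frequencies default to multiples of `fs / n_samples` cycles so that
#' every sinusoid completes an integer number of periods over the window;
#' distinct frequencies are then exactly orthogonal and unplanted category
#' pairs have zero signal-induced correlation.
#'
#' For a correlated pair `(a, b, r)` the partner `b` copies `a`'s
#' deterministic component and shares a latent noise term with mixing
#' weight `w = (r * (s2 + n2) - s2) / n2` where `s2 = amplitude^2 / 2` and
#' `n2 = noise_sd^2`. Targets with `|w| > 1` are unreachable for the given
#' noise level and raise an error at generation time.
#'
#' @param n_subjects Number of subjects (records).
#' @param n_samples Samples per series.
#' @param fs Sampling frequency in Hz.
#' @param categories Character vector of category names.
#' @param n_classes Number of health-condition classes (>= 2; 3 or 5 are
#'   the typical choices).
#' @param class_freqs Per-class signal frequency in Hz (distinct values,
#'   length `n_classes`, below Nyquist).
#' @param signal_categories Categories carrying the class-dependent
#'   sinusoid. Default `"sleep"` so the effect-driving ground truth is a
#'   single planted category.
#' @param amplitude Sinusoid amplitude (signal variance is `amplitude^2/2`).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param corr_spec List of planted correlations, each a
#'   `list(cat_a, cat_b, r)` triple with `|r| <= 1`. A category may appear
#'   in at most one pair.
#' @param effect_map Integer vector mapping class index to effect level
#'   1 (LE) / 2 (ME) / 3 (HE). Default `((class - 1) %% 3) + 1`.
#' @return An object of class `"synth_config"`.
#' @seealso [generate_dataset()], [write_dataset()]
#' @export
synth_config <- function(n_subjects = 300L,
                         n_samples = 256L,
                         fs = 8,
                         categories = c("sleep", "hrv", "motion", "activity", "blood"),
                         n_classes = 3L,
                         class_freqs = NULL,
                         signal_categories = "sleep",
                         amplitude = 1,
                         noise_sd = 0.3,
                         corr_spec = list(list("sleep", "hrv", 0.9)),
                         effect_map = NULL) {
  n_subjects <- as.integer(n_subjects)
  n_samples <- as.integer(n_samples)
  n_classes <- as.integer(n_classes)
  if (n_subjects < 0L) stop_fmt("n_subjects must be >= 0")
  if (n_samples < 2L) stop_fmt("n_samples must be >= 2")
  if (fs <= 0) stop_fmt("fs must be positive")
  if (n_classes < 2L) stop_fmt("n_classes must be >= 2")
  if (anyDuplicated(categories)) stop_fmt("duplicate category names")
  if (!all(signal_categories %in% categories)) {
    stop_fmt("signal_categories must be a subset of categories")
  }
  if (is.null(class_freqs)) {
    class_freqs <- c(0.5, 1.5, 3.0, 2.25, 3.5)[seq_len(n_classes)]
    if (anyNA(class_freqs)) stop_fmt("supply class_freqs for n_classes > 5")
  }
  if (length(class_freqs) != n_classes) {
    stop_fmt("class_freqs must have one entry per class")
  }
  if (anyDuplicated(class_freqs)) stop_fmt("class_freqs must be distinct")
  if (any(class_freqs <= 0) || any(class_freqs >= fs / 2)) {
    stop_fmt("class_freqs must lie in (0, fs/2)")
  }
  # class-independent base frequencies for the non-signal categories,
  # multiples of 0.25 Hz, disjoint from the class frequencies
  pool <- seq(0.25, fs / 2 - 0.25, by = 0.25)
  pool <- setdiff(pool, class_freqs)
  other <- setdiff(categories, signal_categories)
  if (length(pool) < length(other)) stop_fmt("not enough base frequencies below Nyquist")
  base_freqs <- stats::setNames(pool[seq_along(other)], other)

  if (length(corr_spec)) {
    cats_in_pairs <- unlist(lapply(corr_spec, function(p) c(p[[1]], p[[2]])))
    if (!all(cats_in_pairs %in% categories)) stop_fmt("corr_spec names unknown category")
    if (anyDuplicated(cats_in_pairs)) {
      stop_fmt("a category may appear in at most one corr_spec pair")
    }
    for (p in corr_spec) {
      if (abs(p[[3]]) > 1) stop_fmt("target correlation |r| must be <= 1")
    }
  }
  if (is.null(effect_map)) effect_map <- ((seq_len(n_classes) - 1L) %% 3L) + 1L
  if (length(effect_map) != n_classes || !all(effect_map %in% 1:3)) {
    stop_fmt("effect_map must map each class to an effect level in 1..3")
  }
  structure(
    list(
      n_subjects = n_subjects, n_samples = n_samples, fs = fs,
      categories = categories, n_classes = n_classes,
      class_freqs = class_freqs, signal_categories = signal_categories,
      base_freqs = base_freqs, amplitude = amplitude, noise_sd = noise_sd,
      corr_spec = corr_spec, effect_map = effect_map
    ),
    class = "synth_config"
  )
}

#' Effect-level labels
#'
#' @return `c("LE", "ME", "HE")`: the low/medium/high quantization of a
#'   class's contextual effect on health.
#' @export
effect_levels <- function() c("LE", "ME", "HE")

# latent mixing weight for a planted pair; NULL when unreachable
.corr_mixing_weight <- function(r, amplitude, noise_sd) {
  s2 <- amplitude^2 / 2
  n2 <- noise_sd^2
  if (n2 == 0) {
    if (r == 1) return(0) # series are identical copies already
    return(NULL)
  }
  w <- (r * (s2 + n2) - s2) / n2
  if (abs(w) > 1 + 1e-12) return(NULL)
  max(min(w, 1), -1)
}

#' Generate a synthetic multimodal behavioral dataset
#'
#' Draws `config$n_subjects` records. Classes are assigned round-robin so
#' the cohort is balanced. Each series is
#' `amplitude * sin(2*pi*f*t + phase) + noise_sd * eta` with a uniform
#' random phase per subject and category; `f` is the subject's class
#' frequency for signal categories and the category's base frequency
#' otherwise. For every planted pair the partner category copies the
#' first category's deterministic component and shares a latent noise
#' term, mixed with the closed-form weight that achieves the target
#' Pearson correlation in expectation (see [synth_config()]).
#'
#' @param config A [synth_config()] object.
#' @param seed Integer seed; fixes all randomness (bitwise reproducible).
#' @return An object of class `"behavior_dataset"`: a list of records,
#'   each with `subject_id`, a named list `series` of per-category
#'   `behavior_series` objects (`values`, `fs`, `category`), `true_class`
#'   (1-based) and `true_effect` (`"LE"/"ME"/"HE"`). The attribute
#'   `"effect_driving"` names the categories whose series depend on the
#'   class (signal categories and their correlation partners); attribute
#'   `"config"` stores the generator configuration.
#' @examples
#' cfg <- synth_config(n_subjects = 4, n_samples = 64, corr_spec = list())
#' ds <- generate_dataset(cfg, seed = 1)
#' length(ds)
#' @export
generate_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  # resolve mixing weights up front so misconfiguration fails early
  pair_w <- lapply(config$corr_spec, function(p) {
    w <- .corr_mixing_weight(p[[3]], config$amplitude, config$noise_sd)
    if (is.null(w)) {
      stop_fmt(
        "target correlation r=%.3f between '%s' and '%s' is unreachable at noise_sd=%g",
        p[[3]], p[[1]], p[[2]], config$noise_sd
      )
    }
    w
  })
  partner_of <- list() # cat_b -> list(src = cat_a, w = weight)
  for (k in seq_along(config$corr_spec)) {
    p <- config$corr_spec[[k]]
    partner_of[[p[[2]]]] <- list(src = p[[1]], w = pair_w[[k]])
  }

  n <- config$n_subjects
  t <- (seq_len(config$n_samples) - 1L) / config$fs
  classes <- rep_len(seq_len(config$n_classes), n)

  records <- with_seed(seed, {
    lapply(seq_len(n), function(s) {
      cls <- classes[s]
      det <- list()
      for (cat in config$categories) {
        if (!is.null(partner_of[[cat]])) next # filled from its source below
        f <- if (cat %in% config$signal_categories) {
          config$class_freqs[cls]
        } else {
          config$base_freqs[[cat]]
        }
        phase <- stats::runif(1, 0, 2 * pi)
        det[[cat]] <- config$amplitude * sin(2 * pi * f * t + phase)
      }
      for (cat in names(partner_of)) det[[cat]] <- det[[partner_of[[cat]]$src]]

      eta <- lapply(config$categories, function(cat) stats::rnorm(config$n_samples))
      names(eta) <- config$categories
      for (cat in names(partner_of)) {
        w <- partner_of[[cat]]$w
        src <- partner_of[[cat]]$src
        z <- stats::rnorm(config$n_samples) # shared latent component
        eta[[src]] <- sqrt(1 - abs(w)) * eta[[src]] + sqrt(abs(w)) * z
        eta[[cat]] <- sqrt(1 - abs(w)) * eta[[cat]] + sign(w) * sqrt(abs(w)) * z
      }

      series <- lapply(config$categories, function(cat) {
        structure(
          list(
            values = det[[cat]] + config$noise_sd * eta[[cat]],
            fs = config$fs, category = cat
          ),
          class = "behavior_series"
        )
      })
      names(series) <- config$categories
      structure(
        list(
          subject_id = sprintf("S%04d", s),
          series = series,
          true_class = cls,
          true_effect = effect_levels()[config$effect_map[cls]]
        ),
        class = "behavior_record"
      )
    })
  })

  driving <- config$signal_categories
  for (p in config$corr_spec) {
    if (p[[1]] %in% driving) driving <- union(driving, p[[2]])
    if (p[[2]] %in% driving) driving <- union(driving, p[[1]])
  }
  structure(records,
    class = "behavior_dataset",
    config = config,
    effect_driving = driving
  )
}

#' @export
print.behavior_dataset <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<behavior_dataset> %d subjects, %d categories (%s)\n",
    length(x),
    if (length(x)) length(x[[1]]$series) else length(cfg$categories),
    paste(if (length(x)) names(x[[1]]$series) else cfg$categories, collapse = ", ")
  ))
  if (!is.null(attr(x, "effect_driving"))) {
    cat("  effect-driving categories:", paste(attr(x, "effect_driving"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a behavioral dataset as plain CSV
#'
#' The on-disk layout is one CSV per category with columns
#' `subject_id,t,value` plus a `labels.csv` with columns
#' `subject_id,class,effect`. Values are written with 17 significant
#' digits so a write/read round trip reproduces the doubles exactly.
#'
#' @param dataset A `behavior_dataset`.
#' @param path Directory to write into (created if needed).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `behavior_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "behavior_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(dataset, "config")
  cats <- if (length(dataset)) names(dataset[[1]]$series) else cfg$categories
  for (cat in cats) {
    rows <- lapply(dataset, function(rec) {
      s <- rec$series[[cat]]
      data.frame(
        subject_id = rec$subject_id,
        t = formatC((seq_along(s$values) - 1L) / s$fs, digits = 17, format = "g"),
        value = formatC(s$values, digits = 17, format = "g"),
        stringsAsFactors = FALSE
      )
    })
    df <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(subject_id = character(), t = character(), value = character())
    }
    utils::write.csv(df, file.path(path, paste0(cat, ".csv")), row.names = FALSE)
  }
  labels <- data.frame(
    subject_id = vapply(dataset, `[[`, "", "subject_id"),
    class = vapply(dataset, `[[`, 0L, "true_class"),
    effect = vapply(dataset, `[[`, "", "true_effect"),
    stringsAsFactors = FALSE
  )
  if (!length(dataset)) {
    labels <- data.frame(
      subject_id = character(), class = integer(), effect = character()
    )
  }
  utils::write.csv(labels, file.path(path, "labels.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lab_file <- file.path(path, "labels.csv")
  if (!file.exists(lab_file)) stop_fmt("missing labels file: %s", lab_file)
  labels <- utils::read.csv(lab_file, stringsAsFactors = FALSE)
  cat_files <- setdiff(list.files(path, pattern = "\\.csv$"), "labels.csv")
  if (!length(cat_files)) stop_fmt("no category files found in %s", path)
  cats <- sub("\\.csv$", "", cat_files)

  per_cat <- list()
  lens <- NULL
  fs <- NULL
  for (i in seq_along(cats)) {
    df <- utils::read.csv(file.path(path, cat_files[i]), stringsAsFactors = FALSE)
    need <- c("subject_id", "t", "value")
    if (!all(need %in% names(df))) {
      stop_fmt("format error in %s: expected columns %s", cat_files[i], paste(need, collapse = ","))
    }
    split_vals <- split(as.numeric(df$value), df$subject_id)
    split_t <- split(as.numeric(df$t), df$subject_id)
    l <- vapply(split_vals, length, 0L)
    if (length(unique(l)) > 1L) {
      bad <- names(l)[which(l != l[1])[1]]
      stop_fmt(
        "format error in %s: ragged series length for subject %s (row %d)",
        cat_files[i], bad, which(df$subject_id == bad)[1]
      )
    }
    if (length(split_t) && length(split_t[[1]]) > 1L) {
      fs_i <- 1 / diff(split_t[[1]][1:2])
      fs <- fs %||% fs_i
    }
    if (is.null(lens)) lens <- l[1] else if (length(l) && l[1] != lens) {
      stop_fmt("format error: %s series length %d differs from other categories (%d)",
               cat_files[i], l[1], lens)
    }
    per_cat[[cats[i]]] <- split_vals
  }

  all_subjects <- unique(unlist(lapply(per_cat, names)))
  unknown <- setdiff(labels$subject_id, all_subjects)
  if (nrow(labels) && length(all_subjects) == 0L) {
    stop_fmt("labels.csv lists subjects but category files are empty")
  }
  if (length(unknown)) {
    stop_fmt(
      "labels.csv row %d: unknown subject_id '%s'",
      which(labels$subject_id == unknown[1])[1], unknown[1]
    )
  }
  missing_lab <- setdiff(all_subjects, labels$subject_id)
  if (length(missing_lab)) {
    stop_fmt("subject '%s' has series but no label row", missing_lab[1])
  }

  records <- lapply(seq_len(nrow(labels)), function(i) {
    sid <- labels$subject_id[i]
    series <- lapply(cats, function(cat) {
      if (is.null(per_cat[[cat]][[sid]])) {
        stop_fmt("format error: subject %s missing from %s.csv", sid, cat)
      }
      structure(
        list(values = per_cat[[cat]][[sid]], fs = fs %||% 1, category = cat),
        class = "behavior_series"
      )
    })
    names(series) <- cats
    structure(
      list(
        subject_id = sid, series = series,
        true_class = as.integer(labels$class[i]),
        true_effect = labels$effect[i]
      ),
      class = "behavior_record"
    )
  })
  structure(records, class = "behavior_dataset")
}
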