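# Firefly-optimizer feature selection over the Behavioral Feature Vector.
#
# A firefly is a candidate feature subset; its brightness is the summed
# dispersion of the selected feature columns across the training matrix.
# Dim fireflies (below the learning-rate-scaled mean brightness) are
# respawned; the rest are attracted toward the brightest member; the
# final selection is the union of the super-threshold members' sets.

#' Firefly-optimizer configuration
#'
#' The guidance ranges are 10-50 fireflies per dimension, 100-1000
#' iterations and a learning rate in (0.1, 1.0); values outside those
#' ranges are accepted with a warning so small test instances stay cheap.
#'
#' @param n_fireflies Population size.
#' @param n_iterations Number of reconfiguration cycles.
#' @param learning_rate Inter-firefly learning rate `Lr` in `(0, 1]`;
#'   scales both the minimum subset size and the brightness threshold.
#' @param attraction_fraction Fraction of the brightest firefly's index
#'   set adopted by each surviving firefly per iteration.
#' @param standardize Z-score the feature matrix before computing
#'   dispersions. Off by default (raw dispersions drive brightness).
#' @return An object of class `"ffo_config"`.
#' @export
ffo_config <- function(n_fireflies = 20L, n_iterations = 100L,
                       learning_rate = 0.5, attraction_fraction = 0.25,
                       standardize = FALSE) {
  n_fireflies <- as.integer(n_fireflies)
  n_iterations <- as.integer(n_iterations)
  if (n_fireflies < 1L) stop_fmt("n_fireflies must be >= 1")
  if (n_iterations < 0L) stop_fmt("n_iterations must be >= 0")
  if (learning_rate <= 0 || learning_rate > 1) stop_fmt("learning_rate must be in (0, 1]")
  if (attraction_fraction <= 0 || attraction_fraction > 1) {
    stop_fmt("attraction_fraction must be in (0, 1]")
  }
  structure(
    list(
      n_fireflies = n_fireflies, n_iterations = n_iterations,
      learning_rate = learning_rate, attraction_fraction = attraction_fraction,
      standardize = standardize
    ),
    class = "ffo_config"
  )
}

# per-column dispersion vector; brightness of any subset is then a sum
.column_dispersions <- function(bfv_matrix) {
  apply(bfv_matrix, 2L, dispersion)
}

#' Spawn a firefly
#'
#' Draws a subset size `N` uniformly from `[ceiling(Lr * NBFV), NBFV]`
#' (the stochastic-draw contract) and then `N` distinct feature indices
#' uniformly without replacement.
#'
#' @param nbfv Number of BFV features.
#' @param learning_rate `Lr` in `(0, 1]`.
#' @return A list with `indices` (sorted integer vector) and `fb` (`NA`
#'   until scored).
#' @export
spawn_firefly <- function(nbfv, learning_rate) {
  nbfv <- as.integer(nbfv)
  if (nbfv < 1L) stop_fmt("spawn_firefly: need at least one feature")
  lo <- max(1L, as.integer(ceiling(learning_rate * nbfv)))
  n <- if (lo >= nbfv) nbfv else lo + sample.int(nbfv - lo + 1L, 1L) - 1L
  list(indices = sort(sample.int(nbfv, n)), fb = NA_real_)
}

#' Firefly brightness
#'
#' The brightness of a subset is the dispersion statistic
#' `sum((v - mean(v))^2) / (N + 1)` applied column-wise to each selected
#' feature across the records of the training matrix, summed over the
#' subset (the total dispersion of the selected features).
#'
#' @param indices Integer vector of selected feature columns.
#' @param bfv_matrix Records x features matrix (or a single-column matrix
#'   / vector for the degenerate one-feature case).
#' @param col_disp Optional precomputed per-column dispersion vector.
#' @return A single non-negative number.
#' @export
firefly_brightness <- function(indices, bfv_matrix, col_disp = NULL) {
  if (!length(indices)) stop_fmt("firefly_brightness: empty index set")
  if (is.null(col_disp)) {
    if (is.vector(bfv_matrix)) bfv_matrix <- matrix(bfv_matrix, ncol = 1L)
    col_disp <- .column_dispersions(bfv_matrix)
  }
  if (any(indices < 1L) || any(indices > length(col_disp))) {
    stop_fmt("firefly_brightness: index out of range")
  }
  sum(col_disp[indices])
}

#' Brightness threshold
#'
#' `fth = Lr * mean(fb)` over the current population.
#'
#' @param fbs Numeric vector of brightnesses (>= 1 firefly).
#' @param learning_rate `Lr`.
#' @return A single number.
#' @export
brightness_threshold <- function(fbs, learning_rate) {
  if (!length(fbs)) stop_fmt("brightness_threshold: empty population")
  learning_rate * mean(fbs)
}

# one reconfiguration cycle; col_disp precomputed by the caller
.ffo_iterate_once <- function(pop, col_disp, config) {
  fbs <- vapply(pop, `[[`, 0, "fb")
  fth <- brightness_threshold(fbs, config$learning_rate)
  nbfv <- length(col_disp)
  dim_ones <- which(fbs < fth)
  for (j in dim_ones) {
    f <- spawn_firefly(nbfv, config$learning_rate)
    f$fb <- firefly_brightness(f$indices, col_disp = col_disp)
    pop[[j]] <- f
  }
  survivors <- setdiff(seq_along(pop), dim_ones)
  if (length(survivors) > 1L) {
    sfbs <- vapply(pop[survivors], `[[`, 0, "fb")
    best <- survivors[which.max(sfbs)]
    bset <- pop[[best]]$indices
    k <- ceiling(config$attraction_fraction * length(bset))
    # adopt the k highest-dispersion indices of the brightest set,
    # ties broken by lowest index (order() is stable on the index order)
    adopt <- bset[order(-col_disp[bset], bset)][seq_len(k)]
    for (j in setdiff(survivors, best)) {
      pop[[j]]$indices <- sort(union(pop[[j]]$indices, adopt))
      pop[[j]]$fb <- firefly_brightness(pop[[j]]$indices, col_disp = col_disp)
    }
  }
  pop
}

#' Iterate a firefly population
#'
#' Applies the respawn / attraction cycle `n_iterations` times: fireflies
#' with brightness below the threshold are respawned, the remainder adopt
#' a fraction of the brightest firefly's index set, and brightnesses are
#' recomputed. `n_iterations = 0` returns the population unchanged.
#'
#' @inheritParams ffo_select
#' @param pop List of fireflies as produced by [spawn_firefly()] (with
#'   `fb` scored; unscored fireflies are scored first).
#' @param n_iterations Number of cycles.
#' @return The updated population.
#' @export
ffo_iterate <- function(pop, bfv_matrix, config = ffo_config(),
                        n_iterations = 1L) {
  col_disp <- .column_dispersions(bfv_matrix)
  pop <- lapply(pop, function(f) {
    if (is.na(f$fb)) f$fb <- firefly_brightness(f$indices, col_disp = col_disp)
    f
  })
  for (it in seq_len(n_iterations)) pop <- .ffo_iterate_once(pop, col_disp, config)
  pop
}

#' Finalize the selected feature set
#'
#' Union of the index sets of all fireflies with brightness above twice
#' the threshold. When no firefly qualifies the brightest firefly's set
#' is returned so the selection is never empty.
#'
#' @param pop List of fireflies (with `indices` and `fb`).
#' @param fth Brightness threshold.
#' @return Sorted integer vector of selected feature indices.
#' @export
ffo_finalize <- function(pop, fth) {
  if (!length(pop)) stop_fmt("ffo_finalize: empty population")
  fbs <- vapply(pop, `[[`, 0, "fb")
  keep <- which(fbs > 2 * fth)
  if (!length(keep)) keep <- which.max(fbs)
  sort(unique(unlist(lapply(pop[keep], `[[`, "indices"))))
}

#' Firefly-optimizer feature selection
#'
#' Runs the full optimizer: spawn the population, iterate respawn /
#' attraction cycles, and return the finalized union of super-threshold
#' index sets.
#'
#' @param bfv_matrix Records x features numeric matrix.
#' @param config An [ffo_config()].
#' @param seed Integer seed fixing the stochastic draws.
#' @return An object of class `"ffo_selection"`: list with `indices`
#'   (selected feature columns), `fth` (final threshold), `population`
#'   (final fireflies), `brightness_trace` (mean population brightness
#'   per iteration) and `config`.
#' @export
ffo_select <- function(bfv_matrix, config = ffo_config(), seed = 1L) {
  stopifnot(is.matrix(bfv_matrix), ncol(bfv_matrix) >= 1L)
  m <- bfv_matrix
  if (isTRUE(config$standardize)) {
    m <- scale(m)
    m[, attr(m, "scaled:scale") == 0] <- 0
  }
  col_disp <- .column_dispersions(m)
  nbfv <- length(col_disp)
  with_seed(seed, {
    pop <- lapply(seq_len(config$n_fireflies), function(i) {
      f <- spawn_firefly(nbfv, config$learning_rate)
      f$fb <- firefly_brightness(f$indices, col_disp = col_disp)
      f
    })
    trace <- numeric(config$n_iterations)
    for (it in seq_len(config$n_iterations)) {
      pop <- .ffo_iterate_once(pop, col_disp, config)
      trace[it] <- mean(vapply(pop, `[[`, 0, "fb"))
    }
    fth <- brightness_threshold(vapply(pop, `[[`, 0, "fb"), config$learning_rate)
    structure(
      list(
        indices = ffo_finalize(pop, fth), fth = fth, population = pop,
        brightness_trace = trace, config = config
      ),
      class = "ffo_selection"
    )
  })
}

#' @export
print.ffo_selection <- function(x, ...) {
  cat(sprintf(
    "<ffo_selection> %d features selected (threshold fth = %.4g, %d fireflies)\n",
    length(x$indices), x$fth, length(x$population)
  ))
  invisible(x)
}
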