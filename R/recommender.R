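# Correlation-driven recommendation engine: Pearson linkage map between
# behavioral categories, fuzzy c-means clustering of the correlation
# values, an automatically derived Apriori minimum support, frequent
# itemset mining, and red/blue flagging of health-affecting categories
# with templated corrective suggestions.

#' Pearson product-moment correlation
#'
#' The classical formula
#' `r = (n*sum(xy) - sum(x)*sum(y)) / sqrt((n*sum(x^2) - sum(x)^2) * (n*sum(y^2) - sum(y)^2))`.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @return A single number in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop_fmt("pearson: unequal lengths")
  n <- length(x)
  if (n < 2L) stop_fmt("pearson: need n >= 2")
  sxx <- n * sum(x^2) - sum(x)^2
  syy <- n * sum(y^2) - sum(y)^2
  if (sxx <= 0 || syy <= 0) stop_fmt("pearson: zero variance")
  (n * sum(x * y) - sum(x) * sum(y)) / sqrt(sxx * syy)
}

#' Category linkage map
#'
#' Pairwise Pearson correlations between behavioral categories. The
#' default `"series"` method correlates each subject's raw category
#' series pair in time and averages the per-subject coefficients across
#' the cohort; this recovers correlations planted within the series. The
#' `"summary"` method reduces each record's category to a scalar (by
#' `summarizer`, default the series mean) and correlates the summaries
#' across subjects.
#'
#' Cells whose correlation is undefined (zero variance) are recorded as
#' `NA` and excluded downstream.
#'
#' @param dataset A `behavior_dataset` with >= 2 records.
#' @param method `"series"` or `"summary"`.
#' @param summarizer Function `behavior_series -> scalar` for the
#'   summary method.
#' @return An object of class `"linkage_map"`: list with `categories`,
#'   symmetric correlation matrix `r` (unit diagonal) and `n` (paired
#'   observations per cell).
#' @export
build_linkage_map <- function(dataset, method = c("series", "summary"),
                              summarizer = NULL) {
  method <- match.arg(method)
  if (length(dataset) < 2L) stop_fmt("build_linkage_map: need >= 2 subjects")
  cats <- names(dataset[[1]]$series)
  if (length(cats) < 2L) stop_fmt("build_linkage_map: need >= 2 categories")
  k <- length(cats)
  r <- diag(1, k)
  nmat <- matrix(length(dataset), k, k)
  dimnames(r) <- dimnames(nmat) <- list(cats, cats)
  if (method == "series") {
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        rs <- vapply(dataset, function(rec) {
          tryCatch(
            pearson(rec$series[[cats[a]]]$values, rec$series[[cats[b]]]$values),
            error = function(e) NA_real_
          )
        }, 0)
        val <- if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
        r[a, b] <- r[b, a] <- val
        nmat[a, b] <- nmat[b, a] <- sum(!is.na(rs))
      }
    }
  } else {
    summarizer <- summarizer %||% function(s) mean(s$values)
    smat <- category_summaries(dataset, summarizer)
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        val <- tryCatch(pearson(smat[, a], smat[, b]), error = function(e) NA_real_)
        r[a, b] <- r[b, a] <- val
      }
    }
  }
  structure(list(categories = cats, r = r, n = nmat), class = "linkage_map")
}

#' Per-subject category summaries
#'
#' Reduces every record's category series to one scalar. The default
#' summarizer is the dominant (non-DC) spectral frequency in Hz — the
#' feature that separates planted classes — so summaries are comparable
#' across subjects.
#'
#' @param dataset A `behavior_dataset`.
#' @param summarizer Function `behavior_series -> scalar`.
#' @return Numeric matrix, subjects x categories, row-named by subject.
#' @export
category_summaries <- function(dataset, summarizer = spectral_peak) {
  cats <- names(dataset[[1]]$series)
  m <- vapply(
    dataset,
    function(rec) vapply(cats, function(ct) summarizer(rec$series[[ct]]), 0),
    numeric(length(cats))
  )
  m <- t(matrix(m, nrow = length(cats),
                dimnames = list(cats, vapply(dataset, `[[`, "", "subject_id"))))
  m
}

#' Dominant spectral frequency of a series
#'
#' Location (Hz) of the largest non-DC Fourier magnitude over the first
#' half of the spectrum.
#'
#' @param series A `behavior_series` or numeric vector (then `fs = 1`).
#' @return Frequency in Hz.
#' @export
spectral_peak <- function(series) {
  x <- .series_values(series)
  fs <- if (inherits(series, "behavior_series")) series$fs else 1
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[2:floor(n / 2)]
  (which.max(sp)) * fs / n
}

#' Fuzzy c-means clustering
#'
#' Standard FCM: soft memberships `u_ij` summing to one per sample,
#' alternating centroid and membership updates until the largest
#' centroid shift drops below `tol`. The objective
#' `J = sum_ij u_ij^m ||x_i - c_j||^2` is recorded after every full
#' update and is non-increasing. If two centroids collapse onto each
#' other the run restarts with a fresh seed (at most 5 restarts).
#'
#' @param points Numeric matrix (n x d) or vector (treated as n x 1).
#' @param k Number of clusters (>= 2, <= n).
#' @param fuzziness Fuzziness exponent `m > 1` (default 2).
#' @param tol Centroid-shift convergence tolerance.
#' @param max_iter Iteration cap.
#' @param seed Integer seed for the membership initialisation.
#' @return An object of class `"fcm_result"`: `centroids` (k x d),
#'   `membership` (n x k), `cluster` (hard assignment by max
#'   membership), `objective` (history), `fuzziness`, `iterations` and
#'   `points` (the clustered data, kept for the support computation).
#' @export
fcm <- function(points, k = 2L, fuzziness = 2, tol = 1e-8, max_iter = 200L,
                seed = 1L) {
  x <- if (is.null(dim(points))) matrix(points, ncol = 1L) else as.matrix(points)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 2L) stop_fmt("fcm: k must be >= 2")
  if (n < k) stop_fmt("fcm: need at least k points")
  if (fuzziness <= 1) stop_fmt("fcm: fuzziness must be > 1")

  run_once <- function(seed_i) {
    with_seed(seed_i, {
      u <- matrix(stats::runif(n * k), n, k)
      u <- u / rowSums(u)
      obj <- numeric(0)
      cent <- matrix(0, k, ncol(x))
      for (it in seq_len(max_iter)) {
        um <- u^fuzziness
        cent_new <- t(vapply(
          seq_len(k),
          function(j) colSums(um[, j] * x) / sum(um[, j]),
          numeric(ncol(x))
        ))
        if (ncol(x) == 1L) cent_new <- matrix(cent_new, ncol = 1L)
        d2 <- vapply(
          seq_len(k),
          function(j) rowSums((x - matrix(cent_new[j, ], n, ncol(x), byrow = TRUE))^2),
          numeric(n)
        )
        cmin <- min(stats::dist(cent_new))
        if (!is.finite(cmin) || cmin < 1e-12) return(NULL) # collapsed centroids
        zero <- d2 < 1e-30
        u <- matrix(0, n, k)
        for (ii in which(rowSums(zero) > 0L)) u[ii, which(zero[ii, ])[1]] <- 1
        free <- rowSums(zero) == 0L
        if (any(free)) {
          p <- 2 / (fuzziness - 1)
          inv <- d2[free, , drop = FALSE]^(-p / 2)
          u[free, ] <- inv / rowSums(inv)
        }
        obj <- c(obj, sum(u^fuzziness * d2))
        shift <- max(abs(cent_new - cent))
        cent <- cent_new
        if (shift < tol && it > 1L) break
      }
      list(
        centroids = cent, membership = u,
        cluster = argmax_row(u), objective = obj,
        fuzziness = fuzziness, iterations = length(obj),
        points = x
      )
    })
  }
  for (attempt in 0:5) {
    res <- run_once(seed + attempt)
    if (!is.null(res)) {
      if (attempt > 0L) warn_fmt("fcm: restarted %d time(s) after centroid collapse", attempt)
      return(structure(res, class = "fcm_result"))
    }
  }
  stop_fmt("fcm: centroids collapsed in all %d restarts", 6L)
}

#' Automatic minimum support
#'
#' From an FCM clustering of the correlation values:
#' `Minter` is the sum over unordered centroid pairs (and coordinates)
#' of squared differences; `Mintra` is the sum over unordered
#' same-cluster sample pairs (hard assignment by maximum membership) of
#' squared coordinate differences; `Fsup = Mintra / Minter`; and
#' `Minsup = (min(STD(x), VAR(x)) / max(STD(x), VAR(x))) * Fsup`,
#' clamped into `[0.01, 1]` so Apriori never degenerates.
#'
#' @param fcm_result An [fcm()] result.
#' @param corr_values Numeric vector of correlation values `x` (finite).
#' @return An object of class `"support_params"`: list with `Minter`,
#'   `Mintra`, `Fsup`, `Minsup`.
#' @export
support_params <- function(fcm_result, corr_values) {
  stopifnot(inherits(fcm_result, "fcm_result"))
  x <- corr_values[is.finite(corr_values)]
  if (!length(x)) stop_fmt("support_params: no finite correlation values")
  cent <- fcm_result$centroids
  k <- nrow(cent)
  minter <- 0
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) minter <- minter + sum((cent[a, ] - cent[b, ])^2)
  }
  if (minter <= 0) stop_fmt("support_params: coincident centroids (Minter = 0)")
  data_pts <- fcm_result$points
  mintra <- 0
  for (j in seq_len(k)) {
    idx <- which(fcm_result$cluster == j)
    if (!length(idx)) {
      warn_fmt("support_params: cluster %d is empty, skipped in Mintra", j)
      next
    }
    if (length(idx) >= 2L) {
      sub <- data_pts[idx, , drop = FALSE]
      for (a in seq_len(length(idx) - 1L)) {
        for (b in (a + 1L):length(idx)) {
          mintra <- mintra + sum((sub[a, ] - sub[b, ])^2)
        }
      }
    }
  }
  fsup <- mintra / minter
  s <- stats::sd(x)
  v <- stats::var(x)
  ratio <- if (max(s, v) == 0) 1 else min(s, v) / max(s, v)
  minsup <- max(0.01, min(1, ratio * fsup))
  structure(
    list(Minter = minter, Mintra = mintra, Fsup = fsup, Minsup = minsup),
    class = "support_params"
  )
}

#' Apriori frequent-itemset mining
#'
#' Level-wise candidate generation with downward-closure pruning.
#' Support is the fraction of transactions containing the itemset.
#'
#' @param transactions List of character vectors (per-subject item sets).
#' @param minsup Minimum support in `(0, 1]`.
#' @return A data frame with columns `items` (list column of sorted
#'   character vectors), `size` and `support`, ordered by size then
#'   items; zero rows for empty input.
#' @export
apriori <- function(transactions, minsup) {
  if (minsup <= 0 || minsup > 1) stop_fmt("apriori: minsup must be in (0, 1]")
  empty <- data.frame(size = integer(), support = numeric())
  empty$items <- list()
  if (!length(transactions)) return(empty[, c("items", "size", "support")])
  tx <- lapply(transactions, function(t) sort(unique(as.character(t))))
  nt <- length(tx)
  support_of <- function(set) sum(vapply(tx, function(t) all(set %in% t), TRUE)) / nt

  items <- sort(unique(unlist(tx)))
  lev <- lapply(items, identity)
  sup <- vapply(lev, support_of, 0)
  keep <- sup >= minsup
  frequent <- list()
  supports <- numeric(0)
  lev <- lev[keep]
  sup <- sup[keep]
  while (length(lev)) {
    frequent <- c(frequent, lev)
    supports <- c(supports, sup)
    # join step: union pairs sharing all but the last item
    keyed <- vapply(lev, function(s) paste(s[-length(s)], collapse = "\r"), "")
    cand <- list()
    for (key in unique(keyed)) {
      grp <- lev[keyed == key]
      if (length(grp) < 2L) next
      last <- vapply(grp, function(s) s[length(s)], "")
      ord <- order(last)
      grp <- grp[ord]
      for (a in seq_len(length(grp) - 1L)) {
        for (b in (a + 1L):length(grp)) {
          cand[[length(cand) + 1L]] <- c(grp[[a]], grp[[b]][length(grp[[b]])])
        }
      }
    }
    if (!length(cand)) break
    # prune: every (k-1)-subset must be frequent
    freq_keys <- vapply(lev, paste, "", collapse = "\r")
    cand <- Filter(function(s) {
      all(vapply(
        seq_along(s),
        function(drop) paste(s[-drop], collapse = "\r") %in% freq_keys,
        TRUE
      ))
    }, cand)
    if (!length(cand)) break
    sup <- vapply(cand, support_of, 0)
    keep <- sup >= minsup
    lev <- cand[keep]
    sup <- sup[keep]
  }
  if (!length(frequent)) return(empty[, c("items", "size", "support")])
  out <- data.frame(
    size = vapply(frequent, length, 0L),
    support = supports
  )
  out$items <- frequent
  out <- out[order(out$size, vapply(frequent, paste, "", collapse = ",")), ]
  rownames(out) <- NULL
  out[, c("items", "size", "support")]
}

#' Itemize subjects for Apriori
#'
#' One transaction per subject; a category is an item of the subject's
#' transaction when (a) the subject's category summary deviates from the
#' cohort mean by at least one standard deviation and (b) the category
#' participates in at least one linkage-map cell with `|r| >= minsup`.
#'
#' @param summaries Subjects x categories summary matrix
#'   (see [category_summaries()]).
#' @param linkage A [build_linkage_map()] result.
#' @param minsup Minimum support used as the correlation-relevance gate.
#' @return Named list of character vectors (possibly empty), one per
#'   subject.
#' @export
build_transactions <- function(summaries, linkage, minsup) {
  cats <- colnames(summaries)
  r <- linkage$r
  linked <- vapply(cats, function(ct) {
    row <- abs(r[ct, setdiff(linkage$categories, ct)])
    any(row >= minsup, na.rm = TRUE)
  }, TRUE)
  mu <- colMeans(summaries)
  sdv <- apply(summaries, 2L, stats::sd)
  lapply(seq_len(nrow(summaries)), function(i) {
    dev <- sdv > 0 & abs(summaries[i, ] - mu) >= sdv
    cats[dev & linked]
  }) |> stats::setNames(rownames(summaries))
}

#' Flag health-affecting categories and build recommendations
#'
#' A category is *red* (health-affecting) when it appears in a frequent
#' itemset that co-occurs, in at least one subject, with a predicted
#' medium or high effect (ME/HE); all other categories are *blue*.
#' Per-subject corrective suggestions name each red category whose
#' subject summary exceeds the cohort median, with the templated action
#' "reduce/modify". The feedback hook returns per-subject weights (red-
#' linked subjects upweighted x2) for optional classifier retraining;
#' blue subjects pass through with weight 1.
#'
#' @param linkage A [build_linkage_map()] result.
#' @param itemsets An [apriori()] result.
#' @param predictions Data frame from [predict_classes()] (rows aligned
#'   with `transactions`/`summaries`), with an `effect` column.
#' @param transactions Output of [build_transactions()].
#' @param summaries Subjects x categories summary matrix.
#' @param minsup The minimum support used (stored in the report).
#' @return An object of class `"recommendation_report"`: list with
#'   `linkage`, `minsup`, `itemsets`, `red`, `blue`, `suggestions`
#'   (data frame: subject_id, category, effect, action), `weights`
#'   (feedback sample weights) and a non-clinical-use `disclaimer`.
#' @export
flag_and_recommend <- function(linkage, itemsets, predictions, transactions,
                               summaries, minsup = NA_real_) {
  if (is.null(predictions) || !nrow(predictions)) {
    stop_fmt("flag_and_recommend: no predictions available")
  }
  if (length(transactions) != nrow(predictions)) {
    stop_fmt("flag_and_recommend: transactions and predictions misaligned")
  }
  cats <- linkage$categories
  high <- predictions$effect >= 2L
  red <- character(0)
  if (nrow(itemsets)) {
    for (j in seq_len(nrow(itemsets))) {
      set <- itemsets$items[[j]]
      cooccurs <- any(vapply(
        which(high),
        function(i) all(set %in% transactions[[i]]),
        TRUE
      ))
      if (cooccurs) red <- union(red, set)
    }
  }
  red <- intersect(cats, red)
  blue <- setdiff(cats, red)

  med <- apply(summaries, 2L, stats::median)
  sugg <- list()
  subj <- names(transactions) %||% rownames(summaries)
  for (i in seq_len(nrow(predictions))) {
    for (ct in red) {
      if (summaries[i, ct] > med[ct]) {
        sugg[[length(sugg) + 1L]] <- data.frame(
          subject_id = subj[i],
          category = ct,
          effect = predictions$effect_label[i] %||% predictions$effect[i],
          action = "reduce/modify",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  suggestions <- if (length(sugg)) do.call(rbind, sugg) else {
    data.frame(
      subject_id = character(), category = character(),
      effect = character(), action = character(), stringsAsFactors = FALSE
    )
  }
  red_linked <- vapply(transactions, function(t) length(intersect(t, red)) > 0L, TRUE)
  weights <- ifelse(red_linked, 2, 1)
  structure(
    list(
      linkage = linkage, minsup = minsup, itemsets = itemsets,
      red = red, blue = blue, suggestions = suggestions,
      weights = stats::setNames(weights, subj),
      disclaimer = paste(
        "Templated behavioral suggestions derived from statistical",
        "associations; not clinical advice."
      )
    ),
    class = "recommendation_report"
  )
}

#' @export
print.recommendation_report <- function(x, ...) {
  cat("<recommendation_report>\n")
  cat("  minsup:", format(x$minsup, digits = 4), "\n")
  cat("  frequent itemsets:", nrow(x$itemsets), "\n")
  cat("  red (health-affecting):", if (length(x$red)) paste(x$red, collapse = ", ") else "(none)", "\n")
  cat("  blue:", paste(x$blue, collapse = ", "), "\n")
  cat("  suggestions:", nrow(x$suggestions), "\n")
  invisible(x)
}
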