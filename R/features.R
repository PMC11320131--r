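# Multidomain feature bank: Fourier, cosine, windowed-convolution, Gabor
# and Haar-style wavelet components, assembled into the Behavioral
# Feature Vector (BFV).

#' Gabor analysis configuration
#'
#' @param sigma Envelope width (> 0) of the Gaussian term.
#' @param aspect Spatial aspect ratio (> 0) weighting the rotated y
#'   coordinate inside the envelope.
#' @param delta Orientation angles in radians (non-empty, in `(0, 2*pi)`;
#'   0 is accepted as the degenerate "no rotation" case).
#' @param phi Phase offsets in radians added inside the carrier cosine.
#' @param c Wavelength constant: the carrier wavelength is `c / fs` where
#'   `fs` is the series sampling frequency. The constant is a free model
#'   parameter; 1 is the neutral default.
#' @param embedding How the 1-D series is embedded into a 2-D array:
#'   `"delay_matrix"` (rows are lagged copies of the signal) or
#'   `"spectrogram"` (magnitude short-time spectrum via
#'   [signal::specgram()]).
#' @param n_lags Number of rows of the delay-matrix embedding.
#' @return An object of class `"gabor_config"`.
#' @export
gabor_config <- function(sigma = 2, aspect = 1,
                         delta = c(0, pi / 4, pi / 2, 3 * pi / 4),
                         phi = 0, c = 1,
                         embedding = c("delay_matrix", "spectrogram"),
                         n_lags = 16L) {
  embedding <- match.arg(embedding)
  if (sigma <= 0 || aspect <= 0 || c <= 0) stop_fmt("sigma, aspect and c must be > 0")
  if (!length(delta) || !length(phi)) stop_fmt("angle lists must be non-empty")
  structure(
    list(
      sigma = sigma, aspect = aspect, delta = delta, phi = phi, c = c,
      embedding = embedding, n_lags = as.integer(n_lags)
    ),
    class = "gabor_config"
  )
}

#' Feature-extraction configuration
#'
#' @param m Convolution window dimension (>= 2).
#' @param la Leaky-ReLU slope for the negative branch, in `(0, 1)`.
#' @param dct_mode `"paper_literal"` applies the model's printed cosine
#'   transform (`(1/(2*Nf)) * x_i * sum(x) * cos((2*i+1)*pi/(2*Nf))`,
#'   with no summation index inside the cosine); `"standard_dct2"` is the
#'   orthonormal DCT-II. Both are shipped because the literal form is
#'   almost surely a typographical corruption of DCT-II; the literal form
#'   is the default for fidelity.
#' @param conv_padding Boundary handling for the windowed convolution:
#'   `"zero"` or `"reflect"`.
#' @param wavelet_levels Number of pairwise average/difference
#'   decomposition levels (>= 1, at most `log2(series length)`).
#' @param gabor A [gabor_config()].
#' @return An object of class `"feature_config"`.
#' @export
feature_config <- function(m = 4L, la = 0.01,
                           dct_mode = c("paper_literal", "standard_dct2"),
                           conv_padding = c("zero", "reflect"),
                           wavelet_levels = 3L,
                           gabor = gabor_config()) {
  dct_mode <- match.arg(dct_mode)
  conv_padding <- match.arg(conv_padding)
  m <- as.integer(m)
  if (m < 2L) stop_fmt("window dimension m must be >= 2")
  if (la <= 0 || la >= 1) stop_fmt("lrelu slope la must be in (0, 1)")
  if (wavelet_levels < 1L) stop_fmt("wavelet_levels must be >= 1")
  stopifnot(inherits(gabor, "gabor_config"))
  structure(
    list(
      m = m, la = la, dct_mode = dct_mode, conv_padding = conv_padding,
      wavelet_levels = as.integer(wavelet_levels), gabor = gabor
    ),
    class = "feature_config"
  )
}

.check_series_values <- function(x, what) {
  if (!length(x)) stop_fmt("%s: empty series", what)
  if (anyNA(x) || any(!is.finite(x))) stop_fmt("%s: non-finite values in input", what)
  as.numeric(x)
}

.series_values <- function(series) {
  if (inherits(series, "behavior_series")) series$values else series
}

# cached trigonometric bases per series length (DFT is O(N^2) by design;
# the basis matrices dominate, so they are built once per length)
.basis_cache <- new.env(parent = emptyenv())

.dft_basis <- function(n) {
  key <- paste0("dft", n)
  if (is.null(.basis_cache[[key]])) {
    ang <- 2 * pi * outer(seq_len(n), seq_len(n)) / n
    .basis_cache[[key]] <- list(cos = cos(ang), sin = sin(ang))
  }
  .basis_cache[[key]]
}

#' Discrete Fourier features
#'
#' Computes the model's Fourier component bank
#' `DFT_i = sum_j x_j * (cos(2*pi*i*j/Nf) - 1i * sin(2*pi*i*j/Nf))`
#' with both indices running 1..Nf. Under this 1-based convention the DC
#' component sits in bin `Nf` (where `i*j/Nf` is integral), not bin 1.
#'
#' @param series A numeric vector or `behavior_series`.
#' @return Complex vector of length `Nf`.
#' @examples
#' dft_features(c(2, 2, 2, 2)) # DC bin (the 4th) equals 8
#' @export
dft_features <- function(series) {
  x <- .check_series_values(.series_values(series), "dft_features")
  b <- .dft_basis(length(x))
  as.vector(b$cos %*% x) - 1i * as.vector(b$sin %*% x)
}

#' Cosine-transform features
#'
#' In `"paper_literal"` mode entry `i` (1-based) is
#' `(1 / (2*Nf)) * x_i * sum(x) * cos((2*i + 1) * pi / (2*Nf))` — the
#' model's printed cosine feature, in which the cosine argument does not
#' depend on the summation index. In `"standard_dct2"` mode the
#' orthonormal DCT-II is returned instead.
#'
#' @inheritParams dft_features
#' @param mode `"paper_literal"` or `"standard_dct2"`.
#' @return Real vector of length `Nf`.
#' @export
dct_features <- function(series, mode = c("paper_literal", "standard_dct2")) {
  mode <- match.arg(mode)
  x <- .check_series_values(.series_values(series), "dct_features")
  n <- length(x)
  if (mode == "paper_literal") {
    i <- seq_len(n)
    (1 / (2 * n)) * x * sum(x) * cos((2 * i + 1) * pi / (2 * n))
  } else {
    k <- seq_len(n) - 1L # 0-based frequency index
    basis <- cos(pi * outer(k, 2 * (seq_len(n) - 1L) + 1) / (2 * n))
    out <- sqrt(2 / n) * as.vector(basis %*% x)
    out[1] <- out[1] / sqrt(2)
    out
  }
}

#' Leaky rectified linear unit
#'
#' `x` for `x >= 0`, `la * x` otherwise. Vectorised over `x`.
#'
#' @param x Numeric vector.
#' @param la Negative-branch slope.
#' @return Numeric vector of the same length.
#' @export
lrelu <- function(x, la) ifelse(x < 0, la * x, x)

#' Windowed-convolution features
#'
#' `Conv_i = sum_{a = -floor(m/2)}^{floor(m/2)} x(i - a) * LReLU((m + 2a)/2)`.
#' Over that range `(m + 2a)/2 >= 0`, so the kernel is the deterministic
#' ramp `(m + 2a)/2`; out-of-range samples are resolved by the configured
#' padding. The output has the same length as the input.
#'
#' @inheritParams dft_features
#' @param m Window dimension (>= 2, at most the series length).
#' @param la Leaky-ReLU slope (inert for this kernel, kept for fidelity).
#' @param padding `"zero"` or `"reflect"`.
#' @return Numeric vector of the series length.
#' @export
conv_features <- function(series, m = 4L, la = 0.01,
                          padding = c("zero", "reflect")) {
  padding <- match.arg(padding)
  x <- .check_series_values(.series_values(series), "conv_features")
  m <- as.integer(m)
  n <- length(x)
  if (m < 2L) stop_fmt("conv_features: m must be >= 2")
  if (m > n) stop_fmt("conv_features: window m=%d exceeds series length %d", m, n)
  half <- m %/% 2L
  a <- seq.int(-half, half)
  kern <- lrelu((m + 2 * a) / 2, la)
  pad_get <- function(idx) {
    if (padding == "zero") {
      v <- numeric(length(idx))
      ok <- idx >= 1L & idx <= n
      v[ok] <- x[idx[ok]]
      v
    } else {
      # reflect about the edges (abcd -> ba|abcd|dc)
      idx <- ifelse(idx < 1L, 1L - idx, idx)
      idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
      x[pmin(pmax(idx, 1L), n)]
    }
  }
  out <- numeric(n)
  for (j in seq_along(a)) out <- out + kern[j] * pad_get(seq_len(n) - a[j])
  out
}

# 2-D embedding of a 1-D series
.embed_series <- function(x, gabor, fs) {
  if (gabor$embedding == "delay_matrix") {
    L <- gabor$n_lags
    if (length(x) < L + 1L) {
      stop_fmt("series too short (%d) for delay embedding with %d lags", length(x), L)
    }
    ncol <- length(x) - L + 1L
    mat <- matrix(0, nrow = L, ncol = ncol)
    for (r in seq_len(L)) mat[r, ] <- x[r:(r + ncol - 1L)]
    mat
  } else {
    nfft <- min(32L, 2^floor(log2(length(x))))
    sp <- signal::specgram(x, n = nfft, Fs = fs)
    Mod(sp$S)
  }
}

#' Gabor filter responses and energies
#'
#' The series is embedded into a 2-D array (time-delay matrix by default)
#' and correlated with a Gabor kernel
#' `exp(-(x'^2 + aspect^2 * y'^2) / (2 * sigma^2)) * cos(2*pi*x'/lambda + phi)`
#' where `(x', y')` are the grid coordinates rotated by `delta` and the
#' carrier wavelength is `lambda = c / fs`. `gabor_response()` returns the
#' raw signed correlation per `(delta, phi)` pair; `gabor_features()`
#' returns the response energies (squared responses), one per pair.
#'
#' @inheritParams dft_features
#' @param gabor A [gabor_config()].
#' @param fs Sampling frequency in Hz (taken from a `behavior_series`
#'   when available).
#' @return Numeric vector with one entry per `(delta, phi)` pair, named
#'   `d<delta>_p<phi>`.
#' @export
gabor_response <- function(series, gabor = gabor_config(), fs = NULL) {
  vals <- .series_values(series)
  if (is.null(fs)) fs <- if (inherits(series, "behavior_series")) series$fs else 1
  if (fs <= 0) stop_fmt("gabor: fs must be > 0")
  x <- .check_series_values(vals, "gabor")
  E <- .embed_series(x, gabor, fs)
  lambda <- gabor$c / fs
  # centred grid coordinates: columns = time axis, rows = lag/frequency axis
  cx <- (seq_len(ncol(E)) - (ncol(E) + 1) / 2)
  cy <- (seq_len(nrow(E)) - (nrow(E) + 1) / 2)
  X <- matrix(cx, nrow = nrow(E), ncol = ncol(E), byrow = TRUE)
  Y <- matrix(cy, nrow = nrow(E), ncol = ncol(E))
  out <- numeric(length(gabor$delta) * length(gabor$phi))
  nms <- character(length(out))
  k <- 0L
  for (d in gabor$delta) {
    xr <- X * cos(d) + Y * sin(d)
    yr <- -X * sin(d) + Y * cos(d)
    env <- exp(-(xr^2 + gabor$aspect^2 * yr^2) / (2 * gabor$sigma^2))
    for (p in gabor$phi) {
      k <- k + 1L
      out[k] <- sum(env * cos(2 * pi * xr / lambda + p) * E)
      nms[k] <- sprintf("d%.3f_p%.3f", d, p)
    }
  }
  stats::setNames(out, nms)
}

#' @rdname gabor_response
#' @export
gabor_features <- function(series, gabor = gabor_config(), fs = NULL) {
  r <- gabor_response(series, gabor, fs)
  stats::setNames(r^2, names(r))
}

#' Pairwise average/difference wavelet decomposition
#'
#' One level maps non-overlapping sample pairs to approximation
#' `Wa_i = (x_{2i-1} + x_{2i}) / 2` and detail
#' `Wd_i = (x_{2i-1} - x_{2i}) / 2` (a Haar analysis up to scaling, with
#' perfect reconstruction `x_{2i-1} = Wa_i + Wd_i`,
#' `x_{2i} = Wa_i - Wd_i`). The decomposition is repeated on the
#' approximation for `levels` levels. An odd-length input is truncated by
#' one sample with a warning.
#'
#' @inheritParams dft_features
#' @param levels Number of decomposition levels.
#' @return A list with `wa` (deepest-level approximation) and `wd`
#'   (detail coefficients of all levels, finest first, concatenated).
#' @examples
#' wavelet_features(c(1, 3), levels = 1) # wa = 2, wd = -1
#' @export
wavelet_features <- function(series, levels = 1L) {
  x <- .check_series_values(.series_values(series), "wavelet_features")
  levels <- as.integer(levels)
  if (levels < 1L) stop_fmt("wavelet_features: levels must be >= 1")
  details <- list()
  for (l in seq_len(levels)) {
    if (length(x) < 2L) {
      warn_fmt("wavelet_features: series exhausted at level %d; stopping early", l)
      break
    }
    if (length(x) %% 2L == 1L) {
      warn_fmt("wavelet_features: odd length %d, truncating last sample", length(x))
      x <- x[-length(x)]
    }
    odd <- x[seq(1L, length(x), by = 2L)]
    even <- x[seq(2L, length(x), by = 2L)]
    details[[l]] <- (odd - even) / 2
    x <- (odd + even) / 2
  }
  list(wa = x, wd = unlist(details) %||% numeric(0))
}

#' Assemble the Behavioral Feature Vector
#'
#' Concatenates the multidomain features of every category of one record
#' in a deterministic order: categories alphabetically, then transforms
#' in the fixed order DFT, DCT, CONV, GABOR, WA, WD, then feature index.
#' Complex Fourier components enter as magnitudes so the vector is real.
#'
#' @param record A `behavior_record` (or a named list of
#'   `behavior_series` / numeric vectors).
#' @param config A [feature_config()].
#' @return An object of class `"bfv"`: a list with `values` (numeric
#'   vector), `provenance` (data frame with columns `transform`,
#'   `category`, `index`) and `record_id`.
#' @export
build_bfv <- function(record, config = feature_config()) {
  series_list <- if (inherits(record, "behavior_record")) record$series else record
  record_id <- if (inherits(record, "behavior_record")) record$subject_id else NA_character_
  if (!length(series_list) || is.null(names(series_list))) {
    stop_fmt("build_bfv: record must carry named per-category series")
  }
  cats <- sort(names(series_list))
  vals <- list()
  prov <- list()
  for (cat in cats) {
    s <- series_list[[cat]]
    fs <- if (inherits(s, "behavior_series")) s$fs else 1
    blocks <- tryCatch(
      {
        wv <- wavelet_features(s, config$wavelet_levels)
        list(
          DFT = Mod(dft_features(s)),
          DCT = dct_features(s, config$dct_mode),
          CONV = conv_features(s, config$m, config$la, config$conv_padding),
          GABOR = unname(gabor_features(s, config$gabor, fs)),
          WA = wv$wa,
          WD = wv$wd
        )
      },
      error = function(e) {
        stop_fmt("build_bfv: category '%s': %s", cat, conditionMessage(e))
      }
    )
    for (tr in names(blocks)) {
      b <- blocks[[tr]]
      if (!length(b)) next
      vals[[paste(cat, tr)]] <- b
      prov[[paste(cat, tr)]] <- data.frame(
        transform = tr, category = cat, index = seq_along(b),
        stringsAsFactors = FALSE
      )
    }
  }
  values <- unlist(vals, use.names = FALSE)
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  if (any(!is.finite(values))) stop_fmt("build_bfv: non-finite feature values")
  structure(
    list(values = values, provenance = provenance, record_id = record_id),
    class = "bfv"
  )
}

#' Build the feature matrix for a dataset
#'
#' Applies [build_bfv()] to every record and stacks the results.
#'
#' @param dataset A `behavior_dataset` (list of records).
#' @param config A [feature_config()].
#' @return A numeric matrix (records x features) with the shared
#'   provenance data frame in attribute `"provenance"` and record ids as
#'   row names.
#' @export
bfv_matrix <- function(dataset, config = feature_config()) {
  bfvs <- lapply(dataset, build_bfv, config = config)
  lens <- vapply(bfvs, function(b) length(b$values), 0L)
  if (length(unique(lens)) > 1L) stop_fmt("bfv_matrix: records yield unequal feature counts")
  m <- do.call(rbind, lapply(bfvs, `[[`, "values"))
  rownames(m) <- vapply(bfvs, `[[`, "", "record_id")
  colnames(m) <- with(bfvs[[1]]$provenance, paste(category, transform, index, sep = "."))
  attr(m, "provenance") <- bfvs[[1]]$provenance
  m
}
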