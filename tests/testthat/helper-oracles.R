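# Independent brute-force / direct-evaluation oracles. These deliberately
# use naive double loops and scalar arithmetic, not the package's code
# paths.

oracle_dft <- function(x) {
  n <- length(x)
  out <- complex(n)
  for (i in seq_len(n)) {
    acc <- 0 + 0i
    for (j in seq_len(n)) {
      acc <- acc + x[j] * (cos(2 * pi * i * j / n) - 1i * sin(2 * pi * i * j / n))
    }
    out[i] <- acc
  }
  out
}

oracle_dct2 <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (k in 0:(n - 1)) {
    acc <- 0
    for (m in 0:(n - 1)) acc <- acc + x[m + 1] * cos(pi * (2 * m + 1) * k / (2 * n))
    ck <- if (k == 0) 1 / sqrt(2) else 1
    out[k + 1] <- sqrt(2 / n) * ck * acc
  }
  out
}

oracle_dct_literal <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- (1 / (2 * n)) * x[i] * sum(x) * cos((2 * i + 1) * pi / (2 * n))
  }
  out
}

oracle_conv <- function(x, m, la, padding = "zero") {
  n <- length(x)
  half <- m %/% 2
  get <- function(idx) {
    if (idx >= 1 && idx <= n) return(x[idx])
    if (padding == "zero") return(0)
    if (idx < 1) idx <- 1 - idx
    if (idx > n) idx <- 2 * n + 1 - idx
    x[min(max(idx, 1), n)]
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (a in (-half):half) {
      k <- (m + 2 * a) / 2
      k <- if (k < 0) la * k else k
      acc <- acc + get(i - a) * k
    }
    out[i] <- acc
  }
  out
}

oracle_dispersion <- function(v) {
  mu <- 0
  for (vi in v) mu <- mu + vi
  mu <- mu / length(v)
  acc <- 0
  for (vi in v) acc <- acc + (vi - mu)^2
  acc / (length(v) + 1)
}

# scalar (hidden_dim = 1) LSTM replay with plain arithmetic
oracle_lstm_scalar <- function(x, p, n_steps) {
  sig <- function(z) 1 / (1 + exp(-z))
  h <- 0
  cs <- 0
  e_trace <- numeric(n_steps)
  prev <- 0
  for (t in seq_len(n_steps)) {
    i <- sig(x * p$Ui[1, 1] + h * p$Wi[1, 1])
    f <- sig(x * p$Uf[1, 1] + h * p$Wf[1, 1])
    o <- sig(x * p$Uo[1, 1] + h * p$Wo[1, 1])
    g <- tanh(x * p$Ug[1, 1] + h * p$Wg[1, 1])
    cs <- f * cs + i * g
    h <- tanh(cs) * o
    e_trace[t] <- abs(cs - prev)
    prev <- cs
  }
  list(h = h, tout = cs, e_trace = e_trace)
}

# exhaustive frequent-itemset enumeration over all non-empty item subsets
oracle_apriori <- function(transactions, minsup) {
  tx <- lapply(transactions, function(t) sort(unique(as.character(t))))
  items <- sort(unique(unlist(tx)))
  nt <- length(tx)
  out <- list()
  sup <- numeric(0)
  if (length(items)) {
    for (mask in 1:(2^length(items) - 1)) {
      set <- items[bitwAnd(mask, 2^(seq_along(items) - 1)) > 0]
      s <- sum(vapply(tx, function(t) all(set %in% t), TRUE)) / nt
      if (s >= minsup) {
        out[[length(out) + 1]] <- set
        sup <- c(sup, s)
      }
    }
  }
  keys <- vapply(out, paste, "", collapse = ",")
  ord <- order(keys)
  list(keys = keys[ord], support = sup[ord])
}

itemset_keys <- function(apriori_df) {
  keys <- vapply(apriori_df$items, paste, "", collapse = ",")
  ord <- order(keys)
  list(keys = keys[ord], support = apriori_df$support[ord])
}

# small, fast synthetic dataset for pipeline-level tests
tiny_synth <- function(n_subjects = 24, n_samples = 64, noise_sd = 0.3,
                       corr = TRUE) {
  synth_config(
    n_subjects = n_subjects, n_samples = n_samples, noise_sd = noise_sd,
    corr_spec = if (corr) list(list("sleep", "hrv", 0.9)) else list()
  )
}

tiny_ffo <- function() ffo_config(n_fireflies = 6, n_iterations = 10)
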