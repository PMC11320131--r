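# LSTM feature augmentation and softmax classification.
#
# The recurrence is applied repeatedly to the same (selected) feature
# vector; the cell output Tout plays the role of the cell state and hout
# is the hidden vector fed to the softmax head. Gates use the standard
# logistic activation by default; a "variance_literal" mode replaces the
# activation by the scalar dispersion of the pre-activation vector, and a
# "paper_literal" cell mode feeds the input (rather than the previous
# cell state) through the forget gate. Both literal modes are fidelity
# modes for inference only.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM parameters
#'
#' Gate matrices `U*` (input -> hidden) and `W*` (hidden -> hidden) for
#' the input (i), forget (f), output (o) and candidate (g) gates,
#' initialised uniformly in `[-0.1, 0.1]`.
#'
#' @param input_dim Input feature dimension.
#' @param hidden_dim Hidden dimension.
#' @param activation `"sigmoid_standard"` or `"variance_literal"` (the
#'   dispersion statistic applied across each pre-activation vector,
#'   broadcast over the hidden dimension).
#' @param cell `"state"` (previous cell output through the forget gate;
#'   standard LSTM memory) or `"paper_literal"` (the input vector through
#'   the forget gate, which discards memory; requires
#'   `input_dim == hidden_dim`).
#' @param seed Integer seed for the initialisation.
#' @return An object of class `"lstm_params"`.
#' @export
lstm_params <- function(input_dim, hidden_dim = 8L,
                        activation = c("sigmoid_standard", "variance_literal"),
                        cell = c("state", "paper_literal"),
                        seed = 1L) {
  activation <- match.arg(activation)
  cell <- match.arg(cell)
  input_dim <- as.integer(input_dim)
  hidden_dim <- as.integer(hidden_dim)
  if (input_dim < 1L || hidden_dim < 1L) stop_fmt("dimensions must be >= 1")
  if (cell == "paper_literal" && input_dim != hidden_dim) {
    stop_fmt("paper_literal cell mode requires input_dim == hidden_dim")
  }
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -0.1, 0.1), nr, nc)
  with_seed(seed, {
    structure(
      list(
        Ui = rmat(input_dim, hidden_dim), Wi = rmat(hidden_dim, hidden_dim),
        Uf = rmat(input_dim, hidden_dim), Wf = rmat(hidden_dim, hidden_dim),
        Uo = rmat(input_dim, hidden_dim), Wo = rmat(hidden_dim, hidden_dim),
        Ug = rmat(input_dim, hidden_dim), Wg = rmat(hidden_dim, hidden_dim),
        input_dim = input_dim, hidden_dim = hidden_dim,
        activation = activation, cell = cell
      ),
      class = "lstm_params"
    )
  })
}

.as_batch <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, ncol = d)
  as.matrix(x)
}

.gate_activate <- function(pre, mode) {
  if (mode == "sigmoid_standard") {
    sigmoid(pre)
  } else {
    # scalar dispersion of each row's pre-activation vector, broadcast
    g <- apply(pre, 1L, dispersion)
    matrix(g, nrow = nrow(pre), ncol = ncol(pre))
  }
}

#' One LSTM step
#'
#' Computes `i = act(x Ui + h Wi)`, `f = act(x Uf + h Wf)`,
#' `o = act(x Uo + h Wo)`, `C' = tanh(x Ug + h Wg)`,
#' `Tout = f * Tout_prev + i * C'` (or `f * x + i * C'` in paper-literal
#' cell mode) and `hout = tanh(Tout) * o`.
#'
#' @param x Input matrix (records x input_dim) or a single vector.
#' @param state List with `h` and `tout` matrices (records x hidden_dim);
#'   `NULL` for the zero initial state.
#' @param params An [lstm_params()] object.
#' @return A list with updated `h` and `tout`.
#' @export
lstm_step <- function(x, state = NULL, params) {
  stopifnot(inherits(params, "lstm_params"))
  x <- .as_batch(x, params$input_dim)
  if (ncol(x) != params$input_dim) {
    stop_fmt("lstm_step: input dim %d != params input_dim %d", ncol(x), params$input_dim)
  }
  n <- nrow(x)
  if (is.null(state)) {
    state <- list(
      h = matrix(0, n, params$hidden_dim),
      tout = matrix(0, n, params$hidden_dim)
    )
  }
  h <- .as_batch(state$h, params$hidden_dim)
  tout_prev <- .as_batch(state$tout, params$hidden_dim)
  i <- .gate_activate(x %*% params$Ui + h %*% params$Wi, params$activation)
  f <- .gate_activate(x %*% params$Uf + h %*% params$Wf, params$activation)
  o <- .gate_activate(x %*% params$Uo + h %*% params$Wo, params$activation)
  cg <- tanh(x %*% params$Ug + h %*% params$Wg)
  tout <- if (params$cell == "state") f * tout_prev + i * cg else f * x + i * cg
  hout <- tanh(tout) * o
  if (any(!is.finite(tout)) || any(!is.finite(hout))) {
    stop_fmt("lstm_step: non-finite gate output")
  }
  list(h = hout, tout = tout)
}

#' Iterate the LSTM on a fixed input until convergence
#'
#' Repeats [lstm_step()] on the same input; after each step the error is
#' `e = max |Tout_current - Tout_previous|` (max-absolute-entry norm of
#' the cell-output change). Iteration stops when `e < tol` (converged)
#' or after `max_iter` steps (flagged non-converged). An error is raised
#' if `e` grows for 50 consecutive iterations (divergence).
#'
#' @inheritParams lstm_step
#' @param tol Convergence tolerance on `e` (default 0.01).
#' @param max_iter Iteration cap.
#' @return A list with the final `h`, `tout`, the error trace `e_trace`,
#'   the final `e`, `iterations` used and logical `converged`.
#' @export
run_until_converged <- function(x, params, tol = 0.01, max_iter = 100L) {
  if (tol <= 0) stop_fmt("tol must be > 0")
  x <- .as_batch(x, params$input_dim)
  state <- NULL
  tout_prev <- matrix(0, nrow(x), params$hidden_dim)
  e_trace <- numeric(0)
  grow <- 0L
  for (it in seq_len(max_iter)) {
    state <- lstm_step(x, state, params)
    e <- max(abs(state$tout - tout_prev))
    e_trace <- c(e_trace, e)
    if (length(e_trace) >= 2L && e > e_trace[length(e_trace) - 1L]) {
      grow <- grow + 1L
      if (grow >= 50L) stop_fmt("run_until_converged: diverging at iteration %d (e = %g)", it, e)
    } else {
      grow <- 0L
    }
    if (e < tol) {
      return(list(
        h = state$h, tout = state$tout, e = e, e_trace = e_trace,
        iterations = it, converged = TRUE
      ))
    }
    tout_prev <- state$tout
  }
  list(
    h = state$h, tout = state$tout, e = e_trace[length(e_trace)],
    e_trace = e_trace, iterations = max_iter, converged = FALSE
  )
}

# forward pass with caches for backpropagation (standard mode only)
.lstm_forward_cache <- function(x, p, n_steps) {
  n <- nrow(x)
  H <- p$hidden_dim
  h <- matrix(0, n, H)
  cs <- matrix(0, n, H)
  cache <- vector("list", n_steps)
  for (t in seq_len(n_steps)) {
    i <- sigmoid(x %*% p$Ui + h %*% p$Wi)
    f <- sigmoid(x %*% p$Uf + h %*% p$Wf)
    o <- sigmoid(x %*% p$Uo + h %*% p$Wo)
    g <- tanh(x %*% p$Ug + h %*% p$Wg)
    c_new <- f * cs + i * g
    cache[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = cs, h_prev = h, c = c_new)
    cs <- c_new
    h <- tanh(cs) * o
  }
  list(h = h, c = cs, cache = cache)
}

# analytic gradients of the mean cross-entropy through the unrolled
# recurrence; dlogit = (p - y) / n
.lstm_backward <- function(x, p, fw, dlogit, head) {
  H <- p$hidden_dim
  n <- nrow(x)
  zero <- function(a) a * 0
  grads <- list(
    Ui = zero(p$Ui), Wi = zero(p$Wi), Uf = zero(p$Uf), Wf = zero(p$Wf),
    Uo = zero(p$Uo), Wo = zero(p$Wo), Ug = zero(p$Ug), Wg = zero(p$Wg),
    w = crossprod(fw$h, dlogit), b = colSums(dlogit)
  )
  dh <- dlogit %*% t(head$w)
  dc <- matrix(0, n, H)
  for (t in rev(seq_along(fw$cache))) {
    cc <- fw$cache[[t]]
    tc <- tanh(cc$c)
    dc <- dc + dh * cc$o * (1 - tc^2)
    da_o <- (dh * tc) * cc$o * (1 - cc$o)
    da_i <- (dc * cc$g) * cc$i * (1 - cc$i)
    da_g <- (dc * cc$i) * (1 - cc$g^2)
    da_f <- (dc * cc$c_prev) * cc$f * (1 - cc$f)
    grads$Ui <- grads$Ui + crossprod(x, da_i)
    grads$Wi <- grads$Wi + crossprod(cc$h_prev, da_i)
    grads$Uf <- grads$Uf + crossprod(x, da_f)
    grads$Wf <- grads$Wf + crossprod(cc$h_prev, da_f)
    grads$Uo <- grads$Uo + crossprod(x, da_o)
    grads$Wo <- grads$Wo + crossprod(cc$h_prev, da_o)
    grads$Ug <- grads$Ug + crossprod(x, da_g)
    grads$Wg <- grads$Wg + crossprod(cc$h_prev, da_g)
    dh <- da_i %*% t(p$Wi) + da_f %*% t(p$Wf) + da_o %*% t(p$Wo) + da_g %*% t(p$Wg)
    dc <- dc * cc$f
  }
  grads
}

#' Train the LSTM classifier
#'
#' Full-batch gradient descent on the mean cross-entropy of the softmax
#' head applied to the hidden state after `n_steps` applications of the
#' recurrence to the (fixed) input features, with analytic
#' backpropagation through the unrolled recurrence. Gate matrices and
#' the head are trained jointly. Training requires the standard sigmoid
#' activation and cell-state semantics; the literal fidelity modes are
#' inference-only.
#'
#' @param features Numeric matrix (records x features), already on a
#'   comparable scale (the model-level wrapper standardises).
#' @param labels Integer (1-based) or factor class labels; at least two
#'   classes must be present.
#' @param hidden_dim Hidden dimension.
#' @param n_steps Unrolled recurrence depth.
#' @param learning_rate Gradient-descent step size.
#' @param epochs Maximum epochs.
#' @param weight_decay L2 penalty coefficient on the gate matrices and
#'   head weights (biases unpenalised); with many selected features and
#'   modest cohorts the unpenalised fit interpolates noise columns.
#' @param head_only Freeze the recurrence and fit only the (convex)
#'   softmax head.
#' @param patience Epochs without relative improvement `> 1e-8` before
#'   early stop.
#' @param n_classes Number of classes (defaults to `max(labels)`).
#' @param effect_map Integer vector mapping class to effect level 1..3;
#'   default `((class - 1) %% 3) + 1`, the identity for three classes.
#' @param seed Seed for parameter initialisation.
#' @return An object of class `"lstm_model"` with elements `params`,
#'   `head` (`w`, `b`), `history` (per-epoch loss), `n_steps`,
#'   `n_classes`, `effect_map`.
#' @export
train_classifier <- function(features, labels, hidden_dim = 8L, n_steps = 3L,
                             learning_rate = 0.01, epochs = 200L,
                             weight_decay = 0, head_only = FALSE, patience = 25L,
                             n_classes = NULL, effect_map = NULL, seed = 1L) {
  x <- as.matrix(features)
  if (any(!is.finite(x))) stop_fmt("train_classifier: non-finite features")
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop_fmt("train_classifier: need >= 2 classes in labels")
  K <- as.integer(n_classes %||% max(labels))
  if (is.null(effect_map)) effect_map <- ((seq_len(K) - 1L) %% 3L) + 1L
  n <- nrow(x)
  if (length(labels) != n) stop_fmt("train_classifier: labels length != rows")
  y <- matrix(0, n, K)
  y[cbind(seq_len(n), labels)] <- 1

  p <- lstm_params(ncol(x), hidden_dim, seed = seed)
  head <- with_seed(seed + 1L, list(
    w = matrix(stats::runif(hidden_dim * K, -0.1, 0.1), hidden_dim, K),
    b = numeric(K)
  ))

  history <- numeric(0)
  best <- Inf
  stall <- 0L
  for (ep in seq_len(epochs)) {
    fw <- .lstm_forward_cache(x, p, n_steps)
    logits <- fw$h %*% head$w + matrix(head$b, n, K, byrow = TRUE)
    post <- softmax_rows(logits)
    loss <- -mean(log(pmax(post[cbind(seq_len(n), labels)], 1e-300)))
    history <- c(history, loss)
    dlogit <- (post - y) / n
    g <- .lstm_backward(x, p, fw, dlogit, head)
    head$w <- head$w - learning_rate * (g$w + weight_decay * head$w)
    head$b <- head$b - learning_rate * g$b
    if (!head_only) {
      for (nm in c("Ui", "Wi", "Uf", "Wf", "Uo", "Wo", "Ug", "Wg")) {
        p[[nm]] <- p[[nm]] - learning_rate * (g[[nm]] + weight_decay * p[[nm]])
      }
    }
    if (loss < best * (1 - 1e-8)) {
      best <- loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(
    list(
      params = p, head = head, history = history, n_steps = n_steps,
      n_classes = K, effect_map = effect_map
    ),
    class = "lstm_model"
  )
}

#' Classify feature vectors
#'
#' Runs the trained recurrence for the model's unroll depth, applies the
#' softmax head (`SoftMax(sum_i f_i w_i + b)`), and quantizes the argmax
#' class (ties broken by lowest index) into effect levels LE/ME/HE via
#' the model's class-to-effect map.
#'
#' @param model An `"lstm_model"` from [train_classifier()].
#' @param features Numeric matrix (records x features) on the training
#'   scale.
#' @return A data frame with one row per record: posterior columns
#'   `p1..pK`, `class` and `effect` (integer 1..3, labelled via
#'   [effect_levels()] in column `effect_label`).
#' @export
predict_classes <- function(model, features) {
  stopifnot(inherits(model, "lstm_model"))
  x <- as.matrix(features)
  if (ncol(x) != model$params$input_dim) {
    stop_fmt(
      "predict_classes: feature dim %d != model input_dim %d",
      ncol(x), model$params$input_dim
    )
  }
  fw <- .lstm_forward_cache(x, model$params, model$n_steps)
  K <- model$n_classes
  logits <- fw$h %*% model$head$w + matrix(model$head$b, nrow(x), K, byrow = TRUE)
  post <- softmax_rows(logits)
  cls <- argmax_row(post)
  eff <- model$effect_map[cls]
  out <- as.data.frame(post)
  names(out) <- paste0("p", seq_len(K))
  out$class <- cls
  out$effect <- eff
  out$effect_label <- effect_levels()[eff]
  rownames(out) <- rownames(x)
  out
}
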