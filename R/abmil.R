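#' Initialize attention-MIL model parameters
#'
#' The model scores each instance feature vector h_k through a tanh
#' projection and a learned attention vector, turns the scores into softmax
#' attention weights, pools the instances into one bag feature by the
#' attention-weighted sum, and classifies the bag with a small MLP into
#' negative/positive probabilities:
#' \deqn{a_k = \mathrm{softmax}_k\!\left(w^\top \tanh(V h_k + b_V) + b_w\right),
#'       \quad z = \sum_k a_k h_k, \quad p = \mathrm{softmax}(W_2\,
#'       \mathrm{relu}(W_1 z + b_1) + b_2).}
#'
#' @param d instance feature dimension.
#' @param attn_dim dimension of the attention projection (default 128).
#' @param hidden hidden width of the bag-level MLP (default 128).
#' @param seed seed for Glorot-normal initialization.
#' @return an object of class `abmil_params` with elements `V` (attn_dim x
#'   d), `b_v`, `w` (attn_dim), `b_w`, `W1` (hidden x d), `b1`, `W2`
#'   (2 x hidden), `b2`.
#' @export
init_abmil <- function(d, attn_dim = 128L, hidden = 128L, seed = 1L) {
  set.seed(seed)
  glorot <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  structure(list(
    V = glorot(attn_dim, d), b_v = rep(0, attn_dim),
    w = as.vector(glorot(attn_dim, 1L)), b_w = 0,
    W1 = glorot(hidden, d), b1 = rep(0, hidden),
    W2 = glorot(2L, hidden), b2 = rep(0, 2L),
    d = as.integer(d), attn_dim = as.integer(attn_dim),
    hidden = as.integer(hidden)
  ), class = "abmil_params")
}

PARAM_NAMES <- c("V", "b_v", "w", "b_w", "W1", "b1", "W2", "b2")

#' Flatten model parameters to a numeric vector (and back)
#'
#' Used by the optimizer state and by finite-difference gradient checks.
#'
#' @param params an `abmil_params`.
#' @return `param_vector`: numeric vector of all parameters.
#' @export
param_vector <- function(params) {
  unlist(lapply(PARAM_NAMES, function(nm) as.vector(params[[nm]])),
         use.names = FALSE)
}

#' @rdname param_vector
#' @param v numeric vector as produced by [param_vector()].
#' @return `set_param_vector`: the `abmil_params` with values from `v`.
#' @export
set_param_vector <- function(params, v) {
  pos <- 0L
  for (nm in PARAM_NAMES) {
    n <- length(params[[nm]])
    chunk <- v[pos + seq_len(n)]
    params[[nm]] <- if (is.matrix(params[[nm]])) {
      matrix(chunk, nrow(params[[nm]]), ncol(params[[nm]]))
    } else if (n == 1L) chunk else as.vector(chunk)
    pos <- pos + n
  }
  params
}

#' Softmax attention weights over the instances of a bag
#'
#' `a = softmax( w' tanh(V h_k + b_v) + b_w )`, one weight per instance.
#' Nonnegative, summing to one, and invariant to adding a constant to all
#' pre-softmax scores.
#'
#' @param H n x d instance-feature matrix (one row per instance).
#' @param V attn_dim x d projection matrix.
#' @param w length-attn_dim scoring vector.
#' @param b_v optional projection bias (default zeros).
#' @param b_w optional scalar score bias (default 0; has no effect on `a`).
#' @return length-n attention vector on the simplex.
#' @export
attention_weights <- function(H, V, w, b_v = NULL, b_w = 0) {
  if (!is.matrix(H) || nrow(H) == 0L) stop("H must be a non-empty matrix")
  if (is.null(b_v)) b_v <- rep(0, nrow(V))
  Tm <- tanh(H %*% t(V) + matrix(b_v, nrow(H), length(b_v), byrow = TRUE))
  softmax(as.vector(Tm %*% w) + b_w)
}

#' Attention-pool instance features into a bag feature
#'
#' `z = sum_k a_k h_k`: the element-wise product of the feature matrix with
#' the attention weights, summed over instances — a convex combination of
#' the rows of `H`.
#'
#' @param H n x d instance-feature matrix.
#' @param a length-n attention weights.
#' @return length-d bag feature vector.
#' @export
attention_pool <- function(H, a) {
  if (length(a) != nrow(H)) {
    stop(sprintf("shape mismatch: %d attention weights for %d instances",
                 length(a), nrow(H)))
  }
  as.vector(crossprod(H, a))
}

#' Classify a bag feature with the bag-level MLP
#'
#' One ReLU hidden layer followed by a two-class softmax.
#'
#' @param z length-d bag feature.
#' @param classifier list with `W1`, `b1`, `W2`, `b2` (e.g. an
#'   `abmil_params`).
#' @return length-2 probability vector `(negative, positive)`.
#' @export
classify_bag <- function(z, classifier) {
  u <- pmax(as.vector(classifier$W1 %*% z) + classifier$b1, 0)
  softmax(as.vector(classifier$W2 %*% u) + classifier$b2)
}

#' Cross-entropy loss of a bag prediction
#'
#' `-log p[label]`, with the probability clamped at 1e-12 inside the
#' logarithm for numerical safety.
#'
#' @param p length-2 probability pair `(negative, positive)`.
#' @param label 0 (negative) or 1 (positive).
#' @return nonnegative scalar; 0 iff the true class has probability 1.
#' @export
bag_loss <- function(p, label) {
  stopifnot(label %in% c(0L, 1L))
  -log(max(p[label + 1L], 1e-12))
}

#' Full forward pass of the attention-MIL model on one bag
#'
#' Composition attend -> pool -> classify (-> loss when a label is given).
#' The bag function is permutation invariant: reordering instances permutes
#' the attention weights identically and leaves `z` and `p` unchanged.
#' Evaluation mode is deterministic.
#'
#' @param H n x d instance-feature matrix (already encoded).
#' @param params an `abmil_params`.
#' @param label optional 0/1 bag label; when given, the cross-entropy loss
#'   is included.
#' @param mode `"eval"` or `"train"` (augmentation, when used, happens
#'   upstream of encoding; the forward computation is identical).
#' @return list with `a` (attention weights), `z` (bag feature), `p`
#'   (class probabilities), `loss` (or `NULL`).
#' @export
forward_bag <- function(H, params, label = NULL, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (!is.matrix(H) || nrow(H) == 0L) stop("empty bag: cannot run forward pass")
  a <- attention_weights(H, params$V, params$w, params$b_v, params$b_w)
  z <- attention_pool(H, a)
  p <- classify_bag(z, params)
  list(a = a, z = z, p = p,
       loss = if (!is.null(label)) bag_loss(p, label) else NULL)
}

#' Analytic gradients of the bag loss
#'
#' Backpropagates the cross-entropy loss of one bag through the classifier
#' MLP, the attention pooling, and the softmax/tanh attention scores.
#' Matches finite-difference gradients (checked in the test suite).
#'
#' @param H n x d instance-feature matrix.
#' @param params an `abmil_params`.
#' @param label 0/1 bag label.
#' @return list with `loss`, `p`, and `grads` (same shapes as the
#'   parameters).
#' @export
backward_bag <- function(H, params, label) {
  n <- nrow(H)
  Tm <- tanh(H %*% t(params$V) +
               matrix(params$b_v, n, params$attn_dim, byrow = TRUE))
  s <- as.vector(Tm %*% params$w) + params$b_w
  a <- softmax(s)
  z <- as.vector(crossprod(H, a))
  pre1 <- as.vector(params$W1 %*% z) + params$b1
  u <- pmax(pre1, 0)
  logits <- as.vector(params$W2 %*% u) + params$b2
  p <- softmax(logits)
  loss <- -log(max(p[label + 1L], 1e-12))

  dlogits <- p
  dlogits[label + 1L] <- dlogits[label + 1L] - 1
  dW2 <- dlogits %o% u
  db2 <- dlogits
  du <- as.vector(crossprod(params$W2, dlogits))
  dpre1 <- du * (pre1 > 0)
  dW1 <- dpre1 %o% z
  db1 <- dpre1
  dz <- as.vector(crossprod(params$W1, dpre1))
  da <- as.vector(H %*% dz)
  ds <- a * (da - sum(a * da))
  dw <- as.vector(crossprod(Tm, ds))
  db_w <- sum(ds)
  dTm <- (ds %o% params$w) * (1 - Tm^2)
  dV <- crossprod(dTm, H)
  db_v <- colSums(dTm)

  list(loss = loss, p = p,
       grads = list(V = dV, b_v = db_v, w = dw, b_w = db_w,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}
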