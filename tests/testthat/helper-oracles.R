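# Independent oracles: deliberately naive, element-by-element recomputations
# kept separate from the package's vectorized implementations.

# straight-line forward pass with explicit loops
oracle_forward <- function(H, params, label = NULL) {
  n <- nrow(H)
  scores <- numeric(n)
  for (k in seq_len(n)) {
    hk <- H[k, ]
    proj <- numeric(params$attn_dim)
    for (j in seq_len(params$attn_dim)) {
      proj[j] <- tanh(sum(params$V[j, ] * hk) + params$b_v[j])
    }
    scores[k] <- sum(params$w * proj) + params$b_w
  }
  e <- exp(scores - max(scores))
  a <- e / sum(e)
  z <- numeric(ncol(H))
  for (k in seq_len(n)) z <- z + a[k] * H[k, ]
  u <- numeric(params$hidden)
  for (j in seq_len(params$hidden)) {
    u[j] <- max(sum(params$W1[j, ] * z) + params$b1[j], 0)
  }
  logits <- c(sum(params$W2[1, ] * u) + params$b2[1],
              sum(params$W2[2, ] * u) + params$b2[2])
  el <- exp(logits - max(logits))
  p <- el / sum(el)
  list(a = a, z = z, p = p,
       loss = if (is.null(label)) NULL else -log(max(p[label + 1], 1e-12)))
}

# AUC by exhaustive pair enumeration with 0.5 for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) {
    for (sn in neg) {
      tot <- tot + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# histogram entropy via table() on quantized luminance
oracle_entropy <- function(px) {
  lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  lev <- pmin(floor(lum), 255)
  p <- as.numeric(table(lev)) / length(lev)
  -sum(p * log2(p))
}

# two-pass per-channel mean / population variance over a tile list
oracle_mean_var <- function(tiles) {
  out <- list(mean = numeric(3), var = numeric(3))
  for (c in 1:3) {
    vals <- c()
    for (t in tiles) vals <- c(vals, as.vector(t$pixels[, , c]))
    m <- sum(vals) / length(vals)
    out$mean[c] <- m
    out$var[c] <- sum((vals - m)^2) / length(vals)
  }
  out
}

random_tile <- function(seed, magnification = "20x", size = 224L) {
  set.seed(seed)
  list(pixels = array(runif(size * size * 3, 0, 255), c(size, size, 3L)),
       grid_x = 0L, grid_y = 0L, magnification = magnification,
       entropy_bits = NA_real_)
}

random_params <- function(d, attn_dim = 8L, hidden = 6L, seed = 1L) {
  p <- init_abmil(d, attn_dim = attn_dim, hidden = hidden, seed = seed)
  set.seed(seed + 1L)
  v <- param_vector(p)
  set_param_vector(p, rnorm(length(v), sd = 0.5))
}

# a params object whose classifier outputs a fixed positive probability,
# ignoring the input bag
fixed_prob_params <- function(p_pos, d = 2L) {
  pr <- init_abmil(d, attn_dim = 4L, hidden = 3L, seed = 1L)
  pr$W1[] <- 0; pr$b1[] <- 0; pr$W2[] <- 0
  pr$b2 <- c(0, stats::qlogis(p_pos))
  pr
}
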