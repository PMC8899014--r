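# Brute-force double-loop reference implementation of the attention block,
# kept deliberately naive (per-position loops, explicit softmax) and fully
# independent of the package's vectorised code paths.

oracle_attention <- function(i, V, Wp, sc) {
  k <- nrow(V)
  scores <- numeric(k)
  for (t in seq_len(k)) {
    scores[t] <- sum(V[i, ] * (Wp %*% V[t, ])) * sc
  }
  e <- exp(scores - max(scores))
  e / sum(e)
}

oracle_layer <- function(V, W, Wp, sc) {
  out <- matrix(0, nrow(V), ncol(V))
  for (i in seq_len(nrow(V))) {
    a <- oracle_attention(i, V, Wp, sc)
    pooled <- numeric(ncol(V))
    for (t in seq_len(nrow(V))) pooled <- pooled + a[t] * V[t, ]
    out[i, ] <- tanh(as.numeric(W %*% pooled))
  }
  out
}

oracle_encode <- function(ids, params, config) {
  sc <- if (config$scale == "rsqrt_d") 1 / sqrt(config$dim) else 1
  rows <- c(config$vocab_size + 1L, ids)
  X <- params$tok[rows, , drop = FALSE] +
    params$pos[seq_along(rows), , drop = FALSE]
  for (l in seq_len(config$layers)) {
    X <- oracle_layer(X, params$W[[l]], params$Wp[[l]], sc)
  }
  X
}

brute_pair_auc <- function(s, y) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
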