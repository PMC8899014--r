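# The simplified attention-based encoder.  One attention head per layer; the
# upper vector at position i is tanh(W %*% sum_t alpha_t v_t) with
# alpha = softmax over scaled bilinear scores (v_i . W' . v_t) / sqrt(D).
# There is no value projection, no residual, no layer norm and no
# feed-forward sublayer on the reference path: the block is implemented
# literally as formulated.  A "standard" block mode (residual + layer norm
# around the same attention) is available for robustness studies.
#
# Classification reads the position-0 vector on the top layer (the CLS
# vector) through a 2-row linear map followed by softmax/argmax.

#' Configure the attention encoder
#'
#' @param layers Number of stacked layers, >= 0 (0 = the embedded inputs are
#'   returned unchanged).
#' @param dim Embedding / model dimension D.
#' @param window Maximum number of input positions including the reserved
#'   CLS position (so a window of 512 accepts up to 511 content tokens).
#'   512 is the clinical preset; tests use far smaller windows.
#' @param vocab_size Number of content token types; one extra embedding row
#'   is reserved for the CLS token.
#' @param scale Attention score scaling: `"rsqrt_d"` (divide by sqrt(D),
#'   default) or `"none"`.
#' @param block `"paper"` (the literal tanh-attention block, default) or
#'   `"standard"` (adds a residual connection and layer normalisation).
#' @return A list of class `"encoder_config"`.
#' @export
encoder_config <- function(layers = 2L, dim = 32L, window = 64L, vocab_size,
                           scale = c("rsqrt_d", "none"),
                           block = c("paper", "standard")) {
  scale <- match.arg(scale)
  block <- match.arg(block)
  if (window < 2L) stop("window must be >= 2 (CLS plus at least one token)")
  if (layers < 0L) stop("layers must be >= 0")
  structure(list(layers = as.integer(layers), dim = as.integer(dim),
                 window = as.integer(window),
                 vocab_size = as.integer(vocab_size),
                 scale = scale, block = block),
            class = "encoder_config")
}

cls_id <- function(config) config$vocab_size + 1L

#' Initialise encoder parameters
#'
#' Token embeddings (including the reserved CLS row), learned positional
#' embeddings, per-layer attention matrices `W'` and transform matrices `W`,
#' and the 2-row CLS classifier `W1`, all drawn small-normal under the seed.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed.
#' @param init_sd Standard deviation of the initial weights.
#' @return Named list of parameter arrays (`tok`, `pos`, `W`, `Wp`, `W1`).
#' @export
encoder_init <- function(config, seed = 1L, init_sd = 0.1) {
  with_local_seed(seed, {
    D <- config$dim
    list(tok = rand_mat(config$vocab_size + 1L, D, init_sd),
         pos = rand_mat(config$window, D, init_sd),
         W = replicate(config$layers, rand_mat(D, D, init_sd),
                       simplify = FALSE),
         Wp = replicate(config$layers, rand_mat(D, D, init_sd),
                        simplify = FALSE),
         W1 = rand_mat(2L, D, init_sd))
  })
}

#' Embed a token segment with positional information
#'
#' Prepends the reserved CLS id and adds the learned positional embedding of
#' each position to its token embedding.  After this step the layers treat
#' positions uniformly; order information enters only here.
#'
#' @param token_ids Integer ids in `1:vocab_size`; at most `window - 1` of
#'   them.
#' @param params From [encoder_init()].
#' @param config The matching [encoder_config()].
#' @return `(length(token_ids) + 1) x dim` matrix, row 1 = CLS position.
#' @export
embed_input <- function(token_ids, params, config) {
  if (length(token_ids) > config$window - 1L) {
    stop("segment exceeds window: ", length(token_ids), " content tokens, ",
         "window ", config$window, " (including CLS)")
  }
  rows <- c(cls_id(config), as.integer(token_ids))
  params$tok[rows, , drop = FALSE] +
    params$pos[seq_along(rows), , drop = FALSE]
}

attn_scale <- function(config) {
  if (config$scale == "rsqrt_d") 1 / sqrt(config$dim) else 1
}

#' Attention weights of one query position
#'
#' `alpha_t = softmax_t((v_i . W' . v_t) / sqrt(D))` over all positions `t`
#' of the lower layer.  The weights are strictly positive and sum to 1.
#'
#' @param i Query position (row of `V`).
#' @param V `k x D` matrix of lower-layer vectors.
#' @param Wp The layer's bilinear attention matrix `W'`.
#' @param config The [encoder_config()] (controls scaling).
#' @return Numeric weight vector of length `k`.
#' @export
attention_weights <- function(i, V, Wp, config) {
  stopifnot(nrow(V) >= 1L)
  scores <- as.numeric(V[i, , drop = FALSE] %*% Wp %*% t(V)) *
    attn_scale(config)
  softmax_vec(scores)
}

#' Apply one encoder layer
#'
#' Every upper-layer vector is `tanh(W %*% sum_t alpha_t v_t)` where the
#' attention weights are computed against the full lower sequence; outputs
#' are elementwise in (-1, 1).
#'
#' @param V `k x D` lower-layer vectors.
#' @param W,Wp The layer's transform and attention matrices.
#' @param config The [encoder_config()].
#' @return `k x D` matrix of upper-layer vectors.
#' @export
encoder_layer <- function(V, W, Wp, config) {
  layer_forward(V, W, Wp, config)$Y
}

# Forward pass of one layer with everything the backward pass needs.
layer_forward <- function(V, W, Wp, config) {
  sc <- attn_scale(config)
  S <- (V %*% Wp %*% t(V)) * sc
  A <- softmax_rows(S)
  M <- A %*% V
  Tn <- tanh(M %*% t(W))
  if (config$block == "standard") {
    H <- V + Tn
    ln <- ln_forward(H)
    list(Y = ln$Y, A = A, M = M, Tn = Tn, H = H, ln = ln)
  } else {
    list(Y = Tn, A = A, M = M, Tn = Tn)
  }
}

# Row-wise layer normalisation (no affine parameters).
ln_forward <- function(H, eps = 1e-6) {
  mu <- rowMeans(H)
  Hc <- H - mu
  v <- rowMeans(Hc^2)
  inv <- 1 / sqrt(v + eps)
  list(Y = Hc * inv, Hc = Hc, inv = inv)
}

ln_backward <- function(dY, ln) {
  D <- ncol(dY)
  Xhat <- ln$Hc * ln$inv
  (dY - rowMeans(dY) - Xhat * rowMeans(dY * Xhat)) * ln$inv
}

# Backward through one layer.  Returns dV and parameter gradients.
layer_backward <- function(dY, V, W, Wp, config, cache) {
  sc <- attn_scale(config)
  if (config$block == "standard") {
    dH <- ln_backward(dY, cache$ln)
    dTn <- dH
    dV <- dH
  } else {
    dTn <- dY
    dV <- matrix(0, nrow(V), ncol(V))
  }
  dZ <- dTn * (1 - cache$Tn^2)
  dW <- crossprod(dZ, cache$M)          # Z = M W^T
  dM <- dZ %*% W
  dA <- dM %*% t(V)
  dV <- dV + crossprod(cache$A, dM)
  dS <- cache$A * (dA - rowSums(dA * cache$A))
  dV <- dV + sc * (dS %*% V %*% t(Wp) + crossprod(dS, V %*% Wp))
  dWp <- sc * (t(V) %*% dS %*% V)
  list(dV = dV, dW = dW, dWp = dWp)
}

# Full forward pass with caches, used by training.
encoder_forward <- function(token_ids, params, config) {
  X <- embed_input(token_ids, params, config)
  caches <- vector("list", config$layers)
  Xs <- vector("list", config$layers + 1L)
  Xs[[1L]] <- X
  for (l in seq_len(config$layers)) {
    caches[[l]] <- layer_forward(Xs[[l]], params$W[[l]], params$Wp[[l]],
                                 config)
    Xs[[l + 1L]] <- caches[[l]]$Y
  }
  list(Xs = Xs, caches = caches, rows = c(cls_id(config),
                                          as.integer(token_ids)))
}

# Backward from a gradient on the top-layer vectors down to all parameters.
# Returns gradients in the same shape as the parameter list; token-embedding
# gradients are accumulated densely.
encoder_backward <- function(dTop, fwd, params, config) {
  L <- config$layers
  dW <- vector("list", L)
  dWp <- vector("list", L)
  dX <- dTop
  for (l in rev(seq_len(L))) {
    bk <- layer_backward(dX, fwd$Xs[[l]], params$W[[l]], params$Wp[[l]],
                         config, fwd$caches[[l]])
    dW[[l]] <- bk$dW
    dWp[[l]] <- bk$dWp
    dX <- bk$dV
  }
  dtok <- matrix(0, nrow(params$tok), ncol(params$tok))
  agg <- rowsum(dX, group = fwd$rows)
  dtok[as.integer(rownames(agg)), ] <- agg
  dpos <- matrix(0, nrow(params$pos), ncol(params$pos))
  dpos[seq_len(nrow(dX)), ] <- dX
  list(tok = dtok, pos = dpos, W = dW, Wp = dWp)
}

#' Encode one token segment
#'
#' Runs the embedded input through all encoder layers.
#'
#' @inheritParams embed_input
#' @return A list of class `"segment_encoding"` with `top_vectors` (one row
#'   per position, row 1 = CLS) and `cls` (the position-0 top vector).
#' @export
encode_segment <- function(token_ids, params, config) {
  fwd <- encoder_forward(token_ids, params, config)
  top <- fwd$Xs[[config$layers + 1L]]
  structure(list(top_vectors = top, cls = top[1L, ]),
            class = "segment_encoding")
}

#' Classify from a CLS vector
#'
#' `c = argmax(W1 %*% cls)` with softmax scores; exact ties resolve to
#' label 0.
#'
#' @param cls Top-layer CLS vector.
#' @param W1 `2 x D` classifier matrix.
#' @return List with `label` (0/1), `prob` (probability of label 1) and
#'   `probs` (both class probabilities).
#' @export
classify_cls <- function(cls, W1) {
  logits <- as.numeric(W1 %*% cls)
  p <- softmax_vec(logits)
  label <- if (logits[2L] > logits[1L]) 1L else 0L
  list(label = label, prob = p[2L], probs = p)
}
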