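# Internal dense-network plumbing shared by all trainable models: parameter
# initialisation, Adam updates over named lists of arrays, softmax helpers and
# local RNG scoping.  All models in this package are small enough that plain
# BLAS-backed matrix algebra is the right tool.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Small-normal initialisation, the convention for all trainable tensors here.
rand_mat <- function(nrow, ncol, sd = 0.1) {
  matrix(stats::rnorm(nrow * ncol, sd = sd), nrow = nrow, ncol = ncol)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Row-wise softmax of a matrix.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Binary cross-entropy against a 2-way softmax; returns loss and dlogits.
softmax_xent <- function(logits, y) {
  p <- softmax_vec(logits)
  d <- p
  d[y + 1L] <- d[y + 1L] - 1
  list(loss = -log(max(p[y + 1L], 1e-12)), dlogits = d, p1 = p[2L])
}

# Adam over an arbitrary named list of numeric arrays (nested lists allowed
# one level deep, as used for per-layer encoder weights).
adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else array(0, dim = dim(p) %||% length(p))
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, skip = character()) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (nm in names(params)) {
    if (nm %in% skip || is.null(grads[[nm]])) next
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$p
    state$m[[nm]] <- r$m
    state$v[[nm]] <- r$v
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Inverted-dropout mask applied during training only.
dropout_mask <- function(n, rate) {
  if (rate <= 0) return(rep(1, n))
  (stats::runif(n) >= rate) / (1 - rate)
}
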