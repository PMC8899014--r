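# Baseline classifiers: bag-of-words with logistic regression, and the
# convolutional / recurrent (GRU) neural text classifiers.  The neural
# baselines share the package's single-example Adam training loop.

#' Bag-of-words feature vector
#'
#' Pure counting over the vocabulary's unigram block; word positions are
#' ignored and out-of-vocabulary tokens contribute nothing.
#'
#' @param tokens Character token vector (or a [document()] with tokens set).
#' @param vocab A [build_vocabulary()] result.
#' @return Integer count vector of length `vocab$n_unigrams`.
#' @export
bow_featurize <- function(tokens, vocab) {
  if (inherits(tokens, "document")) tokens <- tokens$tokens
  counts <- integer(vocab$n_unigrams)
  ids <- token_ids(tokens, vocab)
  if (length(ids)) {
    tab <- tabulate(ids, nbins = vocab$n_unigrams)
    counts <- as.integer(tab)
  }
  counts
}

#' Bag-of-words design matrix for a document data frame
#'
#' @param data Data frame with a `tokens` list-column.
#' @param vocab A [build_vocabulary()] result.
#' @return `nrow(data) x n_unigrams` count matrix.
#' @export
bow_matrix <- function(data, vocab) {
  t(vapply(data$tokens, bow_featurize, integer(vocab$n_unigrams),
           vocab = vocab))
}

#' Train a linear classifier on count features
#'
#' Logistic regression with an L2 penalty on the weights, fitted by BFGS on
#' the exact penalized objective.  The alternative `loss = "squared"` mode
#' minimises the squared error between the predicted probability and the
#' 0/1 label (the literal reading of "L2 loss"), with the same penalty.
#'
#' @param X Numeric feature matrix (rows = examples).
#' @param y Binary labels; both classes required.
#' @param l2 Ridge penalty strength (applied as `l2/2 * ||w||^2`, bias
#'   unpenalised).
#' @param loss `"logistic"` (cross-entropy, default) or `"squared"`.
#' @param maxit BFGS iteration cap.
#' @return A list of class `"linear_model"` with `weights`, `bias`, `l2`,
#'   `loss`.
#' @export
train_logistic <- function(X, y, l2 = 1e-3, loss = c("logistic", "squared"),
                           maxit = 500L) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("degenerate training set: one class only")
  n <- nrow(X)
  d <- ncol(X)
  obj <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1L]
    p <- sigmoid(as.numeric(X %*% w) + b)
    if (loss == "logistic") {
      -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12))) +
        l2 / 2 * sum(w^2)
    } else {
      mean((p - y)^2) + l2 / 2 * sum(w^2)
    }
  }
  grad <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1L]
    p <- sigmoid(as.numeric(X %*% w) + b)
    r <- if (loss == "logistic") (p - y) / n else 2 * (p - y) * p * (1 - p) / n
    c(as.numeric(crossprod(X, r)) + l2 * w, sum(r))
  }
  fit <- stats::optim(numeric(d + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  structure(list(weights = fit$par[seq_len(d)], bias = fit$par[d + 1L],
                 l2 = l2, loss = loss, value = fit$value),
            class = "linear_model")
}

#' Score examples with a linear model
#'
#' @param model A [train_logistic()] result.
#' @param X Feature matrix.
#' @return Sigmoid scores in (0,1).
#' @export
predict_linear <- function(model, X) {
  sigmoid(as.numeric(as.matrix(X) %*% model$weights) + model$bias)
}

#' Bag-of-words model specification for [train_model()]
#'
#' The convex fit does not need epoch snapshots: the model is fitted once on
#' the (balanced) training partition during the first epoch and reused.
#'
#' @param vocab A [build_vocabulary()] result.
#' @param l2 Ridge penalty.
#' @param loss Passed to [train_logistic()].
#' @return A model spec.
#' @export
bow_spec <- function(vocab, l2 = 1e-3, loss = "logistic") {
  list(
    init = function(seed) list(model = NULL),
    epoch = function(state, train, lr, epoch) {
      if (is.null(state$model)) {
        state$model <- train_logistic(bow_matrix(train, vocab), train$label,
                                      l2 = l2, loss = loss)
      }
      state
    },
    score = function(state, data) {
      predict_linear(state$model, bow_matrix(data, vocab))
    }
  )
}

# ---- convolutional classifier ----------------------------------------------

cnn_init <- function(vocab_n, embed_dim, widths, maps, seed) {
  with_local_seed(seed, {
    list(table = rand_mat(vocab_n, embed_dim),
         conv = lapply(widths, function(k) rand_mat(k * embed_dim, maps)),
         conv_b = lapply(widths, function(k) numeric(maps)),
         out = rand_mat(2L, length(widths) * maps), out_b = numeric(2L))
  })
}

# Forward pass for one document; returns logits and the caches backward needs.
cnn_forward <- function(ids, params, widths, maps) {
  D <- ncol(params$table)
  Tn <- length(ids)
  E <- if (Tn > 0L) params$table[ids, , drop = FALSE] else
    matrix(0, 0L, D)
  feats <- numeric(0)
  caches <- vector("list", length(widths))
  for (wi in seq_along(widths)) {
    k <- widths[wi]
    if (Tn >= k) {
      nk <- Tn - k + 1L
      Xk <- do.call(cbind, lapply(seq_len(k) - 1L, function(off) {
        E[seq_len(nk) + off, , drop = FALSE]
      }))
    } else {
      # short document: single zero-padded window over the real tokens
      nk <- 1L
      pad <- rbind(E, matrix(0, k - Tn, D))
      Xk <- matrix(as.numeric(t(pad)), 1L)
    }
    C <- Xk %*% params$conv[[wi]] +
      matrix(params$conv_b[[wi]], nk, maps, byrow = TRUE)
    R <- pmax(C, 0)
    am <- max.col(t(R), ties.method = "first")
    h <- R[cbind(am, seq_len(maps))]
    feats <- c(feats, h)
    caches[[wi]] <- list(Xk = Xk, C = C, am = am, nk = nk)
  }
  logits <- as.numeric(params$out %*% feats) + params$out_b
  list(logits = logits, feats = feats, caches = caches, E_rows = ids)
}

cnn_backward <- function(fwd, dlogits, dfeats, params, widths, maps) {
  D <- ncol(params$table)
  g <- list(out = dlogits %o% fwd$feats, out_b = dlogits,
            conv = vector("list", length(widths)),
            conv_b = vector("list", length(widths)))
  dE <- NULL
  Tn <- length(fwd$E_rows)
  dEacc <- matrix(0, max(Tn, 1L), D)
  for (wi in seq_along(widths)) {
    k <- widths[wi]
    cache <- fwd$caches[[wi]]
    dh <- dfeats[(wi - 1L) * maps + seq_len(maps)]
    dC <- matrix(0, cache$nk, maps)
    sel <- cbind(cache$am, seq_len(maps))
    act <- cache$C[sel] > 0
    dC[sel] <- dh * act
    g$conv[[wi]] <- crossprod(cache$Xk, dC)
    g$conv_b[[wi]] <- colSums(dC)
    dXk <- dC %*% t(params$conv[[wi]])
    if (Tn >= k) {
      for (off in seq_len(k) - 1L) {
        dEacc[seq_len(cache$nk) + off, ] <-
          dEacc[seq_len(cache$nk) + off, ] +
          dXk[, off * D + seq_len(D), drop = FALSE]
      }
    } else if (Tn > 0L) {
      dpad <- matrix(as.numeric(dXk), k, D, byrow = TRUE)
      dEacc[seq_len(Tn), ] <- dEacc[seq_len(Tn), ] +
        dpad[seq_len(Tn), , drop = FALSE]
    }
  }
  if (Tn > 0L) {
    dtab <- matrix(0, nrow(params$table), D)
    agg <- rowsum(dEacc[seq_len(Tn), , drop = FALSE], group = fwd$E_rows)
    dtab[as.integer(rownames(agg)), ] <- agg
    g$table <- dtab
  }
  g
}

#' Convolutional text classifier
#'
#' Embeddings, parallel convolutions of several widths, ReLU, max-over-time
#' pooling restricted to real token positions (so trailing padding can never
#' influence the output), dropout on the pooled feature vector, and a linear
#' 2-way softmax.
#'
#' @param vocab A [build_vocabulary()] result (unigram block is used).
#' @param embed_dim Embedding dimension.
#' @param widths Convolution filter widths (default `c(3, 4, 5)`).
#' @param maps Feature maps per width (default 100).
#' @param dropout Dropout rate on the pooled features.
#' @return A model spec for [train_model()].
#' @export
cnn_spec <- function(vocab, embed_dim = 50L, widths = c(3L, 4L, 5L),
                     maps = 100L, dropout = 0.1) {
  ids_of <- function(data) lapply(data$tokens, token_ids, vocab = vocab)
  nfeat <- length(widths) * maps
  list(
    init = function(seed) {
      params <- cnn_init(max(vocab$n_unigrams, 1L), embed_dim, widths, maps,
                         seed)
      list(params = params, opt = adam_init(params), seed = seed,
           epoch_losses = numeric(0))
    },
    epoch = function(state, train, lr, epoch) {
      ids <- ids_of(train)
      y <- train$label
      total <- 0
      with_local_seed(state$seed * 10000L + epoch, {
        for (i in sample(length(ids))) {
          fwd <- cnn_forward(ids[[i]], state$params, widths, maps)
          mask <- dropout_mask(nfeat, dropout)
          fd <- fwd$feats * mask
          xe <- softmax_xent(as.numeric(state$params$out %*% fd) +
                               state$params$out_b, y[i])
          total <- total + xe$loss
          dfeats <- as.numeric(t(state$params$out) %*% xe$dlogits) * mask
          fwd$feats <- fd
          g <- cnn_backward(fwd, xe$dlogits, dfeats, state$params, widths,
                            maps)
          st <- adam_step(state$params, g, state$opt, lr = lr)
          state$params <- st$params
          state$opt <- st$state
        }
      })
      state$epoch_losses <- c(state$epoch_losses, total / length(ids))
      state
    },
    score = function(state, data) {
      vapply(ids_of(data), function(id) {
        softmax_vec(cnn_forward(id, state$params, widths, maps)$logits)[2L]
      }, 0)
    }
  )
}

#' @rdname cnn_spec
#' @param train Training data frame (`tokens` list-column + `label`).
#' @param epochs,lr,seed Training-loop settings.
#' @return `conv_text_classifier()` / `recurrent_text_classifier()` return a
#'   fitted scorer: a list with `score(tokens)` mapping a token vector to a
#'   probability in (0,1), plus the spec, state and per-epoch training
#'   losses.
#' @export
conv_text_classifier <- function(train, vocab, embed_dim = 50L,
                                 widths = c(3L, 4L, 5L), maps = 100L,
                                 dropout = 0.1, epochs = 5L, lr = 1e-2,
                                 seed = 1L) {
  spec <- cnn_spec(vocab, embed_dim, widths, maps, dropout)
  fit_scorer(spec, train, vocab, epochs, lr, seed)
}

# ---- recurrent (GRU) classifier --------------------------------------------

gru_init <- function(vocab_n, embed_dim, hidden, seed) {
  with_local_seed(seed, {
    list(table = rand_mat(vocab_n, embed_dim),
         Wg = rand_mat(3L * hidden, embed_dim),   # rows: update, reset, cand
         Ug = rand_mat(3L * hidden, hidden),
         bg = numeric(3L * hidden),
         out = rand_mat(2L, hidden), out_b = numeric(2L))
  })
}

gru_forward <- function(ids, params, hidden) {
  Tn <- length(ids)
  h <- numeric(hidden)
  iz <- seq_len(hidden); ir <- hidden + iz; ic <- 2L * hidden + iz
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- params$table[ids[t], ]
    gx <- as.numeric(params$Wg %*% x) + params$bg
    gh <- as.numeric(params$Ug %*% h)
    z <- sigmoid(gx[iz] + gh[iz])
    r <- sigmoid(gx[ir] + gh[ir])
    hc <- tanh(gx[ic] + as.numeric(params$Ug[ic, ] %*% (r * h)))
    hn <- (1 - z) * h + z * hc
    steps[[t]] <- list(x = x, hprev = h, z = z, r = r, hc = hc)
    h <- hn
  }
  logits <- as.numeric(params$out %*% h) + params$out_b
  list(logits = logits, h = h, steps = steps)
}

# `fwd$h` must be the (possibly dropout-masked) vector the classifier saw;
# `dh0` is the gradient entering the recurrent stack (mask already applied).
gru_backward <- function(fwd, dlogits, dh0, ids, params, hidden) {
  Tn <- length(ids)
  iz <- seq_len(hidden); ir <- hidden + iz; ic <- 2L * hidden + iz
  g <- list(Wg = matrix(0, 3L * hidden, ncol(params$table)),
            Ug = matrix(0, 3L * hidden, hidden),
            bg = numeric(3L * hidden),
            out = dlogits %o% fwd$h, out_b = dlogits)
  dh <- dh0
  dE <- matrix(0, max(Tn, 1L), ncol(params$table))
  for (t in rev(seq_len(Tn))) {
    s <- fwd$steps[[t]]
    dz <- dh * (s$hc - s$hprev) * s$z * (1 - s$z)
    dhc <- dh * s$z * (1 - s$hc^2)
    dh_prev <- dh * (1 - s$z)
    drh <- as.numeric(t(params$Ug[ic, , drop = FALSE]) %*% dhc)
    dr <- drh * s$hprev * s$r * (1 - s$r)
    dh_prev <- dh_prev + drh * s$r
    dgates <- c(dz, dr, dhc)
    g$bg <- g$bg + dgates
    g$Wg <- g$Wg + dgates %o% s$x
    g$Ug[iz, ] <- g$Ug[iz, ] + dz %o% s$hprev
    g$Ug[ir, ] <- g$Ug[ir, ] + dr %o% s$hprev
    g$Ug[ic, ] <- g$Ug[ic, ] + dhc %o% (s$r * s$hprev)
    dh_prev <- dh_prev +
      as.numeric(t(params$Ug[iz, , drop = FALSE]) %*% dz) +
      as.numeric(t(params$Ug[ir, , drop = FALSE]) %*% dr)
    dE[t, ] <- as.numeric(t(params$Wg) %*% dgates)
    dh <- dh_prev
  }
  if (Tn > 0L) {
    dtab <- matrix(0, nrow(params$table), ncol(params$table))
    agg <- rowsum(dE[seq_len(Tn), , drop = FALSE], group = ids)
    dtab[as.integer(rownames(agg)), ] <- agg
    g$table <- dtab
  }
  g
}

#' Recurrent (GRU) text classifier
#'
#' Embeddings fed through a gated recurrent unit; the final hidden state goes
#' to a linear 2-way softmax.
#'
#' @inheritParams cnn_spec
#' @param hidden GRU hidden size (default 256; tests use much smaller).
#' @return A model spec for [train_model()].
#' @export
gru_spec <- function(vocab, embed_dim = 50L, hidden = 256L, dropout = 0.1) {
  ids_of <- function(data) lapply(data$tokens, token_ids, vocab = vocab)
  list(
    init = function(seed) {
      params <- gru_init(max(vocab$n_unigrams, 1L), embed_dim, hidden, seed)
      list(params = params, opt = adam_init(params), seed = seed,
           epoch_losses = numeric(0))
    },
    epoch = function(state, train, lr, epoch) {
      ids <- ids_of(train)
      y <- train$label
      total <- 0
      with_local_seed(state$seed * 10000L + epoch, {
        for (i in sample(length(ids))) {
          if (length(ids[[i]]) == 0L) next
          fwd <- gru_forward(ids[[i]], state$params, hidden)
          mask <- dropout_mask(hidden, dropout)
          hd <- fwd$h * mask
          xe <- softmax_xent(as.numeric(state$params$out %*% hd) +
                               state$params$out_b, y[i])
          total <- total + xe$loss
          dh0 <- as.numeric(t(state$params$out) %*% xe$dlogits) * mask
          fwd$h <- hd
          g <- gru_backward(fwd, xe$dlogits, dh0, ids[[i]], state$params,
                            hidden)
          st <- adam_step(state$params, g, state$opt, lr = lr)
          state$params <- st$params
          state$opt <- st$state
        }
      })
      state$epoch_losses <- c(state$epoch_losses, total / length(ids))
      state
    },
    score = function(state, data) {
      vapply(ids_of(data), function(id) {
        if (length(id) == 0L) return(0.5)
        softmax_vec(gru_forward(id, state$params, hidden)$logits)[2L]
      }, 0)
    }
  )
}

#' @rdname gru_spec
#' @param train Training data frame.
#' @param epochs,lr,seed Training-loop settings.
#' @export
recurrent_text_classifier <- function(train, vocab, embed_dim = 50L,
                                      hidden = 256L, dropout = 0.1,
                                      epochs = 5L, lr = 1e-2, seed = 1L) {
  spec <- gru_spec(vocab, embed_dim, hidden, dropout)
  fit_scorer(spec, train, vocab, epochs, lr, seed)
}

# Shared trainer for the stand-alone scorer interfaces: fixed number of
# epochs on the given training set, no snapshot selection.
fit_scorer <- function(spec, train, vocab, epochs, lr, seed) {
  if (nrow(train) == 0L) stop("empty training set")
  state <- spec$init(seed)
  for (e in seq_len(epochs)) state <- spec$epoch(state, train, lr, e)
  structure(list(
    score = function(tokens) {
      d <- data.frame(doc_id = "x", stringsAsFactors = FALSE)
      d$tokens <- list(tokens)
      spec$score(state, d)
    },
    score_dataset = function(data) spec$score(state, data),
    state = state, spec = spec, epoch_losses = state$epoch_losses
  ), class = "text_scorer")
}
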