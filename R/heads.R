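# Segment-combination heads: seven architectures that map the per-segment
# encodings of a long document to a single document vector v_d, overcoming
# the encoder's fixed input window.  Recurrent heads consume segments in
# document order and read out the final LSTM state; concatenation heads
# produce fixed-dimension vectors via zero padding; pooling heads are
# elementwise over the CLS vectors.

HEAD_STRATEGIES <- c("lstm_cls", "lstm_top", "concat_top", "concat_cls",
                     "mean_cls", "min_cls", "max_cls")

#' Configure a segment-combination head
#'
#' @param strategy One of `"lstm_cls"` (LSTM over the per-segment CLS
#'   vectors, trained end to end), `"lstm_top"` (LSTM over *all* top-layer
#'   vectors; the encoder must be frozen), `"concat_top"` (all top-layer
#'   vectors concatenated; frozen encoder unless `relax_freeze`),
#'   `"concat_cls"` (CLS vectors concatenated, trainable encoder),
#'   `"mean_cls"`, `"min_cls"`, `"max_cls"` (elementwise pooling over CLS
#'   vectors).
#' @param max_segments Fixed segment budget S; longer documents are
#'   truncated at the tail, and concatenation heads zero-pad up to S.  The
#'   default 6 covers a ~2,000-token document at the 512 clinical window.
#' @param hidden LSTM hidden size for the recurrent strategies.
#' @param freeze_encoder If `TRUE`, encoder parameters receive no gradient
#'   updates (required by `lstm_top`, and by `concat_top` unless relaxed).
#' @param relax_freeze Allow `concat_top` with a trainable encoder.
#' @return A list of class `"head_config"`.
#' @export
head_config <- function(strategy = HEAD_STRATEGIES, max_segments = 6L,
                        hidden = 256L, freeze_encoder = FALSE,
                        relax_freeze = FALSE) {
  strategy <- match.arg(strategy)
  if (strategy == "lstm_top" && !freeze_encoder) {
    stop("lstm_top requires freeze_encoder = TRUE")
  }
  if (strategy == "concat_top" && !freeze_encoder && !relax_freeze) {
    stop("concat_top requires freeze_encoder = TRUE (or relax_freeze)")
  }
  if (max_segments < 1L) stop("max_segments must be >= 1")
  structure(list(strategy = strategy, max_segments = as.integer(max_segments),
                 hidden = as.integer(hidden),
                 freeze_encoder = isTRUE(freeze_encoder)),
            class = "head_config")
}

#' Pad or truncate a segment-encoding sequence to exactly S entries
#'
#' Right-pads with zero-vector encodings or drops trailing segments; used by
#' the fixed-dimension concatenation heads.  The number of real segments
#' consumed is recorded.
#'
#' @param encodings List of `"segment_encoding"` objects.
#' @param S Target length, >= 1.
#' @return List with `encodings` (length exactly S) and `n_real`.
#' @export
pad_or_truncate <- function(encodings, S) {
  stopifnot(S >= 1L)
  n_real <- min(length(encodings), S)
  out <- encodings[seq_len(n_real)]
  if (n_real < S && n_real > 0L) {
    D <- length(encodings[[1L]]$cls)
    zero <- structure(list(top_vectors = matrix(0, 1L, D),
                           cls = numeric(D)),
                      class = "segment_encoding")
    out <- c(out, rep(list(zero), S - n_real))
  }
  list(encodings = out, n_real = n_real)
}

# ---- LSTM cell --------------------------------------------------------------

lstm_init <- function(input, hidden, seed = NULL, sd = 0.1) {
  make <- function() list(Wx = rand_mat(4L * hidden, input, sd),
                          Wh = rand_mat(4L * hidden, hidden, sd),
                          b = numeric(4L * hidden))
  if (is.null(seed)) make() else with_local_seed(seed, make())
}

# X: T x input matrix; returns final hidden state + caches for backward.
lstm_forward <- function(X, par, hidden) {
  Tn <- nrow(X)
  ii <- seq_len(hidden); fi <- hidden + ii; gi <- 2L * hidden + ii
  oi <- 3L * hidden + ii
  h <- numeric(hidden); cc <- numeric(hidden)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    a <- as.numeric(par$Wx %*% X[t, ] + par$Wh %*% h) + par$b
    i_g <- sigmoid(a[ii]); f_g <- sigmoid(a[fi])
    g_g <- tanh(a[gi]); o_g <- sigmoid(a[oi])
    cn <- f_g * cc + i_g * g_g
    hn <- o_g * tanh(cn)
    steps[[t]] <- list(x = X[t, ], hprev = h, cprev = cc, i = i_g, f = f_g,
                       g = g_g, o = o_g, c = cn)
    h <- hn; cc <- cn
  }
  list(h = h, steps = steps)
}

lstm_backward <- function(fwd, dh, par, hidden) {
  Tn <- length(fwd$steps)
  ii <- seq_len(hidden); fi <- hidden + ii; gi <- 2L * hidden + ii
  oi <- 3L * hidden + ii
  g <- list(Wx = matrix(0, 4L * hidden, ncol(par$Wx)),
            Wh = matrix(0, 4L * hidden, hidden), b = numeric(4L * hidden))
  dX <- matrix(0, Tn, ncol(par$Wx))
  dc <- numeric(hidden)
  for (t in rev(seq_len(Tn))) {
    s <- fwd$steps[[t]]
    tc <- tanh(s$c)
    do <- dh * tc * s$o * (1 - s$o)
    dc <- dc + dh * s$o * (1 - tc^2)
    di <- dc * s$g * s$i * (1 - s$i)
    df <- dc * s$cprev * s$f * (1 - s$f)
    dg <- dc * s$i * (1 - s$g^2)
    da <- c(di, df, dg, do)
    g$b <- g$b + da
    g$Wx <- g$Wx + da %o% s$x
    g$Wh <- g$Wh + da %o% s$hprev
    dX[t, ] <- as.numeric(t(par$Wx) %*% da)
    dh <- as.numeric(t(par$Wh) %*% da)
    dc <- dc * s$f
  }
  list(dX = dX, grads = g)
}

# ---- head forward / backward -----------------------------------------------

head_init <- function(head_cfg, enc_cfg, seed) {
  D <- enc_cfg$dim
  S <- head_cfg$max_segments
  with_local_seed(seed, {
    vdim <- switch(head_cfg$strategy,
                   lstm_cls = , lstm_top = head_cfg$hidden,
                   concat_cls = S * D,
                   concat_top = S * enc_cfg$window * D,
                   mean_cls = , min_cls = , max_cls = D)
    par <- list(Wout = rand_mat(2L, vdim), bout = numeric(2L))
    if (head_cfg$strategy %in% c("lstm_cls", "lstm_top")) {
      par <- c(par, lstm_init(D, head_cfg$hidden))
    }
    par
  })
}

# Assemble v_d from segment encodings.  Returns v_d plus what backward needs.
head_forward <- function(encodings, head_cfg, enc_cfg, par) {
  if (length(encodings) == 0L) stop("empty encoding sequence")
  D <- enc_cfg$dim
  S <- head_cfg$max_segments
  encodings <- encodings[seq_len(min(length(encodings), S))]
  Cm <- do.call(rbind, lapply(encodings, `[[`, "cls"))
  cache <- list(n_real = length(encodings), Cm = Cm)
  v_d <- switch(head_cfg$strategy,
    mean_cls = colMeans(Cm),
    min_cls = apply(Cm, 2L, min),
    max_cls = apply(Cm, 2L, max),
    concat_cls = {
      v <- numeric(S * D)
      v[seq_len(nrow(Cm) * D)] <- as.numeric(t(Cm))
      v
    },
    concat_top = {
      v <- numeric(S * enc_cfg$window * D)
      off <- 0L
      for (e in encodings) {
        tv <- e$top_vectors
        v[off + seq_len(nrow(tv) * D)] <- as.numeric(t(tv))
        off <- off + enc_cfg$window * D
      }
      v
    },
    lstm_cls = {
      fwd <- lstm_forward(Cm, par, head_cfg$hidden)
      cache$lstm <- fwd
      fwd$h
    },
    lstm_top = {
      Xall <- do.call(rbind, lapply(encodings, `[[`, "top_vectors"))
      fwd <- lstm_forward(Xall, par, head_cfg$hidden)
      cache$lstm <- fwd
      fwd$h
    })
  cache$v_d <- v_d
  cache
}

# Backward from dv_d to head-parameter gradients and per-segment dCLS rows
# (NULL when the strategy reads the whole top layer, in which case the
# encoder must be frozen or dTop is produced for concat_top).
head_backward <- function(dv, cache, head_cfg, enc_cfg, par) {
  D <- enc_cfg$dim
  n <- cache$n_real
  grads <- list()
  dCm <- NULL
  dTop <- NULL
  switch(head_cfg$strategy,
    mean_cls = {
      dCm <- matrix(dv, n, D, byrow = TRUE) / n
    },
    min_cls = {
      dCm <- matrix(0, n, D)
      sel <- apply(cache$Cm, 2L, which.min)
      dCm[cbind(sel, seq_len(D))] <- dv
    },
    max_cls = {
      dCm <- matrix(0, n, D)
      sel <- apply(cache$Cm, 2L, which.max)
      dCm[cbind(sel, seq_len(D))] <- dv
    },
    concat_cls = {
      dCm <- matrix(dv[seq_len(n * D)], n, D, byrow = TRUE)
    },
    concat_top = {
      dTop <- vector("list", n)
      off <- 0L
      for (s in seq_len(n)) {
        k <- nrow(cache$tops[[s]])
        dTop[[s]] <- matrix(dv[off + seq_len(k * D)], k, D, byrow = TRUE)
        off <- off + enc_cfg$window * D
      }
    },
    lstm_cls = {
      bk <- lstm_backward(cache$lstm, dv, par, head_cfg$hidden)
      dCm <- bk$dX
      grads <- bk$grads
    },
    lstm_top = {
      bk <- lstm_backward(cache$lstm, dv, par, head_cfg$hidden)
      grads <- bk$grads
    })
  list(grads = grads, dCm = dCm, dTop = dTop)
}

#' Combine per-segment encodings into a document representation
#'
#' Applies one of the seven segment-combination strategies to a sequence of
#' segment encodings.
#'
#' @param encodings List of `"segment_encoding"` objects in document order.
#' @param config A [head_config()].
#' @param enc_config The [encoder_config()] the encodings came from.
#' @param params Head parameters ([document_model_spec()] creates them; only
#'   the recurrent strategies need any).
#' @return A list of class `"document_representation"` with `v_d`,
#'   `strategy` and `segments_consumed`.
#' @export
combine_segments <- function(encodings, config, enc_config, params = NULL) {
  if (length(encodings) == 0L) stop("empty encoding sequence")
  if (is.null(params) && config$strategy %in% c("lstm_cls", "lstm_top")) {
    params <- lstm_init(enc_config$dim, config$hidden, seed = 1L)
  }
  if (config$strategy %in% c("concat_cls", "concat_top")) {
    padded <- pad_or_truncate(encodings, config$max_segments)
    cache <- head_forward(padded$encodings, config, enc_config, params)
    cache$n_real <- padded$n_real
  } else {
    cache <- head_forward(encodings, config, enc_config, params)
  }
  structure(list(v_d = cache$v_d, strategy = config$strategy,
                 segments_consumed = cache$n_real),
            class = "document_representation")
}

# ---- end-to-end document model ---------------------------------------------

# Internal full forward for one document (list of per-segment id vectors).
# `bits` carries optional boolean attributes, concatenated after the text
# representation before the final classifier.
doc_forward <- function(seg_ids, params, enc_cfg, head_cfg,
                        bits = numeric(0)) {
  fwds <- lapply(seg_ids, encoder_forward, params = params, config = enc_cfg)
  tops <- lapply(fwds, function(f) f$Xs[[enc_cfg$layers + 1L]])
  encs <- lapply(tops, function(tv) list(top_vectors = tv, cls = tv[1L, ]))
  cache <- head_forward(encs, head_cfg, enc_cfg, params)
  cache$tops <- tops
  cache$fused <- c(cache$v_d, bits)
  logits <- as.numeric(params$Wout %*% cache$fused) + params$bout
  list(fwds = fwds, cache = cache, logits = logits)
}

#' End-to-end long-document classifier specification
#'
#' Tokenized documents are mapped to unigram ids, cut into non-overlapping
#' windows of `window - 1` content tokens (the CLS position takes the last
#' slot), each window is encoded, the segment-combination head produces the
#' document vector, and a linear 2-way softmax classifies it.  Training is
#' single-example Adam on the cross-entropy loss, back-propagating through
#' head and encoder jointly — unless the head freezes the encoder, in which
#' case encoder parameters receive no updates at all.
#'
#' When `n_attr > 0`, each document's boolean attribute vector is
#' concatenated after the text representation (text dimensions first) and
#' the final classifier consumes the fused vector, so a zero attribute
#' vector with zero attribute-side weights reduces exactly to the text-only
#' model.
#'
#' @param vocab A [build_vocabulary()] result.
#' @param enc_cfg An [encoder_config()]; its `vocab_size` must equal the
#'   vocabulary's unigram count.
#' @param head_cfg A [head_config()].
#' @param n_attr Number of boolean attributes fused into the classifier
#'   (0 = text only; requires an `attributes` list-column in the data).
#' @return A model spec for [train_model()], with the configs attached as
#'   attributes `enc_cfg` / `head_cfg`.
#' @export
document_model_spec <- function(vocab, enc_cfg, head_cfg, n_attr = 0L) {
  stopifnot(enc_cfg$vocab_size == vocab$n_unigrams)
  seg_of <- function(tokens) {
    ids <- token_ids(tokens, vocab)
    if (length(ids) == 0L) return(NULL)
    segs <- segment_document(ids, enc_cfg$window - 1L)
    segs <- segs[seq_len(min(length(segs), head_cfg$max_segments))]
    lapply(segs, `[[`, "token_ids")
  }
  enc_param_names <- c("tok", "pos", "W", "Wp")
  n_attr <- as.integer(n_attr)
  bits_of <- function(data, i) {
    if (n_attr == 0L) return(numeric(0))
    as.numeric(data$attributes[[i]])
  }

  spec <- list(
    init = function(seed) {
      enc <- encoder_init(enc_cfg, seed = seed)
      enc$W1 <- NULL  # the head classifier replaces the plain CLS classifier
      hp <- head_init(head_cfg, enc_cfg, seed = seed + 1L)
      if (n_attr > 0L) {
        hp$Wout <- cbind(hp$Wout,
                         with_local_seed(seed + 2L,
                                         rand_mat(2L, n_attr)))
      }
      params <- c(enc, hp)
      list(params = params, opt = adam_init(params), seed = seed)
    },
    epoch = function(state, train, lr, epoch) {
      segs <- lapply(train$tokens, seg_of)
      y <- train$label
      skip <- if (head_cfg$freeze_encoder) enc_param_names else character()
      with_local_seed(state$seed * 10000L + epoch, {
        for (i in sample(length(segs))) {
          if (is.null(segs[[i]])) next
          p <- state$params
          fwd <- doc_forward(segs[[i]], p, enc_cfg, head_cfg,
                             bits = bits_of(train, i))
          xe <- softmax_xent(fwd$logits, y[i])
          g <- list(Wout = xe$dlogits %o% fwd$cache$fused,
                    bout = xe$dlogits)
          vdim <- length(fwd$cache$v_d)
          dv <- as.numeric(t(p$Wout[, seq_len(vdim), drop = FALSE]) %*%
                             xe$dlogits)
          hb <- head_backward(dv, fwd$cache, head_cfg, enc_cfg, p)
          g <- c(g, hb$grads)
          if (!head_cfg$freeze_encoder) {
            eg <- NULL
            n_real <- fwd$cache$n_real
            if (!is.null(hb$dCm)) {
              for (s in seq_len(n_real)) {
                dTop <- matrix(0, nrow(fwd$cache$tops[[s]]), enc_cfg$dim)
                dTop[1L, ] <- hb$dCm[s, ]
                sg <- encoder_backward(dTop, fwd$fwds[[s]], p, enc_cfg)
                eg <- if (is.null(eg)) sg else accum_grads(eg, sg)
              }
            } else if (!is.null(hb$dTop)) {
              for (s in seq_len(n_real)) {
                sg <- encoder_backward(hb$dTop[[s]], fwd$fwds[[s]], p,
                                       enc_cfg)
                eg <- if (is.null(eg)) sg else accum_grads(eg, sg)
              }
            }
            g <- c(g, eg)
          }
          st <- adam_step(p, g, state$opt, lr = lr, skip = skip)
          state$params <- st$params
          state$opt <- st$state
        }
      })
      state
    },
    score = function(state, data) {
      vapply(seq_len(nrow(data)), function(i) {
        sg <- seg_of(data$tokens[[i]])
        if (is.null(sg)) return(0.5)
        softmax_vec(doc_forward(sg, state$params, enc_cfg, head_cfg,
                                bits = bits_of(data, i))$logits)[2L]
      }, 0)
    }
  )
  attr(spec, "enc_cfg") <- enc_cfg
  attr(spec, "head_cfg") <- head_cfg
  spec
}

accum_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) Map(`+`, a[[nm]], b[[nm]]) else
      a[[nm]] + b[[nm]]
  }
  a
}

#' Score one document with a trained long-document model
#'
#' @param tokens Character token vector of the document.
#' @param fit A [train_model()] result for a [document_model_spec()].
#' @param spec The spec used for training.
#' @return Probability of the positive class.
#' @export
predict_document <- function(tokens, fit, spec) {
  d <- data.frame(doc_id = "x", stringsAsFactors = FALSE)
  d$tokens <- list(tokens)
  spec$score(fit$state, d)
}
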