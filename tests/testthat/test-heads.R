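enc_of <- function(cls, D = length(cls)) {
  structure(list(top_vectors = rbind(cls), cls = cls),
            class = "segment_encoding")
}

test_that("pooling heads follow their elementwise definitions", {
  ecfg <- encoder_config(layers = 1, dim = 2, window = 4, vocab_size = 5)
  e1 <- enc_of(c(1, -2)); e2 <- enc_of(c(0, 5))
  mn <- combine_segments(list(e1, e2), head_config("min_cls"), ecfg)
  mx <- combine_segments(list(e1, e2), head_config("max_cls"), ecfg)
  av <- combine_segments(list(e1, e2), head_config("mean_cls"), ecfg)
  expect_equal(mn$v_d, c(0, -2))
  expect_equal(mx$v_d, c(1, 5))
  expect_equal(av$v_d, c(0.5, 1.5))
  # identical CLS vectors: the mean is that vector
  same <- replicate(3, enc_of(c(0.3, -0.7)), simplify = FALSE)
  expect_equal(combine_segments(same, head_config("mean_cls"), ecfg)$v_d,
               c(0.3, -0.7))
  expect_error(combine_segments(list(), head_config("mean_cls"), ecfg),
               "empty")
})

test_that("concatenation preserves segment order and fixed dimension", {
  ecfg <- encoder_config(layers = 1, dim = 4, window = 6, vocab_size = 5)
  encs <- lapply(1:3, function(i) enc_of(rep(i, 4)))
  cc <- combine_segments(encs, head_config("concat_cls", max_segments = 3),
                         ecfg)
  expect_length(cc$v_d, 12L)
  expect_equal(cc$v_d, rep(1:3, each = 4))
  # shorter documents zero-pad on the right
  cc2 <- combine_segments(encs[1:2],
                          head_config("concat_cls", max_segments = 3), ecfg)
  expect_equal(cc2$v_d, c(rep(1, 4), rep(2, 4), rep(0, 4)))
  expect_identical(cc2$segments_consumed, 2L)
})

test_that("pad_or_truncate pads with zero encodings and truncates tails", {
  encs <- lapply(1:2, function(i) enc_of(c(i, i)))
  p <- pad_or_truncate(encs, 4L)
  expect_length(p$encodings, 4L)
  expect_identical(p$n_real, 2L)
  expect_equal(p$encodings[[4L]]$cls, c(0, 0))
  encs6 <- lapply(1:6, function(i) enc_of(c(i, i)))
  t6 <- pad_or_truncate(encs6, 4L)
  expect_length(t6$encodings, 4L)
  expect_equal(t6$encodings[[4L]]$cls, c(4, 4))
  same <- pad_or_truncate(encs, 2L)
  expect_identical(same$encodings, encs)
})

test_that("pooled heads are permutation-invariant; sequential heads are not", {
  ecfg <- encoder_config(layers = 1, dim = 3, window = 5, vocab_size = 5)
  set.seed(1)
  encs <- lapply(1:4, function(i) enc_of(rnorm(3)))
  perm <- c(3L, 1L, 4L, 2L)
  for (s in c("mean_cls", "min_cls", "max_cls")) {
    a <- combine_segments(encs, head_config(s), ecfg)$v_d
    b <- combine_segments(encs[perm], head_config(s), ecfg)$v_d
    expect_equal(a, b)
  }
  hc <- head_config("lstm_cls", hidden = 8)
  par <- longnote:::head_init(hc, ecfg, seed = 2)
  a <- combine_segments(encs, hc, ecfg, par)$v_d
  b <- combine_segments(encs[perm], hc, ecfg, par)$v_d
  expect_false(isTRUE(all.equal(a, b)))
  cc <- head_config("concat_cls", max_segments = 4)
  expect_false(isTRUE(all.equal(combine_segments(encs, cc, ecfg)$v_d,
                                combine_segments(encs[perm], cc, ecfg)$v_d)))
})

test_that("min <= mean <= max elementwise on any encoding set", {
  ecfg <- encoder_config(layers = 1, dim = 6, window = 5, vocab_size = 5)
  set.seed(2)
  for (rep in 1:10) {
    encs <- lapply(seq_len(sample(2:6, 1)), function(i) enc_of(rnorm(6)))
    mn <- combine_segments(encs, head_config("min_cls"), ecfg)$v_d
    av <- combine_segments(encs, head_config("mean_cls"), ecfg)$v_d
    mx <- combine_segments(encs, head_config("max_cls"), ecfg)$v_d
    expect_true(all(mn <= av + 1e-12))
    expect_true(all(av <= mx + 1e-12))
  }
})

test_that("with one segment all pooling strategies coincide with the CLS", {
  ecfg <- encoder_config(layers = 1, dim = 4, window = 5, vocab_size = 5)
  v <- c(0.2, -0.4, 0.9, 0)
  e <- list(enc_of(v))
  for (s in c("mean_cls", "min_cls", "max_cls")) {
    expect_equal(combine_segments(e, head_config(s), ecfg)$v_d, v)
  }
  # concat_cls carries the same information: shared classifier weights on
  # the first block give identical scores because padding is zero
  cc <- combine_segments(e, head_config("concat_cls", max_segments = 3),
                         ecfg)$v_d
  W <- matrix(rnorm(8), 2, 4)
  Wc <- cbind(W, matrix(rnorm(16), 2, 8))
  expect_equal(as.numeric(W %*% v), as.numeric(Wc %*% cc))
})

test_that("head config enforces the frozen-encoder contracts", {
  expect_error(head_config("lstm_top"), "freeze_encoder")
  expect_silent(head_config("lstm_top", freeze_encoder = TRUE))
  expect_error(head_config("concat_top"), "freeze_encoder")
  expect_silent(head_config("concat_top", relax_freeze = TRUE))
})

test_that("single-segment document model reduces to the plain encoder score", {
  corp <- planted_corpus(6, len = 10, seed = 3)
  v <- vocab_of(corp)
  ecfg <- encoder_config(layers = 1, dim = 8, window = 16,
                         vocab_size = v$n_unigrams)
  spec <- document_model_spec(v, ecfg, head_config("mean_cls"))
  st <- spec$init(seed = 4)
  tk <- corp$tokens[[1L]]
  p_doc <- spec$score(st, corp[1, ])
  # plain encoder on the same (single) segment, classified with the head's
  # linear layer: pooling over one element is the identity
  enc <- encode_segment(token_ids(tk, v), st$params, ecfg)
  p_cls <- longnote:::softmax_vec(
    as.numeric(st$params$Wout %*% enc$cls) + st$params$bout)[2L]
  expect_equal(unname(p_doc), p_cls)
})

test_that("document-model gradients match numerical differentiation", {
  corp <- planted_corpus(4, len = 17, seed = 5)
  v <- vocab_of(corp)
  ecfg <- encoder_config(layers = 1, dim = 4, window = 7,
                         vocab_size = v$n_unigrams)
  for (strat in c("lstm_cls", "mean_cls", "min_cls", "concat_cls")) {
    hc <- head_config(strat, max_segments = 4, hidden = 5)
    spec <- document_model_spec(v, ecfg, hc)
    st <- spec$init(seed = 6)
    ids <- token_ids(corp$tokens[[1L]], v)
    segs <- lapply(segment_document(ids, 6L), `[[`, "token_ids")
    y <- 1L
    loss_of <- function(par) {
      fwd <- longnote:::doc_forward(segs, par, ecfg, hc)
      -log(longnote:::softmax_vec(fwd$logits)[y + 1L])
    }
    p <- st$params
    fwd <- longnote:::doc_forward(segs, p, ecfg, hc)
    xe <- longnote:::softmax_xent(fwd$logits, y)
    g <- list(Wout = xe$dlogits %o% fwd$cache$v_d, bout = xe$dlogits)
    dv <- as.numeric(t(p$Wout) %*% xe$dlogits)
    hb <- longnote:::head_backward(dv, fwd$cache, hc, ecfg, p)
    g <- c(g, hb$grads)
    eg <- NULL
    for (s in seq_len(fwd$cache$n_real)) {
      dTop <- matrix(0, nrow(fwd$cache$tops[[s]]), ecfg$dim)
      dTop[1L, ] <- hb$dCm[s, ]
      sg <- longnote:::encoder_backward(dTop, fwd$fwds[[s]], p, ecfg)
      eg <- if (is.null(eg)) sg else longnote:::accum_grads(eg, sg)
    }
    g <- c(g, eg)
    for (nm in c("Wout", "bout", "tok", "pos")) {
      num <- num_grad_of(function(x) { p2 <- p; p2[[nm]] <- x; loss_of(p2) },
                         p[[nm]])
      expect_lt(rel_err(g[[nm]], num), 1e-4)
    }
    num <- num_grad_of(function(x) { p2 <- p; p2$W[[1L]] <- x; loss_of(p2) },
                       p$W[[1L]])
    expect_lt(rel_err(g$W[[1L]], num), 1e-4)
    if (strat == "lstm_cls") {
      for (nm in c("Wx", "Wh", "b")) {
        num <- num_grad_of(function(x) { p2 <- p; p2[[nm]] <- x
          loss_of(p2) }, p[[nm]])
        expect_lt(rel_err(g[[nm]], num), 1e-4)
      }
    }
  }
})

test_that("freezing the encoder leaves its parameters bitwise unchanged", {
  corp <- planted_corpus(30, len = 20, seed = 7)
  v <- vocab_of(corp)
  ecfg <- encoder_config(layers = 1, dim = 8, window = 8,
                         vocab_size = v$n_unigrams)
  hc <- head_config("lstm_top", max_segments = 3, hidden = 6,
                    freeze_encoder = TRUE)
  spec <- document_model_spec(v, ecfg, hc)
  st <- spec$init(seed = 8)
  before <- st$params[c("tok", "pos", "W", "Wp")]
  for (e in 1:2) st <- spec$epoch(st, corp, 1e-2, e)
  expect_identical(st$params[c("tok", "pos", "W", "Wp")], before)
  # and the head itself did move
  expect_false(identical(st$params$Wout, spec$init(seed = 8)$params$Wout))
})

test_that("recurrent head recovers signal that only lives in a late segment", {
  # discriminative token appears only in segment 3 of 4; a model that reads
  # only the first segment cannot see it
  set.seed(9)
  n <- 300L
  win <- 16L   # content window 15
  filler <- sprintf("w%02d", 1:25)
  y <- rep(c(0L, 1L), length.out = n)
  tokens <- lapply(seq_len(n), function(i) {
    tk <- sample(filler, 60, replace = TRUE)
    if (y[i] == 1L) tk[sample(31:45, 3L)] <- "marker"  # 3rd window of 15
    tk
  })
  corp <- data.frame(doc_id = sprintf("d%03d", 1:n),
                     group_id = sprintf("d%03d", 1:n), label = y,
                     stringsAsFactors = FALSE)
  corp$tokens <- tokens
  v <- vocab_of(corp)
  ecfg <- encoder_config(layers = 1, dim = 16, window = win,
                         vocab_size = v$n_unigrams)
  parts <- split_dataset(corp, split_spec(seed = 1))
  aucs <- vapply(1:3, function(s) {
    spec <- document_model_spec(v, ecfg, head_config("lstm_cls",
                                                     max_segments = 4,
                                                     hidden = 16))
    fit <- train_model(spec, parts, train_config(epochs = 5, lr = 1e-2,
                                                 seed = s))
    fit$test_roc$auc
  }, 0)
  head_aucs <- vapply(1:3, function(s) {
    spec1 <- document_model_spec(v, ecfg, head_config("mean_cls",
                                                      max_segments = 1))
    fit <- train_model(spec1, parts, train_config(epochs = 5, lr = 1e-2,
                                                  seed = s))
    fit$test_roc$auc
  }, 0)
  expect_gte(median(aucs), 0.9)
  expect_lte(median(head_aucs), 0.6)
})
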