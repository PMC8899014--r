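test_that("bag-of-words counts in-vocabulary tokens only", {
  v <- build_vocabulary(list(c("a", "b", "c")), min_doc_freq = 1L)
  # vocabulary terms are sorted: a, b, c
  expect_identical(bow_featurize(c("a", "a", "b"), v), c(2L, 1L, 0L))
  expect_identical(bow_featurize(character(0), v), c(0L, 0L, 0L))
  expect_identical(bow_featurize(c("zz", "qq"), v), c(0L, 0L, 0L))
})

test_that("bag-of-words counts conserve the in-vocabulary token total", {
  set.seed(1)
  corp <- random_corpus(30, len = 25)
  v <- build_vocabulary(corp, min_doc_freq = 3L)
  for (i in 1:10) {
    tk <- corp$tokens[[i]]
    expect_identical(sum(bow_featurize(tk, v)),
                     sum(tk %in% v$terms[seq_len(v$n_unigrams)]))
  }
})

test_that("logistic training separates a separable toy problem", {
  X <- matrix(rep(c(0, 1), each = 20), ncol = 1)
  y <- rep(c(0, 1), each = 20)
  m <- train_logistic(X, y, l2 = 1e-4)
  expect_equal(auc(predict_linear(m, X), y)$auc, 1.0)
  expect_error(train_logistic(X, rep(1, 40)), "degenerate")
})

test_that("heavy regularization shrinks weights toward the class prior", {
  set.seed(2)
  X <- matrix(rnorm(200), 50)
  y <- rbinom(50, 1, 0.3)
  y[1:2] <- c(0, 1)
  m <- train_logistic(X, y, l2 = 1e6)
  expect_lt(max(abs(m$weights)), 1e-4)
  p <- predict_linear(m, X)
  expect_equal(unname(p), rep(mean(y), 50), tolerance = 1e-3)
})

test_that("BFGS fit matches an independent gradient-descent oracle", {
  set.seed(3)
  X <- matrix(rnorm(50 * 4), 50)
  y <- rbinom(50, 1, 0.5)
  y[1:2] <- c(0, 1)
  l2 <- 0.1
  for (loss in c("logistic", "squared")) {
    m <- train_logistic(X, y, l2 = l2, loss = loss)
    # oracle: plain gradient descent on the same objective, run to a tight
    # tolerance (strongly convex near the optimum thanks to the ridge term)
    theta <- numeric(5)
    sig <- function(z) 1 / (1 + exp(-z))
    for (it in 1:200000) {
      p <- sig(as.numeric(X %*% theta[1:4]) + theta[5])
      r <- if (loss == "logistic") (p - y) / 50 else
        2 * (p - y) * p * (1 - p) / 50
      g <- c(as.numeric(crossprod(X, r)) + l2 * theta[1:4], sum(r))
      theta <- theta - 0.5 * g
      if (max(abs(g)) < 1e-10) break
    }
    expect_lt(max(abs(c(m$weights, m$bias) - theta)), 1e-4)
  }
})

test_that("logistic gradient-descent loss is non-increasing at a small step", {
  set.seed(4)
  X <- matrix(rnorm(30 * 3), 30)
  y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  sig <- function(z) 1 / (1 + exp(-z))
  obj <- function(th) {
    p <- sig(as.numeric(X %*% th[1:3]) + th[4])
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  th <- rnorm(4)
  prev <- obj(th)
  for (it in 1:200) {
    p <- sig(as.numeric(X %*% th[1:3]) + th[4])
    g <- c(as.numeric(crossprod(X, (p - y) / 30)), mean(p - y))
    th <- th - 0.05 * g
    cur <- obj(th)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("CNN gradients match numerical differentiation", {
  corp <- planted_corpus(4, len = 7, seed = 7)
  v <- vocab_of(corp)
  widths <- c(2L, 3L); maps <- 3L
  params <- longnote:::cnn_init(v$n_unigrams, 4L, widths, maps, seed = 1)
  ids <- token_ids(corp$tokens[[1L]], v)
  y <- 1L
  loss_of <- function(par) {
    fwd <- longnote:::cnn_forward(ids, par, widths, maps)
    -log(longnote:::softmax_vec(fwd$logits)[y + 1L])
  }
  fwd <- longnote:::cnn_forward(ids, params, widths, maps)
  xe <- longnote:::softmax_xent(fwd$logits, y)
  dfeats <- as.numeric(t(params$out) %*% xe$dlogits)
  g <- longnote:::cnn_backward(fwd, xe$dlogits, dfeats, params, widths, maps)
  for (nm in c("table", "out", "out_b")) {
    num <- num_grad_of(function(x) { p <- params; p[[nm]] <- x; loss_of(p) },
                       params[[nm]])
    expect_lt(rel_err(g[[nm]], num), 1e-5)
  }
  for (wi in 1:2) {
    num <- num_grad_of(function(x) { p <- params; p$conv[[wi]] <- x
      loss_of(p) }, params$conv[[wi]])
    expect_lt(rel_err(g$conv[[wi]], num), 1e-5)
  }
})

test_that("GRU gradients match numerical differentiation", {
  corp <- planted_corpus(4, len = 6, seed = 8)
  v <- vocab_of(corp)
  hidden <- 4L
  params <- longnote:::gru_init(v$n_unigrams, 3L, hidden, seed = 2)
  ids <- token_ids(corp$tokens[[2L]], v)
  y <- 0L
  loss_of <- function(par) {
    fwd <- longnote:::gru_forward(ids, par, hidden)
    -log(longnote:::softmax_vec(fwd$logits)[y + 1L])
  }
  fwd <- longnote:::gru_forward(ids, params, hidden)
  xe <- longnote:::softmax_xent(fwd$logits, y)
  dh0 <- as.numeric(t(params$out) %*% xe$dlogits)
  g <- longnote:::gru_backward(fwd, xe$dlogits, dh0, ids, params, hidden)
  for (nm in c("table", "Wg", "Ug", "bg", "out", "out_b")) {
    num <- num_grad_of(function(x) { p <- params; p[[nm]] <- x; loss_of(p) },
                       params[[nm]])
    expect_lt(rel_err(g[[nm]], num), 1e-5)
  }
})

test_that("neural baselines learn a planted perfect signal", {
  corp <- planted_corpus(200, len = 15, seed = 9)
  v <- vocab_of(corp)
  cnn <- conv_text_classifier(corp, v, embed_dim = 16, widths = c(2L, 3L),
                              maps = 16, dropout = 0, epochs = 5, seed = 1)
  expect_gte(auc(cnn$score_dataset(corp), corp$label)$auc, 0.99)
  gru <- recurrent_text_classifier(corp, v, embed_dim = 16, hidden = 16,
                                   dropout = 0, epochs = 5, seed = 1)
  expect_gte(auc(gru$score_dataset(corp), corp$label)$auc, 0.99)
})

test_that("untrained scorers sit at chance on label-free data", {
  corp <- random_corpus(1000, len = 12, seed = 10)
  v <- vocab_of(corp)
  cnn0 <- cnn_spec(v, embed_dim = 8, widths = c(2L, 3L), maps = 8)
  st <- cnn0$init(seed = 3)
  expect_lt(abs(auc(cnn0$score(st, corp), corp$label)$auc - 0.5), 0.05)
  gru0 <- gru_spec(v, embed_dim = 8, hidden = 8)
  stg <- gru0$init(seed = 3)
  expect_lt(abs(auc(gru0$score(stg, corp), corp$label)$auc - 0.5), 0.05)
})

test_that("training runs are bitwise repeatable under a fixed seed", {
  corp <- planted_corpus(60, len = 10, seed = 11)
  v <- vocab_of(corp)
  a <- conv_text_classifier(corp, v, embed_dim = 8, widths = 2L, maps = 4,
                            dropout = 0.2, epochs = 2, seed = 5)
  b <- conv_text_classifier(corp, v, embed_dim = 8, widths = 2L, maps = 4,
                            dropout = 0.2, epochs = 2, seed = 5)
  expect_identical(a$epoch_losses, b$epoch_losses)
  expect_identical(a$state$params, b$state$params)
  g1 <- recurrent_text_classifier(corp, v, embed_dim = 8, hidden = 6,
                                  epochs = 2, seed = 5)
  g2 <- recurrent_text_classifier(corp, v, embed_dim = 8, hidden = 6,
                                  epochs = 2, seed = 5)
  expect_identical(g1$epoch_losses, g2$epoch_losses)
})

test_that("CNN scores ignore appended out-of-vocabulary padding", {
  corp <- planted_corpus(30, len = 10, seed = 12)
  v <- vocab_of(corp)
  cnn <- conv_text_classifier(corp, v, embed_dim = 8, widths = c(2L, 3L),
                              maps = 4, epochs = 1, seed = 1)
  tk <- corp$tokens[[1L]]
  expect_equal(cnn$score(tk), cnn$score(c(tk, rep("PADPAD", 7))))
})
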