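# Tiny synthetic corpora used across model tests.

# Balanced corpus where one token ("marker") perfectly determines the label.
planted_corpus <- function(n = 200L, len = 20L, seed = 1L,
                           marker = "marker", n_filler = 30L) {
  set.seed(seed)
  filler <- sprintf("w%02d", seq_len(n_filler))
  y <- rep(c(0L, 1L), length.out = n)
  tokens <- lapply(seq_len(n), function(i) {
    tk <- sample(filler, len, replace = TRUE)
    if (y[i] == 1L) tk[sample(len, 1L)] <- marker
    tk
  })
  out <- data.frame(doc_id = sprintf("d%03d", seq_len(n)),
                    group_id = sprintf("d%03d", seq_len(n)),
                    label = y, stringsAsFactors = FALSE)
  out$tokens <- tokens
  out
}

# Corpus with no token-label association at all.
random_corpus <- function(n = 1000L, len = 15L, seed = 2L, n_filler = 30L) {
  set.seed(seed)
  filler <- sprintf("w%02d", seq_len(n_filler))
  out <- data.frame(doc_id = sprintf("d%04d", seq_len(n)),
                    group_id = sprintf("d%04d", seq_len(n)),
                    label = rep(c(0L, 1L), length.out = n),
                    stringsAsFactors = FALSE)
  out$tokens <- lapply(seq_len(n), function(i) sample(filler, len,
                                                      replace = TRUE))
  out
}

vocab_of <- function(corpus, n_max = 1L) {
  build_vocabulary(corpus, min_doc_freq = 1L, min_count = 1L, n_max = n_max)
}

num_grad_of <- function(f, x, h = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    g[j] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rel_err <- function(a, b) max(abs(a - b) / pmax(abs(b), 1))
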