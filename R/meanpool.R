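# Mean-pooling n-gram embedding classifier: every word and n-gram kept in the
# vocabulary owns a trainable vector; a document is the arithmetic mean of
# the vectors of all its in-vocabulary units (token instances, duplicates
# counted); the mean is fed to a single fully-connected 2-way softmax layer.
# No subword units and no external corpus are ever involved.

#' Extract a document's vocabulary units
#'
#' All in-vocabulary unigrams plus n-grams of orders 2..`n_max`, in document
#' order (unigrams first, then each order's grams).
#'
#' @param tokens Character token vector.
#' @param vocab A [build_vocabulary()] result with order >= `n_max`.
#' @param n_max Maximum n-gram order to use (1 = words only).
#' @return Integer vector of vocabulary ids (possibly empty).
#' @export
extract_units <- function(tokens, vocab, n_max = vocab$n_max) {
  if (n_max > vocab$n_max) {
    stop("vocabulary was built with n_max = ", vocab$n_max)
  }
  keys <- tokens
  if (n_max >= 2L && length(tokens) >= 2L) {
    for (n in 2:n_max) keys <- c(keys, ngram_keys(tokens, n))
  }
  ids <- unname(vocab$ids[keys])
  as.integer(ids[!is.na(ids)])
}

#' Mean-pool unit embeddings into a document vector
#'
#' @param unit_ids Integer ids from [extract_units()].
#' @param table `|V| x D` embedding matrix.
#' @return Length-`D` mean vector; the zero vector when no units are in
#'   vocabulary.
#' @export
mean_pool <- function(unit_ids, table) {
  if (length(unit_ids) == 0L) return(numeric(ncol(table)))
  colMeans(table[unit_ids, , drop = FALSE])
}

#' Initialise a mean-pooling model
#'
#' @param vocab A [build_vocabulary()] result.
#' @param dim Embedding dimension.
#' @param n_max Maximum n-gram order used at scoring time.
#' @param dropout Dropout rate applied to the pooled vector during training.
#' @param seed Seed for the small-normal initialisation.
#' @return A list of class `"meanpool_model"` with the embedding `table`,
#'   `output` weights (2 x D), `bias` (length 2), and settings.
#' @export
meanpool_init <- function(vocab, dim = 50L, n_max = vocab$n_max,
                          dropout = 0.1, seed = 1L) {
  with_local_seed(seed, {
    structure(list(table = rand_mat(max(vocab_size(vocab), 1L), dim),
                   output = rand_mat(2L, dim), bias = numeric(2L),
                   dim = as.integer(dim), n_max = as.integer(n_max),
                   dropout = dropout),
              class = "meanpool_model")
  })
}

#' Score a document with a mean-pooling model
#'
#' Softmax over the 2-way linear output of the pooled document vector.
#'
#' @param unit_ids Integer unit ids ([extract_units()]).
#' @param model A `"meanpool_model"`.
#' @return Probability of the positive class.
#' @export
meanpool_score <- function(unit_ids, model) {
  v <- mean_pool(unit_ids, model$table)
  softmax_vec(as.numeric(model$output %*% v) + model$bias)[2L]
}

#' Mean-pooling model specification for [train_model()]
#'
#' Documents are pre-mapped to unit-id sequences once; each epoch is one
#' shuffled pass of single-example Adam updates on the cross-entropy loss.
#'
#' @param vocab A [build_vocabulary()] result.
#' @param dim Embedding dimension (default 50).
#' @param n_max Maximum n-gram order.
#' @param dropout Dropout rate on the pooled vector.
#' @return A model spec (closures `init`, `epoch`, `score`).
#' @export
meanpool_spec <- function(vocab, dim = 50L, n_max = vocab$n_max,
                          dropout = 0.1) {
  units_of <- function(data) {
    lapply(data$tokens, extract_units, vocab = vocab, n_max = n_max)
  }
  list(
    init = function(seed) {
      model <- meanpool_init(vocab, dim = dim, n_max = n_max,
                             dropout = dropout, seed = seed)
      params <- list(table = model$table, output = model$output,
                     bias = model$bias)
      list(params = params, opt = adam_init(params), model = model,
           seed = seed)
    },
    epoch = function(state, train, lr, epoch) {
      units <- units_of(train)
      y <- train$label
      with_local_seed(state$seed * 10000L + epoch, {
        ord <- sample(length(units))
        for (i in ord) {
          u <- units[[i]]
          p <- state$params
          v <- mean_pool(u, p$table)
          mask <- dropout_mask(length(v), dropout)
          vd <- v * mask
          xe <- softmax_xent(as.numeric(p$output %*% vd) + p$bias, y[i])
          g <- list(output = xe$dlogits %o% vd, bias = xe$dlogits)
          dv <- as.numeric(t(p$output) %*% xe$dlogits) * mask
          if (length(u) > 0L) {
            dtab <- matrix(0, nrow(p$table), ncol(p$table))
            agg <- rowsum(matrix(dv, nrow = length(u), ncol = length(dv),
                                 byrow = TRUE) / length(u), group = u)
            dtab[as.integer(rownames(agg)), ] <- agg
            g$table <- dtab
          }
          st <- adam_step(p, g, state$opt, lr = lr)
          state$params <- st$params
          state$opt <- st$state
        }
      })
      state
    },
    score = function(state, data) {
      model <- state$model
      model$table <- state$params$table
      model$output <- state$params$output
      model$bias <- state$params$bias
      vapply(units_of(data), meanpool_score, 0, model = model)
    }
  )
}
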