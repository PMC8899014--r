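# Synthetic discharge-summary generator.  Emulates the *shape* of an ICU
# discharge-summary corpus — long documents (~2,000 tokens on average),
# heavy-tailed background vocabulary, rare positive targets, optional boolean
# attributes — with a planted class signal whose position inside the document
# is controllable.  It is not a language model: the signal enters as token
# counts, which is exactly the quantity the classifiers under study must
# recover, and makes the best achievable AUC computable in closed form.

#' Configure the synthetic corpus generator
#'
#' The generative model, per document: a true label is drawn Bernoulli(`prevalence`);
#' background tokens are drawn i.i.d. from a Zipf(`zipf_alpha`) distribution
#' over `vocab_size` word types, with document length lognormal (default mean
#' about 2,000 tokens, matching the average combined discharge summary the
#' package targets); a count of dedicated signal tokens is drawn Poisson with
#' rate `base_rate` for negatives and `base_rate * exp(beta)` for positives —
#' so each signal-token occurrence carries `beta` log-odds of evidence — and
#' those tokens overwrite background positions inside the placement region;
#' the observed label flips with probability `label_noise`; boolean
#' attributes are drawn with a per-attribute log-odds shift of `attr_beta`
#' between the classes, independent of the text signal.
#'
#' @param n_docs Number of documents.
#' @param vocab_size Background vocabulary size (word types).
#' @param doc_meanlog,doc_sdlog Lognormal document-length parameters; the
#'   defaults give a mean of ~2,000 tokens.
#' @param min_length Hard floor on document length (tokens).
#' @param prevalence True positive-class probability, in (0,1).
#' @param n_signal Number of distinct signal token types.
#' @param base_rate Poisson rate of signal tokens in negative documents.
#' @param beta Log-odds of evidence per signal-token occurrence (>= 0); 0
#'   means the text is independent of the label.
#' @param placement Where signal tokens land: `"uniform"` (anywhere),
#'   `"head"` (first `window` tokens), `"tail"` (last `window` tokens) or
#'   `"segment_k"` (inside the `segment_k`-th non-overlapping `window`,
#'   0-based).
#' @param window Region size used by `"head"`/`"tail"`/`"segment_k"`
#'   placement (default 512, the clinical encoder window).
#' @param segment_k 0-based segment index for `placement = "segment_k"`.
#' @param label_noise Probability the observed label is flipped, in [0, 0.5).
#' @param n_attr Number of boolean non-text attributes (0 = none).
#' @param attr_beta Per-attribute log-odds shift between classes (scalar or
#'   length `n_attr`).
#' @param attr_base Attribute-on base rate in the negative class.
#' @param zipf_alpha Zipf exponent of the background distribution.
#' @param seed Generator seed; the corpus is a deterministic function of the
#'   full configuration.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_docs = 1000L, vocab_size = 1000L,
                             doc_meanlog = log(2000) - 0.08, doc_sdlog = 0.4,
                             min_length = 16L, prevalence = 0.1,
                             n_signal = 5L, base_rate = 1.0, beta = 2.0,
                             placement = c("uniform", "head", "tail",
                                           "segment_k"),
                             window = 512L, segment_k = 0L,
                             label_noise = 0.0, n_attr = 0L, attr_beta = 2.0,
                             attr_base = 0.3, zipf_alpha = 1.1, seed = 1L) {
  placement <- match.arg(placement)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (beta < 0) stop("beta must be >= 0")
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must be in [0, 0.5)")
  }
  if (n_docs < 1L || vocab_size < 1L || n_signal < 1L || window < 1L) {
    stop("n_docs, vocab_size, n_signal and window must be >= 1")
  }
  if (base_rate <= 0) stop("base_rate must be > 0")
  structure(
    list(n_docs = as.integer(n_docs), vocab_size = as.integer(vocab_size),
         doc_meanlog = doc_meanlog, doc_sdlog = doc_sdlog,
         min_length = as.integer(min_length), prevalence = prevalence,
         n_signal = as.integer(n_signal), base_rate = base_rate, beta = beta,
         placement = placement, window = as.integer(window),
         segment_k = as.integer(segment_k), label_noise = label_noise,
         n_attr = as.integer(n_attr), attr_beta = attr_beta,
         attr_base = attr_base, zipf_alpha = zipf_alpha,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Prevalence presets for the studied prediction targets
#'
#' Class balances of the ten re-admission / fatality targets (positives over
#' a common total of 46,070 admissions), e.g. `"readmit7"` has
#' 1,109 positives and 44,961 negatives.
#'
#' @param name One of `readmit7`, `readmit30`, `readmit90`, `readmit180`,
#'   `readmit365`, `readmit_any`, `fatality30`, `fatality90`, `fatality180`,
#'   `fatality365`.
#' @return The prevalence (positive fraction) as a number.
#' @export
target_prevalence <- function(name) {
  pos <- c(readmit7 = 1109, readmit30 = 2996, readmit90 = 4887,
           readmit180 = 6105, readmit365 = 7378, readmit_any = 10565,
           fatality30 = 2127, fatality90 = 4202, fatality180 = 5963,
           fatality365 = 8078)
  if (!name %in% names(pos)) {
    stop("unknown target: ", name, "; one of ",
         paste(names(pos), collapse = ", "))
  }
  unname(pos[name] / 46070)
}

# Placement region (token positions) for a document of given length.
placement_region <- function(config, len) {
  w <- config$window
  switch(config$placement,
         uniform = seq_len(len),
         head = seq_len(min(w, len)),
         tail = (max(1L, len - w + 1L)):len,
         segment_k = {
           s <- config$segment_k * w + 1L
           if (s > len) seq_len(len) else s:min(s + w - 1L, len)
         })
}

#' Generate a synthetic labelled corpus
#'
#' @param config A [generator_config()].
#' @return A data frame with columns `doc_id`, `group_id`, `text`, `label`
#'   (observed, after label noise), a `tokens` list-column, and — when
#'   `n_attr > 0` — an `attributes` list-column of named 0/1 vectors.  The
#'   `"manifest"` attribute records the configuration, the true labels and
#'   the injected signal counts.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    n <- config$n_docs
    words <- sprintf("w%04d", seq_len(config$vocab_size))
    sig_words <- sprintf("sig%02d", seq_len(config$n_signal))
    zipf <- (seq_len(config$vocab_size))^(-config$zipf_alpha)
    zipf <- zipf / sum(zipf)
    lam1 <- config$base_rate * exp(config$beta)

    y_true <- stats::rbinom(n, 1L, config$prevalence)
    lens <- pmax(config$min_length,
                 round(stats::rlnorm(n, config$doc_meanlog, config$doc_sdlog)))
    tokens <- vector("list", n)
    sig_counts <- integer(n)
    for (i in seq_len(n)) {
      tk <- sample(words, lens[i], replace = TRUE, prob = zipf)
      k <- stats::rpois(1L, if (y_true[i] == 1L) lam1 else config$base_rate)
      if (k > 0L) {
        region <- placement_region(config, lens[i])
        k <- min(k, length(region))
        pos <- if (k == length(region)) region else sample(region, k)
        tk[pos] <- sample(sig_words, k, replace = TRUE)
      }
      sig_counts[i] <- k
      tokens[[i]] <- tk
    }

    flip <- stats::rbinom(n, 1L, config$label_noise)
    y_obs <- ifelse(flip == 1L, 1L - y_true, y_true)

    out <- data.frame(
      doc_id = sprintf("doc%05d", seq_len(n)),
      group_id = sprintf("adm%05d", seq_len(n)),
      label = as.integer(y_obs),
      stringsAsFactors = FALSE
    )
    out$text <- vapply(tokens, paste, "", collapse = " ")
    out$tokens <- tokens

    if (config$n_attr > 0L) {
      ab <- rep_len(config$attr_beta, config$n_attr)
      base_logit <- stats::qlogis(config$attr_base)
      p0 <- stats::plogis(base_logit)
      p1 <- stats::plogis(base_logit + ab)
      anames <- sprintf("attr%03d", seq_len(config$n_attr))
      out$attributes <- lapply(seq_len(n), function(i) {
        p <- if (y_true[i] == 1L) p1 else rep_len(p0, config$n_attr)
        stats::setNames(stats::rbinom(config$n_attr, 1L, p), anames)
      })
    }

    attr(out, "manifest") <- list(config = config, true_labels = y_true,
                                  signal_counts = sig_counts)
    out
  })
}

#' Split generated documents into per-admission summary records
#'
#' Re-expresses a generated corpus in the raw multi-summary form that
#' [assemble_admission()] consumes: each document's text is cut into 1 to
#' `max_summaries` consecutive pieces sharing the document's `group_id`.
#' Reassembling the records of a group in order reproduces the document text.
#'
#' @param corpus A [generate_corpus()] result.
#' @param max_summaries Maximum summaries per admission.
#' @param seed Seed for the per-document piece counts.
#' @return Data frame with `group_id`, `summary_index`, `text`, `label`.
#' @export
corpus_records <- function(corpus, max_summaries = 3L, seed = 1L) {
  with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(corpus)), function(i) {
      tk <- corpus$tokens[[i]]
      m <- sample.int(max_summaries, 1L)
      m <- min(m, length(tk))
      cuts <- sort(sample(length(tk) - 1L, m - 1L))
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, length(tk))
      data.frame(group_id = corpus$group_id[i],
                 summary_index = seq_len(m) - 1L,
                 text = vapply(seq_len(m), function(j) {
                   paste(tk[starts[j]:ends[j]], collapse = " ")
                 }, ""),
                 label = corpus$label[i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Best achievable AUC under the generative model
#'
#' Under the generator, the injected-signal count is a sufficient statistic
#' for the label and the posterior score is monotone in it (for `beta > 0`).
#' The attainable ceiling is therefore the AUC of the count itself against
#' the *observed* (noise-flipped) labels, computed exactly by enumerating the
#' two Poisson count distributions: the observed positive class is a
#' mixture of the rate-`base_rate * exp(beta)` and rate-`base_rate`
#' distributions, with mixture weights given by the fraction of true
#' positives among observed positives (a function of the prevalence and the
#' flip rate), and symmetrically for the negatives.
#'
#' @param config A [generator_config()].
#' @return The ceiling AUC as a number; 0.5 when `beta = 0`.
#' @export
bayes_auc <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$beta == 0) return(0.5)
  lam0 <- config$base_rate
  lam1 <- lam0 * exp(config$beta)
  eps <- config$label_noise
  kmax <- max(stats::qpois(1 - 1e-13, lam1), stats::qpois(1 - 1e-13, lam0)) + 1L
  k <- 0:kmax
  p0 <- stats::dpois(k, lam0)
  p1 <- stats::dpois(k, lam1)
  pi0 <- config$prevalence
  # fraction of true positives among observed positives (and vice versa)
  wpos <- pi0 * (1 - eps) / (pi0 * (1 - eps) + (1 - pi0) * eps)
  wneg <- (1 - pi0) * (1 - eps) / ((1 - pi0) * (1 - eps) + pi0 * eps)
  fpos <- wpos * p1 + (1 - wpos) * p0  # count pmf in the observed positive class
  fneg <- wneg * p0 + (1 - wneg) * p1
  Fneg <- cumsum(fneg)                # P(K_neg <= k)
  Fneg_lt <- c(0, Fneg[-length(Fneg)])
  sum(fpos * (Fneg_lt + 0.5 * fneg))
}
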