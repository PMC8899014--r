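# Text preparation: tokenization, admission assembly, vocabulary construction
# and fixed-window segmentation.  Documents are plain data frames (one row per
# admission-level document) so the evaluation utilities can treat corpora as
# ordinary tabular data.

#' Tokenize raw clinical text
#'
#' Deterministic word-level tokenization: the text is lower-cased, punctuation
#' is split into standalone tokens, digit runs are kept as tokens, and an
#' apostrophe binds to the following characters so possessives surface as a
#' `'s` token.  No stemming, no stopword removal, no weighting is ever
#' applied; word identity is the only normalisation.
#'
#' The scheme is idempotent: re-tokenizing the space-joined token sequence
#' returns the same sequence.
#'
#' @param text A character string (may be empty).
#' @return Character vector of tokens; `character(0)` for empty input.
#' @examples
#' tokenize("Mrs Smith's lungs are clear")
#' tokenize("hematocrit 29. 4")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  x <- tolower(text)
  # apostrophe starts a new token but stays glued to what follows ("smith's"
  # -> "smith 's"); every other punctuation mark becomes its own token
  x <- gsub("'", " '", x, fixed = TRUE)
  x <- gsub("([^[:alnum:][:space:]'])", " \\1 ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1L]]
  toks[nzchar(toks)]
}

#' Construct a document record
#'
#' @param doc_id Unique document identifier.
#' @param group_id Admission/patient grouping identifier used for
#'   leakage-controlled splitting; defaults to `doc_id`.
#' @param text Raw text.
#' @param label Binary outcome (0/1) or `NA` when unlabelled.
#' @param attributes Optional named logical/0-1 vector of non-text attributes.
#' @return A list of class `"document"`.
#' @export
document <- function(doc_id, group_id = doc_id, text = "", label = NA_integer_,
                     attributes = NULL) {
  stopifnot(!is.na(label) || TRUE)
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stop("label must be 0, 1 or NA")
  }
  structure(
    list(doc_id = as.character(doc_id), group_id = as.character(group_id),
         text = text, tokens = NULL, label = as.integer(label),
         attributes = attributes),
    class = "document"
  )
}

#' @export
print.document <- function(x, ...) {
  cat(sprintf("<document %s (group %s), %d chars, label %s>\n",
              x$doc_id, x$group_id, nchar(x$text),
              ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

#' Assemble one admission's summaries into a single document
#'
#' Patients can have several discharge summaries per admission (for example,
#' addendums to earlier summaries).  This multiplicity is removed by
#' concatenating all of an admission's summaries into one document, in the
#' order supplied, separated by a single space.
#'
#' @param records A data frame with columns `group_id` and `text`, in dataset
#'   order, all sharing one `group_id`; or a list of `(group_id, text)` pairs.
#' @param doc_id Identifier for the assembled document; defaults to the group
#'   id.
#' @param label,attributes Passed through to [document()].
#' @return A [document()].
#' @export
assemble_admission <- function(records, doc_id = NULL, label = NA_integer_,
                               attributes = NULL) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- data.frame(
      group_id = vapply(records, function(r) as.character(r[[1L]]), ""),
      text = vapply(records, function(r) as.character(r[[2L]]), ""),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(records) == 0L) stop("no summaries for admission")
  gid <- unique(records$group_id)
  if (length(gid) != 1L) stop("records span multiple admissions: ",
                              paste(gid, collapse = ", "))
  document(doc_id %||% gid, gid, paste(records$text, collapse = " "),
           label = label, attributes = attributes)
}

#' Build a token / n-gram vocabulary from a corpus
#'
#' Unigrams are kept when they occur in at least `min_doc_freq` documents;
#' higher-order n-grams (orders 2 to `n_max`) are kept when their total
#' occurrence count reaches `min_count`.  No stemming or stopword removal.
#' Entry ids are dense, with unigrams occupying the first block (so embedding
#' tables for word-level models can address the unigram portion directly).
#'
#' @param corpus A list of token vectors, a list of [document()]s with
#'   `$tokens` set, or a data frame with a `tokens` list-column.
#' @param min_doc_freq Minimum number of distinct documents a word must
#'   appear in (default 10, the convention for this corpus family).
#' @param min_count Minimum total count for an n-gram of order >= 2
#'   (default 5).
#' @param n_max Maximum n-gram order (1 = words only).
#' @return An object of class `"vocabulary"` with fields `terms` (character,
#'   index = id), `ids` (named lookup), `n_unigrams`, `n_max`,
#'   `min_doc_freq`, `min_count`.
#' @export
build_vocabulary <- function(corpus, min_doc_freq = 10L, min_count = 5L,
                             n_max = 1L) {
  if (n_max < 1L) stop("n_max must be >= 1")
  if (min_doc_freq < 1L || min_count < 1L) stop("thresholds must be >= 1")
  token_lists <- corpus_tokens(corpus)

  if (length(token_lists) == 0L) {
    uni <- character(0)
  } else {
    df <- table(unlist(lapply(token_lists, unique)))
    uni <- sort(names(df)[df >= min_doc_freq])
  }

  grams <- character(0)
  if (n_max >= 2L && length(token_lists) > 0L) {
    for (n in 2:n_max) {
      cnt <- table(unlist(lapply(token_lists, ngram_keys, n = n)))
      grams <- c(grams, sort(names(cnt)[cnt >= min_count]))
    }
  }

  terms <- c(uni, grams)
  ids <- seq_along(terms)
  names(ids) <- terms
  structure(
    list(terms = terms, ids = ids, n_unigrams = length(uni),
         n_max = as.integer(n_max), min_doc_freq = as.integer(min_doc_freq),
         min_count = as.integer(min_count)),
    class = "vocabulary"
  )
}

# Normalise the accepted corpus representations to a list of token vectors.
corpus_tokens <- function(corpus) {
  if (is.data.frame(corpus)) return(corpus$tokens)
  if (length(corpus) == 0L) return(list())
  if (inherits(corpus[[1L]], "document")) {
    return(lapply(corpus, function(d) d$tokens %||% tokenize(d$text)))
  }
  corpus
}

# n-gram key: order prefix + "_"-joined tokens, avoiding collisions between
# orders and with literal words.
ngram_keys <- function(tokens, n) {
  k <- length(tokens) - n + 1L
  if (k < 1L) return(character(0))
  idx <- seq_len(k)
  cols <- lapply(seq_len(n) - 1L, function(off) tokens[idx + off])
  paste0(n, ":", do.call(paste, c(cols, sep = "_")))
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d terms (%d unigrams), n_max=%d>\n",
              length(x$terms), x$n_unigrams, x$n_max))
  invisible(x)
}

#' Number of entries in a vocabulary
#' @param vocab A [build_vocabulary()] result.
#' @export
vocab_size <- function(vocab) length(vocab$terms)

#' Map tokens to dense unigram ids
#'
#' Out-of-vocabulary tokens are dropped.
#'
#' @param tokens Character vector of tokens.
#' @param vocab A [build_vocabulary()] result.
#' @return Integer vector of ids into the unigram block.
#' @export
token_ids <- function(tokens, vocab) {
  ids <- unname(vocab$ids[tokens])
  ids <- ids[!is.na(ids) & ids <= vocab$n_unigrams]
  as.integer(ids)
}

#' Split a token sequence into non-overlapping fixed windows
#'
#' @param tokens Token (or token-id) vector; must be non-empty.
#' @param window Maximum segment length, >= 1.
#' @param doc_id Optional source document id recorded on each segment.
#' @return List of segments, each a list with `source_doc_id`, `index`
#'   (0-based, contiguous) and `token_ids`.  Concatenating the segments in
#'   index order reproduces `tokens` exactly; all segments are full length
#'   except possibly the last.
#' @export
segment_document <- function(tokens, window, doc_id = NA_character_) {
  if (length(tokens) == 0L) stop("cannot segment an empty token sequence")
  if (window < 1L) stop("window must be >= 1")
  starts <- seq.int(1L, length(tokens), by = window)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    list(source_doc_id = doc_id, index = i - 1L,
         token_ids = tokens[s:min(s + window - 1L, length(tokens))])
  })
}

#' Sample one contiguous sub-sequence of at most `window` tokens
#'
#' Used for the shorter-segment experiment design: a random fixed-size window
#' is treated as an independent data point.  Documents shorter than the
#' window are returned whole.
#'
#' @inheritParams segment_document
#' @return A single segment (same shape as [segment_document()] elements).
#' @export
sample_subsequence <- function(tokens, window, doc_id = NA_character_) {
  if (length(tokens) == 0L) stop("cannot sample from an empty token sequence")
  if (window < 1L) stop("window must be >= 1")
  len <- min(window, length(tokens))
  start <- if (length(tokens) > window) {
    sample.int(length(tokens) - window + 1L, 1L)
  } else 1L
  list(source_doc_id = doc_id, index = 0L,
       token_ids = tokens[start:(start + len - 1L)])
}

#' First / last window of a document
#'
#' Deterministic head (first `window` tokens) and tail (last `window` tokens)
#' extraction; documents shorter than the window are returned whole.
#'
#' @inheritParams segment_document
#' @export
take_head <- function(tokens, window, doc_id = NA_character_) {
  if (length(tokens) == 0L) stop("cannot take head of an empty token sequence")
  if (window < 1L) stop("window must be >= 1")
  list(source_doc_id = doc_id, index = 0L,
       token_ids = tokens[seq_len(min(window, length(tokens)))])
}

#' @rdname take_head
#' @export
take_tail <- function(tokens, window, doc_id = NA_character_) {
  if (length(tokens) == 0L) stop("cannot take tail of an empty token sequence")
  if (window < 1L) stop("window must be >= 1")
  len <- min(window, length(tokens))
  list(source_doc_id = doc_id, index = 0L,
       token_ids = tokens[(length(tokens) - len + 1L):length(tokens)])
}

#' Read a document dataset from JSONL or CSV
#'
#' Each record needs `doc_id`, `group_id`, `text`, `label`; an optional
#' `attributes` object (JSONL) or `attr_*` columns (CSV) carries boolean
#' non-text attributes.
#'
#' @param path File path; format inferred from the extension
#'   (`.jsonl`/`.json` vs `.csv`).
#' @return A data frame with columns `doc_id`, `group_id`, `text`, `label`
#'   and, when present, an `attributes` list-column.
#' @export
read_documents <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(doc_id = "character",
                                         group_id = "character"))
    acols <- grep("^attr_", names(df), value = TRUE)
    out <- df[c("doc_id", "group_id", "text", "label")]
    if (length(acols)) {
      amat <- as.matrix(df[acols])
      colnames(amat) <- sub("^attr_", "", acols)
      out$attributes <- lapply(seq_len(nrow(df)), function(i) amat[i, ])
    }
    return(out)
  }
  recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  recs <- recs[vapply(recs, length, 0L) > 0L]
  out <- data.frame(
    doc_id = vapply(recs, function(r) as.character(r$doc_id), ""),
    group_id = vapply(recs, function(r) as.character(r$group_id %||% r$doc_id), ""),
    text = vapply(recs, function(r) as.character(r$text), ""),
    label = vapply(recs, function(r) as.integer(r$label %||% NA_integer_), 1L),
    stringsAsFactors = FALSE
  )
  if (any(vapply(recs, function(r) !is.null(r$attributes), TRUE))) {
    out$attributes <- lapply(recs, function(r) unlist(r$attributes))
  }
  out
}

#' Write a segmented dataset as JSONL
#'
#' One line per segment with `doc_id`, `segment_index` and `token_ids`.
#'
#' @param dataset Data frame with `doc_id` and a `tokens` list-column of
#'   token ids.
#' @param window Segment window size.
#' @param path Output path.
#' @export
write_segments <- function(dataset, window, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(dataset))) {
    segs <- segment_document(dataset$tokens[[i]], window,
                             doc_id = dataset$doc_id[i])
    for (s in segs) {
      writeLines(jsonlite::toJSON(
        list(doc_id = s$source_doc_id, segment_index = s$index,
             token_ids = s$token_ids),
        auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}
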