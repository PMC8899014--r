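# Boolean non-text attribute handling: schema-driven encoding of raw
# attribute records into fixed-order bit vectors, an attribute-only linear
# classifier, and concatenation fusion of attributes with the text model's
# document representation.

#' Define a boolean attribute schema
#'
#' Each attribute is a named rule over a raw record field: a numeric
#' threshold (`op = "ge"`), an equality test (`op = "eq"`) or a truthy flag
#' (`op = "flag"`).  The schema fixes both the attribute order and the
#' encoded dimension.
#'
#' @param rules A list of rules, each `list(name=, field=, op=, value=)`
#'   (`value` unused for `"flag"`).
#' @return A list of class `"attribute_schema"`.
#' @export
attribute_schema <- function(rules) {
  stopifnot(length(rules) >= 1L)
  nms <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate attribute names")
  ops <- vapply(rules, `[[`, "", "op")
  if (!all(ops %in% c("ge", "eq", "flag"))) stop("unknown rule op")
  structure(list(rules = rules, names = nms), class = "attribute_schema")
}

#' @export
print.attribute_schema <- function(x, ...) {
  cat(sprintf("<attribute schema: %d boolean variables>\n", length(x$rules)))
  invisible(x)
}

#' Number of attributes in a schema
#' @param schema An [attribute_schema()].
#' @export
schema_size <- function(schema) length(schema$rules)

#' Encode a raw attribute record against a schema
#'
#' Deterministic and total: every attribute yields exactly one bit, and a
#' missing raw value encodes as 0.
#'
#' @param record Named list / vector of raw attribute values.
#' @param schema An [attribute_schema()].
#' @return Named 0/1 integer vector of length [schema_size()].
#' @export
encode_attributes <- function(record, schema) {
  bits <- vapply(schema$rules, function(r) {
    v <- record[[r$field]]
    if (is.null(v) || length(v) == 0L || is.na(v)) return(0L)
    hit <- switch(r$op,
                  ge = is.numeric(v) && v >= r$value,
                  eq = as.character(v) == as.character(r$value),
                  flag = isTRUE(v) || identical(v, 1) || identical(v, 1L) ||
                    identical(tolower(as.character(v)), "true"))
    as.integer(isTRUE(hit))
  }, 0L)
  stats::setNames(bits, schema$names)
}

#' The 255-variable clinical attribute preset
#'
#' A synthetic stand-in schema with the same dimension and variable families
#' as the non-text attribute set used for the clinical corpus: age
#' thresholds, gender, admission type, insurance, marital status, discharge
#' location, religion, ethnicity and language category memberships — 255
#' boolean variables in total, deliberately excluding anything describing
#' medical treatments.  The exact category lists are generic placeholders;
#' only the family structure and the dimension are meaningful.
#'
#' @return An [attribute_schema()] with 255 rules.
#' @export
clinical_attribute_schema <- function() {
  rules <- list()
  add <- function(rs) rules[[length(rules) + 1L]] <<- rs
  for (t in seq(15, 90, by = 5)) {                      # 16 age thresholds
    add(list(name = sprintf("age_ge_%d", t), field = "age", op = "ge",
             value = t))
  }
  for (g in c("female", "male")) {                      # 2
    add(list(name = paste0("gender_", g), field = "gender", op = "eq",
             value = g))
  }
  for (a in c("emergency", "elective", "urgent", "newborn")) {  # 4
    add(list(name = paste0("admission_", a), field = "admission_type",
             op = "eq", value = a))
  }
  for (i in c("medicare", "medicaid", "private", "government",
              "self_pay")) {                            # 5
    add(list(name = paste0("insurance_", i), field = "insurance", op = "eq",
             value = i))
  }
  for (m in sprintf("marital_%d", 1:7)) {               # 7
    add(list(name = m, field = "marital_status", op = "eq",
             value = sub("marital_", "", m)))
  }
  for (d in sprintf("discharge_loc_%d", 1:25)) {        # 25
    add(list(name = d, field = "discharge_location", op = "eq",
             value = sub("discharge_loc_", "", d)))
  }
  for (r in sprintf("religion_%d", 1:20)) {             # 20
    add(list(name = r, field = "religion", op = "eq",
             value = sub("religion_", "", r)))
  }
  for (e in sprintf("ethnicity_%d", 1:41)) {            # 41
    add(list(name = e, field = "ethnicity", op = "eq",
             value = sub("ethnicity_", "", e)))
  }
  for (l in sprintf("language_%d", 1:135)) {            # 135 -> total 255
    add(list(name = l, field = "language", op = "eq",
             value = sub("language_", "", l)))
  }
  attribute_schema(rules)
}

#' Concatenate a text representation with an attribute bit vector
#'
#' Text dimensions first, attribute bits after; the downstream classifier
#' consumes the fused vector.
#'
#' @param v_text Document representation (or CLS vector).
#' @param bits Attribute 0/1 vector.
#' @return Numeric vector of length `length(v_text) + length(bits)`.
#' @export
fuse_concat <- function(v_text, bits) {
  c(as.numeric(v_text), as.numeric(bits))
}

#' Attribute-only classifier specification
#'
#' A fully-connected single-layer network (linear map + 2-way softmax) over
#' the boolean attribute vector, trained with the shared protocol.
#'
#' @param n_attr Attribute dimension.
#' @return A model spec for [train_model()]; the data frame needs an
#'   `attributes` list-column.
#' @export
attribute_spec <- function(n_attr) {
  bits_of <- function(data) {
    lapply(data$attributes, as.numeric)
  }
  list(
    init = function(seed) {
      params <- with_local_seed(seed, list(W = rand_mat(2L, n_attr),
                                           b = numeric(2L)))
      list(params = params, opt = adam_init(params), seed = seed)
    },
    epoch = function(state, train, lr, epoch) {
      if (length(unique(train$label)) < 2L) {
        stop("degenerate training set: one class only")
      }
      bits <- bits_of(train)
      y <- train$label
      with_local_seed(state$seed * 10000L + epoch, {
        for (i in sample(length(bits))) {
          p <- state$params
          xe <- softmax_xent(as.numeric(p$W %*% bits[[i]]) + p$b, y[i])
          g <- list(W = xe$dlogits %o% bits[[i]], b = xe$dlogits)
          st <- adam_step(p, g, state$opt, lr = lr)
          state$params <- st$params
          state$opt <- st$state
        }
      })
      state
    },
    score = function(state, data) {
      vapply(bits_of(data), function(x) {
        softmax_vec(as.numeric(state$params$W %*% x) + state$params$b)[2L]
      }, 0)
    }
  )
}
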