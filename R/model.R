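VARIANTS <- c("full", "nk", "np")

variant_code <- function(variant) match(variant, VARIANTS) - 1L

#' Model configuration
#'
#' @param embed_dim Dimension d of the shared code/entity/relation
#'   embedding space.
#' @param time_dim Dimension of the sinusoidal time encoding (even).
#' @param hidden_dim LSTM hidden/cell dimension.
#' @param attn_dim Width of the attention scorer's hidden layer
#'   (defaults to `hidden_dim`).
#' @param variant `"full"` (knowledge-graph attention + max pooling),
#'   `"nk"` (no knowledge: the attention step is skipped, one output per
#'   event), or `"np"` (no pooling: the risk is read from the last output
#'   vector).
#' @param fine_tune_kg Fine-tune entity/relation embeddings during
#'   training (TRUE) or freeze them (FALSE).
#' @param seed Integer seed for parameter initialization.
#' @return Object of class `dgrnn_config`.
#' @export
dgrnn_config <- function(embed_dim = 32, time_dim = 16, hidden_dim = 32,
                         attn_dim = NULL, variant = c("full", "nk", "np"),
                         fine_tune_kg = TRUE, seed = 1) {
  variant <- match.arg(variant)
  if (is.null(attn_dim)) attn_dim <- hidden_dim
  stopifnot(embed_dim >= 1, hidden_dim >= 1, attn_dim >= 1,
            time_dim >= 2, time_dim %% 2 == 0)
  structure(list(embed_dim = as.integer(embed_dim),
                 time_dim = as.integer(time_dim),
                 hidden_dim = as.integer(hidden_dim),
                 attn_dim = as.integer(attn_dim), variant = variant,
                 fine_tune_kg = isTRUE(fine_tune_kg),
                 seed = as.integer(seed)),
            class = "dgrnn_config")
}

#' Sinusoidal time encoding
#'
#' Encodes a day offset t as the vector with components
#' sin(t / 10000^(2k/time_dim)) and cos(t / 10000^(2k/time_dim)) at
#' positions 2k and 2k+1.  Deterministic, and injective on distinct days
#' up to the slowest period.
#'
#' @param time Non-negative day offset(s).
#' @param time_dim Even encoding dimension.
#' @return Numeric vector (single time) or matrix with one row per time.
#' @export
encode_time <- function(time, time_dim) {
  stopifnot(time_dim >= 2, time_dim %% 2 == 0)
  if (any(time < 0)) stop("time must be non-negative")
  m <- cpp_time_encoding(as.numeric(time), as.integer(time_dim))
  if (length(time) == 1) drop(m) else m
}

#' Initialize model parameters for a variant
#'
#' Builds the parameter set for a DG-RNN variant: embeddings over the
#' union of the cohort vocabulary and the knowledge-graph entities
#' (pretrained vectors are reused where supplied; codes absent from the
#' knowledge graph get seeded normal(0, 1/sqrt(d)) vectors so the shared
#' space stays total), LSTM gate weights and attention weights drawn
#' uniform within +/- 1/sqrt(hidden_dim), zero biases, and a zero
#' null-knowledge vector used when an event has no graph edges.
#'
#' @param config A [dgrnn_config].
#' @param vocabulary Character vector of medical codes, or a cohort
#'   vocabulary `data.frame` with columns `code`, `category`.
#' @param kg Optional [knowledge_graph]; its entities and relations join
#'   the embedding table.
#' @param embeddings Optional pretrained `embedding_space` from
#'   [pretrain_transe()]; must have `dim == config$embed_dim`.
#' @return Object of class `dgrnn_model`.
#' @export
dgrnn_init <- function(config, vocabulary, kg = NULL, embeddings = NULL) {
  stopifnot(inherits(config, "dgrnn_config"))
  if (is.data.frame(vocabulary)) {
    categories <- setNames(vocabulary$category, vocabulary$code)
    codes <- vocabulary$code
  } else {
    codes <- as.character(vocabulary)
    categories <- setNames(rep("other", length(codes)), codes)
  }
  ents <- codes
  rels <- character()
  if (!is.null(kg)) {
    ents <- union(ents, kg$entities)
    rels <- kg$relations
  }
  ents <- sort(unique(ents))
  d <- config$embed_dim; H <- config$hidden_dim; A <- config$attn_dim
  D <- d + config$time_dim
  if (!is.null(embeddings) && embeddings$dim != d)
    stop("pretrained embedding dim does not match config$embed_dim")

  set.seed(config$seed)
  E <- matrix(rnorm(length(ents) * d, 0, 1 / sqrt(d)), length(ents), d,
              dimnames = list(ents, NULL))
  R <- matrix(rnorm(max(length(rels), 0) * d, 0, 1 / sqrt(d)),
              length(rels), d, dimnames = list(rels, NULL))
  if (!is.null(embeddings)) {
    hit <- intersect(ents, rownames(embeddings$entity_vectors))
    E[hit, ] <- embeddings$entity_vectors[hit, , drop = FALSE]
    hitr <- intersect(rels, rownames(embeddings$relation_vectors))
    R[hitr, ] <- embeddings$relation_vectors[hitr, , drop = FALSE]
  }
  lim <- 1 / sqrt(H)
  params <- list(
    emb_entity = E, emb_relation = R,
    Wx = matrix(runif(4 * H * D, -lim, lim), 4 * H, D),
    Wh = matrix(runif(4 * H * H, -lim, lim), 4 * H, H),
    b  = numeric(4 * H),
    Wa = matrix(runif(A * (H + 3 * d), -lim, lim), A, H + 3 * d),
    ba = numeric(A),
    ua = runif(A, -lim, lim),
    Wo = runif(H, -lim, lim),
    bo = 0,
    g_null = numeric(d))
  structure(list(config = config, entities = ents, relations = rels,
                 categories = categories, params = params),
            class = "dgrnn_model")
}

#' @export
print.dgrnn_model <- function(x, ...) {
  cat(sprintf(paste0("<dgrnn_model (%s): d=%d, hidden=%d, time_dim=%d, ",
                     "%d entities, %d relations>\n"),
              x$config$variant, x$config$embed_dim, x$config$hidden_dim,
              x$config$time_dim, length(x$entities), length(x$relations)))
  invisible(x)
}

# 0-based (relation, tail) index matrices per model entity, in the graph's
# deterministic order; entities without edges get a 0x2 matrix.
adjacency_index <- function(model, kg) {
  empty <- matrix(integer(0), 0, 2)
  if (is.null(kg))
    return(rep(list(empty), length(model$entities)))
  lapply(model$entities, function(e) {
    nb <- kg$adjacency[[e]]
    if (is.null(nb) || nrow(nb) == 0) return(empty)
    ri <- match(nb$relation, model$relations) - 1L
    ti <- match(nb$tail, model$entities) - 1L
    keep <- !is.na(ri) & !is.na(ti)
    cbind(ri[keep], ti[keep])
  })
}

as_model_events <- function(model, x) {
  if (inherits(x, "patient_record")) x <- flatten_events(x, model$entities)
  if (!is.list(x) || is.null(x$codes))
    stop("events must be a patient_record or a flatten_events() result")
  if (length(x$codes) == 0) stop("empty event sequence")
  x
}

#' Knowledge-graph attention for one event
#'
#' Scores each (relation, tail) edge of the head entity with an additive
#' scorer u' tanh(W [cell_state; emb(head); emb(relation); emb(tail)] + b),
#' normalizes the scores with a softmax, and returns the soft-attention
#' result g = sum_m alpha_m emb(tail_m).  When the head has no edges the
#' learnable null-knowledge vector is returned with empty weights.
#'
#' @param model A [dgrnn_model].
#' @param cell_state Numeric vector of length `hidden_dim` (the cell state
#'   produced by the event's LSTM step).
#' @param head Entity id of the event's code.
#' @param kg A [knowledge_graph] (or NULL for no edges).
#' @return List with `g` (length-d vector) and `alpha` (named weights, one
#'   per edge, summing to 1; length 0 without edges).
#' @export
graph_attention <- function(model, cell_state, head, kg) {
  p <- model$params
  stopifnot(length(cell_state) == model$config$hidden_dim)
  nb <- if (is.null(kg)) NULL else kg$adjacency[[head]]
  if (is.null(nb) || nrow(nb) == 0)
    return(list(g = p$g_null, alpha = numeric(0)))
  eh <- p$emb_entity[head, ]
  scores <- vapply(seq_len(nrow(nb)), function(m) {
    q <- c(cell_state, eh, p$emb_relation[nb$relation[m], ],
           p$emb_entity[nb$tail[m], ])
    sum(p$ua * tanh(p$Wa %*% q + p$ba))
  }, numeric(1))
  a <- exp(scores - max(scores))
  alpha <- a / sum(a)
  g <- drop(alpha %*% p$emb_entity[nb$tail, , drop = FALSE])
  list(g = g, alpha = setNames(alpha, paste(nb$relation, nb$tail, sep = ":")))
}

#' Run the DG-RNN forward pass
#'
#' For each event t the code embedding concatenated with its time encoding
#' enters the LSTM, producing output h_{2t-1} and cell state C_{2t-1}; the
#' attention step over the code's knowledge-graph edges (conditioned on
#' C_{2t-1}) yields g_t, which re-enters the LSTM with the same time
#' encoding to produce h_{2t}.  Global max pooling over all output rows
#' gives o_g, and the linear head z = Wo'o_g + bo, y = sigmoid(z).  The
#' `nk` variant skips the attention step (one output row per event); the
#' `np` variant reads z from the last output vector and carries no pooling
#' fields.  Pooling ties resolve to the smallest row index so attribution
#' is deterministic.
#'
#' @param model A [dgrnn_model].
#' @param events A [patient_record] or a [flatten_events()] result.
#' @param kg A [knowledge_graph] (NULL means no edges anywhere).
#' @return Object of class `forward_trace` with fields `H` (step outputs,
#'   2T or T rows), `C` (cell states), `alphas` (per-event attention
#'   weights), `o_g`, `pool_argmax` (1-based winning row per dimension),
#'   `z` and `y`.
#' @export
dgrnn_forward <- function(model, events, kg = NULL) {
  ev <- as_model_events(model, events)
  adj <- adjacency_index(model, kg)
  out <- cpp_forward(model$params, ev$codes - 1L, ev$times, adj,
                     variant_code(model$config$variant))
  if (!is.null(out$o_g)) out$o_g <- as.numeric(out$o_g)
  out$alphas <- lapply(out$alphas, as.numeric)
  out$n_events <- length(ev$codes)
  out$variant <- model$config$variant
  class(out) <- "forward_trace"
  out
}

#' @export
print.forward_trace <- function(x, ...) {
  cat(sprintf("<forward_trace (%s): %d events, %d output rows, z=%.4f, y=%.4f>\n",
              x$variant, x$n_events, nrow(x$H), x$z, x$y))
  invisible(x)
}

#' Binary cross-entropy loss
#'
#' -[label log y + (1 - label) log(1 - y)], with probabilities clamped at
#' 1e-12 away from 0 and 1; vectors give the batch mean.
#'
#' @param y Predicted probability (or vector of them).
#' @param label 0/1 outcome(s).
#' @return Mean loss (scalar).
#' @export
binary_cross_entropy <- function(y, label) {
  if (!all(label %in% c(0, 1))) stop("labels must be 0 or 1")
  yc <- pmin(pmax(y, 1e-12), 1 - 1e-12)
  mean(-(label * log(yc) + (1 - label) * log(1 - yc)))
}

# ---------------------------------------------------------------------------
# checkpointing: JSON container, numeric payload base64-encoded so the
# round trip is bit-exact.

encode_num <- function(x) {
  list(dim = if (is.matrix(x)) dim(x) else length(x),
       rownames = if (is.matrix(x)) rownames(x),
       data = jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                            size = 8, endian = "little")))
}

decode_num <- function(e) {
  x <- readBin(jsonlite::base64_dec(e$data), "numeric",
               n = prod(unlist(e$dim)), size = 8, endian = "little")
  if (length(e$dim) == 2) {
    x <- matrix(x, e$dim[[1]], e$dim[[2]])
    if (!is.null(e$rownames)) rownames(x) <- unlist(e$rownames)
  }
  x
}

#' Save / load a model checkpoint
#'
#' Single-file JSON container holding the configuration, vocabularies and
#' all parameter arrays (base64-encoded IEEE doubles, so save/load
#' round-trips bit-exactly).
#'
#' @param model A [dgrnn_model].
#' @param path Checkpoint path.
#' @return `load_checkpoint` returns the restored [dgrnn_model].
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    entities = model$entities, relations = model$relations,
    categories = as.list(model$categories),
    params = lapply(model$params, encode_num))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path)
  cfg <- do.call(dgrnn_config, payload$config)
  params <- lapply(payload$params, function(p)
    if (is.list(p)) decode_num(p) else as.numeric(p))
  ents <- unlist(payload$entities)
  structure(list(config = cfg, entities = ents,
                 relations = as.character(unlist(payload$relations)),
                 categories = unlist(payload$categories),
                 params = params),
            class = "dgrnn_model")
}
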