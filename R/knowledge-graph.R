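#' Construct a knowledge graph from a triple table
#'
#' @param triples `data.frame` with character columns `head`, `relation`,
#'   `tail`.  Duplicate triples are collapsed.
#' @return Object of class `knowledge_graph` with entity and relation
#'   vocabularies, the triple set, and a head-indexed adjacency list whose
#'   per-head ordering is deterministic (relation id, then tail id).
#' @export
knowledge_graph <- function(triples) {
  if (nrow(triples)) {
    stopifnot(all(c("head", "relation", "tail") %in% names(triples)))
    if (any(!nzchar(triples$head)) || any(!nzchar(triples$tail)))
      stop("empty head or tail entity in triple list")
    triples <- unique(triples[, c("head", "relation", "tail")])
    triples <- triples[order(triples$head, triples$relation, triples$tail), ,
                       drop = FALSE]
    rownames(triples) <- NULL
  } else {
    triples <- data.frame(head = character(), relation = character(),
                          tail = character(), stringsAsFactors = FALSE)
  }
  entities <- sort(unique(c(triples$head, triples$tail)))
  relations <- sort(unique(triples$relation))
  adjacency <- split(triples[, c("relation", "tail")], triples$head)
  adjacency <- lapply(adjacency, function(df) {
    rownames(df) <- NULL
    df
  })
  structure(list(entities = entities, relations = relations,
                 triples = triples, adjacency = adjacency),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph: %d entities, %d relations, %d triples>\n",
              length(x$entities), length(x$relations), nrow(x$triples)))
  invisible(x)
}

#' Read a knowledge graph from a tab-delimited triple list
#'
#' Each line must hold exactly three tab-separated fields
#' (head, relation, tail).  Duplicated lines collapse to one triple; an
#' empty file yields an empty graph (the model then degenerates to its
#' no-knowledge behaviour).
#'
#' @param path Path to the TSV triple file (no header).
#' @return A [knowledge_graph].
#' @export
read_triples <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(knowledge_graph(data.frame(head = character(),
                                      relation = character(),
                                      tail = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    bad <- which(nf != 3)[1]
    stop(sprintf("line %d has %d fields, expected 3 (head, relation, tail)",
                 bad, nf[bad]))
  }
  m <- do.call(rbind, parts)
  knowledge_graph(data.frame(head = m[, 1], relation = m[, 2], tail = m[, 3],
                             stringsAsFactors = FALSE))
}

#' Write a knowledge graph as a triple TSV
#' @param kg A [knowledge_graph].
#' @param path Output path.
#' @export
write_triples <- function(kg, path) {
  write.table(kg$triples, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Outgoing edges of a head entity
#'
#' Returns the (relation, tail) pairs with the given head, in the graph's
#' deterministic order; an empty data.frame when the head is absent.
#'
#' @param kg A [knowledge_graph].
#' @param head Entity id.
#' @return `data.frame` with columns `relation`, `tail`.
#' @export
kg_neighbors <- function(kg, head) {
  adj <- kg$adjacency[[head]]
  if (is.null(adj))
    adj <- data.frame(relation = character(), tail = character(),
                      stringsAsFactors = FALSE)
  adj
}

#' One-hop subgraph payload for visualization
#'
#' Induced 1-hop neighbourhood of a set of codes, serializable to JSON for
#' a knowledge-graph view: shared neighbours are emitted once.
#'
#' @param kg A [knowledge_graph].
#' @param codes Character vector of entity ids.
#' @return List with `nodes` (data.frame id/is_query/n_neighbors) and
#'   `edges` (data.frame head/relation/tail).
#' @export
subgraph_payload <- function(kg, codes) {
  codes <- unique(codes)
  edges <- do.call(rbind, lapply(codes, function(cd) {
    nb <- kg_neighbors(kg, cd)
    if (nrow(nb) == 0) return(NULL)
    data.frame(head = cd, relation = nb$relation, tail = nb$tail,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(head = character(), relation = character(),
                        tail = character(), stringsAsFactors = FALSE)
  ids <- unique(c(codes, edges$tail))
  nodes <- data.frame(
    id = ids, is_query = ids %in% codes,
    n_neighbors = vapply(ids, function(e) nrow(kg_neighbors(kg, e)),
                         integer(1)),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Pretrain translation-based (TransE) embeddings
#'
#' Learns d-dimensional entity and relation vectors such that
#' head + relation is close to tail in L2 distance, by stochastic gradient
#' descent on the margin ranking loss
#' \eqn{\max(0, \gamma + d(h+r, t) - d(h'+r, t'))} with uniform corruption
#' of the head or the tail.  Entity vectors are renormalized to unit norm
#' at the start of each epoch, following the original formulation.
#'
#' @param kg Non-empty [knowledge_graph].
#' @param dim Embedding dimension (>= 2).
#' @param epochs Training epochs.
#' @param margin Ranking margin \eqn{\gamma} (> 0).
#' @param step_size SGD step size.
#' @param negatives_per_positive Corrupted triples sampled per positive
#'   (>= 1).
#' @param seed Integer seed; the run is fully reproducible.
#' @return An `embedding_space`: list with `dim`, `entity_vectors` and
#'   `relation_vectors` (row-named matrices) and a `loss_history`
#'   attribute (mean epoch loss).
#' @export
pretrain_transe <- function(kg, dim, epochs = 100, margin = 1,
                            step_size = 0.01, negatives_per_positive = 1,
                            seed = 1) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (nrow(kg$triples) == 0) stop("cannot pretrain on an empty graph")
  if (margin <= 0) stop("margin must be positive")
  if (negatives_per_positive < 1)
    stop("negatives_per_positive must be >= 1")
  stopifnot(dim >= 2)
  set.seed(as.integer(seed))
  ne <- length(kg$entities); nr <- length(kg$relations)
  # uniform(-6/sqrt(d), 6/sqrt(d)) init as in the original recipe
  lim <- 6 / sqrt(dim)
  E <- matrix(runif(ne * dim, -lim, lim), ne, dim,
              dimnames = list(kg$entities, NULL))
  R <- matrix(runif(nr * dim, -lim, lim), nr, dim,
              dimnames = list(kg$relations, NULL))
  rn <- sqrt(rowSums(R^2)); rn[rn == 0] <- 1
  R <- R / rn

  h <- match(kg$triples$head, kg$entities)
  r <- match(kg$triples$relation, kg$relations)
  t <- match(kg$triples$tail, kg$entities)
  nt <- length(h)
  k <- negatives_per_positive
  eps <- 1e-12
  loss_hist <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    en <- sqrt(rowSums(E^2)); en[en == 0] <- 1
    E <- E / en
    ord <- rep(sample.int(nt), each = k)
    corrupt_head <- runif(nt * k) < 0.5
    repl <- sample.int(ne, nt * k, replace = TRUE)
    ep_loss <- 0
    for (j in seq_along(ord)) {
      i <- ord[j]
      hi <- h[i]; ri <- r[i]; ti <- t[i]
      hc <- hi; tc <- ti
      if (corrupt_head[j]) hc <- repl[j] else tc <- repl[j]
      dp_vec <- E[hi, ] + R[ri, ] - E[ti, ]
      dn_vec <- E[hc, ] + R[ri, ] - E[tc, ]
      dp <- sqrt(sum(dp_vec^2) + eps)
      dn <- sqrt(sum(dn_vec^2) + eps)
      viol <- margin + dp - dn
      if (viol > 0) {
        ep_loss <- ep_loss + viol
        gp <- dp_vec / dp      # d dp / d(h+r-t)
        gn <- dn_vec / dn
        E[hi, ] <- E[hi, ] - step_size * gp
        E[ti, ] <- E[ti, ] + step_size * gp
        R[ri, ] <- R[ri, ] - step_size * (gp - gn)
        E[hc, ] <- E[hc, ] + step_size * gn
        E[tc, ] <- E[tc, ] - step_size * gn
      }
    }
    loss_hist[ep] <- ep_loss / (nt * k)
  }
  structure(list(dim = dim, entity_vectors = E, relation_vectors = R),
            class = "embedding_space", loss_history = loss_hist)
}
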