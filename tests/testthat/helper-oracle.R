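# Independent straight-line re-evaluation of the model's forward pass,
# written with explicit scalar loops and no shared code with the package
# internals.  Used as the oracle for the forward / attention /
# attribution equivalence tests.

oracle_time_encoding <- function(time, time_dim) {
  p <- numeric(time_dim)
  for (k in 0:(time_dim / 2 - 1)) {
    denom <- 10000^((2 * k) / time_dim)
    p[2 * k + 1] <- sin(time / denom)
    p[2 * k + 2] <- cos(time / denom)
  }
  p
}

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# one LSTM step, scalar-by-scalar
oracle_lstm_step <- function(par, x, hprev, cprev) {
  H <- length(hprev)
  pre <- as.numeric(par$Wx %*% x) + as.numeric(par$Wh %*% hprev) + par$b
  i <- oracle_sigmoid(pre[1:H])
  f <- oracle_sigmoid(pre[(H + 1):(2 * H)])
  o <- oracle_sigmoid(pre[(2 * H + 1):(3 * H)])
  cc <- tanh(pre[(3 * H + 1):(4 * H)])
  C <- f * cprev + i * cc
  list(h = o * tanh(C), C = C)
}

oracle_attention <- function(par, Cstate, head, edges) {
  if (nrow(edges) == 0)
    return(list(g = par$g_null, alpha = numeric(0)))
  m <- nrow(edges)
  scores <- numeric(m)
  for (j in 1:m) {
    q <- c(Cstate, par$emb_entity[head, ],
           par$emb_relation[edges$relation[j], ],
           par$emb_entity[edges$tail[j], ])
    a <- tanh(as.numeric(par$Wa %*% q) + par$ba)
    scores[j] <- sum(par$ua * a)
  }
  e <- exp(scores - max(scores))
  alpha <- e / sum(e)
  g <- 0
  for (j in 1:m) g <- g + alpha[j] * par$emb_entity[edges$tail[j], ]
  list(g = g, alpha = alpha)
}

# codes: character vector; kg may be NULL
oracle_forward <- function(model, codes, times, kg,
                           variant = model$config$variant) {
  par <- model$params
  H <- model$config$hidden_dim
  tdim <- model$config$time_dim
  Tn <- length(codes)
  h <- rep(0, H); C <- rep(0, H)
  rows <- list(); alphas <- list()
  for (t in 1:Tn) {
    p_t <- oracle_time_encoding(times[t], tdim)
    x <- c(par$emb_entity[codes[t], ], p_t)
    st <- oracle_lstm_step(par, x, h, C)
    h <- st$h; C <- st$C
    rows[[length(rows) + 1]] <- h
    if (variant != "nk") {
      edges <- if (is.null(kg)) data.frame(relation = character(),
                                           tail = character())
               else kg_neighbors(kg, codes[t])
      att <- oracle_attention(par, C, codes[t], edges)
      alphas[[t]] <- att$alpha
      x2 <- c(att$g, p_t)
      st <- oracle_lstm_step(par, x2, h, C)
      h <- st$h; C <- st$C
      rows[[length(rows) + 1]] <- h
    }
  }
  Hmat <- do.call(rbind, rows)
  if (variant == "np") {
    z <- sum(par$Wo * Hmat[nrow(Hmat), ]) + par$bo
    return(list(H = Hmat, z = z, y = oracle_sigmoid(z), alphas = alphas))
  }
  og <- numeric(H); amax <- integer(H)
  for (d in 1:H) {
    best <- Hmat[1, d]; pos <- 1L
    for (r in seq_len(nrow(Hmat))) {
      if (Hmat[r, d] > best) { best <- Hmat[r, d]; pos <- r }
    }
    og[d] <- best; amax[d] <- pos
  }
  z <- sum(par$Wo * og) + par$bo
  list(H = Hmat, o_g = og, pool_argmax = amax, z = z,
       y = oracle_sigmoid(z), alphas = alphas)
}

# per-event contribution credits by explicit enumeration of argmax winners
oracle_attribute <- function(model, codes, times, kg) {
  fw <- oracle_forward(model, codes, times, kg)
  Tn <- length(codes)
  credit <- numeric(nrow(fw$H))
  for (d in seq_along(fw$o_g)) {
    credit[fw$pool_argmax[d]] <- credit[fw$pool_argmax[d]] +
      model$params$Wo[d] * fw$o_g[d]
  }
  if (model$config$variant == "nk") {
    total <- credit; kg_part <- rep(0, Tn)
  } else {
    total <- numeric(Tn); kg_part <- numeric(Tn)
    for (t in 1:Tn) {
      total[t] <- credit[2 * t - 1] + credit[2 * t]
      kg_part[t] <- credit[2 * t]
    }
  }
  list(total = total, kg = kg_part, z = fw$z)
}

# --- random tiny instance generators -------------------------------------

random_tiny_model <- function(seed, variant = "full") {
  set.seed(seed)
  d <- sample(2:4, 1); H <- sample(2:4, 1); A <- sample(2:4, 1)
  tdim <- sample(c(2, 4), 1)
  ents <- c("a", "b", "c", "d", "e")
  rels <- c("r1", "r2")
  cfg <- dgrnn_config(embed_dim = d, time_dim = tdim, hidden_dim = H,
                      attn_dim = A, variant = variant, seed = seed)
  params <- list(
    emb_entity = matrix(rnorm(length(ents) * d, 0, 0.5), length(ents), d,
                        dimnames = list(ents, NULL)),
    emb_relation = matrix(rnorm(length(rels) * d, 0, 0.5), length(rels), d,
                          dimnames = list(rels, NULL)),
    Wx = matrix(rnorm(4 * H * (d + tdim), 0, 0.4), 4 * H, d + tdim),
    Wh = matrix(rnorm(4 * H * H, 0, 0.4), 4 * H, H),
    b = rnorm(4 * H, 0, 0.1),
    Wa = matrix(rnorm(A * (H + 3 * d), 0, 0.4), A, H + 3 * d),
    ba = rnorm(A, 0, 0.1), ua = rnorm(A, 0, 0.5),
    Wo = rnorm(H, 0, 0.5), bo = rnorm(1, 0, 0.1),
    g_null = rnorm(d, 0, 0.3))
  model <- structure(
    list(config = cfg, entities = ents, relations = rels,
         categories = setNames(rep("diagnosis", length(ents)), ents),
         params = params),
    class = "dgrnn_model")
  # random sparse graph over the same entities
  ntri <- sample(0:6, 1)
  tri <- data.frame(head = sample(ents, ntri, TRUE),
                    relation = sample(rels, ntri, TRUE),
                    tail = sample(ents, ntri, TRUE))
  kg <- knowledge_graph(tri)
  Tn <- sample(1:3, 1)
  codes <- sample(ents, Tn, TRUE)
  times <- sort(round(runif(Tn, 0, 50), 1))
  list(model = model, kg = kg, codes = codes, times = times)
}

random_tiny_patient <- function(inst, seed) {
  set.seed(seed)
  Tn <- length(inst$codes)
  patient_record(
    patient_id = paste0("rt", seed),
    events = data.frame(code = inst$codes,
                        category = rep("diagnosis", Tn),
                        time = inst$times),
    age = 50, sex = "F", race = "White",
    label = sample(0:1, 1), criterion_date = max(inst$times))
}
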