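test_that("time encoding matches the sinusoidal closed form", {
  expect_equal(encode_time(0, 6), c(0, 1, 0, 1, 0, 1))
  # hand-computed at time_dim = 4, time = 1: frequencies 1 and 1/100
  expect_equal(encode_time(1, 4),
               c(sin(1), cos(1), sin(0.01), cos(0.01)), tolerance = 1e-12)
  expect_identical(encode_time(17.5, 8), encode_time(17.5, 8))
  expect_error(encode_time(-1, 4), "non-negative")
  # independent scalar-loop oracle agrees across a range of days
  for (tm in c(0, 1, 7.3, 365, 12345))
    expect_equal(encode_time(tm, 10), oracle_time_encoding(tm, 10),
                 tolerance = 1e-9)
})

test_that("attention weights normalize and degenerate cases follow the contract", {
  toy <- worked_toy()
  # singleton edge set: weight exactly 1, g = tail embedding
  att <- graph_attention(toy$model, c(0.2, -0.1), "250.0", toy$kg)
  expect_equal(unname(att$alpha), 1)
  expect_equal(unname(att$g), unname(toy$model$params$emb_entity["428.0", ]))
  # no edges: null-knowledge vector, empty weights
  att0 <- graph_attention(toy$model, c(0.2, -0.1), "428.0", toy$kg)
  expect_identical(att0$g, toy$model$params$g_null)
  expect_length(att0$alpha, 0)
})

test_that("identical (relation, tail) edges split attention evenly", {
  toy <- worked_toy()
  m <- toy$model
  kg <- knowledge_graph(data.frame(head = c("401.9", "401.9"),
                                   relation = c("causes", "worsens"),
                                   tail = c("428.0", "428.0")))
  # make the two relations share an embedding so the edges are identical
  m$params$emb_relation["worsens", ] <- m$params$emb_relation["causes", ]
  att <- graph_attention(m, c(0.3, 0.4), "401.9", kg)
  expect_equal(unname(att$alpha), c(0.5, 0.5))
})

test_that("attention weights are a distribution for random parameters", {
  for (s in 1:100) {
    inst <- random_tiny_model(s)
    heads <- unique(inst$kg$triples$head)
    if (length(heads) == 0) next
    att <- graph_attention(inst$model,
                           rnorm(inst$model$config$hidden_dim),
                           heads[1], inst$kg)
    expect_true(all(att$alpha >= 0))
    expect_equal(sum(att$alpha), 1, tolerance = 1e-6)
  }
})

test_that("attention agrees with a brute-force evaluation of the scorer", {
  inst <- random_tiny_model(77)
  kg <- knowledge_graph(data.frame(
    head = "a", relation = c("r1", "r2", "r1"), tail = c("b", "c", "d")))
  cs <- rnorm(inst$model$config$hidden_dim)
  att <- graph_attention(inst$model, cs, "a", kg)
  oracle <- oracle_attention(inst$model$params, cs, "a",
                             kg_neighbors(kg, "a"))
  expect_equal(unname(att$alpha), oracle$alpha, tolerance = 1e-12)
  expect_equal(unname(att$g), unname(oracle$g), tolerance = 1e-12)
})

test_that("forward emits two output rows per event and pools their max", {
  toy <- worked_toy()
  one_ev <- toy$patient
  one_ev$events <- one_ev$events[1, , drop = FALSE]
  tr <- dgrnn_forward(toy$model, one_ev, toy$kg)
  expect_equal(nrow(tr$H), 2)
  expect_equal(tr$o_g, apply(tr$H, 2, max))
  expect_equal(tr$y, 1 / (1 + exp(-tr$z)))
})

test_that("worked-toy logit matches the frozen oracle value", {
  toy <- worked_toy()
  fw <- oracle_forward(toy$model, toy$patient$events$code,
                       toy$patient$events$time, toy$kg)
  tr <- dgrnn_forward(toy$model, toy$patient, toy$kg)
  expect_equal(tr$z, fw$z, tolerance = 1e-12)
  # frozen value computed once from the straight-line oracle
  expect_equal(tr$z, 0.12864783077702, tolerance = 1e-10)
})

test_that("forward equals the straight-line oracle on random tiny instances", {
  for (s in 1:25) {
    inst <- random_tiny_model(s)
    tr <- dgrnn_forward(inst$model,
                        list(codes = match(inst$codes,
                                           inst$model$entities),
                             times = inst$times), inst$kg)
    fw <- oracle_forward(inst$model, inst$codes, inst$times, inst$kg)
    expect_equal(tr$z, fw$z, tolerance = 1e-8)
    expect_equal(unname(tr$o_g), unname(fw$o_g), tolerance = 1e-8)
    expect_equal(tr$pool_argmax, fw$pool_argmax)
  }
})

test_that("variant nk skips attention rows; variant np reads the last row", {
  for (s in c(3, 14)) {
    inst <- random_tiny_model(s)
    Tn <- length(inst$codes)
    ev <- list(codes = match(inst$codes, inst$model$entities),
               times = inst$times)
    m_nk <- inst$model; m_nk$config$variant <- "nk"
    tr_nk <- dgrnn_forward(m_nk, ev, inst$kg)
    expect_equal(nrow(tr_nk$H), Tn)
    expect_equal(tr_nk$z, oracle_forward(m_nk, inst$codes, inst$times,
                                         inst$kg, variant = "nk")$z,
                 tolerance = 1e-8)
    m_np <- inst$model; m_np$config$variant <- "np"
    tr_np <- dgrnn_forward(m_np, ev, inst$kg)
    expect_null(tr_np$o_g)
    expect_equal(tr_np$z,
                 sum(inst$model$params$Wo * tr_np$H[nrow(tr_np$H), ]) +
                   inst$model$params$bo, tolerance = 1e-10)
  }
})

test_that("first event step of full and nk variants is identical computation", {
  inst <- random_tiny_model(8)
  ev <- list(codes = match(inst$codes, inst$model$entities),
             times = inst$times)
  tr_full <- dgrnn_forward(inst$model, ev, inst$kg)
  m_nk <- inst$model; m_nk$config$variant <- "nk"
  tr_nk <- dgrnn_forward(m_nk, ev, inst$kg)
  expect_equal(tr_full$H[1, ], tr_nk$H[1, ], tolerance = 1e-14)
})

test_that("pooling dominates every row and is permutation invariant", {
  inst <- random_tiny_model(21)
  ev <- list(codes = match(inst$codes, inst$model$entities),
             times = inst$times)
  tr <- dgrnn_forward(inst$model, ev, inst$kg)
  for (d in seq_along(tr$o_g)) {
    expect_true(all(tr$o_g[d] >= tr$H[, d]))
    expect_equal(tr$o_g[d], tr$H[tr$pool_argmax[d], d])
  }
  # max pooling of a permuted output matrix gives the same pooled vector
  H <- tr$H
  for (perm in list(rev(seq_len(nrow(H))),
                    sample(nrow(H)))) {
    expect_equal(apply(H[perm, , drop = FALSE], 2, max), tr$o_g)
  }
})

test_that("forward rejects empty sequences and unknown codes", {
  toy <- worked_toy()
  expect_error(dgrnn_forward(toy$model,
                             list(codes = integer(0), times = numeric(0)),
                             toy$kg), "empty")
  bad <- toy$patient
  bad$events$code[1] <- "999.9"
  expect_error(dgrnn_forward(toy$model, bad, toy$kg), "999.9")
})

test_that("cross-entropy matches closed forms and validates labels", {
  expect_equal(binary_cross_entropy(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(binary_cross_entropy(0.5, 0), log(2), tolerance = 1e-12)
  expect_equal(binary_cross_entropy(0.8, 1), -log(0.8), tolerance = 1e-12)
  expect_lt(binary_cross_entropy(1 - 1e-9, 1), 1e-6)
  expect_error(binary_cross_entropy(0.5, 2), "labels")
  # batch mean
  expect_equal(binary_cross_entropy(c(0.5, 0.8), c(1, 1)),
               mean(c(log(2), -log(0.8))))
})

test_that("initialization is seed-deterministic and shape-consistent", {
  kg <- worked_toy()$kg
  cfg <- dgrnn_config(embed_dim = 3, time_dim = 4, hidden_dim = 5,
                      seed = 42)
  m1 <- dgrnn_init(cfg, c("x", "y"), kg)
  m2 <- dgrnn_init(cfg, c("x", "y"), kg)
  expect_identical(m1$params, m2$params)
  expect_equal(dim(m1$params$Wx), c(20, 7))
  expect_equal(dim(m1$params$Wa), c(5, 5 + 9))
  expect_equal(m1$params$b, rep(0, 20))
  expect_equal(m1$params$g_null, rep(0, 3))
  # all vocabulary codes and graph entities carry embeddings
  expect_setequal(rownames(m1$params$emb_entity),
                  union(c("x", "y"), kg$entities))
})

test_that("checkpoints round-trip bit-exactly", {
  toy <- worked_toy()
  tr0 <- dgrnn_forward(toy$model, toy$patient, toy$kg)
  path <- tempfile(fileext = ".json")
  save_checkpoint(toy$model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, toy$model$params)
  expect_identical(back$entities, toy$model$entities)
  expect_identical(unclass(back$config), unclass(toy$model$config))
  tr1 <- dgrnn_forward(back, toy$patient, toy$kg)
  expect_identical(tr1$z, tr0$z)
  # a trained-scale model with non-trivial values also survives
  inst <- random_tiny_model(5)
  save_checkpoint(inst$model, path)
  expect_identical(load_checkpoint(path)$params, inst$model$params)
})
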