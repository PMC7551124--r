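test_that("AUROC equals exhaustive pairwise comparison on all small sets", {
  set.seed(1)
  pairwise_auroc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    l <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- sample(seq(0, 1, 0.1), n, TRUE)   # coarse grid forces ties
    expect_equal(auroc(s, l), pairwise_auroc(s, l))
  }
  expect_equal(auroc(c(0.9, 0.1), c(1, 0)), 1)
  expect_error(auroc(c(0.4, 0.6), c(1, 1)), "single class")
})

test_that("AUROC is 0.5-ish under the null and 1 for perfect scores", {
  set.seed(7)
  l <- rbinom(2000, 1, 0.4)
  s <- runif(2000)
  expect_lt(abs(auroc(s, l) - 0.5), 0.05)
  expect_equal(auroc(l + runif(2000, 0, 0.1), l), 1)
})

test_that("metrics report computes sensitivity/specificity at the threshold", {
  rep_ <- dgrnn:::metrics_report(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0),
                                 threshold = 0.5, n_boot = 25, seed = 1)
  expect_equal(rep_$sensitivity, 0.5)
  expect_equal(rep_$specificity, 0.5)
  expect_length(rep_$bootstrap_aurocs, 25)
  expect_true(all(rep_$bootstrap_aurocs >= 0 & rep_$bootstrap_aurocs <= 1))
  perfect <- dgrnn:::metrics_report(c(0.9, 0.8, 0.1), c(1, 1, 0),
                                    n_boot = 0)
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
})

test_that("model comparison behaves like a two-sample t test", {
  a <- c(0.8, 0.8, 0.8) + c(-1, 0, 1) * 1e-3
  b <- c(0.6, 0.6, 0.6) + c(1, 0, -1) * 1e-3
  cmp <- compare_models(a, b)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$difference, 0.2, tolerance = 1e-9)
  swapped <- compare_models(b, a)
  expect_equal(swapped$difference, -cmp$difference)
  expect_equal(swapped$p_value, cmp$p_value)
  same <- compare_models(c(0.7, 0.7), c(0.7, 0.7))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_models(c(0.7, 0.7), c(0.6, 0.6)), "zero-variance")
})

test_that("drug-free LR learns prevalence on label-independent codes", {
  set.seed(2)
  pats <- lapply(1:300, function(i) {
    patient_record(paste0("n", i),
                   data.frame(code = sample(c("A", "B", "C", "D"), 5, TRUE),
                              category = "diagnosis", time = 1:5),
                   50, "F", "White", rbinom(1, 1, 0.3), 10)
  })
  co <- as_cohort(pats)
  sc <- drug_free_lr_risk(co)
  labels <- vapply(co$patients, `[[`, 0L, "label")
  expect_lt(abs(mean(sc) - mean(labels)), 0.05)
  # deterministic
  expect_identical(sc, drug_free_lr_risk(co))
})

test_that("a patient with only drug codes scores at the intercept", {
  set.seed(3)
  pats <- lapply(1:60, function(i) {
    patient_record(paste0("n", i),
                   data.frame(code = sample(c("A", "B"), 4, TRUE),
                              category = "diagnosis", time = 1:4),
                   50, "F", "White", rbinom(1, 1, 0.5), 10)
  })
  pats[[61]] <- patient_record("drugonly",
                               data.frame(code = "RX", category = "drug",
                                          time = 0),
                               50, "F", "White", 0L, 10)
  co <- as_cohort(pats)
  sc <- drug_free_lr_risk(co)
  # the drug-only patient has an all-zero feature vector: sigmoid(intercept)
  # equals the score of any other all-zero patient; verify via a direct
  # refit check that it is strictly between 0 and 1 and matches plogis(b)
  expect_true(sc[["drugonly"]] > 0 && sc[["drugonly"]] < 1)
  pats[[62]] <- patient_record("drugonly2",
                               data.frame(code = "RX", category = "drug",
                                          time = 0),
                               50, "F", "White", 1L, 10)
  sc2 <- drug_free_lr_risk(as_cohort(pats))
  expect_equal(sc2[["drugonly"]], sc2[["drugonly2"]])
})

test_that("degenerate one-class cohorts are rejected", {
  pats <- lapply(1:4, function(i)
    patient_record(paste0("x", i),
                   data.frame(code = "A", category = "diagnosis", time = 0),
                   50, "F", "White", 1L, 10))
  expect_error(drug_free_lr_risk(as_cohort(pats)), "one class")
})

make_strat_cohort <- function(taker_scores, never_scores) {
  n <- length(taker_scores) + length(never_scores)
  pats <- c(
    lapply(seq_along(taker_scores), function(i)
      patient_record(paste0("t", i),
                     data.frame(code = c("A", "RX"),
                                category = c("diagnosis", "drug"),
                                time = c(0, 1)),
                     50, "F", "White", 1L, 10)),
    lapply(seq_along(never_scores), function(i)
      patient_record(paste0("v", i),
                     data.frame(code = "A", category = "diagnosis",
                                time = 0),
                     50, "F", "White", 0L, 10)))
  list(cohort = as_cohort(pats),
       scores = c(taker_scores, never_scores))
}

test_that("resampled batches pair strata equally and never repeat a patient", {
  st <- make_strat_cohort(rep(0.5, 4), rep(0.5, 4))
  plan <- resampled_batches(st$cohort, st$scores, batch_size = 4, seed = 1)
  expect_length(plan$batches, 2)
  takes <- vapply(st$cohort$patients, dgrnn:::patient_takes_drug,
                  logical(1))
  for (b in plan$batches) {
    expect_length(b, 4)
    expect_equal(sum(takes[b]), 2)
  }
  all_idx <- unlist(plan$batches)
  expect_equal(anyDuplicated(all_idx), 0)
})

test_that("greedy pairing matches nearest available scores", {
  st <- make_strat_cohort(c(0.1, 0.9), c(0.11, 0.5))
  plan <- resampled_batches(st$cohort, st$scores, batch_size = 2, seed = 1)
  pairs <- lapply(plan$batches, function(b) sort(st$scores[b]))
  expect_setequal(vapply(pairs, paste, "", collapse = ","),
                  c("0.1,0.11", "0.5,0.9"))
})

test_that("an empty stratum falls back to plain batching with a warning", {
  pats <- lapply(1:6, function(i)
    patient_record(paste0("v", i),
                   data.frame(code = "A", category = "diagnosis", time = 0),
                   50, "F", "White", i %% 2, 10))
  co <- as_cohort(pats)
  expect_warning(plan <- resampled_batches(co, rep(0.5, 6), 2, seed = 1),
                 "stratum")
  expect_equal(sort(unlist(plan$batches)), 1:6)
})

test_that("training drives the loss down on a separable toy and is reproducible", {
  # one code perfectly predicts the label
  set.seed(11)
  pats <- lapply(1:60, function(i) {
    lab <- i %% 2
    codes <- if (lab == 1) c("SICK", "F1") else c("OK", "F1")
    patient_record(paste0("s", i),
                   data.frame(code = codes, category = "diagnosis",
                              time = c(0, 5)),
                   50, "F", "White", lab, 10)
  })
  co <- as_cohort(pats)
  cfg <- dgrnn_config(embed_dim = 8, time_dim = 4, hidden_dim = 8,
                      variant = "full", seed = 1)
  model <- dgrnn_init(cfg, co$vocabulary)
  tc <- train_config(batch_size = 10, epochs = 30, learning_rate = 0.01,
                     seed = 1, resample_drugs = FALSE, val_fraction = 0)
  fit <- dgrnn_train(model, co, NULL, tc)
  expect_lt(tail(fit$loss_history, 1), 0.1)
  fit2 <- dgrnn_train(model, co, NULL, tc)
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("projection keeps near-identical vectors together and is seeded", {
  X <- rbind(matrix(0.01 * rnorm(20), 2, 10),
             rep(8, 10))
  proj <- project_cohort(X, seed = 3, perplexity = 2, n_iter = 120)
  expect_equal(nrow(proj), 3)
  d12 <- sqrt(sum((proj[1, c("x", "y")] - proj[2, c("x", "y")])^2))
  d13 <- sqrt(sum((proj[1, c("x", "y")] - proj[3, c("x", "y")])^2))
  expect_lt(d12, d13)
  proj2 <- project_cohort(X, seed = 3, perplexity = 2, n_iter = 120)
  expect_identical(proj, proj2)
  expect_error(project_cohort(X[1, , drop = FALSE]), "at least 2")
})
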