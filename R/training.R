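#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam, mini-batches of 64
#' patients, 50 epochs, learning rate 1e-4.
#'
#' @param batch_size Patients per mini-batch (>= 2; must be even when
#'   `resample_drugs` is on, since batches then hold drug-taker /
#'   never-taker pairs).
#' @param epochs Training epochs (>= 1).
#' @param learning_rate Adam step size.
#' @param seed Integer seed covering the split, batch shuffling and the
#'   resampling.
#' @param resample_drugs Balance every batch between patients who take
#'   drugs at least once and patients who never do, paired by a drug-free
#'   logistic-regression risk score (guards against the model learning
#'   that drugs cause risk).
#' @param val_fraction Held-out fraction for the seeded stratified split.
#' @param clip Global gradient-norm clip (0 disables).
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 64, epochs = 50,
                         learning_rate = 1e-4, seed = 1,
                         resample_drugs = TRUE, val_fraction = 0.2,
                         clip = 5) {
  stopifnot(batch_size >= 2, epochs >= 1, learning_rate > 0,
            val_fraction >= 0, val_fraction < 1)
  if (resample_drugs && batch_size %% 2 != 0)
    stop("batch_size must be even when resample_drugs is on")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 resample_drugs = isTRUE(resample_drugs),
                 val_fraction = val_fraction, clip = clip),
            class = "train_config")
}

patient_takes_drug <- function(p) any(p$events$category == "drug")

#' Drug-free logistic-regression risk score
#'
#' Fits an L2-regularized logistic regression on bag-of-codes count
#' features with every drug-category code removed, by full-batch gradient
#' descent (deterministic: zero initialization, fixed iteration budget).
#' The scores anchor the drug-aware batch resampling.
#'
#' @param cohort An `ehr_cohort`.
#' @param lambda L2 penalty on the non-intercept weights.
#' @param iters Gradient-descent iterations.
#' @param step Step size.
#' @param seed Integer seed (recorded for provenance; the fit itself is
#'   deterministic).
#' @return Named numeric vector of risks in (0,1), one per patient.
#' @export
drug_free_lr_risk <- function(cohort, lambda = 1e-3, iters = 400,
                              step = 0.1, seed = 1) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  labels <- vapply(cohort$patients, function(p) p$label, integer(1))
  if (length(unique(labels)) < 2)
    stop("cohort labels are all one class; cannot fit a risk model")
  set.seed(as.integer(seed))
  vocab <- cohort$vocabulary
  feat_codes <- vocab$code[vocab$category != "drug"]
  n <- length(cohort$patients); k <- length(feat_codes)
  X <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ev <- cohort$patients[[i]]$events
    ev <- ev[ev$category != "drug", , drop = FALSE]
    if (nrow(ev)) {
      tab <- table(factor(ev$code, levels = feat_codes))
      X[i, ] <- as.numeric(tab)
    }
  }
  # scale counts for a well-conditioned descent
  sc <- apply(X, 2, sd); sc[sc == 0] <- 1
  Xs <- sweep(X, 2, sc, "/")
  w <- numeric(k); b <- 0
  for (it in seq_len(iters)) {
    p <- plogis(drop(Xs %*% w) + b)
    r <- p - labels
    gw <- drop(crossprod(Xs, r)) / n + lambda * w
    gb <- mean(r)
    w <- w - step * gw
    b <- b - step * gb
  }
  scores <- plogis(drop(Xs %*% w) + b)
  names(scores) <- vapply(cohort$patients, function(p) p$patient_id,
                          character(1))
  scores
}

#' Drug-balanced resampled batch plan
#'
#' Splits patients into drug-takers and never-takers, sorts the takers by
#' their drug-free risk score and greedily pairs each with the unused
#' never-taker of nearest score, then packs `batch_size/2` pairs per batch
#' (leftover unpaired patients are dropped from the epoch plan).  When
#' either stratum is empty the plan falls back to plain shuffled batches
#' with a warning.
#'
#' @param cohort An `ehr_cohort`.
#' @param scores Per-patient risk from [drug_free_lr_risk()] (aligned with
#'   `cohort$patients`).
#' @param batch_size Even batch size.
#' @param seed Integer seed for the shuffles.
#' @return Object of class `batch_plan`: list with `batches` (list of
#'   integer patient-index vectors), `n_takers`, `n_never`, `dropped`.
#' @export
resampled_batches <- function(cohort, scores, batch_size, seed = 1) {
  stopifnot(batch_size %% 2 == 0)
  set.seed(as.integer(seed))
  takes <- vapply(cohort$patients, patient_takes_drug, logical(1))
  takers <- which(takes); never <- which(!takes)
  if (length(takers) == 0 || length(never) == 0) {
    warning("one drug stratum is empty; falling back to plain batching")
    idx <- sample.int(length(cohort$patients))
    batches <- split(idx, ceiling(seq_along(idx) / batch_size))
    return(structure(list(batches = unname(batches),
                          n_takers = length(takers),
                          n_never = length(never), dropped = integer(0)),
                     class = "batch_plan"))
  }
  takers <- takers[order(scores[takers])]
  avail <- never[order(scores[never])]
  pairs <- matrix(NA_integer_, 0, 2)
  for (tk in takers) {
    if (length(avail) == 0) break
    j <- which.min(abs(scores[avail] - scores[tk]))
    pairs <- rbind(pairs, c(tk, avail[j]))
    avail <- avail[-j]
  }
  np <- nrow(pairs)
  per_batch <- batch_size / 2
  n_batches <- floor(np / per_batch)
  ord <- sample.int(np)
  dropped <- integer(0)
  if (n_batches == 0) { n_batches <- 1; per_batch <- np }
  used <- ord[seq_len(n_batches * per_batch)]
  dropped <- setdiff(seq_len(length(cohort$patients)),
                     c(pairs[used, 1], pairs[used, 2]))
  batches <- lapply(seq_len(n_batches), function(bi) {
    sel <- used[((bi - 1) * per_batch + 1):(bi * per_batch)]
    as.integer(c(pairs[sel, 1], pairs[sel, 2]))
  })
  structure(list(batches = batches, n_takers = sum(takes),
                 n_never = sum(!takes), dropped = dropped),
            class = "batch_plan")
}

# seeded stratified train/validation split over patient indices
stratified_split <- function(labels, val_fraction, seed) {
  set.seed(as.integer(seed))
  val <- integer(0)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    nv <- round(length(idx) * val_fraction)
    if (nv > 0) val <- c(val, sample(idx, nv))
  }
  list(train = setdiff(seq_along(labels), val), val = sort(val))
}

#' Train a DG-RNN model
#'
#' Mini-batch Adam on the binary cross-entropy, with optional drug-aware
#' resampled batching and a seeded stratified train/validation split.
#' Embeddings are fine-tuned unless frozen via the model configuration;
#' the `nk` variant trains no attention parameters.  The run is fully
#' reproducible under a fixed seed; a non-finite loss aborts with the
#' epoch and batch in the message.
#'
#' @param model A [dgrnn_model] from [dgrnn_init()].
#' @param cohort An `ehr_cohort`.
#' @param kg A [knowledge_graph] or NULL.
#' @param tc A [train_config].
#' @return List with `model` (trained), `loss_history` (per-epoch mean
#'   training loss), `split` (train/val indices) and `val_metrics`
#'   (a [dgrnn_evaluate()] report on the validation patients, or NULL when
#'   `val_fraction` is 0).
#' @export
dgrnn_train <- function(model, cohort, kg = NULL, tc = train_config()) {
  stopifnot(inherits(model, "dgrnn_model"), inherits(cohort, "ehr_cohort"),
            inherits(tc, "train_config"))
  labels <- vapply(cohort$patients, function(p) p$label, integer(1))
  split <- stratified_split(labels, tc$val_fraction, tc$seed)
  train_pat <- cohort$patients[split$train]

  flat <- lapply(train_pat, function(p) {
    fe <- flatten_events(p, model$entities)
    list(codes = fe$codes - 1L, times = fe$times, label = as.numeric(p$label))
  })
  usable <- vapply(flat, function(f) length(f$codes) > 0, logical(1))
  if (!all(usable)) {
    warning(sum(!usable), " empty patient record(s) excluded from training")
    flat <- flat[usable]; train_pat <- train_pat[usable]
  }

  # batch plan for every epoch, built up-front so the C++ loop is
  # deterministic given its inputs
  sub <- new_cohort(train_pat, cohort$holdoff_days)
  plan <- vector("list", tc$epochs)
  if (tc$resample_drugs) {
    scores <- drug_free_lr_risk(sub, seed = tc$seed)
    for (ep in seq_len(tc$epochs)) {
      bp <- resampled_batches(sub, scores, tc$batch_size,
                              seed = tc$seed + ep - 1L)
      plan[[ep]] <- lapply(bp$batches, function(b) b - 1L)
    }
  } else {
    set.seed(tc$seed)
    n <- length(flat)
    for (ep in seq_len(tc$epochs)) {
      idx <- sample.int(n)
      plan[[ep]] <- unname(lapply(
        split(idx, ceiling(seq_along(idx) / tc$batch_size)),
        function(b) b - 1L))
    }
  }

  adj <- adjacency_index(model, kg)
  fit <- cpp_train(model$params, flat, adj,
                   variant_code(model$config$variant), plan,
                   tc$learning_rate, model$config$fine_tune_kg, tc$clip,
                   0.9, 0.999, 1e-8)
  # restore dimnames lost through C++
  rownames(fit$params$emb_entity) <- model$entities
  rownames(fit$params$emb_relation) <- model$relations
  model$params <- fit$params

  val_metrics <- NULL
  if (length(split$val) > 0) {
    valco <- new_cohort(cohort$patients[split$val], cohort$holdoff_days)
    val_metrics <- try(dgrnn_evaluate(model, valco, kg, n_boot = 0,
                                      seed = tc$seed), silent = TRUE)
    if (inherits(val_metrics, "try-error")) val_metrics <- NULL
  }
  list(model = model, loss_history = as.numeric(fit$loss_history),
       split = split, val_metrics = val_metrics)
}

#' Predicted risk probabilities for a set of patients
#'
#' @param model A [dgrnn_model].
#' @param cohort An `ehr_cohort` (or list of [patient_record]).
#' @param kg A [knowledge_graph] or NULL.
#' @return List with `prob`, `logit` (numeric vectors) and `pooled`
#'   (matrix of per-patient pooled vectors o_g; for the `np` variant the
#'   last output vector).
#' @export
dgrnn_predict <- function(model, cohort, kg = NULL) {
  patients <- if (inherits(cohort, "ehr_cohort")) cohort$patients else cohort
  flat <- lapply(patients, function(p) {
    fe <- flatten_events(p, model$entities)
    list(codes = fe$codes - 1L, times = fe$times,
         label = as.numeric(p$label))
  })
  adj <- adjacency_index(model, kg)
  out <- cpp_predict(model$params, flat, adj,
                     variant_code(model$config$variant))
  out$label <- vapply(patients, function(p) p$label, integer(1))
  out$patient_id <- vapply(patients, function(p) p$patient_id, character(1))
  out
}

#' Tie-aware AUROC by the rank (Mann-Whitney) statistic
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 outcomes.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: evaluation set has a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a model on a labeled cohort
#'
#' AUROC by the tie-aware rank statistic, sensitivity TP/(TP+FN) and
#' specificity TN/(TN+FP) at the classification threshold, plus seeded
#' patient-level bootstrap AUROC replicates for model comparison.
#'
#' @param model A [dgrnn_model].
#' @param cohort An `ehr_cohort`.
#' @param kg A [knowledge_graph] or NULL.
#' @param threshold Classification threshold (default 0.5).
#' @param n_boot Bootstrap replicates (default 200; 0 skips).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `metrics_report` with `auroc`, `sensitivity`,
#'   `specificity`, `threshold`, `n`, `prob`, `label`,
#'   `bootstrap_aurocs`.
#' @export
dgrnn_evaluate <- function(model, cohort, kg = NULL, threshold = 0.5,
                           n_boot = 200, seed = 1) {
  pred <- dgrnn_predict(model, cohort, kg)
  metrics_report(pred$prob, pred$label, threshold, n_boot, seed,
                 pooled = pred$pooled, patient_id = pred$patient_id)
}

metrics_report <- function(prob, label, threshold = 0.5, n_boot = 200,
                           seed = 1, pooled = NULL, patient_id = NULL) {
  au <- auroc(prob, label)
  pred_pos <- prob >= threshold
  sens <- sum(pred_pos & label == 1) / sum(label == 1)
  spec <- sum(!pred_pos & label == 0) / sum(label == 0)
  boots <- numeric(0)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    n <- length(prob)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      while (length(unique(label[idx])) < 2)
        idx <- sample.int(n, n, replace = TRUE)
      auroc(prob[idx], label[idx])
    }, numeric(1))
  }
  structure(list(auroc = au, sensitivity = sens, specificity = spec,
                 threshold = threshold, n = length(prob), prob = prob,
                 label = label, bootstrap_aurocs = boots, pooled = pooled,
                 patient_id = patient_id),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: n=%d, AUROC %.4f, sens %.4f, spec %.4f @ %.2f>\n",
              x$n, x$auroc, x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}

#' Compare two models on bootstrap AUROC replicates
#'
#' Two-sample (Welch) t test on the replicate AUROC vectors; the reported
#' difference is mean(a) - mean(b).  Identical replicate sets return
#' difference 0 with p = 1; zero-variance non-identical inputs are an
#' error.
#'
#' @param replicates_a,replicates_b Numeric vectors of bootstrap AUROCs
#'   (length >= 2 each).
#' @return List with `difference`, `p_value`, `t_statistic`.
#' @export
compare_models <- function(replicates_a, replicates_b) {
  stopifnot(length(replicates_a) >= 2, length(replicates_b) >= 2)
  diff <- mean(replicates_a) - mean(replicates_b)
  if (sd(replicates_a) == 0 && sd(replicates_b) == 0) {
    if (diff == 0) return(list(difference = 0, p_value = 1,
                               t_statistic = 0))
    stop("degenerate zero-variance replicates")
  }
  tt <- t.test(replicates_a, replicates_b)
  list(difference = diff, p_value = tt$p.value,
       t_statistic = unname(tt$statistic))
}
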