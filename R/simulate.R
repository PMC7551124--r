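#' Simulation configuration
#'
#' Defines the generative study conditions for the synthetic EHR cohorts
#' and knowledge graphs: timed code sequences whose outcome probability is
#' driven by designated risk codes, their 1-hop "causes" neighbourhood in
#' the graph, and protective treatment drugs.  The defaults emulate the
#' scale of the motivating heart-failure cohorts (roughly 75 events per
#' patient at 2.2 events per visit, a 1:3-ish case:control mix) at a size
#' a single CPU trains in minutes.
#'
#' @param n_entities Total entities in the knowledge graph (risk codes,
#'   neutral codes, drugs and the disease entity are carved out of this).
#' @param n_relations Number of relation types; `causes` and `treats` are
#'   always present, the remainder are generic.
#' @param edge_density Random generic edges as a fraction of
#'   n_entities^2 (on top of the mechanistic causes/treats edges).
#' @param n_patients Patients to simulate.
#' @param visits_per_patient Mean visits per patient (Poisson, >= 1).
#' @param codes_per_visit Mean codes per visit (Poisson, >= 1).
#' @param visit_gap_days Mean day gap between visits (exponential).
#' @param n_risk_codes Designated risk codes.
#' @param n_drugs Treatment drug entities (the what-if panel).
#' @param beta_code Direct per-risk-code-event effect on the logit.
#' @param lambda Knowledge-graph propagation effect: each risk-code event
#'   additionally contributes lambda times the weight of its `causes`
#'   edge(s) to the disease entity.
#' @param drug_effect Per-drug-event effect (negative = protective).
#' @param beta0 Baseline logit.
#' @param label_noise Probability of flipping the sampled label.
#' @param risk_intercept,risk_slope Logistic model tying a patient's
#'   latent severity to the chance each drawn code is a risk code.
#' @param drug_intercept,drug_slope Same for drawing a drug code
#'   (severity-linked, which creates the drug/risk confound the resampled
#'   training is designed to neutralize).
#' @param seed Mandatory integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_entities = 300, n_relations = 6,
                       edge_density = 0.01, n_patients = 2000,
                       visits_per_patient = 34, codes_per_visit = 2.2,
                       visit_gap_days = 30, n_risk_codes = 20,
                       n_drugs = 9, beta_code = 0.4, lambda = 0.25,
                       drug_effect = -0.5, beta0 = -7.5,
                       label_noise = 0.02, risk_intercept = -2.2,
                       risk_slope = 1.2, drug_intercept = -4.6,
                       drug_slope = 0.8, seed = 1) {
  stopifnot(n_entities >= n_risk_codes + n_drugs + 2, n_relations >= 2,
            edge_density >= 0, n_patients >= 1, visits_per_patient >= 1,
            codes_per_visit >= 1, label_noise >= 0, label_noise <= 1)
  if (edge_density > 1) stop("edge_density implies more than n^2 edges")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a medical knowledge graph with a known risk mechanism
#'
#' Every risk code gets a `causes` edge to the disease entity with a
#' ground-truth propagation weight drawn Uniform(0.5, 1); each drug gets
#' `treats` edges to a few risk codes; generic relations fill in random
#' edges at the configured density.  Deterministic under the seed.
#'
#' @param cfg A [sim_config].
#' @return List with `kg` (a [knowledge_graph]), `truth` (data.frame of
#'   the weighted `causes` edges) and the entity role vectors
#'   `risk_codes`, `neutral_codes`, `drug_codes`, `disease`.
#' @export
simulate_kg <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  disease <- "HF.428"
  risk <- sprintf("R%02d", seq_len(cfg$n_risk_codes))
  drugs <- sprintf("RX%02d", seq_len(cfg$n_drugs))
  n_neutral <- cfg$n_entities - cfg$n_risk_codes - cfg$n_drugs - 1
  neutral <- sprintf("N%03d", seq_len(n_neutral))
  entities <- c(disease, risk, drugs, neutral)
  generic <- if (cfg$n_relations > 2)
    sprintf("rel%02d", seq_len(cfg$n_relations - 2)) else character(0)

  tri <- data.frame(head = risk, relation = "causes", tail = disease,
                    stringsAsFactors = FALSE)
  w <- runif(cfg$n_risk_codes, 0.5, 1)
  truth <- data.frame(head = risk, relation = "causes", tail = disease,
                      weight = w, stringsAsFactors = FALSE)
  for (dg in drugs) {
    targets <- sample(risk, min(3, length(risk)))
    tri <- rbind(tri, data.frame(head = dg, relation = "treats",
                                 tail = targets))
  }
  n_random <- round(cfg$edge_density * cfg$n_entities^2)
  if (n_random > 0 && length(generic) > 0) {
    cap <- cfg$n_entities^2 * length(generic)
    if (n_random > cap)
      stop("edge_density implies more edges than the graph can hold")
    seen <- paste(tri$head, tri$relation, tri$tail)
    rnd <- NULL
    while (is.null(rnd) || nrow(rnd) < n_random) {
      k <- n_random - if (is.null(rnd)) 0 else nrow(rnd)
      cand <- data.frame(head = sample(entities, 2 * k + 10, TRUE),
                         relation = sample(generic, 2 * k + 10, TRUE),
                         tail = sample(entities, 2 * k + 10, TRUE))
      key <- paste(cand$head, cand$relation, cand$tail)
      keep <- which(!duplicated(key) & !(key %in% seen))
      keep <- keep[seq_len(min(k, length(keep)))]
      seen <- c(seen, key[keep])
      rnd <- rbind(rnd, cand[keep, , drop = FALSE])
    }
    tri <- rbind(tri, rnd)
  }
  list(kg = knowledge_graph(tri), truth = truth, risk_codes = risk,
       neutral_codes = neutral, drug_codes = drugs, disease = disease)
}

#' Simulate a labeled EHR cohort driven by the knowledge graph
#'
#' Each patient has a latent severity ~ N(0,1); visit counts are Poisson,
#' visit times accumulate exponential day gaps, and each drawn code is a
#' risk code or a drug with severity-linked probability (otherwise a
#' uniform neutral code).  The generating logit is
#' beta0 + beta_code * (#risk events)
#'       + lambda * sum over risk events of their `causes` edge weights
#'       + drug_effect * (#drug events),
#' the label is Bernoulli(sigmoid(logit)) with optional flip noise, and
#' demographics are sampled independently.
#'
#' @param sim Result of [simulate_kg()].
#' @param cfg The same [sim_config].
#' @return List with `cohort` (an `ehr_cohort`) and `truth` (per-patient
#'   generating logits, risk/drug event counts, plus the config and the
#'   edge-weight table).
#' @export
simulate_cohort <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  kgw <- setNames(sim$truth$weight, sim$truth$head)
  n <- cfg$n_patients
  patients <- vector("list", n)
  gl <- numeric(n); nrisk <- integer(n); ndrug <- integer(n)
  for (i in seq_len(n)) {
    s <- rnorm(1)
    nv <- 1 + rpois(1, cfg$visits_per_patient - 1)
    times <- cumsum(c(0, rexp(nv - 1, 1 / cfg$visit_gap_days)))
    times <- round(times, 1)
    p_risk <- plogis(cfg$risk_intercept + cfg$risk_slope * s)
    p_drug <- plogis(cfg$drug_intercept + cfg$drug_slope * s)
    codes <- character(0); cats <- character(0); tms <- numeric(0)
    for (v in seq_len(nv)) {
      nc <- 1 + rpois(1, cfg$codes_per_visit - 1)
      u <- runif(nc)
      kind <- ifelse(u < p_risk, "risk",
                     ifelse(u < p_risk + p_drug, "drug", "neutral"))
      cd <- character(nc)
      cd[kind == "risk"] <- sample(sim$risk_codes, sum(kind == "risk"),
                                   replace = TRUE)
      cd[kind == "drug"] <- sample(sim$drug_codes, sum(kind == "drug"),
                                   replace = TRUE)
      cd[kind == "neutral"] <- sample(sim$neutral_codes,
                                      sum(kind == "neutral"),
                                      replace = TRUE)
      codes <- c(codes, cd)
      cats <- c(cats, ifelse(kind == "drug", "drug", "diagnosis"))
      tms <- c(tms, rep(times[v], nc))
    }
    n_risk_ev <- sum(cats == "diagnosis" & codes %in% sim$risk_codes)
    n_drug_ev <- sum(cats == "drug")
    kg_term <- sum(kgw[codes[codes %in% sim$risk_codes]])
    logit <- cfg$beta0 + cfg$beta_code * n_risk_ev +
      cfg$lambda * kg_term + cfg$drug_effect * n_drug_ev
    lab <- rbinom(1, 1, plogis(logit))
    if (cfg$label_noise > 0 && runif(1) < cfg$label_noise) lab <- 1L - lab
    gl[i] <- logit; nrisk[i] <- n_risk_ev; ndrug[i] <- n_drug_ev
    patients[[i]] <- patient_record(
      patient_id = sprintf("P%05d", i),
      events = data.frame(code = codes, category = cats, time = tms,
                          stringsAsFactors = FALSE),
      age = round(runif(1, 40, 85)),
      sex = sample(c("M", "F"), 1),
      race = sample(c("White", "Black", "Asian", "Other"), 1,
                    prob = c(0.6, 0.2, 0.1, 0.1)),
      label = lab,
      criterion_date = max(tms))
  }
  cohort <- new_cohort(patients, holdoff_days = 0)
  truth <- list(risk_codes = sim$risk_codes, drug_codes = sim$drug_codes,
                edge_weights = sim$truth, generating_logit = gl,
                n_risk_events = nrisk, n_drug_events = ndrug,
                config = unclass(cfg))
  list(cohort = cohort, truth = truth)
}

#' Frozen worked example: tiny patient, graph and hand-set weights
#'
#' A 2-event patient, a 3-triple knowledge graph and a model whose every
#' weight is a small integer over 10, with 2-dimensional embeddings,
#' hidden state and time encoding.  Used by the exact forward and
#' attribution tests and as a checkpoint round-trip fixture.
#'
#' @return List with `patient`, `kg`, `model`.
#' @export
worked_toy <- function() {
  patient <- patient_record(
    patient_id = "toy-1",
    events = data.frame(code = c("250.0", "401.9"),
                        category = c("diagnosis", "diagnosis"),
                        time = c(0, 10)),
    age = 60, sex = "F", race = "White", label = 1L, criterion_date = 10)
  kg <- knowledge_graph(data.frame(
    head = c("250.0", "401.9", "401.9"),
    relation = c("causes", "causes", "worsens"),
    tail = c("428.0", "428.0", "250.0"),
    stringsAsFactors = FALSE))
  cfg <- dgrnn_config(embed_dim = 2, time_dim = 2, hidden_dim = 2,
                      attn_dim = 2, variant = "full", seed = 1)
  ents <- c("250.0", "401.9", "428.0")
  rels <- c("causes", "worsens")
  params <- list(
    emb_entity = matrix(c(1, 3, -2,  2, -1, 4) / 10, 3, 2,
                        dimnames = list(ents, NULL)),
    emb_relation = matrix(c(2, -1,  1, 3) / 10, 2, 2,
                          dimnames = list(rels, NULL)),
    Wx = matrix((((1:32) %% 7) - 3) / 10, 8, 4),
    Wh = matrix((((1:16) %% 5) - 2) / 10, 8, 2),
    b  = rep(c(0.1, -0.1), 4),
    Wa = matrix((((1:16) %% 4) - 1) / 10, 2, 8),
    ba = c(0.1, -0.1),
    ua = c(0.3, -0.2),
    Wo = c(0.5, -0.4),
    bo = 0.1,
    g_null = c(0, 0))
  model <- structure(
    list(config = cfg, entities = ents, relations = rels,
         categories = setNames(c("diagnosis", "diagnosis", "diagnosis"),
                               ents),
         params = params),
    class = "dgrnn_model")
  list(patient = patient, kg = kg, model = model)
}
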