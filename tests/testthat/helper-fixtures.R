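# small in-code fixtures shared across test files

write_ehr_fixture <- function(lines, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

ehr_header <- "patient_id,code,category,time,age,sex,race,label,criterion_date"

toy_records <- function() {
  read_ehr_table(write_ehr_fixture(c(
    ehr_header,
    "p1,428.0,diagnosis,5,60,F,White,1,30",
    "p1,250.0,diagnosis,0,60,F,White,1,30",
    "p2,401.9,diagnosis,0,70,M,Black,0,40",
    "p2,Rx1,drug,10,70,M,Black,0,40")))
}

# cohort of labeled records without matching, for training-level tests
tiny_sim <- function(n_patients = 40, seed = 5, ...) {
  cfg <- sim_config(n_patients = n_patients, n_entities = 40,
                    visits_per_patient = 4, codes_per_visit = 2,
                    n_risk_codes = 5, n_drugs = 3, seed = seed, ...)
  sim <- simulate_kg(cfg)
  out <- simulate_cohort(sim, cfg)
  list(cfg = cfg, sim = sim, cohort = out$cohort, truth = out$truth)
}

make_code_records <- function(counts) {
  # one patient per 3 occurrences to spread codes over patients
  rows <- unlist(lapply(names(counts), function(cd)
    rep(cd, counts[[cd]])))
  recs <- split(rows, ceiling(seq_along(rows) / 3))
  lapply(seq_along(recs), function(i)
    patient_record(paste0("c", i),
                   data.frame(code = recs[[i]], category = "diagnosis",
                              time = seq_along(recs[[i]])),
                   age = 50, sex = "F", race = "White", label = 0L,
                   criterion_date = 100))
}

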