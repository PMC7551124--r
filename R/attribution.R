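#' Decompose the predicted logit into per-event contributions
#'
#' Under a max-pooled linear head the logit decomposes exactly: each pooled
#' dimension j contributes Wo[j] * o_g[j], and that term is credited to the
#' output row that won the max for dimension j (ties went to the smallest
#' row index in the forward pass).  For the full variant, rows 2t-1 and 2t
#' both belong to event t; the credit of row 2t -- the step fed by the
#' knowledge-graph attention result -- is reported as the event's
#' knowledge-graph contribution.  The credits plus the output bias
#' reconstruct the logit to floating-point tolerance.
#'
#' @param model A [dgrnn_model] (variant `full` or `nk`; `np` has no
#'   pooling and is rejected).
#' @param events A [patient_record] or [flatten_events()] result.
#' @param kg A [knowledge_graph] or NULL.
#' @return Object of class `contribution_report`: data.frame `events` with
#'   columns `event` (index), `code` (when available), `time`,
#'   `total_contribution`, `kg_contribution`, plus fields `bias`, `logit`,
#'   `probability`.
#' @export
dgrnn_attribute <- function(model, events, kg = NULL) {
  if (model$config$variant == "np")
    stop("attribution requires max pooling; variant 'np' is unsupported")
  ev <- as_model_events(model, events)
  tr <- dgrnn_forward(model, ev, kg)
  nk <- model$config$variant == "nk"
  T_ <- length(ev$codes)
  credit <- numeric(nrow(tr$H))
  terms <- model$params$Wo * tr$o_g
  for (j in seq_along(terms))
    credit[tr$pool_argmax[j]] <- credit[tr$pool_argmax[j]] + terms[j]
  if (nk) {
    total <- credit
    kg_part <- numeric(T_)
  } else {
    total <- credit[2 * seq_len(T_) - 1] + credit[2 * seq_len(T_)]
    kg_part <- credit[2 * seq_len(T_)]
  }
  structure(list(
    events = data.frame(
      event = seq_len(T_),
      code = model$entities[ev$codes],
      time = ev$times,
      total_contribution = total,
      kg_contribution = kg_part),
    bias = model$params$bo, logit = tr$z, probability = tr$y),
    class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  cat(sprintf("<contribution_report: %d events, logit %.4f (bias %.4f), p=%.4f>\n",
              nrow(x$events), x$logit, x$bias, x$probability))
  print(head(x$events, 10))
  invisible(x)
}

# group events into visits by unique time stamps
visit_times <- function(patient) sort(unique(patient$events$time))

#' Risk trajectory over visit prefixes
#'
#' Runs the forward pass on each successive visit prefix of a patient's
#' history (visits are distinct event times): the probability at visit k is
#' the model's prediction given visits 1..k only, so the final point equals
#' the full-sequence prediction.
#'
#' @param model A [dgrnn_model].
#' @param patient A [patient_record] with at least one visit.
#' @param kg A [knowledge_graph] or NULL.
#' @return `data.frame` with columns `visit`, `time`, `probability`.
#' @export
risk_trajectory <- function(model, patient, kg = NULL) {
  stopifnot(inherits(patient, "patient_record"))
  vt <- visit_times(patient)
  if (length(vt) == 0) stop("patient has no visits")
  ev <- flatten_events(patient, model$entities)
  probs <- vapply(vt, function(tv) {
    keep <- ev$times <= tv
    dgrnn_forward(model, list(codes = ev$codes[keep],
                              times = ev$times[keep]), kg)$y
  }, numeric(1))
  data.frame(visit = seq_along(vt), time = vt, probability = probs)
}

new_whatif <- function(original, edited, edit) {
  structure(list(original = original, edited = edited, edit = edit),
            class = "whatif_result")
}

#' @export
print.whatif_result <- function(x, ...) {
  cat(sprintf("<whatif_result (%s): %d original / %d edited trajectory points>\n",
              x$edit$type, nrow(x$original), nrow(x$edited)))
  invisible(x)
}

#' What-if analysis: remove medical codes
#'
#' Recomputes the risk trajectory after deleting every occurrence of the
#' given codes from the patient's history; the original trajectory is kept
#' for comparison.  Codes absent from the patient are ignored with a
#' warning; an edit that empties the history is an error.
#'
#' @param model A [dgrnn_model].
#' @param patient A [patient_record].
#' @param kg A [knowledge_graph] or NULL.
#' @param codes_to_remove Character vector of codes to delete.
#' @return A `whatif_result` with `original` and `edited` trajectories.
#' @export
whatif_remove <- function(model, patient, kg = NULL, codes_to_remove) {
  stopifnot(inherits(patient, "patient_record"))
  absent <- setdiff(codes_to_remove, patient$events$code)
  if (length(absent))
    warning("codes not present in patient history, ignored: ",
            paste(absent, collapse = ", "))
  edited <- patient
  keep <- !(edited$events$code %in% codes_to_remove)
  if (!any(keep)) stop("removal would empty the event sequence")
  edited$events <- edited$events[keep, , drop = FALSE]
  rownames(edited$events) <- NULL
  new_whatif(risk_trajectory(model, patient, kg),
             risk_trajectory(model, edited, kg),
             list(type = "remove", codes = codes_to_remove))
}

#' What-if analysis: add a drug at a visit
#'
#' Inserts one event with `drug_code` at the time stamp of the chosen
#' visit (sorted after existing same-time events with smaller code ids, per
#' the deterministic tie-break) and recomputes the trajectory.  Earlier
#' prefixes exclude the new event, so trajectory points before the visit
#' are unchanged.
#'
#' @param model A [dgrnn_model].
#' @param patient A [patient_record].
#' @param kg A [knowledge_graph] or NULL.
#' @param visit_index 1-based index into the patient's visits.
#' @param drug_code Code to insert; must be in the model vocabulary.
#' @return A `whatif_result`.
#' @export
whatif_add <- function(model, patient, kg = NULL, visit_index, drug_code) {
  stopifnot(inherits(patient, "patient_record"))
  vt <- visit_times(patient)
  if (visit_index < 1 || visit_index > length(vt))
    stop(sprintf("visit_index %d out of range 1..%d", visit_index,
                 length(vt)))
  if (!drug_code %in% model$entities)
    stop("drug code not in model vocabulary: ", drug_code)
  edited <- patient
  edited$events <- rbind(edited$events,
                         data.frame(code = drug_code, category = "drug",
                                    time = vt[visit_index]))
  ord <- order(edited$events$time, edited$events$code)
  edited$events <- edited$events[ord, , drop = FALSE]
  rownames(edited$events) <- NULL
  new_whatif(risk_trajectory(model, patient, kg),
             risk_trajectory(model, edited, kg),
             list(type = "add", drug = drug_code,
                  visit_index = visit_index))
}

#' JSON payload for the patient history view
#'
#' Bundles, for one patient, the per-event contributions (x = visit index,
#' y = total contribution, colour = knowledge-graph contribution), the
#' per-visit contribution sums, and the risk-trajectory line series.
#'
#' @inheritParams risk_trajectory
#' @return List serializable with `jsonlite::write_json`.
#' @export
history_payload <- function(model, patient, kg = NULL) {
  rep_ <- dgrnn_attribute(model, patient, kg)
  traj <- risk_trajectory(model, patient, kg)
  vt <- visit_times(patient)
  visit_of <- match(rep_$events$time, vt)
  per_visit <- vapply(seq_along(vt), function(v)
    sum(rep_$events$total_contribution[visit_of == v]), numeric(1))
  list(patient_id = patient$patient_id, label = patient$label,
       logit = rep_$logit, probability = rep_$probability,
       codes = data.frame(visit = visit_of, code = rep_$events$code,
                          total_contribution = rep_$events$total_contribution,
                          kg_contribution = rep_$events$kg_contribution),
       visits = data.frame(visit = seq_along(vt), time = vt,
                           contribution = per_visit),
       trajectory = traj)
}
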