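# Greedy autoregressive inference and conversion to SP calls.

#' Greedy autoregressive decoding for one sequence
#'
#' Decodes exactly `length(seq)` steps (capped at the window `N`): step `k`
#' conditions on the previously emitted argmax labels (BOS alone at step 1)
#' and the encoder memory. No stop token exists in the 8-class output, so
#' the output length always matches the input by construction. Argmax ties
#' break to the lowest label id. Inference is deterministic (no sampling,
#' no dropout).
#'
#' @param seq Amino-acid sequence (character scalar) or an [sp_record()].
#' @param group One of [organism_groups()] (ignored when `seq` is a
#'   record, which carries its own).
#' @param params,cfg Model parameters and configuration.
#' @return List of class `sp_prediction`: `labels` (character, length =
#'   min(length(seq), N)), `probs` (rows of per-position probabilities),
#'   `chosen_prob` (probability of each emitted label), `truncated` flag.
#' @export
greedy_decode <- function(seq, group = "eukarya", params, cfg) {
  if (inherits(seq, "sp_record")) {
    group <- seq$group
    seq <- seq$seq
  }
  out <- predict_batch(list(sp_record("q", seq, group = group)), params, cfg)
  out[[1]]$prediction
}

#' Batch prediction: greedy decode + SP call extraction
#'
#' Per record: greedy decoding, then the SP-type/cleavage-site rule
#' ([extract_sp_call()]). Batch results equal per-record results (there is
#' no cross-sequence coupling at inference). Records longer than the
#' window are truncated to the first `N` residues and flagged.
#'
#' @param records List of [sp_record()] (labels not required).
#' @param params,cfg Model parameters and configuration.
#' @return List of lists with elements `record`, `prediction`
#'   (`sp_prediction`) and `call` (`sp_call`).
#' @export
predict_batch <- function(records, params, cfg) {
  if (length(records) == 0L) return(list())
  batch <- prep_batch(records, cfg, need_labels = FALSE)
  res <- cpp_greedy_decode(batch$tokens, batch$n_real, batch$groups, params, cfg)
  lapply(seq_along(records), function(b) {
    nr <- batch$n_real[b]
    ids <- res$labels[b, seq_len(nr)]
    labels <- all_labels()[ids]
    probs <- res$probs[[b]]
    pred <- structure(list(
      labels = labels,
      probs = probs,
      chosen_prob = probs[cbind(seq_len(nr), ids)],
      truncated = batch$truncated[b]), class = "sp_prediction")
    call <- extract_sp_call(labels, probs = probs)
    if (batch$truncated[b]) call$flags <- c(call$flags, "truncated")
    list(record = records[[b]], prediction = pred, call = call)
  })
}

#' @export
print.sp_prediction <- function(x, ...) {
  cat(sprintf("<sp_prediction | %d positions%s>\n", length(x$labels),
              if (x$truncated) " | truncated" else ""))
  invisible(x)
}
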