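# Gradient-based input importance: how much the predicted SP-type (or
# cleavage-site) probability would change for slight changes in the input,
# measured as gradients with respect to the initial (non-contextualized)
# residue embeddings E0, then motif-aligned averaging across sequences.

#' Per-residue input-importance profile
#'
#' Greedy-decodes the record, then takes the gradient of a scalar
#' objective with respect to the rows of the initial embedding `E0`: for
#' `target = "type"` the objective is the predicted probability of the
#' position-1 label; for `target = "cs"` the probability of the emitted
#' label at the predicted cleavage-site position. The decoder is
#' conditioned on the model's own predicted labels. The gradient over the
#' `d` embedding dimensions of each residue is reduced to one non-negative
#' score per residue: mean absolute component by default, L2 norm behind
#' `reduce = "l2"`.
#'
#' @param record An [sp_record()].
#' @param params,cfg Model parameters and configuration.
#' @param target `"type"` or `"cs"`.
#' @param reduce `"absmean"` (default) or `"l2"`.
#' @param prediction Optional precomputed [greedy_decode()] result.
#' @return Object of class `sp_importance`: `scores` (length = decoded
#'   length), `target`, `call`, `record`.
#' @export
importance <- function(record, params, cfg, target = c("type", "cs"),
                       reduce = c("absmean", "l2"), prediction = NULL) {
  target <- match.arg(target)
  reduce <- match.arg(reduce)
  if (is.null(prediction)) prediction <- greedy_decode(record, params = params, cfg = cfg)
  call <- extract_sp_call(prediction$labels, probs = prediction$probs)
  if (target == "cs") {
    if (call$sp_type == "NO_SP" || is.na(call$cs_index)) {
      stop("record ", record$id, ": cleavage-site target needs a positive SP call")
    }
    pos <- call$cs_index
    lab <- label_id(prediction$labels[pos])
  } else {
    pos <- 1L
    lab <- label_id(prediction$labels[1L])
  }
  tok <- aa_tokenize(record$seq, cfg$N)
  n_real <- attr(tok, "n_real")
  lin <- shifted_label_input(prediction$labels, cfg$N)
  g <- cpp_input_grad(as.integer(tok), n_real, group_id(record$group), lin,
                      as.integer(pos), as.integer(lab), params, cfg)
  g <- g[seq_len(n_real), , drop = FALSE]
  scores <- if (reduce == "absmean") rowMeans(abs(g)) else sqrt(rowSums(g * g))
  structure(list(scores = scores, target = target, call = call,
                 record = record), class = "sp_importance")
}

#' Anchor positions for motif-aligned averaging
#'
#' `anchor_rr` returns the position of the first exact "RR" dipeptide
#' within the called SP region (twin-arginine motif); `anchor_cys` returns
#' the called cleavage-site index, i.e. the first mature residue (the Cys
#' position for SPase II substrates). `NA` when absent.
#'
#' @param profile An [importance()] profile (uses its record and call).
#' @return Integer position or `NA`.
#' @export
anchor_rr <- function(profile) {
  call <- profile$call
  if (call$sp_type == "NO_SP") return(NA_integer_)
  sp_end <- if (!is.na(call$cs_index)) call$cs_index - 1L else length(profile$scores)
  sp_seq <- substr(profile$record$seq, 1L, sp_end)
  hit <- regexpr("RR", sp_seq, fixed = TRUE)
  if (hit < 0) NA_integer_ else as.integer(hit)
}

#' @rdname anchor_rr
#' @export
anchor_cys <- function(profile) {
  call <- profile$call
  if (call$sp_type == "NO_SP" || is.na(call$cs_index)) return(NA_integer_)
  call$cs_index
}

#' Align importance profiles on anchors and average
#'
#' Shifts every profile so its anchor sits at offset 0 and averages the
#' scores per relative offset; the per-offset count of contributing
#' sequences is reported alongside. Profiles lacking their anchor are
#' excluded with a warning. Each profile is normalized by its own maximum
#' before averaging (relative importance) unless `normalize = "none"`.
#'
#' @param profiles List of [importance()] profiles.
#' @param anchors Integer anchor positions (e.g. from [anchor_rr()] /
#'   [anchor_cys()]), one per profile; `NA` excludes the profile.
#' @param normalize `"profile_max"` (default) or `"none"`.
#' @return Object of class `sp_aligned`: data.frame with `offset`, `mean`
#'   and `count` (count >= 1 wherever a mean is reported).
#' @export
align_and_average <- function(profiles, anchors,
                              normalize = c("profile_max", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(length(profiles) == length(anchors))
  drop <- is.na(anchors)
  if (any(drop)) {
    warning(sum(drop), " profile(s) lack their anchor motif and were excluded")
    profiles <- profiles[!drop]; anchors <- anchors[!drop]
  }
  if (!length(profiles)) stop("no profiles with anchors to align")
  offsets <- unlist(lapply(seq_along(profiles), function(i) {
    seq_along(profiles[[i]]$scores) - anchors[[i]]
  }))
  vals <- unlist(lapply(profiles, function(p) {
    s <- p$scores
    if (normalize == "profile_max" && max(s) > 0) s <- s / max(s)
    s
  }))
  agg_mean <- tapply(vals, offsets, mean)
  agg_n <- tapply(vals, offsets, length)
  off <- as.integer(names(agg_mean))
  o <- order(off)
  structure(data.frame(offset = off[o], mean = as.numeric(agg_mean)[o],
                       count = as.integer(agg_n)[o]),
            class = c("sp_aligned", "data.frame"))
}
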