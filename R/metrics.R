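# Evaluation suite: tolerance-windowed cleavage-site precision/recall/F1,
# Matthews correlation with two negative-pool definitions, weighted
# summaries, expected calibration error, learning-curve harness.

truth_call <- function(rec) {
  if (is.null(rec$labels)) stop("truth record ", rec$id, " has no labels")
  extract_sp_call(rec$labels)
}

as_call_list <- function(calls) {
  lapply(calls, function(x) {
    if (inherits(x, "sp_call")) list(call = x, id = NULL)
    else if (!is.null(x$call)) list(call = x$call, id = x$record$id)
    else stop("calls must be sp_call objects or predict_batch() elements")
  })
}

#' Score cleavage-site predictions into a confusion ledger
#'
#' Per evaluated record with true SP type `t` and annotated cleavage site
#' `ic`: a call of type `t` with predicted site `ip` within `|ip - ic| <=
#' tol` is a true positive at that tolerance; a call of type `t` outside
#' the window counts as both FP(t) and FN(t); a call of a different SP type
#' `t'` counts as FP(t') and FN(t) at every tolerance; a NO_SP call counts
#' as FN(t). For records without an SP, an SP call of type `t'` is FP(t');
#' a NO_SP call adds nothing to the CS ledger. The ledger also carries
#' type-level binary confusion counts for the two MCC variants: MCC1
#' restricts negatives to records without an SP (soluble and TM proteins),
#' MCC2 additionally counts other SP types as negatives.
#'
#' @param truth List of labeled [sp_record()].
#' @param calls List of [extract_sp_call()] results (or [predict_batch()]
#'   output), one per truth record, same order; ids are checked when
#'   available.
#' @param tolerances Integer tolerances (default 0:3).
#' @return Object of class `sp_ledger`: data.frames `cs` (type, group,
#'   tol, tp, fp, fn), `det` (type, group, variant, tp, tn, fp, fn) and
#'   `n_pos` (positive-record counts per type and group, used as weights).
#' @export
score_cs <- function(truth, calls, tolerances = 0:3) {
  calls <- as_call_list(calls)
  if (length(truth) != length(calls)) stop("one call per record required")
  for (i in seq_along(truth)) {
    if (!is.null(calls[[i]]$id) && !identical(calls[[i]]$id, truth[[i]]$id)) {
      stop("id mismatch at position ", i, ": ", truth[[i]]$id, " vs ", calls[[i]]$id)
    }
  }
  types <- sp_labels(); groups <- organism_groups()
  key <- function(t, g) paste(t, g, sep = "\r")
  cs_tp <- cs_fp <- cs_fn <- array(0L, dim = c(length(types), length(groups), length(tolerances)),
                                   dimnames = list(types, groups, as.character(tolerances)))
  det <- array(0L, dim = c(length(types), length(groups), 2L, 4L),
               dimnames = list(types, groups, c("mcc1", "mcc2"),
                               c("tp", "tn", "fp", "fn")))
  n_pos <- matrix(0L, length(types), length(groups), dimnames = list(types, groups))

  for (i in seq_along(truth)) {
    rec <- truth[[i]]
    tc <- truth_call(rec)
    pc <- calls[[i]]$call
    g <- rec$group
    t_true <- tc$sp_type; ic <- tc$cs_index
    t_pred <- pc$sp_type; ip <- pc$cs_index
    if (t_true != "NO_SP") n_pos[t_true, g] <- n_pos[t_true, g] + 1L
    # cleavage-site ledger
    for (j in seq_along(tolerances)) {
      tol <- tolerances[j]
      if (t_true != "NO_SP") {
        if (t_pred == "NO_SP") {
          cs_fn[t_true, g, j] <- cs_fn[t_true, g, j] + 1L
        } else if (t_pred == t_true) {
          hit <- !is.na(ip) && !is.na(ic) && abs(ip - ic) <= tol
          if (hit) cs_tp[t_true, g, j] <- cs_tp[t_true, g, j] + 1L
          else {
            cs_fp[t_true, g, j] <- cs_fp[t_true, g, j] + 1L
            cs_fn[t_true, g, j] <- cs_fn[t_true, g, j] + 1L
          }
        } else {
          cs_fp[t_pred, g, j] <- cs_fp[t_pred, g, j] + 1L
          cs_fn[t_true, g, j] <- cs_fn[t_true, g, j] + 1L
        }
      } else if (t_pred != "NO_SP") {
        cs_fp[t_pred, g, j] <- cs_fp[t_pred, g, j] + 1L
      }
    }
    # type-level detection ledger for MCC
    for (t in types) {
      pos <- identical(t_true, t)
      called <- identical(t_pred, t)
      in1 <- pos || t_true == "NO_SP"
      for (v in 1:2) {
        if (v == 1L && !in1) next
        slot <- if (pos && called) "tp" else if (pos) "fn" else if (called) "fp" else "tn"
        det[t, g, v, slot] <- det[t, g, v, slot] + 1L
      }
    }
  }
  cs <- expand.grid(type = types, group = groups, tol = tolerances,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cs$tp <- as.vector(cs_tp); cs$fp <- as.vector(cs_fp); cs$fn <- as.vector(cs_fn)
  detdf <- expand.grid(type = types, group = groups, variant = c("mcc1", "mcc2"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  detdf$tp <- as.vector(det[, , , "tp"]); detdf$tn <- as.vector(det[, , , "tn"])
  detdf$fp <- as.vector(det[, , , "fp"]); detdf$fn <- as.vector(det[, , , "fn"])
  structure(list(cs = cs, det = detdf, n_pos = n_pos), class = "sp_ledger")
}

mcc_formula <- function(tp, tn, fp, fn) {
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  num <- tp * tn - fp * fn
  ifelse(den == 0, 0, num / den)
}

#' Matthews correlation per SP type and organism group
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; a zero
#' denominator yields 0 with a flag. Variant 1 restricts the negative pool
#' to records without an SP; variant 2 additionally includes other SP
#' types.
#'
#' @param ledger An [score_cs()] ledger.
#' @param variant 1 or 2.
#' @return data.frame type, group, mcc, n (pool size), zero_denominator.
#' @export
mcc <- function(ledger, variant = 2L) {
  v <- paste0("mcc", variant)
  d <- ledger$det[ledger$det$variant == v, , drop = FALSE]
  den0 <- (d$tp + d$fp) == 0 | (d$tp + d$fn) == 0 | (d$tn + d$fp) == 0 | (d$tn + d$fn) == 0
  data.frame(type = d$type, group = d$group,
             mcc = mcc_formula(d$tp, d$tn, d$fp, d$fn),
             n = d$tp + d$tn + d$fp + d$fn,
             zero_denominator = den0,
             stringsAsFactors = FALSE)
}

#' Summarize a ledger into a metrics report
#'
#' Per (type, group, tolerance) cell: precision, recall and their harmonic
#' mean F1. Cells with no positive truth and no positive calls are
#' undefined; they are excluded from averages and flagged. The average F1
#' is the unweighted mean over populated cells; the weighted F1 weights
#' each populated (type, group) cell by its occurrence count in the
#' evaluated set. Weighted MCC1/MCC2 use the same weights.
#'
#' @param ledger An [score_cs()] ledger.
#' @return Object of class `sp_metrics` with `cells` (per-cell data.frame),
#'   `mcc` (both variants), and `summary` (average/weighted F1 per
#'   tolerance, weighted MCC1/MCC2).
#' @export
summarize_metrics <- function(ledger) {
  cells <- ledger$cs
  cells$populated <- (cells$tp + cells$fp + cells$fn) > 0L
  cells$precision <- ifelse(cells$tp + cells$fp > 0, cells$tp / (cells$tp + cells$fp), NA_real_)
  cells$recall <- ifelse(cells$tp + cells$fn > 0, cells$tp / (cells$tp + cells$fn), NA_real_)
  pr <- ifelse(is.na(cells$precision), 0, cells$precision)
  rc <- ifelse(is.na(cells$recall), 0, cells$recall)
  cells$f1 <- ifelse(cells$populated, ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0), NA_real_)
  cells$weight <- ledger$n_pos[cbind(cells$type, cells$group)]

  per_tol <- lapply(split(cells, cells$tol), function(d) {
    p <- d[d$populated & d$weight > 0, , drop = FALSE]
    data.frame(tol = d$tol[1],
               average_f1 = if (nrow(p)) mean(p$f1) else NA_real_,
               weighted_f1 = if (nrow(p)) sum(p$f1 * p$weight) / sum(p$weight) else NA_real_)
  })
  summ <- do.call(rbind, per_tol)
  rownames(summ) <- NULL

  m1 <- mcc(ledger, 1L); m2 <- mcc(ledger, 2L)
  w <- ledger$n_pos[cbind(m1$type, m1$group)]
  keep <- w > 0
  weighted_mcc <- function(m) sum(m$mcc[keep] * w[keep]) / sum(w[keep])
  structure(list(
    cells = cells,
    mcc = rbind(cbind(m1, variant = "mcc1"), cbind(m2, variant = "mcc2")),
    summary = list(f1 = summ,
                   weighted_mcc1 = weighted_mcc(m1),
                   weighted_mcc2 = weighted_mcc(m2),
                   excluded_cells = sum(!cells$populated))),
    class = "sp_metrics")
}

#' @export
print.sp_metrics <- function(x, ...) {
  cat("Cleavage-site prediction summary (over populated cells):\n")
  print(x$summary$f1, row.names = FALSE)
  cat(sprintf("Weighted MCC1 %.4f | weighted MCC2 %.4f | %d empty cells excluded\n",
              x$summary$weighted_mcc1, x$summary$weighted_mcc2,
              x$summary$excluded_cells))
  invisible(x)
}

#' Expected calibration error
#'
#' Equal-width confidence bins (default 10); `ECE = sum_b (n_b/n) *
#' |accuracy_b - mean confidence_b|`.
#'
#' @param confidences Numeric in \[0,1\].
#' @param correct Logical (or 0/1) correctness flags.
#' @param bins Number of equal-width bins.
#' @return Scalar ECE with attribute `bins` (per-bin data.frame).
#' @export
ece <- function(confidences, correct, bins = 10L) {
  if (length(confidences) == 0L) stop("empty input")
  stopifnot(length(confidences) == length(correct),
            all(confidences >= 0 & confidences <= 1))
  correct <- as.logical(correct)
  b <- pmin(pmax(ceiling(confidences * bins), 1L), bins)
  n <- length(confidences)
  tab <- lapply(seq_len(bins), function(i) {
    sel <- b == i
    if (!any(sel)) return(data.frame(bin = i, n = 0L, accuracy = NA_real_,
                                     confidence = NA_real_))
    data.frame(bin = i, n = sum(sel), accuracy = mean(correct[sel]),
               confidence = mean(confidences[sel]))
  })
  tab <- do.call(rbind, tab)
  nz <- tab$n > 0
  out <- sum(tab$n[nz] / n * abs(tab$accuracy[nz] - tab$confidence[nz]))
  attr(out, "bins") <- tab
  out
}

#' Confidence/correctness pairs for calibration analysis
#'
#' Correctness means: SP type correct and cleavage site within `tol`
#' (records without an SP are correct when called NO_SP). Confidence is
#' the call's confidence scalar.
#'
#' @param truth Labeled records.
#' @param calls Matching calls.
#' @param tol Tolerance used for the correctness definition (default 0).
#' @return data.frame with `confidence` and `correct`.
#' @export
calibration_data <- function(truth, calls, tol = 0L) {
  calls <- as_call_list(calls)
  out <- lapply(seq_along(truth), function(i) {
    tc <- truth_call(truth[[i]])
    pc <- calls[[i]]$call
    correct <- if (tc$sp_type == "NO_SP") pc$sp_type == "NO_SP" else {
      pc$sp_type == tc$sp_type && !is.na(pc$cs_index) && !is.na(tc$cs_index) &&
        abs(pc$cs_index - tc$cs_index) <= tol
    }
    data.frame(confidence = pc$confidence, correct = correct)
  })
  do.call(rbind, out)
}

#' Learning-curve harness
#'
#' Subsamples the training pool without replacement at each fraction,
#' trains a fresh model, and evaluates the overall cleavage-site F1 on a
#' fixed evaluation fold; repeats give a mean and normal-approximation 95%
#' interval.
#'
#' @param pool Labeled training records.
#' @param eval_records Labeled evaluation records, disjoint from `pool`.
#' @param fractions Training-set fractions (default 0.25, 0.5, 0.75, 1).
#' @param repeats Repetitions per fraction.
#' @param seed Base seed; repeat `r` at any fraction uses `seed + r`.
#' @param cfg,tcfg Model / training configuration for each fit.
#' @param tol Cleavage-site tolerance for the evaluated F1.
#' @return data.frame fraction, rep, n_train, f1, with attribute `summary`
#'   (per-fraction mean, lower, upper).
#' @export
learning_curve <- function(pool, eval_records,
                           fractions = c(0.25, 0.5, 0.75, 1.0),
                           repeats = 5L, seed = 1L,
                           cfg = model_config(), tcfg = train_config(compact = TRUE),
                           tol = 0L) {
  rows <- list()
  pool_cls <- vapply(pool, function(p) truth_call(p)$sp_type, "")
  for (fr in fractions) {
    n_take <- max(1L, round(fr * length(pool)))
    for (r in seq_len(repeats)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed + r)
      idx <- if (n_take >= length(pool)) seq_along(pool) else
        sample.int(length(pool), n_take)
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
      tc <- tcfg; tc$seed <- as.integer(seed + r)
      f <- fit(pool[idx], val_records = NULL, cfg = cfg, tcfg = tc, verbose = FALSE)
      preds <- predict_batch(eval_records, f$swa_params, cfg)
      f1 <- overall_cs_f1(eval_records, lapply(preds, `[[`, "call"), tol = tol)
      if (length(unique(pool_cls[idx])) < length(unique(pool_cls))) {
        warning(sprintf("fraction %.2f rep %d: some classes absent from subsample", fr, r))
      }
      rows[[length(rows) + 1L]] <- data.frame(fraction = fr, rep = r,
                                              n_train = n_take, f1 = f1)
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$fraction), function(d) {
    m <- mean(d$f1)
    half <- if (nrow(d) > 1) 1.96 * sd(d$f1) / sqrt(nrow(d)) else 0
    data.frame(fraction = d$fraction[1], mean_f1 = m, lower = m - half, upper = m + half)
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}
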