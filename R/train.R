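# Teacher-forced training: mean per-position cross-entropy over non-PAD
# positions, Adam with constant per-component learning rates, stochastic
# weight averaging updated once per epoch.

# Adam on a single flattened parameter vector (the per-step list
# bookkeeping dominates otherwise at small batch sizes).
adam_state <- function(params, lr_by_param) {
  sizes <- vapply(params, length, 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  n <- sum(sizes)
  list(m = numeric(n), v = numeric(n), t = 0L,
       names = names(params), starts = starts, ends = ends,
       dims = lapply(params, dim),
       lr = rep(unlist(lr_by_param[names(params)]), sizes))
}

flatten_params <- function(params, state) {
  unlist(params[state$names], use.names = FALSE)
}

relist_params <- function(flat, state, template) {
  out <- template
  for (i in seq_along(state$names)) {
    v <- flat[state$starts[i]:state$ends[i]]
    d <- state$dims[[i]]
    out[[state$names[i]]] <- if (is.null(d)) v else matrix(v, d[1], d[2])
  }
  out
}

adam_update <- function(params, grads, state,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  g <- unlist(grads[state$names], use.names = FALSE)
  flat <- flatten_params(params, state)
  cpp_adam_step(flat, g, state$m, state$v, state$lr, state$t, beta1, beta2, eps)
  list(params = relist_params(flat, state, params), state = state)
}

#' One teacher-forced training step
#'
#' Computes the batch loss (mean cross-entropy over non-PAD positions
#' against the 8-label targets, decoder conditioned on gold previous labels
#' shifted right with BOS) and applies one Adam update with the constant
#' per-component learning rates.
#'
#' @param records Batch of labeled [sp_record()].
#' @param params Model parameters ([init_params()]).
#' @param cfg Model configuration.
#' @param tcfg An [train_config()].
#' @param opt Optimizer state (from a previous call, or `NULL` to start).
#' @param dropout_seed Integer seed for this step's dropout draws.
#' @return List with `loss`, updated `params` and `opt`.
#' @export
training_step <- function(records, params, cfg, tcfg = train_config(),
                          opt = NULL, dropout_seed = 0L) {
  batch <- prep_batch(records, cfg, need_labels = TRUE)
  res <- cpp_loss_grad(batch$tokens, batch$n_real, batch$groups,
                       batch$labels_in, batch$targets, params, cfg,
                       want_grads = TRUE, train_mode = TRUE,
                       dropout_seed = as.integer(dropout_seed),
                       class_weights = tcfg$class_weights)
  if (is.null(opt)) {
    lr <- ifelse(param_component(names(params)) == "encoder",
                 tcfg$lr_encoder, tcfg$lr_decoder)
    names(lr) <- names(params)
    opt <- adam_state(params, as.list(lr))
  }
  upd <- adam_update(params, res$grads, opt,
                     beta1 = tcfg$adam_beta1, beta2 = tcfg$adam_beta2)
  list(loss = res$loss, params = structure(upd$params, class = "sp_params", cfg = cfg),
       opt = upd$state)
}

#' Evaluation loss (teacher-forced, no dropout)
#'
#' @inheritParams training_step
#' @return Scalar mean cross-entropy.
#' @export
eval_loss <- function(records, params, cfg, tcfg = train_config()) {
  batch <- prep_batch(records, cfg, need_labels = TRUE)
  res <- cpp_loss_grad(batch$tokens, batch$n_real, batch$groups,
                       batch$labels_in, batch$targets, params, cfg,
                       want_grads = FALSE, train_mode = FALSE, dropout_seed = 0L,
                       class_weights = tcfg$class_weights)
  res$loss
}

#' Update a stochastic-weight-averaging state
#'
#' Maintains the exact arithmetic running mean of all trainable parameter
#' snapshots; called once per epoch end.
#'
#' @param state SWA state (`NULL` to start) with elements `mean` and `count`.
#' @param params Current parameter snapshot.
#' @return Updated state.
#' @export
swa_update <- function(state, params) {
  if (is.null(state)) return(list(mean = params, count = 1L))
  if (!identical(names(state$mean), names(params))) stop("parameter shape mismatch")
  k <- state$count + 1L
  state$mean <- mapply(function(m, p) {
    if (!identical(dim(m), dim(p)) || length(m) != length(p)) stop("parameter shape mismatch")
    m + (p - m) / k
  }, state$mean, params, SIMPLIFY = FALSE)
  state$count <- k
  state
}

overall_cs_f1 <- function(truth, calls, tol = 0L) {
  led <- score_cs(truth, calls)
  cells <- led$cs[led$cs$tol == tol, , drop = FALSE]
  tp <- sum(cells$tp); fp <- sum(cells$fp); fn <- sum(cells$fn)
  if (tp + fp + fn == 0) return(NA_real_)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' Train the model
#'
#' Teacher-forced training with Adam at constant per-component learning
#' rates and stochastic weight averaging updated after every epoch.
#' Deterministic given `tcfg$seed` (init, shuffling and dropout all derive
#' from it).
#'
#' @param train_records Labeled training records.
#' @param val_records Labeled validation records (may be `NULL`; the
#'   per-epoch validation CS-F1 column is then `NA`).
#' @param cfg Model configuration.
#' @param tcfg Training configuration.
#' @param verbose Print per-epoch progress to stderr.
#' @return List of class `sp_fit`: `params` (last epoch), `swa_params`
#'   (SWA mean; equals `params` when SWA is disabled), `best_params`
#'   (parameters of the epoch with the highest validation CS-F1; equals
#'   `params` when no validation records are given), `best_epoch`, `cfg`,
#'   `tcfg`, and `log` (data.frame epoch/loss/val_cs_f1).
#' @export
fit <- function(train_records, val_records = NULL, cfg = model_config(),
                tcfg = train_config(), verbose = TRUE) {
  if (length(train_records) == 0L) stop("empty training set")
  params <- init_params(cfg, seed = tcfg$seed)
  opt <- NULL
  swa <- NULL
  log <- data.frame(epoch = integer(), loss = numeric(), val_cs_f1 = numeric())
  best_val <- -Inf; since_best <- 0L
  best_params <- NULL; best_epoch <- NA_integer_
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(tcfg$seed)
  val_sub <- NULL
  if (!is.null(val_records) && length(val_records)) {
    val_sub <- val_records[seq_len(min(length(val_records), tcfg$val_max))]
  }
  for (epoch in seq_len(tcfg$epochs)) {
    idx <- sample.int(length(train_records))
    starts <- seq(1L, length(idx), by = tcfg$batch_size)
    ep_loss <- 0; ep_n <- 0
    for (s in seq_along(starts)) {
      take <- idx[starts[s]:min(starts[s] + tcfg$batch_size - 1L, length(idx))]
      step <- training_step(train_records[take], params, cfg, tcfg, opt,
                            dropout_seed = (tcfg$seed %% 10007L) * 100003L +
                              epoch * 1000L + s)
      params <- step$params; opt <- step$opt
      ep_loss <- ep_loss + step$loss * length(take)
      ep_n <- ep_n + length(take)
    }
    if (tcfg$swa_enabled) swa <- swa_update(swa, params)
    val_f1 <- NA_real_
    if (!is.null(val_sub)) {
      preds <- predict_batch(val_sub, params, cfg)
      val_f1 <- overall_cs_f1(val_sub, lapply(preds, `[[`, "call"))
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = ep_loss / ep_n,
                                 val_cs_f1 = val_f1))
    if (verbose) {
      message(sprintf("[sigpept] epoch %d/%d  loss %.4f  val CS-F1 %s",
                      epoch, tcfg$epochs, ep_loss / ep_n,
                      ifelse(is.na(val_f1), "-", sprintf("%.3f", val_f1))))
    }
    if (!is.na(val_f1)) {
      if (val_f1 > best_val + 1e-9) {
        best_val <- val_f1; since_best <- 0L
        best_params <- params; best_epoch <- epoch
      } else {
        since_best <- since_best + 1L
        if (is.finite(tcfg$patience) && since_best >= tcfg$patience) {
          if (verbose) message("[sigpept] early stop at epoch ", epoch)
          break
        }
      }
    }
  }
  swa_params <- if (tcfg$swa_enabled && !is.null(swa)) {
    structure(swa$mean, class = "sp_params", cfg = cfg)
  } else params
  if (is.null(best_params)) best_params <- params
  structure(list(params = params, swa_params = swa_params,
                 best_params = best_params, best_epoch = best_epoch,
                 cfg = cfg, tcfg = tcfg, log = log),
            class = "sp_fit")
}

#' @export
print.sp_fit <- function(x, ...) {
  cat(sprintf("<sp_fit | %d epochs | final loss %.4f | d=%d dS=%d H=%d L=%d/%d>\n",
              nrow(x$log), x$log$loss[nrow(x$log)], x$cfg$d, x$cfg$dS,
              x$cfg$H, x$cfg$L_enc, x$cfg$L_dec))
  invisible(x)
}
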