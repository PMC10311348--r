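# Shared fixtures: tiny model configurations, small grammars, and a cached
# compact-model recovery run reused by the slower suites.

tiny_cfg <- function(N = 10L, ...) {
  model_config(d = 16L, dS = 4L, H = 2L, L_enc = 1L, L_dec = 2L, ed = 32L,
               N = N, dropout = 0, ...)
}

tiny_grammar <- function(N = 24L, seq_len_range = c(16L, N), ...) {
  grammar_spec(N = N, seq_len_range = seq_len_range,
               n_region = c(2L, 4L), h_region = c(4L, 6L), c_region = c(3L, 4L),
               br_region = c(2L, 4L), tm_len_range = c(5L, 7L),
               tm_start_min = 4L, ...)
}

random_labels <- function(n) {
  # labels with the SP-block invariant: either no SP, or one SP type from
  # position 1 followed by non-SP labels
  if (runif(1) < 0.4) {
    sample(non_sp_labels(), n, replace = TRUE)
  } else {
    type <- sample(sp_labels(), 1)
    sp_len <- sample.int(max(1L, n - 2L), 1)
    c(rep(type, sp_len), sample(non_sp_labels(), n - sp_len, replace = TRUE))
  }
}

# Cached recovery run: compact model, generator defaults, 3000 training
# records (seed 1), a 300-record validation fold for epoch selection, 500
# held-out records for scoring. Trained once per test session and reused
# (training and saliency suites share it).
recovery_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- model_config()
    spec <- grammar_spec(seed = 1L)
    train <- sample_dataset(spec, 3000L, seed = 1L)
    val <- sample_dataset(spec, 300L, seed = 3L)
    heldout <- sample_dataset(spec, 500L, seed = 2L)
    tcfg <- train_config(lr_encoder = 4e-4, lr_decoder = 4e-4, epochs = 22L,
                         batch_size = 4L, seed = 1L, val_max = 300L,
                         adam_beta2 = 0.98)
    f <- fit(train, val, cfg = cfg, tcfg = tcfg, verbose = FALSE)
    params <- f$best_params
    preds <- predict_batch(heldout, params, cfg)
    cache <<- list(fit = f, params = params, cfg = cfg, spec = spec,
                   heldout = heldout, preds = preds,
                   calls = lapply(preds, `[[`, "call"))
    cache
  }
})
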