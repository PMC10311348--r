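zero_params <- function(p) {
  z <- lapply(p, function(x) x * 0)
  attributes(z) <- attributes(p)
  z
}

test_that("cross-entropy identities: uniform output gives ln 8, confident-correct gives ~0", {
  cfg <- tiny_cfg(N = 8L)
  spec <- tiny_grammar(N = 8L, seq_len_range = c(6L, 8L))
  recs <- sample_dataset(spec, 4, seed = 1)
  p0 <- zero_params(init_params(cfg, seed = 1))
  expect_equal(eval_loss(recs, p0, cfg), log(8), tolerance = 1e-9)

  # route the residue one-hot straight to the correct label with huge weight
  all_ic <- lapply(recs, function(r) {
    r$labels <- rep("intracellular", nchar(r$seq)); r
  })
  p1 <- p0
  ic <- match("intracellular", all_labels())
  p1$WO_out[(cfg$d + cfg$dS + 1):nrow(p1$WO_out), ic] <- 50
  expect_lt(eval_loss(all_ic, p1, cfg), 1e-3)
})

test_that("one optimization step decreases the loss on a toy batch", {
  cfg <- tiny_cfg(N = 16L)
  spec <- tiny_grammar(N = 16L)
  recs <- sample_dataset(spec, 2, seed = 3)
  p <- init_params(cfg, seed = 3)
  tcfg <- train_config(compact = TRUE, seed = 3)
  before <- eval_loss(recs, p, cfg)
  step <- training_step(recs, p, cfg, tcfg, dropout_seed = 1L)
  after <- eval_loss(recs, step$params, cfg)
  expect_lt(after, before)
})

test_that("training refuses unlabeled records and empty training sets", {
  cfg <- tiny_cfg()
  p <- init_params(cfg, seed = 1)
  bare <- sp_record("u", "MKWTE")
  expect_error(training_step(list(bare), p, cfg), "no labels")
  expect_error(fit(list(), cfg = cfg), "empty")
})

test_that("SWA keeps the exact arithmetic mean of snapshots", {
  cfg <- tiny_cfg()
  snaps <- lapply(1:3, function(s) init_params(cfg, seed = s))
  st <- NULL
  for (s in snaps) st <- swa_update(st, s)
  expect_equal(st$count, 3L)
  for (nm in names(snaps[[1]])) {
    manual <- (snaps[[1]][[nm]] + snaps[[2]][[nm]] + snaps[[3]][[nm]]) / 3
    expect_equal(st$mean[[nm]], manual, tolerance = 1e-6)
  }
  # single snapshot: mean equals snapshot; order does not matter
  st1 <- swa_update(NULL, snaps[[2]])
  expect_equal(st1$mean, snaps[[2]])
  stp <- NULL
  for (s in snaps[c(3, 1, 2)]) stp <- swa_update(stp, s)
  for (nm in names(snaps[[1]])) {
    expect_equal(stp$mean[[nm]], st$mean[[nm]], tolerance = 1e-9)
  }
  # shape mismatch errors
  bad <- snaps[[1]]; bad$Wa <- bad$Wa[, 1:3]
  expect_error(swa_update(st, bad), "shape mismatch")
})

test_that("fit is deterministic given the seed and honours swa_enabled = FALSE", {
  cfg <- tiny_cfg(N = 16L)
  spec <- tiny_grammar(N = 16L)
  recs <- sample_dataset(spec, 24, seed = 4)
  tcfg <- train_config(compact = TRUE, epochs = 2L, batch_size = 8L, seed = 5L)
  f1 <- fit(recs, NULL, cfg, tcfg, verbose = FALSE)
  f2 <- fit(recs, NULL, cfg, tcfg, verbose = FALSE)
  expect_equal(f1$log$loss[2], f2$log$loss[2], tolerance = 1e-6)

  tcfg$swa_enabled <- FALSE
  f3 <- fit(recs, NULL, cfg, tcfg, verbose = FALSE)
  expect_identical(f3$params, f3$swa_params)
})

test_that("checkpoints round-trip parameters, config and log", {
  cfg <- tiny_cfg(N = 16L)
  recs <- sample_dataset(tiny_grammar(N = 16L), 8, seed = 6)
  f <- fit(recs, NULL, cfg, train_config(epochs = 1L, batch_size = 8L), verbose = FALSE)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(f, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, f$params)
  expect_equal(back$cfg, f$cfg)
  expect_error(suppressWarnings(load_checkpoint(withr::local_tempfile(fileext = ".rds"))))
})
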