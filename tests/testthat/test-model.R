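test_that("sinusoidal table matches the closed form elementwise", {
  WS <- sinusoidal_pe(8L, 5L)
  expect_equal(dim(WS), c(8L, 6L))
  expect_equal(WS, ref_ws(8L, 5L), tolerance = 1e-12)
  expect_equal(WS[1, 1], sin(1), tolerance = 1e-15)
  expect_equal(WS[2, 1], cos(1), tolerance = 1e-15)
  expect_true(all(WS >= -1 & WS <= 1))
  big <- sinusoidal_pe(16L, 70L)
  expect_equal(big, ref_ws(16L, 70L), tolerance = 1e-12)
  expect_error(sinusoidal_pe(7L, 5L), "even")
})

test_that("compiled forward pass equals the independent R reference", {
  for (seed in 1:3) {
    cfg <- tiny_cfg(N = 8L)
    p <- init_params(cfg, seed = seed)
    set.seed(seed)
    n_real <- sample(3:8, 1)
    tokens <- c(sample(1:20, n_real, replace = TRUE), rep(21L, cfg$N - n_real))
    labels_in <- c(9L, sample(1:8, cfg$N, replace = TRUE))
    group <- sample(1:4, 1)
    got <- sigpept:::cpp_tf_probs(as.integer(tokens), n_real, group,
                                  as.integer(labels_in), p, cfg)
    want <- ref_forward(tokens, n_real, group, labels_in, p, cfg)
    expect_equal(got[1:n_real, ], want[1:n_real, ], tolerance = 1e-10)
    expect_equal(rowSums(got), rep(1, cfg$N), tolerance = 1e-9)
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(d = 8L, dS = 4L, H = 2L, L_enc = 1L, L_dec = 1L,
                      ed = 16L, N = 6L, dropout = 0)
  p <- init_params(cfg, seed = 42)
  spec <- tiny_grammar(N = 6L, seq_len_range = c(5L, 6L))
  recs <- sample_dataset(spec, 2, seed = 5)
  batch <- sigpept:::prep_batch(recs, cfg)
  gr <- function(pp, want_grads) {
    sigpept:::cpp_loss_grad(batch$tokens, batch$n_real, batch$groups,
                            batch$labels_in, batch$targets, pp, cfg,
                            want_grads = want_grads, train_mode = FALSE,
                            dropout_seed = 0L, class_weights = NULL)
  }
  res <- gr(p, TRUE)
  eps <- 1e-5
  set.seed(9)
  for (nm in names(p)) {
    for (i in sample(length(p[[nm]]), min(3L, length(p[[nm]])))) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- gr(pp, FALSE)$loss
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      dn <- gr(pp, FALSE)$loss
      num <- (up - dn) / (2 * eps)
      ana <- res$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("decoder is causal: future label inputs never affect earlier rows", {
  for (draw in 1:20) {
    cfg <- tiny_cfg(N = 8L)
    p <- init_params(cfg, seed = 100 + draw)
    set.seed(draw)
    tokens <- as.integer(sample(1:20, cfg$N, replace = TRUE))
    base_in <- c(9L, sample(1:8, cfg$N, replace = TRUE))
    k <- sample(2:(cfg$N - 1), 1)
    pert_in <- base_in
    pert_in[(k + 1):(cfg$N + 1)] <- sample(1:8, cfg$N + 1 - k, replace = TRUE)
    a <- sigpept:::cpp_tf_probs(tokens, cfg$N, 1L, as.integer(base_in), p, cfg)
    b <- sigpept:::cpp_tf_probs(tokens, cfg$N, 1L, as.integer(pert_in), p, cfg)
    expect_equal(a[1:k, ], b[1:k, ], tolerance = 1e-12)
  }
})

test_that("earlier label inputs do affect later rows (the causal probe detects dependence)", {
  cfg <- tiny_cfg(N = 8L)
  p <- init_params(cfg, seed = 1)
  tokens <- as.integer(rep(5L, cfg$N))
  a_in <- c(9L, rep(1L, cfg$N))
  b_in <- c(9L, 6L, rep(1L, cfg$N - 1L))   # change y1 only
  a <- sigpept:::cpp_tf_probs(tokens, cfg$N, 1L, as.integer(a_in), p, cfg)
  b <- sigpept:::cpp_tf_probs(tokens, cfg$N, 1L, as.integer(b_in), p, cfg)
  expect_equal(a[1, ], b[1, ], tolerance = 1e-12)    # row 1 sees only BOS
  expect_gt(max(abs(a[2:cfg$N, ] - b[2:cfg$N, ])), 1e-8)
})

test_that("pad positions are inert: token content beyond the sequence never matters", {
  cfg <- tiny_cfg(N = 12L)
  p <- init_params(cfg, seed = 7)
  n_real <- 5L
  set.seed(21)
  real <- sample(1:20, n_real, replace = TRUE)
  padded <- as.integer(c(real, rep(21L, cfg$N - n_real)))
  garbage <- as.integer(c(real, sample(1:20, cfg$N - n_real, replace = TRUE)))
  lin <- as.integer(c(9L, rep(3L, cfg$N)))
  a <- sigpept:::cpp_tf_probs(padded, n_real, 2L, lin, p, cfg)
  b <- sigpept:::cpp_tf_probs(garbage, n_real, 2L, lin, p, cfg)
  expect_equal(a[1:n_real, ], b[1:n_real, ], tolerance = 1e-12)

  # and through the greedy decoder
  ga <- sigpept:::cpp_greedy_decode(matrix(padded, 1), n_real, 2L, p, cfg)
  gb <- sigpept:::cpp_greedy_decode(matrix(garbage, 1), n_real, 2L, p, cfg)
  expect_identical(ga$labels[1, 1:n_real], gb$labels[1, 1:n_real])
  expect_equal(ga$probs[[1]], gb$probs[[1]], tolerance = 1e-12)
})

test_that("memory assembly appends the group column and carries the sinusoidal rows", {
  cfg <- tiny_cfg(N = 10L)
  p <- init_params(cfg, seed = 3)
  EL <- matrix(rnorm(cfg$N * cfg$d), cfg$N, cfg$d)
  M <- assemble_memory(EL, "eukarya", p, cfg)
  expect_equal(dim(M), c(cfg$N + 1L, cfg$d + cfg$dS))
  # feature columns d+1..d+dS equal the sinusoidal table exactly
  expect_equal(M[, (cfg$d + 1):(cfg$d + cfg$dS)],
               t(sinusoidal_pe(cfg$dS, cfg$N)), tolerance = 1e-12)
  M2 <- assemble_memory(EL, "archaea", p, cfg)
  diffs <- which(rowSums(abs(M[, 1:cfg$d, drop = FALSE] -
                               M2[, 1:cfg$d, drop = FALSE])) > 0)
  expect_identical(diffs, length(EL[, 1]) + 1L)  # exactly the appended position
  expect_error(assemble_memory(EL, "plants", p, cfg), "group")
})

test_that("initialization is seed-deterministic, Xavier-bounded, and WS is not trainable", {
  cfg <- tiny_cfg()
  a <- init_params(cfg, seed = 11)
  b <- init_params(cfg, seed = 11)
  expect_identical(unclass(a)[names(a)], unclass(b)[names(b)])
  w <- a$d1_sWQ
  bound <- sqrt(6 / (nrow(w) + ncol(w)))
  expect_true(all(abs(w) <= bound))
  w2 <- a$WO_out
  expect_true(all(abs(w2) <= sqrt(6 / (nrow(w2) + ncol(w2)))))
  expect_false(any(grepl("WS", names(a))))
})

test_that("model configuration enforces its divisibility invariants", {
  expect_error(model_config(d = 10L, H = 4L), "divisible")
  expect_error(model_config(dS = 15L), "even")
  expect_error(model_config(ed = 32L, d = 64L), "ed")
  full <- model_config(full_scale = TRUE)
  expect_identical(decoder_width(full), 1152L)
})
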