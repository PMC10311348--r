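test_that("a constant model yields an all-zero importance profile", {
  cfg <- tiny_cfg(N = 12L)
  p <- init_params(cfg, seed = 1)
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  rec <- sp_record("z", "MKWTECQVLSAG")
  prof <- importance(rec, p, cfg, target = "type")
  expect_length(prof$scores, 12L)
  expect_true(all(prof$scores == 0))
})

test_that("input gradients match finite differences of the target probability", {
  cfg <- tiny_cfg(N = 10L)
  p <- init_params(cfg, seed = 6)
  set.seed(6)
  for (trial in 1:5) {
    n <- sample(6:10, 1)
    seq <- paste(sample(sigpept:::AA_ALPHABET, n, replace = TRUE), collapse = "")
    rec <- sp_record(paste0("s", trial), seq, group = sample(organism_groups(), 1))
    pred <- greedy_decode(rec, params = p, cfg = cfg)
    pos <- sample(n, 1)
    lab <- match(pred$labels[pos], all_labels())
    tok <- aa_tokenize(seq, cfg$N)
    lin <- sigpept:::shifted_label_input(pred$labels, cfg$N)
    g <- sigpept:::cpp_input_grad(as.integer(tok), n, sigpept:::group_id(rec$group),
                                  lin, pos, lab, p, cfg)
    # numeric gradient for a few random E0 entries
    eps <- 1e-5
    obj <- function(e0_add) {
      pr <- sigpept:::cpp_tf_probs(as.integer(tok), n, sigpept:::group_id(rec$group),
                                   lin, p, cfg, e0_add = e0_add)
      pr[pos, lab]
    }
    num <- c(); ana <- c()
    for (probe in 1:8) {
      i <- sample(n, 1); j <- sample(cfg$d, 1)
      e0 <- matrix(0, cfg$N, cfg$d)
      e0[i, j] <- eps
      up <- obj(e0); e0[i, j] <- -eps; dn <- obj(e0)
      num <- c(num, (up - dn) / (2 * eps))
      ana <- c(ana, g[i, j])
    }
    expect_gt(cor(num, ana), 0.99)
    expect_lt(max(abs(num - ana)), 1e-5)
  }
})

test_that("cleavage-site saliency requires a positive SP call", {
  cfg <- tiny_cfg(N = 12L)
  p <- init_params(cfg, seed = 2)
  rec <- sp_record("n", "MKWTECQVLSAG")
  pred <- greedy_decode(rec, params = p, cfg = cfg)
  if (extract_sp_call(pred$labels)$sp_type == "NO_SP") {
    expect_error(importance(rec, p, cfg, target = "cs", prediction = pred),
                 "positive SP call")
  } else {
    succeed()
  }
})

test_that("aligned averaging shifts anchors to offset zero and counts overlaps", {
  mk <- function(scores) {
    structure(list(scores = scores, target = "type",
                   call = structure(list(sp_type = "TAT/SPaseI", cs_index = 5L,
                                         confidence = NA_real_, flags = character()),
                                    class = "sp_call"),
                   record = sp_record("x", strrep("A", length(scores)))),
              class = "sp_importance")
  }
  prof <- mk(c(1, 2, 3, 4))
  out <- align_and_average(list(prof, prof), c(2L, 2L), normalize = "none")
  expect_equal(out$offset, c(-1L, 0L, 1L, 2L))
  expect_equal(out$mean, c(1, 2, 3, 4))
  expect_equal(out$count, rep(2L, 4))

  # two profiles offset by one: edges carry count 1, overlap count 2
  out2 <- align_and_average(list(mk(c(1, 1, 1)), mk(c(3, 3, 3))),
                            c(1L, 2L), normalize = "none")
  expect_equal(out2$offset, c(-1L, 0L, 1L, 2L))
  expect_equal(out2$count, c(1L, 2L, 2L, 1L))
  expect_equal(out2$mean, c(3, 2, 2, 1))

  expect_warning(out3 <- align_and_average(list(prof, prof), c(2L, NA)),
                 "excluded")
  expect_equal(max(out3$count), 1L)
})

test_that("motif-aligned averages over synthetic TAT profiles equal an explicit loop", {
  cfg <- tiny_cfg(N = 24L)
  p <- init_params(cfg, seed = 8)
  w <- setNames(rep(0, 8), all_labels()); w["TAT/SPaseI"] <- 1
  recs <- sample_dataset(tiny_grammar(class_weights = w), 50, seed = 8)
  profs <- lapply(recs, importance, params = p, cfg = cfg, target = "type")
  # anchor on the true RR position (the model is untrained; anchors here come
  # from the sequence, not the call)
  anchors <- vapply(seq_along(recs), function(i) {
    cs <- attr(recs[[i]], "intended")$cs_index
    as.integer(regexpr("RR", substr(recs[[i]]$seq, 1, cs - 1), fixed = TRUE))
  }, 1L)
  out <- align_and_average(profs, anchors, normalize = "none")
  # oracle: direct index-wise accumulation
  acc <- new.env()
  for (i in seq_along(profs)) {
    for (j in seq_along(profs[[i]]$scores)) {
      off <- as.character(j - anchors[i])
      acc[[off]] <- c(acc[[off]], profs[[i]]$scores[j])
    }
  }
  for (r in seq_len(nrow(out))) {
    vals <- acc[[as.character(out$offset[r])]]
    expect_equal(out$count[r], length(vals))
    expect_equal(out$mean[r], mean(vals), tolerance = 1e-12)
  }
})
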