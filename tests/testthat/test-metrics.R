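test_that("tolerance windows and the wrong-type FP+FN rule match hand-built cases", {
  truth <- list(make_truth("Sec/SPaseI", 23L, "eukarya"))
  calls <- list(make_call("Sec/SPaseI", 24L))
  led <- score_cs(truth, calls)
  cell <- function(led, t, tol) led$cs[led$cs$type == t & led$cs$group == "eukarya" &
                                         led$cs$tol == tol, ]
  expect_equal(cell(led, "Sec/SPaseI", 0)$fp, 1L)
  expect_equal(cell(led, "Sec/SPaseI", 0)$fn, 1L)
  for (tol in 1:3) expect_equal(cell(led, "Sec/SPaseI", tol)$tp, 1L)

  # wrong SP type: FP for the predicted type, FN for the true type, all tolerances
  truth <- list(make_truth("TAT/SPaseI", 30L, "archaea"))
  calls <- list(make_call("Sec/SPaseI", 30L))
  led <- score_cs(truth, calls)
  for (tol in 0:3) {
    d <- led$cs[led$cs$group == "archaea" & led$cs$tol == tol, ]
    expect_equal(d$fp[d$type == "Sec/SPaseI"], 1L)
    expect_equal(d$fn[d$type == "TAT/SPaseI"], 1L)
    expect_equal(sum(d$tp), 0L)
  }
})

test_that("CS ledger equals the brute-force oracle on 300 randomized pairs", {
  pairs <- random_truth_call_pairs(300L, seed = 42)
  led <- score_cs(pairs$truths, pairs$calls)
  for (t in sp_labels()) for (g in organism_groups()) for (tol in 0:3) {
    expect_cell <- oracle_cell(pairs$truths, pairs$calls, t, g, tol)
    got <- led$cs[led$cs$type == t & led$cs$group == g & led$cs$tol == tol, ]
    expect_equal(c(tp = got$tp, fp = got$fp, fn = got$fn), expect_cell,
                 info = paste(t, g, tol))
  }
})

test_that("MCC closed form agrees with direct correlation of the implied binary vectors", {
  # perfect classifier
  truth <- c(rep(1, 10), rep(0, 10))
  expect_equal(sigpept:::mcc_formula(10, 10, 0, 0), 1.0)
  expect_equal(sigpept:::mcc_formula(5, 5, 5, 5), 0.0)
  tp <- 40L; tn <- 45L; fp <- 5L; fn <- 10L
  y <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  yhat <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  expect_equal(sigpept:::mcc_formula(tp, tn, fp, fn), cor(y, yhat), tolerance = 1e-12)
  # label-swap symmetry: swapping positive/negative leaves MCC unchanged
  expect_equal(sigpept:::mcc_formula(tn, tp, fn, fp),
               sigpept:::mcc_formula(tp, tn, fp, fn), tolerance = 1e-12)
  # inverting the predictions flips the sign
  expect_equal(sigpept:::mcc_formula(fn, fp, tn, tp),
               -sigpept:::mcc_formula(tp, tn, fp, fn), tolerance = 1e-12)
})

test_that("MCC variants use the two negative-pool definitions", {
  truths <- c(lapply(1:10, function(i) make_truth("Sec/SPaseI", 10L, "eukarya", id = paste0("p", i))),
              lapply(1:5, function(i) make_truth("Sec/SPaseII", 12L, "eukarya", id = paste0("l", i))),
              lapply(1:8, function(i) make_truth("NO_SP", NA, "eukarya", id = paste0("n", i))))
  calls <- c(lapply(1:10, function(i) make_call("Sec/SPaseI", 10L)),
             lapply(1:5, function(i) make_call("Sec/SPaseII", 12L)),
             lapply(1:8, function(i) make_call("NO_SP", NA)))
  led <- score_cs(truths, calls)
  d1 <- mcc(led, 1L); d2 <- mcc(led, 2L)
  n1 <- d1$n[d1$type == "Sec/SPaseI" & d1$group == "eukarya"]
  n2 <- d2$n[d2$type == "Sec/SPaseI" & d2$group == "eukarya"]
  expect_equal(n1, 18L)   # positives + no-SP negatives
  expect_equal(n2, 23L)   # ... plus the other SP class
  expect_equal(d1$mcc[d1$type == "Sec/SPaseI" & d1$group == "eukarya"], 1.0)
})

test_that("summaries use harmonic-mean F1, exclude empty cells, and weight by occurrence", {
  truths <- c(lapply(1:10, function(i) make_truth("Sec/SPaseI", 10L, "eukarya", id = paste0("a", i))),
              lapply(1:30, function(i) make_truth("Sec/SPaseII", 12L, "gn-bacteria", id = paste0("b", i))))
  # 6/10 correct in cell 1 (F1 0.6 with one-sided errors), 27/30 in cell 2
  calls <- c(lapply(1:10, function(i) make_call("Sec/SPaseI", if (i <= 6) 10L else 20L)),
             lapply(1:30, function(i) make_call("Sec/SPaseII", if (i <= 27) 12L else 25L)))
  led <- score_cs(truths, calls)
  rep <- summarize_metrics(led)
  cells <- rep$cells[rep$cells$tol == 0 & rep$cells$populated, ]
  expect_equal(nrow(cells), 2L)
  expect_true(all(abs(cells$f1 - 2 * cells$precision * cells$recall /
                        (cells$precision + cells$recall)) < 1e-12))
  expect_equal(sort(cells$f1), c(0.6, 0.9))
  summ <- rep$summary$f1
  expect_equal(summ$weighted_f1[summ$tol == 0], (0.6 * 10 + 0.9 * 30) / 40)
  expect_equal(summ$average_f1[summ$tol == 0], 0.75)
  expect_true(rep$summary$excluded_cells > 0)
})

test_that("F1 harmonic identity holds in every populated report cell on random ledgers", {
  set.seed(7)
  truths <- list(); calls <- list()
  types <- c("NO_SP", sp_labels())
  for (i in 1:200) {
    tt <- sample(types, 1)
    truths[[i]] <- make_truth(tt, sample(2:20, 1), sample(organism_groups(), 1),
                              id = paste0("x", i))
    calls[[i]] <- make_call(sample(types, 1), sample(2:20, 1))
  }
  rep <- summarize_metrics(score_cs(truths, calls))
  cells <- rep$cells[rep$cells$populated, ]
  pr <- ifelse(is.na(cells$precision), 0, cells$precision)
  rc <- ifelse(is.na(cells$recall), 0, cells$recall)
  f1 <- ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)
  expect_equal(cells$f1, f1)
})

test_that("expected calibration error matches its definition", {
  expect_equal(as.numeric(ece(rep(1, 50), rep(TRUE, 50))), 0)
  expect_equal(as.numeric(ece(rep(1, 50), rep(FALSE, 50))), 1)
  set.seed(123)
  n <- 1e5
  conf <- runif(n)
  correct <- runif(n) < conf
  expect_lt(as.numeric(ece(conf, correct)), 0.01)
  expect_error(ece(numeric(0), logical(0)), "empty")
})

test_that("id mismatches between truth and calls are an error", {
  truth <- list(make_truth("Sec/SPaseI", 5L, "eukarya", id = "A"))
  pred <- list(list(record = sp_record("B", "MKW"), call = make_call("NO_SP", NA),
                    prediction = NULL))
  expect_error(score_cs(truth, pred), "id mismatch")
})
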