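# Brute-force scoring oracles shared by the metrics and acceptance suites.

make_truth <- function(type, ic, group, n = 40L, id = "t") {
  labels <- if (type == "NO_SP") rep("intracellular", n) else
    c(rep(type, ic - 1L), rep("extracellular", n - ic + 1L))
  sp_record(id, strrep("A", n), labels = labels, group = group)
}

make_call <- function(type, ip) {
  structure(list(sp_type = type, cs_index = if (type == "NO_SP") NA_integer_ else ip,
                 confidence = NA_real_, flags = character()), class = "sp_call")
}

# independent oracle: per (type, group, tolerance) cell, count tp/fp/fn by
# direct enumeration over records
oracle_cell <- function(truths, calls, t, g, tol) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    if (tr$group != g) next
    tc <- extract_sp_call(tr$labels)
    pc <- calls[[i]]
    hit <- pc$sp_type != "NO_SP" && pc$sp_type == tc$sp_type &&
      !is.na(pc$cs_index) && !is.na(tc$cs_index) &&
      abs(pc$cs_index - tc$cs_index) <= tol
    if (tc$sp_type == t && hit) tp <- tp + 1L
    if (tc$sp_type == t && !hit) fn <- fn + 1L
    if (pc$sp_type == t && !hit) fp <- fp + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

random_truth_call_pairs <- function(n, seed) {
  set.seed(seed)
  types <- c("NO_SP", sp_labels())
  truths <- list(); calls <- list()
  for (i in seq_len(n)) {
    tt <- sample(types, 1, prob = c(0.3, rep(0.14, 5)))
    g <- sample(organism_groups(), 1)
    truths[[i]] <- make_truth(tt, sample(2:30, 1), g, id = paste0("r", i))
    calls[[i]] <- make_call(sample(types, 1, prob = c(0.3, rep(0.14, 5))),
                            sample(2:30, 1))
  }
  list(truths = truths, calls = calls)
}
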