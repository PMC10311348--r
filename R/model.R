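# R surface of the transformer: parameter initialization, the sinusoidal
# positional table, encoder / memory / decoder wrappers, checkpoints.

#' Sinusoidal positional encoding table
#'
#' Fixed (never trained) table `WS` of size `dS x (N+1)`: odd rows
#' `sin(i / 10000^(2k/dS))`, even rows the matching cosine, for positions
#' `i = 1..N+1` (the extra position carries the BOS/organism-group slot).
#'
#' @param dS Encoding dimension (even).
#' @param N Window length.
#' @return Numeric matrix `dS x (N+1)`.
#' @export
sinusoidal_pe <- function(dS, N) {
  if (dS %% 2 != 0) stop("dS must be even")
  cpp_sinusoidal_pe(as.integer(dS), as.integer(N))
}

xavier <- function(m, n) {
  a <- sqrt(6 / (m + n))
  matrix(runif(m * n, -a, a), m, n)
}

#' Initialize model parameters
#'
#' All weight matrices are Xavier-uniform; biases zero; layer-norm scales
#' one. The sinusoidal table is not a parameter (it is fixed) and is
#' recomputed from the configuration wherever needed.
#'
#' @param cfg An [model_config()].
#' @param seed Integer seed; identical seeds give identical parameters.
#' @return Named list of parameter matrices/vectors of class `sp_params`.
#' @export
init_params <- function(cfg, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  d <- cfg$d; dS <- cfg$dS; dm <- d + dS; ed <- cfg$ed; N <- cfg$N
  p <- list(
    Wa = xavier(d, 21L),
    WP = xavier(d, N),
    Wy = xavier(d, 9L),
    WG = xavier(d, 4L),
    WO_out = xavier(dm + 21L, 8L))
  for (l in seq_len(cfg$L_enc)) {
    pre <- sprintf("e%d_", l)
    p[[paste0(pre, "WQ")]] <- xavier(d, d)
    p[[paste0(pre, "WK")]] <- xavier(d, d)
    p[[paste0(pre, "WV")]] <- xavier(d, d)
    p[[paste0(pre, "WO")]] <- xavier(d, d)
    p[[paste0(pre, "W1")]] <- xavier(d, ed)
    p[[paste0(pre, "b1")]] <- numeric(ed)
    p[[paste0(pre, "W2")]] <- xavier(ed, d)
    p[[paste0(pre, "b2")]] <- numeric(d)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- numeric(d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- numeric(d)
  }
  for (l in seq_len(cfg$L_dec)) {
    pre <- sprintf("d%d_", l)
    for (w in c("sWQ", "sWK", "sWV", "sWO", "cWQ", "cWK", "cWV", "cWO")) {
      p[[paste0(pre, w)]] <- xavier(dm, dm)
    }
    p[[paste0(pre, "W1")]] <- xavier(dm, ed)
    p[[paste0(pre, "b1")]] <- numeric(ed)
    p[[paste0(pre, "W2")]] <- xavier(ed, dm)
    p[[paste0(pre, "b2")]] <- numeric(dm)
    for (i in 1:3) {
      p[[sprintf("%sln%d_g", pre, i)]] <- rep(1, dm)
      p[[sprintf("%sln%d_b", pre, i)]] <- numeric(dm)
    }
  }
  structure(p, class = "sp_params", cfg = cfg)
}

# encoder vs decoder parameter split (drives the per-component learning rates)
param_component <- function(names) {
  ifelse(names %in% c("Wa", "WP") | grepl("^e\\d+_", names), "encoder", "decoder")
}

#' Encode residue tokens into contextual representations
#'
#' Runs the multi-head attention encoder (initial embedding + linear
#' positional table, then `L_enc` layers of scaled dot-product attention
#' and feed-forward blocks with post-residual layer normalization).
#' Sequences longer than the window are truncated with a warning.
#'
#' @param seqs Character vector of amino-acid sequences, or a list of
#'   [sp_record()].
#' @param params,cfg Model parameters and configuration.
#' @return List of `N x d` matrices (rows = positions).
#' @export
encode <- function(seqs, params, cfg) {
  if (is.list(seqs) && inherits(seqs[[1]], "sp_record")) {
    seqs <- vapply(seqs, function(r) r$seq, "")
  }
  if (any(nchar(seqs) > cfg$N)) {
    warning("sequence(s) longer than window N = ", cfg$N, " truncated")
  }
  toks <- lapply(seqs, aa_tokenize, N = cfg$N)
  tokens <- do.call(rbind, lapply(toks, as.integer))
  n_real <- vapply(toks, attr, 1L, "n_real")
  cpp_encode(tokens, n_real, params, cfg)
}

#' Assemble the decoder memory
#'
#' Appends the organism-group embedding column to the encoder output along
#' the sequence axis (making `N+1` positions) and concatenates the same
#' sinusoidal positional table used for the decoder inputs along the
#' feature axis, giving the `(N+1) x (d+dS)` memory attended to by the
#' decoder's cross-attention.
#'
#' @param EL `N x d` encoder output.
#' @param group One of [organism_groups()].
#' @param params,cfg Model parameters and configuration.
#' @return `(N+1) x (d+dS)` matrix.
#' @export
assemble_memory <- function(EL, group, params, cfg) {
  cpp_assemble_memory(EL, group_id(group), params, cfg)
}

#' Teacher-forced decoding probabilities
#'
#' Runs the full model on one sequence with the decoder conditioned on a
#' given (shifted-right, BOS-prefixed) label sequence and returns the
#' per-position 8-way probability rows. Used for training-side diagnostics
#' and tests; inference uses [greedy_decode()].
#'
#' @param seq Amino-acid sequence (character scalar).
#' @param labels Character vector of per-residue labels (the gold labels
#'   under teacher forcing).
#' @param group One of [organism_groups()].
#' @param params,cfg Model parameters and configuration.
#' @return `N x 8` matrix of probability rows.
#' @export
decode_teacher_forced <- function(seq, labels, group, params, cfg) {
  tok <- aa_tokenize(seq, cfg$N)
  lin <- shifted_label_input(labels, cfg$N)
  cpp_tf_probs(as.integer(tok), attr(tok, "n_real"), group_id(group),
               lin, params, cfg)
}

# decoder input = (BOS, y1..yN); pad positions carry BOS (masked anyway)
shifted_label_input <- function(labels, N) {
  ids <- label_id(labels)
  n <- min(length(ids), N)
  as.integer(c(bos_id(), ids[seq_len(n)], rep(bos_id(), N - n)))
}

prep_batch <- function(records, cfg, need_labels = TRUE) {
  B <- length(records)
  tokens <- matrix(21L, B, cfg$N)
  n_real <- integer(B)
  groups <- integer(B)
  labels_in <- matrix(bos_id(), B, cfg$N + 1L)
  targets <- matrix(1L, B, cfg$N)
  truncated <- logical(B)
  for (b in seq_len(B)) {
    rec <- records[[b]]
    tok <- aa_tokenize(rec$seq, cfg$N)
    tokens[b, ] <- tok
    n_real[b] <- attr(tok, "n_real")
    truncated[b] <- nchar(rec$seq) > cfg$N
    groups[b] <- group_id(rec$group)
    if (need_labels) {
      if (is.null(rec$labels)) stop("record ", rec$id, " has no labels")
      labels_in[b, ] <- shifted_label_input(rec$labels, cfg$N)
      ids <- label_id(rec$labels)[seq_len(n_real[b])]
      targets[b, seq_len(n_real[b])] <- ids
    }
  }
  list(tokens = tokens, n_real = n_real, groups = groups,
       labels_in = labels_in, targets = targets, truncated = truncated)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the model configuration, raw parameters, the
#' SWA-averaged parameters, the per-epoch log and a format-version tag.
#'
#' @param fit A fit object from [fit()] (or a compatible list).
#' @param path Destination file.
#' @return `path` invisibly; `load_checkpoint` returns the fit object.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(!is.null(fit$params), !is.null(fit$cfg))
  fit$format_version <- "sigpept-checkpoint-1"
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!identical(fit$format_version, "sigpept-checkpoint-1")) {
    stop("not a sigpept checkpoint: ", path)
  }
  fit
}
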