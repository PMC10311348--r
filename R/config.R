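# Model and training configuration, annotation code map, YAML loading.

#' Model configuration
#'
#' Dimensions of the transformer encoder-decoder. The full-scale preset
#' mirrors the published architecture (d = 1024 residue embedding, dS = 128
#' sinusoidal positional encoding so the decoder token width is d + dS =
#' 1152, 16 heads, 30 encoder / 3 decoder layers, feed-forward expansion
#' 4096, dropout 0.1). The compact preset is trainable from scratch on a
#' desk CPU and is the default for everything in this package.
#'
#' @param d Encoder embedding dimension.
#' @param dS Sinusoidal positional-encoding dimension (even).
#' @param H Attention heads per layer; must divide both `d` and `d + dS`.
#' @param L_enc,L_dec Encoder / decoder layer counts.
#' @param ed Feed-forward expansion dimension (> d), used by both stacks.
#' @param N Window length (residues); longer sequences are truncated.
#' @param dropout Dropout rate on decoder attention outputs and feed-forward
#'   activations during training.
#' @param dropout_enc Encoder-side dropout (default 0).
#' @param full_scale If `TRUE`, return the published full-scale dimensions.
#' @return A list of class `sp_model_config`.
#' @export
model_config <- function(d = 64L, dS = 16L, H = 4L, L_enc = 2L, L_dec = 2L,
                         ed = 256L, N = 70L, dropout = 0.1, dropout_enc = 0,
                         full_scale = FALSE) {
  if (full_scale) {
    d <- 1024L; dS <- 128L; H <- 16L; L_enc <- 30L; L_dec <- 3L; ed <- 4096L
  }
  cfg <- list(d = as.integer(d), dS = as.integer(dS), H = as.integer(H),
              L_enc = as.integer(L_enc), L_dec = as.integer(L_dec),
              ed = as.integer(ed), N = as.integer(N),
              dropout = dropout, dropout_enc = dropout_enc,
              n_res_tokens = 21L, n_label_tokens = 9L, n_labels = 8L,
              n_groups = 4L)
  if (cfg$dS %% 2L != 0L) stop("dS must be even")
  if (cfg$d %% cfg$H != 0L) stop("d must be divisible by H")
  if ((cfg$d + cfg$dS) %% cfg$H != 0L) stop("d + dS must be divisible by H")
  if (cfg$ed <= cfg$d) stop("ed must exceed d")
  class(cfg) <- "sp_model_config"
  cfg
}

#' Decoder token width of a model configuration
#'
#' The decoder operates on concatenated representations of width `d + dS`
#' (1152 at full scale).
#'
#' @param cfg An [model_config()].
#' @return Integer width.
#' @export
decoder_width <- function(cfg) cfg$d + cfg$dS

#' Training configuration
#'
#' Constant per-component learning rates: the published setup fine-tunes a
#' pretrained encoder at 1e-5 while the decoder trains at 1e-4. When the
#' compact encoder is trained from scratch there is no pretrained component
#' to protect, so `compact = TRUE` raises the encoder rate to the decoder's
#' (see the methods vignette).
#'
#' @param lr_encoder Constant learning rate for encoder parameters.
#' @param lr_decoder Constant learning rate for decoder parameters.
#' @param epochs Training epochs.
#' @param batch_size Sequences per gradient step.
#' @param seed Integer seed controlling init, shuffling and dropout.
#' @param swa_enabled Maintain a stochastic-weight-averaging running mean,
#'   updated after each epoch.
#' @param patience Early-stop patience (epochs without validation CS-F1
#'   improvement); `Inf` disables early stopping.
#' @param val_max At most this many validation records are greedily decoded
#'   per epoch for the CS-F1 log column.
#' @param class_weights Optional numeric vector of length 8 re-weighting the
#'   cross-entropy per label; `NULL` (default) is unweighted.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param compact Use the from-scratch preset (`lr_encoder = lr_decoder`).
#' @return A list of class `sp_train_config`.
#' @export
train_config <- function(lr_encoder = 1e-5, lr_decoder = 1e-4, epochs = 10L,
                         batch_size = 32L, seed = 1L, swa_enabled = TRUE,
                         patience = Inf, val_max = 200L, class_weights = NULL,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         compact = FALSE) {
  if (compact) lr_encoder <- lr_decoder
  stopifnot(lr_encoder > 0, lr_decoder > 0, epochs >= 1L)
  structure(list(lr_encoder = lr_encoder, lr_decoder = lr_decoder,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), swa_enabled = isTRUE(swa_enabled),
                 patience = patience, val_max = as.integer(val_max),
                 class_weights = class_weights,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2),
            class = "sp_train_config")
}

#' Annotation code map for the three-line dataset format
#'
#' Bijective mapping between single annotation characters and the eight
#' residue labels. The default follows the deposited-dataset convention for
#' the letters that are documented (S = Sec/SPaseI, L = Sec/SPaseII,
#' T = TAT/SPaseI, I/M/O for the non-SP classes); the two remaining SP codes
#' default to P (Sec/SPaseIV) and W (TAT/SPaseII) and should be checked
#' against any externally obtained file before use, which is why the map is
#' configuration rather than a constant.
#'
#' @param codes Named character vector mapping labels to single characters.
#' @return A list of class `sp_code_map` with `label_to_char` and
#'   `char_to_label`.
#' @export
annotation_codes <- function(codes = c("Sec/SPaseI" = "S", "Sec/SPaseII" = "L",
                                       "Sec/SPaseIV" = "P", "TAT/SPaseI" = "T",
                                       "TAT/SPaseII" = "W",
                                       "intracellular" = "I",
                                       "transmembrane" = "M",
                                       "extracellular" = "O")) {
  if (!setequal(names(codes), all_labels())) {
    stop("codes must name exactly the 8 labels")
  }
  if (anyDuplicated(codes)) stop("annotation characters must be distinct")
  codes <- codes[all_labels()]
  structure(list(label_to_char = codes,
                 char_to_label = setNames(names(codes), unname(codes))),
            class = "sp_code_map")
}

#' Load a run configuration from a YAML file
#'
#' Sections `model`, `train`, `grammar` and `codes` override the respective
#' defaults of [model_config()], [train_config()], [grammar_spec()] and
#' [annotation_codes()]; missing sections keep defaults.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return List with elements `model`, `train`, `grammar`, `codes`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  take <- function(section) {
    s <- if (is.null(raw[[section]])) list() else raw[[section]]
    # YAML 1.1 parses a bare key `N` as boolean; map it back
    names(s)[names(s) %in% c("FALSE", "no")] <- "N"
    s
  }
  model <- do.call(model_config, take("model"))
  train <- do.call(train_config, take("train"))
  g <- take("grammar")
  if (is.null(g$N)) g$N <- model$N
  grammar <- do.call(grammar_spec, g)
  codes <- if (is.null(raw$codes)) annotation_codes() else
    annotation_codes(unlist(raw$codes))
  list(model = model, train = train, grammar = grammar, codes = codes)
}
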