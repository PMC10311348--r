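# Label alphabet, organism groups, sequence records, and the SP-type /
# cleavage-site extraction rule shared by every other module.

#' The five signal-peptide labels
#'
#' Signal peptides are distinguished by translocation pathway (Sec vs
#' twin-arginine/TAT) and by the signal peptidase that cleaves them (SPase
#' I, II or IV). Residue-level annotation therefore uses five SP labels.
#'
#' @return Character vector of the five SP labels, in their stable order.
#' @export
sp_labels <- function() {
  c("Sec/SPaseI", "Sec/SPaseII", "Sec/SPaseIV", "TAT/SPaseI", "TAT/SPaseII")
}

#' The three non-SP residue labels
#'
#' @return Character vector: intracellular, transmembrane, extracellular.
#' @export
non_sp_labels <- function() {
  c("intracellular", "transmembrane", "extracellular")
}

#' All eight residue labels in id order
#'
#' Integer ids 1..8 follow this order everywhere (model outputs, annotation
#' codes, metrics). The decoder-side beginning-of-sequence token BOS has id 9
#' and is never emitted as a prediction; the shared residue PAD/UNK token is
#' likewise input-only.
#'
#' @return Character vector of length 8.
#' @export
all_labels <- function() c(sp_labels(), non_sp_labels())

#' @rdname all_labels
#' @export
bos_id <- function() 9L

label_id <- function(label) {
  id <- match(label, all_labels())
  if (anyNA(id)) stop("unknown label(s): ", paste(unique(label[is.na(id)]), collapse = ", "))
  id
}

#' The four organism groups
#'
#' @return Character vector: eukarya, gn-bacteria, gp-bacteria, archaea.
#' @export
organism_groups <- function() {
  c("eukarya", "gn-bacteria", "gp-bacteria", "archaea")
}

group_id <- function(group) {
  id <- match(group, organism_groups())
  if (anyNA(id)) stop("unknown organism group(s): ", paste(unique(group[is.na(id)]), collapse = ", "))
  id
}

# 20-letter amino-acid alphabet; anything else (X, B, Z, U, O, PAD) shares
# token 21, so the one-hot residue representation stays 21-dimensional.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Tokenize an amino-acid sequence
#'
#' Maps residues to integer tokens 1..20; any non-standard residue (X, B, Z,
#' U, O, ...) and padding share token 21. The result is padded or truncated
#' to `N` positions.
#'
#' @param seq Character scalar, amino-acid sequence (any case).
#' @param N Window length; pad/truncate to this many tokens.
#' @return Integer vector of length `N` with attribute `n_real`, the number
#'   of real (non-pad) positions.
#' @export
aa_tokenize <- function(seq, N) {
  chars <- strsplit(toupper(seq), "")[[1]]
  N <- as.integer(N)
  n_real <- as.integer(min(length(chars), N))
  tok <- match(chars[seq_len(n_real)], AA_ALPHABET)
  tok[is.na(tok)] <- 21L
  out <- c(tok, rep(21L, N - n_real))
  attr(out, "n_real") <- n_real
  out
}

#' Construct a sequence record
#'
#' A record bundles an accession, the amino-acid sequence, optional
#' per-residue labels, the organism group, and an optional homology
#' partition id.
#'
#' @param id Accession string.
#' @param seq Amino-acid string (upper-cased on construction).
#' @param labels Optional character vector of per-residue labels from
#'   [all_labels()], same length as `seq`.
#' @param group One of [organism_groups()].
#' @param partition Integer in 0..2, or `NA` when unknown.
#' @return An object of class `sp_record`.
#' @export
sp_record <- function(id, seq, labels = NULL, group = "eukarya", partition = NA_integer_) {
  group <- match.arg(group, organism_groups())
  rec <- structure(
    list(id = as.character(id), seq = toupper(as.character(seq)),
         labels = labels, group = group,
         partition = as.integer(partition)),
    class = "sp_record")
  rec
}

#' @export
print.sp_record <- function(x, ...) {
  cat(sprintf("<sp_record %s | %s | %d aa%s%s>\n", x$id, x$group, nchar(x$seq),
              if (!is.null(x$labels)) " | labeled" else "",
              if (!is.na(x$partition)) paste0(" | partition ", x$partition) else ""))
  invisible(x)
}

#' Validate a sequence record
#'
#' Checks the record invariants and reports violations without ever fixing
#' them: label/sequence length agreement, and (when SP labels occur) that
#' they form a single contiguous block of one SP type starting at the
#' N-terminus.
#'
#' @param rec An [sp_record()].
#' @return Character vector of violation messages; empty when the record is
#'   well formed.
#' @export
validate_record <- function(rec) {
  out <- character()
  n <- nchar(rec$seq)
  if (n < 1L) out <- c(out, "empty sequence")
  if (!is.null(rec$labels)) {
    lab <- rec$labels
    if (length(lab) != n) {
      out <- c(out, sprintf("length mismatch: %d labels for %d residues", length(lab), n))
      return(out)
    }
    bad <- setdiff(unique(lab), all_labels())
    if (length(bad)) {
      out <- c(out, paste0("unknown labels: ", paste(bad, collapse = ", ")))
      return(out)
    }
    is_sp <- lab %in% sp_labels()
    if (any(is_sp)) {
      idx <- which(is_sp)
      if (idx[1] != 1L) out <- c(out, "SP block not at N-terminus")
      if (!all(diff(idx) == 1L)) out <- c(out, "SP labels not contiguous")
      if (length(unique(lab[idx])) > 1L) out <- c(out, "mixed SP types in SP block")
      if (all(is_sp)) out <- c(out, "SP block runs to end of window (no cleavage site)")
    }
  }
  out
}

#' Extract the SP type and cleavage site from a label sequence
#'
#' Applies the residue-labeling call rule: the SP type is read from the
#' label of residue 1 alone; when that label is an SP label, the cleavage
#' site index is the smallest position `c > 1` whose label is one of the
#' three non-SP labels, i.e. the first mature residue (the cleavage site
#' lies between residues `c-1` and `c`).
#'
#' @param labels Character vector over the eight labels of [all_labels()]
#'   (or an `sp_record` with labels, for convenience).
#' @param probs Optional numeric matrix (length x 8) of per-position label
#'   probabilities; used to attach a confidence: the probability of the
#'   emitted label at the CS position for cleavage calls, and of the
#'   position-1 label for type-only calls.
#' @return An object of class `sp_call`: list with `sp_type` (an SP label or
#'   `"NO_SP"`), `cs_index` (1-based first mature residue, or `NA`),
#'   `confidence` (in \[0,1\], or `NA` when no probabilities were supplied)
#'   and `flags` (character; e.g. `"runs_off_window"` when predicted SP
#'   labels never terminate, `"mixed_sp_types"` when later SP labels
#'   disagree with position 1).
#' @export
extract_sp_call <- function(labels, probs = NULL) {
  if (inherits(labels, "sp_record")) labels <- labels$labels
  if (length(labels) < 1L) stop("labels must be non-empty")
  if (!all(labels %in% all_labels())) {
    stop("labels contain entries outside the 8-label alphabet")
  }
  flags <- character()
  first <- labels[1]
  if (!(first %in% sp_labels())) {
    call <- list(sp_type = "NO_SP", cs_index = NA_integer_, confidence = NA_real_,
                 flags = flags)
  } else {
    non_sp_pos <- which(labels %in% non_sp_labels())
    non_sp_pos <- non_sp_pos[non_sp_pos > 1L]
    cs <- if (length(non_sp_pos)) min(non_sp_pos) else NA_integer_
    if (is.na(cs)) {
      flags <- c(flags, "runs_off_window")
      sp_block <- labels[labels %in% sp_labels()]
    } else {
      sp_block <- labels[seq_len(cs - 1L)]
      sp_block <- sp_block[sp_block %in% sp_labels()]
    }
    if (length(unique(sp_block)) > 1L) flags <- c(flags, "mixed_sp_types")
    call <- list(sp_type = first, cs_index = cs, confidence = NA_real_, flags = flags)
  }
  if (!is.null(probs)) {
    stopifnot(is.matrix(probs), nrow(probs) >= length(labels), ncol(probs) == 8L)
    if (call$sp_type != "NO_SP" && !is.na(call$cs_index)) {
      call$confidence <- probs[call$cs_index, label_id(labels[call$cs_index])]
    } else {
      call$confidence <- probs[1L, label_id(first)]
    }
  }
  structure(call, class = "sp_call")
}

#' @export
print.sp_call <- function(x, ...) {
  if (x$sp_type == "NO_SP") {
    cat("<sp_call NO_SP>\n")
  } else if (is.na(x$cs_index)) {
    cat(sprintf("<sp_call %s | cleavage site not in window [%s]>\n",
                x$sp_type, paste(x$flags, collapse = ",")))
  } else {
    cat(sprintf("<sp_call %s | cleavage between residues %d and %d | confidence %s>\n",
                x$sp_type, x$cs_index - 1L, x$cs_index,
                ifelse(is.na(x$confidence), "NA", sprintf("%.3f", x$confidence))))
  }
  invisible(x)
}
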