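# Grammar-based generator of labeled synthetic sequences following the
# canonical signal-peptide architectures: tripartite Sec SPs (basic N-region,
# hydrophobic H-region, polar C-region carrying the SPase I consensus), TAT
# SPs with the twin-arginine dipeptide at the N/H boundary, SPase II
# substrates ending in a lipobox with an invariant Cys immediately after the
# cleavage site, and SPase IV substrates with only a short basic region.

default_profile <- function(x) {
  p <- setNames(rep(0, 20L), AA_ALPHABET)
  p[names(x)] <- x
  rest <- setdiff(AA_ALPHABET, names(x))
  p[rest] <- (1 - sum(x)) / length(rest)
  p
}

#' Grammar specification for the synthetic generator
#'
#' Defines, per SP type, region-length ranges and per-region residue
#' frequency profiles, plus negative-class profiles and mixture weights.
#' Defaults emulate the qualitative region architecture of canonical SPs:
#' the N-region is enriched in K/R (with R kept modest so that a chance
#' twin-arginine dipeptide is rare and can be rejected cheaply), the
#' H-region draws from A/L/I/V/F/M/W, the C-region from polar/small
#' residues with the Ala-X-Ala SPase I consensus at positions cs-3..cs-1,
#' SPase II substrates end in a three-residue lipobox followed by Cys, TAT
#' SPs carry an RR dipeptide delimiting N- and H-regions, and SPase IV
#' substrates have only a short basic region ending in the G|F processing
#' motif. Mature/intracellular/extracellular backgrounds are uniform over
#' the 20 residues.
#'
#' @param N Window length (default 70).
#' @param seq_len_range Total sequence length range (uniform draw).
#' @param class_weights Named mixture weights over the 8 classes (the five
#'   SP types plus the three non-SP classes); default equal.
#' @param group_weights Named mixture weights over [organism_groups()].
#' @param n_region,h_region,c_region,br_region Region length ranges
#'   (2-vectors); TAT N-regions use `n_region` widened by `tat_extra` to
#'   host the RR dipeptide.
#' @param tat_extra Extra length allowance of TAT N-regions.
#' @param tm_len_range,tm_start_min Transmembrane block geometry for the
#'   TM-containing negative class.
#' @param n_profile,h_profile,c_profile,br_profile,background Residue
#'   frequency profiles (named, over the 20-letter alphabet, each summing
#'   to 1).
#' @param lipobox List of three position profiles for the lipobox.
#' @param axa Emit the A-x-A consensus at cs-3..cs-1 for SPase I-cleaved
#'   types (default `TRUE`).
#' @param seed Integer seed; [sample_dataset()] is deterministic given it.
#' @return A list of class `sp_grammar`.
#' @export
grammar_spec <- function(N = 70L,
                         seq_len_range = c(40L, 70L),
                         class_weights = NULL,
                         group_weights = NULL,
                         n_region = c(2L, 10L),
                         h_region = c(7L, 15L),
                         c_region = c(3L, 7L),
                         br_region = c(2L, 8L),
                         tat_extra = 4L,
                         tm_len_range = c(15L, 25L),
                         tm_start_min = 8L,
                         n_profile = NULL, h_profile = NULL,
                         c_profile = NULL, br_profile = NULL,
                         background = NULL, lipobox = NULL,
                         axa = TRUE, seed = 1L) {
  if (is.null(class_weights)) {
    class_weights <- setNames(rep(1 / 8, 8L), all_labels())
  }
  if (is.null(group_weights)) {
    group_weights <- setNames(rep(1 / 4, 4L), organism_groups())
  }
  if (is.null(n_profile)) n_profile <- default_profile(c(K = 0.30, R = 0.08))
  if (is.null(h_profile)) {
    h_profile <- default_profile(c(A = 0.18, L = 0.22, I = 0.15, V = 0.15,
                                   F = 0.12, M = 0.08, W = 0.10))
  }
  if (is.null(c_profile)) {
    c_profile <- default_profile(c(S = 0.22, T = 0.18, N = 0.12, Q = 0.12,
                                   G = 0.14, A = 0.14, P = 0.08))
  }
  if (is.null(br_profile)) br_profile <- default_profile(c(K = 0.35, R = 0.08))
  if (is.null(background)) background <- setNames(rep(1 / 20, 20L), AA_ALPHABET)
  if (is.null(lipobox)) {
    lipobox <- list(default_profile(c(L = 0.8, V = 0.1, I = 0.1)),
                    default_profile(c(A = 0.5, S = 0.5)),
                    default_profile(c(G = 0.5, A = 0.5)))
  }
  spec <- list(N = as.integer(N), seq_len_range = as.integer(seq_len_range),
               class_weights = class_weights, group_weights = group_weights,
               n_region = as.integer(n_region), h_region = as.integer(h_region),
               c_region = as.integer(c_region), br_region = as.integer(br_region),
               tat_extra = as.integer(tat_extra),
               tm_len_range = as.integer(tm_len_range),
               tm_start_min = as.integer(tm_start_min),
               n_profile = n_profile, h_profile = h_profile,
               c_profile = c_profile, br_profile = br_profile,
               background = background, lipobox = lipobox,
               axa = isTRUE(axa), seed = as.integer(seed))
  for (nm in c("n_profile", "h_profile", "c_profile", "br_profile", "background")) {
    p <- spec[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) stop(nm, " must be a frequency profile summing to 1")
  }
  for (p in spec$lipobox) {
    if (abs(sum(p) - 1) > 1e-9) stop("lipobox profiles must sum to 1")
  }
  for (nm in c("n_region", "h_region", "c_region", "br_region")) {
    r <- spec[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L) stop(nm, " range invalid")
  }
  if (abs(sum(class_weights) - 1) > 1e-9 || abs(sum(group_weights) - 1) > 1e-9) {
    stop("mixture weights must sum to 1")
  }
  class(spec) <- "sp_grammar"
  spec
}

draw_region <- function(len, profile) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = profile), collapse = "")
}

rint <- function(range) if (range[1] == range[2]) range[1] else
  sample(seq.int(range[1], range[2]), 1L)

# Draw a region, rejecting chance "RR" dipeptides (so the twin-arginine
# motif stays unique to TAT grammars); falls back to editing after 50 tries.
draw_region_no_rr <- function(len, profile) {
  for (i in 1:50) {
    s <- draw_region(len, profile)
    if (!grepl("RR", s, fixed = TRUE)) return(s)
  }
  gsub("R(?=R)", "K", s, perl = TRUE)
}

#' Sample one labeled synthetic record
#'
#' Draws a class from the grammar's mixture weights and emits sequence plus
#' per-residue labels following that class's region grammar. The intended
#' call (type and cleavage-site index) is attached as attribute `intended`.
#'
#' @param spec An [grammar_spec()].
#' @param id Accession to give the record.
#' @return An [sp_record()] with labels.
#' @export
sample_record <- function(spec, id = "SYN") {
  cls <- sample(names(spec$class_weights), 1L, prob = spec$class_weights)
  group <- sample(names(spec$group_weights), 1L, prob = spec$group_weights)
  partition <- sample(0:2, 1L)
  is_tat <- cls %in% c("TAT/SPaseI", "TAT/SPaseII")
  is_spii <- cls %in% c("Sec/SPaseII", "TAT/SPaseII")

  sp_seq <- NULL
  if (cls %in% sp_labels()) {
    if (cls == "Sec/SPaseIV") {
      br_len <- max(rint(spec$br_region), 2L)
      br <- draw_region_no_rr(br_len, spec$br_profile)
      substr(br, br_len, br_len) <- "G"   # G|F processing motif
      sp_seq <- br
    } else {
      n_range <- spec$n_region
      if (is_tat) n_range <- n_range + c(0L, spec$tat_extra)
      n_core <- draw_region_no_rr(rint(n_range), spec$n_profile)
      if (is_tat) n_core <- paste0(n_core, "RR")
      h <- draw_region(rint(spec$h_region), spec$h_profile)
      if (is_spii) {
        lip <- paste(vapply(spec$lipobox, function(p)
          sample(AA_ALPHABET, 1L, prob = p), ""), collapse = "")
        sp_seq <- paste0(n_core, h, lip)
      } else {
        cr_len <- rint(spec$c_region)
        cr <- draw_region(cr_len, spec$c_profile)
        if (spec$axa && cr_len >= 3L) {
          substr(cr, cr_len - 2L, cr_len - 2L) <- "A"
          substr(cr, cr_len, cr_len) <- "A"
        }
        sp_seq <- paste0(n_core, h, cr)
      }
    }
  }

  if (is.null(sp_seq)) {
    # negative classes
    if (cls == "transmembrane") {
      tm_len <- rint(spec$tm_len_range)
      n <- max(rint(spec$seq_len_range), spec$tm_start_min + tm_len + 5L)
      n <- min(n, spec$N)
      start_max <- n - tm_len - 1L
      start <- if (start_max <= spec$tm_start_min) spec$tm_start_min else
        sample(seq.int(spec$tm_start_min, start_max), 1L)
      seq <- draw_region(n, spec$background)
      substr(seq, start, start + tm_len - 1L) <- draw_region(tm_len, spec$h_profile)
      labels <- rep("intracellular", n)
      labels[start:(start + tm_len - 1L)] <- "transmembrane"
    } else {
      n <- min(rint(spec$seq_len_range), spec$N)
      seq <- draw_region(n, spec$background)
      labels <- rep(cls, n)
    }
    intended <- list(sp_type = "NO_SP", cs_index = NA_integer_)
  } else {
    sp_len <- nchar(sp_seq)
    cs <- sp_len + 1L
    n <- max(min(rint(spec$seq_len_range), spec$N), sp_len + 8L)
    mature <- draw_region(n - sp_len, spec$background)
    if (is_spii) substr(mature, 1L, 1L) <- "C"          # invariant Cys at cs
    if (cls == "Sec/SPaseIV") substr(mature, 1L, 1L) <- "F"
    seq <- paste0(sp_seq, mature)
    labels <- c(rep(cls, sp_len), rep("extracellular", n - sp_len))
    intended <- list(sp_type = cls, cs_index = cs)
  }
  rec <- sp_record(id, seq, labels = labels, group = group, partition = partition)
  attr(rec, "intended") <- intended
  rec
}

#' Sample a labeled synthetic dataset
#'
#' Deterministic given `spec$seed` (the session RNG state is saved and
#' restored). Every record passes [validate_record()] by construction.
#'
#' @param spec An [grammar_spec()].
#' @param n Number of records (>= 1).
#' @param seed Overrides `spec$seed` when given.
#' @return List of [sp_record()].
#' @export
sample_dataset <- function(spec, n, seed = spec$seed) {
  stopifnot(n >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  lapply(seq_len(n), function(i) sample_record(spec, id = sprintf("SYN%06d", i)))
}
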