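# Readers/writers: FASTA, the three-line labeled dataset format used by the
# deposited SP benchmark data, prediction TSV, and GFF3 output.

#' Read protein sequences from FASTA
#'
#' Sequences are upper-cased; non-standard residues are retained in the
#' stored sequence and encoded as the shared unknown token when fed to the
#' model. Record ids are the header up to the first whitespace.
#'
#' @param path FASTA file.
#' @param group Organism group to assign to every record (a per-record
#'   group can be supplied in three-line datasets instead).
#' @return List of [sp_record()] without labels, in file order.
#' @export
read_fasta <- function(path, group = "eukarya") {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) warning("duplicated ids in ", path)
  lapply(seq_along(aa), function(i) {
    sp_record(ids[i], as.character(aa[[i]]), group = group)
  })
}

#' Read a labeled dataset in the three-line format
#'
#' Each record is exactly three lines: a header `>id|group|type|partition`,
#' the amino-acid sequence, and an annotation string of equal length whose
#' characters decode to residue labels via the code map.
#'
#' @param path File path.
#' @param codes An [annotation_codes()] map.
#' @param strict If `TRUE` (default) any malformed record is a hard error
#'   naming the record; if `FALSE`, malformed records are skipped with a
#'   warning and well-formed ones returned.
#' @return List of labeled [sp_record()]; invariant violations found by
#'   [validate_record()] are attached as attribute `violations` on the
#'   record (reported, never silently fixed).
#' @export
read_threeline_dataset <- function(path, codes = annotation_codes(), strict = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty dataset file: ", path)
  if (length(lines) %% 3L != 0L) {
    stop("three-line format violated: ", length(lines), " non-empty lines in ", path)
  }
  groups_uc <- toupper(organism_groups())
  out <- list()
  errs <- character()
  for (i in seq(1L, length(lines), by = 3L)) {
    header <- lines[i]
    fail <- function(msg) sprintf("record at line %d (%s): %s", i, header, msg)
    ok <- tryCatch({
      if (!startsWith(header, ">")) stop(fail("header must start with '>'"))
      fields <- strsplit(sub("^>", "", header), "|", fixed = TRUE)[[1]]
      if (length(fields) != 4L) stop(fail("header must have exactly 4 '|'-separated fields"))
      seq <- toupper(lines[i + 1L])
      ann <- lines[i + 2L]
      if (nchar(seq) != nchar(ann)) {
        stop(fail(sprintf("annotation length %d != sequence length %d",
                          nchar(ann), nchar(seq))))
      }
      gidx <- match(toupper(fields[2]), groups_uc)
      if (is.na(gidx)) stop(fail(paste0("unknown organism group ", fields[2])))
      part <- suppressWarnings(as.integer(fields[4]))
      if (is.na(part) || !(part %in% 0:2)) stop(fail("partition must be 0, 1 or 2"))
      chars <- strsplit(ann, "")[[1]]
      labs <- unname(codes$char_to_label[chars])
      if (anyNA(labs)) {
        stop(fail(paste0("unknown annotation characters: ",
                         paste(unique(chars[is.na(labs)]), collapse = ""))))
      }
      rec <- sp_record(fields[1], seq, labels = labs,
                       group = organism_groups()[gidx], partition = part)
      v <- validate_record(rec)
      if (length(v)) attr(rec, "violations") <- v
      out[[length(out) + 1L]] <- rec
      TRUE
    }, error = function(e) {
      if (strict) stop(e) else errs <<- c(errs, conditionMessage(e))
      FALSE
    })
  }
  if (length(errs)) {
    warning(length(errs), " malformed record(s) skipped:\n",
            paste(errs, collapse = "\n"))
  }
  out
}

#' Write a labeled dataset in the three-line format
#'
#' @param records List of labeled [sp_record()].
#' @param path Output file.
#' @param codes An [annotation_codes()] map.
#' @return `path`, invisibly.
#' @export
write_threeline_dataset <- function(records, path, codes = annotation_codes()) {
  con <- file(path, "w")
  on.exit(close(con))
  type_of <- function(rec) {
    call <- extract_sp_call(rec$labels)
    if (call$sp_type == "NO_SP") "NO_SP" else codes$label_to_char[[call$sp_type]]
  }
  for (rec in records) {
    if (is.null(rec$labels)) stop("record ", rec$id, " has no labels")
    writeLines(c(
      sprintf(">%s|%s|%s|%d", rec$id, toupper(rec$group), type_of(rec),
              if (is.na(rec$partition)) 0L else rec$partition),
      rec$seq,
      paste(codes$label_to_char[rec$labels], collapse = "")), con)
  }
  invisible(path)
}

#' Write prediction calls as TSV or GFF3
#'
#' TSV columns: id, group, sp_type, cs_index, confidence, label_string.
#' GFF3 emits one `signal_peptide` feature per positive call with 1-based
#' inclusive coordinates `1..cs_index-1`.
#'
#' @param calls List of lists with elements `record` ([sp_record()]),
#'   `call` ([extract_sp_call()] result) and `prediction` (may be `NULL`;
#'   its labels provide `label_string`), as produced by [predict_batch()].
#' @param path Output file.
#' @param format `"tsv"` or `"gff3"`.
#' @param codes Code map used to render label strings.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(calls, path, format = c("tsv", "gff3"),
                              codes = annotation_codes()) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(
      id = vapply(calls, function(x) x$record$id, ""),
      group = vapply(calls, function(x) x$record$group, ""),
      sp_type = vapply(calls, function(x) x$call$sp_type, ""),
      cs_index = vapply(calls, function(x)
        if (is.na(x$call$cs_index)) NA_integer_ else x$call$cs_index, 1L),
      confidence = vapply(calls, function(x) x$call$confidence, 1.0),
      label_string = vapply(calls, function(x) {
        lab <- if (!is.null(x$prediction)) x$prediction$labels else NULL
        if (is.null(lab)) "" else paste(codes$label_to_char[lab], collapse = "")
      }, ""),
      stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  } else {
    lines <- "##gff-version 3"
    for (x in calls) {
      if (x$call$sp_type == "NO_SP" || is.na(x$call$cs_index)) next
      lines <- c(lines, paste(
        x$record$id, "sigpept", "signal_peptide",
        1L, x$call$cs_index - 1L,
        formatC(x$call$confidence, format = "g"),
        ".", ".",
        sprintf("ID=%s.SP;sp_type=%s;organism_group=%s", x$record$id,
                x$call$sp_type, x$record$group),
        sep = "\t"))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a prediction TSV back into calls
#'
#' Inverse of [write_predictions()] for `format = "tsv"`.
#'
#' @param path TSV file written by [write_predictions()].
#' @param codes Code map used to decode label strings.
#' @return List of lists with `id`, `group`, `call` and decoded `labels`.
#' @export
read_predictions <- function(path, codes = annotation_codes()) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(label_string = "character"))
  lapply(seq_len(nrow(df)), function(i) {
    labs <- if (nzchar(df$label_string[i]))
      unname(codes$char_to_label[strsplit(df$label_string[i], "")[[1]]]) else NULL
    cs <- df$cs_index[i]
    list(id = df$id[i], group = df$group[i],
         call = structure(list(
           sp_type = df$sp_type[i],
           cs_index = if (is.na(cs)) NA_integer_ else as.integer(cs),
           confidence = df$confidence[i],
           flags = character()), class = "sp_call"),
         labels = labs)
  })
}
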