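write_toy_threeline <- function(path, include_malformed = FALSE) {
  codes <- annotation_codes()
  lines <- c(
    ">Q1|EUKARYA|SP|0",        "MKWVTFISLLAB",       "SSSSSOOOOOOO",
    ">Q2|ARCHAEA|NO_SP|2",     "GATTACAGATTA",       "IIIIIIIIIIII",
    ">Q3|GN-BACTERIA|LIPO|1",  "MKKLLACDEFGH",       "LLLLLLOOOOOO",
    ">Q4|EUKARYA|NO_SP|1",     "AAAAVVVVLLLL",       "IIMMMMMMIIII",
    ">Q5|GP-BACTERIA|TAT|0",   "MRRFLKAAASDE",       "TTTTTTTTTOOO",
    ">Q6|EUKARYA|NO_SP|0",     "DDDDEEEEKKKK",       "OOOOOOOOOOOO")
  if (include_malformed) {
    lines <- c(lines, ">Q7|EUKARYA|SP|0", "MKWVTFISLLA", "SSSSSOOOO")  # length mismatch
  }
  writeLines(lines, path)
  path
}

test_that("three-line records parse into labeled records with group and partition", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_toy_threeline(path)
  recs <- read_threeline_dataset(path)
  expect_length(recs, 6)
  q1 <- recs[[1]]
  expect_equal(q1$group, "eukarya")
  expect_equal(q1$partition, 0L)
  call <- extract_sp_call(q1$labels)
  expect_equal(call$sp_type, "Sec/SPaseI")
  expect_equal(call$cs_index, 6L)
  expect_equal(extract_sp_call(recs[[2]]$labels)$sp_type, "NO_SP")
  expect_equal(extract_sp_call(recs[[5]]$labels)$sp_type, "TAT/SPaseI")
})

test_that("malformed records are a hard error when strict, skipped otherwise", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_toy_threeline(path, include_malformed = TRUE)
  expect_error(read_threeline_dataset(path), "Q7")
  expect_warning(recs <- read_threeline_dataset(path, strict = FALSE),
                 "malformed")
  expect_length(recs, 6)
})

test_that("headers with extra fields fail loudly rather than misparse", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">X|EUKARYA|SP|0|extra", "MKWV", "SSOO"), path)
  expect_error(read_threeline_dataset(path), "4")
})

test_that("three-line write/read round-trips synthetic datasets exactly", {
  spec <- tiny_grammar()
  recs <- sample_dataset(spec, 40, seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_threeline_dataset(recs, path)
  back <- read_threeline_dataset(path)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$id, recs[[i]]$id)
    expect_identical(back[[i]]$seq, recs[[i]]$seq)
    expect_identical(back[[i]]$labels, recs[[i]]$labels)
    expect_identical(back[[i]]$group, recs[[i]]$group)
    expect_identical(back[[i]]$partition, recs[[i]]$partition)
  }
})

test_that("FASTA reading preserves order, upper-cases, and keeps unknown residues", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">seqA some description", "mkwvtf", ">seqB", "ACDEFXH"), path)
  recs <- read_fasta(path)
  expect_length(recs, 2)
  expect_identical(recs[[1]]$id, "seqA")
  expect_identical(recs[[1]]$seq, "MKWVTF")
  expect_identical(recs[[2]]$seq, "ACDEFXH")
  tok <- aa_tokenize(recs[[2]]$seq, 7)
  expect_identical(as.integer(tok)[6], 21L)  # X -> shared unknown token
})

test_that("prediction TSV round-trips and GFF3 uses 1-based inclusive SP coordinates", {
  rec <- sp_record("P1", strrep("A", 30), group = "gn-bacteria")
  call <- structure(list(sp_type = "Sec/SPaseI", cs_index = 24L,
                         confidence = 0.9, flags = character()),
                    class = "sp_call")
  neg <- sp_record("P2", strrep("G", 20))
  ncall <- structure(list(sp_type = "NO_SP", cs_index = NA_integer_,
                          confidence = 0.8, flags = character()),
                     class = "sp_call")
  calls <- list(list(record = rec, call = call, prediction = NULL),
                list(record = neg, call = ncall, prediction = NULL))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(calls, tsv, format = "tsv")
  back <- read_predictions(tsv)
  expect_identical(back[[1]]$call$sp_type, "Sec/SPaseI")
  expect_identical(back[[1]]$call$cs_index, 24L)
  expect_identical(back[[2]]$call$sp_type, "NO_SP")
  expect_true(is.na(back[[2]]$call$cs_index))

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_predictions(calls, gff, format = "gff3")
  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  expect_length(lines, 2)  # one feature, none for the NO_SP call
  f <- strsplit(lines[2], "\t")[[1]]
  expect_identical(f[3], "signal_peptide")
  expect_identical(as.integer(f[4]), 1L)
  expect_identical(as.integer(f[5]), 23L)
})
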