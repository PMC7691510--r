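test_that("constructor validates CDS and exon structure", {
  expect_s3_class(transcript_model("ok", "ATGAAATAA", 9), "transcript_model")
  expect_error(transcript_model("x", "ATGAAATA", 8),
               class = "nmdscan_validation_error")   # not a codon multiple
  expect_error(transcript_model("x", "TTGAAATAA", 9),
               class = "nmdscan_validation_error")   # no ATG
  expect_error(transcript_model("x", "ATGAAAAAA", 9),
               class = "nmdscan_validation_error")   # no terminal stop
  err <- tryCatch(transcript_model("x", "ATGTAAAAATAA", 12),
                  error = function(e) e)
  expect_s3_class(err, "nmdscan_validation_error")
  expect_equal(err$codon_index, 2L)                  # internal stop located
  expect_error(transcript_model("x", "ATGAAATAA", c(3, 3)),
               class = "nmdscan_validation_error")   # lengths do not sum to CDS
})

test_that("SOD1 fixture model matches the published coordinates", {
  t <- sod1_transcript()
  expect_equal(nchar(t$cds_sequence), 465L)
  expect_equal(nchar(t$cds_sequence) / 3, 155)       # 154 aa + stop
  expect_equal(t$exon_junctions_cds, c(72L, 169L, 240L, 357L))
  expect_equal(last_junction_position(t), 357L)
  ex <- exon_of_cds_position(t, c(358L, 357L))
  expect_equal(ex$exon, c(5L, 4L))                   # junction nt -> upstream exon
  aa <- translate_cds(t$cds_sequence)
  expect_equal(which(aa == "*"), 155L)               # single stop, at the end
})

test_that("junctions and exon lookup behave on simple transcripts", {
  single <- transcript_model("one", "ATGAAATAA", 9)
  expect_length(single$exon_junctions_cds, 0)
  expect_true(is.na(last_junction_position(single)))

  t3 <- make_transcript(sim_config(seed = 7, cds_codons = 100,
                                   n_exons = 3, exon_len_nt = c(90, 120)))
  t3 <- transcript_model("synth", t3$cds_sequence, c(90, 120, 90))
  expect_equal(last_junction_position(t3), 210L)
  ex <- exon_of_cds_position(t3, 91)
  expect_equal(ex$exon, 2L)
  expect_equal(ex$exon_cds_length, 120L)
  expect_error(exon_of_cds_position(t3, 0), class = "nmdscan_bounds_error")
  expect_error(exon_of_cds_position(t3, 301), class = "nmdscan_bounds_error")
})

test_that("exon lookup is total and preimage sizes equal exon lengths", {
  cfg <- sim_config(seed = 11, n_exons = c(2, 6), cds_codons = c(60, 120),
                    exon_len_nt = c(20, 200))
  for (i in 1:10) {
    t <- make_transcript(cfg, index = i)
    ex <- exon_of_cds_position(t, seq_len(nchar(t$cds_sequence)))
    expect_equal(as.integer(table(ex$exon)), t$exon_cds_lengths)
  }
})

test_that("JSON round trip is the identity", {
  t <- make_transcript(sim_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_transcript_json(t, path)
  t2 <- load_transcript(path, "json")
  expect_identical(t, t2)
})

test_that("GenBank and GFF3 readers reproduce the JSON model", {
  t <- sod1_transcript()

  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank_fixture(t, gb)
  expect_identical(load_transcript(gb, "genbank"), t)

  gb_minus <- withr::local_tempfile(fileext = ".gb")
  write_genbank_fixture(t, gb_minus, minus = TRUE)
  expect_identical(load_transcript(gb_minus, "genbank"), t)

  skip_if_not_installed("rtracklayer")
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_gff3_fixture(t, gff, fa)
  expect_identical(load_transcript(gff, "gff3", fasta = fa), t)

  gffm <- withr::local_tempfile(fileext = ".gff3")
  fam <- withr::local_tempfile(fileext = ".fa")
  write_gff3_fixture(t, gffm, fam, minus = TRUE)
  expect_identical(load_transcript(gffm, "gff3", fasta = fam), t)
})

test_that("reader errors are structured and name the record", {
  bad <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       NOCDS 10 bp", "ORIGIN", "        1 atgaaataa", "//"),
             bad)
  err <- tryCatch(load_transcript(bad, "genbank"), error = function(e) e)
  expect_s3_class(err, "nmdscan_io_error")
  expect_match(conditionMessage(err), "NOCDS")
  expect_error(load_transcript("/nonexistent/file.json", "json"),
               class = "nmdscan_io_error")
})
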