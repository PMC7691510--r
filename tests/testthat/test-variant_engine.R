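sod1 <- sod1_transcript()

test_that("apply_variant edits in place and guards the reference", {
  mut <- apply_variant(sod1, parse_cdna_hgvs("c.380 T > A"))
  ref <- sod1$cds_sequence
  expect_equal(nchar(mut), nchar(ref))
  diff <- which(strsplit(ref, "")[[1]] != strsplit(mut, "")[[1]])
  expect_equal(diff, 380L)
  expect_equal(substr(mut, 380, 380), "A")

  del <- apply_variant(sod1, parse_cdna_hgvs("c.275_276delAA"))
  expect_equal(nchar(del), nchar(ref) - 2L)

  err <- tryCatch(apply_variant(sod1, parse_cdna_hgvs("c.275_276delGG")),
                  error = function(e) e)
  expect_s3_class(err, "nmdscan_reference_mismatch")
  expect_equal(err$position, 275L)
  expect_equal(err$expected, "GG")
  expect_equal(err$found, "AA")
  expect_error(apply_variant(sod1, parse_cdna_hgvs("c.999A>T")),
               class = "nmdscan_bounds_error")
})

test_that("find_ptc returns NULL on the natural terminator and errors on stop-loss", {
  expect_null(find_ptc(sod1, sod1$cds_sequence))
  # in-frame duplication of a whole codon keeps the natural stop: no PTC
  dup_codon <- cds_variant("duplication", 91, 93)
  expect_null(find_ptc(sod1, apply_variant(sod1, dup_codon)))
  expect_error(find_ptc(sod1, "ATGAAACCC"), class = "nmdscan_no_terminator")
  expect_error(find_ptc(sod1, "TTGAAATAA"), class = "nmdscan_validation_error")
})

test_that("every coding catalogue variant reproduces the printed consequence", {
  tab <- sod1_variants()
  coding <- tab[tab$hgvs_c != "c.358-304C>G", ]
  expect_equal(nrow(coding), 15L)
  for (i in seq_len(nrow(coding))) {
    v <- parse_cdna_hgvs(coding$hgvs_c[i])
    ptc <- find_ptc(sod1, apply_variant(sod1, v))
    expect_equal(ptc$codon_index, coding$ptc_printed[i],
                 label = coding$hgvs_c[i])
    expect_equal(ptc$protein_hgvs, coding$hgvs_p[i],
                 label = coding$hgvs_c[i])
    # printed protein nomenclature implies the same codon
    expect_equal(ptc_codon_from_protein_hgvs(coding$hgvs_p[i]),
                 ptc$codon_index, label = coding$hgvs_p[i])
  }
})

test_that("PTC coordinates project onto the reference frame", {
  # c.88_89insA: stop at mutant codon 37, one nt inserted upstream
  ptc <- find_ptc(sod1, apply_variant(sod1, parse_cdna_hgvs("c.88_89insA")))
  expect_equal(ptc$codon_index, 37L)
  expect_equal(ptc$cds_first_nt, 108L)
  expect_equal(ptc$cds_last_nt, ptc$cds_first_nt + 2L)
  # c.275_276delAA: two nt removed upstream of the stop
  ptc <- find_ptc(sod1, apply_variant(sod1, parse_cdna_hgvs("c.275_276delAA")))
  expect_equal(ptc$codon_index, 100L)
  expect_equal(ptc$cds_first_nt, 3L * 100L - 2L + 2L)
  # nonsense: mutant and reference frames coincide
  ptc <- find_ptc(sod1, apply_variant(sod1, parse_cdna_hgvs("c.441T>A")))
  expect_equal(ptc$cds_first_nt, 3L * 147L - 2L)
})

test_that("find_ptc agrees with the lookup-table oracle on random implants", {
  for (seed in c(5, 17)) {
    cfg <- sim_config(seed = seed, cds_codons = c(80, 200))
    t <- make_transcript(cfg)
    for (i in 1:40) {
      imp <- implant_variant(t, cfg, index = i)
      ptc <- find_ptc(t, apply_variant(t, imp$variant))
      expect_equal(ptc$codon_index, imp$expected_ptc_codon,
                   label = sprintf("seed %d %s", seed, imp$hgvs_c))
      # and against a third, test-local translation path
      aa <- oracle_translate(imp$mutant_cds)
      expect_equal(which(aa == "*")[1], imp$expected_ptc_codon)
    }
  }
})

test_that("transcript edits model splice consequences as insertions", {
  # a pseudo-exon bringing its own in-frame stop right after CDS nt 357
  ed <- transcript_edit(357, "TAG")
  ptc <- find_ptc(sod1, apply_variant(sod1, ed))
  expect_equal(ptc$codon_index, 120L)
  expect_error(transcript_edit(357, ""), class = "nmdscan_validation_error")
  expect_error(apply_variant(sod1, transcript_edit(465, "A")),
               class = "nmdscan_bounds_error")
})
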