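test_that("cDNA HGVS parsing covers the catalogue's syntax inventory", {
  v <- parse_cdna_hgvs("c.88_89insA")
  expect_equal(v[c("kind", "start", "end", "alt_allele")],
               list(kind = "insertion", start = 88L, end = 89L,
                    alt_allele = "A"))

  v <- parse_cdna_hgvs("c.435delGinsCGTTTA")
  expect_equal(v[c("kind", "start", "end", "ref_allele", "alt_allele")],
               list(kind = "delins", start = 435L, end = 435L,
                    ref_allele = "G", alt_allele = "CGTTTA"))

  v <- parse_cdna_hgvs("c.380 T > A")   # internal whitespace tolerated
  expect_equal(v[c("kind", "start", "ref_allele", "alt_allele")],
               list(kind = "substitution", start = 380L,
                    ref_allele = "T", alt_allele = "A"))

  v <- parse_cdna_hgvs("c.380_383dupTGGG")
  expect_equal(v[c("kind", "start", "end")],
               list(kind = "duplication", start = 380L, end = 383L))

  v <- parse_cdna_hgvs("c.275_276delAA")
  expect_equal(v[c("kind", "start", "end", "ref_allele")],
               list(kind = "deletion", start = 275L, end = 276L,
                    ref_allele = "AA"))
  # bases may be omitted
  expect_equal(parse_cdna_hgvs("c.275_276del")$ref_allele, "")
})

test_that("malformed and non-coding strings raise structured conditions", {
  expect_error(parse_cdna_hgvs("c.88_89insA?"), class = "nmdscan_parse_error")
  expect_error(parse_cdna_hgvs("g.12345A>T"), class = "nmdscan_parse_error")
  expect_error(parse_cdna_hgvs("c.88_90insA"), class = "nmdscan_parse_error")
  expect_error(parse_cdna_hgvs("c.275_276delAAA"),
               class = "nmdscan_parse_error")  # span/base length mismatch
  expect_error(parse_cdna_hgvs("c.358-304C > G"),
               class = "nmdscan_not_coding_edit")
  expect_error(parse_cdna_hgvs("c.72+1G>A"),
               class = "nmdscan_not_coding_edit")
})

test_that("parse -> serialize -> parse is the identity on coding variants", {
  coding <- setdiff(sod1_variants()$hgvs_c, "c.358-304C>G")
  for (h in coding) {
    v1 <- parse_cdna_hgvs(h)
    s <- format_cdna_hgvs(v1)
    v2 <- parse_cdna_hgvs(s)
    v1$raw_hgvs <- v2$raw_hgvs <- NA_character_
    expect_identical(v1, v2, label = h)
  }
})

test_that("sequence-aware serialization is 3'-shifted but edit-equivalent", {
  t <- sod1_transcript()
  cfg <- sim_config(seed = 21)
  for (i in 1:25) {
    imp <- implant_variant(t, cfg, index = i)
    v2 <- parse_cdna_hgvs(imp$hgvs_c)
    expect_identical(apply_variant(t, v2), imp$mutant_cds,
                     label = imp$hgvs_c)
  }
  # an insertion that copies the preceding base is spelled dup
  ins <- cds_variant("insertion", 320, 321, alt_allele = "T")
  expect_equal(format_cdna_hgvs(ins, t$cds_sequence), "c.320dupT")
})

test_that("PTC codon is recovered from protein-level nomenclature", {
  expect_equal(ptc_codon_from_protein_hgvs("p.Asp126Thrfs*24"), 149L)
  expect_equal(ptc_codon_from_protein_hgvs("p.Leu127*"), 127L)
  expect_equal(ptc_codon_from_protein_hgvs("p.Lys92Argfs*9"), 100L)
  # one-letter codes and Ter accepted on input
  expect_equal(ptc_codon_from_protein_hgvs("p.K92Rfs*9"), 100L)
  expect_equal(ptc_codon_from_protein_hgvs("p.Leu127Ter"), 127L)
  expect_error(ptc_codon_from_protein_hgvs("p.Met1?"),
               class = "nmdscan_unsupported_nomenclature")
  expect_error(ptc_codon_from_protein_hgvs("p.Glu134del"),
               class = "nmdscan_unsupported_nomenclature")
  expect_error(ptc_codon_from_protein_hgvs("p.Xyz10*"),
               class = "nmdscan_unsupported_nomenclature")
})
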