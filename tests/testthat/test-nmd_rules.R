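sod1 <- sod1_transcript()

test_that("the SOD1 trigger region matches the published bounds", {
  reg <- trigger_region(sod1)
  expect_false(reg$empty)
  expect_equal(c(reg$nt_lo, reg$nt_hi), c(151L, 301L))
  expect_equal(c(reg$codon_lo, reg$codon_hi), c(50L, 100L))
  expect_length(reg$excluded_intervals, 0)
  expect_equal(format_region(reg), "trigger: codons 50-100 (nt 151-301)")
})

test_that("degenerate regions are empty", {
  single <- transcript_model("one", "ATGAAATAA", 9)
  expect_true(trigger_region(single)$empty)
  expect_equal(format_region(trigger_region(single)), "trigger: none")
  # junction too close to the start: bounds cross
  tiny <- make_transcript(sim_config(seed = 2, cds_codons = 70,
                                     n_exons = 2, exon_len_nt = c(30, 200)))
  if (last_junction_position(tiny) <= 206) {
    expect_true(trigger_region(tiny)$empty)
  }
})

test_that("long internal exons are carved out of the region", {
  # exon 2 spans CDS nt 151-600 (450 nt > 400): its codons escape
  cds_codons <- 240L
  t <- make_transcript(sim_config(seed = 13, cds_codons = cds_codons,
                                  n_exons = 3, exon_len_nt = c(120, 450)))
  t <- transcript_model("longexon", t$cds_sequence, c(150, 450, 120))
  reg <- trigger_region(t)
  expect_equal(c(reg$codon_lo, reg$codon_hi), c(50L, 181L))
  expect_length(reg$excluded_intervals, 1)
  # brute-force per-codon check of the exclusion bounds
  codons <- reg$codon_lo:reg$codon_hi
  in_long <- vapply(codons, function(c) {
    p <- 3 * c - 2
    p > 150 && p <= 600
  }, TRUE)
  expect_equal(reg$excluded_intervals[[1]],
               range(codons[in_long]))
  # and classification agrees codon-by-codon with the oracle
  expect_equal(region_status_by_codon(t, nmd_config()),
               oracle_status_by_codon(t$exon_cds_lengths, nmd_config()))
})

test_that("catalogue PTCs classify as published", {
  c127 <- classify_ptc(sod1, find_ptc(sod1, apply_variant(
    sod1, parse_cdna_hgvs("c.380T>A"))))
  expect_equal(c127$status, "escape")
  expect_equal(c127$rules_fired, "last_exon")

  c37 <- classify_ptc(sod1, find_ptc(sod1, apply_variant(
    sod1, parse_cdna_hgvs("c.88_89insA"))))
  expect_equal(c37$status, "escape")
  expect_equal(c37$rules_fired, "start_proximal")

  c100 <- classify_ptc(sod1, find_ptc(sod1, apply_variant(
    sod1, parse_cdna_hgvs("c.275_276delAA"))))
  expect_equal(c100$status, "trigger")
  expect_true(c100$borderline)

  c75 <- classify_ptc(sod1, list(codon_index = 75L, cds_first_nt = 223L))
  expect_equal(c75$status, "trigger")
  expect_false(c75$borderline)

  expect_error(classify_ptc(sod1, list(codon_index = 155L, cds_first_nt = 463L)),
               class = "nmdscan_validation_error")
})

test_that("borderline flag covers both region edges at the configured width", {
  flags <- vapply(c(50, 52, 53, 75, 97, 98, 100), function(c) {
    classify_ptc(sod1, list(codon_index = c, cds_first_nt = 3 * c - 2))$borderline
  }, TRUE)
  expect_equal(flags, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  wide <- nmd_config(borderline_codons = 5)
  expect_true(classify_ptc(sod1, list(codon_index = 95L, cds_first_nt = 283L),
                           wide)$borderline)
})

test_that("classification and region are exhaustively consistent", {
  cfg <- nmd_config()
  transcripts <- c(list(sod1),
                   lapply(1:6, function(i) {
                     make_transcript(sim_config(seed = 31,
                                                n_exons = c(1, 6),
                                                exon_len_nt = c(30, 450),
                                                cds_codons = c(60, 220)),
                                     index = i)
                   }))
  for (t in transcripts) {
    codons <- seq_len(nchar(t$cds_sequence) %/% 3 - 1)
    by_classify <- vapply(codons, function(c) classify_status(t, c, cfg), "")
    expect_equal(by_classify, region_status_by_codon(t, cfg, codons),
                 label = t$transcript_id)
  }
})

test_that("rule thresholds act monotonically", {
  t <- sod1
  codons <- seq_len(154)
  base <- region_status_by_codon(t, nmd_config())
  for (w in c(50, 52, 55, 80)) {
    for (s in c(100, 150, 200)) {
      cfg <- nmd_config(start_proximal_nt = s, junction_window_nt = w)
      cur <- region_status_by_codon(t, cfg, codons)
      # enlarging either threshold must never convert escape -> trigger
      if (w >= 55 && s >= 150) {
        expect_false(any(base == "escape" & cur == "trigger"))
      }
    }
  }
  # explicit nesting along each axis
  esc_at <- function(cfg) region_status_by_codon(t, cfg, codons) == "escape"
  e50 <- esc_at(nmd_config(junction_window_nt = 50))
  e55 <- esc_at(nmd_config(junction_window_nt = 55))
  expect_true(all(e55 >= e50))
  s100 <- esc_at(nmd_config(start_proximal_nt = 100))
  s150 <- esc_at(nmd_config(start_proximal_nt = 150))
  expect_true(all(s150 >= s100))
})

test_that("the SOD1 region is stable over the documented 50-55 nt window", {
  for (w in 50:55) {
    reg <- trigger_region(sod1, nmd_config(junction_window_nt = w))
    expect_equal(reg$codon_lo, 50L)
    # oracle-pinned upper bound: floor((357 - w - 1) / 3)
    expect_equal(reg$codon_hi, (357L - w - 1L) %/% 3L)
    expect_lte(abs(reg$codon_hi - 100L), 2L)
  }
})

test_that("classification equals the partial-sum oracle on random transcripts", {
  cfg <- nmd_config()
  scfg <- sim_config(seed = 41, n_exons = c(1, 7),
                     exon_len_nt = c(25, 500), cds_codons = c(50, 180))
  for (i in 1:120) {
    t <- make_transcript(scfg, index = i)
    expect_equal(region_status_by_codon(t, cfg),
                 oracle_status_by_codon(t$exon_cds_lengths, cfg),
                 label = t$transcript_id)
  }
  # classify_ptc spot checks against the oracle on a sampled transcript
  t <- make_transcript(scfg, index = 121)
  codons <- seq_len(nchar(t$cds_sequence) %/% 3 - 1)
  oracle <- oracle_status_by_codon(t$exon_cds_lengths, cfg)
  for (c in sample(codons, 25)) {
    expect_equal(classify_status(t, c, cfg), oracle[c])
  }
})
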