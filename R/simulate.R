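# Seeded simulator: transcripts, PTC-introducing variants with ground truth,
# and DNA/RNA allele counts under a stated mutant-transcript retention.

# Independent minimal translation path used only to derive simulation ground
# truth (deliberately not sharing code with find_ptc / Biostrings).
ORACLE_CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

SENSE_CODONS <- names(ORACLE_CODON_TABLE)[ORACLE_CODON_TABLE != "*"]

# First-stop scan in the mutant frame, by direct lookup. Returns the mutant
# codon index of the first stop, or NA (none / natural terminator reached).
oracle_first_stop <- function(mutant, ref_len) {
  v <- strsplit(mutant, "")[[1]]
  n <- length(v) %/% 3L
  diff <- length(v) - ref_len
  for (i in seq_len(n)) {
    cod <- paste(v[(3L * i - 2L):(3L * i)], collapse = "")
    if (ORACLE_CODON_TABLE[[cod]] == "*") {
      natural <- diff %% 3L == 0L && (3L * i - 2L) - diff == ref_len - 2L
      return(if (natural) NA_integer_ else i)
    }
  }
  NA_integer_
}

#' Simulation configuration
#'
#' The stated world the simulator draws from: multi-exon coding transcripts
#' free of internal stops, a heterozygous PTC-introducing variant, and
#' binomially sampled DNA/RNA read counts in which NMD acts as a
#' multiplicative loss of the mutant transcript (retention fraction
#' `retention_delta`). Defaults mirror a SOD1-like locus: around 150-250
#' codons over 3-6 exons of roughly 60-300 CDS nt, and a variant-type mix
#' matching the catalogued truncating-variant spectrum (4 nonsense, 3
#' frameshift deletions, 2 insertions, 4 duplications, 2 delins out of 15
#' coding variants).
#'
#' @param seed root RNG seed; per-component child streams are derived from
#'   it by fixed offsets, so a fixed seed reproduces outputs byte for byte.
#' @param n_exons integer range `c(lo, hi)`.
#' @param exon_len_nt CDS-overlap length range per exon, in nt.
#' @param cds_codons range of total codons including the stop.
#' @param variant_mix named proportions over `nonsense`, `frameshift_del`,
#'   `frameshift_ins`, `frameshift_dup`, `delins`; must sum to 1.
#' @param depth_dna,depth_rna mean read depths for count simulation.
#' @param retention_delta true mutant-transcript retention fraction in
#'   `[0, 1]` (1 = no decay).
#' @param n_variants variants per simulated dataset.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_exons = c(3L, 6L),
                       exon_len_nt = c(60L, 300L),
                       cds_codons = c(150L, 250L),
                       variant_mix = c(nonsense = 4, frameshift_del = 3,
                                       frameshift_ins = 2, frameshift_dup = 4,
                                       delins = 2) / 15,
                       depth_dna = 100L, depth_rna = 100L,
                       retention_delta = 0.5,
                       n_variants = 20L) {
  kinds <- c("nonsense", "frameshift_del", "frameshift_ins",
             "frameshift_dup", "delins")
  rng <- function(x) sort(as.integer(rep(x, length.out = 2L)))
  cfg <- list(seed = as.integer(seed), n_exons = rng(n_exons),
              exon_len_nt = rng(exon_len_nt), cds_codons = rng(cds_codons),
              variant_mix = variant_mix, depth_dna = as.integer(depth_dna),
              depth_rna = as.integer(depth_rna),
              retention_delta = retention_delta,
              n_variants = as.integer(n_variants))
  if (!setequal(names(variant_mix), kinds) ||
      abs(sum(variant_mix) - 1) > 1e-8 || any(variant_mix < 0)) {
    nmd_error("nmdscan_validation_error",
              sprintf("variant_mix must be non-negative proportions over {%s} summing to 1",
                      paste(kinds, collapse = ", ")))
  }
  if (cfg$cds_codons[1] < 10L || cfg$n_exons[1] < 1L ||
      cfg$exon_len_nt[1] < 1L ||
      cfg$retention_delta < 0 || cfg$retention_delta > 1 ||
      cfg$depth_dna < 1L || cfg$depth_rna < 1L) {
    nmd_error("nmdscan_validation_error", "invalid simulation ranges")
  }
  structure(cfg, class = "sim_config")
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

#' Simulate a multi-exon coding transcript
#'
#' The CDS is built codon-wise — ATG, then draws from the 61 sense codons,
#' then one stop — so internal stops are impossible by construction. Exon
#' lengths are drawn from `exon_len_nt` and rescaled to partition the CDS
#' exactly (rounding may push individual exons slightly outside the drawn
#' range).
#'
#' @param cfg a [sim_config].
#' @param index stream index; bump to draw independent transcripts from one
#'   root seed.
#' @return a [transcript_model].
#' @export
make_transcript <- function(cfg = sim_config(), index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(child_seed(cfg$seed, 1000L + index), {
    nc <- sample_range(cfg$cds_codons)
    L <- 3L * nc
    # feasible exon count for this CDS length
    lo <- ceiling(L / cfg$exon_len_nt[2]); hi <- L %/% cfg$exon_len_nt[1]
    ok <- max(cfg$n_exons[1], lo):min(cfg$n_exons[2], hi)
    if (length(ok) == 0L || ok[1] > ok[length(ok)]) {
      nmd_error("nmdscan_config_error",
                sprintf("no exon count in [%d,%d] can partition %d nt with exon lengths in [%d,%d]",
                        cfg$n_exons[1], cfg$n_exons[2], L,
                        cfg$exon_len_nt[1], cfg$exon_len_nt[2]))
    }
    ne <- if (length(ok) == 1L) ok else sample(ok, 1L)
    lens <- sample(cfg$exon_len_nt[1]:cfg$exon_len_nt[2], ne, replace = TRUE)
    lens <- pmax(1L, as.integer(round(lens * L / sum(lens))))
    while (sum(lens) != L) {
      i <- if (sum(lens) > L) which.max(lens) else which.min(lens)
      lens[i] <- lens[i] + sign(L - sum(lens))
    }
    cds <- paste0("ATG",
                  paste(sample(SENSE_CODONS, nc - 2L, replace = TRUE),
                        collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    transcript_model(sprintf("SYN%04d-%d", cfg$seed %% 10000L, index),
                     cds, lens)
  })
}

#' Implant a PTC-introducing variant with ground truth
#'
#' Draws a variant type from `variant_mix` and a position, then derives the
#' expected PTC by direct translation of the edited sequence through an
#' independent lookup-table code path (the oracle). Draws that hit the
#' natural terminator or lose the stop are resampled (bounded retries), so
#' the returned truth always carries a PTC.
#'
#' @param t a [transcript_model].
#' @param cfg a [sim_config].
#' @param index stream index for reproducible per-variant streams.
#' @return list with elements `variant` (a [cds_variant]), `hgvs_c`
#'   (normalized name), `mutant_cds`, and `expected_ptc_codon` (oracle
#'   ground truth, mutant-frame codon index).
#' @export
implant_variant <- function(t, cfg = sim_config(), index = 1L) {
  stopifnot(inherits(t, "transcript_model"), inherits(cfg, "sim_config"))
  with_seed(child_seed(cfg$seed, 2000L + index), {
    s <- strsplit(t$cds_sequence, "")[[1]]
    L <- length(s)
    for (try in 1:100) {
      kind <- sample(names(cfg$variant_mix), 1L, prob = cfg$variant_mix)
      v <- switch(kind,
        nonsense = {
          k <- sample(2:(L %/% 3L - 1L), 1L)
          cod <- s[(3L * k - 2L):(3L * k)]
          hits <- list()
          for (pos in 1:3) for (nt in c("A", "C", "G", "T")) {
            if (nt == cod[pos]) next
            mut <- cod; mut[pos] <- nt
            if (paste(mut, collapse = "") %in% STOP_CODONS) {
              hits[[length(hits) + 1L]] <- c(pos, nt)
            }
          }
          if (length(hits) == 0L) next
          h <- hits[[sample.int(length(hits), 1L)]]
          p <- 3L * k - 3L + as.integer(h[1])
          cds_variant("substitution", p, p, s[p], h[2])
        },
        frameshift_del = {
          w <- sample(1:2, 1L)
          p <- sample(4:(L - 3L - w), 1L)
          cds_variant("deletion", p, p + w - 1L,
                      paste(s[p:(p + w - 1L)], collapse = ""), "")
        },
        frameshift_ins = {
          w <- sample(1:2, 1L)
          p <- sample(3:(L - 3L), 1L)
          cds_variant("insertion", p, p + 1L, "",
                      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                            collapse = ""))
        },
        frameshift_dup = {
          w <- sample(1:2, 1L)
          p <- sample(4:(L - 3L - w), 1L)
          cds_variant("duplication", p, p + w - 1L,
                      paste(s[p:(p + w - 1L)], collapse = ""),
                      paste(s[p:(p + w - 1L)], collapse = ""))
        },
        delins = {
          wd <- sample(1:3, 1L)
          wi <- wd + sample(c(-2L, -1L, 1L, 2L)[c(-2L, -1L, 1L, 2L) + wd >= 1L], 1L)
          if ((wi - wd) %% 3L == 0L) next  # keep the frameshift class honest
          p <- sample(4:(L - 3L - wd), 1L)
          alt <- paste(sample(c("A", "C", "G", "T"), wi, replace = TRUE),
                       collapse = "")
          if (alt == paste(s[p:(p + wd - 1L)], collapse = "")) next
          cds_variant("delins", p, p + wd - 1L,
                      paste(s[p:(p + wd - 1L)], collapse = ""), alt)
        })
      mutant <- apply_variant(t, v)
      truth <- oracle_first_stop(mutant, L)
      if (is.na(truth)) next  # natural stop or stop-loss: resample
      return(list(variant = v,
                  hgvs_c = format_cdna_hgvs(v, t$cds_sequence),
                  mutant_cds = mutant,
                  expected_ptc_codon = truth))
    }
    nmd_error("nmdscan_config_error",
              "could not implant a PTC variant within 100 attempts")
  })
}

#' Simulate DNA/RNA allele counts under a retention fraction
#'
#' DNA alt reads are Binomial(depth_dna, 0.5) (heterozygous variant); under
#' retention `delta` the mutant transcript contributes `0.5 * delta` of the
#' RNA pool, so RNA alt reads are Binomial(depth_rna,
#' `0.5 delta / (0.5 delta + 0.5)`). Sampling is seeded. Mapping bias and
#' overdispersion are deliberately ignored (see the methods vignette).
#'
#' @param delta retention fraction in `[0, 1]`.
#' @param depth_dna,depth_rna read depths.
#' @param seed RNG seed.
#' @param sample_id label for the resulting counts.
#' @return an [allele_counts].
#' @export
simulate_counts <- function(delta, depth_dna = 100L, depth_rna = 100L,
                            seed = 1L, sample_id = NA_character_) {
  stopifnot(delta >= 0, delta <= 1)
  with_seed(child_seed(seed, 3000L), {
    dna_alt <- stats::rbinom(1L, depth_dna, 0.5)
    p_rna <- 0.5 * delta / (0.5 * delta + 0.5)
    rna_alt <- stats::rbinom(1L, depth_rna, p_rna)
    # degenerate draws at the DNA margin would make odds undefined downstream
    if (dna_alt == 0L) dna_alt <- 1L
    if (dna_alt == depth_dna) dna_alt <- depth_dna - 1L
    allele_counts(dna_alt, depth_dna - dna_alt,
                  rna_alt, depth_rna - rna_alt, sample_id)
  })
}

#' Emit a complete simulated dataset to a directory
#'
#' Writes `transcript.json`, `variants.tsv` (HGVS input for the pipeline),
#' `truth.tsv` (oracle PTC codons) and `counts.tsv` (one DNA/RNA count set
#' per variant under `retention_delta`), all derived from `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the transcript and the truth data.frame.
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t <- make_transcript(cfg)
  write_transcript_json(t, file.path(out_dir, "transcript.json"))
  rows <- lapply(seq_len(cfg$n_variants), function(i) {
    imp <- implant_variant(t, cfg, index = i)
    cnt <- simulate_counts(cfg$retention_delta, cfg$depth_dna, cfg$depth_rna,
                           seed = child_seed(cfg$seed, 4000L + i),
                           sample_id = sprintf("sim%03d", i))
    data.frame(label = sprintf("sim%03d", i), hgvs_c = imp$hgvs_c,
               kind = imp$variant$kind,
               expected_ptc_codon = imp$expected_ptc_codon,
               dna_alt = cnt$dna_alt, dna_ref = cnt$dna_ref,
               rna_alt = cnt$rna_alt, rna_ref = cnt$rna_ref,
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  utils::write.table(truth[, c("label", "hgvs_c")],
                     file.path(out_dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth[, c("label", "hgvs_c", "kind", "expected_ptc_codon")],
                     file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- truth[, c("label", "dna_alt", "dna_ref", "rna_alt", "rna_ref")]
  names(counts)[1] <- "variant_label"
  counts <- cbind(sample_id = truth$label, counts)
  utils::write.table(counts, file.path(out_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(transcript = t, truth = truth))
}
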