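# HGVS cDNA (c.) and protein (p.) nomenclature handling.

AA_1TO3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
             "*" = "*")
AA_3TO1 <- c(stats::setNames(names(AA_1TO3), AA_1TO3), Ter = "*")

#' Construct a coding-sequence variant
#'
#' Structured representation of a simple cDNA-level edit. `start`/`end` are
#' 1-based CDS positions; for an insertion they are the two flanking
#' positions (`end == start + 1`) and the new bases go between them. A
#' duplication keeps the duplicated span as `start..end`; applying it inserts
#' a copy of that span immediately after `end`.
#'
#' @param kind one of `"substitution"`, `"deletion"`, `"duplication"`,
#'   `"insertion"`, `"delins"`.
#' @param start,end 1-based CDS coordinates (see above).
#' @param ref_allele stated reference bases, possibly `""` when the HGVS
#'   string omits them (e.g. `c.4_6del`).
#' @param alt_allele inserted/replacement bases, `""` for pure deletions.
#' @param raw_hgvs the originating HGVS string, if any.
#' @return object of class `cds_variant`.
#' @export
cds_variant <- function(kind, start, end = start, ref_allele = "",
                        alt_allele = "", raw_hgvs = NA_character_) {
  kind <- match.arg(kind, c("substitution", "deletion", "duplication",
                            "insertion", "delins"))
  start <- as.integer(start); end <- as.integer(end)
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (is.na(start) || is.na(end) || start < 1L) {
    nmd_error("nmdscan_validation_error", "variant coordinates must be >= 1")
  }
  if (kind == "insertion") {
    if (end != start + 1L || nchar(alt_allele) == 0L) {
      nmd_error("nmdscan_validation_error",
                "insertion requires end = start + 1 and non-empty alt allele")
    }
  } else if (end < start) {
    nmd_error("nmdscan_validation_error", "end must be >= start")
  }
  if (!is_dna(ref_allele) || !is_dna(alt_allele)) {
    nmd_error("nmdscan_validation_error",
              "alleles may contain only A/C/G/T")
  }
  if (kind == "substitution" &&
      (nchar(ref_allele) != 1L || nchar(alt_allele) != 1L || start != end)) {
    nmd_error("nmdscan_validation_error",
              "substitution must be a single-nucleotide change")
  }
  if (kind == "delins" && nchar(alt_allele) == 0L) {
    nmd_error("nmdscan_validation_error", "delins requires inserted bases")
  }
  structure(list(kind = kind, start = start, end = end,
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 raw_hgvs = raw_hgvs),
            class = "cds_variant")
}

#' @export
print.cds_variant <- function(x, ...) {
  cat(sprintf("cds_variant <%s> %s [%d..%d] ref='%s' alt='%s'\n",
              x$kind, if (is.na(x$raw_hgvs)) format_cdna_hgvs(x) else x$raw_hgvs,
              x$start, x$end, x$ref_allele, x$alt_allele))
  invisible(x)
}

#' Construct a transcript edit
#'
#' Expresses a splice-consequence edit — e.g. pseudo-exon inclusion caused by
#' a deep intronic mutation — as a plain sequence insertion into the CDS.
#' Used when the cDNA HGVS string is intronic and hence not a coding edit.
#'
#' @param insert_position 1-based CDS position after which the sequence is
#'   inserted.
#' @param inserted_sequence non-empty nucleotide string.
#' @export
transcript_edit <- function(insert_position, inserted_sequence) {
  insert_position <- as.integer(insert_position)
  inserted_sequence <- toupper(inserted_sequence)
  if (is.na(insert_position) || insert_position < 1L) {
    nmd_error("nmdscan_validation_error", "insert_position must be >= 1")
  }
  if (nchar(inserted_sequence) == 0L || !is_dna(inserted_sequence)) {
    nmd_error("nmdscan_validation_error",
              "inserted_sequence must be a non-empty A/C/G/T string")
  }
  structure(list(insert_position = insert_position,
                 inserted_sequence = inserted_sequence),
            class = "transcript_edit")
}

#' Parse a cDNA-level HGVS string
#'
#' Supports the coding-variant syntax inventory used by truncating-variant
#' catalogues: substitutions (`c.380T>A`), deletions (`c.275_276delAA`,
#' `c.376delG`, `c.4_6del`), duplications (`c.320dupT`,
#' `c.380_383dupTGGG`), insertions (`c.88_89insA`) and deletion-insertions
#' (`c.435delGinsCGTTTA`). Internal whitespace is tolerated (`c.380 T > A`).
#' Stated reference/duplicated bases are retained for validation at
#' application time; parsed names are taken at face value (no 3'-shifting).
#'
#' Intronic positions (`c.358-304C>G`) are not coding edits: they raise a
#' condition of class `nmdscan_not_coding_edit`, directing the caller to
#' supply a [transcript_edit] or a protein-level consequence instead.
#'
#' @param s an HGVS string beginning with `c.`.
#' @return a [cds_variant].
#' @export
parse_cdna_hgvs <- function(s) {
  raw <- s
  s <- gsub("[[:space:]]+", "", s)
  if (!startsWith(s, "c.")) {
    nmd_error("nmdscan_parse_error",
              sprintf("not a cDNA (c.) HGVS string: '%s'", raw))
  }
  if (grepl("^c\\.[*-]?\\d+[+-]\\d+", s) || grepl("_[*-]?\\d+[+-]\\d+", s) ||
      grepl("^c\\.-\\d+", s) || grepl("^c\\.\\*\\d+", s)) {
    nmd_error("nmdscan_not_coding_edit",
              sprintf(paste0("'%s' involves non-CDS positions; supply the ",
                             "spliced consequence as a transcript_edit or a ",
                             "protein-level HGVS instead"), raw))
  }

  m <- regexec("^c\\.(\\d+)([ACGT])>([ACGT])$", s)
  g <- regmatches(s, m)[[1]]
  if (length(g)) {
    return(cds_variant("substitution", as.integer(g[2]), as.integer(g[2]),
                       g[3], g[4], raw_hgvs = raw))
  }
  m <- regexec("^c\\.(\\d+)(?:_(\\d+))?del([ACGT]*)ins([ACGT]+)$", s)
  g <- regmatches(s, m)[[1]]
  if (length(g)) {
    start <- as.integer(g[2])
    end <- if (nzchar(g[3])) as.integer(g[3]) else start
    check_span(raw, start, end, g[4])
    return(cds_variant("delins", start, end, g[4], g[5], raw_hgvs = raw))
  }
  m <- regexec("^c\\.(\\d+)(?:_(\\d+))?del([ACGT]*)$", s)
  g <- regmatches(s, m)[[1]]
  if (length(g)) {
    start <- as.integer(g[2])
    end <- if (nzchar(g[3])) as.integer(g[3]) else start
    check_span(raw, start, end, g[4])
    return(cds_variant("deletion", start, end, g[4], "", raw_hgvs = raw))
  }
  m <- regexec("^c\\.(\\d+)(?:_(\\d+))?dup([ACGT]*)$", s)
  g <- regmatches(s, m)[[1]]
  if (length(g)) {
    start <- as.integer(g[2])
    end <- if (nzchar(g[3])) as.integer(g[3]) else start
    check_span(raw, start, end, g[4])
    return(cds_variant("duplication", start, end, g[4], g[4], raw_hgvs = raw))
  }
  m <- regexec("^c\\.(\\d+)_(\\d+)ins([ACGT]+)$", s)
  g <- regmatches(s, m)[[1]]
  if (length(g)) {
    start <- as.integer(g[2]); end <- as.integer(g[3])
    if (end != start + 1L) {
      nmd_error("nmdscan_parse_error",
                sprintf("'%s': insertion flanks must be adjacent", raw))
    }
    return(cds_variant("insertion", start, end, "", g[4], raw_hgvs = raw))
  }
  nmd_error("nmdscan_parse_error",
            sprintf("cannot parse HGVS string '%s'", raw))
}

check_span <- function(raw, start, end, bases) {
  if (end < start) {
    nmd_error("nmdscan_parse_error",
              sprintf("'%s': span end before start", raw))
  }
  if (nzchar(bases) && nchar(bases) != end - start + 1L) {
    nmd_error("nmdscan_parse_error",
              sprintf("'%s': stated bases do not match span length", raw))
  }
}

#' Serialize a coding variant back to HGVS c. notation
#'
#' Without sequence context the stored representation is emitted as-is
#' (normalized spelling: no whitespace, bases upper-case). With `cds` given,
#' generated insertion/duplication names are normalized the HGVS way: the
#' inserted bases are shifted to their 3'-most equivalent placement and an
#' insertion that duplicates the immediately preceding span is written as
#' `dup`.
#'
#' @param v a [cds_variant].
#' @param cds optional reference CDS used for 3'-shifting normalization.
#' @return HGVS string.
#' @export
format_cdna_hgvs <- function(v, cds = NULL) {
  stopifnot(inherits(v, "cds_variant"))
  span <- function(a, b) if (a == b) sprintf("%d", a) else sprintf("%d_%d", a, b)
  if (is.null(cds)) {
    return(switch(v$kind,
      substitution = sprintf("c.%d%s>%s", v$start, v$ref_allele, v$alt_allele),
      deletion = sprintf("c.%sdel%s", span(v$start, v$end), v$ref_allele),
      duplication = sprintf("c.%sdup%s", span(v$start, v$end), v$ref_allele),
      insertion = sprintf("c.%d_%dins%s", v$start, v$end, v$alt_allele),
      delins = sprintf("c.%sdel%sins%s", span(v$start, v$end),
                       v$ref_allele, v$alt_allele)))
  }
  s <- strsplit(toupper(cds), "")[[1]]
  if (v$kind == "substitution") {
    return(sprintf("c.%d%s>%s", v$start, s[v$start], v$alt_allele))
  }
  if (v$kind == "delins") {
    return(sprintf("c.%sdel%sins%s", span(v$start, v$end),
                   paste(s[v$start:v$end], collapse = ""), v$alt_allele))
  }
  if (v$kind == "deletion") {
    a <- v$start; b <- v$end
    while (b + 1L <= length(s) && s[b + 1L] == s[a]) { a <- a + 1L; b <- b + 1L }
    return(sprintf("c.%sdel%s", span(a, b), paste(s[a:b], collapse = "")))
  }
  # insertion or duplication: express as bases inserted after position `pos`,
  # rotate 3'-wards while the next reference base matches the leading
  # inserted base, then prefer dup spelling when a copy precedes.
  ins <- strsplit(v$alt_allele, "")[[1]]
  if (v$kind == "duplication") {
    ins <- s[v$start:v$end]
    pos <- v$end
  } else {
    pos <- v$start
  }
  while (pos + 1L <= length(s) && s[pos + 1L] == ins[1L]) {
    ins <- c(ins[-1L], s[pos + 1L])
    pos <- pos + 1L
  }
  k <- length(ins)
  if (pos - k + 1L >= 1L &&
      identical(paste(s[(pos - k + 1L):pos], collapse = ""),
                paste(ins, collapse = ""))) {
    return(sprintf("c.%sdup%s", span(pos - k + 1L, pos),
                   paste(ins, collapse = "")))
  }
  sprintf("c.%d_%dins%s", pos, pos + 1L, paste(ins, collapse = ""))
}

#' PTC codon index implied by a protein-level HGVS string
#'
#' For a nonsense consequence `p.Xaa{pos}*` the premature stop sits at codon
#' `pos`; for a frameshift `p.Xaa{pos}Yaafs*{N}` it sits at `pos + N - 1`
#' (the frameshift convention counts the first changed residue as 1).
#' Both three-letter (Table-style) and one-letter residue codes are accepted,
#' `Ter` as well as `*` for the stop.
#'
#' @param s protein HGVS string.
#' @return 1-based codon index of the premature stop.
#' @examples
#' ptc_codon_from_protein_hgvs("p.Lys92Argfs*9")  # 100
#' ptc_codon_from_protein_hgvs("p.Leu127*")       # 127
#' @export
ptc_codon_from_protein_hgvs <- function(s) {
  x <- gsub("[[:space:]]+", "", s)
  x <- sub("^p\\.\\(", "p.", sub("\\)$", "", x))
  aa <- "([A-Z][a-z]{2}|[A-Z*])"
  m <- regexec(paste0("^p\\.", aa, "(\\d+)(\\*|Ter)$"), x)
  g <- regmatches(x, m)[[1]]
  if (length(g)) {
    check_aa(s, g[2])
    return(as.integer(g[3]))
  }
  m <- regexec(paste0("^p\\.", aa, "(\\d+)", aa, "fs(\\*|Ter)(\\d+)$"), x)
  g <- regmatches(x, m)[[1]]
  if (length(g)) {
    check_aa(s, g[2]); check_aa(s, g[4])
    return(as.integer(g[3]) + as.integer(g[6]) - 1L)
  }
  nmd_error("nmdscan_unsupported_nomenclature",
            sprintf("unsupported protein HGVS form: '%s' (expected p.Xaa#* or p.Xaa#Yaafs*N)", s))
}

check_aa <- function(raw, code) {
  ok <- if (nchar(code) == 3L) code %in% AA_1TO3 else code %in% names(AA_1TO3)
  if (!ok) {
    nmd_error("nmdscan_unsupported_nomenclature",
              sprintf("unknown amino-acid code '%s' in '%s'", code, raw))
  }
  invisible(TRUE)
}
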