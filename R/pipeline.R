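# Orchestration: variant table in, classification report out.

#' Read a variant table
#'
#' Tab-separated with required column `hgvs_c`; optional `hgvs_p` (printed
#' protein consequence), `label`, and `edit_spec` (inline JSON
#' `{"insert_position": n, "inserted_sequence": "..."}` describing a splice
#' consequence as a [transcript_edit]).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) > 0 && !"hgvs_c" %in% names(df)) {
    nmd_error("nmdscan_io_error",
              sprintf("variant TSV %s lacks an hgvs_c column", path))
  }
  for (col in c("hgvs_p", "label", "edit_spec")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_character_, nrow(df))
  }
  df
}

resolve_row <- function(t, hgvs_c, hgvs_p, edit_spec) {
  # Resolution order: sequence application > transcript edit > printed
  # protein consequence.
  res <- tryCatch({
    v <- parse_cdna_hgvs(hgvs_c)
    mutant <- apply_variant(t, v)
    ptc <- find_ptc(t, mutant)
    if (is.null(ptc)) {
      nmd_error("nmdscan_validation_error",
                sprintf("'%s' does not create a PTC", hgvs_c))
    }
    list(ptc = ptc, route = "sequence", kind = v$kind)
  }, nmdscan_not_coding_edit = function(e) e)

  if (!inherits(res, "condition")) return(res)

  if (!is.na(edit_spec) && nzchar(edit_spec)) {
    spec <- jsonlite::fromJSON(edit_spec)
    ed <- transcript_edit(spec$insert_position, spec$inserted_sequence)
    mutant <- apply_variant(t, ed)
    ptc <- find_ptc(t, mutant)
    if (is.null(ptc)) {
      nmd_error("nmdscan_validation_error",
                sprintf("edit_spec for '%s' does not create a PTC", hgvs_c))
    }
    return(list(ptc = ptc, route = "edit", kind = "splice"))
  }
  if (!is.na(hgvs_p) && nzchar(hgvs_p)) {
    ci <- ptc_codon_from_protein_hgvs(hgvs_p)
    # protein-route calls carry the reference-frame stop coordinates
    return(list(ptc = ptc_call(ci, 3L * ci - 2L, protein_hgvs = hgvs_p),
                route = "protein", kind = "splice"))
  }
  stop(res)
}

variant_class <- function(route, kind, protein) {
  if (route %in% c("edit", "protein")) return("splicing")
  if (!is.na(protein) && grepl("fs\\*", protein)) return("frameshift")
  if (kind == "substitution") return("nonsense")
  if (!is.na(protein) && grepl("^p\\.[A-Z][a-z]{2}\\d+\\*$", protein)) {
    return("nonsense")
  }
  "other"
}

#' Classify a variant table against a transcript's NMD rules
#'
#' For each input variant the premature stop is located (by sequence
#' application when the HGVS string is a coding edit; otherwise via a
#' supplied [transcript_edit] or the printed protein consequence) and
#' classified with [classify_ptc]. When a computed and a printed protein
#' consequence both exist and disagree the row is flagged discordant;
#' classification uses the computed call unless `prefer_printed = TRUE`.
#'
#' @param transcript a [transcript_model] or path to a transcript JSON.
#' @param variants a data.frame ([read_variant_tsv] layout) or TSV path.
#' @param cfg an [nmd_config].
#' @param prefer_printed classify on the printed protein consequence when it
#'   disagrees with the computed one.
#' @param strict error out when any row fails to resolve (otherwise the row
#'   carries an error record and is excluded from the summary tallies).
#' @return object of class `classification_report`: `rows` (one data.frame
#'   row per input variant, input order), `summary`, `region`, `config`.
#' @export
run_classification <- function(transcript, variants, cfg = nmd_config(),
                               prefer_printed = FALSE, strict = FALSE) {
  t <- if (inherits(transcript, "transcript_model")) transcript
       else load_transcript(transcript, "json")
  df <- if (is.data.frame(variants)) variants else read_variant_tsv(variants)
  for (col in c("hgvs_p", "label", "edit_spec")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_character_, nrow(df))
  }
  region <- trigger_region(t, cfg)

  rows <- lapply(seq_len(nrow(df)), function(i) {
    out <- data.frame(
      label = if (is.na(df$label[i])) sprintf("v%03d", i) else df$label[i],
      hgvs_c = df$hgvs_c[i], hgvs_p_printed = df$hgvs_p[i],
      hgvs_p_computed = NA_character_, discordant = FALSE,
      route = NA_character_, class = NA_character_,
      ptc_codon = NA_integer_, ptc_cds_nt = NA_integer_,
      status = NA_character_, rules_fired = NA_character_,
      borderline = NA, error = NA_character_,
      stringsAsFactors = FALSE)
    res <- tryCatch(
      resolve_row(t, df$hgvs_c[i], df$hgvs_p[i], df$edit_spec[i]),
      error = function(e) e)
    if (inherits(res, "condition")) {
      out$error <- conditionMessage(res)
      return(out)
    }
    ptc <- res$ptc
    out$route <- res$route
    out$hgvs_p_computed <- if (res$route == "sequence") ptc$protein_hgvs
                           else NA_character_
    printed <- df$hgvs_p[i]
    if (!is.na(printed) && nzchar(printed) && res$route == "sequence") {
      printed_codon <- tryCatch(ptc_codon_from_protein_hgvs(printed),
                                error = function(e) NA_integer_)
      same <- identical(gsub("[[:space:]]", "", printed), ptc$protein_hgvs) ||
        (!is.na(printed_codon) && printed_codon == ptc$codon_index)
      out$discordant <- !same
      if (out$discordant && prefer_printed && !is.na(printed_codon)) {
        ptc <- ptc_call(printed_codon, 3L * printed_codon - 2L,
                        protein_hgvs = printed)
      }
    }
    call <- classify_ptc(t, ptc, cfg)
    out$class <- variant_class(res$route, res$kind,
                               if (res$route == "sequence") ptc$protein_hgvs
                               else printed)
    out$ptc_codon <- ptc$codon_index
    out$ptc_cds_nt <- ptc$cds_first_nt
    out$status <- call$status
    out$rules_fired <- paste(call$rules_fired, collapse = ",")
    out$borderline <- call$borderline
    out
  })
  rows <- if (length(rows)) do.call(rbind, rows) else empty_rows()
  if (strict && any(!is.na(rows$error))) {
    nmd_error("nmdscan_strict_error",
              sprintf("%d variant(s) failed to resolve: %s",
                      sum(!is.na(rows$error)),
                      paste(rows$label[!is.na(rows$error)], collapse = ", ")))
  }
  ok <- is.na(rows$error)
  rule_names <- c("last_exon", "junction_proximal", "long_exon",
                  "start_proximal")
  by_rule <- vapply(rule_names, function(r) {
    sum(ok & vapply(strsplit(rows$rules_fired, ","),
                    function(x) r %in% x, TRUE))
  }, 0L)
  summary <- list(
    n_total = nrow(rows), n_error = sum(!ok),
    by_class = table(factor(rows$class[ok],
                            c("nonsense", "frameshift", "splicing", "other"))),
    by_rule = by_rule,
    n_escape = sum(rows$status[ok] == "escape"),
    n_trigger = sum(rows$status[ok] == "trigger"),
    n_borderline = sum(ok & rows$borderline))
  structure(list(rows = rows, summary = summary, region = region,
                 config = cfg, transcript_id = t$transcript_id),
            class = "classification_report")
}

empty_rows <- function() {
  data.frame(label = character(), hgvs_c = character(),
             hgvs_p_printed = character(), hgvs_p_computed = character(),
             discordant = logical(), route = character(), class = character(),
             ptc_codon = integer(), ptc_cds_nt = integer(),
             status = character(), rules_fired = character(),
             borderline = logical(), error = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.classification_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("classification_report [%s]: %d variant(s)\n",
              x$transcript_id, s$n_total))
  cat(sprintf("  %s\n", format_region(x$region)))
  cat(sprintf("  escape %d / trigger %d (borderline %d)%s\n",
              s$n_escape, s$n_trigger, s$n_borderline,
              if (s$n_error) sprintf(" / errors %d", s$n_error) else ""))
  cat(sprintf("  by class: %s\n",
              paste(sprintf("%s %d", names(s$by_class), s$by_class),
                    collapse = ", ")))
  cat(sprintf("  by rule: %s\n",
              paste(sprintf("%s %d", names(s$by_rule), s$by_rule),
                    collapse = ", ")))
  invisible(x)
}

#' Compute the trigger region for a transcript source
#'
#' @param transcript a [transcript_model] or path to a transcript JSON.
#' @param cfg an [nmd_config].
#' @return an [nmd_region] (see [trigger_region]).
#' @export
run_region <- function(transcript, cfg = nmd_config()) {
  t <- if (inherits(transcript, "transcript_model")) transcript
       else load_transcript(transcript, "json")
  trigger_region(t, cfg)
}

#' Write report rows as TSV
#' @param report a `classification_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "classification_report"))
  utils::write.table(report$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a full report (rows, summary, region, config) as JSON
#'
#' The payload carries no timestamps, so identical inputs give
#' byte-identical files.
#'
#' @inheritParams write_report_tsv
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "classification_report"))
  region <- report$region
  payload <- list(
    transcript_id = report$transcript_id,
    region = list(nt_lo = region$nt_lo, nt_hi = region$nt_hi,
                  codon_lo = region$codon_lo, codon_hi = region$codon_hi,
                  empty = region$empty,
                  excluded_intervals = region$excluded_intervals,
                  rendered = format_region(region)),
    config = unclass(report$config),
    summary = list(n_total = report$summary$n_total,
                   n_error = report$summary$n_error,
                   by_class = as.list(report$summary$by_class),
                   by_rule = as.list(report$summary$by_rule),
                   n_escape = report$summary$n_escape,
                   n_trigger = report$summary$n_trigger,
                   n_borderline = report$summary$n_borderline),
    rows = report$rows)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}
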