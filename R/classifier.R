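# Surrogate-marker molecular classification of endometrial carcinoma.
#
# Each tumour is scored on three surrogate markers — POLE exonuclease-domain
# mutation status, mismatch-repair protein IHC (or MSI assay), and p53 IHC
# (or TP53 mutation) — and assigned exactly one molecular class. Tumours
# carrying more than one classifying feature ("multiple-classifier" tumours)
# are resolved by the priority POLEmut > MMRd > p53abn, reflecting the
# evidence that TP53 mutations arising on an ultramutated or hypermutated
# background are passenger events.

MMR_PROTEINS <- c("MLH1", "PMS2", "MSH2", "MSH6")

#' Default whitelist of pathogenic POLE exonuclease-domain variants
#'
#' Hotspot substitutions accepted as pathogenic without further scoring.
#' Extensible: pass your own vector to \code{\link{assess_pole}}, or flag
#' individual variants \code{pathogenic} to inject verdicts from an external
#' pathogenicity score.
#'
#' @return character vector of one-letter protein changes.
#' @export
default_pole_whitelist <- function() {
  c("P286R", "V411L", "A456P", "S459F", "P436R", "S297F", "F367S", "L424I", "M295R")
}

AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
            Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
            Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
            Tyr = "Y", Val = "V")

#' Normalise a protein change to one-letter form
#'
#' \code{"p.Pro286Arg"} and \code{"P286R"} both normalise to \code{"P286R"}.
#' @param x character vector of protein changes.
#' @return one-letter form, upper case; unparseable inputs returned stripped
#'   of the \code{p.} prefix.
#' @export
normalize_protein_change <- function(x) {
  y <- sub("^p\\.", "", x)
  m <- regmatches(y, regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$", y))
  vapply(seq_along(y), function(i) {
    g <- m[[i]]
    if (length(g) == 4 && g[2] %in% names(AA3TO1) && g[4] %in% names(AA3TO1)) {
      paste0(AA3TO1[[g[2]]], g[3], AA3TO1[[g[4]]])
    } else toupper(y[i])
  }, character(1))
}

#' Score a p53 immunohistochemistry observation
#'
#' Abnormal (mutation-pattern) staining is strong nuclear expression in over
#' 75\% of tumour cells (overexpression), complete loss of nuclear stain
#' with intact internal control (complete absence), or cytoplasmic staining.
#' An abrupt regionally abnormal pattern occupying at least 10\% of tumour
#' volume is scored subclonal-abnormal. Uninterpretable patterns, or complete
#' absence without internal control, are inconclusive.
#'
#' @param obs a list/one-row data frame with fields
#'   \code{percent_strong_nuclear} (0-100), \code{internal_control_positive},
#'   \code{cytoplasmic_staining}, \code{complete_absence},
#'   \code{regional_abnormal_fraction} (0-100, 0 if no regional pattern),
#'   \code{interpretable}.
#' @return one of \code{"abnormal"}, \code{"subclonal_abnormal"},
#'   \code{"wildtype"}, \code{"inconclusive"}.
#' @export
score_p53_ihc <- function(obs) {
  assert_in_range(obs$percent_strong_nuclear, 0, 100, "percent_strong_nuclear")
  assert_in_range(obs$regional_abnormal_fraction, 0, 100, "regional_abnormal_fraction")
  if (isTRUE(obs$complete_absence) && obs$percent_strong_nuclear > 75) {
    stop_mcec("complete_absence is incompatible with >75% strong nuclear staining")
  }
  if (!isTRUE(obs$interpretable)) return("inconclusive")
  if (isTRUE(obs$complete_absence) && !isTRUE(obs$internal_control_positive)) {
    return("inconclusive")  # cannot distinguish true loss from assay failure
  }
  if (obs$regional_abnormal_fraction > 0) {
    # abrupt regional abnormal pattern: subclonal if it reaches 10% of volume
    if (obs$regional_abnormal_fraction >= 10) return("subclonal_abnormal")
    return("wildtype")
  }
  if (obs$percent_strong_nuclear > 75) return("abnormal")
  if (isTRUE(obs$complete_absence)) return("abnormal")
  if (isTRUE(obs$cytoplasmic_staining)) return("abnormal")
  "wildtype"
}

#' Score a panel of MMR protein IHC observations
#'
#' Deficient if any protein shows loss of nuclear staining with positive
#' internal control; an abrupt, complete regional loss scores
#' subclonal-deficient (counted as deficient for classification).
#' Heterogeneous/patchy staining and stains without internal control are not
#' evidence of deficiency; if no protein is interpretable the panel is
#' inconclusive.
#'
#' @param observations data frame with columns \code{protein} (MLH1/PMS2/
#'   MSH2/MSH6), \code{nuclear_expression} (\code{retained}, \code{lost},
#'   \code{regional_abrupt_loss}, \code{heterogeneous_patchy}) and
#'   \code{internal_control_positive}.
#' @return one of \code{"deficient"}, \code{"subclonal_deficient"},
#'   \code{"proficient"}, \code{"inconclusive"}.
#' @export
score_mmr_ihc <- function(observations) {
  if (is.null(observations) || nrow(observations) == 0) {
    stop_mcec("at least one MMR IHC observation is required")
  }
  bad <- setdiff(observations$protein, MMR_PROTEINS)
  if (length(bad)) stop_mcec("unknown MMR protein: ", paste(bad, collapse = ", "))
  expr <- observations$nuclear_expression
  ctrl <- observations$internal_control_positive
  if (any(expr == "regional_abrupt_loss" & !ctrl)) {
    stop_mcec("regional_abrupt_loss requires positive internal control")
  }
  if (any(expr == "lost" & ctrl)) return("deficient")
  if (any(expr == "regional_abrupt_loss")) return("subclonal_deficient")
  interpretable <- (expr == "retained" & ctrl)
  if (any(interpretable)) return("proficient")
  "inconclusive"
}

#' Assess POLE exonuclease-domain variant pathogenicity
#'
#' A tumour is POLE-mutant when any of its POLE variants matches the
#' pathogenic whitelist or carries an explicit \code{pathogenic} call (e.g.
#' from an external pathogenicity score). Variants flagged
#' \code{non_pathogenic} never count, even if whitelisted.
#'
#' @param variants data frame with columns \code{protein_change} and
#'   \code{pathogenicity_call} (\code{pathogenic}, \code{non_pathogenic},
#'   \code{unknown}); may be empty or NULL.
#' @param whitelist character vector of pathogenic protein changes.
#' @return \code{"pathogenic_mut"} or \code{"no_pathogenic_mut"}.
#' @export
assess_pole <- function(variants, whitelist = default_pole_whitelist()) {
  if (is.null(variants) || nrow(variants) == 0) return("no_pathogenic_mut")
  pc <- normalize_protein_change(variants$protein_change)
  call <- variants$pathogenicity_call %||% rep("unknown", nrow(variants))
  wl <- normalize_protein_change(whitelist)
  hit <- (pc %in% wl & call != "non_pathogenic") | call == "pathogenic"
  if (any(hit)) "pathogenic_mut" else "no_pathogenic_mut"
}

#' Filter TP53 variants for molecular profiling
#'
#' Retains (likely) pathogenic variants and variants of unknown significance;
#' excludes variants classified benign by SIFT, neutral by VEP, or clinically
#' benign. Variants with entirely unknown annotations are retained as VUS.
#'
#' @param variants data frame with columns \code{protein_change},
#'   \code{codon}, \code{sift_class} (\code{benign}/\code{other}/
#'   \code{unknown}), \code{vep_class} (\code{neutral}/\code{other}/
#'   \code{unknown}), \code{clinical_class} (\code{pathogenic},
#'   \code{likely_pathogenic}, \code{VUS}, \code{benign}, \code{unknown}).
#' @return the retained rows, with \code{clinical_class} \code{unknown}
#'   rewritten to \code{VUS} and a logical \code{retained} attribute-free
#'   verdict applied.
#' @export
filter_tp53 <- function(variants) {
  if (is.null(variants) || nrow(variants) == 0) {
    return(variants[0, , drop = FALSE] %||% data.frame())
  }
  sift <- variants$sift_class %||% rep("unknown", nrow(variants))
  vep <- variants$vep_class %||% rep("unknown", nrow(variants))
  clin <- variants$clinical_class %||% rep("unknown", nrow(variants))
  excluded <- sift == "benign" | vep == "neutral" | clin == "benign"
  out <- variants[!excluded, , drop = FALSE]
  if (nrow(out)) out$clinical_class[ (out$clinical_class %||% "unknown") == "unknown"] <- "VUS"
  out
}

#' Resolve a tumour's molecular class from its surrogate-marker assays
#'
#' Builds the raw classifier set \{POLEmut, MMRd, p53abn\} from the three
#' marker axes and resolves multiple-classifier tumours by the priority
#' POLEmut > MMRd > p53abn > NSMP:
#' \itemize{
#'   \item MMR axis: IHC panel if present; otherwise an MSI assay
#'     (MSI_H counts as MMRd). When both are present and discordant, IHC
#'     wins and the discordance is recorded in the rationale.
#'   \item p53 axis: p53 IHC if present and conclusive; an inconclusive or
#'     missing stain falls back to filtered TP53 variants (any retained
#'     variant counts as abnormal). Subclonal-abnormal staining counts as
#'     p53abn but is flagged separately.
#' }
#'
#' @param assay a list with fields \code{sample_id}, \code{pole_variants}
#'   (data frame or NULL), \code{mmr_ihc} (data frame or NULL),
#'   \code{msi_call} (\code{MSI_H}/\code{MSS}/\code{unknown}/NULL),
#'   \code{p53_ihc} (list or NULL), \code{tp53_variants} (data frame or NULL).
#' @param pole_whitelist whitelist passed to \code{\link{assess_pole}}.
#' @return a list of class \code{classification_result} with fields
#'   \code{sample_id}, \code{p53_status}, \code{mmr_status},
#'   \code{pole_status}, \code{raw_classifier_set}, \code{resolved_class},
#'   \code{subclonal_p53}, \code{rationale}.
#' @export
resolve_class <- function(assay, pole_whitelist = default_pole_whitelist()) {
  rationale <- character(0)
  note <- function(id) rationale <<- c(rationale, id)

  has_mmr_axis <- (!is.null(assay$mmr_ihc) && nrow(assay$mmr_ihc) > 0) ||
    (!is.null(assay$msi_call) && assay$msi_call %in% c("MSI_H", "MSS"))
  # an empty-but-present TP53 variant table means "sequenced, nothing found"
  has_p53_axis <- !is.null(assay$p53_ihc) || !is.null(assay$tp53_variants)

  if (!has_mmr_axis || !has_p53_axis) {
    return(structure(list(
      sample_id = assay$sample_id,
      p53_status = "inconclusive", mmr_status = "inconclusive",
      pole_status = assess_pole(assay$pole_variants, pole_whitelist),
      raw_classifier_set = character(0),
      resolved_class = "unclassifiable", subclonal_p53 = FALSE,
      rationale = c(if (!has_mmr_axis) "missing_mmr_axis",
                    if (!has_p53_axis) "missing_p53_axis")),
      class = "classification_result"))
  }

  ## POLE axis
  pole_status <- assess_pole(assay$pole_variants, pole_whitelist)
  if (pole_status == "pathogenic_mut") note("pole_pathogenic_variant")

  ## MMR axis
  if (!is.null(assay$mmr_ihc) && nrow(assay$mmr_ihc) > 0) {
    mmr_status <- score_mmr_ihc(assay$mmr_ihc)
    note(paste0("mmr_ihc_", mmr_status))
    if (!is.null(assay$msi_call) && assay$msi_call %in% c("MSI_H", "MSS")) {
      ihc_def <- mmr_status %in% c("deficient", "subclonal_deficient")
      msi_def <- assay$msi_call == "MSI_H"
      if (mmr_status != "inconclusive" && ihc_def != msi_def) note("msi_ihc_discordant_ihc_wins")
      if (mmr_status == "inconclusive") {
        mmr_status <- if (msi_def) "deficient" else "proficient"
        note("mmr_from_msi_after_inconclusive_ihc")
      }
    }
  } else {
    mmr_status <- if (assay$msi_call == "MSI_H") "deficient" else "proficient"
    note("mmr_from_msi")
  }

  ## p53 axis
  tp53_retained <- filter_tp53(assay$tp53_variants)
  p53_status <- if (!is.null(assay$p53_ihc)) {
    s <- score_p53_ihc(assay$p53_ihc)
    note(paste0("p53_ihc_", s))
    s
  } else "inconclusive"
  if (p53_status == "inconclusive") {
    if (!is.null(assay$tp53_variants)) {
      p53_status <- if (nrow(tp53_retained) > 0) "abnormal" else "wildtype"
      note("p53_from_tp53_sequencing")
    }
  }

  raw <- character(0)
  if (pole_status == "pathogenic_mut") raw <- c(raw, "POLEmut")
  if (mmr_status %in% c("deficient", "subclonal_deficient")) raw <- c(raw, "MMRd")
  if (p53_status %in% c("abnormal", "subclonal_abnormal")) raw <- c(raw, "p53abn")

  resolved <- if ("POLEmut" %in% raw) {
    if (length(raw) > 1) note("multiple_classifier_resolved_POLEmut")
    "POLEmut"
  } else if ("MMRd" %in% raw) {
    if (length(raw) > 1) note("multiple_classifier_resolved_MMRd")
    "MMRd"
  } else if ("p53abn" %in% raw) {
    "p53abn"
  } else if (p53_status == "inconclusive" || mmr_status == "inconclusive") {
    note("inconclusive_axis")
    "unclassifiable"
  } else {
    "NSMP"
  }

  structure(list(
    sample_id = assay$sample_id,
    p53_status = p53_status, mmr_status = mmr_status, pole_status = pole_status,
    raw_classifier_set = raw,
    resolved_class = resolved,
    subclonal_p53 = p53_status == "subclonal_abnormal",
    rationale = rationale),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s: %s  [raw: %s]\n", x$sample_id, x$resolved_class,
              if (length(x$raw_classifier_set)) paste(x$raw_classifier_set, collapse = "+") else "none"))
  invisible(x)
}

raw_set_label <- function(raw) {
  if (length(raw) == 0) return("none")
  paste(intersect(c("MMRd", "POLEmut", "p53abn"), raw), collapse = "-")
}

#' Tabulate a cohort of classification results
#'
#' Counts and percentages per raw classifier combination and per resolved
#' class. Percentages are computed against the total profiled cohort size and
#' rounded half-up.
#'
#' @param results list of \code{classification_result} objects.
#' @param total_n denominator for percentages (default: number of results).
#' @param digits decimal places for percentages (default 1).
#' @return list with \code{n}, data frames \code{by_raw_set} and
#'   \code{by_resolved_class} (columns label, count, percent), and
#'   \code{n_multiple_classifier} / \code{multiple_classifier_percent}.
#' @export
tabulate_cohort <- function(results, total_n = length(results), digits = 1) {
  if (length(results) == 0) stop_mcec("no classification results")
  raw_labels <- vapply(results, function(r) raw_set_label(r$raw_classifier_set), character(1))
  resolved <- vapply(results, function(r) r$resolved_class, character(1))
  pct <- function(k) round_half_up(100 * k / total_n, digits)

  tab_raw <- sort(table(raw_labels), decreasing = TRUE)
  by_raw <- data.frame(raw_set = names(tab_raw), count = as.integer(tab_raw),
                       percent = pct(as.integer(tab_raw)), row.names = NULL)
  tab_res <- table(factor(resolved, levels = c("POLEmut", "MMRd", "p53abn", "NSMP", "unclassifiable")))
  by_res <- data.frame(resolved_class = names(tab_res), count = as.integer(tab_res),
                       percent = pct(as.integer(tab_res)), row.names = NULL)
  n_multi <- sum(vapply(results, function(r) length(r$raw_classifier_set) > 1, logical(1)))
  list(n = length(results), total_n = total_n,
       by_raw_set = by_raw, by_resolved_class = by_res,
       n_multiple_classifier = n_multi,
       multiple_classifier_percent = pct(n_multi))
}

#' Classify every sample in a sample sheet
#'
#' @param samples sample sheet data frame from \code{\link{read_sample_sheet}}.
#' @param pole_whitelist whitelist for \code{\link{assess_pole}}.
#' @return list of \code{classification_result}, one per row.
#' @export
classify_cohort <- function(samples, pole_whitelist = default_pole_whitelist()) {
  if (anyDuplicated(samples$sample_id)) stop_mcec("duplicate sample_id in sample sheet")
  lapply(seq_len(nrow(samples)), function(i) {
    resolve_class(sample_sheet_row_to_assay(samples[i, , drop = FALSE]), pole_whitelist)
  })
}

#' Flatten classification results to a data frame
#' @param results list of \code{classification_result}.
#' @return data frame with one row per sample.
#' @export
classification_table <- function(results) {
  data.frame(
    sample_id = vapply(results, `[[`, character(1), "sample_id"),
    pole_status = vapply(results, `[[`, character(1), "pole_status"),
    mmr_status = vapply(results, `[[`, character(1), "mmr_status"),
    p53_status = vapply(results, `[[`, character(1), "p53_status"),
    raw_classifier_set = vapply(results, function(r) raw_set_label(r$raw_classifier_set), character(1)),
    resolved_class = vapply(results, `[[`, character(1), "resolved_class"),
    subclonal_p53 = vapply(results, `[[`, logical(1), "subclonal_p53"),
    rationale = vapply(results, function(r) paste(r$rationale, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}
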