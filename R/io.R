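# File dialects.
#
# Sample sheet (TSV, one row per tumour):
#   sample_id, pole_variants (semicolon-joined "protein_change:call", call one
#   of pathogenic/non_pathogenic/unknown; empty = none detected),
#   mmr_mlh1/mmr_pms2/mmr_msh2/mmr_msh6 (retained, lost,
#   regional_abrupt_loss, heterogeneous_patchy, lost_no_control; empty = not
#   stained), msi (MSI_H/MSS; empty = not assayed), p53_percent_strong (0-100),
#   p53_regional_fraction (0-100), p53_flags (semicolon-joined subset of
#   complete_absence, cytoplasmic, no_internal_control, uninterpretable,
#   not_stained), tp53_variants (JSON array; "[]" = sequenced and negative,
#   empty = not sequenced).
#
# SNV table: MAF-like TSV with sample_id, chrom, pos (1-based), ref, alt,
# optional context (3-mer) and gene. Survival table: sample_id, time (months),
# event (TRUE/FALSE or 0/1), group, stage.

split_semicolon <- function(x) {
  if (is.na(x) || x == "") character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

parse_pole_field <- function(x) {
  entries <- split_semicolon(x)
  if (length(entries) == 0) {
    return(data.frame(protein_change = character(0),
                      pathogenicity_call = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(entries, ":", fixed = TRUE)
  data.frame(
    protein_change = vapply(parts, `[[`, character(1), 1),
    pathogenicity_call = vapply(parts, function(p) if (length(p) > 1) p[2] else "unknown",
                                character(1)),
    stringsAsFactors = FALSE)
}

parse_mmr_fields <- function(row) {
  cols <- c(MLH1 = "mmr_mlh1", PMS2 = "mmr_pms2", MSH2 = "mmr_msh2", MSH6 = "mmr_msh6")
  obs <- lapply(names(cols), function(p) {
    v <- row[[cols[[p]]]]
    if (is.na(v) || v == "") return(NULL)
    if (v == "lost_no_control") {
      data.frame(protein = p, nuclear_expression = "lost",
                 internal_control_positive = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(protein = p, nuclear_expression = v,
                 internal_control_positive = TRUE, stringsAsFactors = FALSE)
    }
  })
  obs <- do.call(rbind, obs)
  if (is.null(obs) || nrow(obs) == 0) NULL else obs
}

parse_p53_fields <- function(row) {
  flags <- split_semicolon(row$p53_flags %||% "")
  if ("not_stained" %in% flags) return(NULL)
  pct <- suppressWarnings(as.numeric(row$p53_percent_strong))
  reg <- suppressWarnings(as.numeric(row$p53_regional_fraction))
  if (is.na(pct) && is.na(reg) && length(flags) == 0) return(NULL)
  list(percent_strong_nuclear = if (is.na(pct)) 0 else pct,
       internal_control_positive = !("no_internal_control" %in% flags),
       cytoplasmic_staining = "cytoplasmic" %in% flags,
       complete_absence = "complete_absence" %in% flags,
       regional_abnormal_fraction = if (is.na(reg)) 0 else reg,
       interpretable = !("uninterpretable" %in% flags))
}

parse_tp53_field <- function(x) {
  if (is.na(x) || x == "") return(NULL)  # not sequenced
  v <- jsonlite::fromJSON(x, simplifyDataFrame = TRUE)
  if (length(v) == 0 || (is.data.frame(v) && nrow(v) == 0)) {
    return(data.frame(protein_change = character(0), codon = integer(0),
                      sift_class = character(0), vep_class = character(0),
                      clinical_class = character(0), channel = character(0),
                      stringsAsFactors = FALSE))
  }
  as.data.frame(v, stringsAsFactors = FALSE)
}

#' Convert one sample-sheet row into an assay object
#' @param row one-row data frame from \code{\link{read_sample_sheet}}.
#' @return assay list accepted by \code{\link{resolve_class}}.
#' @export
sample_sheet_row_to_assay <- function(row) {
  msi <- row$msi %||% ""
  list(sample_id = row$sample_id,
       pole_variants = parse_pole_field(row$pole_variants %||% ""),
       mmr_ihc = parse_mmr_fields(row),
       msi_call = if (is.na(msi) || msi == "") NULL else msi,
       p53_ihc = parse_p53_fields(row),
       tp53_variants = parse_tp53_field(row$tp53_variants %||% ""))
}

#' Read a surrogate-marker sample sheet
#' @param path TSV path.
#' @return data frame, one row per sample; columns as documented in the
#'   package README.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", na.strings = NULL)
  if (!"sample_id" %in% names(df)) stop_mcec("sample sheet lacks sample_id")
  df
}

#' Read a MAF-like SNV table
#' @param path TSV with sample_id (or sample), chrom, pos, ref, alt, optional
#'   context/gene.
#' @return normalised data frame.
#' @export
read_snv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("sample" %in% names(df) && !"sample_id" %in% names(df)) {
    names(df)[names(df) == "sample"] <- "sample_id"
  }
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_mcec("SNV table lacks columns: ", paste(miss, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df
}

#' Read a survival table
#' @param path TSV with sample_id, time, event, group, optional stage.
#' @return data frame with typed columns.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_mcec("survival table lacks columns: ", paste(miss, collapse = ", "))
  df$time <- as.numeric(df$time)
  ev <- df$event
  df$event <- if (is.logical(ev)) ev else ev %in% c("TRUE", "true", "1", 1, TRUE)
  df
}
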