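# 96-channel trinucleotide mutational spectra.
#
# Single-nucleotide variants are classified into the standard 96 categories:
# 6 pyrimidine-centred substitution classes (C>A, C>G, C>T, T>A, T>C, T>G)
# crossed with the 16 combinations of 5' and 3' flanking bases. Variants
# reported on the purine strand are reverse-complemented. The canonical
# ordering used throughout (serialisation, catalog matrices) is
# substitution-major with alphabetical flanks: A[C>A]A, A[C>A]C, ...,
# T[T>G]T.

SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Canonical labels of the 96 trinucleotide substitution categories
#'
#' Substitution-major ordering (C>A, C>G, C>T, T>A, T>C, T>G), within each
#' substitution the 5' flank varies slowest, flanks alphabetical. Labels are
#' of the form \code{"T[C>A]T"}.
#'
#' @return character vector of length 96.
#' @export
spectrum_channels <- function() {
  labs <- character(96)
  i <- 0L
  for (s in SUBSTITUTIONS) for (f5 in BASES) for (f3 in BASES) {
    i <- i + 1L
    labs[i] <- paste0(f5, "[", s, "]", f3)
  }
  labs
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  # vectorised reverse complement of short upper-case sequences; fast path
  # for the 3-mers that dominate catalog construction
  comp <- chartr("ACGT", "TGCA", x)
  if (all(nchar(x) == 3)) {
    return(paste0(substr(comp, 3, 3), substr(comp, 2, 2), substr(comp, 1, 1)))
  }
  vapply(strsplit(comp, ""), function(b) paste(rev(b), collapse = ""), character(1))
}

#' Map a substitution with trinucleotide context to its 96-channel index
#'
#' Purine-reference substitutions (ref A or G) are reverse-complemented onto
#' the pyrimidine strand before lookup, so e.g. G>T in context AGA maps to
#' the same channel as C>A in context TCT.
#'
#' Vectorised over \code{ref}, \code{alt} and \code{context}. Records with an
#' ambiguous base (anything outside A/C/G/T) or a context whose middle base
#' does not match \code{ref} return \code{NA}; callers are expected to skip
#' and count them.
#'
#' @param ref,alt single reference and alternate bases.
#' @param context 3-mer centred on the variant position, reference strand.
#' @return integer vector of channel indices in 1..96 (NA where
#'   unclassifiable), named by channel label.
#' @export
normalize_to_pyrimidine <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)

  ok <- ref %in% BASES & alt %in% BASES & ref != alt &
    nchar(context) == 3 & substr(context, 2, 2) == ref &
    !grepl("[^ACGT]", context)

  idx <- rep(NA_integer_, n)
  if (!any(ok)) return(idx)

  r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
  pur <- r %in% c("A", "G")
  if (any(pur)) {
    r[pur] <- unname(REVCOMP[r[pur]])
    a[pur] <- unname(REVCOMP[a[pur]])
    ctx[pur] <- revcomp(ctx[pur])
  }
  sub_i <- match(paste0(r, ">", a), SUBSTITUTIONS)
  f5_i <- match(substr(ctx, 1, 1), BASES)
  f3_i <- match(substr(ctx, 3, 3), BASES)
  idx[ok] <- (sub_i - 1L) * 16L + (f5_i - 1L) * 4L + f3_i
  names(idx) <- ifelse(is.na(idx), NA, spectrum_channels()[idx])
  idx
}

new_spectrum96 <- function(sample_id, counts, skipped = 0L) {
  stopifnot(length(counts) == 96, all(counts >= 0))
  structure(
    list(sample_id = sample_id,
         counts = stats::setNames(as.integer(counts), spectrum_channels()),
         n_snv = sum(as.integer(counts)),
         n_skipped = as.integer(skipped)),
    class = "spectrum96")
}

#' @export
print.spectrum96 <- function(x, ...) {
  cat(sprintf("96-channel catalog for %s: %d SNVs (%d skipped)\n",
              x$sample_id, x$n_snv, x$n_skipped))
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  if (length(top)) {
    top <- utils::head(top, 5)
    cat("  top channels:", paste(sprintf("%s=%d", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

extract_context <- function(chrom, pos, reference) {
  # reference: named character vector of chromosome sequences, or a
  # Biostrings::DNAStringSet / FASTA path (Biostrings required for those)
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop_mcec("Biostrings is required to read a reference FASTA")
    }
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (inherits(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  missing <- setdiff(unique(chrom), names(reference))
  if (length(missing)) {
    stop_mcec("chromosomes absent from reference: ", paste(missing, collapse = ", "))
  }
  substring(reference[chrom], pos - 1L, pos + 1L)
}

#' Build a 96-channel catalog for one sample
#'
#' @param records data frame of SNV records with columns \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt} and either a \code{context}
#'   column (3-mer, reference strand) or a \code{reference} argument.
#'   A \code{sample_id} column, if present, must contain a single value.
#' @param reference optional reference genome: named character vector of
#'   chromosome sequences, a \code{Biostrings::DNAStringSet}, or a FASTA path.
#' @param sample_id label for the catalog; defaults to the records' sample id.
#' @return a \code{spectrum96} object. Non-SNV rows (multi-base ref/alt) and
#'   rows with ambiguous bases are skipped and counted in \code{n_skipped}.
#' @export
build_catalog <- function(records, reference = NULL, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- if (!is.null(records$sample_id) && nrow(records) > 0) {
      ids <- unique(records$sample_id)
      if (length(ids) > 1) stop_mcec("records span multiple samples; supply one sample")
      ids
    } else "sample"
  }
  if (nrow(records) == 0) return(new_spectrum96(sample_id, integer(96)))

  is_snv <- nchar(records$ref) == 1 & nchar(records$alt) == 1 &
    toupper(records$ref) %in% BASES & toupper(records$alt) %in% BASES
  snvs <- records[is_snv, , drop = FALSE]
  skipped <- sum(!is_snv)

  ctx_missing <- if (is.null(snvs$context)) rep(TRUE, nrow(snvs)) else
    is.na(snvs$context) | snvs$context == ""
  if (any(ctx_missing)) {
    if (is.null(reference)) {
      stop_mcec("records lack a trinucleotide context and no reference was supplied ",
                "(first offending row: ", which(ctx_missing)[1], ")")
    }
    snvs$context <- extract_context(snvs$chrom, snvs$pos, reference)
  }
  idx <- normalize_to_pyrimidine(snvs$ref, snvs$alt, snvs$context)
  skipped <- skipped + sum(is.na(idx))
  counts <- tabulate(idx[!is.na(idx)], nbins = 96)
  new_spectrum96(sample_id, counts, skipped)
}

#' Build a samples x 96 catalog matrix from a multi-sample SNV table
#'
#' Vectorised equivalent of calling \code{\link{build_catalog}} per sample.
#'
#' @inheritParams build_catalog
#' @return integer matrix, one row per sample (rownames = sample ids),
#'   96 columns in canonical channel order.
#' @export
build_catalog_matrix <- function(records, reference = NULL) {
  stopifnot(!is.null(records$sample_id))
  ids <- sort(unique(records$sample_id))
  is_snv <- nchar(records$ref) == 1 & nchar(records$alt) == 1 &
    toupper(records$ref) %in% BASES & toupper(records$alt) %in% BASES
  snvs <- records[is_snv, , drop = FALSE]
  if (is.null(snvs$context) && !is.null(reference)) {
    snvs$context <- extract_context(snvs$chrom, snvs$pos, reference)
  }
  idx <- normalize_to_pyrimidine(snvs$ref, snvs$alt, snvs$context)
  keep <- !is.na(idx)
  m <- matrix(0L, nrow = length(ids), ncol = 96,
              dimnames = list(ids, spectrum_channels()))
  if (any(keep)) {
    tab <- table(factor(snvs$sample_id[keep], levels = ids),
                 factor(idx[keep], levels = 1:96))
    m[] <- as.integer(tab)
  }
  m
}

catalog_counts <- function(x) {
  if (inherits(x, "spectrum96")) x$counts else {
    stopifnot(is.numeric(x), length(x) == 96)
    x
  }
}

#' Cosine-based distance between two mutational catalogs
#'
#' The mutational-change distance between two samples is
#' \code{(1 - cos(a, b)) / 2} on the catalog proportion vectors, which is 0
#' for identical spectra and 0.5 for spectra with disjoint support. An
#' alternate reading \code{1 - cos(a, b)/2} (range [0.5, 1]) is available via
#' \code{method}; the default is the reading under which the distance
#' vanishes on identical samples.
#'
#' @param a,b \code{spectrum96} objects or numeric vectors of length 96.
#' @param method distance form, \code{"half-one-minus-cos"} (default) or
#'   \code{"one-minus-half-cos"}.
#' @return scalar distance.
#' @export
spectrum_distance <- function(a, b, method = c("half-one-minus-cos", "one-minus-half-cos")) {
  method <- match.arg(method)
  ca <- catalog_counts(a); cb <- catalog_counts(b)
  if (any(ca < 0) || any(cb < 0)) stop_mcec("catalog counts must be non-negative")
  if (sum(ca) == 0 || sum(cb) == 0) {
    stop_mcec("spectrum distance undefined for a zero-count catalog")
  }
  pa <- ca / sum(ca); pb <- cb / sum(cb)
  cs <- sum(pa * pb) / (sqrt(sum(pa^2)) * sqrt(sum(pb^2)))
  cs <- min(1, max(-1, cs))
  if (method == "half-one-minus-cos") (1 - cs) / 2 else 1 - cs / 2
}

#' Fraction of a gene's variants falling in a set of channels
#'
#' E.g. the fraction of TP53 variants that are TCG>TTG (channel
#' \code{"T[C>T]G"}) substitutions.
#'
#' @param records SNV records for a single gene, with \code{ref}, \code{alt},
#'   \code{context} columns (or a precomputed \code{channel} column of labels).
#' @param channels character vector of channel labels to count.
#' @return fraction in [0, 1].
#' @export
gene_category_fraction <- function(records, channels) {
  if (nrow(records) == 0) stop_mcec("no records for the gene")
  bad <- setdiff(channels, spectrum_channels())
  if (length(bad)) stop_mcec("unknown channels: ", paste(bad, collapse = ", "))
  lab <- if (!is.null(records$channel)) {
    records$channel
  } else {
    names(normalize_to_pyrimidine(records$ref, records$alt, records$context))
  }
  sum(lab %in% channels) / nrow(records)
}

#' Write a samples x 96 catalog matrix as TSV
#' @param m catalog matrix from \code{\link{build_catalog_matrix}}.
#' @param path output file.
#' @export
write_catalog_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a catalog matrix written by \code{\link{write_catalog_tsv}}
#' @param path TSV file, first column sample_id, then 96 channel columns.
#' @return integer matrix with sample rownames.
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, spectrum_channels(), drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "integer"
  m
}
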