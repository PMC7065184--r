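# Somatic copy-number burden: fraction of genome altered (FGA).
#
# FGA is the proportion of genome length covered by segments whose mean
# log2 copy ratio exceeds an alteration threshold (default |log2R| > 0.2).
# The default denominator is the total segmented length, which is robust to
# SEG files that do not tile the whole genome; the whole-genome denominator
# is available when a genome model is supplied.

#' A toy two-chromosome genome model
#' @param n_chrom number of chromosomes.
#' @param length_bp length of each chromosome in base pairs.
#' @return named numeric vector of chromosome lengths.
#' @export
toy_genome <- function(n_chrom = 2, length_bp = 1e8) {
  stats::setNames(rep(length_bp, n_chrom), paste0("chr", seq_len(n_chrom)))
}

check_segments <- function(segments) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(segments)))
  if (any(segments$start > segments$end)) stop_mcec("segment start > end")
  by_chr <- split(segments, segments$chrom)
  for (s in by_chr) {
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop_mcec("overlapping segments on ", s$chrom[1])
    }
  }
  invisible(segments)
}

#' Fraction of genome copy-number altered for one sample
#'
#' @param segments data frame of one sample's segments with columns
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive),
#'   \code{value} (segment mean log2 copy ratio, or integer copy number with
#'   \code{value_type = "integer"}).
#' @param genome named vector of chromosome lengths; required for
#'   \code{denominator = "genome"}.
#' @param threshold alteration threshold on |log2 ratio| (default 0.2).
#' @param denominator \code{"segmented"} (default; total length covered by
#'   segments) or \code{"genome"} (total genome length).
#' @param value_type \code{"log2ratio"} (default) or \code{"integer"}.
#' @param neutral_cn neutral copy number for integer mode (default 2).
#' @param exclude_chroms chromosomes to drop (e.g. \code{c("chrX","chrY")});
#'   none by default.
#' @return fraction in [0, 1]; 0 with a warning for an empty segment set.
#' @export
fraction_genome_altered <- function(segments, genome = NULL, threshold = 0.2,
                                    denominator = c("segmented", "genome"),
                                    value_type = c("log2ratio", "integer"),
                                    neutral_cn = 2, exclude_chroms = character(0)) {
  denominator <- match.arg(denominator)
  value_type <- match.arg(value_type)
  if (threshold <= 0 && value_type == "log2ratio") stop_mcec("threshold must be > 0")
  if (!is.null(segments) && nrow(segments) > 0) {
    segments <- segments[!(segments$chrom %in% exclude_chroms), , drop = FALSE]
  }
  if (is.null(segments) || nrow(segments) == 0) {
    warning("empty segment set; FGA reported as 0")
    return(0)
  }
  check_segments(segments)
  len <- segments$end - segments$start + 1
  altered <- if (value_type == "log2ratio") abs(segments$value) > threshold
             else segments$value != neutral_cn
  denom <- if (denominator == "segmented") sum(len) else {
    if (is.null(genome)) stop_mcec("genome model required for whole-genome denominator")
    sum(genome[setdiff(names(genome), exclude_chroms)])
  }
  sum(len[altered]) / denom
}

#' SCNA distance between two samples
#'
#' Absolute difference of the two fractions of genome altered — the simplest
#' metric on [0, 1] consistent with using the per-sample fraction as the
#' copy-number descriptor.
#'
#' @param f_a,f_b fractions of genome altered in [0, 1].
#' @return |f_a - f_b|.
#' @export
scna_distance <- function(f_a, f_b) {
  assert_in_range(f_a, 0, 1, "fraction of genome altered")
  assert_in_range(f_b, 0, 1, "fraction of genome altered")
  abs(f_a - f_b)
}

#' Read a SEG file
#'
#' Tab-separated with header \code{ID chrom loc.start loc.end num.mark
#' seg.mean} (num.mark optional).
#'
#' @param path SEG file path.
#' @return data frame with columns \code{sample_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{num_mark} (NA if absent), \code{value}.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  pick <- function(cands) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) stop_mcec("SEG file lacks a column among: ", paste(cands, collapse = "/"))
    df[[i]]
  }
  out <- data.frame(
    sample_id = as.character(pick(c("id", "sample", "sample_id"))),
    chrom = as.character(pick(c("chrom", "chromosome", "chr"))),
    start = as.numeric(pick(c("loc.start", "start"))),
    end = as.numeric(pick(c("loc.end", "end"))),
    value = as.numeric(pick(c("seg.mean", "value", "log2"))),
    stringsAsFactors = FALSE)
  out$num_mark <- if (any(nm %in% c("num.mark", "num_mark"))) {
    as.numeric(df[[which(nm %in% c("num.mark", "num_mark"))[1]]])
  } else NA_real_
  out
}

#' Write segments as a SEG file
#' @param segments data frame with sample_id, chrom, start, end, value
#'   (and optionally num_mark).
#' @param path output path.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(ID = segments$sample_id, chrom = segments$chrom,
                    loc.start = segments$start, loc.end = segments$end,
                    num.mark = segments$num_mark %||% NA,
                    seg.mean = segments$value, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample FGA for a multi-sample segment table
#' @param segments multi-sample segment data frame (with \code{sample_id}).
#' @param ... passed to \code{\link{fraction_genome_altered}}.
#' @return named numeric vector of FGA values, sorted by sample id.
#' @export
fga_by_sample <- function(segments, ...) {
  ids <- sort(unique(segments$sample_id))
  vapply(ids, function(id) {
    fraction_genome_altered(segments[segments$sample_id == id, , drop = FALSE], ...)
  }, numeric(1))
}
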