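# Combined-distance clustering and reference-group assignment.
#
# Mutational-change distance (cosine-based, [0, 0.5]) and SCNA distance
# (|FGA difference|, [0, 1]) are combined per sample pair as the Euclidean
# norm of the two components. Samples are clustered agglomeratively on the
# resulting matrix; multiple-classifier "query" tumours are assigned to
# single-classifier reference groups by majority label within their cluster
# after cutting the tree.

#' Combine mutational and SCNA distances into a single metric
#'
#' Euclidean norm of the two component distances:
#' \code{sqrt(d_mut^2 + d_scna^2)}. Optionally rescales the mutational
#' component from [0, 0.5] to [0, 1] first.
#'
#' @param d_mut mutational-change distance(s), in [0, 0.5] by default.
#' @param d_scna SCNA distance(s) in [0, 1].
#' @param normalize if TRUE, multiply \code{d_mut} by 2 so both components
#'   span [0, 1] (default FALSE).
#' @return combined distance(s).
#' @export
combined_distance <- function(d_mut, d_scna, normalize = FALSE) {
  if (any(d_mut < 0) || any(d_scna < 0)) stop_mcec("distances must be non-negative")
  if (normalize) d_mut <- 2 * d_mut
  sqrt(d_mut^2 + d_scna^2)
}

#' Build a pairwise distance matrix over samples
#'
#' @param catalogs samples x 96 catalog count matrix (rownames = sample ids);
#'   required for modes \code{"mutational"} and \code{"combined"}.
#' @param fga named numeric vector of per-sample fractions of genome altered;
#'   required for modes \code{"scna"} and \code{"combined"}.
#' @param mode \code{"combined"} (default), \code{"mutational"}, or
#'   \code{"scna"}.
#' @param normalize passed to \code{\link{combined_distance}}.
#' @param method passed to \code{\link{spectrum_distance}}.
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames, and attribute \code{metric} recording the mode.
#' @export
build_distance_matrix <- function(catalogs = NULL, fga = NULL,
                                  mode = c("combined", "mutational", "scna"),
                                  normalize = FALSE,
                                  method = "half-one-minus-cos") {
  mode <- match.arg(mode)
  if (mode %in% c("mutational", "combined") && is.null(catalogs)) {
    stop_mcec("catalog matrix required for mode ", mode)
  }
  if (mode %in% c("scna", "combined") && is.null(fga)) {
    stop_mcec("FGA vector required for mode ", mode)
  }
  ids <- if (!is.null(catalogs)) rownames(catalogs) else names(fga)
  if (mode == "combined") {
    missing_fga <- setdiff(rownames(catalogs), names(fga))
    missing_cat <- setdiff(names(fga), rownames(catalogs))
    if (length(missing_fga) || length(missing_cat)) {
      stop_mcec("sample sets differ between catalogs and FGA (",
                "no FGA: ", paste(missing_fga, collapse = ","),
                "; no catalog: ", paste(missing_cat, collapse = ","), ")")
    }
    fga <- fga[ids]
  }
  n <- length(ids)
  d_mut <- matrix(0, n, n, dimnames = list(ids, ids))
  if (mode %in% c("mutational", "combined")) {
    # cosine distance on catalog proportion rows, computed in one pass
    if (any(rowSums(catalogs) == 0)) {
      stop_mcec("zero-count catalog for sample(s): ",
                paste(ids[rowSums(catalogs) == 0], collapse = ", "))
    }
    p <- catalogs / rowSums(catalogs)
    nrm <- sqrt(rowSums(p^2))
    cs <- (p %*% t(p)) / outer(nrm, nrm)
    cs <- pmax(pmin(cs, 1), -1)  # matrix-first so dimensions are kept
    d_mut <- if (method == "half-one-minus-cos") (1 - cs) / 2 else 1 - cs / 2
    diag(d_mut) <- 0
  }
  d_scna <- matrix(0, n, n, dimnames = list(ids, ids))
  if (mode %in% c("scna", "combined")) {
    d_scna <- abs(outer(fga[ids], fga[ids], "-"))
  }
  m <- switch(mode,
    mutational = d_mut,
    scna = d_scna,
    combined = combined_distance(d_mut, d_scna, normalize = normalize))
  m <- (m + t(m)) / 2  # enforce exact symmetry against floating-point noise
  attr(m, "metric") <- mode
  m
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' @param matrix symmetric distance matrix with sample dimnames.
#' @param linkage \code{"complete"} (default), \code{"average"}, or
#'   \code{"single"}.
#' @return an \code{hclust} object.
#' @export
hierarchical_cluster <- function(matrix, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  if (nrow(matrix) < 2) stop_mcec("at least two samples are required for clustering")
  stats::hclust(stats::as.dist(matrix), method = linkage)
}

#' Export a dendrogram as Newick with merge heights as branch lengths
#' @param hc \code{hclust} object.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Assign query samples to reference groups by co-clustering
#'
#' Cuts the dendrogram into \code{k} clusters and assigns each query the
#' majority reference label within its cluster. A cluster with no labelled
#' member falls back to the query's nearest labelled neighbour by matrix
#' distance; a majority tie is broken by the smaller mean distance from the
#' query to the tied groups' labelled members.
#'
#' @param matrix symmetric distance matrix over references and queries.
#' @param reference_labels named character vector: reference sample id ->
#'   group label.
#' @param query_ids character vector of query sample ids.
#' @param k number of clusters to cut (default: number of distinct reference
#'   groups).
#' @param linkage linkage for \code{\link{hierarchical_cluster}}.
#' @return data frame with columns \code{sample_id}, \code{assigned_group},
#'   \code{cluster}, \code{rule} (\code{majority} or
#'   \code{nearest_neighbour}), \code{support} (labelled members of the
#'   assigned group in the cluster), \code{cluster_label_counts} (semicolon
#'   summary).
#' @export
assign_groups <- function(matrix, reference_labels, query_ids, k = NULL,
                          linkage = "complete") {
  if (length(reference_labels) == 0) stop_mcec("no reference samples supplied")
  ref_ids <- names(reference_labels)
  missing <- setdiff(c(ref_ids, query_ids), rownames(matrix))
  if (length(missing)) stop_mcec("samples absent from matrix: ", paste(missing, collapse = ", "))
  groups <- sort(unique(reference_labels))
  if (is.null(k)) k <- length(groups)
  hc <- hierarchical_cluster(matrix, linkage)
  cl <- stats::cutree(hc, k = k)

  out <- lapply(query_ids, function(q) {
    members <- names(cl)[cl == cl[q]]
    labelled <- intersect(members, ref_ids)
    counts <- table(factor(reference_labels[labelled], levels = groups))
    if (length(labelled) == 0) {
      nn <- ref_ids[which.min(matrix[q, ref_ids])]
      return(data.frame(sample_id = q, assigned_group = unname(reference_labels[nn]),
                        cluster = unname(cl[q]), rule = "nearest_neighbour",
                        support = 0L,
                        cluster_label_counts = "", stringsAsFactors = FALSE))
    }
    top <- names(counts)[counts == max(counts)]
    rule <- "majority"
    if (length(top) > 1) {
      # tie: smaller mean distance from the query to each tied group's
      # labelled members in the cluster
      mean_d <- vapply(top, function(g) {
        mean(matrix[q, labelled[reference_labels[labelled] == g]])
      }, numeric(1))
      top <- top[which.min(mean_d)]
      rule <- "majority_tie_mean_distance"
    }
    data.frame(sample_id = q, assigned_group = top[1], cluster = unname(cl[q]),
               rule = rule, support = as.integer(counts[top[1]]),
               cluster_label_counts = paste(sprintf("%s=%d", names(counts), counts),
                                            collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Contingency-table association test
#'
#' For a 2x2 table with any expected cell at or below 5, a two-sided
#' Fisher's exact test; otherwise Pearson's chi-squared (without continuity
#' correction by default).
#'
#' @param table matrix of non-negative integer counts.
#' @param correct apply Yates continuity correction in the chi-squared branch
#'   (default FALSE).
#' @param force one of \code{"auto"} (default), \code{"fisher"},
#'   \code{"chisq"} to override method choice.
#' @return list with \code{method}, \code{statistic} (NA for Fisher),
#'   \code{df}, \code{p_value}.
#' @export
association_test <- function(table, correct = FALSE, force = c("auto", "fisher", "chisq")) {
  force <- match.arg(force)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop_mcec("contingency table must hold non-negative integer counts")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  use_fisher <- switch(force,
    fisher = TRUE,
    chisq = FALSE,
    auto = all(dim(table) == 2) && any(expected <= 5))
  if (use_fisher) {
    ft <- stats::fisher.test(table)
    list(method = "fisher_exact", statistic = NA_real_, df = NA_integer_,
         p_value = ft$p.value)
  } else {
    # all-zero rows/columns carry no information and make the statistic
    # undefined; drop them before testing
    t2 <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
    if (nrow(t2) < 2 || ncol(t2) < 2) {
      return(list(method = "chi_squared", statistic = 0, df = 0L, p_value = 1))
    }
    ct <- suppressWarnings(stats::chisq.test(t2, correct = correct))
    list(method = "chi_squared", statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value)
  }
}

#' Co-assignment table of query types versus assigned groups
#'
#' @param assignments data frame from \code{\link{assign_groups}}.
#' @param query_types named character vector: query sample id -> type label
#'   (e.g. driver class of the multiple-classifier combination).
#' @return contingency matrix (query types x assigned groups).
#' @export
coassignment_table <- function(assignments, query_types) {
  tab <- table(type = query_types[assignments$sample_id],
               assigned = assignments$assigned_group)
  unclass(as.matrix(tab))
}
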