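# Independent oracles used to cross-check the package's computations.
# These are deliberately naive/brute-force and share no code with R/.

# cosine similarity by explicit elementwise accumulation
oracle_cosine <- function(a, b) {
  dot <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    dot <- dot + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  dot / (sqrt(na) * sqrt(nb))
}

# two-sided Fisher exact p for a 2x2 table by full hypergeometric enumeration
# over all tables with the observed margins, probabilities from binomial
# coefficients
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(a) {
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[match(m[1, 1], support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# per-base tally of altered genome fraction on a small toy genome
oracle_fga_per_base <- function(segments, threshold = 0.2) {
  covered <- 0; altered <- 0
  for (i in seq_len(nrow(segments))) {
    len <- segments$end[i] - segments$start[i] + 1
    covered <- covered + len
    if (abs(segments$value[i]) > threshold) altered <- altered + len
  }
  altered / covered
}

# reverse complement written independently of the package internals
oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# a random 96-channel count vector with guaranteed positive total
random_catalog <- function(total = 500) {
  as.numeric(stats::rmultinom(1, total, prob = stats::runif(96)))
}

# minimal assay constructors for classifier tests
p53_obs <- function(percent = 0, regional = 0, control = TRUE,
                    cytoplasmic = FALSE, absence = FALSE, interpretable = TRUE) {
  list(percent_strong_nuclear = percent, internal_control_positive = control,
       cytoplasmic_staining = cytoplasmic, complete_absence = absence,
       regional_abnormal_fraction = regional, interpretable = interpretable)
}

mmr_obs <- function(protein, expression, control = TRUE) {
  data.frame(protein = protein, nuclear_expression = expression,
             internal_control_positive = control, stringsAsFactors = FALSE)
}

pole_var <- function(change, call = "unknown") {
  data.frame(protein_change = change, pathogenicity_call = call,
             stringsAsFactors = FALSE)
}

tp53_var <- function(change = "p.Arg273His", codon = 273, sift = "other",
                     vep = "other", clin = "pathogenic") {
  data.frame(protein_change = change, codon = codon, sift_class = sift,
             vep_class = vep, clinical_class = clin, stringsAsFactors = FALSE)
}

assay <- function(sample_id = "s1", pole = NULL, mmr = NULL, msi = NULL,
                  p53 = NULL, tp53 = NULL) {
  list(sample_id = sample_id, pole_variants = pole, mmr_ihc = mmr,
       msi_call = msi, p53_ihc = p53, tp53_variants = tp53)
}

# assemble co-assignment results over seeded synthetic cohorts; returns the
# per-driver agreement counts and the pooled type x assigned-group table
run_coassignment <- function(seeds, n_ref = 20, n_query = 20) {
  pooled <- NULL
  agree <- c(MMRd = 0, POLEmut = 0)
  total <- c(MMRd = 0, POLEmut = 0)
  for (s in seeds) {
    cfg <- cohort_config(
      n_reference = c(POLEmut = n_ref, MMRd = n_ref, p53abn = n_ref, NSMP = 0),
      n_query = c(`MMRd-p53abn` = n_query, `POLEmut-p53abn` = n_query),
      seed = s)
    cohort <- generate_cohort(cfg)
    cls <- classification_table(classify_cohort(cohort$samples))
    catalogs <- build_catalog_matrix(cohort$snv)
    fga <- fga_by_sample(cohort$seg)
    is_multi <- grepl("-", cls$raw_classifier_set, fixed = TRUE)
    refs <- cls[!is_multi & cls$resolved_class %in% c("POLEmut", "MMRd", "p53abn"), ]
    labels <- stats::setNames(refs$resolved_class, refs$sample_id)
    queries <- cls$sample_id[is_multi]
    keep <- c(names(labels), queries)
    dm <- build_distance_matrix(catalogs[keep, , drop = FALSE], fga[keep],
                                mode = "combined")
    asg <- assign_groups(dm, labels, queries)
    driver <- stats::setNames(
      ifelse(grepl("POLEmut", cls$raw_classifier_set[is_multi]), "POLEmut", "MMRd"),
      queries)
    tab <- coassignment_table(asg, driver)
    pooled <- if (is.null(pooled)) tab else {
      out <- matrix(0, 2, length(union(colnames(pooled), colnames(tab))),
                    dimnames = list(rownames(tab),
                                    union(colnames(pooled), colnames(tab))))
      out[, colnames(pooled)] <- out[, colnames(pooled)] + pooled
      out[, colnames(tab)] <- out[, colnames(tab)] + tab
      out
    }
    for (d in c("MMRd", "POLEmut")) {
      qd <- names(driver)[driver == d]
      total[d] <- total[d] + length(qd)
      agree[d] <- agree[d] +
        sum(asg$assigned_group[match(qd, asg$sample_id)] == d)
    }
  }
  list(pooled = pooled, agree = agree, total = total)
}
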