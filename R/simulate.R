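# Synthetic cohort generator.
#
# Generates cohorts with the statistical structure the analysis assumes:
# subtype-specific SNV burden and 96-channel spectrum (ultramutated
# POLE-driven tumours concentrate mass on T[C>A]T and T[C>T]G; hypermutated
# MMR-deficient tumours on C>T at CpG with an elevated indel load),
# subtype-specific fraction of genome altered (high only for the
# SCNA-high/p53abn class), surrogate-marker assay results consistent with the
# class, passenger TP53 mutations in MMRd/POLE-driven multiple-classifier
# tumours (frequently multiple, rarely at hotspot codons, often with a
# subclonal p53 staining pattern), and group-specific exponential
# recurrence-free survival. All draws go through R's RNG seeded once from
# the config, so identical seed + config gives identical output.

TP53_HOTSPOTS <- c(175, 245, 248, 249, 273, 282)
TP53_HOTSPOT_CHANGES <- c(`175` = "p.Arg175His", `245` = "p.Gly245Ser",
                          `248` = "p.Arg248Gln", `249` = "p.Arg249Ser",
                          `273` = "p.Arg273His", `282` = "p.Arg282Trp")

weight_vector <- function(assignments, baseline = 1) {
  # assignments: named numeric of channel label -> relative mass; remaining
  # channels share `baseline` relative mass each. Returns a 96-simplex.
  ch <- spectrum_channels()
  w <- stats::setNames(rep(baseline, 96), ch)
  w[names(assignments)] <- assignments
  w / sum(w)
}

pole_spectrum_weights <- function() {
  # Ultramutator profile: dominant T[C>A]T and T[C>T]G with a general C>A tilt
  ch <- spectrum_channels()
  ca <- ch[grepl("C>A", ch, fixed = TRUE)]
  w <- stats::setNames(rep(0.3, 96), ch)
  w[ca] <- 2
  w["T[C>A]T"] <- 35
  w["T[C>T]G"] <- 22
  w / sum(w)
}

mmrd_spectrum_weights <- function() {
  # Hypermutator profile: C>T at CpG dominant, secondary T>C component
  ch <- spectrum_channels()
  ct_cpg <- ch[grepl("\\[C>T\\]G$", ch)]
  ct <- ch[grepl("C>T", ch, fixed = TRUE)]
  tc <- ch[grepl("T>C", ch, fixed = TRUE)]
  w <- stats::setNames(rep(0.3, 96), ch)
  w[ct] <- 1.2
  w[tc] <- 1.5
  w[ct_cpg] <- 10
  w / sum(w)
}

flat_cn_spectrum_weights <- function(cpg_boost = 3) {
  # Ageing-like background: mild C>T at CpG over a flat base
  ch <- spectrum_channels()
  w <- stats::setNames(rep(1, 96), ch)
  w[ch[grepl("\\[C>T\\]G$", ch)]] <- cpg_boost
  w / sum(w)
}

#' Default molecular-subtype generative profiles
#'
#' Per-class parameters for the synthetic cohort generator: log-normal SNV
#' burden, 96-channel spectrum weights, expected indel count, Beta parameters
#' for the fraction of genome altered, TP53 hotspot probability, 5-year
#' recurrence-free survival, and the probability of stage I disease.
#'
#' @return named list of profile lists for POLEmut, MMRd, p53abn, NSMP.
#' @export
subtype_profiles <- function() {
  list(
    POLEmut = list(
      snv_meanlog = log(5000), snv_sdlog = 0.3,
      spectrum_weights = pole_spectrum_weights(),
      indel_rate = 20,
      fga_shape1 = 2, fga_shape2 = 38,
      tp53_hotspot_probability = 0.08,
      tp53_multiple_probability = 0.75,
      rfs_5yr = 0.941, stage1_prob = 0.8),
    MMRd = list(
      snv_meanlog = log(1200), snv_sdlog = 0.3,
      spectrum_weights = mmrd_spectrum_weights(),
      indel_rate = 150,
      fga_shape1 = 2, fga_shape2 = 38,
      tp53_hotspot_probability = 0.08,
      tp53_multiple_probability = 0.364,
      rfs_5yr = 0.922, stage1_prob = 0.75),
    p53abn = list(
      snv_meanlog = log(60), snv_sdlog = 0.3,
      spectrum_weights = flat_cn_spectrum_weights(),
      indel_rate = 5,
      fga_shape1 = 12, fga_shape2 = 12,
      tp53_hotspot_probability = 0.315,
      tp53_multiple_probability = 0.027,
      rfs_5yr = 0.708, stage1_prob = 0.5),
    NSMP = list(
      snv_meanlog = log(40), snv_sdlog = 0.3,
      spectrum_weights = flat_cn_spectrum_weights(cpg_boost = 2),
      indel_rate = 5,
      fga_shape1 = 2, fga_shape2 = 38,
      tp53_hotspot_probability = 0.315,
      tp53_multiple_probability = 0.027,
      rfs_5yr = 0.93, stage1_prob = 0.8)
  )
}

#' Cohort generator configuration
#'
#' @param n_reference named counts of single-classifier reference samples per
#'   class.
#' @param n_query named counts of multiple-classifier query samples per
#'   combination (driver class + TP53/p53 abnormality).
#' @param seed integer RNG seed.
#' @param genome genome model (named chromosome lengths).
#' @param subclonal_p53_prob probability that a multiple-classifier sample's
#'   abnormal p53 stain is subclonal (default 0.5).
#' @param censor_window months; censoring times drawn uniformly on it.
#' @param profiles subtype profiles, see \code{\link{subtype_profiles}}.
#' @return config list.
#' @export
cohort_config <- function(n_reference = c(POLEmut = 20, MMRd = 20, p53abn = 20, NSMP = 20),
                          n_query = c(`MMRd-p53abn` = 20, `POLEmut-p53abn` = 20),
                          seed = 1,
                          genome = toy_genome(),
                          subclonal_p53_prob = 0.5,
                          censor_window = c(24, 144),
                          profiles = subtype_profiles()) {
  if (sum(n_reference) + sum(n_query) == 0) stop_mcec("cohort has zero samples")
  if (any(c(n_reference, n_query) < 0)) stop_mcec("negative sample counts")
  list(n_reference = n_reference, n_query = n_query, seed = seed,
       genome = genome, subclonal_p53_prob = subclonal_p53_prob,
       censor_window = censor_window, profiles = profiles)
}

#' Exponential hazard matching a 5-year survival target
#'
#' @param rfs_5yr survival probability at 60 months, in (0, 1].
#' @return hazard rate per month; \code{S(60) == rfs_5yr} exactly.
#' @export
solve_exponential_rate <- function(rfs_5yr) {
  if (any(rfs_5yr <= 0) || any(rfs_5yr > 1)) stop_mcec("rfs_5yr must lie in (0, 1]")
  -log(rfs_5yr) / 60
}

#' Simulate survival records for one group
#'
#' Event times exponential with hazard solved from the 5-year survival
#' target; censoring uniform on \code{censor_window}.
#'
#' @param n subjects.
#' @param rfs_5yr target 5-year event-free survival.
#' @param group group label.
#' @param censor_window months, length-2.
#' @param stage1_prob probability of stage I (split evenly IA/IB); remaining
#'   mass split over II/III.
#' @param sample_ids optional ids (default group_1..n).
#' @return survival data frame (sample_id, time, event, group, stage).
#' @export
simulate_survival <- function(n, rfs_5yr, group, censor_window = c(24, 144),
                              stage1_prob = 0.75, sample_ids = NULL) {
  rate <- solve_exponential_rate(rfs_5yr)
  t_event <- if (rate == 0) rep(Inf, n) else stats::rexp(n, rate)
  t_cens <- stats::runif(n, censor_window[1], censor_window[2])
  stage <- sample(c("IA", "IB", "II", "III"), n, replace = TRUE,
                  prob = c(stage1_prob / 2, stage1_prob / 2,
                           (1 - stage1_prob) / 2, (1 - stage1_prob) / 2))
  data.frame(
    sample_id = sample_ids %||% sprintf("%s_%03d", group, seq_len(n)),
    time = round(pmin(t_event, t_cens), 2),
    event = t_event <= t_cens,
    group = group, stage = stage, stringsAsFactors = FALSE)
}

simulate_snv_table <- function(sample_id, n_snv, weights, n_indel, genome) {
  ch_lab <- spectrum_channels()
  idx <- sample.int(96, n_snv, replace = TRUE, prob = weights)
  lab <- ch_lab[idx]
  ref <- substr(lab, 3, 3)
  alt <- substr(lab, 5, 5)
  context <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
  # report about half the records on the purine strand, as a real caller would
  flip <- stats::runif(n_snv) < 0.5
  if (any(flip)) {
    ref[flip] <- unname(REVCOMP[ref[flip]])
    alt[flip] <- unname(REVCOMP[alt[flip]])
    context[flip] <- revcomp(context[flip])
  }
  chrom <- sample(names(genome), n_snv + n_indel, replace = TRUE)
  pos <- floor(stats::runif(n_snv + n_indel, 2, genome[chrom] - 1))
  snv <- data.frame(sample_id = sample_id, chrom = chrom[seq_len(n_snv)],
                    pos = pos[seq_len(n_snv)], ref = ref, alt = alt,
                    context = context, gene = "", stringsAsFactors = FALSE)
  if (n_indel > 0) {
    i <- n_snv + seq_len(n_indel)
    indel <- data.frame(sample_id = sample_id, chrom = chrom[i], pos = pos[i],
                        ref = "AT", alt = "A", context = "", gene = "",
                        stringsAsFactors = FALSE)
    snv <- rbind(snv, indel)
  }
  snv
}

#' Simulate a copy-number segment set hitting a target FGA
#'
#' Tiles each chromosome with randomly placed segments and marks a random
#' subset altered (|log2 ratio| in [0.3, 1.2]) so that the altered length
#' equals \code{round(target_fga * genome length)} exactly; the remaining
#' segments get near-neutral values in [-0.1, 0.1].
#'
#' @param sample_id sample label for the SEG rows.
#' @param target_fga desired fraction of genome altered in [0, 1].
#' @param genome named vector of chromosome lengths.
#' @param n_seg_per_chrom segments per chromosome before the exactness split.
#' @return segment data frame (sample_id, chrom, start, end, value, num_mark).
#' @export
simulate_segments <- function(sample_id, target_fga, genome, n_seg_per_chrom = 6) {
  segs <- do.call(rbind, lapply(names(genome), function(chr) {
    len <- genome[[chr]]
    cuts <- sort(sample.int(len - 1, n_seg_per_chrom - 1))
    start <- c(1, cuts + 1)
    end <- c(cuts, len)
    data.frame(chrom = chr, start = start, end = end, stringsAsFactors = FALSE)
  }))
  total <- sum(genome)
  target_len <- round(target_fga * total)
  ord <- sample.int(nrow(segs))
  segs <- segs[ord, , drop = FALSE]
  seg_len <- segs$end - segs$start + 1
  cum <- cumsum(seg_len)
  altered <- cum <= target_len
  # split the segment that crosses the target so the altered length is exact
  cross <- which(!altered)[1]
  extra <- NULL
  if (!is.na(cross)) {
    need <- target_len - if (cross > 1) cum[cross - 1] else 0
    if (need > 0) {
      s <- segs[cross, ]
      extra <- data.frame(chrom = s$chrom, start = s$start,
                          end = s$start + need - 1, stringsAsFactors = FALSE)
      segs$start[cross] <- s$start + need
    }
  }
  n_alt <- sum(altered)
  value <- numeric(nrow(segs))
  value[altered] <- sample(c(-1, 1), n_alt, replace = TRUE) *
    stats::runif(n_alt, 0.3, 1.2)
  value[!altered] <- stats::runif(nrow(segs) - n_alt, -0.1, 0.1)
  segs$value <- value
  if (!is.null(extra)) {
    extra$value <- sample(c(-1, 1), 1) * stats::runif(1, 0.3, 1.2)
    segs <- rbind(segs, extra)
  }
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  data.frame(sample_id = sample_id, segs, num_mark = NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

random_aa_change <- function(codon) {
  aa <- c("Ala", "Cys", "Asp", "Glu", "Phe", "Gly", "His", "Ile", "Lys", "Leu",
          "Met", "Asn", "Pro", "Gln", "Arg", "Ser", "Thr", "Val", "Trp", "Tyr")
  pair <- sample(aa, 2)
  sprintf("p.%s%d%s", pair[1], codon, pair[2])
}

simulate_tp53_variants <- function(n, hotspot_prob, channel_weights,
                                   pathogenic_prob = 0.62) {
  if (n == 0) return(list())
  lapply(seq_len(n), function(i) {
    hs <- stats::runif(1) < hotspot_prob
    codon <- if (hs) sample(TP53_HOTSPOTS, 1) else {
      repeat {
        c0 <- sample(33:393, 1)
        if (!(c0 %in% TP53_HOTSPOTS)) break
      }
      c0
    }
    list(protein_change = if (hs) unname(TP53_HOTSPOT_CHANGES[as.character(codon)])
                          else random_aa_change(codon),
         codon = codon,
         sift_class = "other", vep_class = "other",
         clinical_class = if (stats::runif(1) < pathogenic_prob) "pathogenic" else "VUS",
         channel = sample(names(channel_weights), 1, prob = channel_weights))
  })
}

p53_ihc_fields <- function(pattern) {
  # pattern: wildtype / diffuse / complete_absence / cytoplasmic / subclonal
  switch(pattern,
    wildtype = list(percent = round(stats::runif(1, 5, 50)), regional = 0, flags = ""),
    diffuse = list(percent = round(stats::runif(1, 80, 100)), regional = 0, flags = ""),
    complete_absence = list(percent = 0, regional = 0, flags = "complete_absence"),
    cytoplasmic = list(percent = round(stats::runif(1, 0, 40)), regional = 0,
                       flags = "cytoplasmic"),
    subclonal = list(percent = round(stats::runif(1, 80, 100)),
                     regional = round(stats::runif(1, 10, 60)), flags = ""))
}

mmr_columns <- function(status) {
  # returns values for (mlh1, pms2, msh2, msh6)
  if (status == "proficient") return(rep("retained", 4))
  pattern <- sample(c("MLH1_PMS2", "MSH2_MSH6", "MSH6", "PMS2"), 1,
                    prob = c(0.45, 0.2, 0.2, 0.15))
  v <- rep("retained", 4)
  names(v) <- c("MLH1", "PMS2", "MSH2", "MSH6")
  v[strsplit(pattern, "_")[[1]]] <- "lost"
  unname(v)
}

sample_pole_variant <- function() {
  # frequencies follow the observed hotspot spectrum (P286R and V411L dominate)
  v <- sample(c("p.Pro286Arg", "p.Val411Leu", "p.Ala456Pro", "p.Ser459Phe",
                "p.Pro436Arg", "p.Ser297Phe", "p.Phe367Ser", "p.Leu424Ile",
                "p.Met295Arg"), 1,
              prob = c(16, 10, 3, 1, 1, 2, 2, 1, 1))
  paste0(v, ":unknown")
}

tp53_json <- function(variants) {
  if (length(variants) == 0) return("[]")
  as.character(jsonlite::toJSON(variants, auto_unbox = TRUE))
}

simulate_one_sample <- function(sample_id, class, is_query, profile, config) {
  genome <- config$genome
  n_snv <- max(1L, round(stats::rlnorm(1, profile$snv_meanlog, profile$snv_sdlog)))
  n_indel <- stats::rpois(1, profile$indel_rate)
  fga <- stats::rbeta(1, profile$fga_shape1, profile$fga_shape2)

  snv <- simulate_snv_table(sample_id, n_snv, profile$spectrum_weights, n_indel, genome)
  seg <- simulate_segments(sample_id, fga, genome)

  pole <- ""
  mmr <- rep("retained", 4)
  msi <- "MSS"
  p53_pattern <- "wildtype"
  tp53 <- list()

  if (class == "POLEmut") pole <- sample_pole_variant()
  if (class == "MMRd") {
    mmr <- mmr_columns("deficient")
    msi <- "MSI_H"
  }
  if (class == "p53abn") {
    p53_pattern <- sample(c("diffuse", "complete_absence", "cytoplasmic"), 1,
                          prob = c(0.7, 0.2, 0.1))
    n_tp53 <- 1L + (stats::runif(1) < profile$tp53_multiple_probability)
    tp53 <- simulate_tp53_variants(n_tp53, profile$tp53_hotspot_probability,
                                   profile$spectrum_weights)
  }
  if (is_query) {
    # driver genomics + a passenger TP53 hit: 1-3 retained variants, rarely
    # at hotspots, and a p53 stain that is subclonal with configured odds
    multi <- stats::runif(1) < profile$tp53_multiple_probability
    n_tp53 <- if (multi) sample(2:3, 1) else 1L
    tp53 <- simulate_tp53_variants(n_tp53, profile$tp53_hotspot_probability,
                                   profile$spectrum_weights)
    p53_pattern <- if (stats::runif(1) < config$subclonal_p53_prob) "subclonal"
                   else "diffuse"
  }
  p53 <- p53_ihc_fields(p53_pattern)

  sheet <- data.frame(
    sample_id = sample_id, pole_variants = pole,
    mmr_mlh1 = mmr[1], mmr_pms2 = mmr[2], mmr_msh2 = mmr[3], mmr_msh6 = mmr[4],
    msi = msi, p53_percent_strong = p53$percent,
    p53_regional_fraction = p53$regional, p53_flags = p53$flags,
    tp53_variants = tp53_json(tp53), stringsAsFactors = FALSE)

  truth <- data.frame(
    sample_id = sample_id, true_class = class,
    sample_type = if (is_query) "query" else "reference",
    n_snv = n_snv, n_indel = n_indel, fga_target = fga,
    tp53_n_variants = length(tp53),
    tp53_multiple = length(tp53) > 1,
    p53_pattern = p53_pattern, rfs_5yr = profile$rfs_5yr,
    stringsAsFactors = FALSE)

  list(sheet = sheet, snv = snv, seg = seg, truth = truth)
}

#' Generate a synthetic multi-classifier cohort
#'
#' Emits the exact tables the analysis pipeline reads: a surrogate-marker
#' sample sheet, a MAF-like SNV table with trinucleotide context, a SEG
#' copy-number table, a survival table, and a truth table recording every
#' generating parameter. Query samples carry their driver class's genomics
#' plus passenger TP53 variants and (with configured probability) a subclonal
#' p53 staining pattern.
#'
#' @param config from \code{\link{cohort_config}}.
#' @return list of data frames: \code{samples}, \code{snv}, \code{seg},
#'   \code{survival}, \code{truth}.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  profiles <- config$profiles
  parts <- list()

  for (cls in names(config$n_reference)) {
    n <- config$n_reference[[cls]]
    if (n == 0) next
    for (i in seq_len(n)) {
      id <- sprintf("ref_%s_%03d", cls, i)
      parts[[id]] <- simulate_one_sample(id, cls, FALSE, profiles[[cls]], config)
    }
  }
  for (qt in names(config$n_query)) {
    n <- config$n_query[[qt]]
    if (n == 0) next
    driver <- sub("-p53abn$", "", qt)
    if (!driver %in% names(profiles)) stop_mcec("unknown query type: ", qt)
    for (i in seq_len(n)) {
      id <- sprintf("query_%s_%03d", qt, i)
      parts[[id]] <- simulate_one_sample(id, driver, TRUE, profiles[[driver]], config)
    }
  }
  if (length(parts) == 0) stop_mcec("cohort has zero samples")

  samples <- do.call(rbind, lapply(parts, `[[`, "sheet"))
  snv <- do.call(rbind, lapply(parts, `[[`, "snv"))
  seg <- do.call(rbind, lapply(parts, `[[`, "seg"))
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
  rownames(samples) <- rownames(snv) <- rownames(seg) <- rownames(truth) <- NULL

  surv <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    grp <- if (tr$sample_type == "query") {
      sub("^query_([^_]+(-p53abn)?)_.*$", "\\1", tr$sample_id)
    } else tr$true_class
    pr <- profiles[[tr$true_class]]
    simulate_survival(1, tr$rfs_5yr, grp, config$censor_window,
                      pr$stage1_prob, sample_ids = tr$sample_id)
  }))
  rownames(surv) <- NULL

  list(samples = samples, snv = snv, seg = seg, survival = surv, truth = truth)
}

#' Write a generated cohort to a directory of TSV/SEG files
#'
#' @param cohort from \code{\link{generate_cohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(samples = file.path(dir, "samples.tsv"),
             snv = file.path(dir, "snv.tsv"),
             seg = file.path(dir, "segments.seg"),
             survival = file.path(dir, "survival.tsv"),
             truth = file.path(dir, "truth.tsv"))
  tsv <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                            row.names = FALSE)
  tsv(cohort$samples, paths["samples"])
  tsv(cohort$snv, paths["snv"])
  write_seg(cohort$seg, paths["seg"])
  tsv(cohort$survival, paths["survival"])
  tsv(cohort$truth, paths["truth"])
  invisible(paths)
}
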