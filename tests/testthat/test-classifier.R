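test_that("p53 IHC scoring follows the abnormal-pattern definitions", {
  # diffuse strong nuclear staining in >75% of cells is overexpression
  expect_equal(score_p53_ihc(p53_obs(percent = 90)), "abnormal")
  expect_equal(score_p53_ihc(p53_obs(percent = 76)), "abnormal")
  # threshold is strict: exactly 75% is not overexpression
  expect_equal(score_p53_ihc(p53_obs(percent = 75)), "wildtype")
  # complete absence needs the internal control to be interpretable
  expect_equal(score_p53_ihc(p53_obs(absence = TRUE)), "abnormal")
  expect_equal(score_p53_ihc(p53_obs(absence = TRUE, control = FALSE)), "inconclusive")
  expect_equal(score_p53_ihc(p53_obs(cytoplasmic = TRUE)), "abnormal")
  # abrupt regional abnormal pattern occupying >= 10% of volume is subclonal
  expect_equal(score_p53_ihc(p53_obs(percent = 90, regional = 40)), "subclonal_abnormal")
  expect_equal(score_p53_ihc(p53_obs(percent = 90, regional = 10)), "subclonal_abnormal")
  expect_equal(score_p53_ihc(p53_obs(percent = 50, regional = 5)), "wildtype")
  expect_equal(score_p53_ihc(p53_obs(percent = 0)), "wildtype")
  expect_equal(score_p53_ihc(p53_obs(interpretable = FALSE)), "inconclusive")
  expect_error(score_p53_ihc(p53_obs(percent = 120)), "percent")
  expect_error(score_p53_ihc(p53_obs(percent = 90, absence = TRUE)), "incompatible")
})

test_that("MMR IHC panel scoring requires loss with intact internal control", {
  expect_equal(score_mmr_ihc(rbind(mmr_obs("PMS2", "lost"),
                                   mmr_obs("MSH6", "retained"))), "deficient")
  expect_equal(score_mmr_ihc(mmr_obs(c("MLH1", "PMS2", "MSH2", "MSH6"),
                                     rep("retained", 4))), "proficient")
  # patchy staining is not deficiency; alone it is uninterpretable
  expect_equal(score_mmr_ihc(mmr_obs("MLH1", "heterogeneous_patchy")), "inconclusive")
  expect_equal(score_mmr_ihc(rbind(mmr_obs("MLH1", "heterogeneous_patchy"),
                                   mmr_obs("MSH6", "retained"))), "proficient")
  # loss without internal control is not evidence
  expect_equal(score_mmr_ihc(mmr_obs("PMS2", "lost", control = FALSE)), "inconclusive")
  # abrupt regional loss counts as (subclonal) deficiency
  expect_equal(score_mmr_ihc(rbind(mmr_obs("MLH1", "regional_abrupt_loss"),
                                   mmr_obs("PMS2", "retained"))), "subclonal_deficient")
  expect_error(score_mmr_ihc(mmr_obs("MLH1", "regional_abrupt_loss", control = FALSE)),
               "internal control")
  expect_error(score_mmr_ihc(NULL), "at least one")
  expect_error(score_mmr_ihc(mmr_obs("TP53", "lost")), "unknown MMR protein")
})

test_that("POLE pathogenicity is whitelist plus explicit flag", {
  expect_equal(assess_pole(pole_var("p.Pro286Arg")), "pathogenic_mut")
  expect_equal(assess_pole(pole_var("P286R")), "pathogenic_mut")
  expect_equal(assess_pole(pole_var("V411L")), "pathogenic_mut")
  expect_equal(assess_pole(NULL), "no_pathogenic_mut")
  expect_equal(assess_pole(pole_var("p.Thr278Met", "non_pathogenic")), "no_pathogenic_mut")
  # explicit pathogenic flag admits a non-whitelisted variant
  expect_equal(assess_pole(pole_var("p.Thr278Met", "pathogenic")), "pathogenic_mut")
  # a non_pathogenic review verdict overrides the whitelist
  expect_equal(assess_pole(pole_var("p.Pro286Arg", "non_pathogenic")), "no_pathogenic_mut")
  expect_equal(assess_pole(pole_var("p.Ala456Pro"), whitelist = c("X999Y")),
               "no_pathogenic_mut")
})

test_that("TP53 variant filter drops benign/neutral calls and keeps VUS", {
  kept <- filter_tp53(rbind(tp53_var(clin = "pathogenic"),
                            tp53_var(sift = "benign", clin = "unknown")))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$clinical_class, "pathogenic")
  expect_equal(nrow(filter_tp53(tp53_var(vep = "neutral"))), 0)
  expect_equal(nrow(filter_tp53(tp53_var(clin = "benign"))), 0)
  expect_equal(nrow(filter_tp53(NULL)), 0)
  vus <- filter_tp53(tp53_var(clin = "VUS"))
  expect_equal(vus$clinical_class, "VUS")
  # fully unknown annotations are retained and relabelled VUS
  unk <- filter_tp53(tp53_var(sift = "unknown", vep = "unknown", clin = "unknown"))
  expect_equal(unk$clinical_class, "VUS")
})

test_that("multiple-classifier tumours resolve by POLEmut > MMRd > p53abn priority", {
  mmrd_p53 <- resolve_class(assay(
    mmr = mmr_obs("PMS2", "lost"), p53 = p53_obs(percent = 90)))
  expect_setequal(mmrd_p53$raw_classifier_set, c("MMRd", "p53abn"))
  expect_equal(mmrd_p53$resolved_class, "MMRd")

  triple <- resolve_class(assay(
    pole = pole_var("p.Pro286Arg"), mmr = mmr_obs("MLH1", "lost"),
    p53 = p53_obs(percent = 95)))
  expect_setequal(triple$raw_classifier_set, c("POLEmut", "MMRd", "p53abn"))
  expect_equal(triple$resolved_class, "POLEmut")

  pole_p53 <- resolve_class(assay(
    pole = pole_var("p.Val411Leu"), mmr = mmr_obs("MSH6", "retained"),
    p53 = p53_obs(percent = 90, regional = 40)))
  expect_equal(pole_p53$resolved_class, "POLEmut")
  expect_true(pole_p53$subclonal_p53)

  nsmp <- resolve_class(assay(mmr = mmr_obs("PMS2", "retained"), p53 = p53_obs()))
  expect_equal(nsmp$resolved_class, "NSMP")
  expect_length(nsmp$raw_classifier_set, 0)
})

test_that("MSI and TP53 sequencing act as fallbacks for missing/inconclusive IHC", {
  # MSI-H with no MMR IHC counts as MMRd
  r <- resolve_class(assay(msi = "MSI_H", p53 = p53_obs()))
  expect_equal(r$resolved_class, "MMRd")
  expect_true("mmr_from_msi" %in% r$rationale)
  # discordant MSI and IHC: IHC wins, discordance logged
  r <- resolve_class(assay(mmr = mmr_obs("PMS2", "retained"), msi = "MSI_H",
                           p53 = p53_obs()))
  expect_equal(r$resolved_class, "NSMP")
  expect_true("msi_ihc_discordant_ihc_wins" %in% r$rationale)
  # inconclusive p53 stain falls back to filtered TP53 variants
  r <- resolve_class(assay(mmr = mmr_obs("PMS2", "retained"),
                           p53 = p53_obs(interpretable = FALSE),
                           tp53 = tp53_var(clin = "pathogenic")))
  expect_equal(r$resolved_class, "p53abn")
  expect_true("p53_from_tp53_sequencing" %in% r$rationale)
  # sequenced TP53 with only a benign variant is p53 wildtype
  r <- resolve_class(assay(mmr = mmr_obs("PMS2", "retained"),
                           tp53 = tp53_var(clin = "benign")))
  expect_equal(r$resolved_class, "NSMP")
  # missing both members of an assay pair is unclassifiable with a reason
  r <- resolve_class(assay(p53 = p53_obs(percent = 90)))
  expect_equal(r$resolved_class, "unclassifiable")
  expect_true("missing_mmr_axis" %in% r$rationale)
})

test_that("classification is total, deterministic and priority-monotone", {
  set.seed(11)
  classes <- c("POLEmut", "MMRd", "p53abn", "NSMP", "unclassifiable")
  for (i in 1:50) {
    a <- assay(
      pole = if (runif(1) < 0.4) pole_var(sample(c("p.Pro286Arg", "p.Gly123Asp"), 1)),
      mmr = if (runif(1) < 0.8) mmr_obs(sample(c("MLH1", "PMS2", "MSH6"), 1),
                                        sample(c("lost", "retained", "heterogeneous_patchy"), 1)),
      msi = if (runif(1) < 0.5) sample(c("MSI_H", "MSS"), 1),
      p53 = if (runif(1) < 0.8) p53_obs(percent = sample(0:100, 1),
                                        regional = sample(c(0, 0, 20), 1)),
      tp53 = if (runif(1) < 0.4) tp53_var())
    r1 <- resolve_class(a)
    r2 <- resolve_class(a)
    expect_true(r1$resolved_class %in% classes)
    expect_identical(r1, r2)
    if (!r1$resolved_class %in% c("NSMP", "unclassifiable")) {
      expect_true(r1$resolved_class %in% r1$raw_classifier_set)
    }
    # adding p53 abnormality never changes a POLEmut or MMRd resolution
    if (r1$resolved_class %in% c("POLEmut", "MMRd")) {
      a2 <- a
      a2$p53_ihc <- p53_obs(percent = 95)
      expect_equal(resolve_class(a2)$resolved_class, r1$resolved_class)
    }
  }
})

test_that("cohort tabulation counts and rounds as reported", {
  results <- c(
    replicate(3, resolve_class(assay(mmr = mmr_obs("PMS2", "lost"),
                                     p53 = p53_obs(percent = 90))), simplify = FALSE),
    replicate(2, resolve_class(assay(mmr = mmr_obs("PMS2", "retained"),
                                     p53 = p53_obs())), simplify = FALSE))
  tab <- tabulate_cohort(results)
  expect_equal(sum(tab$by_resolved_class$count), 5)
  expect_equal(tab$by_raw_set$count[tab$by_raw_set$raw_set == "MMRd-p53abn"], 3)
  expect_equal(tab$n_multiple_classifier, 3)
  expect_equal(tab$multiple_classifier_percent, 60)
  one <- tabulate_cohort(results[1])
  expect_equal(one$by_raw_set$percent, 100)
  # half-up rounding of percentages
  expect_equal(round_half_up(1.85, 1), 1.9)
  expect_equal(round_half_up(100 * 64 / 3518, 1), 1.8)
})
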