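bmi_pairs <- function(phenotype) {
  fx <- load_fixture("bmi_shared")
  fg <- fixture_gwas_records(fx, phenotype)
  scan <- scan_overlap(fg$trait, fg$lipolysis,
                       rule = direction_rule_for("BMI", phenotype),
                       phenotype = phenotype, trait = "BMI")
  attach_eqtls(scan, fx$eqtls[fx$eqtls$phenotype == phenotype, ])
}

test_that("eQTL attachment joins FDR-passing pairs and flags VAT", {
  pairs <- bmi_pairs("spontaneous")
  expect_setequal(pairs$gene[pairs$snp_id == "rs10923724"],
                  c("WARS2", "TBX15"))
  expect_equal(nrow(pairs), 7)

  # SNP without any eQTL contributes no pair
  fx <- load_fixture("bmi_shared")
  fg <- fixture_gwas_records(fx, "spontaneous")
  scan <- scan_overlap(fg$trait, fg$lipolysis, rule = "require_concordant",
                       phenotype = "spontaneous", trait = "BMI")
  eq <- fx$eqtls[fx$eqtls$snp_id != "rs967605" &
                   fx$eqtls$phenotype == "spontaneous", ]
  thin <- attach_eqtls(scan, eq)
  expect_false("rs967605" %in% thin$snp_id)

  # VAT eQTLs are admitted with a flag
  wx <- load_fixture("whr_shared")
  wg <- fixture_gwas_records(wx, "stimulated")
  wscan <- scan_overlap(wg$trait, wg$lipolysis, rule = "unconstrained",
                        phenotype = "stimulated", trait = "WHRadjBMI")
  wpairs <- attach_eqtls(wscan,
                         wx$eqtls[wx$eqtls$phenotype == "stimulated", ])
  expect_true(wpairs$vat_flag[wpairs$gene == "NID2"])
  expect_false(any(wpairs$vat_flag[wpairs$gene == "NUP85"]))

  # eQTL allele outside the SNP's allele set is a validation error
  bad <- fx$eqtls[fx$eqtls$phenotype == "spontaneous", ]
  bad$high_allele[1] <- "G"
  expect_error(attach_eqtls(scan, bad), "allele")
  # non-FDR-passing records are excluded
  nofdr <- fx$eqtls[fx$eqtls$phenotype == "spontaneous", ]
  nofdr$fdr_pass <- FALSE
  expect_equal(nrow(attach_eqtls(scan, nofdr)), 0)
})

test_that("the hASC expression filter uses a strict 10 TPM threshold", {
  profiles <- data.frame(
    gene = rep(c("A10", "B", "C"), each = 3),
    timepoint = rep(1:3, 3),
    tpm = c(10, 10, 10,  0, 12, 3,  0, 0, 9.9))
  expect_equal(filter_expressed(c("A10", "B", "C"), profiles), "B")
  expect_message(out <- filter_expressed(c("B", "ZZZ"), profiles),
                 "ZZZ")
  expect_equal(out, "B")
  expect_error(filter_expressed("B", transform(profiles, tpm = -tpm)),
               "non-negative")
})

test_that("fixture hASC flags reproduce the published gene subsets", {
  sp <- bmi_pairs("spontaneous")
  expect_setequal(sp$gene[sp$detected_in_hascs],
                  c("ZNF436", "WARS2", "TBX15"))
  st <- bmi_pairs("stimulated")
  expect_setequal(st$gene[st$detected_in_hascs],
                  c("ZNF436", "FLJ20021", "INVS", "STX17", "ALDH2"))
})

test_that("congruence classification reproduces the published verdicts", {
  kd <- load_fixture("bmi_shared")$knockdown

  sp <- classify_congruence(bmi_pairs("spontaneous"), kd)
  znf <- sp[sp$gene == "ZNF436", ]
  expect_equal(znf$lipolysis_up_allele, "C")
  expect_equal(znf$regulator_prediction, "positive")
  expect_equal(znf$predicted_knockdown_effect, "decrease")
  expect_equal(znf$congruent_with_knockdown, "true")

  tbx <- sp[sp$gene == "TBX15", ]
  expect_equal(tbx$regulator_prediction, "negative")
  expect_equal(tbx$congruent_with_knockdown, "false")

  wx <- load_fixture("whr_shared")
  wg_sp <- fixture_gwas_records(wx, "spontaneous")
  wscan <- scan_overlap(wg_sp$trait, wg_sp$lipolysis,
                        rule = "unconstrained",
                        phenotype = "spontaneous", trait = "WHRadjBMI")
  wcand <- classify_congruence(
    attach_eqtls(wscan, wx$eqtls[wx$eqtls$phenotype == "spontaneous", ]),
    wx$knockdown)
  pck1 <- wcand[wcand$gene == "PCK1", ]
  expect_equal(pck1$lipolysis_up_allele, "C")  # T allele lowers lipolysis
  expect_equal(pck1$expression_up_allele, "T")
  expect_equal(pck1$regulator_prediction, "negative")
  expect_equal(pck1$congruent_with_knockdown, "false")

  wg_st <- fixture_gwas_records(wx, "stimulated")
  stscan <- scan_overlap(wg_st$trait, wg_st$lipolysis,
                         rule = "unconstrained",
                         phenotype = "stimulated", trait = "WHRadjBMI")
  stcand <- classify_congruence(
    attach_eqtls(stscan, wx$eqtls[wx$eqtls$phenotype == "stimulated", ]),
    wx$knockdown)
  nup <- stcand[stcand$gene == "NUP85", ]
  expect_equal(nup$lipolysis_up_allele, "T")
  expect_equal(nup$regulator_prediction, "positive")
  expect_equal(nup$congruent_with_knockdown, "true")
})

test_that("classification is invariant under re-orienting all alleles", {
  fx <- load_fixture("bmi_shared")
  fg <- fixture_gwas_records(fx, "spontaneous")
  eq <- fx$eqtls[fx$eqtls$phenotype == "spontaneous", ]

  flip_trait <- flip_record(fg$trait)
  scan1 <- scan_overlap(fg$trait, fg$lipolysis, rule = "require_concordant",
                        phenotype = "spontaneous", trait = "BMI")
  scan2 <- scan_overlap(flip_trait, fg$lipolysis,
                        rule = "require_concordant",
                        phenotype = "spontaneous", trait = "BMI")
  c1 <- classify_congruence(attach_eqtls(scan1, eq), fx$knockdown)
  c2 <- classify_congruence(attach_eqtls(scan2, eq), fx$knockdown)
  ord <- function(x) x[order(x$snp_id, x$gene), ]
  expect_equal(ord(c1)$regulator_prediction, ord(c2)$regulator_prediction)
  expect_equal(ord(c1)$lipolysis_up_allele, ord(c2)$lipolysis_up_allele)

  # prediction/knockdown invariant: positive <-> decrease
  expect_true(all((c1$regulator_prediction == "positive") ==
                    (c1$predicted_knockdown_effect == "decrease")))
})

test_that("zero lipolysis betas are flagged as unclassifiable", {
  pairs <- bmi_pairs("spontaneous")
  pairs$beta_phenotype[1] <- 0
  expect_warning(out <- classify_congruence(pairs), "zero lipolysis beta")
  expect_true(is.na(out$regulator_prediction[1]))
  expect_equal(out$congruent_with_knockdown[1], "unknown")
})

test_that("prioritization ranks congruent direct-effect genes first", {
  fx <- load_fixture("bmi_shared")
  kd <- fx$knockdown
  lipid <- data.frame(gene = kd$gene, lipid_effect = kd$lipid_effect)
  sp <- prioritize_candidates(classify_congruence(bmi_pairs("spontaneous"),
                                                  kd), lipid)
  expect_equal(sp$gene[1], "ZNF436")
  expect_lt(which(sp$gene == "ZNF436"), which(sp$gene == "TBX15"))

  wx <- load_fixture("whr_shared")
  wg <- fixture_gwas_records(wx, "stimulated")
  wscan <- scan_overlap(wg$trait, wg$lipolysis, rule = "unconstrained",
                        phenotype = "stimulated", trait = "WHRadjBMI")
  wcand <- classify_congruence(
    attach_eqtls(wscan, wx$eqtls[wx$eqtls$phenotype == "stimulated", ]),
    wx$knockdown)
  wr <- prioritize_candidates(wcand,
                              data.frame(gene = wx$knockdown$gene,
                                         lipid_effect = wx$knockdown$lipid_effect))
  expect_equal(wr$gene[1], "NUP85")

  # unknown observations fall back to alphabetical order within tier
  anon <- wcand
  anon$congruent_with_knockdown <- "unknown"
  anon$detected_in_hascs <- TRUE
  ranked <- prioritize_candidates(anon)
  expect_equal(ranked$gene, sort(wcand$gene))
})
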