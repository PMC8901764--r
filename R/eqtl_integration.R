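#' Attach eQTL records to shared-locus hits
#'
#' Joins every FDR-passing SNP-gene eQTL pair to its shared-locus hit by
#' rsID (and by lipolysis phenotype when both tables carry a
#' `phenotype` column). Hits without any eQTL simply contribute no
#' candidate pair. Subcutaneous adipose tissue (SAT) pairs are the
#' primary evidence; visceral (VAT) pairs are admitted but flagged via
#' `vat_flag` so downstream reporting can distinguish them.
#'
#' @param hits data frame of shared-locus hits from [scan_overlap()]
#'   (rows with `is_hit = TRUE` are used when the column is present).
#' @param eqtl_records data frame with columns `snp_id`, `gene`,
#'   `tissue`, `high_allele`, `low_allele`, `fdr_pass`, optionally
#'   `p_nominal`, `detected_in_hascs`, `phenotype`.
#' @param tissues admitted tissues (default SAT plus flagged VAT).
#' @return Data frame of (hit, eQTL) pairs: the hit columns plus `gene`,
#'   `tissue`, `p_eqtl`, `high_allele`, `low_allele`, `vat_flag`, and
#'   `detected_in_hascs` when available.
#' @export
attach_eqtls <- function(hits, eqtl_records, tissues = c("SAT", "VAT")) {
  if ("is_hit" %in% names(hits)) hits <- hits[hits$is_hit, , drop = FALSE]
  eq <- eqtl_records
  if (!"fdr_pass" %in% names(eq)) eq$fdr_pass <- TRUE
  eq <- eq[eq$fdr_pass & eq$tissue %in% tissues, , drop = FALSE]
  by_pheno <- "phenotype" %in% names(hits) && "phenotype" %in% names(eq)
  hit_key <- if (by_pheno) paste(hits$snp_id, hits$phenotype)
             else hits$snp_id
  eq_key <- if (by_pheno) paste(eq$snp_id, eq$phenotype) else eq$snp_id
  keep <- eq_key %in% hit_key
  eq <- eq[keep, , drop = FALSE]
  idx <- match(if (by_pheno) paste(eq$snp_id, eq$phenotype) else eq$snp_id,
               hit_key)
  out <- hits[idx, , drop = FALSE]
  out$gene <- eq$gene
  out$tissue <- eq$tissue
  out$p_eqtl <- if ("p_nominal" %in% names(eq)) eq$p_nominal
                else rep(NA_real_, nrow(out))
  out$high_allele <- toupper(eq$high_allele)
  out$low_allele <- toupper(eq$low_allele)
  out$vat_flag <- eq$tissue == "VAT"
  out$detected_in_hascs <- if ("detected_in_hascs" %in% names(eq))
    eq$detected_in_hascs else rep(NA, nrow(out))
  bad <- which(!(out$high_allele == out$effect_allele |
                   out$high_allele == out$other_allele) |
               !(out$low_allele == out$effect_allele |
                   out$low_allele == out$other_allele))
  if (length(bad) > 0) {
    stop("eQTL allele(s) outside the SNP's allele set: ",
         paste(unique(paste0(out$snp_id[bad], "/", out$gene[bad])),
               collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Filter genes by expression in differentiating hASCs
#'
#' A gene counts as detected in human adipose-derived stem cells when
#' its expression exceeds `threshold_tpm` tags per million (strictly) at
#' some point during the differentiation time course. Genes absent from
#' the profile table are treated as not detected and reported via a
#' message.
#'
#' @param genes character vector of gene symbols.
#' @param profiles long-format expression table with columns `gene` and
#'   `tpm` (one row per gene and time point).
#' @param threshold_tpm detection threshold (default 10 TPM, strict
#'   `>`).
#' @return The subset of `genes` that is detected, in input order.
#' @export
filter_expressed <- function(genes, profiles, threshold_tpm = 10) {
  stopifnot(threshold_tpm >= 0)
  if (any(is.na(profiles$tpm)) || any(profiles$tpm < 0)) {
    stop("TPM values must be non-negative and non-missing")
  }
  peak <- tapply(profiles$tpm, profiles$gene, max)
  absent <- setdiff(genes, names(peak))
  if (length(absent) > 0) {
    message("gene(s) absent from expression table treated as not detected: ",
            paste(absent, collapse = ", "))
  }
  detected <- names(peak)[peak > threshold_tpm]
  genes[genes %in% detected]
}

#' Classify the allele-level congruence of candidate genes
#'
#' For each (hit, eQTL) pair the allele raising the lipolysis phenotype
#' is compared with the allele raising gene expression (the eQTL "high"
#' allele). When they coincide, the gene is predicted to be a positive
#' regulator of lipolysis and its knockdown is predicted to decrease
#' the phenotype; otherwise a negative regulator whose knockdown should
#' increase it. If an observed knockdown direction is supplied, the
#' prediction is scored as congruent or incongruent.
#'
#' @param pairs data frame of (hit, eQTL) pairs from [attach_eqtls()].
#' @param observed_knockdown optional data frame with columns `gene` and
#'   `observed_knockdown` (`decrease`, `increase`, `none`, `unknown`).
#' @return Candidate-gene data frame: `snp_id`, `gene`, `phenotype`,
#'   `trait`, `tissue`, `vat_flag`, `lipolysis_up_allele`,
#'   `expression_up_allele`, `regulator_prediction`,
#'   `predicted_knockdown_effect`, `observed_knockdown_effect`,
#'   `congruent_with_knockdown` (`"true"`, `"false"`, `"unknown"`),
#'   `detected_in_hascs`. Pairs with a lipolysis beta of exactly zero
#'   are flagged with `NA` predictions and congruence `"unknown"`.
#' @export
classify_congruence <- function(pairs, observed_knockdown = NULL) {
  n <- nrow(pairs)
  up <- ifelse(pairs$beta_phenotype > 0, pairs$effect_allele,
               pairs$other_allele)
  zero <- pairs$beta_phenotype == 0
  if (any(zero)) {
    warning("zero lipolysis beta for ",
            paste(unique(pairs$snp_id[zero]), collapse = ", "),
            "; congruence undefined for these pairs")
    up[zero] <- NA_character_
  }
  regulator <- ifelse(up == pairs$high_allele, "positive", "negative")
  predicted <- ifelse(regulator == "positive", "decrease", "increase")
  observed <- rep("unknown", n)
  if (!is.null(observed_knockdown)) {
    m <- match(pairs$gene, observed_knockdown$gene)
    observed <- ifelse(is.na(m), "unknown",
                       observed_knockdown$observed_knockdown[m])
  }
  congruent <- ifelse(
    is.na(regulator) | observed %in% c("unknown", "none"), "unknown",
    ifelse(predicted == observed, "true", "false"))
  data.frame(
    snp_id = pairs$snp_id,
    gene = pairs$gene,
    phenotype = pairs$phenotype,
    trait = pairs$trait,
    tissue = pairs$tissue,
    vat_flag = pairs$vat_flag,
    lipolysis_up_allele = up,
    expression_up_allele = pairs$high_allele,
    regulator_prediction = regulator,
    predicted_knockdown_effect = predicted,
    observed_knockdown_effect = observed,
    congruent_with_knockdown = congruent,
    detected_in_hascs = pairs$detected_in_hascs,
    stringsAsFactors = FALSE
  )
}

#' Rank candidate genes by strength of functional support
#'
#' Ordering criteria, applied in turn: (1) detected in hASCs, (2)
#' knockdown direction congruent with the genetic prediction, (3) no
#' effect on lipid accumulation (a direct effect on lipolysis rather
#' than one secondary to disturbed adipogenesis), then alphabetical by
#' gene. Each candidate is labelled with its tier.
#'
#' @param candidates data frame from [classify_congruence()].
#' @param lipid_effects optional data frame with columns `gene` and
#'   `lipid_effect` (`decrease`, `increase`, `none`, `unknown`).
#' @return The candidates, ranked, with columns `lipid_effect`, `tier`
#'   (label) and `rank` prepended to the ordering.
#' @export
prioritize_candidates <- function(candidates, lipid_effects = NULL) {
  out <- candidates
  out$lipid_effect <- rep("unknown", nrow(out))
  if (!is.null(lipid_effects)) {
    m <- match(out$gene, lipid_effects$gene)
    out$lipid_effect <- ifelse(is.na(m), "unknown",
                               lipid_effects$lipid_effect[m])
  }
  detected <- out$detected_in_hascs %in% TRUE
  congruent <- out$congruent_with_knockdown == "true"
  direct <- out$lipid_effect == "none"
  out$tier <- paste0(
    ifelse(detected, "hASC-detected", "not detected"),
    ifelse(congruent, ", congruent", ""),
    ifelse(direct, ", direct lipolysis effect", "")
  )
  ord <- order(!detected, !congruent, !direct, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
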