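#' Configuration for the summary-statistics simulator
#'
#' Describes a mediation architecture: per-SNP instrument effects
#' `gamma_j` on a cellular phenotype (the exposure), a causal effect
#' `tau` of the phenotype on a downstream trait (the outcome), and
#' optional pleiotropic direct effects `alpha_j`, so the true outcome
#' effect of SNP j is `tau * gamma_j + alpha_j`. Observed betas add
#' sampling noise with the analytic standard error of a standardized
#' trait, `se = 1 / sqrt(2 n p (1 - p))` for allele frequency `p`.
#'
#' @param n_snps number of independent index SNPs.
#' @param maf_range interval within (0, 0.5] for minor-allele
#'   frequencies.
#' @param n_exposure,n_outcome GWAS sample sizes for the two samples.
#' @param tau causal effect of the phenotype on the trait.
#' @param gamma_sd standard deviation of the true instrument effects.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct
#'   effects) or `"directional"` (mean `alpha_mean`).
#' @param alpha_mean,alpha_sd pleiotropic effect parameters.
#' @param prop_null fraction of SNPs with `gamma_j = 0`.
#' @param eqtl_fraction fraction of SNPs given a simulated eQTL gene.
#' @param seed integer seed making the whole cohort reproducible.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_snps = 100, maf_range = c(0.05, 0.5),
                              n_exposure = 1e5, n_outcome = 1e5,
                              tau = 0.2, gamma_sd = 0.05,
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional"),
                              alpha_mean = 0, alpha_sd = 0.02,
                              prop_null = 0, eqtl_fraction = 0.3,
                              seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_exposure >= 2, n_outcome >= 2,
            is.finite(tau), gamma_sd >= 0,
            prop_null >= 0, prop_null <= 1,
            eqtl_fraction >= 0, eqtl_fraction <= 1)
  cfg <- list(n_snps = as.integer(n_snps), maf_range = maf_range,
              n_exposure = n_exposure, n_outcome = n_outcome,
              tau = tau, gamma_sd = gamma_sd,
              pleiotropy_mode = pleiotropy_mode,
              alpha_mean = alpha_mean, alpha_sd = alpha_sd,
              prop_null = prop_null, eqtl_fraction = eqtl_fraction,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# non-palindromic by construction unless strand ambiguity is wanted
ALLELE_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"),
  c("A", "T"), c("C", "G")  # palindromic pairs, drawn less often
)

#' Simulate a paired two-sample GWAS cohort with known truth
#'
#' Generates exposure (cellular phenotype) and outcome (trait) summary
#' statistics under the mediation model of [simulation_config()],
#' together with an eQTL table whose high-expression alleles follow a
#' simulated expression-effect sign, an hASC-style expression profile
#' table, and the generating truth. The outcome table is written with a
#' random ref/alt orientation, and non-palindromic SNPs additionally
#' receive a random strand flip, so harmonization is genuinely
#' exercised; the truth records the canonical orientation.
#'
#' @param config a `simulation_config`.
#' @return List with `exposure`, `outcome` (GWAS record data frames),
#'   `eqtls`, `expression` (long TPM table), and `truth` (per-SNP
#'   `gamma`, `alpha`, `beta_outcome_true`, `maf`, orientation flags,
#'   per-gene `high_allele`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_snps
  snp_id <- sprintf("rs9%06d", seq_len(n))
  chrom <- as.character(sample(1:22, n, replace = TRUE))
  pos <- sample.int(2.4e8, n)
  pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), n, replace = TRUE,
                                  prob = c(rep(0.115, 8), 0.04, 0.04)), ,
                       drop = FALSE]
  ref <- pair[, 1]
  alt <- pair[, 2]
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])

  gamma <- stats::rnorm(n, 0, config$gamma_sd)
  gamma[stats::runif(n) < config$prop_null] <- 0
  alpha <- switch(config$pleiotropy_mode,
                  none = rep(0, n),
                  balanced = stats::rnorm(n, 0, config$alpha_sd),
                  directional = stats::rnorm(n, config$alpha_mean,
                                             config$alpha_sd))
  beta_out_true <- config$tau * gamma + alpha

  se_x <- 1 / sqrt(2 * config$n_exposure * maf * (1 - maf))
  se_y <- 1 / sqrt(2 * config$n_outcome * maf * (1 - maf))
  bx <- gamma + stats::rnorm(n, 0, se_x)
  by <- beta_out_true + stats::rnorm(n, 0, se_y)
  # clamp: very strong instruments can underflow the two-sided p to 0
  two_sided_p <- function(b, se) {
    pmax(2 * stats::pnorm(-abs(b / se)), .Machine$double.xmin)
  }

  exposure <- gwas_records(snp_id, chrom, pos, ref, alt, bx,
                           two_sided_p(bx, se_x), maf, se = se_x,
                           trait_tag = "spontaneous_lipolysis")

  pal <- is_palindromic(ref, alt)
  swap <- stats::runif(n) < 0.5
  strand <- !pal & stats::runif(n) < 0.5
  out_ref <- ifelse(swap, alt, ref)
  out_alt <- ifelse(swap, ref, alt)
  out_beta <- ifelse(swap, -by, by)
  out_freq <- ifelse(swap, 1 - maf, maf)
  out_ref <- ifelse(strand, complement_allele(out_ref), out_ref)
  out_alt <- ifelse(strand, complement_allele(out_alt), out_alt)
  outcome <- gwas_records(snp_id, chrom, pos, out_ref, out_alt, out_beta,
                          two_sided_p(by, se_y), out_freq, se = se_y,
                          trait_tag = "BMI")

  n_eqtl <- round(config$eqtl_fraction * n)
  eqtl_idx <- if (n_eqtl > 0) sort(sample.int(n, n_eqtl)) else integer(0)
  genes <- sprintf("GENE%04d", seq_len(n_eqtl))
  expr_sign <- sample(c(-1, 1), n_eqtl, replace = TRUE)
  high <- ifelse(expr_sign > 0, alt[eqtl_idx], ref[eqtl_idx])
  low <- ifelse(expr_sign > 0, ref[eqtl_idx], alt[eqtl_idx])
  eqtls <- data.frame(
    snp_id = snp_id[eqtl_idx], gene = genes,
    tissue = rep("SAT", n_eqtl),
    p_nominal = stats::runif(n_eqtl, 1e-12, 1e-4),
    high_allele = high, low_allele = low,
    fdr_pass = rep(TRUE, n_eqtl),
    stringsAsFactors = FALSE
  )
  expression <- make_expression_profiles(genes, detected_fraction = 0.7,
                                         seed = NULL)

  truth <- data.frame(
    snp_id = snp_id, maf = maf, gamma = gamma, alpha = alpha,
    beta_outcome_true = beta_out_true, se_exposure = se_x,
    se_outcome = se_y, ref_allele = ref, alt_allele = alt,
    outcome_swapped = swap, outcome_strand_flipped = strand,
    stringsAsFactors = FALSE
  )
  truth$gene <- NA_character_
  truth$gene[eqtl_idx] <- genes
  truth$high_allele <- NA_character_
  truth$high_allele[eqtl_idx] <- high

  list(exposure = exposure, outcome = outcome, eqtls = eqtls,
       expression = expression, truth = truth, config = config)
}

#' Simulate hASC differentiation expression profiles
#'
#' Builds a long-format TPM table over a differentiation time course in
#' which an exact `round(detected_fraction * length(genes))` of the
#' genes peak strictly above 10 TPM (detected) and the rest stay at or
#' below 10 TPM.
#'
#' @param genes gene symbols.
#' @param detected_fraction fraction of genes detected (default 0.7).
#' @param seed integer seed, or `NULL` to draw from the current RNG
#'   state (used inside [simulate_cohort()]).
#' @param n_timepoints time points in the series (default 8).
#' @return Data frame with columns `gene`, `timepoint`, `tpm`.
#' @export
make_expression_profiles <- function(genes, detected_fraction = 0.7,
                                     seed = 1, n_timepoints = 8) {
  stopifnot(detected_fraction >= 0, detected_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(genes)
  if (n == 0) {
    return(data.frame(gene = character(0), timepoint = integer(0),
                      tpm = numeric(0)))
  }
  n_det <- round(detected_fraction * n)
  detected <- rep(FALSE, n)
  if (n_det > 0) detected[sample.int(n, n_det)] <- TRUE
  rows <- lapply(seq_len(n), function(i) {
    base <- stats::runif(n_timepoints, 0, 8)
    if (detected[i]) {
      peak_at <- sample.int(n_timepoints, 1)
      base[peak_at] <- stats::runif(1, 12, 120)
    }
    data.frame(gene = genes[i], timepoint = seq_len(n_timepoints),
               tpm = base, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated cohort to TSV files
#'
#' Writes the exposure, outcome, eQTL, expression and truth tables in
#' the same dialects the package readers consume.
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  gw <- function(x) {
    data.frame(SNP = x$snp_id, CHR = x$chrom, POS = x$pos,
               REF = x$ref_allele, ALT = x$alt_allele, BETA = x$beta,
               SE = x$se, P = x$p, FREQ = x$alt_freq)
  }
  wt(gw(cohort$exposure), "exposure.tsv")
  wt(gw(cohort$outcome), "outcome.tsv")
  wt(cohort$eqtls, "eqtl.tsv")
  wt(cohort$expression, "expression.tsv")
  wt(cohort$truth, "truth.tsv")
  invisible(dir)
}
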