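#' Expected direction rule for a trait/phenotype combination
#'
#' High spontaneous and low catecholamine-stimulated lipolysis accompany
#' higher body weight, so a BMI-raising allele is expected to raise
#' spontaneous lipolysis (concordant) and lower stimulated lipolysis
#' (discordant). For WHRadjBMI the relationship between depot-specific
#' lipolysis and fat distribution is unclear, so effect directions are
#' not constrained.
#'
#' @param trait `"BMI"` or `"WHRadjBMI"`.
#' @param phenotype `"spontaneous"` or `"stimulated"`.
#' @return One of `"require_concordant"`, `"require_discordant"`,
#'   `"unconstrained"`.
#' @export
direction_rule_for <- function(trait = c("BMI", "WHRadjBMI"),
                               phenotype = c("spontaneous", "stimulated")) {
  trait <- match.arg(trait)
  phenotype <- match.arg(phenotype)
  if (trait == "WHRadjBMI") return("unconstrained")
  if (phenotype == "spontaneous") "require_concordant" else "require_discordant"
}

#' Classify the direction of an aligned effect pair
#'
#' @param beta_phenotype,beta_trait betas aligned to a common allele.
#' @return `"concordant"` when the sign product is +1, `"discordant"`
#'   when -1, `"null"` when either beta is exactly zero.
#' @export
direction_class <- function(beta_phenotype, beta_trait) {
  prod <- sign(beta_phenotype) * sign(beta_trait)
  ifelse(prod == 0, "null", ifelse(prod > 0, "concordant", "discordant"))
}

#' Scan trait index SNPs against a cellular-phenotype GWAS
#'
#' The core lookup of the cascade: each index SNP is searched in the
#' phenotype GWAS by rsID, the two records are harmonized to the index
#' SNP's alt allele, the phenotype p-value is compared with `alpha`
#' (strict `<`), and the aligned effect directions are checked against
#' the trait's rule. Index SNPs not found in the phenotype GWAS are
#' counted but produce no row.
#'
#' @param index_snps GWAS records for the trait panel.
#' @param phenotype_gwas GWAS records for the cellular phenotype,
#'   keyed by rsID.
#' @param rule direction rule from [direction_rule_for()].
#' @param alpha nominal significance threshold on the phenotype p-value
#'   (default 0.05, strict).
#' @param strand_mode harmonization mode; the scan defaults to
#'   `"literal"` (trust rsID and printed alleles) because joined lookup
#'   tables normally share an orientation convention.
#' @param palindrome_maf_threshold see [harmonize_pair()].
#' @param phenotype,trait labels attached to the output rows.
#' @return Data frame with one row per index SNP found in the phenotype
#'   GWAS: aligned betas/p-values/frequencies, harmonization `status`,
#'   `direction_class`, `nominal` (p below alpha), `passes_rule`
#'   (direction rule satisfied) and `is_hit` (all filters passed).
#'   Attribute `"counts"` holds the cascade stage counts: `n_panel`,
#'   `n_found`, `n_harmonized`, `n_nominal`,
#'   `n_nominal_and_consistent`, `n_hits`.
#' @export
scan_overlap <- function(index_snps, phenotype_gwas, rule = "unconstrained",
                         alpha = 0.05,
                         strand_mode = c("literal", "mrbase"),
                         palindrome_maf_threshold = 0.3,
                         phenotype = NA_character_, trait = NA_character_) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(alpha > 0, alpha < 1)
  if (!rule %in% c("require_concordant", "require_discordant",
                   "unconstrained")) {
    stop("unknown direction rule: ", rule)
  }
  harm <- harmonize_tables(index_snps, phenotype_gwas,
                           palindrome_maf_threshold = palindrome_maf_threshold,
                           strand_mode = strand_mode)
  idx <- match(harm$snp_id, index_snps$snp_id)
  out <- data.frame(
    snp_id = harm$snp_id,
    chrom = index_snps$chrom[idx],
    pos = index_snps$pos[idx],
    phenotype = phenotype,
    trait = trait,
    effect_allele = harm$effect_allele,
    other_allele = harm$other_allele,
    beta_trait = harm$beta_a,
    p_trait = harm$p_a,
    freq_trait = harm$freq_a,
    beta_phenotype = harm$beta_b,
    p_phenotype = harm$p_b,
    freq_phenotype = harm$freq_b,
    status = harm$status,
    stringsAsFactors = FALSE
  )
  out$direction_class <- direction_class(out$beta_phenotype, out$beta_trait)
  kept <- !startsWith(out$status, "dropped")
  out$nominal <- kept & !is.na(out$p_phenotype) & out$p_phenotype < alpha
  out$passes_rule <- kept & switch(
    rule,
    require_concordant = out$direction_class == "concordant",
    require_discordant = out$direction_class == "discordant",
    unconstrained = rep(TRUE, nrow(out))
  )
  out$is_hit <- out$nominal & out$passes_rule
  attr(out, "counts") <- c(
    n_panel = nrow(index_snps),
    n_found = nrow(out),
    n_harmonized = sum(kept),
    n_nominal = sum(out$nominal),
    n_nominal_and_consistent = sum(out$nominal & out$passes_rule),
    n_hits = sum(out$is_hit)
  )
  out
}

#' Count unique loci across phenotype hit lists
#'
#' Loci are identified by rsID: a SNP shared between the spontaneous and
#' stimulated hit lists counts once.
#'
#' @param ... hit data frames (rows restricted to `is_hit` when that
#'   column is present) or character vectors of rsIDs.
#' @return Integer count of distinct rsIDs.
#' @examples
#' count_unique_loci(c("rs1", "rs2"), c("rs2", "rs3"))  # 3
#' @export
count_unique_loci <- function(...) {
  ids <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) return(x)
    if (is.data.frame(x)) {
      if ("is_hit" %in% names(x)) x <- x[x$is_hit, , drop = FALSE]
      return(x$snp_id)
    }
    stop("expected a hit data frame or character rsIDs")
  }))
  length(unique(ids))
}

#' Tally directional consistency of a whole SNP panel
#'
#' Unlike the hit scan, the tally applies no p-value filter: every panel
#' SNP found and harmonized in the phenotype GWAS with nonzero betas on
#' both sides contributes to `n`, and `k` counts those matching the
#' trait's expected direction pattern (BMI: concordant with spontaneous,
#' discordant with stimulated; WHRadjBMI: concordant, reported
#' descriptively). Enrichment over the 50% chance level is tested with
#' the one-sided exact binomial test.
#'
#' @inheritParams scan_overlap
#' @param trait `"BMI"` or `"WHRadjBMI"`.
#' @param phenotype `"spontaneous"` or `"stimulated"`.
#' @return Object of class `direction_tally`: list with `k`, `n`,
#'   `p_binomial`, `trait`, `phenotype`, `expected` (the tallied
#'   direction class).
#' @export
tally_directions <- function(index_snps, phenotype_gwas,
                             trait = c("BMI", "WHRadjBMI"),
                             phenotype = c("spontaneous", "stimulated"),
                             strand_mode = c("literal", "mrbase"),
                             palindrome_maf_threshold = 0.3) {
  trait <- match.arg(trait)
  phenotype <- match.arg(phenotype)
  strand_mode <- match.arg(strand_mode)
  rule <- direction_rule_for(trait, phenotype)
  expected <- if (rule == "require_discordant") "discordant" else "concordant"
  scan <- scan_overlap(index_snps, phenotype_gwas, rule = "unconstrained",
                       alpha = 0.999999, strand_mode = strand_mode,
                       palindrome_maf_threshold = palindrome_maf_threshold,
                       phenotype = phenotype, trait = trait)
  kept <- !startsWith(scan$status, "dropped") &
    scan$direction_class != "null"
  n <- sum(kept)
  k <- sum(kept & scan$direction_class == expected)
  out <- list(k = k, n = n,
              p_binomial = if (n >= 1) binomial_direction_test(k, n)
                           else NA_real_,
              trait = trait, phenotype = phenotype, expected = expected)
  class(out) <- "direction_tally"
  out
}

#' @export
print.direction_tally <- function(x, ...) {
  cat(sprintf(
    "Direction tally (%s vs %s lipolysis): %d of %d SNPs %s (P[X >= k | 0.5] = %.4g)\n",
    x$trait, x$phenotype, x$k, x$n, x$expected, x$p_binomial))
  invisible(x)
}

#' One-sided exact binomial test against a 50% chance level
#'
#' Computes the exact upper tail `P(X >= k)` for `X ~ Binomial(n, 0.5)`:
#' the probability, under chance, of at least `k` of `n` SNPs showing
#' the expected effect direction.
#'
#' @param k count of directionally consistent SNPs.
#' @param n total SNPs tallied (`n >= 1`).
#' @return The exact one-sided p-value.
#' @examples
#' binomial_direction_test(5, 5)  # 0.5^5 = 0.03125
#' @export
binomial_direction_test <- function(k, n) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n)) {
    stop("need integer counts with 0 <= k <= n and n >= 1")
  }
  stats::pbinom(k - 1, size = n, prob = 0.5, lower.tail = FALSE)
}
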