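#' Is a variant palindromic?
#'
#' A palindromic (ambiguous-strand) SNP has alleles that are each
#' other's reverse complement, i.e. the pair is A/T or C/G. For such
#' variants the strand cannot be resolved from allele letters alone.
#'
#' @param ref,alt nucleotide characters (vectorized).
#' @return Logical vector.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("T", "C")  # FALSE
#' @export
is_palindromic <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (any(!ref %in% VALID_NUCLEOTIDES) || any(!alt %in% VALID_NUCLEOTIDES)) {
    stop("alleles must be A, C, G or T")
  }
  complement_allele(ref) == alt
}

#' Complement nucleotides
#'
#' @param x character vector of A/C/G/T.
#' @return The complementary bases.
#' @export
complement_allele <- function(x) {
  chartr("ACGT", "TGCA", toupper(x))
}

#' Flip the allele orientation of GWAS records
#'
#' Swaps ref and alt, negates beta and complements the allele frequency
#' (`alt_freq` becomes `1 - alt_freq`); p and se are unchanged. This is
#' a pure relabelling: the record describes the same association from
#' the other allele's viewpoint. The operation is an involution.
#'
#' @param record data frame of GWAS records.
#' @return The re-oriented records.
#' @export
flip_record <- function(record) {
  out <- record
  out$ref_allele <- record$alt_allele
  out$alt_allele <- record$ref_allele
  out$beta <- -record$beta
  out$alt_freq <- 1 - record$alt_freq
  out
}

#' Harmonize two association records for the same SNP
#'
#' Aligns record `b` to record `a`'s alternative allele so both betas
#' refer to the same effect allele. Non-palindromic alleles are matched
#' literally, flipping `b` when its orientation is swapped; under
#' `strand_mode = "mrbase"` an allele set that matches only after
#' complementing is strand-corrected. Palindromic SNPs cannot be
#' resolved by letters: under `"mrbase"` they are dropped when the
#' minor-allele frequency in either record exceeds
#' `palindrome_maf_threshold`, and otherwise oriented so that the two
#' alt-allele frequencies fall on the same side of 0.5; under
#' `"literal"` the allele letters are trusted as printed (no strand
#' logic at all). Irreconcilable allele sets give status
#' `dropped_mismatch`. An aligned frequency discrepancy above
#' `freq_warn` triggers a warning but never a drop.
#'
#' @param a,b single-row GWAS record data frames with equal `snp_id`.
#' @param palindrome_maf_threshold minor-allele-frequency bound above
#'   which palindromic SNPs are dropped (default 0.3).
#' @param freq_warn aligned allele-frequency discrepancy that triggers a
#'   warning (default 0.2).
#' @param strand_mode `"mrbase"` (strand correction + palindrome policy)
#'   or `"literal"` (trust rsID and printed alleles).
#' @return One-row data frame: `snp_id`, `effect_allele`,
#'   `other_allele`, aligned `beta_a`, `se_a`, `p_a`, `freq_a`,
#'   `beta_b`, `se_b`, `p_b`, `freq_b`, `status`, `freq_discrepancy`.
#'   `status` is one of `aligned`, `flipped`, `strand_corrected`,
#'   `dropped_palindromic`, `dropped_mismatch`.
#' @export
harmonize_pair <- function(a, b, palindrome_maf_threshold = 0.3,
                           freq_warn = 0.2,
                           strand_mode = c("mrbase", "literal")) {
  strand_mode <- match.arg(strand_mode)
  if (a$snp_id != b$snp_id) {
    stop("snp_id mismatch: ", a$snp_id, " vs ", b$snp_id)
  }
  res <- function(bb, status) {
    fd <- if (startsWith(status, "dropped")) NA_real_ else
      abs(a$alt_freq - bb$alt_freq)
    if (!is.na(fd) && fd > freq_warn) {
      warning("allele-frequency discrepancy ", signif(fd, 3), " for ",
              a$snp_id)
    }
    data.frame(snp_id = a$snp_id, effect_allele = a$alt_allele,
               other_allele = a$ref_allele,
               beta_a = a$beta, se_a = a$se, p_a = a$p,
               freq_a = a$alt_freq,
               beta_b = bb$beta, se_b = bb$se, p_b = bb$p,
               freq_b = bb$alt_freq,
               status = status, freq_discrepancy = fd,
               stringsAsFactors = FALSE)
  }
  pal <- is_palindromic(a$ref_allele, a$alt_allele)
  set_a <- c(a$ref_allele, a$alt_allele)
  set_b <- c(b$ref_allele, b$alt_allele)

  if (pal && strand_mode == "mrbase") {
    if (!setequal(set_a, set_b)) return(res(b, "dropped_mismatch"))
    maf_a <- min(a$alt_freq, 1 - a$alt_freq)
    maf_b <- min(b$alt_freq, 1 - b$alt_freq)
    if (maf_a > palindrome_maf_threshold || maf_b > palindrome_maf_threshold) {
      return(res(b, "dropped_palindromic"))
    }
    bb <- if (b$alt_allele == a$alt_allele) b else flip_record(b)
    # letters are ambiguous for palindromes: orient by frequency instead
    if ((a$alt_freq < 0.5) != (bb$alt_freq < 0.5)) bb <- flip_record(bb)
    # relabel alleles to a's orientation (frequency decided the strand)
    bb$ref_allele <- a$ref_allele
    bb$alt_allele <- a$alt_allele
    status <- if (bb$beta == b$beta && bb$alt_freq == b$alt_freq)
      "aligned" else "flipped"
    return(res(bb, status))
  }

  if (b$alt_allele == a$alt_allele && b$ref_allele == a$ref_allele) {
    return(res(b, "aligned"))
  }
  if (b$alt_allele == a$ref_allele && b$ref_allele == a$alt_allele) {
    return(res(flip_record(b), "flipped"))
  }
  if (strand_mode == "mrbase") {
    bc <- b
    bc$ref_allele <- complement_allele(b$ref_allele)
    bc$alt_allele <- complement_allele(b$alt_allele)
    if (bc$alt_allele == a$alt_allele && bc$ref_allele == a$ref_allele) {
      return(res(bc, "strand_corrected"))
    }
    if (bc$alt_allele == a$ref_allele && bc$ref_allele == a$alt_allele) {
      return(res(flip_record(bc), "strand_corrected"))
    }
  }
  res(b, "dropped_mismatch")
}

#' Harmonize two GWAS record tables by rsID
#'
#' Joins `a` and `b` on `snp_id` (keeping `a`'s order; only SNPs present
#' in both are returned) and harmonizes each pair with
#' [harmonize_pair()].
#'
#' @inheritParams harmonize_pair
#' @param a,b GWAS record data frames.
#' @return Data frame of harmonized pairs, one row per shared SNP.
#' @export
harmonize_tables <- function(a, b, palindrome_maf_threshold = 0.3,
                             freq_warn = 0.2,
                             strand_mode = c("mrbase", "literal")) {
  strand_mode <- match.arg(strand_mode)
  shared <- a$snp_id[a$snp_id %in% b$snp_id]
  b_idx <- match(shared, b$snp_id)
  a_idx <- match(shared, a$snp_id)
  rows <- lapply(seq_along(shared), function(i) {
    harmonize_pair(a[a_idx[i], , drop = FALSE], b[b_idx[i], , drop = FALSE],
                   palindrome_maf_threshold = palindrome_maf_threshold,
                   freq_warn = freq_warn, strand_mode = strand_mode)
  })
  if (length(rows) == 0) {
    return(data.frame(snp_id = character(0), effect_allele = character(0),
                      other_allele = character(0), beta_a = numeric(0),
                      se_a = numeric(0), p_a = numeric(0),
                      freq_a = numeric(0), beta_b = numeric(0),
                      se_b = numeric(0), p_b = numeric(0),
                      freq_b = numeric(0), status = character(0),
                      freq_discrepancy = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Infer a standard error from beta and p
#'
#' Published lookup tables often print the effect size and two-sided
#' p-value but not the standard error. Under the large-sample normal
#' approximation for a Wald test, `se = |beta| / z` with `z` the upper
#' `p/2` standard-normal quantile.
#'
#' @param beta nonzero effect size(s).
#' @param p two-sided p-value(s) strictly inside (0, 1).
#' @return Positive standard error(s).
#' @examples
#' infer_se(0.07, 0.3173)  # close to 0.07, since z is about 1
#' @export
infer_se <- function(beta, p) {
  if (any(is.na(beta)) || any(beta == 0)) {
    stop("se cannot be inferred when beta is 0 or missing")
  }
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    stop("se inference requires 0 < p < 1")
  }
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  abs(beta) / z
}
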