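#' Build a two-sample MR instrument set
#'
#' Harmonizes exposure and outcome summary statistics by rsID, infers
#' missing standard errors from beta and p via [infer_se()], drops SNPs
#' that fail harmonization (including ambiguous palindromes under the
#' minor-allele-frequency policy), and aligns every SNP to its
#' exposure-increasing allele so all `beta_exposure` are positive.
#'
#' @param exposure_gwas,outcome_gwas GWAS record data frames.
#' @param snp_ids optional rsIDs restricting the instrument panel
#'   (e.g. shared-locus hits).
#' @param direction_rule optional direction-consistency filter applied
#'   to the aligned exposure/outcome sign product before inclusion
#'   (`"require_concordant"`, `"require_discordant"` or
#'   `"unconstrained"`).
#' @param palindrome_maf_threshold see [harmonize_pair()] (default 0.3).
#' @param strand_mode harmonization mode (default `"mrbase"`).
#' @return Data frame of class `instrument_set` with columns `snp_id`,
#'   `effect_allele`, `eaf`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`.
#' @export
build_instruments <- function(exposure_gwas, outcome_gwas, snp_ids = NULL,
                              direction_rule = "unconstrained",
                              palindrome_maf_threshold = 0.3,
                              strand_mode = c("mrbase", "literal")) {
  strand_mode <- match.arg(strand_mode)
  if (!is.null(snp_ids)) {
    exposure_gwas <- exposure_gwas[exposure_gwas$snp_id %in% snp_ids, ,
                                   drop = FALSE]
  }
  harm <- harmonize_tables(exposure_gwas, outcome_gwas,
                           palindrome_maf_threshold = palindrome_maf_threshold,
                           strand_mode = strand_mode)
  harm <- harm[!startsWith(harm$status, "dropped") & harm$beta_a != 0, ,
               drop = FALSE]
  if (nrow(harm) == 0) stop("no usable instruments after harmonization")
  need_se_a <- is.na(harm$se_a)
  harm$se_a[need_se_a] <- infer_se(harm$beta_a[need_se_a],
                                   harm$p_a[need_se_a])
  need_se_b <- is.na(harm$se_b)
  harm$se_b[need_se_b] <- infer_se(harm$beta_b[need_se_b],
                                   harm$p_b[need_se_b])
  if (direction_rule != "unconstrained") {
    prod <- sign(harm$beta_a) * sign(harm$beta_b)
    keep <- if (direction_rule == "require_concordant") prod > 0 else prod < 0
    harm <- harm[keep, , drop = FALSE]
  }
  if (nrow(harm) == 0) stop("no instruments left after direction filtering")
  # orient to the exposure-increasing allele
  neg <- harm$beta_a < 0
  effect <- ifelse(neg, harm$other_allele, harm$effect_allele)
  eaf <- ifelse(neg, 1 - harm$freq_a, harm$freq_a)
  out <- data.frame(
    snp_id = harm$snp_id,
    effect_allele = effect,
    eaf = eaf,
    beta_exposure = abs(harm$beta_a),
    se_exposure = harm$se_a,
    beta_outcome = ifelse(neg, -harm$beta_b, harm$beta_b),
    se_outcome = harm$se_b,
    stringsAsFactors = FALSE
  )
  class(out) <- c("instrument_set", "data.frame")
  out
}

mr_result <- function(method, estimate, se, p = NULL,
                      ci_level = 0.95, intercept = NA_real_,
                      intercept_se = NA_real_, intercept_p = NA_real_,
                      q_statistic = NA_real_, i2_gx = NA_real_,
                      n_instruments = NA_integer_,
                      ci_low = NULL, ci_high = NULL) {
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  if (is.null(ci_low)) ci_low <- estimate - zq * se
  if (is.null(ci_high)) ci_high <- estimate + zq * se
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(estimate / se))
  out <- data.frame(method = method, estimate = estimate, se = se,
                    ci_low = ci_low, ci_high = ci_high, p = p,
                    intercept = intercept, intercept_se = intercept_se,
                    intercept_p = intercept_p, q_statistic = q_statistic,
                    i2_gx = i2_gx,
                    n_instruments = as.integer(n_instruments),
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_result", "data.frame")
  out
}

check_instruments <- function(instruments, min_n, method) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(need, names(instruments))
  if (length(miss) > 0) {
    stop("instrument set lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(instruments$se_exposure <= 0) || any(instruments$se_outcome <= 0)) {
    stop("all instrument standard errors must be positive")
  }
  if (nrow(instruments) < min_n) {
    stop(method, " needs at least ", min_n, " instruments",
         if (min_n == 2) " (use wald_ratio for a single SNP)" else "")
  }
  invisible(instruments)
}

#' Single-instrument Wald ratio causal estimate
#'
#' The causal effect of exposure on outcome through one SNP:
#' `beta_outcome / beta_exposure`, with the first-order delta-method
#' standard error `se_outcome / |beta_exposure|` (uncertainty in the
#' instrument-exposure effect is ignored at first order).
#'
#' @param bx,sx instrument-exposure effect and its standard error.
#' @param by,sy instrument-outcome effect and its standard error.
#' @return An `mr_result` row.
#' @examples
#' wald_ratio(0.1, 0.01, 0.05, 0.01)$estimate  # 0.5
#' @export
wald_ratio <- function(bx, sx, by, sy) {
  if (bx == 0) stop("Wald ratio undefined for a zero exposure effect")
  mr_result("wald", estimate = by / bx, se = sy / abs(bx),
            n_instruments = 1L)
}

#' Inverse-variance weighted MR estimate
#'
#' Fixed-effect IVW: the zero-intercept weighted least-squares slope of
#' outcome effects on exposure effects with weights `1/se_outcome^2`,
#' `estimate = sum(w bx by) / sum(w bx^2)`, `se = 1/sqrt(sum(w bx^2))`.
#' Cochran's Q over the per-SNP residuals is reported; with
#' `random_effects = TRUE` the standard error is inflated by
#' `sqrt(max(1, Q/(L-1)))` (multiplicative random-effects model).
#'
#' @param instruments an instrument set (see [build_instruments()]).
#' @param random_effects inflate the SE for residual heterogeneity?
#' @return An `mr_result` row including `q_statistic` and `i2_gx`.
#' @export
ivw <- function(instruments, random_effects = FALSE) {
  check_instruments(instruments, 2, "ivw")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  q <- sum(w * (by - est * bx)^2)
  L <- nrow(instruments)
  if (random_effects) se <- se * sqrt(max(1, q / (L - 1)))
  mr_result("ivw", estimate = est, se = se, q_statistic = q,
            i2_gx = i2_gx(instruments), n_instruments = L)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with an
#' unconstrained intercept, after orienting all exposure effects to be
#' non-negative; weights `1/se_outcome^2`. The slope is the causal
#' estimate (consistent under the InSIDE assumption even with
#' directional pleiotropy) and the intercept estimates the average
#' directional pleiotropic effect. Inference uses the t distribution
#' with L - 2 degrees of freedom and the standard error is not allowed
#' to fall below its fixed-effect value (residual standard deviation
#' truncated at 1). With `bootstrap_reps > 0`, instruments are
#' resampled with replacement and a percentile confidence interval and
#' bootstrap SE replace the analytic ones.
#'
#' @param instruments an instrument set (at least 3 SNPs).
#' @param bootstrap_reps number of bootstrap resamples (0 = analytic).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_result` row with intercept fields filled in.
#' @export
egger <- function(instruments, bootstrap_reps = 0, seed = 1) {
  check_instruments(instruments, 3, "egger")
  flip <- sign(instruments$beta_exposure)
  flip[flip == 0] <- 1
  bx <- abs(instruments$beta_exposure)
  by <- instruments$beta_outcome * flip
  w <- 1 / instruments$se_outcome^2
  L <- length(bx)
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # fixed-effect floor on the SE (residual sd truncated at 1); an exact
  # fit has sigma 0, where the analytic SEs are already 0
  denom <- min(1, sm$sigma)
  if (denom <= 0) denom <- 1
  slope <- sm$coefficients["bx", "Estimate"]
  slope_se <- sm$coefficients["bx", "Std. Error"] / denom
  inter <- sm$coefficients["(Intercept)", "Estimate"]
  inter_se <- sm$coefficients["(Intercept)", "Std. Error"] / denom
  p_slope <- 2 * stats::pt(-abs(slope / slope_se), df = L - 2)
  p_inter <- 2 * stats::pt(-abs(inter / inter_se), df = L - 2)
  q <- sum(w * stats::residuals(fit)^2)
  res <- mr_result("egger", estimate = slope, se = slope_se, p = p_slope,
                   intercept = inter, intercept_se = inter_se,
                   intercept_p = p_inter, q_statistic = q,
                   i2_gx = i2_gx(instruments), n_instruments = L)
  if (bootstrap_reps > 0) {
    set.seed(seed)
    boots <- replicate(bootstrap_reps, {
      idx <- sample.int(L, L, replace = TRUE)
      if (length(unique(bx[idx])) < 2) return(NA_real_)
      stats::coef(stats::lm(by[idx] ~ bx[idx], weights = w[idx]))[2]
    })
    boots <- boots[!is.na(boots)]
    res$method <- "egger_bootstrap"
    res$se <- stats::sd(boots)
    qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    res$ci_low <- qs[1]
    res$ci_high <- qs[2]
    res$p <- 2 * stats::pnorm(-abs(res$estimate / res$se))
  }
  res
}

# per-SNP Wald ratios and their delta-method variances
ratio_components <- function(instruments, nome = FALSE) {
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  r <- by / bx
  v <- sy^2 / bx^2
  if (!nome) v <- v + by^2 * sx^2 / bx^4
  list(ratio = r, var = v)
}

weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  below <- max(which(cw < 0.5))
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1] - r[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

#' Weighted median MR estimate
#'
#' The inverse-variance weighted median of the per-SNP Wald ratios:
#' consistent when at least 50% of the weight comes from valid
#' instruments. Ratio variances use the second-order delta method. The
#' standard error comes from a parametric bootstrap (effects resampled
#' from their sampling distributions).
#'
#' @param instruments an instrument set (at least 3 SNPs).
#' @param boot_reps bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_result` row.
#' @export
weighted_median <- function(instruments, boot_reps = 1000, seed = 1) {
  check_instruments(instruments, 3, "weighted_median")
  rc <- ratio_components(instruments)
  est <- weighted_median_point(rc$ratio, 1 / rc$var)
  set.seed(seed)
  L <- nrow(instruments)
  boots <- replicate(boot_reps, {
    bx <- stats::rnorm(L, instruments$beta_exposure,
                       instruments$se_exposure)
    by <- stats::rnorm(L, instruments$beta_outcome,
                       instruments$se_outcome)
    r <- by / bx
    v <- instruments$se_outcome^2 / bx^2 +
      by^2 * instruments$se_exposure^2 / bx^4
    weighted_median_point(r, 1 / v)
  })
  se <- stats::sd(boots)
  mr_result("weighted_median", estimate = est, se = se,
            i2_gx = i2_gx(instruments), n_instruments = L)
}

weighted_mode_point <- function(r, w, bandwidth_factor) {
  if (max(r) - min(r) < .Machine$double.eps^0.5) return(r[1])
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
  if (s <= 0) s <- 0.9 * stats::sd(r) * length(r)^(-1 / 5)
  h <- bandwidth_factor * s
  d <- stats::density(r, weights = w / sum(w), bw = h, n = 2048)
  d$x[which.max(d$y)]
}

#' Weighted mode MR estimate
#'
#' The mode of the smoothed, weighted empirical density of per-SNP Wald
#' ratios: consistent when the largest group of instruments sharing a
#' ratio is valid (zero modal pleiotropy). The kernel bandwidth is the
#' modified Silverman rule `0.9 min(sd, mad) L^(-1/5)` scaled by
#' `bandwidth_factor`. With `nome = TRUE`, ratio variances assume no
#' measurement error in the instrument-exposure effects. The standard
#' error is the median absolute deviation of parametric-bootstrap
#' estimates.
#'
#' @param instruments an instrument set (at least 3 SNPs).
#' @param nome assume NO Measurement Error in exposure effects?
#' @param bandwidth_factor multiplier on the Silverman bandwidth.
#' @param boot_reps bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_result` row.
#' @export
weighted_mode <- function(instruments, nome = FALSE, bandwidth_factor = 1,
                          boot_reps = 1000, seed = 1) {
  check_instruments(instruments, 3, "weighted_mode")
  rc <- ratio_components(instruments, nome = nome)
  est <- weighted_mode_point(rc$ratio, 1 / rc$var, bandwidth_factor)
  set.seed(seed)
  L <- nrow(instruments)
  boots <- replicate(boot_reps, {
    bx <- stats::rnorm(L, instruments$beta_exposure,
                       instruments$se_exposure)
    by <- stats::rnorm(L, instruments$beta_outcome,
                       instruments$se_outcome)
    r <- by / bx
    v <- instruments$se_outcome^2 / bx^2
    if (!nome) v <- v + by^2 * instruments$se_exposure^2 / bx^4
    weighted_mode_point(r, 1 / v, bandwidth_factor)
  })
  se <- stats::mad(boots)
  mr_result(if (nome) "weighted_mode_nome" else "weighted_mode",
            estimate = est, se = se, i2_gx = i2_gx(instruments),
            n_instruments = L)
}

#' I2-GX instrument-strength diagnostic
#'
#' Measures violation of the NO Measurement Error (NOME) assumption for
#' MR-Egger: with `w = 1/se_exposure^2` and `bw` the weighted mean of
#' the absolute exposure effects, `Q_GX = sum(w (|bx| - bw)^2)` and
#' `I2_GX = max(0, (Q_GX - (L - 1)) / Q_GX)`. Values near 1 indicate
#' that measurement error in the exposure effects is negligible
#' relative to their spread; values below about 0.9 suggest regression
#' dilution of the Egger slope.
#'
#' @param instruments an instrument set (at least 2 SNPs).
#' @return A value in \[0, 1\] (0 when `Q_GX` is 0).
#' @export
i2_gx <- function(instruments) {
  if (nrow(instruments) < 2) return(NA_real_)
  bx <- abs(instruments$beta_exposure)
  w <- 1 / instruments$se_exposure^2
  bw <- sum(w * bx) / sum(w)
  q <- sum(w * (bx - bw)^2)
  if (q == 0) return(0)
  max(0, (q - (length(bx) - 1)) / q)
}

#' Run the full MR estimator suite
#'
#' Convenience wrapper running Wald ratio (single instrument) or IVW,
#' MR-Egger (analytic and bootstrap), weighted median, and weighted
#' mode with and without the NOME weighting, as applicable to the
#' number of instruments.
#'
#' @param instruments an instrument set.
#' @param seed RNG seed shared by all bootstrap procedures.
#' @param boot_reps bootstrap replicates (default 1000).
#' @return Data frame of `mr_result` rows, one per method run.
#' @export
mr_suite <- function(instruments, seed = 1, boot_reps = 1000) {
  L <- nrow(instruments)
  if (L == 1) {
    return(wald_ratio(instruments$beta_exposure, instruments$se_exposure,
                      instruments$beta_outcome, instruments$se_outcome))
  }
  out <- list(ivw(instruments))
  if (L >= 3) {
    out <- c(out, list(
      egger(instruments),
      egger(instruments, bootstrap_reps = boot_reps, seed = seed),
      weighted_median(instruments, boot_reps = boot_reps, seed = seed),
      weighted_mode(instruments, boot_reps = boot_reps, seed = seed),
      weighted_mode(instruments, nome = TRUE, boot_reps = boot_reps,
                    seed = seed)
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
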