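#' Assemble a pipeline configuration
#'
#' Three input modes are supported: `"fixture"` (the packaged shared-
#' locus tables), `"files"` (TSV summary statistics, eQTL, expression
#' and knockdown tables), and `"simulate"` (a synthetic cohort from
#' [simulate_cohort()]).
#'
#' @param mode input mode.
#' @param fixture fixture id for mode `"fixture"`.
#' @param trait trait label (`"BMI"` or `"WHRadjBMI"`); taken from the
#'   fixture when one is used.
#' @param phenotypes lipolysis phenotypes to scan.
#' @param alpha nominal significance threshold (default 0.05).
#' @param threshold_tpm hASC detection threshold (default 10 TPM).
#' @param strand_mode harmonization mode for the overlap scan.
#' @param do_mr run the MR estimator suite on the hit SNPs?
#' @param mr_seed seed for MR bootstraps.
#' @param boot_reps bootstrap replicates for MR.
#' @param inputs named list of file paths for mode `"files"`: `index`,
#'   `gwas_spontaneous` and/or `gwas_stimulated`, optionally `eqtl`,
#'   `expression`, `knockdown`.
#' @param column_map column mapping for GWAS files.
#' @param simulation a [simulation_config()] for mode `"simulate"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("fixture", "files", "simulate"),
                            fixture = "bmi_shared", trait = "BMI",
                            phenotypes = c("spontaneous", "stimulated"),
                            alpha = 0.05, threshold_tpm = 10,
                            strand_mode = "literal", do_mr = TRUE,
                            mr_seed = 1, boot_reps = 1000,
                            inputs = list(),
                            column_map = sumstats_columns(),
                            simulation = NULL) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(simulation)) {
    simulation <- simulation_config()
  }
  if (mode == "files") {
    if (is.null(inputs$index)) {
      stop("configuration error: inputs$index is required in files mode")
    }
    has_gwas <- any(c("gwas_spontaneous", "gwas_stimulated") %in%
                      names(inputs))
    if (!has_gwas) {
      stop("configuration error: inputs$gwas_spontaneous or ",
           "inputs$gwas_stimulated is required in files mode")
    }
  }
  structure(list(mode = mode, fixture = fixture, trait = trait,
                 phenotypes = phenotypes, alpha = alpha,
                 threshold_tpm = threshold_tpm,
                 strand_mode = strand_mode, do_mr = do_mr,
                 mr_seed = mr_seed, boot_reps = boot_reps,
                 inputs = inputs, column_map = column_map,
                 simulation = simulation),
            class = "pipeline_config")
}

# gather per-phenotype inputs as (index, gwas, eqtls, knockdown,
# expression or detected flags) regardless of mode
pipeline_inputs <- function(config) {
  if (config$mode == "fixture") {
    fx <- load_fixture(config$fixture)
    per_pheno <- lapply(config$phenotypes, function(ph) {
      fg <- fixture_gwas_records(fx, ph)
      list(index = fg$trait, gwas = fg$lipolysis,
           eqtls = fx$eqtls[fx$eqtls$phenotype == ph, , drop = FALSE])
    })
    names(per_pheno) <- config$phenotypes
    list(trait = fx$trait, per_pheno = per_pheno,
         knockdown = fx$knockdown,
         lipid = data.frame(gene = fx$knockdown$gene,
                            lipid_effect = fx$knockdown$lipid_effect,
                            stringsAsFactors = FALSE),
         expression = NULL)
  } else if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$simulation)
    per_pheno <- list(spontaneous = list(index = cohort$outcome,
                                         gwas = cohort$exposure,
                                         eqtls = cohort$eqtls))
    list(trait = config$trait, per_pheno = per_pheno, knockdown = NULL,
         lipid = NULL, expression = cohort$expression, cohort = cohort)
  } else {
    ins <- config$inputs
    index <- read_sumstats(ins$index, config$column_map,
                           trait_tag = "custom")
    per_pheno <- list()
    for (ph in config$phenotypes) {
      key <- paste0("gwas_", ph)
      if (is.null(ins[[key]])) next
      gwas <- read_sumstats(ins[[key]], config$column_map,
                            trait_tag = "custom")
      eq <- if (!is.null(ins$eqtl)) {
        e <- utils::read.delim(ins$eqtl, stringsAsFactors = FALSE)
        if ("phenotype" %in% names(e)) {
          e[e$phenotype == ph, , drop = FALSE]
        } else e
      } else NULL
      per_pheno[[ph]] <- list(index = index, gwas = gwas, eqtls = eq)
    }
    if (length(per_pheno) == 0) {
      stop("configuration error: no gwas_<phenotype> input matches ",
           "the requested phenotypes")
    }
    kd <- if (!is.null(ins$knockdown))
      utils::read.delim(ins$knockdown, stringsAsFactors = FALSE) else NULL
    expr <- if (!is.null(ins$expression))
      utils::read.delim(ins$expression, stringsAsFactors = FALSE) else NULL
    lip <- if (!is.null(kd) && "lipid_effect" %in% names(kd)) {
      data.frame(gene = kd$gene, lipid_effect = kd$lipid_effect,
                 stringsAsFactors = FALSE)
    } else NULL
    list(trait = config$trait, per_pheno = per_pheno, knockdown = kd,
         lipid = lip, expression = expr)
  }
}

#' Run the full shared-locus cascade
#'
#' Executes, for each lipolysis phenotype: the nominal-significance and
#' direction-rule overlap scan, the eQTL join, the hASC expression
#' filter, congruence classification against observed knockdowns, and
#' candidate prioritization; then tallies directional consistency over
#' the whole panel and (optionally) runs the two-sample MR suite with
#' the hit SNPs as instruments. All stages are deterministic given the
#' configuration and seeds.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `lipoloci_report`: list with `trait`,
#'   `stage_counts` (per phenotype), `hits`, `candidates`, `tally`,
#'   `mr`, `unique_loci`, and `notes`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  trait_lab <- if (config$mode == "simulate") "BMI" else config$trait
  ins <- pipeline_inputs(config)
  if (!is.null(ins$trait)) trait_lab <- ins$trait

  notes <- character(0)
  all_hits <- list()
  all_cands <- list()
  stage_counts <- list()
  tallies <- list()
  mr_results <- list()

  for (ph in names(ins$per_pheno)) {
    pp <- ins$per_pheno[[ph]]
    rule <- if (trait_lab %in% c("BMI", "WHRadjBMI")) {
      direction_rule_for(trait_lab, ph)
    } else "unconstrained"
    scan <- scan_overlap(pp$index, pp$gwas, rule = rule,
                         alpha = config$alpha,
                         strand_mode = config$strand_mode,
                         phenotype = ph, trait = trait_lab)
    counts <- as.list(attr(scan, "counts"))
    hits <- scan[scan$is_hit, , drop = FALSE]

    cands <- NULL
    if (!is.null(pp$eqtls) && nrow(hits) > 0) {
      pairs <- attach_eqtls(hits, pp$eqtls)
      counts$n_eqtl_snps <- length(unique(pairs$snp_id))
      counts$n_eqtl_genes <- length(unique(pairs$gene))
      if (!is.null(ins$expression)) {
        detected <- filter_expressed(unique(pairs$gene), ins$expression,
                                     config$threshold_tpm)
        pairs$detected_in_hascs <- pairs$gene %in% detected
      }
      counts$n_hasc_genes <-
        length(unique(pairs$gene[pairs$detected_in_hascs %in% TRUE]))
      cands <- classify_congruence(pairs, ins$knockdown)
      cands <- prioritize_candidates(cands, ins$lipid)
      counts$n_candidates <- sum(cands$detected_in_hascs %in% TRUE)
    } else {
      counts$n_eqtl_snps <- 0L
      counts$n_eqtl_genes <- 0L
      counts$n_hasc_genes <- 0L
      counts$n_candidates <- 0L
    }

    if (trait_lab %in% c("BMI", "WHRadjBMI")) {
      tallies[[ph]] <- tally_directions(pp$index, pp$gwas,
                                        trait = trait_lab, phenotype = ph,
                                        strand_mode = config$strand_mode)
    }

    if (config$do_mr && nrow(hits) > 0) {
      outcome_usable <- any(!is.na(pp$index$se)) ||
        any(!is.na(pp$index$p))
      if (!outcome_usable) {
        notes <- c(notes, paste0(
          ph, ": outcome standard errors unavailable ",
          "(no p-values printed); MR skipped"))
      } else {
        inst <- try(build_instruments(
          pp$gwas, pp$index, snp_ids = hits$snp_id,
          direction_rule = rule), silent = TRUE)
        if (inherits(inst, "try-error")) {
          notes <- c(notes, paste0(
            ph, ": MR skipped (",
            conditionMessage(attr(inst, "condition")), ")"))
        } else {
          mr_results[[ph]] <- mr_suite(inst, seed = config$mr_seed,
                                       boot_reps = config$boot_reps)
        }
      }
    }

    stage_counts[[ph]] <- counts
    all_hits[[ph]] <- hits
    if (!is.null(cands)) all_cands[[ph]] <- cands
  }

  hits <- if (length(all_hits) > 0) do.call(rbind, all_hits) else NULL
  if (!is.null(hits)) rownames(hits) <- NULL
  cands <- if (length(all_cands) > 0) do.call(rbind, all_cands) else NULL
  if (!is.null(cands)) rownames(cands) <- NULL

  report <- list(trait = trait_lab, stage_counts = stage_counts,
                 hits = hits, candidates = cands, tally = tallies,
                 mr = mr_results,
                 unique_loci = if (is.null(hits)) 0L
                               else count_unique_loci(hits$snp_id),
                 notes = notes, config = config)
  class(report) <- "lipoloci_report"
  report
}

#' @export
print.lipoloci_report <- function(x, ...) {
  cat("Shared-locus pipeline report (", x$trait, ")\n", sep = "")
  for (ph in names(x$stage_counts)) {
    sc <- x$stage_counts[[ph]]
    cat(sprintf(
      "  %-12s panel %d -> found %d -> nominal %d -> direction-pass %d -> eQTL SNPs %d -> hASC genes %d\n",
      ph, sc$n_panel, sc$n_found, sc$n_nominal,
      sc$n_nominal_and_consistent, sc$n_eqtl_snps, sc$n_hasc_genes))
  }
  cat("  unique shared loci:", x$unique_loci, "\n")
  for (ph in names(x$tally)) {
    t <- x$tally[[ph]]
    cat(sprintf("  direction tally (%s): %d/%d %s, binomial p = %.3g\n",
                ph, t$k, t$n, t$expected, t$p_binomial))
  }
  for (ph in names(x$mr)) {
    m <- x$mr[[ph]]
    iv <- m[m$method == "ivw", ]
    if (nrow(iv) == 1) {
      cat(sprintf("  MR (%s, IVW): %.3f (SE %.3f, p = %.3g, L = %d)\n",
                  ph, iv$estimate, iv$se, iv$p, iv$n_instruments))
    }
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (stage counts mirroring the cascade flowchart,
#' direction tallies, MR estimates, notes; schema version 1), a
#' deterministic `hits.tsv` and, when candidates exist,
#' `candidates.tsv`.
#'
#' @param report a `lipoloci_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  js <- list(
    schema_version = 1L,
    trait = report$trait,
    stage_counts = report$stage_counts,
    unique_loci = report$unique_loci,
    tally = lapply(report$tally, function(t)
      list(k = t$k, n = t$n, p_binomial = t$p_binomial,
           expected = t$expected)),
    mr = lapply(report$mr, function(m)
      lapply(split(m, seq_len(nrow(m))), function(r)
        list(method = r$method, estimate = r$estimate, se = r$se,
             p = r$p, n_instruments = r$n_instruments))),
    notes = report$notes
  )
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$hits)) {
    write_hits_table(report$hits, file.path(dir, "hits.tsv"))
  }
  if (!is.null(report$candidates)) {
    utils::write.table(report$candidates, file.path(dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
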