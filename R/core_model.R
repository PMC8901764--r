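#' lipoloci: shared genetic loci for fat storage traits and adipocyte lipolysis
#'
#' Tools for scanning trait-associated index SNPs against a cellular-phenotype
#' GWAS (adipocyte lipolysis), harmonizing alleles, classifying eQTL
#' congruence, testing directional enrichment, and running two-sample
#' Mendelian randomization, together with a summary-statistics simulator
#' with known causal architecture.
#'
#' @keywords internal
"_PACKAGE"

VALID_TRAIT_TAGS <- c("spontaneous_lipolysis", "stimulated_lipolysis",
                      "BMI", "WHRadjBMI", "custom")
VALID_NUCLEOTIDES <- c("A", "C", "G", "T")

#' Default column mapping for summary-statistics tables
#'
#' Maps the internal field names to the column names found in an input
#' file. Override individual entries to adapt to other file dialects.
#'
#' @param snp,chrom,pos,ref,alt,beta,p,freq,se column names in the file;
#'   `se` may be `NA` if the file carries no standard-error column.
#' @return Named character vector usable as `column_map` in
#'   [read_sumstats()].
#' @examples
#' sumstats_columns(beta = "Effect", p = "Pvalue")
#' @export
sumstats_columns <- function(snp = "SNP", chrom = "CHR", pos = "POS",
                             ref = "REF", alt = "ALT", beta = "BETA",
                             p = "P", freq = "FREQ", se = NA_character_) {
  c(snp_id = snp, chrom = chrom, pos = pos, ref_allele = ref,
    alt_allele = alt, beta = beta, p = p, alt_freq = freq, se = se)
}

#' Assemble and validate a table of GWAS association records
#'
#' The canonical container is a plain data frame with one row per SNP and
#' columns `snp_id`, `chrom`, `pos`, `ref_allele`, `alt_allele`, `beta`,
#' `se`, `p`, `alt_freq`, `trait_tag`. Betas refer to the alternative
#' allele; `alt_freq` is its frequency.
#'
#' @param snp_id rsID strings.
#' @param chrom chromosome labels.
#' @param pos 1-based GRCh37 base-pair positions.
#' @param ref_allele,alt_allele single nucleotides (A/C/G/T).
#' @param beta per-alt-allele effect sizes.
#' @param p nominal p-values (may be `NA`).
#' @param alt_freq alternative-allele frequencies in (0, 1).
#' @param se standard errors (optional, may be `NA`).
#' @param trait_tag one of `r paste(VALID_TRAIT_TAGS, collapse = ", ")`.
#' @return Validated data frame of GWAS records.
#' @export
gwas_records <- function(snp_id, chrom, pos, ref_allele, alt_allele,
                         beta, p, alt_freq, se = NA_real_,
                         trait_tag = "custom") {
  rec <- data.frame(
    snp_id = as.character(snp_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref_allele = toupper(as.character(ref_allele)),
    alt_allele = toupper(as.character(alt_allele)),
    beta = as.numeric(beta),
    se = as.numeric(se),
    p = as.numeric(p),
    alt_freq = as.numeric(alt_freq),
    trait_tag = as.character(trait_tag),
    stringsAsFactors = FALSE
  )
  validate_gwas_records(rec)
}

#' Validate a data frame of GWAS records
#'
#' Checks the record invariants: distinct valid alleles, `0 < p <= 1`
#' (when present), `0 < alt_freq < 1`, positive position, recognised
#' trait tag. All violations are reported together with their row
#' numbers; nothing is silently dropped.
#'
#' @param rec data frame with the columns documented in [gwas_records()].
#' @return `rec`, invisibly unchanged, if valid; otherwise an error
#'   listing every offending row.
#' @export
validate_gwas_records <- function(rec) {
  required <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele",
                "beta", "p", "alt_freq", "trait_tag")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0) {
    stop("missing record column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"se" %in% names(rec)) rec$se <- NA_real_
  problems <- character(0)
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      problems <<- c(problems, paste0("row ", idx, ": ", what))
    }
  }
  bad(is.na(rec$snp_id) | rec$snp_id == "", "missing snp_id")
  bad(!rec$ref_allele %in% VALID_NUCLEOTIDES, "ref_allele not in A/C/G/T")
  bad(!rec$alt_allele %in% VALID_NUCLEOTIDES, "alt_allele not in A/C/G/T")
  bad(rec$ref_allele == rec$alt_allele, "ref_allele equals alt_allele")
  bad(is.na(rec$pos) | rec$pos <= 0, "pos must be a positive integer")
  bad(is.na(rec$beta), "unparsable or missing beta")
  bad(!is.na(rec$p) & (rec$p <= 0 | rec$p > 1), "p outside (0, 1]")
  bad(is.na(rec$alt_freq) | rec$alt_freq <= 0 | rec$alt_freq >= 1,
      "alt_freq outside (0, 1)")
  bad(!is.na(rec$se) & rec$se <= 0, "se must be positive when present")
  bad(!rec$trait_tag %in% VALID_TRAIT_TAGS, "unknown trait_tag")
  if (length(problems) > 0) {
    stop("invalid GWAS record(s):\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(rec)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or whitespace-separated table with a header row, renames
#' columns according to `column_map`, coerces types and validates every
#' row. Duplicated rsIDs keep the first occurrence with a warning
#' (index-SNP panels are expected to be unique). Row order follows the
#' file.
#'
#' @param path path to the file.
#' @param column_map named character vector from [sumstats_columns()].
#' @param trait_tag trait label attached to every record.
#' @return Data frame of validated GWAS records in file order.
#' @export
read_sumstats <- function(path, column_map = sumstats_columns(),
                          trait_tag = "custom") {
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           check.names = FALSE)
  needed <- column_map[!is.na(column_map)]
  absent <- setdiff(unname(needed), names(raw))
  if (length(absent) > 0) {
    stop("mapped column(s) not found in ", path, ": ",
         paste(absent, collapse = ", "))
  }
  pick <- function(field) {
    col <- column_map[[field]]
    if (is.na(col)) rep(NA_character_, nrow(raw)) else raw[[col]]
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  rec <- data.frame(
    snp_id = pick("snp_id"),
    chrom = pick("chrom"),
    pos = suppressWarnings(as.integer(num(pick("pos")))),
    ref_allele = toupper(pick("ref_allele")),
    alt_allele = toupper(pick("alt_allele")),
    beta = num(pick("beta")),
    se = num(pick("se")),
    p = num(pick("p")),
    alt_freq = num(pick("alt_freq")),
    trait_tag = rep(trait_tag, nrow(raw)),
    stringsAsFactors = FALSE
  )
  if (nrow(rec) == 0) return(rec)
  validate_gwas_records(rec)
  dup <- duplicated(rec$snp_id)
  if (any(dup)) {
    warning("duplicate rsID(s) in ", path, ", keeping first occurrence: ",
            paste(unique(rec$snp_id[dup]), collapse = ", "))
    rec <- rec[!dup, , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

#' Load a packaged shared-locus fixture
#'
#' The package ships the published tables of eQTL SNPs shared between
#' adipocyte lipolysis and an anthropometric trait: `bmi_shared`
#' (5 spontaneous-lipolysis + 8 stimulated-lipolysis SNP rows, 11 unique
#' loci) and `whr_shared` (8 + 10 rows, 15 unique loci). Each bundle
#' carries the SNP-level association rows for both the lipolysis
#' phenotype and the trait, the per-gene eQTL rows with the
#' high-expression allele, and per-gene detection flags in hASCs
#' (adipose-derived stem cells) plus the observed siRNA knockdown
#' directions for the genes that were functionally screened.
#'
#' @param table_id `"bmi_shared"` or `"whr_shared"`.
#' @return List with elements `snps` (association rows), `eqtls`
#'   (SNP-gene pairs with `high_allele`, `tissue`, `detected_in_hascs`),
#'   `knockdown` (observed knockdown and lipid-accumulation effects),
#'   and `trait` (`"BMI"` or `"WHRadjBMI"`).
#' @examples
#' fx <- load_fixture("bmi_shared")
#' table(fx$snps$phenotype)
#' @export
load_fixture <- function(table_id = c("bmi_shared", "whr_shared")) {
  table_id <- match.arg(table_id)
  stem <- if (table_id == "bmi_shared") "bmi" else "whr"
  path <- function(f) system.file("extdata", f, package = "lipoloci",
                                  mustWork = TRUE)
  snps <- utils::read.delim(path(paste0(stem, "_shared_snps.tsv")),
                            stringsAsFactors = FALSE)
  eqtls <- utils::read.delim(path(paste0(stem, "_shared_eqtl.tsv")),
                             stringsAsFactors = FALSE)
  kd <- utils::read.delim(path("knockdown_observed.tsv"),
                          stringsAsFactors = FALSE)
  list(snps = snps, eqtls = eqtls, knockdown = kd,
       trait = if (stem == "bmi") "BMI" else "WHRadjBMI")
}

#' Split a fixture bundle into lipolysis and trait GWAS records
#'
#' Reshapes the two association halves of a fixture SNP row into
#' standard GWAS record tables, one per side, so fixture rows can be fed
#' through the same harmonization and scanning code as file input.
#'
#' @param fixture bundle from [load_fixture()].
#' @param phenotype `"spontaneous"` or `"stimulated"`; selects the
#'   segment of the table.
#' @return List with `lipolysis` and `trait` GWAS record data frames.
#' @export
fixture_gwas_records <- function(fixture,
                                 phenotype = c("spontaneous", "stimulated")) {
  phenotype <- match.arg(phenotype)
  seg <- fixture$snps[fixture$snps$phenotype == phenotype, , drop = FALSE]
  lip_tag <- paste0(phenotype, "_lipolysis")
  lip <- gwas_records(seg$snp_id, seg$chrom, seg$pos,
                      seg$ref_lipolysis, seg$alt_lipolysis,
                      seg$beta_lipolysis, seg$p_lipolysis,
                      seg$freq_lipolysis, trait_tag = lip_tag)
  trt <- gwas_records(seg$snp_id, seg$chrom, seg$pos,
                      seg$ref_trait, seg$alt_trait,
                      seg$beta_trait, seg$p_trait, seg$freq_trait,
                      trait_tag = fixture$trait)
  list(lipolysis = lip, trait = trt)
}

#' Write a shared-locus hits table to a TSV file
#'
#' Produces a deterministic report: fixed column order, rows sorted by
#' chromosome, position, then rsID. The file round-trips through
#' [read_hits_table()] without loss.
#'
#' @param hits data frame of shared-locus hits (see [scan_overlap()]).
#' @param path output file path.
#' @param candidates optional candidate-gene table written alongside as
#'   `<path>.candidates.tsv`.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path, candidates = NULL) {
  cols <- c("snp_id", "chrom", "pos", "phenotype", "trait",
            "effect_allele", "beta_phenotype", "beta_trait",
            "p_phenotype", "p_trait", "direction_class", "passes_rule",
            "is_hit")
  cols <- intersect(cols, names(hits))
  out <- hits[, cols, drop = FALSE]
  if (nrow(out) > 0) {
    ord <- order(chrom_order(out$chrom), out$pos, out$snp_id)
    out <- out[ord, , drop = FALSE]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(candidates)) {
    utils::write.table(candidates, paste0(path, ".candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a hits table written by [write_hits_table()]
#'
#' @param path file path.
#' @return Data frame with the written columns and types restored.
#' @export
read_hits_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# numeric sort key for chromosome labels (X/Y/MT after autosomes)
chrom_order <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  n <- suppressWarnings(as.numeric(x))
  n[toupper(x) == "X"] <- 23
  n[toupper(x) == "Y"] <- 24
  n[toupper(x) %in% c("M", "MT")] <- 25
  n[is.na(n)] <- 26
  n
}
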