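# compact builders for test records

rec <- function(snp = "rs1", ref = "A", alt = "G", beta = 0.1, p = 0.01,
                freq = 0.3, se = NA_real_, chrom = "1", pos = 100L,
                tag = "custom") {
  gwas_records(snp, chrom, pos, ref, alt, beta, p, freq, se = se,
               trait_tag = tag)
}

# n random non-palindromic GWAS records with fixed seed
random_panel <- function(n, seed, beta_sd = 0.05, tag = "custom") {
  set.seed(seed)
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  k <- sample.int(8, n, replace = TRUE)
  gwas_records(sprintf("rs%05d", seq_len(n)), sample(1:22, n, TRUE),
               sample.int(1e8, n), pairs[k, 1], pairs[k, 2],
               rnorm(n, 0, beta_sd), runif(n), runif(n, 0.05, 0.95),
               trait_tag = tag)
}

write_sumstats_file <- function(rec, path) {
  df <- data.frame(SNP = rec$snp_id, CHR = rec$chrom, POS = rec$pos,
                   REF = rec$ref_allele, ALT = rec$alt_allele,
                   BETA = rec$beta, P = rec$p, FREQ = rec$alt_freq)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# instrument set straight from numbers
inst_set <- function(bx, sx, by, sy) {
  out <- data.frame(snp_id = sprintf("rs%d", seq_along(bx)),
                    effect_allele = "A", eaf = 0.3,
                    beta_exposure = bx, se_exposure = sx,
                    beta_outcome = by, se_outcome = sy,
                    stringsAsFactors = FALSE)
  class(out) <- c("instrument_set", "data.frame")
  out
}
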