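## Shared fixture builders: everything is generated in code at test time.

toy_cohort <- function(n = 40, p = 12, k = 2, noise_sd = 0.3, seed = 5,
                       link = "linear", effect_sizes = NULL,
                       survival_range = c(0.4, 11)) {
  simulate_cohort(synthetic_spec(
    n_samples = n, n_features = p, informative_features = k,
    effect_sizes = effect_sizes, link = link, noise_sd = noise_sd,
    survival_range = survival_range, seed = seed))
}

## Minimal well-formed 3-feature x 2-sample expression TSV.
write_tiny_expr_tsv <- function(path,
                                ids = c("hsa-miR-21", "hsa-miR-24", "hsa-miR-222")) {
  writeLines(c("miRNA\tS1\tS2",
               paste(ids[1], "1.5", "2.5", sep = "\t"),
               paste(ids[2], "-0.5", "0.25", sep = "\t"),
               paste(ids[3], "3", "4", sep = "\t")), path)
  path
}

write_clinical_lines <- function(path, rows) {
  writeLines(c("sample_id\tdays_to_death\treceived_therapy\tvital_status", rows),
             path)
  path
}

## Chromosome selecting the given feature indices.
chrom_for <- function(idx, p, hp = c(12, 8, 7)) {
  f <- integer(p)
  f[idx] <- 1L
  chromosome(f, hp)
}
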