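# Shared fixtures built in code.

# A small cohort that keeps property tests fast while preserving the default
# group structure proportions.
small_config <- function(seed = 101, ...) {
  sim_config(seed = seed, n_bone = 5, n_tumour_methylated = 8,
             n_tumour_unmethylated = 4, n_xenograft = 6, ...)
}

# Random DNA sequence (no N unless asked for).
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Replicate-level Ct table with programmed per-sample delta-Ct values:
# target Ct = ref_ct + dct (+ replicate noise), reference Ct = ref_ct.
make_ct_table <- function(dct_by_sample, groups, target = "tgt",
                          reference = "ref", n_rep = 3, ct_sd = 0,
                          ref_ct = 20, condition = NULL) {
  rows <- lapply(seq_along(dct_by_sample), function(i) {
    s <- names(dct_by_sample)[i]
    rbind(
      data.frame(sample = s, group = groups[i], assay = target,
                 replicate = seq_len(n_rep),
                 ct = ref_ct + dct_by_sample[i] + rnorm(n_rep, 0, ct_sd)),
      data.frame(sample = s, group = groups[i], assay = reference,
                 replicate = seq_len(n_rep),
                 ct = ref_ct + rnorm(n_rep, 0, ct_sd)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(condition)) out$condition <- condition
  out
}
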