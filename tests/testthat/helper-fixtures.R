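# In-code fixture builders shared across test files.

toy_meta <- function(ids, population = "P1", sex = "F",
                     karyotype = "NORMAL", group = "WEST") {
  df <- data.frame(sample_id = ids, population = population, sex = sex,
                   karyotype = karyotype,
                   longitude = 103.5, latitude = 30.5, group = group,
                   stringsAsFactors = FALSE)
  class(df) <- c("sample_meta", "data.frame")
  df
}

# build an xy_dataset from a per-locus list of n x 2 allele matrices
toy_dataset <- function(calls, sex, karyotype = "NORMAL",
                        population = "P1", locus_panel = NULL,
                        null_sentinels = list()) {
  n <- nrow(calls[[1]])
  ids <- sprintf("i%02d", seq_len(n))
  a1 <- sapply(calls, function(m) m[, 1])
  a2 <- sapply(calls, function(m) m[, 2])
  a1 <- matrix(as.integer(a1), n, length(calls),
               dimnames = list(ids, names(calls)))
  a2 <- matrix(as.integer(a2), n, length(calls),
               dimnames = list(ids, names(calls)))
  gm <- genotype_matrix(a1, a2, null_sentinels = null_sentinels)
  meta <- toy_meta(ids, population = population, sex = sex,
                   karyotype = karyotype)
  validate_dataset(gm, meta, locus_panel = locus_panel)
}

# random dataset: n diploid individuals, L loci, k alleles, 2 groups
random_dataset <- function(n = 8, L = 2, k = 4, miss = 0.05) {
  ids <- sprintf("i%02d", seq_len(n))
  a1 <- matrix(sample.int(k, n * L, replace = TRUE) + 100L, n, L)
  a2 <- matrix(sample.int(k, n * L, replace = TRUE) + 100L, n, L)
  drop <- runif(n * L) < miss
  a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  dimnames(a1) <- dimnames(a2) <- list(ids, paste0("L", seq_len(L)))
  gm <- genotype_matrix(a1, a2)
  validate_dataset(gm, toy_meta(ids))
}

# small complete-linkage simulated dataset shared by several test files
quick_sim <- function(seed = 7, ...) {
  args <- list(n_effective = 60, mu = 2e-3, n_loci_sexlinked = 4,
               n_loci_autosomal = 3, p_translocated = 0.3,
               n_generations = 300, sample_males = 25, sample_females = 25,
               seed = seed)
  args[names(list(...))] <- list(...)
  cfg <- suppressWarnings(do.call(sim_config, args))
  simulate_xy(cfg)
}
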