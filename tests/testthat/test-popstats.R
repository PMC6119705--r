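# Gene diversity, Weir-Cockerham F-statistics, exact/permutation tests,
# and the Mantel machinery.

test_that("unbiased gene diversity matches hand-computed values", {
  expect_equal(expected_heterozygosity(c(10)), 0)          # fixed locus
  expect_equal(expected_heterozygosity(c(1, 1)), 1)        # (2/1)*(1-0.5)
  expect_equal(expected_heterozygosity(c(5, 5)), 10 / 9 * 0.5)
  expect_equal(expected_heterozygosity(c(5, 5), unbiased = FALSE), 0.5)
  expect_true(is.na(expected_heterozygosity(c(1))))        # single copy
})

test_that("gene diversity is invariant to allele relabelling", {
  set.seed(42)
  for (rep in 1:20) {
    cnt <- sample.int(10, sample(2:6, 1), replace = TRUE)
    expect_equal(expected_heterozygosity(cnt),
                 expected_heterozygosity(sample(cnt)))
  }
})

test_that("W&C estimates equal the ANOVA variance-component oracle", {
  set.seed(101)
  for (rep in 1:40) {
    ds <- random_dataset(n = 8, L = 2, k = 4)
    grp <- setNames(sample(c("a", "b"), 8, TRUE), ds$geno$individuals)
    while (length(unique(grp)) < 2)
      grp <- setNames(sample(c("a", "b"), 8, TRUE), ds$geno$individuals)
    fs <- fstat_weir_cockerham(ds, grouping = grp)
    or <- wc_anova_oracle(ds$geno$a1, ds$geno$a2, grp[ds$geno$individuals])
    expect_equal(fs$fst, or$fst, tolerance = 1e-12)
    expect_equal(fs$fis, or$fis, tolerance = 1e-12)
    expect_equal(fs$fit, or$fit, tolerance = 1e-12)
  }
})

test_that("per-group fixation indices match the single-group oracle", {
  set.seed(55)
  ds <- random_dataset(n = 12, L = 3, k = 4)
  grp <- setNames(rep(c("a", "b"), each = 6), ds$geno$individuals)
  fs <- fstat_weir_cockerham(ds, grouping = grp)
  sel <- grp[ds$geno$individuals] == "a"
  expect_equal(fs$fis_by_group[["a"]],
               wc_anova_oracle_within(ds$geno$a1[sel, , drop = FALSE],
                                      ds$geno$a2[sel, , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("F_ST is ~0 under panmixia and 1 under fixed differences", {
  set.seed(9)
  n <- 400
  ids <- sprintf("i%03d", 1:n)
  pool <- function() matrix(sample(101:104, n * 2, TRUE,
                                   prob = c(.4, .3, .2, .1)), n, 2)
  m <- pool()
  a1 <- matrix(m[, 1], n, 1, dimnames = list(ids, "L1"))
  a2 <- matrix(m[, 2], n, 1, dimnames = list(ids, "L1"))
  ds <- validate_dataset(genotype_matrix(a1, a2), toy_meta(ids))
  grp <- setNames(rep(c("a", "b"), each = n / 2), ids)
  expect_lt(abs(fstat_weir_cockerham(ds, grouping = grp)$fst), 0.02)

  a1f <- matrix(rep(c(101L, 105L), each = n / 2), n, 1,
                dimnames = list(ids, "L1"))
  dsf <- validate_dataset(genotype_matrix(a1f, a1f), toy_meta(ids))
  expect_equal(fstat_weir_cockerham(dsf, grouping = grp)$fst, 1)
})

test_that("monomorphic loci are excluded and a permutation p is returned", {
  set.seed(10)
  ds <- random_dataset(n = 10, L = 2, k = 3, miss = 0)
  # make locus 2 monomorphic
  ds$geno$a1[, 2] <- 150L; ds$geno$a2[, 2] <- 150L
  grp <- setNames(rep(c("a", "b"), each = 5), ds$geno$individuals)
  fs <- fstat_weir_cockerham(ds, grouping = grp, n_perm = 99, seed = 1)
  expect_true(is.na(fs$per_locus$fst[2]))
  expect_true(fs$p_value > 0 && fs$p_value <= 1)
  # seed-reproducible
  fs2 <- fstat_weir_cockerham(ds, grouping = grp, n_perm = 99, seed = 1)
  expect_identical(fs$p_value, fs2$p_value)
})

test_that("HWE exact test: monomorphic locus, extreme het excess, seeds", {
  expect_equal(hwe_exact_test(rep(1L, 30), rep(1L, 30)), 1)
  # 50 individuals all heterozygous for the same two alleles
  p <- hwe_exact_test(rep(101L, 50), rep(103L, 50), n_mc = 999, seed = 2)
  expect_lt(p, 0.01)
  expect_identical(p, hwe_exact_test(rep(101L, 50), rep(103L, 50),
                                     n_mc = 999, seed = 2))
})

test_that("HWE genotypes drawn under random union are not over-rejected", {
  set.seed(31)
  rej <- mean(replicate(120, {
    g <- matrix(sample(101:103, 80, TRUE, prob = c(.5, .3, .2)), 40, 2)
    hwe_exact_test(g[, 1], g[, 2], n_mc = 199) <= 0.05
  }))
  expect_lt(rej, 0.12)
})

test_that("LD permutation G-test finds perfect linkage, errors on n_perm=0", {
  set.seed(21)
  n <- 100
  ids <- sprintf("i%03d", 1:n)
  g <- matrix(sample(101:104, n * 2, TRUE), n, 2)
  a1 <- cbind(L1 = g[, 1], L2 = g[, 1])   # locus duplicated as its own pair
  a2 <- cbind(L1 = g[, 2], L2 = g[, 2])
  rownames(a1) <- rownames(a2) <- ids
  ds <- validate_dataset(genotype_matrix(a1, a2), toy_meta(ids))
  expect_lte(ld_test(ds, "L1", "L2", n_perm = 999, seed = 5), 0.001)
  expect_error(ld_test(ds, "L1", "L2", n_perm = 0), "n_perm")
  tab <- ld_test_all(ds, n_perm = 99, seed = 5)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$p_adj, pmin(tab$p * 1, 1))
})

test_that("great-circle distances follow the 6371-km sphere", {
  expect_equal(great_circle_km(103, 30, 103, 30), 0)
  expect_equal(great_circle_km(0, 0, 0, 90), 10007.5, tolerance = 0.1 / 10007)
  expect_equal(great_circle_km(103, 30, 110, 28),
               great_circle_km(110, 28, 103, 30))
  expect_error(great_circle_km(0, 95, 0, 0), "latitude")
})

test_that("Mantel test: identity, linearisation, degenerate input", {
  set.seed(12)
  n <- 8
  pts <- cbind(runif(n, 100, 110), runif(n, 25, 32))
  d <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- great_circle_km(pts[i, 1], pts[i, 2],
                                          pts[j, 1], pts[j, 2])
  mt <- mantel_test(d, d, n_perm = 99, seed = 3)
  expect_equal(mt$r, 1)
  expect_equal(fst_linearized(0.5), 1)
  expect_error(mantel_test(matrix(0, n, n), d, n_perm = 99), "constant")
})

test_that("Mantel r and tail probability agree with vegan", {
  set.seed(13)
  n <- 10
  m1 <- as.matrix(dist(matrix(runif(n * 2), n)))
  m2 <- as.matrix(dist(matrix(runif(n * 2), n)))
  dimnames(m1) <- dimnames(m2) <- list(letters[1:n], letters[1:n])
  ours <- mantel_test(m1, m2, n_perm = 999, seed = 4)
  ref <- vegan::mantel(m1, m2, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_value - ref$signif), 0.08)
})

test_that("Mantel r is invariant under simultaneous relabelling", {
  set.seed(14)
  n <- 9
  m1 <- as.matrix(dist(matrix(runif(n * 2), n)))
  m2 <- as.matrix(dist(matrix(runif(n * 2), n)))
  dimnames(m1) <- dimnames(m2) <- list(letters[1:n], letters[1:n])
  idx <- sample(n)
  r1 <- mantel_test(m1, m2, n_perm = 9, seed = 1)$r
  r2 <- mantel_test(m1[idx, idx], m2[idx, idx], n_perm = 9, seed = 1)$r
  expect_equal(r1, r2)
})
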