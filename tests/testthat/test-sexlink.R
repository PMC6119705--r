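# Male-specific / translocation-specific allele detection, association
# scores, and sex-reversal flagging.

# 8 individuals, 1 locus: 4 males carrying allele 250, 4 females without
ms_toy <- function() {
  calls <- list(L1 = rbind(
    cbind(rep(250L, 4), rep(201L, 4)),   # males: Y=250 private
    cbind(rep(201L, 4), rep(203L, 4))))  # females
  toy_dataset(calls, sex = rep(c("M", "F"), each = 4))
}

test_that("alleles carried only by males are classed male-specific", {
  cls <- find_male_specific_alleles(ms_toy())
  expect_equal(cls$alleles$L1, 250L)
  expect_equal(nrow(cls$exceptions), 0)
})

test_that("alleles shared equally by the sexes are not male-specific", {
  calls <- list(L1 = rbind(cbind(rep(250L, 4), rep(201L, 4)),
                           cbind(rep(250L, 4), rep(201L, 4))))
  ds <- toy_dataset(calls, sex = rep(c("M", "F"), each = 4))
  cls <- find_male_specific_alleles(ds, max_female_carriers = 2)
  expect_length(cls$alleles$L1, 0)
})

test_that("rare female carriers are tolerated and recorded as exceptions", {
  # allele 250 in all 6 males and exactly 2 of 6 females
  calls <- list(L1 = rbind(cbind(rep(250L, 6), rep(201L, 6)),
                           cbind(c(250L, 250L, rep(201L, 4)), rep(203L, 6))))
  ds <- toy_dataset(calls, sex = rep(c("M", "F"), each = 6))
  cls <- find_male_specific_alleles(ds, max_female_carriers = 2)
  expect_equal(cls$alleles$L1, 250L)
  expect_equal(sort(cls$exceptions$sample_id), c("i07", "i08"))
  strict <- find_male_specific_alleles(ds, max_female_carriers = 1)
  expect_length(strict$alleles$L1, 0)
})

test_that("raising the female-carrier tolerance never shrinks the set", {
  set.seed(77)
  for (rep in 1:10) {
    ds <- random_dataset(n = 16, L = 2, k = 5)
    ds$meta$sex <- rep(c("M", "F"), 8)
    prev <- NULL
    for (tol in 0:3) {
      cls <- find_male_specific_alleles(ds, max_female_carriers = tol)
      cur <- lapply(cls$alleles, sort)
      if (!is.null(prev))
        for (loc in names(cur)) expect_true(all(prev[[loc]] %in% cur[[loc]]))
      prev <- cur
    }
  }
})

test_that("classification is idempotent and needs both sexes", {
  ds <- ms_toy()
  c1 <- find_male_specific_alleles(ds)
  c2 <- find_male_specific_alleles(ds)
  expect_identical(c1$alleles, c2$alleles)
  males_only <- subset_individuals(ds, ds$meta$sex == "M")
  expect_error(find_male_specific_alleles(males_only), "both sexes")
})

trans_toy <- function() {
  # translocated male + female carry 215; normals never do
  calls <- list(L1 = rbind(
    cbind(c(215L, 201L), c(203L, 203L)),   # males: MT then MN
    cbind(c(215L, 201L), c(201L, 203L)))) # females: FT then FN
  toy_dataset(calls, sex = c("M", "M", "F", "F"),
              karyotype = c("TRANSLOCATED", "NORMAL",
                            "TRANSLOCATED", "NORMAL"))
}

test_that("alleles private to translocated carriers of both sexes are classed", {
  cls <- find_translocation_specific_alleles(trans_toy())
  expect_equal(cls$alleles$L1, 215L)
})

test_that("alleles shared across karyotypes are excluded", {
  calls <- list(L1 = rbind(cbind(rep(215L, 2), rep(203L, 2)),
                           cbind(rep(215L, 2), rep(203L, 2))))
  ds <- toy_dataset(calls, sex = c("M", "F", "M", "F"),
                    karyotype = rep(c("TRANSLOCATED", "NORMAL"), each = 2))
  cls <- find_translocation_specific_alleles(ds)
  expect_length(cls$alleles$L1, 0)
})

test_that("a scoped population without translocated individuals errors by name", {
  ds <- trans_toy()
  ds$meta$karyotype <- "NORMAL"
  expect_error(find_translocation_specific_alleles(ds), "P1")
})

test_that("per-population scoping keeps deme-specific translocation alleles", {
  mk <- function(pop, al) list(L1 = rbind(
    cbind(c(al, 201L), c(203L, 203L)),
    cbind(c(al, 201L), c(201L, 203L))))
  d1 <- toy_dataset(mk("A", 215L), sex = c("M", "M", "F", "F"),
                    karyotype = c("TRANSLOCATED", "NORMAL",
                                  "TRANSLOCATED", "NORMAL"),
                    population = "A")
  d2 <- toy_dataset(mk("B", 219L), sex = c("M", "M", "F", "F"),
                    karyotype = c("TRANSLOCATED", "NORMAL",
                                  "TRANSLOCATED", "NORMAL"),
                    population = "B")
  ids <- rownames(d1$geno$a1)
  a1 <- rbind(d1$geno$a1, d2$geno$a1)
  a2 <- rbind(d1$geno$a2, d2$geno$a2)
  rownames(a1) <- rownames(a2) <- c(paste0("A", ids), paste0("B", ids))
  g <- genotype_matrix(a1, a2)
  meta <- rbind(toy_meta(paste0("A", ids), population = "A",
                         sex = c("M", "M", "F", "F"),
                         karyotype = c("TRANSLOCATED", "NORMAL",
                                       "TRANSLOCATED", "NORMAL")),
                toy_meta(paste0("B", ids), population = "B",
                         sex = c("M", "M", "F", "F"),
                         karyotype = c("TRANSLOCATED", "NORMAL",
                                       "TRANSLOCATED", "NORMAL")))
  ds <- validate_dataset(g, meta)
  cls <- find_translocation_specific_alleles(ds, per_population = TRUE)
  expect_equal(cls$alleles$L1$A, 215L)
  expect_equal(cls$alleles$L1$B, 219L)
})

test_that("association score D counts carrier individuals against targets", {
  ds <- ms_toy()
  cls <- find_male_specific_alleles(ds)
  sc <- association_score(ds, cls, "L1", "P1", mode = "SEX")
  expect_equal(sc$score, 0)               # every male carries a Y allele
  # no male carries one -> D = 1
  empty <- cls; empty$alleles$L1 <- 999L
  expect_equal(association_score(ds, empty, "L1", "P1", "SEX")$score, 1)
  # 3 of 4 translocated carriers -> D = 0.25
  calls <- list(L1 = cbind(c(215L, 215L, 215L, 201L), rep(203L, 4)))
  dst <- toy_dataset(calls, sex = c("M", "M", "F", "F"),
                     karyotype = "TRANSLOCATED")
  clt <- list(mode = "TRANSLOCATION", per_population = FALSE,
              loci = "L1", alleles = list(L1 = 215L))
  class(clt) <- "allele_classification"
  expect_equal(association_score(dst, clt, "L1", "P1",
                                 "TRANSLOCATION")$score, 0.25)
})

test_that("an empty target class yields a missing score, not an error", {
  ds <- ms_toy()
  cls <- find_male_specific_alleles(ds)
  females <- subset_individuals(ds, ds$meta$sex == "F")
  sc <- association_score(females, cls, "L1", "P1", mode = "SEX")
  expect_true(is.na(sc$score))
  expect_equal(sc$n_target, 0)
})

test_that("sex-discordant individuals are flagged from fully linked loci", {
  # 4 loci; male i05 carries no male-specific allele anywhere; female i06
  # carries them everywhere; i07 is missing everywhere
  mk_locus <- function() rbind(
    cbind(rep(250L, 4), rep(201L, 4)),    # males i01-i04
    c(201L, 203L),                        # i05: male, no private allele
    c(250L, 201L),                        # i06: female carrying 250
    c(NA_integer_, NA_integer_),          # i07: male, all missing
    cbind(rep(201L, 3), rep(203L, 3)))    # females i08-i10
  calls <- list(L1 = mk_locus(), L2 = mk_locus(), L3 = mk_locus(),
                L4 = mk_locus())
  ds <- toy_dataset(calls, sex = c(rep("M", 5), "F", "M", rep("F", 3)))
  cls <- find_male_specific_alleles(ds, max_female_carriers = 2)
  expect_warning(
    flags <- flag_sex_discordant(ds, cls, paste0("L", 1:4)),
    "no informative loci")
  expect_equal(flags$verdict[flags$sample_id == "i05"], "CANDIDATE_REVERSAL")
  expect_equal(flags$verdict[flags$sample_id == "i06"], "CANDIDATE_REVERSAL")
  expect_equal(flags$verdict[flags$sample_id == "i07"], "CONSISTENT")
  expect_equal(flags$n_informative_loci[flags$sample_id == "i07"], 0L)
  expect_equal(sum(flags$verdict == "CANDIDATE_REVERSAL"), 2)
})

test_that("complete linkage without reversal gives D = 0 and no flags", {
  sim <- quick_sim(seed = 19)
  ds <- sim$dataset
  sl <- paste0("SL", 1:4)
  cls <- find_male_specific_alleles(ds, loci = sl)
  tab <- association_table(ds, cls, loci = sl)
  expect_true(all(tab$score == 0))
  flags <- flag_sex_discordant(ds, cls, sl)
  expect_equal(sum(flags$verdict == "CANDIDATE_REVERSAL"), 0)
})
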