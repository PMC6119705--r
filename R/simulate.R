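# Forward-time Wright-Fisher simulator of sex-linked microsatellite data
# with a translocation-tagged X lineage and stepwise mutation.
#
# The state is kept as chromosome-class pools of gene copies rather than
# pedigreed individuals: with N breeding individuals (equal sex ratio) the
# pools hold N/2 Y copies, 3N/2 X copies and 2N autosomal copies — the
# 1:3:4 copy ratio per breeding pair. Pool sizes, and the number of
# translocation-tagged X copies, are conserved every generation, so the
# karyotype polymorphism persists the way it does in the study system
# instead of drifting to loss. Individuals are assembled by random union
# of copies at sampling time.

#' Simulation configuration
#'
#' Parameters of the forward-time generator. `n_effective` is the
#' effective number of breeding individuals (equal sex ratio, so
#' `n_effective/2` pairs); per breeding pair the chromosome classes are
#' present in 4 (autosome) : 3 (X) : 1 (Y) copies, giving class pools of
#' `c * n_effective / 2` gene copies and equilibrium diversity
#' \eqn{\theta = c N_e \mu} for each class.
#'
#' @param n_effective even integer >= 2, breeding individuals per
#'   population.
#' @param mu stepwise mutation rate per gene copy per generation.
#' @param n_loci_sexlinked,n_loci_autosomal locus counts per class.
#' @param p_translocated fraction of the X pool carrying the translocated
#'   lineage tag (held constant: the exact copy count is conserved every
#'   generation). The default 0.25 mirrors a survey where roughly a third
#'   of individuals carry a translocated karyotype. Set 0 for a plain
#'   panmictic XY system.
#' @param p_sex_reversal probability that a sampled individual's phenotypic
#'   sex label contradicts its sex genotype (the label flips; the genotype
#'   never does).
#' @param n_generations burn-in length; >= `10 * n_effective` is
#'   recommended for mutation-drift equilibrium and shorter runs warn.
#' @param suppressed_block indices (into the sex-linked loci) of the block
#'   that travels with the translocation tag (no XT-XN recombination
#'   there); loci outside it recombine freely. Default: all sex-linked
#'   loci.
#' @param n_populations,migration island-model population count and
#'   per-copy symmetric migration probability per generation.
#' @param sample_males,sample_females sampled individuals per population
#'   (at most `n_effective/2` each).
#' @param null_locus optional index of a sex-linked locus whose
#'   translocation-tagged copies are emitted as the amplification-null
#'   sentinel (`null_sentinel`, default 499) instead of their true size.
#' @param founder_x,founder_y,founder_a founder allele sizes (bp); the Y
#'   founder is offset from the X founder so the pools stay disjoint over
#'   realistic burn-ins, giving complete sex linkage.
#' @param founder_xt_offset size offset of the translocated-X founder
#'   allele inside the suppressed block (its diagnostic allele).
#' @param min_allele floor on allele sizes (mutations bounce off it).
#' @param null_sentinel allele code used for amplification nulls.
#' @param seed integer seed used by [simulate_xy()].
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_effective = 500, mu = 1e-3,
                       n_loci_sexlinked = 6, n_loci_autosomal = 5,
                       p_translocated = 0.25, p_sex_reversal = 0,
                       n_generations = 10 * n_effective,
                       suppressed_block = seq_len(n_loci_sexlinked),
                       n_populations = 1, migration = 0,
                       sample_males = 50, sample_females = 50,
                       null_locus = NA_integer_,
                       founder_x = 200L, founder_y = 250L, founder_a = 200L,
                       founder_xt_offset = 15L,
                       min_allele = 100L, null_sentinel = 499L,
                       seed = NULL) {
  stopifnot(n_effective >= 2, n_effective %% 2 == 0,
            mu >= 0, mu <= 1,
            n_loci_sexlinked >= 1, n_loci_autosomal >= 0,
            p_translocated >= 0, p_translocated <= 1,
            p_sex_reversal >= 0, p_sex_reversal <= 1,
            n_generations >= 1, n_populations >= 1,
            migration >= 0, migration <= 1,
            sample_males >= 0, sample_females >= 0)
  stopifnot(all(suppressed_block %in% seq_len(n_loci_sexlinked)))
  n_half <- n_effective / 2
  if (sample_males > n_half || sample_females > n_half)
    stop("sample size exceeds the ", n_half,
         " breeders of that sex per population")
  if (n_generations < 10 * n_effective)
    warning("n_generations < 10 * n_effective: the population may not have ",
            "reached mutation-drift equilibrium")
  cfg <- list(n_effective = n_effective, mu = mu,
              n_loci_sexlinked = n_loci_sexlinked,
              n_loci_autosomal = n_loci_autosomal,
              p_translocated = p_translocated,
              p_sex_reversal = p_sex_reversal,
              n_generations = n_generations,
              suppressed_block = as.integer(suppressed_block),
              n_populations = n_populations, migration = migration,
              sample_males = sample_males, sample_females = sample_females,
              null_locus = null_locus,
              founder_x = founder_x, founder_y = founder_y,
              founder_a = founder_a,
              founder_xt_offset = founder_xt_offset,
              min_allele = min_allele, null_sentinel = null_sentinel,
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Equilibrium theta of a chromosome class
#'
#' The analytic target \eqn{\theta = c N_e \mu} for recovery tests, with
#' c = 4 (A), 3 (X) or 1 (Y).
#'
#' @param config a [sim_config()].
#' @param cls `"A"`, `"X"` or `"Y"`.
#' @export
expected_theta <- function(config, cls) {
  stopifnot(inherits(config, "sim_config"))
  cc <- c(A = 4, X = 3, Y = 1)
  if (!cls %in% names(cc)) stop("unknown chromosome class: ", cls)
  unname(cc[cls]) * config$n_effective * config$mu
}

# stepwise mutation on an integer matrix: each element steps +-1 with
# probability mu (binomial draw of hit count, then positions)
smm_mutate <- function(mat, mu, min_allele) {
  n <- length(mat)
  k <- rbinom(1L, n, mu)
  if (k > 0L) {
    idx <- sample.int(n, k)
    mat[idx] <- pmax(mat[idx] + sample(c(-1L, 1L), k, replace = TRUE),
                     min_allele)
  }
  mat
}

# one generation of the X pool (rows 1..K are the tagged XT copies; tag
# positions are fixed, so the XT copy count is conserved). Each new copy
# takes its suppressed-block loci from a same-tag parent copy; outside the
# block it is transmitted intact w.p. 1/3 (the male-residence fraction of
# X copies) and otherwise recombines per locus with a uniform partner copy.
step_x_pool <- function(X, K, block, mu, min_allele) {
  M <- nrow(X); L <- ncol(X)
  main <- integer(M)
  if (K > 0) main[seq_len(K)] <- sample.int(K, K, replace = TRUE)
  if (K < M) main[(K + 1):M] <- K + sample.int(M - K, M - K, replace = TRUE)
  partner <- sample.int(M, M, replace = TRUE)
  new <- X[main, , drop = FALSE]
  C <- matrix(runif(M * L) < 0.5, M, L)
  C[runif(M) < 1 / 3, ] <- FALSE          # intact (male-borne) transmission
  if (length(block)) C[, block] <- FALSE  # block rides with the main parent
  alt <- X[partner, , drop = FALSE]
  new[C] <- alt[C]
  smm_mutate(new, mu, min_allele)
}

# Y haplotypes are transmitted intact (no recombination): row resampling
step_y_pool <- function(Y, mu, min_allele)
  smm_mutate(Y[sample.int(nrow(Y), nrow(Y), replace = TRUE), , drop = FALSE],
             mu, min_allele)

# autosomal loci are unlinked: per-locus column resampling
step_a_pool <- function(A, mu, min_allele) {
  n <- nrow(A)
  for (l in seq_len(ncol(A)))
    A[, l] <- A[sample.int(n, n, replace = TRUE), l]
  smm_mutate(A, mu, min_allele)
}

#' Simulate a sex-linked microsatellite dataset
#'
#' Forward-time Wright-Fisher resampling of chromosome-class gene-copy
#' pools under male heterogamety: the Y pool (no recombination, transmitted
#' intact), the X pool (free recombination except inside the
#' translocation-suppressed block, whose loci travel with the lineage tag),
#' and the autosomal pool (unlinked loci). Alleles mutate by one repeat
#' step with probability `mu` per copy per generation; pool sizes and the
#' translocation-tagged copy count are conserved every generation. After
#' `n_generations` of burn-in, individuals are assembled by random union of
#' copies — males (X, Y), females (X, X) — the requested numbers are
#' sampled per population, phenotypic sex labels are flipped at rate
#' `p_sex_reversal`, and the result is emitted as a validated dataset plus
#' the generating truth.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`); identical
#'   config + seed reproduces the dataset exactly.
#' @return list with elements `dataset` (an `xy_dataset`; sex-linked loci
#'   named `SL1..`, autosomal `AU1..`, populations `P1..`) and `truth`
#'   (locus classes, founder alleles, and per-individual genotypic sex,
#'   karyotype and reversal flag).
#' @export
simulate_xy <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_effective
  Ny <- N / 2                       # Y copies = males
  Mx <- 3 * N / 2                   # X copies
  Na <- 2 * N                       # autosomal copies
  Ls <- config$n_loci_sexlinked
  La <- config$n_loci_autosomal
  blk <- config$suppressed_block
  mu <- config$mu; mn <- config$min_allele
  k_pop <- config$n_populations
  K <- round(config$p_translocated * Mx)
  xt_allele <- config$founder_x + config$founder_xt_offset

  init_pop <- function() {
    X <- matrix(config$founder_x, Mx, Ls)
    if (K > 0 && length(blk)) X[seq_len(K), blk] <- xt_allele
    list(Y = matrix(config$founder_y, Ny, Ls), X = X,
         A = matrix(config$founder_a, Na, La))
  }
  pops <- replicate(k_pop, init_pop(), simplify = FALSE)

  for (gen in seq_len(config$n_generations)) {
    pops <- lapply(pops, function(p)
      list(Y = step_y_pool(p$Y, mu, mn),
           X = step_x_pool(p$X, K, blk, mu, mn),
           A = if (La) step_a_pool(p$A, mu, mn) else p$A))
    if (k_pop > 1 && config$migration > 0) {
      swap <- function(field, rows) {
        for (p1 in seq_len(k_pop)) {
          mig <- which(runif(length(rows)) < config$migration)
          for (i in mig) {
            p2 <- sample(setdiff(seq_len(k_pop), p1), 1L)
            j <- rows[sample.int(length(rows), 1L)]
            tmp <- pops[[p1]][[field]][rows[i], ]
            pops[[p1]][[field]][rows[i], ] <<- pops[[p2]][[field]][j, ]
            pops[[p2]][[field]][j, ] <<- tmp
          }
        }
      }
      swap("Y", seq_len(Ny))
      if (K > 0) swap("X", seq_len(K))        # tagged copies swap together
      if (K < Mx) swap("X", (K + 1):Mx)
      if (La) swap("A", seq_len(Na))
    }
  }

  # ---- assemble individuals and emit --------------------------------------
  sl_names <- paste0("SL", seq_len(Ls))
  au_names <- if (La) paste0("AU", seq_len(La)) else character(0)
  loci <- c(sl_names, au_names)
  rows_a1 <- rows_a2 <- list(); meta_rows <- list(); truth_rows <- list()
  for (pi in seq_len(k_pop)) {
    p <- pops[[pi]]
    pname <- paste0("P", pi)
    tag <- c(rep(TRUE, K), rep(FALSE, Mx - K))
    xp <- sample.int(Mx, Mx)        # random union: X copies -> individuals
    yp <- sample.int(Ny, Ny)
    nm <- config$sample_males; nf <- config$sample_females
    ix_m <- xp[seq_len(Ny)]                      # one X per assembled male
    ix_f1 <- xp[Ny + 2 * seq_len(Ny) - 1]        # two X per assembled female
    ix_f2 <- xp[Ny + 2 * seq_len(Ny)]
    im <- seq_len(nm); ifm <- seq_len(nf)        # assembly order is random
    ids_m <- if (nm) sprintf("%s_I%03d", pname, im) else character(0)
    ids_f <- if (nf) sprintf("%s_I%03d", pname, nm + ifm) else character(0)
    m_x <- p$X[ix_m[im], , drop = FALSE]
    m_y <- p$Y[yp[im], , drop = FALSE]
    f_x1 <- p$X[ix_f1[ifm], , drop = FALSE]
    f_x2 <- p$X[ix_f2[ifm], , drop = FALSE]
    t_m <- tag[ix_m[im]]; t_f1 <- tag[ix_f1[ifm]]; t_f2 <- tag[ix_f2[ifm]]
    if (!is.na(config$null_locus)) {
      j <- config$null_locus
      m_x[t_m, j] <- config$null_sentinel
      f_x1[t_f1, j] <- config$null_sentinel
      f_x2[t_f2, j] <- config$null_sentinel
    }
    ap <- sample.int(Na, Na)
    n_tot <- nm + nf
    a_c1 <- p$A[ap[2 * seq_len(n_tot) - 1], , drop = FALSE]
    a_c2 <- p$A[ap[2 * seq_len(n_tot)], , drop = FALSE]
    a1 <- cbind(rbind(m_x, f_x1), a_c1)
    a2 <- cbind(rbind(m_y, f_x2), a_c2)
    rownames(a1) <- rownames(a2) <- c(ids_m, ids_f)
    rows_a1[[pi]] <- a1; rows_a2[[pi]] <- a2
    true_sex <- rep(c("M", "F"), c(nm, nf))
    kary <- c(ifelse(t_m, "TRANSLOCATED", "NORMAL"),
              ifelse(t_f1 | t_f2, "TRANSLOCATED", "NORMAL"))
    reversed <- runif(n_tot) < config$p_sex_reversal
    pheno <- ifelse(reversed, ifelse(true_sex == "M", "F", "M"), true_sex)
    meta_rows[[pi]] <- data.frame(
      sample_id = c(ids_m, ids_f), population = pname, sex = pheno,
      karyotype = kary,
      longitude = 103 + 0.3 * pi, latitude = 30 + 0.2 * pi,
      group = "WEST", stringsAsFactors = FALSE)
    truth_rows[[pi]] <- data.frame(
      sample_id = c(ids_m, ids_f), true_sex = true_sex,
      karyotype = kary, reversed = reversed, stringsAsFactors = FALSE)
  }
  a1 <- do.call(rbind, rows_a1); a2 <- do.call(rbind, rows_a2)
  colnames(a1) <- colnames(a2) <- loci
  meta <- do.call(rbind, meta_rows)
  class(meta) <- c("sample_meta", "data.frame")
  nulls <- if (!is.na(config$null_locus))
    setNames(list(config$null_sentinel), sl_names[config$null_locus])
  else list()
  gm <- genotype_matrix(a1, a2, null_sentinels = nulls,
                        populations = meta$population)
  panel <- setNames(rep(c("SEX_LINKED", "AUTOSOMAL"), c(Ls, La)), loci)
  dataset <- validate_dataset(gm, meta, locus_panel = panel)
  truth <- list(
    locus_class = panel,
    male_specific_founder = setNames(rep(config$founder_y, Ls), sl_names),
    translocation_founder = setNames(
      ifelse(seq_len(Ls) %in% blk & K > 0, xt_allele, NA_integer_), sl_names),
    individuals = do.call(rbind, truth_rows),
    config = config)
  list(dataset = dataset, truth = truth)
}
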