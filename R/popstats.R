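#' Nei's unbiased gene diversity (expected heterozygosity)
#'
#' \eqn{H_E = \frac{n}{n-1}\,(1 - \sum_u p_u^2)} with \eqn{n} the number of
#' gene copies, clamped to \[0, 1\]. Works on a vector of allele counts, so
#' it applies equally to diploid samples (n = 2 x individuals) and to
#' haploid chromosome-class pools (Y, XT, XN copies).
#'
#' @param counts named or unnamed vector of nonnegative allele counts.
#' @param unbiased if `FALSE`, return the plain \eqn{1 - \sum p^2}.
#' @return gene diversity in \[0, 1\]; `NA` if fewer than 2 gene copies.
#' @examples
#' expected_heterozygosity(c(5, 5))   # (10/9) * 0.5
#' @export
expected_heterozygosity <- function(counts, unbiased = TRUE) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (is.na(n) || n < 2) return(NA_real_)
  p <- counts / n
  h <- 1 - sum(p^2)
  if (unbiased) h <- h * n / (n - 1)
  min(max(h, 0), 1)
}

# ---- Weir & Cockerham (1984) variance components ---------------------------

# per-locus components for r >= 2 groups; returns per-allele a, b, c
# x1, x2: allele vectors (NA = missing call); grp: factor of group labels
wc_locus_components <- function(x1, x2, grp) {
  ok <- !is.na(x1) & !is.na(grp)
  x1 <- x1[ok]; x2 <- x2[ok]; grp <- droplevels(factor(grp[ok]))
  r <- nlevels(grp)
  if (r < 2) return(NULL)
  n_i <- as.numeric(table(grp))
  if (any(n_i < 1)) return(NULL)
  ntot <- sum(n_i)
  nbar <- ntot / r
  nC <- (ntot - sum(n_i^2) / ntot) / (r - 1)
  alleles <- sort(unique(c(x1, x2)))
  if (length(alleles) < 2) {
    # monomorphic locus: all components zero
    return(list(a = 0, b = 0, c = 0, polymorphic = FALSE))
  }
  a <- b <- cc <- numeric(length(alleles))
  for (k in seq_along(alleles)) {
    u <- alleles[k]
    cnt <- (x1 == u) + (x2 == u)              # copies of u per individual
    p_i <- tapply(cnt, grp, sum) / (2 * n_i)  # freq per group
    h_i <- tapply(cnt == 1L, grp, sum) / n_i  # het-for-u proportion
    pbar <- sum(n_i * p_i) / ntot
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / ntot
    a[k] <- (nbar / nC) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[k] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[k] <- hbar / 2
  }
  list(a = a, b = b, c = cc, polymorphic = TRUE)
}

# single-group Weir-Cockerham f-hat components (r = 1: no "a" term)
wc_locus_components_within <- function(x1, x2) {
  ok <- !is.na(x1)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 2) return(NULL)
  alleles <- sort(unique(c(x1, x2)))
  if (length(alleles) < 2) return(list(b = 0, c = 0, polymorphic = FALSE))
  b <- cc <- numeric(length(alleles))
  for (k in seq_along(alleles)) {
    u <- alleles[k]
    cnt <- (x1 == u) + (x2 == u)
    p <- sum(cnt) / (2 * n)
    h <- sum(cnt == 1L) / n
    b[k] <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
    cc[k] <- h / 2
  }
  list(b = b, c = cc, polymorphic = TRUE)
}

resolve_grouping <- function(data, grouping) {
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% names(data$meta)) {
    g <- data$meta[[grouping]]
    g[g %in% c("UNKNOWN", "")] <- NA
    return(setNames(as.character(g), data$geno$individuals))
  }
  if (is.null(names(grouping)))
    stop("grouping must be a meta column name or a named vector")
  setNames(as.character(grouping),
           names(grouping))[data$geno$individuals]
}

#' Weir-Cockerham F-statistics between arbitrary groups
#'
#' Multi-allelic, multi-locus Weir & Cockerham (1984) estimators: the
#' among-group theta-hat (\eqn{F_{ST}}), the within-group f-hat
#' (\eqn{F_{IS}}) and big-F (\eqn{F_{IT}}), obtained by summing the
#' per-allele variance components a, b, c over alleles and loci. Grouping
#' is arbitrary: sexes (the differentiation-between-sexes diagnostic of a
#' sex-linked region), populations, or karyotype classes. A per-group
#' fixation index (e.g. female and male \eqn{F_{IS}} separately) is
#' computed by restricting the estimator to each group. Estimates can be
#' negative; they are reported as computed, not truncated. A significance
#' level for \eqn{F_{ST} > 0} comes from permuting group labels across
#' individuals.
#'
#' @param data an `xy_dataset`.
#' @param loci character vector of loci to combine (default: all).
#' @param grouping a `meta` column name (`"sex"`, `"population"`,
#'   `"karyotype"`, `"group"`) or a named vector sample_id -> group label.
#'   Individuals with `NA`/`UNKNOWN` labels are excluded.
#' @param n_perm number of label permutations for the p-value (0 = skip).
#'   Surveys of this kind conventionally use 5000 randomizations.
#' @param seed optional integer seed for the permutations.
#' @return an object of class `fstat_result`: overall `fst`, `fis`, `fit`,
#'   `fis_by_group`, a `per_locus` data.frame, and `p_value` (`NA` when
#'   `n_perm = 0`). Loci monomorphic over the analysed individuals are
#'   excluded from the combined estimate and reported `NA` per locus.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
fstat_weir_cockerham <- function(data, loci = NULL, grouping = "sex",
                                 n_perm = 0, seed = NULL) {
  stopifnot(inherits(data, "xy_dataset"))
  loci <- loci %||% data$geno$loci
  stopifnot(all(loci %in% data$geno$loci))
  grp <- resolve_grouping(data, grouping)
  use <- !is.na(grp)
  if (length(unique(grp[use])) < 2)
    stop("need at least 2 groups with individuals; found ",
         length(unique(grp[use])))
  a1 <- data$geno$a1[use, loci, drop = FALSE]
  a2 <- data$geno$a2[use, loci, drop = FALSE]
  g <- factor(grp[use])

  theta_from <- function(gfac) {
    A <- B <- C <- 0
    per <- data.frame(locus = loci, fst = NA_real_, fis = NA_real_)
    for (j in seq_along(loci)) {
      comp <- wc_locus_components(a1[, j], a2[, j], gfac)
      if (is.null(comp) || !comp$polymorphic) next
      sa <- sum(comp$a); sb <- sum(comp$b); sc <- sum(comp$c)
      A <- A + sa; B <- B + sb; C <- C + sc
      per$fst[j] <- sa / (sa + sb + sc)
      per$fis[j] <- 1 - sc / (sb + sc)
    }
    list(fst = if ((A + B + C) != 0) A / (A + B + C) else NA_real_,
         fis = if ((B + C) != 0) 1 - C / (B + C) else NA_real_,
         fit = if ((A + B + C) != 0) 1 - C / (A + B + C) else NA_real_,
         per_locus = per)
  }
  obs <- theta_from(g)

  fis_by_group <- vapply(levels(g), function(lv) {
    sel <- g == lv
    B <- C <- 0
    for (j in seq_along(loci)) {
      comp <- wc_locus_components_within(a1[sel, j], a2[sel, j])
      if (is.null(comp) || !comp$polymorphic) next
      B <- B + sum(comp$b); C <- C + sum(comp$c)
    }
    if ((B + C) != 0) 1 - C / (B + C) else NA_real_
  }, numeric(1))

  p_value <- NA_real_
  if (n_perm > 0 && !is.na(obs$fst)) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      tp <- theta_from(sample(g))$fst
      if (!is.na(tp) && tp >= obs$fst - 1e-12) hits <- hits + 1L
    }
    p_value <- (1 + hits) / (n_perm + 1)
  }

  structure(list(fst = obs$fst, fis = obs$fis, fit = obs$fit,
                 fis_by_group = fis_by_group, per_locus = obs$per_locus,
                 p_value = p_value, n_perm = n_perm,
                 groups = levels(g), loci = loci),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F-statistics over %d locus/loci, groups: %s\n",
              length(x$loci), paste(x$groups, collapse = " vs ")))
  cat(sprintf("  FST = %.4f  FIS = %.4f  FIT = %.4f\n", x$fst, x$fis, x$fit))
  for (g in names(x$fis_by_group))
    cat(sprintf("  FIS[%s] = %.4f\n", g, x$fis_by_group[g]))
  if (!is.na(x$p_value))
    cat(sprintf("  P(FST > 0) = %.4g (%d permutations)\n",
                x$p_value, x$n_perm))
  invisible(x)
}

# ---- Hardy-Weinberg exact test (Monte Carlo) -------------------------------

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test for a multi-allelic locus: the 2n sampled gene
#' copies are repeatedly shuffled into random diploid pairings (which
#' realises the Levene conditional distribution of genotype arrays given
#' the allele counts), and the p-value is the proportion of arrays whose
#' conditional probability does not exceed the observed one. The +1
#' correction makes the estimate valid for finite `n_mc`.
#'
#' @param x1,x2 allele vectors of the two copies per individual (`NA` =
#'   missing call, excluded pairwise).
#' @param n_mc number of Monte-Carlo shuffles.
#' @param seed optional integer seed.
#' @return p-value in (0, 1\]; exactly 1 for a monomorphic locus.
#' @export
hwe_exact_test <- function(x1, x2, n_mc = 1000, seed = NULL) {
  stopifnot(length(x1) == length(x2), n_mc >= 1)
  ok <- !is.na(x1) & !is.na(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 2) return(NA_real_)
  alleles <- sort(unique(c(x1, x2)))
  k <- length(alleles)
  if (k < 2) return(1)
  if (!is.null(seed)) set.seed(seed)
  c1 <- match(x1, alleles); c2 <- match(x2, alleles)
  copies <- c(c1, c2)
  log_stat <- function(u, v) {
    lo <- pmin(u, v); hi <- pmax(u, v)
    tab <- tabulate((lo - 1L) * k + hi, nbins = k * k)
    sum(lo != hi) * log(2) - sum(lfactorial(tab[tab > 0L]))
  }
  s_obs <- log_stat(c1, c2)
  hits <- 0L
  for (b in seq_len(n_mc)) {
    perm <- sample(copies)
    if (log_stat(perm[1:n], perm[(n + 1):(2 * n)]) <= s_obs + 1e-9)
      hits <- hits + 1L
  }
  (1 + hits) / (n_mc + 1)
}

# ---- genotypic linkage-disequilibrium test ---------------------------------

#' Permutation G-test of genotypic linkage disequilibrium
#'
#' Log-likelihood-ratio (G) statistic on the genotype-by-genotype
#' contingency table of a locus pair; the null distribution is obtained by
#' permuting one locus's genotypes across individuals, which breaks any
#' between-locus association while preserving both single-locus genotype
#' arrays.
#'
#' @param data an `xy_dataset`.
#' @param locus1,locus2 locus names.
#' @param individuals optional character/logical subset of individuals.
#' @param n_perm number of permutations (must be >= 1).
#' @param seed optional integer seed.
#' @return p-value; `NA` if fewer than 2 individuals are informative
#'   (non-missing at both loci).
#' @export
ld_test <- function(data, locus1, locus2, individuals = NULL,
                    n_perm = 999, seed = NULL) {
  stopifnot(inherits(data, "xy_dataset"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  g <- data$geno
  stopifnot(locus1 %in% g$loci, locus2 %in% g$loci)
  sel <- rep(TRUE, length(g$individuals))
  if (!is.null(individuals)) {
    if (is.logical(individuals)) sel <- individuals
    else sel <- g$individuals %in% individuals
  }
  gA <- paste(g$a1[sel, locus1], g$a2[sel, locus1])
  gB <- paste(g$a1[sel, locus2], g$a2[sel, locus2])
  ok <- !is.na(g$a1[sel, locus1]) & !is.na(g$a1[sel, locus2])
  gA <- factor(gA[ok]); gB <- factor(gB[ok])
  if (length(gA) < 2) return(NA_real_)
  g_stat <- function(a, b) {
    O <- table(a, b)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    pos <- O > 0
    2 * sum(O[pos] * log(O[pos] / E[pos]))
  }
  G_obs <- g_stat(gA, gB)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm))
    if (g_stat(gA, sample(gB)) >= G_obs - 1e-9) hits <- hits + 1L
  (1 + hits) / (n_perm + 1)
}

#' Linkage-disequilibrium tests over all locus pairs
#'
#' Runs [ld_test()] on every pair from `loci` and applies a familywise
#' multiple-testing correction (Bonferroni by default, the usual convention
#' for locus-pair families).
#'
#' @inheritParams ld_test
#' @param loci loci to pair (default: all).
#' @param adjust method passed to [stats::p.adjust()].
#' @return data.frame `locus1, locus2, p, p_adj`.
#' @export
ld_test_all <- function(data, loci = NULL, individuals = NULL,
                        n_perm = 999, seed = NULL, adjust = "bonferroni") {
  loci <- loci %||% data$geno$loci
  if (length(loci) < 2) stop("need at least two loci")
  prs <- utils::combn(loci, 2)
  if (!is.null(seed)) set.seed(seed)
  p <- apply(prs, 2, function(pr)
    ld_test(data, pr[1], pr[2], individuals = individuals, n_perm = n_perm))
  data.frame(locus1 = prs[1, ], locus2 = prs[2, ], p = p,
             p_adj = p.adjust(p, method = adjust))
}

# ---- Mantel test and geography ---------------------------------------------

#' Linearised genetic distance
#'
#' The Rousset transform \eqn{F_{ST}/(1-F_{ST})} used for isolation-by-
#' distance regressions; `Inf` for complete differentiation.
#'
#' @param fst numeric vector/matrix of F_ST values (< 1).
#' @export
fst_linearized <- function(fst) fst / (1 - fst)

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km (delegates to
#' \pkg{geosphere}).
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distance in km (vectorised).
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Pairwise great-circle distances between populations
#'
#' @param meta a `sample_meta` data.frame; one coordinate per population is
#'   obtained by averaging its samples' coordinates.
#' @return symmetric labelled matrix of distances in km.
#' @export
geo_distance_matrix <- function(meta) {
  pops <- unique(meta$population)
  lon <- tapply(meta$longitude, meta$population, mean)[pops]
  lat <- tapply(meta$latitude, meta$population, mean)[pops]
  n <- length(pops)
  d <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- great_circle_km(lon[i], lat[i], lon[j], lat[j])
  d
}

#' Pairwise Weir-Cockerham F_ST between populations
#'
#' @param data an `xy_dataset`.
#' @param loci loci to combine (default: all).
#' @return symmetric labelled matrix of pairwise multi-locus F_ST.
#' @export
pairwise_fst <- function(data, loci = NULL) {
  pops <- unique(data$meta$population)
  n <- length(pops)
  if (n < 2) stop("need at least two populations")
  out <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sub <- subset_individuals(data, data$meta$population %in% pops[c(i, j)])
    fs <- fstat_weir_cockerham(sub, loci = loci, grouping = "population")
    out[i, j] <- out[j, i] <- fs$fst
  }
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal elements, with significance from
#' joint row/column permutations of the first matrix — the standard test
#' for isolation by distance when `genetic_d` holds linearised genetic
#' distances ([fst_linearized()]) and `geo_d` great-circle distances. The
#' p-value is the upper-tail probability of a correlation at least as large
#' as observed.
#'
#' @param genetic_d,geo_d symmetric matrices with zero diagonals and
#'   matching label order.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return object of class `mantel_result`: `r`, `p_value`,
#'   `n_permutations`.
#' @export
mantel_test <- function(genetic_d, geo_d, n_perm = 5000, seed = NULL) {
  stopifnot(is.matrix(genetic_d), is.matrix(geo_d),
            identical(dim(genetic_d), dim(geo_d)), n_perm >= 1)
  if (!isTRUE(all.equal(genetic_d, t(genetic_d))) ||
      !isTRUE(all.equal(geo_d, t(geo_d))))
    stop("matrices must be symmetric")
  if (any(diag(genetic_d) != 0) || any(diag(geo_d) != 0))
    stop("matrices must have zero diagonals")
  if (!is.null(dimnames(genetic_d)) && !is.null(dimnames(geo_d)) &&
      !identical(rownames(genetic_d), rownames(geo_d)))
    stop("matrix labels do not match")
  lt <- lower.tri(genetic_d)
  x <- genetic_d[lt]; y <- geo_d[lt]
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant distance matrix: correlation undefined")
  r_obs <- cor(x, y)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genetic_d)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample(n)
    if (cor(genetic_d[idx, idx][lt], y) >= r_obs - 1e-12) hits <- hits + 1L
  }
  structure(list(r = r_obs, p_value = (1 + hits) / (n_perm + 1),
                 n_permutations = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$n_permutations))
  invisible(x)
}
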