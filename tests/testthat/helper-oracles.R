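# Independent oracles, coded from first principles and kept separate from
# the package's own computation paths.

# Weir-Cockerham variance components via the nested-ANOVA mean-squares
# route (copies within individuals within groups), per allele and locus.
wc_anova_oracle <- function(a1, a2, grp) {
  grp <- factor(grp)
  A <- B <- C <- 0
  for (j in seq_len(ncol(a1))) {
    x1 <- a1[, j]; x2 <- a2[, j]
    ok <- !is.na(x1)
    x1 <- x1[ok]; x2 <- x2[ok]; g <- droplevels(grp[ok])
    r <- nlevels(g)
    if (r < 2) next   # a locus with <2 informative groups carries no signal
    n_i <- as.numeric(table(g))
    ntot <- sum(n_i)
    nc <- (ntot - sum(n_i^2) / ntot) / (r - 1)
    alleles <- unique(c(x1, x2))
    if (length(alleles) < 2) next
    for (u in alleles) {
      y <- cbind(as.numeric(x1 == u), as.numeric(x2 == u))
      ybar_i <- rowMeans(y)
      ybar_p <- tapply(ybar_i, g, mean)
      ybar <- mean(y)
      SSP <- sum(2 * n_i * (ybar_p - ybar)^2)
      SSI <- sum(2 * (ybar_i - ybar_p[as.integer(g)])^2)
      SSG <- sum((y - ybar_i)^2)
      MSP <- SSP / (r - 1)
      MSI <- SSI / (ntot - r)
      MSG <- SSG / ntot
      A <- A + (MSP - MSI) / (2 * nc)
      B <- B + (MSI - MSG) / 2
      C <- C + MSG
    }
  }
  list(fst = A / (A + B + C), fis = 1 - C / (B + C),
       fit = 1 - C / (A + B + C))
}

# single-group fixation index via the same ANOVA route (no group stratum)
wc_anova_oracle_within <- function(a1, a2) {
  B <- C <- 0
  for (j in seq_len(ncol(a1))) {
    x1 <- a1[, j]; x2 <- a2[, j]
    ok <- !is.na(x1)
    x1 <- x1[ok]; x2 <- x2[ok]
    n <- length(x1)
    alleles <- unique(c(x1, x2))
    if (length(alleles) < 2 || n < 2) next
    for (u in alleles) {
      y <- cbind(as.numeric(x1 == u), as.numeric(x2 == u))
      ybar_i <- rowMeans(y)
      ybar <- mean(y)
      SSI <- sum(2 * (ybar_i - ybar)^2)
      SSG <- sum((y - ybar_i)^2)
      MSI <- SSI / (n - 1)
      MSG <- SSG / n
      B <- B + (MSI - MSG) / 2
      C <- C + MSG
    }
  }
  1 - C / (B + C)
}
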