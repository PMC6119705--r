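# Detection of male-specific (Y-private) and translocation-specific alleles,
# per-population association scoring, and sex-reversal flagging.

# individuals (logical over rows) carrying >= 1 copy of `allele` at `locus`
carries_allele <- function(geno, locus, allele) {
  x1 <- geno$a1[, locus]; x2 <- geno$a2[, locus]
  out <- (!is.na(x1) & x1 == allele) | (!is.na(x2) & x2 == allele)
  out
}

scope_individuals <- function(data, populations) {
  if (is.null(populations)) rep(TRUE, nrow(data$meta))
  else data$meta$population %in% populations
}

# fetch the class-allele set for (locus, population); NULL if the
# classification has no entry for that scope
class_alleles_for <- function(classification, locus, population = NULL) {
  entry <- classification$alleles[[locus]]
  if (is.null(entry)) return(NULL)
  if (!classification$per_population) return(entry)
  if (is.null(population)) return(sort(unique(unlist(entry))))
  entry[[population]]
}

#' Detect male-specific (Y-private) alleles
#'
#' In a male-heterogametic system with suppressed X-Y recombination,
#' Y-borne alleles appear in males and (apart from sex-reversed
#' individuals) never in females. This scans each locus for alleles carried
#' by at least one male and by at most `max_female_carriers` females over
#' the pooled scope populations. Female carriers of a classed allele are
#' recorded as exceptions (candidate sex reversals), not silently dropped.
#'
#' @param data an `xy_dataset`.
#' @param populations population labels to pool (default: all). For a
#'   regional survey, pool the populations where sex linkage is expected
#'   (e.g. the WEST group) rather than the full range.
#' @param max_female_carriers tolerated number of female carriers per
#'   allele (default 2, allowing for rare sex-reversed females).
#' @param loci loci to scan (default: all).
#' @return object of class `allele_classification` with `alleles` (named
#'   list locus -> integer allele vector), a `support` data.frame of
#'   carrier counts per allele, and `exceptions` (female carriers of
#'   classed alleles).
#' @export
find_male_specific_alleles <- function(data, populations = NULL,
                                       max_female_carriers = 2,
                                       loci = NULL) {
  stopifnot(inherits(data, "xy_dataset"), max_female_carriers >= 0)
  loci <- loci %||% data$geno$loci
  sel <- scope_individuals(data, populations)
  is_m <- sel & data$meta$sex == "M"
  is_f <- sel & data$meta$sex == "F"
  if (!any(is_m) || !any(is_f))
    stop("both sexes must be present in the scoped populations")
  alleles <- list(); support <- list(); exceptions <- list()
  for (loc in loci) {
    al <- sort(unique(allele_copies(data$geno, loc, sel)))
    if (!length(al)) { alleles[[loc]] <- integer(0); next }
    n_m <- n_f <- integer(length(al))
    for (k in seq_along(al)) {
      carr <- carries_allele(data$geno, loc, al[k])
      n_m[k] <- sum(carr & is_m)
      n_f[k] <- sum(carr & is_f)
    }
    ms <- n_m >= 1L & n_f <= max_female_carriers
    alleles[[loc]] <- al[ms]
    support[[loc]] <- data.frame(locus = loc, allele = al,
                                 n_male_carriers = n_m,
                                 n_female_carriers = n_f,
                                 male_specific = ms)
    for (k in which(ms & n_f > 0L)) {
      carr <- carries_allele(data$geno, loc, al[k])
      exceptions[[length(exceptions) + 1L]] <- data.frame(
        locus = loc, allele = al[k],
        sample_id = data$geno$individuals[carr & is_f])
    }
  }
  structure(list(mode = "SEX", per_population = FALSE,
                 populations = populations, loci = loci,
                 alleles = alleles,
                 support = do.call(rbind, unname(support)),
                 exceptions = if (length(exceptions))
                   do.call(rbind, exceptions)
                 else data.frame(locus = character(0), allele = integer(0),
                                 sample_id = character(0)),
                 max_other_carriers = max_female_carriers),
            class = "allele_classification")
}

#' Detect translocation-specific alleles
#'
#' Alleles riding on the translocated chromosome are shared by translocated
#' individuals of both sexes and absent (up to `max_normal_carriers`
#' tolerated carriers) from normal-karyotype individuals. Because a
#' translocated haplotype can carry different alleles in different demes,
#' classification can be scoped per population (`per_population = TRUE`).
#'
#' @inheritParams find_male_specific_alleles
#' @param max_normal_carriers tolerated number of normal-karyotype carriers
#'   per allele (default 0).
#' @param per_population classify separately within each scoped population.
#' @param require_both_sexes require at least one translocated carrier of
#'   each sex present among translocated individuals in scope.
#' @return an `allele_classification`; with `per_population = TRUE`,
#'   `alleles[[locus]]` is a named list population -> allele vector.
#' @export
find_translocation_specific_alleles <- function(data, populations = NULL,
                                                max_normal_carriers = 0,
                                                loci = NULL,
                                                per_population = FALSE,
                                                require_both_sexes = TRUE) {
  stopifnot(inherits(data, "xy_dataset"), max_normal_carriers >= 0)
  loci <- loci %||% data$geno$loci
  pops <- populations %||% unique(data$meta$population)
  if (per_population) {
    no_trans <- pops[vapply(pops, function(p)
      !any(data$meta$population == p &
             data$meta$karyotype == "TRANSLOCATED"), logical(1))]
    if (length(no_trans))
      stop("population(s) without translocated individuals: ",
           paste(no_trans, collapse = ", "))
    per_pop <- lapply(pops, function(p)
      find_translocation_specific_alleles(
        data, populations = p, max_normal_carriers = max_normal_carriers,
        loci = loci, per_population = FALSE,
        require_both_sexes = require_both_sexes))
    names(per_pop) <- pops
    alleles <- lapply(loci, function(loc)
      lapply(per_pop, function(cl) cl$alleles[[loc]]))
    names(alleles) <- loci
    support <- do.call(rbind, lapply(pops, function(p) {
      s <- per_pop[[p]]$support
      if (!is.null(s) && nrow(s)) cbind(population = p, s) else NULL
    }))
    exceptions <- do.call(rbind, lapply(pops, function(p) {
      e <- per_pop[[p]]$exceptions
      if (nrow(e)) cbind(population = p, e) else NULL
    }))
    return(structure(list(mode = "TRANSLOCATION", per_population = TRUE,
                          populations = pops, loci = loci, alleles = alleles,
                          support = support,
                          exceptions = exceptions %||%
                            data.frame(population = character(0),
                                       locus = character(0),
                                       allele = integer(0),
                                       sample_id = character(0)),
                          max_other_carriers = max_normal_carriers),
                     class = "allele_classification"))
  }
  sel <- scope_individuals(data, pops)
  is_t <- sel & data$meta$karyotype == "TRANSLOCATED"
  is_n <- sel & data$meta$karyotype == "NORMAL"
  if (!any(is_t))
    stop("no translocated individuals in population(s): ",
         paste(pops, collapse = ", "))
  sexes_present <- unique(data$meta$sex[is_t & data$meta$sex != "UNKNOWN"])
  alleles <- list(); support <- list(); exceptions <- list()
  for (loc in loci) {
    al <- sort(unique(allele_copies(data$geno, loc, sel)))
    if (!length(al)) { alleles[[loc]] <- integer(0); next }
    n_tf <- n_tm <- n_nk <- integer(length(al))
    for (k in seq_along(al)) {
      carr <- carries_allele(data$geno, loc, al[k])
      n_tf[k] <- sum(carr & is_t & data$meta$sex == "F")
      n_tm[k] <- sum(carr & is_t & data$meta$sex == "M")
      n_nk[k] <- sum(carr & is_n)
    }
    if (require_both_sexes) {
      ok_t <- rep(TRUE, length(al))
      if ("F" %in% sexes_present) ok_t <- ok_t & n_tf >= 1L
      if ("M" %in% sexes_present) ok_t <- ok_t & n_tm >= 1L
    } else ok_t <- (n_tf + n_tm) >= 1L
    ts <- ok_t & n_nk <= max_normal_carriers
    alleles[[loc]] <- al[ts]
    support[[loc]] <- data.frame(locus = loc, allele = al,
                                 n_transloc_female_carriers = n_tf,
                                 n_transloc_male_carriers = n_tm,
                                 n_normal_carriers = n_nk,
                                 translocation_specific = ts)
    for (k in which(ts & n_nk > 0L)) {
      carr <- carries_allele(data$geno, loc, al[k])
      exceptions[[length(exceptions) + 1L]] <- data.frame(
        locus = loc, allele = al[k],
        sample_id = data$geno$individuals[carr & is_n])
    }
  }
  structure(list(mode = "TRANSLOCATION", per_population = FALSE,
                 populations = pops, loci = loci, alleles = alleles,
                 support = do.call(rbind, unname(support)),
                 exceptions = if (length(exceptions))
                   do.call(rbind, exceptions)
                 else data.frame(locus = character(0), allele = integer(0),
                                 sample_id = character(0)),
                 max_other_carriers = max_normal_carriers),
            class = "allele_classification")
}

#' @export
print.allele_classification <- function(x, ...) {
  n_cls <- if (x$per_population)
    sum(lengths(unlist(x$alleles, recursive = FALSE)))
  else sum(lengths(x$alleles))
  cat(sprintf("allele_classification (%s%s): %d classed allele(s) over %d loci, %d exception carrier row(s)\n",
              x$mode, if (x$per_population) ", per population" else "",
              n_cls, length(x$loci), nrow(x$exceptions)))
  invisible(x)
}

#' Sex/translocation association score of a locus in a population
#'
#' Deviation score \eqn{D = 1 - N_{carriers}/N_{target}}, where the target
#' class is the males (`mode = "SEX"`) or the translocated individuals
#' (`mode = "TRANSLOCATION"`) of the population, and a carrier is a target
#' individual bearing at least one classed allele at the locus. Under
#' complete recombination suppression every target carries a class allele
#' and D = 0; deviation toward 1 indicates unrestricted recombination.
#' Individuals with a missing call at the locus are excluded from both
#' counts (pairwise deletion).
#'
#' @param data an `xy_dataset`.
#' @param classification an `allele_classification` from
#'   [find_male_specific_alleles()] or
#'   [find_translocation_specific_alleles()].
#' @param locus,population the cell to score.
#' @param mode `"SEX"` or `"TRANSLOCATION"`; defaults to the
#'   classification's own mode.
#' @return one-row data.frame `locus, population, mode, n_carriers,
#'   n_target, score`; `score` is `NA` when the target class is empty
#'   (the break-in-the-line case for a population with no translocated
#'   individuals).
#' @export
association_score <- function(data, classification, locus, population,
                              mode = classification$mode) {
  stopifnot(inherits(data, "xy_dataset"),
            inherits(classification, "allele_classification"),
            mode %in% c("SEX", "TRANSLOCATION"))
  in_pop <- data$meta$population == population
  informative <- in_pop & !is.na(data$geno$a1[, locus])
  target <- if (mode == "SEX") informative & data$meta$sex == "M"
  else informative & data$meta$karyotype == "TRANSLOCATED"
  n_target <- sum(target)
  al <- class_alleles_for(classification, locus, population)
  if (n_target == 0L || is.null(al))
    return(data.frame(locus = locus, population = population, mode = mode,
                      n_carriers = NA_integer_, n_target = n_target,
                      score = NA_real_))
  carr <- rep(FALSE, n_target)
  if (length(al)) {
    carr_mat <- vapply(al, function(u) carries_allele(data$geno, locus, u)[target],
                       logical(n_target))
    carr <- if (n_target == 1L) any(carr_mat) else rowSums(
      matrix(carr_mat, nrow = n_target)) > 0
  }
  n_carriers <- sum(carr)
  data.frame(locus = locus, population = population, mode = mode,
             n_carriers = n_carriers, n_target = n_target,
             score = 1 - n_carriers / n_target)
}

#' Association scores for all loci x populations
#'
#' Long-format table of [association_score()] over every combination, the
#' per-population profile used to localise where recombination suppression
#' holds and where it has broken down.
#'
#' @inheritParams association_score
#' @param populations,loci subsets (default: all populations in `data`,
#'   all loci of the classification).
#' @return data.frame, one row per locus x population.
#' @export
association_table <- function(data, classification, populations = NULL,
                              loci = NULL, mode = classification$mode) {
  populations <- populations %||% unique(data$meta$population)
  loci <- loci %||% classification$loci
  out <- do.call(rbind, lapply(loci, function(loc)
    do.call(rbind, lapply(populations, function(p)
      association_score(data, classification, loc, p, mode = mode)))))
  rownames(out) <- NULL
  out
}

#' Flag putative sex-reversed individuals
#'
#' At loci fully linked to sex, a genotypic male must carry a male-specific
#' allele and a genotypic female must not. A phenotypic male lacking
#' male-specific alleles at `min_discordant` or more informative loci, or a
#' phenotypic female carrying them, is a reversal candidate (e.g.
#' gonad-anomalous individuals whose phenotypic sex contradicts the
#' genotype). Flagged individuals are reported, never removed here; pass
#' the flags to [subset_individuals()] if exclusion is wanted.
#'
#' @param data an `xy_dataset`.
#' @param classification male-specific `allele_classification`.
#' @param fully_linked_loci loci with complete sex linkage to use as
#'   evidence.
#' @param min_discordant minimum number of discordant informative loci to
#'   call a candidate; default (`NULL`) requires discordance at all
#'   informative loci.
#' @return data.frame `sample_id, phenotypic_sex, n_informative_loci,
#'   n_discordant_loci, verdict` (verdict in `CONSISTENT`,
#'   `CANDIDATE_REVERSAL`). Individuals of unknown sex are skipped.
#' @export
flag_sex_discordant <- function(data, classification, fully_linked_loci,
                                min_discordant = NULL) {
  stopifnot(inherits(data, "xy_dataset"), length(fully_linked_loci) >= 1)
  bad <- setdiff(fully_linked_loci, names(classification$alleles))
  if (length(bad)) stop("loci not in classification: ",
                        paste(bad, collapse = ", "))
  known <- which(data$meta$sex %in% c("F", "M"))
  out <- data.frame(sample_id = data$geno$individuals[known],
                    phenotypic_sex = data$meta$sex[known],
                    n_informative_loci = 0L, n_discordant_loci = 0L,
                    verdict = "CONSISTENT", stringsAsFactors = FALSE)
  for (loc in fully_linked_loci) {
    x1 <- data$geno$a1[known, loc]; x2 <- data$geno$a2[known, loc]
    informative <- !is.na(x1)
    has_ms <- rep(FALSE, length(known))
    for (i in which(informative)) {
      al <- class_alleles_for(classification, loc,
                              data$meta$population[known[i]])
      if (length(al))
        has_ms[i] <- x1[i] %in% al || x2[i] %in% al
    }
    out$n_informative_loci <- out$n_informative_loci + informative
    disc <- informative &
      ((out$phenotypic_sex == "M" & !has_ms) |
         (out$phenotypic_sex == "F" & has_ms))
    out$n_discordant_loci <- out$n_discordant_loci + disc
  }
  thr <- if (is.null(min_discordant)) out$n_informative_loci else min_discordant
  flag <- out$n_informative_loci > 0L & out$n_discordant_loci >= thr
  out$verdict[flag] <- "CANDIDATE_REVERSAL"
  if (any(out$n_informative_loci == 0L))
    warning(sum(out$n_informative_loci == 0L),
            " individual(s) with no informative loci left CONSISTENT")
  out
}
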