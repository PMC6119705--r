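# X/Y haplotype phasing from private male alleles, and partition of X
# copies into translocated (XT) vs normal (XN) chromosomes.

#' Phase X and Y haplotypes from private male alleles
#'
#' In the absence of X-Y recombination, a male's Y copy at a fully
#' sex-linked locus is the one matching a male-specific allele, and the
#' other copy is his X; female copies are X by definition. Males carrying
#' no male-specific allele, two different male-specific alleles, or
#' homozygous for one (impossible for a truly Y-private allele, so treated
#' as a genotyping anomaly) are left UNPHASED at that locus — cross-check
#' such individuals with [flag_sex_discordant()].
#'
#' @param data an `xy_dataset`.
#' @param classification male-specific `allele_classification`.
#' @param loci sex-linked loci to phase; default: loci tagged `SEX_LINKED`
#'   in the dataset's locus panel, falling back to the classification's
#'   loci.
#' @return object of class `phased_haplotypes`: `copies`, a long
#'   data.frame (`sample_id, population, locus, copy, allele, class, rule`)
#'   with one row per non-missing allele copy and `class` in
#'   `Y`/`X`/`UNPHASED`; and `individuals`, per-sample inferred sex
#'   genotypes (`XY`/`XX`/`AMBIGUOUS`).
#' @export
phase_xy <- function(data, classification, loci = NULL) {
  stopifnot(inherits(data, "xy_dataset"),
            inherits(classification, "allele_classification"))
  if (is.null(loci)) {
    loci <- names(data$locus_panel)[data$locus_panel == "SEX_LINKED"]
    if (!length(loci)) loci <- classification$loci
  }
  bad <- setdiff(loci, names(classification$alleles))
  if (length(bad))
    stop("locus/loci not in classification: ", paste(bad, collapse = ", "))

  ids <- data$geno$individuals
  sex <- data$meta$sex
  pop <- data$meta$population
  rows <- vector("list", length(loci))
  for (li in seq_along(loci)) {
    loc <- loci[li]
    x1 <- data$geno$a1[, loc]; x2 <- data$geno$a2[, loc]
    ok <- which(!is.na(x1))
    if (!length(ok)) next
    cls1 <- cls2 <- character(length(ok))
    rule <- character(length(ok))
    for (i in seq_along(ok)) {
      j <- ok[i]
      al <- class_alleles_for(classification, loc, pop[j]) %||% integer(0)
      m1 <- x1[j] %in% al; m2 <- x2[j] %in% al
      if (sex[j] == "F") {
        cls1[i] <- cls2[i] <- "X"; rule[i] <- "female"
      } else if (sex[j] == "M") {
        if (m1 && m2 && x1[j] == x2[j]) {
          cls1[i] <- cls2[i] <- "UNPHASED"; rule[i] <- "hom_male_specific"
        } else if (m1 && m2) {
          cls1[i] <- cls2[i] <- "UNPHASED"; rule[i] <- "two_male_specific"
        } else if (m1) {
          cls1[i] <- "Y"; cls2[i] <- "X"; rule[i] <- "male_private_allele"
        } else if (m2) {
          cls1[i] <- "X"; cls2[i] <- "Y"; rule[i] <- "male_private_allele"
        } else {
          cls1[i] <- cls2[i] <- "UNPHASED"; rule[i] <- "no_male_specific"
        }
      } else {
        cls1[i] <- cls2[i] <- "UNPHASED"; rule[i] <- "unknown_sex"
      }
    }
    rows[[li]] <- data.frame(
      sample_id = rep(ids[ok], 2L),
      population = rep(pop[ok], 2L),
      locus = loc,
      copy = rep(1:2, each = length(ok)),
      allele = c(x1[ok], x2[ok]),
      class = c(cls1, cls2),
      rule = rep(rule, 2L),
      stringsAsFactors = FALSE)
  }
  copies <- do.call(rbind, rows)
  if (is.null(copies))
    copies <- data.frame(sample_id = character(0), population = character(0),
                         locus = character(0), copy = integer(0),
                         allele = integer(0), class = character(0),
                         rule = character(0))
  n_y <- tapply(copies$class == "Y", copies$sample_id, sum)
  inferred <- ifelse(sex == "F", "XX",
                     ifelse(sex == "M" &
                              ids %in% names(n_y)[!is.na(n_y) & n_y > 0],
                            "XY", "AMBIGUOUS"))
  structure(list(copies = copies,
                 individuals = data.frame(sample_id = ids,
                                          phenotypic_sex = sex,
                                          inferred = inferred,
                                          stringsAsFactors = FALSE),
                 loci = loci, partitioned = FALSE),
            class = "phased_haplotypes")
}

#' Partition X copies into translocated (XT) and normal (XN) chromosomes
#'
#' X-labelled copies matching a translocation-specific allele become XT,
#' the rest XN — except in individuals of NORMAL karyotype, where an
#' apparent translocation allele is labelled XN and logged as a mismatch
#' (XT labels are only admitted for TRANSLOCATED or UNKNOWN karyotypes,
#' the latter carrying a low-confidence rule mark). Each individual's
#' realised class pair per locus is checked against the karyotype
#' expectation (MT: Y+XT, FT: XN+XT, MN: Y+XN, FN: XN+XN); mismatches are
#' recorded, not fatal.
#'
#' @param phased output of [phase_xy()].
#' @param data the same `xy_dataset`.
#' @param classification translocation-specific `allele_classification`.
#' @return the `phased_haplotypes` with `copies$class` now in
#'   `Y`/`XT`/`XN`/`UNPHASED` and a `mismatches` data.frame of
#'   karyotype-discordant (sample, locus) cells.
#' @export
partition_x <- function(phased, data, classification) {
  stopifnot(inherits(phased, "phased_haplotypes"),
            inherits(data, "xy_dataset"),
            inherits(classification, "allele_classification"))
  copies <- phased$copies
  kary <- setNames(data$meta$karyotype, data$geno$individuals)
  is_x <- copies$class == "X"
  new_cls <- copies$class
  new_rule <- copies$rule
  for (i in which(is_x)) {
    al <- class_alleles_for(classification, copies$locus[i],
                            copies$population[i]) %||% integer(0)
    kt <- kary[[copies$sample_id[i]]]
    if (copies$allele[i] %in% al) {
      if (kt == "NORMAL") {
        new_cls[i] <- "XN"
        new_rule[i] <- paste0(new_rule[i], "+trans_allele_in_normal")
      } else {
        new_cls[i] <- "XT"
        new_rule[i] <- paste0(new_rule[i],
                              if (kt == "UNKNOWN") "+trans_allele_lowconf"
                              else "+trans_allele")
      }
    } else new_cls[i] <- "XN"
  }
  copies$class <- new_cls
  copies$rule <- new_rule

  # karyotype-consistency audit per (individual, locus)
  expect <- c(MT = "XT/Y", FT = "XN/XT", MN = "XN/Y", FN = "XN/XN")
  sexes <- setNames(data$meta$sex, data$geno$individuals)
  key <- paste(copies$sample_id, copies$locus)
  obs <- tapply(copies$class, key, function(cl)
    paste(sort(cl), collapse = "/"))
  ids <- sub(" [^ ]+$", "", names(obs))
  locs <- sub("^.* ", "", names(obs))
  grp <- paste0(ifelse(sexes[ids] == "M", "M", ifelse(sexes[ids] == "F", "F", "?")),
                ifelse(kary[ids] == "TRANSLOCATED", "T",
                       ifelse(kary[ids] == "NORMAL", "N", "?")))
  exp_str <- unname(expect[grp])
  mism <- !is.na(exp_str) & obs != exp_str &
    !grepl("UNPHASED", obs)  # unphased cells are already flagged upstream
  mismatches <- data.frame(sample_id = ids[mism], locus = locs[mism],
                           expected = exp_str[mism],
                           observed = unname(obs[mism]),
                           stringsAsFactors = FALSE)
  rownames(mismatches) <- NULL
  if (nrow(mismatches))
    message(nrow(mismatches),
            " (individual, locus) cell(s) discordant with karyotype ",
            "expectation; see $mismatches")
  phased$copies <- copies
  phased$mismatches <- mismatches
  phased$partitioned <- TRUE
  phased
}

#' @export
print.phased_haplotypes <- function(x, ...) {
  tab <- table(x$copies$class)
  cat("phased_haplotypes over", length(x$loci), "loci:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$mismatches) && nrow(x$mismatches))
    cat(nrow(x$mismatches), "karyotype-discordant cells\n")
  invisible(x)
}

#' Class-count summary of phased copies
#'
#' Gene-copy bookkeeping per population x locus: the number of copies
#' assigned to each chromosome class. Totals equal twice the number of
#' non-missing genotypes, a conservation check worth eyeballing in any run.
#'
#' @param phased a `phased_haplotypes`.
#' @return data.frame population x locus x class counts (wide, one column
#'   per class).
#' @export
class_counts <- function(phased) {
  cp <- phased$copies
  classes <- c("Y", "X", "XT", "XN", "UNPHASED")
  classes <- intersect(classes, unique(cp$class))
  out <- do.call(rbind, lapply(split(cp, list(cp$population, cp$locus),
                                     drop = TRUE), function(d) {
    cnt <- table(factor(d$class, classes))
    cbind(data.frame(population = d$population[1], locus = d$locus[1]),
          as.data.frame.matrix(t(as.matrix(cnt))))
  }))
  rownames(out) <- NULL
  out
}
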