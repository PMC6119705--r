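#' Default population-to-group map for the bundled western/eastern survey
#'
#' Named character vector mapping the sixteen bundled population
#' abbreviations to the `WEST` (Sichuan Basin populations 1-8, where the
#' reciprocal-translocation polymorphism segregates) or `EAST` group.
#' Override or extend it for other datasets.
#'
#' @return named character vector, population -> group.
#' @export
default_group_map <- function() {
  c(PZLMS = "WEST", PZCF = "WEST", QCS = "WEST", DYYEC = "WEST",
    DYGTS = "WEST", QLDZ = "WEST", QLTTS = "WEST", EMPX = "WEST",
    DGTX = "EAST", SYKKS = "EAST", ZYST = "EAST", GDYX = "EAST",
    HJSP = "EAST", BJHL = "EAST", TSCW = "EAST", XSGQ = "EAST")
}

#' Read a per-sample metadata table
#'
#' Expects delimited text (comma or tab, auto-detected from the header)
#' with columns `sample_id, population, sex, karyotype, longitude, latitude`
#' and optionally `group`. Sex tokens are normalised case-insensitively to
#' `F`/`M`/`UNKNOWN`; karyotype tokens to `NORMAL` (Type I) /
#' `TRANSLOCATED` (Types II-V) / `UNKNOWN`. If no `group` column is
#' present, groups are assigned from `group_map`; populations absent from
#' the map get `NA` with a warning.
#'
#' @param path delimited text file.
#' @param group_map named character vector population -> group label.
#' @return data.frame of class `sample_meta`.
#' @export
read_sample_table <- function(path, group_map = default_group_map()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   strip.white = TRUE, comment.char = "")
  names(df) <- tolower(names(df))
  need <- c("sample_id", "population", "sex", "karyotype",
            "longitude", "latitude")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "))
  }
  df$population <- as.character(df$population)
  df$sex <- normalize_sex(df$sex)
  df$karyotype <- normalize_karyotype(df$karyotype)
  df$longitude <- as.numeric(df$longitude)
  df$latitude <- as.numeric(df$latitude)
  if (any(abs(df$latitude) > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if (!"group" %in% names(df)) {
    df$group <- unname(group_map[df$population])
    if (anyNA(df$group))
      warning("populations without a group assignment: ",
              paste(unique(df$population[is.na(df$group)]), collapse = ", "))
  }
  df <- df[c(need, "group")]
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Join genotypes and metadata into a validated dataset
#'
#' Checks that the individual sets of the genotype matrix and the metadata
#' coincide (erroring with the symmetric difference otherwise), tags each
#' locus, and attaches a validation report: per-locus missingness and the
#' per-population sex-by-karyotype sample-size table (FN/FT/MN/MT counts,
#' the usual summary layout for a translocation-polymorphic survey).
#'
#' @param geno a [genotype_matrix()].
#' @param meta a `sample_meta` data.frame ([read_sample_table()]).
#' @param locus_panel optional named character vector locus ->
#'   `SEX_LINKED`/`AUTOSOMAL`/`UNASSIGNED`; unnamed loci default to
#'   `UNASSIGNED`.
#' @return an object of class `xy_dataset` with elements `geno`, `meta`,
#'   `locus_panel` and `report`.
#' @export
validate_dataset <- function(geno, meta, locus_panel = NULL) {
  stopifnot(inherits(geno, "geno_matrix"), is.data.frame(meta))
  g_ids <- geno$individuals
  m_ids <- meta$sample_id
  only_g <- setdiff(g_ids, m_ids)
  only_m <- setdiff(m_ids, g_ids)
  if (!length(intersect(g_ids, m_ids)))
    stop("genotype and metadata individual sets do not overlap")
  if (length(only_g) || length(only_m))
    stop("genotype/metadata id mismatch; only in genotypes: {",
         paste(only_g, collapse = ", "), "}; only in metadata: {",
         paste(only_m, collapse = ", "), "}")
  meta <- meta[match(g_ids, m_ids), , drop = FALSE]
  rownames(meta) <- NULL

  panel <- setNames(rep("UNASSIGNED", length(geno$loci)), geno$loci)
  if (!is.null(locus_panel)) {
    bad <- setdiff(names(locus_panel), geno$loci)
    if (length(bad))
      stop("locus_panel names unknown loci: ", paste(bad, collapse = ", "))
    stopifnot(all(locus_panel %in% c("SEX_LINKED", "AUTOSOMAL", "UNASSIGNED")))
    panel[names(locus_panel)] <- locus_panel
  }

  missingness <- data.frame(
    locus = geno$loci,
    n_missing = colSums(is.na(geno$a1)),
    prop_missing = colMeans(is.na(geno$a1)),
    row.names = NULL)

  ds <- structure(list(geno = geno, meta = meta, locus_panel = panel),
                  class = "xy_dataset")
  ds$report <- list(missingness = missingness, counts = sample_counts(ds))
  ds
}

#' Per-population sex-by-karyotype sample counts
#'
#' @param data an `xy_dataset` (or a `sample_meta` data.frame).
#' @return data.frame with columns `population, FN, FT, MN, MT, other, n`;
#'   `other` collects UNKNOWN sex or karyotype, `n` is the row total.
#' @export
sample_counts <- function(data) {
  meta <- if (inherits(data, "xy_dataset")) data$meta else data
  cls <- rep("other", nrow(meta))
  cls[meta$sex == "F" & meta$karyotype == "NORMAL"] <- "FN"
  cls[meta$sex == "F" & meta$karyotype == "TRANSLOCATED"] <- "FT"
  cls[meta$sex == "M" & meta$karyotype == "NORMAL"] <- "MN"
  cls[meta$sex == "M" & meta$karyotype == "TRANSLOCATED"] <- "MT"
  pops <- unique(meta$population)
  out <- do.call(rbind, lapply(pops, function(p) {
    k <- cls[meta$population == p]
    data.frame(population = p,
               FN = sum(k == "FN"), FT = sum(k == "FT"),
               MN = sum(k == "MN"), MT = sum(k == "MT"),
               other = sum(k == "other"), n = length(k))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.xy_dataset <- function(x, ...) {
  cat("xy_dataset:", length(x$geno$individuals), "individuals,",
      length(x$geno$loci), "loci,",
      length(unique(x$meta$population)), "population(s)\n")
  tab <- table(factor(x$locus_panel,
                      c("SEX_LINKED", "AUTOSOMAL", "UNASSIGNED")))
  cat("locus panel:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a dataset to a subset of individuals
#'
#' @param data an `xy_dataset`.
#' @param individuals character vector of sample ids to keep, or a logical
#'   vector over individuals.
#' @return the restricted `xy_dataset` (report recomputed).
#' @export
subset_individuals <- function(data, individuals) {
  stopifnot(inherits(data, "xy_dataset"))
  if (is.logical(individuals)) individuals <- data$geno$individuals[individuals]
  keep <- data$geno$individuals %in% individuals
  if (!any(keep)) stop("empty individual subset")
  g <- data$geno
  gm <- genotype_matrix(g$a1[keep, , drop = FALSE], g$a2[keep, , drop = FALSE],
                        null_sentinels = g$null_sentinels,
                        populations = g$populations[keep])
  meta <- data$meta[keep, , drop = FALSE]
  class(meta) <- c("sample_meta", "data.frame")
  validate_dataset(gm, meta, locus_panel = data$locus_panel)
}

# internal: allele copies at a locus for a set of individuals (pairwise
# deletion of missing calls; returns integer vector of 2*n_nonmissing codes)
allele_copies <- function(geno, locus, which_ind = NULL) {
  x1 <- geno$a1[, locus]
  x2 <- geno$a2[, locus]
  if (!is.null(which_ind)) {
    x1 <- x1[which_ind]; x2 <- x2[which_ind]
  }
  ok <- !is.na(x1)
  c(x1[ok], x2[ok])
}
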