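# End-to-end orchestration: validate -> classify -> score -> F-statistics ->
# HWE/LD -> phase -> partition -> diversity -> Mantel, with a TSV bundle.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full sex-linkage analysis
#'
#' Executes every stage of the pipeline on one dataset and writes the
#' result bundle as TSV files plus a run log. Stages: dataset validation;
#' male-specific and translocation-specific allele classification;
#' sex-reversal flags; association score tables; per-population
#' between-sex F-statistics (the sample-size/F-statistics summary table);
#' Hardy-Weinberg and pairwise linkage-disequilibrium tests with
#' Bonferroni correction; X/Y phasing and XT/XN partition; the
#' chromosome-class diversity table; and (with three or more populations)
#' a Mantel test of linearised genetic distance against geography.
#'
#' @param config named list, or path to a YAML file, with entries:
#'   `genotypes` (Genepop path) and `metadata` (sample-table path), or
#'   alternatively `dataset` (an `xy_dataset` built in-session);
#'   `sex_linked_loci`, `autosomal_loci`; optional
#'   `classify_populations` (scope for allele classification, default: the
#'   WEST group if present, else all), `max_female_carriers` (2),
#'   `max_normal_carriers` (0), `min_discordant` (NULL = all informative
#'   loci), `n_perm` (5000), `n_mc_hwe` (1000), `seed`, `out_dir`.
#' @return (invisibly) a list with every stage result; files are written
#'   when `out_dir` is set.
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  log <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    say("stage %s", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  seed <- config$seed %||% 1L
  n_perm <- config$n_perm %||% 5000L
  n_mc <- config$n_mc_hwe %||% 1000L

  data <- stage("validate", {
    if (!is.null(config$dataset)) {
      stopifnot(inherits(config$dataset, "xy_dataset"))
      config$dataset
    } else {
      if (is.null(config$genotypes) || is.null(config$metadata))
        stop("config needs 'genotypes' and 'metadata' paths (or 'dataset')")
      if (!file.exists(config$metadata))
        stop("metadata file not found: ", config$metadata)
      if (!file.exists(config$genotypes))
        stop("genotype file not found: ", config$genotypes)
      geno <- read_genepop(config$genotypes,
                           null_sentinels = config$null_sentinels %||% list())
      meta <- read_sample_table(config$metadata)
      panel <- c(setNames(rep("SEX_LINKED", length(config$sex_linked_loci)),
                          config$sex_linked_loci),
                 setNames(rep("AUTOSOMAL", length(config$autosomal_loci)),
                          config$autosomal_loci))
      validate_dataset(geno, meta, locus_panel = panel)
    }
  })
  sl <- config$sex_linked_loci %||%
    names(data$locus_panel)[data$locus_panel == "SEX_LINKED"]
  au <- config$autosomal_loci %||%
    names(data$locus_panel)[data$locus_panel == "AUTOSOMAL"]
  scope <- config$classify_populations %||% {
    w <- unique(data$meta$population[data$meta$group == "WEST"])
    if (length(w)) w else unique(data$meta$population)
  }

  cls_sex <- stage("classify_sex", find_male_specific_alleles(
    data, populations = scope,
    max_female_carriers = config$max_female_carriers %||% 2, loci = sl))
  has_trans <- any(data$meta$karyotype == "TRANSLOCATED" &
                     data$meta$population %in% scope)
  cls_trans <- if (has_trans)
    stage("classify_translocation", find_translocation_specific_alleles(
      data, populations = scope,
      max_normal_carriers = config$max_normal_carriers %||% 0, loci = sl))
  else { say("no translocated individuals in scope; skipping stage"); NULL }

  flags <- stage("flag_reversals", flag_sex_discordant(
    data, cls_sex, fully_linked_loci = sl,
    min_discordant = config$min_discordant))

  assoc <- stage("score", {
    tab <- association_table(data, cls_sex, populations = scope, loci = sl)
    if (!is.null(cls_trans))
      tab <- rbind(tab, association_table(data, cls_trans,
                                          populations = scope, loci = sl))
    tab
  })

  fstats <- stage("fstats", {
    do.call(rbind, lapply(unique(data$meta$population), function(p) {
      sub <- subset_individuals(data, data$meta$population == p)
      if (length(unique(sub$meta$sex[sub$meta$sex != "UNKNOWN"])) < 2)
        return(NULL)
      fs <- fstat_weir_cockerham(sub, loci = sl, grouping = "sex",
                                 n_perm = n_perm, seed = seed + 11L)
      pick <- function(g) if (g %in% names(fs$fis_by_group))
        fs$fis_by_group[[g]] else NA_real_
      data.frame(population = p, fst = fs$fst,
                 fis_f = pick("F"), fis_m = pick("M"),
                 p_value = fs$p_value)
    }))
  })

  hwe <- stage("hwe", {
    do.call(rbind, lapply(unique(data$meta$population), function(p) {
      sel <- data$meta$population == p
      do.call(rbind, lapply(c(sl, au), function(loc) {
        pv <- hwe_exact_test(data$geno$a1[sel, loc], data$geno$a2[sel, loc],
                             n_mc = n_mc, seed = seed + 23L)
        data.frame(population = p, locus = loc, p = pv)
      }))
    }))
  })
  hwe$p_adj <- p.adjust(hwe$p, method = "bonferroni")

  ld <- stage("ld", if (length(sl) >= 2)
    ld_test_all(data, loci = sl, n_perm = min(n_perm, 999L),
                seed = seed + 37L)
    else NULL)

  phased <- stage("phase", phase_xy(data, cls_sex, loci = sl))
  if (!is.null(cls_trans))
    phased <- stage("partition", partition_x(phased, data, cls_trans))

  divers <- stage("diversity", {
    recs <- class_diversity(phased, data, autosomal_loci = au,
                            populations = scope)
    diversity_report(recs)
  })

  mantel <- stage("mantel", {
    pops <- unique(data$meta$population)
    if (length(pops) >= 3) {
      fstm <- pairwise_fst(data, loci = sl)
      mantel_test(fst_linearized(fstm), geo_distance_matrix(data$meta),
                  n_perm = n_perm, seed = seed + 53L)
    } else {
      say("fewer than 3 populations; Mantel test skipped")
      NULL
    }
  })

  bundle <- list(dataset = data, classification_sex = cls_sex,
                 classification_translocation = cls_trans,
                 flags = flags, association = assoc, fstats = fstats,
                 hwe = hwe, ld = ld, phased = phased,
                 diversity = divers, mantel = mantel, log = log,
                 seed = seed)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- function(f) file.path(config$out_dir, f)
    write_tsv(data$report$counts, od("sample_counts.tsv"))
    write_tsv(data$report$missingness, od("missingness.tsv"))
    write_tsv(cls_sex$support, od("male_specific_support.tsv"))
    if (!is.null(cls_trans))
      write_tsv(cls_trans$support, od("translocation_specific_support.tsv"))
    write_tsv(flags, od("sex_discordance_flags.tsv"))
    write_tsv(assoc, od("association_scores.tsv"))
    if (!is.null(fstats)) write_tsv(fstats, od("fstats_by_population.tsv"))
    write_tsv(hwe, od("hwe_tests.tsv"))
    if (!is.null(ld)) write_tsv(ld, od("ld_tests.tsv"))
    write_tsv(phased$copies, od("phased_copies.tsv"))
    write_tsv(as.data.frame(divers), od("diversity_table.tsv"))
    if (!is.null(mantel))
      write_tsv(data.frame(r = mantel$r, p_value = mantel$p_value,
                           n_permutations = mantel$n_permutations),
                od("mantel.tsv"))
    info <- c(sprintf("xylink %s | R %s",
                      as.character(utils::packageVersion("xylink")),
                      paste(R.version$major, R.version$minor, sep = ".")),
              sprintf("seed: %d | n_perm: %d | n_mc_hwe: %d",
                      seed, n_perm, n_mc),
              sprintf("max_female_carriers: %s | max_normal_carriers: %s",
                      config$max_female_carriers %||% 2,
                      config$max_normal_carriers %||% 0),
              log)
    writeLines(info, od("run_log.txt"))
  }
  invisible(bundle)
}
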