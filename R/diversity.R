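# Chromosome-class gene diversity under the stepwise mutation model and
# its comparison with the neutral 4:3:1 autosome:X:Y expectation.

#' Stepwise-mutation-model theta from gene diversity
#'
#' Under mutation-drift equilibrium with stepwise (single-repeat) mutation,
#' gene diversity and the scaled diversity \eqn{\theta = cN_e\mu} relate as
#' \deqn{\theta = \frac{1/(1-H_E)^2 - 1}{2},} strictly increasing on
#' \[0, 1) with \eqn{\theta \to \infty} as \eqn{H_E \to 1} (reported as
#' `Inf`).
#'
#' @param h_exp gene diversity in \[0, 1\] (vectorised).
#' @return theta >= 0, `Inf` where `h_exp == 1`.
#' @seealso [h_from_theta()] for the closed-form inverse.
#' @examples
#' theta_smm(0.5)            # 1.5
#' h_from_theta(theta_smm(0.68))
#' @export
theta_smm <- function(h_exp) {
  if (any(h_exp < 0 | h_exp > 1, na.rm = TRUE))
    stop("h_exp must lie in [0, 1]")
  ifelse(h_exp == 1, Inf, (1 / (1 - h_exp)^2 - 1) / 2)
}

#' Inverse of the SMM theta transform
#'
#' \eqn{H_E = 1 - 1/\sqrt{2\theta + 1}}; the exact inverse of
#' [theta_smm()].
#'
#' @param theta nonnegative scaled diversity (vectorised).
#' @export
h_from_theta <- function(theta) {
  if (any(theta < 0, na.rm = TRUE)) stop("theta must be >= 0")
  1 - 1 / sqrt(2 * theta + 1)
}

#' Expected class diversities under the neutral 4:3:1 ratio
#'
#' With equal effective size and mutation rate in both sexes, autosomes, X
#' and Y are present in 4:3:1 copies per breeding pair, so
#' \eqn{\theta_A : \theta_X : \theta_Y = 4:3:1} at neutral equilibrium.
#' Given observed \eqn{\theta_Y} and \eqn{\theta_X}, the consensus
#' expectations that preserve their sum are
#' \deqn{E(\theta_Y) = (\theta_Y+\theta_X)/4, \quad
#'       E(\theta_X) = 3(\theta_Y+\theta_X)/4,}
#' and the 4-unit total implies \eqn{E(\theta_A) = \theta_Y+\theta_X}.
#' Departures of the observed values from these expectations diagnose a
#' class-specific reduction of effective size (e.g. on a non-recombining
#' Y).
#'
#' @param theta_y,theta_x observed finite nonnegative thetas (vectorised).
#' @return data.frame with columns `e_theta_y`, `e_theta_x`, `e_theta_a`.
#' @examples
#' expected_class_theta(0.21, 1.96)  # 0.5425, 1.6275, 2.17
#' @export
expected_class_theta <- function(theta_y, theta_x) {
  if (any(theta_y < 0 | theta_x < 0, na.rm = TRUE))
    stop("theta values must be >= 0")
  if (any(!is.finite(theta_y) | !is.finite(theta_x)))
    stop("theta values must be finite")
  s <- theta_y + theta_x
  data.frame(e_theta_y = s / 4, e_theta_x = 3 * s / 4, e_theta_a = s)
}

# copies-per-breeding-pair constant for each chromosome class
class_copies <- c(A = 4, X = 3, XT = 3, XN = 3, Y = 1)

#' Per-population chromosome-class diversity
#'
#' Pools phased allele copies per population and chromosome class, computes
#' the unbiased gene diversity of the pool at each locus, converts it to
#' SMM theta, and averages theta over loci within each population x class
#' — the per-class analogue of a per-population diversity table. Classes:
#' `Y` (phased Y copies), `X` (all X-labelled copies: plain X plus XT and
#' XN), `XT`, `XN` (only if [partition_x()] was run), and `A` (both copies
#' of the autosomal loci from all individuals). UNPHASED copies are
#' excluded, never imputed; a locus contributes to a class mean only where
#' the pool holds at least 2 copies.
#'
#' @param phased a `phased_haplotypes`.
#' @param data the matching `xy_dataset`.
#' @param autosomal_loci loci for class A; default: loci tagged
#'   `AUTOSOMAL` in the dataset panel.
#' @param populations subset of populations (default: all with phased
#'   copies).
#' @param unbiased use Nei's sample-size-corrected gene diversity
#'   (default) or the plain \eqn{1-\sum p^2}.
#' @param average if `FALSE`, return the per-locus records instead of the
#'   per-population locus averages.
#' @param combine how to combine loci into a class theta:
#'   `"mean_theta"` (default) averages per-locus thetas — the display
#'   convention of per-population survey tables, robust for reporting but
#'   upward-biased as an estimator because theta is convex in H;
#'   `"theta_of_mean_h"` applies [theta_smm()] to the mean per-locus gene
#'   diversity, the consistent choice when recovering an equilibrium
#'   \eqn{c N_e \mu} from simulated data.
#' @return data.frame `population, cls, h_exp, theta, n_copies, n_loci, c`
#'   (averaged), or `population, cls, locus, h_exp, theta, n_copies, c`
#'   (per locus). `c` is the copies-per-breeding-pair constant of the
#'   class. Empty or single-copy pools yield `NA` records.
#' @export
class_diversity <- function(phased, data, autosomal_loci = NULL,
                            populations = NULL, unbiased = TRUE,
                            average = TRUE,
                            combine = c("mean_theta", "theta_of_mean_h")) {
  stopifnot(inherits(phased, "phased_haplotypes"),
            inherits(data, "xy_dataset"))
  combine <- match.arg(combine)
  autosomal_loci <- autosomal_loci %||%
    names(data$locus_panel)[data$locus_panel == "AUTOSOMAL"]
  pops <- populations %||% unique(data$meta$population)
  cp <- phased$copies
  x_like <- c("X", "XT", "XN")
  recs <- list()
  add <- function(pop, cls, locus, copies) {
    n <- length(copies)
    h <- if (n >= 2) expected_heterozygosity(table(copies), unbiased = unbiased)
    else NA_real_
    recs[[length(recs) + 1L]] <<- data.frame(
      population = pop, cls = cls, locus = locus,
      h_exp = h, theta = if (is.na(h)) NA_real_ else theta_smm(h),
      n_copies = n, c = unname(class_copies[cls]))
  }
  for (pop in pops) {
    sub <- cp[cp$population == pop, , drop = FALSE]
    for (loc in phased$loci) {
      d <- sub[sub$locus == loc, , drop = FALSE]
      add(pop, "Y", loc, d$allele[d$class == "Y"])
      add(pop, "X", loc, d$allele[d$class %in% x_like])
      if (phased$partitioned) {
        add(pop, "XT", loc, d$allele[d$class == "XT"])
        add(pop, "XN", loc, d$allele[d$class == "XN"])
      }
    }
    in_pop <- data$meta$population == pop
    for (loc in autosomal_loci)
      add(pop, "A", loc, allele_copies(data$geno, loc, in_pop))
  }
  per_locus <- do.call(rbind, recs)
  rownames(per_locus) <- NULL
  if (!average) return(per_locus)
  agg <- do.call(rbind, lapply(
    split(per_locus, list(per_locus$population, per_locus$cls), drop = TRUE),
    function(d) {
      use <- !is.na(d$theta)
      h_bar <- if (any(use)) mean(d$h_exp[use]) else NA_real_
      th <- if (!any(use)) NA_real_
      else if (combine == "mean_theta") mean(d$theta[use])
      else theta_smm(h_bar)
      data.frame(population = d$population[1], cls = d$cls[1],
                 h_exp = h_bar, theta = th,
                 n_copies = if (any(use)) mean(d$n_copies[use]) else 0,
                 n_loci = sum(use), c = d$c[1])
    }))
  rownames(agg) <- NULL
  agg
}

#' Assemble the per-population diversity report table
#'
#' Wide per-population table of observed class thetas, the neutral-ratio
#' expectations from [expected_class_theta()], the X:Y and A:X ratio
#' columns (rendered `Inf` over a zero denominator), and an `Average` row
#' of arithmetic column means — the standard summary layout for comparing
#' chromosome-class diversity against the 4:3:1 neutral expectation.
#'
#' @param records averaged output of [class_diversity()] (must contain
#'   classes Y, X and A per population; XT/XN optional).
#' @param digits if non-NULL, round the numeric columns with
#'   [round_half_up()] (2 is the conventional display precision).
#' @return data.frame of class `diversity_table`, one row per population
#'   plus `Average`.
#' @export
diversity_report <- function(records, digits = NULL) {
  need <- c("Y", "X", "A")
  pops <- unique(records$population)
  get <- function(pop, cls) {
    v <- records$theta[records$population == pop & records$cls == cls]
    if (length(v)) v[1] else NA_real_
  }
  out <- do.call(rbind, lapply(pops, function(p) {
    ty <- get(p, "Y"); tx <- get(p, "X"); ta <- get(p, "A")
    if (any(is.na(c(ty, tx))))
      stop("missing Y or X theta record for population ", p)
    ex <- expected_class_theta(ty, tx)
    data.frame(population = p, theta_Y = ty, theta_X = tx, theta_A = ta,
               e_theta_Y = ex$e_theta_y, e_theta_X = ex$e_theta_x,
               e_theta_A = ex$e_theta_a,
               theta_XT = get(p, "XT"), theta_XN = get(p, "XN"),
               ratio_X_Y = if (ty == 0) Inf else tx / ty,
               ratio_A_X = if (is.na(ta)) NA_real_
               else if (tx == 0) Inf else ta / tx)
  }))
  num <- names(out)[-1]
  avg <- data.frame(population = "Average",
                    t(colMeans(out[num], na.rm = TRUE)))
  names(avg) <- names(out)
  # ratio averages over finite rows only (an Inf row would swamp the mean)
  avg$ratio_X_Y <- mean(out$ratio_X_Y[is.finite(out$ratio_X_Y)])
  avg$ratio_A_X <- mean(out$ratio_A_X[is.finite(out$ratio_A_X)])
  out <- rbind(out, avg)
  rownames(out) <- NULL
  if (!is.null(digits))
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  class(out) <- c("diversity_table", "data.frame")
  out
}
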