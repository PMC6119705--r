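#' Construct a diploid genotype matrix
#'
#' The canonical in-memory genotype container: two aligned integer matrices
#' holding the unordered allele pair of each (individual, locus) call.
#' Allele codes are positive integers (microsatellite fragment sizes in bp);
#' a missing call has `NA` in both matrices. Within-pair order carries no
#' meaning, so pairs are stored sorted. Amplification-null alleles that were
#' scored as a sentinel size (e.g. 499) are declared per locus in
#' `null_sentinels` and treated as ordinary alleles by every downstream
#' frequency computation.
#'
#' @param a1,a2 integer matrices (individuals x loci) with row and column
#'   names; `a1[i, l]` and `a2[i, l]` are the two allele copies.
#' @param null_sentinels named list, locus -> integer vector of sentinel
#'   allele codes standing for amplification nulls.
#' @param populations optional character vector (one per individual) of
#'   population labels, e.g. as recovered from Genepop "Pop" blocks.
#' @return an object of class `geno_matrix`.
#' @export
genotype_matrix <- function(a1, a2, null_sentinels = list(),
                            populations = NULL) {
  stopifnot(is.matrix(a1), is.matrix(a2), identical(dim(a1), dim(a2)))
  if (is.null(rownames(a1)) || is.null(colnames(a1)))
    stop("a1 must carry individual (row) and locus (column) names")
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  dimnames(a2) <- dimnames(a1)
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing calls at ", sum(half), " cell(s): both alleles of a ",
         "call must be present or both missing")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele codes must be positive integers")
  if (anyDuplicated(rownames(a1)))
    stop("duplicate individual ids: ",
         paste(unique(rownames(a1)[duplicated(rownames(a1))]), collapse = ", "))
  # unordered pair: store sorted
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  if (!is.null(populations)) {
    stopifnot(length(populations) == nrow(a1))
    populations <- as.character(populations)
  }
  bad_null <- setdiff(names(null_sentinels), colnames(a1))
  if (length(bad_null))
    stop("null_sentinels name unknown loci: ", paste(bad_null, collapse = ", "))
  structure(
    list(individuals = rownames(a1), loci = colnames(a1),
         a1 = lo, a2 = hi,
         null_sentinels = null_sentinels, populations = populations),
    class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat(sprintf("geno_matrix: %d individuals x %d loci (%.1f%% missing calls)\n",
              length(x$individuals), length(x$loci), 100 * miss))
  if (length(x$null_sentinels))
    cat("null sentinels:",
        paste(sprintf("%s=%s", names(x$null_sentinels),
                      vapply(x$null_sentinels, paste, "", collapse = "/")),
              collapse = ", "), "\n")
  invisible(x)
}

#' Read a Genepop genotype file
#'
#' Parses the classic Genepop dialect: a title line, locus names (one per
#' line or comma-separated on one line), then one `Pop` block per
#' population, each individual on one line as
#' `id ,  AAABBB AAABBB ...` with 2- or 3-digits-per-allele diploid codes.
#' The allele width is auto-detected per file from the genotype field
#' widths. Code 0 (`0000`/`000000`) decodes to a missing call.
#'
#' @param path path to a Genepop text file.
#' @param null_sentinels passed through to [genotype_matrix()].
#' @return a [genotype_matrix()] with per-individual population labels
#'   (`pop_1`, `pop_2`, ... in file order).
#' @seealso [write_genepop()]
#' @export
read_genepop <- function(path, null_sentinels = list()) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("Genepop parse error: file too short")
  lines_trim <- trimws(lines)
  is_pop <- toupper(lines_trim) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop))
    stop("Genepop parse error: no 'Pop' line found")
  # loci: lines 2 .. first_pop-1, possibly comma-separated
  loci <- unlist(strsplit(lines_trim[2:(first_pop - 1)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("Genepop parse error: no locus names before 'Pop'")

  ids <- character(0); pops <- character(0)
  geno_fields <- list()
  pop_i <- 0L
  pop_start_line <- NA_integer_
  for (i in seq(first_pop, length(lines))) {
    lt <- lines_trim[i]
    if (!nzchar(lt)) next
    if (toupper(lt) == "POP") {
      if (pop_i > 0L && !any(pops == paste0("pop_", pop_i)))
        stop("Genepop parse error: empty Pop block starting at line ",
             pop_start_line)
      pop_i <- pop_i + 1L
      pop_start_line <- i
      next
    }
    halves <- strsplit(lt, ",")[[1]]
    if (length(halves) < 2)
      stop("Genepop parse error at line ", i, ": expected 'id , genotypes'")
    id <- trimws(halves[1])
    fields <- strsplit(trimws(paste(halves[-1], collapse = ",")),
                       "[[:space:]]+")[[1]]
    if (length(fields) != length(loci))
      stop("Genepop parse error at line ", i, ": individual '", id, "' has ",
           length(fields), " genotype fields, expected ", length(loci))
    if (!all(grepl("^[0-9]+$", fields)))
      stop("Genepop parse error at line ", i, ": non-numeric genotype field")
    ids <- c(ids, id)
    pops <- c(pops, paste0("pop_", pop_i))
    geno_fields[[length(geno_fields) + 1L]] <- fields
  }
  if (pop_i > 0L && !any(pops == paste0("pop_", pop_i)))
    stop("Genepop parse error: empty Pop block starting at line ",
         pop_start_line)
  widths <- unique(nchar(unlist(geno_fields)))
  if (length(widths) != 1L || !widths %in% c(4L, 6L))
    stop("Genepop parse error: malformed allele width; genotype fields must ",
         "be uniformly 4 (2-digit alleles) or 6 (3-digit) characters, found ",
         "widths: ", paste(sort(widths), collapse = ", "))
  aw <- widths / 2L
  n <- length(ids); L <- length(loci)
  a1 <- matrix(NA_integer_, n, L, dimnames = list(ids, loci))
  a2 <- a1
  for (j in seq_len(n)) {
    f <- geno_fields[[j]]
    x1 <- as.integer(substr(f, 1L, aw))
    x2 <- as.integer(substr(f, aw + 1L, 2L * aw))
    x1[x1 == 0L] <- NA_integer_
    x2[x2 == 0L] <- NA_integer_
    miss <- is.na(x1) | is.na(x2)  # partial code 0 treated as missing call
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[j, ] <- x1; a2[j, ] <- x2
  }
  genotype_matrix(a1, a2, null_sentinels = null_sentinels, populations = pops)
}

#' Write a genotype matrix in Genepop format
#'
#' Always emits the 3-digit-per-allele encoding, since microsatellite
#' fragment sizes exceed 99 bp. Individuals are grouped into `Pop` blocks
#' by their population label (file order follows label order of appearance);
#' without labels a single block is written.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gm, path, title = "xylink export") {
  stopifnot(inherits(gm, "geno_matrix"))
  if (any(gm$a1 > 999L, na.rm = TRUE) || any(gm$a2 > 999L, na.rm = TRUE))
    stop("allele codes above 999 cannot be written as 3-digit Genepop")
  pops <- gm$populations %||% rep("pop_1", length(gm$individuals))
  enc <- function(v) ifelse(is.na(v), "000", sprintf("%03d", v))
  out <- c(title, gm$loci)
  for (p in unique(pops)) {
    out <- c(out, "Pop")
    for (j in which(pops == p)) {
      fields <- paste0(enc(gm$a1[j, ]), enc(gm$a2[j, ]))
      out <- c(out, paste(gm$individuals[j], ",", paste(fields, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
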