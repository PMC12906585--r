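#' Construct a 3x3 joint genotype count table
#'
#' The sufficient statistic for all pairwise recombination estimators: cell
#' `[i, j]` counts individuals with allele-count code `i - 1` at the first
#' locus and `j - 1` at the second (rows and columns ordered 0, 1, 2).
#'
#' @param m 3x3 matrix of non-negative integer counts.
#' @return An object of class `joint_count_table` (a 3x3 integer matrix); the
#'   total count is available as `sum(x)`.
#' @export
joint_count_table <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L))) stop("joint count table must be 3x3")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  storage.mode(m) <- "double"
  dimnames(m) <- list(XA = 0:2, XB = 0:2)
  structure(m, class = c("joint_count_table", "matrix", "array"))
}

#' Tally a joint count table from two genotype code vectors
#'
#' Only pairwise-complete entries (both codes non-missing) are counted.
#'
#' @param gA,gB equal-length vectors of codes in 0, 1, 2 or `NA`.
#' @return A [joint_count_table()].
#' @export
build_joint_table <- function(gA, gB) {
  if (length(gA) != length(gB)) stop("genotype vectors must have equal length")
  if (any(!is.na(gA) & !(gA %in% 0:2)) || any(!is.na(gB) & !(gB %in% 0:2)))
    stop("genotype codes must be 0, 1, 2 or NA")
  keep <- !is.na(gA) & !is.na(gB)
  if (!any(keep)) stop("no pairwise-complete genotype pairs: estimation impossible")
  tab <- table(factor(gA[keep], levels = 0:2), factor(gB[keep], levels = 0:2))
  joint_count_table(unclass(tab))
}

#' Read a joint count table from a 3-line TSV
#'
#' Three rows of three integers; rows are the first locus codes 0, 1, 2 and
#' columns the second locus codes 0, 1, 2.
#'
#' @param path file path.
#' @return A [joint_count_table()].
#' @export
read_joint_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  joint_count_table(m)
}

#' Collapse a joint count table to dominant-marker phenotype counts
#'
#' Assumes both loci are dominant in coupling phase: any individual carrying
#' at least one reference allele at a locus shows the dominant phenotype, so
#' the nine genotype classes collapse to four phenotype classes.
#'
#' @param t a [joint_count_table()].
#' @return A list of class `phenotype_counts` with components `n_AB`, `n_Ab`,
#'   `n_aB`, `n_ab`.
#' @export
collapse_to_phenotypes <- function(t) {
  m <- unclass(t)
  out <- list(n_AB = sum(m[2:3, 2:3]), n_Ab = sum(m[2:3, 1]),
              n_aB = sum(m[1, 2:3]), n_ab = m[1, 1])
  structure(out, class = "phenotype_counts")
}

#' Construct phenotype counts directly
#' @param n_AB,n_Ab,n_aB,n_ab non-negative counts of the four dominant-marker
#'   phenotype classes (both dominant, first only, second only, neither).
#' @return A list of class `phenotype_counts`.
#' @export
phenotype_counts <- function(n_AB, n_Ab, n_aB, n_ab) {
  v <- c(n_AB, n_Ab, n_aB, n_ab)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
    stop("phenotype counts must be non-negative integers")
  structure(list(n_AB = n_AB, n_Ab = n_Ab, n_aB = n_aB, n_ab = n_ab),
            class = "phenotype_counts")
}

#' @export
print.phenotype_counts <- function(x, ...) {
  cat(sprintf("phenotype counts: AB=%g Ab=%g aB=%g ab=%g (n=%g)\n",
              x$n_AB, x$n_Ab, x$n_aB, x$n_ab, x$n_AB + x$n_Ab + x$n_aB + x$n_ab))
  invisible(x)
}
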