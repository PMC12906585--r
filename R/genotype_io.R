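#' Construct a genotype matrix
#'
#' A genotype matrix holds allele-count codes for a biparental selfing
#' population: for each marker, 0/1/2 counts the alleles inherited from the
#' designated reference parent (heterozygotes are always 1). Missing genotypes
#' are `NA`.
#'
#' @param values integer matrix, individuals in rows and markers in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param individual_ids,marker_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @param generation_t selfing generation (2 for an F2); `NA` when unknown.
#' @return An object of class `genotype_matrix`: the validated integer matrix
#'   with dimnames and a `generation_t` attribute.
#' @export
genotype_matrix <- function(values, individual_ids = rownames(values),
                            marker_ids = colnames(values),
                            generation_t = NA_integer_) {
  values <- as.matrix(values)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(values)))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(values)))
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids")
  if (length(individual_ids) != nrow(values) || length(marker_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & !(values %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype code at individual '%s', marker '%s'",
                 individual_ids[idx[1L]], marker_ids[idx[2L]]))
  }
  if (!is.na(generation_t) && generation_t < 2) stop("generation_t must be >= 2")
  dimnames(values) <- list(individual_ids, marker_ids)
  structure(values, generation_t = as.integer(generation_t),
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (generation t = %s)\n",
              nrow(x), ncol(x),
              ifelse(is.na(attr(x, "generation_t")), "unknown", attr(x, "generation_t"))))
  cat(sprintf("missing genotypes: %d\n", sum(is.na(x))))
  invisible(x)
}

#' Read a genotype table
#'
#' Reads a delimited table whose header row contains marker ids and whose
#' first column contains individual ids. Cells must be 0, 1, 2, empty or
#' "NA" (case-insensitive); anything else is a parse error naming the cell.
#'
#' @param path file path.
#' @param sep field separator; tab by default, use `","` for CSV.
#' @param generation_t optional selfing generation recorded on the result.
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path, sep = "\t", generation_t = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", row.names = NULL,
                           stringsAsFactors = FALSE, na.strings = NULL)
  if (ncol(raw) < 2L) stop("genotype table needs an id column and at least one marker")
  ind <- raw[[1L]]
  markers <- colnames(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  clean <- trimws(vals)
  is_miss <- clean == "" | toupper(clean) == "NA"
  ok <- is_miss | clean %in% c("0", "1", "2")
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("malformed genotype '%s' at row '%s' (individual '%s'), column '%s'",
                 clean[idx[1L], idx[2L]], idx[1L], ind[idx[1L]], markers[idx[2L]]))
  }
  out <- suppressWarnings(matrix(as.integer(clean), nrow = nrow(clean)))
  out[is_miss] <- NA_integer_
  genotype_matrix(out, individual_ids = ind, marker_ids = markers,
                  generation_t = generation_t)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; missing genotypes are written as "NA".
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param sep field separator (tab by default).
#' @export
write_genotype_table <- function(g, path, sep = "\t") {
  df <- data.frame(id = rownames(g), unclass(g), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Construct a marker map
#'
#' @param id,chromosome,position_bp parallel vectors: marker id, chromosome
#'   label and 1-based physical position. Positions must be strictly
#'   increasing within each chromosome in the supplied order.
#' @param position_cm optional genetic positions in centimorgans.
#' @return A data frame of class `marker_map`.
#' @export
marker_map <- function(id, chromosome, position_bp, position_cm = NULL) {
  df <- data.frame(id = as.character(id), chromosome = as.character(chromosome),
                   position_bp = as.numeric(position_bp), stringsAsFactors = FALSE)
  if (!is.null(position_cm)) df$position_cm <- as.numeric(position_cm)
  if (anyDuplicated(df$id)) stop("duplicate marker ids in map")
  if (any(df$position_bp < 0, na.rm = TRUE)) stop("positions must be >= 0")
  for (chr in unique(df$chromosome)) {
    p <- df$position_bp[df$chromosome == chr]
    if (any(diff(p) <= 0)) {
      off <- df$id[df$chromosome == chr][which(diff(p) <= 0) + 1L]
      stop(sprintf("positions not strictly increasing on chromosome %s: %s",
                   chr, paste(off, collapse = ", ")))
    }
  }
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Read a marker map
#'
#' TSV with columns `id`, `chromosome`, `position_bp` and optionally
#' `position_cm`; file order defines marker order within chromosomes.
#'
#' @param path file path.
#' @return A [marker_map()].
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "chromosome", "position_bp")
  if (!all(need %in% colnames(df)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  marker_map(df$id, df$chromosome, df$position_bp,
             position_cm = if ("position_cm" %in% colnames(df)) df$position_cm)
}

#' Write a marker map
#' @param map a [marker_map()].
#' @param path output file path.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))

#' Write a linkage map
#'
#' Writes a per-marker TSV with columns `chromosome`, `marker`,
#' `theta_to_next`, `se_theta`, `cm_to_next`, `cm_cumulative`. The last
#' marker of each chromosome has empty interval fields. Numeric fields use a
#' fixed 10-significant-digit format, so write / read / write is idempotent.
#'
#' @param map a `linkage_map` as returned by [assemble_map()].
#' @param path output file path.
#' @export
write_linkage_map <- function(map, path) {
  cols <- c("chromosome", "marker", "theta_to_next", "se_theta",
            "cm_to_next", "cm_cumulative")
  df <- as.data.frame(map)[, cols, drop = FALSE]
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(df)) paste(df$chromosome, df$marker,
                                 .fmt_num(df$theta_to_next), .fmt_num(df$se_theta),
                                 .fmt_num(df$cm_to_next), .fmt_num(df$cm_cumulative),
                                 sep = "\t"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a linkage map written by [write_linkage_map()]
#' @param path file path.
#' @return A data frame of class `linkage_map`.
#' @export
read_linkage_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c("character", "character", rep("character", 4)))
  num <- function(v) ifelse(trimws(v) == "", NA_real_, as.numeric(v))
  out <- data.frame(chromosome = df$chromosome, marker = df$marker,
                    theta_to_next = num(df$theta_to_next),
                    se_theta = num(df$se_theta),
                    cm_to_next = num(df$cm_to_next),
                    cm_cumulative = num(df$cm_cumulative),
                    stringsAsFactors = FALSE)
  class(out) <- c("linkage_map", "data.frame")
  out
}
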