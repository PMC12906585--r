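#' Haldane mapping function
#'
#' Converts a recombination fraction into additive genetic distance under no
#' crossover interference: `d = -50 * log(1 - 2 * theta)` centimorgans. The
#' function diverges at `theta = 0.5`; estimates at or above `cap` are mapped
#' to the distance at `cap` and flagged via the `"capped"` attribute.
#'
#' @param theta recombination fraction(s) in `[0, 0.5]`.
#' @param cap clamp point just below the singularity (default 0.4999).
#' @return Distances in cM with a logical attribute `"capped"`.
#' @export
haldane_cm <- function(theta, cap = 0.4999) {
  if (any(is.na(theta)) || any(theta < 0) || any(theta > 0.5))
    stop("theta must be in [0, 0.5]")
  capped <- theta >= cap
  d <- -50 * log(1 - 2 * pmin(theta, cap))
  structure(d, capped = capped)
}

#' Inverse Haldane mapping function
#'
#' @param d distance(s) in cM, `d >= 0`.
#' @return Recombination fraction(s) `theta = (1 - exp(-2d/100)) / 2`.
#' @export
haldane_theta <- function(d) {
  if (any(is.na(d)) || any(d < 0)) stop("distance must be >= 0")
  (1 - exp(-2 * d / 100)) / 2
}

#' Estimate recombination fractions between adjacent markers
#'
#' Sweeps every within-chromosome adjacent marker pair of a genotype matrix
#' (marker order taken from the map) with the chosen estimator. Pairs whose
#' preconditions fail (e.g. a monomorphic margin) are recorded as failed with
#' the reason, never dropped silently.
#'
#' @param g a [genotype_matrix()].
#' @param map a [marker_map()] whose ids cover the columns of `g`.
#' @param method one of `"pcorr"`, `"em_codominant"`, `"em_dominant"` (the
#'   short tags `"emcd"` / `"emd"` are accepted).
#' @param opts an [em_options()] list for the EM methods.
#' @return A data frame of class `adjacent_estimates`: one row per adjacent
#'   pair with `chromosome`, `left`, `right`, `theta`, `se`, `n`, `clamped`,
#'   `converged`, `failed`, `reason`.
#' @export
estimate_adjacent <- function(g, map, method = c("pcorr", "em_codominant",
                                                 "em_dominant", "emcd", "emd"),
                              opts = em_options()) {
  method <- match.arg(method)
  method <- switch(method, emcd = "em_codominant", emd = "em_dominant", method)
  if (!all(map$id %in% colnames(g)))
    stop("marker map contains ids absent from the genotype matrix")
  rows <- list()
  for (chr in unique(map$chromosome)) {
    ids <- map$id[map$chromosome == chr]
    if (length(ids) < 2) next
    for (k in seq_len(length(ids) - 1L)) {
      left <- ids[k]; right <- ids[k + 1L]
      est <- tryCatch({
        tab <- build_joint_table(g[, left], g[, right])
        switch(method,
               pcorr = estimate_pcorr(tab),
               em_codominant = estimate_em_codominant(tab, opts),
               em_dominant = estimate_em_dominant(collapse_to_phenotypes(tab), opts))
      }, error = function(e) e)
      if (inherits(est, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chr, left = left, right = right, theta = NA_real_,
          se = NA_real_, n = NA_real_, clamped = NA, converged = NA,
          failed = TRUE, reason = conditionMessage(est), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chr, left = left, right = right, theta = est$theta,
          se = est$se, n = est$n, clamped = est$clamped,
          converged = est$converged, failed = FALSE, reason = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(), left = character(), right = character(),
               theta = double(), se = double(), n = double(), clamped = logical(),
               converged = logical(), failed = logical(), reason = character(),
               stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("adjacent_estimates", "data.frame")
  out
}

#' Assemble a linkage map from adjacent-pair estimates
#'
#' Converts each adjacent `theta` to Haldane centimorgans and accumulates
#' positions per chromosome, starting at 0. Estimates at the `theta = 0.5`
#' singularity are capped and flagged; failed pairs contribute 0 cM and keep
#' their flag so a chromosome is never aborted by an isolated failure.
#'
#' @param est an `adjacent_estimates` data frame from [estimate_adjacent()].
#' @param cap singularity clamp passed to [haldane_cm()].
#' @return A data frame of class `linkage_map`: one row per marker with
#'   `chromosome`, `marker`, `theta_to_next`, `se_theta`, `cm_to_next`,
#'   `cm_cumulative`, `capped`, `failed` (interval fields are `NA` on the
#'   last marker of each chromosome).
#' @export
assemble_map <- function(est, cap = 0.4999) {
  rows <- list()
  for (chr in unique(est$chromosome)) {
    e <- est[est$chromosome == chr, , drop = FALSE]
    markers <- c(e$left, e$right[nrow(e)])
    theta <- e$theta
    ok <- !e$failed & !is.na(theta)
    cm <- numeric(nrow(e))
    capped <- logical(nrow(e))
    if (any(ok)) {
      d <- haldane_cm(theta[ok], cap = cap)
      cm[ok] <- as.numeric(d)
      capped[ok] <- attr(d, "capped")
    }
    cum <- c(0, cumsum(cm))
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = chr, marker = markers,
      theta_to_next = c(theta, NA_real_), se_theta = c(e$se, NA_real_),
      cm_to_next = c(cm, NA_real_), cm_cumulative = cum,
      capped = c(capped, NA), failed = c(e$failed, NA),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(), marker = character(),
               theta_to_next = double(), se_theta = double(),
               cm_to_next = double(), cm_cumulative = double(),
               capped = logical(), failed = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("linkage_map", "data.frame")
  out
}

#' Total map length per chromosome
#' @param map a `linkage_map`.
#' @return Named numeric vector of chromosome lengths in cM.
#' @export
map_lengths <- function(map) {
  vapply(split(map$cm_to_next, map$chromosome),
         function(v) sum(v, na.rm = TRUE), numeric(1))
}

#' Compare two sets of adjacent-pair estimates
#'
#' Agreement summary between two estimation methods (or two generations) on
#' the same marker pairs: Pearson correlation of the theta vectors, mean
#' absolute difference, and a per-chromosome breakdown. Only pairs where both
#' estimates succeeded enter the summary.
#'
#' @param a,b `adjacent_estimates` data frames over identical marker pairs.
#' @return A list with `R` (pooled correlation of estimates), `mad`,
#'   `n_pairs`, and `per_chromosome` (data frame with the same quantities by
#'   chromosome).
#' @export
compare_methods <- function(a, b) {
  key_a <- paste(a$chromosome, a$left, a$right)
  key_b <- paste(b$chromosome, b$left, b$right)
  if (!identical(key_a, key_b)) stop("estimates cover different marker pairs")
  ok <- !a$failed & !b$failed & !is.na(a$theta) & !is.na(b$theta)
  if (sum(ok) < 2) stop("fewer than 2 commonly estimated pairs")
  x <- a$theta[ok]; y <- b$theta[ok]
  per <- do.call(rbind, lapply(split(seq_along(x), a$chromosome[ok]), function(idx) {
    data.frame(R = if (length(idx) >= 2 && stats::sd(x[idx]) > 0 && stats::sd(y[idx]) > 0)
                     stats::cor(x[idx], y[idx]) else NA_real_,
               mad = mean(abs(x[idx] - y[idx])), n_pairs = length(idx))
  }))
  per <- data.frame(chromosome = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(R = stats::cor(x, y), mad = mean(abs(x - y)), n_pairs = sum(ok),
       per_chromosome = per)
}
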