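# Exact mate-allocation combinatorics. The number of ways to assign d dams
# to s labeled sires, v = d/s dams each, is d!/(v!)^s — the product of the
# binomials choose(v, v) * choose(2v, v) * ... * choose(d, v). Counts beyond
# 2^53 get an exact digit string from a small base-10000 big-integer
# multiply.

# big integers as little-endian base-1e4 limb vectors
.big_from_int <- function(x) {
  limbs <- integer(0)
  while (x > 0) {
    limbs <- c(limbs, x %% 10000)
    x <- x %/% 10000
  }
  if (!length(limbs)) limbs <- 0
  limbs
}

.big_mul <- function(a, b) {
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  carry <- 0
  for (k in seq_along(out)) {
    v <- out[k] + carry
    out[k] <- v %% 10000
    carry <- v %/% 10000
  }
  while (carry > 0) {
    out <- c(out, carry %% 10000)
    carry <- carry %/% 10000
  }
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

.big_to_string <- function(a) {
  a <- rev(a)  # big-endian limbs; pad all but the leading one
  paste0(c(as.character(a[1]), sprintf("%04d", a[-1])), collapse = "")
}

#' Count mating schemes exactly
#'
#' With `s` sires, `d` dams and each sire assigned `v = d/s` dams, the number
#' of distinct allocations is `d! / (v!)^s`. Computed exactly as a product of
#' binomial coefficients; the exact decimal digit string is attached as the
#' `"digits"` attribute (big-integer arithmetic), and the returned numeric is
#' the double-precision value.
#'
#' @param d number of dams.
#' @param s number of sires; must divide `d`.
#' @return Numeric count with attribute `"digits"` (exact decimal string).
#' @export
count_mating_schemes <- function(d, s) {
  if (s < 1 || d < 1) stop("d and s must be >= 1")
  if (d %% s != 0) stop("d must be divisible by s")
  v <- d %/% s
  factors <- choose(seq(v, d, by = v), v)
  big <- .big_from_int(1)
  for (f in factors) big <- .big_mul(big, .big_from_int(round(f)))
  structure(prod(factors), digits = .big_to_string(big))
}

#' Enumerate all mating schemes
#'
#' All distinct assignments of `d` dams into `s` labeled sire groups of size
#' `v = d/s`, in lexicographic order of the group combinations (sire 1's
#' group varies slowest). Each row of the result lists the dam indices, the
#' first `v` columns belonging to sire 1, the next `v` to sire 2, and so on.
#'
#' @param d number of dams.
#' @param s number of sires; must divide `d`.
#' @param cap refuse enumeration beyond this many schemes.
#' @return Integer matrix with `count_mating_schemes(d, s)` rows and `d`
#'   columns.
#' @export
enumerate_mating_schemes <- function(d, s, cap = 1e6) {
  n_total <- count_mating_schemes(d, s)
  if (n_total > cap)
    stop(sprintf("%.3g schemes exceed the enumeration cap (%g); raise `cap` to force",
                 n_total, cap))
  v <- d %/% s
  recurse <- function(remaining, groups_left) {
    if (groups_left == 1L) return(matrix(remaining, nrow = 1))
    combos <- utils::combn(remaining, v)
    parts <- lapply(seq_len(ncol(combos)), function(j) {
      head_grp <- combos[, j]
      rest <- recurse(setdiff(remaining, head_grp), groups_left - 1L)
      cbind(matrix(head_grp, nrow(rest), v, byrow = TRUE), rest)
    })
    do.call(rbind, parts)
  }
  out <- recurse(seq_len(d), s)
  storage.mode(out) <- "integer"
  out
}

#' Exhaustive search for the best mating scheme
#'
#' Scores every allocation of the `d` dams to the `s` sires by the mean of
#' its `d` assigned cross values, returns the argmax (ties broken by the
#' lowest scheme index in the canonical enumeration order), and the relative
#' gain of the best scheme over the average scheme,
#' `gain = (best - average) / average * 100` percent. Because every cross
#' appears equally often across schemes, the all-scheme average equals the
#' mean of the full cross-value table.
#'
#' @param cross_values `s` x `d` matrix of expected progeny values
#'   (`cross_values[i, j]` = sire i crossed to dam j).
#' @param d,s numbers of dams and sires (must match the table dimensions).
#' @param cap enumeration cap passed to [enumerate_mating_schemes()].
#' @return A list of class `mating_search`: `best_index`, `best_scheme`
#'   (integer matrix `s` x `v` of dam indices per sire), `best_value`,
#'   `average_value`, `gain_percent`, `scheme_values`.
#' @export
search_best_scheme <- function(cross_values, d = ncol(cross_values),
                               s = nrow(cross_values), cap = 1e6) {
  if (nrow(cross_values) != s || ncol(cross_values) != d)
    stop("cross_values must be an s x d matrix")
  schemes <- enumerate_mating_schemes(d, s, cap = cap)
  v <- d %/% s
  sire_of_slot <- rep(seq_len(s), each = v)
  vals <- apply(schemes, 1L, function(dams)
    mean(cross_values[cbind(sire_of_slot, dams)]))
  best <- which.max(vals)  # which.max takes the first maximum: lowest index
  avg <- mean(vals)
  structure(list(best_index = best,
                 best_scheme = matrix(schemes[best, ], nrow = s, byrow = TRUE),
                 best_value = vals[best], average_value = avg,
                 gain_percent = (vals[best] - avg) / avg * 100,
                 scheme_values = vals),
            class = "mating_search")
}

#' @export
print.mating_search <- function(x, ...) {
  cat(sprintf("best scheme #%d: mean progeny value %.4f (average %.4f, gain %.2f%%)\n",
              x$best_index, x$best_value, x$average_value, x$gain_percent))
  for (i in seq_len(nrow(x$best_scheme)))
    cat(sprintf("  sire %d -> dams %s\n", i,
                paste(x$best_scheme[i, ], collapse = ", ")))
  invisible(x)
}

#' Relative gain of mate allocation over random mating
#'
#' Only meaningful when the trait is on a positive scale (the percent is
#' relative to the random-mating average).
#'
#' @param best mean progeny value of the selected scheme.
#' @param average mean progeny value over all schemes (random mating).
#' @return Gain in percent, `(best - average) / average * 100`.
#' @export
mating_gain_percent <- function(best, average) (best - average) / average * 100

#' End-to-end genomic mating design
#'
#' Runs the whole workflow on a simulated base population: kinships, REML
#' variance components, GBLUP breeding values, truncation selection (top
#' `n_dams` individuals as dams, the next `n_sires` as sires), marker-effect
#' back-solving, the `s x d` table of expected progeny values for every
#' candidate cross (by Mendelian expectation, optionally also by simulated
#' meiosis), and the exhaustive search for the best allocation.
#'
#' @param pop a `base_population` from [simulate_base_population()].
#' @param n_dams,n_sires numbers of selected dams and sires.
#' @param simulate if `TRUE`, also score every cross by simulated meiosis.
#' @param N_reps progeny per cross for the simulation method.
#' @param seed optional RNG seed for the simulation method.
#' @return A list of class `mating_design`: `vc`, `prediction`, `effects`,
#'   `dams`, `sires` (selected indices in EBV rank order), `ebv_table`,
#'   `cross_expectation` (`s` x `d`), optional `cross_simulation` and
#'   `cross_simulation_se`, `search` (a `mating_search`), `gain_percent`.
#' @export
genomic_mating_design <- function(pop, n_dams = 9L, n_sires = 3L,
                                  simulate = FALSE, N_reps = 1000L, seed = NULL) {
  kin <- build_kinships(pop$Z, pop$W)
  vc <- fit_reml(pop$y, kin$K_gamma, kin$K_delta)
  pred <- predict_polygenic(pop$y, kin$K_gamma, kin$K_delta, vc)
  eff <- backsolve_marker_effects(pred, pop$Z, pop$W)
  ord <- order(pred$xi, decreasing = TRUE)
  dams <- ord[seq_len(n_dams)]
  sires <- ord[n_dams + seq_len(n_sires)]
  ebv_table <- data.frame(rank = seq_len(n_dams + n_sires),
                          individual = c(dams, sires),
                          role = rep(c("dam", "sire"), c(n_dams, n_sires)),
                          ebv = pred$xi[c(dams, sires)])
  cross_exp <- matrix(NA_real_, n_sires, n_dams,
                      dimnames = list(paste0("sire", seq_len(n_sires)),
                                      paste0("dam", seq_len(n_dams))))
  for (i in seq_len(n_sires)) for (j in seq_len(n_dams))
    cross_exp[i, j] <- expected_progeny_value(pop$Z[sires[i], ], pop$Z[dams[j], ], eff)
  cross_sim <- cross_sim_se <- NULL
  if (simulate) {
    if (!is.null(seed)) set.seed(seed)
    cross_sim <- cross_sim_se <- cross_exp * NA_real_
    for (i in seq_len(n_sires)) for (j in seq_len(n_dams)) {
      sim <- simulate_progeny_values(
        list(h1 = pop$h1[sires[i], ], h2 = pop$h2[sires[i], ]),
        list(h1 = pop$h1[dams[j], ], h2 = pop$h2[dams[j], ]),
        eff, pop$map, N = N_reps)
      cross_sim[i, j] <- sim$mean
      cross_sim_se[i, j] <- sim$se
    }
  }
  search <- search_best_scheme(cross_exp, d = n_dams, s = n_sires)
  structure(list(vc = vc, prediction = pred, effects = eff, dams = dams,
                 sires = sires, ebv_table = ebv_table,
                 cross_expectation = cross_exp, cross_simulation = cross_sim,
                 cross_simulation_se = cross_sim_se, search = search,
                 gain_percent = search$gain_percent),
            class = "mating_design")
}
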