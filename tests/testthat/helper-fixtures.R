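# Shared fixtures: the two published rice marker-pair count tables and small
# builders used across test files.

# 3x3 joint counts, rows/cols = allele-count codes 0,1,2 (aa,Aa,AA x bb,Bb,BB)
rice_pair_chr1 <- function() {
  joint_count_table(matrix(c(41, 4, 0,
                             0, 100, 3,
                             0, 2, 41), 3, 3, byrow = TRUE))
}

rice_pair_chr4 <- function() {
  joint_count_table(matrix(c(18, 0, 0,
                             3, 103, 4,
                             2, 2, 59), 3, 3, byrow = TRUE))
}

# evenly spaced single-chromosome map
single_chrom_map <- function(n_markers, spacing_cm = 10) {
  marker_map(id = paste0("m", seq_len(n_markers)), chromosome = "1",
             position_bp = seq_len(n_markers),
             position_cm = (seq_len(n_markers) - 1) * spacing_cm)
}

# numeric maximizer of a 1-d log likelihood: dense grid then optimize()
numeric_argmax <- function(f, lower, upper, grid_n = 2000) {
  gr <- seq(lower, upper, length.out = grid_n)
  vals <- vapply(gr, f, numeric(1))
  i <- which.max(vals)
  lo <- gr[max(1, i - 2)]
  hi <- gr[min(grid_n, i + 2)]
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)$maximum
}

# numerical second derivative (central differences)
numeric_d2 <- function(f, x, h = 1e-5) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}
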