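# Fixture builders: small input files written to tempdir at test time.

write_expr_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# 3 genes x 2 samples, known values
tiny_expr_df <- function() {
  data.frame(gene = c("GAPDH", "ACTB", "TP53"),
             S1 = c(1, 2, 3), S2 = c(4, 5, 6))
}

# Independent dense grid-search oracle for the 2-compartment NNLS.
# Iteratively refined grid over the nonnegative quadrant; evaluates the
# residual sum of squares directly (the objective is convex, so grid
# refinement around the incumbent converges to the global optimum).
grid_nnls_oracle <- function(y, p, final_step = 1e-3) {
  sse <- function(t, s) {
    # direct evaluation of sum_i (y_i - p_i t - (1-p_i) s)^2 on a grid
    yy <- sum(y^2); b1 <- sum(y * p); b2 <- sum(y * (1 - p))
    s11 <- sum(p^2); s12 <- sum(p * (1 - p)); s22 <- sum((1 - p)^2)
    yy - 2 * outer(t, rep(1, length(s))) * b1 -
      2 * outer(rep(1, length(t)), s) * b2 +
      outer(t^2, rep(1, length(s))) * s11 +
      2 * outer(t, s) * s12 +
      outer(rep(1, length(t)), s^2) * s22
  }
  ub <- max(4 * max(y) / max(min(p), 1e-3),
            4 * max(y) / max(min(1 - p), 1e-3), 1)
  lo_t <- 0; hi_t <- ub; lo_s <- 0; hi_s <- ub
  repeat {
    t_grid <- seq(lo_t, hi_t, length.out = 201L)
    s_grid <- seq(lo_s, hi_s, length.out = 201L)
    m <- sse(t_grid, s_grid)
    idx <- arrayInd(which.min(m), dim(m))
    t_best <- t_grid[idx[1L]]; s_best <- s_grid[idx[2L]]
    step_t <- t_grid[2L] - t_grid[1L]; step_s <- s_grid[2L] - s_grid[1L]
    if (max(step_t, step_s) <= final_step) break
    lo_t <- max(0, t_best - 2 * step_t); hi_t <- t_best + 2 * step_t
    lo_s <- max(0, s_best - 2 * step_s); hi_s <- s_best + 2 * step_s
  }
  c(tumor = t_best, stroma = s_best)
}

# Brute-force running-sum enrichment oracle (explicit loop over the ranked
# gene list), independent of ssgsea_score's vectorized implementation.
brute_enrichment <- function(x, in_set, exponent) {
  r <- rank(x, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  n_out <- sum(!in_set)
  w_tot <- sum(r[in_set]^exponent)
  p_in <- 0; p_out <- 0; es <- 0
  for (g in ord) {
    if (in_set[g]) p_in <- p_in + r[g]^exponent / w_tot
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  es
}
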