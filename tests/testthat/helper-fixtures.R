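# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# smooth radial SAR bump in [lo, hi] W/kg on an n x n grid, full mask
make_bump_sar <- function(n = 24, lo = 2, hi = 20) {
  g <- outer(seq(-1, 1, length.out = n), seq(-1, 1, length.out = n),
             function(a, b) exp(-(a^2 + b^2)))
  g <- (g - min(g)) / (max(g) - min(g))
  field_map(lo + (hi - lo) * g, modality = "SAR")
}

make_sar_pair <- function(vals_sim, vals_meas, spacing = c(1, 1)) {
  list(sim = field_map(vals_sim, spacing = spacing, modality = "SAR"),
       meas = field_map(vals_meas, spacing = spacing, modality = "SAR"))
}

# reference budgets from the published body/head validation examples
budget_body_t2 <- function() uncertainty_budget(0.64, 0.39, 0.12,
                                                modeling_source = "B1")
budget_body_t3 <- function() uncertainty_budget(0.77, 0.39, 0.12,
                                                modeling_source = c("B1", "SAR"))
budget_head_t2 <- function() uncertainty_budget(0.21, 0.27, 0.12,
                                                modeling_source = "B1")

# independent nearest-rank quantile oracle: explicit sort + ceiling index
sort_rank_quantile <- function(x, q) {
  s <- sort(x)
  s[ceiling(q * length(s))]
}

# independent brute-force Chebyshev erosion oracle
erode_oracle <- function(mask, depth) {
  dm <- dim(mask)
  out <- array(FALSE, dim = dm)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    lo <- pmax(p - depth, 1)
    hi <- pmin(p + depth, dm)
    # voxels whose neighborhood leaves the grid are eroded (outside = FALSE)
    if (any(p - depth < 1) || any(p + depth > dm)) next
    block <- do.call(`[`, c(list(mask), lapply(seq_along(dm), function(k)
      lo[k]:hi[k])))
    out[matrix(p, 1)] <- all(block)
  }
  out
}
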