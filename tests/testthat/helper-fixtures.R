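# Shared fixtures and independent oracles, all built in code.

# brute-force rank-biserial difference over all pairs
rbc_brute <- function(g1, g2) {
  f <- 0; u <- 0
  for (a in g1) for (b in g2) {
    if (a > b) f <- f + 1
    if (b > a) u <- u + 1
  }
  (f - u) / (length(g1) * length(g2))
}

# brute-force Mann-Whitney U statistic for g1 (ties counted half)
u_brute <- function(g1, g2) {
  u <- 0
  for (a in g1) for (b in g2) {
    if (a > b) u <- u + 1
    else if (a == b) u <- u + 0.5
  }
  u
}

# hand-rolled two-sided Fisher p by hypergeometric enumeration on a 2x2
fisher_brute <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tiny base-count fixture: one donor, hand-set depths
make_counts <- function(cells, pos, A, C, G, T, donor = "D1") {
  data.frame(cell = cells, donor = donor, pos = pos,
             A = A, C = C, G = G, T = T, stringsAsFactors = FALSE)
}

# cohort of n_cells cells covering `n_pos` positions at constant depth,
# useful for QC fixtures; depth may be a scalar or per-cell vector
flat_counts <- function(n_cells, n_pos, depth, donor = "D1",
                        ref_base = "A") {
  cells <- sprintf("%s_c%03d", donor, seq_len(n_cells))
  d <- rep(depth, length.out = n_cells)
  out <- data.frame(
    cell = rep(cells, each = n_pos),
    donor = donor,
    pos = rep(seq_len(n_pos), n_cells),
    A = 0, C = 0, G = 0, T = 0)
  out[[ref_base]] <- rep(d, each = n_pos)
  out
}

# quick classified variant table for statistics tests
make_vt <- function(cell, donor, pos, ref, alt, h,
                    classification = "cryptic", pathology = "low",
                    depth = 1000, report_floor = 0.10) {
  vt <- data.frame(cell = cell, donor = donor, pos = pos, ref = ref,
                   alt = alt, h = h, depth = depth,
                   alt_reads = round(h * depth),
                   classification = classification,
                   pathology = pathology, stringsAsFactors = FALSE)
  attr(vt, "report_floor") <- report_floor
  vt
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
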