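test_that("the cSFS histogram matches hand binning and always sums to one", {
  vt <- make_vt(cell = c("a", "b", "c"), donor = "D", pos = c(1, 2, 3),
                ref = "A", alt = "C", h = c(0.12, 0.12, 0.98))
  sfs <- build_csfs(vt, "D", bins = 2, homoplasmy_cut = 0.95, floor = 0.1)
  expect_equal(sfs$density, c(2 / 3, 0, 1 / 3))
  expect_equal(sum(sfs$density), 1)
  expect_equal(sum(sfs$counts), sfs$n_mutations)

  one <- build_csfs(make_vt("a", "D", 1, "A", "C", 0.5), "D",
                    bins = 4, floor = 0.1)
  expect_equal(sum(one$density == 1), 1)

  none <- make_vt("a", "D", 1, "A", "C", 0.5,
                  classification = "shared")
  empty <- build_csfs(none, "D", floor = 0.1)
  expect_true(empty$empty)
  expect_equal(empty$n_mutations, 0)
})

test_that("cSFS histogram mass equals one for random spectra", {
  set.seed(5)
  for (i in 1:20) {
    h <- runif(sample(1:50, 1), 0.1001, 1)
    sfs <- mitocrypt:::new_csfs(h, "x", floor = 0.1, bins = sample(2:30, 1),
                                homoplasmy_cut = 0.95)
    expect_equal(sum(sfs$density), 1)
    expect_equal(sum(sfs$counts), length(h))
  }
})

test_that("mutation load sums heteroplasmies strictly above the threshold", {
  vt <- make_vt("c1", "D", 1:3, "A", "C", c(0.05, 0.2, 0.6))
  expect_equal(mutation_load(vt, t = 0.10)$load, 0.8)
  # empty set
  vt0 <- make_vt("c1", "D", 1, "A", "C", 0.5,
                 classification = "shared")
  expect_equal(mutation_load(vt0, t = 0.10)$load, 0)
  # boundary: h exactly at the threshold contributes nothing
  vt1 <- make_vt("c1", "D", 1, "A", "C", 0.10)
  expect_equal(mutation_load(vt1, t = 0.10)$load, 0)
  # synonymous exclusion
  vt2 <- make_vt("c1", "D", 1:2, "A", "C", c(0.4, 0.3),
                 pathology = c("synonymous", "high"))
  expect_equal(mutation_load(vt2, t = 0.10)$load, 0.3)
  expect_equal(mutation_load(vt2, t = 0.10,
                             exclude_synonymous = FALSE)$load, 0.7)
})

test_that("mutation load is monotone in each heteroplasmy and in the threshold", {
  set.seed(7)
  for (i in 1:10) {
    h <- runif(6, 0.02, 1)
    vt <- make_vt("c", "D", seq_along(h), "A", "C", h)
    l1 <- mutation_load(vt, t = 0.10)$load
    # raising one h never lowers the load
    h2 <- h; h2[3] <- min(1, h2[3] + 0.2)
    l2 <- mutation_load(make_vt("c", "D", seq_along(h2), "A", "C", h2),
                        t = 0.10)$load
    expect_gte(l2, l1)
    # raising t never raises the load
    l3 <- mutation_load(vt, t = 0.3)$load
    expect_lte(l3, l1)
  }
})

test_that("rank-biserial difference matches hand computation on fixtures", {
  expect_equal(rbc_difference(c(0.3, 0.7), c(0.2, 0.5)), 0.5)
  g <- c(0.1, 0.4, 0.9)
  expect_equal(rbc_difference(g, g), 0)
  expect_equal(rbc_difference(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(rbc_difference(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_error(rbc_difference(numeric(0), 1), "non-empty")
})

test_that("rank-biserial difference equals the brute-force all-pairs value and the U identity", {
  set.seed(11)
  for (n1 in 1:6) for (n2 in 1:6) {
    for (rep in 1:5) {
      g1 <- round(runif(n1), 2)          # rounding induces occasional ties
      g2 <- round(runif(n2), 2)
      r <- rbc_difference(g1, g2)
      expect_equal(r, rbc_brute(g1, g2))
      expect_true(abs(r) <= 1)
      expect_equal(r, -rbc_difference(g2, g1))
      if (!any(outer(g1, g2, "=="))) {
        u2 <- u_brute(g2, g1)            # U of the second sample
        expect_equal(r, 1 - 2 * u2 / (n1 * n2))
      }
    }
  }
})

test_that("spectrum comparison returns the exact U and two-sided p", {
  cs <- compare_sfs(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(cs$U), 0)
  expect_equal(cs$r, -1)
  expect_equal(cs$p, wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value)
  # degenerate all-tied inputs
  cs0 <- compare_sfs(rep(0.5, 4), rep(0.5, 3))
  expect_equal(cs0$p, 1)
  expect_equal(cs0$r, 0)
  # Bonferroni over a family of three comparisons
  gr <- list(a = c(1, 2, 3, 7), b = c(2, 3, 4, 8), c = c(9, 10, 11, 12))
  tab <- compare_sfs_groups(gr)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$p_bonferroni, pmin(1, tab$p * 3))
})

test_that("the Mann-Whitney test is calibrated under the null", {
  set.seed(13)
  p_vals <- replicate(200, {
    g1 <- runif(30); g2 <- runif(30)
    compare_sfs(g1, g2)$p
  })
  expect_gte(mean(p_vals > 0.05), 0.90)
})

test_that("the dN/dS Fisher test matches the hypergeometric oracle", {
  vt_bal <- make_vt("c", "D", 1:40, "A", "C",
                    h = rep(c(0.2, 0.05), each = 20),
                    pathology = rep(c("synonymous", "low"), 20))
  res <- dnds_test(vt_bal, scope = "cryptic", floor = 0.10)
  expect_equal(res$p, 1)
  expect_equal(res$ratio_raw, 1)

  # table (1, 9; 9, 1): 1 non-syn above, 9 below; 9 syn above, 1 below
  h <- c(rep(0.2, 1), rep(0.05, 9), rep(0.2, 9), rep(0.05, 1))
  pathology <- c(rep("low", 10), rep("synonymous", 10))
  vt <- make_vt("c", "D", 1:20, "A", "C", h, pathology = pathology)
  res2 <- dnds_test(vt, scope = "cryptic", floor = 0.10)
  tab <- matrix(c(1, 9, 9, 1), 2, byrow = TRUE)
  expect_equal(res2$p, fisher_brute(tab), tolerance = 1e-10)

  # zero synonymous observations above the floor: flagged, ratio NA
  vt3 <- make_vt("c", "D", 1:4, "A", "C", c(0.3, 0.4, 0.05, 0.06),
                 pathology = c("low", "high", "synonymous", "synonymous"))
  res3 <- dnds_test(vt3, scope = "cryptic", floor = 0.10)
  expect_true(res3$flagged)
  expect_true(is.na(res3$ratio))
})

test_that("the dN/dS test has nominal type-I error under neutral class assignment", {
  set.seed(17)
  p_vals <- replicate(300, {
    n <- 60
    h <- runif(n, 0.02, 0.5)
    pathology <- sample(c("synonymous", "low"), n, replace = TRUE)
    vt <- make_vt("c", "D", seq_len(n), "A", "C", h,
                  pathology = pathology)
    dnds_test(vt, scope = "cryptic", floor = 0.10)$p
  })
  rej <- mean(p_vals < 0.05, na.rm = TRUE)
  expect_lt(rej, 0.10)   # Fisher is conservative; reject well under alpha
})

test_that("pseudobulk heteroplasmy dilutes single-cell mutations", {
  # one mutant cell at h = 0.5 among 100 cells, equal depth
  cells <- sprintf("c%03d", 1:100)
  cc <- do.call(rbind, lapply(cells, function(cl)
    transform(flat_counts(1, 5, depth = 1000), cell = cl)))
  i <- which(cc$cell == "c001" & cc$pos == 1)
  cc[i, c("A", "C")] <- c(500, 500)
  vt <- make_vt("c001", "D1", 1, "A", "C", 0.5)
  pb <- pseudobulk_spectrum(cc, vt, bulk_cut = 0.005)
  expect_equal(pb$variants$pseudobulk_h, 0.005)

  # a variant homoplasmic in every cell has pseudobulk h = 1
  cc2 <- cc
  cc2$C[cc2$pos == 2] <- 1000
  cc2$A[cc2$pos == 2] <- 0
  vt2 <- make_vt(cells, "D1", 2, "A", "C", 1,
                 classification = "shared")
  pb2 <- pseudobulk_spectrum(cc2, vt2, bulk_cut = 0.005)
  expect_equal(pb2$variants$pseudobulk_h, 1)

  # 100 cells with one cryptic mutation each at h = 0.2: every variant
  # is at pseudobulk h = 0.002 < 0.005
  cc3 <- do.call(rbind, lapply(cells, function(cl)
    transform(flat_counts(1, 100, depth = 1000), cell = cl)))
  vt3 <- make_vt(cells, "D1", seq_len(100), "A", "C", 0.2)
  for (k in seq_along(cells)) {
    i <- which(cc3$cell == cells[k] & cc3$pos == k)
    cc3[i, c("A", "C")] <- c(800, 200)
  }
  pb3 <- pseudobulk_spectrum(cc3, vt3, bulk_cut = 0.005)
  expect_true(all(abs(pb3$variants$pseudobulk_h - 0.002) < 1e-12))
  expect_equal(pb3$fraction_below, 1)
  expect_equal(pb3$fraction_single_cell, 1)
})

test_that("per-cell homoplasmy rate is normalized by qualified positions", {
  cc <- do.call(rbind, lapply(sprintf("c%02d", 1:3), function(cl)
    transform(flat_counts(1, 250, depth = 1000), cell = cl, donor = "D")))
  mask <- qc_filter(cc)
  vt <- make_vt(c("c01", "c01"), "D", c(1, 2), "A", "C", c(0.96, 0.5))
  hr <- homoplasmy_rate(vt, mask, cut = 0.95)
  r1 <- hr$per_cell$rate[hr$per_cell$cell == "c01"]
  expect_equal(r1, 1 / 250)
  expect_equal(hr$per_cell$rate[hr$per_cell$cell == "c02"], 0)
  expect_equal(hr$cohort_mean, (1 / 250) / 3)
})

test_that("young Moran cohorts carry no homoplasmic cryptic mutations, old ones do", {
  p <- moran_params(N = 60, t_half = 1, nu = 1e-5)
  young <- ensemble_csfs(p, 300, age_years = 0.05 * fixation_time(p),
                         floor = 0.10, seed = 23)
  old <- ensemble_csfs(p, 300, age_years = 2 * fixation_time(p),
                       floor = 0.10, seed = 24)
  hom_young <- sum(young$h >= 0.95)
  hom_old <- sum(old$h >= 0.95)
  expect_equal(hom_young, 0)
  expect_gt(hom_old, 0)
})
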