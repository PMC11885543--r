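small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_donors = 2, ages_years = c(10, 40),
                   cells_per_donor = 15,
                   moran = moran_params(N = 100, t_half = 0.07, nu = 4.6e-8),
                   shared_variant_rate = 2,
                   common_variant_sites = c(73, 2706),
                   depth_model = list(mean_depth = 1500, dispersion = 5),
                   error_rate = 5e-4, seed = 42L)
  defaults[names(args)] <- args
  do.call(cohort_config, defaults)
}

test_that("no mutation influx and zero age produce mutation-free cohorts", {
  cfg0 <- small_config(moran = moran_params(N = 100, nu = 0), seed = 3L)
  truth <- generate_cohort(cfg0)
  expect_false(any(truth$mutations$origin == "cryptic"))

  cfg_age0 <- small_config(ages_years = c(0, 0), seed = 4L)
  truth0 <- generate_cohort(cfg_age0)
  expect_false(any(truth0$mutations$origin == "cryptic"))
})

test_that("cohort generation is deterministic in the seed", {
  a <- generate_cohort(small_config(seed = 11L))
  b <- generate_cohort(small_config(seed = 11L))
  c <- generate_cohort(small_config(seed = 12L))
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$reference, b$reference)
  cr_a <- a$mutations[a$mutations$origin == "cryptic", ]
  cr_c <- c$mutations[c$mutations$origin == "cryptic", ]
  expect_false(identical(cr_a, cr_c))
})

test_that("config invariants are enforced", {
  expect_error(small_config(ages_years = c(-1, 5)), "non-negative")
  expect_error(small_config(error_rate = 0.05), "error_rate")
  expect_error(small_config(ages_years = c(1, 2, 3)), "length")
  expect_error(small_config(depth_model = list(mean_depth = -5,
                                               dispersion = 2)),
               "mean_depth")
})

test_that("cryptic mutations are unique to one cell of their donor and never collide with planted sites", {
  truth <- generate_cohort(small_config(seed = 21L, cells_per_donor = 25))
  cr <- truth$mutations[truth$mutations$origin == "cryptic", ]
  expect_gt(nrow(cr), 0)
  per_site <- tapply(cr$cell, paste(cr$donor, cr$pos), function(x)
    length(unique(x)))
  expect_true(all(per_site == 1))
  expect_false(any(cr$pos %in% truth$config$common_variant_sites))
  sh <- truth$mutations[truth$mutations$origin == "shared", ]
  expect_false(any(paste(cr$donor, cr$pos) %in% paste(sh$donor, sh$pos)))
  expect_true(all(truth$mutations$freq > 0 & truth$mutations$freq <= 1))
})

test_that("rendered base counts conserve depth and honour the true frequency", {
  truth <- generate_cohort(small_config(seed = 31L))
  counts <- render_base_counts(truth, seed = 32L, n_background = 50)
  # conservation is structural: each row's four bases are the drawn depth;
  # verify against an error-free re-render where ref+alt must reconstruct
  expect_true(all(rowSums(counts[, c("A", "C", "G", "T")]) >= 0))

  # homoplasmic site with no error: every read carries the alt base
  t2 <- truth
  t2$mutations <- data.frame(cell = truth$cells$cell[1],
                             donor = truth$cells$donor[1],
                             pos = 100L, ref = truth$reference[100],
                             alt = setdiff(c("A", "C", "G", "T"),
                                           truth$reference[100])[1],
                             freq = 1.0, origin = "cryptic")
  c2 <- render_base_counts(t2, error_rate = 0, seed = 33L,
                           n_background = 10)
  row <- c2[c2$cell == t2$mutations$cell & c2$pos == 100L, ]
  expect_equal(row[[t2$mutations$alt]],
               sum(row[, c("A", "C", "G", "T")]))
})

test_that("alt reads are binomial at the true frequency", {
  # 1000 replicate cells carrying the same h = 0.5 mutation at depth ~200
  cfg <- small_config(n_donors = 1, ages_years = 0, cells_per_donor = 1000,
                      moran = moran_params(N = 100, nu = 0),
                      depth_model = list(mean_depth = 200,
                                         dispersion = 1e9),
                      error_rate = 0, seed = 41L)
  truth <- generate_cohort(cfg)
  alt <- vapply(seq_len(nrow(truth$cells)), function(i)
    setdiff(c("A", "C", "G", "T"), truth$reference[500])[1], "")
  truth$mutations <- data.frame(cell = truth$cells$cell,
                                donor = truth$cells$donor,
                                pos = 500L, ref = truth$reference[500],
                                alt = alt, freq = 0.5, origin = "shared")
  counts <- render_base_counts(truth, seed = 42L, n_background = 5)
  rows <- counts[counts$pos == 500L, ]
  depth <- rowSums(rows[, c("A", "C", "G", "T")])
  alt_frac_mean <- mean(rows[[alt[1]]] / depth)
  se <- sd(rows[[alt[1]]] / depth) / sqrt(nrow(rows))
  expect_lt(abs(alt_frac_mean - 0.5), 3 * se)
})

test_that("with deep error-free coverage the alt fraction converges to the true frequency", {
  truth <- generate_cohort(small_config(seed = 51L, cells_per_donor = 10))
  counts <- render_base_counts(
    truth, depth_model = list(mean_depth = 3e4, dispersion = 1e9),
    error_rate = 0, seed = 52L, n_background = 10)
  mm <- truth$mutations
  key <- paste(counts$cell, counts$pos)
  idx <- match(paste(mm$cell, mm$pos), key)
  depth <- rowSums(counts[idx, c("A", "C", "G", "T")])
  alt_reads <- vapply(seq_len(nrow(mm)), function(i)
    counts[idx[i], mm$alt[i]], numeric(1))
  expect_lt(max(abs(alt_reads / depth - mm$freq)), 0.02)
})

test_that("depth capped at 200 reads leaves no qualified site downstream", {
  truth <- generate_cohort(small_config(seed = 61L))
  counts <- render_base_counts(
    truth, depth_model = list(mean_depth = 20, dispersion = 1e9),
    seed = 62L, n_background = 30)
  depth <- rowSums(counts[, c("A", "C", "G", "T")])
  expect_true(all(depth <= 200))
  expect_warning(mask <- qc_filter(counts), "no cells retained")
  expect_identical(sum(mask$cells$retained), 0L)
  expect_identical(nrow(mask$qualified), 0L)
})

test_that("annotation tables honour proportions, reject duplicates, and are seed-deterministic", {
  ref <- rep(c("A", "C", "G", "T"), length.out = 100)
  sites <- substitution_universe(ref)
  ann1 <- make_annotation_table(sites, proportions = c(1, 0, 0, 0),
                                seed = 5L)
  expect_true(all(ann1$class == "synonymous"))
  ann2 <- make_annotation_table(sites, seed = 6L)
  ann3 <- make_annotation_table(sites, seed = 6L)
  expect_identical(ann2, ann3)
  dup <- rbind(sites, sites[1, ])
  expect_error(make_annotation_table(dup, seed = 1L), "duplicate")
})

test_that("annotation class fractions match the multinomial proportions", {
  ref <- sample(c("A", "C", "G", "T"), 3400, replace = TRUE)
  sites <- substitution_universe(ref)          # ~10^4 substitutions
  ann <- make_annotation_table(sites,
                               proportions = rep(0.25, 4), seed = 7L)
  n <- nrow(ann)
  se <- sqrt(0.25 * 0.75 / n)
  frac <- table(factor(ann$class, levels = c("synonymous", "low", "high",
                                             "noncoding"))) / n
  expect_true(all(abs(frac - 0.25) < 3 * se + 1e-12))
})
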