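test_that("a position qualifies only above 200 reads and cells need 200 qualified positions", {
  # every site at exactly depth 200: nothing qualifies, cell dropped
  cc <- flat_counts(5, 250, depth = 200)
  expect_warning(mask <- qc_filter(cc), "no cells retained")
  expect_identical(sum(mask$cells$retained), 0L)
  expect_true(all(mask$cells$n_qualified == 0))

  # depth 201 everywhere: all 250 positions qualify, all cells retained
  cc2 <- flat_counts(5, 250, depth = 201)
  mask2 <- qc_filter(cc2)
  expect_true(all(mask2$cells$retained))
  expect_true(all(mask2$cells$n_qualified == 250))

  # 250 positions at depth 201 but only 150 per cell: below min_positions
  cc3 <- flat_counts(5, 150, depth = 201)
  expect_warning(mask3 <- qc_filter(cc3), "no cells retained")
  expect_identical(sum(mask3$cells$retained), 0L)
})

test_that("identical qualified counts give zero variance and full retention", {
  cc <- flat_counts(8, 300, depth = 500)
  mask <- qc_filter(cc)
  expect_true(all(mask$cells$retained))
  expect_true(all(mask$cells$z == 0))
})

test_that("a cell with 10x the typical qualified-position count is a log-normal outlier", {
  # 30 cells with ~500 qualified positions, one with 5000: by hand,
  # log10 counts cluster near 2.7 with small SD, so log10(5000) = 3.7 is
  # far outside 3 SD
  set.seed(99)
  n_pos <- round(runif(30, 480, 520))
  rows <- lapply(seq_len(30), function(i)
    flat_counts(1, n_pos[i], depth = 300)[, ] |>
      transform(cell = sprintf("c%02d", i)))
  big <- transform(flat_counts(1, 5000, depth = 300), cell = "c_outlier")
  cc <- do.call(rbind, c(rows, list(big)))
  mask <- qc_filter(cc)
  lg <- log10(c(n_pos, 5000))
  z_hand <- (lg - mean(lg)) / sd(lg)
  expect_gt(abs(z_hand[31]), 3)
  expect_false(mask$cells$retained[mask$cells$cell == "c_outlier"])
  expect_identical(sum(mask$cells$retained), 30L)
})

test_that("heteroplasmy is the read fraction of each non-reference base", {
  cc <- rbind(
    make_counts("c1", 101, A = 100, C = 300, G = 0, T = 0),
    make_counts("c1", 102, A = 400, C = 0, G = 0, T = 0),
    make_counts("c1", 103, A = 150, C = 90, G = 60, T = 0))
  cc <- rbind(cc, flat_counts(1, 300, depth = 201)[1:300, ] |>
                transform(cell = "c1", pos = 200 + seq_len(300)))
  ref <- setNames(rep("A", 600), 1:600)
  mask <- qc_filter(cc)
  vt <- call_variants(cc, mask, ref)
  v101 <- vt[vt$pos == 101, ]
  expect_equal(nrow(v101), 1)
  expect_equal(v101$alt, "C")
  expect_equal(v101$h, 0.75)
  expect_false(102 %in% vt$pos)          # no alternate reads, no rows
  v103 <- vt[vt$pos == 103, ]
  expect_equal(sort(v103$alt), c("C", "G"))
  expect_equal(v103$h[v103$alt == "C"], 0.30)
  expect_equal(v103$h[v103$alt == "G"], 0.20)
  # alt heteroplasmies plus the reference fraction sum to one
  expect_equal(sum(v103$h) + 150 / 300, 1)
})

test_that("a missing reference base is reported by site", {
  cc <- make_counts("c1", 5, A = 100, C = 150, G = 0, T = 0)
  cc <- rbind(cc, transform(flat_counts(1, 300, depth = 300), cell = "c1"))
  mask <- qc_filter(cc)
  ref <- setNames(rep("A", 300), 1:300)  # site 5 is covered; drop it
  ref <- ref[-5]
  expect_error(call_variants(cc, mask, ref), "site")
})

test_that("classification separates cryptic, shared and common variants", {
  # donor D: site 3243 alt A in one cell at h = 0.2 -> cryptic
  # site 1000 alt C in two cells -> shared
  # site 2000 alt G in 4 donors -> common
  donors <- c("D", "E", "F", "G")
  cc <- do.call(rbind, lapply(donors, function(d) {
    cells <- sprintf("%s_c%02d", d, 1:12)
    base <- do.call(rbind, lapply(cells, function(cl)
      transform(flat_counts(1, 300, depth = 1000), cell = cl, donor = d)))
    base
  }))
  ref <- setNames(rep("A", 3300), 1:3300)
  add_var <- function(cc, cell, pos, alt, h, depth = 1000) {
    i <- which(cc$cell == cell & cc$pos == pos)
    cc[i, "A"] <- round(depth * (1 - h))
    cc[i, alt] <- round(depth * h)
    cc
  }
  # move sites into covered range (<=300)
  cc <- add_var(cc, "D_c01", 243, "C", 0.2)
  cc <- add_var(cc, "D_c02", 100, "C", 0.3)
  cc <- add_var(cc, "D_c03", 100, "C", 0.4)
  for (d in donors) cc <- add_var(cc, sprintf("%s_c05", d), 200, "G", 0.5)
  mask <- qc_filter(cc)
  vt <- call_variants(cc, mask, ref)
  vt <- classify_variants(vt, mask)
  cls <- function(pos, cell) vt$classification[vt$pos == pos &
                                                 vt$cell == cell]
  expect_identical(cls(243, "D_c01"), "cryptic")
  expect_identical(cls(100, "D_c02"), "shared")
  expect_identical(cls(100, "D_c03"), "shared")
  expect_true(all(vt$classification[vt$pos == 200] == "common"))
  # partition completeness
  expect_true(all(vt$classification %in% c("cryptic", "shared", "common")))
})

test_that("variants at thinly covered sites are dropped and floors are strict", {
  cc <- do.call(rbind, lapply(sprintf("D_c%02d", 1:12), function(cl)
    transform(flat_counts(1, 300, depth = 1000), cell = cl, donor = "D")))
  # site 400 covered by only 3 cells (below min_cells_per_site)
  thin <- make_counts(sprintf("D_c%02d", 1:3), 400, A = 700, C = 300,
                      G = 0, T = 0, donor = "D")
  cc <- rbind(cc, thin)
  i <- which(cc$cell == "D_c01" & cc$pos == 50)
  cc[i, c("A", "C")] <- c(900, 100)   # h = 0.10 exactly
  j <- which(cc$cell == "D_c02" & cc$pos == 60)
  cc[j, c("A", "G")] <- c(880, 120)   # h = 0.12
  mask <- qc_filter(cc)
  ref <- setNames(rep("A", 500), 1:500)
  vt <- call_variants(cc, mask, ref)
  out <- classify_variants(vt, mask)
  expect_false(400 %in% out$pos)               # site exclusion
  expect_false(any(out$pos == 50))             # h = 0.10 not > 0.10
  expect_identical(out$classification[out$pos == 60], "cryptic")
  # lowering the report floor retains at least as many variants
  out05 <- classify_variants(vt, mask, report_floor = 0.05)
  expect_gte(nrow(out05), nrow(out))
})

test_that("unknown donors are rejected", {
  cc <- transform(flat_counts(12, 300, depth = 1000), donor = "D")
  cc$cell <- paste0("D", cc$cell)
  mask <- qc_filter(cc)
  vt <- make_vt("x", "NOPE", 10, "A", "C", 0.5)
  expect_error(classify_variants(vt, mask), "unknown donor")
})

test_that("pathology annotation joins, collapses for unscored species, and rejects contradictions", {
  vt <- make_vt(cell = c("c1", "c1", "c2", "c2", "c3"), donor = "D",
                pos = c(10, 20, 30, 40, 50), ref = "A",
                alt = c("C", "G", "T", "C", "G"),
                h = c(0.2, 0.3, 0.4, 0.5, 0.6))
  ann <- data.frame(pos = c(10, 20, 30, 40),
                    ref = "A", alt = c("C", "G", "T", "C"),
                    class = c("synonymous", "low", "high", "noncoding"))
  out <- annotate_variants(vt, ann)
  expect_identical(out$pathology,
                   c("synonymous", "low", "high", "noncoding", "unknown"))
  out_m <- annotate_variants(vt, ann, collapse = TRUE)
  expect_identical(out_m$pathology,
                   c("synonymous", "non-synonymous", "non-synonymous",
                     "noncoding", "unknown"))
  # row counts checked by hand on this 5-row fixture
  expect_identical(sum(out$pathology == "unknown"), 1L)
  bad <- rbind(ann, data.frame(pos = 10, ref = "A", alt = "C",
                               class = "high"))
  expect_error(annotate_variants(vt, bad), "contradictory")
})

test_that("true cryptic mutations are recovered and sequencing error creates no false cryptics", {
  cfg <- cohort_config(
    n_donors = 2, ages_years = c(30, 60), cells_per_donor = 30,
    moran = moran_params(N = 150, t_half = 0.05, nu = 2e-7),
    shared_variant_rate = 2, common_variant_sites = c(73, 2706),
    depth_model = list(mean_depth = 1000, dispersion = 50),
    error_rate = 1e-3, seed = 77L)
  truth <- generate_cohort(cfg)
  counts <- render_base_counts(truth, seed = 78L, n_background = 250)
  mask <- qc_filter(counts)
  vt <- call_variants(counts, mask, truth$reference)
  vt <- classify_variants(vt, mask)
  cr <- vt[vt$classification == "cryptic", ]
  retained_cells <- mask$cells$cell[mask$cells$retained]
  covered <- paste(mask$qualified$cell, mask$qualified$pos)
  ds <- mask$donor_site
  deep_sites <- paste(ds$donor[ds$n_cells >= 10], ds$pos[ds$n_cells >= 10])
  tm <- truth$mutations
  tc <- tm[tm$origin == "cryptic" & tm$freq > 0.15 &
             tm$cell %in% retained_cells &
             paste(tm$cell, tm$pos) %in% covered &
             paste(tm$donor, tm$pos) %in% deep_sites, ]
  expect_gt(nrow(tc), 10)
  recovered <- paste(tc$cell, tc$pos, tc$alt) %in%
    paste(cr$cell, cr$pos, cr$alt)
  expect_gte(mean(recovered), 0.95)
  # no called cryptic that is not a true mutation (error alt fractions
  # concentrate far below the 0.10 report floor at this depth)
  false_cryptic <- !(paste(cr$cell, cr$pos, cr$alt) %in%
                       paste(tm$cell, tm$pos, tm$alt))
  expect_identical(sum(false_cryptic), 0L)
})
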