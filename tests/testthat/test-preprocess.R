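test_that("missingness filter removes strictly-above-70% features only", {
  v <- matrix(1, 10, 3, dimnames = list(sprintf("S%02d", 1:10), c("gone", "kept70", "full")))
  v[1:8, "gone"] <- NA      # 80% missing -> removed
  v[1:7, "kept70"] <- NA    # exactly 70% -> kept (strict "more than")
  ft <- make_ft(v, panel = rep("AA", 3))
  out <- filter_metabolites(ft)
  expect_setequal(feature_ids(out), c("kept70", "full"))
  # feature order otherwise preserved
  expect_identical(feature_ids(out), c("kept70", "full"))
  # idempotent
  expect_identical(filter_metabolites(out)$values, out$values)
  empty <- kcsnet:::ft_subset(ft, samples = integer(0))
  expect_error(filter_metabolites(empty), "zero samples")
})

test_that("median imputation and scaling meet the exact contracts", {
  v <- matrix(c(2, 4, 6, NA), 4, 1, dimnames = list(paste0("S", 1:4), "m"))
  out <- impute_and_median_scale(make_ft(v))
  # missing cell imputed with the observed median (4), then scaled by it
  expect_equal(unname(out$values[, 1]), c(0.5, 1, 1.5, 1))
  expect_identical(unname(out$imputed[, 1]), c(FALSE, FALSE, FALSE, TRUE))
  # median of non-imputed cells is exactly 1
  expect_equal(stats::median(out$values[!out$imputed[, 1], 1]), 1, tolerance = 1e-12)

  # no missing values: plain division by the median
  v2 <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
               dimnames = list(paste0("S", 1:3), c("a", "b")))
  out2 <- impute_and_median_scale(make_ft(v2))
  expect_equal(unname(out2$values), cbind(c(0.5, 1, 1.5), c(0.5, 1, 1.5)))
  # constant feature collapses to all ones
  v3 <- matrix(7, 3, 1, dimnames = list(paste0("S", 1:3), "c"))
  expect_equal(unname(impute_and_median_scale(make_ft(v3))$values[, 1]), c(1, 1, 1))
  # all-missing feature should have been filtered upstream
  v4 <- matrix(NA_real_, 3, 1, dimnames = list(paste0("S", 1:3), "x"))
  expect_error(impute_and_median_scale(make_ft(v4)), "all-missing")
})

test_that("median-scaling contract holds on simulated data within 1e-12", {
  sim <- simulate_study(sim_config(seed = 21))
  out <- impute_and_median_scale(filter_metabolites(sim$metabolome))
  meds <- vapply(seq_len(ncol(out$values)), function(j)
    stats::median(out$values[!out$imputed[, j], j]), 0)
  expect_equal(meds, rep(1, ncol(out$values)), tolerance = 1e-12)
})

test_that("panel normalization makes per-sample panel means 1 and panels independent", {
  v <- matrix(c(1, 3, 2, 6, 5, 5), 1, 6,
              dimnames = list("S1", paste0("m", 1:6)))
  ft <- make_ft(v, panel = c("SCFA", "SCFA", "BA", "BA", "BA", "AA"))
  out <- panel_normalize(ft)
  expect_equal(unname(out$values[1, 1:2]), c(0.5, 1.5))
  # single-metabolite panel collapses to 1
  expect_equal(unname(out$values[1, 6]), 1)
  # normalizing one panel leaves the others unchanged
  ft_scfa_only <- make_ft(v[, 1:2, drop = FALSE], panel = c("SCFA", "SCFA"))
  expect_equal(unname(panel_normalize(ft_scfa_only)$values[1, ]),
               unname(out$values[1, 1:2]))
  # per-sample per-panel means are 1 on simulated data
  sim <- simulate_study(sim_config(seed = 22))
  pn <- panel_normalize(impute_and_median_scale(filter_metabolites(sim$metabolome)))
  for (p in unique(pn$feature_meta$panel)) {
    idx <- pn$feature_meta$panel == p
    expect_equal(unname(rowMeans(pn$values[, idx, drop = FALSE])),
                 rep(1, nrow(pn$values)), tolerance = 1e-12)
  }
  bad <- make_ft(v, panel = c("SCFA", NA, "BA", "BA", "BA", "AA"))
  expect_error(panel_normalize(bad), "panel annotation")
})

test_that("log2 pseudocount transform maps known points exactly", {
  v <- matrix(c(0, 1, 7), 3, 1, dimnames = list(paste0("S", 1:3), "m"))
  out <- log2_pseudo(make_ft(v))
  expect_equal(unname(out$values[, 1]), c(0, 1, 3))
  vneg <- matrix(-1, 1, 1, dimnames = list("S1", "m"))
  expect_error(log2_pseudo(make_ft(vneg)), "negative")
})

test_that("microbiome filter drops singleton features and shallow samples strictly", {
  v <- rbind(S1 = c(5, 999, 0, 0),
             S2 = c(3, 0, 997, 0),
             S3 = c(1000, 0, 0, 0))
  colnames(v) <- c("keep", "singleton", "singleton2", "allzero")
  ft <- make_ft(v, type = "microbiome", genus = colnames(v))
  out <- filter_microbiome(ft, min_total_reads = 0)
  expect_identical(feature_ids(out), "keep")
  # read-depth boundary: 999 removed, exactly 1000 kept
  v2 <- rbind(S1 = c(500, 499), S2 = c(500, 500), S3 = c(600, 600))
  ft2 <- make_ft(v2, type = "microbiome", genus = colnames(v2))
  out2 <- filter_microbiome(ft2)
  expect_setequal(sample_ids(out2), c("S2", "S3"))
  # idempotence
  expect_identical(filter_microbiome(out2)$values, out2$values)
})

test_that("relative abundance and arcsine-sqrt obey their closed forms", {
  v <- rbind(S1 = c(2, 2), S2 = c(1, 3))
  ft <- make_ft(v, type = "microbiome", genus = c("a", "b"))
  rel <- relative_abundance(ft)
  expect_equal(unname(rel$values), rbind(c(0.5, 0.5), c(0.25, 0.75)))
  v2 <- rbind(S1 = c(1, 3, 6))
  rel2 <- relative_abundance(make_ft(v2, type = "microbiome", genus = letters[1:3]))
  expect_equal(unname(rel2$values[1, ]), c(0.1, 0.3, 0.6))
  tr <- arcsine_sqrt(make_ft(rbind(S1 = c(0, 1, 0.25))))
  expect_equal(unname(tr$values[1, ]), c(0, pi / 2, pi / 6))
  expect_error(arcsine_sqrt(make_ft(rbind(S1 = c(0, 1.2)))), "0, 1")
  zero <- make_ft(rbind(S1 = c(0, 0)), type = "microbiome", genus = c("a", "b"))
  expect_error(relative_abundance(zero), "zero total")
})

test_that("preprocessing is invariant to sample order up to the same permutation", {
  sim <- simulate_study(sim_config(seed = 23))
  met <- sim$metabolome
  set.seed(1)
  perm <- sample(nrow(met$values))
  met_p <- kcsnet:::ft_subset(met, samples = perm)
  a <- impute_and_median_scale(filter_metabolites(met))
  b <- impute_and_median_scale(filter_metabolites(met_p))
  expect_equal(b$values, a$values[rownames(b$values), ])
})
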