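md2 <- function(samples, subj) data.frame(Sample = samples, Subject = subj,
                                          stringsAsFactors = FALSE)

test_that("residualization is exact subject-mean centering", {
  v <- matrix(c(1, 3, 10, 14, 7, 7), 6, 1,
              dimnames = list(paste0("S", 1:6), "f"))
  md <- md2(rownames(v), rep(c("a", "b", "c"), each = 2))
  r <- residualize(make_ft(v), md)
  expect_equal(unname(r$values[, 1]), c(-1, 1, -2, 2, 0, 0))
  # per-subject residual means are zero within 1e-10
  for (s in unique(md$Subject))
    expect_lt(abs(mean(r$values[md$Subject == s, 1])), 1e-10)
  # feature equal to subject means -> all residuals zero
  v2 <- matrix(rep(c(2, 9, 4), each = 2), 6, 1,
               dimnames = list(paste0("S", 1:6), "f"))
  expect_equal(unname(residualize(make_ft(v2), md)$values[, 1]), rep(0, 6))
  # location invariance: shifting one subject leaves residuals unchanged
  v3 <- v; v3[1:2, 1] <- v3[1:2, 1] + 100
  expect_equal(residualize(make_ft(v3), md)$values, r$values)
  # single-sample subject: residual 0 with a warning
  md_single <- md2(rownames(v), c("a", "a", "b", "b", "c", "d"))
  expect_warning(rs <- residualize(make_ft(v), md_single), "single sample")
  expect_equal(unname(rs$values[5:6, 1]), c(0, 0))
})

test_that("Spearman rho and p match brute-force and reference computations", {
  mk <- function(x, nm) {
    v <- matrix(x, length(x), 1, dimnames = list(paste0("S", seq_along(x)), nm))
    list(values = v)
  }
  X <- list(values = cbind(inc = 1:5, dec = 5:1, v1 = c(1, 2, 3, 4, 5)))
  rownames(X$values) <- paste0("S", 1:5)
  Y <- list(values = cbind(y = c(3, 1, 2, 5, 4)))
  rownames(Y$values) <- paste0("S", 1:5)
  sp <- spearman_all_pairs(X, Y)
  expect_equal(sp$rho["inc", "y"], bf_spearman(1:5, c(3, 1, 2, 5, 4)))
  expect_equal(sp$rho["v1", "y"], 0.6)   # 1 - 6*8/(5*24)
  within <- spearman_all_pairs(X)
  expect_equal(within$rho["inc", "inc"], 1)
  expect_equal(within$rho["inc", "dec"], -1)
  # p matches cor.test's t-approximation
  set.seed(3)
  x <- rnorm(20); y <- rnorm(20)
  Xr <- list(values = cbind(x = x)); rownames(Xr$values) <- paste0("S", 1:20)
  Yr <- list(values = cbind(y = y)); rownames(Yr$values) <- paste0("S", 1:20)
  sp2 <- spearman_all_pairs(Xr, Yr)
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(unname(sp2$rho["x", "y"]), unname(ct$estimate), tolerance = 1e-12)
  expect_equal(unname(sp2$p["x", "y"]), ct$p.value, tolerance = 1e-9)
})

test_that("association records store each within-dataset pair once and drop constants", {
  set.seed(4)
  v <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("S", 1:10), paste0("f", 1:4)))
  v[, 4] <- 1  # constant feature
  sp <- spearman_all_pairs(list(values = v))
  rec <- association_records(sp, "bact-bact")
  # 4*3/2 = 6 pairs minus the 3 involving the constant feature
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "n_excluded"), 3)
  expect_false(any(rec$feature_x == rec$feature_y))
  # canonical storage: no duplicated unordered pair
  key <- apply(rec[, c("feature_x", "feature_y")], 1,
               function(r) paste(sort(r), collapse = "|"))
  expect_false(anyDuplicated(key) > 0)
})

test_that("per-family BH matches the brute-force oracle and its boundary cases", {
  rec <- data.frame(feature_x = letters[1:4], feature_y = LETTERS[1:4],
                    pair_type = "bact-met",
                    rho = 0.5, p = c(0.01, 0.02, 0.03, 0.04),
                    stringsAsFactors = FALSE)
  out <- adjust_fdr(rec)
  expect_equal(out$q, rep(0.04, 4))               # step-up monotonicity
  expect_equal(out$q, bf_bh(rec$p))
  one <- adjust_fdr(rec[1, ])
  expect_equal(one$q, 0.01)                        # m = 1
  ones <- rec; ones$p <- 1
  expect_equal(adjust_fdr(ones)$q, rep(1, 4))
  # families are adjusted separately
  set.seed(5)
  rec2 <- data.frame(feature_x = paste0("x", 1:60), feature_y = paste0("y", 1:60),
                     pair_type = rep(c("met-met", "bact-bact", "bact-met"), each = 20),
                     rho = 0, p = runif(60), stringsAsFactors = FALSE)
  out2 <- adjust_fdr(rec2)
  for (fam in unique(rec2$pair_type)) {
    i <- rec2$pair_type == fam
    expect_equal(out2$q[i], bf_bh(rec2$p[i]))
  }
  expect_true(all(out2$q >= out2$p - 1e-15))
})

test_that("residualize-then-correlate is invariant to per-subject shifts", {
  sim <- simulate_study(sim_config(seed = 31, n_subjects = 6))
  met <- log2_pseudo(impute_and_median_scale(filter_metabolites(sim$metabolome)))
  md <- sim$metadata
  r1 <- residualize(met, md)
  shifted <- met
  for (s in unique(md$Subject)) {
    rows <- md$Sample[md$Subject == s]
    shifted$values[rows, ] <- shifted$values[rows, ] + rnorm(1, 0, 5)
  }
  r2 <- residualize(shifted, md)
  expect_equal(spearman_all_pairs(r2)$rho, spearman_all_pairs(r1)$rho,
               tolerance = 1e-10)
})

test_that("block ranking finds planted blocks and honors its boundaries", {
  # construct a 6x4 q-matrix with two planted disjoint blocks
  features_x <- paste0("x", 1:6); features_y <- paste0("y", 1:4)
  q <- matrix(0.9, 6, 4, dimnames = list(features_x, features_y))
  q[1:3, 1:2] <- 0.001     # block 1 (min q 0.001)
  q[4:6, 3:4] <- 0.01      # block 2 (min q 0.01)
  rho <- matrix(0.5, 6, 4, dimnames = dimnames(q))
  # dendrograms grouping the block members together
  cx <- matrix(0.1, 6, 6, dimnames = list(features_x, features_x))
  cx[1:3, 1:3] <- 0.9; cx[4:6, 4:6] <- 0.9; diag(cx) <- 1
  cy <- matrix(0.1, 4, 4, dimnames = list(features_y, features_y))
  cy[1:2, 1:2] <- 0.9; cy[3:4, 3:4] <- 0.9; diag(cy) <- 1
  ox <- cluster_order(cx); oy <- cluster_order(cy)
  blocks <- rank_blocks(rho, q, q_threshold = 0.05, ox, oy)
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$rank, 1:2)
  expect_setequal(strsplit(blocks$x_features[1], ";")[[1]], features_x[1:3])
  expect_setequal(strsplit(blocks$y_features[1], ";")[[1]], features_y[1:2])
  expect_lt(blocks$score[1], blocks$score[2])

  # a single significant pair yields exactly one 1x1 block
  q1 <- matrix(0.9, 6, 4, dimnames = dimnames(q)); q1[2, 3] <- 0.01
  b1 <- rank_blocks(rho, q1, 0.05, ox, oy)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$x_features, "x2")
  expect_equal(b1$y_features, "y3")
  # threshold below every q: empty result
  expect_equal(nrow(rank_blocks(rho, q, q_threshold = 1e-6, ox, oy)), 0)
})
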