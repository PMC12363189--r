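test_that("Bray-Curtis matches hand computations and its bounds", {
  v <- rbind(A = c(1, 1), B = c(0, 2), C = c(1, 1), D = c(1, 0), E = c(0, 1))
  d <- bray_curtis(make_ft(v, type = "microbiome", genus = c("g1", "g2")))
  expect_equal(d["A", "B"], 0.5)          # (|1-0|+|1-2|) / 4
  expect_equal(d["A", "C"], 0)            # identical rows
  expect_equal(d["D", "E"], 1)            # disjoint supports
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_equal(d, t(d))
})

test_that("PCoA recovers equilateral and collinear configurations", {
  # three equidistant samples: two equal positive eigenvalues, 50% each
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(LETTERS[1:3], LETTERS[1:3])
  fit <- pcoa(d)
  ev <- fit$eigenvalues[fit$eigenvalues > 1e-8]
  expect_length(ev, 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-8)
  expect_equal(unname(fit$variance_explained), c(0.5, 0.5), tolerance = 1e-8)

  # duplicated sample: coincident coordinates
  v <- rbind(A = c(1, 2), B = c(1, 2), C = c(5, 1), D = c(2, 8))
  dd <- as.matrix(stats::dist(v))
  fit2 <- pcoa(dd)
  expect_equal(fit2$coordinates["A", ], fit2$coordinates["B", ], tolerance = 1e-10)

  # collinear points: axis 1 recovers the ordering (classical scaling = PCA)
  x <- c(0, 1, 3, 7, 10)
  d3 <- as.matrix(stats::dist(x))
  dimnames(d3) <- list(paste0("P", 1:5), paste0("P", 1:5))
  fit3 <- pcoa(d3)
  a1 <- fit3$coordinates[, 1]
  expect_true(all(diff(a1) > 0) || all(diff(a1) < 0))
  expect_equal(unname(abs(diff(a1))), diff(x), tolerance = 1e-8)
  expect_error(pcoa(d[1:2, 1:2]), "at least 3")
})

test_that("PERMANOVA separates planted clusters and reports add-one p-values", {
  set.seed(10)
  v <- rbind(matrix(rnorm(10 * 6, 0), 10, 6), matrix(rnorm(10 * 6, 4), 10, 6))
  v <- abs(v) + 0.1
  rownames(v) <- sprintf("S%02d", 1:20)
  colnames(v) <- sprintf("F%02d", 1:6)
  ft <- make_ft(v, type = "microbiome", genus = colnames(v))
  d <- bray_curtis(ft)
  md <- data.frame(Sample = rownames(v),
                   grp = rep(c("a", "b"), each = 10),
                   stringsAsFactors = FALSE)
  res <- permanova(d, md, terms = "grp", n_perm = 999, seed = 1)
  row <- res[res$term == "grp", ]
  expect_equal(row$p, 1 / 1000)             # minimum attainable at 999 perms
  expect_gt(row$R2, 0.3)
  # R2 partitions to 1
  expect_equal(sum(res$R2[res$term != "Total"]), 1, tolerance = 1e-10)
  # degenerate single-level design is refused
  md$const <- "x"
  expect_error(permanova(d, md, terms = "const"), "single level")
})

test_that("restricted permutations stay within strata", {
  set.seed(11)
  # block effect aligned with strata: free permutation calls it significant,
  # within-block permutation cannot (the term is constant within blocks)
  v <- abs(rbind(matrix(rnorm(8 * 5, 0), 8, 5), matrix(rnorm(8 * 5, 3), 8, 5))) + 0.1
  rownames(v) <- sprintf("S%02d", 1:16)
  colnames(v) <- sprintf("F%02d", 1:5)
  d <- bray_curtis(make_ft(v, type = "microbiome", genus = colnames(v)))
  md <- data.frame(Sample = rownames(v), block = rep(c("b1", "b2"), each = 8),
                   stringsAsFactors = FALSE)
  free <- permanova(d, md, terms = "block", n_perm = 199, seed = 2)
  restr <- permanova(d, md, terms = "block", strata = "block", n_perm = 199, seed = 2)
  expect_lt(free$p[free$term == "block"], 0.05)
  expect_equal(restr$p[restr$term == "block"], 1)  # F invariant within blocks
})

test_that("PERMANOVA type-I error is calibrated on null data", {
  set.seed(12)
  rej <- vapply(seq_len(500), function(i) {
    v <- abs(matrix(rnorm(12 * 5), 12, 5)) + 0.1
    rownames(v) <- sprintf("S%02d", 1:12)
    colnames(v) <- sprintf("F%02d", 1:5)
    d <- bray_curtis(make_ft(v, type = "microbiome", genus = colnames(v)))
    md <- data.frame(Sample = rownames(v), grp = rep(c("a", "b"), 6),
                     stringsAsFactors = FALSE)
    p <- permanova(d, md, terms = "grp", n_perm = 199, seed = i)$p[1]
    p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("mixed model recovers a planted log2 fold change", {
  set.seed(13)
  est <- vapply(seq_len(100), function(i) {
    n_sub <- 10
    subj <- rep(sprintf("M%02d", 1:n_sub), each = 4)
    cond <- rep(c("Control", "Pre", "Iso", "Post"), n_sub)
    b <- rep(rnorm(n_sub, 0, 0.5), each = 4)
    y <- b + ifelse(cond == "Pre", 1.0, 0) + rnorm(40, 0, 0.3)
    v <- matrix(y, 40, 1, dimnames = list(sprintf("S%02d", 1:40), "m1"))
    md <- data.frame(Sample = rownames(v), Subject = subj,
                     Treatment_Condition = cond, stringsAsFactors = FALSE)
    res <- lmm_differential(make_ft(v), md)
    res$log2FC[res$condition == "Pre"]
  }, 0)
  expect_equal(mean(est), 1.0, tolerance = 0.1)
})

test_that("mixed model null and degenerate behavior", {
  set.seed(14)
  # zero-effect simulation: BH-significant fraction stays near/below 5%
  frac <- vapply(seq_len(30), function(i) {
    n_sub <- 10
    subj <- rep(sprintf("M%02d", 1:n_sub), each = 4)
    cond <- rep(c("Control", "Pre", "Iso", "Post"), n_sub)
    v <- matrix(rep(rnorm(n_sub, 0, 1), each = 4) + rnorm(40 * 8, 0, 0.5),
                40, 8, dimnames = list(sprintf("S%02d", 1:40), paste0("m", 1:8)))
    md <- data.frame(Sample = rownames(v), Subject = subj,
                     Treatment_Condition = cond, stringsAsFactors = FALSE)
    res <- lmm_differential(make_ft(v), md)
    mean(res$significant)
  }, 0)
  expect_lte(mean(frac), 0.05)

  # response equal to subject means: all condition coefficients ~ 0
  subj <- rep(sprintf("M%02d", 1:6), each = 4)
  cond <- rep(c("Control", "Pre", "Iso", "Post"), 6)
  y <- rep(c(1, 5, 3, 7, 2, 4), each = 4)
  v <- matrix(y, 24, 1, dimnames = list(sprintf("S%02d", 1:24), "m1"))
  md <- data.frame(Sample = rownames(v), Subject = subj,
                   Treatment_Condition = cond, stringsAsFactors = FALSE)
  res <- lmm_differential(make_ft(v), md)
  expect_equal(res$log2FC, rep(0, 3), tolerance = 1e-8)
  # q >= p always
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("Bray-Curtis equals half the Manhattan distance for compositions", {
  sim <- simulate_study(sim_config(seed = 24))
  rel <- relative_abundance(filter_microbiome(sim$microbiome))
  d <- bray_curtis(rel)
  manh <- as.matrix(stats::dist(rel$values, method = "manhattan"))
  expect_equal(unclass(d), manh / 2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(d <= 1 + 1e-12))
})
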