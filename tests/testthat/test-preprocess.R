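# Build a matrix where cell j detects exactly ng[j] genes.
counts_with_ngenes <- function(ng, n_genes = max(ng)) {
  m <- matrix(0L, n_genes, length(ng))
  for (j in seq_along(ng)) m[seq_len(ng[j]), j] <- 1L
  make_counts(m)
}

test_that("cell filtering keeps the boundary counts and is idempotent", {
  x <- counts_with_ngenes(c(150, 200, 2500, 2600))
  f <- filter_cells(x)
  expect_identical(colnames(f$counts), c("c2", "c3"))
  expect_identical(nrow(f$counts), nrow(x$counts))
  expect_identical(filter_cells(f)$counts, f$counts)

  all_in <- counts_with_ngenes(c(300, 400))
  expect_identical(filter_cells(all_in)$counts, all_in$counts)

  expect_warning(filter_cells(counts_with_ngenes(c(10, 20))), "no cells")
})

test_that("gene filtering thresholds on cells detected and is idempotent", {
  m <- matrix(0L, 3, 4)
  m[1, 1:2] <- 1L   # detected in 2 cells
  m[2, 1:3] <- 5L   # detected in 3 cells
  x <- make_counts(m) # gene 3 all-zero
  f <- filter_genes(x, min_cells = 3)
  expect_identical(rownames(f$counts), "g2")
  expect_identical(filter_genes(x, min_cells = 0)$counts, x$counts)
  expect_identical(rownames(filter_genes(x, min_cells = 1)$counts), c("g1", "g2"))
  expect_identical(filter_genes(f, min_cells = 3)$counts, f$counts)
})

test_that("log-normalization matches its formula and preserves totals", {
  m <- matrix(0L, 2, 2)
  m[1, 1] <- 1L; m[2, 1] <- 9999L
  m[1, 2] <- 5L; m[2, 2] <- 4995L
  nm <- log_normalize(make_counts(m), scale_factor = 10000)
  expect_equal(nm[1, 1], log(2), tolerance = 1e-12)   # count 1, total 10,000
  expect_equal(nm[1, 2], log(11), tolerance = 1e-12)  # count 5, total 5,000
  expect_equal(nm[2, 2] == 0, FALSE)

  # zeros stay zero and back-transformed columns sum to the scale factor
  set.seed(1)
  big <- make_counts(matrix(rpois(600, 2), 30, 20))
  big$counts[3, ] <- 0L
  nmb <- log_normalize(filter_cells(big, 1, Inf))
  expect_true(all((as.matrix(nmb) == 0) == (as.matrix(big$counts) == 0)))
  expect_equal(unname(colSums(expm1(as.matrix(nmb)))), rep(10000, 20))

  zero_cell <- make_counts(matrix(c(1L, 0L, 0L, 0L), 2))
  expect_error(log_normalize(zero_cell), class = "rscope_validation_error")
})

test_that("variable-gene selection applies the mean window and z cutoff", {
  # identical genes: every dispersion equals the bin mean, z = 0, none selected
  flat <- make_nm(rep(c(1, 2, 1.5, 0.5), each = 10), n_genes = 10, n_cells = 4)
  vg <- find_variable_genes(flat)
  expect_true(all(vg$disp_z == 0))
  expect_false(any(vg$selected))

  # a low-mean gene is excluded regardless of dispersion
  set.seed(2)
  m <- matrix(abs(rnorm(40 * 20, 1, 0.3)), 40, 20)
  m[1, ] <- c(rep(0.01, 19), 0.05)  # mu below 0.0125
  nm <- make_nm(m)
  vg2 <- find_variable_genes(nm)
  expect_true(vg2$mu[1] < 0.0125)
  expect_false(vg2$selected[1])
})

test_that("within-bin dispersion z-scores match a direct computation", {
  # 50 flat genes plus one variance-inflated gene, all in one mean bin
  set.seed(3)
  m <- matrix(abs(rnorm(51 * 40, 1, 0.08)), 51, 40)
  m[51, ] <- rep(c(0.3, 1.8), 20) + rnorm(40, 0, 0.02)  # inflated variance
  nm <- make_nm(m)
  vg <- find_variable_genes(nm, n_bins = 1)  # single bin isolates the z-score rule
  ex <- expm1(m)
  disp <- log(apply(ex, 1, var) / rowMeans(ex))
  z_direct <- (disp - mean(disp)) / sd(disp)
  expect_equal(vg$disp_z, unname(z_direct), tolerance = 1e-10)
  expect_true(vg$selected[51])
  expect_equal(which(vg$disp_z > 3), 51L)
})

test_that("covariate regression matches lm and handles degenerate cases", {
  set.seed(4)
  numi <- runif(30, 800, 4000)
  y <- 0.5 * numi + rnorm(30, 0, 0.1)
  flat <- rnorm(30, 2, 0.5)
  nm <- make_nm(rbind(0.001 * y, flat), n_genes = 2, n_cells = 30)
  out <- regress_and_scale(nm, numi)

  # perfectly linear gene: residuals collapse, row is zeroed by the sd guard
  exact <- make_nm(rbind(2 + 0.003 * numi), n_genes = 1, n_cells = 30)
  expect_equal(unname(regress_and_scale(exact, numi)[1, ]), rep(0, 30))

  # noisy gene: equals scaled lm residuals
  fit <- lm(flat ~ numi)
  expect_equal(unname(out[2, ]), unname(scale(resid(fit))[, 1]), tolerance = 1e-8)

  # constant covariate reduces to centering + scaling
  cc <- regress_and_scale(nm, rep(5, 30))
  expect_equal(unname(cc[2, ]), unname(scale(flat)[, 1]), tolerance = 1e-10)

  # clipping bounds extreme values
  spike <- make_nm(rbind(c(rep(0, 29), 100)), n_genes = 1, n_cells = 30)
  expect_lte(max(regress_and_scale(spike, numi, clip = 2)), 2)
})

test_that("PCA is exact, orthonormal, sign-fixed, and flags rank deficiency", {
  set.seed(5)
  m <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:30)))
  p <- run_pca(m, n_pcs = 5)
  expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(p$variance) <= 1e-12))
  # variances equal eigenvalues of the sample covariance of cells
  ev <- eigen(cov(t(m)), symmetric = TRUE)$values
  expect_equal(p$variance, ev[1:5], tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in 1:5) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)

  # rank-2 data: trailing variances collapse, with a warning
  low <- tcrossprod(matrix(rnorm(20 * 2), 20, 2), matrix(rnorm(15 * 2), 15, 2))
  dimnames(low) <- list(paste0("g", 1:20), paste0("c", 1:15))
  expect_warning(p2 <- run_pca(low, n_pcs = 11), "zero variance")
  expect_true(all(p2$variance[3:11] < 1e-8))

  expect_error(run_pca(m, n_pcs = 25), class = "rscope_validation_error")
})

test_that("PC1 separates two planted cell groups", {
  set.seed(6)
  m <- matrix(rnorm(40 * 60), 40, 60,
              dimnames = list(paste0("g", 1:40), paste0("c", 1:60)))
  m[1:10, 1:30] <- m[1:10, 1:30] + 6
  p <- run_pca(m, n_pcs = 3)
  grp <- rep(c(1, 0), each = 30)
  expect_gt(abs(cor(p$coords[, 1], grp)), 0.99)
})

test_that("SNN-Louvain recovers separated blobs and respects resolution", {
  x <- make_blobs(200, list(0, 10), seed = 0)
  cl <- cluster_snn_louvain(x, seed = 0)
  expect_equal(length(unique(cl)), 2)
  expect_equal(ari(cl, rep(1:2, each = 200)), 1)

  one <- make_blobs(300, list(0), seed = 0)
  expect_equal(length(unique(cluster_snn_louvain(one, resolution = 0.1, seed = 0))), 1)

  expect_error(cluster_snn_louvain(x[1:10, ], k_neighbors = 30),
               class = "rscope_validation_error")
})

test_that("clustering is invariant to cell order up to relabeling", {
  x <- make_blobs(150, list(0, 10, -10), seed = 1)
  cl <- cluster_snn_louvain(x, seed = 0)
  perm <- withr::with_seed(99, sample(nrow(x)))
  cl_perm <- cluster_snn_louvain(x[perm, ], seed = 0)
  expect_equal(ari(cl_perm, cl[perm]), 1)
})

test_that("composition percentages are exact and size-normalization corrects depth", {
  cl <- c(rep(0, 40), rep(1, 20))
  cond <- c(rep("SPF", 30), rep("GF", 10), rep("SPF", 15), rep("GF", 5))
  comp <- cluster_composition(cl, cond)
  c0 <- comp[comp$cluster == 0, ]
  expect_equal(c0$pct[c0$condition == "SPF"], 75)
  expect_equal(c0$pct[c0$condition == "GF"], 25)

  # one condition only
  one <- cluster_composition(cl, rep("SPF", 60))
  expect_true(all(one$pct == 100) && all(one$norm_pct == 100))

  # unequal condition totals: 400 vs 200 cells, focal cluster 40 + 20
  cl2 <- c(rep(0, 60), rep(1, 540))
  cond2 <- c(rep("SPF", 40), rep("GF", 20), rep("SPF", 360), rep("GF", 180))
  comp2 <- cluster_composition(cl2, cond2)
  f <- comp2[comp2$cluster == 0, ]
  expect_equal(f$pct[f$condition == "SPF"], 200 / 3, tolerance = 1e-10)
  expect_equal(f$pct[f$condition == "GF"], 100 / 3, tolerance = 1e-10)
  expect_equal(f$norm_pct[f$condition == "SPF"], 50)
  expect_equal(f$norm_pct[f$condition == "GF"], 50)
})

test_that("composition-shift flag marks only strongly underrepresented clusters", {
  cl <- rep(0:1, each = 300)
  cond <- c(rep(c("SPF", "GF"), 150),            # cluster 0 balanced
            rep("SPF", 270), rep("GF", 30))      # cluster 1 GF-depleted
  fl <- flag_composition_shift(cluster_composition(cl, cond), "GF")
  expect_identical(fl$depleted, c(FALSE, TRUE))
  expect_error(flag_composition_shift(cluster_composition(cl, cond), "nope"),
               class = "rscope_validation_error")
})
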