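test_that("RSS is 1 for perfectly concentrated activity and matches the JSD oracle", {
  cl <- c(0, 0, 1, 1, 1)
  am <- matrix(c(1, 1, 0, 0, 0), 1, 5,
               dimnames = list("A(+)", paste0("c", 1:5)))
  rss <- compute_rss(am, cl)
  expect_equal(rss["A(+)", "0"], 1)

  # uniform activity over 4 cells against a 2-cell cluster
  am2 <- matrix(1, 1, 4, dimnames = list("U(+)", paste0("c", 1:4)))
  rss2 <- compute_rss(am2, c(0, 0, 1, 1))
  expect_equal(rss2["U(+)", "0"], 0.4420770, tolerance = 1e-6)
  expect_equal(rss2["U(+)", "0"],
               oracle_rss(rep(1, 4), c(1, 1, 0, 0)), tolerance = 1e-12)

  # scale invariance of the activity row
  set.seed(20)
  am3 <- matrix(runif(12), 2, 6, dimnames = list(c("A", "B"), paste0("c", 1:6)))
  cl3 <- c(0, 0, 1, 1, 2, 2)
  expect_equal(compute_rss(am3 * 37.5, cl3), compute_rss(am3, cl3))

  # all-zero rows come back as NA with a warning
  am4 <- rbind(am3, Z = 0)
  expect_warning(rss4 <- compute_rss(am4, cl3), "all-zero")
  expect_true(all(is.na(rss4["Z", ])))
  expect_false(anyNA(rss4[c("A", "B"), ]))
})

test_that("RSS decreases when activity mass moves out of the cluster", {
  set.seed(21)
  cl <- rep(0:1, each = 10)
  for (i in 1:100) {
    ras <- runif(20, 0.05, 1)
    base <- compute_rss(matrix(ras, 1, 20, dimnames = list("R", paste0("c", 1:20))),
                        cl)["R", "0"]
    inside <- sample(which(cl == 0), 1)
    outside <- sample(which(cl == 1), 1)
    eps <- runif(1, 0.01, 0.9) * ras[inside]
    shifted <- ras
    shifted[inside] <- shifted[inside] - eps
    shifted[outside] <- shifted[outside] + eps
    moved <- compute_rss(matrix(shifted, 1, 20,
                                dimnames = list("R", paste0("c", 1:20))),
                         cl)["R", "0"]
    expect_lt(moved, base)
  }
})

test_that("RSSZ standardizes within clusters with the population convention", {
  rss <- matrix(c(0.2, 0.2, 0.8, 0.5, 0.5, 0.5), 3, 2,
                dimnames = list(paste0("R", 1:3), c("0", "1")))
  z <- compute_rssz(rss)
  expect_equal(unname(z[, "0"]), c(-1 / sqrt(2), -1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  expect_equal(unname(z[, "1"]), c(0, 0, 0))
  # a strictly dominant regulon has the unique maximal z
  rss2 <- matrix(c(0.3, 0.35, 0.9, 0.32), 4, 1,
                 dimnames = list(paste0("R", 1:4), "0"))
  z2 <- compute_rssz(rss2)
  expect_equal(which.max(z2[, 1]), 3L, ignore_attr = TRUE)
  expect_true(all(z2[-3, 1] < z2[3, 1]))
  expect_error(compute_rssz(rss[1, , drop = FALSE]),
               class = "rscope_validation_error")
})

test_that("the significance rule applies both cutoffs strictly", {
  spec <- data.frame(
    regulon = paste0("R", 1:4), cluster = 0,
    rss = c(0.9, 0.9, 0.9, 0.9),
    rssz = c(1.5, 0.9, 1.5, 1.2),
    mean_ras = c(0.2, 0.5, 0.21, 0.19))
  out <- significant_regulons(spec)
  flags <- out$significant[match(paste0("R", 1:4), out$regulon)]
  # R1: mean_ras exactly at the cutoff -> excluded (strict >)
  # R2: rssz below -> excluded; R3: both above -> included; R4: ras below
  expect_identical(flags, c(FALSE, FALSE, TRUE, FALSE))
  # sorted by decreasing rssz within cluster
  expect_equal(out$rssz, sort(out$rssz, decreasing = TRUE))
})

test_that("CSI matches brute-force counting and is a proper similarity", {
  # hand-specified correlation structure, verified cell by cell
  pcc <- matrix(c(1, 0.9, 0.1, 0.2,
                  0.9, 1, 0.15, 0.1,
                  0.1, 0.15, 1, 0.8,
                  0.2, 0.1, 0.8, 1), 4, 4,
                dimnames = list(paste0("R", 1:4), paste0("R", 1:4)))
  got <- rscope:::csi_from_cor(pcc, 0.05)
  expect_equal(got, oracle_csi(pcc, 0.05))
  expect_equal(got["R1", "R2"], 1)  # both others fall below 0.9 - 0.05
  expect_equal(got["R1", "R3"], 0)

  # exhaustive agreement for random instances up to N = 10
  set.seed(22)
  for (N in 4:10) {
    am <- matrix(rnorm(N * 12), N, 12,
                 dimnames = list(paste0("R", 1:N), paste0("m", 1:12)))
    csi <- compute_csi(am, delta = 0.05)
    expect_equal(unname(csi), unname(oracle_csi(attr(csi, "pcc"), 0.05)),
                 ignore_attr = TRUE)
    expect_true(isSymmetric(unname(csi)))
    expect_true(all(csi >= 0 & csi <= 1))
    expect_equal(unname(diag(csi)), rep(1, N))
  }

  # two regulons sharing a profile against a noise background
  set.seed(23)
  sig <- rnorm(30)
  am2 <- rbind(A = sig + rnorm(30, 0, 0.05), B = sig + rnorm(30, 0, 0.05),
               matrix(rnorm(8 * 30), 8, 30,
                      dimnames = list(paste0("N", 1:8), NULL)))
  colnames(am2) <- paste0("m", 1:30)
  expect_gt(compute_csi(am2)["A", "B"], 0.9)

  expect_error(compute_csi(am2[1:2, ]), class = "rscope_validation_error")
  expect_warning(compute_csi(rbind(am2, K = 1)), "constant")
})

test_that("module detection cuts the CSI tree into the planted blocks", {
  blocks <- rep(1:3, times = c(5, 4, 3))
  csi <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0.1))
  diag(csi) <- 1
  dimnames(csi) <- list(paste0("R", 1:12), paste0("R", 1:12))
  mod <- detect_modules(csi, n_modules = 3)
  expect_equal(ari(mod, blocks), 1)
  # ids ordered by decreasing size
  expect_equal(unname(table(mod)), c(5L, 4L, 3L), ignore_attr = TRUE)
  expect_equal(unique(mod[blocks == 1]), 1L)

  expect_equal(length(unique(detect_modules(csi, 1))), 1)
  expect_equal(length(unique(detect_modules(csi, 12))), 12)
  expect_error(detect_modules(csi, 13), class = "rscope_validation_error")

  # invariance to regulon input order up to relabeling
  perm <- withr::with_seed(5, sample(12))
  mod_perm <- detect_modules(csi[perm, perm], n_modules = 3)
  expect_equal(ari(mod_perm, blocks[perm]), 1)

  # sub-modules re-partition one module
  sub <- detect_submodules(csi, mod, module = 1, n_sub = 2)
  expect_length(sub, 5)
  expect_equal(length(unique(sub)), 2)
})

test_that("connectivity counts cells above the module-level AUCZ cutoff", {
  cl <- c(0, 0, 1, 1, 2, 2)
  aucz <- matrix(0, 4, 6, dimnames = list(paste0("R", 1:4), paste0("c", 1:6)))
  modules <- c(R1 = 1L, R2 = 1L, R3 = 2L, R4 = 2L)

  # all below the cutoff: every count zero
  conn0 <- connectivity(aucz, cl, modules)
  expect_true(all(conn0$count == 0) && all(conn0$fraction == 0))

  # one cell of cluster 2 crosses for module 1 only
  aucz2 <- aucz
  aucz2[c("R1", "R2"), "c5"] <- 3.0
  conn <- connectivity(aucz2, cl, modules)
  hit <- conn[conn$count > 0, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$cluster, 2)
  expect_equal(hit$module, 1)
  expect_equal(hit$count, 1)
  expect_equal(hit$fraction, 1)

  # counts can never exceed cluster sizes; fractions sum to <= 1 per cluster
  set.seed(24)
  auczr <- matrix(rnorm(4 * 6, 0, 2), 4, 6,
                  dimnames = dimnames(aucz))
  connr <- connectivity(auczr, cl, modules)
  sizes <- table(cl)
  for (i in seq_len(nrow(connr))) {
    expect_lte(connr$count[i], sizes[as.character(connr$cluster[i])])
  }
  agg <- tapply(connr$fraction, connr$cluster, sum)
  expect_true(all(agg <= 1 + 1e-12))

  expect_warning(connectivity(aucz, cl, c(modules, R9 = 3L)), "no scored")
})
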