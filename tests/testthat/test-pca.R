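test_that("imputation preserves observed cells and is deterministic", {
  set.seed(1)
  x <- matrix(runif(30 * 12, 0.1, 0.9), 30)
  expect_identical(impute_missing(x), x)  # nothing missing: unchanged
  miss <- sample(length(x), 40)
  xm <- x; xm[miss] <- NA
  for (m in c("forest", "knn", "mean")) {
    out <- impute_missing(xm, method = m, seed = 5, num_trees = 30)
    expect_identical(out[!is.na(xm)], xm[!is.na(xm)])
    expect_true(all(out >= 0 & out <= 1))
    expect_false(anyNA(out))
  }
  o1 <- impute_missing(xm, method = "forest", seed = 5, num_trees = 30)
  o2 <- impute_missing(xm, method = "forest", seed = 5, num_trees = 30)
  expect_identical(o1, o2)
  bad <- xm; bad[3, ] <- NA
  expect_error(impute_missing(bad), "no observed value")
})

test_that("structure-aware imputation beats per-site means on low-rank
          data", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    L <- matrix(rnorm(40 * 3), 40); F_ <- matrix(rnorm(3 * 30), 3)
    x <- plogis(L %*% F_ * 0.8)
    miss <- sample(length(x), round(0.1 * length(x)))
    xm <- x; xm[miss] <- NA
    knn <- impute_missing(xm, method = "knn", k = 8)
    mn <- impute_missing(xm, method = "mean")
    rmse <- function(y) sqrt(mean((y[miss] - x[miss])^2))
    wins <- wins + (rmse(knn) < rmse(mn))
  }
  expect_gte(wins, 9)
})

test_that("PCA reconstructs the matrix and matches an eigen oracle", {
  set.seed(2)
  x <- matrix(rnorm(20 * 15), 20)
  p <- compute_pcs(x)
  xc <- t(scale(t(x), scale = FALSE))  # centre over samples
  # X_centred (samples x sites) = scores %*% t(loadings)
  expect_equal(p$scores %*% t(p$loadings), scale(t(x), scale = FALSE),
               tolerance = 1e-8, ignore_attr = TRUE)
  ev <- eigen(cov(t(x)))$values
  expect_equal(p$sdev^2, ev[seq_along(p$sdev)], tolerance = 1e-10)
  # loadings are orthonormal, variance fractions sum to one
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(p$var_frac), 1)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (k in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  # rank-2 matrix concentrates variance on two components
  lr <- matrix(rnorm(20 * 2), 20) %*% matrix(rnorm(2 * 15), 2)
  p2 <- compute_pcs(lr)
  expect_gt(sum(p2$var_frac[1:2]), 0.999)
  expect_error(compute_pcs(matrix(1, 4, 4)), "zero-variance")
})

test_that("sample permutation permutes scores and not variance fractions", {
  set.seed(3)
  x <- matrix(rnorm(15 * 12), 15)
  p1 <- compute_pcs(x)
  perm <- sample(12)
  p2 <- compute_pcs(x[, perm])
  expect_equal(p2$scores, p1$scores[perm, ], ignore_attr = TRUE)
  expect_equal(p2$var_frac, p1$var_frac)
})

test_that("plateau rule keeps dominant components only", {
  expect_equal(choose_n_pcs(c(0.5, 0.3, rep(0.01, 20))), 2)
  expect_equal(choose_n_pcs(rep(1 / 30, 30)), 1)  # flat spectrum
  expect_equal(choose_n_pcs(c(0.9, rep(0.1 / 29, 29))), 1)
  fm <- simulate_factor_matrix(n_factors = 5, seed = 8)
  expect_equal(choose_n_pcs(compute_pcs(fm$mat)$var_frac), 5)
})

test_that("PC-variable association dispatches by variable role", {
  co <- small_cohort()
  em <- compute_editing_levels(co$counts)
  m <- impute_missing(em$ratio[co$truth$strong_sites, ], method = "knn")
  p <- compute_pcs(m)
  cells4 <- co$cells[, c("dc", "monocytes", "neutrophils", "th")]
  vars <- data.frame(dc = co$cells$dc, fake = p$scores[, 1],
                     row.names = rownames(p$scores))
  res <- pc_variable_association(p$scores[, 1:3], vars, cells4)
  expect_equal(res$kind[res$variable == "dc"][1], "cell_fraction")
  expect_equal(res$kind[res$variable == "fake"][1], "biological")
  # a variable equal to PC1 scores is significant for PC1 only
  p_fake <- res[res$variable == "fake", ]
  expect_lt(p_fake$p[p_fake$pc == 1], 1e-12)
  expect_gt(min(p_fake$p[p_fake$pc != 1]), 1e-4)
  expect_error(pc_variable_association(p$scores[1:10, ], vars, cells4),
               "misaligned")
})

test_that("a driver planted on factor 2 lights up PC2 and not PC1", {
  hits <- 0
  for (s in 1:10) {
    fm <- simulate_factor_matrix(n_sites = 120, n_samples = 80,
                                 n_factors = 3, seed = 100 + s)
    p <- compute_pcs(fm$mat)
    # which PC picked up planted factor 2?
    cors <- abs(cor(fm$factors[2, ], p$scores[, 1:3]))
    driver <- fm$factors[2, ] + rnorm(80, 0, 0.4)
    cells <- data.frame(c1 = rnorm(80), c2 = rnorm(80))
    res <- pc_variable_association(
      p$scores[, 1:3], data.frame(drv = driver), cells)
    hits <- hits + (which.min(res$p) == which.max(cors))
  }
  expect_gte(hits, 8)
})

test_that("site-PC correlation classes follow the literal bands", {
  set.seed(5)
  n <- 60
  s1 <- rnorm(n)
  scores <- cbind(PC1 = s1)
  mat <- rbind(
    exact = s1,                                  # |r| = 1
    moderate = 0.45 * scale(s1)[, 1] + sqrt(1 - 0.45^2) * rnorm(n),
    noise = rnorm(n))
  res <- classify_site_pc_correlation(mat, scores, alpha = 0.05)
  # |r| = 1 lies outside both literal bands
  expect_equal(as.character(res$band[res$site_id == "exact"]), "none")
  expect_equal(as.character(res$class[res$site_id == "exact"]), "strong")
  ex <- res[res$site_id == "moderate", ]
  if (abs(ex$r) >= 0.3 && abs(ex$r) <= 0.5 && ex$p < 0.05 / 3)
    expect_equal(as.character(ex$band), "moderate")
  # direct classification oracle on random data
  mat2 <- matrix(rnorm(10 * n), 10,
                 dimnames = list(paste0("s", 1:10), NULL))
  res2 <- classify_site_pc_correlation(mat2, scores, alpha = 0.05)
  thr <- 0.05 / (10 * 1)
  for (i in 1:10) {
    ct <- cor.test(mat2[i, ], s1)
    row <- res2[res2$site_id == paste0("s", i), ]
    expect_equal(row$r, unname(ct$estimate))
    want <- if (ct$p.value >= thr) "none"
    else if (abs(ct$estimate) > 0.5) "none"
    else if (abs(ct$estimate) >= 0.3) "moderate" else "weak"
    expect_equal(as.character(row$band), want)
  }
})
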