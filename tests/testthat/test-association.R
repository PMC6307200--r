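test_that("ridge residualisation reduces to least squares and to centring", {
  set.seed(1)
  n <- 40
  Z <- matrix(rnorm(n * 3), n)
  Y <- matrix(rnorm(5 * n), 5, dimnames = list(paste0("g", 1:5), NULL))
  # closed-form oracle at lambda = 1
  lam <- 1
  Zc <- scale(Z, scale = FALSE)
  for (i in 1:5) {
    yc <- Y[i, ] - mean(Y[i, ])
    beta <- solve(t(Zc) %*% Zc + lam * diag(3), t(Zc) %*% yc)
    expect_equal(unname(ridge_residualize(Y, Z, lam)[i, ]),
                 unname(yc - as.numeric(Zc %*% beta)), tolerance = 1e-10)
  }
  # lambda -> Inf shrinks the fit to the intercept
  expect_equal(unname(ridge_residualize(Y, Z, 1e12)),
               unname(Y - rowMeans(Y)), tolerance = 1e-6)
  # covariates orthogonal to expression at lambda = 0: centred expression
  Zo <- matrix(rep(c(-1, 1), each = n / 2), n, 1)
  Yo <- matrix(rep(rnorm(n / 2), 2), 1)  # symmetric, orthogonal to Zo
  expect_equal(unname(ridge_residualize(Yo, Zo, 0)),
               unname(Yo - rowMeans(Yo)), tolerance = 1e-10)
  expect_error(ridge_residualize(Y, cbind(Z, Z[, 1]), 0), "lambda")
})

test_that("robust association agrees with OLS on clean gaussian data", {
  set.seed(2)
  n <- 200
  z <- matrix(rnorm(2 * n), n)
  x <- rnorm(n)
  y <- 0.4 * x + z %*% c(0.2, -0.1) + rnorm(n)
  rob <- robust_association(y, x, z, method = "huber")
  ols <- robust_association(y, x, z, method = "ols")
  expect_lt(abs(rob$beta - ols$beta), 2 * ols$se)
  expect_lt(rob$p, 1e-6)
  expect_gt(rob$partial_r2, 0.05)
  # OLS flavour matches lm() exactly
  fit <- lm(y ~ z + x)
  expect_equal(ols$beta, unname(coef(fit)["x"]), tolerance = 1e-10)
  expect_equal(ols$p, summary(fit)$coefficients["x", 4],
               tolerance = 1e-8)
})

test_that("nested-model p is invariant to affine covariate rescaling", {
  set.seed(3)
  n <- 120
  z <- matrix(rnorm(2 * n), n)
  x <- rnorm(n)
  y <- 0.3 * x + z[, 1] + rnorm(n)
  a1 <- robust_association(y, x, z)
  a2 <- robust_association(y, x, sweep(z, 2, c(100, 0.01), `*`) + 5)
  expect_equal(a1$p, a2$p, tolerance = 1e-6)
  expect_equal(a1$partial_r2, a2$partial_r2, tolerance = 1e-6)
})

test_that("constant predictors are flagged degenerate with p = 1", {
  set.seed(4)
  a <- robust_association(rnorm(50), rep(2, 50), NULL)
  expect_true(a$degenerate)
  expect_equal(a$p, 1)
  expect_equal(a$partial_r2, 0)
})

test_that("genome-wide scan recovers planted genes and ADAR removal drops
          mediated ones", {
  co <- generate_cohort(small_sim_config(
    seed = 7, n_samples = 220, n_sites = 150, n_genes = 150,
    n_snps = 100, n_assoc_genes = 20, n_mediated_genes = 10))
  rate <- total_editing_rate(co$counts, co$truth$strong_sites)
  cells4 <- co$cells[, c("dc", "monocytes", "neutrophils", "th")]
  depth <- log2(colSums(
    (co$counts$a + co$counts$g)[co$truth$strong_sites, ]))
  cov <- cbind(cells4, depth = depth)
  scan <- genomewide_expression_scan(co$expression, rate, cov,
                                     min_genes = 50)
  expect_equal(nrow(scan), nrow(co$expression))
  expect_true(all(scan$fdr >= scan$p))
  # BH monotone: ordering by fdr respects ordering by p
  o <- order(scan$p)
  expect_true(all(diff(scan$fdr[o]) >= -1e-12))
  # ADAR is strongly associated and lands in the significant tier
  expect_lt(scan$p[scan$gene == "ADAR"], 1e-3)
  expect_true(scan$sig05[scan$gene == "ADAR"])
  # planted direct genes are recovered
  expect_gte(mean(scan$sig05[scan$gene %in% co$truth$assoc_genes]), 0.75)
  # after removing the ADAR effect, ADAR itself explains ~ nothing
  # (self-regression guard) and ADAR-mediated genes drop out while
  # direct ones survive
  scan2 <- genomewide_expression_scan(co$expression, rate, cov,
                                      remove_adar = TRUE, min_genes = 50)
  expect_lt(scan2$partial_r2[scan2$gene == "ADAR"], 0.02)
  med_before <- scan$sig05[scan$gene %in% co$truth$mediated_genes]
  med_after <- scan2$sig05[scan2$gene %in% co$truth$mediated_genes]
  expect_lt(sum(med_after), sum(med_before))
  expect_gte(mean(scan2$sig05[scan2$gene %in% co$truth$assoc_genes]),
             0.75)
  expect_error(genomewide_expression_scan(
    co$expression[setdiff(rownames(co$expression), "ADAR"), ], rate, cov,
    remove_adar = TRUE, min_genes = 50), "ADAR")
})

test_that("variable tests dispatch on kind and adjust for cells", {
  co <- small_cohort()
  rate <- total_editing_rate(co$counts, co$truth$strong_sites)
  cells4 <- co$cells[, c("dc", "monocytes", "neutrophils", "th")]
  # continuous variable equal to the target: r = 1, p ~ 0
  v <- variable_association(rate, "continuous", rate, cells4)
  expect_equal(v$r, 1, tolerance = 1e-12)
  expect_lt(v$p, 1e-20)
  expect_equal(v$test, "pearson")
  # binary variable with identical group value distributions: p = 1
  y <- rep(rnorm(30), 2)
  grp <- rep(c(0, 1), each = 30)
  cells60 <- cells4[rep(1:30, 2), ]
  vb <- variable_association(grp, "binary", y, cells60)
  expect_gte(vb$p, 0.99)
  expect_equal(vb$test, "wilcoxon")
  # categorical dispatch
  vc <- variable_association(sample(letters[1:3], 60, TRUE),
                             "categorical", rnorm(60), cells60)
  expect_equal(vc$test, "kruskal-wallis")
  # kind/data mismatches
  expect_error(variable_association(sample(letters[1:3], 60, TRUE),
                                    "binary", rnorm(60), cells60),
               "2 levels")
  expect_error(variable_association(rnorm(20), "continuous", rnorm(20),
                                    cells4[1:20, ]), "fewer than")
})

test_that("hypergeometric enrichment matches phyper conventions", {
  bg <- paste0("g", 1:20)
  sets <- list(all = bg, none = paste0("x", 1:5),
               some = paste0("g", 1:8))
  # significant = background: p = 1 for every testable set
  res <- hypergeometric_enrichment(bg, bg, list(c1 = sets))
  expect_true(all(res$p[res$note == ""] == 1))
  expect_equal(res$note[res$set_id == "none"], "no_background_overlap")
  # zero overlap still gives p = 1 (upper tail includes the observed 0)
  res2 <- hypergeometric_enrichment(paste0("g", 9:14), bg,
                                    list(c1 = list(s = paste0("g", 1:8))))
  expect_equal(res2$p, 1)
  expect_error(hypergeometric_enrichment("zzz", bg, list()), "subset")
})

test_that("gmt collections round-trip through the enrichment interface", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), path)
  res <- hypergeometric_enrichment(c("g1", "g2"), paste0("g", 1:10),
                                   list(db = path))
  expect_equal(res$overlap[res$set_id == "setA"], 2)
  expect_equal(res$overlap[res$set_id == "setB"], 0)
})
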