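clean_panel <- function(n = 80, m = 1500, seed = 1) {
  set.seed(seed)
  freq <- runif(m, 0.2, 0.5)
  dos <- sapply(freq, function(f) rbinom(n, 2, f))
  colnames(dos) <- paste0("snp", seq_len(m))
  rownames(dos) <- paste0("I", seq_len(n))
  map <- data.frame(snp = colnames(dos), chrom = "chr1",
                    pos = seq_len(m) * 1000, a1 = "A", a2 = "G")
  genotype_set(map, dos)
}

test_that("HWE exact test matches enumeration and handles extremes", {
  expect_equal(hwe_fisher(100, 0, 0), 1)        # monomorphic
  expect_equal(hwe_fisher(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
  for (cnt in list(c(3, 5, 2), c(10, 2, 8), c(0, 10, 0), c(7, 0, 3)))
    expect_equal(do.call(hwe_fisher, as.list(cnt)),
                 do.call(hwe_oracle, as.list(cnt)), tolerance = 1e-12)
  # extreme heterozygote deficit
  p_def <- hwe_fisher(50, 0, 50)
  expect_lt(p_def, 1e-6)
  expect_equal(p_def, hwe_oracle(50, 0, 50), tolerance = 1e-10)
})

test_that("QC removes the documented sample and SNP classes", {
  g <- clean_panel()
  q <- genotype_qc(g)
  att <- attr(q, "attrition")
  expect_equal(sum(att$n_removed), 0)           # clean panel: no removals
  # 2% missing genotypes: sample removed
  d <- g$dosage
  d[1, seq_len(ceiling(0.02 * ncol(d)))] <- NA
  q2 <- genotype_qc(genotype_set(g$map, d))
  a2 <- attr(q2, "attrition")
  expect_equal(a2$n_removed[a2$filter == "sample_missingness"], 1)
  # MAF 0.005 SNP removed and attributed to the maf filter
  d3 <- g$dosage
  d3[, 1] <- 0; d3[1, 1] <- 1  # one het in 80 samples: maf = 1/160
  q3 <- genotype_qc(genotype_set(g$map, d3))
  a3 <- attr(q3, "attrition")
  expect_equal(a3$n_removed[a3$filter == "maf"], 1)
  expect_false("snp1" %in% q3$map$snp)
  # attrition counts sum: removed + retained = input, per axis
  expect_equal(nrow(q3$map) +
                 sum(a3$n_removed[a3$filter %in%
                                    c("snp_missingness", "hwe", "maf")]),
               nrow(g$map))
})

test_that("duplicated samples are flagged as related and one is removed", {
  g <- clean_panel(seed = 3)
  d <- g$dosage
  d[2, ] <- d[1, ]  # identical twins: PI_HAT ~ 1
  q <- genotype_qc(genotype_set(g$map, d))
  a <- attr(q, "attrition")
  expect_equal(a$n_removed[a$filter == "relatedness"], 1)
})

test_that("genotype PCs separate planted populations", {
  set.seed(6)
  n <- 60; m <- 120
  f1 <- runif(m, 0.1, 0.9)
  f2 <- pmin(pmax(f1 + sample(c(-1, 1), m, TRUE) * 0.3, 0.02), 0.98)
  pop <- rep(c(1, 2), each = n / 2)
  dos <- t(sapply(pop, function(p)
    rbinom(m, 2, if (p == 1) f1 else f2)))
  dimnames(dos) <- list(paste0("I", 1:n), paste0("snp", 1:m))
  map <- data.frame(snp = colnames(dos), chrom = "chr1",
                    pos = seq_len(m) * 500, a1 = "A", a2 = "C")
  pcs <- genotype_pcs(genotype_set(map, dos), k = 2)
  # silhouette of PC1 split
  s1 <- pcs[pop == 1, 1]; s2 <- pcs[pop == 2, 1]
  sep <- abs(mean(s1) - mean(s2)) / (sd(s1) + sd(s2))
  expect_gt(sep, 1)
  expect_error(genotype_pcs(clean_panel(20, 10), k = 15), "rank")
})

test_that("allele flips negate beta but keep p and r2", {
  g <- clean_panel(seed = 9)
  set.seed(9)
  rate <- 0.1 + 0.004 * g$dosage[, 5] + rnorm(80, 0, 0.01)
  sa <- snp_association(g, rate)
  flip <- g
  flip$dosage[, 5] <- 2 - flip$dosage[, 5]
  sf <- snp_association(flip, rate)
  expect_equal(sf$BETA[5], -sa$BETA[5], tolerance = 1e-10)
  expect_equal(sf$P[5], sa$P[5], tolerance = 1e-10)
  expect_equal(ld_r2(g$dosage[, 5], 2 - g$dosage[, 5]), 1)
  expect_equal(ld_r2(g$dosage[, 5], g$dosage[, 5]), 1)
  # independent dosages have near-zero r2
  set.seed(10)
  expect_lt(ld_r2(rbinom(1000, 2, 0.3), rbinom(1000, 2, 0.3)), 0.02)
  expect_error(ld_r2(rep(1, 10), rbinom(10, 2, 0.5)), "zero-variance")
  # monomorphic SNP is skipped with a note
  g2 <- clean_panel(seed = 4)
  g2$dosage[, 2] <- 2
  sa2 <- snp_association(g2, rate)
  expect_equal(sa2$note[2], "monomorphic")
  expect_true(is.na(sa2$P[2]))
})

test_that("clumping is greedy by p with window and r2 rules", {
  # two SNPs 10 kb apart in strong LD collapse into one clump
  set.seed(12)
  base <- rbinom(100, 2, 0.4)
  noisy <- base; flip <- sample(100, 5)
  noisy[flip] <- sample(0:2, 5, TRUE)
  dos <- cbind(s1 = base, s2 = noisy, s3 = rbinom(100, 2, 0.4))
  rownames(dos) <- paste0("I", 1:100)
  map <- data.frame(snp = c("s1", "s2", "s3"), chrom = "chr1",
                    pos = c(100000, 110000, 90000000),
                    a1 = "A", a2 = "G")
  g <- genotype_set(map, dos)
  assoc <- data.frame(SNP = c("s1", "s2", "s3"), P = c(1e-8, 1e-5, 0.3))
  cl <- clump(assoc, g)
  expect_equal(length(cl), 2)
  expect_equal(cl[[1]]$index, "s1")
  expect_setequal(cl[[1]]$members$snp, c("s1", "s2"))
  # single SNP forms a singleton clump
  cl1 <- clump(assoc[3, , drop = FALSE], g)
  expect_equal(length(cl1), 1)
  expect_equal(cl1[[1]]$members$snp, "s3")
  # membership partitions all tested SNPs
  expect_setequal(unlist(lapply(cl, function(x) x$members$snp)),
                  assoc$SNP)
})

test_that("clumping matches an independent greedy reference on simulated
          LD blocks", {
  co <- small_cohort(seed = 77)
  g <- co$genotypes
  keep <- colSums(is.na(g$dosage)) == 0
  g <- genotype_set(g$map[keep, ], g$dosage[, keep])
  set.seed(77)
  assoc <- data.frame(SNP = g$map$snp, P = runif(nrow(g$map)))
  got <- clump(assoc, g, window_kb = 300, r2_min = 0.5)
  # reference: an independently coded greedy pass over a p-sorted table
  ref_members <- ref_clump(assoc, g, window_kb = 300, r2_min = 0.5)
  expect_equal(length(got), length(ref_members))
  for (cl in got)
    expect_identical(sort(cl$members$snp), ref_members[[cl$index]])
})

test_that("SNP-set variance prunes duplicates and matches nested lm", {
  g <- clean_panel(seed = 21)
  set.seed(21)
  z <- matrix(rnorm(160), 80)
  rate <- 0.1 + 0.003 * g$dosage[, 1] + z %*% c(0.01, 0.005) +
    rnorm(80, 0, 0.008)
  sv <- snpset_variance(c("snp1", "snp2"), g, rate, z)
  m0 <- lm(rate ~ z)
  m1 <- lm(rate ~ z + g$dosage[, 1] + g$dosage[, 2])
  expect_equal(sv$r2, 1 - sum(resid(m1)^2) / sum(resid(m0)^2),
               tolerance = 1e-10)
  expect_equal(sv$p, anova(m0, m1)[2, "Pr(>F)"], tolerance = 1e-10)
  # duplicated SNP in the set is pruned, result unchanged
  g2 <- g
  g2$map$snp[3] <- "dup"; colnames(g2$dosage)[3] <- "dup"
  g2$dosage[, 3] <- g2$dosage[, 1]
  sv2 <- snpset_variance(c("snp1", "dup", "snp2"), g2, rate, z)
  expect_equal(sv2$r2, sv$r2, tolerance = 1e-10)
  expect_equal(sv2$pruned, "dup")
  expect_error(snpset_variance(character(0), g, rate, z), "empty")
})
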