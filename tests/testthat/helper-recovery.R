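# Full-scale parameter-recovery runs are expensive, so they are computed
# once per test session and shared between the acceptance blocks that
# assert different aspects of the same study conditions
# (450 subjects, 2000 sites, 5000 SNPs, 20 seeds).

.recovery_cache <- new.env(parent = emptyenv())

recovery_results <- function(n_seeds = 20) {
  if (!is.null(.recovery_cache$res)) return(.recovery_cache$res)
  adar_pr2 <- h2 <- numeric(n_seeds)
  top_clump <- logical(n_seeds)
  beta_ok <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    co <- generate_cohort(sim_config(seed = i))
    rate <- total_editing_rate(co$counts, co$truth$strong_sites)
    cells4 <- co$cells[, c("dc", "monocytes", "neutrophils", "th")]
    depth <- log2(colSums(
      (co$counts$a + co$counts$g)[co$truth$strong_sites, ]))
    cov <- cbind(cells4, depth = depth)
    adar_pr2[i] <- robust_association(rate, co$expression["ADAR", ],
                                      cov)$partial_r2
    q <- genotype_qc(co$genotypes)
    sm <- rownames(q$dosage)
    gcov <- cbind(cov[sm, ], genotype_pcs(q, k = 5))
    sa <- snp_association(q, rate[sm], gcov)
    cl <- clump(sa, q)
    top_clump[i] <- co$truth$causal_snp %in% cl[[1]]$members$snp
    est <- sa$BETA[sa$SNP == co$truth$causal_snp]
    se <- sa$SE[sa$SNP == co$truth$causal_snp]
    beta_ok[i] <- length(est) == 1 && !is.na(est) &&
      abs(est - co$truth$eqtl_beta_rate) < 2 * se
    set_snps <- intersect(co$truth$eqtl_set, q$map$snp)
    h2[i] <- snpset_variance(set_snps, q, rate[sm], gcov)$r2
  }
  .recovery_cache$res <- list(adar_pr2 = adar_pr2, top_clump = top_clump,
                              beta_ok = beta_ok, h2 = h2)
  .recovery_cache$res
}
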