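# Shared fixtures: a small synthetic cohort reused across test files, and
# a builder for quick editing matrices. Everything is generated in code.

small_sim_config <- function(seed = 42, ...) {
  args <- list(n_samples = 60, n_sites = 120, n_genes = 150, n_snps = 200,
               seed = seed, n_assoc_genes = 15, n_mediated_genes = 8)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

.cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function(seed = 42) {
  key <- paste0("c", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(small_sim_config(seed = seed))
  .cohort_cache[[key]]
}

# editing_matrix straight from a ratio matrix (coverage set high enough
# that nothing is masked); NA entries stay missing
em_from_ratio <- function(ratio, coverage = 100) {
  cov <- matrix(coverage, nrow(ratio), ncol(ratio),
                dimnames = dimnames(ratio))
  cov[is.na(ratio)] <- 0
  structure(list(ratio = ratio, coverage = cov, min_coverage = 10),
            class = "editing_matrix")
}

random_counts <- function(n_sites, n_samples, seed, max_reads = 60) {
  set.seed(seed)
  a <- matrix(rpois(n_sites * n_samples, max_reads / 3), n_sites,
              dimnames = list(paste0("chr1_", 1000 + seq_len(n_sites) * 10),
                              paste0("S", seq_len(n_samples))))
  g <- matrix(rpois(n_sites * n_samples, max_reads / 6), n_sites,
              dimnames = dimnames(a))
  edit_counts(a, g)
}

granges_interval <- function(chrom, start1, end1) {
  # 1-based closed interval, as rtracklayer returns for BED
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1))
}
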