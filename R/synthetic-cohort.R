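# Fully synthetic blood-editing cohort with recorded planted truth.
#
# The generator emulates the statistical structure the downstream modules
# are designed to detect: per-site editing probabilities on the logit
# scale, a sample-level signal split between an ADAR-expression component
# (a configurable share of the covariate-adjusted signal variance), a
# cell-composition component, an eQTL dosage component in an LD block, and
# unexplained noise; negative-binomial sequencing depth with binomial
# edited-read counts on top.

#' Build and validate a simulation configuration
#'
#' Defaults describe the emulated study conditions: 450 subjects, 2000
#' consistently edited sites (plus weak and excluded decoy sites), 3000
#' genes, 5000 SNPs in LD blocks, an ADAR-expression effect carrying 13%
#' of the covariate-adjusted signal variance in the total editing rate,
#' and a planted eQTL with a per-allele effect of about 0.004 on the rate
#' scale.
#'
#' @param n_samples,n_sites,n_genes,n_snps cohort dimensions.
#' @param seed master seed; every output stream derives its own seed from
#'   it, so regenerating a single component is reproducible.
#' @param adar_r2 share of the signal variance (beyond cell composition)
#'   carried by ADAR expression, in \[0, 1\].
#' @param eqtl_beta per-allele effect of the causal SNP on the logit of
#'   per-site editing.
#' @param cell_fraction_dirichlet 7 positive Dirichlet concentrations for
#'   the blood cell fractions (neutrophils, Th, monocytes, B, NK, DC,
#'   eosinophils).
#' @param coverage_mean,coverage_dispersion negative-binomial read-depth
#'   parameters (mean reads per site, dispersion size).
#' @param prevalence_spectrum `"blood"` (moderate editing 0.06-0.36 with a
#'   small highly edited tail) or `"uniform"`.
#' @param network_enrichment_odds odds ratio wiring truly associated genes
#'   into the ADAR neighbourhood of the synthetic PPI network.
#' @param signal_sd sd of the sample-level signal (logit scale) beyond
#'   cell composition.
#' @param cell_effect_sd sd of the cell-composition component (logit).
#' @param site_noise_sd sd of per-site, per-sample logit noise.
#' @param n_assoc_genes,n_mediated_genes planted genes associated with the
#'   rate directly (surviving ADAR removal) and only through ADAR.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 450, n_sites = 2000, n_genes = 3000,
                       n_snps = 5000, seed = 1, adar_r2 = 0.13,
                       eqtl_beta = 0.032,
                       cell_fraction_dirichlet =
                         c(neutrophils = 28, th = 10, monocytes = 5,
                           b = 4, nk = 3, dc = 2, eosinophils = 2),
                       coverage_mean = 40, coverage_dispersion = 5,
                       prevalence_spectrum = "blood",
                       network_enrichment_odds = 10,
                       signal_sd = 0.10, cell_effect_sd = 0.12,
                       site_noise_sd = 0.30,
                       n_assoc_genes = 50, n_mediated_genes = 30) {
  chk_count <- function(x, f, lo = 1) if (length(x) != 1 || is.na(x) ||
                                          x < lo || x != round(x))
    config_error(f, paste("must be an integer >=", lo))
  chk_count(n_samples, "n_samples", 10)
  chk_count(n_sites, "n_sites", 10)
  chk_count(n_genes, "n_genes", 10)
  chk_count(n_snps, "n_snps", 20)
  chk_count(seed, "seed", 0)
  if (!is.numeric(adar_r2) || adar_r2 < 0 || adar_r2 > 1)
    config_error("adar_r2", "must be a fraction in [0, 1]")
  if (!is.numeric(eqtl_beta) || !is.finite(eqtl_beta))
    config_error("eqtl_beta", "must be finite")
  if (length(cell_fraction_dirichlet) != 7 ||
      any(cell_fraction_dirichlet <= 0))
    config_error("cell_fraction_dirichlet",
                 "must be 7 positive concentrations")
  if (coverage_mean <= 0) config_error("coverage_mean", "must be > 0")
  if (coverage_dispersion <= 0)
    config_error("coverage_dispersion", "must be > 0")
  if (!prevalence_spectrum %in% c("blood", "uniform"))
    config_error("prevalence_spectrum", "must be 'blood' or 'uniform'")
  if (network_enrichment_odds <= 0)
    config_error("network_enrichment_odds", "must be > 0")
  for (f in c("signal_sd", "cell_effect_sd", "site_noise_sd")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0) config_error(f, "must be >= 0")
  }
  if (n_assoc_genes + n_mediated_genes > n_genes - 2)
    config_error("n_assoc_genes", "planted genes exceed n_genes")
  structure(list(
    n_samples = n_samples, n_sites = n_sites, n_genes = n_genes,
    n_snps = n_snps, seed = seed, adar_r2 = adar_r2,
    eqtl_beta = eqtl_beta,
    cell_fraction_dirichlet = cell_fraction_dirichlet,
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    prevalence_spectrum = prevalence_spectrum,
    network_enrichment_odds = network_enrichment_odds,
    signal_sd = signal_sd, cell_effect_sd = cell_effect_sd,
    site_noise_sd = site_noise_sd, n_assoc_genes = n_assoc_genes,
    n_mediated_genes = n_mediated_genes), class = "sim_config")
}

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

# width-1 GRanges for a subset of sites (BED export then covers each
# 1-based site position as a 0-based half-open interval).
bed_from_sites <- function(sites, idx, name = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom[idx],
    ranges = IRanges::IRanges(start = sites$pos[idx], width = 1L))
  if (!is.null(name)) gr$name <- name
  gr
}

#' Generate annotation / exclusion mask BED channels for a site table
#'
#' Exclusive channels partition the sites (their fractions must not sum
#' above 1); each remaining channel independently covers its own rounded
#' fraction of sites. Every channel becomes a width-1 BED interval set
#' covering exactly `round(fraction * n)` sites.
#'
#' @param sites data.frame with `site_id`, `chrom`, `pos`.
#' @param fractions named numeric vector of per-channel fractions in
#'   \[0, 1\].
#' @param seed RNG seed.
#' @param exclusive names of channels forming the mutually exclusive
#'   region classification.
#' @return named list of `GRanges`; attribute `"assignment"` maps each
#'   site to its exclusive channel (or NA).
#' @export
generate_masks <- function(sites, fractions, seed = 1,
                           exclusive = c("utr3", "utr5", "intron",
                                         "exon_cds", "ncRNA")) {
  if (any(fractions < 0 | fractions > 1))
    stop("mask fractions must be in [0, 1]", call. = FALSE)
  n <- nrow(sites)
  excl <- intersect(names(fractions), exclusive)
  if (sum(fractions[excl]) > 1 + 1e-9)
    stop("exclusive category fractions overlap (sum > 1)", call. = FALSE)
  out <- list()
  assignment <- rep(NA_character_, n)
  with_stream(seed, "masks", {
    pool <- sample.int(n)  # random order, then carve exact counts
    offset <- 0L
    for (ch in excl) {
      k <- round(fractions[[ch]] * n)
      idx <- pool[seq_len(k) + offset]
      offset <- offset + k
      assignment[idx] <- ch
      out[[ch]] <- bed_from_sites(sites, idx)
    }
    for (ch in setdiff(names(fractions), excl)) {
      k <- round(fractions[[ch]] * n)
      out[[ch]] <- bed_from_sites(sites, sample.int(n, k))
    }
  })
  attr(out, "assignment") <- assignment
  out
}

#' Generate a synthetic PPI network in three source dialects
#'
#' Two ADAR seeds plus a reserve third are wired to a set of direct
#' partners; every other node joins the 2-hop ADAR neighbourhood with a
#' base probability, boosted to the stated odds ratio for truth genes.
#' Uniform background edges, sub-threshold STRING edges (combined score
#' <= 400) and non-physical BioGRID edges are added so the build filters
#' have genuine work, as do a few promiscuous ubiquitin-family nodes.
#'
#' @param n_nodes number of gene/protein nodes (>= 10), including the ADAR
#'   seeds.
#' @param enrichment_odds odds ratio (> 0) of truth genes joining the ADAR
#'   neighbourhood; 1 means no enrichment.
#' @param truth_genes ids of genes to be preferentially wired.
#' @param seed RNG seed.
#' @param node_ids optional explicit node id vector (ADAR seeds are added
#'   if absent).
#' @param base_connect_prob baseline probability of joining the
#'   neighbourhood (default 0.25).
#' @return list with `edges` (data.frames `string`, `biogrid`, `bioplex`),
#'   `direct_partners`, `seeds`, `ubiquitin_nodes`, `pi_base`, `pi_truth`.
#' @export
generate_ppi <- function(n_nodes, enrichment_odds, truth_genes = character(),
                         seed = 1, node_ids = NULL,
                         base_connect_prob = 0.25) {
  if (n_nodes < 10) stop("n_nodes must be >= 10", call. = FALSE)
  if (enrichment_odds <= 0) stop("enrichment_odds must be > 0",
                                 call. = FALSE)
  seeds <- c("ADAR", "ADARB1", "ADARB2")
  if (is.null(node_ids))
    node_ids <- c(seeds, sprintf("gene_%04d", seq_len(n_nodes - 3)))
  else node_ids <- union(seeds, node_ids)
  others <- setdiff(node_ids, seeds)
  ub <- c("UBB", "UBC")
  pi_truth <- plogis(qlogis(base_connect_prob) + log(enrichment_odds))
  with_stream(seed, "ppi", {
    n_direct <- max(5L, round(0.035 * length(node_ids)))
    direct <- sample(others, n_direct)
    e <- list(data.frame(a = direct,
                         b = sample(seeds[1:2], n_direct, replace = TRUE)))
    rest <- setdiff(others, direct)
    p_conn <- ifelse(rest %in% truth_genes, pi_truth, base_connect_prob)
    conn <- rest[runif(length(rest)) < p_conn]
    if (length(conn))
      e[[2]] <- data.frame(a = conn,
                           b = sample(direct, length(conn),
                                      replace = TRUE))
    n_bg <- length(node_ids)
    e[[3]] <- data.frame(a = sample(node_ids, n_bg, replace = TRUE),
                         b = sample(node_ids, n_bg, replace = TRUE))
    edges <- do.call(rbind, e)
    edges <- edges[edges$a != edges$b, ]
    # promiscuous ubiquitin nodes, to be blacklisted at build time
    edges <- rbind(edges, data.frame(
      a = rep(ub, each = 8),
      b = sample(c(direct, seeds[1:2]), 16, replace = TRUE)))
    src <- sample(c("string", "biogrid", "bioplex"), nrow(edges),
                  replace = TRUE)
    dup <- sample.int(nrow(edges), round(0.1 * nrow(edges)))
    edges2 <- edges[dup, ]
    src2 <- vapply(src[dup], function(s)
      sample(setdiff(c("string", "biogrid", "bioplex"), s), 1), "")
    all_e <- rbind(edges, edges2)
    all_src <- c(src, src2)
    string_keep <- all_e[all_src == "string", ]
    string_df <- data.frame(
      protein1 = string_keep$a, protein2 = string_keep$b,
      combined_score = sample(401:999, nrow(string_keep), replace = TRUE),
      experimental = rbinom(nrow(string_keep), 1, 0.7))
    string_df$database <- ifelse(string_df$experimental == 0, 1,
                                 rbinom(nrow(string_df), 1, 0.4))
    biogrid_keep <- all_e[all_src == "biogrid", ]
    biogrid_df <- data.frame(gene_a = biogrid_keep$a,
                             gene_b = biogrid_keep$b,
                             evidence = "physical")
    bioplex_keep <- all_e[all_src == "bioplex", ]
    bioplex_df <- data.frame(gene_a = bioplex_keep$a,
                             gene_b = bioplex_keep$b,
                             p_interaction = round(runif(
                               nrow(bioplex_keep), 0.75, 1), 3))
    # decoy edges the build filters must drop
    n_noise <- max(2L, round(0.05 * length(node_ids)))
    noise_pairs <- data.frame(a = sample(node_ids, n_noise, replace = TRUE),
                              b = sample(node_ids, n_noise, replace = TRUE))
    noise_pairs <- noise_pairs[noise_pairs$a != noise_pairs$b, ]
    half <- seq_len(floor(nrow(noise_pairs) / 2))
    if (length(half))
      string_df <- rbind(string_df, data.frame(
        protein1 = noise_pairs$a[half], protein2 = noise_pairs$b[half],
        combined_score = sample(100:400, length(half), replace = TRUE),
        experimental = 1, database = 0))
    rest_idx <- setdiff(seq_len(nrow(noise_pairs)), half)
    if (length(rest_idx))
      biogrid_df <- rbind(biogrid_df, data.frame(
        gene_a = noise_pairs$a[rest_idx],
        gene_b = noise_pairs$b[rest_idx], evidence = "genetic"))
    list(edges = list(string = string_df, biogrid = biogrid_df,
                      bioplex = bioplex_df),
         direct_partners = direct, seeds = seeds[1:2],
         ubiquitin_nodes = ub,
         pi_base = base_connect_prob, pi_truth = pi_truth)
  })
}

#' Simulate a latent factor matrix with planted rank
#'
#' Sites x samples matrix `L F + E` with `n_factors` equally strong
#' factors, used to exercise component-retention rules on data whose true
#' dimensionality is known.
#'
#' @param n_sites,n_samples dimensions.
#' @param n_factors planted rank (default 5).
#' @param loading_sd sd of factor loadings (default 0.35).
#' @param noise_sd residual sd (default 1).
#' @param seed RNG seed.
#' @return list with `mat`, `loadings`, `factors`.
#' @export
simulate_factor_matrix <- function(n_sites = 300, n_samples = 200,
                                   n_factors = 5, loading_sd = 0.35,
                                   noise_sd = 1, seed = 1) {
  with_stream(seed, "factor", {
    L <- matrix(rnorm(n_sites * n_factors, sd = loading_sd), n_sites)
    F_ <- matrix(rnorm(n_factors * n_samples), n_factors)
    E <- matrix(rnorm(n_sites * n_samples, sd = noise_sd), n_sites)
    list(mat = L %*% F_ + E, loadings = L, factors = F_)
  })
}

scale1 <- function(x) as.numeric(scale(x))

# residualize x on columns of M and rescale to unit variance
orthonormalize <- function(x, M) {
  r <- lm.fit(cbind(1, M), x)$residuals
  r / sd(r)
}

#' Generate a complete synthetic cohort with recorded truth
#'
#' Produces base counts (with negative-binomial depth and binomial edited
#' reads), residual-style expression, covariates (technical, 7 cell
#' fractions, 28 biological/pharmacological variables), genotypes in LD
#' blocks with a planted causal eQTL, a PPI network enriched around ADAR
#' for truly associated genes, annotation and exclusion BED channels, an
#' SNV decoy list and a catalogue — everything the downstream modules
#' consume — plus a truth record of all planted structure.
#'
#' Per-site editing follows
#' `logit p = baseline + signal_t + 0.4 local + latent + noise`, where the
#' sample signal `t` is a cell-composition component plus a variance-
#' targeted mix of ADAR expression (share `adar_r2`), causal-SNP dosage
#' and unexplained noise, so the planted variance fractions are exact in
#' sample.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all components are also
#'   written as plain-text files via [write_cohort()].
#' @return list of class `synthetic_cohort`; see Details in the vignette.
#' @export
generate_cohort <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  ns <- config$n_sites
  sample_ids <- sprintf("S%04d", seq_len(n))

  ## ---- sites ----
  n_weak <- round(0.15 * ns)
  n_excl_each <- round(0.05 * ns)
  excl_reasons <- c("catalogue", "snv", "segdup", "pseudogene",
                    "single_exon")
  n_raw <- ns + n_weak + n_excl_each * length(excl_reasons)
  sites <- with_stream(config$seed, "sites", {
    chrom <- paste0("chr", sample(1:22, n_raw, replace = TRUE))
    pos <- sample.int(5e7, n_raw) + 1e6   # globally unique positions
    # plant close pairs among the strong sites for distance stratification
    n_cl <- max(2L, round(0.02 * ns))
    comp <- seq_len(n_cl) * 2
    base <- comp - 1L
    chrom[comp] <- chrom[base]
    repeat {
      pos[comp] <- pos[base] + sample(5:45, n_cl, replace = TRUE)
      if (!anyDuplicated(paste(chrom, pos))) break
    }
    d <- data.frame(chrom = chrom, pos = pos,
                    strand = sample(c("+", "-"), n_raw, replace = TRUE),
                    stringsAsFactors = FALSE)
    d$site_id <- site_id(d$chrom, d$pos)
    d$cluster <- NA_integer_
    d$cluster[seq_len(2 * n_cl)] <- rep(seq_len(n_cl), each = 2)
    d$class <- c(rep("strong", ns), rep("weak", n_weak),
                 rep(excl_reasons, each = n_excl_each))
    d
  })
  good <- sites$class %in% c("strong", "weak")
  n_good <- sum(good)

  # annotation channels over the good sites (region fractions mirror the
  # observed CES distribution; miRNA overlaps concentrate in 3'UTRs)
  region_frac <- c(utr3 = 0.594, utr5 = 0.005, intron = 0.355,
                   exon_cds = 0.011, ncRNA = 0.026)
  good_sites <- sites[good, ]
  masks_ann <- generate_masks(good_sites, c(region_frac, alu = 0.868),
                              seed = stream_seed(config$seed, "annot"))
  assignment <- attr(masks_ann, "assignment")
  mirna_class <- with_stream(config$seed, "mirna", {
    k_mirna <- round(0.238 * n_good)
    utr3_idx <- which(assignment == "utr3")
    k_utr3 <- min(length(utr3_idx), round(0.94 * k_mirna))
    pick <- c(sample(utr3_idx, k_utr3),
              sample(setdiff(seq_len(n_good), utr3_idx),
                     k_mirna - k_utr3))
    cls <- rep("none", n_good)
    cls[pick] <- sample(c("nonconserved", "conserved",
                          "broadly_conserved"), k_mirna, replace = TRUE,
                        prob = c(0.90, 0.08, 0.02))
    cls
  })
  mirna_idx <- which(mirna_class != "none")
  masks_ann$mirna <- bed_from_sites(good_sites, mirna_idx,
                                    name = mirna_class[mirna_idx])
  recoding <- rep(NA_character_, n_good)
  cds_idx <- which(assignment == "exon_cds")
  recoding[utils::head(cds_idx, max(1, round(0.45 * length(cds_idx))))] <-
    "S/G"
  exclusion_masks <- list(
    segdup = bed_from_sites(sites, which(sites$class == "segdup")),
    pseudogene = bed_from_sites(sites, which(sites$class == "pseudogene")),
    single_exon = bed_from_sites(sites,
                                 which(sites$class == "single_exon")))
  catalogue <- sites$site_id[sites$class != "catalogue"]
  snv <- data.frame(chrom = sites$chrom[sites$class == "snv"],
                    pos = sites$pos[sites$class == "snv"])

  ## ---- cell fractions ----
  cells <- with_stream(config$seed, "cells", {
    f <- rdirichlet(n, config$cell_fraction_dirichlet)
    colnames(f) <- names(config$cell_fraction_dirichlet)
    rownames(f) <- sample_ids
    as.data.frame(f)
  })

  ## ---- genotypes ----
  geno <- with_stream(config$seed, "genotypes", {
    snps_per_block <- 10L
    n_block <- ceiling(config$n_snps / snps_per_block)
    block_chrom <- paste0("chr", rep(1:22, length.out = n_block))
    block_start <- 1e6 + (seq_len(n_block) %/% 22) * 2e6
    map <- do.call(rbind, lapply(seq_len(n_block), function(b) {
      k <- min(snps_per_block, config$n_snps - (b - 1) * snps_per_block)
      data.frame(block = b, chrom = block_chrom[b],
                 pos = sort(sample.int(4e5, k)) + block_start[b])
    }))
    map$snp <- sprintf("rs%06d", seq_len(nrow(map)))
    map$a1 <- sample(c("A", "C", "G", "T"), nrow(map), replace = TRUE)
    map$a2 <- vapply(map$a1, function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    # four founder haplotypes per block; each SNP's founder alleles are
    # drawn with most SNPs polymorphic among founders, so common variants
    # dominate as on a genotyping array
    n_founder <- 4L
    m_snp <- nrow(map)
    k_ones <- sample(0:4, m_snp, replace = TRUE,
                     prob = c(0.08, 0.22, 0.40, 0.22, 0.08))
    founders <- t(vapply(k_ones, function(k)
      sample(c(rep(1L, k), rep(0L, n_founder - k))), integer(n_founder)))
    causal_block <- ceiling(n_block / 2)
    in_cb <- which(map$block == causal_block)
    causal_idx <- in_cb[ceiling(length(in_cb) / 2)]
    # founders split at the causal SNP and at half its block mates so
    # the clump has high-LD members
    mates <- setdiff(in_cb, causal_idx)
    diff_mates <- mates[seq_len(ceiling(length(mates) / 2))]
    founders[c(causal_idx, diff_mates), ] <- rep(c(1L, 1L, 0L, 0L),
                                                 each = length(diff_mates) + 1)
    dosage <- matrix(0L, n, nrow(map),
                     dimnames = list(sample_ids, map$snp))
    for (b in seq_len(n_block)) {
      idx <- which(map$block == b)
      k <- length(idx)
      fA <- sample.int(n_founder, n, replace = TRUE)
      fB <- sample.int(n_founder, n, replace = TRUE)
      hA <- founders[idx, fA, drop = FALSE]
      hB <- founders[idx, fB, drop = FALSE]
      mutA <- matrix(runif(k * n) < 0.02, nrow = k)
      mutB <- matrix(runif(k * n) < 0.02, nrow = k)
      hA <- abs(hA - mutA); hB <- abs(hB - mutB)
      dosage[, idx] <- t(hA + hB)
    }
    dosage[matrix(runif(length(dosage)) < 0.002,
                  nrow(dosage))] <- NA_real_
    ord <- order(map$chrom, map$pos)
    list(map = map[ord, c("snp", "chrom", "pos", "a1", "a2", "block")],
         dosage = dosage[, ord, drop = FALSE],
         causal_snp = map$snp[causal_idx],
         causal_block = causal_block)
  })
  g <- genotype_set(geno$map[, c("snp", "chrom", "pos", "a1", "a2")],
                    geno$dosage)
  dose_raw <- geno$dosage[, geno$causal_snp]
  dose <- ifelse(is.na(dose_raw), mean(dose_raw, na.rm = TRUE), dose_raw)

  ## ---- sample-level signal (variance-targeted) ----
  sig <- with_stream(config$seed, "signal", {
    dc <- dose - mean(dose)
    z <- orthonormalize(rnorm(n), dc)          # ADAR driver, unit sd
    b <- config$eqtl_beta
    a <- sqrt(config$adar_r2) * config$signal_sd
    v_dose <- mean(dc^2)
    u_var <- config$signal_sd^2 - a^2 - b^2 * v_dose
    if (u_var <= 0)
      config_error("signal_sd",
                   "too small for the planted ADAR and eQTL effects")
    u <- orthonormalize(rnorm(n), cbind(dc, z)) * sqrt(u_var)
    cw <- c(neutrophils = 1, th = -0.8, monocytes = 0.9, dc = 0.7,
            b = 0, nk = 0, eosinophils = 0)
    c_raw <- as.matrix(cells)[, names(cw)] %*% cw
    c_eff <- config$cell_effect_sd * scale1(c_raw)
    t_j <- as.numeric(c_eff + a * z + b * dc + u)
    list(z = z, u = u, c_eff = as.numeric(c_eff), t = t_j, a = a, b = b,
         v_dose = v_dose)
  })

  ## ---- per-site editing probabilities and counts ----
  p0 <- with_stream(config$seed, "baseline", {
    draw_strong <- function(k) {
      hi <- runif(k) < 0.016
      ifelse(hi, runif(k, 0.92, 0.97), 0.06 + 0.30 * rbeta(k, 1.5, 3.5))
    }
    cls <- sites$class
    out <- numeric(n_raw)
    if (config$prevalence_spectrum == "blood") {
      out[cls == "strong"] <- draw_strong(sum(cls == "strong"))
      out[cls == "weak"] <- runif(sum(cls == "weak"), 0.005, 0.012)
      out[!cls %in% c("strong", "weak")] <-
        draw_strong(sum(!cls %in% c("strong", "weak")))
    } else out <- runif(n_raw, 0.02, 0.95)
    out
  })
  counts <- with_stream(config$seed, "counts", {
    # baseline + unit site sensitivity * sample signal
    logit <- matrix(qlogis(p0), n_raw, n) +
      matrix(sig$t, n_raw, n, byrow = TRUE)
    # local co-editing factors for clustered sites
    cl <- sites$cluster
    for (ci in unique(na.omit(cl))) {
      lf <- rnorm(n)
      logit[which(cl == ci), ] <-
        logit[which(cl == ci), , drop = FALSE] +
        matrix(0.4 * lf, sum(cl == ci, na.rm = TRUE), n, byrow = TRUE)
    }
    # latent factors with zero-mean loadings (shape, not rate, variation)
    for (lf_i in 1:2) {
      lo <- rnorm(n_raw, 0, 0.2)
      fa <- rnorm(n)
      logit <- logit + outer(lo, fa)
    }
    logit <- logit + matrix(rnorm(n_raw * n, 0, config$site_noise_sd),
                            n_raw)
    p <- plogis(logit)
    C <- matrix(rnbinom(n_raw * n, size = config$coverage_dispersion,
                        mu = config$coverage_mean), n_raw)
    G <- matrix(rbinom(n_raw * n, as.vector(C), as.vector(p)), n_raw)
    dimnames(C) <- dimnames(G) <- list(sites$site_id, sample_ids)
    list(ec = edit_counts(a = C - G, g = G), p = p)
  })

  ## ---- expression ----
  gene_ids <- c("ADAR", "ADARB1",
                sprintf("gene_%04d", seq_len(config$n_genes - 2)))
  expr_truth <- with_stream(config$seed, "expression", {
    pool <- setdiff(gene_ids, c("ADAR", "ADARB1"))
    assoc <- sample(pool, config$n_assoc_genes)
    mediated <- sample(setdiff(pool, assoc), config$n_mediated_genes)
    E <- matrix(rnorm(config$n_genes * n), config$n_genes,
                dimnames = list(gene_ids, sample_ids))
    E["ADAR", ] <- sig$z + rnorm(n, 0, 0.15)
    g_non <- scale1(sig$b * (dose - mean(dose)) + sig$u)
    for (gn in assoc) E[gn, ] <- 0.35 * g_non + sqrt(1 - 0.35^2) * rnorm(n)
    for (gn in mediated) E[gn, ] <- 0.6 * sig$z + 0.8 * rnorm(n)
    list(E = E, assoc = assoc, mediated = mediated)
  })

  ## ---- covariates ----
  covars <- with_stream(config$seed, "covariates", {
    d <- data.frame(
      sample_id = sample_ids,
      batch = sample(paste0("b", 1:3), n, replace = TRUE),
      rin = round(rnorm(n, 8, 0.5), 2))
    d <- cbind(d, round(cells, 5))
    d$age <- round(48 + 4 * scale1(sig$c_eff) + rnorm(n, 0, 8), 1)
    d$sex <- sample(c("F", "M"), n, replace = TRUE)
    d$bmi <- round(rnorm(n, 26, 4), 1)
    d$smoke <- rbinom(n, 1, 0.3)
    d$alcohol <- rbinom(n, 1, 0.4)
    for (i in seq_len(23))
      d[[sprintf("med_%02d", i)]] <- rbinom(n, 1, runif(1, 0.1, 0.5))
    d
  })

  ## ---- PPI ----
  ppi <- generate_ppi(
    n_nodes = config$n_genes,
    enrichment_odds = config$network_enrichment_odds,
    truth_genes = c(expr_truth$assoc, expr_truth$mediated),
    seed = stream_seed(config$seed, "ppi-master"),
    node_ids = gene_ids)

  ## ---- realized truth ----
  rstar <- colMeans(counts$p[sites$class == "strong", , drop = FALSE])
  fit <- lm(rstar ~ dose + sig$z + sig$c_eff + sig$u)
  truth <- list(
    planted = list(adar_r2 = config$adar_r2,
                   eqtl_beta_logit = config$eqtl_beta,
                   snpset_h2 = sig$b^2 * sig$v_dose / config$signal_sd^2,
                   signal_sd = config$signal_sd,
                   cell_effect_sd = config$cell_effect_sd),
    eqtl_beta_rate = unname(coef(fit)["dose"]),
    baseline_editing = stats::setNames(p0, sites$site_id),
    strong_sites = sites$site_id[sites$class == "strong"],
    weak_sites = sites$site_id[sites$class == "weak"],
    excluded_sites = stats::setNames(
      sites$class[!good], sites$site_id[!good]),
    assoc_genes = expr_truth$assoc,
    mediated_genes = expr_truth$mediated,
    adar_gene = "ADAR",
    causal_snp = geno$causal_snp,
    eqtl_set = {
      cb <- geno$map$snp[geno$map$block == geno$causal_block]
      r2 <- vapply(cb, function(s)
        tryCatch(ld_r2(dose_raw, geno$dosage[, s]), error = function(e) 0),
        numeric(1))
      cb[r2 >= 0.5]
    },
    ppi_direct_partners = ppi$direct_partners,
    ubiquitin_nodes = ppi$ubiquitin_nodes)

  gs <- good_sites[, c("site_id", "chrom", "pos", "strand")]
  gs$region <- assignment
  gs$mirna <- mirna_class
  gs$recoding <- recoding
  rownames(gs) <- NULL
  cohort <- structure(list(
    config = config,
    sites = sites[, c("site_id", "chrom", "pos", "strand", "class")],
    good_sites = gs,
    counts = counts$ec,
    expression = expr_truth$E,
    covariates = covars,
    cells = cells,
    genotypes = g,
    annotation_masks = masks_ann,
    exclusion_masks = exclusion_masks,
    catalogue = catalogue,
    snv = snv,
    ppi = ppi$edges,
    truth = truth), class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$config$n_samples, " samples; ",
      nrow(x$sites), " sites (", length(x$truth$strong_sites),
      " strong); ", nrow(x$expression), " genes; ",
      ncol(x$genotypes$dosage), " SNPs\n", sep = "")
  invisible(x)
}

write_vcf_minimal <- function(map, dosage, path) {
  fix <- cbind(CHROM = map$chrom,
               POS = as.character(map$pos), ID = map$snp, REF = map$a2,
               ALT = map$a1, QUAL = ".", FILTER = "PASS", INFO = ".")
  gtm <- apply(dosage, 1, function(d)
    c("0/0", "0/1", "1/1")[d + 1])  # SNPs x samples after apply
  gtm[is.na(gtm)] <- "./."
  gt <- cbind(FORMAT = "GT", gtm)
  colnames(gt) <- c("FORMAT", rownames(dosage))
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = c("##fileformat=VCFv4.2",
                             "##source=bloodedit_synthetic"),
                    fix = fix, gt = gt)
  vcfR::write.vcf(v, path)
  invisible(path)
}

#' Write a synthetic cohort to plain-text files
#'
#' Produces counts.tsv (long format), expression.tsv, covariates.tsv,
#' genotype map/dosage TSVs plus genotypes.vcf.gz, PPI edge TSVs per
#' source dialect, one BED per annotation/exclusion channel, snv.vcf.gz,
#' catalogue.tsv, sites.tsv and truth.json.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_base_counts(cohort$counts, fp("counts.tsv"))
  write_tsv(as.data.frame(cohort$expression), fp("expression.tsv"),
            row_names = TRUE)
  write_tsv(cohort$covariates, fp("covariates.tsv"))
  write_tsv(cohort$genotypes$map, fp("snp_map.tsv"))
  dos <- as.data.frame(cohort$genotypes$dosage)
  dos <- cbind(sample_id = rownames(dos), dos)
  write_tsv(dos, fp("dosages.tsv"))
  write_vcf_minimal(cohort$genotypes$map, cohort$genotypes$dosage,
                    fp("genotypes.vcf.gz"))
  write_tsv(cohort$ppi$string, fp("ppi_string.tsv"))
  write_tsv(cohort$ppi$biogrid, fp("ppi_biogrid.tsv"))
  write_tsv(cohort$ppi$bioplex, fp("ppi_bioplex.tsv"))
  for (ch in names(cohort$annotation_masks))
    write_bed(cohort$annotation_masks[[ch]], fp(paste0(ch, ".bed")))
  for (ch in names(cohort$exclusion_masks))
    write_bed(cohort$exclusion_masks[[ch]], fp(paste0(ch, ".bed")))
  if (nrow(cohort$snv)) {
    snv_map <- data.frame(snp = site_id(cohort$snv$chrom, cohort$snv$pos),
                          chrom = cohort$snv$chrom, pos = cohort$snv$pos,
                          a1 = "G", a2 = "A")
    write_vcf_minimal(snv_map,
                      matrix(1, 1, nrow(snv_map),
                             dimnames = list("ref", snv_map$snp)),
                      fp("snv.vcf.gz"))
  }
  write_tsv(data.frame(site_id = cohort$catalogue), fp("catalogue.tsv"))
  write_tsv(cohort$sites, fp("sites.tsv"))
  truth <- cohort$truth
  truth$baseline_editing <- as.list(truth$baseline_editing)
  truth$excluded_sites <- as.list(truth$excluded_sites)
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
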