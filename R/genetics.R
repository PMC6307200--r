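# Genotype QC, additive SNP association, LD clumping, SNP-set variance.

#' Construct a genotype set
#'
#' @param map data.frame with `snp`, `chrom`, `pos` (1-based), `a1`, `a2`;
#'   positions must be sorted within chromosome.
#' @param dosage samples x SNPs matrix of A1-allele counts in
#'   `{0, 1, 2, NA}`; column names match `map$snp`.
#' @return object of class `genotype_set`.
#' @export
genotype_set <- function(map, dosage) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(map),
            all(c("snp", "chrom", "pos", "a1", "a2") %in% names(map)),
            ncol(dosage) == nrow(map))
  if (is.null(colnames(dosage))) colnames(dosage) <- map$snp
  if (!identical(colnames(dosage), as.character(map$snp)))
    stop("dosage columns must match map$snp", call. = FALSE)
  if (any(vapply(split(map$pos, map$chrom), is.unsorted, logical(1))))
    stop("positions must be sorted within chromosome", call. = FALSE)
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing", call. = FALSE)
  structure(list(map = map, dosage = dosage), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("<genotype_set> ", nrow(x$dosage), " samples x ", nrow(x$map),
      " SNPs\n", sep = "")
  invisible(x)
}

#' Read genotypes from a dosage TSV plus SNP map TSV
#' @param dosage_path TSV with sample rows (first column `sample_id`).
#' @param map_path TSV with `snp`, `chrom`, `pos`, `a1`, `a2`.
#' @return a [genotype_set()].
#' @export
read_dosage_tsv <- function(dosage_path, map_path) {
  d <- read_tsv(dosage_path)
  rn <- d$sample_id
  d$sample_id <- NULL
  m <- as.matrix(d)
  rownames(m) <- rn
  genotype_set(read_tsv(map_path), m)
}

#' Read genotypes from a VCF (GT field)
#'
#' A1 is the ALT allele; dosage counts ALT copies.
#' @param path VCF path (.vcf or .vcf.gz).
#' @return a [genotype_set()].
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), fix[, "ID"]))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[] <- t(vapply(seq_len(nrow(gt)), function(i) {
    g <- clean[i, ]
    out <- rep(NA_real_, length(g))
    known <- !is.na(g) & g %in% c("0/0", "0/1", "1/0", "1/1")
    out[known] <- vapply(strsplit(g[known], "/"), function(al)
      sum(al == "1"), numeric(1))
    out
  }, numeric(ncol(gt))))
  map <- data.frame(snp = fix[, "ID"], chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), a1 = fix[, "ALT"],
                    a2 = fix[, "REF"])
  genotype_set(map, dos)
}

#' Hardy-Weinberg exact test from genotype counts
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_fisher(100, 0, 0)  # monomorphic: p = 1
hwe_fisher <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("total genotype count must be >= 1", call. = FALSE)
  nA <- 2 * n_AA + n_Aa
  hmax <- min(nA, 2 * n - nA)
  if (hmax < 1) return(1)
  h <- seq.int(nA %% 2, hmax, by = 2)
  logp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial(n - (nA + h) / 2) + h * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# PLINK-style method-of-moments PI_HAT from IBS sharing, computed on SNPs
# with complete dosages across the given samples. Returns an n x n matrix.
pi_hat_matrix <- function(dosage) {
  complete <- colSums(is.na(dosage)) == 0L
  X <- dosage[, complete, drop = FALSE]
  m <- ncol(X)
  if (m < 10L)
    stop("too few complete SNPs for relatedness estimation", call. = FALSE)
  p <- colMeans(X) / 2
  q <- 1 - p
  X2 <- X^2; X3 <- X^3
  S2 <- rowSums(X2); S4 <- rowSums(X^4)
  A <- tcrossprod(X)
  d2 <- outer(S2, S2, `+`) - 2 * A
  d4 <- outer(S4, S4, `+`) - 4 * tcrossprod(X3, X) -
    4 * tcrossprod(X, X3) + 6 * tcrossprod(X2)
  N0 <- round((d4 - d2) / 12)
  N1 <- round(d2 - 4 * N0)
  N2 <- m - N0 - N1
  e0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p * q * (p^2 + q^2))
  e2_ibd0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibd1 <- sum(2 * p * q)
  e2_ibd1 <- m - e1_ibd1
  P0 <- N0 / e0
  P1 <- (N1 - P0 * e1_ibd0) / e1_ibd1
  P2 <- (N2 - P0 * e2_ibd0 - P1 * e2_ibd1) / m
  P0 <- pmax(P0, 0); P1 <- pmax(P1, 0); P2 <- pmax(P2, 0)
  tot <- P0 + P1 + P2
  pihat <- (P1 / 2 + P2) / tot
  diag(pihat) <- 1
  pihat
}

#' Genotype quality control
#'
#' Filters are applied in order: samples first (missingness strictly above
#' `sample_miss_max`; heterozygosity-rate z-score beyond `het_sd`;
#' relatedness PI_HAT strictly above `pi_hat_max`, removing the
#' higher-missingness member of each pair), then SNPs (missingness strictly
#' above `snp_miss_max`; Hardy-Weinberg exact p strictly below
#' `hwe_p_min`; minor allele frequency strictly below `maf_min`).
#'
#' @param g a [genotype_set()].
#' @param sample_miss_max,het_sd,pi_hat_max,snp_miss_max,hwe_p_min,maf_min
#'   thresholds (defaults 0.01, 3, 0.18, 0.05, 1e-6, 0.01).
#' @return filtered `genotype_set`; attribute `"attrition"` is a
#'   data.frame of per-filter removal counts.
#' @export
genotype_qc <- function(g, sample_miss_max = 0.01, het_sd = 3,
                        pi_hat_max = 0.18, snp_miss_max = 0.05,
                        hwe_p_min = 1e-6, maf_min = 0.01) {
  stopifnot(inherits(g, "genotype_set"))
  X <- g$dosage
  att <- list()
  # -- samples
  smiss <- rowMeans(is.na(X))
  drop_miss <- smiss > sample_miss_max
  att$sample_missingness <- sum(drop_miss)
  X <- X[!drop_miss, , drop = FALSE]
  het <- rowMeans(X == 1, na.rm = TRUE)
  z <- if (sd(het) > 0) (het - mean(het)) / sd(het) else rep(0, nrow(X))
  drop_het <- abs(z) > het_sd
  att$heterozygosity <- sum(drop_het)
  X <- X[!drop_het, , drop = FALSE]
  ph <- pi_hat_matrix(X)
  ph[upper.tri(ph, diag = TRUE)] <- 0
  drop_rel <- rep(FALSE, nrow(X))
  miss_now <- rowMeans(is.na(X))
  repeat {
    idx <- which(ph > pi_hat_max & !outer(drop_rel, drop_rel, `|`),
                 arr.ind = TRUE)
    if (nrow(idx) == 0L) break
    pair <- idx[1, ]
    victim <- pair[which.max(miss_now[pair])]
    drop_rel[victim] <- TRUE
  }
  att$relatedness <- sum(drop_rel)
  X <- X[!drop_rel, , drop = FALSE]
  if (nrow(X) == 0L) stop("all samples removed by QC", call. = FALSE)
  # -- SNPs
  vmiss <- colMeans(is.na(X))
  drop_vmiss <- vmiss > snp_miss_max
  att$snp_missingness <- sum(drop_vmiss)
  keep <- !drop_vmiss
  hwe_p <- vapply(which(keep), function(j) {
    d <- X[, j]
    hwe_fisher(sum(d == 2, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
               sum(d == 0, na.rm = TRUE))
  }, numeric(1))
  drop_hwe <- rep(FALSE, ncol(X))
  drop_hwe[which(keep)[hwe_p < hwe_p_min]] <- TRUE
  att$hwe <- sum(drop_hwe)
  keep <- keep & !drop_hwe
  af <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  drop_maf <- keep & maf < maf_min
  att$maf <- sum(drop_maf)
  keep <- keep & !drop_maf
  out <- genotype_set(g$map[keep, , drop = FALSE],
                      X[, keep, drop = FALSE])
  attr(out, "attrition") <- data.frame(filter = names(att),
                                       n_removed = unlist(att),
                                       row.names = NULL)
  out
}

#' Ancestry principal components from genotypes
#'
#' PCA on mean-imputed, standardised dosages.
#'
#' @param g a post-QC [genotype_set()].
#' @param k number of components (default 5).
#' @return samples x k score matrix; attribute `"var_frac"` holds the
#'   explained-variance fractions.
#' @export
genotype_pcs <- function(g, k = 5) {
  X <- g$dosage
  cm <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0L)) X[is.na(X[, j]), j] <- cm[j]
  sds <- apply(X, 2, sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  if (k > min(dim(X)) - 1) stop("k exceeds matrix rank", call. = FALSE)
  pr <- prcomp(X, center = FALSE, scale. = FALSE)
  out <- pr$x[, seq_len(k), drop = FALSE]
  attr(out, "var_frac") <- pr$sdev^2 / sum(pr$sdev^2)
  out
}

#' Additive per-SNP association with the total editing rate
#'
#' Ordinary least squares of the rate on A1-allele dosage plus covariates
#' (typically the selected biological covariates and the leading genotype
#' PCs), casewise-complete per SNP. Monomorphic SNPs are skipped with a
#' note.
#'
#' @param g a [genotype_set()].
#' @param rate per-sample total editing rate, aligned with dosage rows.
#' @param covariates samples x q matrix/data.frame or `NULL`.
#' @return data.frame with `SNP`, `CHR`, `BP`, `A1`, `BETA`, `SE`, `P`,
#'   `N`, `note`.
#' @export
snp_association <- function(g, rate, covariates = NULL) {
  X <- g$dosage
  if (length(rate) != nrow(X))
    stop("rate and dosage samples are misaligned", call. = FALSE)
  Z <- as_covariate_matrix(covariates)
  base_cc <- !is.na(rate) & (if (is.null(Z)) TRUE else
    stats::complete.cases(Z))
  res <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    dose <- X[, j]
    cc <- base_cc & !is.na(dose)
    n <- sum(cc)
    if (n < 10 || sd(dose[cc]) == 0) {
      res[[j]] <- data.frame(BETA = NA_real_, SE = NA_real_, P = NA_real_,
                             N = n, note = if (n >= 10) "monomorphic"
                             else "too_few_samples")
      next
    }
    M <- cbind(1, if (is.null(Z)) NULL else Z[cc, , drop = FALSE],
               dose = dose[cc])
    f <- lm.fit(M, rate[cc])
    r <- f$residuals
    df <- n - f$rank
    sigma2 <- sum(r^2) / df
    XtXinv <- chol2inv(chol(crossprod(M)))
    k <- ncol(M)
    se <- sqrt(sigma2 * XtXinv[k, k])
    beta <- f$coefficients[k]
    res[[j]] <- data.frame(BETA = unname(beta), SE = se,
                           P = 2 * pt(-abs(beta / se), df), N = n,
                           note = "")
  }
  cbind(data.frame(SNP = g$map$snp, CHR = g$map$chrom, BP = g$map$pos,
                   A1 = g$map$a1), do.call(rbind, res))
}

#' Squared LD correlation between two dosage vectors
#'
#' @param x,y dosage vectors; pairwise-complete samples are used.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(x, y) {
  cc <- !is.na(x) & !is.na(y)
  if (sum(cc) < 2) stop("need >= 2 complete pairs", call. = FALSE)
  if (sd(x[cc]) == 0 || sd(y[cc]) == 0)
    stop("r2 undefined for a zero-variance dosage vector", call. = FALSE)
  cor(x[cc], y[cc])^2
}

#' Greedy LD clumping of association results
#'
#' Repeatedly takes the unassigned SNP with the smallest association
#' p-value as an index (ties broken by genomic order) and absorbs every
#' unassigned SNP on the same chromosome within `window_kb` and with
#' r-squared to the index of at least `r2_min`.
#'
#' @param assoc data.frame with `SNP` and `P` (e.g. from
#'   [snp_association()]); SNPs with missing p are ignored.
#' @param g the [genotype_set()] providing the map and dosages.
#' @param window_kb half-window in kilobases (default 500).
#' @param r2_min inclusive r-squared threshold (default 0.5).
#' @return list of clumps; each has `index`, `index_p`, `members`
#'   (data.frame with `snp`, `r2`, `p`) and `window` bounds. Every tested
#'   SNP belongs to exactly one clump.
#' @export
clump <- function(assoc, g, window_kb = 500, r2_min = 0.5) {
  map <- g$map
  i <- match(assoc$SNP, map$snp)
  if (anyNA(i)) stop("assoc contains SNPs absent from the map",
                     call. = FALSE)
  d <- data.frame(snp = assoc$SNP, p = assoc$P, chrom = map$chrom[i],
                  pos = map$pos[i], col = i)
  d <- d[!is.na(d$p), , drop = FALSE]
  ord <- order(d$p, d$chrom, d$pos)
  d <- d[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(d))
  clumps <- list()
  w <- window_kb * 1000
  while (!all(assigned)) {
    idx <- which(!assigned)[1]
    assigned[idx] <- TRUE
    cand <- which(!assigned & d$chrom == d$chrom[idx] &
                    abs(d$pos - d$pos[idx]) <= w)
    memb <- data.frame(snp = d$snp[idx], r2 = 1, p = d$p[idx])
    for (ci in cand) {
      r2 <- tryCatch(ld_r2(g$dosage[, d$col[idx]], g$dosage[, d$col[ci]]),
                     error = function(e) 0)
      if (r2 >= r2_min) {
        assigned[ci] <- TRUE
        memb <- rbind(memb, data.frame(snp = d$snp[ci], r2 = r2,
                                       p = d$p[ci]))
      }
    }
    clumps[[length(clumps) + 1L]] <-
      list(index = d$snp[idx], index_p = d$p[idx], members = memb,
           window = c(chrom = d$chrom[idx],
                      start = d$pos[idx] - w, end = d$pos[idx] + w))
  }
  clumps
}

#' Variance in the editing rate explained by a SNP set
#'
#' Joint fixed-effect linear model of the rate on all set SNPs on top of
#' the covariates: R-squared is (RSS_cov - RSS_full) / RSS_cov and the
#' p-value an F-test on the added degrees of freedom. Collinear or
#' duplicated SNPs are pruned (via the QR decomposition inside `lm`) with
#' a notice.
#'
#' @param snp_ids SNP ids forming the set (e.g. known ADAR eQTLs).
#' @param g a [genotype_set()].
#' @param rate per-sample total editing rate.
#' @param covariates samples x q matrix/data.frame or `NULL`.
#' @return list with `r2`, `p`, `df`, `n`, `pruned` (dropped SNP ids).
#' @export
snpset_variance <- function(snp_ids, g, rate, covariates = NULL) {
  snp_ids <- unique(snp_ids)
  if (length(snp_ids) == 0L) stop("empty SNP set", call. = FALSE)
  miss <- setdiff(snp_ids, g$map$snp)
  if (length(miss)) stop("SNPs absent from genotypes: ",
                         paste(utils::head(miss, 3), collapse = ", "),
                         call. = FALSE)
  D <- g$dosage[, snp_ids, drop = FALSE]
  if (length(snp_ids) >= nrow(D) / 2)
    stop("SNP set too large for the sample size", call. = FALSE)
  cm <- colMeans(D, na.rm = TRUE)
  for (j in which(colSums(is.na(D)) > 0L)) D[is.na(D[, j]), j] <- cm[j]
  Z <- as_covariate_matrix(covariates)
  cc <- !is.na(rate) & (if (is.null(Z)) TRUE else stats::complete.cases(Z))
  y <- rate[cc]
  X0 <- cbind(1, if (is.null(Z)) NULL else Z[cc, , drop = FALSE])
  f0 <- lm.fit(X0, y)
  f1 <- lm.fit(cbind(X0, D[cc, , drop = FALSE]), y)
  pruned <- snp_ids[is.na(f1$coefficients[(ncol(X0) + 1):
                                            (ncol(X0) + ncol(D))])]
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  df1 <- f1$rank - f0$rank
  df2 <- length(y) - f1$rank
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(r2 = (rss0 - rss1) / rss0,
       p = pf(Fstat, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), n = length(y), pruned = pruned)
}
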