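# CES total editing rate, co-editing correlations, concordance.

#' Per-sample CES total editing rate
#'
#' For each sample the total editing rate over a site subset is
#' sum(G_i) / sum(C_i): the number of edited (G) reads summed over the
#' subset sites covered by at least `min_coverage` reads in that sample,
#' divided by the summed coverage at those sites. It is the
#' coverage-weighted mean of the per-site editing levels present in the
#' sample.
#'
#' @param counts an [edit_counts()] object.
#' @param site_subset site ids to pool (e.g. the CES list, or its ALU /
#'   non-ALU subsets); must all exist in `counts`.
#' @param min_coverage per-site inclusive coverage threshold (default 10).
#' @return named numeric vector, one rate per sample; `NA` where no subset
#'   site is covered.
#' @export
total_editing_rate <- function(counts, site_subset, min_coverage = 10) {
  stopifnot(inherits(counts, "edit_counts"))
  if (length(site_subset) == 0L) stop("empty site subset", call. = FALSE)
  miss <- setdiff(site_subset, rownames(counts$a))
  if (length(miss))
    stop("subset sites absent from counts: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  a <- counts$a[site_subset, , drop = FALSE]
  g <- counts$g[site_subset, , drop = FALSE]
  cov <- a + g
  ok <- cov >= min_coverage
  gs <- colSums(g * ok)
  cs <- colSums(cov * ok)
  rate <- gs / cs
  rate[cs == 0] <- NA_real_
  rate
}

#' Co-editing correlation between site pairs
#'
#' Computes Spearman's rho (average-rank ties) with a two-sided p-value for
#' every unordered pair of the given sites, over pairwise-complete samples.
#' Pairs with fewer than `min_pairs` complete observations, or a constant
#' vector, are skipped and reported with a reason. Adjusted p-values use a
#' dependence-robust FDR by default (Benjamini-Yekutieli), since co-editing
#' tests on overlapping samples are strongly related;
#' Benjamini-Hochberg is selectable.
#'
#' @param em an `editing_matrix`.
#' @param ces site ids to test (rows of `em`).
#' @param fdr_method `"BY"` (default) or `"BH"`.
#' @param min_pairs minimum complete observations per pair (default 3).
#' @return list with `records` (site_a, site_b, n, rho, p, fdr),
#'   `skipped` (site_a, site_b, reason), and the test-count accounting:
#'   `n_tests_unordered` = m(m-1)/2 and `n_tests_all_against_all` = m^2
#'   (the convention used when each site is analysed against all others).
#' @export
pairwise_site_correlation <- function(em, ces, fdr_method = c("BY", "BH"),
                                      min_pairs = 3) {
  stopifnot(inherits(em, "editing_matrix"))
  fdr_method <- match.arg(fdr_method)
  x <- em$ratio[rownames(em$ratio) %in% ces, , drop = FALSE]
  m <- nrow(x)
  if (m < 2L) stop("need at least two sites", call. = FALSE)
  ids <- rownames(x)
  recs <- vector("list", m * (m - 1) / 2)
  skip <- list()
  k <- 0L
  for (i in seq_len(m - 1L)) {
    xi <- x[i, ]
    for (j in (i + 1L):m) {
      cc <- !is.na(xi) & !is.na(x[j, ])
      n <- sum(cc)
      if (n < min_pairs) {
        skip[[length(skip) + 1L]] <-
          data.frame(site_a = ids[i], site_b = ids[j],
                     reason = "too_few_pairs")
        next
      }
      ri <- rank(xi[cc]); rj <- rank(x[j, cc])
      if (sd(ri) == 0 || sd(rj) == 0) {
        skip[[length(skip) + 1L]] <-
          data.frame(site_a = ids[i], site_b = ids[j], reason = "constant")
        next
      }
      rho <- cor(ri, rj)
      # two-sided p via the t approximation on ranks
      p <- if (abs(rho) >= 1) 0 else {
        tt <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * pt(-abs(tt), df = n - 2)
      }
      k <- k + 1L
      recs[[k]] <- data.frame(site_a = ids[i], site_b = ids[j],
                              n = n, rho = rho, p = p)
    }
  }
  records <- if (k) do.call(rbind, recs[seq_len(k)]) else
    data.frame(site_a = character(), site_b = character(),
               n = integer(), rho = numeric(), p = numeric())
  records$fdr <- p.adjust(records$p, method = fdr_method)
  list(records = records,
       skipped = if (length(skip)) do.call(rbind, skip) else NULL,
       n_tests_unordered = m * (m - 1) / 2,
       n_tests_all_against_all = m^2)
}

#' Test-count conventions for m sites
#'
#' @param m number of sites.
#' @return list with `unordered` = m(m-1)/2 unique pairs and
#'   `all_against_all` = m^2 (each site against every site, the convention
#'   used for the printed total number of correlation tests).
#' @export
pair_test_count <- function(m) {
  list(unordered = m * (m - 1) / 2, all_against_all = m * m)
}

#' Stratify correlation records by rho band and genomic distance
#'
#' Distance classes for a pair on the same chromosome are `"lt50bp"`
#' (strictly below 50 bp), `"le1kb"` (50 bp to 1 kb inclusive) and
#' `"far"` (> 1 kb); pairs on different chromosomes are
#' `"inter_chromosomal"`. Rho bands: `high` (rho >= 0.5), `middle`
#' (0.3 <= rho < 0.5), `other`.
#'
#' @param records data.frame with `site_a`, `site_b`, `rho`.
#' @param sites site table with `site_id`, `chrom`, `pos`.
#' @return list with the annotated `records` (added `distance`,
#'   `distance_class`, `rho_band`) and a `counts` table of band x class.
#' @export
stratify_by_distance <- function(records, sites) {
  ia <- match(records$site_a, sites$site_id)
  ib <- match(records$site_b, sites$site_id)
  if (anyNA(ia) || anyNA(ib))
    stop("records contain sites absent from the site table", call. = FALSE)
  same <- sites$chrom[ia] == sites$chrom[ib]
  dist <- ifelse(same, abs(sites$pos[ia] - sites$pos[ib]), NA_real_)
  cls <- ifelse(!same, "inter_chromosomal",
                ifelse(dist < 50, "lt50bp",
                       ifelse(dist <= 1000, "le1kb", "far")))
  band <- ifelse(records$rho >= 0.5, "high",
                 ifelse(records$rho >= 0.3, "middle", "other"))
  records$distance <- dist
  records$distance_class <- factor(
    cls, levels = c("lt50bp", "le1kb", "far", "inter_chromosomal"))
  records$rho_band <- factor(band, levels = c("high", "middle", "other"))
  list(records = records,
       counts = table(band = records$rho_band,
                      distance_class = records$distance_class))
}

#' Lin's concordance correlation coefficient
#'
#' CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2), with
#' population (1/n) moments. It penalises both decorrelation and
#' location/scale shift, so |CCC| <= |Pearson r|.
#'
#' @param x,y paired numeric vectors without missing values.
#' @return scalar CCC.
#' @export
#' @examples
#' concordance_correlation(1:10, 1:10)  # exactly 1
concordance_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must be paired vectors of length >= 2", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0)
    stop("concordance undefined: zero variance and equal means",
         call. = FALSE)
  2 * cxy / denom
}
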