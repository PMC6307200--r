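# Association of expression, cell composition and biological variables
# with the CES total editing rate; hypergeometric gene-set enrichment.

# Expand a covariate data.frame/matrix into a numeric model matrix
# (factors dummy-coded, no intercept column).
as_covariate_matrix <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  if (is.matrix(covariates)) return(covariates)
  mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  mm[, -1, drop = FALSE]
}

fit_ols <- function(X, y) {
  f <- lm.fit(X, y)
  r <- f$residuals
  p <- f$rank
  rss <- sum(r^2)
  sigma2 <- rss / (length(y) - p)
  XtXinv <- chol2inv(chol(crossprod(X)))
  list(coef = f$coefficients, resid = r, rss_w = rss,
       df = length(y) - p, se = sqrt(diag(XtXinv) * sigma2),
       w = rep(1, length(y)))
}

fit_huber <- function(X, y) {
  f <- MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345, maxit = 50)
  s <- summary(f, method = "XtX")
  list(coef = coef(f), resid = f$residuals,
       rss_w = sum(f$w * f$residuals^2),
       df = length(y) - ncol(X), se = s$coefficients[, "Std. Error"],
       w = f$w)
}

#' Residualise expression on technical covariates by ridge regression
#'
#' Per-gene residuals of a ridge fit of (log) expression on a covariate
#' matrix, with an unpenalised intercept (covariates and responses are
#' centred before the penalised solve). `lambda = 0` reduces to least
#' squares; as `lambda -> Inf` the fit shrinks to the intercept and the
#' residuals approach the centred expression.
#'
#' @param log_counts genes x samples numeric matrix.
#' @param covariates samples x q matrix/data.frame, no missing values.
#' @param lambda ridge penalty, `>= 0`.
#' @return genes x samples residual matrix.
#' @export
ridge_residualize <- function(log_counts, covariates, lambda = 1) {
  Y <- as.matrix(log_counts)
  Z <- as_covariate_matrix(covariates)
  if (nrow(Z) != ncol(Y))
    stop("covariate rows must match expression columns", call. = FALSE)
  if (anyNA(Z)) stop("missing covariates not allowed", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  if (lambda == 0 && qr(Zc)$rank < ncol(Zc))
    stop("covariates are rank-deficient with lambda = 0; use lambda > 0",
         call. = FALSE)
  Yc <- Y - rowMeans(Y)
  B <- solve(crossprod(Zc) + diag(lambda, ncol(Zc)), crossprod(Zc, t(Yc)))
  res <- Yc - t(Zc %*% B)
  dimnames(res) <- dimnames(Y)
  res
}

#' Robust association between a predictor and the total editing rate
#'
#' Fits a full model (covariates + predictor) and a null model (covariates
#' only) by Huber M-estimation (tuning constant 1.345) and compares them:
#' the p-value is a robust F-type test on the predictor term (squared Wald
#' t on F(1, n - p)), and the partial R-squared is
#' (RSS_null - RSS_full) / RSS_null, with both models' residuals weighted
#' by the full fit's robustness weights so outlier downweighting cancels
#' in the ratio - the share of residual variability beyond the covariates
#' that the predictor explains. An ordinary least-squares flavour is selectable
#' for cross-checks.
#'
#' @param y per-sample response (the total editing rate).
#' @param predictor per-sample numeric predictor (e.g. a gene's expression).
#' @param covariates samples x q matrix/data.frame or `NULL`.
#' @param method `"huber"` (default) or `"ols"`.
#' @param null_fit optional pre-computed null-model fit (internal use by the
#'   genome-wide scan, where the null model is shared across genes).
#' @return object of class `edit_assoc`: list with `beta`, `se`,
#'   `statistic` (F), `p`, `partial_r2`, `df`, `n`, `method`, `degenerate`.
#' @export
robust_association <- function(y, predictor, covariates = NULL,
                               method = c("huber", "ols"),
                               null_fit = NULL) {
  method <- match.arg(method)
  Z <- as_covariate_matrix(covariates)
  cc <- !is.na(y) & !is.na(predictor)
  if (!is.null(Z)) cc <- cc & stats::complete.cases(Z)
  y <- y[cc]; predictor <- predictor[cc]
  Z <- if (is.null(Z)) NULL else Z[cc, , drop = FALSE]
  n <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n), Z)
  if (n < ncol(X0) + 11)
    stop("need n >= p + 10 samples", call. = FALSE)
  # degenerate predictors: constant, or collinear with the covariates
  # (e.g. the ADAR gene scanned while ADAR is itself a covariate)
  pred_resid <- lm.fit(X0, predictor)$residuals
  if (sd(predictor) == 0 ||
      sd(pred_resid) < 1e-10 * max(sd(predictor), 1)) {
    out <- list(beta = NA_real_, se = NA_real_, statistic = NA_real_,
                p = 1, partial_r2 = 0, df = n - ncol(X0) - 1, n = n,
                method = method, degenerate = TRUE)
    class(out) <- "edit_assoc"
    return(out)
  }
  fitter <- if (method == "huber") fit_huber else fit_ols
  f0 <- null_fit %||% fitter(X0, y)
  f1 <- fitter(cbind(X0, predictor = predictor), y)
  k <- ncol(X0) + 1L
  tval <- f1$coef[k] / f1$se[k]
  Fstat <- tval^2
  p <- pf(Fstat, 1, f1$df, lower.tail = FALSE)
  # partial R2 on weighted residuals; the full fit's robustness weights are
  # applied to both models so outlier downweighting cancels in the ratio
  rss0 <- sum(f1$w * f0$resid^2)
  rss1 <- sum(f1$w * f1$resid^2)
  pr2 <- min(max((rss0 - rss1) / rss0, 0), 1)
  out <- list(beta = unname(f1$coef[k]), se = unname(f1$se[k]),
              statistic = unname(Fstat), p = unname(p), partial_r2 = pr2,
              df = f1$df, n = n, method = method, degenerate = FALSE)
  class(out) <- "edit_assoc"
  out
}

#' @export
print.edit_assoc <- function(x, ...) {
  cat("<edit_assoc> beta =", signif(x$beta, 4), " p =", signif(x$p, 3),
      " partial R2 =", signif(x$partial_r2, 3), " (", x$method, ", n =",
      x$n, ")\n")
  invisible(x)
}

#' Genome-wide association between expression and the total editing rate
#'
#' One [robust_association()] per gene against a shared covariate set
#' (the null model is fitted once). With `remove_adar`, the ADAR gene's
#' expression row is appended to the covariates so the scan reports effects
#' beyond ADAR. P-values are Benjamini-Hochberg adjusted; significance
#' tiers at FDR < 0.05 and FDR < 0.01 are flagged.
#'
#' @param expression genes x samples residual-expression matrix.
#' @param rate per-sample total editing rate (aligned to columns).
#' @param covariates samples x q matrix/data.frame or `NULL` (typically the
#'   selected biological covariates plus log2 summed CES coverage).
#' @param remove_adar append ADAR expression as a covariate.
#' @param adar_id rowname of the ADAR gene (default `"ADAR"`).
#' @param method `"huber"` or `"ols"`.
#' @param min_genes smallest scan considered meaningful (default 100).
#' @return data.frame with one row per gene: `gene`, `beta`, `p`,
#'   `partial_r2`, `fdr`, `sig05`, `sig01`, `model` flavour.
#' @export
genomewide_expression_scan <- function(expression, rate, covariates = NULL,
                                       remove_adar = FALSE,
                                       adar_id = "ADAR",
                                       method = c("huber", "ols"),
                                       min_genes = 100) {
  method <- match.arg(method)
  expression <- as.matrix(expression)
  if (nrow(expression) < min_genes)
    stop("scan requires at least ", min_genes, " genes", call. = FALSE)
  Z <- as_covariate_matrix(covariates)
  if (remove_adar) {
    if (!adar_id %in% rownames(expression))
      stop("ADAR id '", adar_id, "' absent from expression matrix",
           call. = FALSE)
    Z <- cbind(Z, adar = expression[adar_id, ])
  }
  cc <- !is.na(rate)
  if (!is.null(Z)) cc <- cc & stats::complete.cases(Z)
  y <- rate[cc]
  Zcc <- if (is.null(Z)) NULL else Z[cc, , drop = FALSE]
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), Zcc)
  fitter <- if (method == "huber") fit_huber else fit_ols
  f0 <- fitter(X0, y)
  genes <- rownames(expression) %||% as.character(seq_len(nrow(expression)))
  res <- lapply(seq_len(nrow(expression)), function(i) {
    a <- robust_association(y, expression[i, cc], Zcc, method = method,
                            null_fit = f0)
    data.frame(gene = genes[i], beta = a$beta, p = a$p,
               partial_r2 = a$partial_r2)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$sig05 <- out$fdr < 0.05
  out$sig01 <- out$fdr < 0.01
  out$model <- if (remove_adar) "without_adar_effect" else "with_adar_effect"
  out
}

#' Test a covariate's association with editing, with and without
#' cell-composition adjustment
#'
#' The raw test is dispatched on the variable kind: Pearson correlation for
#' continuous, Mann-Whitney-Wilcoxon for binary, Kruskal-Wallis for
#' categorical variables. `p_cell` comes from a likelihood-ratio comparison
#' of linear models of the target on the cell-composition covariates with
#' and without the variable, and so measures the variable's effect beyond
#' blood cell composition.
#'
#' @param variable per-sample values (numeric, or factor/character for
#'   categorical).
#' @param kind `"continuous"`, `"binary"` or `"categorical"`.
#' @param target per-sample response (total editing rate or an expression
#'   vector).
#' @param cell_covariates samples x c matrix/data.frame of the
#'   rate-associated cell fractions.
#' @param min_informative minimum non-missing observations (default 30,
#'   mirroring the study's relevance rule).
#' @return data.frame row: `kind`, `test`, `n`, `r` (continuous only),
#'   `p`, `p_cell`.
#' @export
variable_association <- function(variable, kind, target, cell_covariates,
                                 min_informative = 30) {
  kind <- match.arg(kind, c("continuous", "binary", "categorical"))
  cells <- as_covariate_matrix(cell_covariates)
  cc <- !is.na(variable) & !is.na(target) & stats::complete.cases(cells)
  v <- variable[cc]; y <- target[cc]
  cells <- cells[cc, , drop = FALSE]
  if (sum(cc) < min_informative)
    stop("variable informative in fewer than ", min_informative,
         " samples", call. = FALSE)
  r <- NA_real_
  if (kind == "continuous") {
    if (!is.numeric(v)) stop("continuous variable must be numeric",
                             call. = FALSE)
    ct <- cor.test(v, y)
    p <- ct$p.value; r <- unname(ct$estimate); test <- "pearson"
    vmod <- v
  } else {
    f <- factor(v)
    if (kind == "binary" && nlevels(f) != 2)
      stop("binary variable must have exactly 2 levels, found ",
           nlevels(f), call. = FALSE)
    if (kind == "categorical" && nlevels(f) < 2)
      stop("categorical variable needs >= 2 levels", call. = FALSE)
    p <- if (kind == "binary")
      suppressWarnings(wilcox.test(y ~ f)$p.value)
    else kruskal.test(y, f)$p.value
    test <- if (kind == "binary") "wilcoxon" else "kruskal-wallis"
    vmod <- f
  }
  d0 <- data.frame(y = y, cells)
  m0 <- lm(y ~ ., data = d0)
  m1 <- lm(y ~ ., data = cbind(d0, .var = vmod))
  p_cell <- anova(m0, m1, test = "LRT")[2, "Pr(>Chi)"]
  data.frame(kind = kind, test = test, n = sum(cc), r = r, p = p,
             p_cell = p_cell)
}

# Minimal GMT reader: one set per line, "name <tab> description <tab>
# gene1 <tab> gene2 ...".
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, "", 1L))
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided upper-tail hypergeometric test per set: the probability of
#' drawing at least the observed overlap when `|significant|` genes are
#' sampled from the background. Set membership is intersected with the
#' background first; sets with no background overlap are skipped with a
#' note. BH adjustment is applied within each collection.
#'
#' @param significant character vector of significant genes (must be a
#'   subset of `background`).
#' @param background character vector of all testable genes.
#' @param collections named list; each element is a named list of character
#'   vectors (gene sets) or a path to a GMT file.
#' @return data.frame: `collection`, `set_id`, `set_size_bg`, `overlap`,
#'   `p`, `fdr`, `note`.
#' @export
hypergeometric_enrichment <- function(significant, background, collections) {
  significant <- unique(significant); background <- unique(background)
  if (!all(significant %in% background))
    stop("significant genes must be a subset of the background",
         call. = FALSE)
  N <- length(background); n <- length(significant)
  out <- list()
  for (cn in names(collections)) {
    sets <- collections[[cn]]
    if (is.character(sets) && length(sets) == 1L) sets <- read_gmt(sets)
    rows <- lapply(names(sets), function(sn) {
      s <- intersect(sets[[sn]], background)
      K <- length(s)
      if (K == 0L)
        return(data.frame(collection = cn, set_id = sn, set_size_bg = 0L,
                          overlap = 0L, p = NA_real_,
                          note = "no_background_overlap"))
      k <- length(intersect(s, significant))
      # upper tail including the observed overlap
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      data.frame(collection = cn, set_id = sn, set_size_bg = K,
                 overlap = k, p = p, note = "")
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- NA_real_
    ok <- !is.na(tab$p)
    tab$fdr[ok] <- p.adjust(tab$p[ok], method = "BH")
    out[[cn]] <- tab
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
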