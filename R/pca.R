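# PCA of the editing matrix: imputation, components, plateau rule,
# PC-variable and PC-site associations.

#' Impute missing editing levels
#'
#' Default method is missForest-style iterative imputation with
#' random-forest regressors: after a mean initialisation, each site with
#' missing values is regressed (across samples) on all other sites and its
#' missing entries replaced by the forest prediction, iterating until the
#' relative change of imputed values falls below `tol` or `max_iter` is
#' reached. A k-nearest-site average (`"knn"`, correlation-ranked
#' neighbours) and a per-site mean (`"mean"`) are provided as fast
#' options. Imputed values are clipped to \[0, 1\]; observed entries are
#' never altered; results are deterministic under `seed`.
#'
#' @param em an `editing_matrix` or a plain sites x samples matrix with
#'   `NA`s.
#' @param method `"forest"`, `"knn"` or `"mean"`.
#' @param seed RNG seed for the forest (default 1).
#' @param k neighbours for `"knn"` (default 10).
#' @param max_iter,tol forest iteration controls.
#' @param num_trees trees per forest (default 100).
#' @return complete numeric matrix of the same dimension.
#' @export
impute_missing <- function(em, method = c("forest", "knn", "mean"),
                           seed = 1, k = 10, max_iter = 10, tol = 1e-4,
                           num_trees = 100) {
  method <- match.arg(method)
  x <- if (inherits(em, "editing_matrix")) em$ratio else as.matrix(em)
  if (any(rowSums(!is.na(x)) == 0L))
    stop("sites with no observed value cannot be imputed; exclude them first",
         call. = FALSE)
  obs <- !is.na(x)
  if (all(obs)) return(x)
  row_means <- rowMeans(x, na.rm = TRUE)
  filled <- x
  filled[!obs] <- row_means[row(x)[!obs]]
  if (method == "mean") return(filled)
  if (method == "knn") {
    # neighbours by euclidean profile distance on the mean-initialised
    # matrix; squared distances via the cross-product identity
    xf <- filled
    sq <- rowSums(xf^2)
    D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(xf)
    diag(D2) <- Inf
    for (i in which(rowSums(!obs) > 0L)) {
      nb <- order(D2[i, ])[seq_len(min(k, nrow(x) - 1))]
      for (j in which(!obs[i, ])) {
        v <- x[nb, j]
        x[i, j] <- if (all(is.na(v))) row_means[i] else mean(v, na.rm = TRUE)
      }
    }
    return(pmin(pmax(x, 0), 1))
  }
  # iterative forest, sites ordered by increasing missingness
  ord <- order(rowSums(!obs), decreasing = TRUE)
  targets <- ord[rowSums(!obs)[ord] < ncol(x)]
  targets <- targets[rowSums(!obs[targets, , drop = FALSE]) > 0L]
  prev <- filled
  for (it in seq_len(max_iter)) {
    for (i in targets) {
      oth <- t(filled[-i, , drop = FALSE])
      colnames(oth) <- paste0("s", seq_len(ncol(oth)))
      train <- data.frame(.y = x[i, obs[i, ]],
                          oth[obs[i, ], , drop = FALSE])
      rf <- ranger::ranger(.y ~ ., data = train, num.trees = num_trees,
                           seed = stream_seed(seed, paste0("imp", i)),
                           num.threads = 1)
      pred <- predict(rf, data.frame(oth[!obs[i, ], , drop = FALSE]))
      filled[i, !obs[i, ]] <- pred$predictions
    }
    delta <- sqrt(sum((filled[!obs] - prev[!obs])^2) /
                    max(sum(filled[!obs]^2), .Machine$double.eps))
    if (delta < tol) break
    prev <- filled
  }
  filled[obs] <- x[obs]
  pmin(pmax(filled, 0), 1)
}

#' Principal components of a complete editing matrix
#'
#' Singular value decomposition of the centred (optionally scaled)
#' samples x sites matrix, as `prcomp` does. The sign of each component is
#' fixed so that its largest-magnitude loading is positive.
#'
#' @param mat complete sites x samples matrix.
#' @param center,scale. passed to the decomposition (defaults: centred,
#'   unscaled, mirroring `prcomp`).
#' @return object of class `editing_pca`: `scores` (samples x k),
#'   `loadings` (sites x k), `sdev`, `var_frac` (explained-variance
#'   fractions).
#' @export
compute_pcs <- function(mat, center = TRUE, scale. = FALSE) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(mat)) stop("matrix must be complete; impute first",
                       call. = FALSE)
  if (all(apply(mat, 1, sd) == 0))
    stop("zero-variance matrix", call. = FALSE)
  pr <- prcomp(t(mat), center = center, scale. = scale.)
  flip <- apply(pr$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, `*`)
  loadings <- sweep(pr$rotation, 2, flip, `*`)
  structure(list(scores = scores, loadings = loadings, sdev = pr$sdev,
                 var_frac = pr$sdev^2 / sum(pr$sdev^2)),
            class = "editing_pca")
}

#' @export
print.editing_pca <- function(x, ...) {
  cat("<editing_pca> ", nrow(x$scores), " samples, ",
      length(x$var_frac), " components; top variance fractions: ",
      paste(signif(utils::head(x$var_frac, 5), 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Choose the number of PCs by the plateau rule
#'
#' Looks at the explained-variance fractions of the top `window`
#' components and keeps the components that still stand out above the
#' plateau: k is the number of fractions strictly greater than
#' `baseline + ratio * (first - baseline)`, where `baseline` is the mean
#' fraction over the window. A flat spectrum therefore gives k = 1
#' (nothing stands out), while a spectrum with a few dominant components
#' followed by a plateau keeps exactly the dominant ones.
#'
#' @param var_frac explained-variance fractions (e.g. from
#'   [compute_pcs()]).
#' @param window number of leading components examined (default 30).
#' @param ratio fraction of the first component's excess over the baseline
#'   required to count as above the plateau (default 0.2).
#' @return integer k >= 1.
#' @export
choose_n_pcs <- function(var_frac, window = 30, ratio = 0.2) {
  v <- utils::head(var_frac, window)
  baseline <- mean(v)
  thr <- baseline + ratio * (v[1] - baseline)
  max(1L, sum(v > thr))
}

#' Associate PCs with cohort variables
#'
#' Cell-fraction variables are tested by Pearson correlation against each
#' PC; other (biological / pharmacological) variables by a
#' likelihood-ratio comparison of linear models of the PC on the cell
#' covariates with and without the variable.
#'
#' @param scores samples x k PC score matrix (rownames = sample ids).
#' @param variables data.frame of per-sample variables (rownames or
#'   `sample_id` column aligned with `scores`).
#' @param cell_covariates samples x c matrix/data.frame of cell fractions
#'   used as the background model.
#' @return long data.frame: `pc`, `variable`, `kind`, `estimate`
#'   (Pearson r where applicable), `p`.
#' @export
pc_variable_association <- function(scores, variables, cell_covariates) {
  scores <- as.matrix(scores)
  if (!is.null(rownames(scores)) && !is.null(rownames(variables)) &&
      !identical(rownames(scores), rownames(variables)))
    stop("sample ids of scores and variables are misaligned",
         call. = FALSE)
  if (nrow(variables) != nrow(scores))
    stop("sample ids of scores and variables are misaligned",
         call. = FALSE)
  cells <- as_covariate_matrix(cell_covariates)
  cell_names <- colnames(cell_covariates) %||% colnames(cells)
  out <- list()
  for (pc in seq_len(ncol(scores))) {
    s <- scores[, pc]
    for (vn in names(variables)) {
      v <- variables[[vn]]
      if (vn %in% cell_names) {
        ct <- cor.test(as.numeric(v), s)
        out[[length(out) + 1L]] <- data.frame(
          pc = pc, variable = vn, kind = "cell_fraction",
          estimate = unname(ct$estimate), p = ct$p.value)
      } else {
        vv <- if (is.numeric(v)) v else factor(v)
        cc <- !is.na(vv)
        d0 <- data.frame(y = s[cc], cells[cc, , drop = FALSE])
        m0 <- lm(y ~ ., data = d0)
        m1 <- lm(y ~ ., data = cbind(d0, .var = vv[cc]))
        p <- anova(m0, m1, test = "LRT")[2, "Pr(>Chi)"]
        out[[length(out) + 1L]] <- data.frame(
          pc = pc, variable = vn, kind = "biological",
          estimate = NA_real_, p = p)
      }
    }
  }
  do.call(rbind, out)
}

#' Classify site-PC correlations into literal strength bands
#'
#' Pearson correlation of each site's editing levels (non-missing samples)
#' with each PC score vector. The `band` column follows the literal
#' definition: `moderate` when 0.3 <= |r| <= 0.5 and the test passes the
#' Bonferroni threshold alpha / (n_sites * k); `weak` when |r| < 0.3 and
#' Bonferroni-significant; otherwise `none` (note that |r| > 0.5 lies
#' outside both bands). The `class` column additionally names
#' Bonferroni-significant |r| > 0.5 correlations `strong` so they are not
#' silently discarded.
#'
#' @param mat sites x samples editing matrix (may contain `NA`).
#' @param scores samples x k PC scores.
#' @param alpha family-wise alpha before Bonferroni division
#'   (default 0.05).
#' @return data.frame: `site_id`, `pc`, `r`, `p`, `band`, `class`.
#' @export
classify_site_pc_correlation <- function(mat, scores, alpha = 0.05) {
  mat <- if (inherits(mat, "editing_matrix")) mat$ratio else as.matrix(mat)
  scores <- as.matrix(scores)
  kpc <- ncol(scores)
  thr <- alpha / (nrow(mat) * kpc)
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  out <- list()
  for (i in seq_len(nrow(mat))) {
    for (pc in seq_len(kpc)) {
      cc <- !is.na(mat[i, ])
      if (sum(cc) < 3 || sd(mat[i, cc]) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- cor.test(mat[i, cc], scores[cc, pc])
        r <- unname(ct$estimate); p <- ct$p.value
      }
      sig <- !is.na(p) && p < thr
      band <- if (sig && !is.na(r) && abs(r) >= 0.3 && abs(r) <= 0.5)
        "moderate" else if (sig && !is.na(r) && abs(r) < 0.3) "weak"
      else "none"
      cls <- if (sig && !is.na(r) && abs(r) > 0.5) "strong" else band
      out[[length(out) + 1L]] <- data.frame(
        site_id = ids[i], pc = pc, r = r, p = p, band = band, class = cls)
    }
  }
  res <- do.call(rbind, out)
  res$band <- factor(res$band, levels = c("moderate", "weak", "none"))
  res$class <- factor(res$class,
                      levels = c("strong", "moderate", "weak", "none"))
  res
}
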