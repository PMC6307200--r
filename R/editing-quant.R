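# Editing quantification: strand-aware base counts -> editing-level matrix.

#' Resolve per-base counts to strand-aware (A, G) counts
#'
#' A-to-I editing is read as A>G on the gene strand. For a site on the plus
#' strand the relevant counts are the A (reference) and G (edited) read
#' counts; for a minus-strand site the sequencer reports the opposite strand,
#' so T plays the role of A and C the role of G.
#'
#' @param counts named numeric vector (or matrix with columns) `A`, `C`, `G`,
#'   `T` of plus-strand base counts.
#' @param strand `"+"` or `"-"`.
#' @return list with `a_reads` and `g_reads` (vectors if `counts` is a
#'   matrix).
#' @export
#' @examples
#' strand_resolve(c(A = 7, C = 0, G = 3, T = 0), "+")
#' strand_resolve(c(A = 0, C = 3, G = 0, T = 7), "-")
strand_resolve <- function(counts, strand) {
  if (is.matrix(counts)) {
    stopifnot(all(c("A", "C", "G", "T") %in% colnames(counts)))
    get_base <- function(b) counts[, b]
  } else {
    stopifnot(all(c("A", "C", "G", "T") %in% names(counts)))
    get_base <- function(b) unname(counts[b])
  }
  if (any(get_base("A") < 0 | get_base("C") < 0 |
          get_base("G") < 0 | get_base("T") < 0))
    stop("base counts must be non-negative", call. = FALSE)
  if (!all(strand %in% c("+", "-")))
    stop("unknown strand symbol: ", paste(setdiff(strand, c("+", "-")),
                                          collapse = ", "), call. = FALSE)
  if (length(strand) == 1L) {
    if (strand == "+") list(a_reads = get_base("A"), g_reads = get_base("G"))
    else               list(a_reads = get_base("T"), g_reads = get_base("C"))
  } else {
    plus <- strand == "+"
    list(
      a_reads = ifelse(plus, get_base("A"), get_base("T")),
      g_reads = ifelse(plus, get_base("G"), get_base("C"))
    )
  }
}

#' Construct a base-count container
#'
#' Holds parallel sites x samples matrices of reference (A) and edited (G)
#' read counts on the gene strand. Row names are site ids, column names
#' sample ids.
#'
#' @param a,g non-negative integer matrices of identical dimension.
#' @return object of class `edit_counts`.
#' @export
edit_counts <- function(a, g) {
  a <- as.matrix(a); g <- as.matrix(g)
  if (!identical(dim(a), dim(g)))
    stop("a and g matrices must have identical dimensions", call. = FALSE)
  bad <- which(a < 0 | g < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative counts at cells: ",
         paste(utils::head(paste0("[", bad[, 1], ",", bad[, 2], "]"), 5),
               collapse = " "), call. = FALSE)
  structure(list(a = a, g = g), class = "edit_counts")
}

#' @export
print.edit_counts <- function(x, ...) {
  cat("<edit_counts> ", nrow(x$a), " sites x ", ncol(x$a), " samples\n",
      sep = "")
  invisible(x)
}

#' Read a long-format base-count TSV
#'
#' Expects columns `site_id`, `sample_id`, `a_reads`, `g_reads`; missing
#' site/sample combinations get zero counts.
#'
#' @param path TSV path.
#' @return an [edit_counts()] object.
#' @export
read_base_counts <- function(path) {
  d <- read_tsv(path)
  need <- c("site_id", "sample_id", "a_reads", "g_reads")
  if (!all(need %in% names(d)))
    stop("counts TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sites <- unique(d$site_id); samples <- unique(d$sample_id)
  a <- g <- matrix(0, length(sites), length(samples),
                   dimnames = list(sites, samples))
  i <- cbind(match(d$site_id, sites), match(d$sample_id, samples))
  a[i] <- d$a_reads; g[i] <- d$g_reads
  edit_counts(a, g)
}

#' Write base counts in long TSV format
#' @param counts an [edit_counts()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_base_counts <- function(counts, path) {
  d <- data.frame(
    site_id = rep(rownames(counts$a), times = ncol(counts$a)),
    sample_id = rep(colnames(counts$a), each = nrow(counts$a)),
    a_reads = as.vector(counts$a),
    g_reads = as.vector(counts$g)
  )
  write_tsv(d, path)
}

#' Compute per-site, per-sample editing levels
#'
#' The editing level at a site in a sample is g / (a + g), the fraction of
#' edited reads among gene-strand A/G reads. Sites with coverage
#' (a + g) below `min_coverage` in a sample are recorded as missing (`NA`)
#' in that sample; the coverage matrix is retained for the total editing
#' rate statistic.
#'
#' @param counts an [edit_counts()] object.
#' @param min_coverage inclusive minimum coverage (default 10 reads).
#' @return object of class `editing_matrix` with elements `ratio`
#'   (editing levels with `NA` for low coverage), `coverage` (a + g) and
#'   `min_coverage`.
#' @export
#' @examples
#' ec <- edit_counts(a = matrix(5, 1, 1), g = matrix(5, 1, 1))
#' compute_editing_levels(ec, min_coverage = 10)$ratio
compute_editing_levels <- function(counts, min_coverage = 10) {
  stopifnot(inherits(counts, "edit_counts"))
  if (min_coverage < 1) stop("min_coverage must be >= 1", call. = FALSE)
  cov <- counts$a + counts$g
  ratio <- counts$g / cov
  ratio[cov < min_coverage] <- NA_real_
  structure(list(ratio = ratio, coverage = cov, min_coverage = min_coverage),
            class = "editing_matrix")
}

#' @export
print.editing_matrix <- function(x, ...) {
  cat("<editing_matrix> ", nrow(x$ratio), " sites x ", ncol(x$ratio),
      " samples; min coverage ", x$min_coverage, "; ",
      sprintf("%.1f%%", 100 * mean(is.na(x$ratio))), " missing\n", sep = "")
  invisible(x)
}

#' Write/read an editing-level matrix TSV ("NA" for missing)
#' @param em an `editing_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_editing_matrix <- function(em, path) {
  write_tsv(as.data.frame(em$ratio), path, row_names = TRUE)
}

#' Per-site coverage and detectability summary
#'
#' @param em an `editing_matrix`.
#' @param detect_level editing level at or above which a site counts as
#'   detectably edited in a sample (default 0.05).
#' @return data.frame with per-site `n_covered` (samples with non-missing
#'   level), `median_coverage` (over covered samples) and `n_detectable`
#'   (covered samples with level >= `detect_level`).
#' @export
coverage_summary <- function(em, detect_level = 0.05) {
  stopifnot(inherits(em, "editing_matrix"))
  if (nrow(em$ratio) == 0L) stop("empty editing matrix", call. = FALSE)
  present <- !is.na(em$ratio)
  covm <- em$coverage
  covm[!present] <- NA_real_
  data.frame(
    site_id = rownames(em$ratio) %||% seq_len(nrow(em$ratio)),
    n_covered = rowSums(present),
    median_coverage = apply(covm, 1, function(r)
      if (all(is.na(r))) NA_real_ else median(r, na.rm = TRUE)),
    n_detectable = rowSums(em$ratio >= detect_level, na.rm = TRUE),
    row.names = NULL
  )
}
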