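# CES selection: site exclusion filters, consistency rule, annotation.

#' Read SNV positions from a VCF exclusion list
#'
#' Only CHROM/POS are used: a candidate editing site matching a known single
#' nucleotide variant is treated as a genomic polymorphism, not editing.
#'
#' @param path VCF path (plain or bgzipped).
#' @return data.frame with `chrom` and `pos` (1-based).
#' @export
read_snv_positions <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  data.frame(chrom = as.character(fix[, "CHROM"]),
             pos = as.integer(fix[, "POS"]))
}

as_mask_granges <- function(mask) {
  if (methods::is(mask, "GRanges")) mask else read_bed(mask)
}

#' Apply catalogue, SNV and alignment-artifact filters to candidate sites
#'
#' Retains sites that (i) are present in the editing-site catalogue,
#' (ii) never appear in the known-SNV list, and (iii) fall outside every
#' exclusion mask channel (pseudogenes, segmental duplications with >= 99%
#' identity, single-exon genes, ...). Masks are BED intervals (0-based
#' half-open); site positions are 1-based.
#'
#' @param sites data.frame with at least `site_id`, `chrom`, `pos`, `strand`.
#' @param catalogue character vector of catalogue site ids (RADAR-like).
#' @param snv either a VCF path or a data.frame with `chrom`/`pos`.
#' @param masks named list of BED paths or `GRanges`, one per exclusion
#'   channel.
#' @return the retained subset of `sites`; attribute `"attrition"` holds a
#'   data.frame of per-filter removal counts (a site is attributed to every
#'   filter that would remove it).
#' @export
apply_site_filters <- function(sites, catalogue, snv = NULL, masks = list()) {
  stopifnot(is.data.frame(sites),
            all(c("site_id", "chrom", "pos") %in% names(sites)))
  drop <- list()
  drop[["catalogue"]] <- !(sites$site_id %in% catalogue)
  if (!is.null(snv)) {
    if (is.character(snv)) snv <- read_snv_positions(snv)
    # chrom naming may or may not carry a "chr" prefix; compare without it
    drop[["snv"]] <- paste(sub("^chr", "", sites$chrom), sites$pos) %in%
      paste(sub("^chr", "", snv$chrom), snv$pos)
  }
  gr <- sites_as_granges(sites)
  for (ch in names(masks)) {
    m <- as_mask_granges(masks[[ch]])
    drop[[ch]] <- IRanges::overlapsAny(gr, m, ignore.strand = TRUE)
  }
  removed <- Reduce(`|`, drop, rep(FALSE, nrow(sites)))
  attrition <- data.frame(filter = names(drop),
                          n_removed = vapply(drop, sum, integer(1)),
                          row.names = NULL)
  out <- sites[!removed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attrition") <- attrition
  out
}

#' Select consistently edited sites (CES)
#'
#' A site is consistently edited when its editing level reaches at least
#' `min_level` in at least `ceil(min_fraction * n_samples)` samples. Both
#' thresholds are inclusive; missing levels never count.
#'
#' @param em an `editing_matrix` from [compute_editing_levels()].
#' @param min_level detectable-editing threshold (default 0.05).
#' @param min_fraction required fraction of samples (default 0.20).
#' @return character vector of CES site ids.
#' @export
select_consistent_sites <- function(em, min_level = 0.05,
                                    min_fraction = 0.20) {
  stopifnot(inherits(em, "editing_matrix"))
  if (nrow(em$ratio) == 0L || ncol(em$ratio) == 0L)
    stop("empty editing matrix", call. = FALSE)
  need <- ceiling(min_fraction * ncol(em$ratio))
  n_ok <- rowSums(em$ratio >= min_level, na.rm = TRUE)
  ids <- rownames(em$ratio) %||% as.character(seq_len(nrow(em$ratio)))
  ids[n_ok >= need]
}

#' Annotate sites with ALU / region / miRNA-binding channels
#'
#' Each channel is a BED interval set; a site is labelled when its 1-based
#' position falls inside an interval. Region categories are mutually
#' exclusive per site (checked). The miRNA channel's BED name field carries
#' the conservation class; a site overlapping several miRNA intervals gets
#' the maximum class in the order
#' nonconserved < conserved < broadly_conserved.
#'
#' @param sites data.frame with `site_id`, `chrom`, `pos`.
#' @param channels named list of BED paths or `GRanges`. Names among
#'   `c("utr3","utr5","intron","exon_cds","ncRNA")` form the exclusive
#'   region classification; a channel named `alu` sets the ALU flag; a
#'   channel named `mirna` sets the conservation class.
#' @return `sites` with added columns `alu` (logical), `region` (factor or
#'   NA) and `mirna_overlap`.
#' @export
annotate_sites <- function(sites, channels) {
  gr <- sites_as_granges(sites)
  region_levels <- c("utr3", "utr5", "intron", "exon_cds", "ncRNA")
  mirna_levels <- c("none", "nonconserved", "conserved", "broadly_conserved")
  region <- rep(NA_character_, nrow(sites))
  alu <- rep(FALSE, nrow(sites))
  mirna <- factor(rep("none", nrow(sites)), levels = mirna_levels)
  for (ch in names(channels)) {
    m <- as_mask_granges(channels[[ch]])
    if (ch %in% region_levels) {
      hit <- IRanges::overlapsAny(gr, m, ignore.strand = TRUE)
      clash <- hit & !is.na(region) & region != ch
      if (any(clash))
        stop("region channels overlap for sites: ",
             paste(utils::head(sites$site_id[clash], 5), collapse = ", "),
             call. = FALSE)
      region[hit] <- ch
    } else if (ch == "alu") {
      alu <- alu | IRanges::overlapsAny(gr, m, ignore.strand = TRUE)
    } else if (ch == "mirna") {
      ov <- GenomicRanges::findOverlaps(gr, m, ignore.strand = TRUE)
      cls <- as.character(m$name %||% rep("nonconserved", length(m)))
      cls <- cls[S4Vectors::subjectHits(ov)]
      idx <- S4Vectors::queryHits(ov)
      lev <- match(cls, mirna_levels)
      best <- tapply(lev, idx, max)
      mirna[as.integer(names(best))] <-
        mirna_levels[as.integer(best)]
    } else {
      stop("unknown annotation channel: ", ch, call. = FALSE)
    }
  }
  sites$alu <- alu
  sites$region <- factor(region, levels = region_levels)
  sites$mirna_overlap <- mirna
  sites
}

#' Summarise annotation categories of a site table
#'
#' Reports, for an annotated CES table, the count and percentage of ALU
#' sites, of each region class, of miRNA-binding-site overlaps (by
#' conservation class), of recoding sites if a `recoding` column is present,
#' and the share of miRNA-overlapping sites located in 3'UTRs. Percentages
#' are 100 * count / total to one decimal.
#'
#' @param annotated a site table from [annotate_sites()].
#' @return list with `total`, a `categories` data.frame
#'   (`category`, `count`, `percent`) and `mirna_in_utr3_percent`.
#' @export
summarize_categories <- function(annotated) {
  if (!is.data.frame(annotated) || nrow(annotated) == 0L)
    stop("empty site table", call. = FALSE)
  n <- nrow(annotated)
  pct <- function(k) round(100 * k / n, 1)
  rows <- list(data.frame(category = "alu", count = sum(annotated$alu),
                          percent = pct(sum(annotated$alu))))
  for (r in levels(annotated$region)) {
    k <- sum(annotated$region == r, na.rm = TRUE)
    rows[[length(rows) + 1L]] <-
      data.frame(category = paste0("region_", r), count = k, percent = pct(k))
  }
  mir <- annotated$mirna_overlap != "none"
  rows[[length(rows) + 1L]] <-
    data.frame(category = "mirna_overlap", count = sum(mir),
               percent = pct(sum(mir)))
  for (m in c("nonconserved", "conserved", "broadly_conserved")) {
    k <- sum(annotated$mirna_overlap == m)
    rows[[length(rows) + 1L]] <-
      data.frame(category = paste0("mirna_", m), count = k, percent = pct(k))
  }
  if (!is.null(annotated$recoding)) {
    k <- sum(!is.na(annotated$recoding) & annotated$recoding != "")
    rows[[length(rows) + 1L]] <-
      data.frame(category = "recoding", count = k, percent = pct(k))
  }
  mirna_in_utr3 <- if (any(mir))
    round(100 * sum(mir & !is.na(annotated$region) &
                      annotated$region == "utr3") / sum(mir), 1)
  else NA_real_
  list(total = n, categories = do.call(rbind, rows),
       mirna_in_utr3_percent = mirna_in_utr3)
}

#' Identify highly edited sites
#'
#' @param em an `editing_matrix`.
#' @param ces character vector of CES site ids.
#' @param threshold inclusive mean-editing threshold (default 0.9).
#' @return data.frame of retained sites with their mean editing level over
#'   non-missing samples.
#' @export
classify_highly_edited <- function(em, ces, threshold = 0.9) {
  stopifnot(inherits(em, "editing_matrix"))
  if (length(ces) == 0L) stop("ces must be nonempty", call. = FALSE)
  sub <- em$ratio[rownames(em$ratio) %in% ces, , drop = FALSE]
  mean_edit <- rowMeans(sub, na.rm = TRUE)
  keep <- !is.nan(mean_edit) & mean_edit >= threshold
  data.frame(site_id = rownames(sub)[keep],
             mean_editing = unname(mean_edit[keep]), row.names = NULL)
}
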