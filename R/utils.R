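# Internal helpers shared across modules.

#' Derive a named RNG stream seed from a master seed
#'
#' Each synthetic output file gets its own reproducible RNG stream so that a
#' single component can be regenerated without disturbing the others. The
#' derivation is a polynomial rolling hash of the stream name folded into the
#' master seed, reduced modulo 2^31 - 2 so it is always a valid 32-bit seed.
#'
#' @param seed master integer seed.
#' @param name character stream name, e.g. `"counts"`.
#' @return a single integer seed.
#' @keywords internal
stream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% m
  as.integer((abs(as.numeric(seed)) %% m + h * 7919) %% (m - 1) + 1)
}

# Evaluate `expr` under a local RNG state seeded from (seed, name).
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  expr
}

#' Render a site identifier in `chrN_pos` form
#'
#' @param chrom chromosome names (with or without a `chr` prefix).
#' @param pos 1-based positions.
#' @return character vector like `"chr3_49398423"`.
#' @export
#' @examples
#' site_id("3", 49398423)
site_id <- function(chrom, pos) {
  stopifnot(all(pos >= 1))
  chrom <- ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  paste0(chrom, "_", format(pos, scientific = FALSE, trim = TRUE))
}

#' Convert 1-based site positions to a GRanges of width-1 points
#'
#' All BED-vs-site coordinate conversion is centralised here: BED channels are
#' 0-based half-open, sites are 1-based points, so a site at 1-based position
#' p overlaps a BED interval [start, end) iff start < p <= end.
#'
#' @param sites data.frame with `chrom` and `pos` columns.
#' @return `GenomicRanges::GRanges` of width-1 ranges.
#' @keywords internal
sites_as_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = 1L)
  )
}

# Read a BED file (BED3+name) into GRanges; rtracklayer handles the 0-based
# half-open to 1-based closed conversion.
read_bed <- function(path) {
  tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
}

write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# TSV helpers: plain tab-separated, header, no quoting, "NA" for missing.
write_tsv <- function(x, path, row_names = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# Stop with a configuration error naming the offending field.
config_error <- function(field, msg) {
  stop("invalid configuration field '", field, "': ", msg, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
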