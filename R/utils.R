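# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Normalise a chromosome-sizes input
#'
#' Accepts a named numeric vector or a two-column data frame
#' (chrom, size) and returns a named numeric vector of integer sizes.
#'
#' @param chrom_sizes named numeric vector or data.frame with columns
#'   `chrom` and `size` (a chrom.sizes table).
#' @return named numeric vector of chromosome lengths in bp.
#' @export
as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    if (ncol(chrom_sizes) < 2)
      stop("chrom_sizes data frame needs columns chrom, size")
    sizes <- as.numeric(chrom_sizes[[2]])
    names(sizes) <- as.character(chrom_sizes[[1]])
    chrom_sizes <- sizes
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chromosome sizes must be named")
  if (any(chrom_sizes <= 0))
    stop("zero-length chromosome: ",
         paste(names(chrom_sizes)[chrom_sizes <= 0], collapse = ", "))
  chrom_sizes
}

# Validate a BED-like data frame (0-based half-open intervals).
check_bed <- function(x, what = "intervals") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    if (ncol(x) >= 3) names(x)[1:3] <- need
    else stop("malformed ", what, ": need columns chrom, start, end")
  }
  if (any(x$start < 0) || any(x$end < x$start))
    stop("malformed ", what, ": start must be >= 0 and end >= start")
  x
}

# data.frame of 0-based intervals -> GRanges (1-based closed).
bed_to_gr <- function(x) {
  x <- check_bed(x)
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

gr_to_bed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Benjamini-Hochberg with an explicit number of tests m >= length(p):
# untested hypotheses implicitly carry p = 1.
bh_adjust <- function(p, m = length(p)) {
  stats::p.adjust(p, method = "BH", n = max(m, length(p)))
}

# floor-based count for "top fraction" rules; deterministic.
top_n_of <- function(n, fraction) as.integer(floor(n * fraction))
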