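#' Genome binnings
#'
#' A binning is an ordered, non-overlapping partition of every chromosome
#' into intervals, carried as a data frame of class `arcc_bins` with
#' columns `chrom`, `start`, `end` (0-based half-open), `id` (global
#' index, strictly increasing in coordinate order) and `is_regulatory`.
#'
#' @name arcc_bins
NULL

new_bins <- function(df, chrom_sizes) {
  df$id <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, chrom_sizes = chrom_sizes,
            class = c("arcc_bins", "data.frame"))
}

#' Tile the genome with fixed-width bins
#'
#' @param chrom_sizes chromosome sizes (named vector or chrom.sizes
#'   data frame).
#' @param width bin width in bp; the final partial bin of each chromosome
#'   is retained.
#' @return an `arcc_bins` data frame.
#' @examples
#' make_fixed_bins(c(chrI = 10200), 5000)
#' @export
make_fixed_bins <- function(chrom_sizes, width) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  stopifnot(width > 0)
  per_chrom <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + width, len),
               is_regulatory = FALSE, stringsAsFactors = FALSE)
  })
  new_bins(do.call(rbind, per_chrom), chrom_sizes)
}

#' Segment the genome into regulatory-element-anchored ~500-bp bins
#'
#' Regulatory elements within `merge_gap` of one another are merged, each
#' merged element is expanded symmetrically toward `target_width` (or
#' until it would touch a neighbouring element or the chromosome edge; an
#' odd leftover base goes to the right), and the residual gaps are tiled
#' left-to-right with `target_width` bins, a final short bin absorbing
#' the remainder.  Elements are never split across bins.
#'
#' @param chrom_sizes chromosome sizes.
#' @param re_intervals BED-like data frame of regulatory elements.
#' @param target_width target bin width in bp (default 500).
#' @param merge_gap elements separated by at most this many bp are merged
#'   first (default 100).
#' @return an `arcc_bins` data frame; element-derived bins have
#'   `is_regulatory = TRUE`.
#' @export
make_re_anchored_bins <- function(chrom_sizes, re_intervals,
                                  target_width = 500, merge_gap = 100) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (is.null(re_intervals) || nrow(re_intervals) == 0)
    return(make_fixed_bins(chrom_sizes, target_width))
  re_intervals <- check_bed(re_intervals, "regulatory elements")
  bad <- !re_intervals$chrom %in% names(chrom_sizes)
  if (any(bad))
    stop("unknown chromosome in RE intervals: ",
         paste(unique(re_intervals$chrom[bad]), collapse = ", "))
  if (any(re_intervals$end > chrom_sizes[re_intervals$chrom]))
    stop("RE interval beyond chromosome end")
  gr <- bed_to_gr(re_intervals)
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1))
    message("overlapping input REs merged")
  # merge elements with inter-element gap <= merge_gap
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  mdf <- gr_to_bed(merged)
  per_chrom <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    m <- mdf[mdf$chrom == ch, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    n <- nrow(m)
    if (n == 0) {
      re_bins <- m
    } else {
      # per-side expansion budget: half the gap to the original
      # neighbouring element (so hungry neighbours never overlap),
      # the full gap at chromosome edges
      gap_left <- c(m$start[1],
                    if (n > 1) m$start[-1] - m$end[-n] else numeric(0))
      gap_right <- c(if (n > 1) m$start[-1] - m$end[-n] else numeric(0),
                     len - m$end[n])
      room_left <- ifelse(seq_len(n) == 1, gap_left, floor(gap_left / 2))
      room_right <- ifelse(seq_len(n) == n, gap_right, floor(gap_right / 2))
      w <- m$end - m$start
      extra <- pmax(target_width - w, 0)
      ext_l <- pmin(floor(extra / 2), room_left)
      ext_r <- pmin(extra - ext_l, room_right)
      ext_l <- pmin(extra - ext_r, room_left)  # backfill left if right capped
      re_bins <- data.frame(chrom = ch, start = m$start - ext_l,
                            end = m$end + ext_r, stringsAsFactors = FALSE)
    }
    # tile the gaps between expanded elements
    bounds <- rbind(c(0, if (n > 0) re_bins$start[1] else len),
                    if (n > 1) cbind(re_bins$end[-n], re_bins$start[-1]),
                    if (n > 0) c(re_bins$end[n], len))
    gap_bins <- do.call(rbind, lapply(seq_len(nrow(bounds)), function(k) {
      g0 <- bounds[k, 1]; g1 <- bounds[k, 2]
      if (g1 <= g0) return(NULL)
      starts <- seq(g0, g1 - 1, by = target_width)
      data.frame(chrom = ch, start = starts,
                 end = pmin(starts + target_width, g1),
                 stringsAsFactors = FALSE)
    }))
    if (n > 0) re_bins$is_regulatory <- TRUE
    if (!is.null(gap_bins) && nrow(gap_bins) > 0)
      gap_bins$is_regulatory <- FALSE
    out <- rbind(re_bins[, c("chrom", "start", "end", "is_regulatory")],
                 gap_bins)
    out[order(out$start), , drop = FALSE]
  })
  new_bins(do.call(rbind, per_chrom), chrom_sizes)
}

# Map genomic positions to global bin ids; errors on unknown chromosomes
# or out-of-range positions.
bin_lookup <- function(bins, chrom, pos) {
  stopifnot(inherits(bins, "arcc_bins"))
  out <- integer(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    b <- bins[bins$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0) stop("unknown chromosome: ", ch)
    p <- pos[sel]
    idx <- findInterval(p, b$start)
    if (any(idx < 1) || any(p >= b$end[nrow(b)]))
      stop("position outside binning on ", ch)
    out[sel] <- b$id[idx]
  }
  out
}

bin_midpoints <- function(bins) (bins$start + bins$end) / 2

#' @export
print.arcc_bins <- function(x, ...) {
  cat(sprintf("Genome binning: %d bins on %d chromosome(s), mean width %.1f bp",
              nrow(x), length(unique(x$chrom)), mean(x$end - x$start)))
  if (any(x$is_regulatory))
    cat(sprintf("; %d regulatory-element bins", sum(x$is_regulatory)))
  cat("\n")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
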