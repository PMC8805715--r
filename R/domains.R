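#' Chromatin domain aggregation
#'
#' Domain sets are BED-like data frames with a `type` column over a
#' fixed vocabulary (`"active"`, `"H3K27me3"`).  TAD strength is
#' measured by aggregating on-diagonal domain squares scaled to 9 x 9
#' bins with up to 25 kb of opposite-type flank scaled to 5 bins on each
#' side (a 19 x 19 grid); compartment structure by aggregating
#' off-diagonal domain-pair rectangles the same way and contrasting
#' same-type with cross-type central signal.
#'
#' @name arcc_domains
NULL

domain_types <- c("active", "H3K27me3")

check_domains <- function(domains, exclude_chroms) {
  domains <- check_bed(domains, "domains")
  if (is.null(domains$type) || !all(domains$type %in% domain_types))
    stop("domains need a type column with values in: ",
         paste(domain_types, collapse = ", "))
  domains <- domains[!domains$chrom %in% exclude_chroms, , drop = FALSE]
  domains[order(domains$chrom, domains$start), , drop = FALSE]
}

# area-weighted 1D rescale operator: n_src x n_tgt column-stochastic
# weight matrix; conserves the mean of a constant block
rescale_weights <- function(n_src, n_tgt) {
  W <- matrix(0, n_src, n_tgt)
  step <- n_src / n_tgt
  for (t in seq_len(n_tgt)) {
    lo <- (t - 1) * step; hi <- t * step
    cells <- seq(floor(lo) + 1, ceiling(hi))
    ov <- pmin(hi, cells) - pmax(lo, cells - 1)
    W[cells, t] <- ov
  }
  sweep(W, 2, colSums(W), "/")
}

# rescale a (l, c, r)-partitioned square/rectangular block matrix into
# the fixed 19 x 19 layout (flanks 5, core 9); absent flanks give NA
rescale_grid <- function(M, row_parts, col_parts) {
  blocks_r <- split_parts(row_parts)
  blocks_c <- split_parts(col_parts)
  out <- matrix(NA_real_, 19, 19)
  tgt <- list(1:5, 6:14, 15:19)
  for (a in 1:3) for (b in 1:3) {
    if (is.null(blocks_r[[a]]) || is.null(blocks_c[[b]])) next
    sub <- M[blocks_r[[a]], blocks_c[[b]], drop = FALSE]
    Wr <- rescale_weights(nrow(sub), length(tgt[[a]]))
    Wc <- rescale_weights(ncol(sub), length(tgt[[b]]))
    # NA-aware: each target cell averages the defined source cells it
    # overlaps, weighted by overlap area
    ok <- !is.na(sub)
    num <- t(Wr) %*% ifelse(ok, sub, 0) %*% Wc
    den <- t(Wr) %*% (ok * 1) %*% Wc
    out[tgt[[a]], tgt[[b]]] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

split_parts <- function(parts) {
  # parts = c(n_left_flank, n_core, n_right_flank) in source bins
  idx <- list(NULL, NULL, NULL)
  at <- 0
  for (k in 1:3) {
    if (parts[k] > 0) idx[[k]] <- at + seq_len(parts[k])
    at <- at + parts[k]
  }
  idx
}

# side rectangles of the 19 x 19 grid (5 x 10 each, flush with the core)
grid_side_cells <- function(grid) {
  c(grid[1:5, 6:15], grid[15:19, 5:14], grid[6:15, 1:5], grid[5:14, 15:19])
}

grid_center_cells <- function(grid) grid[6:14, 6:14]

domain_bins <- function(bins_ch, start, end) {
  # bins whose midpoint falls inside [start, end)
  mids <- (bins_ch$start + bins_ch$end) / 2
  which(mids >= start & mids < end)
}

#' Intra-domain (TAD) aggregation
#'
#' For each domain of the requested type that is at least `min_size`
#' wide, the on-diagonal contact square plus up to `flank` bp of the
#' neighbouring opposite-type domains (truncated to the neighbour's
#' actual extent; absent at chromosome ends) is extracted from the
#' normalized map, rescaled to the 19 x 19 layout and aggregated by
#' element-wise mean.  The strength statistic is the log2 fold change
#' of the central 9 x 9 mean over the mean of the four flanking 5 x 10
#' rectangles; the percent difference is
#' `100 * (center - side) / side`.  A two-sided t-test across the
#' per-domain log2 ratios tests departure from zero.
#'
#' @param cm balanced, decay-normalized `arcc_matrix` on fixed-width
#'   bins (5 kb in the reference analysis).
#' @param domains typed domain set.
#' @param type domain type to aggregate.
#' @param min_size minimum domain width in bp (default 5000).
#' @param flank maximum flank width in bp (default 25000).
#' @param exclude_chroms chromosomes excluded from domain analyses
#'   (default the X chromosome, where reference domain calls are
#'   unavailable).
#' @return an `arcc_domain_aggregate`.
#' @export
aggregate_intra_domain <- function(cm, domains, type = "active",
                                   min_size = 5000, flank = 25000,
                                   exclude_chroms = c("chrX", "X")) {
  domains <- check_domains(domains, exclude_chroms)
  stopifnot(type %in% domain_types)
  grids <- list(); stats <- numeric(0)
  for (ch in unique(domains$chrom)) {
    if (!ch %in% cm_chroms(cm)) next
    dch <- domains[domains$chrom == ch, , drop = FALSE]
    D <- cm_dense(cm, ch)
    bch <- cm$bins[cm$bins$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(dch))) {
      if (dch$type[k] != type) next
      if (dch$end[k] - dch$start[k] < min_size) next
      core <- domain_bins(bch, dch$start[k], dch$end[k])
      if (length(core) < 1) next
      lf <- flank_bins(bch, dch, k, flank, "left")
      rf <- flank_bins(bch, dch, k, flank, "right")
      idx <- c(lf, core, rf)
      M <- D[idx, idx, drop = FALSE]
      g <- rescale_grid(M, c(length(lf), length(core), length(rf)),
                        c(length(lf), length(core), length(rf)))
      ctr <- mean(grid_center_cells(g), na.rm = TRUE)
      sid <- mean(grid_side_cells(g), na.rm = TRUE)
      if (!is.finite(ctr) || !is.finite(sid) || sid <= 0) next
      grids[[length(grids) + 1]] <- g
      stats <- c(stats, log2(ctr / sid))
    }
  }
  if (length(grids) == 0) stop("no qualifying domain of type ", type)
  finish_domain_aggregate(grids, stats, type, "intra")
}

# bins of the opposite-type neighbour domain adjacent to domain k,
# truncated to `flank` bp and to the neighbour's actual extent
flank_bins <- function(bch, dch, k, flank, side) {
  nb <- if (side == "left") k - 1 else k + 1
  if (nb < 1 || nb > nrow(dch)) return(integer(0))
  if (side == "left") {
    lo <- max(dch$start[nb], dch$start[k] - flank)
    domain_bins(bch, lo, dch$start[k])
  } else {
    hi <- min(dch$end[nb], dch$end[k] + flank)
    domain_bins(bch, dch$end[k], hi)
  }
}

finish_domain_aggregate <- function(grids, stats, type, kind) {
  G <- Reduce(`+`, lapply(grids, function(g) ifelse(is.na(g), 0, g)))
  Gn <- Reduce(`+`, lapply(grids, function(g) (!is.na(g)) * 1))
  grid <- G / Gn
  ctr <- mean(grid_center_cells(grid), na.rm = TRUE)
  sid <- mean(grid_side_cells(grid), na.rm = TRUE)
  tt <- if (length(stats) >= 2 && sd(stats) > 0) t.test(stats) else NULL
  structure(list(grid = grid, n = length(grids), type = type, kind = kind,
                 center = ctr, side = sid,
                 percent_diff = 100 * (ctr - sid) / sid,
                 log2fc = log2(ctr / sid),
                 per_region = stats,
                 p = if (is.null(tt)) NA_real_ else tt$p.value),
            class = "arcc_domain_aggregate")
}

#' @export
print.arcc_domain_aggregate <- function(x, ...) {
  cat(sprintf(
    "Domain aggregate (%s, %s): %d regions, center/side percent difference %+.1f%% (log2FC %.3f, t-test p = %.3g)\n",
    x$kind, x$type, x$n, x$percent_diff, x$log2fc, x$p))
  invisible(x)
}

#' Inter-domain (compartment) aggregation
#'
#' Aggregates off-diagonal rectangles for all pairs of domains of the
#' requested kind whose midpoint distance lies in `[d_min, d_max]`,
#' scaled to the 19 x 19 layout as in [aggregate_intra_domain()].
#'
#' @inheritParams aggregate_intra_domain
#' @param pair_kind `"same_type"` (active-active and
#'   H3K27me3-H3K27me3) or `"cross_type"`.
#' @param d_min,d_max domain midpoint distance range in bp (defaults
#'   50 kb and 2 Mb).
#' @return an `arcc_domain_aggregate`.
#' @export
aggregate_inter_domain <- function(cm, domains, pair_kind = c("same_type", "cross_type"),
                                   d_min = 50000, d_max = 2e6,
                                   min_size = 5000, flank = 25000,
                                   exclude_chroms = c("chrX", "X")) {
  pair_kind <- match.arg(pair_kind)
  domains <- check_domains(domains, exclude_chroms)
  grids <- list(); stats <- numeric(0)
  for (ch in unique(domains$chrom)) {
    if (!ch %in% cm_chroms(cm)) next
    dch <- domains[domains$chrom == ch, , drop = FALSE]
    D <- cm_dense(cm, ch)
    bch <- cm$bins[cm$bins$chrom == ch, , drop = FALSE]
    mid <- (dch$start + dch$end) / 2
    wide <- dch$end - dch$start >= min_size
    for (a in seq_len(nrow(dch))) {
      if (!wide[a]) next
      for (b in seq_len(nrow(dch))) {
        if (b <= a || !wide[b]) next
        same <- dch$type[a] == dch$type[b]
        if ((pair_kind == "same_type") != same) next
        d_ab <- abs(mid[b] - mid[a])
        if (d_ab < d_min || d_ab > d_max) next
        ra <- domain_bins(bch, dch$start[a], dch$end[a])
        rb <- domain_bins(bch, dch$start[b], dch$end[b])
        if (!length(ra) || !length(rb)) next
        lfa <- flank_bins(bch, dch, a, flank, "left")
        rfa <- flank_bins(bch, dch, a, flank, "right")
        lfb <- flank_bins(bch, dch, b, flank, "left")
        rfb <- flank_bins(bch, dch, b, flank, "right")
        M <- D[c(lfa, ra, rfa), c(lfb, rb, rfb), drop = FALSE]
        g <- rescale_grid(M, c(length(lfa), length(ra), length(rfa)),
                          c(length(lfb), length(rb), length(rfb)))
        ctr <- mean(grid_center_cells(g), na.rm = TRUE)
        sid <- mean(grid_side_cells(g), na.rm = TRUE)
        if (!is.finite(ctr)) next
        grids[[length(grids) + 1]] <- g
        stats <- c(stats, if (is.finite(sid) && sid > 0) log2(ctr / sid)
                          else NA_real_)
      }
    }
  }
  if (length(grids) == 0) stop("no qualifying ", pair_kind, " domain pairs")
  finish_domain_aggregate(grids, stats[!is.na(stats)],
                          pair_kind, "inter")
}

#' Compartment strength
#'
#' Percent difference of the central aggregated contact signal between
#' same-type and cross-type domain pairs:
#' `100 * (center_same - center_cross) / center_cross`.
#'
#' @inheritParams aggregate_inter_domain
#' @return list with the two aggregates and `percent_diff`.
#' @export
compartment_strength <- function(cm, domains, d_min = 50000, d_max = 2e6,
                                 min_size = 5000, flank = 25000,
                                 exclude_chroms = c("chrX", "X")) {
  same <- aggregate_inter_domain(cm, domains, "same_type", d_min, d_max,
                                 min_size, flank, exclude_chroms)
  cross <- aggregate_inter_domain(cm, domains, "cross_type", d_min, d_max,
                                  min_size, flank, exclude_chroms)
  list(same = same, cross = cross,
       percent_diff = 100 * (same$center - cross$center) / cross$center)
}

#' Strain fold change of domain strength
#'
#' Ratio of the wild-type percent difference to the mutant percent
#' difference (and its reciprocal).  A mutant percent difference of
#' zero or below means the structure is qualitatively lost and the
#' ratio is reported as undefined.
#'
#' @param wt,mut `arcc_domain_aggregate` objects (or plain percent
#'   differences) from the same domain set and settings.
#' @return list with `fold_change`, `reciprocal`, the two percent
#'   differences and an `undefined` flag.
#' @export
strain_fold_change <- function(wt, mut) {
  pd <- function(x) if (inherits(x, "arcc_domain_aggregate")) x$percent_diff
                    else if (is.list(x) && !is.null(x$percent_diff)) x$percent_diff
                    else as.numeric(x)
  w <- pd(wt); m <- pd(mut)
  undef <- !is.finite(m) || m <= 0
  list(fold_change = if (undef) NA_real_ else w / m,
       reciprocal = if (undef) NA_real_ else m / w,
       wt_percent_diff = w, mut_percent_diff = m,
       undefined = undef)
}

#' Stratify domains by a mark signal
#'
#' Splits a domain set into the top `top_fraction` by signal ("high")
#' and the remainder ("low"), ties broken by genomic order.
#'
#' @param domains typed domain set.
#' @param signal numeric per-domain signal (e.g. mean H3K9me coverage),
#'   same length and order as `domains`.
#' @param top_fraction fraction classed high (default 0.25).
#' @return list with `high` and `low` domain subsets.
#' @export
stratify_domains <- function(domains, signal, top_fraction = 0.25) {
  stopifnot(length(signal) == nrow(domains), all(is.finite(signal)))
  n <- nrow(domains)
  ord <- order(-signal, domains$chrom, domains$start)
  n_high <- top_n_of(n, top_fraction)
  high_idx <- sort(ord[seq_len(n_high)])
  list(high = domains[high_idx, , drop = FALSE],
       low = domains[setdiff(seq_len(n), high_idx), , drop = FALSE])
}
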