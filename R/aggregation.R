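#' Sample cis contacts among binding sites
#'
#' Enumerates all same-chromosome site pairs whose midpoint distance
#' lies in `[d_min, d_max]` and uniformly subsamples them without
#' replacement down to `max_contacts` when there are more.
#'
#' @param sites BED-like data frame of binding sites (optional `score`
#'   column carries accessibility).
#' @param d_min,d_max distance range in bp (defaults 20 kb and 1 Mb).
#' @param max_contacts cap on the number of returned pairs (default
#'   50000); `Inf` disables the cap.
#' @param seed RNG seed for the subsampling (deterministic given seed).
#' @return data frame `chrom`, `pos1`, `pos2` (site midpoints,
#'   pos1 < pos2), `d`, and site indices `site1`, `site2`.
#' @export
sample_site_contacts <- function(sites, d_min = 20000, d_max = 1e6,
                                 max_contacts = 50000, seed = NULL) {
  sites <- check_bed(sites, "sites")
  if (nrow(sites) < 2) stop("need at least 2 sites")
  sites$.row <- seq_len(nrow(sites))
  per_chrom <- lapply(split(sites, sites$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    m <- (s$start + s$end) / 2
    n <- length(m)
    lo <- findInterval(m + d_min * (1 - 1e-12), m) + 1L
    hi <- findInterval(m + d_max, m)
    cnt <- pmax(hi - lo + 1L, 0L)
    if (sum(cnt) == 0) return(NULL)
    i <- rep(seq_len(n), cnt)
    j <- unlist(lapply(which(cnt > 0), function(k) seq(lo[k], hi[k])))
    data.frame(chrom = s$chrom[1], pos1 = m[i], pos2 = m[j],
               d = m[j] - m[i], site1 = s$.row[i], site2 = s$.row[j],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, per_chrom)
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no eligible site pairs in the distance range")
  rownames(pairs) <- NULL
  if (nrow(pairs) > max_contacts) {
    idx <- with_seed(seed, sort(sample.int(nrow(pairs), max_contacts)))
    pairs <- pairs[idx, , drop = FALSE]
  }
  pairs
}

#' Aggregated contact analysis over point contacts
#'
#' Extracts the `(2*half_width+1)^2` window of the balanced,
#' distance-normalized contact map centred on each contact's bin pair
#' and averages the windows element-wise.  The enrichment statistic is
#' the log2 fold change of the central point over the mean of the other
#' points of the aggregated window.  Contacts whose window is not fully
#' inside the matrix are skipped (and counted).
#'
#' @param cm balanced and decay-normalized `arcc_matrix` on fixed-width
#'   bins (1 kb for binding-site analysis; 10 kb for long-range
#'   point-pair analysis).
#' @param contacts data frame from [sample_site_contacts()] (columns
#'   `chrom`, `pos1`, `pos2`).
#' @param half_width window half-width in bins (default 10, i.e. a
#'   21 x 21 window).
#' @param engine optional [aca_engine()] built from `cm`, reused across
#'   many aggregations to avoid re-densifying the matrix.
#' @return an `arcc_aca` object: aggregated `grid`, `n` contacts used,
#'   `n_skipped`, and `stat`.
#' @export
aca <- function(cm, contacts, half_width = 10, engine = NULL) {
  if (is.null(engine)) engine <- aca_engine(cm)
  r <- aca_stat(engine, contacts, half_width, want_grid = TRUE)
  if (r$n == 0) stop("no usable contacts after skipping")
  structure(list(grid = r$grid, n = r$n, n_skipped = r$n_skipped,
                 stat = r$stat, half_width = half_width),
            class = "arcc_aca")
}

#' Precompute dense matrices for repeated aggregation
#'
#' @param cm a normalized `arcc_matrix`.
#' @return an opaque engine object accepted by [aca()] and
#'   [matched_null_test()].
#' @export
aca_engine <- function(cm) {
  stopifnot(inherits(cm, "arcc_matrix"))
  dense <- lapply(cm_chroms(cm), function(ch) cm_dense(cm, ch))
  names(dense) <- cm_chroms(cm)
  list(dense = dense, bins = cm$bins,
       coverage = unlist(lapply(cm$chrom, `[[`, "coverage"),
                         use.names = FALSE))
}

# Core window aggregation; contacts are (chrom, pos1, pos2) rows.
aca_stat <- function(env, contacts, half_width, want_grid = FALSE) {
  hw <- half_width; side <- 2L * hw + 1L
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  n_used <- 0L; n_skip <- 0L
  for (ch in unique(contacts$chrom)) {
    D <- env$dense[[ch]]
    if (is.null(D)) stop("contact on chromosome absent from matrix: ", ch)
    b <- env$bins[env$bins$chrom == ch, , drop = FALSE]
    sel <- contacts$chrom == ch
    bi <- findInterval(contacts$pos1[sel], b$start)
    bj <- findInterval(contacts$pos2[sel], b$start)
    n <- nrow(D)
    ok <- bi - hw >= 1 & bj - hw >= 1 & bi + hw <= n & bj + hw <= n
    n_skip <- n_skip + sum(!ok)
    bi <- bi[ok]; bj <- bj[ok]
    n_used <- n_used + length(bi)
    if (!length(bi)) next
    for (da in -hw:hw) {
      rows <- bi + da
      for (db in -hw:hw) {
        v <- D[cbind(rows, bj + db)]
        acc[da + hw + 1L, db + hw + 1L] <-
          acc[da + hw + 1L, db + hw + 1L] + sum(v, na.rm = TRUE)
        cnt[da + hw + 1L, db + hw + 1L] <-
          cnt[da + hw + 1L, db + hw + 1L] + sum(!is.na(v))
      }
    }
  }
  grid <- acc / cnt
  c_idx <- hw + 1L
  center <- grid[c_idx, c_idx]
  rest <- grid[-((c_idx - 1L) * side + c_idx)]
  stat <- log2(center / mean(rest, na.rm = TRUE))
  list(grid = if (want_grid) grid else NULL, n = n_used,
       n_skipped = n_skip, stat = stat)
}

#' @export
print.arcc_aca <- function(x, ...) {
  cat(sprintf(
    "Aggregated contact analysis: %d contacts (%d skipped), %dx%d grid, log2 center/background = %.3f\n",
    x$n, x$n_skipped, nrow(x$grid), ncol(x$grid), x$stat))
  if (!is.null(x$p)) cat(sprintf("  permutation p = %.4g (%d null sets)\n",
                                 x$p, x$n_sets))
  invisible(x)
}

#' Permutation test with matched random contacts
#'
#' Generates `n_sets` random contact sets of the same size as the
#' observed set, each random pair drawn from the site universe to match
#' the corresponding observed pair's distance stratum and both ends'
#' accessibility strata, aggregates each and compares the resulting
#' null statistics with the observed one:
#' `p = (1 + #(null >= observed)) / (n_sets + 1)`.
#'
#' @param cm the normalized `arcc_matrix` used for the observed
#'   analysis.
#' @param observed the observed `arcc_aca` result.
#' @param contacts the observed contact set.
#' @param universe BED-like data frame of candidate sites; an optional
#'   `score` column is the accessibility used for matching (when
#'   absent, the site bin's cis coverage from `cm` is used).
#' @param n_sets number of random sets (default 1000).
#' @param d_min,d_max distance range of the contact universe.
#' @param n_dist_strata log-spaced distance strata for matching
#'   (default 20); accessibility is matched on deciles.
#' @param seed RNG seed.
#' @param engine optional [aca_engine()] built from `cm`.
#' @param pool optional precomputed universe pair pool
#'   (`sample_site_contacts(universe, d_min, d_max, Inf)`), reused when
#'   testing many factors against one universe.
#' @return the `arcc_aca` object with `p`, `null_stats` and `n_sets`
#'   added.
#' @export
matched_null_test <- function(cm, observed, contacts, universe,
                              n_sets = 1000, d_min = 20000, d_max = 1e6,
                              n_dist_strata = 20, seed = NULL,
                              engine = NULL, pool = NULL) {
  stopifnot(inherits(observed, "arcc_aca"))
  universe <- check_bed(universe, "site universe")
  env <- if (is.null(engine)) aca_engine(cm) else engine
  acc <- site_accessibility(universe, cm, env)
  # universe pair pool with stratum keys
  if (is.null(pool))
    pool <- sample_site_contacts(universe, d_min = d_min, d_max = d_max,
                                 max_contacts = Inf)
  d_edges <- exp(seq(log(d_min * (1 - 1e-9)), log(d_max),
                     length.out = n_dist_strata + 1))
  d_edges[n_dist_strata + 1] <- d_max * (1 + 1e-9)
  a_strat <- acc_strata(acc)
  key_of <- function(d, s1, s2) {
    ds <- findInterval(d, d_edges, rightmost.closed = TRUE)
    paste(ds, pmin(s1, s2), pmax(s1, s2))
  }
  pool_key <- key_of(pool$d, a_strat[pool$site1], a_strat[pool$site2])
  groups <- split(seq_len(nrow(pool)), pool_key)
  obs_acc <- if (!is.null(universe$score)) {
    # look observed site scores up from the overlapping universe site
    sgr <- bed_to_gr(contacts_sites(contacts))
    ugr <- bed_to_gr(universe)
    hit <- GenomicRanges::nearest(sgr, ugr)
    as.numeric(universe$score)[hit]
  } else {
    site_accessibility(contacts_sites(contacts), cm, env)
  }
  obs_s <- acc_strata_against(obs_acc, acc)
  obs_key <- key_of(abs(contacts$pos2 - contacts$pos1),
                    obs_s$s1, obs_s$s2)
  # widen where a stratum has no candidates: drop accessibility, then distance
  missing <- !obs_key %in% names(groups)
  if (any(missing)) {
    message(sum(missing), " contact(s) matched on distance stratum only")
    pool_dkey <- sub(" .*", "", pool_key)
    dgroups <- split(seq_len(nrow(pool)), pool_dkey)
    obs_dkey <- sub(" .*", "", obs_key)
    if (any(!obs_dkey[missing] %in% names(dgroups)))
      stop("no matching candidates even after widening")
  }
  with_seed(seed, {
    draw_idx <- matrix(NA_integer_, nrow(contacts), n_sets)
    for (k in unique(obs_key)) {
      rows <- which(obs_key == k)
      cand <- if (k %in% names(groups)) groups[[k]]
              else dgroups[[sub(" .*", "", k)]]
      draw_idx[rows, ] <- cand[sample.int(length(cand),
                                          length(rows) * n_sets,
                                          replace = TRUE)]
    }
    null_stats <- vapply(seq_len(n_sets), function(s) {
      aca_stat(env, pool[draw_idx[, s], , drop = FALSE],
               observed$half_width)$stat
    }, numeric(1))
    observed$null_stats <- null_stats
    observed$n_sets <- n_sets
    observed$p <- (1 + sum(null_stats >= observed$stat)) / (n_sets + 1)
    observed
  })
}

contacts_sites <- function(contacts) {
  data.frame(chrom = c(contacts$chrom, contacts$chrom),
             start = c(contacts$pos1, contacts$pos2),
             end = c(contacts$pos1, contacts$pos2) + 1,
             stringsAsFactors = FALSE)
}

# accessibility of a site: its score column, else the cis coverage of
# the bin containing its midpoint
site_accessibility <- function(sites, cm, env = NULL) {
  if (!is.null(sites$score)) return(as.numeric(sites$score))
  mids <- floor((sites$start + sites$end) / 2)
  if (!is.null(env)) {
    ids <- bin_lookup(env$bins, sites$chrom, mids)
    return(env$coverage[ids])
  }
  ids <- bin_lookup(cm$bins, sites$chrom, mids)
  cov <- unlist(lapply(cm$chrom, `[[`, "coverage"), use.names = FALSE)
  cov[ids]
}

acc_strata <- function(acc, n = 10) {
  q <- unique(quantile(acc, probs = seq(0, 1, length.out = n + 1)))
  findInterval(acc, q, rightmost.closed = TRUE, all.inside = TRUE)
}

# strata of observed site accessibilities against the universe deciles;
# observed sites come as ends 1 then ends 2 stacked
acc_strata_against <- function(obs_acc, univ_acc, n = 10) {
  q <- unique(quantile(univ_acc, probs = seq(0, 1, length.out = n + 1)))
  s <- findInterval(obs_acc, q, rightmost.closed = TRUE, all.inside = TRUE)
  half <- length(s) / 2
  list(s1 = s[seq_len(half)], s2 = s[half + seq_len(half)])
}

#' Filter highly occupied (HOT) intervals from peak sets
#'
#' Builds the merged interval universe across all factors, scores each
#' merged interval by the number of factors calling it, removes the top
#' `top_fraction` by that rank (ties broken by genomic order) from every
#' set, and drops sets left with fewer than `min_peaks` peaks.
#'
#' @param peak_sets named list of BED-like peak data frames, one per
#'   factor.
#' @param top_fraction fraction of the merged universe removed as HOT
#'   (default 0.20).
#' @param min_peaks minimum surviving peaks for a factor to be kept
#'   (default 300).
#' @return list with `sets` (filtered peak sets), `hot` (removed
#'   intervals, with factor counts), and `dropped` (names of discarded
#'   factors).
#' @export
filter_hot <- function(peak_sets, top_fraction = 0.20, min_peaks = 300) {
  stopifnot(length(peak_sets) >= 1, !is.null(names(peak_sets)))
  grs <- lapply(peak_sets, bed_to_gr)
  universe <- GenomicRanges::reduce(do.call(c, unname(grs)))
  score <- rowSums(vapply(grs, function(g)
    GenomicRanges::countOverlaps(universe, g) > 0, logical(length(universe))))
  udf <- gr_to_bed(universe)
  ord <- order(-score, udf$chrom, udf$start)
  n_hot <- top_n_of(length(universe), top_fraction)
  hot_idx <- ord[seq_len(n_hot)]
  hot <- universe[hot_idx]
  sets <- lapply(peak_sets, function(s) {
    gr <- bed_to_gr(s)
    s[GenomicRanges::countOverlaps(gr, hot) == 0, , drop = FALSE]
  })
  kept <- vapply(sets, nrow, integer(1)) >= min_peaks
  if (any(!kept))
    message("dropped factors with < ", min_peaks, " peaks: ",
            paste(names(sets)[!kept], collapse = ", "))
  hot_df <- udf[hot_idx, , drop = FALSE]
  hot_df$n_factors <- score[hot_idx]
  rownames(hot_df) <- NULL
  list(sets = sets[kept], hot = hot_df, dropped = names(sets)[!kept])
}

#' Differential aggregated contact analysis between genotypes
#'
#' To compare per-factor aggregate enrichments between a mutant and
#' wild type while absorbing global differences between the two maps,
#' the mutant statistics are regressed on the wild-type statistics
#' (`mut = a + b * wt`) across factors; each factor's residual measures
#' its specific change.  Two-sided significance comes from resampling
#' the residual distribution `n_boot` times.
#'
#' @param wt,mut named numeric vectors of per-factor ACA statistics
#'   (log2 center fold changes); names must match.
#' @param n_boot bootstrap draws (default 10000).
#' @param seed RNG seed.
#' @return data frame of class `arcc_diff_aca` with per-factor wt, mut,
#'   fitted value, residual, bootstrap p and BH q; intercept and slope
#'   as attributes.
#' @export
differential_aca <- function(wt, mut, n_boot = 10000, seed = NULL) {
  stopifnot(!is.null(names(wt)), !is.null(names(mut)))
  mut <- mut[names(wt)]
  if (anyNA(mut)) stop("factor lists differ between genotypes")
  if (length(wt) < 3) stop("need at least 3 factors to fit the relation")
  fit <- lm(mut ~ wt)
  res <- residuals(fit)
  boot <- with_seed(seed, sample(res, n_boot, replace = TRUE))
  p <- vapply(res, function(r) (1 + sum(abs(boot) >= abs(r))) / (n_boot + 1),
              numeric(1))
  out <- data.frame(factor = names(wt), wt = as.numeric(wt),
                    mut = as.numeric(mut), fitted = fitted(fit),
                    residual = res, p = p,
                    q = bh_adjust(p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("arcc_diff_aca", "data.frame"),
            intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

#' @export
print.arcc_diff_aca <- function(x, ...) {
  cat(sprintf(
    "Differential ACA over %d factors: mut = %.3f + %.3f * wt\n",
    nrow(x), attr(x, "intercept"), attr(x, "slope")))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
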