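#' Interval visibility model
#'
#' Accessible-chromatin conformation data over-represent open intervals,
#' and part of that excess is true interaction signal with other open
#' intervals.  To correct representation without normalizing the signal
#' away, visibility is estimated from "off-peak" coverage: per interval,
#' the cis contact count excluding contacts whose partner interval is a
#' coverage peak.  Intervals in the top `peak_quantile` of the cis
#' coverage distribution are peaks; intervals in the bottom
#' `drop_quantile` are removed from all downstream sets.  The visibility
#' of a retained interval is
#' `v_i = (c_offpeak_i / median(c_offpeak))^alpha`, with the median
#' taken over retained intervals (per chromosome by default, matching
#' the per-chromosome contact total used by the binomial model).
#'
#' @param cm an `arcc_matrix` of raw counts on the calling binning.
#' @param peak_quantile coverage quantile above which intervals count as
#'   peaks (default 0.90).
#' @param drop_quantile coverage quantile below which intervals are
#'   removed (default 0.10).
#' @param alpha visibility exponent (default 0.87, the shipped value
#'   estimated from balancing factors; see
#'   [estimate_correction_exponent()]).
#' @param per_chrom compute quantiles and medians per chromosome
#'   (default) or genome-wide.
#' @return an `arcc_visibility` model: a table of per-interval coverage,
#'   flags and visibilities (`v`, plus `v_norm` rescaled to mean 1 for
#'   use in expected frequencies).
#' @export
compute_visibility <- function(cm, peak_quantile = 0.90,
                               drop_quantile = 0.10, alpha = 0.87,
                               per_chrom = TRUE) {
  stopifnot(inherits(cm, "arcc_matrix"),
            peak_quantile > 0, peak_quantile < 1,
            drop_quantile > 0, drop_quantile < 1)
  groups <- if (per_chrom) cm_chroms(cm) else list(cm_chroms(cm))
  tabs <- list()
  for (g in groups) {
    cov <- unlist(lapply(cm$chrom[g], `[[`, "coverage"), use.names = FALSE)
    ids <- unlist(lapply(g, function(ch)
      cm$chrom[[ch]]$offset + seq_len(cm$chrom[[ch]]$n_bins)))
    peak <- cov >= quantile(cov, peak_quantile)
    removed <- cov <= quantile(cov, drop_quantile)
    if (all(removed | peak)) stop("degenerate coverage: all intervals removed or peaks")
    # off-peak coverage: contacts whose partner is not a peak
    offpeak <- numeric(length(cov))
    for (ch in g) {
      cc <- cm$chrom[[ch]]
      loc_peak <- peak[match(cc$offset + seq_len(cc$n_bins), ids)]
      tr <- cc$trip
      op <- numeric(cc$n_bins)
      keep_i <- !loc_peak[tr$j]  # partner of i is j
      op <- op + tapply_sum(tr$i[keep_i], tr$x[keep_i], cc$n_bins)
      offd <- tr$i != tr$j
      keep_j <- offd & !loc_peak[tr$i]
      op <- op + tapply_sum(tr$j[keep_j], tr$x[keep_j], cc$n_bins)
      offpeak[match(cc$offset + seq_len(cc$n_bins), ids)] <- op
    }
    removed <- removed | offpeak <= 0
    med <- median(offpeak[!removed])
    v <- rep(NA_real_, length(cov))
    v[!removed] <- (offpeak[!removed] / med)^alpha
    tabs[[length(tabs) + 1]] <- data.frame(
      id = ids, c_cis = cov, c_offpeak = offpeak,
      peak = peak, removed = removed, v = v,
      median_offpeak = med, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tabs)
  tab <- tab[order(tab$id), , drop = FALSE]
  tab$v_norm <- tab$v / mean(tab$v, na.rm = TRUE)
  tab <- merge(tab, cm$bins[, c("id", "chrom")], by = "id", sort = TRUE)
  structure(list(table = tab, alpha = alpha,
                 peak_quantile = peak_quantile,
                 drop_quantile = drop_quantile),
            class = "arcc_visibility")
}

#' @export
print.arcc_visibility <- function(x, ...) {
  cat(sprintf(
    "Visibility model: %d intervals (%d peaks, %d removed), alpha = %.2f\n",
    nrow(x$table), sum(x$table$peak), sum(x$table$removed), x$alpha))
  invisible(x)
}

#' Call significant interactions
#'
#' For every retained interval pair (i, j) at midpoint distance
#' `d_min <= d <= d_max`, the observed count n_ij is tested against
#' `n_ij ~ Binomial(N, f_ij)` with
#' `f_ij = v_i * v_j * F(d_ij) / N`, where N is the chromosome's total
#' cis contact count, F the two-pass distance-decay model fitted on raw
#' counts, and v the mean-normalized visibilities.  One global
#' calibration constant per chromosome rescales f so the summed expected
#' count over testable pairs equals the summed observed count.  P-values
#' are one-sided (enrichment); q-values are Benjamini-Hochberg over all
#' testable pairs of the chromosome (zero-count pairs enter with p = 1).
#' A call passes when `q < fdr_level` and `n_ij > support_min`.
#'
#' @param cm raw-count `arcc_matrix` on the calling binning.
#' @param visibility an `arcc_visibility` model from the same matrix.
#' @param decay an `arcc_decay` model fitted on the same matrix (two
#'   pass); fitted internally when NULL.
#' @param d_min,d_max tested distance range in bp (defaults 1 kb, 1 Mb).
#' @param fdr_level FDR threshold (default 0.05).
#' @param support_min calls must be supported by strictly more than this
#'   many read pairs (default 5).
#' @param pool_chromosomes apply BH across all chromosomes at once
#'   instead of per chromosome (default FALSE).
#' @return an `arcc_calls` data frame: one row per tested nonzero pair
#'   with distance, count, expected frequency, p, q and `pass`.
#' @export
call_interactions <- function(cm, visibility, decay = NULL,
                              d_min = 1000, d_max = 1e6,
                              fdr_level = 0.05, support_min = 5,
                              pool_chromosomes = FALSE) {
  stopifnot(inherits(cm, "arcc_matrix"), inherits(visibility, "arcc_visibility"))
  if (is.null(decay))
    decay <- fit_distance_decay(cm, d_min, d_max, visibility = visibility)
  vnorm <- visibility_vector(visibility, cm$bins)
  res <- list()
  for (ch in cm_chroms(cm)) {
    cc <- cm$chrom[[ch]]
    if (cc$N == 0) stop("no cis contacts on ", ch)
    mid <- cc$mid
    gid <- cc$offset + seq_len(cc$n_bins)
    retained <- !is.na(vnorm[gid])
    tr <- cc$trip
    keep <- tr$i != tr$j & retained[tr$i] & retained[tr$j]
    d <- abs(mid[tr$j] - mid[tr$i])
    keep <- keep & d >= d_min & d <= d_max
    tr <- tr[keep, , drop = FALSE]
    d <- d[keep]
    # all testable pairs (zero cells included) among retained intervals
    rm_ <- mid[retained]
    n_ret <- length(rm_)
    m_total <- sum(findInterval(rm_ + d_max, rm_) -
                     findInterval(rm_ + d_min * (1 - 1e-9), rm_))
    f_raw <- vnorm[gid[tr$i]] * vnorm[gid[tr$j]] *
      predict_decay(decay, ch, d, clamp = TRUE) / cc$N
    # moment-matching calibration over testable pairs: zero cells enter
    # through stratum pair counts over retained intervals
    st <- decay$chrom[[ch]]$strata
    in_rng <- st$d >= d_min & st$d <= d_max
    npl <- vapply(decay$edges, function(e)
      sum(findInterval(rm_ + e, rm_)) - n_ret * (n_ret + 1) / 2,
      numeric(1))
    cnt_ret <- diff(npl)
    exp_total <- sum(cnt_ret[in_rng] *
                       exp(predict(decay$chrom[[ch]]$fit,
                                   log(st$d[in_rng]))$y)) / cc$N
    obs_total <- sum(tr$x) / cc$N
    kappa <- if (exp_total > 0) obs_total / exp_total else 1
    f <- pmin(pmax(f_raw * kappa, 1e-15), 1 - 1e-15)
    if (any(f_raw * kappa >= 1))
      warning("expected frequency >= 1 capped on ", ch)
    p <- pbinom(tr$x - 1, cc$N, f, lower.tail = FALSE)
    out <- data.frame(chrom = ch, bin1 = gid[tr$i], bin2 = gid[tr$j],
                      d = d, n = tr$x, f = f, p = p,
                      m_total = m_total, stringsAsFactors = FALSE)
    res[[ch]] <- out
  }
  calls <- do.call(rbind, res)
  rownames(calls) <- NULL
  if (nrow(calls) > 0) {
    if (pool_chromosomes) {
      calls$q <- bh_adjust(calls$p, m = sum(vapply(res, function(x)
        if (nrow(x)) x$m_total[1] else 0, numeric(1))))
    } else {
      calls$q <- NA_real_
      for (ch in names(res)) {
        sel <- calls$chrom == ch
        if (any(sel))
          calls$q[sel] <- bh_adjust(calls$p[sel], m = calls$m_total[sel][1])
      }
    }
    calls$pass <- calls$q < fdr_level & calls$n > support_min
  } else {
    calls$q <- numeric(0); calls$pass <- logical(0)
  }
  calls$m_total <- NULL
  b <- cm$bins
  calls$start1 <- b$start[calls$bin1]; calls$end1 <- b$end[calls$bin1]
  calls$start2 <- b$start[calls$bin2]; calls$end2 <- b$end[calls$bin2]
  structure(calls, class = c("arcc_calls", "data.frame"),
            fdr_level = fdr_level, support_min = support_min)
}

#' @export
print.arcc_calls <- function(x, ...) {
  cat(sprintf("Interaction calls: %d tested nonzero pairs, %d passing (q < %g, n > %d)\n",
              nrow(x), sum(x$pass), attr(x, "fdr_level"),
              attr(x, "support_min")))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Annotate interaction calls with element classes
#'
#' Tags each interval of each call with the annotation classes it
#' overlaps (e.g. promoter, enhancer) and labels the interaction by its
#' end-type pair such as "P-P" or "P-other", using the first overlapping
#' class in the order the annotation sets are given.
#'
#' @param calls an `arcc_calls` table.
#' @param annotations named list of BED-like data frames; names are the
#'   class labels.
#' @return the calls with `class1`, `class2` and `type` columns.
#' @export
annotate_calls <- function(calls, annotations) {
  stopifnot(is.list(annotations), length(names(annotations)) > 0)
  grs <- lapply(annotations, bed_to_gr)
  end_class <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = start + 1, end = pmax(end, start + 1)))
    cls <- rep("other", length(gr))
    for (nm in rev(names(grs)))  # earlier sets take priority
      cls[GenomicRanges::countOverlaps(gr, grs[[nm]]) > 0] <- nm
    cls
  }
  calls$class1 <- end_class(calls$chrom, calls$start1, calls$end1)
  calls$class2 <- end_class(calls$chrom, calls$start2, calls$end2)
  ord <- c(names(annotations), "other")
  a <- calls$class1; b <- calls$class2
  swap <- match(a, ord) > match(b, ord)
  calls$type <- paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "-")
  calls
}
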