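#' Distance-decay background model
#'
#' Models the average contact value per bin pair as a smooth function
#' F(d) of midpoint distance d, per chromosome, by fitting a cubic
#' smoothing spline (smoothing chosen by generalized cross-validation)
#' to log mean value versus log distance over log-spaced distance
#' strata.  Stratum means include the zero cells: the number of bin
#' pairs per stratum is computed by coordinate arithmetic, not from the
#' stored triplets.
#'
#' Fitting is two-pass in the Fit-Hi-C style: pairs significant under
#' the pass-1 model (binomial upper tail, BH FDR < `fdr`) are removed
#' and the spline refit, so that strong point interactions (loops) do
#' not inflate the background.
#'
#' @param cm an `arcc_matrix`; values may be raw counts (for calling) or
#'   balanced values (for map normalization).
#' @param d_min,d_max fitted distance range in bp.
#' @param n_strata number of log-spaced distance strata (default 100).
#' @param visibility optional [compute_visibility()] model; its
#'   mean-normalized visibilities refine the pass-1 expected counts.
#' @param two_pass refit after removing pass-1 significant pairs
#'   (default TRUE).
#' @param fdr pass-1 outlier threshold (default 0.05).
#' @param min_strata minimum usable strata per chromosome (default 5).
#' @param exclude_domains optional typed domain set (BED-like with
#'   `type`): cells whose two bins fall in the same domain are excluded
#'   from the background fit, in the same spirit as the two-pass loop
#'   exclusion, so that self-interacting domains do not inflate the
#'   background and dampen their own measured strength.
#' @return an `arcc_decay` model; evaluate with [predict_decay()].
#' @export
fit_distance_decay <- function(cm, d_min, d_max, n_strata = 100,
                               visibility = NULL, two_pass = TRUE,
                               fdr = 0.05, min_strata = 5,
                               exclude_domains = NULL) {
  stopifnot(inherits(cm, "arcc_matrix"), d_min < d_max, d_min > 0)
  edges <- exp(seq(log(d_min), log(d_max), length.out = n_strata + 1))
  edges[1] <- d_min * (1 - 1e-9)  # make d == d_min fall inside stratum 1
  dmid <- sqrt(edges[-1] * edges[-length(edges)])
  vnorm <- visibility_vector(visibility, cm$bins)
  per_chrom <- list()
  for (ch in cm_chroms(cm)) {
    cc <- cm$chrom[[ch]]
    mid <- cc$mid
    # bin pairs per stratum, zero cells included, by coordinate arithmetic
    pairs_le <- function(m) vapply(edges, function(e)
      sum(findInterval(m + e, m)) - length(m) * (length(m) + 1) / 2,
      numeric(1))
    cnt <- diff(pairs_le(mid))
    dom_of <- NULL
    if (!is.null(exclude_domains)) {
      dch <- exclude_domains[exclude_domains$chrom == ch, , drop = FALSE]
      dch <- dch[order(dch$start), , drop = FALSE]
      if (nrow(dch) > 0) {
        idx <- findInterval(mid, dch$start)
        dom_of <- ifelse(idx >= 1 & mid < dch$end[pmax(idx, 1)], idx, NA)
        # subtract same-domain pair counts from each stratum
        for (k in unique(dom_of[!is.na(dom_of)]))
          cnt <- cnt - diff(pairs_le(mid[!is.na(dom_of) & dom_of == k]))
      }
    }
    off <- cc$trip$i != cc$trip$j
    if (!is.null(dom_of)) {
      same_dom <- !is.na(dom_of[cc$trip$i]) & !is.na(dom_of[cc$trip$j]) &
        dom_of[cc$trip$i] == dom_of[cc$trip$j]
      off <- off & !same_dom
    }
    ti <- cc$trip$i[off]; tj <- cc$trip$j[off]; tx <- cc$trip$x[off]
    td <- abs(mid[tj] - mid[ti])
    stratum <- findInterval(td, edges, left.open = TRUE)
    inr <- stratum >= 1 & stratum <= n_strata
    sums <- tapply_sum(stratum[inr], tx[inr], n_strata)
    fit1 <- fit_decay_spline(dmid, sums, cnt, min_strata, ch)
    fit <- fit1
    if (two_pass && cc$N > 0) {
      vv <- if (is.null(vnorm)) 1
            else vnorm[ti + cc$offset] * vnorm[tj + cc$offset]
      mu <- vv * exp(predict(fit1, log(pmin(pmax(td, d_min), d_max)))$y)
      p <- pbinom(tx - 1, cc$N, pmin(pmax(mu / cc$N, 1e-15), 1 - 1e-15),
                  lower.tail = FALSE)
      q <- bh_adjust(ifelse(inr, p, 1), m = sum(cnt))
      out1 <- inr & q < fdr & !is.na(vv * td)
      if (any(out1)) {
        sums2 <- sums - tapply_sum(stratum[out1], tx[out1], n_strata)
        cnt2 <- cnt - tabulate(stratum[out1], nbins = n_strata)
        fit <- fit_decay_spline(dmid, sums2, cnt2, min_strata, ch)
      }
    }
    per_chrom[[ch]] <- list(fit = fit, fit_pass1 = fit1,
                            strata = data.frame(d = dmid, n_pairs = cnt,
                                                sum = sums),
                            total_pairs = sum(cnt))
  }
  structure(list(chrom = per_chrom, d_min = d_min, d_max = d_max,
                 edges = edges),
            class = "arcc_decay")
}

fit_decay_spline <- function(dmid, sums, cnt, min_strata, ch) {
  ok <- cnt > 0 & sums > 0
  if (sum(ok) < min_strata)
    stop("too few usable distance strata on ", ch,
         " (", sum(ok), " < ", min_strata, ")")
  mu <- sums[ok] / cnt[ok]
  stats::smooth.spline(x = log(dmid[ok]), y = log(mu), w = cnt[ok],
                       cv = FALSE, all.knots = TRUE)
}

# mean-normalized visibility per global bin id (NA for removed bins),
# or NULL when no visibility model is supplied
visibility_vector <- function(visibility, bins) {
  if (is.null(visibility)) return(NULL)
  stopifnot(inherits(visibility, "arcc_visibility"))
  v <- rep(NA_real_, nrow(bins))
  v[visibility$table$id] <- visibility$table$v_norm
  v
}

#' Evaluate a distance-decay model
#'
#' @param model an `arcc_decay` model.
#' @param chrom chromosome name.
#' @param d distances in bp.
#' @param clamp if TRUE, distances outside the fitted range are clamped
#'   to it; if FALSE (default) they evaluate to NA.
#' @return expected mean contact value per bin pair at each distance.
#' @export
predict_decay <- function(model, chrom, d, clamp = FALSE) {
  stopifnot(inherits(model, "arcc_decay"))
  mc <- model$chrom[[chrom]]
  if (is.null(mc)) stop("no decay model for chromosome ", chrom)
  dc <- pmin(pmax(d, model$d_min), model$d_max)
  out <- exp(predict(mc$fit, log(dc))$y)
  if (!clamp) out[d < model$d_min | d > model$d_max] <- NA_real_
  out
}

#' @export
print.arcc_decay <- function(x, ...) {
  cat(sprintf("Distance-decay model: %d chromosome(s), range %g-%g bp\n",
              length(x$chrom), x$d_min, x$d_max))
  invisible(x)
}

#' Remove distance-dependent background from a contact map
#'
#' Divides every off-diagonal cell by the model's expected value F(d) at
#' the cell's midpoint distance.  Cells outside the model range
#' (including the diagonal) are masked: they are excluded from any later
#' aggregation.  After normalization the mean value per distance stratum
#' is ~1 by construction.
#'
#' @param cm a balanced `arcc_matrix` (the model should have been fitted
#'   on the same values).
#' @param model an `arcc_decay` model fitted on `cm`.
#' @return the matrix with normalized values and
#'   `decay_normalized = TRUE`.
#' @export
normalize_distance <- function(cm, model) {
  stopifnot(inherits(cm, "arcc_matrix"), inherits(model, "arcc_decay"))
  for (ch in cm_chroms(cm)) {
    cc <- cm$chrom[[ch]]
    mid <- cc$mid
    d <- abs(mid[cc$trip$j] - mid[cc$trip$i])
    f <- predict_decay(model, ch, d)
    keep <- !is.na(f)
    cc$trip <- cc$trip[keep, , drop = FALSE]
    cc$trip$x <- cc$trip$x / f[keep]
    cm$chrom[[ch]] <- cc
  }
  cm$decay_normalized <- TRUE
  cm$norm_range <- c(model$d_min, model$d_max)
  cm
}
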