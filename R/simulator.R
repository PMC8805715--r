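#' Simulation configuration
#'
#' Defines a synthetic genome and the generative model for
#' proximity-ligation read pairs biased toward accessible chromatin.
#' Pair probabilities factorize as
#' `P(i, j) proportional to b_i * b_j * F(|m_i - m_j|) * boost(i, j)`
#' over simulation bins, where b is a per-bin accessibility bias
#' (lognormal, multiplied by `accessibility_fold` inside regulatory
#' elements), `F(d) = d^(-gamma)` the distance decay, and boost plants
#' loops (point fold changes), self-interacting domains
#' (`domain_enrichment` within a domain) and compartments
#' (`compartment_preference` between same-type domains in
#' `compartment_range`).  This mirrors the calling model, so parameter
#' recovery is well-posed.
#'
#' Defaults describe the reference desk-scale dataset: two 5-Mb
#' chromosomes at 500-bp resolution and 2 million cis pairs, regulatory
#' elements covering ~21\% of the genome with an accessibility fold of
#' 2.9 (which puts ~44\% of read ends in elements), lognormal bias with
#' sdlog 0.4, decay exponent 1, and no planted structure.
#'
#' @param chrom_sizes named chromosome lengths (bp).
#' @param bin_width simulation resolution (bp).
#' @param n_pairs number of cis pairs to emit (pre-duplication).
#' @param gamma distance-decay exponent (counts ~ d^-gamma).
#' @param bias_sdlog sdlog of the lognormal per-bin bias.
#' @param re_fraction genome fraction covered by regulatory elements.
#' @param re_width NULL (default) places elements as single simulation
#'   bins aligned to the grid, which makes the accessibility fold
#'   translate exactly into the element read-end share; a `c(min, max)`
#'   range places unaligned elements of uniform random width instead.
#' @param accessibility_fold bias multiplier inside elements.
#' @param domain_mean_size,domain_sdlog lognormal domain sizes (bp).
#' @param domain_grid domain boundaries snap to this grid (bp; default
#'   5000, the resolution real domain tracks are typically called at).
#' @param domain_enrichment within-domain contact boost e (1 = none).
#' @param compartment_preference same-type inter-domain boost r
#'   (1 = none).
#' @param compartment_range distance range (bp) over which the
#'   same-type preference acts.
#' @param loops data frame `chrom`, `pos1`, `pos2`, `fold` of planted
#'   point interactions (anchors are `loop_width`-wide windows).
#' @param loop_width anchor width in bp (default one bin).
#' @param site_sets named integer vector: binding-site sets to place
#'   inside random elements.
#' @param duplicate_rate fraction of extra exact-duplicate pairs
#'   appended.
#' @param pair_d_min,pair_d_max distance range of emitted pairs (bp).
#' @return an `arcc_sim_config` list.
#' @export
sim_config <- function(chrom_sizes = c(chrI = 5e6, chrII = 5e6),
                       bin_width = 500, n_pairs = 2e6, gamma = 1,
                       bias_sdlog = 0.4, re_fraction = 0.211,
                       re_width = NULL, accessibility_fold = 2.9,
                       domain_mean_size = 5e4, domain_sdlog = 0.4,
                       domain_grid = 5000,
                       domain_enrichment = 1, compartment_preference = 1,
                       compartment_range = c(5e4, 2e6), loops = NULL,
                       loop_width = NULL, site_sets = NULL,
                       duplicate_rate = 0, pair_d_min = NULL,
                       pair_d_max = Inf) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (is.null(loop_width)) loop_width <- bin_width
  if (is.null(pair_d_min)) pair_d_min <- bin_width
  stopifnot(domain_enrichment > 0, compartment_preference > 0,
            accessibility_fold > 0, n_pairs > 0)
  if (!is.null(loops)) stopifnot(all(loops$fold > 0))
  structure(list(chrom_sizes = chrom_sizes, bin_width = bin_width,
                 n_pairs = n_pairs, gamma = gamma,
                 bias_sdlog = bias_sdlog, re_fraction = re_fraction,
                 re_width = re_width,
                 accessibility_fold = accessibility_fold,
                 domain_mean_size = domain_mean_size,
                 domain_sdlog = domain_sdlog,
                 domain_grid = domain_grid,
                 domain_enrichment = domain_enrichment,
                 compartment_preference = compartment_preference,
                 compartment_range = compartment_range,
                 loops = loops, loop_width = loop_width,
                 site_sets = site_sets, duplicate_rate = duplicate_rate,
                 pair_d_min = pair_d_min, pair_d_max = pair_d_max),
            class = "arcc_sim_config")
}

#' Simulate genome annotation with planted structure
#'
#' Places non-overlapping regulatory elements covering `re_fraction` of
#' each chromosome, alternating active / H3K27me3 domains covering the
#' chromosomes without gaps, binding-site sets inside random elements,
#' and draws the per-bin accessibility bias.
#'
#' @param config an `arcc_sim_config`.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with `re`, `domains`, `sites` (named list of BED data
#'   frames) and `truth` (per-bin bias, element track, config echo).
#' @export
simulate_annotation <- function(config, seed) {
  stopifnot(inherits(config, "arcc_sim_config"))
  with_seed(seed, {
    res <- list(); doms <- list(); bias <- list()
    for (ch in names(config$chrom_sizes)) {
      L <- config$chrom_sizes[[ch]]
      nb <- ceiling(L / config$bin_width)
      if (is.null(config$re_width)) {
        # default: elements are single simulation bins, so the per-bin
        # accessibility fold translates exactly into the fraction of
        # read ends landing in elements
        n_re <- round(config$re_fraction * nb)
        pick <- sort(sample.int(nb, n_re))
        re <- data.frame(chrom = rep(ch, n_re),
                         start = (pick - 1) * config$bin_width,
                         end = pmin(pick * config$bin_width, L),
                         stringsAsFactors = FALSE)
        res[[ch]] <- re
      } else {
      # explicit widths: uniform widths, exponential stick-breaking gaps
      mean_w <- mean(config$re_width)
      n_re <- round(config$re_fraction * L / mean_w)
      if (n_re > 0) {
        w <- round(runif(n_re, config$re_width[1], config$re_width[2]))
        if (sum(w) >= L)
          stop("infeasible regulatory-element density on ", ch)
        g <- stats::rexp(n_re + 1)
        g <- floor(g / sum(g) * (L - sum(w)))
        starts <- cumsum(c(g[1], w[-n_re] + g[-c(1, n_re + 1)] + 0))
        re <- data.frame(chrom = ch, start = starts, end = starts + w,
                         stringsAsFactors = FALSE)
        re <- re[re$end <= L, , drop = FALSE]
      } else {
        re <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0))
      }
      res[[ch]] <- re
      }
      # alternating typed domains covering the chromosome
      # boundaries snap to domain_grid, as real domain tracks are
      # quantized to the resolution of the maps they were called on
      gr <- config$domain_grid
      sizes <- numeric(0); tot <- 0
      while (tot < L) {
        s <- rlnorm(1, log(config$domain_mean_size) -
                      config$domain_sdlog^2 / 2, config$domain_sdlog)
        s <- max(gr, round(s / gr) * gr, 5000)
        sizes <- c(sizes, min(s, L - tot)); tot <- tot + s
      }
      ends <- cumsum(sizes)
      doms[[ch]] <- data.frame(
        chrom = ch, start = c(0, ends[-length(ends)]), end = ends,
        type = rep(domain_types, length.out = length(ends)),
        stringsAsFactors = FALSE)
      # per-bin accessibility bias
      b <- rlnorm(nb, 0, config$bias_sdlog)
      mids <- (seq_len(nb) - 0.5) * config$bin_width
      if (nrow(re) > 0) {
        in_re <- findInterval(mids, re$start) >= 1 &
          mids < re$end[pmax(findInterval(mids, re$start), 1)]
        b[in_re] <- b[in_re] * config$accessibility_fold
      }
      bias[[ch]] <- b
    }
    re_all <- do.call(rbind, res); rownames(re_all) <- NULL
    dom_all <- do.call(rbind, doms); rownames(dom_all) <- NULL
    sites <- list()
    if (!is.null(config$site_sets)) {
      for (nm in names(config$site_sets)) {
        n <- config$site_sets[[nm]]
        if (n > nrow(re_all)) stop("site set ", nm, " larger than RE count")
        pick <- re_all[sort(sample.int(nrow(re_all), n)), , drop = FALSE]
        mid <- floor((pick$start + pick$end) / 2)
        sites[[nm]] <- data.frame(chrom = pick$chrom, start = mid,
                                  end = mid + 1, stringsAsFactors = FALSE)
      }
    }
    list(re = re_all, domains = dom_all, sites = sites,
         truth = list(bias = bias, config = config))
  })
}

#' Simulate proximity-ligation read pairs
#'
#' Draws `n_pairs` cis pairs from the factorized model of
#' [sim_config()], mixing a background component (gap sampled from the
#' decay-weighted bias autocorrelation, endpoint from the per-gap bias
#' product) with planted loop / domain / compartment components whose
#' extra weight is `(boost - 1)` times the background weight of their
#' cells, so the marginal enrichment of a planted cell equals its boost
#' exactly.  Strands are independent uniform; duplicates are exact
#' copies appended at `duplicate_rate`.
#'
#' @param config an `arcc_sim_config`.
#' @param annotation output of [simulate_annotation()].
#' @param seed RNG seed.
#' @return list with `pairs` (read-pair table with `is_duplicate`
#'   column) and `truth` (planted loops with expected fold, bias,
#'   domains, expected orientation fractions).
#' @export
simulate_pairs <- function(config, annotation, seed) {
  stopifnot(inherits(config, "arcc_sim_config"))
  bw <- config$bin_width
  with_seed(seed, {
    comps <- list()   # per chrom: list of components with weights
    totals <- numeric(0)
    for (ch in names(config$chrom_sizes)) {
      b <- annotation$truth$bias[[ch]]
      nb <- length(b)
      mids <- (seq_len(nb) - 0.5) * bw
      Fg <- gap_decay(config, nb)
      # bias autocorrelation by FFT: R_k = sum_i b_i b_{i+k}
      z <- stats::convolve(b, rev(b), type = "open")
      Rk <- pmax(z[nb - seq_len(nb - 1)], 0)
      wk <- Fg * Rk
      groups <- plant_groups(config, annotation, ch, b, mids, Fg)
      comps[[ch]] <- list(b = b, nb = nb, wk = wk, groups = groups)
      totals[ch] <- sum(wk) + sum(vapply(groups, `[[`, numeric(1), "w"))
    }
    n_by_chrom <- as.numeric(rmultinom(1, config$n_pairs, totals))
    names(n_by_chrom) <- names(totals)
    out <- list()
    for (ch in names(config$chrom_sizes)) {
      cc <- comps[[ch]]
      n_ch <- n_by_chrom[[ch]]
      if (n_ch == 0) next
      gw <- vapply(cc$groups, `[[`, numeric(1), "w")
      alloc <- as.numeric(rmultinom(1, n_ch, c(sum(cc$wk), gw)))
      ij <- sample_background(cc$b, cc$wk, alloc[1])
      for (g in seq_along(cc$groups)) {
        if (alloc[g + 1] == 0) next
        grp <- cc$groups[[g]]
        cell <- sample.int(length(grp$wm), alloc[g + 1], replace = TRUE,
                           prob = grp$wm)
        ij <- rbind(ij, cbind(grp$bi[(cell - 1) %% length(grp$bi) + 1],
                              grp$bj[(cell - 1) %/% length(grp$bi) + 1]))
      }
      L <- config$chrom_sizes[[ch]]
      pos_of <- function(bin) {
        w_bin <- pmin(bin * bw, L) - (bin - 1) * bw
        (bin - 1) * bw + floor(runif(length(bin)) * w_bin)
      }
      out[[ch]] <- data.frame(
        chrom1 = ch, pos1 = pos_of(ij[, 1]),
        strand1 = sample(c("+", "-"), nrow(ij), replace = TRUE),
        mapq1 = 60L, nm1 = 0L,
        chrom2 = ch, pos2 = pos_of(ij[, 2]),
        strand2 = sample(c("+", "-"), nrow(ij), replace = TRUE),
        mapq2 = 60L, nm2 = 0L, stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, out)
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]  # shuffle chroms
    rownames(pairs) <- NULL
    pairs$read_id <- sprintf("sim%08d", seq_len(nrow(pairs)))
    pairs$is_duplicate <- FALSE
    if (config$duplicate_rate > 0) {
      n_dup <- round(config$duplicate_rate * nrow(pairs))
      dup <- pairs[sample.int(nrow(pairs), n_dup, replace = TRUE), ,
                   drop = FALSE]
      dup$is_duplicate <- TRUE
      pairs <- rbind(pairs, dup)
      rownames(pairs) <- NULL
    }
    truth <- annotation$truth
    truth$loops <- config$loops
    truth$domains <- annotation$domains
    truth$expected_orientation <- c(FF = .25, FR = .25, RF = .25, RR = .25)
    truth$n_emitted <- sum(!pairs$is_duplicate)
    list(pairs = pairs, truth = truth)
  })
}

# decay weight per gap k (distance k * bin_width), restricted to the
# configured pair distance range
gap_decay <- function(config, nb) {
  k <- seq_len(nb - 1)
  d <- k * config$bin_width
  Fg <- if (config$gamma == 0) rep(1, nb - 1) else d^(-config$gamma)
  Fg[d < config$pair_d_min | d > config$pair_d_max] <- 0
  Fg
}

# background sampling: gap from wk, endpoint i | gap from b_i * b_{i+k}
sample_background <- function(b, wk, n) {
  if (n == 0) return(cbind(integer(0), integer(0)))
  nb <- length(b)
  gaps <- sample.int(nb - 1, n, replace = TRUE, prob = wk)
  tab <- tabulate(gaps, nbins = nb - 1)
  ij <- matrix(0L, n, 2)
  at <- 1L
  for (k in which(tab > 0)) {
    m <- tab[k]
    pk <- b[seq_len(nb - k)] * b[k + seq_len(nb - k)]
    i <- sample.int(nb - k, m, replace = TRUE, prob = pk)
    ij[at:(at + m - 1L), ] <- cbind(i, i + k)
    at <- at + m
  }
  ij
}

# planted components on one chromosome: loops, intra-domain enrichment,
# same-type inter-domain preference; each carries its extra weight
# (boost - 1) * background weight and the cell grid to sample from
plant_groups <- function(config, annotation, ch, b, mids, Fg) {
  bw <- config$bin_width
  nb <- length(b)
  fd <- function(d) {
    k <- pmax(round(d / bw), 1)
    ifelse(k <= nb - 1, Fg[pmin(k, nb - 1)], 0)
  }
  groups <- list()
  add_rect <- function(bi, bj, boost) {
    wm <- outer(b[bi], b[bj]) * fd(abs(outer(mids[bi], mids[bj], "-")))
    w <- (boost - 1) * sum(wm)
    if (w <= 0) return()
    groups[[length(groups) + 1]] <<- list(bi = bi, bj = bj,
                                          wm = as.numeric(wm), w = w)
  }
  if (!is.null(config$loops)) {
    lp <- config$loops[config$loops$chrom == ch, , drop = FALSE]
    hw <- config$loop_width / 2
    for (k in seq_len(nrow(lp))) {
      bi <- bins_in(mids, lp$pos1[k] - hw, lp$pos1[k] + hw)
      bj <- bins_in(mids, lp$pos2[k] - hw, lp$pos2[k] + hw)
      if (!length(bi) || !length(bj))
        stop("planted loop anchor outside chromosome ", ch, ": ",
             lp$pos1[k], " - ", lp$pos2[k])
      add_rect(bi, bj, lp$fold[k])
    }
  }
  doms <- annotation$domains[annotation$domains$chrom == ch, , drop = FALSE]
  if (config$domain_enrichment > 1) {
    for (k in seq_len(nrow(doms))) {
      bi <- bins_in(mids, doms$start[k], doms$end[k])
      if (length(bi) < 2) next
      wm <- outer(b[bi], b[bi]) * fd(abs(outer(mids[bi], mids[bi], "-")))
      wm[lower.tri(wm, diag = TRUE)] <- 0
      w <- (config$domain_enrichment - 1) * sum(wm)
      if (w > 0)
        groups[[length(groups) + 1]] <- list(bi = bi, bj = bi,
                                             wm = as.numeric(wm), w = w)
    }
  }
  if (config$compartment_preference > 1 && nrow(doms) > 1) {
    dm <- (doms$start + doms$end) / 2
    for (a in seq_len(nrow(doms) - 1)) for (bb in (a + 1):nrow(doms)) {
      if (doms$type[a] != doms$type[bb]) next
      d_ab <- dm[bb] - dm[a]
      if (d_ab < config$compartment_range[1] ||
          d_ab > config$compartment_range[2]) next
      bi <- bins_in(mids, doms$start[a], doms$end[a])
      bj <- bins_in(mids, doms$start[bb], doms$end[bb])
      if (length(bi) && length(bj))
        add_rect(bi, bj, config$compartment_preference)
    }
  }
  groups
}

bins_in <- function(mids, lo, hi) which(mids >= lo & mids < hi)

#' Recovery of planted structure
#'
#' Compares interaction calls with the planted loop list: a planted
#' loop is recovered when a passing call's bin pair matches the bins of
#' its anchors (within `slack` bins per end); a passing call matching
#' no planted loop is a false discovery.
#'
#' @param calls an `arcc_calls` table.
#' @param truth the `truth` element of [simulate_pairs()] output.
#' @param bins the binning the calls were made on.
#' @param slack allowed bin offset per end (default 0).
#' @return list with `sensitivity`, `fdp`, `n_pass`, `n_planted` and
#'   the planted table augmented with a `recovered` flag.
#' @export
evaluate_recovery <- function(calls, truth, bins, slack = 0) {
  if (is.null(truth$loops) || nrow(truth$loops) == 0)
    stop("no planted loops in ground truth")
  lp <- truth$loops
  p1 <- bin_lookup(bins, lp$chrom, pmin(lp$pos1, lp$pos2))
  p2 <- bin_lookup(bins, lp$chrom, pmax(lp$pos1, lp$pos2))
  pass <- calls[calls$pass, , drop = FALSE]
  c1 <- pmin(pass$bin1, pass$bin2); c2 <- pmax(pass$bin1, pass$bin2)
  match_any <- function(x1, x2, y1, y2)
    vapply(seq_along(x1), function(k)
      any(abs(y1 - x1[k]) <= slack & abs(y2 - x2[k]) <= slack),
      logical(1))
  recovered <- if (nrow(pass)) match_any(p1, p2, c1, c2)
               else rep(FALSE, length(p1))
  false_call <- if (nrow(pass)) !match_any(c1, c2, p1, p2) else logical(0)
  lp$recovered <- recovered
  list(sensitivity = mean(recovered),
       fdp = if (nrow(pass) > 0) mean(false_call) else 0,
       n_pass = nrow(pass), n_planted = nrow(lp), planted = lp)
}
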