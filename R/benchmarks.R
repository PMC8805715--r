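#' Validation benchmarks with planted ground truth
#'
#' Each benchmark runs one fixed, seeded simulation experiment and
#' measures how the pipeline recovers the planted structure.  They
#' define the package's reference study conditions: the acceptance
#' script and the test suite call these rather than re-specifying the
#' experiments.
#'
#' @name arcc_benchmarks
NULL

bench_seed <- function(seed, k) as.integer((seed * 1009 + k) %% 2147483647)

#' Orientation calibration of simulated ligation pairs
#'
#' Simulates random-ligation pairs on a 1-Mb chromosome with inter-end
#' distances between 601 bp and 100 kb and independent uniform strands,
#' then tabulates the four end-orientation configurations among pairs
#' more than 600 bp apart.  Each configuration should sit near 25\%.
#'
#' @param seed RNG seed.
#' @param n_pairs number of simulated pairs (default 100000).
#' @return list with `percent` (named FF/FR/RF/RR percentages), `n`,
#'   and `worst` (the percentage farthest from 25).
#' @export
benchmark_orientation <- function(seed, n_pairs = 1e5) {
  cfg <- sim_config(chrom_sizes = c(chr_sim = 1e6), n_pairs = n_pairs,
                    gamma = 0, bias_sdlog = 0, re_fraction = 0,
                    pair_d_min = 601, pair_d_max = 1e5)
  ann <- simulate_annotation(cfg, seed = bench_seed(seed, 1))
  sim <- simulate_pairs(cfg, ann, seed = bench_seed(seed, 2))
  p <- sim$pairs[abs(sim$pairs$pos1 - sim$pairs$pos2) > 600, ]
  op <- orientation_profile(p, c(600, 1e5 + 1000))
  pct <- 100 * c(FF = op$FF[1], FR = op$FR[1], RF = op$RF[1],
                 RR = op$RR[1])
  list(percent = pct, n = op$n[1],
       worst = pct[which.max(abs(pct - 25))])
}

# planted 8-fold interactions for the calling benchmark: 200 bin pairs
# at log-uniform distances 2-100 kb, anchors snapped to the calling grid
plant_calling_loops <- function(seed, n_loops = 200, chrom_len = 5e6,
                                bin = 500, fold = 8) {
  with_seed(bench_seed(seed, 3), {
    d <- round(exp(runif(n_loops, log(2000), log(1e5))))
    pos1 <- round(runif(n_loops, 1e5, chrom_len - 1e5 - d))
    snap <- function(p) floor(p / bin) * bin + bin / 2
    loops <- data.frame(chrom = "chrI", pos1 = snap(pos1),
                        pos2 = snap(pos1 + d), fold = fold)
    loops <- loops[loops$pos2 - loops$pos1 >= 3 * bin, ]
    loops[!duplicated(paste(loops$pos1, loops$pos2)), ]
  })
}

#' False-discovery control of the interaction-calling pipeline
#'
#' Simulates a 5-Mb chromosome at 500-bp resolution with 2 million cis
#' pairs following a d^-1 decay and lognormal per-bin visibility
#' biases, plants 200 bin-pair interactions boosted 8-fold, runs
#' visibility estimation (alpha 0.87), two-pass spline fitting and
#' one-sided binomial calling with BH correction at level 0.05 plus the
#' more-than-five-read support filter, and reports the fraction of
#' passing calls that are not planted.
#'
#' @param seeds vector of seeds; one simulation per seed.
#' @param n_pairs pairs per simulation (default 2e6).
#' @return list with per-seed `fdp`, `sensitivity`, `n_pass`, and the
#'   averages `mean_fdp`, `mean_sensitivity`.
#' @export
benchmark_fdr <- function(seeds = 1:10, n_pairs = 2e6) {
  sizes <- c(chrI = 5e6)
  bins <- make_fixed_bins(sizes, 500)
  fdp <- sens <- npass <- numeric(length(seeds))
  for (k in seq_along(seeds)) {
    loops <- plant_calling_loops(seeds[k])
    cfg <- sim_config(chrom_sizes = sizes, n_pairs = n_pairs,
                      loops = loops, re_fraction = 0)
    ann <- simulate_annotation(cfg, seed = bench_seed(seeds[k], 4))
    sim <- simulate_pairs(cfg, ann, seed = bench_seed(seeds[k], 5))
    cl <- classify_pairs(sim$pairs, sizes)
    cm <- contact_matrix(cl$pairs, bins)
    vis <- compute_visibility(cm)
    calls <- call_interactions(cm, vis)
    rec <- evaluate_recovery(calls, sim$truth, bins)
    fdp[k] <- rec$fdp; sens[k] <- rec$sensitivity
    npass[k] <- rec$n_pass
  }
  list(fdp = fdp, sensitivity = sens, n_pass = npass,
       mean_fdp = mean(fdp), mean_sensitivity = mean(sens))
}

#' Recovery of the planted distance-decay exponent
#'
#' @param seed RNG seed.
#' @param gamma planted exponent (default 1).
#' @return list with the fitted log-log `slope` (expected near -gamma).
#' @export
benchmark_decay <- function(seed, gamma = 1) {
  sizes <- c(chrI = 5e6)
  cfg <- sim_config(chrom_sizes = sizes, n_pairs = 1e6, gamma = gamma)
  ann <- simulate_annotation(cfg, seed = bench_seed(seed, 6))
  sim <- simulate_pairs(cfg, ann, seed = bench_seed(seed, 7))
  cl <- classify_pairs(sim$pairs, sizes)
  cm <- contact_matrix(cl$pairs, make_fixed_bins(sizes, 500))
  dec <- fit_distance_decay(cm, 1000, 1e6)
  d <- exp(seq(log(2000), log(5e5), length.out = 40))
  slope <- unname(coef(lm(log(predict_decay(dec, "chrI", d)) ~ log(d)))[2])
  list(slope = slope, gamma = gamma)
}

#' Recovery of planted point-interaction strength by aggregation
#'
#' Plants 3-fold interactions at 200 one-kb anchors, builds the
#' balanced decay-normalized 1-kb map, and aggregates 21 x 21 windows
#' at the planted pairs; the statistic should approach log2(3).
#'
#' @param seed RNG seed.
#' @param fold planted fold change (default 3).
#' @return list with `stat` and `expected`.
#' @export
benchmark_loop_aca <- function(seed, fold = 3) {
  sizes <- c(chrI = 5e6)
  loops <- with_seed(bench_seed(seed, 8), {
    d <- round(exp(runif(200, log(2e4), log(2e5))))
    pos1 <- round(runif(200, 2e5, 5e6 - 2.5e5 - d))
    snap <- function(p) floor(p / 1000) * 1000 + 500
    lp <- data.frame(chrom = "chrI", pos1 = snap(pos1),
                     pos2 = snap(pos1 + d), fold = fold)
    lp[!duplicated(paste(lp$pos1, lp$pos2)), ]
  })
  cfg <- sim_config(chrom_sizes = sizes, n_pairs = 4e6, loops = loops,
                    loop_width = 1000)
  ann <- simulate_annotation(cfg, seed = bench_seed(seed, 9))
  sim <- simulate_pairs(cfg, ann, seed = bench_seed(seed, 10))
  cl <- classify_pairs(sim$pairs, sizes)
  cm <- contact_matrix(cl$pairs, make_fixed_bins(sizes, 1000))
  cmb <- kr_balance(cm)
  cmn <- normalize_distance(cmb, fit_distance_decay(cmb, 2000, 2e6))
  res <- aca(cmn, data.frame(chrom = "chrI", pos1 = loops$pos1,
                             pos2 = loops$pos2), half_width = 10)
  list(stat = res$stat, expected = log2(fold))
}

#' Recovery of planted domain and compartment strength
#'
#' One simulation with within-domain enrichment e plants TAD-like
#' structure; a second with same-type preference r plants compartment
#' structure.  Both are read back as percent differences from the 5-kb
#' normalized map (the TAD background decay is fitted excluding
#' intra-domain cells).
#'
#' @param seed RNG seed.
#' @param enrichment planted within-domain enrichment e (default 1.2).
#' @param preference planted same-type preference r (default 1.5).
#' @return list with `domain_percent_diff` (expected ~100 (e-1)) and
#'   `compartment_percent_diff` (expected ~100 (r-1)).
#' @export
benchmark_domains <- function(seed, enrichment = 1.2, preference = 1.5) {
  sizes <- c(chrI = 5e6)
  run <- function(e, r, s0) {
    cfg <- sim_config(chrom_sizes = sizes, n_pairs = 2e6,
                      domain_enrichment = e, compartment_preference = r)
    ann <- simulate_annotation(cfg, seed = bench_seed(seed, s0))
    sim <- simulate_pairs(cfg, ann, seed = bench_seed(seed, s0 + 1))
    cl <- classify_pairs(sim$pairs, sizes)
    cm <- contact_matrix(cl$pairs, make_fixed_bins(sizes, 5000))
    cmb <- kr_balance(cm)
    list(cm = cmb, domains = ann$domains)
  }
  x <- run(enrichment, 1, 11)
  dec <- fit_distance_decay(x$cm, 10000, 3e6, exclude_domains = x$domains)
  cmn <- normalize_distance(x$cm, dec)
  ta <- aggregate_intra_domain(cmn, x$domains, "active")
  th <- aggregate_intra_domain(cmn, x$domains, "H3K27me3")
  dom_pd <- mean(c(ta$percent_diff, th$percent_diff))
  y <- run(1, preference, 13)
  cmn2 <- normalize_distance(y$cm, fit_distance_decay(y$cm, 10000, 3e6))
  cs <- compartment_strength(cmn2, y$domains)
  list(domain_percent_diff = dom_pd,
       compartment_percent_diff = cs$percent_diff,
       expected = c(100 * (enrichment - 1), 100 * (preference - 1)))
}

#' Correction-exponent identification on pure bin bias
#'
#' Simulates contacts with no distance structure and strong lognormal
#' bin bias, balances the matrix and scans coverage exponents; the
#' optimum should be near 1 because balancing factors are then
#' reciprocal coverage.
#'
#' @param seed RNG seed.
#' @return list with `alpha`.
#' @export
benchmark_exponent <- function(seed) {
  sizes <- c(chrI = 1e6)
  cfg <- sim_config(chrom_sizes = sizes, n_pairs = 1e6, gamma = 0,
                    bias_sdlog = 0.6, re_fraction = 0)
  ann <- simulate_annotation(cfg, seed = bench_seed(seed, 15))
  sim <- simulate_pairs(cfg, ann, seed = bench_seed(seed, 16))
  cl <- classify_pairs(sim$pairs, sizes)
  cm <- contact_matrix(cl$pairs, make_fixed_bins(sizes, 500))
  cmb <- kr_balance(cm)
  list(alpha = estimate_correction_exponent(cmb)$best)
}

#' Calibration of matched-permutation p-values under the null
#'
#' Builds one normalized map without planted site structure, then tests
#' many "factors" whose sites are random draws from a common universe;
#' their matched-null permutation p-values should be uniform.
#'
#' @param seed RNG seed.
#' @param n_factors number of null factors (default 200).
#' @param n_sets permutation sets per factor (default 99).
#' @return list with the p-values `p`, the Kolmogorov-Smirnov `ks_p`
#'   against uniformity, and `frac_05`.
#' @export
benchmark_null_calibration <- function(seed, n_factors = 200,
                                       n_sets = 99) {
  sizes <- c(chrI = 3e6)
  cfg <- sim_config(chrom_sizes = sizes, n_pairs = 1.5e6)
  ann <- simulate_annotation(cfg, seed = bench_seed(seed, 17))
  sim <- simulate_pairs(cfg, ann, seed = bench_seed(seed, 18))
  cl <- classify_pairs(sim$pairs, sizes)
  cm <- contact_matrix(cl$pairs, make_fixed_bins(sizes, 1000))
  cmb <- kr_balance(cm)
  cmn <- normalize_distance(cmb, fit_distance_decay(cmb, 2000, 1.5e6))
  eng <- aca_engine(cmn)
  universe <- with_seed(bench_seed(seed, 19), {
    st <- sort(sample(seq(25000, 2.97e6, by = 1000), 500))
    data.frame(chrom = "chrI", start = st, end = st + 1)
  })
  pool <- sample_site_contacts(universe, 20000, 1e6, Inf)
  p <- vapply(seq_len(n_factors), function(f) {
    sites <- with_seed(bench_seed(seed, 100 + f),
      universe[sort(sample.int(nrow(universe), 40)), ])
    ct <- sample_site_contacts(sites, 20000, 1e6, 60,
                               seed = bench_seed(seed, 5000 + f))
    obs <- aca(cmn, ct, 10, engine = eng)
    r <- matched_null_test(cmn, obs, ct, universe, n_sets = n_sets,
                           seed = bench_seed(seed, 9000 + f),
                           engine = eng, pool = pool)
    r$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  list(p = p, ks_p = ks$p.value, frac_05 = mean(p < 0.05))
}
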