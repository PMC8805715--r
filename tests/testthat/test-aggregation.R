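test_that("site-pair sampling respects the distance range and the cap", {
  s3 <- data.frame(chrom = "c1", start = c(0, 30000, 60000),
                   end = c(0, 30000, 60000) + 1)
  p3 <- sample_site_contacts(s3, d_min = 20000, d_max = 1e6)
  expect_equal(nrow(p3), 3)  # C(3,2), all in range

  # pairs closer than d_min are excluded
  s2 <- data.frame(chrom = "c1", start = c(0, 10000), end = c(1, 10001))
  expect_error(sample_site_contacts(s2, d_min = 20000, d_max = 1e6),
               "no eligible")

  # 400 sites, all pairs in range -> capped at exactly max_contacts
  s400 <- data.frame(chrom = "c1", start = seq(0, by = 2500,
                                               length.out = 400))
  s400$end <- s400$start + 1
  pc <- sample_site_contacts(s400, d_min = 0.1, d_max = 1e6,
                             max_contacts = 50000, seed = 2)
  expect_equal(nrow(pc), 50000)
  expect_identical(pc, sample_site_contacts(s400, d_min = 0.1, d_max = 1e6,
                                            max_contacts = 50000, seed = 2))
})

test_that("aggregation reads planted point enrichment off the map", {
  # constructed map: uniform background 4, 3x at chosen centres
  n <- 120
  M <- matrix(4L, n, n)
  # centres spaced further apart than the window so windows stay clean
  centers <- cbind(c(20, 45, 70), c(50, 75, 100))
  for (k in seq_len(nrow(centers))) {
    M[centers[k, 1], centers[k, 2]] <- 12L
    M[centers[k, 2], centers[k, 1]] <- 12L
  }
  cm <- cm_from_dense(M, width = 1000)
  contacts <- data.frame(chrom = "chrT",
                         pos1 = (centers[, 1] - 0.5) * 1000,
                         pos2 = (centers[, 2] - 0.5) * 1000)
  res <- aca(cm, contacts, half_width = 10)
  expect_equal(res$stat, log2(3), tolerance = 1e-6)
  expect_equal(res$n, nrow(centers))

  # uniform map: statistic is zero
  res0 <- aca(cm_from_dense(matrix(4L, 60, 60)),
              data.frame(chrom = "chrT", pos1 = c(20500, 30500),
                         pos2 = c(30500, 45500)), half_width = 5)
  expect_equal(res0$stat, 0, tolerance = 1e-9)

  # global scaling leaves the statistic unchanged
  res3 <- aca(cm_from_dense(M * 7L, width = 1000), contacts, half_width = 10)
  expect_equal(res3$stat, res$stat, tolerance = 1e-9)

  # windows sticking out of the matrix are skipped and counted
  edge <- rbind(contacts, data.frame(chrom = "chrT", pos1 = 500,
                                     pos2 = 50500))
  res2 <- aca(cm, edge, half_width = 10)
  expect_equal(res2$n_skipped, 1)
})

test_that("matched nulls preserve strata and give valid permutation p", {
  x <- quick_sim(301, n_pairs = 6e5)
  cl <- classify_pairs(x$sim$pairs, x$cfg$chrom_sizes)
  cm <- contact_matrix(cl$pairs, make_fixed_bins(x$cfg$chrom_sizes, 1000))
  cmb <- kr_balance(cm)
  cmn <- normalize_distance(cmb, fit_distance_decay(cmb, 2000, 1e6))
  eng <- aca_engine(cmn)
  set.seed(31)
  universe <- data.frame(chrom = "chrI",
                         start = sort(sample(seq(30000, 1.97e6, 1000), 300)))
  universe$end <- universe$start + 1
  pool <- sample_site_contacts(universe, 20000, 5e5, Inf)
  sites <- universe[sort(sample.int(300, 40)), ]
  ct <- sample_site_contacts(sites, 20000, 5e5, 50, seed = 3)
  obs <- aca(cmn, ct, 10, engine = eng)
  r <- matched_null_test(cmn, obs, ct, universe, n_sets = 200,
                         d_min = 20000, d_max = 5e5, seed = 5,
                         engine = eng, pool = pool)
  # a null factor's statistic sits inside its own null distribution
  expect_gte(r$p, 0.02)
  expect_lte(r$p, 0.98)
  expect_equal(length(r$null_stats), 200)

  # planted enrichment at the tested contacts drives p to the floor
  M <- matrix(2L, 400, 400)
  idx <- cbind(seq(30, 200, 15), seq(80, 250, 15))
  M[idx] <- 30L; M[idx[, 2:1]] <- 30L
  cmx <- cm_from_dense(M, width = 1000)
  ctx <- data.frame(chrom = "chrT", pos1 = (idx[, 1] - 0.5) * 1000,
                    pos2 = (idx[, 2] - 0.5) * 1000)
  ux <- data.frame(chrom = "chrT", start = seq(20000, 380000, 3000))
  ux$end <- ux$start + 1
  ox <- aca(cmx, ctx, 5)
  rx <- matched_null_test(cmx, ox, ctx, ux, n_sets = 99,
                          d_min = 20000, d_max = 3e5, seed = 7)
  expect_equal(rx$p, 1 / 100)
})

test_that("highly occupied intervals are removed with deterministic ties", {
  # 20 factors over a 30-interval universe; intervals 1..6 called by
  # 12+ factors and must go everywhere
  uni <- data.frame(chrom = "c1", start = seq(0, by = 1000,
                                              length.out = 30))
  uni$end <- uni$start + 200
  sets <- lapply(1:20, function(f) {
    hot <- uni[1:6, ]
    extra <- uni[6 + ((f * 3 + 1:9) %% 24) + 1, ]
    rbind(hot, extra)
  })
  names(sets) <- paste0("f", 1:20)
  fh <- filter_hot(sets, top_fraction = 0.2, min_peaks = 1)
  expect_equal(nrow(fh$hot), 6)
  expect_true(all(fh$hot$n_factors == 20))
  expect_true(all(vapply(fh$sets, function(s) all(s$start >= 6000),
                         logical(1))))

  # factors below the minimum peak count are dropped (and reported)
  sets2 <- list(big = uni, small = uni[1:4, ])
  fh2 <- suppressMessages(filter_hot(sets2, top_fraction = 0.2,
                                     min_peaks = 10))
  expect_identical(fh2$dropped, "small")

  # all-tied scores: exactly top_fraction removed, by genomic order
  sets3 <- list(a = uni)
  fh3 <- filter_hot(sets3, top_fraction = 0.2, min_peaks = 1)
  expect_equal(nrow(fh3$hot), 6)
  expect_equal(fh3$hot$start, uni$start[1:6])
})

test_that("differential aggregate analysis isolates the shifted factor", {
  set.seed(41)
  wt <- setNames(runif(20, 0.2, 1.5), paste0("f", 1:20))
  mut <- wt + rnorm(20, 0, 0.02)
  # identity relation a = 0, b = 1 recovered from mut = wt + noise
  res0 <- differential_aca(wt, mut, n_boot = 1000, seed = 9)
  expect_equal(attr(res0, "slope"), 1, tolerance = 0.05)
  expect_equal(attr(res0, "intercept"), 0, tolerance = 0.05)

  mut["f7"] <- wt["f7"] - 1.0
  res <- differential_aca(wt, mut, n_boot = 5000, seed = 9)
  expect_equal(res$factor[which.min(res$residual)], "f7")
  expect_lt(res$p[res$factor == "f7"], 0.05)

  # exact identity: all residuals vanish
  res2 <- differential_aca(wt, wt, n_boot = 1000, seed = 9)
  expect_true(all(abs(res2$residual) < 1e-12))
  expect_error(differential_aca(wt[1:2], mut[1:2]), "3 factors")
})
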