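test_that("contact counting conserves pairs and respects the cis contract", {
  bins <- make_fixed_bins(c(chrI = 10000), 1000)
  p <- make_pairs("chrI", c(3500, 3600, 3800, 6200),
                  "chrI", c(8100, 8500, 8900, 6400))
  cm <- contact_matrix(p, bins)
  cc <- cm$chrom$chrI
  expect_equal(cc$trip$x[cc$trip$i == 4 & cc$trip$j == 9], 3)
  expect_equal(cc$N, 4)
  expect_equal(sum(cc$trip$x), nrow(p))
  # both ends in one bin increment the diagonal
  expect_equal(cc$trip$x[cc$trip$i == 7 & cc$trip$j == 7], 1)
  # symmetric query through the dense view
  D <- arcc:::cm_dense(cm, "chrI")
  expect_equal(D[9, 4], 3)
  expect_error(contact_matrix(make_pairs("chrI", 1, "chrII", 1),
                              make_fixed_bins(c(chrI = 1e4, chrII = 1e4), 1000)),
               "cis-only")
})

test_that("Knight-Ruiz balancing equalizes row sums and matches oracles", {
  # analytic 2x2: weights 1/sqrt(2)
  r <- kr_balance(matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(r$weights, rep(1 / sqrt(2), 2), tolerance = 1e-10)

  set.seed(5)
  A <- matrix(runif(2500, 0.1, 3), 50, 50)
  A <- A + t(A)
  r2 <- kr_balance(A, tol = 1e-12)
  rs <- rowSums(r2$balanced)
  expect_lt(sd(rs) / mean(rs), 1e-6)
  # independent iterative-proportional-fitting oracle
  w_ipf <- sinkhorn_weights(A)
  expect_equal(r2$weights / w_ipf, rep(1, 50), tolerance = 1e-6)
  # already balanced: weights all ~1 (idempotence)
  r3 <- kr_balance(r2$balanced)
  expect_equal(max(abs(r3$weights - 1)), 0, tolerance = 1e-6)

  # on a contact matrix: masked all-zero rows get NA weights
  M <- matrix(0, 6, 6)
  M[1, 2] <- M[2, 3] <- M[1, 3] <- M[4, 5] <- M[4, 6] <- M[5, 6] <- 4
  M <- M + t(M)
  cmb <- kr_balance(cm_from_dense(M))
  expect_false(any(is.na(cmb$chrom$chrT$weights)))
  M[, 4] <- M[4, ] <- 0
  cmb2 <- kr_balance(cm_from_dense(M))
  expect_true(is.na(cmb2$chrom$chrT$weights[4]))
})

test_that("distance decay recovers a planted power law and stays flat without one", {
  x <- quick_sim(101, n_pairs = 3e5)
  cl <- classify_pairs(x$sim$pairs, x$cfg$chrom_sizes)
  cm <- contact_matrix(cl$pairs, make_fixed_bins(x$cfg$chrom_sizes, 500))
  dec <- fit_distance_decay(cm, 1000, 1e6)
  d <- exp(seq(log(2000), log(5e5), length.out = 40))
  slope <- unname(coef(lm(log(predict_decay(dec, "chrI", d)) ~ log(d)))[2])
  expect_equal(slope, -1, tolerance = 0.1)

  # no planted decay: flat within sampling error
  y <- quick_sim(103, n_pairs = 3e5, gamma = 0)
  cl2 <- classify_pairs(y$sim$pairs, y$cfg$chrom_sizes)
  cm2 <- contact_matrix(cl2$pairs, make_fixed_bins(y$cfg$chrom_sizes, 500))
  dec2 <- fit_distance_decay(cm2, 1000, 1e6)
  f2 <- predict_decay(dec2, "chrI", d)
  expect_lt(max(f2) / min(f2), 1.25)
})

test_that("second-pass decay drops below the first at planted loop distances", {
  loops <- data.frame(chrom = "chrI",
                      pos1 = seq(2e5, 1.4e6, by = 4e4) + 250,
                      pos2 = seq(2e5, 1.4e6, by = 4e4) + 30250, fold = 40)
  x <- quick_sim(105, n_pairs = 3e5, loops = loops)
  cl <- classify_pairs(x$sim$pairs, x$cfg$chrom_sizes)
  cm <- contact_matrix(cl$pairs, make_fixed_bins(x$cfg$chrom_sizes, 500))
  dec <- fit_distance_decay(cm, 1000, 1e6)
  at_loop <- log(30000)
  f1 <- exp(predict(dec$chrom$chrI$fit_pass1, at_loop)$y)
  f2 <- exp(predict(dec$chrom$chrI$fit, at_loop)$y)
  expect_lt(f2, f1)
})

test_that("distance normalization flattens strata and preserves planted loops", {
  x <- quick_sim(107, n_pairs = 4e5)
  cl <- classify_pairs(x$sim$pairs, x$cfg$chrom_sizes)
  cm <- contact_matrix(cl$pairs, make_fixed_bins(x$cfg$chrom_sizes, 1000))
  cmb <- kr_balance(cm)
  dec <- fit_distance_decay(cmb, 2000, 1e6)
  cmn <- normalize_distance(cmb, dec)
  expect_true(cmn$decay_normalized)
  cc <- cmn$chrom$chrI
  d <- abs(cc$mid[cc$trip$j] - cc$mid[cc$trip$i])
  edges <- exp(seq(log(2000), log(1e6), length.out = 8))
  mids <- cc$mid
  npairs <- diff(vapply(edges, function(e)
    sum(findInterval(mids + e, mids)) - length(mids) * (length(mids) + 1) / 2,
    numeric(1)))
  sums <- tapply(cc$trip$x, cut(d, edges), sum)
  expect_equal(unname(as.numeric(sums) / npairs), rep(1, 7), tolerance = 0.1)

  # strong planted loops read as their fold change after normalization
  pos1 <- seq(2e5, 1.5e6, by = 70000) + 500
  loops <- data.frame(chrom = "chrI", pos1 = pos1, pos2 = pos1 + 30000,
                      fold = 5)
  y <- quick_sim(109, n_pairs = 2e6, loops = loops, loop_width = 1000,
                 bias_sdlog = 0, re_fraction = 0)
  cl2 <- classify_pairs(y$sim$pairs, y$cfg$chrom_sizes)
  cm2 <- contact_matrix(cl2$pairs, make_fixed_bins(y$cfg$chrom_sizes, 1000))
  cm2b <- kr_balance(cm2)
  cm2n <- normalize_distance(cm2b, fit_distance_decay(cm2b, 2000, 1e6))
  cc2 <- cm2n$chrom$chrI
  li <- floor(loops$pos1 / 1000) + 1
  m <- match(paste(li, li + 30), paste(cc2$trip$i, cc2$trip$j))
  vals <- cc2$trip$x[m]
  vals[is.na(vals)] <- 0
  expect_equal(mean(vals), 5, tolerance = 0.15)
})

test_that("insulation is flat on uniform maps and dips at block boundaries", {
  U <- matrix(5L, 30, 30)
  cmu <- kr_balance(cm_from_dense(U))
  insu <- insulation_profile(cmu, 3000)
  expect_equal(max(abs(insu$score), na.rm = TRUE), 0, tolerance = 1e-9)

  B <- matrix(1L, 30, 30)
  B[1:15, 1:15] <- 8L
  B[16:30, 16:30] <- 8L
  cmb <- cm_from_dense(B)
  ins <- insulation_profile(cmb, 4000)
  expect_true(which.min(ins$score) %in% 15:16)
  expect_true(all(is.na(ins$score[1:4])))  # incomplete windows masked
  expect_error(insulation_profile(cmb, 1000), "2 bins")
})

test_that("the correction exponent scan finds constructed optima", {
  set.seed(9)
  cov <- exp(runif(400, 0, 3))
  ex <- estimate_correction_exponent(list(weights = cov^(-0.5),
                                          coverage = cov))
  expect_identical(ex$best, 0.5)
  expect_error(
    estimate_correction_exponent(list(weights = runif(10),
                                      coverage = rep(3, 10))),
    "constant")
})
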