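test_that("visibility flags deciles and scales off-peak coverage", {
  cm <- make_visibility_fixture()
  vis <- compute_visibility(cm)
  tab <- vis$table
  expect_identical(which(tab$peak), 19:20)
  expect_identical(which(tab$removed), 1:2)
  # removed intervals carry no visibility and are excluded downstream
  expect_true(all(is.na(tab$v[1:2])))
  # off-peak coverage excludes contacts whose partner is a peak bin
  cc <- cm$chrom$chrT
  manual <- sum(cc$trip$x[(cc$trip$i == 5 & !cc$trip$j %in% 19:20) |
                            (cc$trip$j == 5 & !cc$trip$i %in% 19:20)])
  expect_equal(tab$c_offpeak[5], manual)
  # interval at the median has v = 1; 2x median has v = 2^alpha
  med <- tab$median_offpeak[5]
  expect_equal((tab$c_offpeak[5] / med)^0.87, tab$v[5])
  expect_equal(2^0.87, 1.8277, tolerance = 1e-4)
  v_fun <- (tab$c_offpeak / med)^0.87
  expect_equal(tab$v[!tab$removed], v_fun[!tab$removed])
})

test_that("binomial tail matches the exact summation oracle", {
  set.seed(21)
  for (k in 1:50) {
    N <- sample(1e4:1e6, 1)
    f <- 10^runif(1, -7, -4)
    n <- sample(1:30, 1)
    p_impl <- pbinom(n - 1, N, f, lower.tail = FALSE)
    p_oracle <- binom_upper_tail_oracle(n, N, f)
    expect_lt(abs(p_impl - p_oracle) / p_oracle, 1e-12)
  }
})

test_that("interaction calls honour the support filter and distance range", {
  loops <- data.frame(chrom = "chrI",
                      pos1 = c(300250, 900250), pos2 = c(315250, 915250),
                      fold = 40)
  x <- quick_sim(201, n_pairs = 5e5, loops = loops)
  cl <- classify_pairs(x$sim$pairs, x$cfg$chrom_sizes)
  cm <- contact_matrix(cl$pairs, make_fixed_bins(x$cfg$chrom_sizes, 500))
  vis <- compute_visibility(cm)
  calls <- call_interactions(cm, vis)
  # distance range: nothing tested beyond 1 Mb or below 1 kb
  expect_true(all(calls$d >= 1000 & calls$d <= 1e6))
  # the support filter is strict: n > 5, so n = 5 never passes
  expect_false(any(calls$pass & calls$n <= 5))
  n5 <- calls[calls$n == 5, ]
  expect_false(any(n5$pass))
  # planted strong loops are recovered
  rec <- evaluate_recovery(calls, x$sim$truth,
                           make_fixed_bins(x$cfg$chrom_sizes, 500))
  expect_equal(rec$sensitivity, 1)
  # q is monotone in p within a chromosome
  ord <- order(calls$p)
  expect_true(all(diff(calls$q[ord]) >= -1e-12))
})

test_that("visibility and p-values are invariant to pair-row permutation", {
  x <- quick_sim(205, n_pairs = 1e5)
  cl <- classify_pairs(x$sim$pairs, x$cfg$chrom_sizes)
  bins <- make_fixed_bins(x$cfg$chrom_sizes, 500)
  perm <- cl$pairs[sample.int(nrow(cl$pairs)), ]
  cm1 <- contact_matrix(cl$pairs, bins)
  cm2 <- contact_matrix(perm, bins)
  v1 <- compute_visibility(cm1)
  v2 <- compute_visibility(cm2)
  expect_equal(v1$table$v, v2$table$v)
  c1 <- call_interactions(cm1, v1, d_max = 5e5)
  c2 <- call_interactions(cm2, v2, d_max = 5e5)
  expect_equal(c1$p, c2$p)
})

test_that("calls are annotated by end element classes", {
  calls <- structure(
    data.frame(chrom = "chrI", bin1 = 1:3, bin2 = 4:6,
               start1 = c(0, 1000, 2000), end1 = c(500, 1500, 2500),
               start2 = c(8000, 9000, 9500), end2 = c(8500, 9500, 10000)),
    class = c("arcc_calls", "data.frame"))
  ann <- list(P = data.frame(chrom = "chrI", start = c(100, 8100),
                             end = c(300, 8300)),
              E = data.frame(chrom = "chrI", start = 1100, end = 1300))
  out <- annotate_calls(calls, ann)
  expect_equal(out$type, c("P-P", "E-other", "other-other"))
})
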