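sizes <- c(chrI = 1e6, chrII = 1e6)

test_that("pairs are classified by quality, chromosome and distance", {
  p <- make_pairs(
    chrom1 = rep("chrI", 5),
    pos1 = c(1000, 1000, 1000, 1000, 1000),
    chrom2 = c("chrI", "chrI", "chrI", "chrI", "chrII"),
    pos2 = c(1900, 1400, 5000, 1600, 5000),
    mapq1 = c(60, 60, 20, 60, 60))
  res <- classify_pairs(p, sizes)
  expect_identical(res$pairs$label,
                   c("cis_informative",       # 900 bp > 600
                     "valid_noninformative",  # 400 bp
                     "discarded",             # mapq 20 < 30
                     "valid_noninformative",  # exactly 600: strict >
                     "trans_informative"))    # different chromosomes
  expect_identical(res$stats$n_input, 5L)
  expect_equal(sum(unlist(res$stats$counts)), 5)
})

test_that("mismatch filter, blacklist overlap and unknown chromosomes", {
  p <- make_pairs("chrI", c(1000, 1000), "chrI", c(5000, 5000),
                  nm1 = c(3, 0))
  res <- classify_pairs(p, sizes)
  expect_identical(res$pairs$label, c("discarded", "cis_informative"))

  bl <- data.frame(chrom = "chrI", start = 990, end = 1010)
  res2 <- classify_pairs(p[2, ], sizes, blacklist = bl)
  expect_identical(res2$pairs$label, "discarded")
  # 5' base just outside the blacklist survives
  bl2 <- data.frame(chrom = "chrI", start = 0, end = 1000)
  res3 <- classify_pairs(p[2, ], sizes, blacklist = bl2)
  expect_identical(res3$pairs$label, "cis_informative")

  expect_error(classify_pairs(make_pairs("chrQ", 1, "chrI", 5000), sizes),
               "chrQ")
  expect_error(classify_pairs(p[, -2], sizes), "malformed|unpaired")
})

test_that("every pair gets exactly one label and the threshold is monotone", {
  set.seed(11)
  n <- 500
  p <- make_pairs("chrI", sample.int(9e5, n), "chrI", sample.int(9e5, n),
                  mapq1 = sample(c(10, 60), n, TRUE))
  counts <- vapply(c(200, 600, 2000, 5e4), function(thr) {
    res <- classify_pairs(p, sizes, informative_distance = thr)
    expect_equal(sum(unlist(res$stats$counts)), n)
    sum(res$pairs$label == "cis_informative")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # determinism: identical input, identical output
  expect_identical(classify_pairs(p, sizes), classify_pairs(p, sizes))
})

test_that("duplicates share both ends exactly, end order ignored", {
  p <- make_pairs("chrI", c(1000, 1000, 1001, 5000), "chrI",
                  c(5000, 5000, 5000, 1000),
                  strand1 = c("+", "+", "+", "-"),
                  strand2 = c("-", "-", "-", "+"))
  p$label <- "cis_informative"
  out <- deduplicate(p)
  # row 2 repeats row 1; row 4 is row 1 with ends swapped; row 3 differs by 1 bp
  expect_identical(out$label,
                   c("cis_informative", "duplicate", "cis_informative",
                     "duplicate"))
  expect_identical(nrow(deduplicate(p[0, ])), 0L)
})

test_that("orientation fractions sum to one and recover planted mixtures", {
  # all forward-reverse at short range
  p <- make_pairs("chrI", rep(0, 50), "chrI", seq(100, 490, length.out = 50))
  op <- orientation_profile(p, c(0, 500, 1000))
  expect_equal(op$FR[1], 1.0)
  expect_true(is.na(op$FF[2]))  # empty stratum is undefined, not zero

  # planted mixture recovered within binomial error
  set.seed(3)
  n <- 20000
  conf <- sample(c("FF", "FR", "RF", "RR"), n, TRUE,
                 prob = c(0.4, 0.2, 0.2, 0.2))
  s1 <- ifelse(conf %in% c("FF", "FR"), "+", "-")
  s2 <- ifelse(conf %in% c("FF", "RF"), "+", "-")
  p2 <- make_pairs("chrI", rep(1000, n), "chrI", rep(5000, n),
                   strand1 = s1, strand2 = s2)
  op2 <- orientation_profile(p2, c(0, 1e4))
  expect_lt(abs(op2$FF[1] - 0.4), 0.02)
  expect_lt(abs(op2$RR[1] - 0.2), 0.02)
  expect_equal(op2$FF[1] + op2$FR[1] + op2$RF[1] + op2$RR[1], 1)
})
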