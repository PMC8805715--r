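make_expr <- function() {
  set.seed(17)
  n_genes <- 60; n_ct <- 12
  expr <- matrix(rlnorm(n_genes * n_ct, 2, 0.6), n_genes, n_ct)
  rownames(expr) <- sprintf("g%02d", seq_len(n_genes))
  colnames(expr) <- paste0("ct", seq_len(n_ct))
  expr
}

test_that("linked-pair correlations: sign, best bidirectional candidate, drops", {
  expr <- make_expr()
  expr["g01", ] <- 1:12
  expr["g02", ] <- 2 * (1:12) + 3   # perfectly correlated with g01
  expr["g03", ] <- rev(1:12) * 2    # perfectly anti-correlated
  expr["g04", ] <- 5                # zero variance

  links <- data.frame(gene1 = c("g01", "g01", "g01", "g05", "g01"),
                      gene2 = c("g02", "g03", "g04", "gZZ", "g10"),
                      stringsAsFactors = FALSE)
  out <- linked_pair_correlations(links, expr)
  expect_equal(out$r[out$gene2 == "g02"], 1)
  expect_equal(out$r[out$gene2 == "g03"], -1)
  expect_false("g04" %in% out$gene2)     # zero variance dropped
  expect_false("gZZ" %in% out$gene2)     # missing gene dropped
  expect_equal(attr(out, "n_missing"), 1)
  expect_equal(attr(out, "n_zero_var"), 1)
  expect_true(all(out$r >= -1 & out$r <= 1))

  # bidirectional promoter: the candidate pair with highest r is kept
  links2 <- data.frame(gene1 = c("g01", "g01"), gene2 = c("g02", "g03"),
                       link_id = c("L1", "L1"))
  out2 <- linked_pair_correlations(links2, expr)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$gene2, "g02")
})

test_that("CV stratification uses conjunctive genome-wide cuts", {
  expr <- make_expr()
  cv <- cv_expression(expr)
  rk <- rank(cv, ties.method = "first")
  low_genes <- names(cv)[rk <= floor(0.3 * length(cv))]
  g_lo <- low_genes[1:2]
  g_hi <- setdiff(names(cv), low_genes)[1:2]
  pairs <- data.frame(gene1 = c(g_lo[1], g_lo[1], g_hi[1]),
                      gene2 = c(g_lo[2], g_hi[1], g_hi[2]),
                      r = c(0.5, 0.2, 0.1), stringsAsFactors = FALSE)
  st <- stratify_by_cv(pairs, expr, low_fraction = 0.30)
  expect_equal(nrow(st$all), 3)
  expect_equal(nrow(st$both_low), 1)    # only the low-low pair
  expect_equal(nrow(st$both_high), 1)   # only the high-high pair
  # the straddling pair is in neither "both" subset
  expect_false(any(st$both_low$gene2 == g_hi[1]))
  expect_false(any(st$both_high$gene1 == g_lo[1]))
  # subsets nest in all
  expect_true(all(rownames(st$both_low) %in% rownames(st$all)))
})

test_that("matched random controls detect planted co-expression", {
  set.seed(23)
  n_genes <- 80
  base <- matrix(rlnorm(n_genes * 10, 2, 0.7), n_genes, 10)
  rownames(base) <- sprintf("g%02d", seq_len(n_genes))
  coords <- data.frame(gene = rownames(base), chrom = "chrI",
                       tss = seq(10000, by = 20000,
                                 length.out = n_genes))
  # planted: genes 1..30 share a strong common program pairwise
  prog <- rlnorm(10, 2, 0.7)
  for (g in 1:30) base[g, ] <- prog * rlnorm(10, 0, 0.15)
  links <- data.frame(gene1 = sprintf("g%02d", seq(1, 29, 2)),
                      gene2 = sprintf("g%02d", seq(2, 30, 2)))
  obs <- linked_pair_correlations(links, base)
  ctrl <- matched_random_control(obs, base, coords, n_sets = 30, seed = 3)
  expect_gt(ctrl$observed_mean_r, ctrl$control_mean_r)
  expect_lt(ctrl$p, 0.01)
  # each control draw has the same number of pairs as the observed set
  expect_equal(length(ctrl$control_r), 30 * nrow(obs))
})

test_that("genes are marked at the median-multiple threshold", {
  sig <- c(a = 10, b = 16.1, c = 10, d = 14.9, e = 10)
  m <- mark_genes_by_signal(sig, factor = 1.5)
  expect_identical(unname(m), c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_false(mark_genes_by_signal(c(x = 5, y = 5, z = 5))[["x"]])
})
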