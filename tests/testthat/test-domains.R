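alt_domains <- function(n = 10, size = 20000, chrom = "chrT") {
  data.frame(chrom = chrom, start = seq(0, by = size, length.out = n),
             end = seq(size, by = size, length.out = n),
             type = rep(c("active", "H3K27me3"), length.out = n),
             stringsAsFactors = FALSE)
}

test_that("scaled aggregation of a constant map is constant", {
  cm <- cm_from_dense(matrix(6L, 100, 100), width = 2000)
  doms <- alt_domains(10, 20000)
  agg <- aggregate_intra_domain(cm, doms, "active", flank = 10000,
                                exclude_chroms = character(0))
  inner <- agg$grid[!is.na(agg$grid)]
  expect_equal(max(abs(inner - 6)), 0, tolerance = 1e-9)
  expect_equal(agg$percent_diff, 0, tolerance = 1e-9)
  expect_equal(agg$log2fc, 0, tolerance = 1e-9)
})

test_that("short domains are skipped and the X chromosome excluded", {
  cm <- cm_from_dense(matrix(2L, 50, 50), width = 1000)
  doms <- data.frame(chrom = "chrT", start = c(0, 4000, 30000),
                     end = c(4000, 30000, 50000),
                     type = c("active", "H3K27me3", "active"))
  agg <- aggregate_intra_domain(cm, doms, "active", min_size = 5000,
                                flank = 5000, exclude_chroms = character(0))
  expect_equal(agg$n, 1)  # the 4-kb active domain is skipped
  doms$chrom <- "chrX"
  expect_error(aggregate_intra_domain(cm, doms, "active"), "qualifying")
})

test_that("planted within-domain enrichment appears as percent difference", {
  # constructed normalized map: 1.2x inside on-diagonal domain squares
  n <- 200; w <- 5000
  doms <- alt_domains(20, 50000)  # 10 bins per domain
  M <- matrix(10, n, n)
  dom_of <- findInterval((seq_len(n) - 0.5) * w, doms$start)
  same <- outer(dom_of, dom_of, "==")
  M[same] <- 12
  cm <- cm_from_dense(matrix(as.integer(M), n), width = w)
  agg <- aggregate_intra_domain(cm, doms, "active",
                                exclude_chroms = character(0))
  expect_equal(agg$percent_diff, 20, tolerance = 1.5 / 20)
  # noise-free construction: every domain reads the same ratio
  expect_lt(max(abs(agg$per_region - log2(1.2))), 0.05)
})

test_that("compartment aggregation contrasts same- with cross-type pairs", {
  n <- 300; w <- 5000
  doms <- alt_domains(30, 50000)
  dom_of <- findInterval((seq_len(n) - 0.5) * w, doms$start)
  type_of <- doms$type[dom_of]
  M <- matrix(10, n, n)
  same_type <- outer(type_of, type_of, "==") &
    !outer(dom_of, dom_of, "==")
  M[same_type] <- 15
  cm <- cm_from_dense(matrix(as.integer(M), n), width = w)
  cs <- compartment_strength(cm, doms, d_min = 50000, d_max = 1.2e6,
                             exclude_chroms = character(0))
  expect_equal(cs$percent_diff, 50, tolerance = 5)

  # domain pairs beyond d_max are excluded
  agg <- aggregate_inter_domain(cm, doms, "same_type", d_min = 50000,
                                d_max = 120000,
                                exclude_chroms = character(0))
  expect_lt(agg$n, 60)
})

test_that("strain comparison reports fold change or qualitative loss", {
  sfc <- strain_fold_change(30, 30)
  expect_equal(sfc$fold_change, 1)
  sfc2 <- strain_fold_change(50, 5)
  expect_equal(sfc2$fold_change, 10)
  sfc3 <- strain_fold_change(50, -3)
  expect_true(sfc3$undefined)
  expect_true(is.na(sfc3$fold_change))
})

test_that("domain stratification splits the top fraction deterministically", {
  doms <- alt_domains(100, 10000)
  sig <- seq_len(100)  # monotone: high set = 25 largest
  sp <- stratify_domains(doms, sig, top_fraction = 0.25)
  expect_equal(nrow(sp$high), 25)
  expect_equal(nrow(sp$low), 75)
  expect_true(all(sp$high$start >= doms$start[76]))
  # constant signal: deterministic tie-broken split of the same size
  sp2 <- stratify_domains(doms, rep(1, 100), top_fraction = 0.25)
  expect_equal(nrow(sp2$high), 25)
  sp3 <- stratify_domains(doms, rep(1, 100), top_fraction = 0.25)
  expect_identical(sp2$high, sp3$high)
})
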