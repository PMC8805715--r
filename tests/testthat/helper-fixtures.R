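# Shared fixture builders. Everything is generated in code; no data files.

# Build a contact matrix from a dense symmetric integer matrix of counts
# over fixed-width bins on one chromosome.
cm_from_dense <- function(M, width = 1000, chrom = "chrT") {
  stopifnot(isSymmetric(unname(M)))
  n <- nrow(M)
  bins <- make_fixed_bins(setNames(n * width, chrom), width)
  idx <- which(upper.tri(M, diag = TRUE) & M > 0, arr.ind = TRUE)
  cnt <- M[idx]
  i <- rep(idx[, 1], cnt); j <- rep(idx[, 2], cnt)
  pairs <- data.frame(
    chrom1 = chrom, pos1 = (i - 1) * width + width %/% 2, strand1 = "+",
    chrom2 = chrom, pos2 = (j - 1) * width + width %/% 2, strand2 = "-",
    stringsAsFactors = FALSE)
  contact_matrix(pairs, bins)
}

# Minimal well-formed pair table
make_pairs <- function(chrom1, pos1, chrom2, pos2,
                       strand1 = "+", strand2 = "-",
                       mapq1 = 60, mapq2 = 60, nm1 = 0, nm2 = 0) {
  data.frame(chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             mapq1 = mapq1, nm1 = nm1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
             mapq2 = mapq2, nm2 = nm2, stringsAsFactors = FALSE)
}

# Independent Sinkhorn (iterative proportional fitting) oracle for
# doubly-stochastic balancing; deliberately different from the package's
# Newton-based implementation.
sinkhorn_weights <- function(A, iters = 5000, tol = 1e-12) {
  x <- rep(1, nrow(A))
  for (k in seq_len(iters)) {
    r <- as.numeric(A %*% x) * x
    x <- x / sqrt(r)
    if (max(abs(r - 1)) < tol) break
  }
  x
}

# Exact upper-tail binomial probability P(X >= n), X ~ Bin(N, f), by
# direct term summation with the multiplicative recurrence; independent
# of pbinom.
binom_upper_tail_oracle <- function(n, N, f) {
  if (n <= 0) return(1)
  if (n > N) return(0)
  log_t <- lchoose(N, n) + n * log(f) + (N - n) * log1p(-f)
  t <- exp(log_t)
  s <- t
  k <- n
  while (k < N) {
    t <- t * ((N - k) / (k + 1)) * (f / (1 - f))
    s <- s + t
    k <- k + 1
    if (t < s * 1e-17) break
  }
  s
}

# Small end-to-end simulation shared by several tests
quick_sim <- function(seed, n_pairs = 2e5, chrom_len = 2e6, ...) {
  cfg <- sim_config(chrom_sizes = c(chrI = chrom_len), n_pairs = n_pairs, ...)
  ann <- simulate_annotation(cfg, seed = seed)
  sim <- simulate_pairs(cfg, ann, seed = seed + 1)
  list(cfg = cfg, ann = ann, sim = sim)
}

make_visibility_fixture <- function() {
  # 20 bins with strictly graded coverage: top decile (2 bins) are
  # peaks, bottom decile (2 bins) are removed
  n <- 20
  M <- matrix(0L, n, n)
  base <- c(1L, 2L, 3:19, 60L)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    M[i, j] <- M[j, i] <- as.integer(base[i] * base[j] %/% 3L + 1L)
  cm_from_dense(M, width = 500)
}

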