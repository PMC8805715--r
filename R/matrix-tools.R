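#' Insulation profile
#'
#' Per bin, the mean contact value in the `w x w` square crossing the
#' diagonal at that bin (rows `i-w..i-1`, columns `i+1..i+w`, with
#' `w = window / bin width`), log2-scaled relative to the chromosome
#' mean of such scores.  Bins whose window is incomplete at chromosome
#' ends are NA.  Local minima mark insulated (domain) boundaries.
#'
#' @param cm an `arcc_matrix` on a fixed-width binning.
#' @param window window size in bp; must be a multiple of the bin width
#'   and at least two bins.
#' @return data frame with `chrom`, `start`, `end`, `score`.
#' @export
insulation_profile <- function(cm, window) {
  bins <- cm$bins
  widths <- bins$end - bins$start
  width <- widths[1]
  last_of_chrom <- !duplicated(bins$chrom, fromLast = TRUE)
  if (any(widths[!last_of_chrom] != width))
    stop("insulation requires a fixed-width binning")
  w <- window / width
  if (w != round(w)) stop("window must be a multiple of the bin width")
  w <- as.integer(w)
  if (w < 2) stop("window must span at least 2 bins")
  out <- list()
  for (ch in cm_chroms(cm)) {
    A <- cm_dense(cm, ch)
    n <- nrow(A)
    score <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i - w < 1 || i + w > n) next
      score[i] <- mean(A[(i - w):(i - 1), (i + 1):(i + w)], na.rm = TRUE)
    }
    rel <- log2(score / mean(score, na.rm = TRUE))
    b <- bins[bins$chrom == ch, , drop = FALSE]
    out[[ch]] <- data.frame(chrom = ch, start = b$start, end = b$end,
                            score = rel, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate the coverage exponent approximating balancing factors
#'
#' Matrix-balancing correction factors can be approximated by the
#' reciprocal of coverage raised to some exponent alpha.  This scans a
#' grid of exponents and returns the one maximizing the Pearson
#' correlation between the Knight-Ruiz weights and coverage^(-alpha).
#' On real accessible-chromatin data the optimum sits near 0.87, the
#' package default for visibility correction.
#'
#' @param cm a balanced `arcc_matrix`, or a list with numeric
#'   `weights` and `coverage`.
#' @param exponent_grid exponents to scan (default 0.1 to 1.5 by 0.01).
#' @return list of class `arcc_exponent` with `best` and the
#'   correlation `curve`.
#' @export
estimate_correction_exponent <- function(cm,
                                         exponent_grid = seq(0.1, 1.5, by = 0.01)) {
  if (inherits(cm, "arcc_matrix")) {
    if (!cm$balanced) stop("matrix must be balanced first")
    w <- unlist(lapply(cm$chrom, `[[`, "weights"), use.names = FALSE)
    cov <- unlist(lapply(cm$chrom, `[[`, "coverage"), use.names = FALSE)
  } else {
    w <- cm$weights; cov <- cm$coverage
  }
  keep <- !is.na(w) & cov > 0
  w <- w[keep]; cov <- cov[keep]
  if (length(unique(cov)) < 3 || sd(cov) == 0)
    stop("coverage is (near-)constant: correlation undefined")
  curve <- vapply(exponent_grid, function(a) cor(w, cov^(-a)), numeric(1))
  best <- exponent_grid[which.max(curve)]
  structure(list(best = best,
                 curve = data.frame(alpha = exponent_grid, cor = curve)),
            class = "arcc_exponent")
}

#' @export
print.arcc_exponent <- function(x, ...) {
  cat(sprintf("Best coverage exponent: %.2f (cor = %.4f)\n", x$best,
              max(x$curve$cor)))
  invisible(x)
}
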