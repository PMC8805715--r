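#' Contact matrices
#'
#' An `arcc_matrix` stores, per chromosome, the upper triangle of a
#' symmetric contact matrix in triplet form over a genome binning,
#' together with the total cis contact count N of the chromosome, raw
#' per-bin coverage, and (after balancing) per-bin weights.  The `x`
#' column holds raw counts at construction and transformed values after
#' [kr_balance()] / [normalize_distance()]; `N` and `coverage` always
#' refer to the raw counts.
#'
#' @name arcc_matrix
NULL

#' Count contacts between bins
#'
#' Each same-chromosome pair increments exactly one cell (i, j), i <= j,
#' of its chromosome's matrix; pairs with both ends in one bin land on
#' the diagonal.  Pairs on different chromosomes are an error: the
#' contract is cis-only.
#'
#' @param pairs pair table; if a `label` column is present only
#'   `cis_informative` rows are counted.
#' @param bins an [arcc_bins] binning covering every chromosome present.
#' @return an `arcc_matrix`.
#' @export
contact_matrix <- function(pairs, bins) {
  stopifnot(inherits(bins, "arcc_bins"))
  if (!is.null(pairs$label))
    pairs <- pairs[pairs$label == "cis_informative", , drop = FALSE]
  if (nrow(pairs) > 0 && any(pairs$chrom1 != pairs$chrom2))
    stop("trans pair in input: contact matrices are cis-only")
  chroms <- unique(bins$chrom)
  per_chrom <- setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    nb <- nrow(b)
    sel <- pairs$chrom1 == ch
    if (any(sel)) {
      g1 <- bin_lookup(bins, pairs$chrom1[sel], pairs$pos1[sel]) - b$id[1] + 1L
      g2 <- bin_lookup(bins, pairs$chrom2[sel], pairs$pos2[sel]) - b$id[1] + 1L
      i <- pmin(g1, g2); j <- pmax(g1, g2)
      sm <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nb, nb))
      tri <- Matrix::summary(sm)
      trip <- data.frame(i = tri$i, j = tri$j, x = tri$x)
    } else {
      trip <- data.frame(i = integer(0), j = integer(0), x = numeric(0))
    }
    per_chrom[[ch]] <- list(
      trip = trip, n_bins = nb, N = sum(trip$x),
      coverage = chrom_coverage(trip, nb),
      offset = b$id[1] - 1L, mid = bin_midpoints(b)
    )
  }
  structure(list(bins = bins, chrom = per_chrom,
                 balanced = FALSE, decay_normalized = FALSE,
                 norm_range = NULL),
            class = "arcc_matrix")
}

# per-bin contact coverage: each pair counted once per involved bin
# (diagonal pairs once).
chrom_coverage <- function(trip, nb) {
  cov <- numeric(nb)
  off <- trip$i != trip$j
  cov <- cov + tapply_sum(trip$i, trip$x, nb)
  cov <- cov + tapply_sum(trip$j[off], trip$x[off], nb)
  cov
}

tapply_sum <- function(idx, x, n) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

cm_chroms <- function(cm) names(cm$chrom)

# Dense symmetric matrix of a chromosome's current values.  Cells whose
# midpoint distance falls outside the decay-normalisation range (once
# applied) are NA; bins masked during balancing are NA throughout.
cm_dense <- function(cm, ch) {
  cc <- cm$chrom[[ch]]
  A <- matrix(0, cc$n_bins, cc$n_bins)
  if (nrow(cc$trip)) {
    ij <- cbind(cc$trip$i, cc$trip$j)
    A[ij] <- cc$trip$x
    A[ij[, 2:1, drop = FALSE]] <- cc$trip$x
  }
  if (!is.null(cc$masked) && any(cc$masked)) {
    A[cc$masked, ] <- NA_real_
    A[, cc$masked] <- NA_real_
  }
  if (!is.null(cm$norm_range)) {
    d <- abs(outer(cc$mid, cc$mid, "-"))
    A[d < cm$norm_range[1] | d > cm$norm_range[2]] <- NA_real_
  }
  A
}

#' @export
print.arcc_matrix <- function(x, ...) {
  ntot <- sum(vapply(x$chrom, `[[`, numeric(1), "N"))
  cat(sprintf(
    "Contact matrix: %d chromosome(s), %d bins, %g cis contacts\n",
    length(x$chrom), nrow(x$bins), ntot))
  cat(sprintf("  balanced: %s, distance-normalized: %s\n",
              x$balanced, x$decay_normalized))
  invisible(x)
}

#' Knight-Ruiz matrix balancing
#'
#' Finds per-bin weights x so that diag(x) A diag(x) has equal row sums
#' (here 1) on every retained bin, using the Knight-Ruiz inner-outer
#' Newton iteration with conjugate-gradient inner solves.  Bins with no
#' off-diagonal counts are masked out before balancing and get NA
#' weights.
#'
#' @param cm an `arcc_matrix` (raw counts), or a plain symmetric
#'   non-negative matrix.
#' @param tol relative tolerance on the row sums (default 1e-8).
#' @param max_iter maximum outer iterations (default 200).
#' @return for an `arcc_matrix`: the matrix with `x` replaced by
#'   balanced values, `balanced = TRUE`, and a `weights` vector per
#'   chromosome (NA at masked bins).  For a plain matrix: a list with
#'   `weights` and `balanced`.
#' @export
kr_balance <- function(cm, tol = 1e-8, max_iter = 200) {
  if (is.matrix(cm) || inherits(cm, "Matrix")) {
    w <- kr_weights(cm, tol = tol, max_iter = max_iter)
    return(list(weights = w,
                balanced = cm * tcrossprod(ifelse(is.na(w), 0, w))))
  }
  stopifnot(inherits(cm, "arcc_matrix"))
  for (ch in cm_chroms(cm)) {
    cc <- cm$chrom[[ch]]
    off_cov <- chrom_coverage(cc$trip[cc$trip$i != cc$trip$j, , drop = FALSE],
                              cc$n_bins)
    masked <- off_cov == 0
    A <- Matrix::sparseMatrix(i = cc$trip$i, j = cc$trip$j, x = cc$trip$x,
                              dims = c(cc$n_bins, cc$n_bins), symmetric = TRUE)
    w <- rep(NA_real_, cc$n_bins)
    if (any(!masked)) {
      sub <- as(A[!masked, !masked, drop = FALSE], "generalMatrix")
      w[!masked] <- kr_weights(sub, tol = tol, max_iter = max_iter)
    }
    keep <- !is.na(w[cc$trip$i]) & !is.na(w[cc$trip$j])
    trip <- cc$trip[keep, , drop = FALSE]
    trip$x <- trip$x * w[trip$i] * w[trip$j]
    cc$trip <- trip
    cc$weights <- w
    cc$masked <- masked | is.na(w)
    cm$chrom[[ch]] <- cc
  }
  cm$balanced <- TRUE
  cm
}
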