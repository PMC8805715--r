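#' Expression correlation of linked promoters
#'
#' Genes linked by promoter-promoter interactions tend to be
#' co-expressed across cell types.  These functions compute per-pair
#' Pearson correlations over an expression matrix (genes x cell types),
#' stratify pairs by expression variability (coefficient of variation),
#' and compare against distance-matched random gene pairs.
#'
#' @name arcc_expression
NULL

#' Coefficient of variation per gene
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids),
#'   cell types in columns.
#' @return named vector sd/mean per gene; NA where the mean is not
#'   positive.
#' @export
cv_expression <- function(expr) {
  m <- rowMeans(expr)
  s <- apply(expr, 1, sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  names(cv) <- rownames(expr)
  cv
}

#' Pearson correlation of linked gene pairs
#'
#' Pairs with a gene absent from the matrix are dropped (counted), as
#' are pairs involving a zero-variance gene.  When several candidate
#' gene pairs share a `link_id` (bidirectional promoters), the pair
#' with the highest correlation is retained.
#'
#' @param links data frame with `gene1`, `gene2` (optional `link_id`).
#' @param expr expression matrix (genes x cell types).
#' @return data frame `gene1`, `gene2`, `r` (plus `link_id` if given),
#'   with attributes `n_missing` and `n_zero_var`.
#' @export
linked_pair_correlations <- function(links, expr) {
  stopifnot(all(c("gene1", "gene2") %in% names(links)))
  present <- links$gene1 %in% rownames(expr) & links$gene2 %in% rownames(expr)
  n_missing <- sum(!present)
  links <- links[present, , drop = FALSE]
  v <- apply(expr, 1, sd)
  nzv <- v[links$gene1] > 0 & v[links$gene2] > 0
  n_zero_var <- sum(!nzv)
  links <- links[nzv, , drop = FALSE]
  r <- vapply(seq_len(nrow(links)), function(k)
    cor(expr[links$gene1[k], ], expr[links$gene2[k], ]), numeric(1))
  out <- cbind(links, r = r)
  if (!is.null(out$link_id)) {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$link_id),
                          function(ix) ix[which.max(out$r[ix])]))
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, n_missing = n_missing, n_zero_var = n_zero_var)
}

#' Stratify linked pairs by expression variability
#'
#' Genes are ranked by CV over all genes in the expression matrix; the
#' bottom `low_fraction` are "wide expression" (low CV), the
#' complementary top `1 - low_fraction` "regulated expression".  Ranks
#' are tie-broken by gene order, so the split is deterministic.
#'
#' @param pairs output of [linked_pair_correlations()].
#' @param expr expression matrix.
#' @param low_fraction bottom CV fraction (default 0.30).
#' @return list of pair subsets: `all`, `both_low` (both genes in the
#'   bottom fraction), `both_high` (both in the top complement).
#' @export
stratify_by_cv <- function(pairs, expr, low_fraction = 0.30) {
  cv <- cv_expression(expr)
  cv <- cv[!is.na(cv)]
  rk <- rank(cv, ties.method = "first")
  low <- names(cv)[rk <= top_n_of(length(cv), low_fraction)]
  is_low1 <- pairs$gene1 %in% low
  is_low2 <- pairs$gene2 %in% low
  known <- pairs$gene1 %in% names(cv) & pairs$gene2 %in% names(cv)
  list(all = pairs,
       both_low = pairs[known & is_low1 & is_low2, , drop = FALSE],
       both_high = pairs[known & !is_low1 & !is_low2, , drop = FALSE])
}

#' Distance-matched random control for linked-pair correlations
#'
#' Draws `n_sets` random gene-pair sets of the same size as the
#' observed set from the same gene universe, matching each observed
#' pair's distance stratum (log-spaced strata over the observed
#' distance range; strata without candidates are widened to their
#' neighbours with a message).  The difference in mean correlation is
#' tested with a two-sided t-test pooling the control draws.
#'
#' @param pairs observed pairs with `r` (from
#'   [linked_pair_correlations()]).
#' @param expr expression matrix.
#' @param gene_coords data frame `gene`, `chrom`, `tss` (5' end, used
#'   as the promoter-proxy anchor for pair distance).
#' @param n_sets number of control sets (default 1).
#' @param n_dist_strata log-spaced distance strata (default 20).
#' @param seed RNG seed.
#' @return list with `control_r`, `t_test`, `p`, observed and control
#'   mean correlations.
#' @export
matched_random_control <- function(pairs, expr, gene_coords, n_sets = 1,
                                   n_dist_strata = 20, seed = NULL) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(gene_coords)))
  genes <- intersect(rownames(expr), gene_coords$gene)
  gc <- gene_coords[match(genes, gene_coords$gene), , drop = FALSE]
  pos <- setNames(gc$tss, gc$gene)
  chr <- setNames(as.character(gc$chrom), gc$gene)
  ok <- pairs$gene1 %in% genes & pairs$gene2 %in% genes &
    chr[pairs$gene1] == chr[pairs$gene2]
  obs <- pairs[ok, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observed pairs with usable coordinates")
  d_obs <- abs(pos[obs$gene1] - pos[obs$gene2])
  edges <- exp(seq(log(max(min(d_obs), 1) * (1 - 1e-9)),
                   log(max(d_obs)), length.out = n_dist_strata + 1))
  strat_obs <- findInterval(d_obs, edges, rightmost.closed = TRUE,
                            all.inside = TRUE)
  # candidate same-chromosome gene pairs per stratum
  cand <- list()
  for (ch in unique(chr)) {
    g <- names(chr)[chr == ch]
    if (length(g) < 2) next
    p <- sort(pos[g])
    for (s in seq_len(n_dist_strata)) {
      lo <- findInterval(p + edges[s], p) + 1L
      hi <- findInterval(p + edges[s + 1], p)
      cnt <- pmax(hi - lo + 1L, 0L)
      if (sum(cnt) == 0) next
      i <- rep(seq_along(p), cnt)
      j <- unlist(lapply(which(cnt > 0), function(k) seq(lo[k], hi[k])))
      cand[[as.character(s)]] <- rbind(cand[[as.character(s)]],
                                       cbind(names(p)[i], names(p)[j]))
    }
  }
  with_seed(seed, {
    control_r <- replicate(n_sets, {
      g1 <- character(nrow(obs)); g2 <- character(nrow(obs))
      for (s in unique(strat_obs)) {
        rows <- which(strat_obs == s)
        pool <- cand[[as.character(s)]]
        widen <- 1
        while (is.null(pool) && widen <= n_dist_strata) {
          nb <- as.character(c(s - widen, s + widen))
          pool <- do.call(rbind, cand[nb[nb %in% names(cand)]])
          widen <- widen + 1
        }
        if (is.null(pool)) stop("no candidate pairs for distance stratum ", s)
        if (widen > 1) message("widened distance stratum ", s)
        take <- sample.int(nrow(pool), length(rows), replace = TRUE)
        g1[rows] <- pool[take, 1]; g2[rows] <- pool[take, 2]
      }
      vapply(seq_along(g1), function(k)
        suppressWarnings(cor(expr[g1[k], ], expr[g2[k], ])), numeric(1))
    })
    control_r <- as.numeric(control_r)
    control_r <- control_r[!is.na(control_r)]
    tt <- t.test(obs$r, control_r)
    list(observed_mean_r = mean(obs$r), control_mean_r = mean(control_r),
         control_r = control_r, t_test = tt, p = tt$p.value)
  })
}

#' Mark genes by signal threshold
#'
#' A gene is marked when its average signal exceeds `factor` times the
#' median signal over all genes.
#'
#' @param signal named numeric vector of per-gene mark signal.
#' @param factor multiple of the median required (default 1.5).
#' @return named logical vector.
#' @export
mark_genes_by_signal <- function(signal, factor = 1.5) {
  stopifnot(all(is.finite(signal)))
  signal > factor * median(signal)
}
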