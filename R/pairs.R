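#' Read-pair classification
#'
#' Paired-end alignment records are carried as a data frame with one row
#' per pair and columns `chrom1`, `pos1` (0-based 5' coordinate),
#' `strand1`, `mapq1`, `nm1` and the same for end 2 (`read_id` optional).
#' Classification assigns each pair exactly one label:
#' \describe{
#'   \item{discarded}{an end fails mapq/mismatch filters or overlaps the
#'     blacklist}
#'   \item{valid_noninformative}{same chromosome, ends within the
#'     informative distance (mostly unligated fragments)}
#'   \item{cis_informative}{same chromosome, ends strictly more than
#'     `informative_distance` bp apart}
#'   \item{trans_informative}{ends on different chromosomes}
#' }
#'
#' @param pairs pair table (see above).
#' @param chrom_sizes chromosome sizes of the assembly; unknown
#'   chromosomes in `pairs` are an error.
#' @param blacklist optional BED-like data frame of excluded regions;
#'   overlap is tested on the single 5' base of each end
#'   (`blacklist_mode = "point"`), or on `[pos, pos + len)` when the
#'   table carries `len1`/`len2` columns and `blacklist_mode = "span"`.
#' @param min_mapq minimum mapping quality per end (default 30).
#' @param max_mismatch maximum mismatch count per end (default 2).
#' @param informative_distance cis pairs must be strictly more than this
#'   many bp apart to count as informative (default 600).
#' @param blacklist_mode `"point"` or `"span"`.
#' @return list with `pairs` (input plus `label` column) and `stats`
#'   (an `arcc_pair_stats` list of label counts).
#' @export
classify_pairs <- function(pairs, chrom_sizes, blacklist = NULL,
                           min_mapq = 30, max_mismatch = 2,
                           informative_distance = 600,
                           blacklist_mode = c("point", "span")) {
  blacklist_mode <- match.arg(blacklist_mode)
  need <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  if (!all(need %in% names(pairs)))
    stop("unpaired or malformed input: need columns ",
         paste(need, collapse = ", "))
  if (nrow(pairs) > 0 && (anyNA(pairs$pos1) || anyNA(pairs$pos2)))
    stop("unpaired input: missing end coordinates")
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  for (col in c("chrom1", "chrom2")) {
    bad <- !pairs[[col]] %in% names(chrom_sizes)
    if (any(bad))
      stop("unknown chromosome: ",
           paste(unique(pairs[[col]][bad]), collapse = ", "))
  }
  n <- nrow(pairs)
  mapq1 <- if ("mapq1" %in% names(pairs)) pairs$mapq1 else rep(Inf, n)
  mapq2 <- if ("mapq2" %in% names(pairs)) pairs$mapq2 else rep(Inf, n)
  nm1 <- if ("nm1" %in% names(pairs)) pairs$nm1 else rep(0, n)
  nm2 <- if ("nm2" %in% names(pairs)) pairs$nm2 else rep(0, n)
  keep <- mapq1 >= min_mapq & mapq2 >= min_mapq &
    nm1 <= max_mismatch & nm2 <= max_mismatch
  if (!is.null(blacklist) && nrow(blacklist) > 0 && n > 0) {
    bl <- bed_to_gr(blacklist)
    in_bl <- function(chrom, pos, len) {
      end1 <- if (blacklist_mode == "span") pos + len else pos + 1
      gr <- GenomicRanges::GRanges(chrom,
              IRanges::IRanges(start = pos + 1, end = end1))
      GenomicRanges::countOverlaps(gr, bl) > 0
    }
    len1 <- if ("len1" %in% names(pairs)) pairs$len1 else rep(1, n)
    len2 <- if ("len2" %in% names(pairs)) pairs$len2 else rep(1, n)
    keep <- keep & !in_bl(pairs$chrom1, pairs$pos1, len1) &
      !in_bl(pairs$chrom2, pairs$pos2, len2)
  }
  label <- rep("discarded", n)
  same <- pairs$chrom1 == pairs$chrom2
  d <- abs(pairs$pos1 - pairs$pos2)
  label[keep & !same] <- "trans_informative"
  label[keep & same & d > informative_distance] <- "cis_informative"
  label[keep & same & d <= informative_distance] <- "valid_noninformative"
  pairs$label <- label
  list(pairs = pairs, stats = pair_stats(label, n))
}

#' Tabulate pair classification labels
#'
#' @param label character vector of pair labels.
#' @param n_input number of input pairs.
#' @return an `arcc_pair_stats` list of per-label counts.
#' @export
pair_stats <- function(label, n_input) {
  lv <- c("discarded", "duplicate", "valid_noninformative",
          "cis_informative", "trans_informative")
  counts <- table(factor(label, levels = lv))
  structure(list(n_input = n_input, counts = as.list(counts)),
            class = "arcc_pair_stats")
}

#' @export
print.arcc_pair_stats <- function(x, ...) {
  cat("Pair classification of", x$n_input, "read pairs:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Remove PCR duplicates
#'
#' Pairs sharing identical (chrom, pos, strand) on both ends, after
#' ordering the two ends canonically by (chrom, pos, strand), are
#' duplicates: the first occurrence keeps its label, the rest are
#' relabelled `"duplicate"`.  Pairs already labelled `"discarded"` are
#' ignored by the keying.
#'
#' @param pairs labelled pair table (from [classify_pairs()]).
#' @return the pair table with duplicates relabelled.
#' @export
deduplicate <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  if (is.null(pairs$label)) pairs$label <- "valid_noninformative"
  flip <- pairs$chrom2 < pairs$chrom1 |
    (pairs$chrom2 == pairs$chrom1 & pairs$pos2 < pairs$pos1) |
    (pairs$chrom2 == pairs$chrom1 & pairs$pos2 == pairs$pos1 &
       pairs$strand2 < pairs$strand1)
  c1 <- ifelse(flip, pairs$chrom2, pairs$chrom1)
  p1 <- ifelse(flip, pairs$pos2, pairs$pos1)
  s1 <- ifelse(flip, pairs$strand2, pairs$strand1)
  c2 <- ifelse(flip, pairs$chrom1, pairs$chrom2)
  p2 <- ifelse(flip, pairs$pos1, pairs$pos2)
  s2 <- ifelse(flip, pairs$strand1, pairs$strand2)
  key <- paste(c1, p1, s1, c2, p2, s2, sep = "\r")
  consider <- pairs$label != "discarded"
  dup <- rep(FALSE, nrow(pairs))
  dup[consider] <- duplicated(key[consider])
  pairs$label[dup] <- "duplicate"
  pairs
}

#' Orientation of end alignments as a function of distance
#'
#' For same-chromosome pairs, the two ends are ordered by coordinate and
#' the strand configuration (FF, FR, RF, RR) is tabulated per distance
#' stratum.  The fraction of each configuration should sit near 25\%
#' beyond the informative-distance threshold if pairs arise from
#' ligation; short-range unligated fragments are overwhelmingly FR.
#'
#' @param pairs pair table (same-chromosome pairs only are used).
#' @param distance_edges increasing vector of stratum boundaries in bp;
#'   strata are `[e_k, e_{k+1})`.
#' @return data frame with one row per stratum: `n` and the four
#'   orientation fractions (NA, not 0, for empty strata).
#' @export
orientation_profile <- function(pairs, distance_edges) {
  stopifnot(length(distance_edges) >= 2, !is.unsorted(distance_edges))
  cis <- pairs[pairs$chrom1 == pairs$chrom2, , drop = FALSE]
  d <- abs(cis$pos1 - cis$pos2)
  first_is_1 <- cis$pos1 <= cis$pos2
  s_first <- ifelse(first_is_1, cis$strand1, cis$strand2)
  s_second <- ifelse(first_is_1, cis$strand2, cis$strand1)
  conf <- paste0(ifelse(s_first == "+", "F", "R"),
                 ifelse(s_second == "+", "F", "R"))
  stratum <- cut(d, breaks = distance_edges, right = FALSE)
  tab <- table(stratum, factor(conf, levels = c("FF", "FR", "RF", "RR")))
  n <- rowSums(tab)
  frac <- sweep(tab, 1, n, "/")
  frac[n == 0, ] <- NA_real_
  out <- data.frame(stratum = rownames(tab), n = as.integer(n),
                    FF = frac[, "FF"], FR = frac[, "FR"],
                    RF = frac[, "RF"], RR = frac[, "RR"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
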