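#' Read a pairs-like TSV
#'
#' Tab-delimited pair tables in the 4DN style: columns `read_id`,
#' `chrom1`, `pos1`, `chrom2`, `pos2`, `strand1`, `strand2`, plus
#' optional `mapq1`, `mapq2`, `nm1`, `nm2`.  Lines starting with `#`
#' are headers/comments.
#'
#' @param path file path.
#' @return pair data frame.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2")
  if (!all(need %in% names(df)))
    stop("pairs file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Write a pairs table as TSV
#' @param pairs pair data frame.
#' @param path output path.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read paired alignments from a name-sorted SAM/BAM file
#'
#' Requires the Rsamtools package.  Mate pairs are joined on read name;
#' the 5' mapped coordinate of each end is reported 0-based, and the NM
#' tag (if present) gives the mismatch count.
#'
#' @param path SAM or BAM path.
#' @return pair data frame as accepted by [classify_pairs()].
#' @export
read_pairs_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading SAM/BAM requires the Rsamtools package")
  if (grepl("\\.sam$", path)) {
    path <- Rsamtools::asBam(path,
      destination = tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq", "qwidth"),
    tag = "NM")
  x <- Rsamtools::scanBam(path, param = prm)[[1]]
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(0L, length(x$qname))
  aln <- data.frame(qname = x$qname, flag = x$flag,
                    chrom = as.character(x$rname),
                    strand = as.character(x$strand),
                    mapq = x$mapq, nm = nm,
                    qwidth = x$qwidth, pos1based = x$pos,
                    stringsAsFactors = FALSE)
  aln <- aln[!is.na(aln$pos1based), , drop = FALSE]
  # 5' mapped coordinate, 0-based
  aln$pos <- ifelse(aln$strand == "-",
                    aln$pos1based + aln$qwidth - 2L, aln$pos1based - 1L)
  first <- bitwAnd(aln$flag, 64L) > 0
  a <- aln[first, , drop = FALSE]
  b <- aln[!first, , drop = FALSE]
  m <- match(a$qname, b$qname)
  if (anyNA(m)) stop("unpaired input: mate missing for some reads")
  data.frame(read_id = a$qname,
             chrom1 = a$chrom, pos1 = a$pos, strand1 = a$strand,
             mapq1 = a$mapq, nm1 = a$nm, len1 = a$qwidth,
             chrom2 = b$chrom[m], pos2 = b$pos[m], strand2 = b$strand[m],
             mapq2 = b$mapq[m], nm2 = b$nm[m], len2 = b$qwidth[m],
             stringsAsFactors = FALSE)
}

#' Read a BED3+ file
#' @param path file path; columns beyond the third are kept as `name`,
#'   `score`, ... when present.
#' @return BED-like data frame (0-based half-open).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("malformed BED: fewer than 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  check_bed(df)
}

#' Write intervals as BED
#' @param x BED-like data frame; extra columns appended after the
#'   first three.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  x <- check_bed(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom.sizes table
#' @param path two-column TSV (chrom, size).
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_chrom_sizes(data.frame(chrom = df[[1]], size = df[[2]]))
}

#' Export a contact matrix as triplet TSV plus binning BED
#'
#' @param cm an `arcc_matrix`.
#' @param prefix output path prefix; writes `<prefix>.triplets.tsv`
#'   (bin_id1, bin_id2, value; global upper-triangle ids) and
#'   `<prefix>.bins.bed` (BED4, name = `RE`/`bin` flag).
#' @return invisibly, the two paths.
#' @export
write_matrix_tsv <- function(cm, prefix) {
  trips <- do.call(rbind, lapply(cm_chroms(cm), function(ch) {
    cc <- cm$chrom[[ch]]
    data.frame(bin_id1 = cc$trip$i + cc$offset,
               bin_id2 = cc$trip$j + cc$offset, value = cc$trip$x)
  }))
  tpath <- paste0(prefix, ".triplets.tsv")
  bpath <- paste0(prefix, ".bins.bed")
  utils::write.table(trips, tpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  b <- cm$bins
  write_bed(data.frame(chrom = b$chrom, start = b$start, end = b$end,
                       name = ifelse(b$is_regulatory, "RE", "bin")),
            bpath)
  invisible(c(tpath, bpath))
}

#' Read a contact matrix from triplet TSV plus binning BED
#' @param prefix path prefix used by [write_matrix_tsv()].
#' @param chrom_sizes chromosome sizes of the assembly.
#' @return an `arcc_matrix` (raw-count semantics).
#' @export
read_matrix_tsv <- function(prefix, chrom_sizes) {
  bed <- read_bed(paste0(prefix, ".bins.bed"))
  bed$is_regulatory <- !is.null(bed$name) & bed$name == "RE"
  bins <- new_bins(bed[, c("chrom", "start", "end", "is_regulatory")],
                   as_chrom_sizes(chrom_sizes))
  trips <- utils::read.table(paste0(prefix, ".triplets.tsv"),
                             header = TRUE, sep = "\t")
  cm <- contact_matrix(data.frame(chrom1 = character(0), pos1 = numeric(0),
                                  chrom2 = character(0), pos2 = numeric(0)),
                       bins)
  for (ch in cm_chroms(cm)) {
    cc <- cm$chrom[[ch]]
    ids <- bins$id[bins$chrom == ch]
    sel <- trips$bin_id1 %in% ids
    cc$trip <- data.frame(i = trips$bin_id1[sel] - cc$offset,
                          j = trips$bin_id2[sel] - cc$offset,
                          x = trips$value[sel])
    cc$N <- sum(cc$trip$x)
    cc$coverage <- chrom_coverage(cc$trip, cc$n_bins)
    cm$chrom[[ch]] <- cc
  }
  cm
}

#' Write classification statistics as JSON
#' @param stats an `arcc_pair_stats` object.
#' @param path output path.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(list(n_input = stats$n_input, counts = stats$counts),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
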