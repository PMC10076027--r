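as_dna_set <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(Biostrings::DNAStringSet(genome))
  }
  stop("genome must be a named character vector or a DNAStringSet")
}

# integer base codes 1..4 (A,C,G,T); anything else (N, ambiguity) -> NA
BASE_CODE_TABLE <- local({
  tbl <- rep(NA_integer_, 256L)
  tbl[utf8ToInt("A")] <- 1L; tbl[utf8ToInt("a")] <- 1L
  tbl[utf8ToInt("C")] <- 2L; tbl[utf8ToInt("c")] <- 2L
  tbl[utf8ToInt("G")] <- 3L; tbl[utf8ToInt("g")] <- 3L
  tbl[utf8ToInt("T")] <- 4L; tbl[utf8ToInt("t")] <- 4L
  tbl
})

seq_codes <- function(seq) {
  BASE_CODE_TABLE[utf8ToInt(as.character(seq))]
}

# lattice scores of every window of width k, for one or two weight
# matrices at once (shares the window subsets); windows touching NA
# codes -> NA
window_lattice_scores <- function(codes, iw, iw2 = NULL) {
  k <- nrow(iw)
  n <- length(codes) - k + 1L
  if (n < 1L) {
    return(list(integer(0), if (!is.null(iw2)) integer(0)))
  }
  win <- codes[seq_len(n)]
  s <- iw[1L, ][win]
  s2 <- if (!is.null(iw2)) iw2[1L, ][win]
  if (k > 1L) {
    for (i in 2:k) {
      win <- codes[i:(n + i - 1L)]
      s <- s + iw[i, ][win]
      if (!is.null(iw2)) s2 <- s2 + iw2[i, ][win]
    }
  }
  list(s, s2)
}

#' Scan genome sequences for motif matches below an ln(P) threshold
#'
#' Slides a motif matrix across every offset of every sequence, on one or
#' both strands, and reports windows whose ln(P) passes the threshold.
#' Minus-strand matches are scored by the reverse-complement matrix under
#' the complement-swapped background, which gives the exact p-value of
#' the reverse-complement word under the original matrix. Windows
#' containing non-ACGT characters are skipped silently; their count is
#' attached as the `skipped_windows` attribute.
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet`.
#' @param matrix A [motif_matrix()].
#' @param threshold ln(P) cutoff (non-positive). Hits with
#'   `ln_p <= threshold` are reported (`strict = TRUE` for `<`).
#' @param strands `"both"` (default) or `"forward"`.
#' @param collapse When both strands pass at one offset, report only the
#'   better (more negative ln(P)) strand (default `TRUE`); ties go to
#'   `"+"`. Set `FALSE` to report both.
#' @param strict Use a strict `<` comparison instead of inclusive `<=`.
#' @param granularity Score lattice step (default 1e-4). Scans use a
#'   coarser lattice than the 1e-5 point-query default of [ln_p()]: the
#'   residual ln(P) discretisation (~0.02 worst case) is negligible
#'   against any practical scan threshold, and the distribution builds
#'   an order of magnitude faster.
#' @return A data.frame of hits with columns `chrom`, `start` (0-based),
#'   `end` (exclusive), `strand`, `score`, `ln_p` and `motif`, sorted by
#'   (chrom, start).
#' @export
scan_genome <- function(genome, matrix, threshold, strands = c("both", "forward"),
                        collapse = TRUE, strict = FALSE, granularity = 1e-4) {
  strands <- match.arg(strands)
  genome <- as_dna_set(genome)
  if (length(genome) == 0L) stop("genome is empty")
  if (threshold > 0) stop("threshold must be a non-positive ln(P)")
  k <- matrix$length
  dist_f <- score_distribution(matrix, granularity)
  log_surv_f <- log(dist_f$survival)
  if (strands == "both") {
    rc <- reverse_complement_matrix(matrix)
    dist_r <- score_distribution(rc, granularity)
    log_surv_r <- log(dist_r$survival)
  }
  pass <- if (strict) function(lp) lp < threshold else function(lp) lp <= threshold
  skipped <- 0L
  res <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[[ci]]
    codes <- seq_codes(genome[[ci]])
    if (length(codes) < k) next
    sc <- window_lattice_scores(codes, dist_f$iw,
                                if (strands == "both") dist_r$iw)
    sf <- sc[[1L]]
    skipped <- skipped + sum(is.na(sf))
    lp_f <- rep(NA_real_, length(sf))
    ok <- !is.na(sf)
    lp_f[ok] <- log_surv_f[sf[ok] - dist_f$origin + 1L]
    hit_f <- ok & pass(lp_f)
    if (strands == "both") {
      sr <- sc[[2L]]
      lp_r <- rep(NA_real_, length(sr))
      lp_r[ok] <- log_surv_r[sr[ok] - dist_r$origin + 1L]
      hit_r <- ok & pass(lp_r)
      if (collapse) {
        both <- hit_f & hit_r
        # keep the better strand; ties -> "+"
        hit_r[both & lp_f <= lp_r] <- FALSE
        hit_f[both & lp_r < lp_f] <- FALSE
      }
    }
    rows <- list()
    if (any(hit_f)) {
      o <- which(hit_f)
      rows$f <- data.frame(chrom = chrom, start = o - 1L, end = o - 1L + k,
                           strand = "+",
                           score = sf[o] * granularity, ln_p = lp_f[o],
                           stringsAsFactors = FALSE)
    }
    if (strands == "both" && any(hit_r)) {
      o <- which(hit_r)
      rows$r <- data.frame(chrom = chrom, start = o - 1L, end = o - 1L + k,
                           strand = "-",
                           score = sr[o] * granularity, ln_p = lp_r[o],
                           stringsAsFactors = FALSE)
    }
    if (length(rows) > 0L) res[[ci]] <- do.call(rbind, rows)
  }
  hits <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(hits)) {
    hits <- data.frame(chrom = character(), start = integer(), end = integer(),
                       strand = character(), score = numeric(), ln_p = numeric(),
                       stringsAsFactors = FALSE)
  }
  hits$motif <- rep(matrix$id, nrow(hits))
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "threshold") <- threshold
  attr(hits, "skipped_windows") <- skipped
  hits
}

#' Cumulative motif counts per chromosome along a threshold grid
#'
#' For each threshold t the count is the number of hits with
#' `ln_p <= t`; counts are therefore non-increasing as t becomes more
#' negative (nesting).
#'
#' @param hits A hit data.frame from [scan_genome()].
#' @param thresholds Numeric ln(P) grid, sorted (any direction).
#' @return A data.frame with columns `threshold`, `chrom`, `count`, one
#'   row per (threshold, chromosome present in `hits`).
#' @export
count_by_threshold <- function(hits, thresholds) {
  if (is.unsorted(thresholds) && is.unsorted(rev(thresholds))) {
    stop("thresholds must be sorted")
  }
  chroms <- unique(hits$chrom)
  if (length(chroms) == 0L) chroms <- character(0)
  grid <- expand.grid(threshold = thresholds, chrom = chroms,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) {
    return(data.frame(threshold = thresholds,
                      chrom = rep(NA_character_, length(thresholds)),
                      count = 0L))
  }
  grid$count <- mapply(function(t, ch) {
    sum(hits$chrom == ch & hits$ln_p <= t)
  }, grid$threshold, grid$chrom)
  grid
}

#' Write motif hits to BED6 (plus a full-precision TSV)
#'
#' BED columns: chrom, start, end, name (motif id), score (ln(P) rounded
#' to 2 dp), strand. A sibling `.tsv` with full precision is written
#' when `tsv = TRUE`.
#'
#' @param hits Hit data.frame from [scan_genome()].
#' @param path Output BED path.
#' @param tsv Also write `<path>.tsv` with full-precision scores.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, tsv = TRUE) {
  bed <- data.frame(hits$chrom, hits$start, hits$end, hits$motif,
                    round(hits$ln_p, 2L), hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (tsv) {
    utils::write.table(hits, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read motif hits from the full-precision TSV written by [write_hits_bed()]
#'
#' @param path Path to the hits TSV.
#' @return A hit data.frame.
#' @export
read_hits_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
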