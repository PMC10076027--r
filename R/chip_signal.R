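#' Construct a binned signal track
#'
#' A fixed-step, per-chromosome coverage track. Bins are half-open
#' `[start, start + bin_size)` with 0-based starts that are multiples of
#' `bin_size`.
#'
#' @param chrom Character vector of chromosome names, one per bin.
#' @param start Integer vector of 0-based bin starts.
#' @param value Numeric signal per bin (e.g. RPKM); must be >= 0.
#' @param bin_size Bin width in bp.
#' @param total_mapped_reads Library size the values were normalised to
#'   (optional bookkeeping).
#' @return A data.frame of class `signal_track` with attributes
#'   `bin_size` and `total_mapped_reads`.
#' @export
signal_track <- function(chrom, start, value, bin_size,
                         total_mapped_reads = NA_real_) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (any(value < 0)) stop("signal values must be >= 0")
  if (any(start %% bin_size != 0)) {
    stop("bin starts must be multiples of bin_size")
  }
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  if (anyDuplicated(df[, c("chrom", "start")])) {
    stop("overlapping/duplicate bins in track")
  }
  rownames(df) <- NULL
  structure(df, bin_size = as.integer(bin_size),
            total_mapped_reads = total_mapped_reads,
            class = c("signal_track", "data.frame"))
}

#' RPKM-normalise binned read counts
#'
#' RPKM = count / ((bin_size / 1000) * (total_mapped_reads / 1e6)):
#' reads per kilobase of bin per million mapped reads. Scale-invariant
#' under joint doubling of counts and library size.
#'
#' @param bin_counts Either a numeric vector of per-bin read counts (in
#'   which case `chrom` and `start` locate the bins) or a data.frame
#'   with columns `chrom`, `start`, `count`.
#' @param total_mapped_reads Total uniquely mapped reads (> 0).
#' @param bin_size Bin width in bp.
#' @param chrom,start Bin locations when `bin_counts` is a bare vector.
#' @return A [signal_track()] of RPKM values.
#' @export
rpkm_normalize <- function(bin_counts, total_mapped_reads, bin_size,
                           chrom = NULL, start = NULL) {
  if (is.data.frame(bin_counts)) {
    chrom <- bin_counts$chrom
    start <- bin_counts$start
    counts <- bin_counts$count
  } else {
    counts <- bin_counts
    if (is.null(chrom)) chrom <- rep("chr", length(counts))
    if (is.null(start)) start <- (seq_along(counts) - 1L) * bin_size
  }
  if (is.na(total_mapped_reads) || total_mapped_reads <= 0) {
    stop("total_mapped_reads must be > 0")
  }
  rpkm <- counts / ((bin_size / 1000) * (total_mapped_reads / 1e6))
  signal_track(chrom, start, rpkm, bin_size, total_mapped_reads)
}

#' Read a coverage track from bedGraph or fixed-step wiggle
#'
#' Uses rtracklayer for parsing. Intervals that do not sit on a uniform
#' `bin_size` grid are re-binned by length-weighted averaging onto the
#' requested grid.
#'
#' @param path Path to a bedGraph (`.bedgraph`/`.bg`) or wiggle file.
#' @param bin_size Target bin width; defaults to the (uniform) width
#'   found in the file, error if the file is irregular and no `bin_size`
#'   is given.
#' @param total_mapped_reads Optional library-size bookkeeping.
#' @return A [signal_track()].
#' @export
read_signal_track <- function(path, bin_size = NULL,
                              total_mapped_reads = NA_real_) {
  fmt <- if (grepl("\\.(wig|wiggle)$", path, ignore.case = TRUE)) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  w <- GenomicRanges::width(gr)
  st <- GenomicRanges::start(gr) - 1L  # to 0-based
  ch <- as.character(GenomicRanges::seqnames(gr))
  sc <- as.numeric(S4Vectors::mcols(gr)$score)
  uniform <- length(unique(w)) == 1L && all(st %% w[[1L]] == 0L)
  if (is.null(bin_size)) {
    if (!uniform) {
      stop("track bins are not on a uniform grid; supply `bin_size` to re-bin")
    }
    bin_size <- w[[1L]]
  }
  if (uniform && w[[1L]] == bin_size) {
    return(signal_track(ch, st, sc, bin_size, total_mapped_reads))
  }
  rebin_track(ch, st, st + w, sc, bin_size, total_mapped_reads)
}

# length-weighted averaging of arbitrary intervals onto a fixed grid
rebin_track <- function(chrom, start, end, value, bin_size,
                        total_mapped_reads = NA_real_) {
  out <- list()
  for (ch in unique(chrom)) {
    i <- chrom == ch
    s <- start[i]; e <- end[i]; v <- value[i]
    last <- max(e)
    nb <- ceiling(last / bin_size)
    wsum <- numeric(nb)
    vsum <- numeric(nb)
    for (j in seq_along(s)) {
      b0 <- s[[j]] %/% bin_size
      b1 <- (e[[j]] - 1L) %/% bin_size
      for (b in b0:b1) {
        ov <- min(e[[j]], (b + 1) * bin_size) - max(s[[j]], b * bin_size)
        wsum[[b + 1L]] <- wsum[[b + 1L]] + ov
        vsum[[b + 1L]] <- vsum[[b + 1L]] + ov * v[[j]]
      }
    }
    keep <- wsum > 0
    out[[ch]] <- data.frame(chrom = ch,
                            start = (which(keep) - 1L) * bin_size,
                            value = vsum[keep] / wsum[keep])
  }
  df <- do.call(rbind, out)
  signal_track(df$chrom, df$start, df$value, bin_size, total_mapped_reads)
}

#' Write a signal track as bedGraph
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  bs <- attr(track, "bin_size")
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L,
                                                track$start + bs))
  S4Vectors::mcols(gr)$score <- track$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Call occupancy peaks by simple thresholding
#'
#' Maximal runs of bins with value >= `threshold_rpkm`, merged across
#' gaps of at most `merge_gap` bp, discarded when narrower than
#' `min_width`. The summit is the start of the maximum bin (leftmost on
#' ties).
#'
#' @param track A [signal_track()].
#' @param threshold_rpkm Calling threshold (> 0).
#' @param min_width Minimum peak width in bp.
#' @param merge_gap Merge runs separated by at most this many bp.
#' @return A data.frame with columns `peak`, `chrom`, `start`, `end`
#'   (0-based half-open), `summit`, `max_rpkm`.
#' @export
call_peaks <- function(track, threshold_rpkm, min_width = 0L, merge_gap = 0L) {
  if (threshold_rpkm <= 0) stop("threshold_rpkm must be > 0")
  bs <- attr(track, "bin_size")
  peaks <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    hot <- sub$start[sub$value >= threshold_rpkm]
    if (length(hot) == 0L) next
    hot <- sort(hot)
    # runs of threshold-passing bins, merging gaps <= merge_gap bp
    brk <- which(diff(hot) > bs + merge_gap)
    run_start <- hot[c(1L, brk + 1L)]
    run_end <- hot[c(brk, length(hot))] + bs
    for (r in seq_along(run_start)) {
      if (run_end[[r]] - run_start[[r]] < min_width) next
      inside <- sub$start >= run_start[[r]] & sub$start < run_end[[r]]
      vmax <- max(sub$value[inside])
      summit <- min(sub$start[inside][sub$value[inside] == vmax])
      peaks[[length(peaks) + 1L]] <-
        data.frame(chrom = ch, start = run_start[[r]], end = run_end[[r]],
                   summit = summit, max_rpkm = vmax)
    }
  }
  if (length(peaks) == 0L) {
    return(data.frame(peak = character(), chrom = character(),
                      start = integer(), end = integer(),
                      summit = integer(), max_rpkm = numeric()))
  }
  out <- do.call(rbind, peaks)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(peak = paste0("peak_", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

# fast per-position lookup of track values: position -> containing bin value
track_lookup <- function(track) {
  bs <- attr(track, "bin_size")
  env <- new.env(parent = emptyenv())
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    vec <- rep(NA_real_, max(sub$start) / bs + 1L)
    vec[sub$start / bs + 1L] <- sub$value
    assign(ch, vec, envir = env)
  }
  function(chrom, pos) {
    vec <- if (exists(chrom, envir = env)) get(chrom, envir = env) else numeric(0)
    idx <- pos %/% bs + 1L
    out <- rep(NA_real_, length(pos))
    ok <- pos >= 0L & idx <= length(vec)
    out[ok] <- vec[idx[ok]]
    out
  }
}

#' Motif-anchored meta-profile of a signal track
#'
#' Averages the track around the midpoints of anchor intervals, per
#' group, reporting the mean, standard error (sample SD / sqrt(n)) and
#' number of contributing anchors at each signed offset. Anchors close
#' to chromosome ends contribute only their in-range offsets. A group
#' with zero anchors is omitted with a warning.
#'
#' @param track A [signal_track()].
#' @param anchors Hit data.frame (needs `chrom`, `start`, `end`).
#' @param groups Character/factor vector of group labels per anchor
#'   (default one group `"all"`).
#' @param half_window Half-width of the profile in bp; must be a
#'   multiple of `profile_bin`.
#' @param profile_bin Offset step in bp.
#' @return A data.frame with columns `group`, `offset`, `mean`, `se`,
#'   `n`. `se` is 0 where n = 1.
#' @export
meta_profile <- function(track, anchors, groups = NULL,
                         half_window = 5000L, profile_bin = 50L) {
  if (half_window %% profile_bin != 0) {
    stop("half_window must be a multiple of profile_bin")
  }
  if (is.null(groups)) groups <- rep("all", nrow(anchors))
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(anchors))
  lookup <- track_lookup(track)
  offsets <- seq(-half_window, half_window, by = profile_bin)
  mids <- as.integer(floor((anchors$start + anchors$end) / 2))
  out <- list()
  for (g in unique(groups)) {
    gi <- which(groups == g)
    if (length(gi) == 0L) {
      warning("group '", g, "' has no anchors; omitted")
      next
    }
    # rows = anchors, cols = offsets
    vals <- vapply(offsets, function(off) {
      lookup_many(lookup, anchors$chrom[gi], mids[gi] + off)
    }, numeric(length(gi)))
    if (length(gi) == 1L) vals <- matrix(vals, nrow = 1L)
    n <- colSums(!is.na(vals))
    mu <- colMeans(vals, na.rm = TRUE)
    sdv <- apply(vals, 2L, stats::sd, na.rm = TRUE)
    se <- ifelse(n > 1L, sdv / sqrt(n), 0)
    keep <- n >= 1L
    out[[g]] <- data.frame(group = g, offset = offsets[keep],
                           mean = mu[keep], se = se[keep], n = n[keep])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

lookup_many <- function(lookup, chroms, pos) {
  out <- numeric(length(pos))
  for (ch in unique(chroms)) {
    i <- chroms == ch
    out[i] <- lookup(ch, pos[i])
  }
  out
}

#' Classify anchors as inside or outside rex-site peaks
#'
#' An anchor is `"in-rex"` iff its interval overlaps any peak interval
#' by at least 1 bp.
#'
#' @param anchors Hit data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param peaks Peak data.frame from [call_peaks()] (same convention).
#' @return Character vector `"in-rex"` / `"not-in-rex"`, one per anchor.
#' @export
assign_rex_membership <- function(anchors, peaks) {
  if (nrow(anchors) == 0L) return(character(0))
  if (nrow(peaks) == 0L) return(rep("not-in-rex", nrow(anchors)))
  a <- GenomicRanges::GRanges(anchors$chrom,
                              IRanges::IRanges(anchors$start + 1L, anchors$end))
  p <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$start + 1L, peaks$end))
  hit <- GenomicRanges::countOverlaps(a, p, minoverlap = 1L) > 0L
  ifelse(hit, "in-rex", "not-in-rex")
}

#' Annotate rex-site peaks with their motifs and inter-motif spacing
#'
#' For each peak, lists the overlapping thresholded motif hits in
#' positional order with their ln(P) and strand, and the gaps between
#' adjacent motifs (start of next minus end of previous, in bp). Peaks
#' without any motif are still listed, with an empty motif list.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param hits A hit data.frame, or a named list of hit data.frames (one
#'   per motif matrix) which are concatenated.
#' @return A data.frame with one row per peak: `peak`, `chrom`, `start`,
#'   `end`, `summit`, `max_rpkm`, `n_motifs`, `motifs` (comma-separated
#'   `id[ln_p](strand)` entries) and `gaps_bp`. The per-motif long table
#'   is attached as attribute `"motif_table"`.
#' @export
annotate_rex <- function(peaks, hits) {
  if (is.list(hits) && !is.data.frame(hits)) {
    hits <- do.call(rbind, hits)
  }
  rows <- list()
  long <- list()
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    sel <- hits$chrom == pk$chrom & hits$start < pk$end & hits$end > pk$start
    m <- hits[sel, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    gaps <- if (nrow(m) > 1L) m$start[-1L] - m$end[-nrow(m)] else integer(0)
    rows[[i]] <- data.frame(
      peak = pk$peak, chrom = pk$chrom, start = pk$start, end = pk$end,
      summit = pk$summit, max_rpkm = pk$max_rpkm, n_motifs = nrow(m),
      motifs = paste(sprintf("%s[%.2f](%s)", m$motif, m$ln_p, m$strand),
                     collapse = ","),
      gaps_bp = paste(gaps, collapse = ","))
    if (nrow(m) > 0L) {
      m$peak <- pk$peak
      m$gap_to_next <- c(gaps, NA_integer_)
      long[[length(long) + 1L]] <- m
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "motif_table") <- if (length(long) > 0L) {
    do.call(rbind, long)
  } else {
    hits[0, , drop = FALSE]
  }
  out
}

#' Extract summit-centred sequence windows for motif discovery
#'
#' One record per peak, centred on the summit, clipped to chromosome
#' bounds (clipped windows are flagged in the `clipped` attribute).
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param genome Named character vector or `DNAStringSet`.
#' @param width Window width in bp (default 500).
#' @param path Optional FASTA output path.
#' @return A `DNAStringSet` named `peak|chrom:start-end` (0-based
#'   half-open coordinates in the name).
#' @export
discovery_windows <- function(peaks, genome, width = 500L, path = NULL) {
  genome <- as_dna_set(genome)
  seqs <- character(nrow(peaks))
  nms <- character(nrow(peaks))
  clipped <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    if (!pk$chrom %in% names(genome)) {
      stop("peak chromosome not in genome: ", pk$chrom)
    }
    L <- Biostrings::width(genome)[[match(pk$chrom, names(genome))]]
    if (pk$summit < 0 || pk$summit >= L) {
      stop("summit outside chromosome bounds for peak ", pk$peak)
    }
    half <- width %/% 2L
    s <- max(0L, pk$summit - half)
    e <- min(L, pk$summit + (width - half))
    clipped[[i]] <- (e - s) < width
    seqs[[i]] <- toupper(as.character(Biostrings::subseq(genome[[pk$chrom]],
                                                         s + 1L, e)))
    nms[[i]] <- sprintf("%s|%s:%d-%d", pk$peak, pk$chrom, s, e)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nms
  attr(out, "clipped") <- clipped
  if (!is.null(path)) Biostrings::writeXStringSet(out, path)
  out
}
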