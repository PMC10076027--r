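#' Default planted-motif matrix for simulations
#'
#' A sharp 13 bp matrix around a MEX-like consensus carrying the CAGGG
#' core (97 consensus counts and 1 count for each alternative base per
#' position, 100 sites). Its information content puts the consensus
#' ln(P) near -18, comparable to a strong X-enriched recruitment motif,
#' so planted instances separate cleanly from background matches.
#'
#' @param consensus Consensus word (default `"TGGGCAGGGAAGG"`).
#' @param background Background probabilities for the weight rule.
#' @return A [motif_matrix()].
#' @export
default_sim_matrix <- function(consensus = "TGGGCAGGGAAGG",
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25)) {
  idx <- match(strsplit(consensus, "", fixed = TRUE)[[1L]], DNA_BASES)
  counts <- matrix(1, nrow = length(idx), ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  counts[cbind(seq_along(idx), idx)] <- 97
  motif_from_counts(counts, background = background, id = "simMEX")
}

#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic-genome generator:
#' chromosome layout (an X class versus pooled autosomes), background
#' base composition, the planted motif matrix, per-class planting
#' densities, and the rex-site clustering specification.
#'
#' Default chromosome sizes are desk-scale (X 2 Mb, two autosomes of
#' 2 Mb each); default densities (X 1500 motifs/Mb versus autosome
#' 125/Mb, a 12:1 per-bp ratio) are sized so the X and autosome hit
#' counts make the X:A density ratio estimable to a few percent from a
#' single genome.
#'
#' @param seed Integer seed; every generator call is a pure function of
#'   (config, seed).
#' @param chroms Data.frame with columns `name`, `class`
#'   (`"X"`/`"autosome"`), `length` (bp).
#' @param background Background base probabilities.
#' @param matrix Planted [motif_matrix()].
#' @param x_density_per_mb,a_density_per_mb Planted motifs per Mb on the
#'   X class and the autosome class.
#' @param n_rex Number of rex-like clustered sites planted on X.
#' @param rex_motifs Range (length-2 integer) of motifs per rex site.
#' @param rex_gap Range (length-2 integer) of inter-motif gaps within a
#'   rex site, in bp.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chroms = data.frame(
                         name = c("chrX", "chrI", "chrII"),
                         class = c("X", "autosome", "autosome"),
                         length = c(2e6, 2e6, 2e6)),
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       matrix = default_sim_matrix(),
                       x_density_per_mb = 1500,
                       a_density_per_mb = 125,
                       n_rex = 12L,
                       rex_motifs = c(1L, 4L),
                       rex_gap = c(20L, 120L)) {
  stopifnot(all(c("name", "class", "length") %in% names(chroms)))
  if (any(!chroms$class %in% c("X", "autosome"))) {
    stop("chromosome class must be 'X' or 'autosome'")
  }
  if (x_density_per_mb < 0 || a_density_per_mb < 0) {
    stop("planting densities must be >= 0")
  }
  if (any(chroms$length < 10 * matrix$length)) {
    stop("chromosome lengths must be at least 10x the motif length")
  }
  background <- validate_background(background)
  structure(list(seed = as.integer(seed), chroms = chroms,
                 background = background, matrix = matrix,
                 x_density_per_mb = x_density_per_mb,
                 a_density_per_mb = a_density_per_mb,
                 n_rex = as.integer(n_rex),
                 rex_motifs = as.integer(rex_motifs),
                 rex_gap = as.integer(rex_gap)),
            class = "sim_config")
}

# sample n instance words from the matrix's per-position frequencies;
# returns an n x k character matrix of bases
sample_motif_words <- function(matrix, n) {
  probs <- matrix$counts / matrix$n_sites
  k <- matrix$length
  out <- matrix("", nrow = n, ncol = k)
  for (i in seq_len(k)) {
    out[, i] <- sample(DNA_BASES, n, replace = TRUE, prob = probs[i, ])
  }
  out
}

COMP_BASE <- c(A = "T", C = "G", G = "C", T = "A")

#' Generate a synthetic genome with planted motif instances
#'
#' Draws i.i.d. background sequence per chromosome, then plants motif
#' instances sampled from the matrix's per-position frequencies at
#' uniform-random non-overlapping positions at the class density, on a
#' random strand each. On X-class chromosomes, `n_rex` clustered
#' rex-like sites are planted first (1-4 motifs each, spaced by the
#' configured gap range); the remaining instances are placed singly.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with `genome` (`DNAStringSet`), `truth` (data.frame
#'   `chrom`, `start`, `end`, `strand`, `word`, `in_rex`, `rex_id`) and
#'   `rex_sites` (data.frame `rex_id`, `chrom`, `start`, `end`,
#'   `summit`).
#' @export
simulate_genome <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  k <- config$matrix$length
  genome <- character(nrow(config$chroms))
  names(genome) <- config$chroms$name
  truth <- list()
  rex_sites <- list()
  for (ci in seq_len(nrow(config$chroms))) {
    ch <- config$chroms$name[[ci]]
    L <- as.integer(config$chroms$length[[ci]])
    cls <- config$chroms$class[[ci]]
    chars <- sample(DNA_BASES, L, replace = TRUE, prob = config$background)
    occupied <- logical(L)
    dens <- if (cls == "X") config$x_density_per_mb else config$a_density_per_mb
    n_total <- round(dens * L / 1e6)
    starts <- integer(0)   # 0-based placement starts
    rex_id <- character(0) # NA for singles
    n_placed <- 0L
    if (cls == "X" && config$n_rex > 0L) {
      for (r in seq_len(config$n_rex)) {
        rid <- sprintf("%s_rex_%d", ch, r)
        n_mot <- sample(seq(config$rex_motifs[[1L]], config$rex_motifs[[2L]]), 1L)
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 1000L) stop("could not place rex site ", rid,
                                  "; density too high")
          anchor <- sample.int(L - (k + max(config$rex_gap)) * n_mot, 1L) - 1L
          gaps <- sample(seq(config$rex_gap[[1L]], config$rex_gap[[2L]]),
                         n_mot, replace = TRUE)
          pos <- anchor + cumsum(c(0L, (k + gaps)[-n_mot]))
          if (all(pos >= 0L) && all(pos + k <= L) &&
              !any(occupied[unlist(lapply(pos, function(p) (p + 1L):(p + k)))])) {
            for (p in pos) occupied[(p + 1L):(p + k)] <- TRUE
            starts <- c(starts, pos)
            rex_id <- c(rex_id, rep(rid, n_mot))
            break
          }
        }
        n_placed <- n_placed + n_mot
        rex_sites[[length(rex_sites) + 1L]] <- data.frame(
          rex_id = rid, chrom = ch, start = pos[[1L]], end = pos[[n_mot]] + k,
          summit = as.integer(floor((pos[[1L]] + pos[[n_mot]] + k) / 2)))
      }
    }
    n_single <- max(0L, n_total - n_placed)
    tries <- 0L
    while (n_single > 0L) {
      tries <- tries + 1L
      if (tries > 50L * (n_total + 20L)) {
        stop("could not place planted motifs without overlap on ", ch,
             "; density too high")
      }
      p <- sample.int(L - k + 1L, 1L) - 1L
      if (!any(occupied[(p + 1L):(p + k)])) {
        occupied[(p + 1L):(p + k)] <- TRUE
        starts <- c(starts, p)
        rex_id <- c(rex_id, NA_character_)
        n_single <- n_single - 1L
      }
    }
    n_pl <- length(starts)
    if (n_pl > 0L) {
      words_mat <- sample_motif_words(config$matrix, n_pl)
      strand <- sample(c("+", "-"), n_pl, replace = TRUE)
      ins_mat <- words_mat
      minus <- strand == "-"
      if (any(minus)) {
        ins_mat[minus, ] <- COMP_BASE[words_mat[minus, rev(seq_len(k)),
                                                drop = FALSE]]
      }
      idx <- rep(starts, each = k) + seq_len(k)  # 1-based genome indices
      chars[idx] <- as.vector(t(ins_mat))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = ch, start = starts, end = starts + k, strand = strand,
        word = apply(words_mat, 1L, paste, collapse = ""),
        in_rex = !is.na(rex_id), rex_id = rex_id)
    }
    genome[[ci]] <- paste(chars, collapse = "")
  }
  truth <- if (length(truth) > 0L) {
    do.call(rbind, truth)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), word = character(), in_rex = logical(),
               rex_id = character())
  }
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = Biostrings::DNAStringSet(genome),
       truth = truth,
       rex_sites = if (length(rex_sites) > 0L) {
         do.call(rbind, rex_sites)
       } else {
         data.frame(rex_id = character(), chrom = character(),
                    start = integer(), end = integer(), summit = integer())
       })
}

#' Simulate ChIP coverage with localized enrichment at rex sites
#'
#' Per-bin read counts are Poisson with rate
#' `background_rate + sum_site amplitude * exp(-d^2 / (2 sigma^2))`,
#' where d is the distance from the bin centre to the site summit. The
#' counts are RPKM-normalised against the realised total read count.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param rex_sites Data.frame with `chrom` and `summit` columns (e.g.
#'   from [simulate_genome()]); may be empty for a flat track.
#' @param bin_size Bin width in bp (default 50).
#' @param background_rate Expected background reads per bin (default 20).
#' @param amplitude Expected extra reads per bin at a site summit
#'   (default 160, i.e. 8x background).
#' @param sigma Gaussian width of the enrichment bump in bp (default 400).
#' @param seed Optional seed.
#' @return List with `track` (a [signal_track()] of RPKM), `counts`
#'   (data.frame `chrom`, `start`, `count`), `total_reads`, and `truth`
#'   (per-site summit/amplitude/sigma plus the background rate in RPKM
#'   units as attributes `background_rpkm` and `amplitude_rpkm`).
#' @export
simulate_coverage <- function(chrom_lengths, rex_sites = NULL, bin_size = 50L,
                              background_rate = 20, amplitude = 160,
                              sigma = 400, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- list()
  for (ch in names(chrom_lengths)) {
    nb <- floor(chrom_lengths[[ch]] / bin_size)
    start <- (seq_len(nb) - 1L) * bin_size
    lambda <- rep(background_rate, nb)
    if (!is.null(rex_sites) && nrow(rex_sites) > 0L) {
      centers <- start + bin_size / 2
      for (i in which(rex_sites$chrom == ch)) {
        d <- centers - rex_sites$summit[[i]]
        lambda <- lambda + amplitude * exp(-d^2 / (2 * sigma^2))
      }
    }
    counts[[ch]] <- data.frame(chrom = ch, start = start,
                               count = stats::rpois(nb, lambda))
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL
  total <- sum(counts$count)
  track <- rpkm_normalize(counts, total, bin_size)
  to_rpkm <- 1 / ((bin_size / 1000) * (total / 1e6))
  truth <- if (!is.null(rex_sites) && nrow(rex_sites) > 0L) {
    data.frame(rex_sites, amplitude = amplitude, sigma = sigma)
  } else {
    data.frame()
  }
  attr(truth, "background_rpkm") <- background_rate * to_rpkm
  attr(truth, "amplitude_rpkm") <- amplitude * to_rpkm
  list(track = track, counts = counts, total_reads = total, truth = truth)
}

#' Simulate replicate ChIP-qPCR measurements
#'
#' Each replicate receives a shared log-normal scale factor; each site's
#' level is the true level times that factor times multiplicative
#' log-normal noise of coefficient of variation `noise_cv`. Levels are
#' converted to threshold cycles through a perfectly efficient standard
#' curve (slope -1/log10(2)), and a noise-free standards table (10% and
#' three serial 10-fold dilutions) is included.
#'
#' @param true_levels Named numeric vector of true fraction-of-input
#'   levels per site (> 0).
#' @param noise_cv Coefficient of variation of the per-measurement
#'   multiplicative noise (0 for noise-free).
#' @param n_replicates Number of replicates (default 3).
#' @param scale_sd SD of the per-replicate log-scale factor (default 0.3).
#' @param intercept Ct at fraction 1 on the true curve (default 13).
#' @param seed Optional seed.
#' @return List with `samples` (data.frame `site`, `replicate`, `ct`),
#'   `standards` (data.frame `fraction`, `ct`), `slope`, `intercept` and
#'   `true_levels`.
#' @export
simulate_qpcr <- function(true_levels, noise_cv = 0.1, n_replicates = 3L,
                          scale_sd = 0.3, intercept = 13, seed = NULL) {
  if (any(true_levels <= 0)) stop("true levels must be > 0")
  if (!is.null(seed)) set.seed(seed)
  slope <- -1 / log10(2)
  sdlog <- sqrt(log(1 + noise_cv^2))
  samples <- list()
  for (r in seq_len(n_replicates)) {
    scale_r <- stats::rlnorm(1L, 0, scale_sd)
    noise <- if (sdlog > 0) {
      stats::rlnorm(length(true_levels), 0, sdlog)
    } else {
      rep(1, length(true_levels))
    }
    lev <- scale_r * true_levels * noise
    samples[[r]] <- data.frame(site = names(true_levels), replicate = r,
                               ct = intercept + slope * log10(lev))
  }
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL
  fractions <- 0.1 * 10^-(0:3)
  standards <- data.frame(fraction = fractions,
                          ct = intercept + slope * log10(fractions))
  list(samples = samples, standards = standards,
       slope = slope, intercept = intercept, true_levels = true_levels)
}
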