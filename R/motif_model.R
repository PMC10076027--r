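DNA_BASES <- c("A", "C", "G", "T")

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Build a motif matrix from aligned instances
#'
#' Constructs a position weight matrix (PWM) from a set of equal-length,
#' gap-free nucleotide instances. Per-position log-weights follow the
#' Patser convention
#' \deqn{w_{i,b} = \ln\frac{n_{i,b} + p_b}{(N + 1)\,p_b}}
#' where \eqn{n_{i,b}} is the count of base \eqn{b} at position \eqn{i},
#' \eqn{N} the number of instances and \eqn{p_b} the background
#' probability of \eqn{b}. The pseudocount guarantees finite weights for
#' unobserved bases. A plain log-odds rule with an additive pseudocount
#' is available via `pseudocount = "additive"`.
#'
#' @param instances Character vector of equal-length strings over A/C/G/T.
#' @param background Named numeric vector of base probabilities for
#'   A, C, G, T; strictly positive, summing to 1. Default uniform.
#' @param id Label carried through scans and annotations.
#' @param pseudocount `"patser"` (default) or `"additive"`.
#' @param additive_pseudo Total pseudocount mass for the additive rule,
#'   split across bases proportionally to the background.
#' @return An object of class `motif_matrix`: a list with elements
#'   `id`, `length`, `counts` (length x 4 matrix), `n_sites`,
#'   `background` and `weights` (length x 4 log-weight matrix).
#' @examples
#' m <- motif_matrix(c("AA", "AC"))
#' m$weights
#' @export
motif_matrix <- function(instances,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         id = "motif",
                         pseudocount = c("patser", "additive"),
                         additive_pseudo = 1) {
  pseudocount <- match.arg(pseudocount)
  if (length(instances) < 1L) {
    stop("at least one instance is required")
  }
  widths <- nchar(instances)
  if (length(unique(widths)) != 1L) {
    stop("instances have ragged lengths: ", paste(unique(widths), collapse = ", "))
  }
  chars <- strsplit(toupper(instances), "", fixed = TRUE)
  bad <- setdiff(unique(unlist(chars)), DNA_BASES)
  if (length(bad) > 0L) {
    stop("instances contain non-ACGT characters: ", paste(bad, collapse = ", "))
  }
  k <- widths[[1L]]
  counts <- matrix(0, nrow = k, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  for (inst in chars) {
    idx <- match(inst, DNA_BASES)
    counts[cbind(seq_len(k), idx)] <- counts[cbind(seq_len(k), idx)] + 1
  }
  motif_from_counts(counts, background = background, id = id,
                    pseudocount = pseudocount, additive_pseudo = additive_pseudo)
}

#' Build a motif matrix from a count table
#'
#' Lower-level constructor used by [motif_matrix()] and the MEME/TSV
#' readers. Rows are motif positions, columns the bases A, C, G, T.
#'
#' @param counts Numeric matrix (positions x 4) of non-negative counts;
#'   every row must sum to the same total.
#' @inheritParams motif_matrix
#' @return A `motif_matrix` object.
#' @export
motif_from_counts <- function(counts,
                              background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                              id = "motif",
                              pseudocount = c("patser", "additive"),
                              additive_pseudo = 1) {
  pseudocount <- match.arg(pseudocount)
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("counts must have 4 columns (A, C, G, T)")
  colnames(counts) <- DNA_BASES
  if (any(counts < 0)) stop("counts must be non-negative")
  background <- validate_background(background)
  row_tot <- rowSums(counts)
  if (max(row_tot) - min(row_tot) > 1e-6 * max(row_tot, 1)) {
    stop("every position's counts must sum to the same number of sites")
  }
  n_sites <- row_tot[[1L]]
  bg <- matrix(background, nrow = nrow(counts), ncol = 4L, byrow = TRUE)
  weights <- switch(pseudocount,
    patser = log((counts + bg) / ((n_sites + 1) * bg)),
    additive = log(((counts + additive_pseudo * bg) /
                      (n_sites + additive_pseudo)) / bg)
  )
  stopifnot(all(is.finite(weights)))
  structure(
    list(id = id, length = nrow(counts), counts = counts, n_sites = n_sites,
         background = background, weights = weights, pseudocount = pseudocount),
    class = "motif_matrix"
  )
}

validate_background <- function(background) {
  if (is.null(names(background))) names(background) <- DNA_BASES
  background <- background[DNA_BASES]
  if (anyNA(background) || any(background <= 0)) {
    stop("background probabilities must be strictly positive for A, C, G, T")
  }
  if (abs(sum(background) - 1) > 1e-9) {
    stop("background probabilities must sum to 1 (got ", sum(background), ")")
  }
  background
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix '%s': %d bp, %g sites, %s pseudocount\n",
              x$id, x$length, x$n_sites, x$pseudocount))
  cat(sprintf("consensus: %s  max theoretical ln(P): %.4f\n",
              consensus_word(x), max_theoretical_ln_p(x)))
  invisible(x)
}

word_to_idx <- function(word, k) {
  chars <- strsplit(toupper(word), "", fixed = TRUE)[[1L]]
  if (length(chars) != k) {
    stop("word length ", length(chars), " does not match matrix length ", k)
  }
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx)) stop("word contains non-ACGT characters")
  idx
}

#' Score a word against a motif matrix
#'
#' The match score is the sum of the per-position log-weights of the
#' word's bases. Higher scores are better matches.
#'
#' @param matrix A `motif_matrix`.
#' @param word A string over A/C/G/T of the matrix length.
#' @return The match score in natural-log units.
#' @examples
#' m <- motif_matrix(c("AA", "AC"))
#' score_word(m, "AA")  # ln(5)
#' @export
score_word <- function(matrix, word) {
  idx <- word_to_idx(word, matrix$length)
  sum(matrix$weights[cbind(seq_len(matrix$length), idx)])
}

#' Consensus (per-position argmax) word of a motif matrix
#'
#' @param matrix A `motif_matrix`.
#' @return The word maximising [score_word()]; ties resolve to the
#'   alphabetically first base.
#' @export
consensus_word <- function(matrix) {
  paste(DNA_BASES[apply(matrix$weights, 1L, which.max)], collapse = "")
}

#' Exact distribution of the match score under the background model
#'
#' Computes, by dynamic-programming convolution across motif positions,
#' the exact probability mass function of the match score of a random
#' word drawn from the background distribution, on a discrete lattice of
#' step `granularity`. Per-position weights are rounded to the lattice
#' (half away from zero) before convolution, so any word's lattice score
#' is the sum of its per-position lattice weights; the discretisation
#' error of a k-position score is bounded by k * granularity / 2.
#'
#' @param matrix A `motif_matrix`.
#' @param granularity Lattice step in log units (default 1e-5 for
#'   point queries; genome scans use a coarser lattice, see
#'   [scan_genome()]).
#' @param max_lattice Guard on the total number of lattice points; a
#'   finer granularity than this bound allows raises an error with
#'   guidance rather than exhausting memory.
#' @return An object of class `score_distribution` with elements
#'   `granularity`, `support` (lattice scores), `pmf`, `survival`
#'   (P(S >= s)), the integer weight lattice `iw` and its index origin.
#' @export
score_distribution <- function(matrix, granularity = 1e-5, max_lattice = 2e7) {
  if (granularity <= 0) stop("granularity must be > 0")
  span <- sum(apply(matrix$weights, 1L, max) - apply(matrix$weights, 1L, min))
  n_points <- span / granularity + 1
  if (!is.finite(n_points) || n_points > max_lattice) {
    stop("score lattice would need ~", format(n_points, digits = 3),
         " points (> ", max_lattice,
         "); increase `granularity` or raise `max_lattice`")
  }
  iw <- round_half_away(matrix$weights / granularity)
  mode(iw) <- "integer"
  # pmf over integer lattice offsets, origin shifting as positions accrue
  pmf <- 1
  origin <- 0L
  for (i in seq_len(matrix$length)) {
    w <- iw[i, ]
    new_origin <- origin + min(w)
    new_len <- length(pmf) + (max(w) - min(w))
    acc <- numeric(new_len)
    for (b in 1:4) {
      off <- w[[b]] - min(w)
      acc[(1 + off):(length(pmf) + off)] <-
        acc[(1 + off):(length(pmf) + off)] + pmf * matrix$background[[b]]
    }
    pmf <- acc
    origin <- new_origin
  }
  survival <- rev(cumsum(rev(pmf)))
  structure(
    list(granularity = granularity,
         support = (origin + seq_along(pmf) - 1L) * granularity,
         pmf = pmf,
         survival = survival,
         iw = iw,
         origin = origin),
    class = "score_distribution"
  )
}

lattice_index <- function(dist, word_idx) {
  sum(dist$iw[cbind(seq_len(nrow(dist$iw)), word_idx)])
}

survival_at_index <- function(dist, idx) {
  pos <- idx - dist$origin + 1L
  if (pos <= 0L) return(1)
  if (pos > length(dist$survival)) {
    stop("score outside the distribution range")
  }
  dist$survival[[pos]]
}

#' ln(P): log-probability that a random word matches at least as well
#'
#' `ln_p` is the natural log of the probability that a random
#' background-drawn word of the motif length scores at least as high as
#' the given word (or score). More negative values indicate better
#' matches; the minimum-scoring word has ln(P) = 0.
#'
#' @param matrix A `motif_matrix`.
#' @param word A word over A/C/G/T of the matrix length, or `NULL` if
#'   `score` is given.
#' @param score A raw match score, used when `word` is `NULL`; it is
#'   rounded to the lattice (half away from zero).
#' @param dist Optional pre-computed [score_distribution()] (must match
#'   `granularity`); computing it once and reusing it is much faster in
#'   loops.
#' @param granularity Lattice step, forwarded to [score_distribution()].
#' @return ln(P), a non-positive number.
#' @examples
#' m <- motif_matrix(c("AA", "AC"))
#' ln_p(m, "AA")  # log(2/16)
#' @export
ln_p <- function(matrix, word = NULL, score = NULL, dist = NULL,
                 granularity = 1e-5) {
  if (is.null(dist)) dist <- score_distribution(matrix, granularity)
  if (!is.null(word)) {
    idx <- lattice_index(dist, word_to_idx(word, matrix$length))
  } else if (!is.null(score)) {
    idx <- round_half_away(score / dist$granularity)
  } else {
    stop("provide `word` or `score`")
  }
  log(survival_at_index(dist, idx))
}

#' Most negative attainable ln(P) of a matrix
#'
#' The ln(P) of the per-position argmax (consensus) word: the best match
#' probability any word can achieve. For an uninformative matrix all
#' words tie and the value is 0.
#'
#' @inheritParams ln_p
#' @return The minimum attainable ln(P) (a non-positive number).
#' @export
max_theoretical_ln_p <- function(matrix, dist = NULL, granularity = 1e-5) {
  if (is.null(dist)) dist <- score_distribution(matrix, granularity)
  ln_p(matrix, word = consensus_word(matrix), dist = dist)
}

#' Reverse-complement of a motif matrix
#'
#' Reverses the positions and complements the base columns, so scoring a
#' window with the reverse-complement matrix equals scoring the
#' reverse-complement of the window with the original matrix.
#'
#' @param matrix A `motif_matrix`.
#' @return A `motif_matrix` for the opposite strand. Its background is
#'   the complement-swapped background, so that a random-word score
#'   distribution is consistent for minus-strand p-values.
#' @export
reverse_complement_matrix <- function(matrix) {
  comp <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
  counts <- matrix$counts[rev(seq_len(matrix$length)), comp, drop = FALSE]
  colnames(counts) <- DNA_BASES
  bg <- matrix$background[comp]
  names(bg) <- DNA_BASES
  motif_from_counts(counts, background = bg,
                    id = paste0(matrix$id, "_rc"),
                    pseudocount = matrix$pseudocount)
}
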