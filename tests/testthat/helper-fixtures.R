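# shared fixtures and independent oracles, built in code at test time

dinuc_matrix <- function() motif_matrix(c("AA", "AC"))

random_background <- function() {
  p <- stats::runif(4, min = 0.1, max = 1)
  p <- p / sum(p)
  names(p) <- c("A", "C", "G", "T")
  p
}

random_matrix <- function(k = sample(2:8, 1L), background = random_background(),
                          n_sites = sample(5:40, 1L)) {
  counts <- t(stats::rmultinom(k, n_sites, prob = stats::runif(4, 0.2, 1)))
  colnames(counts) <- c("A", "C", "G", "T")
  motif_from_counts(counts, background = background,
                    id = sprintf("rand%d", k))
}

# brute-force score/ln(P) oracle: enumerate all 4^k words, weight by the
# background; independent of the DP lattice implementation
enumerate_words <- function(matrix) {
  scores <- 0
  probs <- 1
  for (i in seq_len(matrix$length)) {
    scores <- as.vector(outer(matrix$weights[i, ], scores, "+"))
    probs <- as.vector(outer(matrix$background, probs, "*"))
  }
  list(scores = scores, probs = probs)
}

brute_ln_p <- function(matrix, word, enum = enumerate_words(matrix)) {
  s <- score_word(matrix, word)
  log(sum(enum$probs[enum$scores >= s - 1e-9]))
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

rc_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# plant word into sequence at 0-based offset
plant_word <- function(seq, word, at) {
  paste0(substr(seq, 1L, at), word, substr(seq, at + nchar(word) + 1L,
                                           nchar(seq)))
}

# perfect-efficiency dilution series: ct doubles material per cycle
perfect_dilutions <- function(intercept = 13) {
  fr <- 0.1 * 10^-(0:3)
  data.frame(fraction = fr, ct = intercept - log10(fr) / log10(2))
}

# chromosome class/length maps for the default sim layout
sim_class_map <- function(cfg) stats::setNames(cfg$chroms$class, cfg$chroms$name)
sim_length_map <- function(cfg) stats::setNames(cfg$chroms$length, cfg$chroms$name)
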