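#' Read motifs from MEME minimal text format
#'
#' Parses the `letter-probability matrix` blocks of a MEME minimal motif
#' file. Probabilities are converted back to counts by multiplying by the
#' number of sites (`nsites` from the file, overridable), since the
#' weight rule operates on counts.
#'
#' @param path Path to a MEME minimal format file.
#' @param n_sites Optional number of sites used to scale probabilities
#'   to counts; defaults to each motif's `nsites=` field (error if that
#'   is absent too).
#' @param background Background probabilities for the weight rule; if
#'   `NULL`, the file's `Background letter frequencies` line is used
#'   when present, else uniform.
#' @return A named list of [motif_matrix()] objects.
#' @export
read_meme_motifs <- function(path, n_sites = NULL, background = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME minimal format file (missing 'MEME version' line): ", path)
  }
  if (is.null(background)) {
    bg_i <- grep("^Background letter frequencies", lines)
    if (length(bg_i) > 0L) {
      tok <- strsplit(trimws(lines[[bg_i[[1L]] + 1L]]), "\\s+")[[1L]]
      background <- as.numeric(tok[c(FALSE, TRUE)])
      names(background) <- tok[c(TRUE, FALSE)]
    } else {
      background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    }
  }
  motif_starts <- grep("^MOTIF\\s", lines)
  if (length(motif_starts) == 0L) stop("no MOTIF blocks found in ", path)
  out <- list()
  for (s in motif_starts) {
    id <- strsplit(trimws(lines[[s]]), "\\s+")[[1L]][[2L]]
    h <- grep("^letter-probability matrix", lines[seq(s, length(lines))])[[1L]] + s - 1L
    header <- lines[[h]]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", header))
    ns <- n_sites
    if (is.null(ns)) {
      if (!grepl("nsites=", header)) {
        stop("motif '", id, "' has no nsites= field; supply `n_sites`")
      }
      ns <- as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", header))
    }
    probs <- do.call(rbind, lapply(lines[(h + 1L):(h + w)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    }))
    out[[id]] <- motif_from_counts(probs * ns, background = background, id = id)
  }
  out
}

#' Read a motif count table from TSV
#'
#' Expects columns `A`, `C`, `G`, `T` with one row per motif position.
#'
#' @param path Path to the TSV file.
#' @inheritParams motif_matrix
#' @return A [motif_matrix()] object.
#' @export
read_motif_tsv <- function(path,
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           id = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!all(DNA_BASES %in% names(tab))) {
    stop("motif TSV must have columns A, C, G, T: ", path)
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  motif_from_counts(as.matrix(tab[, DNA_BASES]), background = background, id = id)
}

#' Write a motif count table to TSV
#'
#' @param matrix A [motif_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(matrix, path) {
  utils::write.table(as.data.frame(matrix$counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
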