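# Monoisotopic residue masses (Da), standard IUPAC/Unimod values to >= 5 dp.
RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276

#' Named variable modifications available for mass matching
#'
#' Monoisotopic mass deltas (Da) of the modifications used to reconcile
#' MALDI-TOF peptide masses: methionine oxidation and the two common
#' cysteine adducts (iodoacetamide carbamidomethylation and acrylamide
#' propionamide).
#'
#' @return Named numeric vector of mass deltas with a `target` attribute
#'   naming the modified residue of each.
#' @export
pmf_modifications <- function() {
  structure(
    c(ox_met = 15.994915,
      carbamidomethyl_cys = 57.021464,
      propionamide_cys = 71.037114),
    target = c(ox_met = "M",
               carbamidomethyl_cys = "C",
               propionamide_cys = "C")
  )
}

check_residues <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), names(RESIDUE_MONO))
  if (length(bad) > 0L) {
    stop("non-standard residues in peptide/protein: ", paste(bad, collapse = ", "))
  }
  chars
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P (the proline
#' rule), and enumerates peptides carrying up to `max_missed` internal
#' missed cleavage sites. The zero-missed peptides partition the protein
#' in order.
#'
#' @param protein Amino-acid string over the 20 standard residues.
#' @param max_missed Maximum internal missed cleavages (default 0).
#' @return Data.frame with columns `sequence`, `start`, `end` (1-based
#'   inclusive residue range), `missed_cleavages` and `mh_plus`
#'   (unmodified monoisotopic MH+).
#' @export
digest_protein <- function(protein, max_missed = 0L) {
  chars <- check_residues(protein)
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)  # fragment f spans (bounds[f]+1) .. bounds[f+1]
  nfrag <- length(bounds) - 1L
  out <- list()
  for (f in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      g <- f + m
      if (g > nfrag) break
      s <- bounds[[f]] + 1L
      e <- bounds[[g + 1L]]
      pep <- paste(chars[s:e], collapse = "")
      out[[length(out) + 1L]] <- data.frame(
        sequence = pep, start = s, end = e, missed_cleavages = m,
        mh_plus = mono_mh(pep))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monoisotopic MH+ of a peptide
#'
#' Sum of residue monoisotopic masses plus water (18.010565 Da) plus one
#' proton (1.007276 Da), plus any modification deltas. Full precision is
#' returned; comparisons to printed tables are conventionally made at
#' 2 dp.
#'
#' @param peptide Amino-acid string.
#' @param modifications Either a numeric vector of mass deltas (Da) to
#'   add, or a character vector of modification names from
#'   [pmf_modifications()] (each occurrence adds one delta; the target
#'   residue must be present).
#' @return MH+ in Da.
#' @examples
#' round(mono_mh("YHENVVR"), 2)  # 916.46
#' @export
mono_mh <- function(peptide, modifications = NULL) {
  chars <- check_residues(peptide)
  m <- sum(RESIDUE_MONO[chars]) + MASS_WATER + MASS_PROTON
  if (!is.null(modifications)) {
    if (is.character(modifications)) {
      mods <- pmf_modifications()
      unknown <- setdiff(modifications, names(mods))
      if (length(unknown) > 0L) {
        stop("unknown modification label(s): ", paste(unknown, collapse = ", "))
      }
      targets <- attr(mods, "target")[modifications]
      for (i in seq_along(modifications)) {
        if (!targets[[i]] %in% chars) {
          stop("modification ", modifications[[i]], " targets residue ",
               targets[[i]], " which is absent from ", peptide)
        }
      }
      modifications <- unname(mods[modifications])
    }
    m <- m + sum(modifications)
  }
  m
}

#' Relative mass deviation in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed Observed mass (Da).
#' @param theoretical Theoretical mass (Da, > 0).
#' @return Deviation in ppm.
#' @export
ppm_delta <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be > 0")
  1e6 * (observed - theoretical) / theoretical
}

# all modification count combinations for a peptide, up to max_mods total
mod_combinations <- function(sequence, variable_mods, max_mods) {
  mods <- pmf_modifications()
  variable_mods <- intersect(variable_mods, names(mods))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  caps <- vapply(variable_mods, function(mn) {
    sum(chars == attr(mods, "target")[[mn]])
  }, integer(1L))
  caps <- pmin(caps, max_mods)
  grids <- lapply(caps, function(cp) 0:cp)
  combos <- expand.grid(grids)
  if (ncol(combos) == 0L) combos <- data.frame(row.names = 1L)
  keep <- rowSums(combos) <= max_mods
  # cysteine adducts are alternatives on the same residues: joint count
  # cannot exceed the cysteine count
  cys_mods <- variable_mods[attr(mods, "target")[variable_mods] == "C"]
  if (length(cys_mods) > 1L) {
    keep <- keep & rowSums(combos[, cys_mods, drop = FALSE]) <= sum(chars == "C")
  }
  combos <- combos[keep, , drop = FALSE]
  delta <- as.numeric(as.matrix(combos) %*% mods[variable_mods])
  labels <- apply(combos, 1L, function(cnt) {
    nz <- cnt > 0
    if (!any(nz)) return("")
    paste(sprintf("%dx%s", cnt[nz], variable_mods[nz]), collapse = "+")
  })
  data.frame(mods = labels, delta = delta, stringsAsFactors = FALSE)
}

#' Match observed masses to peptides within a ppm tolerance
#'
#' For every observed mass, reports each peptide/modification
#' combination whose theoretical MH+ lies within `tolerance_ppm`.
#' Variable modifications are enumerated combinatorially up to
#' `max_mods` per peptide. Matches for the same observed mass are ranked
#' by |delta ppm|.
#'
#' @param observed Numeric vector of observed MH+ masses (Da).
#' @param peptides A digest data.frame from [digest_protein()] or a
#'   character vector of peptide sequences.
#' @param tolerance_ppm Matching tolerance (> 0), default 25 ppm.
#' @param variable_mods Names from [pmf_modifications()] to enumerate
#'   (default all three); `character(0)` for none.
#' @param max_mods Cap on total modifications per peptide (default 2).
#' @return Data.frame with columns `observed`, `sequence`, `mods`,
#'   `mh_plus`, `delta_ppm` (empty when nothing matches).
#' @export
match_masses <- function(observed, peptides, tolerance_ppm = 25,
                         variable_mods = names(pmf_modifications()),
                         max_mods = 2L) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0")
  if (is.character(peptides)) {
    peptides <- data.frame(sequence = peptides,
                           mh_plus = vapply(peptides, mono_mh, numeric(1L)),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  cand <- do.call(rbind, lapply(seq_len(nrow(peptides)), function(i) {
    cmb <- mod_combinations(peptides$sequence[[i]], variable_mods, max_mods)
    data.frame(sequence = peptides$sequence[[i]], mods = cmb$mods,
               mh_plus = peptides$mh_plus[[i]] + cmb$delta,
               stringsAsFactors = FALSE)
  }))
  out <- list()
  for (obs in observed) {
    dp <- ppm_delta(obs, cand$mh_plus)
    sel <- which(abs(dp) <= tolerance_ppm)
    if (length(sel) == 0L) next
    sel <- sel[order(abs(dp[sel]))]
    out[[length(out) + 1L]] <- data.frame(
      observed = obs, sequence = cand$sequence[sel], mods = cand$mods[sel],
      mh_plus = cand$mh_plus[sel], delta_ppm = dp[sel],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(observed = numeric(), sequence = character(),
                      mods = character(), mh_plus = numeric(),
                      delta_ppm = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
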