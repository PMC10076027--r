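#' Fit a qPCR standard curve
#'
#' Ordinary least squares of threshold cycle on log10(fraction of
#' input): `ct = slope * log10(fraction) + intercept`. A perfectly
#' efficient assay gives slope `-1/log10(2)` (about -3.3219 cycles per
#' decade).
#'
#' @param dilutions Data.frame with columns `fraction` (> 0) and `ct`,
#'   or a two-column matrix in that order. At least two distinct
#'   fractions are required.
#' @return An object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared` and the `dilution_points`.
#' @export
fit_standard_curve <- function(dilutions) {
  dilutions <- as.data.frame(dilutions)
  if (!all(c("fraction", "ct") %in% names(dilutions))) {
    names(dilutions)[1:2] <- c("fraction", "ct")
  }
  if (any(dilutions$fraction <= 0)) stop("fractions must be > 0")
  if (length(unique(dilutions$fraction)) < 2L) {
    stop("at least two distinct dilution fractions are required")
  }
  fit <- stats::lm(ct ~ log10(fraction), data = dilutions)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((dilutions$ct - mean(dilutions$ct))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(slope = unname(stats::coef(fit)[[2L]]),
         intercept = unname(stats::coef(fit)[[1L]]),
         r_squared = r2,
         dilution_points = dilutions),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: slope %.4f cycles/decade, intercept %.4f, r2 %.5f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Quantify a threshold cycle against a standard curve
#'
#' Inverts the fitted line: fraction = 10^((ct - intercept) / slope).
#'
#' @param ct Threshold cycle(s).
#' @param curve A [fit_standard_curve()] result; its slope must be
#'   negative (valid amplification).
#' @return Fraction(s) of input.
#' @export
quantify_ct <- function(ct, curve) {
  if (!inherits(curve, "standard_curve")) stop("curve must be a standard_curve")
  if (curve$slope >= 0) stop("invalid standard curve: slope must be negative")
  10^((ct - curve$intercept) / curve$slope)
}

#' Normalise site levels to the mean of control rex sites, per replicate
#'
#' Within each replicate, every site's level is divided by the mean
#' level of the named control sites in that replicate. This removes any
#' shared per-replicate scale factor exactly.
#'
#' @param levels Data.frame with columns `site`, `replicate`, `level`.
#' @param control_sites Character vector of control site labels; every
#'   control must be measured in every replicate.
#' @return `levels` with an added `normalized` column.
#' @export
normalize_to_controls <- function(levels, control_sites) {
  stopifnot(all(c("site", "replicate", "level") %in% names(levels)))
  if (length(control_sites) == 0L) stop("control_sites must be non-empty")
  out <- levels
  out$normalized <- NA_real_
  for (rep_id in unique(levels$replicate)) {
    i <- levels$replicate == rep_id
    ctrl <- levels$level[i & levels$site %in% control_sites]
    found <- unique(levels$site[i & levels$site %in% control_sites])
    missing <- setdiff(control_sites, found)
    if (length(missing) > 0L) {
      stop("control sites missing in replicate ", rep_id, ": ",
           paste(missing, collapse = ", "))
    }
    m <- mean(ctrl)
    if (m == 0) stop("control mean is zero in replicate ", rep_id)
    out$normalized[i] <- levels$level[i] / m
  }
  out
}

#' Per-site mean and SD of normalised levels across replicates
#'
#' @param normalized Output of [normalize_to_controls()].
#' @return Data.frame with `site`, `mean`, `sd`, `n_replicates`.
#' @export
summarize_levels <- function(normalized) {
  stopifnot("normalized" %in% names(normalized))
  sites <- unique(normalized$site)
  data.frame(
    site = sites,
    mean = vapply(sites, function(s) {
      mean(normalized$normalized[normalized$site == s])
    }, numeric(1L)),
    sd = vapply(sites, function(s) {
      stats::sd(normalized$normalized[normalized$site == s])
    }, numeric(1L)),
    n_replicates = vapply(sites, function(s) {
      sum(normalized$site == s)
    }, integer(1L)),
    row.names = NULL
  )
}

#' Observed progeny as a percentage of the expected class
#'
#' `100 * observed / (total * expected_fraction)`: the observed count of
#' a genotype class expressed as a percentage of the number expected if
#' that class were fully viable.
#'
#' @param observed Observed count of the class (0 <= observed <= total).
#' @param total Total progeny scored (> 0).
#' @param expected_fraction Expected proportion of the class among all
#'   progeny (0 < f <= 1), e.g. 0.25 for non-GFP self-progeny of a
#'   balanced heterozygote.
#' @return Percent of expected.
#' @export
percent_of_expected <- function(observed, total, expected_fraction) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(expected_fraction <= 0 | expected_fraction > 1)) {
    stop("expected_fraction must be in (0, 1]")
  }
  if (any(observed < 0) || any(observed > total)) {
    stop("observed must be between 0 and total")
  }
  100 * observed / (total * expected_fraction)
}

#' XO male viability from a cross with 50% expected males
#'
#' `(n_males / (total_f1 / 2)) * 100`; identical to
#' [percent_of_expected()] with expected fraction 1/2.
#'
#' @param n_males Number of live F1 males.
#' @param total_f1 Total F1 progeny (> 0).
#' @return Percent XO viability.
#' @export
xo_viability <- function(n_males, total_f1) {
  percent_of_expected(n_males, total_f1, 0.5)
}

#' XO rescue percentage when only one-third of viable progeny can be male
#'
#' `(n_males / (total_progeny / 3)) * 100`; identical to
#' [percent_of_expected()] with expected fraction 1/3. The 1/3 arises
#' because the non-rescued XO class is inviable, leaving two viable XX
#' classes per expected male class.
#'
#' @param n_males Number of live males.
#' @param total_progeny Total viable progeny (> 0).
#' @return Percent XO rescue.
#' @export
xo_rescue <- function(n_males, total_progeny) {
  percent_of_expected(n_males, total_progeny, 1 / 3)
}
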