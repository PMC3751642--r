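#' Fit a smooth intensity trend to a log2 profile
#'
#' Robust smooth fit of log2 values against a per-probe covariate (a
#' mean-signal proxy) used to remove dye-bias trends. The trend is a
#' B-spline regression estimated by M-estimation (Tukey bisquare), so the
#' robust iterations down-weight CNV-bearing probes and the trend tracks the
#' dye bias, not the copy-number signal. Being a (weighted) projection, the
#' fit is numerically idempotent: the trend of a detrended profile is ~0.
#'
#' The `span` parameter controls smoothness the way a loess span would:
#' the spline uses roughly `3 / span` degrees of freedom, so the default
#' span of 0.3 gives a 10-df smooth. A constant covariate returns a constant
#' trend equal to the median of the values.
#'
#' @param values numeric log2 series.
#' @param covariate numeric series of the same length.
#' @param span smoothness in (0, 1]; smaller = wigglier. Default 0.3.
#' @return Numeric trend evaluated at each probe.
#' @export
fit_trend <- function(values, covariate, span = 0.3) {
  if (length(values) != length(covariate))
    stop_bad("values and covariate differ in length")
  if (span <= 0 || span > 1) stop_bad("span must lie in (0, 1]")
  ok <- is.finite(values) & is.finite(covariate)
  if (!any(ok)) stop_bad("no finite values to fit")
  if (diff(range(covariate[ok])) == 0)
    return(rep(median(values[ok]), length(values)))
  df <- max(4L, ceiling(3 / span))
  bknots <- range(covariate[is.finite(covariate)])
  basis <- splines::bs(covariate, df = df, Boundary.knots = bknots)
  X <- cbind(1, basis[ok, , drop = FALSE])
  fit <- MASS::rlm(X, values[ok], psi = MASS::psi.bisquare, maxit = 50)
  out <- drop(cbind(1, basis) %*% fit$coefficients)
  out[!is.finite(out)] <- median(values[ok])
  out
}

#' Remove the dye-bias trend and centre a profile
#'
#' Iteratively subtracts the robust covariate trend until the fitted trend
#' is numerically negligible (which makes normalization idempotent), then
#' median-centres the profile genome-wide. With `per_chromosome_center` the
#' sex chromosomes (Z, W) are additionally re-centred per chromosome;
#' autosomes are never centred individually, so whole-chromosome dosage
#' signal survives.
#'
#' Up to 20% non-finite input values are tolerated and imputed to the local
#' trend (residual 0); more is an error.
#'
#' @param values numeric log2 series, or an `acgh_profile` from
#'   [get_profile()].
#' @param probe_map probe map aligned with `values` (taken from the profile
#'   when one is supplied).
#' @param covariate optional per-probe covariate; when absent only centring
#'   is performed.
#' @param span smoothness, see [fit_trend()].
#' @param per_chromosome_center re-centre Z/W per chromosome.
#' @param max_iter trend-removal iteration cap.
#' @return Numeric normalized values (median 0), same length and order.
#' @export
normalize_profile <- function(values, probe_map = NULL, covariate = NULL,
                              span = 0.3, per_chromosome_center = FALSE,
                              max_iter = 20L) {
  if (inherits(values, "acgh_profile")) {
    probe_map <- values$probe_map
    if (is.null(covariate)) covariate <- values$covariate
    values <- values$values
  }
  n <- length(values)
  n_bad <- sum(!is.finite(values))
  if (n_bad > 0.2 * n)
    stop_bad("%d of %d probe values are non-finite (> 20%%)", n_bad, n)
  out <- values
  if (!is.null(covariate)) {
    for (i in seq_len(max_iter)) {
      tr <- fit_trend(out, covariate, span = span)
      out <- ifelse(is.finite(out), out - tr, 0)
      if (sqrt(mean(tr[is.finite(tr)]^2)) < 1e-9) break
    }
  } else {
    out[!is.finite(out)] <- median(out[is.finite(out)])
  }
  out <- out - median(out)
  if (per_chromosome_center) {
    if (is.null(probe_map)) stop_bad("per-chromosome centring needs a probe map")
    sex <- toupper(sub("^(chr|GGA)", "", probe_map$chrom, ignore.case = TRUE)) %in% c("Z", "W")
    for (ch in unique(probe_map$chrom[sex])) {
      idx <- which(probe_map$chrom == ch)
      out[idx] <- out[idx] - median(out[idx])
    }
  }
  out
}

#' Normalize every sample of a cohort
#'
#' @param cohort an `acgh_cohort`.
#' @inheritParams normalize_profile
#' @return The cohort with its `log2` matrix normalized.
#' @export
normalize_cohort <- function(cohort, span = 0.3, per_chromosome_center = FALSE) {
  stopifnot(inherits(cohort, "acgh_cohort"))
  for (j in seq_len(ncol(cohort$log2)))
    cohort$log2[, j] <- normalize_profile(cohort$log2[, j], cohort$probe_map,
                                          cohort$covariate, span = span,
                                          per_chromosome_center = per_chromosome_center)
  cohort$normalized <- TRUE
  cohort
}
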