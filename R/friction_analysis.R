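#' Friction coefficient of a single sliding trial
#'
#' Pointwise friction force \eqn{F_f = \sqrt{F_x^2 + F_y^2}} and
#' coefficient \eqn{\mu(t) = F_f / F_z}, evaluated on samples whose
#' normal force is at least \code{fz_floor} (default 0.1 N, guarding
#' against lift-off blow-ups); the trial value is the mean of
#' \eqn{\mu(t)} over retained samples (mean of ratios).  Set
#' \code{ratio_of_means = TRUE} for the alternative
#' \eqn{\langle F_f\rangle / \langle F_z\rangle} sensitivity check.
#'
#' @param trace a \code{\link{simulate_force_trace}}-style data frame
#'   with columns \code{fx}, \code{fy}, \code{fz}.
#' @param fz_floor minimum normal force (N) for a sample to be scored.
#' @param ratio_of_means use ratio of means instead of mean of ratios.
#' @return Trial friction coefficient (dimensionless).
#' @export
trial_friction <- function(trace, fz_floor = 0.1, ratio_of_means = FALSE) {
  if (nrow(trace) == 0) stop("empty force trace")
  keep <- trace$fz >= fz_floor
  if (!any(keep)) stop("no samples with normal force above fz_floor")
  ff <- sqrt(trace$fx[keep]^2 + trace$fy[keep]^2)
  if (ratio_of_means) mean(ff) / mean(trace$fz[keep]) else mean(ff / trace$fz[keep])
}

#' Per-sample mean friction coefficients
#'
#' Arithmetic mean of the per-trial friction coefficients for each
#' sample, over all participants and trials.
#'
#' @param records a \code{friction_records} data frame (columns
#'   \code{sample}, \code{mu}, ...).
#' @param sample_ids optional vector of ids that must all be present; an
#'   absent id is an error naming it.
#' @return An object of class \code{"friction_summary"}: data frame with
#'   columns \code{sample}, \code{mean_mu}, \code{n_trials}.
#' @export
sample_friction_means <- function(records, sample_ids = NULL) {
  if (!all(c("sample", "mu") %in% names(records)))
    stop("records must have columns 'sample' and 'mu'")
  if (!is.null(sample_ids)) {
    missing_ids <- setdiff(sample_ids, records$sample)
    if (length(missing_ids))
      stop("no friction records for sample(s): ",
           paste(missing_ids, collapse = ", "))
  }
  agg <- stats::aggregate(mu ~ sample, data = records,
                          FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(sample = agg$sample, mean_mu = agg$mu[, 1],
                    n_trials = as.integer(agg$mu[, 2]))
  structure(out[order(out$sample), ],
            class = c("friction_summary", "data.frame"))
}
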