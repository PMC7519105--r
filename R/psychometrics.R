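#' Metric-based stimulus intensity of triplet decisions
#'
#' \eqn{S = |D_{left,ref} - D_{right,ref}|}: how strongly the
#' dissimilarity metric separates the two alternatives from the
#' reference.
#'
#' @param decisions data frame with \code{ref}, \code{left}, \code{right}.
#' @param D symmetric dissimilarity matrix with sample-id dimnames.
#' @return Numeric vector of stimulus intensities.
#' @export
stimulus_metric <- function(decisions, D) {
  ids <- rownames(D)
  if (!all(c(decisions$ref, decisions$left, decisions$right) %in% ids))
    stop("decision references a sample id absent from the dissimilarity table")
  abs(D[cbind(decisions$left, decisions$ref)] -
      D[cbind(decisions$right, decisions$ref)])
}

#' Friction-based stimulus intensity
#'
#' \eqn{S = ||\mu_{left} - \mu_{ref}| - |\mu_{right} - \mu_{ref}||},
#' computed from the per-trial friction coefficients of the three
#' samples involved in a decision.
#'
#' @param mu_left,mu_right,mu_ref friction coefficients (vectorized).
#' @return Numeric vector of stimulus intensities.
#' @export
stimulus_friction <- function(mu_left, mu_right, mu_ref) {
  if (anyNA(c(mu_left, mu_right, mu_ref)))
    stop("missing friction coefficient in stimulus computation")
  abs(abs(mu_left - mu_ref) - abs(mu_right - mu_ref))
}

#' Expected choice side under a dissimilarity structure
#'
#' The side whose dissimilarity to the reference is smaller; exact ties
#' return \code{NA} (they carry no stimulus and are excluded from
#' psychometric curves).
#'
#' @param d_left,d_right dissimilarities (or |mu - mu_ref| differences)
#'   of the two alternatives to the reference.
#' @return Character vector \code{"left"}/\code{"right"}, \code{NA} on ties.
#' @export
expected_side <- function(d_left, d_right) {
  out <- ifelse(d_left < d_right, "left",
                ifelse(d_right < d_left, "right", NA_character_))
  n_tie <- sum(is.na(out))
  if (n_tie > 0)
    message(n_tie, " tied decision(s) excluded (equal dissimilarity to reference)")
  out
}

#' Bin decisions into an equal-count psychometric curve
#'
#' Sorts the stimulus intensities, splits them into \code{n_bins} bins
#' of equal count (sizes differing by at most one), and reports the mean
#' stimulus and the fraction of decisions matching the expectation per
#' bin.
#'
#' @param S stimulus intensities.
#' @param matched logical: did the decision match the expected side?
#'   (\code{NA} pairs with tied stimuli are dropped.)
#' @param n_bins number of bins (>= 2).
#' @return An object of class \code{"psychometric_curve"}: data frame
#'   with columns \code{S} (bin mean stimulus), \code{prop} (proportion
#'   matched) and \code{n} (bin count).
#' @export
bin_proportions <- function(S, matched, n_bins = 10) {
  keep <- !is.na(matched) & !is.na(S)
  S <- S[keep]; matched <- matched[keep]
  if (n_bins < 2) stop("need at least 2 bins")
  if (length(S) < 2 * n_bins)
    stop("too few data points (", length(S), ") for ", n_bins, " bins")
  ord <- order(S)
  sizes <- rep(length(S) %/% n_bins, n_bins)
  extra <- length(S) %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  bin <- rep(seq_len(n_bins), times = sizes)
  out <- data.frame(
    S = as.numeric(tapply(S[ord], bin, mean)),
    prop = as.numeric(tapply(matched[ord], bin, mean)),
    n = as.integer(table(bin)))
  structure(out, class = c("psychometric_curve", "data.frame"))
}

#' Weibull psychometric function
#'
#' \eqn{P(S) = 1 - 0.5 \exp(-(k S)^d)}: rises from the 2AFC chance level
#' 0.5 at \eqn{S = 0} towards 1.
#'
#' @param S stimulus intensity.
#' @param k rate parameter (inverse stimulus units).
#' @param d shape parameter.
#' @return Proportion of expected decisions.
#' @export
weibull_p <- function(S, k, d) 1 - 0.5 * exp(-(k * S)^d)

#' Fit the Weibull sigmoid to a psychometric curve
#'
#' Nonlinear least squares of the binned proportions; a coarse grid
#' search seeds the optimizer and serves as fallback if it fails to
#' converge.  Goodness of fit \code{R} is the Pearson correlation
#' between fitted and observed bin proportions.
#'
#' @param curve a \code{\link{bin_proportions}} result (>= 3 bins).
#' @return An object of class \code{"weibull_fit"}: list with \code{k},
#'   \code{d}, \code{R}, \code{converged}.
#' @export
fit_weibull <- function(curve) {
  if (nrow(curve) < 3) stop("need at least 3 bins to fit the sigmoid")
  s_scale <- stats::median(curve$S[curve$S > 0])
  grid <- expand.grid(k = exp(seq(log(0.05 / s_scale), log(50 / s_scale),
                                  length.out = 40)),
                      d = exp(seq(log(0.3), log(5), length.out = 25)))
  sse <- vapply(seq_len(nrow(grid)), function(i)
    sum((weibull_p(curve$S, grid$k[i], grid$d[i]) - curve$prop)^2), numeric(1))
  start <- grid[which.min(sse), ]
  fit <- tryCatch(
    minpack.lm::nlsLM(prop ~ 1 - 0.5 * exp(-(k * S)^d), data = curve,
                      start = list(k = start$k, d = start$d),
                      lower = c(1e-8, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    k <- start$k; d <- start$d; converged <- FALSE
  } else {
    co <- stats::coef(fit); k <- co[["k"]]; d <- co[["d"]]; converged <- TRUE
  }
  pred <- weibull_p(curve$S, k, d)
  R <- if (stats::sd(pred) == 0 || stats::sd(curve$prop) == 0) NA_real_
       else stats::cor(pred, curve$prop)
  structure(list(k = k, d = d, R = R, converged = converged),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("weibull_fit: k = %.4g, d = %.4g, R = %.3f%s\n", x$k, x$d,
              x$R, if (x$converged) "" else " (grid fallback)"))
  invisible(x)
}

#' Just-noticeable difference from a Weibull fit
#'
#' Stimulus intensity at which the proportion of expected decisions
#' crosses \code{level} (default 0.75, the 2AFC standard threshold):
#' closed form \eqn{S^* = (-\ln(2(1 - level)))^{1/d} / k}.
#'
#' @param fit a \code{\link{fit_weibull}} result (or list with \code{k},
#'   \code{d}).
#' @param level threshold proportion, in (0.5, 1).
#' @return The JND in stimulus units.
#' @export
jnd <- function(fit, level = 0.75) {
  if (level <= 0.5 || level >= 1) stop("level must lie in (0.5, 1)")
  (-log(2 * (1 - level)))^(1 / fit$d) / fit$k
}

#' Structural agreement rates of similarity decisions
#'
#' Two conditions per decision set, counting only unbiased triplets:
#' (a) the two alternatives share the same Hurst exponent and exactly
#' one shares the reference's topography -- the rate of choosing the
#' topography-matched sample; (b) the two alternatives share the same
#' topography and exactly one shares the reference's Hurst exponent --
#' the rate of choosing the H-matched sample.  Each rate comes with an
#' exact two-sided binomial test against chance (0.5).
#'
#' @param decisions a decision data frame (\code{ref}, \code{left},
#'   \code{right}, \code{choice}).
#' @param labels data frame with columns \code{id}, \code{topo_id},
#'   \code{hurst} for every sample.
#' @return An object of class \code{"agreement_report"}: data frame with
#'   one row per condition: \code{condition}, \code{n}, \code{n_agree},
#'   \code{percent}, \code{p_value} (rows with \code{n = 0} report
#'   \code{NA}s).
#' @export
agreement_rates <- function(decisions, labels) {
  need <- unique(c(decisions$ref, decisions$left, decisions$right))
  if (!all(need %in% labels$id))
    stop("labels missing for sample(s): ",
         paste(setdiff(need, labels$id), collapse = ", "))
  topo <- stats::setNames(labels$topo_id, labels$id)
  hurst <- stats::setNames(labels$hurst, labels$id)
  t_ref <- topo[decisions$ref]; t_l <- topo[decisions$left]; t_r <- topo[decisions$right]
  h_ref <- hurst[decisions$ref]; h_l <- hurst[decisions$left]; h_r <- hurst[decisions$right]

  one_row <- function(condition, sel, match_left) {
    n <- sum(sel)
    if (n == 0)
      return(data.frame(condition = condition, n = 0L, n_agree = NA_integer_,
                        percent = NA_real_, p_value = NA_real_))
    agree <- (decisions$choice[sel] == "left") == match_left[sel]
    bt <- stats::binom.test(sum(agree), n, p = 0.5)
    data.frame(condition = condition, n = n, n_agree = sum(agree),
               percent = 100 * mean(agree), p_value = bt$p.value)
  }
  # (a) same-H alternatives, exactly one topography match with reference
  sel_a <- (h_l == h_r) & xor(t_l == t_ref, t_r == t_ref)
  # (b) same-topography alternatives, exactly one H match with reference
  sel_b <- (t_l == t_r) & xor(h_l == h_ref, h_r == h_ref)
  out <- rbind(one_row("same_topography_as_reference", sel_a, t_l == t_ref),
               one_row("same_hurst_as_reference", sel_b, h_l == h_ref))
  structure(out, class = c("agreement_report", "data.frame"))
}

#' Build a psychometric curve and Weibull fit from decisions
#'
#' Convenience wrapper: computes the stimulus intensity (metric- or
#' friction-based), the expected side, bins the matched proportions and
#' fits the Weibull sigmoid.
#'
#' @param decisions a decision data frame.
#' @param D dissimilarity matrix (metric-based stimulus), or \code{NULL}
#'   when \code{friction} is given.
#' @param friction optional \code{friction_records} aligned to the
#'   decisions (roles ref/left/right per participant and trial); when
#'   supplied the friction-based stimulus is used.
#' @param n_bins bins for the curve.
#' @return List with \code{curve}, \code{fit}, \code{jnd} and the
#'   per-decision \code{S}/\code{matched} vectors.
#' @export
psychometric_analysis <- function(decisions, D = NULL, friction = NULL,
                                  n_bins = 10) {
  if (is.null(D) && is.null(friction))
    stop("supply a dissimilarity table or friction records")
  if (is.null(friction)) {
    S <- stimulus_metric(decisions, D)
    exp_side <- expected_side(D[cbind(decisions$left, decisions$ref)],
                              D[cbind(decisions$right, decisions$ref)])
  } else {
    key <- function(p, t, role) paste(p, t, role)
    mu <- stats::setNames(friction$mu,
                          key(friction$participant, friction$trial, friction$role))
    mu_ref <- mu[key(decisions$participant, decisions$trial, "ref")]
    mu_l <- mu[key(decisions$participant, decisions$trial, "left")]
    mu_r <- mu[key(decisions$participant, decisions$trial, "right")]
    S <- stimulus_friction(mu_l, mu_r, mu_ref)
    exp_side <- expected_side(abs(mu_l - mu_ref), abs(mu_r - mu_ref))
  }
  matched <- decisions$choice == exp_side
  curve <- bin_proportions(S, matched, n_bins)
  fit <- fit_weibull(curve)
  list(curve = curve, fit = fit, jnd = jnd(fit), S = S, matched = matched)
}
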