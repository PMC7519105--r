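#' Configuration of the synthetic 2AFC observer
#'
#' Collects the parameters of the simulated observer: the planted
#' topography salience \code{alpha_true} used to build the generative
#' dissimilarity structure, the decision-noise scale \code{noise_scale}
#' (the logistic scale applied to dissimilarity differences), a lapse
#' rate, seeded RNG, and the experiment size.
#'
#' Presets mirror the study designs: \code{"visual"} 15 participants x 50
#' triplets, \code{"tapping"} 10 x 28, \code{"sliding"} 13 x 28, each
#' drawn from the 252 triplet combinations of 9 samples.  The preset
#' \code{alpha_true} values (2.68, 1.22, 0.97 mm^-1) mirror the salience
#' hierarchy reported for the three modalities.
#'
#' @param modality \code{"visual"}, \code{"tapping"}, \code{"sliding"} or
#'   \code{"custom"}.
#' @param alpha_true planted topography salience (mm^-1).
#' @param noise_scale decision-noise scale sigma (mm^-1, >= 0); 0 gives a
#'   deterministic observer.
#' @param lapse probability of a uniformly random choice.
#' @param seed integer RNG seed; every random draw of the simulation
#'   derives from it.
#' @param n_participants,triplets_per_participant experiment size.
#' @param link \code{"logistic"} (default) or \code{"probit"} choice link.
#' @param mu_intercept,mu_slope planted friction line: population mean
#'   friction coefficient \code{mu_intercept + mu_slope * kappa}.
#'   Defaults run from 0.35 at kappa = 1 mm^-1 to 0.45 at 3.5 mm^-1.
#' @param participant_sd,trial_sd friction noise: sd of the per-participant
#'   additive offset and of the per-measurement trial noise.
#' @return An object of class \code{"observer_config"}.
#' @export
observer_config <- function(modality = c("custom", "visual", "tapping", "sliding"),
                            alpha_true = 1, noise_scale = 0.5, lapse = 0,
                            seed = 1L, n_participants = NULL,
                            triplets_per_participant = NULL,
                            link = c("logistic", "probit"),
                            mu_intercept = 0.35 - 0.1 / 2.5,
                            mu_slope = 0.1 / 2.5,
                            participant_sd = 0.05, trial_sd = 0.02) {
  modality <- match.arg(modality)
  link <- match.arg(link)
  preset <- switch(modality,
    visual = list(n = 15L, t = 50L, a = 2.68),
    tapping = list(n = 10L, t = 28L, a = 1.22),
    sliding = list(n = 13L, t = 28L, a = 0.97),
    custom = list(n = 10L, t = 28L, a = NULL))
  if (is.null(n_participants)) n_participants <- preset$n
  if (is.null(triplets_per_participant)) triplets_per_participant <- preset$t
  if (modality != "custom" && missing(alpha_true) && !is.null(preset$a))
    alpha_true <- preset$a
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  if (lapse < 0 || lapse > 1) stop("lapse must lie in [0, 1]")
  structure(list(modality = modality, alpha_true = alpha_true,
                 noise_scale = noise_scale, lapse = lapse,
                 seed = as.integer(seed), n_participants = as.integer(n_participants),
                 triplets_per_participant = as.integer(triplets_per_participant),
                 link = link, mu_intercept = mu_intercept, mu_slope = mu_slope,
                 participant_sd = participant_sd, trial_sd = trial_sd),
            class = "observer_config")
}

#' Enumerate all 2AFC triplets of a sample set
#'
#' Every ordered choice of a reference sample times an unordered pair of
#' two distinct other samples: \eqn{n \binom{n-1}{2}} triplets (252 for
#' nine samples).
#'
#' @param sample_ids character vector of at least three distinct ids.
#' @return Data frame with columns \code{ref}, \code{a}, \code{b}
#'   (\code{a < b} lexicographically; the pair is unordered).
#' @export
enumerate_triplets <- function(sample_ids) {
  sample_ids <- as.character(sample_ids)
  if (length(unique(sample_ids)) < 3)
    stop("need at least 3 distinct sample ids")
  sample_ids <- unique(sample_ids)
  out <- lapply(sample_ids, function(r) {
    others <- sort(setdiff(sample_ids, r))
    pairs <- utils::combn(others, 2)
    data.frame(ref = r, a = pairs[1, ], b = pairs[2, ])
  })
  do.call(rbind, out)
}

#' Planted generative dissimilarity table
#'
#' The ground-truth pairwise dissimilarity the synthetic observer's
#' decisions are based on: \code{\link{metric_D}} with
#' \code{alpha = alpha_true} applied to per-sample rms curvatures and
#' topography labels.
#'
#' @param cfg an \code{\link{observer_config}}.
#' @param summaries a \code{\link{roughness_summary}} (or any data frame
#'   with columns \code{id}, \code{topo_id}, \code{kappa}).
#' @return Symmetric dissimilarity matrix (mm^-1), dimnames = sample ids.
#' @export
planted_dissimilarity <- function(cfg, summaries) {
  stopifnot(inherits(cfg, "observer_config"))
  kappas <- stats::setNames(summaries$kappa, summaries$id)
  dissimilarity_matrix(kappas, summaries$topo_id, cfg$alpha_true)
}

choice_prob_left <- function(dl, dr, sigma, lapse, link = "logistic") {
  linkfun <- if (link == "probit") stats::pnorm else stats::plogis
  p <- if (sigma > 0) linkfun((dr - dl) / sigma)
       else ifelse(dl < dr, 1, ifelse(dl > dr, 0, 0.5))
  lapse * 0.5 + (1 - lapse) * p
}

#' Simulate 2AFC decisions for a set of triplets
#'
#' With probability \code{lapse} the choice is uniformly random;
#' otherwise the probability of choosing the left sample is
#' \code{link((D[right,ref] - D[left,ref]) / sigma)}, the deterministic
#' argmin as \code{sigma -> 0} (an exact tie at \code{sigma = 0} falls
#' back to a fair coin).
#'
#' @param triplets data frame with columns \code{ref}, \code{left},
#'   \code{right} (or \code{a}/\code{b}, taken as left/right).
#' @param D symmetric dissimilarity matrix with sample-id dimnames.
#' @param sigma decision-noise scale.
#' @param lapse lapse rate.
#' @param link \code{"logistic"} or \code{"probit"}.
#' @return The triplet data frame with a \code{choice} column
#'   (\code{"left"}/\code{"right"}).  RNG: uses the current stream.
#' @export
simulate_decision <- function(triplets, D, sigma, lapse = 0,
                              link = "logistic") {
  if (!all(c("left", "right") %in% names(triplets))) {
    triplets$left <- triplets$a
    triplets$right <- triplets$b
  }
  if (max(abs(D - t(D))) > 1e-12) stop("dissimilarity table must be symmetric")
  dl <- D[cbind(triplets$left, triplets$ref)]
  dr <- D[cbind(triplets$right, triplets$ref)]
  p <- choice_prob_left(dl, dr, sigma, lapse, link)
  triplets$choice <- ifelse(stats::runif(nrow(triplets)) < p, "left", "right")
  triplets
}

#' Simulate a full triplet similarity experiment
#'
#' Per participant, draws a seeded random subset (without replacement) of
#' all triplets of the nine samples, randomizes the left/right assignment
#' of each pair, and answers each triplet with the noisy planted-metric
#' observer.  All randomness flows from \code{cfg$seed}; reruns are
#' identical.
#'
#' @param cfg an \code{\link{observer_config}}.
#' @param summaries a \code{\link{roughness_summary}} table (columns
#'   \code{id}, \code{topo_id}, \code{kappa}) for the samples.
#' @return An object of class \code{"decision_set"}: data frame with
#'   columns \code{modality}, \code{participant}, \code{trial},
#'   \code{ref}, \code{left}, \code{right}, \code{choice}; attribute
#'   \code{"config"} stores the generating configuration.
#' @export
simulate_experiment <- function(cfg, summaries) {
  stopifnot(inherits(cfg, "observer_config"))
  all_triplets <- enumerate_triplets(summaries$id)
  if (cfg$triplets_per_participant > nrow(all_triplets))
    stop("triplets_per_participant exceeds the ", nrow(all_triplets),
         " available triplet combinations")
  D <- planted_dissimilarity(cfg, summaries)
  out <- with_preserved_rng(cfg$seed, {
    res <- lapply(seq_len(cfg$n_participants), function(p) {
      idx <- sample.int(nrow(all_triplets), cfg$triplets_per_participant)
      tr <- all_triplets[idx, ]
      flip <- stats::runif(nrow(tr)) < 0.5
      tr$left <- ifelse(flip, tr$b, tr$a)
      tr$right <- ifelse(flip, tr$a, tr$b)
      tr <- simulate_decision(tr, D, cfg$noise_scale, cfg$lapse, cfg$link)
      data.frame(modality = cfg$modality, participant = p,
                 trial = seq_len(nrow(tr)), ref = tr$ref,
                 left = tr$left, right = tr$right, choice = tr$choice)
    })
    do.call(rbind, res)
  })
  rownames(out) <- NULL
  structure(out, config = cfg, planted_D = D,
            class = c("decision_set", "data.frame"))
}

#' Simulate per-trial friction records
#'
#' Per trial and sample, the friction coefficient is drawn from the
#' planted line \eqn{\mu = a + b\kappa} plus a per-participant additive
#' offset and independent trial noise.  With default \code{(a, b)} the
#' population mean runs from 0.35 at \eqn{\kappa = 1} mm^-1 to 0.45 at
#' \eqn{\kappa = 3.5} mm^-1.
#'
#' @param cfg an \code{\link{observer_config}}.
#' @param summaries roughness summary with \code{id} and \code{kappa}.
#' @param decisions optional \code{\link{simulate_experiment}} result; if
#'   supplied, friction is generated for exactly its (participant, trial)
#'   sample triplets so the records align with the decisions.  Otherwise
#'   one record per sample per participant per trial index is generated.
#' @return An object of class \code{"friction_records"}: data frame with
#'   columns \code{participant}, \code{trial}, \code{sample}, \code{mu},
#'   plus \code{role} (ref/left/right) when aligned to decisions.
#' @export
simulate_friction <- function(cfg, summaries, decisions = NULL) {
  stopifnot(inherits(cfg, "observer_config"))
  kappa <- stats::setNames(summaries$kappa, summaries$id)
  mu_base <- cfg$mu_intercept + cfg$mu_slope * kappa
  if (any(mu_base <= 0))
    stop("friction parameterization yields non-positive mean mu")
  out <- with_preserved_rng(cfg$seed + 1L, {
    if (is.null(decisions)) {
      grid <- expand.grid(participant = seq_len(cfg$n_participants),
                          trial = seq_len(cfg$triplets_per_participant),
                          sample = names(kappa), stringsAsFactors = FALSE)
      grid <- grid[order(grid$participant, grid$trial), ]
      offs <- stats::rnorm(cfg$n_participants, 0, cfg$participant_sd)
      grid$mu <- mu_base[grid$sample] + offs[grid$participant] +
        stats::rnorm(nrow(grid), 0, cfg$trial_sd)
      grid
    } else {
      long <- do.call(rbind, lapply(c("ref", "left", "right"), function(role)
        data.frame(participant = decisions$participant,
                   trial = decisions$trial, sample = decisions[[role]],
                   role = role)))
      long <- long[order(long$participant, long$trial), ]
      np <- max(decisions$participant)
      offs <- stats::rnorm(np, 0, cfg$participant_sd)
      long$mu <- mu_base[long$sample] + offs[long$participant] +
        stats::rnorm(nrow(long), 0, cfg$trial_sd)
      long
    }
  })
  if (any(out$mu <= 0))
    stop("friction noise parameterization produced non-positive mu; reduce noise")
  rownames(out) <- NULL
  structure(out, config = cfg, class = c("friction_records", "data.frame"))
}

#' Simulate a circular-sliding force trace
#'
#' Fingertip friction during circular sliding: the lateral force rotates
#' with the motion, \code{Fx = mu Fz cos(theta)}, \code{Fy = mu Fz
#' sin(theta)}, with \code{theta} advancing at \code{cycles_per_s}
#' (typical exploration speed 0.5--1 cycles/s).  Optional multiplicative
#' noise perturbs each force channel.
#'
#' @param mu_true planted friction coefficient.
#' @param fz_profile vector of normal forces (N), all > 0.
#' @param dt sampling interval (s).
#' @param cycles_per_s rotation rate of the circular motion.
#' @param noise_sd sd of multiplicative noise (fraction of signal).
#' @return An object of class \code{"force_trace"}: data frame with
#'   columns \code{t}, \code{fx}, \code{fy}, \code{fz}.
#' @export
simulate_force_trace <- function(mu_true, fz_profile, dt = 0.001,
                                 cycles_per_s = 0.75, noise_sd = 0) {
  if (any(fz_profile <= 0)) stop("fz_profile must be positive throughout")
  n <- length(fz_profile)
  t <- (seq_len(n) - 1) * dt
  theta <- 2 * pi * cycles_per_s * t
  fx <- mu_true * fz_profile * cos(theta)
  fy <- mu_true * fz_profile * sin(theta)
  fz <- fz_profile
  if (noise_sd > 0) {
    fx <- fx * (1 + stats::rnorm(n, 0, noise_sd))
    fy <- fy * (1 + stats::rnorm(n, 0, noise_sd))
    fz <- fz * (1 + stats::rnorm(n, 0, noise_sd))
  }
  structure(data.frame(t = t, fx = fx, fy = fy, fz = fz),
            class = c("force_trace", "data.frame"))
}
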