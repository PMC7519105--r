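#' Ordinal (non-metric) embedding of triplet similarity decisions
#'
#' Recovers an n-dimensional perceptual space from 2AFC triplet
#' decisions by maximizing the likelihood of the observed choices.  The
#' probability of choosing "left" is
#' \code{link((d(right, ref) - d(left, ref)) / link_scale)} with
#' Euclidean distances between the embedded samples; a weak Gaussian
#' prior on coordinates resolves the translation/rotation degeneracy in
#' practice.  Optimization is multi-start quasi-Newton (BFGS) with
#' analytic gradients; the best likelihood wins, ties broken by start
#' index.  Returned coordinates are centred at the origin and scaled to
#' unit rms norm; the absolute scale absorbed by this normalization is
#' kept in the \code{scale} field so likelihoods can be re-evaluated.
#'
#' @name ordinal_embedding
NULL

decision_indices <- function(decisions, ids) {
  list(ref = match(decisions$ref, ids),
       left = match(decisions$left, ids),
       right = match(decisions$right, ids),
       y = decisions$choice == "left")
}

pair_dist <- function(X, i, j) {
  d2 <- rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2)
  sqrt(pmax(d2, 1e-300))
}

embed_nll <- function(X, idx, link_scale, prior, link = "logistic") {
  dl <- pair_dist(X, idx$left, idx$ref)
  dr <- pair_dist(X, idx$right, idx$ref)
  z <- (dr - dl) / link_scale
  ll <- if (link == "probit") {
    stats::pnorm(ifelse(idx$y, z, -z), log.p = TRUE)
  } else {
    stats::plogis(ifelse(idx$y, z, -z), log.p = TRUE)
  }
  -sum(ll) + prior * sum(X^2)
}

embed_nll_grad <- function(X, idx, link_scale, prior, link = "logistic") {
  n <- nrow(X)
  dl <- pair_dist(X, idx$left, idx$ref)
  dr <- pair_dist(X, idx$right, idx$ref)
  z <- (dr - dl) / link_scale
  # dNLL/dz = P(left) - y for the logistic link; probit uses the
  # inverse Mills ratio with the matching sign.
  dz <- if (link == "probit") {
    s <- ifelse(idx$y, 1, -1)
    -s * exp(stats::dnorm(s * z, log = TRUE) -
             stats::pnorm(s * z, log.p = TRUE))
  } else {
    stats::plogis(z) - idx$y
  }
  ul <- (X[idx$left, , drop = FALSE] - X[idx$ref, , drop = FALSE]) / dl
  ur <- (X[idx$right, , drop = FALSE] - X[idx$ref, , drop = FALSE]) / dr
  G <- matrix(0, n, ncol(X))
  add_rows <- function(G, rows, contrib) {
    agg <- rowsum(contrib, rows)
    take <- as.integer(rownames(agg))
    G[take, ] <- G[take, , drop = FALSE] + agg
    G
  }
  w <- dz / link_scale
  G <- add_rows(G, idx$right, w * ur)
  G <- add_rows(G, idx$left, -w * ul)
  G <- add_rows(G, idx$ref, w * (ul - ur))
  G + 2 * prior * X
}

#' Log-likelihood of one decision under an embedding
#'
#' @param space a \code{perceptual_space} (or a plain coordinate matrix
#'   with sample-id rownames).
#' @param decision one-row data frame with \code{ref}, \code{left},
#'   \code{right}, \code{choice} (several rows give the summed
#'   log-likelihood of each row as a vector).
#' @param link_scale scale of the choice link applied to the distance
#'   difference; defaults to the space's fitted effective scale.
#' @param link \code{"logistic"} or \code{"probit"}.
#' @return Log-probability of the recorded choice(s).
#' @export
decision_loglik <- function(space, decision, link_scale = NULL,
                            link = "logistic") {
  X <- if (inherits(space, "perceptual_space")) space$coordinates else space
  if (is.null(link_scale))
    link_scale <- if (inherits(space, "perceptual_space"))
      space$link_scale / space$scale else 1
  ids <- rownames(X)
  if (!all(c(decision$ref, decision$left, decision$right) %in% ids))
    stop("decision references a sample id absent from the embedding")
  idx <- decision_indices(decision, ids)
  dl <- pair_dist(X, idx$left, idx$ref)
  dr <- pair_dist(X, idx$right, idx$ref)
  z <- (dr - dl) / link_scale
  if (link == "probit") stats::pnorm(ifelse(idx$y, z, -z), log.p = TRUE)
  else stats::plogis(ifelse(idx$y, z, -z), log.p = TRUE)
}

#' Fit a perceptual space to triplet decisions
#'
#' @param decisions a \code{decision_set} data frame.
#' @param n_dims embedding dimensionality.
#' @param n_starts number of seeded random restarts (best fit wins).
#' @param link_scale link scale held fixed during optimization (the
#'   coordinate scale is free, so this only sets the units).
#' @param prior weight of the Gaussian coordinate prior.
#' @param seed RNG seed for the restarts.
#' @param link choice link.
#' @param maxit BFGS iteration cap per start.
#' @return An object of class \code{"perceptual_space"}: list with
#'   \code{coordinates} (samples x dims, centred, unit rms norm),
#'   \code{scale} (rms norm of the unnormalized optimum, so distances
#'   times \code{scale} are in likelihood units), \code{n_dims},
#'   \code{loglik} (at the optimum, prior excluded), \code{link},
#'   \code{link_scale}, \code{n_decisions} and provenance.
#' @export
fit_embedding <- function(decisions, n_dims = 3, n_starts = 16,
                          link_scale = 1, prior = 1e-3, seed = 1L,
                          link = c("logistic", "probit"), maxit = 500) {
  link <- match.arg(link)
  ids <- sort(unique(c(decisions$ref, decisions$left, decisions$right)))
  if (length(ids) < n_dims + 1)
    stop("need at least n_dims + 1 distinct samples in the decisions")
  idx <- decision_indices(decisions, ids)
  n <- length(ids)
  fn <- function(par) embed_nll(matrix(par, n, n_dims), idx, link_scale, prior, link)
  gr <- function(par) as.vector(embed_nll_grad(matrix(par, n, n_dims),
                                               idx, link_scale, prior, link))
  fits <- with_preserved_rng(seed, {
    lapply(seq_len(n_starts), function(s) {
      par0 <- stats::rnorm(n * n_dims)
      stats::optim(par0, fn, gr, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10))
    })
  })
  vals <- vapply(fits, `[[`, 0, "value")
  if (all(!is.finite(vals)))
    stop("embedding optimization failed to converge in all starts; ",
         "values: ", paste(signif(vals, 4), collapse = ", "))
  best <- which.min(vals)            # first index wins ties
  X <- matrix(fits[[best]]$par, n, n_dims)
  ll <- -embed_nll(X, idx, link_scale, prior = 0, link)
  X <- sweep(X, 2, colMeans(X))
  sc <- sqrt(mean(rowSums(X^2)))
  if (sc > 0) X <- X / sc
  rownames(X) <- ids
  structure(list(coordinates = X, scale = sc, n_dims = n_dims,
                 loglik = ll, link = link, link_scale = link_scale,
                 n_decisions = nrow(decisions),
                 provenance = list(seed = seed, n_starts = n_starts,
                                   prior = prior, convergence = fits[[best]]$convergence)),
            class = "perceptual_space")
}

#' @export
print.perceptual_space <- function(x, ...) {
  cat(sprintf("perceptual_space: %d samples in %d dims, logLik %.2f over %d decisions\n",
              nrow(x$coordinates), x$n_dims, x$loglik, x$n_decisions))
  invisible(x)
}

#' Pairwise distances of an embedded space
#'
#' @param space a \code{perceptual_space}.
#' @return Symmetric matrix of Euclidean distances between samples (unit
#'   rms-norm scale).
#' @export
space_distances <- function(space) {
  as.matrix(stats::dist(space$coordinates))
}

#' Cross-validate embedding dimensionality
#'
#' Seeded k-fold partition of the decision set; for each candidate
#' dimensionality, fits the embedding on each training set and scores
#' the held-out decisions by their mean log-likelihood per decision
#' (evaluated at the fitted scale) and by the fraction predicted
#' correctly.
#'
#' @param decisions a \code{decision_set}.
#' @param dims_list candidate dimensionalities.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold partition and the fits.
#' @param ... further arguments to \code{\link{fit_embedding}} (e.g.
#'   \code{n_starts}).
#' @return An object of class \code{"cv_report"}: data frame with one
#'   row per dimensionality: \code{n_dims}, \code{mean_loglik},
#'   \code{sd_loglik} (across folds), \code{mean_accuracy}.
#' @export
crossvalidate_dims <- function(decisions, dims_list = 1:5, k = 10,
                               seed = 1L, ...) {
  n <- nrow(decisions)
  if (n < k) stop("fewer decisions than folds")
  fold <- with_preserved_rng(seed, sample(rep(seq_len(k), length.out = n)))
  rows <- lapply(dims_list, function(nd) {
    scores <- vapply(seq_len(k), function(f) {
      train <- decisions[fold != f, , drop = FALSE]
      test <- decisions[fold == f, , drop = FALSE]
      sp <- fit_embedding(train, n_dims = nd, seed = seed + f, ...)
      ll <- decision_loglik(sp, test)
      X <- sp$coordinates
      idx <- decision_indices(test, rownames(X))
      pred_left <- pair_dist(X, idx$left, idx$ref) < pair_dist(X, idx$right, idx$ref)
      c(mean(ll), mean(pred_left == idx$y))
    }, numeric(2))
    data.frame(n_dims = nd, mean_loglik = mean(scores[1, ]),
               sd_loglik = stats::sd(scores[1, ]),
               mean_accuracy = mean(scores[2, ]))
  })
  structure(do.call(rbind, rows), k = k,
            class = c("cv_report", "data.frame"))
}

#' Bootstrap reliability of embedding distances
#'
#' Resamples the decision set with replacement B times, refits the
#' embedding on each resample, and reports the coefficient of variation
#' (sd/mean) of every pairwise distance across resampled embeddings
#' (each embedding carries the per-resample unit-rms normalization),
#' plus the average CoV.
#'
#' @param decisions a \code{decision_set}.
#' @param B number of bootstrap resamples (>= 2).
#' @param n_dims embedding dimensionality.
#' @param seed RNG seed.
#' @param ... further arguments to \code{\link{fit_embedding}}.
#' @return An object of class \code{"bootstrap_report"}: list with
#'   \code{B}, \code{pair_cov} (data frame \code{i}, \code{j},
#'   \code{cov}) and \code{average_cov}.
#' @export
bootstrap_reliability <- function(decisions, B = 1000, n_dims = 3,
                                  seed = 1L, ...) {
  if (B < 2) stop("need at least 2 bootstrap resamples")
  n <- nrow(decisions)
  draws <- with_preserved_rng(seed,
    replicate(B, sample.int(n, n, replace = TRUE), simplify = FALSE))
  dists <- lapply(seq_len(B), function(b) {
    sp <- fit_embedding(decisions[draws[[b]], , drop = FALSE],
                        n_dims = n_dims, seed = seed + b, ...)
    space_distances(sp)
  })
  ids <- rownames(dists[[1]])
  arr <- simplify2array(lapply(dists, function(d) d[ids, ids]))
  lt <- which(lower.tri(arr[, , 1]), arr.ind = TRUE)
  cov <- apply(lt, 1, function(ij) {
    v <- arr[ij[1], ij[2], ]
    stats::sd(v) / mean(v)
  })
  pair_cov <- data.frame(i = ids[lt[, 2]], j = ids[lt[, 1]], cov = cov)
  structure(list(B = B, pair_cov = pair_cov, average_cov = mean(cov)),
            class = "bootstrap_report")
}

#' Align an embedding so dimension 1 tracks the Hurst exponent
#'
#' Orthogonal rotation (Procrustes-style, no scaling) such that the
#' first coordinate axis is the direction whose coordinates correlate
#' best with the per-sample Hurst exponents; the sign is fixed so H
#' increases along +dim1.  Pairwise distances are unchanged.
#'
#' @param space a \code{perceptual_space}.
#' @param hurst_values named vector of Hurst exponents (names = sample
#'   ids) or a vector aligned with the coordinate rows.
#' @return The rotated \code{perceptual_space} (with a \code{rotation}
#'   field and \code{dim1_cor}, the achieved correlation).
#' @export
procrustes_align <- function(space, hurst_values) {
  X <- space$coordinates
  if (!is.null(names(hurst_values))) hurst_values <- hurst_values[rownames(X)]
  h <- as.numeric(hurst_values)
  if (stats::sd(h) == 0) {
    warning("all Hurst values equal; returning identity rotation")
    space$rotation <- diag(ncol(X))
    space$dim1_cor <- NA_real_
    return(space)
  }
  hc <- h - mean(h)
  # direction maximizing corr(Xw, h): w proportional to (X'X)^{-1} X'h
  w <- solve(crossprod(X), crossprod(X, hc))
  w <- w / sqrt(sum(w^2))
  Q <- qr.Q(qr(cbind(w, diag(ncol(X))[, -1, drop = FALSE])))
  if (sum(Q[, 1] * w) < 0) Q[, 1] <- -Q[, 1]
  Xr <- X %*% Q
  if (stats::cor(Xr[, 1], h) < 0) { Q[, 1] <- -Q[, 1]; Xr[, 1] <- -Xr[, 1] }
  space$coordinates <- Xr
  space$rotation <- Q
  space$dim1_cor <- stats::cor(Xr[, 1], h)
  space
}

#' Between- versus within-topography distance ratio
#'
#' Ratio of the mean pairwise distance between samples with different
#' labels to the mean pairwise distance within labels, computed in a
#' chosen coordinate plane (default dims 2 and 3, the plane mapping
#' topographic dissimilarity).
#'
#' @param space a \code{perceptual_space}.
#' @param topo_labels named vector of labels (names = sample ids) or a
#'   vector aligned with coordinate rows.
#' @param dims coordinate dimensions defining the projection plane.
#' @return The distance ratio (\code{Inf} when all within-label
#'   distances vanish).
#' @export
topo_distance_ratio <- function(space, topo_labels, dims = c(2, 3)) {
  X <- space$coordinates
  if (max(dims) > ncol(X)) stop("requested dims exceed the embedding dimensionality")
  if (!is.null(names(topo_labels))) topo_labels <- topo_labels[rownames(X)]
  labs <- as.character(topo_labels)
  if (length(unique(labs)) < 2) stop("need at least two distinct labels")
  if (any(table(labs) < 2)) stop("every label needs at least two members")
  D <- as.matrix(stats::dist(X[, dims, drop = FALSE]))
  same <- outer(labs, labs, `==`)
  lt <- lower.tri(D)
  within <- mean(D[lt & same])
  between <- mean(D[lt & !same])
  if (within == 0) return(Inf)
  between / within
}
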