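coords3 <- function() {
  X <- matrix(c(0, 0, 1, 0, 2, 0), 3, 2, byrow = TRUE)
  rownames(X) <- c("r", "x", "y")
  X
}

test_that("decision log-likelihood matches hand-computed logistic values", {
  X <- coords3()
  tie <- data.frame(ref = "x", left = "r", right = "y", choice = "left")
  # d(r,x) = 1 and d(y,x) = 1: exact tie, log 0.5
  expect_equal(decision_loglik(X, tie, link_scale = 1),
               log(0.5), tolerance = 1e-12)
  dec <- data.frame(ref = "r", left = "x", right = "y", choice = "left")
  # z = (2 - 1)/1 = 1: P(left) = plogis(1)
  expect_equal(decision_loglik(X, dec, link_scale = 1),
               log(0.731058578630005), tolerance = 1e-12)
  # swapping the labels maps P -> 1 - P
  swap <- data.frame(ref = "r", left = "y", right = "x", choice = "left")
  expect_equal(exp(decision_loglik(X, swap, link_scale = 1)),
               1 - 0.731058578630005, tolerance = 1e-12)
  bad <- data.frame(ref = "r", left = "zz", right = "x", choice = "left")
  expect_error(decision_loglik(X, bad), "absent")
})

test_that("likelihood is invariant under rotation and translation of the space", {
  set.seed(20)
  X <- matrix(rnorm(12), 4, 3)
  rownames(X) <- letters[1:4]
  dec <- data.frame(ref = c("a", "b", "c"), left = c("b", "c", "d"),
                    right = c("c", "d", "a"),
                    choice = c("left", "right", "left"))
  ll0 <- sum(decision_loglik(X, dec, link_scale = 1))
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  Xr <- sweep(X %*% Q, 2, c(5, -2, 0.3), `+`)
  rownames(Xr) <- rownames(X)
  expect_equal(sum(decision_loglik(Xr, dec, link_scale = 1)), ll0,
               tolerance = 1e-10)
})

test_that("noise-free 1D planted order is recovered by a 1D embedding", {
  ids <- c("a", "b", "c", "d")
  pos <- c(a = 0, b = 1, c = 2.2, d = 3.1)
  D <- as.matrix(dist(pos)); dimnames(D) <- list(ids, ids)
  tr <- enumerate_triplets(ids)
  tr$left <- tr$a; tr$right <- tr$b
  set.seed(1)
  dec <- simulate_decision(tr, D, sigma = 0)
  sp <- fit_embedding(dec, n_dims = 1, n_starts = 8, seed = 2)
  x <- sp$coordinates[ids, 1]
  ord <- order(x)
  expect_true(identical(ids[ord], ids) || identical(ids[rev(ord)], ids))
})

test_that("embedding recovers planted pairwise distances from a sliding-size experiment", {
  sm <- fake_summary()
  cfg <- observer_config("sliding", noise_scale = 0.3, seed = 21)
  dec <- simulate_experiment(cfg, sm)
  sp <- fit_embedding(dec, n_dims = 3, n_starts = 8, seed = 21)
  Dt <- planted_dissimilarity(cfg, sm)[rownames(sp$coordinates),
                                       rownames(sp$coordinates)]
  r <- cor(space_distances(sp)[lower.tri(Dt)], Dt[lower.tri(Dt)])
  expect_gte(r, 0.9)
  # recovery degrades monotonically with observer noise
  r_noisy <- sapply(c(2, 8), function(sig) {
    d2 <- simulate_experiment(observer_config("sliding", noise_scale = sig,
                                              seed = 21), sm)
    s2 <- fit_embedding(d2, n_dims = 3, n_starts = 4, seed = 21)
    D2 <- planted_dissimilarity(cfg, sm)[rownames(s2$coordinates),
                                         rownames(s2$coordinates)]
    cor(space_distances(s2)[lower.tri(D2)], D2[lower.tri(D2)])
  })
  expect_true(r > r_noisy[1] && r_noisy[1] > r_noisy[2])
})

test_that("cross-validation scores plateau at the planted dimensionality", {
  sm <- fake_summary()
  dec <- simulate_experiment(observer_config("visual", noise_scale = 0.4,
                                             seed = 22), sm)
  cv <- crossvalidate_dims(dec, dims_list = 1:4, k = 5, seed = 3, n_starts = 4)
  expect_identical(nrow(cv), 4L)
  # 3D fits the planted structure better than 1D ...
  expect_gt(cv$mean_loglik[3], cv$mean_loglik[1])
  # ... and adding a 4th dimension buys less than one standard error
  expect_lt(cv$mean_loglik[4] - cv$mean_loglik[3], cv$sd_loglik[3])
  # seeded partition: identical rerun
  cv2 <- crossvalidate_dims(dec, dims_list = 1:4, k = 5, seed = 3, n_starts = 4)
  expect_identical(cv, cv2)
  expect_error(crossvalidate_dims(dec[1:4, ], k = 10), "fewer decisions")
})

test_that("leave-one-out folds have size one", {
  sm <- fake_summary()
  dec <- simulate_experiment(observer_config("custom", n_participants = 2,
                                             triplets_per_participant = 10,
                                             noise_scale = 0.3, seed = 30), sm)
  cv <- crossvalidate_dims(dec, dims_list = 2, k = nrow(dec), seed = 1,
                           n_starts = 2)
  expect_identical(nrow(cv), 1L)
  expect_true(is.finite(cv$mean_loglik))
})

test_that("bootstrap reliability grows with observer noise", {
  sm <- fake_summary()
  covs <- sapply(c(0.2, 2), function(sig) {
    dec <- simulate_experiment(observer_config("sliding", noise_scale = sig,
                                               seed = 23), sm)
    bootstrap_reliability(dec, B = 12, n_dims = 3, seed = 5,
                          n_starts = 4)$average_cov
  })
  expect_true(all(covs >= 0))
  expect_lt(covs[1], covs[2])
  expect_lt(covs[1], 0.25)
  expect_error(bootstrap_reliability(data.frame(), B = 1), "at least 2")
})

test_that("procrustes alignment restores dimension 1 after a random rotation", {
  sm <- fake_summary()
  dec <- simulate_experiment(observer_config("sliding", noise_scale = 0.4,
                                             seed = 24), sm)
  sp <- fit_embedding(dec, n_dims = 3, n_starts = 6, seed = 24)
  h <- setNames(sm$hurst, sm$id)
  al <- procrustes_align(sp, h)
  expect_gt(al$dim1_cor, 0)
  # rotate arbitrarily, realign: same dim-1 correlation, same distances
  set.seed(99)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  rot <- sp; rot$coordinates <- sp$coordinates %*% Q
  rownames(rot$coordinates) <- rownames(sp$coordinates)
  al2 <- procrustes_align(rot, h)
  expect_equal(al2$dim1_cor, al$dim1_cor, tolerance = 1e-8)
  expect_equal(space_distances(al2), space_distances(sp), tolerance = 1e-8)
  # aligned space: realignment is identity up to sign
  al3 <- procrustes_align(al, h)
  expect_equal(abs(diag(al3$rotation)), rep(1, 3), tolerance = 1e-6)
  # degenerate H values warn and return identity
  expect_warning(procrustes_align(sp, setNames(rep(0.5, 9), sm$id)), "equal")
})

test_that("topography distance ratio matches an analytic cluster construction", {
  centers <- rbind(c(0, 0), c(10, 0), c(5, 10 * sqrt(3) / 2))
  offs <- rbind(c(0.5, 0), c(-0.25, 0.4330127), c(-0.25, -0.4330127))
  X <- do.call(rbind, lapply(1:3, function(ci)
    sweep(offs, 2, centers[ci, ], `+`)))
  X <- cbind(0, X)  # ratio evaluated in dims 2:3
  rownames(X) <- paste0("s", 1:9)
  sp <- structure(list(coordinates = X, n_dims = 3), class = "perceptual_space")
  labs <- setNames(rep(c("A", "B", "C"), each = 3), rownames(X))
  ratio <- topo_distance_ratio(sp, labs)
  # within-cluster pairs all have length 0.866; between ~ 10
  expect_equal(ratio, 10 / 0.8660254, tolerance = 0.05)
  # permuting labels consistently leaves the ratio unchanged
  labs2 <- setNames(rep(c("C", "A", "B"), each = 3), rownames(X))
  expect_equal(topo_distance_ratio(sp, labs2), ratio)
  # identical points within labels: infinite separation ratio
  Xc <- X[rep(c(1, 4, 7), each = 3), ]; rownames(Xc) <- rownames(X)
  spc <- structure(list(coordinates = Xc, n_dims = 3), class = "perceptual_space")
  expect_identical(topo_distance_ratio(spc, labs), Inf)
  expect_error(topo_distance_ratio(sp, setNames(c("A", rep("B", 8)), rownames(X))),
               "at least two members")
})
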