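test_that("geometric features match hand-computed values", {
  cx <- bare_complex(matrix(0, 1, 3), matrix(c(3, 4, 0), 1, 3))
  run <- fake_run(cx, list(cx$reference))
  expect_equal(unname(geometry_features(run, "com_distance")$values[1, 1]), 5)
  expect_equal(unname(geometry_features(run, "inverse_sq_com")$values[1, 1]), 0.04)

  # mass-weighted COM with a two-bead chain
  cx2 <- bare_complex(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE),
                      matrix(c(10, 0, 0), 1, 3))
  run2 <- fake_run(cx2, list(cx2$reference))
  expect_equal(unname(geometry_features(run2, "com_distance")$values[1, 1]), 9)

  pd <- geometry_features(run2, "pair_distances",
                          pairs = rbind(c(1, 1), c(2, 1)))
  expect_equal(as.numeric(pd$values), c(10, 8))
  expect_error(geometry_features(run2, "pair_distances",
                                 pairs = rbind(c(3, 1))), "invalid")
})

test_that("rmsd_min is invariant to rigid motions and has the two-bead closed form", {
  toy <- make_toy_complex(nA = 5, nB = 4, seed = 8)
  cx <- toy$complex
  R <- gomsm:::random_rotation()
  rot <- cx$reference %*% t(R) + matrix(c(5, -3, 1), cx$n, 3, byrow = TRUE)
  run <- fake_run(cx, list(cx$reference, rot))
  r <- rmsd_min(run)
  expect_equal(unname(r$values[1, 1]), 0, tolerance = 1e-10)
  expect_lt(r$values[2, 1], 1e-8)

  # two beads at separation d vs d + delta: optimal RMSD = delta / 2
  cx2 <- bare_complex(matrix(0, 1, 3), matrix(c(4, 0, 0), 1, 3))
  frame <- cx2$reference; frame[2, 1] <- 4.6
  run2 <- fake_run(cx2, list(frame))
  expect_equal(unname(rmsd_min(run2)$values[1, 1]), 0.3, tolerance = 1e-10)

  expect_error(rmsd_min(run, reference = matrix(0, 3, 3)), "mismatch")
})

test_that("long-lived contact filter applies the lifetime rule", {
  cx <- bare_complex(matrix(0, 1, 3), matrix(c(5, 0, 0), 1, 3))
  frames_at <- function(ds) lapply(ds, function(d) {
    p <- cx$reference; p[2, 1] <- d; p
  })
  # continuously bound for the whole 2 ns run
  run_bound <- fake_run(cx, frames_at(rep(5, 200)), frame_interval = 0.01)
  expect_equal(nrow(long_lived_contacts(run_bound, 12, 1)), 1)
  # below cutoff for a single 0.01 ns frame
  run_blip <- fake_run(cx, frames_at(c(rep(20, 100), 5, rep(20, 99))),
                       frame_interval = 0.01)
  expect_equal(nrow(long_lived_contacts(run_blip, 12, 1)), 0)
  # alternating below/above every frame: max segment 1 frame < lifetime
  run_alt <- fake_run(cx, frames_at(rep(c(5, 20), 150)),
                      frame_interval = 0.01)
  expect_equal(nrow(long_lived_contacts(run_alt, 12, 1)), 0)
  # boundary frames exactly at the cutoff count as unbound (strict <)
  run_edge <- fake_run(cx, frames_at(rep(12, 200)), frame_interval = 0.01)
  expect_equal(nrow(long_lived_contacts(run_edge, 12, 1)), 0)
  # unresolvable lifetime
  expect_error(long_lived_contacts(run_bound, 12, 0.001), "resolved")
})

test_that("long-lived contact filter is monotone in its thresholds", {
  toy <- make_toy_complex(seed = 4)
  run <- run_langevin(toy$complex,
                      langevin_params(timestep = 5, n_steps = 30000,
                                      save_stride = 100, seed = 6))
  key <- function(m) paste(m[, 1], m[, 2])
  base <- key(long_lived_contacts(run, 8, 0.01))
  wider <- key(long_lived_contacts(run, 10, 0.01))
  shorter <- key(long_lived_contacts(run, 8, 0.005))
  expect_true(all(base %in% wider))
  expect_true(all(base %in% shorter))
})

test_that("TICA recovers AR(1) autocorrelations and axes", {
  set.seed(1)
  n <- 1e5
  x <- numeric(n); for (t in 2:n) x[t] <- 0.9 * x[t - 1] + rnorm(1)
  y <- numeric(n); for (t in 2:n) y[t] <- 0.5 * y[t - 1] + rnorm(1)

  m1 <- tica_fit(feature_series(cbind(x = x), "x", 0.01), lag = 1)
  expect_equal(m1$eigenvalues, 0.9, tolerance = 0.02 / 0.9)
  expect_equal(m1$timescales, -1 * 0.01 / log(m1$eigenvalues))

  m2 <- tica_fit(feature_series(cbind(x, y), c("x", "y"), 0.01), lag = 1)
  expect_equal(m2$eigenvalues[1], 0.9, tolerance = 0.03)
  expect_equal(m2$eigenvalues[2], 0.5, tolerance = 0.03)
  # eigenvectors axis-aligned up to sign and scale
  U <- abs(m2$eigenvectors / sqrt(colSums(m2$eigenvectors^2))[col(m2$eigenvectors)])
  expect_gt(U[1, 1], 0.99); expect_gt(U[2, 2], 0.99)

  # white noise: no time correlation
  set.seed(2)
  w <- matrix(rnorm(3 * n), ncol = 3)
  mw <- tica_fit(feature_series(w, c("a", "b", "c"), 0.01), lag = 1)
  expect_true(all(abs(mw$eigenvalues) < 3 / sqrt(n)))
})

test_that("TICA transform projects onto the slow subspace", {
  set.seed(3)
  n <- 2e4
  x <- numeric(n); for (t in 2:n) x[t] <- 0.95 * x[t - 1] + rnorm(1)
  noise <- matrix(rnorm(3 * n), ncol = 3)
  X <- cbind(x + noise[, 1] * 0.1, noise[, 2], x - noise[, 3])
  fs <- feature_series(X, c("a", "b", "c"), 1)
  m <- tica_fit(fs, lag = 5)

  # d = 1: output proportional to mean-free input
  fs1 <- feature_series(cbind(x), "x", 1)
  m1 <- tica_fit(fs1, lag = 5)
  z <- tica_transform(m1, fs1, 1)
  expect_equal(cor(z$values[, 1], x - mean(x)), 1, tolerance = 1e-12)

  # transforming the model's own mean gives the zero vector
  z0 <- tica_transform(m, feature_series(matrix(m$mean, 1), fs$names, 1), 3)
  expect_equal(as.numeric(z0$values), c(0, 0, 0), tolerance = 1e-12)
  expect_error(tica_transform(m, fs, 4), "exceeds")

  # IC1 lag-autocorrelation beats 100 random unit projections
  lac <- function(v) {
    v <- v - mean(v)
    sum(v[1:(n - 5)] * v[6:n]) / sum(v^2)
  }
  a1 <- lac(tica_transform(m, fs, 1)$values[, 1])
  set.seed(4)
  worst <- max(vapply(1:100, function(i) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    lac(X %*% u)
  }, numeric(1)))
  expect_gte(a1, worst - 1e-10)
})

test_that("k-means discretization is exact on separated blobs", {
  set.seed(5)
  X <- rbind(matrix(rnorm(200, 0, 0.5), ncol = 2),
             matrix(rnorm(200, 10, 0.5), ncol = 2))
  labels <- rep(1:2, each = 100)
  d <- kmeans_cluster(X, 2, seed = 1)
  agree <- max(mean(d$assignments == labels), mean(d$assignments == 3 - labels))
  expect_equal(agree, 1)
  expect_equal(length(d$assignments), 200)
  expect_gte(d$inertia, 0)

  # k = n gives zero inertia; k > n errors
  Xs <- matrix(seq_len(12), ncol = 2)
  expect_equal(kmeans_cluster(Xs, 6, seed = 2)$inertia, 0, tolerance = 1e-12)
  expect_error(kmeans_cluster(Xs, 7), "exceeds")
  expect_error(kmeans_cluster(Xs, 0), "k must be")
  # determinism per seed
  expect_identical(kmeans_cluster(X, 3, seed = 9)$assignments,
                   kmeans_cluster(X, 3, seed = 9)$assignments)
})

test_that("elbow selection finds the knee of the inertia curve", {
  ks <- 2:10
  # sharp knee at k = 5
  inr <- ifelse(ks <= 5, 100 - 20 * (ks - 2), 40 - 1 * (ks - 5))
  names(inr) <- ks
  expect_equal(elbow_choose_k(inr), 5L)
  # exactly linear: degenerate, smallest interior k with a warning
  lin <- setNames(100 - 10 * (ks - 2), ks)
  expect_warning(k <- elbow_choose_k(lin), "degenerate")
  expect_equal(k, 3L)
  expect_error(elbow_choose_k(setNames(c(10, 5), 2:3)), "3 candidate")
  expect_error(elbow_choose_k(setNames(c(10, 12, 5, 4), 2:5)),
               "non-increasing")
})

test_that("feature series round-trip through delimited text", {
  fs <- feature_series(matrix(rnorm(20), ncol = 2), c("a", "b"), 0.25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_series(fs, path)
  back <- read_feature_series(path)
  expect_equal(back$values, fs$values, tolerance = 1e-15)
  expect_equal(back$frame_interval, 0.25)
  expect_equal(back$names, c("a", "b"))
})

test_that("feature maps are invariant to frame ordering", {
  toy <- make_toy_complex(seed = 4)
  run <- run_langevin(toy$complex,
                      langevin_params(timestep = 5, n_steps = 5000,
                                      save_stride = 100, seed = 6))
  perm <- sample(nrow(run$frames))
  run_p <- run; run_p$frames <- run$frames[perm, ]
  expect_equal(geometry_features(run_p, "com_distance")$values[, 1],
               geometry_features(run, "com_distance")$values[perm, 1])
  expect_equal(rmsd_min(run_p)$values[, 1], rmsd_min(run)$values[perm, 1])
})
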