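test_that("sliding-window counting enumerates transitions", {
  cm <- count_transitions(list(c(1, 1, 2, 2, 1)), lag = 1, frame_interval = 1)
  expect_equal(cm$counts, matrix(c(1, 1, 1, 1), 2, 2), ignore_attr = TRUE)
  # two copies double the counts; no cross-trajectory transitions
  cm2 <- count_transitions(list(c(1, 1, 2, 2, 1), c(1, 1, 2, 2, 1)), 1,
                           frame_interval = 1)
  expect_equal(cm2$counts, 2 * cm$counts)
  expect_error(count_transitions(list(c(1, 2, 1)), lag = 3,
                                 frame_interval = 1), "lag")
})

test_that("transition-matrix estimation handles both modes and connectivity", {
  cm <- structure(list(counts = matrix(c(8, 2, 2, 8), 2, 2), lag = 1L,
                       frame_interval = 1), class = "count_matrix")
  for (rev in c(TRUE, FALSE)) {
    m <- estimate_transition_matrix(cm, reversible = rev)
    expect_equal(m$T, matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  }
  # an unconnected state is dropped from the active set
  cm$counts <- rbind(cbind(matrix(c(8, 2, 2, 8), 2, 2), 0), c(0, 0, 5))
  m <- estimate_transition_matrix(cm)
  expect_equal(m$active_set, 1:2)
  expect_equal(dim(m$T), c(2, 2))

  # reversible estimate satisfies detailed balance on asymmetric counts
  set.seed(1)
  cm$counts <- matrix(rpois(25, 20) + 1, 5, 5)
  m <- estimate_transition_matrix(cm, reversible = TRUE)
  flux <- m$pi * m$T
  expect_lt(max(abs(flux - t(flux))), 1e-8)
  expect_lt(max(abs(rowSums(m$T) - 1)), 1e-12)
  expect_lt(max(abs(m$pi %*% m$T - m$pi)), 1e-10)
})

test_that("stationary distributions solve pi T = pi", {
  expect_equal(stationary_distribution(matrix(c(.9, .1, .1, .9), 2, 2,
                                              byrow = TRUE)), c(0.5, 0.5))
  # balance: pi1 * 0.1 = pi2 * 0.2
  expect_equal(stationary_distribution(matrix(c(.9, .1, .2, .8), 2, 2,
                                              byrow = TRUE)),
               c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_error(stationary_distribution(diag(2)), "reducible")
})

test_that("implied timescales follow -lag / ln(lambda)", {
  lam2 <- exp(-1)
  T_ <- matrix(c((1 + lam2) / 2, (1 - lam2) / 2,
                 (1 - lam2) / 2, (1 + lam2) / 2), 2, 2)
  m <- markov_model(T_, lag_time = 12)
  expect_equal(implied_timescales(m, 1)[1], 12, tolerance = 1e-10)

  T5 <- matrix(c(0.75, 0.25, 0.25, 0.75), 2, 2)  # lambda2 = 0.5
  m5 <- markov_model(T5, lag_time = 1)
  expect_equal(implied_timescales(m5, 1)[1], 1.4427, tolerance = 1e-4)

  # disconnected limit: eigenvalue 1 below the Perron root
  md <- gomsm:::build_markov_model(diag(2), c(0.5, 0.5), 12, 1:2, TRUE)
  ts <- implied_timescales(md, 1)
  expect_true(is.infinite(ts[1]))
  expect_true(attr(ts, "infinite")[1])
  expect_error(implied_timescales(m, 2), "smaller")
})

test_that("MFPTs match closed forms, an absorbing bound, and oracles", {
  T_ <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  m <- markov_model(T_, lag_time = 12)
  expect_equal(mfpt_between_sets(m, 1, 2), 120, tolerance = 1e-10)

  # target absorbing in one step from everywhere: MFPT = lag exactly
  T3 <- matrix(c(0, 0, 1, 0, 0, 1, 0.3, 0.3, 0.4), 3, 3, byrow = TRUE)
  m3 <- markov_model(T3, lag_time = 7)
  expect_equal(mfpt_between_sets(m3, 1:2, 3), 7, tolerance = 1e-10)

  # value-iteration oracle on random 6-state models
  set.seed(11)
  for (rep in 1:5) {
    T6 <- matrix(rexp(36), 6, 6); T6 <- T6 / rowSums(T6)
    m6 <- markov_model(T6, lag_time = 1)
    src <- 1:2; tgt <- 5:6
    mf <- mfpt_between_sets(m6, src, tgt)
    # independent iterative solve m = 1 + T_UU m
    U <- setdiff(1:6, tgt)
    mU <- rep(0, length(U))
    for (it in 1:10000) {
      mU_new <- 1 + T6[U, U] %*% mU
      if (max(abs(mU_new - mU)) < 1e-13) break
      mU <- mU_new
    }
    mfull <- numeric(6); mfull[U] <- mU
    w <- m6$pi[src] / sum(m6$pi[src])
    expect_equal(mf, sum(w * mfull[src]), tolerance = 1e-9)
  }
  # Monte-Carlo oracle on a 3-state model
  set.seed(12)
  T3r <- matrix(rexp(9), 3, 3); T3r <- T3r / rowSums(T3r)
  m3r <- markov_model(T3r, lag_time = 1)
  mf <- mfpt_between_sets(m3r, 1, 3)
  steps <- vapply(1:20000, function(i) {
    s <- 1L; nstep <- 0L
    while (s != 3L) {
      s <- sample.int(3, 1, prob = T3r[s, ])
      nstep <- nstep + 1L
    }
    nstep
  }, integer(1))
  se <- sd(steps) / sqrt(length(steps))
  expect_lt(abs(mf - mean(steps)), 2 * se + 1e-9)

  expect_error(mfpt_between_sets(m, 1, 1), "disjoint")
  expect_error(mfpt_between_sets(m, integer(0), 2), "non-empty")
})

test_that("PCCA+ recovers block structure and degenerate limits", {
  eps <- 1e-3
  Tb <- matrix(c(0.89, 0.10, eps, 0,
                 0.10, 0.89, 0, eps,
                 eps, 0, 0.89, 0.10,
                 0, eps, 0.10, 0.89), 4, 4, byrow = TRUE)
  Tb <- Tb / rowSums(Tb)
  m <- markov_model(Tb, 1)
  pc <- pcca_assign(m, 2)
  expect_equal(pc$crisp_labels[1], pc$crisp_labels[2])
  expect_equal(pc$crisp_labels[3], pc$crisp_labels[4])
  expect_false(pc$crisp_labels[1] == pc$crisp_labels[3])
  expect_equal(rowSums(pc$memberships), rep(1, 4), tolerance = 1e-10)
  expect_true(all(pc$memberships >= 0 & pc$memberships <= 1))

  # m = n: memberships are the identity up to permutation
  pcn <- pcca_assign(m, 4)
  P <- pcn$memberships
  expect_equal(sort(pcn$crisp_labels), 1:4)
  expect_equal(max(abs(P[cbind(1:4, pcn$crisp_labels)] - 1)), 0,
               tolerance = 1e-6)

  expect_error(pcca_assign(m, 1), "at least 2")
  expect_error(pcca_assign(m, 5), "exceeds")
  mnr <- gomsm:::build_markov_model(Tb, m$pi, 1, 1:4, FALSE)
  expect_error(pcca_assign(mnr, 2), "reversible")
})

test_that("bulk volume implements the spherical-shell formula", {
  expect_equal(bulk_volume(73.46, 29), 4 / 3 * pi * (73.46^3 - 29^3))
  expect_equal(bulk_volume(73.46, 29) / 1e6, 1.558, tolerance = 1e-3)
  expect_equal(bulk_volume(10, 0), 4 / 3 * pi * 1000)
  expect_error(bulk_volume(10, 10), "smaller")
})

test_that("binding observables satisfy the two-state identities", {
  T_ <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  m <- markov_model(T_, lag_time = 12)
  obs <- binding_observables(m, 1, r_cavity = 73.46, r_cut = 29)
  V <- bulk_volume(73.46, 29)
  expect_equal(obs$dG_b, 0, tolerance = 1e-12)       # P_bound = P_unbound
  expect_equal(obs$K_eq, V, tolerance = 1e-10)
  expect_equal(obs$kBT, kBT(300))

  # K_eq = k_on / k_off exactly for any 2-state model
  set.seed(3)
  for (rep in 1:5) {
    p <- runif(2, 0.05, 0.5)
    T2 <- matrix(c(1 - p[1], p[1], p[2], 1 - p[2]), 2, 2, byrow = TRUE)
    m2 <- markov_model(T2, lag_time = 5)
    o <- binding_observables(m2, 1, 73.46, 29)
    expect_equal(o$k_on / o$k_off, o$K_eq, tolerance = 1e-10)
  }
  expect_error(binding_observables(m, 1:2, 73.46, 29), "proper subset")
  expect_error(binding_observables(m, integer(0), 73.46, 29), "empty")
})

test_that("K_eq identity holds within 5% for metastable chains", {
  # two deep wells with a symmetric barrier, partitioned at the barrier
  # midpoint so recrossing corrections affect both MFPTs alike; timescale
  # separation ~60x (implied timescales 175 vs 2.8 steps)
  E <- c(0, 0.2, 3, 3, 0.1, 0.3)
  bd <- birth_death_reference(E, 0.3)
  m <- markov_model(bd$T, lag_time = 1)
  o <- binding_observables(m, 1:3, 73.46, 29)
  expect_lt(abs(o$k_on / o$k_off / o$K_eq - 1), 0.05)
})

test_that("PMF binding constant integrates the radial Boltzmann weight", {
  r <- seq(0, 12, by = 0.01)
  flat <- cbind(r, 0)
  expect_equal(pmf_binding_constant(flat, 10), 4 / 3 * pi * 1000,
               tolerance = 1e-5)
  # strongly repulsive profile suppresses the integral
  high <- cbind(r, 50 * kBT(300))
  expect_lt(suppressWarnings(pmf_binding_constant(high, 10)),
            1e-15 * pmf_binding_constant(flat, 10))
  # square well of depth kBT ln 2: exactly twice the flat value
  well <- cbind(r, -kBT(300) * log(2))
  expect_equal(suppressWarnings(pmf_binding_constant(well, 10)) /
                 pmf_binding_constant(flat, 10), 2,
               tolerance = 1e-12)
  expect_error(pmf_binding_constant(cbind(seq(5, 12, 0.1), 0), 10),
               "cover")
  expect_warning(pmf_binding_constant(cbind(r, 1), 10), "tail")
})

test_that("trajectory bootstrap tracks the CLT and handles degenerate cases", {
  set.seed(7)
  trajs <- lapply(1:50, function(i) rnorm(20))
  est <- function(lst) mean(unlist(lst))
  b <- bootstrap_errors(trajs, est, n_boot = 200, seed = 1)
  se_clt <- sd(vapply(trajs, mean, numeric(1))) / sqrt(50)
  expect_lt(abs(b$sd / se_clt - 1), 0.30)
  # deterministic per seed
  b2 <- bootstrap_errors(trajs, est, n_boot = 200, seed = 1)
  expect_identical(b$replicates, b2$replicates)

  expect_equal(bootstrap_errors(trajs, function(lst) 42, n_boot = 10,
                                seed = 2)$sd[[1]], 0)
  expect_error(bootstrap_errors(trajs, est, n_boot = 1), "n_boot")
  expect_error(bootstrap_errors(trajs[1], est, n_boot = 5), "at least 2")
  # failures are excluded and counted
  flaky <- function(lst) if (runif(1) < 0.5) stop("boom") else 1
  bf <- bootstrap_errors(trajs, flaky, n_boot = 40, seed = 3)
  expect_gt(bf$n_failed, 0)
})

test_that("estimators are consistent on sampled chains", {
  E <- c(0, 1.5, 0.5, 2, 1)
  bd <- birth_death_reference(E, 0.3)
  errs <- vapply(c(1e4, 1e6), function(n) {
    s <- sample_markov_chain(bd$T, n, seed = 21)
    m <- estimate_transition_matrix(count_transitions(list(s), 1,
                                                      frame_interval = 1))
    max(abs(m$T - bd$T[m$active_set, m$active_set]))
  }, numeric(1))
  expect_lt(errs[2], 0.01)
  expect_lt(errs[2], errs[1])
})
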