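test_that("complex construction wires contacts and elastic network", {
  A <- matrix(c(0,0,0, 3,0,0, 6,0,0, 30,0,0), 4, 3, byrow = TRUE)
  B <- matrix(c(0,8,0, 3,8,0, 6,8,0, 30,8,0), 4, 3, byrow = TRUE)
  cx <- build_complex(A, B, go_contacts(1, 1, 8, 1),
                      restraint_spec(12, 10, 10), confinement_sphere(50, 10))
  expect_equal(nrow(cx$contacts), 1)
  # every intra-chain pair within 12 A bonded, rest length = separation
  dA <- as.matrix(dist(A))
  expected <- sum(dA[upper.tri(dA)] <= 12) * 2  # same geometry per chain
  expect_equal(nrow(cx$bonds), expected)
  expect_true(all(abs(cx$bonds$r0 -
    sqrt(rowSums((cx$reference[cx$bonds$i, ] - cx$reference[cx$bonds$j, ])^2))) < 1e-12))
  # no inter-chain elastic bonds
  expect_true(all((cx$bonds$i <= 4) == (cx$bonds$j <= 4)))
})

test_that("curated contact table is stored verbatim and validated", {
  ct <- barnase_barstar_contacts()
  cx <- build_complex(matrix(rnorm(110 * 3), 110, 3),
                      matrix(rnorm(89 * 3) + 50, 89, 3), ct)
  expect_equal(cx$contacts$r_min, c(4.96, 5.65, 4.82, 5.83))
  expect_equal(cx$contacts$epsilon, rep(3, 4))
  # out-of-range and duplicate contacts are rejected
  expect_error(build_complex(matrix(0, 4, 3), matrix(1, 4, 3),
                             go_contacts(5, 1, 5, 1)), "out of range")
  expect_error(build_complex(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3),
                             go_contacts(c(1, 1), c(2, 2), c(5, 6), 1)),
               "duplicate")
  expect_error(build_complex(matrix(c(0, 0, NA), 1, 3), matrix(1, 1, 3)),
               "non-finite")
})

test_that("single-contact potential matches the 6-12 closed form", {
  for (rm in c(4.96, 5.65, 4.82, 5.83)) {
    cx <- pair_complex(r_min = rm, epsilon = 3, r = rm)
    expect_equal(potential_energy(cx), -3.0, tolerance = 1e-13)
    # zero crossing at rm * 2^(-1/6)
    p <- cx$reference; p[2, 1] <- rm * 2^(-1 / 6)
    expect_equal(potential_energy(cx, p), 0, tolerance = 1e-12)
    # decay: |U| < 1e-5 at 10 r_min
    p[2, 1] <- 10 * rm
    expect_lt(abs(potential_energy(cx, p)), 1e-5)
  }
  # singular configuration
  cx <- pair_complex(r = 4.82)
  p <- cx$reference; p[2, ] <- 0
  expect_error(potential_energy(cx, p), "singular")
})

test_that("forces are the analytic gradient", {
  cx <- pair_complex(r = 4.82)
  expect_equal(max(abs(forces(cx))), 0, tolerance = 1e-12)  # at the minimum

  # chain-B COM strictly inside the cavity feels no wall force
  cxw <- build_complex(matrix(0, 1, 3), matrix(c(10, 0, 0), 1, 3), NULL,
                       restraint_spec(1e-6, 0, 0), confinement_sphere(50, 10))
  expect_equal(max(abs(forces(cxw))), 0, tolerance = 1e-12)

  # random 8-bead configuration vs central differences, all terms active
  toy <- make_toy_complex(nA = 5, nB = 3, n_contacts = 2, seed = 3)
  cx2 <- toy$complex
  set.seed(42)
  pos <- cx2$reference + matrix(rnorm(cx2$n * 3, sd = 0.3), ncol = 3)
  bias <- umbrella_bias(8, 2)
  f <- forces(cx2, pos, bias)
  h <- 1e-5
  fd <- matrix(0, cx2$n, 3)
  for (i in seq_len(cx2$n)) for (k in 1:3) {
    pp <- pos; pp[i, k] <- pp[i, k] + h
    pm <- pos; pm[i, k] <- pm[i, k] - h
    fd[i, k] <- -(potential_energy(cx2, pp, bias) -
                    potential_energy(cx2, pm, bias)) / (2 * h)
  }
  expect_lt(max(abs(f - fd)) / max(abs(f)), 1e-6)
})

test_that("energy symmetries: rotation, translation, force balance", {
  toy <- make_toy_complex(nA = 5, nB = 4, n_contacts = 2, seed = 9)
  cx <- toy$complex
  # free the chain-A tether; keep wall (rotations about the origin allowed)
  cx$restraints$chainA_positional_k <- 0
  set.seed(1)
  pos <- cx$reference + matrix(rnorm(cx$n * 3, sd = 0.2), ncol = 3)
  e0 <- potential_energy(cx, pos)
  R <- gomsm:::random_rotation()
  expect_equal(potential_energy(cx, pos %*% t(R)), e0, tolerance = 1e-10)

  # translation invariance additionally needs the wall off
  cx$confinement$wall_k <- 0
  e1 <- potential_energy(cx, pos)
  shift <- matrix(c(3, -7, 2), cx$n, 3, byrow = TRUE)
  expect_equal(potential_energy(cx, pos + shift), e1, tolerance = 1e-10)
  # pair interactions obey Newton's third law
  expect_equal(max(abs(colSums(forces(cx, pos)))), 0, tolerance = 1e-10)
})

test_that("potential is continuous at the wall boundary and contact minimum", {
  cxw <- build_complex(matrix(0, 1, 3), matrix(c(10, 0, 0), 1, 3), NULL,
                       restraint_spec(1e-6, 0, 0), confinement_sphere(20, 10))
  rs <- seq(19.99, 20.01, by = 1e-5)
  es <- vapply(rs, function(r) {
    p <- cxw$reference; p[2, 1] <- r
    potential_energy(cxw, p)
  }, numeric(1))
  expect_lt(max(abs(diff(es))), 1e-6)   # no jump across the flat-bottom edge
  expect_true(all(es[rs <= 20] == 0))

  cx <- pair_complex(r = 4.82)
  rs <- seq(4.81, 4.83, by = 1e-5)
  es <- vapply(rs, function(r) {
    p <- cx$reference; p[2, 1] <- r
    potential_energy(cx, p)
  }, numeric(1))
  expect_lt(max(abs(diff(es))), 1e-6)
  expect_equal(min(es), -3, tolerance = 1e-7)
})

test_that("contact tables round-trip through delimited text", {
  ct <- barnase_barstar_contacts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_table(ct, path)
  back <- read_contact_table(path)
  expect_equal(back$r_min, ct$r_min)
  expect_equal(back$iA, ct$iA)
  # comma-separated, headerless variant
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# contacts", "37,46,4.96,3.0", "59,35,5.65,3.0"), path2)
  back2 <- read_contact_table(path2)
  expect_equal(back2$r_min, c(4.96, 5.65))
})
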