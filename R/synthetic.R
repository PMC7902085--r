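#' Generate a synthetic two-chain bead complex
#'
#' A stand-in association system mirroring the architecture of the
#' curated two-protein model: chain A is a compact random blob tethered at
#' the origin, chain B a second blob free to diffuse inside a (smaller)
#' confinement sphere, and a handful of attractive Go contacts are placed
#' between the closest interface beads of a constructed bound pose.  Each
#' contact's r_min equals its bound-pose distance, so the bound pose is
#' the joint minimum of all contact terms.  Deterministic for a given
#' seed.
#'
#' @param nA,nB bead counts (>= 1).
#' @param n_contacts number of Go contacts (<= nA * nB).
#' @param seed RNG seed.
#' @param epsilon contact well depth, kcal/mol (default 1.5, a few kBT so
#'   association and dissociation are both observable in short runs).
#' @param compactness chain packing radius scale, A: beads are placed in a
#'   sphere of radius compactness * n^(1/3) with a 3 A minimum separation
#'   (default 2.5, giving compact blobs whose bound-pose COM separation is
#'   well below the cavity radius).
#' @param r_cavity toy confinement radius, A (default 20; small enough
#'   that dissociated chains re-associate within nanoseconds).
#' @param contact_gap closest inter-chain approach of the bound pose, A.
#' @return list with `complex` (a `cg_complex`) and `bound_pose`
#'   (the reference coordinates).
#' @export
make_toy_complex <- function(nA = 6, nB = 5, n_contacts = 3, seed = 1,
                             epsilon = 1.5, compactness = 2.5,
                             r_cavity = 20, contact_gap = 4.5) {
  stopifnot(nA >= 1, nB >= 1, n_contacts >= 1)
  if (n_contacts > nA * nB) stop("n_contacts exceeds nA * nB")
  set.seed(seed)
  blob <- function(n) {
    R <- compactness * max(n, 2)^(1 / 3)
    pts <- matrix(NA_real_, n, 3)
    i <- 1
    while (i <= n) {
      p <- runif(3, -R, R)
      if (sqrt(sum(p^2)) > R) next
      if (i > 1) {
        d <- sqrt(rowSums(sweep(pts[seq_len(i - 1), , drop = FALSE], 2, p)^2))
        if (min(d) < 3.0) next
      }
      pts[i, ] <- p
      i <- i + 1
    }
    sweep(pts, 2, colMeans(pts))
  }
  A <- blob(nA)
  B <- blob(nB)
  # slide chain B along +x until the closest inter-chain approach is
  # contact_gap: bound pose
  shift <- 0
  repeat {
    Bs <- sweep(B, 2, c(shift, 0, 0), "+")
    dmin <- min(cross_distances(A, Bs))
    if (dmin >= contact_gap) break
    shift <- shift + 0.05
  }
  B <- sweep(B, 2, c(shift, 0, 0), "+")
  d <- cross_distances(A, B)
  ord <- order(d)[seq_len(n_contacts)]
  iA <- ((ord - 1) %% nA) + 1
  iB <- ((ord - 1) %/% nA) + 1
  contacts <- go_contacts(iA, iB, d[ord], epsilon)
  cx <- build_complex(A, B, contacts,
                      restraints = restraint_spec(),
                      confinement = confinement_sphere(r_cavity, 10))
  list(complex = cx, bound_pose = cx$reference)
}

cross_distances <- function(A, B) {
  # nA x nB matrix of pairwise distances
  out <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(nrow(B)))
    out[, j] <- sqrt(rowSums(sweep(A, 2, B[j, ])^2))
  out
}

#' Sample a discrete Markov chain
#'
#' @param T_ row-stochastic transition matrix.
#' @param n_steps trajectory length (frames, including the start state).
#' @param seed RNG seed.
#' @param start 1-based start state.
#' @return integer state sequence of length `n_steps`.
#' @export
sample_markov_chain <- function(T_, n_steps, seed = 1, start = 1) {
  T_ <- as.matrix(T_)
  if (max(abs(rowSums(T_) - 1)) > 1e-10) stop("T is not row-stochastic")
  if (start < 1 || start > nrow(T_)) stop("invalid start state")
  set.seed(seed)
  sample_chain_cpp(T_, as.integer(n_steps), as.integer(start))
}

#' Birth-death reference chain with closed-form thermodynamics
#'
#' Nearest-neighbour Metropolis chain over states with energies E_i (kBT
#' units): T[i, i+-1] = attempt_prob * min(1, exp(-(E_neighbour - E_i))),
#' diagonal absorbing the remainder.  The stationary distribution is the
#' Boltzmann distribution analytically, and the mean-first-passage-time
#' table is computed by the first-step recursion and verified internally
#' against a dense linear solve.
#'
#' @param energies state energies in kBT (>= 2 states).
#' @param attempt_prob move attempt probability per neighbour, in (0, 0.5].
#' @return an object of class `birth_death_reference` with fields
#'   `energies`, `T`, `analytic_pi`, `mfpt` (steps, `mfpt[i, j]` = i -> j).
#' @export
birth_death_reference <- function(energies, attempt_prob = 0.25) {
  E <- as.numeric(energies)
  n <- length(E)
  if (n < 2) stop("need at least 2 states")
  if (attempt_prob <= 0 || attempt_prob > 0.5)
    stop("attempt_prob must be in (0, 0.5]")
  T_ <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i < n) T_[i, i + 1] <- attempt_prob * min(1, exp(-(E[i + 1] - E[i])))
    if (i > 1) T_[i, i - 1] <- attempt_prob * min(1, exp(-(E[i - 1] - E[i])))
    T_[i, i] <- 1 - sum(T_[i, ])
  }
  pi_ <- exp(-(E - min(E)))
  pi_ <- pi_ / sum(pi_)

  # upward passage times by first-step recursion:
  # tau_up[i] = E[steps i -> i+1] = 1/p_up[i] + (p_dn[i]/p_up[i]) tau_up[i-1]
  p_up <- c(T_[cbind(seq_len(n - 1), 2:n)], NA)
  p_dn <- c(NA, T_[cbind(2:n, seq_len(n - 1))])
  tau_up <- numeric(n - 1)
  tau_up[1] <- 1 / p_up[1]
  if (n > 2) for (i in 2:(n - 1))
    tau_up[i] <- 1 / p_up[i] + p_dn[i] / p_up[i] * tau_up[i - 1]
  tau_dn <- numeric(n - 1)  # tau_dn[i] = E[steps i+1 -> i]
  tau_dn[n - 1] <- 1 / p_dn[n]
  if (n > 2) for (i in (n - 2):1)
    tau_dn[i] <- 1 / p_dn[i + 1] + p_up[i + 1] / p_dn[i + 1] * tau_dn[i + 1]
  mfpt <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) mfpt[i, j] <- sum(tau_up[i:(j - 1)])
    if (i > j) mfpt[i, j] <- sum(tau_dn[j:(i - 1)])
  }
  # internal oracle equivalence: dense linear solve per target
  for (j in seq_len(n)) {
    dense <- mfpt_per_state(T_, j)
    stopifnot(max(abs(dense - mfpt[, j])) < 1e-10 * max(1, max(mfpt[, j])))
  }
  structure(list(energies = E, attempt_prob = attempt_prob, T = T_,
                 analytic_pi = pi_, mfpt = mfpt),
            class = "birth_death_reference")
}

#' Biased ensembles of the birth-death chain for TRAM validation
#'
#' Builds one unbiased ensemble plus one ensemble per bias vector: each
#' bias is a per-state energy offset in kBT, the biased chain is the
#' Metropolis chain of energies E + b, and every trajectory carries the
#' full bias matrix (columns: unbiased zero column, then each bias).
#'
#' @param ref a [birth_death_reference()].
#' @param biases list of per-state bias vectors (kBT).
#' @param n_steps frames per trajectory.
#' @param seed base seed; ensemble k uses seed + k.
#' @param n_unbiased number of unbiased trajectories.
#' @return list of [ensemble_data()], ensemble ids 1 (unbiased) to
#'   1 + length(biases).
#' @export
birth_death_ensembles <- function(ref, biases = list(), n_steps = 10000,
                                  seed = 1, n_unbiased = 1) {
  stopifnot(inherits(ref, "birth_death_reference"))
  n <- length(ref$energies)
  K <- 1L + length(biases)
  bias_cols <- c(list(rep(0, n)), lapply(biases, function(b) {
    stopifnot(length(b) == n)
    as.numeric(b)
  }))
  bias_matrix_for <- function(states)
    vapply(bias_cols, function(b) b[states], numeric(length(states)))
  out <- vector("list", K)
  dtrajs <- lapply(seq_len(n_unbiased), function(r)
    sample_markov_chain(ref$T, n_steps, seed = seed * 1000 + r,
                        start = which.min(ref$energies)))
  out[[1]] <- ensemble_data(dtrajs, lapply(dtrajs, bias_matrix_for),
                            ensemble_id = 1, frame_interval = 1)
  for (k in seq_along(biases)) {
    refb <- birth_death_reference(ref$energies + bias_cols[[k + 1]],
                                  ref$attempt_prob)
    s <- sample_markov_chain(refb$T, n_steps, seed = seed * 1000 + 100 + k,
                             start = which.min(refb$energies))
    out[[k + 1]] <- ensemble_data(list(s), list(bias_matrix_for(s)),
                                  ensemble_id = k + 1, frame_interval = 1)
  }
  out
}
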