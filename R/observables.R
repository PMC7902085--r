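#' Bulk volume of the confining cavity outside the bound region
#'
#' V = (4/3) pi (r_cavity^3 - r_cut^3): the volume accessible to the
#' dissociated complex, which fixes the effective concentration C = 1/V.
#'
#' @param r_cavity confinement radius, A.
#' @param r_cut bound/unbound cutoff distance, A (0 <= r_cut < r_cavity).
#' @return volume in A^3.
#' @export
bulk_volume <- function(r_cavity, r_cut) {
  if (r_cut < 0) stop("r_cut must be non-negative")
  if (r_cut >= r_cavity) stop("r_cut must be smaller than r_cavity")
  4 / 3 * pi * (r_cavity^3 - r_cut^3)
}

#' Binding thermodynamics and kinetics from a Markov model
#'
#' With P_bound the stationary probability of the bound set:
#' K_eq = (P_bound / P_unbound) V with C = 1/V the effective concentration;
#' Delta G_b = -kBT ln(P_bound / P_unbound); k_on = 1 / (MFPT_on C) and
#' k_off = 1 / MFPT_off with MFPTs computed between the bound set and its
#' complement (pi-weighted over the source set).
#'
#' @param model a `markov_model` (lag time in ns).
#' @param bound_set non-empty proper subset of model state indices.
#' @param r_cavity,r_cut cavity and cutoff radii defining the bulk volume.
#' @param temperature Kelvin (default 300).
#' @return an object of class `observable_set`: `K_eq` (A^3), `dG_b`
#'   (kcal/mol), `k_on` (A^3 s^-1), `k_off` (s^-1), `mfpt_on`, `mfpt_off`
#'   (s), `V` (A^3), `concentration` (A^-3), `kBT`, `P_bound`, `P_unbound`.
#' @export
binding_observables <- function(model, bound_set, r_cavity, r_cut,
                                temperature = 300) {
  n <- nrow(model$T)
  bound_set <- unique(as.integer(bound_set))
  if (!length(bound_set)) stop("bound set is empty")
  if (any(bound_set < 1) || any(bound_set > n))
    stop("bound set outside the active set")
  unbound_set <- setdiff(seq_len(n), bound_set)
  if (!length(unbound_set)) stop("bound set must be a proper subset")
  V <- bulk_volume(r_cavity, r_cut)
  P_bound <- sum(model$pi[bound_set])
  P_unbound <- 1 - P_bound
  K_eq <- P_bound / P_unbound * V
  dG_b <- -kBT(temperature) * log(P_bound / P_unbound)
  mfpt_on <- mfpt_between_sets(model, unbound_set, bound_set) * 1e-9   # s
  mfpt_off <- mfpt_between_sets(model, bound_set, unbound_set) * 1e-9
  C <- 1 / V
  structure(list(K_eq = K_eq, dG_b = dG_b,
                 k_on = 1 / (mfpt_on * C), k_off = 1 / mfpt_off,
                 mfpt_on = mfpt_on, mfpt_off = mfpt_off,
                 V = V, concentration = C, kBT = kBT(temperature),
                 P_bound = P_bound, P_unbound = P_unbound),
            class = "observable_set")
}

#' @export
print.observable_set <- function(x, ...) {
  cat(sprintf("K_eq    %.4g A^3\ndG_b    %.4g kcal/mol\nk_on    %.4g A^3/s\nk_off   %.4g 1/s\n",
              x$K_eq, x$dG_b, x$k_on, x$k_off))
  invisible(x)
}

#' Binding constant from a radial potential of mean force
#'
#' K_eq = integral_0^r_cut 4 pi r^2 exp(-W(r)/kBT) dr by trapezoidal
#' quadrature on the supplied grid.  The profile must be offset so that
#' W -> 0 in the bulk; if the last profile point beyond r_cut has
#' |W| > 0.1 kBT a warning is issued.
#'
#' @param profile two-column matrix or data.frame of (r in A, W in
#'   kcal/mol), covering [0, r_cut] (the first grid point must lie within
#'   one grid spacing of 0; W is continued flat to r = 0).
#' @param r_cut integration limit, A.
#' @param temperature Kelvin.
#' @return binding constant in A^3.
#' @export
pmf_binding_constant <- function(profile, r_cut, temperature = 300) {
  profile <- as.matrix(profile)
  r <- profile[, 1]; W <- profile[, 2]
  ord <- order(r); r <- r[ord]; W <- W[ord]
  kt <- kBT(temperature)
  if (max(r) < r_cut) stop("profile does not cover [0, r_cut]")
  spacing <- if (length(r) > 1) stats::median(diff(r)) else Inf
  if (r[1] > spacing + 1e-9)
    stop("profile does not cover [0, r_cut]: first point too far from r = 0")
  if (abs(W[length(W)]) > 0.1 * kt && max(r) > r_cut)
    warning("PMF tail is not zeroed: |W| > 0.1 kBT at the largest r")
  if (r[1] > 0) { r <- c(0, r); W <- c(W[1], W) }
  keep <- r <= r_cut
  r_in <- r[keep]; W_in <- W[keep]
  if (max(r_in) < r_cut) {
    # interpolate the profile at the integration limit
    Wc <- stats::approx(r, W, xout = r_cut)$y
    r_in <- c(r_in, r_cut); W_in <- c(W_in, Wc)
  }
  f <- 4 * pi * r_in^2 * exp(-W_in / kt)
  sum(diff(r_in) * (head(f, -1) + tail(f, -1)) / 2)
}
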