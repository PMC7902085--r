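#' Bundle trajectories generated under one thermodynamic state
#'
#' Each trajectory carries, per frame, the reduced bias energy
#' u_k(x) / kBT evaluated in *every* thermodynamic state k (for the
#' unbiased state that column is identically zero).
#'
#' @param dtrajs list of [discrete_trajectory()] (or integer vectors).
#' @param bias list of frames x K matrices of reduced bias energies, one
#'   per trajectory, aligned with the frames.
#' @param ensemble_id 1-based index of the thermodynamic state that
#'   generated these trajectories.
#' @param frame_interval used when raw integer vectors are supplied.
#' @return an object of class `ensemble_data`.
#' @export
ensemble_data <- function(dtrajs, bias, ensemble_id, frame_interval = NULL) {
  dtrajs <- as_dtraj_list(dtrajs, frame_interval)
  if (is.matrix(bias)) bias <- list(bias)
  if (length(bias) != length(dtrajs))
    stop("need one bias matrix per trajectory")
  for (i in seq_along(dtrajs)) {
    bias[[i]] <- as.matrix(bias[[i]])
    if (nrow(bias[[i]]) != length(dtrajs[[i]]$states))
      stop("bias row count must equal the trajectory frame count")
  }
  structure(list(dtrajs = dtrajs, bias = bias,
                 ensemble_id = as.integer(ensemble_id)),
            class = "ensemble_data")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# elementwise log(exp(a) + exp(b))
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(-abs(a - b)))
  r[!is.finite(m)] <- m[!is.finite(m)]
  r
}

row_logsumexp <- function(M) {
  K <- ncol(M)
  m <- M[, 1]
  if (K > 1) for (k in 2:K) m <- pmax(m, M[, k])
  s <- exp(M[, 1] - m)
  if (K > 1) for (k in 2:K) s <- s + exp(M[, k] - m)
  out <- m + log(s)
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# column-wise logsumexp of a matrix
col_logsumexp <- function(M) {
  m <- apply(M, 2, max)
  out <- m
  ok <- is.finite(m)
  if (any(ok))
    out[ok] <- m[ok] +
      log(colSums(exp(sweep(M[, ok, drop = FALSE], 2, m[ok]))))
  out
}

#' TRAM: multi-ensemble Markov model estimation
#'
#' Combines unbiased and biased (e.g. umbrella-sampling) discrete
#' trajectories into a single unbiased thermodynamic and kinetic model.
#' Within each thermodynamic state k a reversible Markov model is assumed;
#' the ensembles are coupled through the reduced bias energies of every
#' sample.  The coupled maximum-likelihood problem is solved by the
#' standard self-consistent iteration on the biased state free energies
#' f_i^k and Lagrange multipliers nu_i^k, carried out in log space.
#'
#' @param ensembles list of [ensemble_data()]; ensemble ids must form a
#'   contiguous range 1..K matching the bias-matrix columns.
#' @param lag lag time in frames for transition counting.
#' @param tol convergence tolerance on the max change of f_i^k per
#'   iteration, in kBT (default 1e-10).
#' @param max_iter iteration cap (default 1e5); exceeding it raises an
#'   error carrying the last increment unless `on_nonconvergence =
#'   "warn"`.
#' @param on_nonconvergence `"error"` (default) or `"warn"`.
#' @return an object of class `tram_model`: `state_free_energies` (K x n,
#'   kBT, gauge min = 0), `unbiased_pi`, `transition_matrices` (list per
#'   ensemble), `unbiased_model` (a `markov_model` over the active set
#'   built from the unbiased ensemble's transition matrix if an unbiased
#'   ensemble exists, otherwise from ensemble 1), `active_set`,
#'   `converged`, `increment`, `n_iter`.
#' @export
estimate_tram <- function(ensembles, lag, tol = 1e-10, max_iter = 100000,
                          on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (inherits(ensembles, "ensemble_data")) ensembles <- list(ensembles)
  if (!length(ensembles)) stop("need at least one ensemble")
  lag <- as.integer(lag)
  K <- max(vapply(ensembles, function(e) e$ensemble_id, numeric(1)))
  Kb <- unique(vapply(ensembles, function(e) ncol(e$bias[[1]]), numeric(1)))
  if (length(Kb) != 1) stop("all bias matrices must have the same column count")
  K <- max(K, Kb)
  n <- max(vapply(ensembles, function(e)
    max(vapply(e$dtrajs, function(d) max(d$states), numeric(1))), numeric(1)))
  fi_ns <- ensembles[[1]]$dtrajs[[1]]$frame_interval

  # per-thermodynamic-state transition counts and state counts
  counts <- lapply(seq_len(K), function(k) matrix(0, n, n))
  state_counts <- matrix(0, K, n)
  for (e in ensembles) {
    k <- e$ensemble_id
    cm <- count_transitions(e$dtrajs, lag, n = n)$counts
    counts[[k]] <- counts[[k]] + cm
    for (d in e$dtrajs)
      state_counts[k, ] <- state_counts[k, ] +
        tabulate(d$states, nbins = n)
  }

  # connectivity across the union of symmetrised count graphs
  adj <- Reduce(`+`, lapply(counts, function(cm) cm + t(cm)))
  comp <- scc_components(adj)
  sampled <- which(colSums(state_counts) > 0)
  comps_sampled <- unique(comp[sampled])
  if (length(comps_sampled) > 1) {
    groups <- vapply(comps_sampled, function(cc) {
      ens <- which(vapply(seq_len(K), function(k)
        any(state_counts[k, comp == cc] > 0), logical(1)))
      paste(ens, collapse = ",")
    }, character(1))
    stop("disconnected replica graph: ensembles split into groups {",
         paste(groups, collapse = "} {"), "} with no transition overlap")
  }
  active <- intersect(largest_connected_set(adj), sampled)
  if (!length(active)) stop("empty connected set")
  amap <- match(seq_len(n), active)  # original -> active index (NA outside)
  na <- length(active)
  counts <- lapply(counts, function(cm) cm[active, active, drop = FALSE])
  state_counts <- state_counts[, active, drop = FALSE]

  # flatten samples: active state index + bias row
  samp_state <- integer(0)
  samp_bias <- NULL
  for (e in ensembles) {
    for (ti in seq_along(e$dtrajs)) {
      s <- amap[e$dtrajs[[ti]]$states]
      keep <- !is.na(s)
      samp_state <- c(samp_state, s[keep])
      samp_bias <- rbind(samp_bias, e$bias[[ti]][keep, , drop = FALSE])
    }
  }
  # collapse duplicate (state, bias-row) samples into weighted samples:
  # with state-wise constant biases this reduces the per-iteration cost
  # from O(frames) to O(states)
  key <- paste0(samp_state, "|",
                apply(samp_bias, 1, paste, collapse = ","))
  first <- !duplicated(key)
  map <- match(key, key[first])
  logw <- log(tabulate(map, nbins = sum(first)))
  samp_state <- samp_state[first]
  samp_bias <- samp_bias[first, , drop = FALSE]
  S <- length(samp_state)
  by_state <- split(seq_len(S), factor(samp_state, levels = seq_len(na)))

  CK <- lapply(counts, function(cm) cm + t(cm))
  logCK <- lapply(CK, function(cm) {
    out <- suppressWarnings(log(cm)); out[cm == 0] <- -Inf; out
  })
  incoming <- t(vapply(counts, colSums, numeric(na)))       # K x na
  extra <- pmax(state_counts - incoming, 0)                 # frames never a target

  # init: f from the biased sample counts, nu from row sums
  f <- matrix(0, K, na)
  lognu <- t(vapply(counts, function(cm) log(pmax(rowSums(cm), 1)), numeric(na)))

  increment <- Inf
  it <- 0L
  logR <- matrix(-Inf, K, na)
  while (it < max_iter) {
    it <- it + 1L
    # --- nu update ---
    lognu_new <- lognu
    for (k in seq_len(K)) {
      if (sum(CK[[k]]) == 0) next
      a <- outer(lognu[k, ], -f[k, ], "+")      # log(nu_i e^{-f_j})
      logD <- logaddexp(a, t(a))
      contrib <- logCK[[k]] + a - logD
      contrib[CK[[k]] == 0] <- -Inf
      lognu_new[k, ] <- apply(contrib, 1, logsumexp)
    }
    lognu <- lognu_new

    # --- modified state counts: R_i = sum_j CK_ij nu_j e^{-f_i}/D_ij +
    #     (N_i - incoming_i); gauge-invariant under uniform shifts of f ---
    for (k in seq_len(K)) {
      a <- outer(lognu[k, ], -f[k, ], "+")
      logD <- logaddexp(a, t(a))
      contrib <- sweep(sweep(logCK[[k]] - logD, 2, lognu[k, ], "+"),
                       1, f[k, ], "-")
      contrib[CK[[k]] == 0] <- -Inf
      sums <- apply(contrib, 1, logsumexp)
      logR[k, ] <- logaddexp(sums, suppressWarnings(log(extra[k, ])))
    }

    # --- f update ---
    A <- t(logR + f)[samp_state, , drop = FALSE] - samp_bias  # S x K
    div <- row_logsumexp(A)
    f_new <- f
    for (i in seq_len(na)) {
      ix <- by_state[[i]]
      M <- logw[ix] - samp_bias[ix, , drop = FALSE] - div[ix]  # |ix| x K
      f_new[, i] <- -col_logsumexp(M)
    }
    # fix the (neutral) uniform gauge mode before measuring the increment
    f_new <- f_new - min(f_new[is.finite(f_new)])
    increment <- max(abs(f_new - f)[is.finite(f_new) & is.finite(f)])
    f <- f_new
    if (increment < tol) break
  }
  converged <- increment < tol
  if (!converged) {
    msg <- sprintf("TRAM did not converge in %d iterations (last increment %.3g)",
                   it, increment)
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }

  # unbiased sample weights mu(x) and stationary vector
  A <- t(logR + f)[samp_state, , drop = FALSE] - samp_bias
  div <- row_logsumexp(A)
  logpi <- vapply(seq_len(na), function(i) {
    ix <- by_state[[i]]
    if (!length(ix)) -Inf else logsumexp(logw[ix] - div[ix])
  }, numeric(1))
  logpi <- logpi - logsumexp(logpi)
  unbiased_pi <- exp(logpi)

  # per-ensemble reversible transition matrices
  Ts <- vector("list", K)
  for (k in seq_len(K)) {
    a <- outer(lognu[k, ], -f[k, ], "+")
    logD <- logaddexp(a, t(a))
    Tk <- exp(sweep(logCK[[k]] - logD, 2, -f[k, ], "+"))
    Tk[CK[[k]] == 0] <- 0
    diag(Tk) <- 0
    rs <- rowSums(Tk)
    if (any(rs > 1)) Tk <- Tk / pmax(rs, 1)   # numerical safety
    diag(Tk) <- 1 - rowSums(Tk)
    Ts[[k]] <- Tk
  }

  # kinetic model of the unbiased ensemble (zero bias column), if present
  zero_bias <- which(apply(samp_bias, 2, function(col) all(col == 0)))
  kin_k <- if (length(zero_bias)) zero_bias[1] else 1L
  unbiased_model <- build_markov_model(Ts[[kin_k]], unbiased_pi,
                                       lag * fi_ns, active,
                                       reversible = TRUE)

  structure(list(state_free_energies = f, lagrangian_log = lognu,
                 unbiased_pi = unbiased_pi,
                 transition_matrices = Ts,
                 unbiased_model = unbiased_model,
                 active_set = active, lag = lag, frame_interval = fi_ns,
                 converged = converged, increment = increment, n_iter = it),
            class = "tram_model")
}

#' @export
print.tram_model <- function(x, ...) {
  cat(sprintf("tram_model: %d states x %d ensembles, lag %d frames, %s (increment %.3g, %d iterations)\n",
              length(x$active_set), nrow(x$state_free_energies), x$lag,
              if (x$converged) "converged" else "NOT converged",
              x$increment, x$n_iter))
  invisible(x)
}

#' Free-energy profile over a binned feature
#'
#' W_b = -kBT ln sum of pi over the microstates mapped to bin b, offset so
#' the minimum is zero.  Empty bins are masked (NA) and flagged.
#'
#' @param pi stationary probability vector over microstates.
#' @param bin_map integer bin index per microstate (NA to drop a state).
#' @param bin_centers optional numeric centres per bin (defaults to the
#'   bin index).
#' @param temperature Kelvin.
#' @return data.frame with columns `bin`, `center`, `W` (kcal/mol,
#'   NA = masked), `n_states`.
#' @export
free_energy_profile <- function(pi, bin_map, bin_centers = NULL,
                                temperature = 300) {
  bin_map <- as.integer(bin_map)
  stopifnot(length(bin_map) == length(pi))
  if (all(is.na(bin_map))) stop("all states are unbinned")
  nb <- max(bin_map, na.rm = TRUE)
  P <- vapply(seq_len(nb), function(b)
    sum(pi[which(bin_map == b)]), numeric(1))
  ns <- tabulate(bin_map, nbins = nb)
  if (all(P == 0)) stop("all bins are empty")
  W <- ifelse(P > 0, -kBT(temperature) * log(P), NA_real_)
  W <- W - min(W, na.rm = TRUE)
  centers <- if (is.null(bin_centers)) seq_len(nb) else bin_centers
  data.frame(bin = seq_len(nb), center = centers, W = W, n_states = ns)
}
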