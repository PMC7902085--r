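#' Local sensitivity of the stationary distribution
#'
#' Derivatives d pi_i / d T_jk under the row-compensation convention: a
#' perturbation of the off-diagonal element T_jk is absorbed by T_jj so
#' that the perturbed matrix stays stochastic.  Computed with the
#' fundamental matrix Z = (I - T + 1 pi)^(-1):
#' d pi_i / d T_jk = pi_j (Z_ki - Z_ji).  Diagonal entries (j = k) are
#' stored as zero, consistent with the convention.
#'
#' @param model an irreducible `markov_model`.
#' @return an object of class `local_sensitivity` with field `S`, a list
#'   of n matrices (one per observable pi_i), each n x n over (j, k).
#' @export
local_sensitivity_stationary <- function(model) {
  T_ <- model$T
  n <- nrow(T_)
  pi_ <- model$pi
  comp <- scc_components(T_)
  if (length(unique(comp)) > 1) stop("model is reducible")
  Z <- solve(diag(n) - T_ + matrix(1, n, 1) %*% matrix(pi_, 1, n))
  S <- vector("list", n)
  for (i in seq_len(n)) {
    # d pi_i / d T_jk = pi_j (Z[k, i] - Z[j, i])
    M <- sweep(outer(pi_, Z[, i]), 1, pi_ * Z[, i], "-")
    diag(M) <- 0
    S[[i]] <- M
  }
  structure(list(S = S, observable = "stationary_distribution"),
            class = "local_sensitivity")
}

#' Dirichlet posterior covariance of transition-matrix rows
#'
#' Rows of T are modelled as independent Dirichlet posteriors with
#' parameters counts + alpha:
#' cov[T_ij, T_il] = Tbar_ij (delta_jl - Tbar_il) / (c_i + alpha n + 1),
#' zero across rows.
#'
#' @param counts a [count_transitions()] object (or raw count matrix).
#' @param alpha pseudocount added to every entry (default 0).
#' @return an object of class `transition_covariance` with fields `blocks`
#'   (list of per-row n x n covariance matrices), `mean` (posterior mean
#'   matrix), `row_totals`.
#' @export
transition_matrix_covariance <- function(counts, alpha = 0) {
  C <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  n <- ncol(C)
  rows <- rowSums(C) + alpha * n
  if (any(rows <= 0)) stop("empty count row with alpha = 0")
  Tbar <- (C + alpha) / rows
  blocks <- lapply(seq_len(n), function(i) {
    p <- Tbar[i, ]
    (diag(p, n) - p %o% p) / (rows[i] + 1)
  })
  structure(list(blocks = blocks, mean = Tbar, row_totals = rows,
                 alpha = alpha),
            class = "transition_covariance")
}

#' Global (variance-based, Sobol) sensitivities
#'
#' First-order propagated variance of each observable:
#' S_global = sum over matrix entries of S_jk cov[T_jk, T_lm] S_lm,
#' using the row-block structure of the Dirichlet covariance (zero across
#' rows).
#'
#' @param S a [local_sensitivity_stationary()] object.
#' @param covariance a [transition_matrix_covariance()] object.
#' @return an object of class `global_sensitivity` with fields `S_global`
#'   (one non-negative value per observable) and `per_state` (the
#'   aggregate over observables localised on each state; for pi
#'   observables this equals `S_global`).
#' @export
global_sensitivity <- function(S, covariance) {
  stopifnot(inherits(S, "local_sensitivity"),
            inherits(covariance, "transition_covariance"))
  n <- nrow(covariance$mean)
  if (nrow(S$S[[1]]) != n) stop("shape mismatch between sensitivity and covariance")
  out <- vapply(S$S, function(M) {
    tot <- 0
    for (j in seq_len(n)) {
      s <- M[j, ]
      tot <- tot + drop(s %*% covariance$blocks[[j]] %*% s)
    }
    max(tot, 0)
  }, numeric(1))
  structure(list(S_global = out, per_state = out),
            class = "global_sensitivity")
}

#' Select umbrella windows from microstate sensitivities
#'
#' Microstates are ranked by aggregate sensitivity (ties broken towards
#' the smaller average COM distance); the smallest prefix whose cumulative
#' sensitivity reaches the coverage fraction is mapped to its COM-distance
#' range, and all window centres inside that closed interval are selected.
#'
#' @param global a [global_sensitivity()] object (or bare numeric vector
#'   of per-state sensitivities).
#' @param com_of_state average COM distance per microstate, A.
#' @param grid a [make_window_grid()] candidate window set.
#' @param coverage fraction of total sensitivity to cover (default 0.9).
#' @return an object of class `window_selection` with fields
#'   `ranked_states`, `states_used`, `com_range`, `selected_centers`,
#'   `coverage`.
#' @export
select_windows <- function(global, com_of_state, grid, coverage = 0.9) {
  s <- if (inherits(global, "global_sensitivity")) global$per_state else as.numeric(global)
  if (length(s) != length(com_of_state))
    stop("sensitivities and COM map must have equal length")
  if (!length(grid$centers)) stop("window grid is empty")
  if (all(s == 0)) stop("all sensitivities are zero")
  ord <- order(-s, com_of_state)
  cum <- cumsum(s[ord]) / sum(s)
  n_used <- which(cum >= coverage - 1e-12)[1]
  used <- ord[seq_len(n_used)]
  rng <- range(com_of_state[used])
  sel <- grid$centers[grid$centers >= rng[1] - 1e-9 &
                        grid$centers <= rng[2] + 1e-9]
  structure(list(ranked_states = ord, states_used = used,
                 com_range = rng, selected_centers = sel,
                 coverage = coverage),
            class = "window_selection")
}

#' @export
print.window_selection <- function(x, ...) {
  cat(sprintf("window_selection: %d states cover %.0f%%, COM range %.3g - %.3g A, %d windows\n",
              length(x$states_used), 100 * x$coverage,
              x$com_range[1], x$com_range[2], length(x$selected_centers)))
  invisible(x)
}
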