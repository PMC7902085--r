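#' Discrete trajectory
#'
#' @param states integer state sequence (1-based labels).
#' @param frame_interval time between frames, ns.
#' @return an object of class `discrete_trajectory`.
#' @export
discrete_trajectory <- function(states, frame_interval) {
  states <- as.integer(states)
  if (any(states < 1)) stop("states must be positive integers")
  stopifnot(frame_interval > 0)
  structure(list(states = states, frame_interval = frame_interval),
            class = "discrete_trajectory")
}

as_dtraj_list <- function(dtrajs, frame_interval = NULL) {
  if (inherits(dtrajs, "discrete_trajectory")) dtrajs <- list(dtrajs)
  if (is.numeric(dtrajs)) dtrajs <- list(dtrajs)
  lapply(dtrajs, function(d) {
    if (inherits(d, "discrete_trajectory")) d
    else discrete_trajectory(d, frame_interval %||% 1)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sliding-window transition counts
#'
#' Counts c[s_t, s_(t+lag)] summed over trajectories; transitions never
#' cross trajectory boundaries.
#'
#' @param dtrajs list of [discrete_trajectory()] (or integer vectors).
#' @param lag lag in frames (>= 1, shorter than every trajectory).
#' @param n number of states (default: largest label observed).
#' @param frame_interval used when raw integer vectors are supplied.
#' @return an object of class `count_matrix` with fields `counts`, `lag`,
#'   `frame_interval`.
#' @export
count_transitions <- function(dtrajs, lag, n = NULL, frame_interval = NULL) {
  dtrajs <- as_dtraj_list(dtrajs, frame_interval)
  lag <- as.integer(lag)
  stopifnot(lag >= 1)
  lens <- vapply(dtrajs, function(d) length(d$states), numeric(1))
  if (any(lens <= lag)) stop("lag must be shorter than every trajectory")
  if (is.null(n)) n <- max(vapply(dtrajs, function(d) max(d$states), numeric(1)))
  counts <- matrix(0, n, n)
  for (d in dtrajs) {
    s <- d$states
    L <- length(s)
    from <- s[seq_len(L - lag)]
    to <- s[(lag + 1):L]
    tab <- table(factor(from, levels = seq_len(n)),
                 factor(to, levels = seq_len(n)))
    counts <- counts + unclass(tab)
  }
  dimnames(counts) <- NULL
  structure(list(counts = counts, lag = lag,
                 frame_interval = dtrajs[[1]]$frame_interval),
            class = "count_matrix")
}

# strongly connected components of the directed graph counts > 0 (Tarjan,
# iterative); returns component id per node
scc_components <- function(adj) {
  n <- nrow(adj)
  index <- rep(NA_integer_, n); low <- integer(n)
  onstack <- rep(FALSE, n); stack <- integer(0)
  comp <- rep(NA_integer_, n); ncomp <- 0L; counter <- 0L
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] > 0 & seq_len(n) != i))
  for (root in seq_len(n)) {
    if (!is.na(index[root])) next
    work <- list(list(v = root, pi = 0L))
    while (length(work)) {
      fr <- work[[length(work)]]
      v <- fr$v
      if (fr$pi == 0L) {
        counter <- counter + 1L
        index[v] <- low[v] <- counter
        stack <- c(stack, v); onstack[v] <- TRUE
      }
      advanced <- FALSE
      ns <- nbrs[[v]]
      while (fr$pi < length(ns)) {
        fr$pi <- fr$pi + 1L
        w <- ns[fr$pi]
        if (is.na(index[w])) {
          work[[length(work)]] <- fr
          work[[length(work) + 1L]] <- list(v = w, pi = 0L)
          advanced <- TRUE
          break
        } else if (onstack[w]) {
          low[v] <- min(low[v], index[w])
        }
      }
      if (advanced) next
      work[[length(work)]] <- NULL
      if (low[v] == index[v]) {
        ncomp <- ncomp + 1L
        repeat {
          w <- stack[length(stack)]
          stack <- stack[-length(stack)]
          onstack[w] <- FALSE
          comp[w] <- ncomp
          if (w == v) break
        }
      }
      if (length(work)) {
        parent <- work[[length(work)]]
        low[parent$v] <- min(low[parent$v], low[v])
        work[[length(work)]] <- parent
      }
    }
  }
  comp
}

largest_connected_set <- function(counts) {
  comp <- scc_components(counts)
  visited <- table(comp)
  # prefer the component with most states, ties by total counts
  best <- NULL; best_key <- c(-1, -1)
  for (cc in as.integer(names(visited))) {
    states <- which(comp == cc)
    key <- c(length(states), sum(counts[states, states]))
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2])) {
      best <- states; best_key <- key
    }
  }
  sort(best)
}

#' Estimate a Markov state model from transition counts
#'
#' The estimate is restricted to the largest strongly connected component of
#' the count graph (`active_set` records the original labels).  In
#' non-reversible mode rows are simply normalised; in reversible mode
#' (default) the maximum-likelihood transition matrix satisfying detailed
#' balance is found by the standard self-consistent fixed-point iteration.
#'
#' @param counts a [count_transitions()] object.
#' @param reversible enforce detailed balance (default TRUE).
#' @param tol convergence tolerance on the stationary distribution.
#' @param max_iter iteration cap for the reversible estimator.
#' @return an object of class `markov_model` with fields `T` (row
#'   stochastic), `pi`, `eigenvalues`, `lag_time` (ns), `active_set`,
#'   `reversible`, `counts`.
#' @export
estimate_transition_matrix <- function(counts, reversible = TRUE,
                                       tol = 1e-12, max_iter = 100000) {
  stopifnot(inherits(counts, "count_matrix"))
  C <- counts$counts
  if (sum(C) == 0) stop("empty count matrix")
  active <- largest_connected_set(C)
  if (length(active) == 0) stop("empty connected set")
  C <- C[active, active, drop = FALSE]
  n <- nrow(C)
  if (reversible && n > 1) {
    Csym <- C + t(C)
    ci <- rowSums(C)
    x <- Csym
    xi <- rowSums(x)
    pi_old <- xi / sum(xi)
    for (it in seq_len(max_iter)) {
      denom <- outer(ci / xi, ci / xi, "+")
      x <- Csym / denom
      x[Csym == 0] <- 0
      xi <- rowSums(x)
      pi_new <- xi / sum(xi)
      if (max(abs(pi_new - pi_old)) < tol) break
      pi_old <- pi_new
    }
    T_ <- x / xi
    pi_ <- xi / sum(xi)
  } else {
    T_ <- C / rowSums(C)
    pi_ <- stationary_distribution(T_)
  }
  build_markov_model(T_, pi_, counts$lag * counts$frame_interval,
                     active, reversible, C)
}

build_markov_model <- function(T_, pi_, lag_time, active_set, reversible,
                               counts = NULL) {
  ev <- transition_eigenvalues(T_, pi_, reversible)
  structure(list(T = T_, pi = pi_, eigenvalues = ev, lag_time = lag_time,
                 active_set = active_set, reversible = reversible,
                 counts = counts),
            class = "markov_model")
}

transition_eigenvalues <- function(T_, pi_, reversible) {
  n <- nrow(T_)
  if (reversible && all(pi_ > 0)) {
    s <- sqrt(pi_)
    A <- (s %o% (1 / s)) * T_
    A <- (A + t(A)) / 2
    sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  } else {
    ev <- eigen(T_, only.values = TRUE)$values
    Re(ev[order(Mod(ev), decreasing = TRUE)])
  }
}

#' Markov model from an explicit transition matrix
#'
#' @param T_ row-stochastic matrix.
#' @param lag_time lag time in ns.
#' @param reversible whether `T_` satisfies detailed balance.
#' @return a `markov_model`.
#' @export
markov_model <- function(T_, lag_time = 1, reversible = NULL) {
  T_ <- as.matrix(T_)
  if (max(abs(rowSums(T_) - 1)) > 1e-10) stop("rows of T must sum to 1")
  pi_ <- stationary_distribution(T_)
  if (is.null(reversible)) {
    db <- max(abs(pi_ * T_ - t(pi_ * T_)))
    reversible <- db < 1e-10
  }
  build_markov_model(T_, pi_, lag_time, seq_len(nrow(T_)), reversible)
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: %d states, lag %.4g ns, %s\n",
              nrow(x$T), x$lag_time,
              if (x$reversible) "reversible" else "non-reversible"))
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' Unique probability vector with pi T = pi for an irreducible
#' row-stochastic matrix.
#'
#' @param T_ row-stochastic matrix.
#' @param tol tolerance on stochasticity and eigenvalue degeneracy checks.
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(T_, tol = 1e-10) {
  T_ <- as.matrix(T_)
  n <- nrow(T_)
  if (n == 1) return(1)
  if (max(abs(rowSums(T_) - 1)) > 1e-8) stop("T is not row-stochastic")
  comp <- scc_components(T_)
  if (length(unique(comp)) > 1) stop("T is reducible: no unique stationary distribution")
  ed <- eigen(t(T_))
  i <- which.min(Mod(ed$values - 1))
  v <- Re(ed$vectors[, i])
  if (all(v <= tol)) v <- -v
  if (any(v < -1e-8 * max(abs(v)))) stop("invalid stationary eigenvector")
  v <- pmax(v, 0)
  v / sum(v)
}

#' Implied relaxation timescales
#'
#' t_i = -lag_time / ln(lambda_i) for the k eigenvalues below the Perron
#' root; eigenvalues >= 1 (disconnected limit) are reported as `Inf` and
#' flagged in the `infinite` attribute.
#'
#' @param model a `markov_model`.
#' @param k number of timescales (k < number of states).
#' @return numeric vector of timescales in ns.
#' @export
implied_timescales <- function(model, k = nrow(model$T) - 1) {
  n <- nrow(model$T)
  if (k >= n) stop("k must be smaller than the number of states")
  lam <- model$eigenvalues[2:(k + 1)]
  ts <- ifelse(lam >= 1, Inf, -model$lag_time / log(abs(lam)))
  attr(ts, "infinite") <- lam >= 1
  ts
}

#' Mean first passage time between state sets
#'
#' Per-state MFPTs solve the first-step linear system (zero on the target
#' set); the reported value averages over the source set with the
#' stationary distribution restricted to it and renormalised, and is
#' multiplied by the lag time.
#'
#' @param model a `markov_model`.
#' @param source,target disjoint non-empty sets of model state indices.
#' @return MFPT in ns (physical time).
#' @export
mfpt_between_sets <- function(model, source, target) {
  n <- nrow(model$T)
  source <- unique(as.integer(source)); target <- unique(as.integer(target))
  if (!length(source) || !length(target)) stop("source and target must be non-empty")
  if (length(intersect(source, target))) stop("source and target must be disjoint")
  if (any(c(source, target) < 1) || any(c(source, target) > n))
    stop("state index outside the active set")
  m <- mfpt_per_state(model$T, target)
  w <- model$pi[source] / sum(model$pi[source])
  sum(w * m[source]) * model$lag_time
}

# expected hitting steps of `target` from every state
mfpt_per_state <- function(T_, target) {
  n <- nrow(T_)
  U <- setdiff(seq_len(n), target)
  m <- numeric(n)
  if (length(U)) {
    A <- diag(length(U)) - T_[U, U, drop = FALSE]
    m[U] <- solve(A, rep(1, length(U)))
  }
  m
}

#' Bootstrap errors over trajectories
#'
#' Resamples whole trajectories with replacement, re-runs the estimator and
#' reports the spread.  Estimator failures on a resample are excluded and
#' counted.
#'
#' @param inputs list of trajectories (any objects the estimator accepts).
#' @param estimator function taking a list of trajectories and returning a
#'   numeric scalar or named vector.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @return list with `mean`, `sd`, `n_failed`, `replicates`.
#' @export
bootstrap_errors <- function(inputs, estimator, n_boot = 100, seed = 1) {
  if (length(inputs) < 2) stop("need at least 2 trajectories to bootstrap")
  if (n_boot < 2) stop("n_boot must be >= 2")
  set.seed(seed)
  reps <- vector("list", n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(inputs), replace = TRUE)
    reps[b] <- list(tryCatch(estimator(inputs[idx]),
                             error = function(e) NULL))
    if (is.null(reps[[b]])) failed <- failed + 1L
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (!any(ok)) stop("estimator failed on every bootstrap resample")
  mat <- do.call(rbind, reps[ok])
  list(mean = colMeans(mat), sd = apply(mat, 2, sd),
       n_failed = failed, replicates = mat)
}
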