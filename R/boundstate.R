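#' Bound-state indicator series
#'
#' h(t) = 1 when the COM separation is within `r_cut` (the boundary counts
#' as bound), 0 otherwise.
#'
#' @param com a [feature_series()] holding a COM-distance column, or a
#'   numeric vector of distances.
#' @param r_cut cutoff distance, A (>= 0).
#' @param frame_interval ns, required when `com` is a bare vector.
#' @return an object of class `indicator_series` with fields `h`,
#'   `frame_interval`.
#' @export
bound_indicator <- function(com, r_cut, frame_interval = NULL) {
  if (r_cut < 0) stop("r_cut must be non-negative")
  if (inherits(com, "feature_series")) {
    frame_interval <- com$frame_interval
    com <- com$values[, 1]
  }
  if (is.null(frame_interval)) stop("frame_interval required for bare vectors")
  structure(list(h = as.integer(com <= r_cut),
                 frame_interval = frame_interval),
            class = "indicator_series")
}

#' Normalised autocorrelation of bound-state indicators
#'
#' Per trajectory the mean-subtracted, variance-normalised autocovariance
#' is computed; trajectories are aggregated by length-weighted averaging,
#' never forming products across trajectory boundaries.  Constant
#' trajectories carry no correlation information and are dropped (an error
#' if all are constant).
#'
#' @param series an `indicator_series` or list of them.
#' @param max_lag largest lag in ns.
#' @return an object of class `autocorr_curve` with fields `lags` (ns) and
#'   `values`; value at lag 0 is 1.
#' @export
indicator_autocorrelation <- function(series, max_lag) {
  if (inherits(series, "indicator_series")) series <- list(series)
  fi <- series[[1]]$frame_interval
  nlag <- floor(max_lag / fi + 1e-9)
  acc <- numeric(nlag + 1)
  wts <- numeric(nlag + 1)
  used <- 0L
  for (s in series) {
    h <- as.numeric(s$h)
    N <- length(h)
    hb <- mean(h)
    v <- sum((h - hb)^2)
    if (v == 0) next
    used <- used + 1L
    kmax <- min(nlag, N - 1)
    d <- h - hb
    for (tau in 0:kmax) {
      ct <- sum(d[seq_len(N - tau)] * d[(tau + 1):N]) / v
      acc[tau + 1] <- acc[tau + 1] + N * ct
      wts[tau + 1] <- wts[tau + 1] + N
    }
  }
  if (used == 0L) stop("all indicator series are constant (zero variance)")
  vals <- ifelse(wts > 0, acc / wts, NA_real_)
  structure(list(lags = (0:nlag) * fi, values = vals),
            class = "autocorr_curve")
}

#' Fit a biexponential decay to an autocorrelation curve
#'
#' Least-squares fit of A1 exp(-t/tau1) + A2 exp(-t/tau2) with A_i >= 0 and
#' tau_i > 0, reported with tau1 <= tau2.  The timescales are optimised by
#' variable projection (amplitudes solved linearly at each candidate
#' timescale pair), initialised from log-linear fits of the head and tail
#' segments of the curve.
#'
#' @param curve an `autocorr_curve` (or list with `lags`, `values`), at
#'   least 5 finite points.
#' @return an object of class `biexp_fit` with fields `A1`, `tau1`, `A2`,
#'   `tau2`, `residual_norm`, `degenerate` (TRUE when the two components
#'   are indistinguishable).
#' @export
fit_biexponential <- function(curve) {
  t <- curve$lags; y <- curve$values
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 5) stop("need at least 5 points to fit a biexponential")

  # log-linear initial guesses from head / tail segments (positive values)
  pos <- which(y > 0 & t > 0)
  guess_tau <- function(ix) {
    if (length(ix) < 2) return(NA_real_)
    fit <- stats::lm.fit(cbind(1, t[ix]), log(y[ix]))
    sl <- fit$coefficients[2]
    if (!is.finite(sl) || sl >= 0) NA_real_ else -1 / sl
  }
  n_pos <- length(pos)
  tau1_0 <- guess_tau(pos[seq_len(max(2, ceiling(n_pos * 0.2)))])
  tau2_0 <- guess_tau(pos[pos >= pos[max(1, floor(n_pos * 0.6))]])
  span <- max(t[t > 0])
  if (!is.finite(tau1_0)) tau1_0 <- span / 20
  if (!is.finite(tau2_0)) tau2_0 <- span / 2
  if (tau2_0 <= tau1_0) tau2_0 <- tau1_0 * 3

  amps_for <- function(tau) {
    X <- cbind(exp(-t / tau[1]), exp(-t / tau[2]))
    a <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) c(NA, NA))
    if (any(!is.finite(a)) || any(a < 0)) {
      # non-negative fallback: try each amplitude pinned at zero
      best <- NULL; bestss <- Inf
      for (j in 1:2) {
        aa <- c(0, 0)
        cj <- sum(X[, j] * y) / sum(X[, j]^2)
        aa[j] <- max(cj, 0)
        ss <- sum((y - X %*% aa)^2)
        if (ss < bestss) { bestss <- ss; best <- aa }
      }
      a <- best
    }
    a
  }
  obj <- function(ltau) {
    tau <- exp(ltau)
    a <- amps_for(tau)
    sum((y - a[1] * exp(-t / tau[1]) - a[2] * exp(-t / tau[2]))^2)
  }
  fit <- optim(log(c(tau1_0, tau2_0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (!is.finite(fit$value)) stop("biexponential fit failed to converge")
  tau <- exp(fit$par)
  a <- amps_for(tau)
  ord <- order(tau)
  tau <- tau[ord]; a <- a[ord]
  degenerate <- (tau[2] / tau[1] < 1.05) || any(a < 1e-4 * max(a, 1e-12))
  structure(list(A1 = a[1], tau1 = tau[1], A2 = a[2], tau2 = tau[2],
                 residual_norm = sqrt(fit$value), degenerate = degenerate),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("biexp_fit: A1 = %.4g, tau1 = %.4g ns; A2 = %.4g, tau2 = %.4g ns%s\n",
              x$A1, x$tau1, x$A2, x$tau2,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Scan bound-state cutoffs for maximal indicator relaxation time
#'
#' For each candidate r_cut the COM traces are binarised, the aggregate
#' indicator autocorrelation computed and a biexponential fitted.  The
#' optimal cutoff maximises the slow relaxation time tau2 (ties resolved
#' to the smaller r_cut); both timescales are tabulated for every grid
#' point.
#'
#' @param com_series list of COM-distance [feature_series()] (or numeric
#'   vectors with `frame_interval` given).
#' @param grid candidate r_cut values, A.
#' @param max_lag autocorrelation range, ns.
#' @param frame_interval ns, for bare numeric input.
#' @return an object of class `rcut_scan` with a `table` data.frame
#'   (r_cut, A1, tau1, A2, tau2, ok, error) and `optimal_rcut`.
#' @export
scan_rcut <- function(com_series, grid, max_lag, frame_interval = NULL) {
  if (!length(grid)) stop("r_cut grid is empty")
  if (inherits(com_series, "feature_series") || is.numeric(com_series))
    com_series <- list(com_series)
  rows <- vector("list", length(grid))
  fits <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    res <- tryCatch({
      ind <- lapply(com_series, bound_indicator, r_cut = grid[g],
                    frame_interval = frame_interval)
      ac <- indicator_autocorrelation(ind, max_lag)
      fit_biexponential(ac)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[g]] <- data.frame(r_cut = grid[g], A1 = NA, tau1 = NA,
                              A2 = NA, tau2 = NA, ok = FALSE,
                              error = conditionMessage(res))
    } else {
      fits[[g]] <- res
      rows[[g]] <- data.frame(r_cut = grid[g], A1 = res$A1, tau1 = res$tau1,
                              A2 = res$A2, tau2 = res$tau2, ok = TRUE,
                              error = "")
    }
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$ok)) stop("biexponential fit failed on every grid point")
  okt <- tab[tab$ok, ]
  best <- okt$r_cut[order(-okt$tau2, okt$r_cut)][1]
  structure(list(table = tab, optimal_rcut = best, fits = fits),
            class = "rcut_scan")
}

#' @export
print.rcut_scan <- function(x, ...) {
  cat(sprintf("rcut_scan: %d grid points, optimal r_cut = %.4g A\n",
              nrow(x$table), x$optimal_rcut))
  print(x$table[, c("r_cut", "tau1", "tau2", "ok")], row.names = FALSE)
  invisible(x)
}
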