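#' Construct a feature time series
#'
#' @param values frames x d numeric matrix.
#' @param names d feature labels (unique).
#' @param frame_interval time between frames, ns.
#' @return an object of class `feature_series`.
#' @export
feature_series <- function(values, names, frame_interval) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("feature values must be finite")
  names <- as.character(names)
  if (length(names) != ncol(values) || anyDuplicated(names))
    stop("feature names must be unique, one per column")
  colnames(values) <- names
  stopifnot(frame_interval > 0)
  structure(list(values = values, names = names,
                 frame_interval = frame_interval),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("feature_series: %d frames x %d features, interval %.4g ns\n",
              nrow(x$values), ncol(x$values), x$frame_interval))
  invisible(x)
}

#' Geometric featurizations of a trajectory
#'
#' Modes: `com_distance` (mass-weighted COM separation of the two chains,
#' A), `inverse_sq_com` (1/d^2, A^-2), and `pair_distances` (Euclidean
#' distances for selected (chain A bead, chain B bead) pairs, A).
#'
#' @param run a `run_result`.
#' @param mode one of `"com_distance"`, `"inverse_sq_com"`,
#'   `"pair_distances"`.
#' @param pairs for `pair_distances`, a 2-column matrix of chain-local bead
#'   indices (iA, iB).
#' @return a [feature_series()].
#' @export
geometry_features <- function(run, mode = c("com_distance", "inverse_sq_com",
                                            "pair_distances"),
                              pairs = NULL) {
  mode <- match.arg(mode)
  if (mode == "com_distance") {
    return(feature_series(matrix(com_series(run), ncol = 1), "com_distance",
                          run$frame_interval))
  }
  if (mode == "inverse_sq_com") {
    return(feature_series(matrix(1 / com_series(run)^2, ncol = 1),
                          "inverse_sq_com", run$frame_interval))
  }
  cx <- run$cx
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must be a 2-column (iA, iB) matrix")
  if (any(pairs[, 1] < 1 | pairs[, 1] > cx$nA) ||
      any(pairs[, 2] < 1 | pairs[, 2] > cx$nB))
    stop("invalid bead pair")
  vals <- pair_distance_matrix(run, pairs)
  feature_series(vals, sprintf("d_%d_%d", pairs[, 1], pairs[, 2]),
                 run$frame_interval)
}

# frames x npairs matrix of A-B bead distances (chain-local pair indices)
pair_distance_matrix <- function(run, pairs) {
  cx <- run$cx
  gi <- pairs[, 1]              # global index on chain A
  gj <- cx$nA + pairs[, 2]      # global index on chain B
  dx <- run$frames[, 3 * gi - 2, drop = FALSE] - run$frames[, 3 * gj - 2, drop = FALSE]
  dy <- run$frames[, 3 * gi - 1, drop = FALSE] - run$frames[, 3 * gj - 1, drop = FALSE]
  dz <- run$frames[, 3 * gi, drop = FALSE] - run$frames[, 3 * gj, drop = FALSE]
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Minimum RMSD to a reference pose
#'
#' Per-frame root-mean-square deviation after optimal rigid superposition
#' (Kabsch algorithm, rotations + translations; all beads equally weighted).
#'
#' @param run a `run_result`.
#' @param reference n x 3 reference coordinates (default: the complex's
#'   bound reference pose).
#' @return a [feature_series()] with one `rmsd_min` column, A.
#' @export
rmsd_min <- function(run, reference = NULL) {
  if (is.null(reference)) reference <- run$cx$reference
  reference <- as_coords(reference, "reference")
  n <- ncol(run$frames) / 3
  if (nrow(reference) != n) stop("mismatched bead counts")
  refc <- sweep(reference, 2, colMeans(reference))
  out <- vapply(seq_len(nrow(run$frames)), function(t) {
    x <- matrix(run$frames[t, ], ncol = 3, byrow = TRUE)
    kabsch_rmsd(x, refc, centered_ref = TRUE)
  }, numeric(1))
  feature_series(matrix(out, ncol = 1), "rmsd_min", run$frame_interval)
}

# RMSD after optimal superposition of x onto ref.  The rotation is applied
# explicitly and the residual computed directly, which stays accurate for
# near-zero deviations (no cancellation of large squared norms).
kabsch_rmsd <- function(x, ref, centered_ref = FALSE) {
  if (!centered_ref) ref <- sweep(ref, 2, colMeans(ref))
  x <- sweep(x, 2, colMeans(x))
  s <- svd(crossprod(x, ref))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(sum((x %*% R - ref)^2) / nrow(x))
}

#' Filter long-lived inter-chain contacts
#'
#' A (chain A, chain B) bead pair is kept if, in at least one run, it stays
#' within `dist_cutoff` (strictly below; boundary frames count as unbound)
#' for a contiguous stretch of at least `min_lifetime`.  A stretch of m
#' consecutive frames counts as m * frame_interval of lifetime.
#'
#' @param runs list of `run_result`.
#' @param dist_cutoff contact distance cutoff, A (default 12).
#' @param min_lifetime minimum contiguous lifetime, ns (default 1).
#' @return 2-column matrix of kept (iA, iB) pairs (chain-local indices).
#' @export
long_lived_contacts <- function(runs, dist_cutoff = 12, min_lifetime = 1) {
  if (inherits(runs, "run_result")) runs <- list(runs)
  cx <- runs[[1]]$cx
  pairs <- as.matrix(expand.grid(iA = seq_len(cx$nA), iB = seq_len(cx$nB)))
  keep <- rep(FALSE, nrow(pairs))
  for (run in runs) {
    if (min_lifetime < run$frame_interval)
      stop("min_lifetime below the frame interval cannot be resolved")
    need <- ceiling(min_lifetime / run$frame_interval - 1e-9)
    d <- pair_distance_matrix(run, pairs)
    below <- d < dist_cutoff
    keep <- keep | apply(below, 2, function(b) max_run_length(b) >= need)
  }
  pairs[keep, , drop = FALSE]
}

max_run_length <- function(b) {
  if (!any(b)) return(0L)
  r <- rle(b)
  max(r$lengths[r$values])
}

#' Fit a TICA model
#'
#' Time-lagged independent component analysis on mean-free data: the
#' instantaneous covariance C(0) and time-lagged covariance C(tau) are
#' estimated with the 1/(N - tau - 1) normalisation, C(tau) is symmetrised,
#' and the generalized eigenproblem C(tau) U = C(0) U Lambda is solved with
#' a small ridge on C(0).  Eigenvectors are normalised to unit C(0)-metric
#' (u' C(0) u = 1) and sorted by descending eigenvalue.
#'
#' @param X a [feature_series()] or list of them (no lagged products are
#'   formed across series).
#' @param lag lag time in frames (>= 1).
#' @param ridge relative ridge regularisation added to the diagonal of C(0)
#'   (default 1e-8 of mean diagonal).
#' @return an object of class `tica_model` with fields `mean`, `C0`, `Ctau`,
#'   `lag`, `eigenvalues`, `eigenvectors`, `timescales` (ns),
#'   `frame_interval`.
#' @export
tica_fit <- function(X, lag, ridge = 1e-8) {
  if (inherits(X, "feature_series")) X <- list(X)
  stopifnot(length(X) >= 1, lag >= 1)
  lag <- as.integer(lag)
  d <- ncol(X[[1]]$values)
  fi <- X[[1]]$frame_interval
  lens <- vapply(X, function(s) nrow(s$values), numeric(1))
  if (any(lens <= lag)) stop("every series must be longer than the lag")

  total <- sum(lens)
  mu <- colSums(do.call(rbind, lapply(X, function(s) colSums(s$values)))) / total
  S0 <- matrix(0, d, d); St <- matrix(0, d, d)
  n0 <- 0; nt <- 0
  for (s in X) {
    v <- sweep(s$values, 2, mu)
    S0 <- S0 + crossprod(v)
    n0 <- n0 + nrow(v)
    a <- v[seq_len(nrow(v) - lag), , drop = FALSE]
    b <- v[(lag + 1):nrow(v), , drop = FALSE]
    St <- St + crossprod(a, b)
    nt <- nt + nrow(a)
  }
  C0 <- S0 / (n0 - 1)
  Ctau <- St / (nt - 1)
  Ctau <- (Ctau + t(Ctau)) / 2

  C0r <- C0 + diag(ridge * sum(diag(C0)) / d, d)
  ev0 <- eigen(C0r, symmetric = TRUE)
  if (any(ev0$values <= 0)) {
    bad <- which(ev0$values <= 0)
    stop("C(0) is rank deficient beyond regularisation; null directions: ",
         paste(bad, collapse = ", "))
  }
  # whiten: L = C0^(-1/2), solve symmetric ordinary eigenproblem
  L <- ev0$vectors %*% diag(1 / sqrt(ev0$values), d) %*% t(ev0$vectors)
  M <- L %*% Ctau %*% L
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  lam <- em$values[ord]
  U <- L %*% em$vectors[, ord, drop = FALSE]   # u' C0 u = 1
  ts <- -lag * fi / log(pmin(abs(lam), 1 - 1e-15))
  structure(list(mean = mu, C0 = C0, Ctau = Ctau, lag = lag,
                 eigenvalues = lam, eigenvectors = U, timescales = ts,
                 frame_interval = fi),
            class = "tica_model")
}

#' Project data onto the leading independent components
#'
#' z(t) = (x(t) - mean) U restricted to the `n_components` slowest ICs.
#'
#' @param model a [tica_fit()] model.
#' @param X a [feature_series()] (same features as the fit).
#' @param n_components number of leading ICs to keep.
#' @return a [feature_series()] of IC coordinates.
#' @export
tica_transform <- function(model, X, n_components = length(model$eigenvalues)) {
  stopifnot(inherits(model, "tica_model"), inherits(X, "feature_series"))
  d <- length(model$mean)
  if (n_components > d) stop("n_components exceeds the feature dimension")
  if (ncol(X$values) != d) stop("feature dimension mismatch")
  z <- sweep(X$values, 2, model$mean) %*%
    model$eigenvectors[, seq_len(n_components), drop = FALSE]
  feature_series(z, sprintf("IC%d", seq_len(n_components)), X$frame_interval)
}

#' k-means discretization of feature space
#'
#' k-means++ initialisation followed by Lloyd iterations; deterministic for
#' a given seed.  Final assignments are recomputed as the nearest centre,
#' ties resolved to the lowest centre index.
#'
#' @param X numeric matrix (or [feature_series()]) of points x dimensions.
#' @param k number of clusters (1 <= k <= n points).
#' @param seed RNG seed.
#' @param iter_max maximum Lloyd iterations.
#' @return an object of class `discretization` with fields `centers`
#'   (k x d), `assignments` (per-frame 1-based state index), `inertia`.
#' @export
kmeans_cluster <- function(X, k, seed = 1, iter_max = 200) {
  if (inherits(X, "feature_series")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of points")
  set.seed(seed)
  init <- kmeanspp_init(X, k)
  fit <- if (k == 1) {
    list(centers = matrix(colMeans(X), 1))
  } else {
    suppressWarnings(kmeans(X, centers = init, iter.max = iter_max,
                            algorithm = "Lloyd"))
  }
  centers <- as.matrix(fit$centers)
  asg <- assign_to_centers(X, centers)
  inertia <- sum((X - centers[asg, , drop = FALSE])^2)
  structure(list(centers = centers, assignments = asg, inertia = inertia),
            class = "discretization")
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ], "-")^2)
  for (i in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[i + 1] <- sample.int(n, 1, prob = p)
    nd <- rowSums(sweep(X, 2, X[idx[i + 1], ], "-")^2)
    d2 <- pmin(d2, nd)
  }
  X[idx, , drop = FALSE]
}

#' Assign points to the nearest of a set of centres
#'
#' @param X points x d matrix.
#' @param centers k x d matrix.
#' @return integer vector of 1-based centre indices (ties to lowest index).
#' @export
assign_to_centers <- function(X, centers) {
  if (inherits(X, "feature_series")) X <- X$values
  X <- as.matrix(X); centers <- as.matrix(centers)
  cn2 <- rowSums(centers^2)
  d2 <- sweep(X %*% t(centers) * -2, 2, cn2, "+")
  max.col(-d2, ties.method = "first")
}

#' Choose the number of clusters by the elbow criterion
#'
#' Returns the k maximising the perpendicular distance from (k, inertia) to
#' the chord joining the first and last points of the curve.  An exactly
#' linear curve has no elbow; the smallest interior k is returned with a
#' warning.
#'
#' @param inertia_by_k named numeric vector (names = k) of non-increasing
#'   within-cluster sums of squares, at least 3 candidates.
#' @return the selected k (integer).
#' @export
elbow_choose_k <- function(inertia_by_k) {
  ks <- as.numeric(names(inertia_by_k))
  if (length(ks) < 3 || any(is.na(ks)))
    stop("need >= 3 candidate k values with names giving k")
  ord <- order(ks)
  ks <- ks[ord]; inr <- as.numeric(inertia_by_k)[ord]
  if (any(diff(inr) > 1e-9 * max(abs(inr), 1)))
    stop("inertia must be non-increasing in k")
  p1 <- c(ks[1], inr[1]); p2 <- c(ks[length(ks)], inr[length(inr)])
  chord <- p2 - p1
  nrm <- sqrt(sum(chord^2))
  dist <- abs(chord[1] * (p1[2] - inr) - chord[2] * (p1[1] - ks)) / nrm
  scale <- max(dist)
  if (scale <= 1e-12 * max(abs(inr), 1)) {
    warning("degenerate elbow: inertia curve is linear; returning smallest interior k")
    return(as.integer(ks[2]))
  }
  as.integer(ks[which.max(dist)])
}

#' Write / read a feature series as delimited text
#'
#' A header comment carries the frame interval; columns are the features.
#'
#' @param x a [feature_series()].
#' @param path file path.
#' @return `read_feature_series()` returns a [feature_series()].
#' @export
write_feature_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval_ns %.17g", x$frame_interval), con)
  writeLines(paste(x$names, collapse = "\t"), con)
  writeLines(apply(x$values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_feature_series
#' @export
read_feature_series <- function(path) {
  first <- readLines(path, n = 1L)
  fi <- as.numeric(sub("# frame_interval_ns ", "", first, fixed = TRUE))
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE)
  feature_series(as.matrix(tab), colnames(tab), fi)
}
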