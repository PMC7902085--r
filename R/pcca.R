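#' PCCA+ metastable decomposition
#'
#' Perron-cluster cluster analysis: the m dominant right eigenvectors of a
#' reversible transition matrix span a simplex whose vertices correspond to
#' metastable sets.  Vertices are located with the inner simplex algorithm
#' and memberships obtained by the linear transform onto barycentric
#' coordinates; small negative memberships are clipped and rows
#' renormalised.  Crisp labels are the membership argmax (ties to the
#' lowest index).
#'
#' @param model a reversible `markov_model`.
#' @param m number of metastable sets (2 <= m <= n states).
#' @return an object of class `metastable_assignment` with fields
#'   `memberships` (n x m, rows sum to 1) and `crisp_labels`.
#' @export
pcca_assign <- function(model, m) {
  stopifnot(inherits(model, "markov_model"))
  if (!model$reversible) stop("PCCA+ requires a reversible model")
  n <- nrow(model$T)
  if (m < 2) stop("m must be at least 2 (decomposition undefined for m = 1)")
  if (m > n) stop("m exceeds the number of states")

  # right eigenvectors via the pi-symmetrised form (real spectra)
  s <- sqrt(model$pi)
  A <- (s %o% (1 / s)) * model$T
  A <- (A + t(A)) / 2
  ed <- eigen(A, symmetric = TRUE)
  ord <- order(ed$values, decreasing = TRUE)[seq_len(m)]
  psi <- ed$vectors[, ord, drop = FALSE] / s
  psi[, 1] <- 1  # Perron eigenvector is constant

  vert <- inner_simplex_vertices(psi)
  Ainv <- solve(psi[vert, , drop = FALSE])
  chi <- psi %*% Ainv
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  labels <- max.col(chi, ties.method = "first")
  structure(list(memberships = chi, crisp_labels = labels,
                 vertex_states = vert),
            class = "metastable_assignment")
}

# inner simplex algorithm: greedily pick the m rows of X spanning the
# largest simplex.  After anchoring the first vertex, each next vertex is
# the row farthest from the affine span of those already chosen
# (Gram-Schmidt on the shifted rows).
inner_simplex_vertices <- function(X) {
  m <- ncol(X)
  ind <- integer(m)
  ind[1] <- which.max(rowSums(X^2))
  Y <- sweep(X, 2, X[ind[1], ])
  for (k in seq_len(m - 1)) {
    ind[k + 1] <- which.max(rowSums(Y^2))
    u <- Y[ind[k + 1], ]
    nu <- sqrt(sum(u^2))
    if (nu > 0) {
      u <- u / nu
      Y <- Y - (Y %*% u) %*% t(u)
    }
  }
  ind
}
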