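#' Restraint specification for a coarse-grained complex
#'
#' Intra-chain folds are maintained by a harmonic elastic network between all
#' bead pairs of a chain closer than `elastic_network_cutoff` in the
#' reference pose.  Chain A is additionally pinned to its reference pose by
#' per-bead harmonic tethers (`chainA_positional_k`), which fixes both its
#' position and orientation so that the chain-chain centre-of-mass (COM)
#' distance is a well-defined association coordinate.
#'
#' All harmonic terms use the U = (k/2) dx^2 convention.
#'
#' @param elastic_network_cutoff distance cutoff in Angstrom for creating
#'   intra-chain elastic bonds (default 12).
#' @param elastic_network_k spring constant, kcal/mol/A^2 (default 10).
#' @param chainA_positional_k per-bead tether constant for chain A,
#'   kcal/mol/A^2 (default 10); 0 leaves chain A free.
#' @return an object of class `restraint_spec`.
#' @export
restraint_spec <- function(elastic_network_cutoff = 12,
                           elastic_network_k = 10,
                           chainA_positional_k = 10) {
  stopifnot(elastic_network_cutoff > 0,
            elastic_network_k >= 0, chainA_positional_k >= 0)
  structure(list(elastic_network_cutoff = elastic_network_cutoff,
                 elastic_network_k = elastic_network_k,
                 chainA_positional_k = chainA_positional_k),
            class = "restraint_spec")
}

#' Flat-bottom spherical confinement
#'
#' The free chain (chain B) is confined by a half-harmonic wall acting on the
#' radial coordinate of its COM: zero inside `r_cavity`, harmonic outside.
#' The cavity fixes the effective concentration of the two-body system,
#' C = 1/V with V the accessible volume.
#'
#' @param r_cavity cavity radius in Angstrom (default 73.46).
#' @param wall_k wall spring constant, kcal/mol/A^2 (default 10); 0 disables
#'   the wall.
#' @return an object of class `confinement_sphere`.
#' @export
confinement_sphere <- function(r_cavity = 73.46, wall_k = 10) {
  stopifnot(r_cavity > 0, wall_k >= 0)
  structure(list(r_cavity = r_cavity, wall_k = wall_k),
            class = "confinement_sphere")
}

#' Harmonic umbrella bias on the COM-COM distance
#'
#' U_bias(d) = (spring_k/2) (d - center)^2 where d is the mass-weighted
#' COM separation of the two chains.
#'
#' @param center window centre d0 in Angstrom.
#' @param spring_k spring constant in kcal/mol/A^2 (default 1).
#' @return an object of class `umbrella_bias`.
#' @export
umbrella_bias <- function(center, spring_k = 1) {
  stopifnot(is.finite(center), spring_k >= 0)
  structure(list(center = center, spring_k = spring_k),
            class = "umbrella_bias")
}

#' Construct a Go contact table
#'
#' Native contacts are attractive 6-12 pair potentials between one bead on
#' chain A and one on chain B:
#' U(r) = epsilon * ((r_min/r)^12 - 2 (r_min/r)^6), with minimum -epsilon
#' exactly at r = r_min.
#'
#' @param iA,iB 1-based bead indices on chain A / chain B.
#' @param r_min minimum-energy distances, Angstrom.
#' @param epsilon well depths, kcal/mol.
#' @return a data.frame with columns iA, iB, r_min, epsilon.
#' @export
go_contacts <- function(iA, iB, r_min, epsilon) {
  ct <- data.frame(iA = as.integer(iA), iB = as.integer(iB),
                   r_min = as.numeric(r_min), epsilon = as.numeric(epsilon))
  if (any(!is.finite(ct$r_min)) || any(ct$r_min <= 0))
    stop("r_min must be positive and finite")
  if (any(!is.finite(ct$epsilon)) || any(ct$epsilon <= 0))
    stop("epsilon must be positive and finite")
  ct
}

#' Curated barnase-barstar Go contacts
#'
#' The four native contacts of the residue-level barnase-barstar model
#' (chain A = barnase, 110 residues; chain B = barstar, 89 residues), with
#' the bead index equal to the residue number and a common well depth of
#' 3.0 kcal/mol.
#'
#' @return a contact data.frame (see [go_contacts()]) with a `label` column.
#' @export
barnase_barstar_contacts <- function() {
  ct <- go_contacts(iA = c(37L, 59L, 102L, 102L),
                    iB = c(46L, 35L, 31L, 36L),
                    r_min = c(4.96, 5.65, 4.82, 5.83),
                    epsilon = 3.0)
  ct$label <- c("Asp37-Glu46", "Arg59-Asp35", "His102-Gly31", "His102-Ala36")
  ct
}

#' Build a two-chain coarse-grained complex
#'
#' One bead per residue.  The supplied coordinates define the reference
#' (bound) pose; elastic-network bonds are created between all intra-chain
#' bead pairs whose reference separation is at most the restraint cutoff,
#' with rest length equal to that separation.
#'
#' @param coords_A,coords_B nA x 3 and nB x 3 matrices of bead coordinates
#'   in Angstrom.
#' @param contacts contact table from [go_contacts()] (chain-local indices).
#' @param restraints a [restraint_spec()].
#' @param confinement a [confinement_sphere()].
#' @param mass bead mass in amu, scalar or per-bead vector of length nA+nB
#'   (default 110, a typical residue mass).
#' @return an object of class `cg_complex`.
#' @export
build_complex <- function(coords_A, coords_B, contacts = NULL,
                          restraints = restraint_spec(),
                          confinement = confinement_sphere(),
                          mass = 110) {
  coords_A <- as_coords(coords_A, "coords_A")
  coords_B <- as_coords(coords_B, "coords_B")
  nA <- nrow(coords_A); nB <- nrow(coords_B)
  if (nA < 1 || nB < 1) stop("both chains must be non-empty")
  if (is.null(contacts))
    contacts <- data.frame(iA = integer(), iB = integer(),
                           r_min = numeric(), epsilon = numeric())
  stopifnot(all(c("iA", "iB", "r_min", "epsilon") %in% names(contacts)))
  if (nrow(contacts)) {
    if (any(contacts$iA < 1 | contacts$iA > nA))
      stop("contact index out of range on chain A")
    if (any(contacts$iB < 1 | contacts$iB > nB))
      stop("contact index out of range on chain B")
    if (anyDuplicated(contacts[, c("iA", "iB")]))
      stop("duplicate Go contact pair")
    if (any(contacts$r_min <= 0) || any(contacts$epsilon <= 0))
      stop("contacts require r_min > 0 and epsilon > 0")
  }
  stopifnot(inherits(restraints, "restraint_spec"),
            inherits(confinement, "confinement_sphere"))
  n <- nA + nB
  mass <- rep_len(as.numeric(mass), n)
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("bead masses must be > 0")

  ref <- rbind(coords_A, coords_B)
  chain <- rep(c("A", "B"), c(nA, nB))
  bonds <- rbind(elastic_bonds(coords_A, restraints$elastic_network_cutoff, 0L),
                 elastic_bonds(coords_B, restraints$elastic_network_cutoff, nA))
  structure(list(n = n, nA = nA, nB = nB, chain = chain, mass = mass,
                 reference = ref, contacts = contacts, bonds = bonds,
                 restraints = restraints, confinement = confinement),
            class = "cg_complex")
}

as_coords <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(what, " must be an n x 3 matrix")
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop(what, " contains non-finite coordinates")
  x
}

elastic_bonds <- function(coords, cutoff, offset) {
  n <- nrow(coords)
  if (n < 2)
    return(data.frame(i = integer(), j = integer(), r0 = numeric()))
  d <- as.matrix(stats::dist(coords))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  data.frame(i = idx[, 1] + offset, j = idx[, 2] + offset,
             r0 = d[idx])
}

#' @export
print.cg_complex <- function(x, ...) {
  cat(sprintf(
    "cg_complex: %d + %d beads, %d Go contacts, %d elastic bonds\n",
    x$nA, x$nB, nrow(x$contacts), nrow(x$bonds)))
  cat(sprintf("  cavity %.2f A (wall k = %g), tether k = %g, EN k = %g\n",
              x$confinement$r_cavity, x$confinement$wall_k,
              x$restraints$chainA_positional_k,
              x$restraints$elastic_network_k))
  invisible(x)
}

# Flattened description consumed by the C++ kernels (0-based indices).
cg_sys_list <- function(cx) {
  ct <- cx$contacts
  list(mass = cx$mass,
       idxA = seq_len(cx$nA) - 1L,
       idxB = cx$nA + seq_len(cx$nB) - 1L,
       contact_i = as.integer(ct$iA) - 1L,
       contact_j = cx$nA + as.integer(ct$iB) - 1L,
       contact_rmin = as.numeric(ct$r_min),
       contact_eps = as.numeric(ct$epsilon),
       bond_i = as.integer(cx$bonds$i) - 1L,
       bond_j = as.integer(cx$bonds$j) - 1L,
       bond_r0 = as.numeric(cx$bonds$r0),
       bond_k = rep(cx$restraints$elastic_network_k,
                    nrow(cx$bonds)),
       tether_k = cx$restraints$chainA_positional_k,
       ref = cx$reference,
       r_cavity = cx$confinement$r_cavity,
       wall_k = cx$confinement$wall_k)
}

check_positions <- function(cx, positions) {
  if (is.null(positions)) return(cx$reference)
  positions <- as_coords(positions, "positions")
  if (nrow(positions) != cx$n)
    stop("positions must provide one row per bead")
  positions
}

bias_args <- function(bias) {
  if (is.null(bias)) list(has = FALSE, d0 = 0, k = 0)
  else {
    stopifnot(inherits(bias, "umbrella_bias"))
    list(has = TRUE, d0 = bias$center, k = bias$spring_k)
  }
}

#' Potential energy of a configuration
#'
#' Sum of Go contact terms, intra-chain elastic-network terms, chain-A
#' positional tethers, the half-harmonic confinement wall on the chain-B COM
#' radius, and (optionally) an umbrella bias on the COM-COM distance.
#'
#' @param cx a [build_complex()] object.
#' @param positions n x 3 coordinate matrix (default: reference pose).
#' @param bias optional [umbrella_bias()].
#' @return scalar energy in kcal/mol.
#' @export
potential_energy <- function(cx, positions = NULL, bias = NULL) {
  stopifnot(inherits(cx, "cg_complex"))
  positions <- check_positions(cx, positions)
  b <- bias_args(bias)
  cg_energy_cpp(cg_sys_list(cx), positions, b$has, b$d0, b$k)
}

#' Forces on every bead
#'
#' Analytic negative gradient of [potential_energy()].
#'
#' @inheritParams potential_energy
#' @return n x 3 matrix of forces in kcal/mol/A.
#' @export
forces <- function(cx, positions = NULL, bias = NULL) {
  stopifnot(inherits(cx, "cg_complex"))
  positions <- check_positions(cx, positions)
  b <- bias_args(bias)
  cg_forces_cpp(cg_sys_list(cx), positions, b$has, b$d0, b$k)
}

#' COM separation of the two chains for one configuration
#'
#' @inheritParams potential_energy
#' @return mass-weighted COM-COM distance in Angstrom.
#' @export
com_distance <- function(cx, positions = NULL) {
  positions <- check_positions(cx, positions)
  a <- seq_len(cx$nA); b <- cx$nA + seq_len(cx$nB)
  ca <- colSums(positions[a, , drop = FALSE] * cx$mass[a]) / sum(cx$mass[a])
  cb <- colSums(positions[b, , drop = FALSE] * cx$mass[b]) / sum(cx$mass[b])
  sqrt(sum((ca - cb)^2))
}

#' Read / write whitespace- or comma-delimited Go contact tables
#'
#' Columns iA, iB, r_min, epsilon; a header line is optional and `#`
#' comments are ignored.
#'
#' @param path file path.
#' @return `read_contact_table()` returns a contact data.frame.
#' @export
read_contact_table <- function(path) {
  lines <- readLines(path)
  first <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))][1]
  if (is.na(first)) stop("empty contact table")
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  tab <- read.table(path, header = header, sep = sep, comment.char = "#",
                    strip.white = TRUE)
  if (ncol(tab) < 4) stop("contact table needs columns iA, iB, r_min, epsilon")
  go_contacts(tab[[1]], tab[[2]], tab[[3]], tab[[4]])
}

#' @rdname read_contact_table
#' @param contacts contact data.frame.
#' @export
write_contact_table <- function(contacts, path) {
  write.table(contacts[, c("iA", "iB", "r_min", "epsilon")], path,
              quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
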