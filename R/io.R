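#' Read a CA-only bead structure from PDB
#'
#' One bead per residue, in file order, split by chain identifier.
#'
#' @param path PDB file with CA ATOM records.
#' @return named list of n x 3 coordinate matrices, one per chain.
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  atoms <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(atoms)) stop("no ATOM records in ", path)
  name <- trimws(substr(atoms, 13, 16))
  ca <- atoms[name == "CA"]
  if (!length(ca)) stop("no CA records in ", path)
  chain <- substr(ca, 22, 22)
  x <- as.numeric(substr(ca, 31, 38))
  y <- as.numeric(substr(ca, 39, 46))
  z <- as.numeric(substr(ca, 47, 54))
  if (any(is.na(x) | is.na(y) | is.na(z))) stop("malformed coordinate fields")
  out <- lapply(split(seq_along(ca), chain),
                function(ix) cbind(x = x[ix], y = y[ix], z = z[ix]))
  out[unique(chain)]
}

#' Write a complex's reference pose as a CA-only PDB
#'
#' @param cx a `cg_complex`.
#' @param path output path.
#' @param positions optional coordinates to write instead of the
#'   reference pose.
#' @export
write_structure <- function(cx, path, positions = NULL) {
  pos <- check_positions(cx, positions)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(cx$n)) {
    resseq <- if (cx$chain[i] == "A") i else i - cx$nA
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, cx$chain[i], resseq, pos[i, 1], pos[i, 2], pos[i, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Export a trajectory as plain XYZ
#'
#' @param run a `run_result`.
#' @param path output path.
#' @export
write_xyz <- function(run, path) {
  n <- ncol(run$frames) / 3
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(nrow(run$frames))) {
    writeLines(c(sprintf("%d", n),
                 sprintf("frame %d t= %.6f ns", t, run$frame_times[t])), con)
    x <- get_frame(run, t)
    writeLines(sprintf("CA %10.4f %10.4f %10.4f", x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}

MODEL_DOC_VERSION <- 1L

#' Save / load model objects as JSON documents
#'
#' Markov, TICA, TRAM and r_cut-scan models serialise to a JSON document
#' with a type tag and format version; numeric payloads round-trip at full
#' double precision.  A reloaded Markov model is re-verified (pi T = pi)
#' on load; tampered documents are rejected.
#'
#' @param model a `markov_model`, `tica_model`, `tram_model` or
#'   `rcut_scan`.
#' @param path file path.
#' @return `load_model()` returns the reconstructed object.
#' @export
save_model <- function(model, path) {
  type <- class(model)[1]
  if (!type %in% c("markov_model", "tica_model", "tram_model", "rcut_scan"))
    stop("unrecognised model type: ", type)
  payload <- unclass(model)
  payload$fits <- NULL  # rcut_scan closures are not serialisable
  doc <- list(type = type, version = MODEL_DOC_VERSION, payload = payload)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$type) || !doc$type %in%
      c("markov_model", "tica_model", "tram_model", "rcut_scan"))
    stop("unknown model type tag: ", doc$type %||% "<missing>")
  if (!identical(as.integer(doc$version), MODEL_DOC_VERSION))
    stop("model document version mismatch: ", doc$version)
  p <- doc$payload
  out <- switch(doc$type,
    markov_model = {
      m <- structure(list(T = as.matrix(p$T), pi = as.numeric(p$pi),
                          eigenvalues = as.numeric(p$eigenvalues),
                          lag_time = p$lag_time,
                          active_set = as.integer(p$active_set),
                          reversible = isTRUE(p$reversible),
                          counts = if (!is.null(p$counts)) as.matrix(p$counts)),
                     class = "markov_model")
      resid <- max(abs(m$pi %*% m$T - m$pi))
      if (resid > 1e-8)
        stop("integrity error: stored pi is not stationary for stored T (residual ",
             format(resid, digits = 3), ")")
      m
    },
    tica_model = {
      structure(list(mean = as.numeric(p$mean), C0 = as.matrix(p$C0),
                     Ctau = as.matrix(p$Ctau), lag = as.integer(p$lag),
                     eigenvalues = as.numeric(p$eigenvalues),
                     eigenvectors = as.matrix(p$eigenvectors),
                     timescales = as.numeric(p$timescales),
                     frame_interval = p$frame_interval),
                class = "tica_model")
    },
    tram_model = {
      p$state_free_energies <- as.matrix(p$state_free_energies)
      p$unbiased_pi <- as.numeric(p$unbiased_pi)
      p$transition_matrices <- lapply(p$transition_matrices, as.matrix)
      p$unbiased_model <- NULL
      structure(p, class = "tram_model")
    },
    rcut_scan = {
      structure(list(table = as.data.frame(p$table),
                     optimal_rcut = p$optimal_rcut, fits = NULL),
                class = "rcut_scan")
    })
  out
}

#' Default workflow configuration
#'
#' All tunables of the simulation/featurization/estimation pipeline with
#' their package defaults.  `run_workflow()` rejects unknown keys.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    recipe = "tram_1d",          # msm_6d | tram_6d | tram_1d | tram_1d_inv
    seed = 1,
    # toy system
    toy_nA = 6, toy_nB = 5, toy_contacts = 3, toy_epsilon = 1.5,
    toy_r_cavity = 20,
    # simulation
    temperature = 300, friction = 1, timestep = 5,
    n_unbiased_runs = 8, unbiased_steps = 400000, save_stride = 500,
    window_start = 6, window_stop = 19, window_spacing = 1,
    window_spring_k = 1, umbrella_steps = 240000,
    # featurization / discretization
    tica_lag_ns = 0.05, n_components = 4,
    contact_cutoff = 12, contact_min_lifetime = 0.01,
    n_microstates = 25, cluster_seed = 7,
    # estimation
    lag_ns = 0.05, tram_tol = 5e-7, tram_max_iter = 5000,
    # observables
    bound_rcut = 12, n_boot = 12,
    profile_bin_width = 1
  )
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(base, config)
}
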