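#' Run an end-to-end model recipe on the synthetic complex
#'
#' Executes simulate -> featurize -> discretize -> estimate -> observables
#' for one of the four model recipes:
#' \describe{
#'   \item{msm_6d}{TICA components of long-lived pair distances + minimum
#'     RMSD + COM distance, unbiased simulations, reversible MSM.}
#'   \item{tram_6d}{the same 6-D featurization, unbiased + umbrella
#'     simulations, TRAM.}
#'   \item{tram_1d}{COM distance only, unbiased + umbrella, TRAM.}
#'   \item{tram_1d_inv}{squared inverse COM distance, unbiased + umbrella,
#'     TRAM.}
#' }
#' All randomness derives from `config$seed`; identical configs give
#' identical reports.
#'
#' @param config list of options; see [default_config()] for keys and
#'   defaults.  Unknown keys are rejected.
#' @param data optional precomputed simulation data from
#'   [simulate_workflow_data()], to share trajectories across recipes.
#' @return a report list: `recipe`, `model`, `observables`, `bootstrap`
#'   (mean/sd of K_eq, dG_b, k_on, k_off), `profile` (free energy vs COM),
#'   `bound_states`, `state_com`, `discretization`, `manifest`.
#' @export
run_workflow <- function(config = list(), data = NULL) {
  cfg <- validate_config(config)
  t0 <- Sys.time()
  if (is.null(data)) data <- simulate_workflow_data(cfg)
  cx <- data$complex
  recipe <- match.arg(cfg$recipe, c("msm_6d", "tram_6d", "tram_1d",
                                    "tram_1d_inv"))
  use_us <- recipe != "msm_6d"

  feats_unb <- featurize_runs(data$unbiased, recipe, cfg, data)
  feats_all <- feats_unb
  if (use_us) feats_all <- c(feats_all, featurize_runs(data$umbrella, recipe,
                                                       cfg, data))
  runs_all <- if (use_us) c(data$unbiased, data$umbrella) else data$unbiased

  X <- do.call(rbind, lapply(feats_all, function(f) f$values))
  disc <- kmeans_cluster(X, cfg$n_microstates, seed = cfg$cluster_seed)
  lens <- vapply(feats_all, function(f) nrow(f$values), integer(1))
  dtrajs <- split_assignments(disc$assignments, lens)
  fi <- feats_all[[1]]$frame_interval
  lag_frames <- max(1L, round(cfg$lag_ns / fi))

  # average COM distance per microstate (over all clustered frames)
  com_all <- unlist(lapply(runs_all, com_series))
  state_com <- vapply(seq_len(cfg$n_microstates), function(s) {
    ix <- disc$assignments == s
    if (any(ix)) mean(com_all[ix]) else NA_real_
  }, numeric(1))

  n_unb <- length(data$unbiased)
  dtrajs_unb <- dtrajs[seq_len(n_unb)]
  windows <- data$windows

  make_estimate <- function(dtrajs_unb_subset) {
    if (!use_us) {
      cm <- count_transitions(dtrajs_unb_subset, lag_frames,
                              n = cfg$n_microstates, frame_interval = fi)
      estimate_transition_matrix(cm, reversible = TRUE)
    } else {
      ens <- workflow_ensembles(dtrajs_unb_subset, data, dtrajs, n_unb,
                                windows, fi)
      tr <- estimate_tram(ens, lag_frames, tol = cfg$tram_tol,
                          max_iter = cfg$tram_max_iter,
                          on_nonconvergence = "warn")
      tr$unbiased_model
    }
  }
  model <- make_estimate(dtrajs_unb)

  bound <- which(state_com[model$active_set] <= cfg$bound_rcut)
  if (!length(bound) || length(bound) == nrow(model$T))
    stop("degenerate bound-state definition: adjust bound_rcut")
  obs <- binding_observables(model, bound, cx$confinement$r_cavity,
                             cfg$bound_rcut, cfg$temperature)

  bins <- pmin(pmax(floor(state_com / cfg$profile_bin_width) + 1L, 1L),
               ceiling(cx$confinement$r_cavity / cfg$profile_bin_width))
  prof <- free_energy_profile(model$pi, bins[model$active_set],
                              temperature = cfg$temperature)
  prof$center <- (prof$bin - 0.5) * cfg$profile_bin_width

  estimator <- function(subset) {
    m <- make_estimate(subset)
    b <- which(state_com[m$active_set] <= cfg$bound_rcut)
    if (!length(b) || length(b) == nrow(m$T)) stop("degenerate bound set")
    o <- binding_observables(m, b, cx$confinement$r_cavity,
                             cfg$bound_rcut, cfg$temperature)
    c(K_eq = o$K_eq, dG_b = o$dG_b, k_on = o$k_on, k_off = o$k_off)
  }
  boot <- bootstrap_errors(dtrajs_unb, estimator, n_boot = cfg$n_boot,
                           seed = cfg$seed + 99991)

  list(recipe = recipe, model = model, observables = obs,
       bootstrap = boot, profile = prof,
       bound_states = bound, state_com = state_com,
       discretization = disc, dtrajs = dtrajs,
       manifest = list(seed = cfg$seed, config = cfg,
                       n_unbiased = n_unb,
                       n_windows = if (use_us) length(windows$centers) else 0,
                       elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                       units = "secs"))))
}

#' Simulate the shared trajectory data of a workflow
#'
#' Generates the toy complex, the unbiased Langevin runs (alternating
#' bound and randomized dissociated starts) and the umbrella campaign.
#'
#' @param config full config list (already validated, or raw options).
#' @return list with `complex`, `unbiased`, `umbrella`, `windows`.
#' @export
simulate_workflow_data <- function(config = list()) {
  cfg <- validate_config(config)
  toy <- make_toy_complex(nA = cfg$toy_nA, nB = cfg$toy_nB,
                          n_contacts = cfg$toy_contacts,
                          seed = cfg$seed, epsilon = cfg$toy_epsilon,
                          r_cavity = cfg$toy_r_cavity)
  cx <- toy$complex
  unbiased <- lapply(seq_len(cfg$n_unbiased_runs), function(r) {
    p <- langevin_params(temperature = cfg$temperature,
                         friction = cfg$friction, timestep = cfg$timestep,
                         n_steps = cfg$unbiased_steps,
                         save_stride = cfg$save_stride,
                         seed = cfg$seed * 131 + r)
    run_langevin(cx, p, start = if (r %% 2) NULL else "dissociated")
  })
  windows <- make_window_grid(cfg$window_start, cfg$window_stop,
                              cfg$window_spacing, cfg$window_spring_k)
  umbrella <- run_umbrella_set(cx, windows,
                               langevin_params(temperature = cfg$temperature,
                                               friction = cfg$friction,
                                               timestep = cfg$timestep,
                                               n_steps = cfg$umbrella_steps,
                                               save_stride = cfg$save_stride,
                                               seed = cfg$seed * 977))
  list(complex = cx, unbiased = unbiased, umbrella = umbrella,
       windows = windows,
       cache = new.env(parent = emptyenv()))  # shared featurization cache
}

featurize_runs <- function(runs, recipe, cfg, data) {
  if (recipe == "tram_1d")
    return(lapply(runs, geometry_features, mode = "com_distance"))
  if (recipe == "tram_1d_inv")
    return(lapply(runs, geometry_features, mode = "inverse_sq_com"))
  # 6-D: TICA of long-lived pair distances (+ RMSD + COM)
  env <- data$cache
  if (is.null(env$tica)) {
    pairs <- long_lived_contacts(data$unbiased,
                                 dist_cutoff = cfg$contact_cutoff,
                                 min_lifetime = cfg$contact_min_lifetime)
    if (nrow(pairs) < 2) pairs <- as.matrix(expand.grid(
      iA = seq_len(data$complex$nA), iB = seq_len(data$complex$nB)))
    pd <- lapply(data$unbiased, geometry_features, mode = "pair_distances",
                 pairs = pairs)
    lagf <- max(1L, round(cfg$tica_lag_ns / pd[[1]]$frame_interval))
    env$pairs <- pairs
    env$tica <- tica_fit(pd, lagf)
    env$nc <- min(cfg$n_components, length(env$tica$eigenvalues))
  }
  lapply(runs, function(run) {
    ics <- tica_transform(env$tica,
                          geometry_features(run, "pair_distances",
                                            pairs = env$pairs), env$nc)
    vals <- cbind(ics$values,
                  rmsd_min(run)$values,
                  geometry_features(run, "com_distance")$values)
    feature_series(vals, c(ics$names, "rmsd_min", "com_distance"),
                   run$frame_interval)
  })
}

split_assignments <- function(assignments, lens) {
  ends <- cumsum(lens)
  starts <- c(1, head(ends, -1) + 1)
  lapply(seq_along(lens), function(i) assignments[starts[i]:ends[i]])
}

workflow_ensembles <- function(dtrajs_unb_subset, data, dtrajs, n_unb,
                               windows, fi) {
  K <- 1L + length(windows$centers)
  # indices of the unbiased runs actually used (bootstrap may resample);
  # match by identity of the state sequences
  bias_for_unbiased <- function(run) cbind(0, window_bias_energies(run, windows))
  # map subset back to run objects: dtrajs_unb_subset elements are plain
  # integer vectors originating from dtrajs[seq_len(n_unb)]
  ens <- list()
  used_bias <- list(); used_traj <- list()
  for (d in dtrajs_unb_subset) {
    ix <- which(vapply(seq_len(n_unb), function(i)
      identical(as.integer(dtrajs[[i]]), as.integer(d)), logical(1)))[1]
    run <- data$unbiased[[ix]]
    used_traj[[length(used_traj) + 1]] <- d
    used_bias[[length(used_bias) + 1]] <- bias_for_unbiased(run)
  }
  ens[[1]] <- ensemble_data(used_traj, used_bias, ensemble_id = 1,
                            frame_interval = fi)
  for (w in seq_along(windows$centers)) {
    run <- data$umbrella[[w]]
    ens[[w + 1]] <- ensemble_data(list(dtrajs[[n_unb + w]]),
                                  list(cbind(0, run$bias_energies)),
                                  ensemble_id = w + 1, frame_interval = fi)
  }
  ens
}
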