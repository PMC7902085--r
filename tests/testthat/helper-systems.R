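# shared fixtures built in code

# a single Go contact pair, all other terms off
pair_complex <- function(r_min = 4.82, epsilon = 3, r = r_min) {
  build_complex(matrix(0, 1, 3), matrix(c(r, 0, 0), 1, 3),
                go_contacts(1, 1, r_min, epsilon),
                restraint_spec(elastic_network_cutoff = 1e-6,
                               elastic_network_k = 0,
                               chainA_positional_k = 0),
                confinement_sphere(1e6, 0))
}

# a fake run_result wrapping explicit frames (list of n x 3 matrices)
fake_run <- function(cx, frames, frame_interval = 1) {
  fr <- do.call(rbind, lapply(frames, function(x) as.numeric(t(x))))
  structure(list(frames = fr,
                 frame_times = (seq_along(frames) - 1) * frame_interval,
                 frame_interval = frame_interval,
                 params = langevin_params(temperature = 300, timestep = 1,
                                          n_steps = 1, save_stride = 1),
                 window = NULL, cx = cx, bias_energies = NULL),
            class = "run_result")
}

# simple two-chain complex from explicit coordinates, restraints off
bare_complex <- function(coords_A, coords_B, contacts = NULL) {
  build_complex(coords_A, coords_B, contacts,
                restraint_spec(elastic_network_cutoff = 1e-6,
                               elastic_network_k = 0,
                               chainA_positional_k = 0),
                confinement_sphere(1e6, 0))
}

# memoised toy-complex dataset and recipe reports shared by the
# scaled-down acceptance checks
.toy_env <- new.env(parent = emptyenv())
toy_workflow_data <- function() {
  if (is.null(.toy_env$data)) {
    .toy_env$cfg <- default_config()
    .toy_env$data <- simulate_workflow_data(.toy_env$cfg)
  }
  list(cfg = .toy_env$cfg, data = .toy_env$data)
}

toy_reports <- function() {
  if (is.null(.toy_env$reports)) {
    tw <- toy_workflow_data()
    .toy_env$reports <- lapply(
      c("msm_6d", "tram_6d", "tram_1d", "tram_1d_inv"),
      function(rec) run_workflow(modifyList(tw$cfg, list(recipe = rec)),
                                 data = tw$data))
    names(.toy_env$reports) <- c("msm_6d", "tram_6d", "tram_1d",
                                 "tram_1d_inv")
  }
  .toy_env$reports
}

# two-basin jump-diffusion COM trace: hidden bound/unbound state with OU
# fluctuations; the equal-density crossing of the two basins sits at 29 A
# ((x - 21)/3 = (41 - x)/4.5  =>  x = 29)
jump_diffusion_com <- function(n, seed, p_switch = 1 / 300,
                               mu = c(21, 41), sig = c(3, 4.5), phi = 0.8) {
  set.seed(seed)
  x <- numeric(n)
  s <- 1L; z <- 0
  sw <- runif(n); eps <- rnorm(n)
  for (t in seq_len(n)) {
    if (sw[t] < p_switch) s <- 3L - s
    z <- phi * z + sqrt(1 - phi^2) * eps[t]
    x[t] <- mu[s] + sig[s] * z
  }
  feature_series(matrix(x, ncol = 1), "com_distance", 1)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) < tol),
              label = sprintf("relative error %.3g within %.3g",
                              max(abs(actual / expected - 1)), tol))
}
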