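# Shared fixtures: all synthetic, generated in code.

# fast unit-test schedule: well-separated modes, ~7k samples; t_on covers
# ~12 mass relaxation times so the off phase starts from steady state
quick_config <- function(noise_sd = 0, n_shots = 1, seed = 1L,
                         tau_th = 1e-3, tau = 0.03, A0 = 0.6,
                         t_on = 0.35, t_off = 0.35, dt = 1e-4) {
  simulation_config(signal_params_q(tau_th, tau, A0),
                    t_on = t_on, t_off = t_off, dt = dt,
                    noise_sd = noise_sd, n_shots = n_shots, seed = seed)
}

# experiment-like schedule: protein-like D with a 21 um fringe grating
exp_config <- function(noise_sd = 0.01, n_shots = 3000, seed = 1L,
                       A0 = -0.25) {
  simulation_config(signal_params_q(5e-4, 0.25, A0),
                    t_on = 1.75, t_off = 1.75, dt = 5e-5,
                    noise_sd = noise_sd, n_shots = n_shots, seed = seed)
}

# signal_params without the time-scale warning (tests draw arbitrary ratios)
signal_params_q <- function(tau_th, tau, A0) {
  suppressWarnings(signal_params(tau_th, tau, A0))
}

std_geometry <- function() grating_geometry(q = 1.17e5)
std_contrast <- function() contrast_factors(dn_dT = -1.0e-4, dn_dc = 0.183)
std_cw <- 0.007

soret_truth <- function() soret_params(0.025, -0.132, 12)

apomb_sequence <- function() {
  path <- system.file("extdata", "apomyoglobin_P68082.fasta",
                      package = "tdfrs")
  read_protein_fasta(path)[[1]]
}

conditions_fixture <- function() {
  read_conditions(system.file("extdata", "apomb_conditions.csv",
                              package = "tdfrs"))
}

# conditions table on an exact line delta_ST = slope * helix + intercept
conditions_on_line <- function(slope = 4e-4, intercept = 2e-3) {
  rec <- conditions_fixture()
  rec$delta_ST <- slope * rec$helix_pct + intercept
  rec$delta_ST_sd <- 1e-4
  rec
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
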