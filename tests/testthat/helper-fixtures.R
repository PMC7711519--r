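# Shared fixtures: parameter grids and small data constructors.

# Parameter headers of the simulation tables with their reliabilities
# (as reproduced by quadrature to 4 d.p.).
table_params <- list(
  list(theta = c(2.0, 1.9, 3.7, 3.8), R = 0.4683),
  list(theta = c(1.5, 4.0, 2.0, 1.9), R = 0.8248),
  list(theta = c(0.9, 0.9, 0.9, 0.9), R = 0.5000),
  list(theta = c(1.7, 3.5, 2.0, 2.1), R = 0.7529),
  list(theta = c(1.9, 1.8, 3.6, 4.5), R = 0.4228)
)

fiber_data <- function() {
  ss_data(load_dataset("fiber_20mm")$values, load_dataset("fiber_10mm")$values)
}

bank_data <- function() {
  ss_data(load_dataset("bank_A")$values, load_dataset("bank_B")$values)
}

# A bootstrap_draws object with prescribed draws, for interval-rule tests.
fake_boot_draws <- function(r_star, r_hat = mean(r_star)) {
  structure(list(r_star = r_star, B = length(r_star), seed = NULL,
                 n_failed = 0L, r_hat = r_hat),
            class = "bootstrap_draws")
}
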