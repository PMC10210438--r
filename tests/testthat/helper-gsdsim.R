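# Shared fixtures: small deterministic configurations and populations.

# A small, fast configuration for structural tests.
tiny_config <- function(...) {
  sim_config(modifyList(
    list(seed = 1, n_demes = 4, capacity = 60, offspring_per_deme = 120,
         generations = 20, record_every = 5, sigma_eps = 0),
    list(...)))
}

# One ancestral XX female and one XY male as single-row populations.
xx_female <- function(deme = 0L) {
  pop <- build_individual("F/F; +/+", deme = deme)
  pop[, "sex"] <- 1
  pop
}

xy_male <- function(deme = 0L) {
  pop <- build_individual("F/F; +/M_Y", deme = deme)
  pop[, "sex"] <- 2
  pop
}

# Independent scalar re-implementation of the net-expression formula used
# as an oracle; deliberately written without the package's vectorized code.
oracle_net_f <- function(z_f0, s_fm, temp, z_m_hat, eps, beta) {
  amount <- z_f0 * (1 + beta * temp) + eps
  if (amount < 0) amount <- 0
  kept <- 1 - s_fm * z_m_hat
  if (kept < 0) kept <- 0
  amount * kept
}

# Binomial 99% confidence bounds for a proportion.
binom_ci99 <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(p - 2.576 * se, p + 2.576 * se)
}
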