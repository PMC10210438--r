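# Pre-packaged simulation campaigns and the sweep driver ----------------------

#' Deterministic per-run seed derivation
#'
#' Pure function of the master seed and run counter, so sweeps are
#' reproducible and individual runs can be re-executed in isolation.
#'
#' @param master_seed Integer master seed.
#' @param i Run counter (>= 1).
#' @return Integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master_seed, i) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(master_seed)) %% m)
  as.integer(((s * 48271) %% m + as.numeric(i) * 8191) %% (m - 1) + 1)
}

#' Build a pre-packaged simulation campaign
#'
#' Three campaigns mirror the package's main simulation experiments:
#'
#' * `"regimes"`: no temperature dependence (`beta = 0`), no
#'   Y-chromosomal fitness effects; sweeps the two thresholds and the
#'   de novo activation rate (`theta_m ~ U(0.1, 0.6)`,
#'   `theta_f ~ U(0.8, 1.9)`, `mu_d ~ U(0, 0.05)`). Threshold ranges are
#'   chosen so the ancestral XY system is developmentally functional at
#'   the start (two expressed F alleles exceed `theta_f`).
#' * `"cline"`: sweeps the temperature slope and feminization threshold
#'   (`beta ~ U(0, 1)`, `theta_f ~ U(0.8, 1.6)`) at `theta_m = 0.2`,
#'   `mu_d = 0.001`; the first run is pinned to the reference cline
#'   point `theta_f = 1.20`, `theta_m = 0.2`, `beta = 0.76`,
#'   `mu_d = 0.014`.
#' * `"y_effects"`: fixes `theta_f = 1.2`, `theta_m = 0.3`, `beta = 0.5`
#'   and sweeps `mu_d ~ U(0, 0.05)`, `s_a ~ U(0, 0.5)`,
#'   `s_yy ~ U(0.5, 1)`.
#'
#' The scale factor shrinks the replicate count, carrying capacity and run
#' length proportionally (with floors of 1 run, K = 50 and 200
#' generations) for desk-scale exploration.
#'
#' @param name Campaign name.
#' @param scale Scale factor in (0, 1\].
#' @param base Named list of additional configuration overrides applied to
#'   every run (after the campaign's own settings).
#' @return A list of class `"gsd_sweep_spec"` with elements `campaign`,
#'   `n_runs`, `base` (config overrides), and `sample_params` (a function
#'   drawing one run's sampled parameters from the current RNG state).
#' @export
build_campaign <- function(name = c("regimes", "cline", "y_effects"),
                           scale = 1, base = list()) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  full_runs <- c(regimes = 10000, cline = 2000, y_effects = 10000)[[name]]
  n_runs <- max(1L, as.integer(round(full_runs * scale)))
  common <- list(
    capacity = max(50L, as.integer(round(200 * scale))),
    offspring_per_deme = max(100L, as.integer(round(400 * scale))),
    generations = max(200L, as.integer(round(5000 * scale))),
    record_every = 10L
  )
  if (name == "regimes") {
    camp_base <- list(beta = 0, s_a = 0, s_yy = 1)
    sampler <- function(run) {
      list(theta_m = runif(1, 0.1, 0.6),
           theta_f = runif(1, 0.8, 1.9),
           mu_d = runif(1, 0, 0.05))
    }
  } else if (name == "cline") {
    camp_base <- list(theta_m = 0.2, mu_d = 0.001, s_a = 0, s_yy = 1)
    sampler <- function(run) {
      if (run == 1) {
        list(theta_f = 1.20, theta_m = 0.2, beta = 0.76, mu_d = 0.014)
      } else {
        list(theta_f = runif(1, 0.8, 1.6), beta = runif(1, 0, 1))
      }
    }
  } else {
    camp_base <- list(theta_f = 1.2, theta_m = 0.3, beta = 0.5)
    sampler <- function(run) {
      list(mu_d = runif(1, 0, 0.05),
           s_a = runif(1, 0, 0.5),
           s_yy = runif(1, 0.5, 1))
    }
  }
  structure(list(campaign = name, scale = scale, n_runs = n_runs,
                 base = modifyList(modifyList(common, camp_base), base),
                 sample_params = sampler),
            class = "gsd_sweep_spec")
}

#' Execute a parameter sweep
#'
#' Runs every configuration of a sweep specification with a deterministic
#' per-run seed derived from the master seed ([derive_seed()]), and
#' summarizes each run into one row: the sampled parameters, the
#' single-allele activity regime at both gradient ends, the SD-system
#' call from the modal genotype pair in the edge demes, window-averaged
#' edge-deme allele frequencies, and the housefly-like verdict. A failing
#' run is recorded in its `error` column and the sweep continues.
#'
#' @param spec A `"gsd_sweep_spec"` from [build_campaign()] (or built by
#'   hand with the same fields).
#' @param master_seed Integer master seed for the whole sweep.
#' @param keep_trajectories If `TRUE`, full trajectories are attached as
#'   the `"trajectories"` attribute of the result.
#' @return A data frame with one row per run.
#' @export
run_sweep <- function(spec, master_seed, keep_trajectories = FALSE) {
  stopifnot(inherits(spec, "gsd_sweep_spec") || is.list(spec))
  rows <- vector("list", spec$n_runs)
  trajs <- if (keep_trajectories) vector("list", spec$n_runs) else NULL
  for (i in seq_len(spec$n_runs)) {
    seed_i <- derive_seed(master_seed, i)
    set.seed(seed_i)
    sampled <- spec$sample_params(i)
    over <- modifyList(spec$base, sampled)
    over$seed <- seed_i
    row <- tryCatch({
      cfg <- sim_config(over)
      sim <- run_simulation(cfg)
      an <- analyze_simulation(sim)
      if (keep_trajectories) trajs[[i]] <- sim$trajectory
      eq <- an$equilibrium
      cold <- eq[eq$deme == min(eq$deme), , drop = FALSE]
      warm <- eq[eq$deme == max(eq$deme), , drop = FALSE]
      data.frame(
        run = i, seed = seed_i,
        theta_f = cfg$theta_f, theta_m = cfg$theta_m, beta = cfg$beta,
        mu_d = cfg$mu_d, s_a = cfg$s_a, s_yy = cfg$s_yy,
        regime_cold = regime_label(cfg$z_f0_init, cfg$theta_m, cfg$theta_f),
        regime_warm = regime_label(cfg$z_f0_init * (1 + cfg$beta),
                                   cfg$theta_m, cfg$theta_f),
        sd_system_cold = if (is.null(an$sd_system_cold)) NA_character_
                         else an$sd_system_cold$label,
        sd_system_warm = if (is.null(an$sd_system_warm)) NA_character_
                         else an$sd_system_warm$label,
        freq_fi_cold = cold$freq_fi_mat_f, freq_fi_warm = warm$freq_fi_mat_f,
        freq_my_cold = cold$freq_my_pat_m, freq_my_warm = warm$freq_my_pat_m,
        freq_ma_cold = cold$freq_ma_pat_m, freq_ma_warm = warm$freq_ma_pat_m,
        housefly_like = if (is.na(an$housefly_like)) NA else an$housefly_like,
        extinct = sim$extinct,
        error = NA_character_,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(run = i, seed = seed_i,
                 theta_f = NA_real_, theta_m = NA_real_, beta = NA_real_,
                 mu_d = NA_real_, s_a = NA_real_, s_yy = NA_real_,
                 regime_cold = NA_character_, regime_warm = NA_character_,
                 sd_system_cold = NA_character_, sd_system_warm = NA_character_,
                 freq_fi_cold = NA_real_, freq_fi_warm = NA_real_,
                 freq_my_cold = NA_real_, freq_my_warm = NA_real_,
                 freq_ma_cold = NA_real_, freq_ma_warm = NA_real_,
                 housefly_like = NA, extinct = NA,
                 error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (keep_trajectories) attr(out, "trajectories") <- trajs
  out
}
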