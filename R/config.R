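# Configuration --------------------------------------------------------------
#
# All model parameters are exposed as one flat key-value namespace so that a
# YAML configuration file, the sim_config() constructor, and the resolved
# dump written next to simulation outputs all use identical keys.

#' Default values for every simulation parameter
#'
#' @return Named list of defaults, with the same keys accepted by
#'   [sim_config()] and by configuration files.
#' @export
config_defaults <- function() {
  list(
    seed = NULL,
    # metapopulation and life cycle
    n_demes = 20L,
    capacity = 200L,
    offspring_per_deme = 400L,
    dispersal_rate = 0.05,
    generations = 5000L,
    record_every = 1L,
    # initial allele values (ancestral XY system)
    z_f0_init = 1.0,
    s_fm_init = 1.0,
    z_my_init = 1.0,
    # mutation model
    p_mut = 0.01,
    p_null = 0.05,
    sigma_mut = 0.01,
    mu_d = 0.0,
    z_m_init = 1.0,
    # sexual development
    theta_f = 1.2,
    theta_m = 0.2,
    beta = 0.0,
    sigma_eps = 0.05,
    # Y-chromosomal fitness effects
    s_yy = 1.0,
    s_a = 0.0,
    sa_on_mating = FALSE,
    # analysis conventions
    eps_class = 0.01,
    eq_window = 0.1
  )
}

validate_config_values <- function(v) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs[[length(errs) + 1L]] <<- msg
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(v$n_demes) && v$n_demes >= 2, "n_demes: need an integer >= 2")
  chk(num1(v$capacity) && v$capacity >= 1, "capacity: need a positive count")
  chk(num1(v$offspring_per_deme) && v$offspring_per_deme >= 1,
      "offspring_per_deme: need a positive count")
  chk(num1(v$dispersal_rate) && v$dispersal_rate >= 0 && v$dispersal_rate <= 1,
      "dispersal_rate: d must lie in [0, 1]")
  chk(num1(v$generations) && v$generations >= 0,
      "generations: need a count >= 0")
  chk(num1(v$record_every) && v$record_every >= 1,
      "record_every: need a positive count")
  chk(num1(v$z_f0_init) && v$z_f0_init >= 0, "z_f0_init: must be >= 0")
  chk(num1(v$s_fm_init) && v$s_fm_init >= 0 && v$s_fm_init <= 1,
      "s_fm_init: sensitivity must lie in [0, 1]")
  chk(num1(v$z_my_init) && v$z_my_init >= 0, "z_my_init: must be >= 0")
  for (key in c("p_mut", "p_null", "mu_d")) {
    chk(num1(v[[key]]) && v[[key]] >= 0 && v[[key]] <= 1,
        paste0(key, ": probability must lie in [0, 1]"))
  }
  chk(num1(v$sigma_mut) && v$sigma_mut >= 0, "sigma_mut: must be >= 0")
  chk(num1(v$z_m_init) && v$z_m_init >= 0, "z_m_init: must be >= 0")
  chk(num1(v$theta_f) && num1(v$theta_m) && v$theta_m < v$theta_f,
      "theta_m/theta_f: thresholds must satisfy theta_m < theta_f")
  chk(num1(v$beta) && v$beta >= 0, "beta: must be >= 0")
  chk(num1(v$sigma_eps) && v$sigma_eps >= 0, "sigma_eps: must be >= 0")
  chk(num1(v$s_yy) && v$s_yy >= 0 && v$s_yy <= 1, "s_yy: must lie in [0, 1]")
  chk(num1(v$s_a) && v$s_a >= 0, "s_a: must be >= 0")
  chk(is.logical(v$sa_on_mating) && length(v$sa_on_mating) == 1,
      "sa_on_mating: must be TRUE or FALSE")
  chk(num1(v$eps_class) && v$eps_class > 0, "eps_class: must be > 0")
  chk(num1(v$eq_window) && v$eq_window > 0 && v$eq_window <= 1,
      "eq_window: must lie in (0, 1]")
  if (!is.null(v$seed)) {
    chk(num1(v$seed) && v$seed == round(v$seed), "seed: must be an integer")
  }
  errs
}

#' Build a simulation configuration
#'
#' Accepts any subset of the keys in [config_defaults()] and fills in the
#' rest. All range invariants (thresholds ordered, probabilities and the
#' dispersal rate in \[0, 1\], counts positive) are checked together and
#' every violation is reported.
#'
#' @param ... Named parameter overrides; see [config_defaults()] for the
#'   full key set, units, and defaults.
#' @return A list of class `"gsd_config"` with the flat parameter values
#'   plus assembled `mutation`, `development`, and `fitness` parameter
#'   objects.
#' @export
sim_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  defs <- config_defaults()
  unknown <- setdiff(names(over), names(defs))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  v <- modifyList(defs, over, keep.null = TRUE)
  errs <- validate_config_values(v)
  if (length(errs) > 0) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  for (key in c("n_demes", "capacity", "offspring_per_deme", "generations",
                "record_every")) {
    v[[key]] <- as.integer(v[[key]])
  }
  v$mutation <- mutation_params(p_mut = v$p_mut, p_null = v$p_null,
                                sigma_mut = v$sigma_mut, mu_d = v$mu_d,
                                z_m_init = v$z_m_init)
  v$development <- development_params(theta_f = v$theta_f,
                                      theta_m = v$theta_m,
                                      beta = v$beta,
                                      sigma_eps = v$sigma_eps)
  v$fitness <- fitness_params(s_yy = v$s_yy, s_a = v$s_a,
                              sa_on_mating = v$sa_on_mating)
  attr(v, "user_keys") <- names(over)
  class(v) <- "gsd_config"
  v
}

#' @export
print.gsd_config <- function(x, ...) {
  cat("<gsd_config>\n")
  flat <- x[names(config_defaults())]
  for (key in names(flat)) {
    val <- flat[[key]]
    cat(sprintf("  %-20s %s\n", key,
                if (is.null(val)) "<unset>" else format(val)))
  }
  invisible(x)
}

config_flat_values <- function(config) {
  stopifnot(inherits(config, "gsd_config"))
  config[names(config_defaults())]
}

#' Load and validate a configuration file
#'
#' Reads a YAML file of flat `key: value` pairs, merges it over
#' [config_defaults()], rejects unknown keys, and reports every violated
#' range invariant (all collected, not just the first).
#'
#' @param path Path to a YAML configuration file. An empty file yields the
#'   full default configuration.
#' @return A `"gsd_config"` object; the names of keys that were set by the
#'   file (rather than defaulted) are kept in the `"user_keys"` attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw) || (length(raw) > 0 && is.null(names(raw)))) {
    stop("configuration file must be a mapping of key: value pairs")
  }
  sim_config(raw)
}

#' Write the resolved configuration to a YAML file
#'
#' @param config A `"gsd_config"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  flat <- config_flat_values(config)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Write simulation outputs and a hashed manifest
#'
#' Emits the trajectory as TSV, the fully resolved configuration as YAML,
#' and a manifest listing the MD5 hash of each emitted file. Re-running
#' the same configuration and seed reproduces identical hashes.
#'
#' @param sim A `"gsd_simulation"` result from [run_simulation()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a data frame manifest with columns `file` and `md5`.
#' @export
write_outputs <- function(sim, out_dir) {
  stopifnot(inherits(sim, "gsd_simulation"))
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory: ", out_dir)
  }
  traj_path <- file.path(out_dir, "trajectory.tsv")
  write.table(sim$trajectory, traj_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  dump_config(sim$config, cfg_path)
  files <- c(traj_path, cfg_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  man_path <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, man_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}
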