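# Metapopulation life cycle ---------------------------------------------------
#
# Non-overlapping generations on a linear array of demes:
# reproduce -> develop + viability selection -> disperse -> regulate/mature.

#' Normalized deme temperatures
#'
#' Temperature is linear in deme index: 0 at deme 0 (the cold, "northern"
#' end) and 1 at deme `n_demes - 1` (the warm, "southern" end).
#'
#' @param n_demes Number of demes (>= 2).
#' @return Numeric vector of length `n_demes`.
#' @export
deme_temperatures <- function(n_demes) {
  stopifnot(n_demes >= 2)
  (seq_len(n_demes) - 1) / (n_demes - 1)
}

#' Initialize the ancestral XY metapopulation
#'
#' Every deme starts at carrying capacity with a 1:1 sex ratio: females are
#' XX and males XY with a single expressed Y-linked masculinizer. All F
#' alleles share the configured baseline expression and sensitivity and no
#' autosomal masculinizers exist yet. For odd capacity the female count is
#' rounded down.
#'
#' @param config A [sim_config()] object.
#' @return A population matrix of developed adults.
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "gsd_config"))
  K <- config$capacity
  n_f <- K %/% 2L
  n_m <- K - n_f
  per_deme <- function(d) {
    pop <- new_population(K)
    pop[, "deme"] <- d
    pop[, c("zf0_mat", "zf0_pat")] <- config$z_f0_init
    pop[, c("sfm_mat", "sfm_pat")] <- config$s_fm_init
    pop[, "sex"] <- rep(c(SEX_FEMALE, SEX_MALE), c(n_f, n_m))
    males <- pop[, "sex"] == SEX_MALE
    pop[males, "y_pat"] <- 1
    pop[males, "zmy_pat"] <- config$z_my_init
    pop
  }
  do.call(rbind, lapply(seq_len(config$n_demes) - 1L, per_deme))
}

# Draw B mother and father rows for one deme; returns NULL when either sex
# is absent (or carries zero total mating weight).
sample_parents_deme <- function(pop, fem_rows, mal_rows, B, fitness) {
  if (length(fem_rows) < 1 || length(mal_rows) < 1) return(NULL)
  if (fitness$sa_on_mating && fitness$s_a > 0) {
    ybear <- function(rows) pop[rows, "y_mat"] != 0 | pop[rows, "y_pat"] != 0
    wf <- ifelse(ybear(fem_rows), max(0, 1 - fitness$s_a), 1)
    wm <- ifelse(ybear(mal_rows), 1 + fitness$s_a, 1)
    if (sum(wf) <= 0 || sum(wm) <= 0) return(NULL)
    mothers <- fem_rows[sample.int(length(fem_rows), B, TRUE, prob = wf)]
    fathers <- mal_rows[sample.int(length(mal_rows), B, TRUE, prob = wm)]
  } else {
    mothers <- fem_rows[sample.int(length(fem_rows), B, TRUE)]
    fathers <- mal_rows[sample.int(length(mal_rows), B, TRUE)]
  }
  list(mothers = mothers, fathers = fathers)
}

#' Produce one deme's offspring pool
#'
#' If the deme holds at least one adult female and one adult male, draws
#' `B` mother/father pairs uniformly with replacement (intersexes never
#' reproduce), forms gametes with [make_gametes()]'s model, and fuses them
#' into undeveloped offspring in the natal deme. With either sex absent
#' the deme produces no offspring.
#'
#' @param pop Population matrix of adults.
#' @param deme Deme index (0-based).
#' @param B Number of offspring to produce.
#' @param mutation A [mutation_params()] object.
#' @param fitness A [fitness_params()] object; only used when the sexually
#'   antagonistic effect is configured to act on mating success.
#' @return A population matrix of undeveloped offspring (possibly 0 rows).
#' @export
reproduce_deme <- function(pop, deme, B, mutation = mutation_params(),
                           fitness = fitness_params()) {
  pop <- as_pop_matrix(pop)
  here <- pop[, "deme"] == deme
  fem <- which(here & pop[, "sex"] == SEX_FEMALE)
  mal <- which(here & pop[, "sex"] == SEX_MALE)
  pr <- sample_parents_deme(pop, fem, mal, B, fitness)
  if (is.null(pr)) return(new_population(0))
  eggs <- cpp_make_gametes(pop, pr$mothers, mutation$p_mut, mutation$p_null,
                           mutation$sigma_mut, mutation$mu_d,
                           mutation$z_m_init)
  sperm <- cpp_make_gametes(pop, pr$fathers, mutation$p_mut, mutation$p_null,
                            mutation$sigma_mut, mutation$mu_d,
                            mutation$z_m_init)
  colnames(eggs) <- colnames(sperm) <- gamete_columns()
  fertilize(eggs, sperm, deme)
}

# All demes at once: uniform parent draws are vectorized over the whole
# offspring pool (one runif() per parent slot), and one gamete-kernel call
# covers all mothers and one all fathers, so the per-generation R overhead
# stays flat in deme count.
reproduce_all <- function(pop, config) {
  N <- config$n_demes
  B <- config$offspring_per_deme
  sex <- pop[, "sex"]
  deme <- pop[, "deme"]
  fem <- which(sex == SEX_FEMALE)
  mal <- which(sex == SEX_MALE)
  fd <- deme[fem]; md <- deme[mal]
  of <- fem[order(fd)]; om <- mal[order(md)]
  cf <- tabulate(fd + 1, nbins = N)
  cm <- tabulate(md + 1, nbins = N)
  weighted <- config$fitness$sa_on_mating && config$fitness$s_a > 0
  if (weighted) {
    offf <- c(0L, cumsum(cf)); offm <- c(0L, cumsum(cm))
    mo <- vector("list", N); fa <- vector("list", N); natal <- vector("list", N)
    for (j in seq_len(N)) {
      fj <- of[seq_len(cf[j]) + offf[j]]
      mj <- om[seq_len(cm[j]) + offm[j]]
      pr <- sample_parents_deme(pop, fj, mj, B, config$fitness)
      if (!is.null(pr)) {
        mo[[j]] <- pr$mothers
        fa[[j]] <- pr$fathers
        natal[[j]] <- rep.int(j - 1L, B)
      }
    }
    mothers <- unlist(mo); fathers <- unlist(fa); nd <- unlist(natal)
    if (length(mothers) == 0) return(new_population(0))
  } else {
    ok <- which(cf > 0 & cm > 0)
    if (length(ok) == 0) return(new_population(0))
    nd <- rep(ok - 1L, each = B)
    j <- rep(ok, each = B)
    offf <- c(0L, cumsum(cf)); offm <- c(0L, cumsum(cm))
    mothers <- of[offf[j] + floor(runif(length(j)) * cf[j]) + 1]
    fathers <- om[offm[j] + floor(runif(length(j)) * cm[j]) + 1]
  }
  mut <- config$mutation
  eggs <- cpp_make_gametes(pop, mothers, mut$p_mut, mut$p_null,
                           mut$sigma_mut, mut$mu_d, mut$z_m_init)
  sperm <- cpp_make_gametes(pop, fathers, mut$p_mut, mut$p_null,
                            mut$sigma_mut, mut$mu_d, mut$z_m_init)
  colnames(eggs) <- colnames(sperm) <- gamete_columns()
  fertilize(eggs, sperm, nd)
}

#' Sexual development and viability selection
#'
#' Determines each undeveloped juvenile's sex at its natal deme's
#' temperature, then applies viability selection. The Y-chromosomal
#' fitness factors are relative fitnesses; survival probability is the
#' individual's factor divided by the largest attainable factor
#' (`1 + s_a`), i.e. soft selection, so that the male advantage of a
#' Y is not silently capped at a survival probability of one. Intersexes
#' are viable (subject to the YY cost) but infertile. When the sexually
#' antagonistic effect is configured to act on mating success, only the
#' YY viability component applies here.
#'
#' @param juveniles Population matrix of undeveloped individuals.
#' @param config A [sim_config()] object.
#' @return Population matrix of developed survivors.
#' @export
develop_and_select <- function(juveniles, config) {
  juveniles <- as_pop_matrix(juveniles)
  if (nrow(juveniles) == 0) return(juveniles)
  temps <- deme_temperatures(config$n_demes)
  juveniles <- determine_sex(juveniles, temps[juveniles[, "deme"] + 1],
                             config$development)
  fit <- config$fitness
  s_a_dev <- if (fit$sa_on_mating) 0 else fit$s_a
  if (fit$s_yy >= 1 && s_a_dev == 0) return(juveniles)
  w <- cpp_fitness_factor(juveniles, fit$s_yy, s_a_dev)
  keep <- runif(nrow(juveniles)) < pmin(1, w / (1 + s_a_dev))
  juveniles[keep, , drop = FALSE]
}

#' Nearest-neighbour dispersal
#'
#' Each individual migrates with probability `d`. Migrants from interior
#' demes move to the left or right neighbour with probability 1/2 each;
#' migrants from an edge deme move to their single neighbour. No
#' individual is created or destroyed.
#'
#' @param pop Population matrix.
#' @param d Dispersal rate in \[0, 1\].
#' @param n_demes Number of demes.
#' @return The population matrix with updated deme indices.
#' @export
migrate <- function(pop, d, n_demes) {
  pop <- as_pop_matrix(pop)
  stopifnot(d >= 0, d <= 1)
  n <- nrow(pop)
  if (n == 0 || d == 0) return(pop)
  moves <- runif(n) < d
  dir <- ifelse(runif(n) < 0.5, -1, 1)
  deme <- pop[, "deme"]
  dir[deme == 0] <- 1
  dir[deme == n_demes - 1] <- -1
  pop[moves, "deme"] <- deme[moves] + dir[moves]
  pop
}

#' Density regulation and maturation
#'
#' Within each deme, if more than `K` juveniles are present after
#' dispersal, `K` are retained by uniform sampling without replacement.
#' Survivors mature into the next adult generation; the previous adults
#' are gone (non-overlapping generations).
#'
#' @param pop Population matrix of juveniles after dispersal.
#' @param K Carrying capacity per deme.
#' @param n_demes Number of demes.
#' @return Population matrix of the new adults.
#' @export
regulate_and_mature <- function(pop, K, n_demes) {
  pop <- as_pop_matrix(pop)
  n <- nrow(pop)
  if (n == 0) return(pop)
  counts <- tabulate(pop[, "deme"] + 1, nbins = n_demes)
  if (all(counts <= K)) return(pop)
  # one sort key: deme index plus a sub-unit random tie-break
  ord <- order(pop[, "deme"] + runif(n) * 0.5)
  rank_in_deme <- sequence(counts)
  pop[ord[rank_in_deme <= K], , drop = FALSE]
}

# One life-cycle iteration composed from the exported operations.
step_generation_r <- function(pop, config) {
  off <- reproduce_all(pop, config)
  off <- develop_and_select(off, config)
  off <- migrate(off, config$dispersal_rate, config$n_demes)
  regulate_and_mature(off, config$capacity, config$n_demes)
}

# Same iteration through the fused compiled step.
step_generation_cpp <- function(pop, config) {
  mut <- config$mutation
  dev <- config$development
  fit <- config$fitness
  out <- cpp_step_generation(pop, config$n_demes, config$offspring_per_deme,
                             config$capacity,
                             deme_temperatures(config$n_demes),
                             mut$p_mut, mut$p_null, mut$sigma_mut,
                             mut$mu_d, mut$z_m_init,
                             dev$theta_f, dev$theta_m, dev$beta,
                             dev$sigma_eps,
                             fit$s_yy, fit$s_a, config$dispersal_rate)
  colnames(out) <- pop_columns()
  out
}

#' Run the full simulation
#'
#' Initializes the ancestral XY metapopulation and iterates the life cycle
#' (reproduction, development and viability selection, dispersal,
#' regulation) for the configured number of generations, recording
#' per-deme summaries at the configured cadence (generation 0 and the
#' final generation are always recorded). The configured seed fully
#' determines the outcome: identical configurations give bitwise-identical
#' trajectories.
#'
#' @param config A [sim_config()] object with a non-`NULL` `seed`.
#' @param engine `"cpp"` (default) runs each life-cycle iteration through
#'   a fused compiled step; `"r"` composes the exported operations
#'   ([reproduce_deme()], [develop_and_select()], [migrate()],
#'   [regulate_and_mature()]) and is several-fold slower. Both implement
#'   the identical model; when the sexually antagonistic effect acts on
#'   mating success the R composition is always used.
#' @param initial_pop Optional population matrix of developed adults to
#'   start from (e.g. reloaded with [read_snapshot()]) instead of the
#'   ancestral XY metapopulation.
#' @return A list of class `"gsd_simulation"` with elements `trajectory`
#'   (data frame of per-generation, per-deme summaries, see
#'   [summarize_generation()]), `final_pop` (population matrix),
#'   `config`, `extinct` (logical), and `generations_run`.
#' @export
run_simulation <- function(config, engine = c("cpp", "r"),
                           initial_pop = NULL) {
  stopifnot(inherits(config, "gsd_config"))
  engine <- match.arg(engine)
  if (config$fitness$sa_on_mating) engine <- "r"
  step <- if (engine == "cpp") step_generation_cpp else step_generation_r
  if (is.null(config$seed)) stop("config$seed must be set for a simulation run")
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  G <- config$generations
  pop <- if (is.null(initial_pop)) initialize_population(config)
         else as_pop_matrix(initial_pop)
  if (nrow(pop) > 0 && max(pop[, "deme"]) >= config$n_demes) {
    stop("initial population references demes beyond n_demes")
  }
  n_rec <- length(unique(c(0L, seq(0L, G, by = config$record_every), G)))
  rec <- vector("list", n_rec + 1L)
  ri <- 1L
  rec[[ri]] <- summary_matrix(pop, config, 0L)
  extinct <- FALSE
  gen <- 0L
  while (gen < G) {
    gen <- gen + 1L
    pop <- step(pop, config)
    if (nrow(pop) == 0) {
      extinct <- TRUE
    }
    if (extinct || gen %% config$record_every == 0L || gen == G) {
      ri <- ri + 1L
      rec[[ri]] <- summary_matrix(pop, config, gen)
    }
    if (extinct) break
  }
  traj <- as.data.frame(do.call(rbind, rec[seq_len(ri)]))
  structure(list(trajectory = traj, final_pop = pop, config = config,
                 extinct = extinct, generations_run = gen),
            class = "gsd_simulation")
}

#' @export
print.gsd_simulation <- function(x, ...) {
  cat(sprintf(
    "<gsd_simulation> %d demes, %d/%d generations%s, %d final individuals\n",
    x$config$n_demes, x$generations_run, x$config$generations,
    if (x$extinct) " (extinct)" else "", nrow(x$final_pop)))
  invisible(x)
}
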