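test_that("the initial metapopulation is an ancestral XY system at capacity", {
  cfg <- tiny_config(n_demes = 5, capacity = 100)
  pop <- initialize_population(cfg)
  expect_equal(nrow(pop), 500)
  expect_equal(sum(pop[, "sex"] == 1), 250)
  expect_equal(sum(pop[, "sex"] == 2), 250)
  females <- pop[pop[, "sex"] == 1, ]
  males <- pop[pop[, "sex"] == 2, ]
  expect_true(all(n_y_chromosomes(females) == 0))
  expect_true(all(n_y_chromosomes(males) == 1))
  expect_true(all(males[, "zmy_pat"] == cfg$z_my_init))
  # no autosomal masculinizers at generation zero
  expect_true(all(pop[, c("a_mat", "a_pat")] == 0))
  expect_true(all(pop[, c("zf0_mat", "zf0_pat")] == cfg$z_f0_init))
  # odd capacity rounds the female count down
  cfg2 <- tiny_config(capacity = 7)
  pop2 <- initialize_population(cfg2)
  expect_equal(sum(pop2[, "sex"] == 1 & pop2[, "deme"] == 0), 3)
  expect_equal(sum(pop2[, "sex"] == 2 & pop2[, "deme"] == 0), 4)
})

test_that("initial genotypes develop as female and male across all demes", {
  cfg <- tiny_config(n_demes = 6, beta = 0.7, sigma_eps = 0)
  pop <- initialize_population(cfg)
  redev <- pop
  redev[, "sex"] <- 0
  temps <- deme_temperatures(cfg$n_demes)[redev[, "deme"] + 1]
  redev <- determine_sex(redev, temps, cfg$development)
  expect_identical(redev[, "sex"], pop[, "sex"])
})

test_that("reproduction requires both sexes and produces B offspring", {
  cfg <- tiny_config()
  females_only <- xx_female()
  expect_equal(nrow(reproduce_deme(females_only, 0, 100)), 0)
  # intersexes do not reproduce
  with_ix <- rbind(xx_female(), xx_female())
  with_ix[2, "sex"] <- 3
  expect_equal(nrow(reproduce_deme(with_ix, 0, 100)), 0)
  set.seed(31)
  pair <- rbind(xx_female(), xy_male())
  off <- reproduce_deme(pair, 0, 400, mutation_params(p_mut = 0))
  expect_equal(nrow(off), 400)
  expect_true(all(off[, "sex"] == 0))
  # single-pair offspring genotypes follow Mendelian expectation: half XY
  ci <- binom_ci99(0.5, 400)
  expect_gt(mean(off[, "y_pat"]), ci[1] - 0.05)
  expect_lt(mean(off[, "y_pat"]), ci[2] + 0.05)
})

test_that("development and selection set sexes and apply the YY cost", {
  cfg <- tiny_config(s_yy = 1, s_a = 0)
  off <- reproduce_deme(rbind(xx_female(), xy_male()), 0, 500,
                        cfg$mutation)
  dev <- develop_and_select(off, cfg)
  expect_equal(nrow(dev), 500)  # survival probability one for everyone
  expect_true(all(dev[, "sex"] %in% 1:3))
  # YY juveniles survive at rate s_yy
  set.seed(32)
  yy <- build_individual("F_0/F_0; M_Y/M_Y")
  yy <- yy[rep(1, 10000), , drop = FALSE]
  cfg2 <- tiny_config(s_yy = 0.8, s_a = 0, n_demes = 4)
  surv <- develop_and_select(yy, cfg2)
  ci <- binom_ci99(0.8, 10000)
  expect_gt(nrow(surv) / 10000, ci[1])
  expect_lt(nrow(surv) / 10000, ci[2])
})

test_that("intersex juveniles survive but are never recruited as parents", {
  cfg <- tiny_config(theta_f = 1.2, theta_m = 0.3)
  ix <- build_individual("F/F; +/+", z_f0 = 0.25)
  ix <- ix[rep(1, 50), , drop = FALSE]
  dev <- develop_and_select(ix, cfg)
  expect_equal(nrow(dev), 50)
  expect_true(all(dev[, "sex"] == 3))
  expect_equal(nrow(reproduce_deme(dev, 0, 100)), 0)
})

test_that("dispersal moves individuals to neighbours and conserves counts", {
  cfg <- tiny_config()
  pop <- initialize_population(cfg)
  expect_identical(migrate(pop, 0, cfg$n_demes), pop)
  # d = 1 with two demes swaps everyone
  two <- initialize_population(tiny_config(n_demes = 2, capacity = 40))
  swapped <- migrate(two, 1, 2)
  expect_identical(swapped[, "deme"], 1 - two[, "deme"])
  # interior deme splits d/2 per side
  set.seed(33)
  mid <- new_population(10000)
  mid[, "deme"] <- 1
  moved <- migrate(mid, 0.2, 3)
  expect_equal(nrow(moved), 10000)
  counts <- table(factor(moved[, "deme"], levels = 0:2))
  ci <- binom_ci99(0.1, 10000)
  expect_gt(counts[["0"]] / 10000, ci[1])
  expect_lt(counts[["0"]] / 10000, ci[2])
  expect_gt(counts[["2"]] / 10000, ci[1])
  expect_lt(counts[["2"]] / 10000, ci[2])
})

test_that("regulation caps each deme at carrying capacity", {
  set.seed(34)
  juv <- new_population(700)
  juv[, "deme"] <- rep(c(0, 1, 2), c(500, 150, 50))
  out <- regulate_and_mature(juv, K = 100, n_demes = 3)
  counts <- table(factor(out[, "deme"], levels = 0:2))
  expect_equal(as.integer(counts), c(100, 100, 50))
  # under capacity everyone matures
  expect_equal(nrow(regulate_and_mature(juv[juv[, "deme"] == 2, ], 100, 3)), 50)
})

test_that("identical seeds give bitwise-identical simulations", {
  cfg <- tiny_config(generations = 30, mu_d = 0.01, sigma_eps = 0.05)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_pop, b$final_pop)
  # and the R-composed engine is deterministic too
  a_r <- run_simulation(cfg, engine = "r")
  b_r <- run_simulation(cfg, engine = "r")
  expect_identical(a_r$trajectory, b_r$trajectory)
})

test_that("runs can restart from a saved snapshot", {
  cfg <- tiny_config(generations = 10, mu_d = 0.02, sigma_eps = 0.05)
  first <- run_simulation(cfg)
  path <- tempfile(fileext = ".tsv")
  write_snapshot(first$final_pop, path)
  cfg2 <- tiny_config(seed = 99, generations = 10, mu_d = 0.02,
                      sigma_eps = 0.05)
  resumed <- run_simulation(cfg2, initial_pop = read_snapshot(path))
  direct <- run_simulation(cfg2, initial_pop = first$final_pop)
  expect_identical(resumed$trajectory, direct$trajectory)
  expect_equal(nrow(resumed$final_pop),
               cfg2$n_demes * cfg2$capacity)
  bad <- first$final_pop
  bad[1, "deme"] <- 99
  expect_error(run_simulation(cfg2, initial_pop = bad), "demes beyond")
})

test_that("a zero-generation run records only the initial state", {
  cfg <- tiny_config(generations = 0)
  sim <- run_simulation(cfg)
  expect_equal(unique(sim$trajectory$generation), 0)
  expect_equal(nrow(sim$trajectory), cfg$n_demes)
  expect_equal(sim$generations_run, 0)
})

test_that("generations do not overlap: adults are replaced every cycle", {
  cfg <- tiny_config(generations = 1, p_mut = 0, mu_d = 0, sigma_eps = 0)
  pop0 <- initialize_population(cfg)
  # tag the founders with a recognizably different trait value
  sim <- run_simulation(cfg)
  # founders had exactly z_f0_init everywhere; offspring of generation 1
  # are new individuals: the adult count is conserved but rows differ
  expect_equal(nrow(sim$final_pop), nrow(pop0))
  expect_false(identical(sim$final_pop, pop0))
})

test_that("an all-intersex regime goes extinct and is flagged", {
  cfg <- tiny_config(theta_f = 3, theta_m = 1, generations = 10,
                     z_f0_init = 1)
  sim <- run_simulation(cfg)
  expect_true(sim$extinct)
  expect_lt(sim$generations_run, 10)
  expect_equal(nrow(sim$final_pop), 0)
})

test_that("with mutation, dispersal and selection off, only drift operates", {
  cfg <- tiny_config(p_mut = 0, mu_d = 0, dispersal_rate = 0, sigma_eps = 0,
                     s_yy = 1, s_a = 0, generations = 40)
  sim <- run_simulation(cfg)
  pop <- sim$final_pop
  # trait values cannot change without mutation
  expect_true(all(pop[, c("zf0_mat", "zf0_pat")] == cfg$z_f0_init))
  expect_true(all(pop[, c("sfm_mat", "sfm_pat")] == cfg$s_fm_init))
  # the M_Y allele stays fixed among males (every male is X/Y)
  tr <- sim$trajectory
  last <- tr[tr$generation == max(tr$generation), ]
  expect_true(all(last$freq_my_pat_m == 1))
})

test_that("both engines produce statistically equivalent dynamics", {
  freqs <- function(engine, seeds) {
    sapply(seeds, function(s) {
      cfg <- tiny_config(seed = s, generations = 150, mu_d = 0.02,
                         sigma_eps = 0.05, capacity = 100,
                         offspring_per_deme = 200)
      sim <- run_simulation(cfg, engine = engine)
      eq <- equilibrium_summary(sim$trajectory, 0.25)
      c(ma = mean(eq$freq_ma_pat_m, na.rm = TRUE),
        fem = sum(eq$n_female) / sum(eq$n_total))
    })
  }
  cpp <- freqs("cpp", 1:4)
  rr <- freqs("r", 5:8)
  # same model: replicate means agree within a few points
  expect_lt(abs(mean(cpp["ma", ]) - mean(rr["ma", ])), 0.1)
  expect_lt(abs(mean(cpp["fem", ]) - mean(rr["fem", ])), 0.05)
})
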