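default_sizes_for_test <- function() {
  c(BF = 20000, MC = 20000, PY = 20000, CM = 20000)
}

test_that("prior draws respect their log-uniform bounds and seed", {
  cfg <- prior_config("rad")
  scn <- scenario_17()
  set.seed(31)
  draws <- replicate(10000, sample_prior(cfg, scn), simplify = FALSE)
  ne <- unlist(purrr::map(draws, "sizes"))
  expect_true(all(ne >= 1 & ne <= 4e5))
  tt <- purrr::map(draws, "times")
  expect_true(all(unlist(tt) >= 1e3 & unlist(tt) <= 1e7))
  # event ordering preserved by the sort
  expect_true(all(vapply(tt, function(x) !is.unsorted(x), logical(1))))
  mu <- unlist(purrr::map(draws, "mu"))
  expect_true(all(mu >= 1e-8 & mu <= 1e-6))

  # median of log-uniform(1, 4e5) is sqrt(4e5)
  set.seed(32)
  x <- radscape:::rloguniform(100000, 1, 4e5)
  expect_equal(median(x), sqrt(4e5), tolerance = 0.05)

  d1 <- sample_prior(cfg, scn, seed = 7)
  d2 <- sample_prior(cfg, scn, seed = 7)
  expect_identical(d1[c("times", "sizes", "mu")], d2[c("times", "sizes", "mu")])
})

test_that("mitochondrial priors scale to the quarter effective size", {
  cfg <- prior_config("mito")
  draw <- sample_prior(cfg, scenario_17(), seed = 8)
  expect_true(all(draw$sizes >= 0.25 & draw$sizes <= 1e5))
  # the scenario carries the nuclear-equivalent (x4) sizes
  expect_equal(unname(draw$scenario$sizes[names(draw$sizes)]),
               unname(draw$sizes * 4))
})

small_table <- local({
  scns <- scenario_library()
  cfg <- prior_config("rad", ne_bounds = c(5e3, 5e4),
                      time_bounds = c(1e5, 2e6))
  des <- study_design_rad(n_loci = 30)
  list(table = build_reference_table(scns, cfg, des, n_per_scenario = 60,
                                     seed = 33),
       scns = scns, cfg = cfg, des = des)
})

test_that("reference tables have the configured shape and are seeded", {
  tab <- small_table$table
  expect_equal(nrow(tab), 180)
  expect_equal(as.integer(table(tab$scenario)), rep(60L, 3))
  expect_equal(sum(grepl("^s[0-9]+$", names(tab))), 34)
  tab2 <- build_reference_table(small_table$scns, small_table$cfg,
                                small_table$des, n_per_scenario = 60,
                                seed = 33)
  expect_identical(tibble::as_tibble(tab), tibble::as_tibble(tab2))
})

test_that("deep splits raise simulated between-region F_ST over panmixia", {
  flat <- scenario("flat",
                   events = data.frame(time = c(1, 2, 3),
                                       derived = c("BF", "MC", "PY"),
                                       ancestral = c("MC", "PY", "CM")),
                   sizes = default_sizes_for_test())
  deep <- scenario_17(sizes = default_sizes_for_test())
  des <- study_design_rad(n_loci = 40)
  des$mutation_rate <- 1e-6
  mean_fst <- function(scn, seeds) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      vec <- radscape:::stat_vector_core(radscape:::sim_state(scn, des),
                                         names(des$samples))
      mean(vec[grep("\\.fst$", names(vec))], na.rm = TRUE)
    }, numeric(1)), na.rm = TRUE)
  }
  expect_gt(mean_fst(deep, 1:20), mean_fst(flat, 1:20) + 0.1)
})

test_that("rejection sampling recovers trivially separable scenarios", {
  tab <- small_table$table
  # observed identical to one row of s17: its scenario dominates the closest set
  row <- tab[tab$scenario == "s17", ][1, ]
  obs <- as.numeric(row[, grep("^s[0-9]+$", names(tab))])
  d <- radscape:::abc_distances(obs, tab)
  expect_equal(tab$scenario[which.min(d)], "s17")

  direct <- abc_direct(obs, tab, n_closest = 20)
  expect_equal(sum(direct$probability), 1, tolerance = 1e-9)
  expect_true(all(direct$probability >= 0 & direct$probability <= 1))
  expect_true(all(direct$lower <= direct$probability &
                    direct$probability <= direct$upper))
})

test_that("identical simulators split probability evenly", {
  # two scenarios that are the same history under different names
  a <- scenario_17(); a$name <- "a"
  b <- scenario_17(); b$name <- "b"
  cfg <- prior_config("rad", ne_bounds = c(5e3, 5e4),
                      time_bounds = c(1e5, 2e6))
  des <- study_design_rad(n_loci = 25)
  tab <- build_reference_table(list(a = a, b = b), cfg, des,
                               n_per_scenario = 150, seed = 35)
  set.seed(36)
  draw <- sample_prior(cfg, a)
  des$mutation_rate <- draw$mu
  obs <- radscape:::stat_vector_core(radscape:::sim_state(draw$scenario, des),
                                     names(des$samples))
  direct <- abc_direct(obs, tab, n_closest = 100)
  expect_lt(abs(direct$probability[direct$scenario == "a"] - 0.5),
            3 * sqrt(0.25 / 100) + 0.05)
  logistic <- abc_logistic(obs, tab, n_retained = 100)
  expect_equal(sum(logistic$probability), 1, tolerance = 1e-6)
  expect_lt(abs(logistic$probability[logistic$scenario == "a"] - 0.5), 0.35)
})

test_that("logistic estimation handles the one-scenario degenerate path", {
  tab <- small_table$table
  # an observation so extreme that only one scenario could be close is
  # emulated by retaining very few rows
  row <- tab[tab$scenario == "s6", ][3, ]
  obs <- as.numeric(row[, grep("^s[0-9]+$", names(tab))])
  lg <- abc_logistic(obs, tab, n_retained = 2)
  expect_equal(sum(lg$probability), 1, tolerance = 1e-9)
})

test_that("probabilities sum to one and smooth toward the prior", {
  tab <- small_table$table
  set.seed(37)
  draw <- sample_prior(small_table$cfg, small_table$scns$s17)
  des <- small_table$des
  des$mutation_rate <- draw$mu
  obs <- radscape:::stat_vector_core(radscape:::sim_state(draw$scenario, des),
                                     names(des$samples))
  direct_small <- abc_direct(obs, tab, n_closest = 30)
  direct_all <- abc_direct(obs, tab, n_closest = nrow(tab))
  expect_equal(sum(direct_small$probability), 1, tolerance = 1e-9)
  # retaining the whole table returns the prior exactly (1/3 each)
  expect_equal(direct_all$probability, rep(1 / 3, 3), tolerance = 1e-9)
  lg <- abc_logistic(obs, tab, n_retained = 100)
  expect_equal(sum(lg$probability), 1, tolerance = 1e-6)
})
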