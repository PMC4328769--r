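test_that("pair TMRCA matches the closed-form coalescent expectation", {
  # two haploid lineages, one deme: E[T2] = 2 Ne(marker); the mito marker
  # coalesces at a quarter of the nominal diploid size
  ne <- 800
  scn <- one_pop_scenario(ne = ne)
  des <- sample_design("mito", c(A = 2), 1)
  set.seed(41)
  tmrca <- replicate(10000, max(draw_coalescent_tree(scn, des)$node_time))
  expected <- 2 * ne / 4
  mc_se <- sd(tmrca) / sqrt(length(tmrca))
  expect_lt(abs(mean(tmrca) - expected), 3 * mc_se)

  # diploid RAD lineages: pair rate 1/(2 Ne) for two sampled chromosomes
  des_rad <- sample_design("rad", c(A = 1), 1)  # one individual = 2 lineages
  set.seed(42)
  tmrca_rad <- replicate(10000, max(draw_coalescent_tree(scn, des_rad)$node_time))
  mc_se_rad <- sd(tmrca_rad) / sqrt(length(tmrca_rad))
  expect_lt(abs(mean(tmrca_rad) - 2 * ne), 3 * mc_se_rad)
})

test_that("lineages from two regions never coalesce before the merge time", {
  t_split <- 5e4
  scn <- two_pop_scenario(t = t_split, ne = c(A = 2000, B = 2000))
  des <- sample_design("rad", c(A = 3, B = 3), 1)
  set.seed(7)
  for (i in 1:50) {
    tr <- draw_coalescent_tree(scn, des)
    cross <- radscape:::cross_region_node_times(tr)
    expect_true(all(cross >= t_split))
  }
})

test_that("gene trees are deterministic under a fixed seed", {
  scn <- two_pop_scenario()
  des <- sample_design("rad", c(A = 2, B = 2), 1)
  n1 <- gene_tree_newick(draw_coalescent_tree(scn, des, seed = 123))
  n2 <- gene_tree_newick(draw_coalescent_tree(scn, des, seed = 123))
  expect_identical(n1, n2)
  n3 <- gene_tree_newick(draw_coalescent_tree(scn, des, seed = 124))
  expect_false(identical(n1, n3))
})

test_that("disconnected histories raise a configuration error", {
  # caught by scenario validation at the R surface
  scn <- one_pop_scenario(label = "A")
  scn$leaves <- c("A", "B")
  scn$sizes <- c(A = 100, B = 100)
  des <- sample_design("rad", c(A = 2, B = 2), 1)
  expect_error(draw_coalescent_tree(scn, des), "root lineage|single leaf")
  # and by the engine itself if validation were bypassed
  expect_error(
    radscape:::cpp_coal_tree(c(0L, 0L, 1L, 1L), 2L, c(200, 200),
                             numeric(0), integer(0), integer(0)),
    "disconnected"
  )
  # sampling a region the scenario does not know is a configuration error
  scn2 <- two_pop_scenario()
  expect_error(
    draw_coalescent_tree(scn2, sample_design("rad", c(A = 2, Z = 2), 1)),
    "absent from scenario"
  )
})

test_that("mutation overlay honours the zero-rate and all-invariant limits", {
  scn <- one_pop_scenario(ne = 500)
  des <- sample_design("rad", c(A = 4), 1)
  tr <- draw_coalescent_tree(scn, des, seed = 1)

  des0 <- des
  des0$mutation_rate <- 0
  haps <- mutate_locus(tr, des0, seed = 2)
  expect_equal(length(unique(haps$sequence)), 1)

  des1 <- sample_design("rad", c(A = 4), 1, invariant_fraction = 1)
  haps1 <- mutate_locus(tr, des1, seed = 3)
  expect_true(all(haps1$sequence == ""))  # no variable sites at all
})

test_that("expected pairwise differences match 2 E[T2] mu L_var", {
  ne <- 500
  mu <- 5e-6
  scn <- one_pop_scenario(ne = ne)
  des <- sample_design("mito", c(A = 2), 1, locus_length = 200,
                       mutation_rate = mu, invariant_fraction = 0.5)
  l_var <- 100
  set.seed(11)
  diffs <- replicate(10000, {
    tr <- draw_coalescent_tree(scn, des)
    haps <- mutate_locus(tr, des)
    as.integer(p_distance(haps$sequence[1], haps$sequence[2])$substitutions)
  })
  # E[pairwise diffs] = 2 * E[T2] * mu * L_var, slightly deflated by
  # finite-sites multiple hits (< 1% at this divergence)
  expected <- 2 * (2 * ne / 4) * mu * l_var
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - expected), 3 * mc_se + 0.01 * expected)
})

test_that("panmictic simulations recover Watterson's theta and neutral D", {
  # simulator calibration: E[S] = a1 * theta with theta = 4 Ne mu L_var
  # (RAD marker, 2n = 10 lineages), and mean Tajima's D near zero
  ne <- 2000
  mu <- 2e-6
  n_loci <- 1500
  scn <- one_pop_scenario(ne = ne)
  des <- sample_design("rad", c(A = 5), n_loci = n_loci,
                       mutation_rate = mu)  # L_var = 2
  sim <- simulate_dataset(scn, des, NULL, seed = 99)
  h <- radscape:::haplotype_state_matrix(sim$catalog, sim$rad_popmap)
  expect_equal(nrow(h$mat), 10)

  n <- nrow(h$mat)
  a1 <- sum(1 / seq_len(n - 1))
  theta <- 4 * ne * mu * 2
  # per-locus S: count segregating columns per locus block
  poly <- colSums(h$mat != h$mat[rep(1, n), , drop = FALSE]) > 0
  s_total <- sum(poly)
  expected_s <- a1 * theta * n_loci
  # var(S) per locus ~ a1*theta + a2*theta^2; use binomial-ish SE bound
  se_s <- sqrt(expected_s)
  expect_lt(abs(s_total - expected_s), 3 * se_s)

  # one dataset's pooled D is a noisy draw (SD ~ 0.26 at this theta); just
  # check it is not pathological — the calibrated replicate-mean check lives
  # with the acceptance properties
  tj <- tajimas_d(sim$catalog, sim$rad_popmap)
  expect_true(abs(tj$D) < 1)
})

test_that("identical seeds give bit-identical catalogs", {
  scn <- scenario_17()
  des <- study_design_rad(n_loci = 40)
  s1 <- simulate_dataset(scn, des, NULL, seed = 5)
  s2 <- simulate_dataset(scn, des, NULL, seed = 5)
  expect_identical(tibble::as_tibble(s1$catalog), tibble::as_tibble(s2$catalog))
})
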