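sim_cat <- local({
  sim <- simulate_dataset(scenario_17(), study_design_rad(n_loci = 400),
                          NULL, seed = 101, rad_popmap = study_popmap("rad"))
  list(catalog = sim$catalog, popmap = sim$rad_popmap)
})

test_that("locus subsampling is uniform, seeded, and bounded", {
  cat0 <- sim_cat$catalog
  # full draw is the identity set
  full <- subsample_loci(cat0, n_loci(cat0), seed = 1)
  expect_setequal(catalog_locus_ids(full), catalog_locus_ids(cat0))
  # seeded determinism
  expect_identical(catalog_locus_ids(subsample_loci(cat0, 50, seed = 3)),
                   catalog_locus_ids(subsample_loci(cat0, 50, seed = 3)))
  expect_error(subsample_loci(cat0, n_loci(cat0) + 1), "cannot draw")
  # L = 1 over many seeds: every locus roughly equally likely
  small <- simulate_dataset(one_pop_scenario(), sample_design("rad", c(A = 2), 10),
                            NULL, seed = 4)$catalog
  set.seed(5)
  draws <- replicate(4000, catalog_locus_ids(subsample_loci(small, 1)))
  freq <- table(factor(draws, levels = 1:10)) / 4000
  expect_true(all(abs(freq - 0.1) < 3 * sqrt(0.1 * 0.9 / 4000) + 0.02))
})

test_that("degenerate catalogs give zero replicate SD", {
  # every individual heterozygous at every locus: subsampled heterozygosity
  # is exactly 1 whatever the draw
  inds <- sprintf("i%02d", 1:4)
  all_het <- simulate_planted_catalog(setNames(rep(1, 4), inds),
                                      n_loci = 120, seed = 6)
  pm <- tibble::tibble(individual = inds, site = "s",
                       region = rep(c("X", "Y"), each = 2))
  hs <- het_saturation(all_het, pm, grid = seq(10, 100, 10), reps = 50,
                       seed = 7)
  expect_true(all(hs$sd == 0))
  expect_true(all(hs$mean == 1))
})

test_that("replicate SD shrinks as more loci are sampled", {
  hs <- het_saturation(sim_cat$catalog, sim_cat$popmap,
                       grid = seq(10, 400, 10), reps = 300, seed = 8)
  for (g in unique(hs$group)) {
    cc <- hs[hs$group == g, ]
    expect_lt(cc$sd[cc$L == 400], cc$sd[cc$L == 10])
  }
  # grand mean at every L is an unbiased estimate of the full-data value
  full <- region_heterozygosity(sim_cat$catalog, sim_cat$popmap)
  for (g in unique(hs$group)) {
    cc <- hs[hs$group == g, ]
    fv <- full$mean_het[full$region == g]
    se <- cc$sd / sqrt(attr(hs, "reps"))
    expect_true(all(abs(cc$mean - fv) < 4 * se + 1e-3))
  }
})

test_that("planted heterozygosity contrast separates within the grid", {
  inds <- sprintf("i%02d", 1:17)
  rates <- setNames(c(rep(0.025, 10), rep(0.145, 7)), inds)
  cat0 <- simulate_planted_catalog(rates, n_loci = 1000, seed = 9)
  hs <- het_saturation(cat0, level = "individual",
                       track = c("i01", "i17"), reps = 100, seed = 10)
  conv <- attr(hs, "convergence")
  expect_false(is.na(conv))
  expect_lte(conv, 1000)
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(11)
  for (n in 4:8) {
    true_tree <- ape::rtree(n, br = function(k) runif(k, 0.3, 1.2))
    dmat <- cophenetic(true_tree)
    est <- nj_tree(dmat[true_tree$tip.label, true_tree$tip.label])
    expect_equal(suppressMessages(phangorn::RF.dist(est, true_tree)), 0)
    # branch lengths recovered too (additivity)
    expect_equal(sort(round(cophenetic(est)[true_tree$tip.label,
                                            true_tree$tip.label], 8)),
                 sort(round(dmat, 8)))
  }
})

test_that("neighbor joining handles 3 taxa and input order permutations", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3)
  # the unique star: patristic distances reproduce the input exactly
  expect_equal(cophenetic(tr)[rownames(d), rownames(d)], d)
  set.seed(12)
  true_tree <- ape::rtree(7, br = function(k) runif(k, 0.3, 1.2))
  dmat <- cophenetic(true_tree)
  t1 <- nj_tree(dmat)
  perm <- sample(rownames(dmat))
  t2 <- nj_tree(dmat[perm, perm])
  expect_equal(suppressMessages(phangorn::RF.dist(t1, t2)), 0)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("rescaled RF matches hand enumeration on the 17-leaf constraint", {
  pm <- study_popmap("rad")
  ref <- study_constraint_tree(pm)
  expect_equal(radscape:::n_splits(ref), 4)

  # binary tree containing all reference splits -> 0
  grp <- split(pm$individual, pm$region)
  cater <- function(x) {
    if (length(x) == 1) return(x)
    paste0("(", x[1], ",", cater(x[-1]), ")")
  }
  good <- ape::read.tree(text = sprintf("((%s,(%s,%s)),(%s,%s));",
    cater(grp$BF), grp$MC[1], grp$MC[2], cater(grp$PY), cater(grp$CM)))
  expect_equal(radscape:::n_splits(good), 14)  # binary: n - 3
  expect_equal(rescaled_rf(good, ref), 0)

  # a caterpillar over an interleaved leaf order shares no reference split -> 1
  bad <- ape::read.tree(text = paste0(
    cater(pm$individual[order(rep_len(1:4, 17))]), ";"))
  expect_equal(rescaled_rf(bad, ref), 1)

  # exactly 2 reference splits present (BF and PY clades; the CM clade and
  # the north/south split broken): d = (14-2) + (4-2) = 14, rescaled
  # (14-10)/(18-10) = 0.5
  half <- ape::read.tree(text = sprintf("((%s,(%s,(%s,%s))),(%s,(%s,%s)));",
    cater(grp$BF), grp$MC[1], grp$CM[1], grp$CM[2],
    cater(grp$PY), grp$MC[2], grp$CM[3]))
  expect_equal(radscape:::n_splits(half), 14)
  expect_equal(rescaled_rf(half, ref), 0.5)
  expect_equal(rescaled_rf(half, ref), oracle_rescaled_rf(half, ref))
})

test_that("rescaled RF equals the split-enumeration oracle on small trees", {
  set.seed(13)
  labels <- letters[1:8]
  for (i in 1:25) {
    t1 <- random_tree(labels)
    t2 <- random_tree(labels)
    expect_equal(rescaled_rf(t1, t2), oracle_rescaled_rf(t1, t2))
  }
  # star reference is degenerate
  star <- ape::read.tree(text = paste0("(", paste(labels, collapse = ","), ");"))
  expect_error(rescaled_rf(random_tree(labels), star), "star")
  # leaf-set mismatch
  expect_error(rescaled_rf(random_tree(labels), random_tree(LETTERS[1:8])),
               "leaf set")
})

test_that("topology saturation converges on diverged data", {
  ref <- study_constraint_tree(sim_cat$popmap)
  ts <- topology_saturation(sim_cat$catalog, sim_cat$popmap, ref,
                            grid = seq(50, 400, 50), reps = 12, seed = 14)
  expect_false(is.na(ts$convergence_L))
  # mean curve roughly non-increasing: late mean no larger than early mean
  expect_lte(mean(tail(ts$curve$mean, 3)), mean(head(ts$curve$mean, 3)) + 0.02)
  # threshold 1.0 is met from the first grid point
  ts2 <- topology_saturation(sim_cat$catalog, sim_cat$popmap, ref,
                             grid = seq(50, 150, 50), reps = 4,
                             threshold = 1.0, seed = 15)
  expect_equal(ts2$convergence_L, 50)
  # star reference refused
  star <- ape::read.tree(text = paste0(
    "(", paste(sim_cat$popmap$individual, collapse = ","), ");"))
  expect_error(topology_saturation(sim_cat$catalog, sim_cat$popmap, star,
                                   grid = c(50), reps = 2), "star")
})
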