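test_that("FASTA round trip preserves labels and sequences", {
  aln <- tibble::tibble(
    individual = c("ind1", "ind2", "ind3"),
    sequence = c("ACGTACGT", "ACGTACGA", "ACGTNNGA")
  )
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln, path)
  back <- read_fasta(path)
  expect_equal(back, aln)
})

test_that("empty and mixed-case FASTA inputs are handled", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty), "empty")

  mixed <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgTacgt", ">b", "ACGTacga"), mixed)
  back <- read_fasta(mixed)
  expect_equal(back$sequence, c("ACGTACGT", "ACGTACGA"))
})

test_that("ragged alignments are rejected", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGTAA"), path)
  expect_error(read_fasta(path), "ragged")
})

make_filter_catalog <- function() {
  # 5 loci: 1-2 clean biallelic, 3 triallelic, 4 triallelic, 5 has 3 SNPs
  individuals <- c("i1", "i2", "i3", "i4")
  build_toy_catalog(list(
    list(pos = 10, geno = list(i1 = "A/A", i2 = "A/G", i3 = "G/G", i4 = "A/A")),
    list(pos = c(5, 50),
         geno = list(i1 = c("C/C", "T/T"), i2 = c("C/T", "T/A"),
                     i3 = c("T/T", "A/A"), i4 = c("C/C", "T/T"))),
    list(pos = 20, geno = list(i1 = "A/A", i2 = "C/C", i3 = "G/G", i4 = "A/A")),
    list(pos = 30, geno = list(i1 = "A/C", i2 = "C/G", i3 = "A/A", i4 = "C/C")),
    list(pos = c(1, 2, 3),
         geno = list(i1 = c("A/A", "C/C", "G/G"), i2 = c("A/G", "C/T", "G/T"),
                     i3 = c("G/G", "T/T", "T/T"), i4 = c("A/A", "C/C", "G/G")))
  ), individuals)
}

test_that("triallelic and many-SNP loci are dropped as hand-enumerated", {
  cat0 <- make_filter_catalog()
  filt <- filter_catalog(cat0, min_depth = 0, max_snps = 2,
                         min_individuals = 1)
  expect_setequal(catalog_locus_ids(filt), c(1L, 2L))  # 3,4 triallelic; 5 has 3 SNPs
  # with the SNP-count rule relaxed, only the triallelic loci go
  filt2 <- filter_catalog(cat0, min_depth = 0, max_snps = 100,
                          min_individuals = 1)
  expect_setequal(catalog_locus_ids(filt2), c(1L, 2L, 5L))
  # with the biallelic rule off too, everything stays
  filt3 <- filter_catalog(cat0, min_depth = 0, max_snps = 100,
                          min_individuals = 1, biallelic_only = FALSE)
  expect_setequal(catalog_locus_ids(filt3), 1:5)
})

test_that("depth masking feeds the presence rule in order", {
  individuals <- c("i1", "i2", "i3")
  depths <- list(list(i1 = 10, i2 = 3, i3 = 10))
  cat0 <- build_toy_catalog(list(
    list(pos = 10, geno = list(i1 = "A/A", i2 = "A/G", i3 = "G/G"))
  ), individuals, depths = depths)
  # i2 is masked at depth 3, so presence drops to 2
  expect_equal(n_loci(filter_catalog(cat0, min_depth = 5, min_individuals = 2)), 1)
  expect_equal(n_loci(filter_catalog(cat0, min_depth = 5, min_individuals = 3)), 0)
  kept <- filter_catalog(cat0, min_depth = 5, min_individuals = 2)
  expect_false(kept$called[kept$individual == "i2"])
  expect_true(is.na(kept$allele1[kept$individual == "i2"]))
})

test_that("identity filter settings change nothing", {
  cat0 <- make_filter_catalog()
  filt <- filter_catalog(cat0, min_depth = 0,
                         max_snps = attr(cat0, "locus_length"),
                         min_individuals = 1, biallelic_only = FALSE)
  expect_identical(tibble::as_tibble(filt), tibble::as_tibble(cat0))
})

test_that("filtering is idempotent and monotone in min_individuals", {
  sim <- simulate_dataset(scenario_17(), study_design_rad(n_loci = 300),
                          NULL, seed = 21)
  cat0 <- apply_observation_model(sim$catalog, observation_model(12, 3, 5),
                                  seed = 22)
  f9 <- filter_catalog(cat0, min_individuals = 9)
  f9_again <- filter_catalog(f9, min_individuals = 9)
  expect_identical(tibble::as_tibble(f9), tibble::as_tibble(f9_again))

  f11 <- filter_catalog(cat0, min_individuals = 11)
  expect_true(all(catalog_locus_ids(f11) %in% catalog_locus_ids(f9)))
  expect_lte(n_loci(f11), n_loci(f9))

  expect_error(filter_catalog(cat0, min_individuals = 18),
               "min_individuals")
})

test_that("catalog TSV round trip is lossless", {
  sim <- simulate_dataset(scenario_17(), study_design_rad(n_loci = 30),
                          NULL, seed = 30)
  cat0 <- apply_observation_model(sim$catalog, observation_model(10, 3, 5),
                                  seed = 31)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_genotype_matrix(cat0, path, format = "tsv")
  back <- read_catalog(path)
  expect_identical(tibble::as_tibble(back), tibble::as_tibble(cat0))
  expect_identical(catalog_individuals(back), catalog_individuals(cat0))
})

test_that("genepop-like export matches a hand-written golden file", {
  individuals <- c("i1", "i2")
  cat0 <- build_toy_catalog(list(
    list(pos = 10, geno = list(i1 = "A/G", i2 = "./.")),
    list(pos = c(2, 7), geno = list(i1 = c("C/C", "T/T"), i2 = c("C/T", "T/G")))
  ), individuals)
  path <- withr::local_tempfile(fileext = ".gen")
  export_genotype_matrix(cat0, path, format = "genepop")
  expect_identical(readLines(path), c(
    "radscape genepop-like export",
    "L1_10", "L2_2", "L2_7",
    "POP",
    "i1 , 0103 0202 0404",
    "i2 , 0000 0204 0403"
  ))
})

test_that("haplotype collapsing conserves counts and merges N compatibly", {
  aln <- tibble::tibble(
    individual = paste0("x", 1:4),
    sequence = rep("ACGTACGT", 4)
  )
  tab <- collapse_haplotypes(aln)
  expect_equal(nrow(tab$haplotypes), 1)
  expect_equal(tab$haplotypes$n, 4L)

  # N matches any base; merged toward the compatible called haplotype
  aln2 <- tibble::tibble(
    individual = c("a", "b"),
    sequence = c("ACGT", "ACNT")
  )
  tab2 <- collapse_haplotypes(aln2)
  expect_equal(nrow(tab2$haplotypes), 1)
  expect_equal(tab2$haplotypes$sequence, "ACGT")
  expect_equal(tab2$haplotypes$n, 2L)

  # with two compatible called haplotypes, the lexicographically smallest wins
  aln3 <- tibble::tibble(
    individual = c("a", "b", "c"),
    sequence = c("ACGT", "ACTT", "ACNT")
  )
  tab3 <- collapse_haplotypes(aln3)
  assign_c <- tab3$assignment$haplotype[tab3$assignment$individual == "c"]
  seq_c <- tab3$haplotypes$sequence[tab3$haplotypes$haplotype == assign_c]
  expect_equal(seq_c, "ACGT")

  # an incompatible N-sequence stays its own haplotype
  aln4 <- tibble::tibble(
    individual = c("a", "b"),
    sequence = c("ACGT", "TTNT")
  )
  expect_equal(nrow(collapse_haplotypes(aln4)$haplotypes), 2)
})

test_that("352 sequences planted from 24 haplotypes collapse back to 24", {
  set.seed(77)
  base <- strsplit(paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                         collapse = ""), "")[[1]]
  # 24 planted haplotypes, each a distinct single-site variant of the base
  planted <- vapply(1:24, function(k) {
    s <- base
    s[k] <- setdiff(c("A", "C", "G", "T"), s[k])[1 + k %% 3]
    paste(s, collapse = "")
  }, character(1))
  counts <- as.vector(stats::rmultinom(1, 352 - 24, rep(1 / 24, 24))) + 1
  seqs <- rep(planted, counts)
  aln <- tibble::tibble(individual = sprintf("s%03d", 1:352),
                        sequence = sample(seqs))
  tab <- collapse_haplotypes(aln)
  expect_equal(nrow(tab$haplotypes), 24)
  expect_equal(sum(tab$haplotypes$n), 352L)
})

test_that("population map round trips through TSV", {
  pm <- study_popmap("rad")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_popmap(pm, path)
  expect_equal(read_popmap(path), pm)
})
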