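#' Simulate a RAD catalog and a mitochondrial alignment under one scenario
#'
#' RAD loci are unlinked: each locus gets an independent coalescent genealogy
#' of the 2n sampled lineages (two per diploid individual), finite-sites
#' mutations on its variable sites, and the two lineages of an individual are
#' paired into an unphased genotype. The mitochondrial alignment is a single
#' haploid locus (one maternal lineage per individual) simulated at a quarter
#' of the nuclear effective size, returned as full-length sequences with an
#' invariant backbone drawn from the design's base composition. Loci with
#' more than two alleles are retained here; filtering is a downstream step
#' ([filter_catalog()]).
#'
#' @param scn a [scenario()] object
#' @param rad_design,mito_design [sample_design()]s (either may be `NULL` to
#'   skip that marker); regions sampled by a design must exist in the
#'   scenario
#' @param seed optional integer seed
#' @param rad_popmap,mito_popmap optional population maps; defaults assign
#'   each region a single sampling site
#' @return list with elements `catalog` (a [locus_catalog()] or `NULL`),
#'   `alignment` (tibble `individual`, `region`, `sequence`, or `NULL`),
#'   `rad_popmap`, `mito_popmap`
#' @examples
#' scn <- scenario_17()
#' sim <- simulate_dataset(scn, study_design_rad(n_loci = 20), NULL, seed = 1)
#' n_loci(sim$catalog)
#' @export
simulate_dataset <- function(scn, rad_design, mito_design = NULL, seed = NULL,
                             rad_popmap = NULL, mito_popmap = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_scenario(scn)
  out <- list(catalog = NULL, alignment = NULL,
              rad_popmap = NULL, mito_popmap = NULL)
  if (!is.null(rad_design)) {
    check_design_regions(rad_design, scn)
    out$catalog <- sim_rad_catalog(scn, rad_design)
    out$rad_popmap <- rad_popmap %||% default_popmap(rad_design)
  }
  if (!is.null(mito_design)) {
    check_design_regions(mito_design, scn)
    out$alignment <- sim_mito_alignment(scn, mito_design)
    out$mito_popmap <- mito_popmap %||% default_popmap(mito_design)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_design_regions <- function(design, scn) {
  missing_regions <- setdiff(names(design$samples), scn$leaves)
  if (length(missing_regions)) {
    stop("design samples region(s) absent from scenario: ",
         paste(missing_regions, collapse = ", "), call. = FALSE)
  }
}

default_popmap <- function(design) {
  tibble::tibble(
    individual = design_individual_labels(design),
    site = paste0(rep(names(design$samples), design$samples), "_s1"),
    region = rep(names(design$samples), design$samples)
  )
}

design_individual_labels <- function(design) {
  unlist(purrr::map(names(design$samples), function(r) {
    sprintf("%s_%02d", r, seq_len(design$samples[[r]]))
  }), use.names = FALSE)
}

# simulate all RAD loci in one C++ call and assemble the tidy catalog
sim_rad_catalog <- function(scn, design) {
  lineages <- design_lineages(design)
  tip_region <- rep(names(lineages), lineages)
  inds <- design_individual_labels(design)
  n_ind <- length(inds)
  l_var <- design_l_var(design)
  mat <- cpp_sim_loci(
    n_loci = design$n_loci,
    sample_region = match(tip_region, scn$leaves) - 1L,
    n_labels = length(scn$leaves),
    two_ne = as.numeric(design_two_ne(design, scn)),
    ev_time = scn$events$time,
    ev_from = match(scn$events$derived, scn$leaves) - 1L,
    ev_to = match(scn$events$ancestral, scn$leaves) - 1L,
    L_var = l_var, mu = design$mutation_rate, base_freq = design$base_freq
  )
  # site positions within each locus for the variable-site mask
  site_pos <- t(vapply(seq_len(design$n_loci), function(i) {
    sort(sample.int(design$locus_length, l_var)) - 1L
  }, integer(l_var)))

  poly <- if (ncol(mat) > 0) {
    matrixStats_colmax(mat) != matrixStats_colmin(mat)
  } else logical(0)
  col_locus <- rep(seq_len(design$n_loci), each = l_var)

  a1_rows <- seq(1, 2 * n_ind, by = 2)
  a2_rows <- a1_rows + 1

  poly_cols <- which(poly)
  if (length(poly_cols)) {
    snp <- tibble::tibble(
      locus_id = rep(col_locus[poly_cols], each = n_ind),
      pos = rep(site_pos[cbind(col_locus[poly_cols],
                               ((poly_cols - 1) %% l_var) + 1)], each = n_ind),
      individual = rep(inds, length(poly_cols)),
      allele1 = BASES[as.vector(mat[a1_rows, poly_cols, drop = FALSE])],
      allele2 = BASES[as.vector(mat[a2_rows, poly_cols, drop = FALSE])],
      depth = NA_real_, called = TRUE
    )
  } else {
    snp <- NULL
  }
  mono_loci <- setdiff(seq_len(design$n_loci), unique(col_locus[poly_cols]))
  mono <- if (length(mono_loci)) {
    tibble::tibble(
      locus_id = rep(mono_loci, each = n_ind),
      pos = NA_integer_,
      individual = rep(inds, length(mono_loci)),
      allele1 = NA_character_, allele2 = NA_character_,
      depth = NA_real_, called = TRUE
    )
  } else NULL
  g <- dplyr::bind_rows(snp, mono) |>
    dplyr::arrange(.data$locus_id, .data$pos, .data$individual)
  locus_catalog(g, inds, design$locus_length)
}

matrixStats_colmax <- function(m) apply(m, 2, max)
matrixStats_colmin <- function(m) apply(m, 2, min)

sim_mito_alignment <- function(scn, design) {
  lineages <- design_lineages(design)
  tip_region <- rep(names(lineages), lineages)
  inds <- design_individual_labels(design)
  l_var <- design_l_var(design)
  mat <- cpp_sim_loci(
    n_loci = 1L,
    sample_region = match(tip_region, scn$leaves) - 1L,
    n_labels = length(scn$leaves),
    two_ne = as.numeric(design_two_ne(design, scn)),
    ev_time = scn$events$time,
    ev_from = match(scn$events$derived, scn$leaves) - 1L,
    ev_to = match(scn$events$ancestral, scn$leaves) - 1L,
    L_var = l_var, mu = design$mutation_rate, base_freq = design$base_freq
  )
  backbone <- sample(4L, design$locus_length, replace = TRUE,
                     prob = design$base_freq)
  var_pos <- sort(sample.int(design$locus_length, l_var))
  full <- matrix(rep(backbone, each = length(inds)), nrow = length(inds))
  full[, var_pos] <- mat
  tibble::tibble(
    individual = inds,
    region = tip_region,
    sequence = matrix_to_seqs(full)
  )
}

#' Describe a read-depth observation model
#'
#' Per-genotype read depths are negative-binomial with the given mean and
#' dispersion (`size` parameter; larger is less overdispersed); genotypes
#' sequenced below `min_depth` are masked as missing when the model is
#' applied.
#'
#' @param depth_mean expected read depth per genotype
#' @param depth_dispersion negative-binomial size parameter; `Inf` makes the
#'   depth deterministic at `depth_mean`
#' @param min_depth minimum depth for a genotype call
#' @return an object of class `observation_model`
#' @export
observation_model <- function(depth_mean = 20, depth_dispersion = 5,
                              min_depth = 5) {
  stopifnot(depth_mean >= 0, depth_dispersion > 0, min_depth >= 0)
  structure(list(depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 min_depth = min_depth),
            class = "observation_model")
}

#' Overlay read depths and missingness on a simulated catalog
#'
#' Draws one negative-binomial depth per locus x individual (all SNPs of a
#' locus share their stack's depth) and masks genotypes below the model's
#' `min_depth`. With `min_depth = 0` the genotypes are unchanged.
#'
#' @param catalog a [locus_catalog()]
#' @param model an [observation_model()]
#' @param seed optional integer seed
#' @return the catalog with `depth` filled in and sub-threshold genotypes
#'   masked
#' @export
apply_observation_model <- function(catalog, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- tibble::as_tibble(catalog)
  pairs <- dplyr::distinct(g, .data$locus_id, .data$individual)
  pairs$depth <- if (is.infinite(model$depth_dispersion)) {
    rep(model$depth_mean, nrow(pairs))
  } else {
    rnbinom(nrow(pairs), size = model$depth_dispersion,
            mu = model$depth_mean)
  }
  g$depth <- NULL
  g <- dplyr::left_join(g, pairs, by = c("locus_id", "individual"))
  g$called <- g$called & g$depth >= model$min_depth
  g$allele1[!g$called] <- NA_character_
  g$allele2[!g$called] <- NA_character_
  rewrap_catalog(g[, c("locus_id", "pos", "individual", "allele1", "allele2",
                       "depth", "called")], catalog)
}

#' Simulate a catalog with planted per-individual heterozygosity rates
#'
#' A direct (non-coalescent) generator for saturation experiments: every
#' locus carries one biallelic SNP, and each individual is heterozygous at
#' it independently with its planted rate, otherwise homozygous for one of
#' the two alleles at random. Useful for planting a known heterozygosity
#' contrast between individuals or regions.
#'
#' @param het_rates named numeric vector, per-individual probability that a
#'   SNP genotype is heterozygous
#' @param n_loci number of loci
#' @param locus_length locus length in bp
#' @param seed optional integer seed
#' @return a [locus_catalog()]
#' @export
simulate_planted_catalog <- function(het_rates, n_loci = 1000,
                                     locus_length = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inds <- names(het_rates)
  n_ind <- length(inds)
  het <- matrix(runif(n_loci * n_ind) < rep(het_rates, each = n_loci),
                nrow = n_loci)
  hom_allele <- matrix(sample(c("A", "G"), n_loci * n_ind, replace = TRUE),
                       nrow = n_loci)
  g <- tibble::tibble(
    locus_id = rep(seq_len(n_loci), n_ind),
    pos = 0L,
    individual = rep(inds, each = n_loci),
    allele1 = ifelse(as.vector(het), "A", as.vector(hom_allele)),
    allele2 = ifelse(as.vector(het), "G", as.vector(hom_allele)),
    depth = NA_real_, called = TRUE
  )
  locus_catalog(g, inds, locus_length)
}
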