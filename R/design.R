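#' Describe a sampling and mutation design for one marker
#'
#' Bundles everything the simulator needs to know about a marker: how many
#' individuals are sampled per region, locus count and length, the per-site
#' per-generation mutation rate, and the fraction of sites held invariant.
#' RAD loci are diploid (two lineages per individual); the mitochondrial
#' marker is haploid (one maternal lineage per individual) and coalesces at a
#' quarter of the nuclear effective size.
#'
#' @param marker `"rad"` or `"mito"`
#' @param samples named integer vector: individuals sampled per region
#' @param n_loci number of unlinked loci (forced to 1 for `"mito"`)
#' @param locus_length locus length in bp (default 100 for RAD, 658 for mito)
#' @param mutation_rate per-site per-generation mutation rate (defaults:
#'   1e-7 RAD, 1e-6 mito)
#' @param invariant_fraction proportion of sites held invariant (defaults:
#'   0.98 RAD, 0.95 mito)
#' @param base_freq nucleotide frequencies (A, C, G, T) used for ancestral
#'   states; defaults to the empirical composition of the study alignment
#' @return an object of class `sample_design`
#' @examples
#' sample_design("rad", samples = c(BF = 10, MC = 2, PY = 2, CM = 3),
#'               n_loci = 200)
#' @export
sample_design <- function(marker = c("rad", "mito"), samples, n_loci = 1,
                          locus_length = NULL, mutation_rate = NULL,
                          invariant_fraction = NULL,
                          base_freq = c(0.269, 0.228, 0.225, 0.278)) {
  marker <- match.arg(marker)
  stopifnot(is.numeric(samples), !is.null(names(samples)), all(samples > 0))
  if (is.null(locus_length)) locus_length <- if (marker == "rad") 100L else 658L
  if (is.null(mutation_rate)) mutation_rate <- if (marker == "rad") 1e-7 else 1e-6
  if (is.null(invariant_fraction)) {
    invariant_fraction <- if (marker == "rad") 0.98 else 0.95
  }
  if (invariant_fraction < 0 || invariant_fraction > 1) {
    stop("invariant_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (marker == "mito") n_loci <- 1L
  base_freq <- base_freq / sum(base_freq)
  structure(
    list(
      marker = marker,
      samples = samples,
      n_loci = as.integer(n_loci),
      locus_length = as.integer(locus_length),
      mutation_rate = mutation_rate,
      invariant_fraction = invariant_fraction,
      base_freq = base_freq
    ),
    class = "sample_design"
  )
}

#' @export
print.sample_design <- function(x, ...) {
  cat("<sample_design> ", x$marker, "\n", sep = "")
  cat("  individuals: ",
      paste(sprintf("%s=%d", names(x$samples), x$samples), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  loci: %d x %d bp, mu = %g, invariant = %g\n",
              x$n_loci, x$locus_length, x$mutation_rate, x$invariant_fraction))
  invisible(x)
}

# haploid lineages sampled per region (2x individuals for diploid RAD)
design_lineages <- function(design) {
  mult <- if (design$marker == "rad") 2L else 1L
  design$samples * mult
}

# variable sites per locus
design_l_var <- function(design) {
  as.integer(round(design$locus_length * (1 - design$invariant_fraction)))
}

# marker-scaled 2*Ne per scenario population (mito: quarter effective size)
design_two_ne <- function(design, scn) {
  scale <- if (design$marker == "mito") 0.25 else 1
  2 * scn$sizes[scn$leaves] * scale
}

#' Study-shaped sampling designs and population maps
#'
#' `study_design_rad()` and `study_design_mito()` return [sample_design()]s
#' matching the four-region study layout: 17 diploid individuals (Black
#' Forest 10, Massif Central 2, Pyrenees 2, Cantabrian Mountains 3) genotyped
#' at ~100-bp RAD loci, and 352 haploid CO1-like sequences (219/7/61/65) of
#' 658 bp. `study_popmap()` returns the matching population map, distributing
#' individuals over 8 RAD sampling sites (3/1/2/2) or 26 mitochondrial sites
#' (13/1/5/7).
#'
#' @param n_loci number of RAD loci to simulate (default 12514, the size of
#'   the filtered study catalog)
#' @param marker `"rad"` or `"mito"`
#' @return a `sample_design`, or for `study_popmap()` a tibble with columns
#'   `individual`, `site`, `region`
#' @export
study_design_rad <- function(n_loci = 12514) {
  sample_design("rad", samples = c(BF = 10, MC = 2, PY = 2, CM = 3),
                n_loci = n_loci)
}

#' @rdname study_design_rad
#' @export
study_design_mito <- function() {
  sample_design("mito", samples = c(BF = 219, MC = 7, PY = 61, CM = 65))
}

#' @rdname study_design_rad
#' @export
study_popmap <- function(marker = c("rad", "mito")) {
  marker <- match.arg(marker)
  if (marker == "rad") {
    counts <- c(BF = 10, MC = 2, PY = 2, CM = 3)
    n_sites <- c(BF = 3, MC = 1, PY = 2, CM = 2)
  } else {
    counts <- c(BF = 219, MC = 7, PY = 61, CM = 65)
    n_sites <- c(BF = 13, MC = 1, PY = 5, CM = 7)
  }
  purrr::map_dfr(names(counts), function(r) {
    n <- counts[[r]]
    sites <- sprintf("%s_s%d", r, seq_len(n_sites[[r]]))
    tibble::tibble(
      individual = sprintf("%s_%02d", r, seq_len(n)),
      site = rep_len(sites, n),
      region = r
    )
  })
}

#' Read or write a population map
#'
#' A population map is a headerless three-column TSV mapping each individual
#' to its sampling site and region.
#'
#' @param path file path
#' @param popmap tibble with columns `individual`, `site`, `region`
#' @return `read_popmap()` returns a tibble with those columns
#' @export
read_popmap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("individual", "site", "region"))
  tibble::as_tibble(df)
}

#' @rdname read_popmap
#' @export
write_popmap <- function(popmap, path) {
  write.table(popmap[, c("individual", "site", "region")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
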