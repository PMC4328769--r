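#' Per-individual SNP heterozygosity
#'
#' The proportion of an individual's called SNP genotypes that are
#' heterozygous. With `per_locus = TRUE` the proportion is computed per locus
#' first (a locus counts as heterozygous when any of its SNPs is) and
#' averaged over called loci.
#'
#' @param catalog a [locus_catalog()]
#' @param per_locus compute per-locus rather than per-SNP heterozygosity
#' @return tibble with columns `individual`, `n_called`, `n_het`,
#'   `heterozygosity`; individuals with no called SNP genotype get `NA`
#' @export
individual_heterozygosity <- function(catalog, per_locus = FALSE) {
  g <- tibble::as_tibble(catalog) |>
    dplyr::filter(!is.na(.data$pos), .data$called)
  if (per_locus) {
    g <- g |>
      dplyr::group_by(.data$individual, .data$locus_id) |>
      dplyr::summarise(het = any(.data$allele1 != .data$allele2),
                       .groups = "drop")
  } else {
    g <- g |> dplyr::mutate(het = .data$allele1 != .data$allele2)
  }
  res <- g |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(n_called = dplyr::n(), n_het = sum(.data$het),
                     .groups = "drop") |>
    dplyr::mutate(heterozygosity = .data$n_het / .data$n_called)
  all_inds <- tibble::tibble(individual = catalog_individuals(catalog))
  dplyr::left_join(all_inds, res, by = "individual")
}

#' Per-region heterozygosity summary
#'
#' Individual heterozygosities averaged within regions; the standard
#' deviation is taken over the member individuals.
#'
#' @param catalog a [locus_catalog()]
#' @param popmap population map tibble (`individual`, `site`, `region`)
#' @param per_locus see [individual_heterozygosity()]
#' @return tibble with columns `region`, `n_individuals`, `mean_het`,
#'   `sd_het`
#' @export
region_heterozygosity <- function(catalog, popmap, per_locus = FALSE) {
  individual_heterozygosity(catalog, per_locus = per_locus) |>
    dplyr::inner_join(popmap[, c("individual", "region")], by = "individual") |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      mean_het = mean(.data$heterozygosity, na.rm = TRUE),
      sd_het = sd(.data$heterozygosity, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Nei's unbiased haplotype diversity per region
#'
#' `H = n/(n-1) * (1 - sum p_i^2)` with `p_i` the haplotype frequencies in
#' the region's sample of `n` sequences. Regions with fewer than two
#' sequences get `NA`.
#'
#' @param table a [collapse_haplotypes()] result
#' @param region optional single region to report
#' @return tibble with columns `region`, `n`, `n_haplotypes`, `H`
#' @export
haplotype_diversity <- function(table, region = NULL) {
  counts <- haplotype_counts(table)
  if (!is.null(region)) counts <- counts[counts$region %in% region, ]
  counts |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      H = {
        tot <- sum(.data$n)
        if (tot < 2) NA_real_ else {
          tot / (tot - 1) * (1 - sum((.data$n / tot)^2))
        }
      },
      n = sum(.data$n),
      n_haplotypes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("region", "n", "n_haplotypes", "H")
}

#' Nucleotide diversity per region
#'
#' The mean proportion of differing sites over all `n(n-1)/2` sequence pairs
#' within a region, with pairwise deletion of missing data.
#'
#' @param alignment tibble with `individual`, `sequence` and optionally
#'   `region`
#' @param popmap optional population map supplying regions; with neither,
#'   all sequences form one sample
#' @return tibble with columns `region`, `n`, `pi`
#' @export
nucleotide_diversity <- function(alignment, popmap = NULL) {
  region <- if ("region" %in% names(alignment)) {
    alignment$region
  } else if (!is.null(popmap)) {
    popmap$region[match(alignment$individual, popmap$individual)]
  } else {
    rep("all", nrow(alignment))
  }
  mat <- seqs_to_matrix(setNames(alignment$sequence, alignment$individual))
  purrr::map_dfr(unique(region), function(r) {
    rows <- which(region == r)
    if (length(rows) < 2) {
      return(tibble::tibble(region = r, n = length(rows), pi = NA_real_))
    }
    pd <- cpp_pair_diffs(mat[rows, , drop = FALSE])
    ut <- upper.tri(pd$diff)
    ok <- ut & pd$comp > 0
    tibble::tibble(region = r, n = length(rows),
                   pi = mean(pd$diff[ok] / pd$comp[ok]))
  })
}

# Tajima's D core on an integer state matrix (rows = one region's sequences).
# Sites with missing data in the region are dropped for both S and pi.
tajima_core <- function(mat) {
  n <- nrow(mat)
  if (n < 2) return(list(n = n, S = NA_integer_, pi = NA_real_, D = NA_real_))
  complete <- colSums(is.na(mat)) == 0
  sub <- mat[, complete, drop = FALSE]
  S <- if (ncol(sub) == 0) 0 else {
    sum(colSums(sub != sub[rep(1L, n), , drop = FALSE]) > 0)
  }
  pd <- cpp_pair_diffs(sub)
  pi_hat <- mean(pd$diff[upper.tri(pd$diff)])
  if (S == 0) return(list(n = n, S = 0L, pi = pi_hat, D = NA_real_))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(n = n, S = as.integer(S), pi = pi_hat, D = D)
}

#' Tajima's D per region
#'
#' Standard Tajima (1989) D computed from the mean pairwise difference and
#' the number of segregating sites, with the a1..e2 constants from the
#' region's sample size. For a [locus_catalog()], locus SNP columns are
#' pooled (unlinked loci concatenated); sites with missing data within the
#' region are excluded from both S and the pairwise differences. Regions
#' with no segregating site get `D = NA` (the statistic is undefined).
#'
#' @param x a [locus_catalog()] or an alignment tibble (`individual`,
#'   `sequence`)
#' @param popmap population map; optional for alignments carrying a `region`
#'   column
#' @return tibble with columns `region`, `n`, `S`, `pi`, `D` (`n` counts
#'   sequences: 2 per individual for a diploid catalog)
#' @export
tajimas_d <- function(x, popmap = NULL) {
  h <- haplotype_state_matrix(x, popmap)
  purrr::map_dfr(unique(h$region), function(r) {
    res <- tajima_core(h$mat[h$region == r, , drop = FALSE])
    tibble::tibble(region = r, n = res$n, S = res$S, pi = res$pi, D = res$D)
  })
}

# Build the pooled haplotype state matrix (rows = haploid sequences) and the
# per-row region labels for either marker type.
# For catalogs, each individual contributes two pseudo-haplotype rows with
# arbitrary within-locus phase (allele1 row, allele2 row).
haplotype_state_matrix <- function(x, popmap = NULL) {
  if (inherits(x, "locus_catalog")) {
    g <- tibble::as_tibble(x) |> dplyr::filter(!is.na(.data$pos))
    inds <- catalog_individuals(x)
    snps <- g |> dplyr::distinct(.data$locus_id, .data$pos) |>
      dplyr::arrange(.data$locus_id, .data$pos)
    n_snp <- nrow(snps)
    key <- match(paste(g$locus_id, g$pos), paste(snps$locus_id, snps$pos))
    row1 <- match(g$individual, inds) * 2L - 1L
    mat <- matrix(NA_integer_, 2 * length(inds), n_snp)
    mat[cbind(row1, key)] <- encode_bases(g$allele1)
    mat[cbind(row1 + 1L, key)] <- encode_bases(g$allele2)
    rownames(mat) <- paste0(rep(inds, each = 2), c("_a", "_b"))
    region <- if (is.null(popmap)) rep("all", length(inds)) else {
      popmap$region[match(inds, popmap$individual)]
    }
    list(mat = mat, region = rep(region, each = 2),
         individual = rep(inds, each = 2), diploid = TRUE,
         col_locus = snps$locus_id)
  } else {
    mat <- seqs_to_matrix(setNames(x$sequence, x$individual))
    region <- if ("region" %in% names(x)) {
      x$region
    } else if (!is.null(popmap)) {
      popmap$region[match(x$individual, popmap$individual)]
    } else {
      rep("all", nrow(x))
    }
    list(mat = mat, region = region, individual = x$individual,
         diploid = FALSE, col_locus = rep(1L, ncol(mat)))
  }
}
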