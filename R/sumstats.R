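#' DIYABC-style summary-statistic vector
#'
#' Computes, for every region: (1) the mean and (2) the variance of pairwise
#' differences among the region's haploid sequences (two pseudo-haplotypes
#' per diploid individual, locus SNP columns pooled, pairwise deletion of
#' missing data), (3) Tajima's D and (4) the number of segregating sites
#' (sites complete within the region); and for every unordered region pair:
#' (5) the mean of pairwise differences within (w, the average of the two
#' within-region means), (6) the mean of pairwise differences between (b)
#' and (7) F_ST (Weir-Cockerham for diploid catalogs, Hudson's `1 - Hw/Hb`
#' for haploid alignments). Region blocks follow the popmap's region order;
#' with `R` regions the flattened vector has `4R + 3 R(R-1)/2` entries
#' (34 for four regions). Statistics undefined on the data (e.g. Tajima's D
#' without a segregating site) are `NA` sentinels.
#'
#' @param x a [locus_catalog()] or alignment tibble (`individual`,
#'   `sequence`, optionally `region`)
#' @param popmap population map (`individual`, `region`)
#' @return an object of class `summary_stat_vector`: a tibble with columns
#'   `stat`, `scope`, `value`, in fixed order
#' @export
summary_stats <- function(x, popmap) {
  h <- haplotype_state_matrix(x, popmap)
  regions <- unique(popmap$region)
  regions <- regions[regions %in% h$region]
  if (length(regions) < 2) stop("need at least two regions", call. = FALSE)
  stat_vector_from_state(h, regions)
}

# numeric core: named stat vector straight from a haplotype state list
# (kept free of tibble overhead; the ABC reference-table builder calls this
# tens of thousands of times)
stat_vector_core <- function(h, regions) {
  pd <- cpp_pair_diffs(h$mat)
  rows <- lapply(regions, function(r) which(h$region == r))
  names(rows) <- regions
  region_stats <- c("mean_pairwise_diff", "var_pairwise_diff", "tajima_d",
                    "segregating_sites")
  pair_stats <- c("mean_pairwise_diff_w", "mean_pairwise_diff_b", "fst")

  within_mean <- setNames(rep(NA_real_, length(regions)), regions)
  out <- numeric(0)
  for (r in regions) {
    ri <- rows[[r]]
    vals <- rep(NA_real_, 4)
    if (length(ri) >= 2) {
      dd <- pd$diff[ri, ri][upper.tri(diag(length(ri)))]
      tj <- tajima_core(h$mat[ri, , drop = FALSE])
      within_mean[r] <- mean(dd)
      vals <- c(mean(dd), if (length(dd) > 1) var(dd) else NA_real_,
                tj$D, as.numeric(tj$S))
    }
    out <- c(out, setNames(vals, paste(r, region_stats, sep = ".")))
  }
  if (h$diploid) {
    odd <- seq(1, nrow(h$mat), by = 2)
    A1 <- h$mat[odd, , drop = FALSE]
    A2 <- h$mat[odd + 1, , drop = FALSE]
    ind_region <- h$region[odd]
  }
  for (pr in utils::combn(regions, 2, simplify = FALSE)) {
    ra <- rows[[pr[1]]]; rb <- rows[[pr[2]]]
    b <- mean(pd$diff[ra, rb, drop = FALSE])
    w <- mean(within_mean[pr])
    fst <- if (h$diploid) {
      keep <- ind_region %in% pr
      wc_theta_core(A1[keep, , drop = FALSE], A2[keep, , drop = FALSE],
                    ind_region[keep])
    } else {
      hudson_fst_core(h$mat, ra, rb, distance = "sequence")
    }
    out <- c(out, setNames(c(w, b, fst),
                           paste(paste(pr, collapse = ":"), pair_stats,
                                 sep = ".")))
  }
  out
}

# tidy wrapper around the numeric core
stat_vector_from_state <- function(h, regions) {
  vec <- stat_vector_core(h, regions)
  parts <- strsplit(names(vec), ".", fixed = TRUE)
  out <- tibble::tibble(
    stat = vapply(parts, `[`, character(1), 2),
    scope = vapply(parts, `[`, character(1), 1),
    value = unname(vec)
  )
  structure(out, class = c("summary_stat_vector", class(tibble::tibble())))
}

#' Flatten a summary-statistic table to a named numeric vector
#' @param stats a [summary_stats()] result
#' @return named numeric vector in the table's fixed order
#' @export
as_stat_vector <- function(stats) {
  setNames(stats$value, paste(stats$scope, stats$stat, sep = "."))
}
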