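# Weir & Cockerham (1984) theta for one pair of populations, summed over all
# SNPs and alleles (ratio of sums). A1/A2: individuals x sites integer state
# matrices (NA = missing); pop: factor with two levels per individual row.
wc_theta_core <- function(A1, A2, pop) {
  r <- 2
  lv <- unique(pop)
  called <- !is.na(A1) & !is.na(A2)
  het <- called & (A1 != A2)
  num <- 0
  den <- 0
  idx <- lapply(lv, function(p) which(pop == p))
  n1 <- colSums(called[idx[[1]], , drop = FALSE])
  n2 <- colSums(called[idx[[2]], , drop = FALSE])
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 3
  if (!any(ok)) return(NA_real_)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  for (s in 1:4) {
    is_s1 <- (A1 == s) & called
    is_s2 <- (A2 == s) & called
    cnt1 <- colSums(is_s1[idx[[1]], , drop = FALSE]) +
      colSums(is_s2[idx[[1]], , drop = FALSE])
    cnt2 <- colSums(is_s1[idx[[2]], , drop = FALSE]) +
      colSums(is_s2[idx[[2]], , drop = FALSE])
    p1 <- cnt1 / (2 * n1)
    p2 <- cnt2 / (2 * n2)
    hs <- het & ((A1 == s) | (A2 == s))
    h1 <- colSums(hs[idx[[1]], , drop = FALSE]) / n1
    h2 <- colSums(hs[idx[[2]], , drop = FALSE]) / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    use <- ok & !is.na(a)
    num <- num + sum(a[use])
    den <- den + sum((a + b + cc)[use])
  }
  if (den == 0) NA_real_ else num / den
}

# Hudson-style F_ST = 1 - Hw/Hb for one pair of regions from a haploid state
# matrix. distance = "sequence" uses per-site p-distances; "haplotype" scores
# any difference as 1 (frequency-based haplotype F_ST).
hudson_fst_core <- function(mat, rows_a, rows_b, distance = "sequence") {
  pd <- cpp_pair_diffs(mat[c(rows_a, rows_b), , drop = FALSE])
  d <- pd$diff / ifelse(pd$comp == 0, NA, pd$comp)
  if (distance == "haplotype") d <- (d > 0) * 1
  na <- length(rows_a)
  nb <- length(rows_b)
  ia <- seq_len(na)
  ib <- na + seq_len(nb)
  within <- c(d[ia, ia][upper.tri(diag(na))], d[ib, ib][upper.tri(diag(nb))])
  between <- d[ia, ib]
  hw <- mean(within, na.rm = TRUE)
  hb <- mean(between, na.rm = TRUE)
  if (!is.finite(hb) || hb == 0) return(NA_real_)
  1 - hw / hb
}

#' Pairwise F_ST between regions
#'
#' For diploid RAD catalogs the default is the Weir-Cockerham (1984) theta,
#' accumulated over all SNPs and alleles as a ratio of sums; negative
#' estimates are reported as computed. For haploid sequence alignments
#' Hudson's estimator `1 - Hw/Hb` is available on per-site p-distances
#' (`"hudson"`) or on haplotype identity (`"haplotype"`, a frequency-based
#' haplotype F_ST). Data monomorphic across a pair give `NA`. Significance
#' can be assessed by permuting individuals across the two regions.
#'
#' @param x a [locus_catalog()] or alignment tibble
#' @param popmap population map (`individual`, `region`)
#' @param estimator `"wc"`, `"hudson"` or `"haplotype"`; defaults to `"wc"`
#'   for catalogs and `"hudson"` for alignments
#' @param permutations number of label permutations for a p-value (0 = none)
#' @param seed optional integer seed for the permutations
#' @return tibble with columns `region_a`, `region_b`, `fst` and, with
#'   permutations, `p_value`
#' @export
pairwise_fst <- function(x, popmap, estimator = NULL, permutations = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(estimator)) {
    estimator <- if (inherits(x, "locus_catalog")) "wc" else "hudson"
  }
  estimator <- match.arg(estimator, c("wc", "hudson", "haplotype"))
  h <- haplotype_state_matrix(x, popmap)
  if (estimator == "wc" && !h$diploid) {
    stop("the Weir-Cockerham estimator needs diploid catalog data",
         call. = FALSE)
  }
  regions <- unique(h$region[!is.na(h$region)])
  if (length(regions) < 2) stop("need at least two regions", call. = FALSE)
  pairs <- utils::combn(regions, 2, simplify = FALSE)

  one_fst <- function(region_of_row) {
    function(ra, rb) {
      if (estimator == "wc") {
        odd <- seq(1, nrow(h$mat), by = 2)
        A1 <- h$mat[odd, , drop = FALSE]
        A2 <- h$mat[odd + 1, , drop = FALSE]
        ind_region <- region_of_row[odd]
        keep <- ind_region %in% c(ra, rb)
        wc_theta_core(A1[keep, , drop = FALSE], A2[keep, , drop = FALSE],
                      ind_region[keep])
      } else {
        hudson_fst_core(h$mat, which(region_of_row == ra),
                        which(region_of_row == rb), distance = estimator)
      }
    }
  }
  observed <- one_fst(h$region)

  purrr::map_dfr(pairs, function(pr) {
    fst <- observed(pr[1], pr[2])
    out <- tibble::tibble(region_a = pr[1], region_b = pr[2], fst = fst)
    if (permutations > 0 && is.finite(fst)) {
      # permute individuals (both rows of a diploid individual move together)
      ind <- unique(h$individual[h$region %in% pr])
      ind_region <- h$region[match(ind, h$individual)]
      perm_vals <- vapply(seq_len(permutations), function(i) {
        shuffled <- sample(ind_region)
        perm_region <- h$region
        perm_region[h$individual %in% ind] <-
          shuffled[match(h$individual[h$individual %in% ind], ind)]
        one_fst(perm_region)(pr[1], pr[2])
      }, numeric(1))
      out$p_value <- (sum(perm_vals >= fst, na.rm = TRUE) + 1) /
        (permutations + 1)
    }
    out
  })
}

#' Combined F_ST matrix for two marker sets
#'
#' Arranges two [pairwise_fst()] results as one square matrix with the first
#' marker's values above the diagonal and the second's below (the
#' conventional two-marker presentation).
#'
#' @param upper,lower tibbles from [pairwise_fst()] (e.g. RAD above,
#'   mitochondrial below)
#' @param regions optional region ordering
#' @return a numeric matrix with `NA` diagonal
#' @export
fst_matrix <- function(upper, lower, regions = NULL) {
  if (is.null(regions)) {
    regions <- unique(c(upper$region_a, upper$region_b))
  }
  m <- matrix(NA_real_, length(regions), length(regions),
              dimnames = list(regions, regions))
  for (i in seq_len(nrow(upper))) {
    m[upper$region_a[i], upper$region_b[i]] <- upper$fst[i]
  }
  for (i in seq_len(nrow(lower))) {
    m[lower$region_b[i], lower$region_a[i]] <- lower$fst[i]
  }
  m
}
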