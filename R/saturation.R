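#' Subsample loci uniformly without replacement
#'
#' @param catalog a [locus_catalog()]
#' @param L number of loci to draw
#' @param seed optional integer seed
#' @return a `locus_catalog` restricted to the sampled loci (original ids
#'   kept)
#' @export
subsample_loci <- function(catalog, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- catalog_locus_ids(catalog)
  if (L > length(ids)) {
    stop("cannot draw ", L, " loci from a catalog of ", length(ids),
         call. = FALSE)
  }
  keep <- sample(ids, L)
  rewrap_catalog(tibble::as_tibble(catalog)[catalog$locus_id %in% keep, ],
                 catalog)
}

# per-locus x individual counts of called and heterozygous SNP genotypes
het_count_matrices <- function(catalog) {
  g <- tibble::as_tibble(catalog) |>
    dplyr::filter(!is.na(.data$pos), .data$called)
  inds <- catalog_individuals(catalog)
  ids <- catalog_locus_ids(catalog)
  called <- matrix(0L, length(ids), length(inds),
                   dimnames = list(ids, inds))
  het <- called
  li <- match(g$locus_id, ids)
  ii <- match(g$individual, inds)
  for (k in seq_len(nrow(g))) {
    called[li[k], ii[k]] <- called[li[k], ii[k]] + 1L
    if (g$allele1[k] != g$allele2[k]) het[li[k], ii[k]] <- het[li[k], ii[k]] + 1L
  }
  list(called = called, het = het, individuals = inds, ids = ids)
}

#' Heterozygosity saturation curves under locus subsampling
#'
#' Mirrors the bootstrap permutation test for how many loci are needed for
#' stable heterozygosity estimates: for each subsample size `L` on the grid
#' and each replicate, per-SNP heterozygosity is recomputed on a random locus
#' subsample, and the mean and standard deviation over replicates are
#' reported per region (or per tracked individual). Within one replicate the
#' subsamples are nested prefixes of a single random locus permutation — at
#' each `L` this is still a uniform draw without replacement, and it makes
#' 1000 replicates cheap.
#'
#' The convergence point is the smallest grid `L` from which on, at every
#' larger grid point, the replicate SD stays below `sd_fraction` of the mean
#' (region level), or the mean +/- SD bands of the two tracked individuals no
#' longer overlap (individual level).
#'
#' @param catalog a [locus_catalog()]
#' @param popmap population map (required for `level = "region"`)
#' @param grid increasing locus counts (default 10 to 1000 in steps of 10)
#' @param reps replicates per grid point (defaults: 1000 region, 100
#'   individual)
#' @param level `"region"` or `"individual"`
#' @param track for individual level, the two individuals to follow; default
#'   picks the highest- and lowest-heterozygosity individuals
#' @param sd_fraction region-level convergence tolerance (SD as a fraction
#'   of the mean)
#' @param seed optional integer seed
#' @return a tibble of class `saturation_curve` with columns `L`, `group`,
#'   `mean`, `sd`; attributes `level`, `reps` and `convergence` (named
#'   integer vector per group or pair, `NA` when never reached)
#' @export
het_saturation <- function(catalog, popmap = NULL,
                           grid = seq(10, 1000, by = 10), reps = NULL,
                           level = c("region", "individual"), track = NULL,
                           sd_fraction = 0.1, seed = NULL) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reps)) reps <- if (level == "region") 1000L else 100L
  cm <- het_count_matrices(catalog)
  n <- nrow(cm$called)
  if (max(grid) > n) stop("grid exceeds the catalog's locus count", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }

  if (level == "region") {
    if (is.null(popmap)) stop("region level needs a popmap", call. = FALSE)
    region <- popmap$region[match(cm$individuals, popmap$individual)]
    groups <- unique(region[!is.na(region)])
    if (!length(groups)) stop("no region contains catalog individuals", call. = FALSE)
    member <- lapply(groups, function(r) which(region == r))
  } else {
    if (is.null(track)) {
      full <- colSums(cm$het) / pmax(colSums(cm$called), 1)
      track <- cm$individuals[c(which.max(full), which.min(full))]
    }
    if (length(track) != 2) stop("track must name two individuals", call. = FALSE)
    groups <- track
    member <- lapply(track, function(ind) match(ind, cm$individuals))
  }

  vals <- array(NA_real_, c(length(grid), length(groups), reps))
  for (rep_i in seq_len(reps)) {
    perm <- sample.int(n)
    cum_called <- apply(cm$called[perm, , drop = FALSE], 2, cumsum)
    cum_het <- apply(cm$het[perm, , drop = FALSE], 2, cumsum)
    het_ind <- cum_het[grid, , drop = FALSE] / cum_called[grid, , drop = FALSE]
    for (gi in seq_along(groups)) {
      vals[, gi, rep_i] <- rowMeans(het_ind[, member[[gi]], drop = FALSE],
                                    na.rm = TRUE)
    }
  }
  curve <- purrr::map_dfr(seq_along(groups), function(gi) {
    tibble::tibble(
      L = grid, group = groups[gi],
      mean = apply(vals[, gi, , drop = FALSE], 1, mean, na.rm = TRUE),
      sd = apply(vals[, gi, , drop = FALSE], 1, sd, na.rm = TRUE)
    )
  })

  convergence <- if (level == "region") {
    vapply(groups, function(g) {
      cc <- curve[curve$group == g, ]
      first_sustained(cc$sd <= sd_fraction * cc$mean, grid)
    }, numeric(1))
  } else {
    c1 <- curve[curve$group == groups[1], ]
    c2 <- curve[curve$group == groups[2], ]
    lo <- ifelse(c1$mean >= c2$mean, c1$mean - c1$sd, c2$mean - c2$sd)
    hi <- ifelse(c1$mean >= c2$mean, c2$mean + c2$sd, c1$mean + c1$sd)
    setNames(first_sustained(lo > hi, grid), paste(groups, collapse = ":"))
  }

  structure(curve,
            level = level, reps = reps, convergence = convergence,
            class = c("saturation_curve", class(tibble::tibble())))
}

# smallest grid value from which the condition holds at every later point
first_sustained <- function(ok, grid) {
  ok[is.na(ok)] <- FALSE
  holds_on <- rev(cumprod(rev(ok))) > 0
  if (!any(holds_on)) return(NA_real_)
  grid[which(holds_on)[1]]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via ape) on a symmetric
#' zero-diagonal distance matrix; the result is unrooted.
#'
#' @param d symmetric numeric matrix with zero diagonal and row names
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric", call. = FALSE)
  ape::nj(d)
}

# number of nontrivial splits (internal edges) of an unrooted tree
n_splits <- function(tree) {
  tree <- ape::unroot(tree)
  sum(tree$edge[, 2] > ape::Ntip(tree))
}

#' Rescaled Robinson-Foulds distance to a constraint tree
#'
#' The symmetric-difference metric `d` counts the nontrivial splits present
#' in exactly one of the two trees. With `b` splits in the test tree
#' (`n - 3` when binary) and `k` in the reference, the theoretical extremes
#' are `d_min = b - k` (reference fully contained) and `d_max = b + k` (no
#' shared split), and the returned value is `(d - d_min)/(d_max - d_min)`,
#' in `[0, 1]`.
#'
#' @param tree test tree (`phylo`)
#' @param reference constraint tree (`phylo`, typically multifurcating) on
#'   the same leaf set
#' @return rescaled distance in `[0, 1]`
#' @export
rescaled_rf <- function(tree, reference) {
  if (!setequal(tree$tip.label, reference$tip.label)) {
    stop("trees must share the same leaf set", call. = FALSE)
  }
  b <- n_splits(tree)
  k <- n_splits(reference)
  if (k == 0) {
    stop("reference tree is a star: rescaling is degenerate (d_min = d_max)",
         call. = FALSE)
  }
  # RF.dist warns when the reference is multifurcating; that is exactly the
  # intended use here
  d <- suppressMessages(suppressWarnings(
    phangorn::RF.dist(ape::unroot(tree), ape::unroot(reference))
  ))
  (d - (b - k)) / (2 * k)
}

#' Constraint tree for the four-region study design
#'
#' Builds the partially resolved reference topology used for topology
#' saturation: the Black Forest individuals form a clade that joins the two
#' Massif Central individuals (northern group), and the Pyrenees and
#' Cantabrian Mountains individuals form southern clades —
#' `(((BF), MC1, MC2), ((PY), (CM)))`, four nontrivial splits on 17 leaves.
#'
#' @param popmap population map with regions `BF`, `MC`, `PY`, `CM`
#' @return a multifurcating `phylo` constraint tree
#' @export
study_constraint_tree <- function(popmap) {
  grp <- split(popmap$individual, popmap$region)
  paste_clade <- function(x) paste0("(", paste(x, collapse = ","), ")")
  txt <- sprintf("((%s,%s),(%s,%s));",
                 paste_clade(grp$BF), paste(grp$MC, collapse = ","),
                 paste_clade(grp$PY), paste_clade(grp$CM))
  ape::read.tree(text = txt)
}

#' Topology saturation under locus subsampling
#'
#' For each grid size `L` and replicate: draw `L` loci, concatenate their
#' SNP columns into one pseudo-haplotype per individual (heterozygous sites
#' resolved to the catalog-wide major allele), compute pairwise K2P
#' distances with pairwise deletion, build a neighbor-joining tree and
#' measure its [rescaled_rf()] distance to the reference constraint tree.
#' Individuals without data in a subsample are dropped from that replicate's
#' tree (and the reference pruned accordingly); such replicates are counted
#' in the `n_dropped` attribute. The convergence point is the smallest grid
#' `L` whose mean distance is below `threshold` there and at every larger
#' grid point.
#'
#' @param catalog a [locus_catalog()]
#' @param popmap population map (used only to order individuals)
#' @param reference constraint tree (`phylo`) on the catalog's individuals
#' @param grid increasing locus counts (default 100 to 5000 in steps of 100)
#' @param reps replicates per grid point
#' @param threshold convergence threshold on the mean rescaled distance
#' @param seed optional integer seed
#' @return list with `curve` (a `saturation_curve` tibble: `L`, `group`,
#'   `mean`, `sd`) and `convergence_L` (`NA` when never reached)
#' @export
topology_saturation <- function(catalog, popmap, reference,
                                grid = seq(100, 5000, by = 100), reps = 100,
                                threshold = 0.025, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_splits(reference) == 0) {
    stop("reference tree is a star: rescaling is degenerate (d_min = d_max)",
         call. = FALSE)
  }
  ph <- pseudo_haplotypes(catalog)
  if (max(grid) > length(ph$locus_cols)) {
    stop("grid exceeds the catalog's locus count", call. = FALSE)
  }
  n_loci_total <- length(ph$locus_cols)
  n_dropped <- 0L
  vals <- matrix(NA_real_, length(grid), reps)
  for (li in seq_along(grid)) {
    for (rep_i in seq_len(reps)) {
      pick <- sample.int(n_loci_total, grid[li])
      cols <- unlist(ph$locus_cols[pick], use.names = FALSE)
      sub <- ph$mat[, cols, drop = FALSE]
      has_data <- rowSums(!is.na(sub)) > 0
      if (sum(has_data) < 4) { n_dropped <- n_dropped + 1L; next }
      if (!all(has_data)) n_dropped <- n_dropped + 1L
      dmat <- k2p_matrix(sub[has_data, , drop = FALSE])
      if (any(!is.finite(dmat))) next
      tr <- nj_tree(dmat)
      ref <- reference
      if (!all(has_data)) {
        ref <- ape::drop.tip(ref, rownames(ph$mat)[!has_data])
        if (n_splits(ref) == 0) next
      }
      vals[li, rep_i] <- rescaled_rf(tr, ref)
    }
  }
  curve <- tibble::tibble(
    L = grid, group = "topology",
    mean = rowMeans(vals, na.rm = TRUE),
    sd = apply(vals, 1, sd, na.rm = TRUE)
  )
  curve <- structure(curve, level = "topology", reps = reps,
                     n_dropped = n_dropped,
                     class = c("saturation_curve", class(tibble::tibble())))
  list(curve = curve,
       convergence_L = first_sustained(curve$mean < threshold, grid))
}

# one pseudo-haplotype sequence per individual: heterozygous SNPs resolved
# to the catalog-wide major allele (ties to the smallest state code)
pseudo_haplotypes <- function(catalog) {
  h <- haplotype_state_matrix(catalog)
  a1 <- h$mat[seq(1, nrow(h$mat), 2), , drop = FALSE]
  a2 <- h$mat[seq(2, nrow(h$mat), 2), , drop = FALSE]
  major <- vapply(seq_len(ncol(a1)), function(j) {
    tab <- tabulate(c(a1[, j], a2[, j]), 4)
    which.max(tab)  # ties -> smallest code
  }, integer(1))
  het <- !is.na(a1) & !is.na(a2) & a1 != a2
  out <- a1
  out[het] <- rep(major, each = nrow(a1))[het]
  rownames(out) <- unique(h$individual)
  # keep monomorphic loci as empty column sets: they are legitimate draws
  # that contribute no SNP columns
  ids <- catalog_locus_ids(catalog)
  list(mat = out, locus_cols = split(seq_along(h$col_locus),
                                     factor(h$col_locus, levels = ids)))
}
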