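#' Draw one coalescent genealogy under a divergence scenario
#'
#' Simulates a rooted binary genealogy of all sampled lineages backward in
#' time. Within a population, pairs of lineages coalesce at rate
#' `1/(2 N_e)` per generation (with `N_e` the marker's effective size:
#' the diploid size for RAD loci, a quarter of it for the mitochondrial
#' marker); lineages in different populations cannot coalesce before the
#' populations merge.
#'
#' @param scn a [scenario()] object
#' @param design a [sample_design()]; lineage counts are twice the individual
#'   counts for the diploid RAD marker
#' @param seed optional integer seed for reproducibility
#' @return an object of class `gene_tree` with elements `parent` (1-based
#'   parent index per node, `NA` at the root), `node_time` (generations),
#'   `tip_label`, `tip_region` and `n_tip`; tips are nodes `1..n_tip`
#' @examples
#' scn <- scenario("pair", data.frame(time = 1e4, derived = "B", ancestral = "A"),
#'                 sizes = c(A = 500, B = 500))
#' tr <- draw_coalescent_tree(scn, sample_design("rad", c(A = 2, B = 2), 1), seed = 1)
#' ape::read.tree(text = gene_tree_newick(tr))
#' @export
draw_coalescent_tree <- function(scn, design, seed = NULL) {
  validate_scenario(scn)
  if (!is.null(seed)) set.seed(seed)
  missing_regions <- setdiff(names(design$samples), scn$leaves)
  if (length(missing_regions)) {
    stop("design samples region(s) absent from scenario: ",
         paste(missing_regions, collapse = ", "), call. = FALSE)
  }
  lineages <- design_lineages(design)
  tip_region <- rep(names(lineages), lineages)
  mult <- if (design$marker == "rad") 2L else 1L
  tip_label <- unlist(purrr::map(names(design$samples), function(r) {
    inds <- sprintf("%s_%02d", r, seq_len(design$samples[[r]]))
    if (mult == 2L) paste0(rep(inds, each = 2), c("_a", "_b")) else inds
  }), use.names = FALSE)
  res <- cpp_coal_tree(
    sample_region = match(tip_region, scn$leaves) - 1L,
    n_labels = length(scn$leaves),
    two_ne = as.numeric(design_two_ne(design, scn)),
    ev_time = scn$events$time,
    ev_from = match(scn$events$derived, scn$leaves) - 1L,
    ev_to = match(scn$events$ancestral, scn$leaves) - 1L
  )
  structure(
    list(
      parent = ifelse(res$parent < 0, NA_integer_, res$parent + 1L),
      node_time = res$node_time,
      tip_label = tip_label,
      tip_region = tip_region,
      n_tip = res$n_tip
    ),
    class = "gene_tree"
  )
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("<gene_tree> ", x$n_tip, " tips, TMRCA = ",
      format(max(x$node_time)), " generations\n", sep = "")
  invisible(x)
}

#' Newick representation of a gene tree
#'
#' @param tree a `gene_tree` from [draw_coalescent_tree()]
#' @param digits significant digits for branch lengths
#' @return a Newick string (rooted, with branch lengths in generations)
#' @export
gene_tree_newick <- function(tree, digits = 8) {
  n_node <- length(tree$parent)
  children <- vector("list", n_node)
  for (v in seq_len(n_node - 1)) {
    p <- tree$parent[v]
    children[[p]] <- c(children[[p]], v)
  }
  fmt <- function(v) {
    if (v <= tree$n_tip) {
      tree$tip_label[v]
    } else {
      paste0("(", paste(vapply(children[[v]], function(ch) {
        len <- tree$node_time[v] - tree$node_time[ch]
        paste0(fmt(ch), ":", format(len, digits = digits))
      }, character(1)), collapse = ","), ")")
    }
  }
  paste0(fmt(n_node), ";")
}

#' Convert a gene tree to an ape phylo object
#' @param tree a `gene_tree`
#' @return an object of class `phylo`
#' @export
as_phylo_gene_tree <- function(tree) {
  ape::read.tree(text = gene_tree_newick(tree))
}

#' Node heights (times) of the internal nodes joining two regions
#' @noRd
cross_region_node_times <- function(tree) {
  n_node <- length(tree$parent)
  # regions carried by each node's descendant tips
  below <- vector("list", n_node)
  for (v in seq_len(tree$n_tip)) below[[v]] <- tree$tip_region[v]
  for (v in (tree$n_tip + 1):n_node) below[[v]] <- character()
  ord <- order(tree$node_time[seq_len(n_node - 1)])  # children before parents
  for (v in seq_len(n_node - 1)) {
    p <- tree$parent[v]
    below[[p]] <- union(below[[p]], below[[v]])
  }
  internal <- (tree$n_tip + 1):n_node
  multi <- vapply(internal, function(v) length(below[[v]]) > 1, logical(1))
  tree$node_time[internal[multi]]
}

#' Drop finite-sites mutations on a genealogy
#'
#' Overlays 4-state mutations on the variable sites of one locus: the number
#' of mutations on a branch is Poisson with mean
#' `mutation_rate * L_variable * branch_length`, where
#' `L_variable = locus_length * (1 - invariant_fraction)`; each mutation hits
#' a uniformly chosen variable site and substitutes one of the other three
#' bases. The invariant-site mask is fixed per locus, so returned sequences
#' contain only the variable sites.
#'
#' @param tree a `gene_tree` from [draw_coalescent_tree()]
#' @param design the [sample_design()] supplying `mutation_rate`,
#'   `locus_length`, `invariant_fraction` and base composition
#' @param seed optional integer seed
#' @return tibble with columns `label`, `region`, `sequence` (variable sites
#'   only, A/C/G/T)
#' @export
mutate_locus <- function(tree, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  l_var <- design_l_var(design)
  parent0 <- ifelse(is.na(tree$parent), -1L, tree$parent - 1L)
  mat <- cpp_mutate_tree(parent0, tree$node_time, tree$n_tip, l_var,
                         design$mutation_rate, design$base_freq)
  tibble::tibble(
    label = tree$tip_label,
    region = tree$tip_region,
    sequence = if (l_var > 0) matrix_to_seqs(mat) else rep("", tree$n_tip)
  )
}
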