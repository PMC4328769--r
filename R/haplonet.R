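#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps `j` for which a connection between
#' two haplotypes is non-homoplastic with probability at least `alpha`. The
#' probability of parsimony is derived from a pair coalescent with
#' finite-sites Jukes-Cantor mutation: conditional on the coalescence time,
#' the number of hits per site is Poisson, the per-site scaled mutation rate
#' is estimated from the observed divergence `j/m` by method of moments, and
#' the probability that all `j` observed differences are single hits (and no
#' site is hit twice) is integrated over the exponential coalescence-time
#' distribution. Single-step connections are always accepted. The
#' probability decreases in `j`, so the limit is the last `j` still above
#' `alpha`.
#'
#' @param sequence_length alignment length `m` in bp
#' @param alpha required probability of parsimony (0 < alpha < 1)
#' @param max_j search ceiling
#' @return the connection limit in steps (>= 1)
#' @examples
#' parsimony_connection_limit(658, 0.95)
#' @export
parsimony_connection_limit <- function(sequence_length, alpha = 0.95,
                                       max_j = 100L) {
  stopifnot(sequence_length > 0, alpha > 0, alpha < 1)
  j <- 1L
  while (j < max_j &&
         parsimony_probability(j + 1L, sequence_length) >= alpha) {
    j <- j + 1L
  }
  j
}

#' Probability that a j-step connection is parsimonious
#'
#' See [parsimony_connection_limit()] for the model. Exposed for diagnostic
#' use; `parsimony_probability(1, m)` is 1 by the single-step convention.
#'
#' @param j number of observed differences (steps)
#' @param m alignment length in bp
#' @return probability in (0, 1]
#' @export
parsimony_probability <- function(j, m) {
  stopifnot(j >= 0, m > 0, j <= m)
  if (j <= 1) return(1)
  x <- j / m
  if (x >= 0.75) return(0)
  theta <- x / (1 - 4 * x / 3)  # method-of-moments per-site rate
  # numerator: all j differing sites are single hits, no other site hit;
  # closed form from integrating lambda^j exp(-m lambda) over T ~ Exp(1)
  log_num <- j * log(theta) + lgamma(j + 1) - (j + 1) * log(m * theta + 1)
  # denominator: probability of observing exactly this difference pattern
  den <- integrate(function(t) {
    lam <- theta * t
    u <- exp(-4 * lam / 3)
    exp(j * log(0.75 * (1 - u)) + (m - j) * log(0.25 + 0.75 * u) - t)
  }, 0, Inf, rel.tol = 1e-10)$value
  min(1, exp(log_num) / den)
}

#' Build a statistical-parsimony haplotype network
#'
#' A minimum-spanning network over haplotype Hamming distances (pairwise
#' deletion for N): distance classes are processed in increasing order and
#' every edge of a class that links two components still separate before the
#' class is kept, so alternative equal-length connections are retained.
#' Edges longer than the connection limit are excluded, which may leave the
#' network disconnected; `force_connect = TRUE` afterwards joins remaining
#' components with their minimal over-limit links (flagged in the edge
#' table). Each edge of `s` steps implies `s - 1` unsampled intermediate
#' haplotypes.
#'
#' @param table a [collapse_haplotypes()] result
#' @param max_steps connection limit in steps; default derives it from the
#'   alignment length via [parsimony_connection_limit()] (`Inf` disables the
#'   limit)
#' @param alpha probability level for the derived limit
#' @param force_connect connect over-limit components anyway
#' @return an object of class `haplotype_network`: list with `nodes`
#'   (tibble `haplotype`, `n`, `frequency`), `node_regions` (per-region
#'   counts), `edges` (tibble `from`, `to`, `steps`, `intermediates`,
#'   `over_limit`) and `max_steps`
#' @export
build_parsimony_network <- function(table, max_steps = NULL, alpha = 0.95,
                                    force_connect = FALSE) {
  haps <- table$haplotypes
  if (nrow(haps) == 0) stop("empty haplotype table", call. = FALSE)
  if (is.null(max_steps)) {
    max_steps <- parsimony_connection_limit(nchar(haps$sequence[1]), alpha)
  }
  n <- nrow(haps)
  d <- hamming_matrix(setNames(haps$sequence, haps$haplotype))

  edges <- NULL
  if (n > 1) {
    comp <- seq_len(n)  # union-find forest
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    all_pairs <- which(upper.tri(d) & !is.na(d), arr.ind = TRUE)
    steps <- d[all_pairs]
    keep_classes <- sort(unique(steps[steps >= 1]))
    for (s in keep_classes) {
      over <- s > max_steps
      if (over && !force_connect) break
      in_class <- all_pairs[steps == s, , drop = FALSE]
      roots <- cbind(vapply(in_class[, 1], find, integer(1)),
                     vapply(in_class[, 2], find, integer(1)))
      new_link <- roots[, 1] != roots[, 2]
      if (any(new_link)) {
        edges <- rbind(edges, cbind(in_class[new_link, , drop = FALSE],
                                    s, as.integer(over)))
        for (k in which(new_link)) {
          comp[find(in_class[k, 1])] <- find(in_class[k, 2])
        }
      }
    }
  }
  edges_tbl <- if (is.null(edges)) {
    tibble::tibble(from = character(), to = character(), steps = integer(),
                   intermediates = integer(), over_limit = logical())
  } else {
    tibble::tibble(
      from = haps$haplotype[edges[, 1]],
      to = haps$haplotype[edges[, 2]],
      steps = as.integer(edges[, 3]),
      intermediates = as.integer(edges[, 3]) - 1L,
      over_limit = edges[, 4] == 1
    )
  }
  nodes <- haps |>
    dplyr::mutate(frequency = .data$n / sum(.data$n)) |>
    dplyr::select("haplotype", "n", "frequency")
  structure(
    list(nodes = nodes, node_regions = haplotype_counts(table),
         edges = edges_tbl, max_steps = max_steps),
    class = "haplotype_network"
  )
}

#' @export
print.haplotype_network <- function(x, ...) {
  g <- network_igraph(x)
  cat(sprintf(
    "<haplotype_network> %d haplotypes, %d edges (limit %s steps), %d component(s)\n",
    nrow(x$nodes), nrow(x$edges), format(x$max_steps),
    igraph::components(g)$no))
  invisible(x)
}

#' Number of connected components of a haplotype network
#' @param network a [build_parsimony_network()] result
#' @return integer
#' @export
network_components <- function(network) {
  igraph::components(network_igraph(network))$no
}

#' Export a haplotype network
#'
#' Writes the node and edge tables as TSV (`<stem>_nodes.tsv`,
#' `<stem>_edges.tsv`) or the graph as GraphML.
#'
#' @param network a [build_parsimony_network()] result
#' @param stem output path stem (TSV) or file path (GraphML)
#' @param format `"tsv"` or `"graphml"`
#' @return the written path(s), invisibly
#' @export
write_network <- function(network, stem, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    paths <- paste0(stem, c("_nodes.tsv", "_edges.tsv"))
    write.table(network$nodes, paths[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(network$edges, paths[2], sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(paths))
  }
  g <- network_igraph(network)
  igraph::V(g)$n <- network$nodes$n
  if (nrow(network$edges)) {
    igraph::E(g)$steps <- network$edges$steps
  }
  igraph::write_graph(g, stem, format = "graphml")
  invisible(stem)
}

network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = network$nodes$haplotype
  )
}
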