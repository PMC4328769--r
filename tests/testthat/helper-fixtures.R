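# fixtures and independent oracles shared across the suite

# hand-assembled catalog from a compact genotype specification:
# loci = list(list(pos = c(...), geno = list(ind = c("A/G", ...))))
# "./." marks a missing genotype; depth optional per locus x individual
build_toy_catalog <- function(loci, individuals, locus_length = 100L,
                              depths = NULL) {
  rows <- list()
  for (li in seq_along(loci)) {
    locus <- loci[[li]]
    pos <- locus$pos
    for (ind in individuals) {
      gt <- locus$geno[[ind]]
      dep <- if (is.null(depths)) NA_real_ else depths[[li]][[ind]]
      if (is.null(gt)) gt <- rep("./.", max(1, length(pos)))
      if (length(pos) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          locus_id = li, pos = NA_integer_, individual = ind,
          allele1 = NA_character_, allele2 = NA_character_,
          depth = dep, called = gt[1] != "./."
        )
      } else {
        for (k in seq_along(pos)) {
          parts <- strsplit(gt[k], "/", fixed = TRUE)[[1]]
          miss <- gt[k] == "./."
          rows[[length(rows) + 1]] <- data.frame(
            locus_id = li, pos = pos[k], individual = ind,
            allele1 = if (miss) NA_character_ else parts[1],
            allele2 = if (miss) NA_character_ else parts[2],
            depth = dep, called = !miss
          )
        }
      }
    }
  }
  locus_catalog(do.call(rbind, rows), individuals, locus_length)
}

# single-population scenario (no events)
one_pop_scenario <- function(ne = 1000, label = "A") {
  scenario("one",
           events = data.frame(time = numeric(0), derived = character(0),
                               ancestral = character(0)),
           sizes = setNames(ne, label), leaves = label)
}

two_pop_scenario <- function(t = 1e4, ne = c(A = 1000, B = 1000)) {
  scenario("two", events = data.frame(time = t, derived = "B",
                                      ancestral = "A"),
           sizes = ne)
}

# brute-force nucleotide diversity: mean pairwise proportion over all pairs
oracle_pi <- function(sequences) {
  n <- length(sequences)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- strsplit(sequences[i], "")[[1]]
      b <- strsplit(sequences[j], "")[[1]]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
    }
  }
  mean(vals)
}

# brute-force Tajima's D from first principles (complete data)
oracle_tajima_d <- function(sequences) {
  n <- length(sequences)
  mat <- do.call(rbind, strsplit(sequences, ""))
  S <- sum(apply(mat, 2, function(col) length(unique(col)) > 1))
  pairs <- combn(n, 2)
  pi_hat <- mean(apply(pairs, 2, function(p) sum(mat[p[1], ] != mat[p[2], ])))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# brute-force nontrivial splits of an unrooted phylo tree, as canonical
# leaf-set strings (side not containing the alphabetically first leaf name)
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  n <- ape::Ntip(tree)
  internal <- setdiff(unique(tree$edge[, 1]), seq_len(n))
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, function(k) if (k <= n) tree$tip.label[k] else desc(k)))
  }
  splits <- character(0)
  for (node in internal) {
    below <- sort(desc(node))
    if (length(below) <= 1 || length(below) >= n - 1) next
    side <- if (anchor %in% below) sort(setdiff(tips, below)) else below
    splits <- c(splits, paste(side, collapse = "|"))
  }
  unique(splits)
}

# brute-force rescaled symmetric difference from enumerated splits
oracle_rescaled_rf <- function(tree, reference) {
  st <- oracle_splits(tree)
  sr <- oracle_splits(reference)
  d <- length(setdiff(st, sr)) + length(setdiff(sr, st))
  b <- length(st)
  k <- length(sr)
  (d - (b - k)) / (2 * k)
}

# random binary coalescent-shaped tree on given labels
random_tree <- function(labels) {
  ape::rtree(length(labels), tip.label = sample(labels))
}
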