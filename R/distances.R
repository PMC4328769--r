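#' Uncorrected p-distance between two aligned sequences
#'
#' Counts substitutions over the sites where both sequences carry a called
#' base (pairwise deletion of N and gaps) and reports the proportion of
#' differing sites.
#'
#' @param seq_a,seq_b equal-length sequence strings
#' @return tibble with columns `substitutions`, `sites`, `proportion`
#' @examples
#' p_distance(strrep("A", 658), paste0(strrep("A", 655), "CCC"))
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- encode_bases(strsplit(toupper(seq_a), "")[[1]])
  b <- encode_bases(strsplit(toupper(seq_b), "")[[1]])
  if (length(a) != length(b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) stop("no comparable sites between sequences", call. = FALSE)
  subs <- sum(a[both] != b[both])
  tibble::tibble(substitutions = subs, sites = sum(both),
                 proportion = subs / sum(both))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Corrects separately for transitions (P: A<->G, C<->T) and transversions
#' (Q) over the comparable sites:
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`. Saturated pairs for which
#' the logarithm is undefined are flagged with an infinite distance.
#'
#' @param seq_a,seq_b equal-length sequence strings
#' @return the K2P distance (substitutions per site), possibly `Inf`
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- encode_bases(strsplit(toupper(seq_a), "")[[1]])
  b <- encode_bases(strsplit(toupper(seq_b), "")[[1]])
  if (length(a) != length(b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  both <- which(!is.na(a) & !is.na(b))
  if (!length(both)) stop("no comparable sites between sequences", call. = FALSE)
  k2p_from_counts(a[both], b[both])
}

# K2P from two integer state vectors (1=A,2=C,3=G,4=T), no missing values
k2p_from_counts <- function(a, b) {
  n <- length(a)
  diff <- a != b
  purine_a <- a == 1L | a == 3L
  purine_b <- b == 1L | b == 3L
  ts <- sum(diff & (purine_a == purine_b)) / n  # transition proportion P
  tv <- sum(diff & (purine_a != purine_b)) / n  # transversion proportion Q
  arg1 <- 1 - 2 * ts - tv
  arg2 <- 1 - 2 * tv
  if (arg1 <= 0 || arg2 <= 0) return(Inf)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Pairwise K2P distance matrix for an integer state matrix
#'
#' Rows are sequences; `NA` entries are treated as missing with pairwise
#' deletion. Pairs with no comparable sites get `NA`.
#' @noRd
k2p_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- which(!is.na(mat[i, ]) & !is.na(mat[j, ]))
      d[i, j] <- d[j, i] <- if (length(both)) {
        k2p_from_counts(mat[i, both], mat[j, both])
      } else NA_real_
    }
  }
  d
}

#' Hamming distance between haplotype sequences with pairwise deletion
#' @noRd
hamming_matrix <- function(sequences) {
  mat <- seqs_to_matrix(sequences)
  mat[is.na(mat)] <- 0L
  pd <- cpp_pair_diffs(mat)
  d <- pd$diff
  d[pd$comp == 0 & upper.tri(d)] <- NA_integer_
  d[pd$comp == 0 & lower.tri(d)] <- NA_integer_
  dimnames(d) <- list(names(sequences), names(sequences))
  d
}

#' Convert a p-distance to an age under a strict molecular clock
#'
#' With a clock rate expressed as percent divergence accumulating between two
#' lineages per million years (default 3.54, an insect mitochondrial CO1
#' rate), a pairwise distance of `rate` percent corresponds to 1 My of
#' separation.
#'
#' @param p_distance_percent uncorrected p-distance in percent (e.g. 1.77)
#' @param rate_percent_per_my clock rate, percent divergence per million years
#' @return divergence time in million years
#' @examples
#' strict_clock_time(3.54)  # 1 My
#' @export
strict_clock_time <- function(p_distance_percent, rate_percent_per_my = 3.54) {
  if (rate_percent_per_my <= 0) stop("clock rate must be > 0", call. = FALSE)
  if (any(p_distance_percent < 0)) stop("distance must be >= 0", call. = FALSE)
  p_distance_percent / rate_percent_per_my
}
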