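#' Read or write a haplotype alignment as FASTA
#'
#' Sequences are returned upper-case in a tidy tibble; all sequences must
#' have equal length (alphabet A, C, G, T, N, -).
#'
#' @param path FASTA file
#' @param alignment tibble with columns `individual` and `sequence`
#' @return `read_fasta()` returns a tibble with columns `individual`,
#'   `sequence`
#' @export
read_fasta <- function(path) {
  if (file.info(path)$size == 0) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("no sequences in FASTA file: ", path, call. = FALSE)
  seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  if (length(unique(nchar(seqs))) != 1) {
    stop("ragged alignment: sequences have unequal lengths", call. = FALSE)
  }
  tibble::tibble(individual = names(dna), sequence = unname(seqs))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(alignment, path) {
  lines <- as.vector(rbind(paste0(">", alignment$individual),
                           alignment$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Collapse an alignment into a haplotype table
#'
#' Identical sequences are merged into haplotypes. `N` is treated as missing
#' and matches any base: a sequence containing `N` is merged into a fully
#' called haplotype when compatible at every site; when several are
#' compatible, the lexicographically smallest representative sequence wins.
#' Sequences with `N` compatible with no fully called sequence stay distinct
#' haplotypes. Total counts are conserved.
#'
#' @param alignment tibble with columns `individual`, `sequence`, optionally
#'   `region`
#' @param popmap optional population map supplying `region`
#' @return an object of class `haplotype_table`: list with `haplotypes`
#'   (tibble `haplotype`, `sequence`, `n`) and `assignment` (tibble
#'   `individual`, `haplotype`, `region`)
#' @examples
#' aln <- tibble::tibble(individual = c("a", "b", "c"),
#'                       sequence = c("ACGT", "ACGT", "ACTT"))
#' collapse_haplotypes(aln)$haplotypes
#' @export
collapse_haplotypes <- function(alignment, popmap = NULL) {
  stopifnot(nrow(alignment) > 0)
  seqs <- toupper(alignment$sequence)
  if (length(unique(nchar(seqs))) != 1) {
    stop("ragged alignment: sequences have unequal lengths", call. = FALSE)
  }
  region <- if ("region" %in% names(alignment)) {
    alignment$region
  } else if (!is.null(popmap)) {
    popmap$region[match(alignment$individual, popmap$individual)]
  } else {
    rep(NA_character_, nrow(alignment))
  }

  complete <- !grepl("[^ACGT]", seqs)
  reps <- sort(unique(seqs[complete]))  # lexicographic tie-break
  assigned <- rep(NA_integer_, length(seqs))
  assigned[complete] <- match(seqs[complete], reps)

  if (any(!complete)) {
    rep_mat <- seqs_to_matrix(reps)
    for (i in which(!complete)) {
      s <- encode_bases(strsplit(seqs[i], "")[[1]])
      ok <- which(vapply(seq_along(reps), function(k) {
        both <- !is.na(s) & !is.na(rep_mat[k, ])
        all(s[both] == rep_mat[k, both])
      }, logical(1)))
      if (length(ok)) {
        assigned[i] <- ok[1]  # reps are sorted, so first match is smallest
      }
    }
    # incompatible N-sequences become their own haplotypes
    leftover <- which(is.na(assigned))
    if (length(leftover)) {
      extra <- sort(unique(seqs[leftover]))
      reps <- c(reps, extra)
      assigned[leftover] <- match(seqs[leftover], reps)
    }
  }

  used <- sort(unique(assigned))
  reps <- reps[used]
  assigned <- match(assigned, used)
  hap_id <- sprintf("H%02d", seq_along(reps))
  haplotypes <- tibble::tibble(
    haplotype = hap_id,
    sequence = reps,
    n = as.integer(tabulate(assigned, length(reps)))
  )
  assignment <- tibble::tibble(
    individual = alignment$individual,
    haplotype = hap_id[assigned],
    region = region
  )
  structure(list(haplotypes = haplotypes, assignment = assignment),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> %d haplotypes from %d sequences\n",
              nrow(x$haplotypes), nrow(x$assignment)))
  print(x$haplotypes, ...)
  invisible(x)
}

#' Haplotype counts per region
#' @param table a [collapse_haplotypes()] result
#' @return tibble with columns `haplotype`, `region`, `n`
#' @export
haplotype_counts <- function(table) {
  dplyr::count(table$assignment, .data$haplotype, .data$region, name = "n")
}
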