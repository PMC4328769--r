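#' Construct a RAD locus catalog
#'
#' A locus catalog is a tidy genotype table with one row per locus x
#' individual x SNP position. Loci without any SNP keep one row per
#' individual with `pos = NA` so that per-locus presence can still be
#' assessed. Coordinates are 0-based within the locus; genotypes are
#' unphased allele pairs; `called = FALSE` marks genotypes masked by depth
#' filtering or missing altogether (their alleles are `NA`).
#'
#' @param genotypes data frame with columns `locus_id`, `pos`, `individual`,
#'   `allele1`, `allele2`, `depth`, `called`
#' @param individuals ordered character vector of all genotyped individuals
#' @param locus_length locus length in bp (uniform across loci)
#' @return a tibble of class `locus_catalog`
#' @export
locus_catalog <- function(genotypes, individuals, locus_length = 100L) {
  g <- tibble::as_tibble(genotypes)
  needed <- c("locus_id", "pos", "individual", "allele1", "allele2",
              "depth", "called")
  missing_cols <- setdiff(needed, names(g))
  if (length(missing_cols)) {
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  g <- g[needed]
  bad <- setdiff(unique(g$individual), individuals)
  if (length(bad)) {
    stop("genotypes reference undeclared individual(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(g$pos) & (g$pos < 0 | g$pos >= locus_length))) {
    stop("SNP positions must lie in [0, locus_length)", call. = FALSE)
  }
  if (any(!is.na(g$depth) & g$depth < 0)) {
    stop("depths must be >= 0", call. = FALSE)
  }
  structure(g,
            individuals = individuals,
            locus_length = as.integer(locus_length),
            class = c("locus_catalog", class(tibble::tibble())))
}

#' @export
print.locus_catalog <- function(x, ...) {
  cat(sprintf("<locus_catalog> %d loci x %d individuals (%d bp loci)\n",
              n_loci(x), length(catalog_individuals(x)),
              attr(x, "locus_length")))
  NextMethod()
}

#' Catalog accessors
#'
#' `n_loci()` counts loci, `catalog_individuals()` returns the declared
#' individual labels, `catalog_locus_ids()` the locus identifiers.
#' @param catalog a [locus_catalog()]
#' @return integer or character vector
#' @export
n_loci <- function(catalog) length(unique(catalog$locus_id))

#' @rdname n_loci
#' @export
catalog_individuals <- function(catalog) attr(catalog, "individuals")

#' @rdname n_loci
#' @export
catalog_locus_ids <- function(catalog) unique(catalog$locus_id)

# rebuild the class/attributes after dplyr operations strip them
rewrap_catalog <- function(g, template) {
  locus_catalog(g, catalog_individuals(template), attr(template, "locus_length"))
}

#' Read or write a locus catalog as TSV
#'
#' The dialect is one row per locus x individual x SNP position with columns
#' `locus_id`, `pos`, `individual`, `allele1`, `allele2`, `depth`; masked or
#' absent genotypes carry `.` alleles, monomorphic loci one `pos = NA` row
#' per individual. The locus length is kept in a `#locus_length=` header
#' comment. The round trip is lossless for genotypes, depths and missingness.
#'
#' @param catalog a [locus_catalog()]
#' @param path file path
#' @return `read_catalog()` returns a `locus_catalog`
#' @export
write_catalog <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#locus_length=%d", attr(catalog, "locus_length")), con)
  writeLines(sprintf("#individuals=%s",
                     paste(catalog_individuals(catalog), collapse = ",")), con)
  out <- as.data.frame(catalog)
  # "." = missing genotype; "-" = present but invariant (monomorphic locus)
  filler <- ifelse(out$called, "-", ".")
  out$allele1 <- ifelse(out$called & !is.na(out$allele1), out$allele1, filler)
  out$allele2 <- ifelse(out$called & !is.na(out$allele2), out$allele2, filler)
  out$called <- NULL
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE, na = "NA"))
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  header <- readLines(path, n = 2)
  if (!grepl("^#locus_length=", header[1])) {
    stop("not a radscape catalog file (missing #locus_length header)",
         call. = FALSE)
  }
  locus_length <- as.integer(sub("^#locus_length=", "", header[1]))
  individuals <- strsplit(sub("^#individuals=", "", header[2]), ",")[[1]]
  g <- read.table(path, sep = "\t", header = TRUE, skip = 2,
                  stringsAsFactors = FALSE, na.strings = "NA",
                  colClasses = c("integer", "integer", "character",
                                 "character", "character", "numeric"))
  g$called <- g$allele1 != "." & !is.na(g$allele1)
  g$allele1[g$allele1 %in% c(".", "-") | is.na(g$allele1)] <- NA_character_
  g$allele2[g$allele2 %in% c(".", "-") | is.na(g$allele2)] <- NA_character_
  locus_catalog(g, individuals, locus_length)
}

#' Apply the study's catalog filtering rules
#'
#' Filtering proceeds in the fixed order: (1) genotypes sequenced below
#' `min_depth` are masked as missing; (2) loci are dropped when any SNP shows
#' more than two alleles among called genotypes (putative paralogs, with
#' `biallelic_only = TRUE`) or when more than `max_snps` sites remain
#' polymorphic; (3) loci called in fewer than `min_individuals` individuals
#' are dropped. The defaults reproduce a >=5x coverage, <=2 SNP, >=9-of-n
#' presence filter. Filtering is idempotent and raising `min_individuals`
#' can only shrink the retained set.
#'
#' @param catalog a [locus_catalog()]
#' @param min_depth minimum per-genotype read depth (genotypes with unknown
#'   depth are kept)
#' @param max_snps maximum number of polymorphic sites per retained locus
#' @param min_individuals minimum number of individuals with called data
#' @param biallelic_only drop loci with a SNP showing more than two alleles
#' @return the filtered `locus_catalog`
#' @export
filter_catalog <- function(catalog, min_depth = 5, max_snps = 2,
                           min_individuals = 9, biallelic_only = TRUE) {
  inds <- catalog_individuals(catalog)
  if (min_individuals > length(inds)) {
    stop("min_individuals exceeds the number of genotyped individuals",
         call. = FALSE)
  }
  g <- tibble::as_tibble(catalog)
  # (1) depth mask
  g$called <- g$called & (is.na(g$depth) | g$depth >= min_depth)
  g$allele1[!g$called] <- NA_character_
  g$allele2[!g$called] <- NA_character_

  # (2) allele and SNP-count rules on called genotypes
  site_stats <- g |>
    dplyr::filter(!is.na(.data$pos), .data$called) |>
    dplyr::group_by(.data$locus_id, .data$pos) |>
    dplyr::summarise(
      n_alleles = dplyr::n_distinct(c(.data$allele1, .data$allele2)),
      .groups = "drop"
    )
  locus_site <- site_stats |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      max_alleles = max(.data$n_alleles),
      n_snps = sum(.data$n_alleles >= 2),
      .groups = "drop"
    )
  drop_allele <- if (biallelic_only) {
    locus_site$locus_id[locus_site$max_alleles > 2]
  } else integer()
  drop_snps <- locus_site$locus_id[locus_site$n_snps > max_snps]

  # (3) presence after masking
  presence <- g |>
    dplyr::filter(.data$called) |>
    dplyr::distinct(.data$locus_id, .data$individual) |>
    dplyr::count(.data$locus_id, name = "n_present")
  all_loci <- unique(g$locus_id)
  present_n <- setNames(rep(0L, length(all_loci)), all_loci)
  present_n[as.character(presence$locus_id)] <- presence$n_present
  drop_presence <- all_loci[present_n[as.character(all_loci)] < min_individuals]

  drop <- unique(c(drop_allele, drop_snps, drop_presence))
  rewrap_catalog(g[!g$locus_id %in% drop, ], catalog)
}

#' Wide genotype-matrix view of a catalog
#'
#' One row per locus, one column per individual; cells concatenate the
#' allele pairs over the locus's SNPs as `"AG/AT"`, `"-"` for loci
#' monomorphic in the catalog and `"./."` for missing genotypes.
#'
#' @param catalog a [locus_catalog()]
#' @return tibble with `locus_id` plus one column per individual
#' @export
as_genotype_matrix <- function(catalog) {
  inds <- catalog_individuals(catalog)
  g <- tibble::as_tibble(catalog) |>
    dplyr::arrange(.data$locus_id, .data$pos) |>
    dplyr::group_by(.data$locus_id, .data$individual) |>
    dplyr::summarise(
      gt = if (all(is.na(.data$pos))) {
        if (any(.data$called)) "-" else "./."
      } else if (!any(.data$called)) {
        "./."
      } else {
        paste0(paste(.data$allele1, collapse = ""), "/",
               paste(.data$allele2, collapse = ""))
      },
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "individual", values_from = "gt")
  present <- intersect(inds, names(g))
  for (ind in setdiff(inds, names(g))) g[[ind]] <- "./."
  g[, c("locus_id", inds)]
}

#' Export catalog genotypes
#'
#' `format = "tsv"` writes the lossless long TSV dialect (see
#' [write_catalog()]); `format = "genepop"` writes a genepop-like file in
#' which each SNP is a locus, alleles are coded `01`-`04` (A, C, G, T), a
#' diploid genotype is a 4-digit code and missing data are `0000`.
#'
#' @param catalog a [locus_catalog()]
#' @param path output file
#' @param format `"tsv"` or `"genepop"`
#' @param popmap optional population map; with one, genepop `POP` blocks
#'   follow regions, otherwise all individuals form one block
#' @return the path, invisibly
#' @export
export_genotype_matrix <- function(catalog, path, format = c("tsv", "genepop"),
                                   popmap = NULL) {
  format <- match.arg(format)
  if (format == "tsv") return(write_catalog(catalog, path))

  g <- tibble::as_tibble(catalog) |> dplyr::filter(!is.na(.data$pos))
  snps <- g |> dplyr::distinct(.data$locus_id, .data$pos) |>
    dplyr::arrange(.data$locus_id, .data$pos)
  snp_name <- sprintf("L%d_%d", snps$locus_id, snps$pos)
  inds <- catalog_individuals(catalog)
  code <- function(a) {
    i <- match(a, BASES)
    ifelse(is.na(i), "00", sprintf("%02d", i))
  }
  g$gt <- paste0(code(g$allele1), code(g$allele2))
  g$gt[!g$called] <- "0000"
  wide <- g |>
    dplyr::mutate(snp = sprintf("L%d_%d", .data$locus_id, .data$pos)) |>
    dplyr::select("individual", "snp", "gt") |>
    tidyr::pivot_wider(names_from = "snp", values_from = "gt",
                       values_fill = "0000")
  rows <- setNames(
    lapply(inds, function(ind) {
      r <- wide[wide$individual == ind, snp_name, drop = FALSE]
      if (nrow(r) == 0) rep("0000", length(snp_name)) else unlist(r[1, ])
    }), inds)

  lines <- c("radscape genepop-like export", snp_name)
  groups <- if (is.null(popmap)) list(all = inds) else {
    split(popmap$individual[match(inds, popmap$individual)],
          popmap$region[match(inds, popmap$individual)])
  }
  for (grp in groups) {
    lines <- c(lines, "POP",
               vapply(grp, function(ind) {
                 paste0(ind, " , ", paste(rows[[ind]], collapse = " "))
               }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}
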