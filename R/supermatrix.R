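# Supermatrix assembly: concatenate per-locus alignments, gap-fill
# missing species, emit partitions, occupancy and completeness.

#' Build a concatenated supermatrix from per-locus alignments
#'
#' Alignments with fewer taxa than `min_taxa` are dropped (inclusive rule
#' by default: an alignment with exactly `min_taxa` rows is kept; set
#' `strict = TRUE` for a strictly-greater rule). Loci concatenate in
#' sorted og_id order; species absent from a locus are filled with "-".
#'
#' Completeness by locus and species = filled cells / (species x loci);
#' completeness by characters = non-gap characters / (species x total
#' length).
#'
#' @param alignments named list (og_id -> named character vector of
#'   gapped rows); row names are species/sample names, consistent across
#'   loci.
#' @param min_taxa minimum taxa per kept alignment (default 6).
#' @param strict use a strictly-greater-than rule instead of >=.
#' @return object of class `supermatrix`: list with `alignment` (named
#'   character, sorted species), `partitions` (og_id, start, end; 1-based
#'   inclusive), `occupancy` (species x locus logical matrix),
#'   `completeness_by_locus`, `completeness_by_characters`,
#'   `n_species`, `n_loci`, `total_length`.
#' @export
build_supermatrix <- function(alignments, min_taxa = 6L, strict = FALSE) {
  ntax <- vapply(alignments, length, integer(1))
  keep <- if (strict) ntax > min_taxa else ntax >= min_taxa
  alignments <- alignments[keep]
  if (length(alignments) == 0)
    stop("no alignment passes the minimum-taxa filter", call. = FALSE)
  alignments <- alignments[order(names(alignments))]
  species <- sort(unique(unlist(lapply(alignments, names))))
  lens <- vapply(alignments, function(a) nchar(a[[1]]), integer(1))
  starts <- cumsum(c(1L, lens[-length(lens)]))
  ends <- cumsum(lens)
  partitions <- data.frame(og_id = names(alignments),
                           start = as.integer(starts), end = as.integer(ends),
                           stringsAsFactors = FALSE, row.names = NULL)
  occupancy <- matrix(FALSE, length(species), length(alignments),
                      dimnames = list(species, names(alignments)))
  rows <- setNames(vector("list", length(species)), species)
  for (sp in species) rows[[sp]] <- character(length(alignments))
  for (li in seq_along(alignments)) {
    a <- alignments[[li]]
    for (sp in species) {
      if (sp %in% names(a)) {
        rows[[sp]][li] <- a[[sp]]
        occupancy[sp, li] <- TRUE
      } else {
        rows[[sp]][li] <- strrep("-", lens[li])
      }
    }
  }
  aln <- vapply(rows, paste, character(1), collapse = "")
  total_len <- sum(lens)
  nongap <- sum(vapply(aln, function(r)
    nchar(r) - lengths(regmatches(r, gregexpr("-", r, fixed = TRUE))),
    numeric(1)))
  structure(list(alignment = aln, partitions = partitions,
                 occupancy = occupancy,
                 completeness_by_locus = mean(occupancy),
                 completeness_by_characters =
                   nongap / (length(species) * total_len),
                 n_species = length(species),
                 n_loci = length(alignments),
                 total_length = total_len),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf(
    "supermatrix: %d species x %d bp (%d loci)\n  %.1f%% complete by locus and species, %.1f%% by characters\n",
    x$n_species, x$total_length, x$n_loci,
    100 * x$completeness_by_locus, 100 * x$completeness_by_characters))
  invisible(x)
}

#' Write a supermatrix
#'
#' `format = "fasta"` writes the concatenated rows; `"phylip"` writes
#' relaxed PHYLIP (counts header, name and row separated by whitespace);
#' `"partitions"` writes a RAxML-style partition file
#' (`DNA, og0001 = 1-1378`); `"json"` writes the completeness report.
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @param format one of "fasta", "phylip", "partitions", "json".
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(sm, path,
                              format = c("fasta", "phylip", "partitions",
                                         "json")) {
  format <- match.arg(format)
  if (format == "fasta") {
    write_fasta(sm$alignment, path)
  } else if (format == "phylip") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%d %d", sm$n_species, sm$total_length), con)
    writeLines(sprintf("%s  %s", names(sm$alignment), sm$alignment), con)
  } else if (format == "partitions") {
    writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$og_id,
                       sm$partitions$start, sm$partitions$end), path)
  } else {
    jsonlite::write_json(list(
      n_species = sm$n_species, n_loci = sm$n_loci,
      total_length = sm$total_length,
      completeness_by_locus = sm$completeness_by_locus,
      completeness_by_characters = sm$completeness_by_characters),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
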