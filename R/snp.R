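# VCF -> SNP matrix: quality/biallelic/zero-missing site filters, IUPAC
# genotype coding, NEXUS / relaxed PHYLIP / FASTA writers.

#' Read variant sites from a VCF
#'
#' Thin wrapper over `vcfR::read.vcfR`; keeps CHROM, POS, REF, ALT, QUAL
#' and the GT (and, when present, GQ) fields.
#'
#' @param path VCF file (plain or bgzipped).
#' @return object of class `variant_sites`: list with `sites` (data frame
#'   chrom, pos, ref, alt, qual), `gt` (site x sample character matrix of
#'   GT strings, `NA` for missing), `gq` (numeric matrix or NULL) and
#'   `samples`.
#' @export
read_vcf_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  fx <- matrix(fx, ncol = ncol(vcfR::getFIX(v)),
               dimnames = dimnames(vcfR::getFIX(v)))
  sites <- data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
                      ref = fx[, "REF"], alt = fx[, "ALT"],
                      qual = as.numeric(fx[, "QUAL"]),
                      stringsAsFactors = FALSE, row.names = NULL)
  gt <- vcfR::extract.gt(v, element = "GT")
  gq <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)),
    error = function(e) NULL)
  new_variant_sites(sites, gt, gq)
}

new_variant_sites <- function(sites, gt, gq = NULL) {
  rownames(gt) <- NULL
  if (!is.null(gq)) rownames(gq) <- NULL
  structure(list(sites = sites, gt = gt, gq = gq, samples = colnames(gt)),
            class = "variant_sites")
}

gt_is_missing <- function(gt) {
  is.na(gt) | gt %in% c(".", "./.", ".|.")
}

#' Filter variant sites
#'
#' Filters apply in order quality -> biallelic SNP -> zero missing, each
#' tallied. Quality is strict: a site survives only when its score is
#' strictly greater than `min_qual` (default 30). The biallelic filter
#' keeps single-ALT SNPs (one-base REF and ALT; multi-allelic sites and
#' indels are dropped, not split). The zero-missing filter keeps sites
#' where every sample has a called genotype.
#'
#' @param v a `variant_sites` object.
#' @param min_qual strict lower bound on the quality score.
#' @param biallelic_only drop multi-allelic sites and indels.
#' @param zero_missing drop sites with any missing genotype.
#' @param qual_source `"QUAL"` (the VCF site quality, default) or `"GQ"`
#'   (minimum per-sample genotype quality at the site).
#' @return filtered `variant_sites` with a `tally` attribute: n_input,
#'   removed_qual, removed_not_biallelic, removed_missing, n_output.
#' @export
filter_sites <- function(v, min_qual = 30, biallelic_only = TRUE,
                         zero_missing = TRUE,
                         qual_source = c("QUAL", "GQ")) {
  qual_source <- match.arg(qual_source)
  n_input <- nrow(v$sites)
  qual <- if (qual_source == "QUAL") v$sites$qual else {
    if (is.null(v$gq)) stop("no GQ field in this VCF", call. = FALSE)
    apply(v$gq, 1, min)
  }
  keep <- !is.na(qual) & qual > min_qual
  removed_qual <- sum(!keep)
  idx <- which(keep)
  if (biallelic_only) {
    ok <- v$sites$ref[idx] %in% c("A", "C", "G", "T") &
      v$sites$alt[idx] %in% c("A", "C", "G", "T")
    removed_bi <- sum(!ok)
    idx <- idx[ok]
  } else removed_bi <- 0L
  if (zero_missing) {
    miss <- apply(gt_is_missing(v$gt[idx, , drop = FALSE]), 1, any)
    removed_missing <- sum(miss)
    idx <- idx[!miss]
  } else removed_missing <- 0L
  out <- new_variant_sites(v$sites[idx, , drop = FALSE],
                           v$gt[idx, , drop = FALSE],
                           if (!is.null(v$gq)) v$gq[idx, , drop = FALSE])
  attr(out, "tally") <- list(n_input = n_input, removed_qual = removed_qual,
                             removed_not_biallelic = removed_bi,
                             removed_missing = removed_missing,
                             n_output = length(idx))
  out
}

IUPAC2 <- c(AG = "R", GA = "R", CT = "Y", TC = "Y", GC = "S", CG = "S",
            AT = "W", TA = "W", GT = "K", TG = "K", AC = "M", CA = "M",
            AA = "A", CC = "C", GG = "G", TT = "T")

#' Encode a diploid genotype as a single IUPAC character
#'
#' Homozygotes map to their base, heterozygotes to the two-base IUPAC
#' ambiguity code (A/G -> R, C/T -> Y, G/C -> S, A/T -> W, G/T -> K,
#' A/C -> M); missing calls map to the missing symbol. Phased and
#' unphased separators are treated identically.
#'
#' @param gt genotype string(s) such as "0/1", "1|1", "./.".
#' @param ref reference allele (single base).
#' @param alt comma-separated alternate allele(s).
#' @param missing missing-data symbol (default "?").
#' @return character vector of single IUPAC codes.
#' @export
encode_genotype <- function(gt, ref, alt, missing = "?") {
  alleles <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
  if (any(!alleles %in% c("A", "C", "G", "T")))
    stop(sprintf("non-SNP allele in %s/%s", ref, alt), call. = FALSE)
  vapply(gt, function(g) {
    if (gt_is_missing(g)) return(missing)
    parts <- strsplit(g, "[/|]")[[1]]
    if (any(parts == ".")) return(missing)
    ai <- as.integer(parts) + 1L
    if (any(is.na(ai)) || any(ai > length(alleles)))
      stop(sprintf("genotype '%s' indexes missing allele", g), call. = FALSE)
    if (length(ai) == 1L) return(alleles[ai])
    IUPAC2[[paste0(alleles[ai[1]], alleles[ai[2]])]]
  }, character(1), USE.NAMES = FALSE)
}

#' Build the samples x sites SNP matrix
#'
#' @param v a (typically filtered) `variant_sites` object.
#' @param missing missing-data symbol.
#' @return object of class `snp_matrix`: list with `samples`, `sites`
#'   (chrom, pos) and `codes` (sample x site character matrix of IUPAC
#'   codes).
#' @export
build_snp_matrix <- function(v, missing = "?") {
  if (nrow(v$sites) == 0) stop("no sites to encode", call. = FALSE)
  codes <- matrix(missing, nrow = length(v$samples), ncol = nrow(v$sites),
                  dimnames = list(v$samples, NULL))
  for (i in seq_len(nrow(v$sites))) {
    codes[, i] <- encode_genotype(v$gt[i, ], v$sites$ref[i], v$sites$alt[i],
                                  missing)
  }
  structure(list(samples = v$samples,
                 sites = v$sites[, c("chrom", "pos")],
                 codes = codes, missing = missing),
            class = "snp_matrix")
}

snp_strings <- function(m) {
  setNames(apply(m$codes, 1, paste, collapse = ""), m$samples)
}

#' Write a SNP matrix
#'
#' NEXUS output is a `data` block with a
#' `dimensions ntax=<n> nchar=<m>;` line and
#' `format datatype=dna missing=<sym> gap=-;`. PHYLIP output is relaxed
#' (counts header, whitespace-separated names). Output is byte-stable
#' for a fixed matrix.
#'
#' @param m an `snp_matrix`.
#' @param path output path.
#' @param format one of "nexus", "phylip", "fasta".
#' @return `path`, invisibly.
#' @export
write_snp_matrix <- function(m, path, format = c("nexus", "phylip", "fasta")) {
  format <- match.arg(format)
  if (length(m$samples) == 0 || ncol(m$codes) == 0)
    stop("empty SNP matrix", call. = FALSE)
  rows <- snp_strings(m)
  if (format == "nexus") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("#NEXUS", "begin data;",
                 sprintf("dimensions ntax=%d nchar=%d;",
                         length(m$samples), ncol(m$codes)),
                 sprintf("format datatype=dna missing=%s gap=-;", m$missing),
                 "matrix",
                 sprintf("%s  %s", names(rows), rows),
                 ";", "end;"), con)
  } else if (format == "phylip") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%d %d", length(m$samples), ncol(m$codes)), con)
    writeLines(sprintf("%s  %s", names(rows), rows), con)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste0(">", names(rows), "\n", rows), con)
  }
  invisible(path)
}
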