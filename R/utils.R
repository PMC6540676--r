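# Internal sequence helpers. All coordinates in this package are 0-based
# half-open unless a writer documents otherwise (hit tables are 1-based
# inclusive, following the BLAST tabular dialect).

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) unname(COMPLEMENT[b])

check_nucleotides <- function(seq, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, seq)
  if (any(bad)) {
    stop(sprintf("%s contains non-%s characters (first offender: %s)",
                 what, if (allow_n) "ACGTN" else "ACGT",
                 substr(seq[bad][1], 1, 30)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Coerce sequences to a named character vector
#'
#' Accepts a named character vector, a `Biostrings::DNAStringSet`, or a
#' path to a FASTA file. Sequences are uppercased.
#'
#' @param x sequences in any accepted form.
#' @return named character vector of upper-case sequences.
#' @export
as_seq_vector <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (!is.character(x)) stop("expected character vector, DNAStringSet or FASTA path")
  toupper(x)
}

gc_fraction <- function(seqs) {
  n_gc <- sum(vapply(seqs, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  }, numeric(1)))
  n_tot <- sum(nchar(seqs))
  if (n_tot == 0) return(NA_real_)
  n_gc / n_tot
}

# seed helper: derive a stage seed from a master seed, kept under 2^31
stage_seed <- function(seed, stage) {
  (seed * 1000003L + stage * 7919L) %% 2147483629L
}

write_fasta <- function(seqs, path, width = 80L) {
  dna <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dna, filepath = path, width = width)
  invisible(path)
}
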