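# In silico AFLP: restriction digest, adapter compatibility, size
# selection, selective amplification and bait pooling.

#' Define a restriction enzyme
#'
#' @param name enzyme name (used to label fragment ends).
#' @param recognition_site exact recognition sequence (A/C/G/T only; the
#'   default enzymes are palindromic so a single top-strand scan finds all
#'   sites).
#' @param cut_offset 0-based offset of the top-strand cut within the site.
#' @return an object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("MluI", "ACGCGT", 1L)
#' @export
restriction_enzyme <- function(name, recognition_site, cut_offset) {
  recognition_site <- toupper(recognition_site)
  check_nucleotides(recognition_site, "recognition_site", allow_n = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition_site))
    stop("cut_offset must lie within the recognition site", call. = FALSE)
  structure(list(name = name, recognition_site = recognition_site,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' Default AFLP enzyme pair: MluI (A^CGCGT) and SbfI (CCTGCA^GG)
#'
#' @return named list of two `restriction_enzyme` objects.
#' @export
aflp_enzymes <- function() {
  list(MluI = restriction_enzyme("MluI", "ACGCGT", 1L),
       SbfI = restriction_enzyme("SbfI", "CCTGCAGG", 6L))
}

#' Selective primer combination
#'
#' A selective AFLP primer carries one extra 3' nucleotide; only fragments
#' whose first insert base matches it amplify. `NA` on a side means no
#' selection there (preamplification behaviour).
#'
#' @param forward_base selective base of the forward (MluI-side) primer,
#'   one of A/C/G/T or `NA`.
#' @param reverse_base selective base of the reverse (SbfI-side) primer.
#' @return an object of class `selective_combination`.
#' @export
selective_combination <- function(forward_base = NA, reverse_base = NA) {
  chk <- function(b, side) {
    if (is.na(b)) return(NA_character_)
    b <- toupper(b)
    if (!b %in% c("A", "C", "G", "T"))
      stop(side, " selective base must be one of A/C/G/T or NA", call. = FALSE)
    b
  }
  structure(list(forward_base = chk(forward_base, "forward"),
                 reverse_base = chk(reverse_base, "reverse")),
            class = "selective_combination")
}

#' The four-combination default used for bait pooling
#'
#' Forward selective bases \{A, T\} crossed with reverse selective bases
#' \{C, G\} (primers MluI-F-SA / MluI-F-ST x SbfI-R-SC / SbfI-R-SG).
#'
#' @return list of four `selective_combination` objects.
#' @export
default_combinations <- function() {
  list(selective_combination("A", "C"), selective_combination("A", "G"),
       selective_combination("T", "C"), selective_combination("T", "G"))
}

new_fragments <- function(source_id, start, end, left_end, right_end, sequence) {
  df <- data.frame(source_id = source_id, start = as.integer(start),
                   end = as.integer(end), left_end = left_end,
                   right_end = right_end, sequence = sequence,
                   stringsAsFactors = FALSE)
  class(df) <- c("aflp_fragments", "data.frame")
  df
}

#' Digest a sequence with a set of restriction enzymes
#'
#' Finds every exact top-strand occurrence of each recognition site
#' (windows containing N never match), cuts at site start + cut_offset,
#' and returns the fragments between consecutive cuts plus the two
#' terminal fragments. Fragment sequences concatenate back to the input.
#'
#' @param seq a single nucleotide string (A/C/G/T/N).
#' @param enzymes list of `restriction_enzyme` objects.
#' @param id source identifier recorded in each fragment.
#' @return an `aflp_fragments` data frame (columns source_id, start, end,
#'   left_end, right_end, sequence; coordinates 0-based half-open; end
#'   labels are enzyme names or "terminal" at the source extremities).
#' @examples
#' frags <- digest_sequence(paste0("TTTT", "ACGCGT", "GGGG"),
#'                          aflp_enzymes()["MluI"])
#' frags$sequence  # "TTTTA", "CGCGTGGGG"
#' @export
digest_sequence <- function(seq, enzymes = aflp_enzymes(), id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  check_nucleotides(seq, "seq")
  L <- nchar(seq)
  subj <- Biostrings::DNAString(seq)
  cuts <- integer(0); labels <- character(0)
  for (enz in enzymes) {
    hits <- Biostrings::matchPattern(enz$recognition_site, subj, fixed = TRUE)
    if (length(hits) == 0L) next
    pos <- (Biostrings::start(hits) - 1L) + enz$cut_offset  # 0-based cut
    keep <- pos > 0L & pos < L
    cuts <- c(cuts, pos[keep])
    labels <- c(labels, rep(enz$name, sum(keep)))
  }
  if (length(cuts)) {
    o <- order(cuts)
    cuts <- cuts[o]; labels <- labels[o]
    dup <- duplicated(cuts)  # two enzymes cutting at one position: keep first
    cuts <- cuts[!dup]; labels <- labels[!dup]
  }
  bounds <- c(0L, cuts, L)
  lab_left <- c("terminal", labels)
  lab_right <- c(labels, "terminal")
  n <- length(bounds) - 1L
  new_fragments(rep(id, n), bounds[-length(bounds)], bounds[-1L],
                lab_left, lab_right,
                substring(seq, bounds[-length(bounds)] + 1L, bounds[-1L]))
}

#' Digest every record of a FASTA file or sequence set
#'
#' @param x FASTA path, `DNAStringSet`, or named character vector.
#' @inheritParams digest_sequence
#' @return an `aflp_fragments` data frame over all records.
#' @export
digest_fasta <- function(x, enzymes = aflp_enzymes()) {
  seqs <- as_seq_vector(x)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- do.call(rbind, lapply(names(seqs), function(id)
    digest_sequence(seqs[[id]], enzymes, id = id)))
  class(out) <- c("aflp_fragments", "data.frame")
  out
}

#' Keep fragments that would carry both adapters
#'
#' Y-adapter chemistry amplifies only fragments with one MluI-cut end and
#' one SbfI-cut end; same-enzyme and terminal-ended fragments are dropped.
#'
#' @param fragments an `aflp_fragments` data frame.
#' @param enzyme_a,enzyme_b the two end labels that must both be present.
#' @return the adapter-compatible subset, same class.
#' @export
adapter_compatible <- function(fragments, enzyme_a = "MluI", enzyme_b = "SbfI") {
  keep <- (fragments$left_end == enzyme_a & fragments$right_end == enzyme_b) |
          (fragments$left_end == enzyme_b & fragments$right_end == enzyme_a)
  fragments[keep, , drop = FALSE]
}

#' Size-select fragments
#'
#' @param fragments an `aflp_fragments` data frame.
#' @param min_len,max_len inclusive length window in bp (the protocol
#'   default is 500-2,000 bp).
#' @return fragments with min_len <= length <= max_len.
#' @export
size_select <- function(fragments, min_len = 500L, max_len = 2000L) {
  if (min_len <= 0 || min_len > max_len)
    stop("size window requires 0 < min_len <= max_len", call. = FALSE)
  len <- fragments$end - fragments$start
  fragments[len >= min_len & len <= max_len, , drop = FALSE]
}

# Orient fragments so the MluI-labeled end is leftmost; reverse-complement
# where needed. Adds a `flipped` logical column.
normalize_fragments <- function(fragments, enzyme_a = "MluI") {
  flip <- fragments$right_end == enzyme_a & fragments$left_end != enzyme_a
  if (any(flip)) {
    fragments$sequence[flip] <- revcomp(fragments$sequence[flip])
    l <- fragments$left_end[flip]
    fragments$left_end[flip] <- fragments$right_end[flip]
    fragments$right_end[flip] <- l
  }
  fragments$flipped <- flip
  fragments
}

#' Selective amplification of adapter-compatible fragments
#'
#' Models one selective-primer pair. The forward base is tested on the
#' sense strand immediately 3' of the MluI remnant; the reverse base on
#' the antisense strand immediately 3' of the SbfI remnant (the direction
#' the primers extend). A single selective base on each side retains, in
#' expectation, 1/16 of compatible fragments with uniform insert bases.
#' An N at a tested position never matches. Fragments too short to expose
#' both tested positions are rejected and tallied in the
#' `too_short_to_test` attribute of the result.
#'
#' @param fragments adapter-compatible `aflp_fragments` (any orientation;
#'   normalized internally so the MluI end is leftmost).
#' @param combo a `selective_combination`.
#' @param enzymes the enzyme pair (remnant lengths are derived from the
#'   recognition sites and cut offsets).
#' @return retained fragments (MluI-end-left orientation), with attribute
#'   `too_short_to_test` counting untestable fragments.
#' @export
selective_amplify <- function(fragments, combo = selective_combination(),
                              enzymes = aflp_enzymes()) {
  stopifnot(inherits(combo, "selective_combination"))
  ea <- enzymes[[1]]; eb <- enzymes[[2]]
  fragments <- normalize_fragments(fragments, enzyme_a = ea$name)
  rem_f <- nchar(ea$recognition_site) - ea$cut_offset  # sense-strand remnant
  rem_r <- eb$cut_offset                               # antisense-strand remnant
  len <- nchar(fragments$sequence)
  too_short <- len < rem_f + rem_r + 2L
  fwd_ok <- rep(TRUE, nrow(fragments))
  rev_ok <- rep(TRUE, nrow(fragments))
  if (!is.na(combo$forward_base)) {
    b <- substr(fragments$sequence, rem_f + 1L, rem_f + 1L)
    fwd_ok <- b == combo$forward_base  # N never equals a selective base
  }
  if (!is.na(combo$reverse_base)) {
    b <- complement_base(substr(fragments$sequence, len - rem_r, len - rem_r))
    rev_ok <- b == combo$reverse_base
  }
  out <- fragments[!too_short & fwd_ok & rev_ok, , drop = FALSE]
  attr(out, "too_short_to_test") <- sum(too_short)
  out
}

#' Pool selective-amplification products into a bait set
#'
#' Runs `selective_amplify` under each combination and takes the union of
#' products, deduplicated by source coordinates. With the default four
#' combinations (\{A,T\} x \{C,G\}) the pool retains, in expectation, a
#' quarter of the compatible fragments. A warning is emitted when the
#' bait count falls outside the recommended 500-5,000 window.
#'
#' @param fragments adapter-compatible (and typically size-selected)
#'   fragments.
#' @param combos list of `selective_combination` objects.
#' @param enzymes the enzyme pair.
#' @param recommended bait-count window that triggers a warning outside it.
#' @return an object of class `bait_set`: list with `fragments`, `combos`,
#'   `per_combo_counts` and `summary` (count, length min/mean/max, GC
#'   fraction).
#' @export
pool_baits <- function(fragments, combos = default_combinations(),
                       enzymes = aflp_enzymes(), recommended = c(500L, 5000L)) {
  if (length(combos) == 0L) stop("combos must be non-empty", call. = FALSE)
  picked <- list(); counts <- integer(length(combos))
  for (i in seq_along(combos)) {
    res <- selective_amplify(fragments, combos[[i]], enzymes)
    counts[i] <- nrow(res)
    picked[[i]] <- res
  }
  pool <- do.call(rbind, picked)
  key <- paste(pool$source_id, pool$start, pool$end, sep = ":")
  pool <- pool[!duplicated(key), , drop = FALSE]
  pool <- pool[order(pool$source_id, pool$start), , drop = FALSE]
  rownames(pool) <- NULL
  len <- nchar(pool$sequence)
  summ <- list(count = nrow(pool),
               length_min = if (nrow(pool)) min(len) else NA_integer_,
               length_mean = if (nrow(pool)) mean(len) else NA_real_,
               length_max = if (nrow(pool)) max(len) else NA_integer_,
               gc = gc_fraction(pool$sequence))
  if (nrow(pool) < recommended[1] || nrow(pool) > recommended[2])
    warning(sprintf(
      "bait count %d outside the recommended window [%d, %d]",
      nrow(pool), recommended[1], recommended[2]), call. = FALSE)
  structure(list(fragments = pool, combos = combos,
                 per_combo_counts = counts, summary = summ),
            class = "bait_set")
}

#' Full in silico bait design on a genome
#'
#' digest -> adapter compatibility -> size selection -> selective
#' amplification under each combination -> pooled bait set. The selective
#' fraction is reported against two denominators: all digestion fragments
#' and adapter-compatible fragments (the theoretical 1/16-per-combination
#' expectation refers to fragments that can amplify at all).
#'
#' @param x genome FASTA path, `DNAStringSet` or named character vector.
#' @param enzymes enzyme pair.
#' @param size_range inclusive length window, bp.
#' @param combos selective combinations to pool.
#' @return a `bait_set` whose `summary` additionally carries
#'   `n_total_fragments`, `n_compatible`, `n_size_selected`,
#'   `fraction_of_total` and `fraction_of_compatible`.
#' @export
design_baits <- function(x, enzymes = aflp_enzymes(),
                         size_range = c(500L, 2000L),
                         combos = default_combinations()) {
  frags <- digest_fasta(x, enzymes)
  compat <- adapter_compatible(frags, enzymes[[1]]$name, enzymes[[2]]$name)
  sized <- size_select(compat, size_range[1], size_range[2])
  baits <- pool_baits(sized, combos, enzymes)
  baits$summary$n_total_fragments <- nrow(frags)
  baits$summary$n_compatible <- nrow(compat)
  baits$summary$n_size_selected <- nrow(sized)
  baits$summary$fraction_of_total <-
    if (nrow(frags)) baits$summary$count / nrow(frags) else NA_real_
  baits$summary$fraction_of_compatible <-
    if (nrow(sized)) baits$summary$count / nrow(sized) else NA_real_
  baits
}

#' @export
print.bait_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf("bait_set: %d baits from %d combination(s)\n",
              s$count, length(x$combos)))
  cat(sprintf("  length %s..%s (mean %.1f), GC %.3f\n",
              s$length_min, s$length_max, s$length_mean, s$gc))
  if (!is.null(s$fraction_of_compatible))
    cat(sprintf("  fraction of compatible fragments: %.4f (of all: %.4f)\n",
                s$fraction_of_compatible, s$fraction_of_total))
  invisible(x)
}

#' Write a bait set to FASTA
#'
#' Headers follow `srcID:start-end|left=MluI|right=SbfI` with 0-based
#' half-open coordinates.
#'
#' @param baits a `bait_set`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_bait_fasta <- function(baits, path) {
  fr <- baits$fragments
  hdr <- sprintf("%s:%d-%d|left=%s|right=%s",
                 fr$source_id, fr$start, fr$end, fr$left_end, fr$right_end)
  write_fasta(setNames(fr$sequence, hdr), path)
}
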