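# Local-similarity search: a k-mer seeded Smith-Waterman aligner with
# Karlin-Altschul e-values, plus an importer/writer for the 12-column
# BLAST tabular (outfmt-6) dialect. Imported and built-in hit tables are
# interchangeable downstream.

#' Alignment scoring parameters
#'
#' Defaults are megablast-like: match +2, mismatch -3, gap open 5, gap
#' extend 2 (penalties as positive magnitudes; a gap of length g costs
#' open + g * extend), seed word size 11. `lambda` and `K` are the
#' Karlin-Altschul parameters for this scoring system, used to convert
#' raw scores to bit scores and e-values.
#'
#' @param match,mismatch match reward and mismatch penalty.
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @param k seed word size; two sequences with no shared k-mer (either
#'   strand) produce no hit.
#' @param lambda,K Karlin-Altschul parameters for the scoring system.
#' @return a list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                          gap_extend = 2L, k = 11L,
                          lambda = 0.625, K = 0.41) {
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), k = as.integer(k),
                 lambda = lambda, K = K),
            class = "align_scoring")
}

bitscore_from_raw <- function(score, scoring) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

evalue_from_bits <- function(bits, m, n) m * n * 2^(-bits)

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, 1:(n - k + 1), k:n)
  unique(km[!grepl("N", km, fixed = TRUE)])
}

has_seed <- function(a, b, k) length(intersect(seq_kmers(a, k), seq_kmers(b, k))) > 0

#' Smith-Waterman local alignment (exhaustive, no seeding)
#'
#' Affine-gap optimal local alignment; used directly for redundancy
#' clustering and as the extension stage of [local_align()].
#'
#' @param a,b nucleotide strings.
#' @param scoring an [align_scoring()] list.
#' @return `NULL` when the optimal score is not positive; otherwise a
#'   list with score, 1-based coordinates (qstart/qend on `a`,
#'   sstart/send on `b`), matches, mismatches, gapopen, aln_len and the
#'   two gapped alignment strings.
#' @export
sw_align <- function(a, b, scoring = align_scoring()) {
  r <- .c_sw_align(toupper(a), toupper(b), scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
  if (isTRUE(r$empty)) return(NULL)
  r$empty <- NULL
  r
}

#' Needleman-Wunsch global alignment
#'
#' Affine gaps, end gaps penalized. Used by the progressive aligner and
#' available as an oracle-checkable primitive.
#'
#' @inheritParams sw_align
#' @return list with score, matches, mismatches, gapopen, aln_len and the
#'   gapped strings `aln_a`, `aln_b`.
#' @export
nw_align <- function(a, b, scoring = align_scoring()) {
  .c_nw_align(toupper(a), toupper(b), scoring$match, scoring$mismatch,
              scoring$gap_open, scoring$gap_extend)
}

#' Best local alignment between two sequences (seed-and-extend)
#'
#' Requires a shared exact k-mer on the plus or minus strand before
#' extending with Smith-Waterman; with no seed on either strand the
#' result is `NULL` (as in word-based search programs). Minus-strand hits
#' are reported with `send < sstart` (tabular dialect convention).
#'
#' @inheritParams sw_align
#' @return `NULL` or a list with score, bitscore, coordinates, identity
#'   counts and `strand` ("+"/"-").
#' @export
local_align <- function(a, b, scoring = align_scoring()) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  brc <- revcomp(b)
  seeded_align(a, b, brc,
               seq_kmers(a, scoring$k), seq_kmers(b, scoring$k),
               seq_kmers(brc, scoring$k), scoring)
}

# seed-gated extension with precomputed k-mer sets; brc = revcomp(b)
seeded_align <- function(a, b, brc, ka, kb, kbrc, scoring) {
  best <- NULL
  if (any(ka %in% kb)) {
    r <- sw_align(a, b, scoring)
    if (!is.null(r)) { r$strand <- "+"; best <- r }
  }
  if (any(ka %in% kbrc)) {
    r <- sw_align(a, brc, scoring)
    if (!is.null(r) && (is.null(best) || r$score > best$score)) {
      m <- nchar(b)
      r$sstart <- m - r$sstart + 1L
      r$send <- m - r$send + 1L
      r$strand <- "-"
      best <- r
    }
  }
  if (is.null(best)) return(NULL)
  best$bitscore <- bitscore_from_raw(best$score, scoring)
  best$pct_identity <- 100 * best$matches / best$aln_len
  best
}

hit_table_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")

new_hit_table <- function(df, provenance = "built-in") {
  if (is.null(df) || nrow(df) == 0) {
    df <- as.data.frame(setNames(
      list(character(0), character(0), numeric(0), integer(0), integer(0),
           integer(0), integer(0), integer(0), integer(0), integer(0),
           numeric(0), numeric(0)), hit_table_columns))
  }
  stopifnot(identical(names(df), hit_table_columns))
  attr(df, "provenance") <- provenance
  class(df) <- c("hit_table", "data.frame")
  df
}

#' All-vs-all local similarity search
#'
#' Aligns every query against every subject (self-pairings, identical
#' ids, are skipped), computes e-values from bit scores and the search
#' space (query length x total subject length), and keeps hits with
#' e-value at or below the ceiling. Ordering is deterministic: query id,
#' then descending bitscore, ascending e-value, descending length,
#' ascending subject id.
#'
#' @param queries,subjects named character vectors, `DNAStringSet`s or
#'   FASTA paths; ids must be unique within each set.
#' @param evalue_max e-value ceiling (the orthology default is 1e-10).
#' @param scoring an [align_scoring()] list.
#' @return a `hit_table` data frame in the 12-column tabular dialect.
#' @export
search_all <- function(queries, subjects, evalue_max = 1e-10,
                       scoring = align_scoring()) {
  queries <- as_seq_vector(queries); subjects <- as_seq_vector(subjects)
  if (anyDuplicated(names(queries))) stop("duplicate query ids", call. = FALSE)
  if (anyDuplicated(names(subjects))) stop("duplicate subject ids", call. = FALSE)
  db_len <- sum(nchar(subjects))
  # per-sequence precomputation: k-mer sets and subject reverse complements
  qk <- lapply(queries, seq_kmers, k = scoring$k)
  sk <- lapply(subjects, seq_kmers, k = scoring$k)
  src <- revcomp(subjects)
  names(src) <- names(subjects)
  srck <- lapply(src, seq_kmers, k = scoring$k)
  rows <- list(); ri <- 0L
  for (qi in names(queries)) {
    for (si in names(subjects)) {
      if (identical(qi, si)) next
      h <- seeded_align(queries[[qi]], subjects[[si]], src[[si]],
                        qk[[qi]], sk[[si]], srck[[si]], scoring)
      if (is.null(h)) next
      ev <- evalue_from_bits(h$bitscore, nchar(queries[[qi]]), db_len)
      if (ev > evalue_max) next
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        qseqid = qi, sseqid = si, pident = h$pct_identity,
        length = h$aln_len, mismatch = h$mismatches, gapopen = h$gapopen,
        qstart = h$qstart, qend = h$qend, sstart = h$sstart, send = h$send,
        evalue = ev, bitscore = h$bitscore, stringsAsFactors = FALSE)
    }
  }
  df <- if (ri) do.call(rbind, rows) else NULL
  if (!is.null(df)) {
    o <- order(df$qseqid, -df$bitscore, df$evalue, -df$length, df$sseqid,
               method = "radix")
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  new_hit_table(df, provenance = "built-in")
}

#' Read a 12-column tabular hit file (outfmt-6 dialect)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. Minus-strand hits are preserved via
#' `send < sstart`.
#'
#' @param path tab-separated hit file.
#' @return a `hit_table` with provenance "imported".
#' @export
read_hits_tabular <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0)
    return(new_hit_table(NULL, provenance = "imported"))
  bad <- which(nf != 12L)
  if (length(bad))
    stop(sprintf("line %d of %s has %d columns; expected 12",
                 bad[1], path, nf[bad[1]]), call. = FALSE)
  df <- read.table(path, sep = "\t", quote = "", comment.char = "",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric",
                                  "integer", "integer", "integer", "integer",
                                  "integer", "integer", "integer", "numeric",
                                  "numeric"))
  names(df) <- hit_table_columns
  new_hit_table(df, provenance = "imported")
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param table a `hit_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tabular <- function(table, path) {
  df <- as.data.frame(table)
  df$pident <- vapply(df$pident, function(x) format(x, digits = 15), character(1))
  df$evalue <- vapply(df$evalue, function(x) format(x, digits = 15), character(1))
  df$bitscore <- vapply(df$bitscore, function(x) format(x, digits = 15), character(1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Best hit of a query
#'
#' Maximal bitscore; ties broken by lower e-value, then longer alignment,
#' then lexicographically smallest subject id — fully deterministic and
#' invariant to row order.
#'
#' @param table a `hit_table` (already filtered to the e-value ceiling).
#' @param query_id query sequence id.
#' @return a single-row `hit_table`, or `NULL` when the query has no hit.
#' @export
best_hit <- function(table, query_id) {
  sub <- table[table$qseqid == query_id, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  o <- order(-sub$bitscore, sub$evalue, -sub$length, sub$sseqid,
             method = "radix")
  sub[o[1], , drop = FALSE]
}
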