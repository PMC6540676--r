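# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# adapter-compatible fragments with uniform i.i.d. insert bases:
# MluI remnant (CGCGT) + insert + SbfI remnant (CCTGCA), MluI end left.
make_compatible_fragments <- function(n, insert_len = 12L, seed = 1L) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * insert_len, replace = TRUE),
              nrow = n)
  ins <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  seqs <- paste0("CGCGT", ins, "CCTGCA")
  df <- data.frame(source_id = "sim", start = (seq_len(n) - 1L) * 30L,
                   end = (seq_len(n) - 1L) * 30L + nchar(seqs),
                   left_end = "MluI", right_end = "SbfI",
                   sequence = seqs, stringsAsFactors = FALSE)
  class(df) <- c("aflp_fragments", "data.frame")
  df
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# point-mutate a fraction p of positions (to any base, may stay equal)
mutate_seq <- function(s, p) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(v)) < p
  v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  paste(v, collapse = "")
}

# brute-force oracle for the trim window: scan integer columns
oracle_trim_window <- function(spans, threshold) {
  n <- nrow(spans)
  k <- ceiling(threshold * n)
  cols <- min(spans$ref_start):(max(spans$ref_end) - 1L)
  cov <- vapply(cols, function(p)
    sum(spans$ref_start <= p & p < spans$ref_end), integer(1))
  feas <- cols[cov >= k]
  if (length(feas) == 0) return(NULL)
  list(ref_start = min(feas), ref_end = max(feas) + 1L)
}

# random projected-span table (only the fields the window search reads)
random_spans <- function(n, start_max = 150L, len_min = 50L, len_max = 300L) {
  start <- sample(0:start_max, n, replace = TRUE)
  len <- sample(len_min:len_max, n, replace = TRUE)
  data.frame(sample = sprintf("s%02d", seq_len(n)),
             member_id = sprintf("c%02d", seq_len(n)),
             ref_start = start, ref_end = start + len,
             stringsAsFactors = FALSE)
}
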