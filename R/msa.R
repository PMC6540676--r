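# Multiple alignment of trimmed group sequences: a built-in progressive
# (center-star) aligner over the affine-gap global kernel, an optional
# external-command backend, and the low-similarity row filter.

# merge a new pairwise alignment of the center into the running MSA.
# mc: current gapped center row; ac/as: center and new sequence from the
# pairwise alignment. Returns list(master_keep, new_row) where
# master_keep is a vector of indices/NA describing column surgery.
merge_star <- function(rows, center_name, ac, as_new, new_name) {
  mc <- strsplit(rows[[center_name]], "", fixed = TRUE)[[1]]
  acv <- strsplit(ac, "", fixed = TRUE)[[1]]
  asv <- strsplit(as_new, "", fixed = TRUE)[[1]]
  i <- 1L; j <- 1L
  ncol_old <- length(mc)
  take_old <- integer(0)   # index into old columns, NA = new gap column
  new_row <- character(0)
  while (i <= ncol_old || j <= length(acv)) {
    old_gap <- i <= ncol_old && mc[i] == "-"
    new_gap <- j <= length(acv) && acv[j] == "-"
    if (i <= ncol_old && j <= length(acv) && !old_gap && !new_gap) {
      take_old <- c(take_old, i); new_row <- c(new_row, asv[j])
      i <- i + 1L; j <- j + 1L
    } else if (i <= ncol_old && j <= length(acv) && old_gap && new_gap) {
      take_old <- c(take_old, i); new_row <- c(new_row, asv[j])
      i <- i + 1L; j <- j + 1L
    } else if (old_gap || j > length(acv)) {
      take_old <- c(take_old, i); new_row <- c(new_row, "-")
      i <- i + 1L
    } else { # new alignment inserts a column absent from the master
      take_old <- c(take_old, NA_integer_); new_row <- c(new_row, asv[j])
      j <- j + 1L
    }
  }
  out <- lapply(rows, function(r) {
    rv <- strsplit(r, "", fixed = TRUE)[[1]]
    paste(ifelse(is.na(take_old), "-", rv[pmax(take_old, 1L)]), collapse = "")
  })
  out[[new_name]] <- paste(new_row, collapse = "")
  out
}

align_star <- function(seqs, scoring) {
  n <- length(seqs)
  ids <- names(seqs)
  score <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    sc <- nw_align(seqs[[i]], seqs[[j]], scoring)$score
    score[i, j] <- sc; score[j, i] <- sc
  }
  tot <- rowSums(score)
  center <- ids[order(-tot, ids)[1]]
  others <- setdiff(ids, center)
  others <- others[order(-score[center, others], others)]
  rows <- setNames(list(unname(seqs[[center]])), center)
  for (id in others) {
    pa <- nw_align(seqs[[center]], seqs[[id]], scoring)
    rows <- merge_star(rows, center, pa$aln_a, pa$aln_b, id)
  }
  unlist(rows)[ids]
}

#' Align a group of sequences
#'
#' The built-in backend is a progressive center-star aligner: the center
#' is the sequence with the highest summed global-alignment score to all
#' others, remaining sequences join in order of decreasing similarity to
#' the center, and gaps merge under the once-a-gap-always-a-gap rule. An
#' external aligner can be substituted with a command template containing
#' `{in}` and `{out}` placeholders (e.g. `"mafft --auto {in} > {out}"`).
#'
#' @param seqs named character vector of >= 2 ungapped sequences.
#' @param backend `"builtin"` or an external command template.
#' @param scoring an [align_scoring()] list (built-in backend only).
#' @return named character vector of equal-length gapped rows, input
#'   order preserved.
#' @export
align_group <- function(seqs, backend = "builtin", scoring = align_scoring()) {
  if (length(seqs) < 2)
    stop_group_rejected("alignment needs at least 2 sequences")
  seqs <- toupper(seqs)
  if (identical(backend, "builtin")) return(align_star(seqs, scoring))
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(seqs, fin)
  cmd <- gsub("{in}", fin, gsub("{out}", fout, backend, fixed = TRUE),
              fixed = TRUE)
  status <- system(paste0(cmd, " 2> ", fout, ".log"))
  if (status != 0 || !file.exists(fout))
    stop(sprintf("external aligner failed (status %d): %s\n%s", status, cmd,
                 paste(readLines(paste0(fout, ".log"), warn = FALSE),
                       collapse = "\n")), call. = FALSE)
  aln <- as_seq_vector(fout)
  aln[names(seqs)]
}

stop_group_rejected <- function(msg) {
  stop(structure(class = c("aflpcap_group_rejected", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Pairwise row similarities of a multiple alignment
#'
#' Similarity of two rows = identical characters over columns where both
#' rows are non-gap; 0 when they share no columns.
#'
#' @param aln named character vector of equal-length gapped rows.
#' @return symmetric numeric matrix of pairwise similarities in [0, 1].
#' @export
pairwise_row_similarity <- function(aln) {
  mat <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  n <- nrow(mat)
  sim <- matrix(1, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    both <- mat[i, ] != "-" & mat[j, ] != "-"
    sim[i, j] <- sim[j, i] <-
      if (!any(both)) 0 else sum(mat[i, both] == mat[j, both]) / sum(both)
  }
  sim
}

#' Remove alignment rows of low average similarity
#'
#' A row is discarded when its mean pairwise similarity to all other rows
#' is strictly below the cutoff (default 30%); removal is a single pass
#' over the original alignment, and the survivors are realigned once.
#'
#' @param aln named character vector of >= 2 gapped rows.
#' @param min_mean_similarity fraction; rows strictly below are removed.
#' @param realign realign the survivors after removal (done once).
#' @param backend,scoring passed to [align_group()] for the realignment.
#' @return filtered (and realigned) alignment; attribute `removed` lists
#'   discarded row names. Raises a group-rejected condition when fewer
#'   than 2 rows survive.
#' @export
filter_low_similarity <- function(aln, min_mean_similarity = 0.3,
                                  realign = TRUE, backend = "builtin",
                                  scoring = align_scoring()) {
  stopifnot(length(aln) >= 2)
  sim <- pairwise_row_similarity(aln)
  mean_sim <- (rowSums(sim) - 1) / (nrow(sim) - 1)
  keep <- mean_sim >= min_mean_similarity
  removed <- names(aln)[!keep]
  if (sum(keep) == 0) stop_group_rejected("all rows fell below the similarity cutoff")
  if (sum(keep) == 1) stop_group_rejected("fewer than 2 rows survive the similarity filter")
  out <- aln[keep]
  if (length(removed) && realign)
    out <- align_group(gsub("-", "", out, fixed = TRUE), backend, scoring)
  attr(out, "removed") <- removed
  out
}
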