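# Optimal aligning-region search: project each group member onto
# reference coordinates via its linking hit, find the widest window whose
# two boundary columns are each covered by at least the threshold
# fraction of members, and crop.

#' Project group members onto reference coordinates
#'
#' Each member's offset is derived from its linking hit, treated as
#' ungapped for offset purposes: offset = (sstart - 1) - (qstart - 1) on
#' the plus strand; minus-strand members (send < sstart) are
#' reverse-complemented first and their hit coordinates recomputed. The
#' reference projects to [0, ref_len).
#'
#' @param group one element of an `orthology_groups` object.
#' @param member_seqs named character vector holding every member
#'   sequence (by member id).
#' @param ref_seq the reference contig sequence for this group.
#' @param reference_name sample name used for the reference row.
#' @return data frame of class `projected_spans`: sample, member_id,
#'   ref_start, ref_end (0-based half-open, may extend beyond the
#'   reference), strand, and the oriented sequence.
#' @export
project_members <- function(group, member_seqs, ref_seq,
                            reference_name = "REF") {
  m <- group$members
  rows <- list()
  rows[[1]] <- data.frame(sample = reference_name,
                          member_id = group$reference_id,
                          ref_start = 0L, ref_end = nchar(ref_seq),
                          strand = "+", seq = unname(ref_seq),
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    id <- m$member_id[i]
    if (!id %in% names(member_seqs))
      stop(sprintf("no sequence for member '%s'", id), call. = FALSE)
    s <- member_seqs[[id]]
    len <- nchar(s)
    qstart <- m$qstart[i]; qend <- m$qend[i]
    sstart <- m$sstart[i]; send <- m$send[i]
    if (qend > len || max(sstart, send) > nchar(ref_seq))
      stop(sprintf("hit coordinates exceed sequence length for '%s'", id),
           call. = FALSE)
    strand <- "+"
    if (send < sstart) {            # minus strand: flip the member
      s <- revcomp(s)
      qs <- len - qend + 1L
      qend <- len - qstart + 1L
      qstart <- qs
      tmp <- sstart; sstart <- send; send <- tmp
      strand <- "-"
    }
    offset <- (sstart - 1L) - (qstart - 1L)
    rows[[i + 1L]] <- data.frame(sample = m$sample[i], member_id = id,
                                 ref_start = offset, ref_end = offset + len,
                                 strand = strand, seq = s,
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("projected_spans", "data.frame")
  out
}

#' Find the optimal trim window over projected spans
#'
#' With cov(p) = number of spans containing reference column p and
#' k = ceiling(threshold * span count), the window is
#' [min F, max F + 1) where F = \{p : cov(p) >= k\}. Both boundary
#' columns meet the threshold by construction; interior coverage dips are
#' permitted (the rule constrains only the boundaries). The default
#' threshold demands data from at least 50% of members at both
#' boundaries.
#'
#' @param spans a `projected_spans` data frame (>= 2 rows).
#' @param threshold fraction in (0, 1].
#' @return object of class `trim_window`: list with `status`
#'   ("ok" or "no_feasible_window"), `ref_start`, `ref_end`,
#'   `boundary_coverage_up`, `boundary_coverage_down`, `k`, `n_spans`.
#' @export
find_trim_window <- function(spans, threshold = 0.5) {
  stopifnot(nrow(spans) >= 2, threshold > 0, threshold <= 1)
  n <- nrow(spans)
  k <- ceiling(threshold * n)
  off <- min(spans$ref_start)
  ir <- IRanges::IRanges(start = spans$ref_start - off + 1L,
                         end = spans$ref_end - off)
  cov <- IRanges::coverage(ir)
  feas <- which(as.integer(cov) >= k)
  if (length(feas) == 0)
    return(structure(list(status = "no_feasible_window", k = k, n_spans = n),
                     class = "trim_window"))
  lo <- min(feas); hi <- max(feas)
  covv <- as.integer(cov)
  structure(list(status = "ok",
                 ref_start = lo - 1L + off, ref_end = hi + off,
                 boundary_coverage_up = covv[lo],
                 boundary_coverage_down = covv[hi],
                 k = k, n_spans = n),
            class = "trim_window")
}

#' Crop group members to the trim window
#'
#' Each member keeps the part of its span intersecting the window, mapped
#' back to member-local coordinates; members with empty intersection are
#' dropped (recorded in the `dropped` attribute). The reference row is
#' cropped like any other member.
#'
#' @param spans a `projected_spans` data frame (with oriented sequences).
#' @param window a `trim_window` with status "ok".
#' @return named character vector (names = sample) of trimmed sequences;
#'   attribute `dropped` lists samples with empty intersection.
#' @export
trim_group <- function(spans, window) {
  if (window$status != "ok") stop("window has no feasible region", call. = FALSE)
  out <- character(0); dropped <- character(0)
  for (i in seq_len(nrow(spans))) {
    s0 <- max(spans$ref_start[i], window$ref_start)
    e0 <- min(spans$ref_end[i], window$ref_end)
    if (s0 >= e0) { dropped <- c(dropped, spans$sample[i]); next }
    loc_s <- s0 - spans$ref_start[i]   # 0-based local
    loc_e <- e0 - spans$ref_start[i]
    out[spans$sample[i]] <- substr(spans$seq[i], loc_s + 1L, loc_e)
  }
  attr(out, "dropped") <- dropped
  out
}
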