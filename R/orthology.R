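# Contig QC, redundancy reduction and mutual-best-hit (MBH) orthology.

#' Read per-sample contigs with optional depths
#'
#' Depth is taken from a two-column tab-separated file (contig id, mean
#' depth) when given, otherwise parsed from assembler-style FASTA headers
#' containing `cov_<float>`.
#'
#' @param fasta FASTA path or `DNAStringSet`.
#' @param depth_tsv optional path to a two-column depth table.
#' @return list with `seqs` (named character) and `depths` (named numeric,
#'   `NA` where unknown).
#' @export
read_contigs <- function(fasta, depth_tsv = NULL) {
  seqs <- as_seq_vector(fasta)
  depths <- setNames(rep(NA_real_, length(seqs)), names(seqs))
  if (!is.null(depth_tsv)) {
    d <- read.table(depth_tsv, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("id", "depth"))
    depths[match(d$id, names(depths))] <- d$depth
  } else {
    m <- regmatches(names(seqs), regexpr("cov_[0-9.]+", names(seqs)))
    if (length(m)) {
      has <- grepl("cov_[0-9.]+", names(seqs))
      depths[has] <- as.numeric(sub("cov_", "", m))
    }
  }
  list(seqs = seqs, depths = depths)
}

#' Quality-filter contigs by length and mean depth
#'
#' Retains contigs with length >= `min_len` and mean depth >= `min_depth`
#' (both inclusive; the pipeline defaults are 200 bp and 5x).
#'
#' @param seqs named character vector of contigs.
#' @param depths named numeric vector of mean depths (required when
#'   `min_depth` > 0).
#' @param min_len minimum contig length, bp.
#' @param min_depth minimum mean sequencing depth, fold-coverage.
#' @return list with `seqs` (the retained contigs), `depths`, and
#'   `report`: counts of inputs, failures per criterion and retained.
#' @export
qc_filter_contigs <- function(seqs, depths = NULL, min_len = 200L,
                              min_depth = 5) {
  len_ok <- nchar(seqs) >= min_len
  if (min_depth > 0) {
    if (is.null(depths)) stop("depths required when min_depth > 0", call. = FALSE)
    depths <- depths[names(seqs)]
    if (anyNA(depths))
      stop(sprintf("missing depth for contig '%s'",
                   names(seqs)[which(is.na(depths))[1]]), call. = FALSE)
    dep_ok <- depths >= min_depth
  } else {
    dep_ok <- rep(TRUE, length(seqs))
  }
  keep <- len_ok & dep_ok
  list(seqs = seqs[keep],
       depths = if (!is.null(depths)) depths[keep] else NULL,
       report = list(n_input = length(seqs),
                     removed_length = sum(!len_ok),
                     removed_depth = sum(!dep_ok),
                     n_retained = sum(keep)))
}

#' Reduce contig redundancy by greedy longest-first clustering
#'
#' Contigs are visited longest first (ties by id). A contig joins an
#' existing representative when the best local hit between them covers
#' identical positions amounting to at least `identity_cutoff` of the
#' shorter sequence; otherwise it founds a new cluster. Only
#' representatives are returned. Identity here is hit identities over the
#' shorter sequence length, a local-alignment analogue of the clustering
#' tools' global identity; the cutoff is configurable.
#'
#' @param seqs named character vector of contigs from one sample.
#' @param identity_cutoff fraction in (0,1]; default 0.95.
#' @param scoring an [align_scoring()] list.
#' @return named character vector of representatives (attribute
#'   `clusters` maps every input contig to its representative).
#' @export
reduce_redundancy <- function(seqs, identity_cutoff = 0.95,
                              scoring = align_scoring()) {
  o <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[o]
  reps <- character(0)
  assign <- setNames(character(length(seqs)), names(seqs))
  for (id in names(seqs)) {
    placed <- FALSE
    for (rid in reps) {
      h <- local_align(seqs[[id]], seqs[[rid]], scoring)
      if (is.null(h)) next
      idfrac <- h$matches / min(nchar(seqs[[id]]), nchar(seqs[[rid]]))
      if (idfrac >= identity_cutoff) { assign[id] <- rid; placed <- TRUE; break }
    }
    if (!placed) { reps <- c(reps, id); assign[id] <- id }
  }
  out <- seqs[reps]
  attr(out, "clusters") <- assign
  out
}

#' Build 1:1 orthology groups by mutual best hit
#'
#' For each sample, queries are searched against the reference and the
#' reference against the sample (both directions, e-value ceiling
#' applied). A sample contig joins the group anchored on reference contig
#' r iff each is the other's best hit. The reference sample contributes
#' each group's anchor; groups are keyed and ordered by reference id.
#'
#' @param reference named character vector: the designated bait-sample
#'   contig set.
#' @param samples named list of named character vectors, one per sample.
#' @param evalue_max e-value ceiling (default 1e-10).
#' @param scoring an [align_scoring()] list.
#' @param reference_name sample name reserved for the reference.
#' @param hits optional precomputed searches: a named list per sample,
#'   each `list(forward = , reverse = )` of `hit_table`s (forward =
#'   sample queries vs reference subjects). Imported tables are accepted.
#' @return object of class `orthology_groups`: list of groups, each
#'   `list(og_id, reference_id, members)` where `members` is a data frame
#'   of (sample, member_id) plus the linking hit fields (member as query,
#'   reference as subject).
#' @export
mutual_best_hit_groups <- function(reference, samples, evalue_max = 1e-10,
                                   scoring = align_scoring(),
                                   reference_name = "REF", hits = NULL) {
  reference <- as_seq_vector(reference)
  if (any(names(samples) == reference_name))
    stop("a sample is named identically to the reference", call. = FALSE)
  members <- list()
  for (sname in names(samples)) {
    sseqs <- as_seq_vector(samples[[sname]])
    if (!is.null(hits) && sname %in% names(hits)) {
      fwd <- hits[[sname]]$forward; rev <- hits[[sname]]$reverse
      fwd <- fwd[fwd$evalue <= evalue_max, , drop = FALSE]
      rev <- rev[rev$evalue <= evalue_max, , drop = FALSE]
    } else {
      fwd <- search_all(sseqs, reference, evalue_max, scoring)
      rev <- search_all(reference, sseqs, evalue_max, scoring)
    }
    for (cid in names(sseqs)) {
      bh <- best_hit(fwd, cid)
      if (is.null(bh)) next
      rid <- bh$sseqid
      back <- best_hit(rev, rid)
      if (is.null(back) || back$sseqid != cid) next
      row <- cbind(data.frame(sample = sname, member_id = cid,
                              stringsAsFactors = FALSE),
                   as.data.frame(bh)[, setdiff(hit_table_columns,
                                               c("qseqid", "sseqid"))])
      members[[rid]] <- rbind(members[[rid]], row)
    }
  }
  rids <- sort(names(members))
  groups <- lapply(seq_along(rids), function(i) {
    m <- members[[rids[i]]]
    rownames(m) <- NULL
    list(og_id = sprintf("og%04d", i), reference_id = rids[i], members = m)
  })
  structure(groups, class = "orthology_groups",
            reference_name = reference_name)
}

#' @export
print.orthology_groups <- function(x, ...) {
  cat(sprintf("orthology_groups: %d group(s)\n", length(x)))
  for (g in utils::head(x, 10))
    cat(sprintf("  %s <- %s: %d member(s)\n", g$og_id, g$reference_id,
                nrow(g$members)))
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Write orthology groups as a TSV
#'
#' Columns: og_id, reference_id, sample, member_id, pident, length,
#' bitscore, evalue.
#'
#' @param groups an `orthology_groups` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(groups, path) {
  rows <- do.call(rbind, lapply(groups, function(g)
    cbind(data.frame(og_id = g$og_id, reference_id = g$reference_id,
                     stringsAsFactors = FALSE),
          g$members[, c("sample", "member_id", "pident", "length",
                        "bitscore", "evalue")])))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
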