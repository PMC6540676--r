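# End-to-end driver: orthology groups -> projection -> trim window ->
# alignment -> similarity filter -> supermatrix.

#' Process orthology groups into per-locus alignments
#'
#' For each group: project members onto the reference, find the trim
#' window (boundary-coverage rule), crop, align, and apply the
#' low-similarity row filter with one realignment. Groups rejected at
#' any stage (no feasible window, fewer than two usable rows, all rows
#' below the similarity cutoff) are skipped and recorded.
#'
#' @param groups an `orthology_groups` object.
#' @param reference named character vector of reference contigs.
#' @param samples named list of per-sample contig vectors.
#' @param threshold boundary-coverage threshold for the trim window.
#' @param min_similarity row filter cutoff (fraction).
#' @param backend aligner backend for [align_group()].
#' @param scoring an [align_scoring()] list.
#' @return list with `alignments` (named list og_id -> alignment, rows
#'   named by sample) and `rejected` (named character of og_id ->
#'   reason).
#' @export
align_orthology_groups <- function(groups, reference, samples,
                                   threshold = 0.5, min_similarity = 0.3,
                                   backend = "builtin",
                                   scoring = align_scoring()) {
  reference_name <- attr(groups, "reference_name")
  all_members <- unlist(lapply(samples, as_seq_vector))
  names(all_members) <- unlist(lapply(samples, function(s)
    names(as_seq_vector(s))))
  alignments <- list(); rejected <- character(0)
  for (g in groups) {
    res <- tryCatch({
      spans <- project_members(g, all_members, reference[[g$reference_id]],
                               reference_name)
      win <- find_trim_window(spans, threshold)
      if (win$status != "ok") stop_group_rejected("no feasible window")
      trimmed <- trim_group(spans, win)
      if (length(trimmed) < 2) stop_group_rejected("fewer than 2 members after trimming")
      aln <- align_group(trimmed, backend, scoring)
      filter_low_similarity(aln, min_similarity, realign = TRUE,
                            backend = backend, scoring = scoring)
    }, aflpcap_group_rejected = function(e) e)
    if (inherits(res, "aflpcap_group_rejected")) {
      rejected[g$og_id] <- conditionMessage(res)
    } else {
      alignments[[g$og_id]] <- res
    }
  }
  list(alignments = alignments, rejected = rejected)
}

#' Run the full capture pipeline on contig sets
#'
#' QC filter -> (optional) redundancy reduction -> mutual-best-hit
#' orthology -> trimming/alignment -> supermatrix.
#'
#' @param reference named character vector (bait-sample contigs).
#' @param samples named list of per-sample contig vectors.
#' @param depths optional named list of per-sample depth vectors
#'   (reference depths under the reference name).
#' @param min_len,min_depth contig QC thresholds.
#' @param identity_cutoff redundancy cutoff (`NA` skips the step).
#' @param redundancy_first run redundancy reduction before the
#'   length/depth filter instead of after it.
#' @param evalue_max MBH e-value ceiling.
#' @param threshold,min_similarity,min_taxa trimming/filter/supermatrix
#'   parameters.
#' @param reference_name sample name for the reference.
#' @param scoring an [align_scoring()] list.
#' @return list with `groups`, `alignments`, `rejected`, `supermatrix`
#'   (NULL when no alignment passes `min_taxa`).
#' @export
run_capture_pipeline <- function(reference, samples, depths = NULL,
                                 min_len = 200L, min_depth = 5,
                                 identity_cutoff = NA,
                                 redundancy_first = FALSE,
                                 evalue_max = 1e-10,
                                 threshold = 0.5, min_similarity = 0.3,
                                 min_taxa = 6L, reference_name = "REF",
                                 scoring = align_scoring()) {
  qc <- function(nm, seqs) {
    s <- as_seq_vector(seqs)
    d <- if (!is.null(depths)) depths[[nm]] else NULL
    dedup <- function(x) {
      if (is.na(identity_cutoff)) x
      else reduce_redundancy(x, identity_cutoff, scoring)
    }
    if (redundancy_first) s <- dedup(s)
    s <- qc_filter_contigs(s, d, min_len, min_depth)$seqs
    if (!redundancy_first) s <- dedup(s)
    s
  }
  reference <- qc(reference_name, reference)
  samples <- setNames(lapply(names(samples), function(nm)
    qc(nm, samples[[nm]])), names(samples))
  groups <- mutual_best_hit_groups(reference, samples, evalue_max, scoring,
                                   reference_name)
  al <- align_orthology_groups(groups, reference, samples, threshold,
                               min_similarity, scoring = scoring)
  sm <- tryCatch(build_supermatrix(al$alignments, min_taxa),
                 error = function(e) NULL)
  list(groups = groups, alignments = al$alignments,
       rejected = al$rejected, supermatrix = sm)
}
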