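# Seeded synthetic data with known truth: random genomes, ortholog
# families evolved under Jukes-Cantor, per-sample contigs with staggered
# flanks / dropout / simulated depths, and toy VCFs with planted filter
# classes. Every generator is deterministic for a fixed seed.

#' Simulate an i.i.d. random genome
#'
#' Bases are drawn independently with P(G) + P(C) = `gc` (split equally
#' within each pair).
#'
#' @param length genome length, bp.
#' @param gc GC fraction in [0, 1].
#' @param seed optional integer seed.
#' @return a single nucleotide string.
#' @export
simulate_genome <- function(length, gc = 0.5, seed = NULL) {
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]", call. = FALSE)
  stopifnot(length >= 1)
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Evolve an ortholog family under Jukes-Cantor
#'
#' Each species sequence is generated from the ancestor at branch length
#' `divergence` (expected substitutions/site): every site mutates with
#' probability (3/4)(1 - exp(-4d/3)) to a uniformly chosen different
#' base, so the realized p-distance to the ancestor concentrates on that
#' closed form.
#'
#' @param ancestor ancestral nucleotide string.
#' @param n_species number of descendant species.
#' @param divergence per-species branch length d >= 0.
#' @param seed optional integer seed.
#' @return named character vector (`sp01`, `sp02`, ...).
#' @export
evolve_family <- function(ancestor, n_species, divergence, seed = NULL) {
  stopifnot(divergence >= 0, n_species >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- 0.75 * (1 - exp(-4 * divergence / 3))
  anc <- strsplit(toupper(ancestor), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  out <- vapply(seq_len(n_species), function(i) {
    s <- anc
    hit <- runif(length(s)) < p
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
    }
    paste(s, collapse = "")
  }, character(1))
  setNames(out, sprintf("sp%02d", seq_len(n_species)))
}

#' Simulate a set of ortholog families
#'
#' Independent random ancestors (lengths uniform in `locus_length`),
#' each evolved into `n_species` descendants at the given divergence.
#'
#' @param n_families number of families.
#' @param n_species species per family.
#' @param divergence per-species branch length.
#' @param locus_length length range c(min, max), bp.
#' @param gc ancestor GC fraction.
#' @param seed optional integer seed.
#' @return list with `ancestors` (named character, `fam01`...) and
#'   `species` (list family -> named character of species sequences).
#' @export
simulate_families <- function(n_families, n_species, divergence,
                              locus_length = c(400L, 800L), gc = 0.5,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fam_ids <- sprintf("fam%02d", seq_len(n_families))
  lens <- sample(seq(locus_length[1], locus_length[2]), n_families,
                 replace = TRUE)
  ancestors <- setNames(vapply(lens, function(L)
    simulate_genome(L, gc), character(1)), fam_ids)
  species <- lapply(ancestors, evolve_family, n_species = n_species,
                    divergence = divergence)
  list(ancestors = ancestors, species = species)
}

#' Simulate per-species contigs from ortholog families
#'
#' Each retained species x family pair yields one contig: the species'
#' locus sequence extended by independent random flanks (lengths uniform
#' on 0..`flank_length` per end, i.i.d. random sequence), with a
#' log-normal depth draw. Species drop a family independently with
#' probability `dropout`. The truth table records every emitted contig.
#'
#' @param families output of [simulate_families()].
#' @param flank_length maximum flank length per end, bp.
#' @param dropout probability a species lacks a family.
#' @param depth_meanlog,depth_sdlog log-normal depth parameters.
#' @param seed optional integer seed.
#' @return list with `contigs` (list species -> named character),
#'   `depths` (list species -> named numeric) and `truth` (data frame:
#'   family, species, contig_id, flank_left, flank_right, locus_length).
#' @export
simulate_contigs <- function(families, flank_length = 100L, dropout = 0,
                             depth_meanlog = log(20), depth_sdlog = 0.5,
                             seed = NULL) {
  stopifnot(dropout >= 0, dropout <= 1)
  if (!is.null(seed)) set.seed(seed)
  sp_ids <- names(families$species[[1]])
  contigs <- setNames(vector("list", length(sp_ids)), sp_ids)
  depths <- setNames(vector("list", length(sp_ids)), sp_ids)
  truth <- list(); ti <- 0L
  for (sp in sp_ids) {
    k <- 0L
    for (fam in names(families$species)) {
      if (runif(1) < dropout) next
      k <- k + 1L
      locus <- families$species[[fam]][[sp]]
      fl <- if (flank_length > 0) sample(0:flank_length, 1L) else 0L
      fr <- if (flank_length > 0) sample(0:flank_length, 1L) else 0L
      contig <- paste0(if (fl) simulate_genome(fl) else "", locus,
                       if (fr) simulate_genome(fr) else "")
      cid <- sprintf("%s_c%03d", sp, k)
      contigs[[sp]][cid] <- contig
      depths[[sp]][cid] <- rlnorm(1, depth_meanlog, depth_sdlog)
      ti <- ti + 1L
      truth[[ti]] <- data.frame(family = fam, species = sp, contig_id = cid,
                                flank_left = fl, flank_right = fr,
                                locus_length = nchar(locus),
                                stringsAsFactors = FALSE)
    }
  }
  if (ti == 0L) {
    warning("dropout removed every contig", call. = FALSE)
    truth_df <- data.frame(family = character(0), species = character(0),
                           contig_id = character(0), flank_left = integer(0),
                           flank_right = integer(0),
                           locus_length = integer(0))
  } else truth_df <- do.call(rbind, truth)
  list(contigs = contigs, depths = depths, truth = truth_df)
}

#' Simulate a toy VCF with planted filter classes
#'
#' Emits exactly the requested number of sites per class: `pass`
#' (QUAL > 30, biallelic SNP, no missing genotype), `low_qual`
#' (QUAL <= 30, one site placed exactly at 30 when the class is
#' non-empty), `multi_allelic` (two ALT alleles, QUAL > 30) and
#' `with_missing` (biallelic, QUAL > 30, at least one ./. genotype).
#'
#' @param n_samples number of samples.
#' @param classes named integer vector with elements `pass`, `low_qual`,
#'   `multi_allelic`, `with_missing`.
#' @param path output VCF path.
#' @param seed optional integer seed.
#' @return list with `path` and `truth` (the class counts).
#' @export
simulate_vcf <- function(n_samples,
                         classes = c(pass = 10L, low_qual = 5L,
                                     multi_allelic = 3L, with_missing = 2L),
                         path = tempfile(fileext = ".vcf"), seed = NULL) {
  stopifnot(all(classes >= 0), n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_total <- sum(classes)
  cls <- rep(names(classes), classes)
  pos <- sort(sample.int(100000L, n_total))
  samples <- sprintf("s%02d", seq_len(n_samples))
  recs <- character(n_total)
  first_lowqual <- TRUE
  for (i in seq_len(n_total)) {
    ref <- sample(bases, 1L)
    alt1 <- sample(setdiff(bases, ref), 1L)
    alt <- alt1
    qual <- round(runif(1, 30.5, 80), 2)
    gts <- sample(c("0/0", "0/1", "1/1"), n_samples, replace = TRUE)
    if (cls[i] == "low_qual") {
      qual <- if (first_lowqual) 30 else round(runif(1, 5, 29.9), 2)
      first_lowqual <- FALSE
    } else if (cls[i] == "multi_allelic") {
      alt <- paste(alt1, sample(setdiff(bases, c(ref, alt1)), 1L), sep = ",")
      gts[1] <- "1/2"
    } else if (cls[i] == "with_missing") {
      gts[sample.int(n_samples, 1L)] <- "./."
    }
    recs[i] <- paste(c("ref1", pos[i], ".", ref, alt, format(qual), "PASS",
                       ".", "GT", gts), collapse = "\t")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=ref1,length=100000>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, recs), path)
  list(path = path, truth = as.list(classes))
}

#' Simulate a complete capture dataset
#'
#' Families, contigs, and a reference/sample split: species `sp01` plays
#' the bait-sample reference, the rest are capture samples. Per-stage
#' seeds are derived from the master seed.
#'
#' @param n_families,n_species,divergence,locus_length,flank_length,dropout
#'   passed to the family and contig generators.
#' @param seed master integer seed.
#' @return list with `reference` (named character), `samples` (named list
#'   of named character), `depths`, `truth` and `reference_species`.
#' @export
simulate_capture_dataset <- function(n_families = 12L, n_species = 6L,
                                     divergence = 0.05,
                                     locus_length = c(400L, 800L),
                                     flank_length = 80L, dropout = 0,
                                     seed = 1L) {
  fam <- simulate_families(n_families, n_species, divergence, locus_length,
                           seed = stage_seed(seed, 1L))
  ct <- simulate_contigs(fam, flank_length, dropout,
                         seed = stage_seed(seed, 2L))
  ref_sp <- names(ct$contigs)[1]
  list(reference = ct$contigs[[ref_sp]],
       samples = ct$contigs[setdiff(names(ct$contigs), ref_sp)],
       depths = ct$depths, truth = ct$truth, families = fam,
       reference_species = ref_sp)
}
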