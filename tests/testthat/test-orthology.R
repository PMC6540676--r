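# Contig QC, redundancy reduction, mutual-best-hit orthology.

test_that("QC thresholds are inclusive and applied jointly", {
  seqs <- c(a = strrep("A", 199), b = strrep("C", 200), c = strrep("G", 5000))
  depths <- c(a = 10, b = 5.0, c = 4.9)
  out <- qc_filter_contigs(seqs, depths, min_len = 200, min_depth = 5)
  expect_equal(names(out$seqs), "b")
  expect_equal(out$report$removed_length, 1L)
  expect_equal(out$report$removed_depth, 1L)
  expect_equal(out$report$n_retained, 1L)
})

test_that("QC with zeroed thresholds is the identity", {
  seqs <- c(a = "ACGT", b = "A")
  out <- qc_filter_contigs(seqs, min_len = 0, min_depth = 0)
  expect_equal(out$seqs, seqs)
})

test_that("missing depth is an input error naming the contig", {
  seqs <- c(k7 = strrep("A", 300))
  expect_error(qc_filter_contigs(seqs, c(other = 9), min_depth = 5), "k7")
  expect_error(qc_filter_contigs(seqs, NULL, min_depth = 5), "depths")
})

test_that("a 7-contig fixture bracketing both thresholds matches hand enumeration", {
  seqs <- setNames(strrep("ACGT", c(40, 50, 50, 60, 75, 49, 100)),
                   sprintf("c%d", 1:7))
  depths <- setNames(c(4, 5, 6, 4.99, 5.01, 100, 5), names(seqs))
  # lengths: 160 200 200 240 300 196 400 ; keep len>=200 & depth>=5
  keep_hand <- c("c2", "c3", "c5", "c7")
  out <- qc_filter_contigs(seqs, depths, 200, 5)
  expect_equal(names(out$seqs), keep_hand)
})

test_that("redundancy reduction keeps the longer of a near-identical pair", {
  set.seed(21)
  long <- random_seq(1200)
  short <- mutate_seq(substr(long, 1, 1000), 0.01)
  out <- reduce_redundancy(c(s = short, l = long), identity_cutoff = 0.95)
  expect_equal(names(out), "l")
  cl <- attr(out, "clusters")
  expect_equal(unname(cl["s"]), "l")
})

test_that("dissimilar contigs all become representatives", {
  set.seed(22)
  seqs <- setNames(vapply(1:4, function(i) random_seq(400), character(1)),
                   sprintf("r%d", 1:4))
  out <- reduce_redundancy(seqs, identity_cutoff = 0.95)
  expect_setequal(names(out), names(seqs))
})

test_that("greedy chain clustering follows the longest-first order", {
  set.seed(23)
  A <- random_seq(1000)
  B <- paste0(mutate_seq(substr(A, 1, 500), 0.02), random_seq(400))  # ~A on half
  C <- paste0(substr(B, 501, 900), random_seq(300))  # shares B's tail only
  seqs <- c(A = A, B = B, C = C)
  out <- reduce_redundancy(seqs, identity_cutoff = 0.5)
  # brute-force the greedy pass with the same membership rule
  ids <- names(sort(-nchar(seqs)))
  reps <- character(0)
  for (id in ids) {
    placed <- FALSE
    for (r in reps) {
      h <- local_align(seqs[[id]], seqs[[r]])
      if (!is.null(h) &&
          h$matches / min(nchar(seqs[[id]]), nchar(seqs[[r]])) >= 0.5) {
        placed <- TRUE; break
      }
    }
    if (!placed) reps <- c(reps, id)
  }
  expect_equal(names(out), reps)
  expect_true("A" %in% reps)
})

test_that("planted orthologs form mutual-best-hit groups", {
  set.seed(24)
  refs <- c(r1 = random_seq(600), r2 = random_seq(600))
  mk_sample <- function() c(
    m1 = mutate_seq(refs[["r1"]], 0.07),
    m2 = mutate_seq(refs[["r2"]], 0.07))
  samples <- list(sA = mk_sample(), sB = mk_sample())
  names(samples$sA) <- c("sA_1", "sA_2")
  names(samples$sB) <- c("sB_1", "sB_2")
  gr <- mutual_best_hit_groups(refs, samples)
  expect_length(gr, 2L)
  expect_equal(vapply(gr, function(g) nrow(g$members), integer(1)),
               c(2L, 2L))
  expect_equal(gr[[1]]$reference_id, "r1")
  expect_setequal(gr[[1]]$members$member_id, c("sA_1", "sB_1"))
  # injectivity: a member appears in at most one group
  all_members <- unlist(lapply(gr, function(g) g$members$member_id))
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("a sample with no hits appears in no group", {
  set.seed(25)
  refs <- c(r1 = random_seq(600))
  samples <- list(sA = c(sA_1 = mutate_seq(refs[["r1"]], 0.05)),
                  sEmpty = c(sE_1 = strrep("AC", 200)))
  gr <- mutual_best_hit_groups(refs, samples)
  expect_length(gr, 1L)
  expect_equal(gr[[1]]$members$sample, "sA")
})

test_that("the paralog trap leaves the one-way best hit unassigned", {
  # synthetic hit tables: x's best hit is r1, but r1's best hit is y
  mk <- function(q, s, bits) data.frame(
    qseqid = q, sseqid = s, pident = 95, length = 400L, mismatch = 20L,
    gapopen = 0L, qstart = 1L, qend = 400L, sstart = 1L, send = 400L,
    evalue = 1e-50, bitscore = bits, stringsAsFactors = FALSE)
  fwd <- aflpcap:::new_hit_table(rbind(mk("x", "r1", 300), mk("y", "r1", 350)))
  rev <- aflpcap:::new_hit_table(rbind(mk("r1", "y", 350), mk("r1", "x", 300)))
  dummy <- strrep("ACGT", 100)
  gr <- mutual_best_hit_groups(
    c(r1 = dummy), list(s1 = c(x = dummy, y = dummy)),
    hits = list(s1 = list(forward = fwd, reverse = rev)))
  expect_length(gr, 1L)
  expect_equal(gr[[1]]$members$member_id, "y")
  # brute-force MBH over the tables agrees
  for (q in c("x", "y")) {
    b <- best_hit(fwd, q)
    mutual <- !is.null(b) && identical(best_hit(rev, b$sseqid)$sseqid, q)
    expect_equal(mutual, q == "y")
  }
})

test_that("MBH membership is invariant to swapping search direction labels", {
  set.seed(26)
  refs <- c(r1 = random_seq(500), r2 = random_seq(500))
  samples <- list(sA = c(a1 = mutate_seq(refs[["r1"]], 0.08),
                         a2 = mutate_seq(refs[["r2"]], 0.08)))
  fwd <- search_all(samples$sA, refs)
  rev <- search_all(refs, samples$sA)
  g1 <- mutual_best_hit_groups(refs, samples,
                               hits = list(sA = list(forward = fwd,
                                                     reverse = rev)))
  # swapped labels: rebuild tables by exchanging query/subject roles
  swap <- function(t) {
    s <- t[, c("sseqid", "qseqid", "pident", "length", "mismatch", "gapopen",
               "sstart", "send", "qstart", "qend", "evalue", "bitscore")]
    names(s) <- aflpcap:::hit_table_columns
    aflpcap:::new_hit_table(s[order(s$qseqid, -s$bitscore), ])
  }
  g2 <- mutual_best_hit_groups(refs, samples,
                               hits = list(sA = list(forward = swap(rev),
                                                     reverse = swap(fwd))))
  m1 <- lapply(g1, function(g) g$members$member_id)
  m2 <- lapply(g2, function(g) g$members$member_id)
  expect_equal(m1, m2)
})

test_that("a sample named like the reference is rejected", {
  expect_error(mutual_best_hit_groups(c(r = "ACGT"),
                                      list(REF = c(x = "ACGT"))),
               "identically")
})

test_that("depth parsing accepts TSV and cov_ headers", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">n1_cov_12.5", strrep("ACGT", 60),
               ">n2_cov_3.0", strrep("ACGT", 60)), fa)
  ct <- read_contigs(fa)
  expect_equal(unname(ct$depths), c(12.5, 3.0))
  tsv <- tempfile()
  writeLines(c("n1_cov_12.5\t7", "n2_cov_3.0\t8"), tsv)
  ct2 <- read_contigs(fa, tsv)
  expect_equal(unname(ct2$depths), c(7, 8))
})
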