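# In silico AFLP: digestion, adapter compatibility, size selection,
# selective amplification, pooling.

test_that("digestion with no recognition site returns the whole sequence", {
  f <- digest_sequence("ATATATATAT", aflp_enzymes())
  expect_equal(nrow(f), 1L)
  expect_equal(f$start, 0L)
  expect_equal(f$end, 10L)
  expect_equal(f$left_end, "terminal")
  expect_equal(f$right_end, "terminal")
})

test_that("cut position is site start + cut_offset", {
  f <- digest_sequence(paste0("TTTT", "ACGCGT", "GGGG"),
                       aflp_enzymes()["MluI"])
  expect_equal(f$sequence, c("TTTTA", "CGCGTGGGG"))
  expect_equal(f$start, c(0L, 5L))
  expect_equal(f$end, c(5L, 14L))
  expect_equal(f$right_end[1], "MluI")
  expect_equal(f$left_end[2], "MluI")
})

test_that("digestion conserves the sequence and fragment count", {
  set.seed(101)
  for (rep in 1:5) {
    s <- paste0(random_seq(3000), "ACGCGT", random_seq(500), "CCTGCAGG",
                random_seq(2000))
    f <- digest_sequence(s, aflp_enzymes())
    expect_equal(paste(f$sequence, collapse = ""), s)
    n_sites <- length(gregexpr("ACGCGT", s, fixed = TRUE)[[1]]) +
      length(gregexpr("CCTGCAGG", s, fixed = TRUE)[[1]])
    expect_equal(nrow(f), n_sites + 1L)
    expect_true(all(f$end > f$start))
    # internal labels only at cut positions, terminals at extremities
    expect_equal(f$left_end[1], "terminal")
    expect_equal(f$right_end[nrow(f)], "terminal")
  }
})

test_that("MluI cut count on a 1 Mb uniform sequence matches 4^-6 expectation", {
  s <- simulate_genome(1e6, gc = 0.5, seed = 99)
  f <- digest_sequence(s, aflp_enzymes()["MluI"])
  n_cuts <- nrow(f) - 1L
  expected <- (1e6 - 5) * 4^-6
  sd <- sqrt(expected)  # Poisson-scale spread of rare-site counts
  expect_lt(abs(n_cuts - expected), 4 * sd)
})

test_that("N inside a site window suppresses the cut", {
  f <- digest_sequence("TTTTACGNGTGGGG", aflp_enzymes())
  expect_equal(nrow(f), 1L)
  expect_error(digest_sequence("ACGTX"), "non-ACGTN")
})

test_that("digesting the reverse complement mirrors the fragments", {
  set.seed(42)
  s <- paste0(random_seq(800), "ACGCGT", random_seq(400), "CCTGCAGG",
              random_seq(600))
  f1 <- digest_sequence(s, aflp_enzymes())
  f2 <- digest_sequence(aflpcap:::revcomp(s), aflp_enzymes())
  L <- nchar(s)
  expect_equal(nrow(f1), nrow(f2))
  # palindromic sites map onto themselves under reflection, but the
  # top-strand cut sits asymmetrically inside each site: a cut c from an
  # enzyme with site length l and offset o reappears at (L - c) - (l - 2o)
  # in the reverse complement (the overhang stagger; overhangs themselves
  # are not modeled).
  stagger <- c(MluI = 6L - 2L * 1L, SbfI = 8L - 2L * 6L)
  cuts1 <- f1$start[-1]; enz1 <- f1$left_end[-1]
  cuts2 <- f2$start[-1]; enz2 <- f2$left_end[-1]
  mapped <- sort((L - cuts1) - stagger[enz1])
  expect_equal(unname(mapped), sort(cuts2))
  expect_equal(sort(as.vector(table(enz1))), sort(as.vector(table(enz2))))
})

test_that("adapter compatibility keeps exactly mixed-end fragments", {
  f <- data.frame(source_id = "x", start = c(0, 10, 20, 30),
                  end = c(10, 20, 30, 40),
                  left_end = c("MluI", "MluI", "SbfI", "terminal"),
                  right_end = c("MluI", "SbfI", "SbfI", "MluI"),
                  sequence = strrep("A", 10), stringsAsFactors = FALSE)
  class(f) <- c("aflp_fragments", "data.frame")
  kept <- adapter_compatible(f)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$left_end, "MluI")
  expect_equal(kept$right_end, "SbfI")
  expect_equal(nrow(adapter_compatible(f[0, ])), 0L)
})

test_that("compatible count equals adjacent cut pairs with differing enzymes", {
  set.seed(7)
  s <- paste(vapply(1:60, function(i) {
    piece <- random_seq(sample(100:300, 1))
    site <- sample(c("ACGCGT", "CCTGCAGG", ""), 1)
    paste0(piece, site)
  }, character(1)), collapse = "")
  f <- digest_sequence(s, aflp_enzymes())
  kept <- adapter_compatible(f)
  # independent brute force: rebuild the cut list from the raw sequence
  site_pos <- function(site, off) {
    p <- gregexpr(site, s, fixed = TRUE)[[1]]
    if (p[1] == -1) integer(0) else (p - 1L) + off
  }
  cuts <- rbind(data.frame(pos = site_pos("ACGCGT", 1L), enz = "MluI"),
                data.frame(pos = site_pos("CCTGCAGG", 6L), enz = "SbfI"))
  cuts <- cuts[order(cuts$pos), ]
  n_expect <- sum(cuts$enz[-1] != cuts$enz[-nrow(cuts)])
  expect_equal(nrow(kept), n_expect)
})

test_that("size selection window is inclusive on both edges", {
  f <- data.frame(source_id = "x", start = 0,
                  end = c(499, 500, 2000, 2001),
                  left_end = "MluI", right_end = "SbfI",
                  sequence = "A", stringsAsFactors = FALSE)
  f$start <- 0L; f$sequence <- strrep("A", f$end)
  class(f) <- c("aflp_fragments", "data.frame")
  kept <- size_select(f, 500, 2000)
  expect_equal(kept$end, c(500, 2000))
  expect_equal(nrow(size_select(f[0, ], 500, 2000)), 0L)
  expect_equal(nrow(size_select(kept, 1, 1e6)), 2L)
  expect_error(size_select(f, 10, 5), "config|min_len")
})

test_that("selective bases are tested on the correct strands", {
  # insert sense base A right of the MluI remnant; antisense base right
  # of the SbfI remnant is the complement of the last insert base (G -> C)
  fr <- data.frame(source_id = "x", start = 0L, end = 0L,
                   left_end = "MluI", right_end = "SbfI",
                   sequence = paste0("CGCGT", "A", "TTTT", "G", "CCTGCA"),
                   stringsAsFactors = FALSE)
  fr$end <- nchar(fr$sequence)
  class(fr) <- c("aflp_fragments", "data.frame")
  expect_equal(nrow(selective_amplify(fr, selective_combination("A", "C"))), 1L)
  expect_equal(nrow(selective_amplify(fr, selective_combination("T", "C"))), 0L)
  expect_equal(nrow(selective_amplify(fr, selective_combination("A", "G"))), 0L)
  # unset combo retains everything (preamplification)
  expect_equal(nrow(selective_amplify(fr, selective_combination())), 1L)
  # N at a tested position never matches
  frN <- fr; frN$sequence <- paste0("CGCGT", "N", "TTTT", "G", "CCTGCA")
  expect_equal(nrow(selective_amplify(frN, selective_combination("A", "C"))), 0L)
  expect_equal(nrow(selective_amplify(frN, selective_combination())), 1L)
})

test_that("fragments flipped to put MluI left are tested identically", {
  fwd <- paste0("CGCGT", "A", "TTTT", "G", "CCTGCA")
  fr <- data.frame(source_id = "x", start = 0L, end = nchar(fwd),
                   left_end = "SbfI", right_end = "MluI",
                   sequence = aflpcap:::revcomp(fwd),
                   stringsAsFactors = FALSE)
  class(fr) <- c("aflp_fragments", "data.frame")
  expect_equal(nrow(selective_amplify(fr, selective_combination("A", "C"))), 1L)
})

test_that("too-short fragments are rejected and tallied", {
  fr <- data.frame(source_id = "x", start = 0L, end = 12L,
                   left_end = "MluI", right_end = "SbfI",
                   sequence = paste0("CGCGT", "A", "CCTGCA"),  # 12 bp < 13
                   stringsAsFactors = FALSE)
  class(fr) <- c("aflp_fragments", "data.frame")
  out <- selective_amplify(fr, selective_combination())
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "too_short_to_test"), 1L)
})

test_that("the 16 single-base combinations partition N-free compatible fragments", {
  fr <- make_compatible_fragments(400, insert_len = 10L, seed = 5)
  combos <- list()
  for (fb in c("A", "C", "G", "T")) for (rb in c("A", "C", "G", "T"))
    combos[[paste0(fb, rb)]] <- selective_combination(fb, rb)
  picks <- lapply(combos, function(cb)
    selective_amplify(fr, cb)$start)  # start is a unique key here
  all_picked <- sort(unname(unlist(picks)))
  expect_equal(all_picked, sort(fr$start))          # union = everything
  expect_equal(anyDuplicated(all_picked), 0L)        # pairwise disjoint
})

test_that("pooling deduplicates and a single combo equals its own output", {
  fr <- make_compatible_fragments(300, seed = 8)
  one <- selective_amplify(fr, selective_combination("A", "C"))
  pooled <- suppressWarnings(
    pool_baits(fr, list(selective_combination("A", "C"))))
  expect_equal(sort(pooled$fragments$start), sort(one$start))
  # same combo twice: union unchanged
  pooled2 <- suppressWarnings(
    pool_baits(fr, list(selective_combination("A", "C"),
                        selective_combination("A", "C"))))
  expect_equal(pooled2$summary$count, pooled$summary$count)
  expect_warning(pool_baits(fr, list(selective_combination("A", "C"))),
                 "recommended window")
})

test_that("bait design on a synthetic genome reports both denominators", {
  set.seed(11)
  core <- vapply(1:80, function(i)
    paste0("ACGCGT", random_seq(sample(450:1200, 1)), "CCTGCAGG"),
    character(1))
  genome <- paste0(random_seq(200), paste(core, collapse = ""),
                   random_seq(200))
  baits <- suppressWarnings(design_baits(setNames(genome, "g1")))
  s <- baits$summary
  expect_true(s$n_total_fragments >= s$n_compatible)
  expect_true(s$n_compatible >= s$n_size_selected)
  expect_true(s$count <= s$n_size_selected)
  expect_equal(s$fraction_of_compatible, s$count / s$n_size_selected)
  expect_true(all(nchar(baits$fragments$sequence) >= 500 &
                  nchar(baits$fragments$sequence) <= 2000))
  # every bait has one MluI and one SbfI end
  expect_true(all(baits$fragments$left_end == "MluI" &
                  baits$fragments$right_end == "SbfI"))
  p <- tempfile(fileext = ".fa")
  write_bait_fasta(baits, p)
  back <- as_seq_vector(p)
  expect_equal(length(back), s$count)
})
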