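make_cands <- function(seqs, start0 = 1000L, gap = 2000L) {
  n <- length(seqs)
  starts <- start0 + (seq_len(n) - 1L) * gap
  data.frame(contig_id = "c1", start = starts,
             end = starts + nchar(seqs), strand = ".",
             tir_length = 12L, tir_mismatches = 0L, tsd_seq = "TA",
             tsd_len = 2L, score = 14 + seq_len(n), seq = seqs,
             stringsAsFactors = FALSE)
}

test_that("identical sequences form one family; pairs fall below the
           three-copy filter", {
  set.seed(1)
  s <- random_dna_gc(200, 0.45)
  five <- cluster_candidates(make_cands(rep(s, 5)))
  expect_equal(length(five$families), 1L)
  expect_equal(nrow(five$families[[1]]$members), 5L)
  expect_equal(nrow(five$singletons), 0L)

  two <- cluster_candidates(make_cands(rep(s, 2)))
  expect_equal(length(two$families), 0L)
  expect_equal(nrow(two$singletons), 2L)
})

test_that("two planted families at ~10% internal divergence are recovered as
           the truth partition", {
  set.seed(2)
  mA <- random_dna_gc(220, 0.45)
  mB <- random_dna_gc(300, 0.45)
  seqs <- c(vapply(1:10, function(i) mutate_k2p(mA, 0.05), character(1)),
            vapply(1:10, function(i) mutate_k2p(mB, 0.05), character(1)))
  truth_part <- rep(1:2, each = 10)
  cl <- cluster_candidates(make_cands(seqs))
  expect_equal(length(cl$families), 2L)
  # adjusted-Rand-style exact check: each family is pure and complete
  for (f in cl$families) {
    orig <- truth_part[match(f$members$seq, seqs)]
    expect_equal(length(unique(orig)), 1L)
    expect_equal(nrow(f$members), 10L)
  }
  # partition property: every candidate in exactly one family or singleton
  n_assigned <- sum(vapply(cl$families, function(f) nrow(f$members),
                           integer(1))) + nrow(cl$singletons)
  expect_equal(n_assigned, 20L)
})

test_that("flank distinctness collapses tandem duplicates but keeps
           independent insertions", {
  set.seed(3)
  elem <- random_dna_gc(150, 0.45)
  ctx <- random_dna_gc(60, 0.45)
  # tandem: the same element+context appears twice back to back
  genome <- c(c1 = paste0(random_dna_gc(300, 0.45), ctx, elem, ctx, elem,
                          ctx, random_dna_gc(4000, 0.45)))
  starts <- c(300L + 60L, 300L + 60L + 150L + 60L)
  fam <- list(family_id = "F", members = data.frame(
    contig_id = "c1", start = starts, end = starts + 150L, strand = ".",
    tir_length = 10L, tir_mismatches = 0L, tsd_seq = "TA", tsd_len = 2L,
    score = c(20, 18), seq = elem, stringsAsFactors = FALSE))
  out <- flank_distinctness_filter(fam, genome)
  expect_equal(nrow(out$members), 1L)
  expect_equal(out$members$score, 20)  # higher-scoring representative

  # far-apart copies with random flanks both survive
  genome2 <- c(c1 = paste0(random_dna_gc(500, 0.45), elem,
                           random_dna_gc(2000, 0.45), elem,
                           random_dna_gc(500, 0.45)))
  starts2 <- c(500L, 500L + 150L + 2000L)
  fam2 <- fam
  fam2$members$start <- starts2
  fam2$members$end <- starts2 + 150L
  expect_equal(nrow(flank_distinctness_filter(fam2, genome2)$members), 2L)
})

test_that("member at contig start is compared on its available flank only", {
  set.seed(4)
  elem <- random_dna_gc(150, 0.45)
  genome <- c(c1 = paste0(elem, random_dna_gc(1000, 0.45), elem,
                          random_dna_gc(200, 0.45)))
  starts <- c(0L, 150L + 1000L)
  fam <- list(family_id = "F", members = data.frame(
    contig_id = "c1", start = starts, end = starts + 150L, strand = ".",
    tir_length = 10L, tir_mismatches = 0L, tsd_seq = "TA", tsd_len = 2L,
    score = c(20, 18), seq = elem, stringsAsFactors = FALSE))
  expect_equal(nrow(flank_distinctness_filter(fam, genome)$members), 2L)
})

test_that("merge_annotation_sets applies the <100 bp identity rule and is
           idempotent", {
  a <- make_cands(c("ACGTACGTAC", "GGGGCCCCGG", "TTTTAAAATT"))
  b <- a[1:2, ]
  b$start <- b$start + c(40L, 150L)
  b$end <- b$end + c(40L, 150L)
  b$tir_length <- c(20L, 20L)
  m <- merge_annotation_sets(a, b)
  # first record matched within tolerance -> the longer-TIR version is kept
  expect_equal(nrow(m), 4L)  # 3 from a, minus 1 merged, plus shifted b[2]
  expect_true(any(m$tir_length == 20L & m$start == a$start[1] + 40L))
  # offset 150 is beyond tolerance -> both survive
  expect_equal(sum(abs(m$start - a$start[2]) < 200), 2L)
  # disjoint sets pass through
  expect_equal(nrow(merge_annotation_sets(a[1:3, ], make_cands(
    c("AAAA", "CCCC"), start0 = 50000L))), 5L)
  # idempotence: merge(x, x) == x
  expect_equal(merge_annotation_sets(a, a), a)
})

test_that("select_seed maximises boundary completeness deterministically", {
  cands <- make_cands(rep("ACGTACGTACGTACGTACGT", 3))
  cands$tir_mismatches <- c(2L, 0L, 2L)
  cands$score <- c(10, 10, 10)
  fam <- list(members = cands)
  expect_equal(select_seed(fam)$tir_mismatches, 0L)
  # all-identical members: leftmost wins
  cands2 <- make_cands(rep("ACGTACGTACGTACGTACGT", 3))
  cands2$score <- c(10, 10, 10)
  expect_equal(select_seed(list(members = cands2))$start,
               min(cands2$start))
})

test_that("seed of a planted family is a pristine copy", {
  spec <- simulation_spec(genome_length = 120000L, n_contigs = 1L,
                          n_families = 2L, copies_per_family = 6L,
                          age_model = data.frame(weight = 1, k_min = 0,
                                                 k_max = 0),
                          seed = 9L)
  sim <- generate_genome(spec)
  fams <- build_families(detect_mites(sim$genome), sim$genome)
  expect_gte(length(fams$families), 2L)
  for (f in fams$families) {
    expect_true(f$seed$seq %in% sim$masters)
  }
})
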