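test_that("parameter validation enforces the structural windows", {
  expect_error(detection_params(mite_min_len = 900), "min <= max")
  expect_error(detection_params(tir_min_len = 6), "tir_min_len")
})

test_that("a constructed TA-TSD element is found exactly once with exact
           coordinates", {
  set.seed(11)
  tir <- "GGCCAGTCACAATG"          # 14 bp
  internal <- random_dna_gc(172, 0.45)
  bg <- random_dna_gc(700, 0.45)
  pl <- plant_elements(bg, list(list(tir = tir, internal = internal,
                                     tsd = "TA")), 300L)
  cand <- find_tir_candidates(pl$seq, "c1")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, pl$truth$start)
  expect_equal(cand$end, pl$truth$end)
  expect_identical(cand$tsd_seq, "TA")
})

test_that("elements outside the length window are not reported", {
  set.seed(12)
  tir <- random_dna_gc(12, 0.45)
  # 49 bp element: 12 + 25 + 12
  pl <- plant_elements(random_dna_gc(500, 0.45),
                       list(list(tir = tir,
                                 internal = random_dna_gc(25, 0.45),
                                 tsd = "GACT")), 200L)
  expect_equal(nrow(find_tir_candidates(pl$seq, "c1")), 0L)
})

test_that("candidates with N in TIR or TSD are rejected", {
  set.seed(13)
  tir <- random_dna_gc(14, 0.45)
  el <- list(tir = tir, internal = random_dna_gc(100, 0.45), tsd = "GCAT")
  pl <- plant_elements(random_dna_gc(600, 0.45), list(el), 250L)
  expect_equal(nrow(find_tir_candidates(pl$seq, "c1")), 1L)
  # poison the left TIR with an N
  poisoned <- paste0(substring(pl$seq, 1, pl$truth$start + 5),
                     "N", substring(pl$seq, pl$truth$start + 7,
                                    nchar(pl$seq)))
  expect_equal(nrow(find_tir_candidates(poisoned, "c1")), 0L)
})

test_that("detection equals the brute-force all-substring oracle on small
           contigs", {
  set.seed(21)
  for (rep in 1:3) {
    bg <- random_dna_gc(1800, 0.42)
    els <- list(
      list(tir = random_dna_gc(15, 0.42),
           internal = random_dna_gc(120, 0.42), tsd = "TA"),
      list(tir = random_dna_gc(30, 0.42),
           internal = random_dna_gc(200, 0.42),
           tsd = random_dna_gc(9, 0.42)))
    pl <- plant_elements(bg, els, c(400L, 1100L))
    mine <- find_tir_candidates(pl$seq, "c1")
    orc <- oracle_tir_candidates(pl$seq)
    cols <- c("start", "end", "tir_length", "tir_mismatches", "tsd_seq",
              "tsd_len", "score")
    expect_equal(mine[, cols], orc[, cols], ignore_attr = TRUE)
    # the two planted elements are among the recovered candidates
    expect_true(all(paste(pl$truth$start, pl$truth$end) %in%
                      paste(mine$start, mine$end)))
  }
})

test_that("random background yields at most the calibrated spurious rate", {
  set.seed(31)
  n_hits <- 0L
  total <- 0L
  for (rep in 1:3) {
    bg <- random_dna_gc(100000, 0.42)
    n_hits <- n_hits + nrow(find_tir_candidates(bg, "bg"))
    total <- total + 100000L
  }
  expect_lte(n_hits / (total / 1e5), 1)  # <= 1 spurious per 100 kb
})

test_that("resolve_overlaps keeps the declared winner", {
  base <- data.frame(contig_id = "c1", strand = ".", tir_length = 12L,
                     tir_mismatches = 0L, tsd_seq = "TA", tsd_len = 2L,
                     seq = "ACGT", stringsAsFactors = FALSE)
  two <- rbind(cbind(base, start = 100L, end = 300L, score = 20),
               cbind(base, start = 100L, end = 300L, score = 18))
  expect_equal(resolve_overlaps(two)$score, 20)
  disjoint <- rbind(cbind(base, start = 100L, end = 300L, score = 20),
                    cbind(base, start = 500L, end = 700L, score = 18))
  expect_equal(nrow(resolve_overlaps(disjoint)), 2L)
  # 5 random overlapping candidates match exhaustive application of the rule
  set.seed(5)
  rand <- do.call(rbind, lapply(1:5, function(i)
    cbind(base, start = 100L + sample(0:40, 1),
          end = 300L + sample(0:40, 1), score = sample(10:30, 1))))
  res <- resolve_overlaps(rand)
  # brute force: greedy by (score, tsd_len, start)
  ord <- order(-rand$score, -rand$tsd_len, rand$start)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      ov <- min(rand$end[i], rand$end[k]) - max(rand$start[i], rand$start[k])
      if (ov > 0 && ov > 0.5 * (rand$end[i] - rand$start[i]) &&
          ov > 0.5 * (rand$end[k] - rand$start[k])) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  expect_setequal(paste(res$start, res$end, res$score),
                  paste(rand$start[kept], rand$end[kept], rand$score[kept]))
})

test_that("recall at K*=0 is >=99% with exact boundaries after family
           refinement, and detection recall degrades monotonically with
           divergence", {
  recalls <- numeric(0)
  for (K in c(0, 0.05, 0.15)) {
    spec <- simulation_spec(genome_length = 150000L, n_contigs = 1L,
                            n_families = 3L, copies_per_family = 7L,
                            age_model = data.frame(weight = 1, k_min = K,
                                                   k_max = K),
                            seed = 101L)
    sim <- generate_genome(spec)
    cand <- detect_mites(sim$genome)
    key <- paste(sim$truth$contig_id, sim$truth$start, sim$truth$end)
    if (K == 0) {
      fams <- build_families(cand, sim$genome,
                             cluster_params(min_copies = 3L))
      mem <- do.call(rbind, lapply(fams$families, function(f) f$members))
      exact <- sum(key %in% paste(mem$contig_id, mem$start, mem$end))
      expect_gte(exact / nrow(sim$truth), 0.99)
    }
    # loose-boundary detection recall for the degradation curve
    hit <- vapply(seq_len(nrow(sim$truth)), function(i) {
      any(cand$contig_id == sim$truth$contig_id[i] &
            abs(cand$start - sim$truth$start[i]) <= 25 &
            abs(cand$end - sim$truth$end[i]) <= 25)
    }, logical(1))
    recalls <- c(recalls, mean(hit))
  }
  expect_true(all(diff(recalls) <= 1e-9))  # non-increasing in K*
})
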