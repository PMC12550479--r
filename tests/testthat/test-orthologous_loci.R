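test_that("a verbatim planted query is recovered as one covering region and
           absent homology returns empty", {
  set.seed(1)
  q_core <- random_dna_gc(2200, 0.45)
  target <- c(chr1 = paste0(random_dna_gc(5000, 0.45), q_core,
                            random_dna_gc(5000, 0.45)))
  query <- list(seq = q_core, elem_lo = 1001L, elem_hi = 1200L,
                query_len = 2200L)
  regs <- search_homologs(query, target)
  expect_equal(length(regs), 1L)
  cov <- mitekit:::.span_coverage(
    as.matrix(regs[[1]]$hits[, c("q_lo", "q_hi")]), 1L, 2200L)
  expect_equal(cov, 2200L)

  empty <- search_homologs(query, c(chr1 = random_dna_gc(8000, 0.45)))
  expect_equal(length(empty), 0L)
})

test_that("discontiguous blocks within 1 kb merge into one locus region", {
  set.seed(2)
  left <- random_dna_gc(900, 0.45)
  right <- random_dna_gc(900, 0.45)
  mid <- random_dna_gc(300, 0.45)      # query middle absent from target
  query <- list(seq = paste0(left, mid, right), elem_lo = 901L,
                elem_hi = 1200L, query_len = 2100L)
  # target: left and right flank images separated by 400 unrelated bp
  target <- c(chr1 = paste0(random_dna_gc(3000, 0.45), left,
                            random_dna_gc(400, 0.45), right,
                            random_dna_gc(3000, 0.45)))
  regs <- search_homologs(query, target)
  expect_equal(length(regs), 1L)
  expect_gte(nrow(regs[[1]]$hits), 2L)
})

test_that("ortho query construction truncates flanks at contig ends", {
  genome <- c(c1 = strrep("ACGT", 1000))
  q <- build_ortho_query(genome, "c1", 100L, 400L, flank_len = 1000L)
  expect_equal(q$query_len, 1400L)
  expect_equal(q$elem_lo, 101L)
  expect_equal(q$elem_hi, 400L)
  expect_error(build_ortho_query(genome, "c9", 0L, 10L), "unknown contig")
  expect_error(build_ortho_query(genome, "c1", 0L, 10L, flank_len = 0L),
               "positive")
})

test_that("the seeded 3-species scenario is classified in full agreement
           with generator truth", {
  scen <- generate_ortholog_scenario(n_species = 3L, n_loci = 20L,
                                     shared_fraction = 0.3,
                                     flank_conservation = 0.95, seed = 7L)
  agree <- 0L
  for (i in seq_len(nrow(scen$loci))) {
    carrier <- scen$loci$carrier[i]
    tr <- scen$truth[scen$truth$locus_id == scen$loci$locus_id[i] &
                       scen$truth$species_id == carrier, ]
    elems <- data.frame(locus_id = tr$locus_id, contig_id = tr$contig_id,
                        start = tr$start, end = tr$end,
                        stringsAsFactors = FALSE)
    res <- classify_loci(elems, scen$genomes[[carrier]],
                         scen$genomes[setdiff(names(scen$genomes), carrier)])
    want <- if (scen$loci$locus_class[i] == "shared") "shared"
            else "species_specific"
    if (res$classification == want) agree <- agree + 1L
  }
  expect_equal(agree, 20L)
})

test_that("statuses only degrade toward unresolved as flank divergence
           grows", {
  rank_of <- c(shared = 2L, specific_absent = 2L, unresolved = 1L)
  prev_resolved <- Inf
  for (cons in c(0.95, 0.85, 0.6)) {
    scen <- generate_ortholog_scenario(n_species = 2L, n_loci = 8L,
                                       shared_fraction = 0.5,
                                       flank_conservation = cons,
                                       genome_length = 60000L, seed = 11L)
    statuses <- character(0)
    for (i in seq_len(nrow(scen$loci))) {
      carrier <- scen$loci$carrier[i]
      other <- setdiff(names(scen$genomes), carrier)
      tr <- scen$truth[scen$truth$locus_id == scen$loci$locus_id[i] &
                         scen$truth$species_id == carrier, ]
      q <- build_ortho_query(scen$genomes[[carrier]], tr$contig_id,
                             tr$start, tr$end)
      regs <- search_homologs(q, scen$genomes[[other]])
      st <- classify_species_status(q, regs)
      statuses <- c(statuses, st)
      # a locus never flips shared <-> specific directly: wrong resolved
      # calls are forbidden at any divergence
      want <- if (scen$loci$locus_class[i] == "shared") "shared"
              else "specific_absent"
      expect_true(st %in% c(want, "unresolved"))
    }
    resolved <- sum(rank_of[statuses] == 2L)
    expect_lte(resolved, prev_resolved)
    prev_resolved <- resolved
  }
})

test_that("polymorphism matrix matches truth counts and assigns loci to
           tree nodes", {
  scen <- generate_ortholog_scenario(n_species = 3L, n_loci = 20L,
                                     shared_fraction = 0.3, seed = 7L)
  # classification built from generator truth (statuses as an exact caller
  # would produce them) to test the matrix/tree logic in isolation
  loci <- scen$loci
  for (s in paste0("sp", 1:3)) {
    loci[[paste0("status_", s)]] <- ifelse(
      loci$locus_class == "shared", "shared",
      ifelse(loci$carrier == s, "carrier", "specific_absent"))
  }
  mat <- polymorphism_matrix(loci, paste0("sp", 1:3))$matrix
  expect_equal(dim(mat), c(3L, 20L))
  shared_cols <- loci$locus_class == "shared"
  expect_true(all(colSums(mat[, shared_cols]) == 3L))
  expect_true(all(colSums(mat[, !shared_cols]) == 1L))

  tree <- ape::read.tree(text = "((sp1:5,sp2:5):5,sp3:10):2;")
  pm <- polymorphism_matrix(loci, paste0("sp", 1:3), tree)
  nc <- pm$node_counts
  root_internal <- ape::getMRCA(tree, paste0("sp", 1:3))
  expect_equal(nc$count[nc$node == root_internal], 6L)
  expect_equal(sum(nc$count), 20L)
  expect_equal(nc$count_per_my, nc$count / nc$stem_my)
  bad_tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_error(polymorphism_matrix(loci, paste0("sp", 1:3), bad_tree),
               "tip labels")
})
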