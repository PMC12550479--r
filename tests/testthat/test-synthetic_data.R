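test_that("spec validation rejects bad inputs", {
  expect_error(simulation_spec(gc_content = 1.2), "gc_content")
  expect_error(simulation_spec(superfamily_mix = c(A = 0.5)), "sum to 1")
  expect_error(simulation_spec(
    age_model = data.frame(weight = c(0.5, 0.4), k_min = 0, k_max = 0.1)),
    "weights")
})

test_that("zero families gives pure background with empty truth", {
  sim <- generate_genome(simulation_spec(genome_length = 20000L,
                                         n_contigs = 2L, n_families = 0L,
                                         seed = 1L))
  expect_equal(sum(nchar(sim$genome)), 20000L)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("zero-divergence copies are identical to the master with intact
           TIRs and TSDs", {
  spec <- simulation_spec(genome_length = 60000L, n_contigs = 1L,
                          n_families = 2L, copies_per_family = 5L,
                          age_model = data.frame(weight = 1, k_min = 0,
                                                 k_max = 0),
                          seed = 3L)
  sim <- generate_genome(spec)
  expect_equal(nrow(sim$truth), 10L)
  s <- sim$genome[[1L]]
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    elem <- substring(s, tr$start + 1L, tr$end)
    expect_identical(elem, unname(sim$masters[[tr$family_id]]))
    # TIRs are exact reverse complements
    tir <- substring(elem, 1L, tr$tir_length)
    tail_ <- substring(elem, nchar(elem) - tr$tir_length + 1L, nchar(elem))
    expect_identical(tail_, rc_chr(tir))
    # TSD written on both flanks
    tl <- nchar(tr$tsd_seq)
    expect_identical(substring(s, tr$start - tl + 1L, tr$start), tr$tsd_seq)
    expect_identical(substring(s, tr$end + 1L, tr$end + tl), tr$tsd_seq)
  }
})

test_that("same seed regenerates byte-identical output; truth intervals never
           overlap", {
  spec <- simulation_spec(genome_length = 80000L, n_contigs = 2L,
                          n_families = 3L, copies_per_family = 6L, seed = 42L)
  a <- generate_genome(spec)
  b <- generate_genome(spec)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 18L)  # conservation: one record per insertion
  for (cid in unique(a$truth$contig_id)) {
    tr <- a$truth[a$truth$contig_id == cid, ]
    tr <- tr[order(tr$start), ]
    if (nrow(tr) > 1L)
      expect_true(all(tr$start[-1L] >= tr$end[-nrow(tr)]))
  }
})

test_that("mutation engine recovers planted divergence through the K80
           estimator", {
  set.seed(7)
  master <- random_dna_gc(2000, 0.45)
  for (K_true in c(0.05, 0.15, 0.3)) {
    ks <- replicate(60, {
      mut <- mutate_k2p(master, K_true, kappa = 2)
      k2p(master, mut)$K
    })
    se <- sd(ks) / sqrt(length(ks))
    expect_lt(abs(mean(ks) - K_true), 3 * se + 1e-3)
  }
})

test_that("ortholog scenario plants the advertised shared/specific split", {
  scen <- generate_ortholog_scenario(n_species = 3L, n_loci = 20L,
                                     shared_fraction = 0.3, seed = 7L)
  expect_equal(sum(scen$loci$locus_class == "shared"), 6L)
  expect_equal(sum(scen$loci$locus_class == "specific"), 14L)
  # shared loci present in all species, specific in exactly one
  tab <- table(scen$truth$locus_id)
  shared_ids <- scen$loci$locus_id[scen$loci$locus_class == "shared"]
  expect_true(all(tab[shared_ids] == 3L))
  expect_true(all(tab[setdiff(names(tab), shared_ids)] == 1L))
  # planted element sequences sit at the recorded coordinates
  tr1 <- scen$truth[scen$truth$species_id == "sp1", ][1L, ]
  g1 <- scen$genomes$sp1[["chr1"]]
  expect_equal(nchar(substring(g1, tr1$start + 1L, tr1$end)),
               tr1$end - tr1$start)

  expect_error(generate_ortholog_scenario(n_species = 1L), "n_species")
  expect_error(generate_ortholog_scenario(shared_fraction = 1.5),
               "shared_fraction")
})

test_that("shared_fraction extremes label every locus accordingly", {
  all_shared <- generate_ortholog_scenario(n_species = 2L, n_loci = 8L,
                                           shared_fraction = 1,
                                           genome_length = 60000L, seed = 2L)
  expect_true(all(all_shared$loci$locus_class == "shared"))
  none <- generate_ortholog_scenario(n_species = 3L, n_loci = 8L,
                                     shared_fraction = 0,
                                     genome_length = 60000L, seed = 2L)
  expect_true(all(none$loci$locus_class == "specific"))
  expect_true(all(table(none$truth$locus_id) == 1L))
})

test_that("miRNA precursor set labels provenance and is reproducible", {
  spec <- simulation_spec(genome_length = 60000L, n_contigs = 1L,
                          n_families = 2L, copies_per_family = 5L, seed = 3L)
  sim <- generate_genome(spec)
  a <- generate_mirna_set(sim$genome, sim$truth, 6L, 5L, seed = 3L)
  b <- generate_mirna_set(sim$genome, sim$truth, 6L, 5L, seed = 3L)
  expect_identical(a, b)
  expect_equal(sum(a$from_mite), 6L)
  expect_equal(sum(!a$from_mite), 5L)
  bg_only <- generate_mirna_set(sim$genome, sim$truth, 0L, 4L, seed = 1L)
  expect_true(all(!bg_only$from_mite))
  expect_error(generate_mirna_set(sim$genome, sim$truth[0, ], 3L, 0L),
               "no planted")
})
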