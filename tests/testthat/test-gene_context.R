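mk_genes <- function(df, exons) {
  attr(df, "exons") <- exons
  class(df) <- c("mite_genes", class(df))
  df
}

mk_hits <- function(starts, ends, contig = "c1") {
  data.frame(hit_id = sprintf("h%03d", seq_along(starts)),
             contig_id = rep(contig, length.out = length(starts)),
             start = starts, end = ends,
             stringsAsFactors = FALSE)
}

simple_gene <- function(id = "g1", start = 20000L, end = 21000L,
                        strand = "+", contig = "c1",
                        exons = NULL) {
  if (is.null(exons))
    exons <- matrix(c(start, start + 300L, end - 300L, end),
                    ncol = 2L, byrow = TRUE,
                    dimnames = list(NULL, c("start", "end")))
  mk_genes(data.frame(gene_id = id, contig_id = contig, start = start,
                      end = end, strand = strand, stringsAsFactors = FALSE),
           setNames(list(exons), id))
}

test_that("midpoints inside genes split into exon and intron; distance 0", {
  genes <- simple_gene()
  hits <- mk_hits(c(20050L, 20400L), c(20150L, 20500L))
  a <- assign_regions(hits, genes)
  expect_identical(a$region, c("exon", "intron"))
  expect_true(all(a$distance_to_gene == 0L))
  expect_identical(a$gene_id, c("g1", "g1"))
})

test_that("flank bins follow the 500 bp convention and strandedness", {
  genes <- simple_gene(strand = "+")
  # midpoint 700 bp 5' of the gene start -> upstream bin 1
  h <- mk_hits(20000L - 750L, 20000L - 650L)
  a <- assign_regions(h, genes)
  expect_identical(a$region, "upstream")
  expect_equal(a$bin_index, 1L)
  expect_equal(a$distance_to_gene, 700L)
  # the same hit relative to a minus-strand gene is downstream
  a_m <- assign_regions(h, simple_gene(strand = "-"))
  expect_identical(a_m$region, "downstream")
  expect_equal(a_m$bin_index, 1L)
  # beyond 5 kb -> intergenic
  far <- mk_hits(20000L - 6050L, 20000L - 5950L)
  expect_identical(assign_regions(far, genes)$region, "intergenic")
})

test_that("mirroring a gene to the minus strand swaps the flank profiles
           exactly", {
  set.seed(1)
  genes_p <- simple_gene(strand = "+")
  genes_m <- simple_gene(strand = "-")
  starts <- c(20000L - sample(100:4900, 20), 21000L + sample(100:4900, 20))
  hits <- mk_hits(starts - 25L, starts + 25L)
  ap <- assign_regions(hits, genes_p)
  am <- assign_regions(hits, genes_m)
  up_p <- sort(ap$bin_index[ap$region == "upstream"])
  dn_m <- sort(am$bin_index[am$region == "downstream"])
  expect_identical(up_p, dn_m)
  expect_identical(sort(ap$bin_index[ap$region == "downstream"]),
                   sort(am$bin_index[am$region == "upstream"]))
})

test_that("every hit gets exactly one region label and counts add up", {
  set.seed(2)
  spec <- simulation_spec(genome_length = 100000L, n_contigs = 1L,
                          n_families = 2L, copies_per_family = 5L,
                          seed = 31L)
  sim <- generate_genome(spec)
  genes <- generate_gene_models(sim$genome, n_genes = 5L, seed = 4L)
  hits <- mk_hits(sim$truth$start, sim$truth$end,
                  contig = sim$truth$contig_id)
  a <- assign_regions(hits, genes)
  expect_equal(nrow(a), nrow(hits))
  expect_true(all(a$region %in% c("exon", "intron", "upstream",
                                  "downstream", "intergenic")))
  bd <- binned_density(a)
  expect_equal(sum(bd$regions$count), nrow(hits))
})

test_that("hits on contigs without annotation become intergenic with a
           warning", {
  genes <- simple_gene()
  h <- mk_hits(100L, 200L, contig = "cX")
  expect_warning(a <- assign_regions(h, genes), "no gene annotation")
  expect_identical(a$region, "intergenic")
})

test_that("hits planted only in the 500-1000 bp upstream band land in bin 1
           and normalisation preserves ratios", {
  set.seed(3)
  genes <- simple_gene()
  d <- sample(501:1000, 30, replace = TRUE)
  hits <- mk_hits(20000L - d - 10L, 20000L - d + 10L)
  a <- assign_regions(hits, genes)
  bd_raw <- binned_density(a, normalize = FALSE)
  up <- bd_raw$bins[bd_raw$bins$region == "upstream", ]
  expect_equal(up$count[up$bin_index == 1L], 30L)
  expect_equal(sum(up$count), 30L)
  bd_norm <- binned_density(a, normalize = TRUE)
  upn <- bd_norm$bins[bd_norm$bins$region == "upstream", ]
  nonzero <- up$count > 0
  expect_equal(up$count[nonzero] / sum(up$count),
               upn$value[nonzero] / sum(upn$value))
})

test_that("gene grouping by insertion region builds promoter and complement
           sets", {
  genes <- rbind(simple_gene()$gene_id)  # placeholder to appease lints
  g2 <- mk_genes(
    data.frame(gene_id = c("g1", "g2"), contig_id = "c1",
               start = c(20000L, 60000L), end = c(21000L, 61000L),
               strand = "+", stringsAsFactors = FALSE),
    list(g1 = matrix(c(20000L, 21000L), ncol = 2,
                     dimnames = list(NULL, c("start", "end"))),
         g2 = matrix(c(60000L, 61000L), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))))
  # one hit in g1's 1.2 kb upstream (promoter band), one in g2's gene body
  hits <- mk_hits(c(20000L - 1250L, 60100L), c(20000L - 1150L, 60200L))
  a <- assign_regions(hits, g2)
  grp <- group_genes_by_insertion(a, g2)
  expect_identical(grp$with_insertion$promoter, "g1")
  expect_identical(grp$with_insertion$exon, "g2")
  expect_identical(grp$without_insertion$exon, "g1")
  # no hits at all -> every gene is in every complement set
  a0 <- assign_regions(mk_hits(integer(0), integer(0)), g2)
  grp0 <- group_genes_by_insertion(a0, g2)
  expect_identical(grp0$without_insertion$intron, c("g1", "g2"))
})
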