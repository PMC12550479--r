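# Synthetic genomes with planted MITEs and machine-readable ground truth.
#
# The generator emulates the data a MITE annotation pipeline consumes:
# multi-contig genomes of i.i.d. background composition, families of
# TIR-bounded elements with superfamily-consistent TSDs, age-dependent K80
# divergence of the copies from their family master, orthologous
# multi-species insertion scenarios, gene models and hairpin-capable miRNA
# precursors. Every planted feature is recorded in a truth table so each
# pipeline stage can be scored against construction rather than against
# another annotation.

.TS_MAP <- c(A = "G", G = "A", C = "T", T = "C", N = "N")
.TV_MAP1 <- c(A = "C", G = "C", C = "A", T = "A", N = "N")
.TV_MAP2 <- c(A = "T", G = "T", C = "G", T = "G", N = "N")

#' Mutate a DNA string under the K80 model
#'
#' Applies substitutions so that the expected K80 distance from the input is
#' `K`, with transition/transversion rate ratio `kappa`: each site is hit by
#' a transition with the model's expected probability `P(K, kappa)` and by a
#' transversion (either target equally) with probability `Q(K, kappa)`.
#' Substitution only (no indels), so coordinates are preserved. Uses the
#' current RNG state.
#'
#' @param seq DNA string.
#' @param K expected substitutions per site (>= 0).
#' @param kappa transition/transversion rate ratio.
#' @return mutated DNA string of the same length.
#' @export
mutate_k2p <- function(seq, K, kappa = 2) {
  if (K < 0) .stopf("K must be non-negative")
  n <- nchar(seq)
  if (n == 0L || K == 0) return(seq)
  pq <- .k2p_expected_PQ(K, kappa)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  u <- runif(n)
  u2 <- runif(n)
  ts <- u < pq[["P"]]
  tv <- !ts & u < pq[["P"]] + pq[["Q"]]
  chars[ts] <- .TS_MAP[chars[ts]]
  tv1 <- tv & u2 < 0.5
  tv2 <- tv & !tv1
  chars[tv1] <- .TV_MAP1[chars[tv1]]
  chars[tv2] <- .TV_MAP2[chars[tv2]]
  paste(chars, collapse = "")
}

.DEFAULT_MIX <- c("Mutator" = 0.35, "Tc1/Mariner" = 0.20,
                  "PIF/Harbinger" = 0.15, "hAT" = 0.12,
                  "CACTA" = 0.10, "Micron" = 0.08)

#' Simulation specification for a planted-MITE genome
#'
#' Defaults describe the package's standard benchmark genome: 1 Mb over five
#' contigs at 42% GC carrying ten families of twenty copies each, with
#' per-copy expected divergence drawn uniformly from a recent amplification
#' burst (`K* in [0, 0.05]`, i.e. insertions within the last ~1.9 My at the
#' default rate).
#'
#' @param genome_length total genome size in bp.
#' @param n_contigs number of contigs (sizes equal up to rounding).
#' @param gc_content background GC fraction in (0,1).
#' @param n_families number of planted families.
#' @param copies_per_family copies planted per family.
#' @param superfamily_mix named numeric vector of superfamily fractions
#'   (must sum to 1).
#' @param age_model `data.frame` with columns `weight`, `k_min`, `k_max`:
#'   a mixture of uniform divergence components; each copy draws its
#'   expected divergence `K*` from one component. A burst at age `T` years
#'   corresponds to a component centred on `K* = 2 * rate * T`.
#' @param rate host substitution rate r (substitutions/site/year), used to
#'   translate planted divergences into ages.
#' @param kappa transition/transversion rate ratio of the mutation engine.
#' @param seed integer RNG seed; the same spec regenerates the same genome
#'   byte for byte.
#' @return object of class `mite_sim_spec`.
#' @export
simulation_spec <- function(genome_length = 1e6L, n_contigs = 5L,
                            gc_content = 0.42, n_families = 10L,
                            copies_per_family = 20L,
                            superfamily_mix = .DEFAULT_MIX,
                            age_model = data.frame(weight = 1,
                                                   k_min = 0, k_max = 0.05),
                            rate = 1.3e-8, kappa = 2, seed = 1L) {
  if (gc_content <= 0 || gc_content >= 1) .stopf("gc_content must be in (0,1)")
  if (abs(sum(superfamily_mix) - 1) > 1e-8)
    .stopf("superfamily_mix fractions must sum to 1")
  if (any(c(genome_length, n_contigs, copies_per_family) < 1) ||
      n_families < 0)
    .stopf("counts must be positive")
  if (abs(sum(age_model$weight) - 1) > 1e-8)
    .stopf("age_model weights must sum to 1")
  structure(list(genome_length = as.integer(genome_length),
                 n_contigs = as.integer(n_contigs),
                 gc_content = gc_content, n_families = as.integer(n_families),
                 copies_per_family = as.integer(copies_per_family),
                 superfamily_mix = superfamily_mix, age_model = age_model,
                 rate = rate, kappa = kappa, seed = as.integer(seed)),
            class = "mite_sim_spec")
}

# Construct a random master element for a superfamily: perfect TIRs, a
# superfamily-consistent TSD, and (for Micron) a microsatellite context
# string to be written immediately outside the left TSD.
.make_master <- function(superfamily, gc) {
  elem_len <- sample(120:450, 1L)
  tsd <- switch(superfamily,
    "Tc1/Mariner" = "TA",
    "PIF/Harbinger" = sample(c("TAA", "TTA"), 1L),
    "Mutator" = .random_dna(sample(9:10, 1L), gc),
    "hAT" = .random_dna(8L, gc),
    "CACTA" = .random_dna(sample(2:3, 1L), gc),
    "Micron" = "TA")
  tir_len <- switch(superfamily,
    "Tc1/Mariner" = sample(15:30, 1L),
    "PIF/Harbinger" = sample(14:25, 1L),
    "Mutator" = sample(30:60, 1L),
    "hAT" = sample(10:15, 1L),
    "CACTA" = sample(12:20, 1L),
    "Micron" = sample(12:20, 1L))
  tir <- .random_dna(tir_len, gc)
  if (superfamily == "CACTA")
    tir <- paste0(sample(c("CACTA", "CACTG"), 1L),
                  substring(tir, 6L, tir_len))
  internal <- .random_dna(elem_len - 2L * tir_len, gc)
  context <- if (superfamily == "Micron")
    paste(rep("TA", sample(5:8, 1L)), collapse = "") else ""
  list(superfamily = superfamily, seq = paste0(tir, internal, revcomp(tir)),
       tsd = tsd, tir_len = tir_len, context = context)
}

.draw_k <- function(n, age_model) {
  comp <- sample.int(nrow(age_model), n, replace = TRUE,
                     prob = age_model$weight)
  runif(n, age_model$k_min[comp], age_model$k_max[comp])
}

# Place n_items insertion points on contigs so that inserted blocks plus
# min_gap never collide. Returns data.frame(contig_idx, pos) with pos in
# 0-based background coordinates.
.draw_sites <- function(contig_lens, n_items, block_len, min_gap = 150L) {
  slots <- block_len + min_gap
  per_cap <- pmax(0L, floor((contig_lens - min_gap) / slots))
  if (sum(per_cap) < n_items)
    .stopf("genome too small to host %d insertions without overlap", n_items)
  # spread items over contigs proportionally to capacity
  contig_idx <- rep(seq_along(contig_lens), per_cap)
  pick <- sort(sample.int(length(contig_idx), n_items))
  out <- data.frame(contig_idx = contig_idx[pick], pos = NA_integer_)
  for (ci in unique(out$contig_idx)) {
    k <- sum(out$contig_idx == ci)
    # jitter within a regular grid keeps neighbouring blocks >= min_gap apart
    grid <- floor(seq(min_gap, contig_lens[ci] - slots, length.out = k + 1L))
    lo <- grid[seq_len(k)]
    hi <- pmax(lo, grid[-1L] - slots)
    out$pos[out$contig_idx == ci] <-
      as.integer(lo + floor(runif(k) * (hi - lo + 1L)))
  }
  out
}

.empty_truth <- function() {
  data.frame(element_id = character(0), family_id = character(0),
             superfamily = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             tsd_seq = character(0), tir_length = integer(0),
             planted_K = numeric(0), stringsAsFactors = FALSE)
}

# Splice planted blocks into one background contig, tracking final element
# coordinates. `rows` must be sorted by pos and carry columns: pos, context,
# tsd, elem_seq (already mutated, WITHOUT tsds), planted block assembled here.
.splice_contig <- function(bg, rows) {
  pieces <- character(0)
  cursor <- 0L
  out_len <- 0L
  starts <- integer(nrow(rows))
  ends <- integer(nrow(rows))
  for (r in seq_len(nrow(rows))) {
    pre <- substring(bg, cursor + 1L, rows$pos[r])
    block <- paste0(rows$context[r], rows$left_tsd[r], rows$elem_seq[r],
                    rows$right_tsd[r])
    starts[r] <- out_len + nchar(pre) + nchar(rows$context[r]) +
      nchar(rows$left_tsd[r])
    ends[r] <- starts[r] + nchar(rows$elem_seq[r])
    pieces <- c(pieces, pre, block)
    out_len <- out_len + nchar(pre) + nchar(block)
    cursor <- rows$pos[r]
  }
  pieces <- c(pieces, substring(bg, cursor + 1L, nchar(bg)))
  list(seq = paste(pieces, collapse = ""), start = starts, end = ends)
}

#' Generate a genome with planted MITE families and a truth set
#'
#' Background sequence is i.i.d. at the spec's GC. Each family has a master
#' sequence with perfect TIRs and a superfamily-consistent TSD; each copy is
#' inserted at a random non-colliding position with its TSD written on both
#' flanks (the target-site duplication convention), then the TSD+element+TSD
#' block is mutated under K80 at the copy's drawn expected divergence `K*`,
#' so old copies carry degenerate TSDs and TIRs exactly as real ones do.
#' Micron families additionally receive a `(TA)n` microsatellite context
#' immediately outside the insertion.
#'
#' @param spec a [simulation_spec()].
#' @return list with `genome` (named character vector), `truth`
#'   (`data.frame`: `element_id`, `family_id`, `superfamily`, `contig_id`,
#'   `start`, `end` (0-based half-open, element without TSDs), `strand`,
#'   `tsd_seq`, `tir_length`, `planted_K`), `masters` (named character
#'   vector of family master sequences) and `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "mite_sim_spec"))
  n_fam <- spec$n_families
  n_copies <- n_fam * spec$copies_per_family

  masters <- .with_phase_seed(spec$seed, 101L, {
    sf <- if (n_fam > 0L)
      sample(names(spec$superfamily_mix), n_fam, replace = TRUE,
             prob = spec$superfamily_mix) else character(0)
    lapply(sf, .make_master, gc = spec$gc_content)
  })
  fam_ids <- if (n_fam > 0L) sprintf("FAM%03d", seq_len(n_fam)) else character(0)

  base_lens <- rep(floor(spec$genome_length / spec$n_contigs), spec$n_contigs)
  base_lens[1L] <- base_lens[1L] + spec$genome_length %% spec$n_contigs
  contigs <- .with_phase_seed(spec$seed, 102L, {
    vapply(base_lens, .random_dna, character(1), gc = spec$gc_content)
  })
  names(contigs) <- paste0("contig", seq_along(contigs))

  if (n_copies == 0L || n_fam == 0L)
    return(list(genome = contigs, truth = .empty_truth(),
                masters = character(0), spec = spec))

  max_block <- max(vapply(masters, function(m)
    nchar(m$seq) + 2L * nchar(m$tsd) + nchar(m$context), integer(1)))
  plan <- .with_phase_seed(spec$seed, 103L, {
    sites <- .draw_sites(base_lens, n_copies, max_block)
    sites$family_idx <- sample(rep(seq_len(n_fam), spec$copies_per_family))
    sites$planted_K <- .draw_k(n_copies, spec$age_model)
    sites
  })

  genome <- character(length(contigs))
  names(genome) <- names(contigs)
  truth_list <- vector("list", length(contigs))
  copy_base <- 0L
  set.seed((spec$seed + 104L) %% .Machine$integer.max)
  for (ci in seq_along(contigs)) {
    rows <- plan[plan$contig_idx == ci, , drop = FALSE]
    rows <- rows[order(rows$pos), , drop = FALSE]
    n_r <- nrow(rows)
    if (n_r == 0L) {
      genome[ci] <- contigs[[ci]]
      truth_list[[ci]] <- NULL
      next
    }
    blk <- data.frame(pos = rows$pos, context = NA_character_,
                      left_tsd = NA_character_, right_tsd = NA_character_,
                      elem_seq = NA_character_, stringsAsFactors = FALSE)
    elen <- integer(n_r)
    for (r in seq_len(n_r)) {
      m <- masters[[rows$family_idx[r]]]
      tl <- nchar(m$tsd)
      mut <- mutate_k2p(paste0(m$tsd, m$seq, m$tsd),
                        rows$planted_K[r], spec$kappa)
      blk$context[r] <- m$context
      blk$left_tsd[r] <- substring(mut, 1L, tl)
      blk$elem_seq[r] <- substring(mut, tl + 1L, nchar(mut) - tl)
      blk$right_tsd[r] <- substring(mut, nchar(mut) - tl + 1L, nchar(mut))
      elen[r] <- nchar(m$seq)
    }
    sp <- .splice_contig(contigs[[ci]], blk)
    genome[ci] <- sp$seq
    truth_list[[ci]] <- data.frame(
      element_id = sprintf("MITE%05d", copy_base + seq_len(n_r)),
      family_id = fam_ids[rows$family_idx],
      superfamily = vapply(masters[rows$family_idx], `[[`, character(1),
                           "superfamily"),
      contig_id = names(contigs)[ci],
      start = sp$start, end = sp$end, strand = ".",
      tsd_seq = vapply(masters[rows$family_idx], `[[`, character(1), "tsd"),
      tir_length = vapply(masters[rows$family_idx], function(m)
        as.integer(m$tir_len), integer(1)),
      planted_K = rows$planted_K, stringsAsFactors = FALSE)
    copy_base <- copy_base + n_r
  }
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  list(genome = genome, truth = truth,
       masters = setNames(vapply(masters, `[[`, character(1), "seq"), fam_ids),
       spec = spec)
}

#' Generate non-overlapping gene models on a genome
#'
#' Plants simple multi-exon gene models (1-3 exons, both strands) at
#' non-colliding positions, for exercising the gene-context module.
#'
#' @param genome named character vector of contigs.
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @return `mite_genes` data.frame as from [read_gff()].
#' @export
generate_gene_models <- function(genome, n_genes = 50L, seed = 1L) {
  lens <- nchar(genome)
  .with_phase_seed(seed, 301L, {
    sites <- .draw_sites(lens, n_genes, 2500L, min_gap = 11000L)
    gene_rows <- vector("list", n_genes)
    exon_list <- list()
    for (i in seq_len(n_genes)) {
      n_ex <- sample(1:3, 1L)
      ex_len <- sample(100:300, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(80:200, n_ex - 1L, replace = TRUE)
                else integer(0)
      gstart <- sites$pos[i]
      offs <- cumsum(c(0L, head(as.integer(ex_len + c(in_len, 0L)),
                                n_ex - 1L)))
      ex <- cbind(start = gstart + offs, end = gstart + offs + ex_len)
      gid <- sprintf("gene%04d", i)
      gene_rows[[i]] <- data.frame(
        gene_id = gid, contig_id = names(genome)[sites$contig_idx[i]],
        start = gstart, end = max(ex[, "end"]),
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      exon_list[[gid]] <- ex
    }
    out <- do.call(rbind, gene_rows)
    attr(out, "exons") <- exon_list
    class(out) <- c("mite_genes", class(out))
    out
  })
}

#' Write gene models to GFF3
#'
#' @param genes a `mite_genes` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  exons <- attr(genes, "exons")
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    writeLines(paste(genes$contig_id[i], "mitekit", "gene",
                     genes$start[i] + 1L, genes$end[i], ".",
                     genes$strand[i], ".", paste0("ID=", gid), sep = "\t"),
               con)
    ex <- exons[[gid]]
    for (j in seq_len(nrow(ex)))
      writeLines(paste(genes$contig_id[i], "mitekit", "exon",
                       ex[j, 1L] + 1L, ex[j, 2L], ".", genes$strand[i], ".",
                       paste0("ID=", gid, ".e", j, ";Parent=", gid),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Generate a miRNA precursor set with known MITE provenance
#'
#' `n_from_mite` precursors copy at least 60% of their length from a planted
#' element (lightly mutated, 5% expected divergence); `n_background`
#' precursors are random hairpin-forming stem-loops with no planted
#' homology.
#'
#' @param genome named character vector of contigs.
#' @param truth truth table from [generate_genome()].
#' @param n_from_mite number of MITE-derived precursors.
#' @param n_background number of background precursors.
#' @param seed RNG seed.
#' @return `data.frame` with `mirna_id`, `sequence`, `from_mite`,
#'   `element_id`.
#' @export
generate_mirna_set <- function(genome, truth, n_from_mite = 10L,
                               n_background = 10L, seed = 1L) {
  if (n_from_mite > 0L && nrow(truth) == 0L)
    .stopf("truth has no planted MITEs to derive precursors from")
  .with_phase_seed(seed, 401L, {
    rows <- list()
    if (n_from_mite > 0L) {
      big <- truth[truth$end - truth$start >= 120L, , drop = FALSE]
      pick <- big[sample.int(nrow(big), n_from_mite, replace = TRUE), ]
      for (i in seq_len(n_from_mite)) {
        elem <- substring(genome[[pick$contig_id[i]]],
                          pick$start[i] + 1L, pick$end[i])
        plen <- sample(100:180, 1L)
        core_len <- min(nchar(elem), ceiling(0.6 * plen))
        off <- sample.int(nchar(elem) - core_len + 1L, 1L)
        core <- mutate_k2p(substring(elem, off, off + core_len - 1L), 0.05)
        pad <- plen - core_len
        seq <- paste0(.random_dna(floor(pad / 2)), core,
                      .random_dna(ceiling(pad / 2)))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = sprintf("mir_mite%03d", i), sequence = seq,
          from_mite = TRUE, element_id = pick$element_id[i],
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(n_background)) {
      arm <- .random_dna(sample(35:60, 1L))
      loop <- .random_dna(8L)
      seq <- paste0(arm, loop, revcomp(mutate_k2p(arm, 0.05)))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = sprintf("mir_bg%03d", i), sequence = seq,
        from_mite = FALSE, element_id = NA_character_,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate an orthologous multi-species insertion scenario
#'
#' An ancestral genome is generated and MITE loci are planted at well
#' separated positions. A deterministic `round(shared_fraction * n_loci)`
#' loci are present in every species (shared); the rest are present in
#' exactly one carrier species and absent - flanks contiguous - in the
#' others (species-specific). Each species genome is then mutated under K80
#' so that orthologous flanks of any two species differ by about
#' `1 - flank_conservation` substitutions per site.
#'
#' @param n_species number of species (>= 2).
#' @param n_loci number of planted loci.
#' @param shared_fraction fraction of loci shared by all species.
#' @param flank_conservation expected flank identity between two species.
#' @param genome_length ancestral genome length (bp).
#' @param gc_content background GC fraction.
#' @param seed RNG seed.
#' @return list with `genomes` (named list of single-contig genomes,
#'   `sp1..spN`), `loci` (per-locus truth: `locus_id`, `locus_class`,
#'   `carrier`), and `truth` (per-species element records with coordinates:
#'   `locus_id`, `species_id`, `contig_id`, `start`, `end`, `locus_class`).
#' @export
generate_ortholog_scenario <- function(n_species = 3L, n_loci = 20L,
                                       shared_fraction = 0.3,
                                       flank_conservation = 0.95,
                                       genome_length = 150000L,
                                       gc_content = 0.42, seed = 7L) {
  if (n_species < 2L) .stopf("n_species must be >= 2")
  if (shared_fraction < 0 || shared_fraction > 1)
    .stopf("shared_fraction must be in [0, 1]")
  n_shared <- as.integer(round(shared_fraction * n_loci))
  sp_ids <- paste0("sp", seq_len(n_species))
  div_per_species <- (1 - flank_conservation) / 2

  anc <- .with_phase_seed(seed, 501L, .random_dna(genome_length, gc_content))
  scen <- .with_phase_seed(seed, 502L, {
    masters <- lapply(sample(names(.DEFAULT_MIX), 3L, replace = TRUE),
                      .make_master, gc = gc_content)
    sites <- .draw_sites(genome_length, n_loci, 600L, min_gap = 4500L)
    list(masters = masters, sites = sites,
         fam_idx = sample.int(3L, n_loci, replace = TRUE),
         class = sample(rep(c("shared", "specific"),
                            c(n_shared, n_loci - n_shared))),
         carrier = sample.int(n_species, n_loci, replace = TRUE))
  })
  loci <- data.frame(
    locus_id = sprintf("locus%03d", seq_len(n_loci)),
    locus_class = scen$class,
    carrier = ifelse(scen$class == "shared", sp_ids[1L],
                     sp_ids[scen$carrier]),
    stringsAsFactors = FALSE)

  elem_seqs <- .with_phase_seed(seed, 503L, {
    vapply(seq_len(n_loci), function(i) {
      m <- scen$masters[[scen$fam_idx[i]]]
      mutate_k2p(m$seq, 0.02)
    }, character(1))
  })

  genomes <- setNames(vector("list", n_species), sp_ids)
  truth_rows <- list()
  for (s in seq_len(n_species)) {
    present <- scen$class == "shared" |
      (scen$class == "specific" & scen$carrier == s)
    if (!any(present)) {
      genomes[[s]] <- setNames(
        .with_phase_seed(seed, 510L + s, mutate_k2p(anc, div_per_species)),
        "chr1")
      next
    }
    rows <- data.frame(pos = scen$sites$pos[present],
                       context = "",
                       left_tsd = vapply(scen$masters[scen$fam_idx[present]],
                                         `[[`, character(1), "tsd"),
                       right_tsd = vapply(scen$masters[scen$fam_idx[present]],
                                          `[[`, character(1), "tsd"),
                       elem_seq = elem_seqs[present],
                       stringsAsFactors = FALSE)
    ord <- order(rows$pos)
    rows <- rows[ord, , drop = FALSE]
    sp <- .splice_contig(anc, rows)
    mutated <- .with_phase_seed(seed, 510L + s,
                                mutate_k2p(sp$seq, div_per_species))
    genomes[[s]] <- setNames(mutated, "chr1")
    truth_rows[[s]] <- data.frame(
      locus_id = loci$locus_id[present][ord],
      species_id = sp_ids[s], contig_id = "chr1",
      start = sp$start, end = sp$end,
      locus_class = scen$class[present][ord],
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(genomes = genomes, loci = loci, truth = truth)
}
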