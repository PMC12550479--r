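# Genome-wide recovery of all family copies from the curated seed library,
# emulating the repeat-masking stage of a MITE annotation pipeline: k-mer
# seeded, gapped local alignment of each library seed around co-linear seed
# matches, retention at Kimura divergence <= 15% and a minimum alignment
# score, per-family merging and cross-family overlap resolution, plus the
# four landscape indices.

.SCAN_SUBST <- NULL  # built lazily; nucleotideSubstitutionMatrix(1, -1)

.scan_subst_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

# Fraction of the hit covered by its most abundant dinucleotide step
# (the "-nolow" equivalent low-complexity test).
.dinuc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n < 4L) return(0)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  steps <- paste0(chars[-n], chars[-1L])
  best <- names(sort(table(steps), decreasing = TRUE))[1L]
  # count positions lying inside a run of the best step
  run <- gregexpr(sprintf("(%s)+", best), seq)[[1L]]
  if (run[1L] == -1L) return(0)
  sum(attr(run, "match.length")) / n
}

# K2P divergence and identity of a pairwise alignment object (gap-free
# columns only for the divergence; identity = matches / columns).
.aln_stats <- function(pat_str, sub_str) {
  p <- strsplit(pat_str, "", fixed = TRUE)[[1L]]
  s <- strsplit(sub_str, "", fixed = TRUE)[[1L]]
  ident <- sum(p == s & p != "-") / length(p)
  keep <- p != "-" & s != "-"
  kd <- k2p(paste(p[keep], collapse = ""), paste(s[keep], collapse = ""))
  list(identity = ident, k2p = kd)
}

#' Scan a genome with a MITE seed library
#'
#' For every seed (both orientations) exact 11-mers are located through a
#' dictionary match, co-linear matches are grouped into windows, and the
#' seed is aligned locally (match +1, mismatch -1, gap open -4, extend -1)
#' inside each window. Hits are retained when the K80 divergence of the
#' gap-free alignment columns is at most `max_divergence` and the score
#' reaches `min_score`; overlapping hits of one family merge; cross-family
#' conflicts (>50% reciprocal overlap) resolve to the highest score. Hits
#' made of more than 80% of a single dinucleotide are dropped unless the
#' family is Micron, preventing microsatellite pileup while keeping the
#' microsatellite-context class.
#'
#' @param genome named character vector of contigs.
#' @param seeds named character vector of seed sequences; names are
#'   `familyID` or `familyID#superfamily`.
#' @param max_divergence K80 divergence ceiling (default 0.15, the `-div 15`
#'   convention).
#' @param min_score minimum alignment score (default 50, the shortest
#'   admissible perfect 50 bp hit under this scoring).
#' @param k seeding word size.
#' @param full_length_coverage seed coverage at or above which a hit with
#'   both ends present counts as full length.
#' @return hit `data.frame` (see [write_annotation()] for the columns).
#' @export
scan_genome <- function(genome, seeds, max_divergence = 0.15,
                        min_score = 50, k = 11L,
                        full_length_coverage = 0.9) {
  if (length(seeds) == 0L) .stopf("empty seed library")
  fam_ids <- sub("#.*$", "", names(seeds))
  superfams <- ifelse(grepl("#", names(seeds)),
                      sub("^.*#", "", names(seeds)), "unknown")
  # dictionary of all seed k-mers, both orientations
  kmer_tab <- list()
  for (si in seq_along(seeds)) {
    s <- seeds[[si]]
    ls <- nchar(s)
    if (ls < k) next
    for (strand in c("+", "-")) {
      ss <- if (strand == "+") s else revcomp(s)
      starts <- seq_len(ls - k + 1L)
      kmer_tab[[length(kmer_tab) + 1L]] <- data.table::data.table(
        kmer = substring(ss, starts, starts + k - 1L),
        seed_idx = si, strand = strand, qpos = starts)
    }
  }
  kt <- data.table::rbindlist(kmer_tab)
  kt <- kt[!grepl("N", kt$kmer, fixed = TRUE)]
  if (nrow(kt) == 0L) .stopf("seed library has no usable %d-mers", k)
  uniq <- unique(kt$kmer)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq))

  hits_out <- list()
  for (cid in names(genome)) {
    subject <- Biostrings::DNAString(genome[[cid]])
    clen <- length(subject)
    mt <- Biostrings::matchPDict(pd, subject)
    starts_by_kmer <- Biostrings::startIndex(mt)
    anchor_list <- list()
    for (ui in seq_along(uniq)) {
      tpos <- starts_by_kmer[[ui]]
      if (is.null(tpos) || length(tpos) == 0L) next
      rows <- kt[kt$kmer == uniq[ui]]
      anchor_list[[length(anchor_list) + 1L]] <-
        data.table::data.table(seed_idx = rep(rows$seed_idx, each = length(tpos)),
                               strand = rep(rows$strand, each = length(tpos)),
                               qpos = rep(rows$qpos, each = length(tpos)),
                               tpos = rep(tpos, times = nrow(rows)))
    }
    if (length(anchor_list) == 0L) next
    anchors <- data.table::rbindlist(anchor_list)

    for (grp in split(anchors,
                      paste(anchors$seed_idx, anchors$strand))) {
      si <- grp$seed_idx[1L]
      strand <- grp$strand[1L]
      ls <- nchar(seeds[[si]])
      qseq <- if (strand == "+") seeds[[si]] else revcomp(seeds[[si]])
      grp <- grp[order(grp$tpos)]
      # windows: break where consecutive anchor target positions jump by
      # more than one seed length
      brk <- c(0L, which(diff(grp$tpos) > ls), nrow(grp))
      for (wi in seq_len(length(brk) - 1L)) {
        sub <- grp[(brk[wi] + 1L):brk[wi + 1L]]
        w_lo <- max(1L, min(sub$tpos) - max(sub$qpos) - 20L)
        w_hi <- min(clen, max(sub$tpos) + k - 1L +
                      (ls - min(sub$qpos)) + 20L)
        win <- Biostrings::subseq(subject, w_lo, w_hi)
        aln <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::DNAString(qseq), subject = win,
          type = "local", substitutionMatrix = .scan_subst_matrix(),
          gapOpening = 3, gapExtension = 1)
        if (Biostrings::score(aln) < min_score) next
        st <- .aln_stats(as.character(Biostrings::pattern(aln)),
                         as.character(Biostrings::subject(aln)))
        if (!st$k2p$valid || st$k2p$K > max_divergence) next
        sr <- aln@subject@range
        qr <- aln@pattern@range
        qlo <- IRanges::start(qr); qhi <- IRanges::end(qr)
        if (strand == "-") {  # map back to seed coordinates
          tmp <- ls - qhi + 1L
          qhi <- ls - qlo + 1L
          qlo <- tmp
        }
        full <- (qhi - qlo + 1L) >= full_length_coverage * ls &&
          qlo <= 10L && qhi >= ls - 9L
        hit_start <- w_lo + IRanges::start(sr) - 2L  # 0-based
        hit_end <- w_lo + IRanges::end(sr) - 1L
        hseq <- substring(genome[[cid]], hit_start + 1L, hit_end)
        if (.dinuc_fraction(hseq) > 0.8 && superfams[si] != "Micron") next
        hits_out[[length(hits_out) + 1L]] <- data.frame(
          family_id = fam_ids[si], superfamily = superfams[si],
          contig_id = cid, start = hit_start, end = hit_end,
          strand = if (strand == "-") "-" else ".",
          identity_to_seed = st$identity, kimura_divergence = st$k2p$K,
          full_length = full, score = Biostrings::score(aln),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits_out) == 0L) return(.empty_hits())
  hits <- do.call(rbind, hits_out)
  hits <- .merge_family_hits(hits)
  hits <- .resolve_cross_family(hits)
  hits <- hits[order(hits$contig_id, hits$start, hits$end), , drop = FALSE]
  hits$hit_id <- sprintf("hit%05d", seq_len(nrow(hits)))
  rownames(hits) <- NULL
  hits[, .HIT_COLS]
}

# Merge overlapping hits of the same family on the same contig; the merged
# record keeps the best-scoring constituent's statistics and the union
# interval.
.merge_family_hits <- function(hits) {
  out <- list()
  for (key in unique(paste(hits$family_id, hits$contig_id))) {
    hh <- hits[paste(hits$family_id, hits$contig_id) == key, , drop = FALSE]
    ir <- IRanges::IRanges(start = hh$start + 1L, end = hh$end)
    red <- IRanges::reduce(ir)
    grp <- IRanges::findOverlaps(ir, red, select = "first")
    for (g in seq_along(red)) {
      members <- hh[grp == g, , drop = FALSE]
      best <- members[which.max(members$score), , drop = FALSE]
      best$start <- IRanges::start(red)[g] - 1L
      best$end <- IRanges::end(red)[g]
      out[[length(out) + 1L]] <- best
    }
  }
  do.call(rbind, out)
}

# Cross-family conflicts: >50% reciprocal overlap keeps the highest score.
.resolve_cross_family <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$score)
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    if (!keep[i]) next
    for (pos2 in seq_along(ord)) {
      j <- ord[pos2]
      if (j == i || !keep[j] || hits$score[j] > hits$score[i]) next
      if (hits$contig_id[i] != hits$contig_id[j]) next
      if (hits$family_id[i] == hits$family_id[j]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (ov <= 0) next
      if (ov > 0.5 * (hits$end[i] - hits$start[i]) &&
          ov > 0.5 * (hits$end[j] - hits$start[j])) keep[j] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Landscape summary of a hit set
#'
#' The four landscape indices: genome proportion (merged masked bases /
#' genome size, percent), copy density per Mb, mean hit length and the
#' number of distinct families hit.
#'
#' @param hits hit `data.frame`.
#' @param genome named character vector of contigs.
#' @return one-row `data.frame`: `proportion_of_genome`, `density_per_mb`,
#'   `mean_length`, `family_count`.
#' @export
summarize_landscape <- function(hits, genome) {
  gsize <- sum(nchar(genome))
  if (nrow(hits) == 0L)
    return(data.frame(proportion_of_genome = 0, density_per_mb = 0,
                      mean_length = 0, family_count = 0L))
  masked <- 0L
  for (cid in unique(hits$contig_id)) {
    hh <- hits[hits$contig_id == cid, ]
    masked <- masked +
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = hh$start + 1L, end = hh$end))))
  }
  data.frame(proportion_of_genome = 100 * masked / gsize,
             density_per_mb = nrow(hits) / (gsize / 1e6),
             mean_length = mean(hits$end - hits$start),
             family_count = length(unique(hits$family_id)))
}
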