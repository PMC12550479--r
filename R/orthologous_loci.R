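# Shared vs species-specific classification of MITE insertion loci.
#
# Each full-length element is extended by 1 kb of flank on both sides and
# searched against the other genomes. Local alignments are kept at E-value
# < 1e-9 (Karlin-Altschul, +2/-3 nucleotide parameters) and identity > 80%;
# hits landing within 1 kb of each other on the target merge into one locus
# region. A species shows the locus as *shared* when one region covers
# essentially the whole query including the element, and as an *empty site*
# (specific_absent) when both flanks align with a target-side interspacing
# under 1 kb while the element span itself is absent.

#' Build a flank-extended ortholog query
#'
#' @param genome named character vector of contigs (reference species).
#' @param contig_id,start,end element interval (0-based half-open).
#' @param flank_len flank extension in bp (default 1000); truncated at
#'   contig ends.
#' @return list with `seq`, `elem_lo`, `elem_hi` (1-based element span
#'   within the query), `query_len`.
#' @export
build_ortho_query <- function(genome, contig_id, start, end,
                              flank_len = 1000L) {
  if (flank_len <= 0L) .stopf("flank_len must be positive")
  if (!(contig_id %in% names(genome)))
    .stopf("unknown contig: %s", contig_id)
  s <- genome[[contig_id]]
  L <- nchar(s)
  lo <- max(0L, start - flank_len)
  hi <- min(L, end + flank_len)
  list(seq = substring(s, lo + 1L, hi),
       elem_lo = start - lo + 1L,
       elem_hi = end - lo,
       query_len = hi - lo)
}

# Split one gapped full local alignment into maximal-scoring segments with
# an X-drop rule: walking the per-column score path (match +2, mismatch
# -3, gap open -5, extend -2), a segment ends at its running score maximum
# whenever the path later falls more than `xdrop` below that maximum.
# This is how a local aligner's extension would terminate, so a long
# deletion (an excised element at an empty site) or an unrelated spacer
# splits into separate HSP-like blocks instead of being bridged.
.alignment_blocks <- function(pat, sub, q_off, t_off, xdrop = 40) {
  p <- strsplit(pat, "", fixed = TRUE)[[1L]]
  s <- strsplit(sub, "", fixed = TRUE)[[1L]]
  gap <- p == "-" | s == "-"
  col_score <- ifelse(gap, -2, ifelse(p == s, 2, -3))
  gap_start <- gap & c(TRUE, !gap[-length(gap)])
  col_score[gap_start] <- col_score[gap_start] - 5
  qpos <- cumsum(p != "-") + q_off - 1L
  tpos <- cumsum(s != "-") + t_off - 1L

  rows <- list()
  emit <- function(lo, hi) {
    idx <- lo:hi
    idx <- idx[!gap[idx]]
    if (length(idx) < 20L) return()
    cols <- min(idx):max(idx)
    matches <- sum(p[cols] == s[cols] & !gap[cols])
    rows[[length(rows) + 1L]] <<- data.frame(
      q_lo = qpos[min(idx)], q_hi = qpos[max(idx)],
      t_lo = tpos[min(idx)], t_hi = tpos[max(idx)],
      identity = matches / length(cols),
      score = sum(col_score[cols]),
      stringsAsFactors = FALSE)
  }
  seg_start <- 1L
  cur <- 0
  max_val <- 0
  max_pos <- 0L
  for (i in seq_along(col_score)) {
    cur <- cur + col_score[i]
    if (cur > max_val) { max_val <- cur; max_pos <- i }
    if (cur < 0) {                      # prefix is pure loss: restart
      if (max_val > 0) emit(seg_start, max_pos)
      seg_start <- i + 1L
      cur <- 0; max_val <- 0; max_pos <- i
    } else if (max_val - cur >= xdrop) {  # X-drop: close at the maximum
      emit(seg_start, max_pos)
      seg_start <- i + 1L
      cur <- 0; max_val <- 0; max_pos <- i
    }
  }
  if (max_val > 0 && max_pos >= seg_start) emit(seg_start, max_pos)
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# Iterative local alignment of query against a target window with masking,
# under the +2/-3 scheme used for E-values. Each alignment is split into
# blocks at long gap runs; blocks are filtered individually. Returns
# data.frame of hits with query spans (1-based, query coordinates) and
# target spans (1-based contig coordinates).
.window_hits <- function(query, target_win, win_offset, n_search,
                         evalue_max, identity_min, max_rounds = 6L) {
  subst <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE)
  m <- nchar(query)
  hits <- list()
  win <- target_win
  for (round in seq_len(max_rounds)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(query),
      subject = Biostrings::DNAString(win),
      type = "local", substitutionMatrix = subst,
      gapOpening = 5, gapExtension = 2)
    sr <- aln@subject@range
    qr <- aln@pattern@range
    if (IRanges::width(sr) < 20L || Biostrings::score(aln) <= 0) break
    blocks <- .alignment_blocks(as.character(Biostrings::pattern(aln)),
                                as.character(Biostrings::subject(aln)),
                                IRanges::start(qr), IRanges::start(sr))
    found <- FALSE
    if (!is.null(blocks)) {
      blocks$evalue <- karlin_altschul_evalue(blocks$score, m, n_search)
      blocks$t_lo <- win_offset + blocks$t_lo - 1L
      blocks$t_hi <- win_offset + blocks$t_hi - 1L
      keep <- blocks$evalue < evalue_max & blocks$identity > identity_min
      if (any(keep)) {
        hits[[length(hits) + 1L]] <- blocks[keep, , drop = FALSE]
        found <- TRUE
      }
    }
    if (!found && round > 1L) break
    # mask the found subject span and search again for secondary matches
    mask <- paste(rep("N", IRanges::width(sr)), collapse = "")
    win <- paste0(substring(win, 1L, IRanges::start(sr) - 1L), mask,
                  substring(win, IRanges::end(sr) + 1L, nchar(win)))
  }
  if (length(hits) == 0L) return(NULL)
  do.call(rbind, hits)
}

#' Search a target genome for homologs of an ortholog query
#'
#' k-mer anchors locate candidate windows; each window is aligned locally
#' under the +2/-3 scheme with iterative masking so that discontiguous
#' blocks (e.g. the two flanks of an empty site) are all recovered. Hits
#' are filtered at `evalue < evalue_max` and `identity > identity_min`,
#' then hits within `merge_gap` bp of each other on the target merge into
#' locus regions.
#'
#' @param query list from [build_ortho_query()].
#' @param target_genome named character vector of contigs.
#' @param evalue_max E-value ceiling (default 1e-9).
#' @param identity_min identity floor (default 0.8).
#' @param merge_gap target-side merge distance (default 1000).
#' @param k anchor word size.
#' @return list of locus regions; each a list with `contig_id`, `t_lo`,
#'   `t_hi`, `hits` (the member hit data.frame).
#' @export
search_homologs <- function(query, target_genome, evalue_max = 1e-9,
                            identity_min = 0.8, merge_gap = 1000L,
                            k = 13L) {
  qseq <- query$seq
  m <- nchar(qseq)
  n_search <- sum(nchar(target_genome))
  starts <- seq(1L, m - k + 1L, by = 4L)  # stride keeps the anchor set lean
  kmers <- substring(qseq, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  kmers <- kmers[ok]; kstart <- starts[ok]
  if (length(kmers) == 0L) return(list())
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unique(kmers)))
  kmap <- split(kstart, kmers)[unique(kmers)]

  regions <- list()
  for (cid in names(target_genome)) {
    subject <- Biostrings::DNAString(target_genome[[cid]])
    clen <- length(subject)
    mt <- Biostrings::matchPDict(pd, subject)
    si <- Biostrings::startIndex(mt)
    tpos <- unlist(si)
    if (is.null(tpos) || length(tpos) == 0L) next
    tpos <- sort(unique(tpos))
    # windows: anchors closer than one query length belong together
    brk <- c(0L, which(diff(tpos) > m), length(tpos))
    for (wi in seq_len(length(brk) - 1L)) {
      tp <- tpos[(brk[wi] + 1L):brk[wi + 1L]]
      w_lo <- max(1L, min(tp) - m)
      w_hi <- min(clen, max(tp) + m)
      hh <- .window_hits(qseq,
                         as.character(Biostrings::subseq(subject, w_lo, w_hi)),
                         w_lo, n_search, evalue_max, identity_min)
      if (is.null(hh)) next
      hh$contig_id <- cid
      regions[[length(regions) + 1L]] <- hh
    }
  }
  if (length(regions) == 0L) return(list())
  allh <- do.call(rbind, regions)
  # merge hits within merge_gap on the target into locus regions
  out <- list()
  for (cid in unique(allh$contig_id)) {
    hh <- allh[allh$contig_id == cid, , drop = FALSE]
    hh <- hh[order(hh$t_lo), , drop = FALSE]
    grp <- cumsum(c(1L, ifelse(hh$t_lo[-1L] -
                                 cummax(hh$t_hi)[-nrow(hh)] > merge_gap,
                               1L, 0L)))
    for (g in unique(grp)) {
      mem <- hh[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- list(contig_id = cid,
                                      t_lo = min(mem$t_lo),
                                      t_hi = max(mem$t_hi),
                                      hits = mem)
    }
  }
  out
}

#' Classify one locus in one target species
#'
#' @param query list from [build_ortho_query()].
#' @param regions locus regions from [search_homologs()] against that
#'   species.
#' @param shared_coverage query coverage at or above which the locus is
#'   shared (element present).
#' @param flank_coverage per-flank coverage floor for the empty-site call.
#' @param element_absent_max element-span coverage ceiling for the
#'   empty-site call.
#' @param max_interspacing maximum target-side gap between the two flank
#'   images of an empty site (bp).
#' @return one of `"shared"`, `"specific_absent"`, `"unresolved"`.
#' @export
classify_species_status <- function(query, regions, shared_coverage = 0.95,
                                    flank_coverage = 0.8,
                                    element_absent_max = 0.2,
                                    max_interspacing = 1000L) {
  if (length(regions) == 0L) return("unresolved")
  qlen <- query$query_len
  e_lo <- query$elem_lo
  e_hi <- query$elem_hi
  elen <- e_hi - e_lo + 1L
  best <- "unresolved"
  for (reg in regions) {
    spans <- as.matrix(reg$hits[, c("q_lo", "q_hi")])
    qcov <- .span_coverage(spans, 1L, qlen) / qlen
    ecov <- .span_coverage(spans, e_lo, e_hi) / elen
    if (qcov >= shared_coverage && ecov >= 0.8) return("shared")
    # empty-site test: both flanks covered, element absent, flank images
    # close together on the target
    lf_len <- e_lo - 1L
    rf_len <- qlen - e_hi
    if (lf_len == 0L || rf_len == 0L) next
    lcov <- .span_coverage(spans, 1L, lf_len) / lf_len
    rcov <- .span_coverage(spans, e_hi + 1L, qlen) / rf_len
    if (lcov >= flank_coverage && rcov >= flank_coverage &&
        ecov < element_absent_max) {
      # interspacing between the rightmost left-flank image and the
      # leftmost right-flank image
      lhits <- reg$hits[reg$hits$q_lo <= lf_len, , drop = FALSE]
      rhits <- reg$hits[reg$hits$q_hi > e_hi, , drop = FALSE]
      if (nrow(lhits) && nrow(rhits)) {
        gap <- min(rhits$t_lo) - max(lhits$t_hi)
        if (gap < max_interspacing) best <- "specific_absent"
      }
    }
  }
  best
}

#' Classify orthologous MITE loci across species
#'
#' For every reference element the flank-extended query is searched in each
#' target species and the per-species status recorded. The locus is
#' `shared` when every non-reference species shows it shared,
#' `species_specific` when every non-reference species shows the empty
#' site, otherwise `ambiguous`. Queries of loci classified shared are then
#' withheld from specific-locus calling by construction (each locus is
#' classified once from its carrier species).
#'
#' @param elements `data.frame` with `locus_id`, `contig_id`, `start`,
#'   `end` of reference elements (in the reference/carrier species).
#' @param ref_genome reference species genome.
#' @param target_genomes named list of other species' genomes.
#' @param flank_len flank extension (bp).
#' @param ... tuning constants passed to [classify_species_status()].
#' @return `data.frame` with `locus_id`, per-species status columns
#'   (`status_<species>`), and `classification`.
#' @export
classify_loci <- function(elements, ref_genome, target_genomes,
                          flank_len = 1000L, ...) {
  sp <- names(target_genomes)
  rows <- vector("list", nrow(elements))
  for (i in seq_len(nrow(elements))) {
    q <- build_ortho_query(ref_genome, elements$contig_id[i],
                           elements$start[i], elements$end[i], flank_len)
    status <- vapply(sp, function(s) {
      regs <- search_homologs(q, target_genomes[[s]])
      classify_species_status(q, regs, ...)
    }, character(1))
    cls <- if (all(status == "shared")) "shared"
           else if (all(status == "specific_absent")) "species_specific"
           else "ambiguous"
    row <- data.frame(locus_id = elements$locus_id[i],
                      classification = cls, stringsAsFactors = FALSE)
    for (s in sp) row[[paste0("status_", s)]] <- status[[s]]
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Presence/absence polymorphism matrix and tree-node assignment
#'
#' Builds the binary species-by-locus matrix from locus classifications.
#' When a rooted, ultrametric tree with branch lengths (in My) is supplied,
#' each locus present in at least two species is assigned to the most
#' recent common ancestor of the species carrying it, and per-node counts
#' plus counts per My of the node's stem branch are reported.
#'
#' @param loci `data.frame` from [classify_loci()] plus a `carrier` column
#'   naming the species the locus was queried from.
#' @param species character vector of all species names.
#' @param tree optional `ape::phylo` tree whose tip labels match `species`.
#' @return list with `matrix` (species x locus 0/1) and, when a tree is
#'   given, `node_counts` (`data.frame`: `node`, `count`, `stem_my`,
#'   `count_per_my`).
#' @export
polymorphism_matrix <- function(loci, species, tree = NULL) {
  mat <- matrix(0L, nrow = length(species), ncol = nrow(loci),
                dimnames = list(species, loci$locus_id))
  for (i in seq_len(nrow(loci))) {
    carrier <- loci$carrier[i]
    mat[carrier, i] <- 1L
    for (s in setdiff(species, carrier)) {
      col <- paste0("status_", s)
      if (col %in% names(loci) && loci[[col]][i] == "shared")
        mat[s, i] <- 1L
    }
  }
  out <- list(matrix = mat)
  if (!is.null(tree)) {
    if (!all(species %in% tree$tip.label))
      .stopf("tree tip labels do not cover the species list")
    node_of <- integer(ncol(mat))
    for (i in seq_len(ncol(mat))) {
      present <- rownames(mat)[mat[, i] == 1L]
      node_of[i] <- if (length(present) == 1L)
        which(tree$tip.label == present)
      else ape::getMRCA(tree, present)
    }
    tab <- table(node_of)
    stem_len <- vapply(as.integer(names(tab)), function(nd) {
      e <- which(tree$edge[, 2L] == nd)
      if (length(e)) tree$edge.length[e] else NA_real_
    }, numeric(1))
    out$node_counts <- data.frame(
      node = as.integer(names(tab)),
      count = as.integer(tab),
      stem_my = stem_len,
      count_per_my = as.integer(tab) / stem_len)
  }
  out
}
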