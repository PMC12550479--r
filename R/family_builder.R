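# Building MITE families from candidates: greedy centroid clustering at 80%
# global identity (emulating vsearch --iddef 1 --id 0.8), the three-copy
# family filter, the 50-bp flank-distinctness collapse, merging of two
# detection sources at <100 bp positional tolerance, and seed selection.

#' Clustering parameter set
#'
#' @param identity_threshold global-alignment identity to join a centroid
#'   (matching columns / alignment columns including end gaps).
#' @param flank_len flank window used by the distinctness filter (bp).
#' @param flank_identity_collapse identity at or above which two members'
#'   concatenated flanks are considered the same insertion.
#' @param merge_tolerance positional tolerance (bp) when merging two
#'   annotation sources.
#' @param min_copies minimum members for a family to be retained.
#' @return object of class `mite_cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 0.8, flank_len = 50L,
                           flank_identity_collapse = 0.8,
                           merge_tolerance = 100L, min_copies = 3L) {
  if (identity_threshold <= 0 || identity_threshold > 1 ||
      flank_identity_collapse <= 0 || flank_identity_collapse > 1)
    .stopf("identity thresholds must be in (0, 1]")
  structure(list(identity_threshold = identity_threshold,
                 flank_len = as.integer(flank_len),
                 flank_identity_collapse = flank_identity_collapse,
                 merge_tolerance = as.integer(merge_tolerance),
                 min_copies = as.integer(min_copies)),
            class = "mite_cluster_params")
}

# Global-alignment identity: matches / alignment columns, end gaps included
# in the column count (the iddef-1 definition). Scoring only steers the
# path: match +1, mismatch -1, gap open -2, extend -1.
.global_identity <- function(a, b) {
  .global_identity_many(a, b)
}

# Vectorised variant: identity of many sequences against one centroid.
# Columns = aligned columns plus clipped terminal tails (end gaps count).
.global_identity_many <- function(seqs, centroid) {
  if (length(seqs) == 0L) return(numeric(0))
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs),
    subject = Biostrings::DNAString(centroid),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 1, gapExtension = 1)
  aligned_cols <- Biostrings::nchar(aln)
  p_tail <- nchar(seqs) - IRanges::width(aln@pattern@range)
  s_tail <- nchar(centroid) - IRanges::width(aln@subject@range)
  Biostrings::nmatch(aln) / (aligned_cols + p_tail + s_tail)
}

#' Greedy centroid clustering of MITE candidates
#'
#' Candidates are processed by decreasing length; each joins the first
#' centroid whose global-alignment identity (end gaps counted) reaches the
#' threshold, otherwise it founds a new centroid. Families smaller than
#' `min_copies` are dissolved into singletons.
#'
#' @param candidates candidate `data.frame` with a `seq` column; an
#'   `element_id` column is added if absent.
#' @param params a [cluster_params()] object.
#' @return list with `families` (named list; each family a list with
#'   `family_id`, `members` data.frame, `seed` placeholder NULL) and
#'   `singletons` (data.frame of unassigned candidates).
#' @export
cluster_candidates <- function(candidates, params = cluster_params()) {
  if (is.null(candidates$element_id))
    candidates$element_id <- sprintf("cand%05d", seq_len(nrow(candidates)))
  if (nrow(candidates) == 0L)
    return(list(families = list(), singletons = candidates))
  ord <- order(-(candidates$end - candidates$start), candidates$contig_id,
               candidates$start)
  cc <- candidates[ord, , drop = FALSE]
  centroid_seq <- character(0)
  assign <- integer(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    hit <- 0L
    if (length(centroid_seq)) {
      # identity of the candidate against every existing centroid in one
      # batched alignment; the first centroid reaching the threshold wins
      ids <- .global_identity_many(centroid_seq, cc$seq[i])
      hits <- which(ids >= params$identity_threshold)
      if (length(hits)) hit <- hits[1L]
    }
    if (hit == 0L) {
      centroid_seq <- c(centroid_seq, cc$seq[i])
      assign[i] <- length(centroid_seq)
    } else assign[i] <- hit
  }
  fam_sizes <- table(assign)
  keep <- as.integer(names(fam_sizes)[fam_sizes >= params$min_copies])
  families <- list()
  fam_no <- 0L
  for (k in sort(keep)) {
    fam_no <- fam_no + 1L
    fid <- sprintf("FAM%03d", fam_no)
    families[[fid]] <- list(family_id = fid,
                            members = cc[assign == k, , drop = FALSE],
                            seed = NULL, consensus = NULL,
                            superfamily = "unknown")
  }
  singles <- cc[!(assign %in% keep), , drop = FALSE]
  rownames(singles) <- NULL
  list(families = families, singletons = singles)
}

.flank_seqs <- function(members, genome, flank_len) {
  vapply(seq_len(nrow(members)), function(i) {
    s <- genome[[members$contig_id[i]]]
    L <- nchar(s)
    left <- substring(s, max(1L, members$start[i] - flank_len + 1L),
                      members$start[i])
    right <- substring(s, members$end[i] + 1L,
                       min(L, members$end[i] + flank_len))
    paste0(left, right)
  }, character(1))
}

#' Collapse family members with indistinct flanking sequences
#'
#' MITEs do not transpose with their flanks, so two members whose
#' concatenated left+right flanks align at or above
#' `flank_identity_collapse` are the same insertion seen twice (e.g. a
#' tandem artefact); the higher-scoring member is retained. The collapse is
#' transitive. Members at contig ends are compared on the available flank
#' only and are never collapsed when no flank exists at all.
#'
#' @param family a family list (from [cluster_candidates()]).
#' @param genome named character vector of contigs.
#' @param params a [cluster_params()] object.
#' @return the family with duplicates removed from `members`.
#' @export
flank_distinctness_filter <- function(family, genome,
                                      params = cluster_params()) {
  m <- family$members
  n <- nrow(m)
  if (n <= 1L) return(family)
  fl <- .flank_seqs(m, genome, params$flank_len)
  # transitive closure via union-find; alignments batched per member
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) {
    if (nchar(fl[i]) == 0L) next
    js <- (i + 1L):n
    js <- js[nchar(fl[js]) > 0L]
    if (length(js) == 0L) next
    ids <- .global_identity_many(fl[js], fl[i])
    for (j in js[ids >= params$flank_identity_collapse]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- vapply(split(seq_len(n), root), function(ix) {
    ix[order(-m$score[ix], m$start[ix])][1L]
  }, integer(1))
  family$members <- m[sort(keep), , drop = FALSE]
  rownames(family$members) <- NULL
  family
}

#' Refine member boundaries by family majority vote
#'
#' Element boundaries of single copies can be ambiguous: a flanking
#' coincidence (e.g. a background base matching the element edge, or a
#' self-complementary TSD absorbed into the TIR) shifts one copy's
#' detected interval by a few bp. Mirroring the curation step in which
#' each element is extended by `flank_len` bp and its boundary corrected
#' against the family, every member's extended sequence is aligned to a
#' reference member, detected boundaries are projected into reference
#' coordinates, and each member is moved to the modal family boundary.
#'
#' @param family a family list with a `members` data.frame.
#' @param genome named character vector of contigs.
#' @param flank_len extension used for the alignment (bp, default 50).
#' @return the family with member `start`/`end`/`seq` corrected.
#' @export
refine_family_boundaries <- function(family, genome, flank_len = 50L) {
  m <- family$members
  n <- nrow(m)
  if (n < 3L) return(family)
  ext <- vector("list", n)
  for (i in seq_len(n)) {
    s <- genome[[m$contig_id[i]]]
    lo <- max(0L, m$start[i] - flank_len)
    hi <- min(nchar(s), m$end[i] + flank_len)
    ext[[i]] <- list(seq = substring(s, lo + 1L, hi), lo = lo,
                     e_lo = m$start[i] - lo + 1L,       # 1-based in ext
                     e_hi = m$end[i] - lo)
  }
  ref <- 1L
  # per-member maps between extended-sequence positions and reference
  # positions, via one batched global alignment against the reference
  maps <- vector("list", n)
  votes_lo <- integer(n); votes_hi <- integer(n)
  maps[[ref]] <- seq_len(nchar(ext[[ref]]$seq))
  votes_lo[ref] <- ext[[ref]]$e_lo
  votes_hi[ref] <- ext[[ref]]$e_hi
  others <- setdiff(seq_len(n), ref)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(
      vapply(ext[others], `[[`, character(1), "seq")),
    subject = Biostrings::DNAString(ext[[ref]]$seq),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 1, gapExtension = 1)
  rows_full <- .global_alignment_rows(
    aln, vapply(ext[others], `[[`, character(1), "seq"), ext[[ref]]$seq)
  pat_rows <- strsplit(rows_full$pattern, "")
  sub_rows <- strsplit(rows_full$subject, "")
  for (oi in seq_along(others)) {
    i <- others[oi]
    p <- pat_rows[[oi]]
    s <- sub_rows[[oi]]
    # map member position -> reference position (0 where unaligned)
    mp <- integer(nchar(ext[[i]]$seq))
    pi_ <- 0L; si_ <- 0L
    for (k in seq_along(p)) {
      if (p[k] != "-") pi_ <- pi_ + 1L
      if (s[k] != "-") si_ <- si_ + 1L
      if (p[k] != "-") mp[pi_] <- if (s[k] != "-") si_ else 0L
    }
    maps[[i]] <- mp
    votes_lo[i] <- if (ext[[i]]$e_lo <= length(mp)) mp[ext[[i]]$e_lo] else 0L
    votes_hi[i] <- if (ext[[i]]$e_hi <= length(mp)) mp[ext[[i]]$e_hi] else 0L
  }
  mode_of <- function(v) {
    v <- v[v > 0L]
    if (length(v) == 0L) return(0L)
    tab <- sort(table(v), decreasing = TRUE)
    as.integer(names(tab)[1L])
  }
  ref_lo <- mode_of(votes_lo)
  ref_hi <- mode_of(votes_hi)
  if (ref_lo == 0L || ref_hi == 0L || ref_hi <= ref_lo) return(family)
  for (i in seq_len(n)) {
    if (votes_lo[i] == ref_lo && votes_hi[i] == ref_hi) next
    mp <- maps[[i]]
    new_lo <- match(ref_lo, mp)
    new_hi <- match(ref_hi, mp)
    if (is.na(new_lo) || is.na(new_hi) || new_hi <= new_lo) next
    new_start <- ext[[i]]$lo + new_lo - 1L   # back to 0-based contig coords
    new_end <- ext[[i]]$lo + new_hi
    s <- genome[[m$contig_id[i]]]
    m$start[i] <- new_start
    m$end[i] <- new_end
    m$seq[i] <- substring(s, new_start + 1L, new_end)
    st <- .boundary_stats(s, new_start, new_end)
    m$tir_length[i] <- st$tir_length
    m$tir_mismatches[i] <- st$tir_mismatches
    m$tsd_seq[i] <- st$tsd_seq
    m$tsd_len[i] <- st$tsd_len
    m$score[i] <- st$score
  }
  family$members <- m
  family
}

# Re-derive TIR/TSD statistics for an element interval after its boundary
# moved; works on a local window so whole-contig splitting is avoided.
# A member whose corrected boundary has no exact flanking repeat keeps an
# empty TSD (degenerate, as in old real copies).
.boundary_stats <- function(contig_seq, start, end,
                            params = detection_params()) {
  pad <- params$tsd_max_len
  w_lo <- max(0L, start - pad)
  w_hi <- min(nchar(contig_seq), end + pad)
  chars <- strsplit(substring(contig_seq, w_lo + 1L, w_hi), "",
                    fixed = TRUE)[[1L]]
  a <- start - w_lo + 1L
  b <- end - w_lo
  half <- (b - a + 1L) %/% 2L
  core <- 0L
  while (core < half) {
    la <- chars[a + core]; ra <- chars[b - core]
    if (la == "N" || ra == "N" || .COMP[[la]] != ra) break
    core <- core + 1L
  }
  tir <- if (core > 0L) .extend_inward(chars, a, b, core, params)
         else list(len = 0L, mm = 0L)
  tsd <- .find_tsd(chars, length(chars), a, b, params)
  if (is.null(tsd)) tsd <- ""
  list(tir_length = tir$len, tir_mismatches = tir$mm, tsd_seq = tsd,
       tsd_len = nchar(tsd), score = tir$len + nchar(tsd) - tir$mm)
}

#' Merge two candidate annotation sets
#'
#' Records from the two sets on the same contig whose start and end
#' coordinates each differ by less than `tolerance` bp describe the same
#' element; the record with the stricter boundary evidence (longer TIR,
#' then longer TSD) is kept. Everything else passes through.
#'
#' @param set_a,set_b candidate `data.frame`s on the same genome.
#' @param tolerance positional tolerance in bp (default 100).
#' @return merged candidate `data.frame`.
#' @export
merge_annotation_sets <- function(set_a, set_b, tolerance = 100L) {
  if (nrow(set_a) == 0L) return(set_b)
  if (nrow(set_b) == 0L) return(set_a)
  used_b <- logical(nrow(set_b))
  rows <- vector("list", nrow(set_a))
  for (i in seq_len(nrow(set_a))) {
    j <- which(!used_b &
                 set_b$contig_id == set_a$contig_id[i] &
                 abs(set_b$start - set_a$start[i]) < tolerance &
                 abs(set_b$end - set_a$end[i]) < tolerance)
    if (length(j) == 0L) { rows[[i]] <- set_a[i, , drop = FALSE]; next }
    j <- j[1L]
    used_b[j] <- TRUE
    a_better <- set_a$tir_length[i] > set_b$tir_length[j] ||
      (set_a$tir_length[i] == set_b$tir_length[j] &&
         set_a$tsd_len[i] >= set_b$tsd_len[j])
    rows[[i]] <- if (a_better) set_a[i, , drop = FALSE]
                 else set_b[j, , drop = FALSE]
  }
  out <- rbind(do.call(rbind, rows), set_b[!used_b, , drop = FALSE])
  out <- out[order(out$contig_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the curated seed member of a family
#'
#' The seed is the member with the most complete boundary evidence: maximal
#' TSD length, then maximal TIR length, then fewest TIR mismatches; ties
#' broken by smallest mean divergence to the other members, then leftmost
#' coordinate. Deterministic.
#'
#' @param family a family list with a `members` data.frame.
#' @return single-row `data.frame`: the seed member.
#' @export
select_seed <- function(family) {
  m <- family$members
  if (nrow(m) == 0L) .stopf("select_seed: empty family")
  ord <- order(-m$tsd_len, -m$tir_length, m$tir_mismatches)
  top <- which(m$tsd_len == m$tsd_len[ord[1L]] &
                 m$tir_length == m$tir_length[ord[1L]] &
                 m$tir_mismatches == m$tir_mismatches[ord[1L]])
  if (length(top) > 1L && nrow(m) > 1L) {
    mean_div <- vapply(top, function(i) {
      others <- setdiff(seq_len(nrow(m)), i)
      mean(1 - .global_identity_many(m$seq[others], m$seq[i]))
    }, numeric(1))
    top <- top[order(mean_div, m$contig_id[top], m$start[top])]
  } else {
    top <- top[order(m$contig_id[top], m$start[top])]
  }
  m[top[1L], , drop = FALSE]
}

#' Build curated MITE families from candidates
#'
#' Runs clustering, the flank-distinctness collapse, the three-copy filter
#' re-check, seed selection and superfamily classification in one pass.
#'
#' @param candidates candidate `data.frame` (with `seq`).
#' @param genome named character vector of contigs.
#' @param params a [cluster_params()] object.
#' @param rules superfamily rule table (see [superfamily_rules()]).
#' @return list with `families` (each with `seed` and `superfamily` filled)
#'   and `singletons`.
#' @export
build_families <- function(candidates, genome, params = cluster_params(),
                           rules = superfamily_rules()) {
  cl <- cluster_candidates(candidates, params)
  families <- list()
  extra_singles <- list()
  fam_no <- 0L
  for (fam in cl$families) {
    fam <- flank_distinctness_filter(fam, genome, params)
    if (nrow(fam$members) < params$min_copies) {
      extra_singles[[length(extra_singles) + 1L]] <- fam$members
      next
    }
    fam <- refine_family_boundaries(fam, genome, params$flank_len)
    fam_no <- fam_no + 1L
    fam$family_id <- sprintf("FAM%03d", fam_no)
    fam$seed <- select_seed(fam)
    fam$superfamily <- classify_superfamily(fam$seed, genome, rules)
    families[[fam$family_id]] <- fam
  }
  singles <- do.call(rbind, c(list(cl$singletons), extra_singles))
  rownames(singles) <- NULL
  list(families = families, singletons = singles)
}

#' Extract the seed library of a family set
#'
#' @param families list of families from [build_families()].
#' @return named character vector seed sequences, names
#'   `familyID#superfamily`.
#' @export
seed_library <- function(families) {
  if (length(families) == 0L) return(character(0))
  setNames(vapply(families, function(f) f$seed$seq, character(1)),
           vapply(families, function(f)
             paste0(f$family_id, "#", f$superfamily), character(1)))
}
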