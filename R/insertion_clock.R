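# Kimura two-parameter dating of MITE copies against the family consensus.
#
# The K80 substitution model separates transitions (proportion P) from
# transversions (proportion Q) and corrects the observed difference to
#   K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))
# substitutions per site. Insertion ages follow as T = K / (2r) with r the
# per-site per-year substitution rate of the host lineage.

#' Kimura two-parameter distance between two aligned sequences
#'
#' Only columns where both symbols are in `{A,C,G,T}` are counted; gaps and
#' Ns are excluded. When the observed P/Q push either logarithm argument to
#' zero or below the distance is saturated and flagged invalid rather than
#' clamped.
#'
#' @param seq_a,seq_b equal-length aligned strings (may contain `-` gaps).
#' @return list with `P`, `Q`, `K`, `sites`, `valid`.
#' @export
k2p <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    .stopf("k2p: aligned strings differ in length (%d vs %d)",
           nchar(seq_a), nchar(seq_b))
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L)
    return(list(P = NA_real_, Q = NA_real_, K = NA_real_,
                sites = 0L, valid = FALSE))
  diff <- a != b
  ts <- sum(diff & .is_transition(a, b))
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    return(list(P = P, Q = Q, K = NA_real_, sites = n, valid = FALSE))
  K <- -0.5 * log(arg1 * sqrt(arg2))
  list(P = P, Q = Q, K = K, sites = n, valid = TRUE)
}

# Expected observable transition/transversion proportions after divergence d
# under K80 with transition/transversion rate ratio kappa. This is the model
# inverse of k2p(): feeding its P,Q back through the estimator returns d.
.k2p_expected_PQ <- function(d, kappa = 2) {
  beta <- d / (kappa + 2)
  alpha <- kappa * beta
  P <- 0.25 + 0.25 * exp(-4 * beta) - 0.5 * exp(-2 * (alpha + beta))
  Q <- 0.5 - 0.5 * exp(-4 * beta)
  c(P = P, Q = Q)
}

#' Center-star multiple alignment of a MITE family
#'
#' Aligns every member globally to the seed (match +1, mismatch -1, gap
#' open/extend -2/-1) and merges the pairwise alignments on seed coordinates,
#' the classical center-star construction. Deterministic; adequate for
#' substitution-dominated MITE families.
#'
#' @param members named character vector of member sequences; the first
#'   element is used as the center unless `seed` is given.
#' @param seed optional center sequence (character scalar).
#' @return named character matrix-free alignment: a named character vector of
#'   equal-length gapped strings, seed first under the name `"<seed>"` if it
#'   was not a member.
#' @export
family_alignment <- function(members, seed = NULL) {
  if (length(members) == 0L) .stopf("family_alignment: no sequences")
  if (is.null(names(members)))
    names(members) <- paste0("m", seq_along(members))
  if (is.null(seed)) {
    seed <- members[[1L]]
    others <- members[-1L]
    center_name <- names(members)[1L]
  } else {
    others <- members
    center_name <- ".center"
  }
  if (length(others) == 0L)
    return(setNames(seed, center_name))

  subj <- Biostrings::DNAStringSet(unname(others))
  aln <- Biostrings::pairwiseAlignment(
    pattern = subj,
    subject = Biostrings::DNAString(seed),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 1, gapExtension = 1)
  rows_full <- .global_alignment_rows(aln, unname(others), seed)
  pat_aln <- rows_full$pattern   # member rows
  sub_aln <- rows_full$subject   # seed rows

  L <- nchar(seed)
  # per pairwise alignment: residues of the member at each seed column, and
  # insertions (relative to the seed) keyed by the seed column they follow
  # (0 = before the first seed base).
  per <- lapply(seq_along(others), function(i) {
    s <- strsplit(sub_aln[i], "", fixed = TRUE)[[1L]]
    p <- strsplit(pat_aln[i], "", fixed = TRUE)[[1L]]
    at_col <- rep("-", L)
    ins <- vector("list", L + 1L)
    col <- 0L
    buf <- character(0)
    for (k in seq_along(s)) {
      if (s[k] == "-") {
        buf <- c(buf, p[k])
      } else {
        if (length(buf)) { ins[[col + 1L]] <- buf; buf <- character(0) }
        col <- col + 1L
        at_col[col] <- p[k]
      }
    }
    if (length(buf)) ins[[col + 1L]] <- buf
    list(at_col = at_col, ins = ins)
  })

  ins_len <- integer(L + 1L)
  for (pp in per) {
    li <- lengths(pp$ins)
    ins_len <- pmax(ins_len, li)
  }
  seed_chars <- strsplit(seed, "", fixed = TRUE)[[1L]]
  build_row <- function(at_col, ins) {
    parts <- character(0)
    for (j in 0:L) {
      if (ins_len[j + 1L] > 0L) {
        block <- ins[[j + 1L]]
        pad <- ins_len[j + 1L] - length(block)
        parts <- c(parts, block, rep("-", pad))
      }
      if (j < L) parts <- c(parts, at_col[j + 1L])
    }
    paste(parts, collapse = "")
  }
  center_row <- build_row(seed_chars, vector("list", L + 1L))
  rows <- vapply(per, function(pp) build_row(pp$at_col, pp$ins), character(1))
  setNames(c(center_row, rows), c(center_name, names(others)))
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column: the majority symbol among non-gap residues, provided non-gap
#' residues make up at least half of the rows; otherwise the column is
#' dropped. Residue ties are resolved by the first row's symbol, then
#' lexicographically.
#'
#' @param alignment named character vector of equal-length gapped strings;
#'   the first row is treated as the seed for tie-breaking.
#' @return consensus DNA string (no gaps).
#' @export
consensus_sequence <- function(alignment) {
  if (length(alignment) == 0L) .stopf("consensus_sequence: empty alignment")
  mat <- do.call(rbind, strsplit(unname(alignment), "", fixed = TRUE))
  nr <- nrow(mat)
  out <- character(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    res <- col[col != "-"]
    if (length(res) * 2L < nr) next
    tab <- table(res)
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1L) {
      seed_sym <- mat[1L, j]
      pick <- if (seed_sym %in% best) seed_sym else sort(best)[1L]
    } else pick <- best
    out <- c(out, pick)
  }
  paste(out, collapse = "")
}

#' Build per-family consensus sequences and per-copy K80 distances
#'
#' For each family, members are aligned to the seed (center-star), the
#' consensus is taken, every member is re-aligned to the consensus and its
#' K80 distance recorded. Families larger than `max_consensus_members` are
#' subsampled (seeded) for the consensus step only; all members are still
#' dated.
#'
#' @param families list of family objects from [build_families()], or a named
#'   list of named character vectors of member sequences.
#' @param max_consensus_members subsampling cap for consensus construction.
#' @param seed RNG seed for the subsampling draw.
#' @return `data.frame` with `element_id`, `family_id`, `P`, `Q`, `K`,
#'   `valid`; the per-family consensus strings are attached as the
#'   `consensus` attribute (named character vector).
#' @export
family_divergences <- function(families, max_consensus_members = 500L,
                               seed = 1L) {
  seqs_of <- function(fam) {
    if (is.list(fam) && !is.null(fam$members)) {
      setNames(fam$members$seq, fam$members$element_id)
    } else unlist(fam)
  }
  seed_of <- function(fam) {
    if (is.list(fam) && !is.null(fam$seed)) fam$seed$seq else NULL
  }
  fam_ids <- names(families)
  if (is.null(fam_ids)) fam_ids <- paste0("F", seq_along(families))
  res <- vector("list", length(families))
  consensi <- character(length(families))
  for (i in seq_along(families)) {
    seqs <- seqs_of(families[[i]])
    if (is.null(names(seqs)))
      names(seqs) <- paste0(fam_ids[i], ".", seq_along(seqs))
    ctr <- seed_of(families[[i]])
    sub <- seqs
    if (length(seqs) > max_consensus_members) {
      sub <- .with_phase_seed(seed, i, {
        seqs[sort(sample.int(length(seqs), max_consensus_members))]
      })
    }
    aln <- family_alignment(sub, seed = ctr)
    cons <- consensus_sequence(aln)
    consensi[i] <- cons
    aln2 <- family_alignment(seqs, seed = cons)
    center <- aln2[[1L]]
    rows <- aln2[-1L]
    dd <- lapply(rows, function(r) k2p(center, r))
    res[[i]] <- data.frame(
      element_id = names(rows),
      family_id = fam_ids[i],
      P = vapply(dd, `[[`, numeric(1), "P"),
      Q = vapply(dd, `[[`, numeric(1), "Q"),
      K = vapply(dd, `[[`, numeric(1), "K"),
      valid = vapply(dd, `[[`, logical(1), "valid"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "consensus") <- setNames(consensi, fam_ids)
  out
}

#' Insertion-time estimates from K80 distances
#'
#' Applies `T = K / (2r)` per copy. Invalid (saturated) distances are
#' excluded and counted in the `n_invalid` attribute rather than clamped.
#'
#' @param divergences `data.frame` with at least `element_id`, `family_id`,
#'   `K`, `valid` (see [family_divergences()]).
#' @param rate substitution rate r in substitutions/site/year; must be > 0.
#' @return `data.frame` with `element_id`, `family_id`, `K`, `rate`,
#'   `time_years`.
#' @export
insertion_times <- function(divergences, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    .stopf("substitution rate must be a single positive number")
  ok <- divergences$valid & !is.na(divergences$K)
  out <- data.frame(element_id = divergences$element_id[ok],
                    family_id = divergences$family_id[ok],
                    K = divergences$K[ok],
                    rate = rate,
                    time_years = divergences$K[ok] / (2 * rate),
                    stringsAsFactors = FALSE)
  attr(out, "n_invalid") <- sum(!ok)
  rownames(out) <- NULL
  out
}

#' Amplification histogram of insertion times
#'
#' Bins insertion ages into `[i*w, (i+1)*w)` intervals from zero; fractions
#' sum to one over valid estimates.
#'
#' @param estimates output of [insertion_times()].
#' @param bin_width bin width in years; must be > 0.
#' @return `data.frame` with `bin_start`, `bin_end`, `count`, `fraction`.
#' @export
amplification_histogram <- function(estimates, bin_width) {
  if (bin_width <= 0) .stopf("bin_width must be positive")
  t <- estimates$time_years
  if (length(t) == 0L)
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0), fraction = numeric(0)))
  idx <- floor(t / bin_width)
  tab <- table(factor(idx, levels = 0:max(idx)))
  data.frame(bin_start = as.numeric(names(tab)) * bin_width,
             bin_end = (as.numeric(names(tab)) + 1) * bin_width,
             count = as.integer(tab),
             fraction = as.integer(tab) / length(t),
             stringsAsFactors = FALSE)
}
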