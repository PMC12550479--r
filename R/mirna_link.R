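# MITE-derived miRNA identification and hairpin-stability comparison.
#
# A precursor is MITE-derived when it aligns locally to a MITE over at
# least half of its own length at more than 80% identity with E-value
# below 1e-5; the aligned MITE becomes a MITE-miRNA. Hairpin stability is
# scored by a deterministic maximum-weight nested-pairing dynamic
# programme (GC -3, AU -2, GU -1, minimum loop 3), a documented proxy for
# thermodynamic minimum free energy with a plug-in hook for an external
# folder; the normalised value (NMFE) is the energy divided by length.

#' Link miRNA precursors to MITEs
#'
#' @param precursors `data.frame` with `mirna_id`, `sequence` (RNA or DNA;
#'   U is normalised to T), or a named character vector.
#' @param mites named character vector of MITE sequences (names are element
#'   or family ids).
#' @param evalue_max E-value ceiling (default 1e-5).
#' @param identity_min identity floor (default 0.8, exclusive).
#' @param coverage_min minimum aligned fraction of the precursor length
#'   (default 0.5, inclusive).
#' @return `data.frame` with `mirna_id`, `mite_id`, `identity`, `coverage`,
#'   `evalue`, `score`; one row per retained precursor-MITE pair.
#' @export
link_mirnas <- function(precursors, mites, evalue_max = 1e-5,
                        identity_min = 0.8, coverage_min = 0.5) {
  if (is.character(precursors))
    precursors <- data.frame(mirna_id = names(precursors),
                             sequence = unname(precursors),
                             stringsAsFactors = FALSE)
  if (nrow(precursors) == 0L || length(mites) == 0L)
    .stopf("both precursor and MITE sets must be non-empty")
  subst <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE)
  n_search <- sum(nchar(mites))
  out <- list()
  for (i in seq_len(nrow(precursors))) {
    pseq <- .normalize_dna(precursors$sequence[i])
    plen <- nchar(pseq)
    for (mi in seq_along(mites)) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(pseq),
        subject = Biostrings::DNAString(mites[[mi]]),
        type = "local", substitutionMatrix = subst,
        gapOpening = 5, gapExtension = 2)
      sc <- Biostrings::score(aln)
      ev <- karlin_altschul_evalue(sc, plen, n_search)
      if (ev >= evalue_max) next
      st <- .aln_stats(as.character(Biostrings::pattern(aln)),
                       as.character(Biostrings::subject(aln)))
      qr <- aln@pattern@range
      cov <- IRanges::width(qr) / plen
      if (st$identity > identity_min && cov >= coverage_min) {
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = precursors$mirna_id[i], mite_id = names(mites)[mi],
          identity = st$identity, coverage = cov, evalue = ev, score = sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(mirna_id = character(0), mite_id = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      evalue = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.PAIR_W <- matrix(0, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                           c("A", "C", "G", "T", "N")))
.PAIR_W["G", "C"] <- .PAIR_W["C", "G"] <- 3
.PAIR_W["A", "T"] <- .PAIR_W["T", "A"] <- 2
.PAIR_W["G", "T"] <- .PAIR_W["T", "G"] <- 1

#' Hairpin pairing energy of a sequence
#'
#' Maximum-weight nested pairing by dynamic programming with pair weights
#' GC = -3, AU = -2, GU = -1 (arbitrary energy units; more negative = more
#' stable) and a minimum hairpin loop of 3 unpaired bases. `mfe` is the
#' optimal total weight and `nmfe = mfe / length`. The recursion is the
#' Nussinov scheme with weighted pairs. An external thermodynamic folder
#' can be plugged in through the `folder` argument, which must return an
#' MFE for a sequence.
#'
#' @param sequence DNA or RNA string, length >= 10.
#' @param folder optional function(sequence) -> numeric MFE override.
#' @return list with `mfe` and `nmfe`.
#' @export
fold_energy <- function(sequence, folder = NULL) {
  seq0 <- toupper(chartr("u", "t", sequence))
  seq0 <- chartr("U", "T", seq0)
  if (grepl("[^ACGTN]", seq0))
    .stopf("fold_energy: non-nucleotide symbols in sequence")
  n <- nchar(seq0)
  if (n < 10L) .stopf("fold_energy: sequence shorter than 10 nt")
  if (!is.null(folder)) {
    mfe <- folder(sequence)
    return(list(mfe = mfe, nmfe = mfe / n))
  }
  x <- strsplit(seq0, "", fixed = TRUE)[[1L]]
  W <- matrix(0, n, n)
  minloop <- 3L
  for (span in (minloop + 1L):(n - 1L)) {
    i <- seq_len(n - span)
    j <- i + span
    # option 1: j unpaired
    best <- W[cbind(i, j - 1L)]
    # option 2: j pairs with some k in [i, j - minloop - 1]
    for (idx in seq_along(i)) {
      ii <- i[idx]; jj <- j[idx]
      ks <- ii:(jj - minloop - 1L)
      w <- .PAIR_W[x[ks], x[jj]]
      pk <- ks[w > 0]
      if (length(pk)) {
        wk <- w[w > 0]
        left <- ifelse(pk > ii, W[cbind(pmax(ii, 1L), pmax(pk - 1L, 1L))], 0)
        left[pk == ii] <- 0
        inner <- W[cbind(pk + 1L, jj - 1L)]
        cand <- max(left + inner + wk)
        if (cand > best[idx]) best[idx] <- cand
      }
    }
    W[cbind(i, j)] <- best
  }
  mfe <- -W[1L, n]
  list(mfe = mfe, nmfe = mfe / n)
}

#' Compare normalised folding energies of two groups
#'
#' Reports group medians and a Mann-Whitney U statistic with a
#' normal-approximation p-value (tie-corrected). With fewer than 3
#' observations in either group the statistic is suppressed and only
#' medians are returned.
#'
#' @param group_a,group_b numeric vectors of NMFE values.
#' @return list with `median_a`, `median_b`, and (when both groups have at
#'   least 3 values) `U`, `z`, `p_value` (two-sided) and `p_less`
#'   (one-sided: a < b).
#' @export
compare_nmfe <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    .stopf("both groups must be non-empty")
  out <- list(median_a = median(group_a), median_b = median(group_b))
  na <- length(group_a); nb <- length(group_b)
  if (na < 3L || nb < 3L) return(out)
  r <- rank(c(group_a, group_b))
  Ra <- sum(r[seq_len(na)])
  U <- Ra - na * (na + 1) / 2          # Mann-Whitney U of group_a
  mu <- na * nb / 2
  N <- na + nb
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
  z <- if (sigma > 0) (U - mu) / sigma else 0
  out$U <- U
  out$z <- z
  out$p_value <- 2 * pnorm(-abs(z))
  out$p_less <- pnorm(z)
  out
}
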