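# Independent brute-force oracles used to validate the optimised
# implementations on small instances, plus small fixture builders.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

rc_chr <- function(s) {
  paste(rev(unname(COMP[strsplit(s, "", fixed = TRUE)[[1]]])), collapse = "")
}

random_dna_gc <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Build a contig with elements planted at known 0-based positions.
# Each element: list(tir, internal, tsd); returns list(seq, truth df).
plant_elements <- function(bg, elements, positions) {
  stopifnot(length(elements) == length(positions))
  ord <- order(positions)
  elements <- elements[ord]; positions <- positions[ord]
  pieces <- character(0); cursor <- 0L; out <- 0L
  truth <- list()
  for (k in seq_along(elements)) {
    el <- elements[[k]]
    eseq <- paste0(el$tir, el$internal, rc_chr(el$tir))
    pre <- substring(bg, cursor + 1L, positions[k])
    start <- out + nchar(pre) + nchar(el$tsd)
    pieces <- c(pieces, pre, el$tsd, eseq, el$tsd)
    out <- out + nchar(pre) + 2L * nchar(el$tsd) + nchar(eseq)
    cursor <- positions[k]
    truth[[k]] <- data.frame(start = start, end = start + nchar(eseq),
                             tsd = el$tsd, tir_len = nchar(el$tir))
  }
  pieces <- c(pieces, substring(bg, cursor + 1L, nchar(bg)))
  list(seq = paste(pieces, collapse = ""), truth = do.call(rbind, truth))
}

# ---- detection oracle -----------------------------------------------------
# All-substring reverse-complement word-pair enumeration (vectorised over
# offsets, no k-mer index), followed by a plain re-implementation of the
# extension/retraction/TSD contract and the overlap rule.

oracle_tir_candidates <- function(seq, params = detection_params()) {
  L <- nchar(seq)
  w <- params$tir_min_len
  if (L < params$mite_min_len) return(NULL)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  starts <- seq_len(L - w + 1L)
  words <- substring(seq, starts, starts + w - 1L)
  rcw <- vapply(words, rc_chr, character(1), USE.NAMES = FALSE)
  okw <- !grepl("N", words, fixed = TRUE)

  comp_ok <- function(x, y) x != "N" && y != "N" && COMP[[x]] == y

  tsd_at <- function(a, b) {
    for (t in seq(params$tsd_max_len, params$tsd_min_len)) {
      if (a - t < 1L || b + t > L) next
      lf <- chars[(a - t):(a - 1L)]
      rt <- chars[(b + 1L):(b + t)]
      if (any(lf == "N") || any(rt == "N")) next
      if (all(lf == rt)) return(paste(lf, collapse = ""))
    }
    NULL
  }

  inward <- function(a, b, core) {
    half <- (b - a + 1L) %/% 2L
    len <- core; mm_best <- 0L; net <- core; mm <- 0L; k <- core
    while (k < half) {
      if (!comp_ok(chars[a + k], chars[b - k])) mm <- mm + 1L
      k <- k + 1L
      if (mm / k <= params$tir_max_mismatch_frac) {
        len <- k; mm_best <- mm
        if (k - 2L * mm > net) net <- k - 2L * mm
      }
    }
    c(len, mm_best, net)
  }

  micron_ctx <- function(a, b) {
    pat <- "(TA){5,}|(CA){5,}|(GT){5,}"
    side <- function(lo, hi) {
      if (hi < 1L || lo > L) return(FALSE)
      lo <- max(1L, lo)
      seg <- paste(chars[lo:min(L, hi + 9L)], collapse = "")
      m <- regexpr(pat, seg)
      m > 0L && (lo + as.integer(m) - 1L) <= hi
    }
    side(a - 20L, a - 1L) || side(b + 1L, b + 20L)
  }

  bonus_of <- function(tsd, a, b, d, net) {
    bn <- 0
    h <- if (b - a + 1L >= 5L) paste(chars[a:(a + 4L)], collapse = "")
         else ""
    cacta <- h %in% c("CACTA", "CACTG")
    if (tsd %in% c("TA", "TAA", "TTA") && d - nchar(tsd) < 2L &&
        (net >= 13L || cacta || micron_ctx(a, b))) bn <- bn + 8
    if (nchar(tsd) <= 3L && cacta) bn <- bn + 8
    bn
  }

  best_per_interval <- new.env(hash = TRUE)
  seen_runs <- new.env(hash = TRUE)
  dmin <- params$mite_min_len - w
  dmax <- params$mite_max_len - w
  for (d_off in dmin:dmax) {
    i_idx <- starts[okw & starts + d_off <= L - w + 1L]
    if (length(i_idx) == 0L) next
    j_idx <- i_idx + d_off
    match_ok <- words[j_idx] == rcw[i_idx] & okw[j_idx]
    for (i in i_idx[match_ok]) {
      j <- i + d_off
      out <- 0L
      while (i - out - 1L >= 1L && j + w + out <= L &&
             comp_ok(chars[i - out - 1L], chars[j + w + out])) out <- out + 1L
      a0 <- i - out; b0 <- j + w - 1L + out
      rkey <- paste0(a0, "_", b0)
      if (!is.null(seen_runs[[rkey]])) next
      seen_runs[[rkey]] <- TRUE
      half <- (b0 - a0 + 1L) %/% 2L
      core0 <- 0L
      while (core0 < half && comp_ok(chars[a0 + core0], chars[b0 - core0]))
        core0 <- core0 + 1L
      if (core0 < w) next
      best <- NULL; best_sel <- -Inf; best_d <- Inf
      for (d in 0:min(core0 - w, params$tsd_max_len + 6L)) {
        a <- a0 + d; b <- b0 - d
        elen <- b - a + 1L
        if (elen < params$mite_min_len || elen > params$mite_max_len) next
        tir <- inward(a, b, min(core0 - d, elen %/% 2L))
        tirL <- chars[a:(a + tir[1] - 1L)]
        tirR <- chars[(b - tir[1] + 1L):b]
        if (any(tirL == "N") || any(tirR == "N")) next
        tsd <- tsd_at(a, b)
        if (is.null(tsd)) next
        sc <- tir[1] + nchar(tsd) - tir[2]
        sel <- tir[3] + nchar(tsd) + bonus_of(tsd, a, b, d, tir[3])
        if (sel < params$min_candidate_score) next
        if (sel > best_sel || (sel == best_sel && d < best_d)) {
          best <- data.frame(start = a - 1L, end = b, tir_length = tir[1],
                             tir_mismatches = tir[2], tsd_seq = tsd,
                             tsd_len = nchar(tsd), score = sc)
          best_sel <- sel; best_d <- d
        }
      }
      if (is.null(best)) next
      ikey <- paste0(best$start, "_", best$end)
      prev <- best_per_interval[[ikey]]
      if (is.null(prev) || best$score > prev$score)
        best_per_interval[[ikey]] <- best
    }
  }
  cands <- as.list(best_per_interval)
  if (length(cands) == 0L) return(NULL)
  out <- do.call(rbind, cands)
  # overlap rule: >50% reciprocal overlap keeps highest score, ties longer
  # TSD then leftmost
  ord <- order(-out$score, -out$tsd_len, out$start)
  out <- out[ord, , drop = FALSE]
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    ok <- TRUE
    for (k in which(keep)) {
      ov <- min(out$end[i], out$end[k]) - max(out$start[i], out$start[k])
      if (ov > 0 && ov > 0.5 * (out$end[i] - out$start[i]) &&
          ov > 0.5 * (out$end[k] - out$start[k])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- exhaustive local-alignment scan oracle -------------------------------
# Repeated full Smith-Waterman of each seed (both strands) against the whole
# contig with masking, no k-mer seeding or windowing.

oracle_scan <- function(genome, seeds, max_divergence = 0.15,
                        min_score = 50) {
  subst <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE)
  hits <- list()
  for (cid in names(genome)) {
    for (si in seq_along(seeds)) {
      for (strand in c("+", "-")) {
        qs <- if (strand == "+") seeds[[si]] else rc_chr(seeds[[si]])
        sub <- genome[[cid]]
        repeat {
          aln <- Biostrings::pairwiseAlignment(
            pattern = Biostrings::DNAString(qs),
            subject = Biostrings::DNAString(sub),
            type = "local", substitutionMatrix = subst,
            gapOpening = 3, gapExtension = 1)
          if (Biostrings::score(aln) < min_score) break
          p <- as.character(Biostrings::pattern(aln))
          s <- as.character(Biostrings::subject(aln))
          pc <- strsplit(p, "")[[1]]; sc2 <- strsplit(s, "")[[1]]
          keep <- pc != "-" & sc2 != "-"
          kd <- k2p(paste(pc[keep], collapse = ""),
                    paste(sc2[keep], collapse = ""))
          lo <- IRanges::start(aln@subject@range)
          hi <- IRanges::end(aln@subject@range)
          if (kd$valid && kd$K <= max_divergence) {
            hits[[length(hits) + 1L]] <- data.frame(
              family_id = names(seeds)[si], contig_id = cid,
              start = lo - 1L, end = hi,
              score = Biostrings::score(aln))
          }
          sub <- paste0(substring(sub, 1, lo - 1L),
                        strrep("N", hi - lo + 1L),
                        substring(sub, hi + 1L, nchar(sub)))
        }
      }
    }
  }
  if (length(hits) == 0L) return(NULL)
  out <- do.call(rbind, hits)
  out[order(out$contig_id, out$start), , drop = FALSE]
}

# ---- exhaustive nested-pairing enumeration --------------------------------
# Naive recursion over all pairing choices (no memoisation): the optimal
# weighted nested pairing for short sequences.

oracle_fold <- function(seq) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  wt <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1, 0)
  }
  rec <- function(i, j) {
    if (j - i < 4L) return(0)
    best <- rec(i, j - 1L)
    for (k in i:(j - 4L)) {
      wkj <- wt(x[k], x[j])
      if (wkj > 0) {
        left <- if (k > i) rec(i, k - 1L) else 0
        cand <- left + rec(k + 1L, j - 1L) + wkj
        if (cand > best) best <- cand
      }
    }
    best
  }
  -rec(1L, length(x))
}

# ---- per-base bitmap confusion oracle -------------------------------------

oracle_confusion <- function(contig_lengths, predicted, reference) {
  tp <- fp <- fn <- tn <- 0L
  for (cid in names(contig_lengths)) {
    n <- contig_lengths[[cid]]
    pv <- logical(n); rv <- logical(n)
    p <- predicted[predicted$contig_id == cid, , drop = FALSE]
    r <- reference[reference$contig_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(p))) pv[(p$start[i] + 1L):p$end[i]] <- TRUE
    for (i in seq_len(nrow(r))) rv[(r$start[i] + 1L):r$end[i]] <- TRUE
    tp <- tp + sum(pv & rv); fp <- fp + sum(pv & !rv)
    fn <- fn + sum(!pv & rv); tn <- tn + sum(!pv & !rv)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}
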