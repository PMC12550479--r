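# Superfamily assignment from TSD and TIR signatures.
#
# The five classical MITE superfamilies are diagnosed by their target site
# duplication and terminal inverted repeat: Tc1/Mariner (TA), PIF/Harbinger
# (TAA/TTA), Mutator (8-10 bp TSD), hAT (8 bp TSD with a short TIR), CACTA
# (CACT[AG] TIR start), plus the Micron group defined by insertion into
# (TA)n / (CA)n / (GT)n microsatellite context. Rules are applied in
# priority order and exactly one fires; the table ships as editable YAML so
# curators can override it without code changes.

#' Load the superfamily rule table
#'
#' @param path YAML rule file; defaults to the table shipped with the
#'   package.
#' @return list of rule records ordered by priority.
#' @export
superfamily_rules <- function(path = system.file("extdata",
                                                 "superfamily_rules.yaml",
                                                 package = "mitekit")) {
  rules <- yaml::read_yaml(path)$rules
  rules[order(vapply(rules, `[[`, numeric(1), "priority"))]
}

#' Detect microsatellite (Micron) insertion context
#'
#' TRUE when a `(TA)n`, `(CA)n` or `(GT)n` run of at least `min_units` units
#' starts within `window` bp of either element boundary, outside the
#' element.
#'
#' @param contig_seq contig sequence.
#' @param start,end element interval, 0-based half-open.
#' @param min_units minimum dinucleotide unit count.
#' @param window search window outside each boundary (bp).
#' @return logical scalar.
#' @export
detect_micron_context <- function(contig_seq, start, end, min_units = 5L,
                                  window = 20L) {
  L <- nchar(contig_seq)
  need <- 2L * min_units
  pat <- sprintf("(TA){%d,}|(CA){%d,}|(GT){%d,}",
                 min_units, min_units, min_units)
  check_side <- function(lo, hi) {
    # a qualifying run must START within [lo, hi] (1-based)
    if (hi < 1L || lo > L) return(FALSE)
    lo <- max(1L, lo)
    hi_ext <- min(L, hi + need - 1L)  # run may extend past the window
    seg <- substring(contig_seq, lo, hi_ext)
    m <- regexpr(pat, seg)
    m > 0L && (lo + as.integer(m) - 1L) <= hi
  }
  # left of the element: run starting in [start-window+1 .. start] (0-based
  # start => 1-based element start is start+1)
  check_side(start - window + 1L, start) ||
    check_side(end + 1L, end + window)
}

.tir_of_candidate <- function(seed) {
  substring(seed$seq, 1L, max(1L, seed$tir_length))
}

#' Classify a family seed into a superfamily
#'
#' Applies the rule table in priority order: Micron context first (it is
#' context-defined, not TSD-defined), then CACTA (2-3 bp TSD with a
#' CACT[AG] TIR start), Tc1/Mariner (TSD "TA"), PIF/Harbinger (TSD
#' TAA/TTA), hAT (8 bp TSD with TIR length 5-27), Mutator (8-10 bp TSD);
#' anything else is "unknown". Deterministic.
#'
#' @param seed single-row candidate `data.frame` (the family seed), with
#'   `seq`, `tsd_seq`, `tir_length`, `contig_id`, `start`, `end`.
#' @param genome named character vector of contigs (for Micron context).
#' @param rules rule table from [superfamily_rules()].
#' @return superfamily label (character scalar).
#' @export
classify_superfamily <- function(seed, genome, rules = superfamily_rules()) {
  tsd <- seed$tsd_seq
  if (is.null(tsd) || is.na(tsd) || !nzchar(tsd)) {
    out <- "unknown"
    attr(out, "reason") <- "missing TSD"
    return(out)
  }
  tir <- .tir_of_candidate(seed)
  tir_len <- seed$tir_length
  contig <- genome[[seed$contig_id]]
  for (rule in rules) {
    hit <- TRUE
    if (isTRUE(rule$micron_context)) {
      hit <- !is.null(contig) &&
        detect_micron_context(contig, seed$start, seed$end,
                              min_units = rule$min_units %||% 5L,
                              window = rule$window %||% 20L)
    }
    if (hit && !is.null(rule$tsd_exact))
      hit <- tsd %in% unlist(rule$tsd_exact)
    if (hit && !is.null(rule$tsd_len_min))
      hit <- nchar(tsd) >= rule$tsd_len_min
    if (hit && !is.null(rule$tsd_len_max))
      hit <- nchar(tsd) <= rule$tsd_len_max
    if (hit && !is.null(rule$tir_prefix_regex))
      hit <- grepl(rule$tir_prefix_regex, tir)
    if (hit && !is.null(rule$tir_len_min))
      hit <- tir_len >= rule$tir_len_min
    if (hit && !is.null(rule$tir_len_max))
      hit <- tir_len <= rule$tir_len_max
    if (hit) return(rule$name)
  }
  "unknown"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
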