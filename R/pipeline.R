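# End-to-end convenience wrapper: detect -> families -> classify -> scan.

#' Run the full MITE annotation pipeline on a genome
#'
#' De novo candidate detection, family building (clustering, flank
#' distinctness, three-copy filter), superfamily classification, and the
#' seed-library genome scan, in one call.
#'
#' @param genome named character vector of contigs.
#' @param detection a [detection_params()] object.
#' @param clustering a [cluster_params()] object.
#' @param rules superfamily rule table.
#' @param max_divergence,min_score scan retention thresholds.
#' @return list with `candidates`, `families`, `singletons`, `seeds`,
#'   `hits`, `landscape`.
#' @export
annotate_mites <- function(genome, detection = detection_params(),
                           clustering = cluster_params(),
                           rules = superfamily_rules(),
                           max_divergence = 0.15, min_score = 50) {
  candidates <- detect_mites(genome, detection)
  fams <- build_families(candidates, genome, clustering, rules)
  seeds <- seed_library(fams$families)
  hits <- if (length(seeds)) scan_genome(genome, seeds,
                                         max_divergence = max_divergence,
                                         min_score = min_score)
          else .empty_hits()
  list(candidates = candidates, families = fams$families,
       singletons = fams$singletons, seeds = seeds, hits = hits,
       landscape = summarize_landscape(hits, genome))
}
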