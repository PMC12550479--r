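# Assignment of MITE hits to genomic region classes relative to genes:
# exon > intron > flank (5 kb up/downstream, 500 bp bins) > intergenic,
# decided by the hit midpoint; upstream/downstream are strand-aware.

#' Assign MITE hits to gene-relative regions
#'
#' Each hit is placed by the midpoint of its interval. A midpoint inside a
#' gene is exonic or intronic; a midpoint within `flank_len` bp of one or
#' more genes goes to the gene with the nearer boundary (tie: the gene for
#' which the hit is upstream), with `bin_index = floor(distance /
#' bin_width)`; anything else is intergenic. Upstream means 5' of the gene
#' on its own strand.
#'
#' @param hits hit `data.frame` (columns `hit_id`, `contig_id`, `start`,
#'   `end`).
#' @param genes `mite_genes` object from [read_gff()] /
#'   [generate_gene_models()].
#' @param flank_len flank extent (bp, default 5000).
#' @param bin_width flank bin width (bp, default 500).
#' @return `data.frame`: `hit_id`, `region` (exon/intron/upstream/
#'   downstream/intergenic), `gene_id`, `distance_to_gene`, `bin_index`.
#' @export
assign_regions <- function(hits, genes, flank_len = 5000L,
                           bin_width = 500L) {
  exons <- attr(genes, "exons")
  n <- nrow(hits)
  region <- character(n); gene_id <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n); bin <- rep(NA_integer_, n)
  warned_contigs <- character(0)
  for (i in seq_len(n)) {
    mid <- (hits$start[i] + hits$end[i]) %/% 2L  # 0-based position
    gg <- genes[genes$contig_id == hits$contig_id[i], , drop = FALSE]
    if (nrow(gg) == 0L) {
      if (!(hits$contig_id[i] %in% warned_contigs)) {
        .warnf("contig %s has no gene annotation; hits become intergenic",
               hits$contig_id[i])
        warned_contigs <- c(warned_contigs, hits$contig_id[i])
      }
      region[i] <- "intergenic"
      next
    }
    inside <- which(gg$start <= mid & mid < gg$end)
    if (length(inside)) {
      g <- inside[1L]
      ex <- exons[[gg$gene_id[g]]]
      in_exon <- any(ex[, 1L] <= mid & mid < ex[, 2L])
      region[i] <- if (in_exon) "exon" else "intron"
      gene_id[i] <- gg$gene_id[g]
      dist[i] <- 0L
      next
    }
    # distance to the nearest gene boundary within the flank window
    d_left <- gg$start - 1L - mid    # gene is to the right of the midpoint
    d_right <- mid - gg$end          # gene is to the left of the midpoint
    d <- pmax(d_left, d_right) + 1L  # bp from midpoint to nearest boundary
    near <- which(d >= 1L & d <= flank_len)
    if (length(near) == 0L) { region[i] <- "intergenic"; next }
    # side relative to each nearby gene, on the gene's own strand
    side <- ifelse(d_left[near] >= 0L,
                   ifelse(gg$strand[near] == "+", "upstream", "downstream"),
                   ifelse(gg$strand[near] == "+", "downstream", "upstream"))
    ord <- order(d[near], side != "upstream")
    pick <- near[ord[1L]]
    region[i] <- side[ord[1L]]
    gene_id[i] <- gg$gene_id[pick]
    dist[i] <- d[pick]
    bin[i] <- (d[pick] - 1L) %/% bin_width
  }
  data.frame(hit_id = hits$hit_id, region = region, gene_id = gene_id,
             distance_to_gene = dist, bin_index = bin,
             stringsAsFactors = FALSE)
}

#' Per-region and per-bin hit counts / densities
#'
#' @param assignments `data.frame` from [assign_regions()].
#' @param flank_len,bin_width the binning used in [assign_regions()].
#' @param normalize when TRUE, counts are divided by the total number of
#'   assigned hits and by the bin width in kb (comparable unit densities).
#' @return list with `regions` (`data.frame`: region, count, value) and
#'   `bins` (`data.frame`: region, bin_index, bin_start, count, value).
#' @export
binned_density <- function(assignments, flank_len = 5000L, bin_width = 500L,
                           normalize = FALSE) {
  total <- nrow(assignments)
  scale <- if (normalize && total > 0L) 1 / (total * bin_width / 1000)
           else 1
  reg_levels <- c("exon", "intron", "upstream", "downstream", "intergenic")
  rtab <- table(factor(assignments$region, levels = reg_levels))
  regions <- data.frame(region = names(rtab), count = as.integer(rtab),
                        value = as.integer(rtab) *
                          (if (normalize && total > 0L) 1 / total else 1),
                        stringsAsFactors = FALSE)
  n_bins <- flank_len %/% bin_width
  bins <- expand.grid(region = c("upstream", "downstream"),
                      bin_index = seq_len(n_bins) - 1L,
                      stringsAsFactors = FALSE)
  bins$bin_start <- bins$bin_index * bin_width
  bins$count <- mapply(function(r, b)
    sum(assignments$region == r & !is.na(assignments$bin_index) &
          assignments$bin_index == b),
    bins$region, bins$bin_index)
  bins$value <- bins$count * scale
  bins <- bins[order(bins$region, bins$bin_index), ]
  rownames(bins) <- NULL
  list(regions = regions, bins = bins)
}

#' Group genes by where MITEs inserted
#'
#' Returns, per region class, the set of genes with at least one assigned
#' hit; `promoter` is the union of upstream bins 0-3 (0-2000 bp). Sets are
#' not required to be disjoint. The complement (genes with no hit in that
#' region) supports expression-style comparisons downstream.
#'
#' @param assignments `data.frame` from [assign_regions()].
#' @param genes `mite_genes` object (for the complement sets).
#' @return list with `with_insertion` and `without_insertion`, each a named
#'   list of gene-id character vectors per region.
#' @export
group_genes_by_insertion <- function(assignments, genes) {
  regions <- c("exon", "intron", "upstream", "downstream", "promoter")
  with_ins <- setNames(vector("list", length(regions)), regions)
  for (r in setdiff(regions, "promoter")) {
    with_ins[[r]] <- sort(unique(assignments$gene_id[
      assignments$region == r & !is.na(assignments$gene_id)]))
  }
  with_ins$promoter <- sort(unique(assignments$gene_id[
    assignments$region == "upstream" & !is.na(assignments$bin_index) &
      assignments$bin_index <= 3L]))
  without <- lapply(with_ins, function(g) setdiff(genes$gene_id, g))
  list(with_insertion = with_ins, without_insertion = without)
}
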