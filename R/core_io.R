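# Shared genomic data model and format I/O.
#
# Conventions used throughout the package:
#   * a genome is a named character vector of uppercase DNA strings over
#     {A,C,G,T,N}; names are contig ids and must be unique;
#   * all internal coordinates are 0-based half-open [start, end);
#     1-based inclusive coordinates exist only inside GFF3 text;
#   * strand is "+", "-" or "." (unstranded).

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased and every IUPAC ambiguity code other than N is
#' mapped to N, so downstream code only ever sees `{A,C,G,T,N}`.
#'
#' @param path path to a (multi-)FASTA file.
#' @return named character vector of contig sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .stopf("malformed FASTA '%s': %s",
                                             path, conditionMessage(e)))
  if (length(set) == 0L) .stopf("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    .stopf("duplicate contig id in %s: %s", path,
           ids[duplicated(ids)][1L])
  seqs <- .normalize_dna(as.character(set))
  setNames(seqs, ids)
}

#' Write a genome to a FASTA file
#'
#' @param genome named character vector of contig sequences.
#' @param path output path.
#' @param width line-wrap width in bp.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "wb")  # binary mode: byte-identical output on any OS
  on.exit(close(con))
  for (id in names(genome)) {
    s <- genome[[id]]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = width)
    lines <- substring(s, starts, pmin(starts + width - 1L, n))
    writeLines(c(paste0(">", id), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features; exons are attached to their parent gene
#' either directly or through an intermediate mRNA feature. GFF3 1-based
#' inclusive coordinates are converted to the package's 0-based half-open
#' convention.
#'
#' @param path path to a GFF3 file.
#' @return a `data.frame` of class `mite_genes` with one row per gene
#'   (`gene_id`, `contig_id`, `start`, `end`, `strand`) and an `exons`
#'   attribute: a named list of per-gene exon matrices (columns start, end,
#'   0-based half-open, sorted).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) .stopf("GFF3 file not found: %s", path)
  g <- rtracklayer::readGFF(path,
                            columns = c("seqid", "type", "start", "end",
                                        "strand"),
                            tags = c("ID", "Parent"))
  g <- as.data.frame(g)
  if (any(g$end < g$start))
    .stopf("GFF3 feature with end < start at line for seqid %s",
           g$seqid[which(g$end < g$start)[1L]])
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  genes <- g[g$type == "gene", , drop = FALSE]
  rnas  <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- g[g$type == "exon", , drop = FALSE]
  rna2gene <- setNames(rnas$Parent, rnas$ID)

  gene_ids <- as.character(genes$ID)
  exon_list <- setNames(vector("list", nrow(genes)), gene_ids)
  for (i in seq_len(nrow(exons))) {
    p <- exons$Parent[i]
    if (!is.na(p) && p %in% names(rna2gene)) p <- rna2gene[[p]]
    if (is.na(p) || !(p %in% gene_ids)) {
      .warnf("exon without resolvable parent gene (Parent=%s); skipped",
             if (is.na(p)) "<missing>" else p)
      next
    }
    exon_list[[p]] <- rbind(exon_list[[p]],
                            c(exons$start[i] - 1L, exons$end[i]))
  }
  for (id in gene_ids) {
    ex <- exon_list[[id]]
    if (is.null(ex)) {  # exonless gene record: treat the body as one exon
      k <- match(id, gene_ids)
      ex <- matrix(c(genes$start[k] - 1L, genes$end[k]), ncol = 2L)
    }
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    colnames(ex) <- c("start", "end")
    exon_list[[id]] <- ex
  }
  out <- data.frame(gene_id = gene_ids,
                    contig_id = as.character(genes$seqid),
                    start = genes$start - 1L,
                    end = as.integer(genes$end),
                    strand = as.character(genes$strand),
                    stringsAsFactors = FALSE)
  attr(out, "exons") <- exon_list
  class(out) <- c("mite_genes", class(out))
  out
}

.HIT_COLS <- c("hit_id", "family_id", "superfamily", "contig_id",
               "start", "end", "strand", "identity_to_seed",
               "kimura_divergence", "full_length", "score")

.empty_hits <- function() {
  data.frame(hit_id = character(0), family_id = character(0),
             superfamily = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             identity_to_seed = numeric(0), kimura_divergence = numeric(0),
             full_length = logical(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write MITE hits to GFF3, BED6 or TSV
#'
#' GFF3 output is 1-based inclusive with family/superfamily and the scan
#' statistics carried in the attribute column; BED6 and TSV keep the internal
#' 0-based half-open convention. [read_annotation()] round-trips all three
#' dialects.
#'
#' @param hits a hit `data.frame` as produced by [scan_genome()].
#' @param path output path.
#' @param dialect one of `"gff3"`, `"bed"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(hits, path, dialect = c("gff3", "bed", "tsv")) {
  dialect <- match.arg(dialect)
  if (nrow(hits) > 0 && !all(.HIT_COLS %in% names(hits)))
    .stopf("hits table lacks columns: %s",
           paste(setdiff(.HIT_COLS, names(hits)), collapse = ", "))
  con <- file(path, "wb")
  on.exit(close(con))
  fmt_num <- function(x) formatC(x, format = "g", digits = 10)
  if (dialect == "gff3") {
    writeLines("##gff-version 3", con)
    if (nrow(hits)) {
      attrs <- sprintf(
        "ID=%s;family_id=%s;superfamily=%s;identity=%s;kimura=%s;full_length=%s",
        hits$hit_id, hits$family_id, hits$superfamily,
        fmt_num(hits$identity_to_seed), fmt_num(hits$kimura_divergence),
        ifelse(hits$full_length, "true", "false"))
      writeLines(paste(hits$contig_id, "mitekit", "MITE",
                       hits$start + 1L, hits$end, fmt_num(hits$score),
                       hits$strand, ".", attrs, sep = "\t"), con)
    }
  } else if (dialect == "bed") {
    writeLines(paste0("track name=mite_hits"), con)
    if (nrow(hits)) {
      name <- paste(hits$hit_id, hits$family_id, hits$superfamily,
                    fmt_num(hits$identity_to_seed),
                    fmt_num(hits$kimura_divergence),
                    ifelse(hits$full_length, "true", "false"), sep = "|")
      writeLines(paste(hits$contig_id, hits$start, hits$end, name,
                       fmt_num(hits$score), hits$strand, sep = "\t"), con)
    }
  } else {
    writeLines(paste(.HIT_COLS, collapse = "\t"), con)
    if (nrow(hits)) {
      h <- hits[, .HIT_COLS]
      h$identity_to_seed <- fmt_num(h$identity_to_seed)
      h$kimura_divergence <- fmt_num(h$kimura_divergence)
      h$score <- fmt_num(h$score)
      h$full_length <- ifelse(hits$full_length, "true", "false")
      writeLines(do.call(paste, c(h, sep = "\t")), con)
    }
  }
  invisible(path)
}

#' Read MITE hits written by [write_annotation()]
#'
#' @param path input path.
#' @param dialect one of `"gff3"`, `"bed"`, `"tsv"`.
#' @return hit `data.frame` in internal 0-based half-open coordinates.
#' @export
read_annotation <- function(path, dialect = c("gff3", "bed", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  lines <- readLines(path)
  body <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  if (length(body) == 0L) return(.empty_hits())
  f <- strsplit(body, "\t", fixed = TRUE)
  get_attr <- function(a, key) sub(sprintf(".*%s=([^;]*).*", key), "\\1", a)
  if (dialect == "gff3") {
    a <- vapply(f, `[`, character(1), 9L)
    out <- data.frame(
      hit_id = get_attr(a, "ID"),
      family_id = get_attr(a, "family_id"),
      superfamily = get_attr(a, "superfamily"),
      contig_id = vapply(f, `[`, character(1), 1L),
      start = as.integer(vapply(f, `[`, character(1), 4L)) - 1L,
      end = as.integer(vapply(f, `[`, character(1), 5L)),
      strand = vapply(f, `[`, character(1), 7L),
      identity_to_seed = as.numeric(get_attr(a, "identity")),
      kimura_divergence = as.numeric(get_attr(a, "kimura")),
      full_length = get_attr(a, "full_length") == "true",
      score = as.numeric(vapply(f, `[`, character(1), 6L)),
      stringsAsFactors = FALSE)
  } else if (dialect == "bed") {
    nm <- strsplit(vapply(f, `[`, character(1), 4L), "|", fixed = TRUE)
    out <- data.frame(
      hit_id = vapply(nm, `[`, character(1), 1L),
      family_id = vapply(nm, `[`, character(1), 2L),
      superfamily = vapply(nm, `[`, character(1), 3L),
      contig_id = vapply(f, `[`, character(1), 1L),
      start = as.integer(vapply(f, `[`, character(1), 2L)),
      end = as.integer(vapply(f, `[`, character(1), 3L)),
      strand = vapply(f, `[`, character(1), 6L),
      identity_to_seed = as.numeric(vapply(nm, `[`, character(1), 4L)),
      kimura_divergence = as.numeric(vapply(nm, `[`, character(1), 5L)),
      full_length = vapply(nm, `[`, character(1), 6L) == "true",
      score = as.numeric(vapply(f, `[`, character(1), 5L)),
      stringsAsFactors = FALSE)
  } else {
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (!identical(hdr, .HIT_COLS)) .stopf("unexpected TSV header in %s", path)
    rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
    if (length(rows) == 0L) return(.empty_hits())
    col <- function(i) vapply(rows, `[`, character(1), i)
    out <- data.frame(
      hit_id = col(1L), family_id = col(2L), superfamily = col(3L),
      contig_id = col(4L), start = as.integer(col(5L)),
      end = as.integer(col(6L)), strand = col(7L),
      identity_to_seed = as.numeric(col(8L)),
      kimura_divergence = as.numeric(col(9L)),
      full_length = col(10L) == "true", score = as.numeric(col(11L)),
      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
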