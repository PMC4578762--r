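#' Call conserved elements from a gapped pairwise alignment
#'
#' Windowed identity calling: an alignment column is conserved iff
#' some window of `window` consecutive columns covering it contains at
#' least `min_matches` identical non-gap matches. Maximal runs of
#' conserved columns are merged and reported in the ungapped coordinates
#' of the first sequence. Gap columns never count as matches; gap
#' columns of sequence A inside a conserved run do not break the run but
#' contribute no A-coordinate.
#'
#' @param seq_a,seq_b Aligned sequences (equal length, `-` for gaps).
#' @param window Window size in alignment columns.
#' @param min_matches Minimum identical non-gap matches per window.
#' @param seqname Sequence name attached to the output intervals.
#' @return Tibble with `seqnames`, `start`, `end` (1-based closed, in
#'   ungapped A coordinates) and `mean_identity` (mean per-column match
#'   indicator over the element's alignment columns).
#' @export
#' @examples
#' window_conservation(strrep("ACGT", 25), strrep("ACGT", 25))
window_conservation <- function(seq_a, seq_b, window = 30L,
                                min_matches = 23L, seqname = "seq") {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) {
    stop("aligned sequences must have equal column counts", call. = FALSE)
  }
  stopifnot(window >= 1L, min_matches > 0L, min_matches <= window)
  L <- length(a)
  empty <- tibble::tibble(seqnames = character(), start = integer(),
                          end = integer(), mean_identity = numeric())
  if (L < window) {
    return(empty)
  }
  match_col <- as.integer(a == b & a != "-" & b != "-")
  cs <- cumsum(c(0L, match_col))
  wsum <- cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]
  good <- which(wsum >= min_matches)  # window start columns
  if (!length(good)) {
    return(empty)
  }
  conserved_col <- logical(L)
  for (g in good) {
    conserved_col[g:(g + window - 1L)] <- TRUE
  }
  # Map alignment columns to ungapped A coordinates.
  a_pos <- cumsum(a != "-")
  r <- rle(conserved_col)
  ends_col <- cumsum(r$lengths)
  starts_col <- ends_col - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(k) {
    cols <- starts_col[k]:ends_col[k]
    cols_a <- cols[a[cols] != "-"]
    if (!length(cols_a)) {
      return(NULL)
    }
    tibble::tibble(
      seqnames = seqname,
      start = a_pos[cols_a[1L]],
      end = a_pos[cols_a[length(cols_a)]],
      mean_identity = mean(match_col[cols])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty else out
}

# Intervals tibble -> GRanges (1-based closed, as stored).
as_granges <- function(x, strand = NULL) {
  st <- strand %||% (if ("strand" %in% names(x)) x$strand else "*")
  GenomicRanges::GRanges(
    seqnames = x$seqnames,
    ranges = IRanges::IRanges(start = x$start, end = x$end),
    strand = st
  )
}

# Extract subsequences from a DNAStringSet by coordinate tibble columns.
get_subseqs <- function(genome, seqnames, start, end) {
  vapply(seq_along(start), function(i) {
    as.character(Biostrings::subseq(genome[[seqnames[i]]],
                                    start = start[i], end = end[i]))
  }, character(1))
}

# Coding bases of a gene-model list: exons, UTRs and any transcript-track
# extra exons, reduced to a disjoint set.
coding_ranges <- function(models) {
  f <- models$features
  if (is.null(f) || nrow(f) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::reduce(as_granges(f))
}

#' Partition conserved elements into coding and non-coding
#'
#' Base-level partition: conserved bases overlapping any exon, UTR or
#' transcript-derived exon are coding-conserved; all remaining conserved
#' bases are non-coding-conserved. Elements straddling a boundary are
#' split.
#'
#' @param elements Tibble of conserved intervals (`seqnames`, `start`,
#'   `end`, 1-based closed).
#' @param models Gene models: a list with a `features` tibble
#'   (`gene_id`, `type`, `start`, `end`, `seqnames` optional) as
#'   produced by [simulate_genomes()] or [read_gene_models()].
#' @return List with tibbles `coding` and `noncoding`, each with
#'   `seqnames`, `start`, `end`, `class`.
#' @export
partition_conserved <- function(elements, models) {
  empty <- tibble::tibble(seqnames = character(), start = integer(),
                          end = integer(), class = character())
  if (is.null(elements) || nrow(elements) == 0L) {
    return(list(coding = empty, noncoding = empty))
  }
  if (!"seqnames" %in% names(models$features) &&
      nrow(models$features) > 0L) {
    models$features <- dplyr::left_join(
      models$features,
      dplyr::select(models$genes, "gene_id", "seqnames"),
      by = "gene_id"
    )
  }
  el <- GenomicRanges::reduce(as_granges(elements))
  cod <- coding_ranges(models)
  coding_part <- GenomicRanges::intersect(el, cod)
  noncoding_part <- GenomicRanges::setdiff(el, cod)
  to_tbl <- function(gr, cls) {
    if (length(gr) == 0L) {
      return(empty)
    }
    tibble::tibble(
      seqnames = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      class = cls
    )
  }
  list(coding = to_tbl(coding_part, "coding"),
       noncoding = to_tbl(noncoding_part, "noncoding"))
}

#' Extract conserved non-coding sequence near a gene set
#'
#' Returns the non-coding conserved pieces intersecting the window
#' `[gene start - flank, gene end + flank]` of any gene in `gene_set`
#' (which covers the gene body, hence also its introns), clipped to the
#' intersection. Pieces of length `<= min_len` bp are discarded; record
#' ids encode the source gene and coordinates. Flank windows are
#' strand-agnostic.
#'
#' @param gene_set Character vector of gene ids.
#' @param models Gene-model list (`genes` tibble with `gene_id`,
#'   `seqnames`, `start`, `end`).
#' @param noncoding Tibble of non-coding conserved elements.
#' @param genome A [Biostrings::DNAStringSet].
#' @param flank Flank width in bp (default 3000, i.e. +/- 3 kb).
#' @param min_len Pieces must be strictly longer than this (default 8).
#' @return Tibble with `region_id`, `gene_id`, `seqnames`, `start`,
#'   `end`, `seq`. Genes absent from the models are reported in the
#'   `"excluded"` attribute.
#' @export
extract_gene_set_regions <- function(gene_set, models, noncoding, genome,
                                     flank = 3000L, min_len = 8L) {
  genes <- models$genes
  gene_set <- sort(unique(gene_set))
  excluded <- setdiff(gene_set, genes$gene_id)
  gset <- genes[genes$gene_id %in% gene_set, ]
  gset <- gset[order(gset$gene_id), ]
  out <- tibble::tibble(region_id = character(), gene_id = character(),
                        seqnames = character(), start = integer(),
                        end = integer(), seq = character())
  if (nrow(gset) > 0L && nrow(noncoding) > 0L) {
    nc <- as_granges(noncoding[order(noncoding$seqnames, noncoding$start,
                                     noncoding$end), ])
    win <- GenomicRanges::GRanges(
      gset$seqnames,
      IRanges::IRanges(pmax(1L, gset$start - as.integer(flank)),
                       gset$end + as.integer(flank))
    )
    hits <- GenomicRanges::findOverlaps(nc, win)
    if (length(hits)) {
      pieces <- GenomicRanges::pintersect(
        nc[S4Vectors::queryHits(hits)],
        win[S4Vectors::subjectHits(hits)]
      )
      gid <- gset$gene_id[S4Vectors::subjectHits(hits)]
      keep <- GenomicRanges::width(pieces) > min_len
      pieces <- pieces[keep]
      gid <- gid[keep]
      if (length(pieces)) {
        sq <- get_subseqs(genome,
                          as.character(GenomicRanges::seqnames(pieces)),
                          GenomicRanges::start(pieces),
                          GenomicRanges::end(pieces))
        out <- tibble::tibble(
          region_id = sprintf("%s|%s:%d-%d", gid,
                              as.character(GenomicRanges::seqnames(pieces)),
                              GenomicRanges::start(pieces),
                              GenomicRanges::end(pieces)),
          gene_id = gid,
          seqnames = as.character(GenomicRanges::seqnames(pieces)),
          start = GenomicRanges::start(pieces),
          end = GenomicRanges::end(pieces),
          seq = sq
        )
        out <- dplyr::arrange(out, .data$gene_id, .data$seqnames,
                              .data$start, .data$end)
      }
    }
  }
  attr(out, "excluded") <- excluded
  out
}
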