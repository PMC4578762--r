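# Readers and writers for the pipeline's on-disk interchange formats.
# Internally all coordinates are 1-based closed (Bioconductor
# convention); rtracklayer converts to/from BED (0-based half-open) and
# GFF3 (1-based inclusive) on IO.

#' Read a long-format expression table
#'
#' Expected columns: `gene_id`, `stage`, `replicate`, `value` (TSV).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "stage", "replicate", "value")
  if (!all(need %in% names(df))) {
    stop("expression TSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[, need])
}

#' @rdname read_expression_tsv
#' @param x Tibble to write.
#' @export
write_expression_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an ortholog table (one gene-id column per species)
#'
#' @param path File path.
#' @return A tibble whose first column is `ortholog_id`.
#' @export
read_orthologs_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_orthologs_tsv
#' @param x Tibble to write.
#' @export
write_orthologs_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene-to-GO annotations (`gene_id <tab> term`)
#'
#' @param path File path.
#' @return Tibble with `gene_id`, `term`.
#' @export
read_go_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene_id", "term"))
  tibble::as_tibble(df)
}

#' @rdname read_go_tsv
#' @param x Tibble to write.
#' @export
write_go_tsv <- function(x, path) {
  utils::write.table(x[, c("gene_id", "term")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' @param models List with `genes` and `features` tibbles (see
#'   [simulate_genomes()]).
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  f <- models$features
  f2 <- dplyr::left_join(
    f, dplyr::select(g, "gene_id", "seqnames", "strand"), by = "gene_id"
  )
  gr_g <- GenomicRanges::GRanges(
    g$seqnames, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id
  )
  gr_f <- GenomicRanges::GRanges(
    f2$seqnames, IRanges::IRanges(f2$start, f2$end), strand = f2$strand,
    type = f2$type, ID = NA_character_
  )
  S4Vectors::mcols(gr_f)$Parent <- f2$gene_id
  S4Vectors::mcols(gr_g)$Parent <- NA_character_
  rtracklayer::export(c(gr_g, gr_f), path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Inverse of [write_gene_models()]: `gene` records become the `genes`
#' tibble; `exon`, `five_prime_UTR` and `three_prime_UTR` records (plus
#' any transcript-track exons) become `features`, keyed to their parent
#' gene.
#'
#' @param path GFF3 path.
#' @return A gene-model list with `genes` and `features` tibbles.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  is_gene <- type == "gene"
  genes <- tibble::tibble(
    gene_id = as.character(md$ID[is_gene]),
    seqnames = as.character(GenomicRanges::seqnames(gr[is_gene])),
    start = GenomicRanges::start(gr[is_gene]),
    end = GenomicRanges::end(gr[is_gene]),
    strand = as.character(GenomicRanges::strand(gr[is_gene]))
  )
  genes <- dplyr::arrange(genes, .data$seqnames, .data$start, .data$end)
  fsel <- type %in% c("exon", "five_prime_UTR", "three_prime_UTR")
  parent <- as.character(md$Parent[fsel])
  features <- tibble::tibble(
    gene_id = parent,
    type = type[fsel],
    start = GenomicRanges::start(gr[fsel]),
    end = GenomicRanges::end(gr[fsel])
  )
  features <- dplyr::arrange(features, .data$gene_id, .data$start,
                             .data$end, .data$type)
  list(genes = genes, features = features)
}

#' Write / read conserved-element intervals as BED
#'
#' @param elements Tibble with `seqnames`, `start`, `end` and optionally
#'   a name column (`block_id` or `name`).
#' @param path BED path.
#' @export
write_conserved_bed <- function(elements, path) {
  nm <- elements$block_id %||% elements$name %||%
    sprintf("el%05d", seq_len(nrow(elements)))
  gr <- GenomicRanges::GRanges(
    elements$seqnames, IRanges::IRanges(elements$start, elements$end),
    name = nm
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_conserved_bed
#' @return `read_conserved_bed()` returns a tibble with `seqnames`,
#'   `start`, `end`, `block_id` (1-based closed coordinates).
#' @export
read_conserved_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    block_id = as.character(S4Vectors::mcols(gr)$name %||%
                              sprintf("el%05d", seq_along(gr)))
  )
}

#' Write region sequences as FASTA
#'
#' @param regions Tibble from [extract_gene_set_regions()] (`region_id`,
#'   `seq`).
#' @param path Output FASTA path.
#' @export
write_regions_fasta <- function(regions, path) {
  ss <- Biostrings::DNAStringSet(stats::setNames(regions$seq,
                                                 regions$region_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a complete synthetic world to a directory
#'
#' Emits every pipeline input as plain-text files: genome FASTA, gene
#' models GFF3 and conserved blocks BED per genome species, expression
#' and GO TSVs, the ortholog TSV and a JSON truth file.
#'
#' @param world A `crossnet_world` from [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(world$expression)) {
    write_expression_tsv(world$expression[[s]],
                         file.path(dir, paste0("expr_", s, ".tsv")))
  }
  write_orthologs_tsv(world$orthologs, file.path(dir, "orthologs.tsv"))
  for (s in names(world$genomes)) {
    Biostrings::writeXStringSet(world$genomes[[s]],
                                file.path(dir, paste0("genome_", s, ".fa")))
    write_gene_models(world$models[[s]],
                      file.path(dir, paste0("genes_", s, ".gff3")))
    write_conserved_bed(world$conserved[[s]],
                        file.path(dir, paste0("conserved_", s, ".bed")))
    write_go_tsv(world$annotations[[s]],
                 file.path(dir, paste0("go_", s, ".tsv")))
  }
  truth <- list(truth = world$truth, truth_sites = world$truth_sites,
                motifs = world$motifs)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null")
  invisible(dir)
}
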