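# Randomized-GO negative control: whole per-gene term sets are shuffled
# among previously annotated genes, and every motif-associated gene set
# is re-tested for category-term enrichment per randomization.

#' Shuffle whole per-gene GO term sets among annotated genes
#'
#' Permutes which annotated gene carries which term set; unannotated
#' genes receive nothing. Preserves the multiset of per-gene term-set
#' sizes and every term's gene count.
#'
#' @param annotations Tibble (`gene_id`, `term`).
#' @return A shuffled annotation tibble over the same genes.
#' @export
shuffle_annotations <- function(annotations) {
  genes <- unique(annotations$gene_id)
  remap <- stats::setNames(sample(genes), genes)
  out <- annotations
  out$gene_id <- unname(remap[annotations$gene_id])
  dplyr::arrange(out, .data$gene_id, .data$term)
}

#' Randomized GO term control for motif-associated gene sets
#'
#' Repeats `n_rand` times: shuffle the annotation table with
#' [shuffle_annotations()], then test every motif-associated gene set
#' for GO enrichment and ask whether any category term reaches
#' `FDR < fdr`. `n_tests = n_motif_sets * n_rand`; `n_recovered` counts
#' the (motif, randomization) runs in which some category term was
#' called enriched. With real planted structure absent or destroyed by
#' the shuffle, `n_recovered` should be 0.
#'
#' @param annotations Tibble (`gene_id`, `term`) for the species.
#' @param assoc Motif-gene association tibble (`motif_id`, `gene_id`)
#'   from [associate_nearest()].
#' @param population Population gene ids for the enrichment test.
#' @param category_terms GO terms whose recovery is counted.
#' @param n_rand Number of randomizations (default 100).
#' @param fdr Significance threshold (default 0.05).
#' @param fdr_family BH family passed to [go_enrichment()]; defaults to
#'   `"all"` (correction across the full annotated vocabulary, the
#'   convention of genome-annotation enrichment suites).
#' @param seed RNG seed.
#' @return A list: `n_tests`, `n_recovered`, and `detail` (tibble with
#'   one row per (randomization, motif) run).
#' @export
randomized_go_control <- function(annotations, assoc, population,
                                  category_terms, n_rand = 100L,
                                  fdr = 0.05, fdr_family = "all",
                                  seed = 1L) {
  if (n_rand < 0L) {
    stop("`n_rand` must be >= 0", call. = FALSE)
  }
  if (nrow(annotations) == 0L) {
    stop("empty annotation table", call. = FALSE)
  }
  motif_ids <- sort(unique(assoc$motif_id))
  if (n_rand == 0L || length(motif_ids) == 0L) {
    return(list(n_tests = 0L, n_recovered = 0L,
                detail = tibble::tibble(randomization = integer(),
                                        motif_id = character(),
                                        recovered = logical(),
                                        min_category_fdr = numeric())))
  }
  detail <- vector("list", n_rand)
  with_seed(derive_seed(seed, "go_control"), {
    for (r in seq_len(n_rand)) {
      shuf <- shuffle_annotations(annotations)
      rows <- lapply(motif_ids, function(m) {
        study <- intersect(assoc$gene_id[assoc$motif_id == m],
                           population)
        if (length(study) == 0L) {
          return(tibble::tibble(randomization = r, motif_id = m,
                                recovered = FALSE,
                                min_category_fdr = NA_real_))
        }
        enr <- go_enrichment(study, population, shuf,
                             fdr_family = fdr_family)
        cat_fdr <- enr$fdr[enr$term %in% category_terms]
        tibble::tibble(
          randomization = r, motif_id = m,
          recovered = length(cat_fdr) > 0L && any(cat_fdr < fdr),
          min_category_fdr = if (length(cat_fdr)) min(cat_fdr) else
            NA_real_
        )
      })
      detail[[r]] <- dplyr::bind_rows(rows)
    }
  })
  detail <- dplyr::bind_rows(detail)
  list(
    n_tests = length(motif_ids) * as.integer(n_rand),
    n_recovered = sum(detail$recovered),
    detail = detail
  )
}
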