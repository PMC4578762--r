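# Motif-gene association and GO-term enrichment.

#' Associate motif hits with their nearest gene models
#'
#' Each genomic hit is assigned to the gene(s) at minimal genomic
#' distance (0 when overlapping the gene span); equidistant ties are
#' all retained. Per-motif gene sets are deduplicated, keeping the
#' smallest distance per (motif, gene).
#'
#' @param hits Tibble of genomic hits (`motif_id`, `seqnames`, `start`,
#'   `end`).
#' @param models Gene-model list (`genes` tibble).
#' @return Tibble with `motif_id`, `gene_id`, `distance`.
#' @export
associate_nearest <- function(hits, models) {
  genes <- models$genes
  if (is.null(genes) || nrow(genes) == 0L) {
    stop("empty gene model set", call. = FALSE)
  }
  if (nrow(hits) == 0L) {
    return(tibble::tibble(motif_id = character(), gene_id = character(),
                          distance = integer()))
  }
  gr_h <- GenomicRanges::GRanges(hits$seqnames,
                                 IRanges::IRanges(hits$start, hits$end))
  gr_g <- GenomicRanges::GRanges(genes$seqnames,
                                 IRanges::IRanges(genes$start, genes$end))
  # Candidate nearest genes per hit: any overlapping gene plus the
  # closest gene on each side; all minimum-distance candidates are kept
  # so equidistant ties survive.
  ov <- GenomicRanges::findOverlaps(gr_h, gr_g)
  idx_next <- GenomicRanges::precede(gr_h, gr_g)
  idx_prev <- GenomicRanges::follow(gr_h, gr_g)
  qh <- c(S4Vectors::queryHits(ov),
          which(!is.na(idx_next)), which(!is.na(idx_prev)))
  sh <- c(S4Vectors::subjectHits(ov),
          idx_next[!is.na(idx_next)], idx_prev[!is.na(idx_prev)])
  cand <- tibble::tibble(
    hit = qh,
    motif_id = hits$motif_id[qh],
    gene_id = genes$gene_id[sh],
    distance = GenomicRanges::distance(gr_h[qh], gr_g[sh])
  )
  out <- cand %>%
    dplyr::group_by(.data$hit) %>%
    dplyr::filter(.data$distance == min(.data$distance)) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"hit") %>%
    dplyr::distinct()
  out %>%
    dplyr::group_by(.data$motif_id, .data$gene_id) %>%
    dplyr::summarise(distance = min(.data$distance), .groups = "drop") %>%
    dplyr::arrange(.data$motif_id, .data$gene_id)
}

#' GO-term over-representation of a study gene set
#'
#' One-sided hypergeometric (Fisher's exact) p-value per term present
#' in the study set, with Benjamini-Hochberg FDR. Annotations are used
#' as given (no GO-graph propagation).
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of population gene ids.
#' @param annotations Tibble (`gene_id`, `term`).
#' @param fdr_family Multiple-testing family for the BH correction:
#'   `"present"` (default) adjusts across the terms present in the
#'   study set; `"all"` adjusts across every annotated term in the
#'   population (the full tested vocabulary, as annotation-suite tools
#'   do), which is more conservative.
#' @return Tibble with `term`, `study_hits`, `study_size`, `pop_hits`,
#'   `pop_size`, `p`, `fdr`, sorted by `p`.
#' @export
go_enrichment <- function(study, population, annotations,
                          fdr_family = c("present", "all")) {
  fdr_family <- match.arg(fdr_family)
  study <- unique(study)
  population <- unique(population)
  if (length(study) == 0L) {
    stop("empty study set", call. = FALSE)
  }
  if (!all(study %in% population)) {
    stop("`study` must be a subset of `population`", call. = FALSE)
  }
  ann <- annotations[annotations$gene_id %in% population, , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(tibble::tibble(term = character(), study_hits = integer(),
                          study_size = integer(), pop_hits = integer(),
                          pop_size = integer(), p = numeric(),
                          fdr = numeric()))
  }
  n_pop <- length(population)
  n_study <- length(study)
  per_term <- ann %>%
    dplyr::distinct(.data$gene_id, .data$term) %>%
    dplyr::group_by(.data$term) %>%
    dplyr::summarise(
      pop_hits = dplyr::n(),
      study_hits = sum(.data$gene_id %in% study),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$study_hits > 0L)
  n_terms_tested <- dplyr::n_distinct(ann$term)
  if (nrow(per_term) == 0L) {
    return(tibble::tibble(term = character(), study_hits = integer(),
                          study_size = integer(), pop_hits = integer(),
                          pop_size = integer(), p = numeric(),
                          fdr = numeric()))
  }
  p <- stats::phyper(per_term$study_hits - 1L, per_term$pop_hits,
                     n_pop - per_term$pop_hits, n_study,
                     lower.tail = FALSE)
  out <- tibble::tibble(
    term = per_term$term,
    study_hits = per_term$study_hits,
    study_size = n_study,
    pop_hits = per_term$pop_hits,
    pop_size = n_pop,
    p = pmin(p, 1),
    fdr = stats::p.adjust(pmin(p, 1), method = "BH",
                          n = if (fdr_family == "all") {
                            n_terms_tested
                          } else {
                            length(p)
                          })
  )
  dplyr::arrange(out, .data$p, .data$term)
}

# Enrichment for every motif-associated gene set of one species.
enrich_motif_sets <- function(assoc, population, annotations) {
  assoc %>%
    dplyr::group_by(.data$motif_id) %>%
    dplyr::group_modify(function(d, key) {
      go_enrichment(d$gene_id, population, annotations)
    }) %>%
    dplyr::ungroup()
}

#' Motif-associated GO terms shared between two species
#'
#' A (motif, term) pair qualifies when its enrichment FDR is below
#' `fdr` in both species. The shared-ortholog fraction is computed in
#' both directions (fraction of one species' motif-associated genes for
#' the term whose 1:1 ortholog is in the other species' set); the
#' minimum of the two directions is compared against `overlap_min`.
#'
#' @param enrich_a,enrich_b Per-motif enrichment tibbles (from
#'   [enrich_motif_sets()]) for species A and B.
#' @param assoc_a,assoc_b Motif-gene association tibbles for the two
#'   species.
#' @param annotations_a,annotations_b Annotation tibbles (`gene_id`,
#'   `term`).
#' @param orthologs Ortholog table; `cols` names its species-A and -B
#'   gene-id columns (default columns 2 and 3).
#' @param fdr Enrichment FDR threshold (default 0.05).
#' @param overlap_min Minimum shared-ortholog fraction (default 0.30).
#' @param cols Length-2 character vector of ortholog-table columns.
#' @return Tibble of class `mag_pairs`: `motif_id`, `term`, per-species
#'   FDRs, gene-set sizes, `shared_ab`, `shared_ba`, `pct_shared`
#'   (minimum direction), `passes_overlap`, and list-columns
#'   `genes_a`, `genes_b`, `shared_orthologs` (species-A ids of the
#'   shared 1:1 targets).
#' @export
shared_mags <- function(enrich_a, enrich_b, assoc_a, assoc_b,
                        annotations_a, annotations_b, orthologs,
                        fdr = 0.05, overlap_min = 0.30, cols = NULL) {
  has_orth <- !is.null(orthologs)
  cols <- cols %||% if (has_orth) names(orthologs)[2:3] else NULL
  sig_a <- enrich_a[enrich_a$fdr < fdr, c("motif_id", "term", "fdr")]
  sig_b <- enrich_b[enrich_b$fdr < fdr, c("motif_id", "term", "fdr")]
  shared <- dplyr::inner_join(sig_a, sig_b, by = c("motif_id", "term"),
                              suffix = c("_a", "_b"))
  if (nrow(shared) == 0L) {
    out <- tibble::tibble(
      motif_id = character(), term = character(), fdr_a = numeric(),
      fdr_b = numeric(), n_a = integer(), n_b = integer(),
      shared_ab = numeric(), shared_ba = numeric(),
      pct_shared = numeric(), passes_overlap = logical(),
      genes_a = list(), genes_b = list(), shared_orthologs = list()
    )
    class(out) <- c("mag_pairs", class(out))
    return(out)
  }
  ann_a <- dplyr::distinct(annotations_a, .data$gene_id, .data$term)
  ann_b <- dplyr::distinct(annotations_b, .data$gene_id, .data$term)
  a2b <- if (has_orth) {
    stats::setNames(orthologs[[cols[2]]], orthologs[[cols[1]]])
  } else {
    NULL
  }
  b2a <- if (has_orth) {
    stats::setNames(orthologs[[cols[1]]], orthologs[[cols[2]]])
  } else {
    NULL
  }
  rows <- lapply(seq_len(nrow(shared)), function(i) {
    mt <- shared$motif_id[i]
    tm <- shared$term[i]
    ga <- intersect(assoc_a$gene_id[assoc_a$motif_id == mt],
                    ann_a$gene_id[ann_a$term == tm])
    gb <- intersect(assoc_b$gene_id[assoc_b$motif_id == mt],
                    ann_b$gene_id[ann_b$term == tm])
    if (has_orth) {
      orth_ab <- a2b[ga]
      orth_ba <- b2a[gb]
      sh_ab <- if (length(ga)) {
        sum(!is.na(orth_ab) & orth_ab %in% gb) / length(ga)
      } else {
        0
      }
      sh_ba <- if (length(gb)) {
        sum(!is.na(orth_ba) & orth_ba %in% ga) / length(gb)
      } else {
        0
      }
      shared_ids <- ga[!is.na(orth_ab) & orth_ab %in% gb]
      pct <- min(sh_ab, sh_ba)
      pass <- pct >= overlap_min
    } else {
      sh_ab <- NA_real_
      sh_ba <- NA_real_
      pct <- NA_real_
      pass <- FALSE
      shared_ids <- character(0)
    }
    tibble::tibble(
      motif_id = mt, term = tm,
      fdr_a = shared$fdr_a[i], fdr_b = shared$fdr_b[i],
      n_a = length(ga), n_b = length(gb),
      shared_ab = sh_ab, shared_ba = sh_ba, pct_shared = pct,
      passes_overlap = pass,
      genes_a = list(ga), genes_b = list(gb),
      shared_orthologs = list(shared_ids)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mag_pairs", class(out))
  out
}
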