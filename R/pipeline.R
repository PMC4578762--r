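# End-to-end orchestration: expression conservation -> stage sets ->
# conserved non-coding regions -> motif discovery -> scanning and
# filtering -> motif-gene association -> GO enrichment -> shared MAGs ->
# category networks -> randomized-GO control.

#' Pipeline parameters
#'
#' Aggregates every stage threshold with the published defaults:
#' 10/5 FPKM binarization, cosine > 0.95, 10% stage contribution,
#' stage sets > 30 genes, +/- 3 kb flanks, regions > 8 bp, motif widths
#' 6-12, scan q <= 0.3, motif-match overlap >= 5 and p < 0.05,
#' enrichment FDR < 0.05, 30% shared orthologs, degree >= 5, and 100
#' randomizations. Discovery search effort (`nmotifs`, `n_seeds`,
#' `n_keep`) defaults to desk-scale settings suited to the synthetic
#' worlds; raise them for larger inputs.
#'
#' @param thresholds A [conservation_thresholds()].
#' @param flank,min_len Region extraction controls (bp).
#' @param minw,maxw,nmotifs,n_seeds,n_keep,max_iter,tol Motif-discovery
#'   controls (see [discover_motifs()]).
#' @param q_threshold Scan q-value threshold.
#' @param redundancy_p,min_overlap,n_perm Redundancy-filter controls.
#' @param enrich_fdr,overlap_min MAG intersection controls.
#' @param min_degree Network degree filter.
#' @param n_rand Randomized-control randomizations.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(thresholds = conservation_thresholds(),
                            flank = 3000L, min_len = 8L,
                            minw = 8L, maxw = 8L, nmotifs = 4L,
                            n_seeds = 400L, n_keep = 5L,
                            max_iter = 100L, tol = 1e-4,
                            q_threshold = 0.3, redundancy_p = 0.05,
                            min_overlap = 5L, n_perm = 500L,
                            enrich_fdr = 0.05, overlap_min = 0.30,
                            min_degree = 5L, n_rand = 100L,
                            seed = 1L) {
  p <- list(thresholds = thresholds, flank = as.integer(flank),
            min_len = as.integer(min_len), minw = as.integer(minw),
            maxw = as.integer(maxw), nmotifs = as.integer(nmotifs),
            n_seeds = as.integer(n_seeds), n_keep = as.integer(n_keep),
            max_iter = as.integer(max_iter), tol = tol,
            q_threshold = q_threshold, redundancy_p = redundancy_p,
            min_overlap = as.integer(min_overlap),
            n_perm = as.integer(n_perm), enrich_fdr = enrich_fdr,
            overlap_min = overlap_min,
            min_degree = as.integer(min_degree),
            n_rand = as.integer(n_rand), seed = as.integer(seed))
  class(p) <- "pipeline_params"
  p
}

# Conserved non-coding element sequences of one genome species, as a
# region tibble usable for both discovery and scanning.
noncoding_regions <- function(world, species) {
  part <- partition_conserved(world$conserved[[species]],
                              world$models[[species]])
  nc <- part$noncoding
  if (nrow(nc) == 0L) {
    return(tibble::tibble(region_id = character(),
                          seqnames = character(), start = integer(),
                          end = integer(), seq = character()))
  }
  sq <- get_subseqs(world$genomes[[species]], nc$seqnames, nc$start,
                    nc$end)
  tibble::tibble(
    region_id = sprintf("%s:%d-%d", nc$seqnames, nc$start, nc$end),
    seqnames = nc$seqnames, start = nc$start, end = nc$end, seq = sq
  )
}

# Lift element-local hits back to genomic coordinates.
hits_to_genomic <- function(hits, regions) {
  m <- match(hits$seq_id, regions$region_id)
  hits$seqnames <- regions$seqnames[m]
  offset <- regions$start[m] - 1L
  hits$start <- hits$start + offset
  hits$end <- hits$end + offset
  hits
}

#' Run the full conserved-network pipeline on a synthetic world
#'
#' Executes every stage in dependency order on a [simulate_world()]
#' object: cosine (and binarized) expression conservation between the
#' two congeners, stage-specific set assignment, conserved non-coding
#' partitioning for both genome species, per-set motif discovery in the
#' first congener's regions, redundancy and mappability filtering,
#' scanning in both genomes, nearest-gene association, per-species GO
#' enrichment, cross-genus MAG intersection, category networks and the
#' randomized-GO control.
#'
#' @param world A `crossnet_world`.
#' @param params A [pipeline_params()].
#' @param out_dir Optional directory; when given, result tables,
#'   networks (JSON/GraphML) and the run report (JSON and text) are
#'   written there.
#' @return A list of class `crossnet_run` with all stage outputs and a
#'   `report` tibble of per-stage counts.
#' @export
run_pipeline <- function(world, params = pipeline_params(),
                         out_dir = NULL) {
  stopifnot(inherits(world, "crossnet_world"))
  t0 <- Sys.time()
  sp <- sim_species()
  thr <- params$thresholds
  report <- list()
  note <- function(stage, ...) {
    report[[stage]] <<- tibble::tibble(stage = stage, ...)
  }

  # 1. Expression conservation between the two congeners.
  cons <- cosine_conservation(world$expression[[sp[["a"]]]],
                              world$expression[[sp[["b"]]]],
                              world$orthologs, thr,
                              cols = c(sp[["a"]], sp[["b"]]))
  bin <- binary_conservation(world$expression[[sp[["a"]]]],
                             world$expression[[sp[["b"]]]],
                             world$orthologs, thr,
                             cols = c(sp[["a"]], sp[["b"]]))
  note("expression_conservation",
       n_orthologs = nrow(cons),
       n_cosine_conserved = sum(cons$call == "conserved"),
       n_binary_conserved = sum(bin$call == "conserved"))

  # 2. Stage-specific sets of conserved orthologs.
  sets <- stage_specific_sets(cons, world$expression[[sp[["a"]]]],
                              world$expression[[sp[["b"]]]],
                              world$orthologs, thr,
                              cols = c(sp[["a"]], sp[["b"]]))
  mineable <- sets[sets$mineable, ]
  note("stage_sets", n_assigned = nrow(sets),
       n_labels = length(unique(sets$label)),
       n_mineable_labels = length(unique(mineable$label)))
  if (nrow(mineable) == 0L) {
    warning("no stage-specific set exceeds `min_set_size`; ",
            "pipeline ends with an empty network", call. = FALSE)
  }

  # 3. Conserved non-coding regions for both genome species.
  regions <- list()
  for (s in names(world$genomes)) {
    regions[[s]] <- noncoding_regions(world, s)
  }
  note("noncoding_regions",
       n_a = nrow(regions[[sp[["a"]]]]),
       n_b = nrow(regions[[sp[["c"]]]]))

  # 4. Motif discovery per mineable stage set (first congener genome).
  found <- list()
  for (lab in sort(unique(mineable$label))) {
    og <- mineable$ortholog_id[mineable$label == lab]
    gset <- world$orthologs[[sp[["a"]]]][
      world$orthologs$ortholog_id %in% og]
    reg <- extract_gene_set_regions(
      gset, world$models[[sp[["a"]]]],
      regions[[sp[["a"]]]][, c("seqnames", "start", "end")],
      world$genomes[[sp[["a"]]]],
      flank = params$flank, min_len = params$min_len
    )
    if (nrow(reg) < 2L) next
    ms <- discover_motifs(
      stats::setNames(reg$seq, reg$region_id),
      minw = params$minw, maxw = params$maxw,
      nmotifs = params$nmotifs, max_iter = params$max_iter,
      tol = params$tol, n_seeds = params$n_seeds,
      n_keep = params$n_keep,
      seed = derive_seed(params$seed, paste0("discover_", lab)),
      motif_prefix = paste0("set_", lab)
    )
    if (nrow(ms) > 0L) found[[lab]] <- ms
  }
  all_motifs <- if (length(found)) {
    bgs <- lapply(found, motif_background)
    bg <- Reduce(`+`, bgs) / length(bgs)
    new_motif_set(dplyr::bind_rows(lapply(found, tibble::as_tibble)),
                  background = bg,
                  provenance = list(stage = "discovery",
                                    seed = params$seed))
  } else {
    new_motif_set(tibble::tibble(motif_id = character(),
                                 width = integer(), nsites = integer(),
                                 score = numeric(),
                                 consensus = character(), pwm = list()))
  }
  note("motif_discovery", n_sets_mined = length(found),
       n_motifs = nrow(all_motifs))

  # 5. Redundancy filter, scan both species, mappability filter.
  nonred <- if (nrow(all_motifs) > 1L) {
    remove_redundant(all_motifs, p_threshold = params$redundancy_p,
                     min_overlap = params$min_overlap,
                     n_perm = params$n_perm,
                     seed = derive_seed(params$seed, "dedupe"))
  } else {
    all_motifs
  }
  hits <- list()
  for (s in names(world$genomes)) {
    h <- scan_motifs(nonred,
                     stats::setNames(regions[[s]]$seq,
                                     regions[[s]]$region_id),
                     q_threshold = params$q_threshold)
    hits[[s]] <- hits_to_genomic(h, regions[[s]])
  }
  final_motifs <- drop_unmappable(nonred, hits[[sp[["a"]]]],
                                  hits[[sp[["c"]]]])
  for (s in names(hits)) {
    hits[[s]] <- hits[[s]][hits[[s]]$motif_id %in%
                             final_motifs$motif_id, ]
  }
  note("motif_filtering", n_nonredundant = nrow(nonred),
       n_mappable = nrow(final_motifs),
       n_hits_a = nrow(hits[[sp[["a"]]]]),
       n_hits_b = nrow(hits[[sp[["c"]]]]))

  # 6. Nearest-gene association and per-species GO enrichment.
  assoc <- list()
  enrich <- list()
  for (s in names(world$genomes)) {
    assoc[[s]] <- associate_nearest(hits[[s]], world$models[[s]])
    pop <- world$models[[s]]$genes$gene_id
    enrich[[s]] <- if (nrow(assoc[[s]])) {
      enrich_motif_sets(assoc[[s]], pop, world$annotations[[s]])
    } else {
      tibble::tibble(motif_id = character(), term = character(),
                     study_hits = integer(), study_size = integer(),
                     pop_hits = integer(), pop_size = integer(),
                     p = numeric(), fdr = numeric())
    }
  }
  note("association", n_pairs_a = nrow(assoc[[sp[["a"]]]]),
       n_pairs_b = nrow(assoc[[sp[["c"]]]]))

  # 7. Shared MAGs and category networks.
  orth_ac <- world$orthologs[, c("ortholog_id", sp[["a"]], sp[["c"]])]
  mags <- shared_mags(enrich[[sp[["a"]]]], enrich[[sp[["c"]]]],
                      assoc[[sp[["a"]]]], assoc[[sp[["c"]]]],
                      world$annotations[[sp[["a"]]]],
                      world$annotations[[sp[["c"]]]],
                      orth_ac, fdr = params$enrich_fdr,
                      overlap_min = params$overlap_min)
  networks <- list()
  for (tm in world$config$category_terms) {
    networks[[tm]] <- build_category_network(
      mags, tm, category = tm, min_degree = params$min_degree
    )
  }
  note("networks", n_mags = nrow(mags),
       n_mags_passing = sum(mags$passes_overlap),
       n_categories = length(networks))

  # 8. Randomized-GO control (first congener, as in the source study
  # design: one species' annotations shuffled).
  control <- if (params$n_rand > 0L && nrow(assoc[[sp[["a"]]]]) > 0L) {
    randomized_go_control(
      world$annotations[[sp[["a"]]]], assoc[[sp[["a"]]]],
      world$models[[sp[["a"]]]]$genes$gene_id,
      world$config$category_terms, n_rand = params$n_rand,
      fdr = params$enrich_fdr,
      seed = derive_seed(params$seed, "control")
    )
  } else {
    list(n_tests = 0L, n_recovered = 0L, detail = tibble::tibble())
  }
  note("randomized_control", n_tests = control$n_tests,
       n_recovered = control$n_recovered)

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  rep_tbl <- dplyr::bind_rows(lapply(report, function(x) {
    tibble::tibble(stage = x$stage[1],
                   counts = paste(names(x)[-1], unlist(x[1, -1]),
                                  sep = "=", collapse = ", "))
  }))
  run <- structure(
    list(conservation = cons, binary = bin, stage_sets = sets,
         regions = regions, motifs = all_motifs,
         final_motifs = final_motifs, hits = hits, assoc = assoc,
         enrich = enrich, mags = mags, networks = networks,
         control = control, params = params, report = rep_tbl,
         elapsed = elapsed),
    class = "crossnet_run"
  )
  if (!is.null(out_dir)) {
    write_run(run, out_dir)
  }
  run
}

#' @export
print.crossnet_run <- function(x, ...) {
  cat("<crossnet_run>\n")
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  %-24s %s\n", x$report$stage[i], x$report$counts[i]))
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `crossnet_run`.
#' @param ... Unused.
#' @exportS3Method
glance.crossnet_run <- function(x, ...) {
  tibble::tibble(
    n_orthologs = nrow(x$conservation),
    n_cosine_conserved = sum(x$conservation$call == "conserved"),
    n_motifs = nrow(x$motifs),
    n_final_motifs = nrow(x$final_motifs),
    n_mags_passing = sum(x$mags$passes_overlap),
    control_tests = x$control$n_tests,
    control_recovered = x$control$n_recovered,
    elapsed_s = x$elapsed
  )
}

# Write all run artifacts to a directory.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(run$conservation, "conservation_cosine.tsv")
  wt(run$binary, "conservation_binary.tsv")
  wt(run$stage_sets, "stage_sets.tsv")
  if (nrow(run$final_motifs)) {
    write_meme(run$final_motifs, file.path(out_dir, "motifs.meme"))
  }
  for (s in names(run$hits)) {
    wt(run$hits[[s]], paste0("hits_", s, ".tsv"))
    wt(run$assoc[[s]], paste0("assoc_", s, ".tsv"))
    wt(run$enrich[[s]], paste0("enrich_", s, ".tsv"))
  }
  wt(dplyr::select(run$mags, -"genes_a", -"genes_b",
                   -"shared_orthologs"), "mags.tsv")
  for (tm in names(run$networks)) {
    safe <- gsub("[^A-Za-z0-9]", "_", tm)
    write_network(run$networks[[tm]],
                  json_path = file.path(out_dir,
                                        paste0("network_", safe, ".json")),
                  graphml_path = file.path(out_dir,
                                           paste0("network_", safe,
                                                  ".graphml")))
  }
  jsonlite::write_json(
    list(report = run$report, elapsed_s = run$elapsed,
         seed = run$params$seed),
    file.path(out_dir, "run_report.json"),
    dataframe = "rows", auto_unbox = TRUE
  )
  writeLines(
    c("crossnet run report",
      sprintf("%-24s %s", run$report$stage, run$report$counts),
      sprintf("elapsed: %.1f s", run$elapsed)),
    file.path(out_dir, "run_report.txt")
  )
  invisible(out_dir)
}
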