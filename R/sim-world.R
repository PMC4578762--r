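#' Simulate developmental expression for three species
#'
#' Generates per-stage, per-replicate expression (FPKM/TPM-like units)
#' for `n_orthologs` 1:1:1 ortholog triples across two congeners
#' (`g1s1`, `g1s2`) and a distant outgroup (`g2s1`). Conserved orthologs
#' share one stage profile across all species up to multiplicative
#' lognormal noise; divergent orthologs have the stage axis of the
#' second congener's profile permuted, with the permutation re-drawn
#' until the permuted profile is not cosine-conserved (<= 0.95) relative
#' to the original, so truth labels are unambiguous. Planted GO-category
#' genes are always conserved and share a concentrated stage profile per
#' category, which places them together in one stage-specific set.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (named list of three long
#'   tibbles: `gene_id`, `stage`, `replicate`, `value`), `orthologs`
#'   (tibble with one gene-id column per species), and `truth` (tibble
#'   with `ortholog_id`, `conservation_label`, `true_stage_set`,
#'   `category_term`, `planted_motif_id`).
#' @export
#' @examples
#' w <- simulate_expression(sim_config(n_orthologs = 20, seed = 3))
#' head(w$truth)
simulate_expression <- function(config) {
  validate_sim_config(config)
  cfg <- config
  sp <- sim_species()
  n <- cfg$n_orthologs
  S <- length(cfg$stages)

  with_seed(derive_seed(cfg$seed, "expression"), {
    og <- sprintf("OG%05d", seq_len(n))
    orthologs <- tibble::tibble(
      ortholog_id = og,
      !!sp[["a"]] := sprintf("%s_G%05d", toupper(sp[["a"]]), seq_len(n)),
      !!sp[["b"]] := sprintf("%s_G%05d", toupper(sp[["b"]]), seq_len(n)),
      !!sp[["c"]] := sprintf("%s_G%05d", toupper(sp[["c"]]), seq_len(n))
    )

    n_cons <- round(cfg$frac_conserved * n)
    conserved_idx <- sort(sample.int(n, n_cons))
    label <- ifelse(seq_len(n) %in% conserved_idx, "conserved", "divergent")

    # Planted categories draw from conserved orthologs only.
    n_cat <- length(cfg$category_terms)
    category_term <- rep(NA_character_, n)
    planted_motif <- rep(NA_character_, n)
    if (n_cat > 0L && cfg$category_size > 0L && cfg$n_planted_motifs > 0L) {
      need <- n_cat * cfg$category_size
      if (need > length(conserved_idx)) {
        stop("not enough conserved orthologs to host the planted ",
             "categories; raise `frac_conserved` or shrink ",
             "`category_size`", call. = FALSE)
      }
      pool <- sample(conserved_idx, need)
      for (k in seq_len(n_cat)) {
        idx <- pool[((k - 1L) * cfg$category_size + 1L):(k * cfg$category_size)]
        category_term[idx] <- cfg$category_terms[[k]]
        motif_k <- ((k - 1L) %% cfg$n_planted_motifs) + 1L
        planted_motif[idx] <- sprintf("planted_%02d", motif_k)
      }
    }

    # Stage profiles: concentrated Dirichlet for ordinary orthologs,
    # fixed concentrated profiles per category so category genes share a
    # stage-specific set.
    cat_profile <- function(k) {
      p <- rep(0.1 / max(S - 1L, 1L), S)
      p[((k - 1L) %% S) + 1L] <- 0.9
      p / sum(p)
    }
    base_prof <- matrix(NA_real_, n, S)
    for (i in seq_len(n)) {
      if (!is.na(category_term[i])) {
        k <- match(category_term[i], cfg$category_terms)
        base_prof[i, ] <- cat_profile(k)
      } else {
        base_prof[i, ] <- rdirichlet1(rep(0.3, S))
      }
    }

    # Divergent orthologs: permute the stage axis in g1s2 until the
    # permuted profile is no longer cosine-conserved with the original.
    perm_prof <- base_prof
    for (i in which(label == "divergent")) {
      tries <- 0L
      repeat {
        pm <- sample.int(S)
        cand <- base_prof[i, pm]
        if (!all(pm == seq_len(S)) &&
            cosine_similarity(base_prof[i, ], cand) <= 0.95) {
          perm_prof[i, ] <- cand
          break
        }
        tries <- tries + 1L
        if (tries > 50L) {
          base_prof[i, ] <- rdirichlet1(rep(0.3, S))
          tries <- 0L
        }
      }
    }

    # Total expression shared across species (conserved overall level);
    # category genes kept comfortably above the binarization thresholds.
    total <- exp(stats::rnorm(n, log(100), 0.8))
    total[!is.na(category_term)] <-
      exp(stats::rnorm(sum(!is.na(category_term)), log(300), 0.3))

    make_expr <- function(prof) {
      nr <- cfg$n_replicates
      mean_mat <- prof * total  # n x S stage means
      rows <- n * S * nr
      gene_col <- rep(seq_len(n), each = S * nr)
      stage_col <- rep(rep(cfg$stages, each = nr), times = n)
      rep_col <- rep(rep(seq_len(nr), times = S), times = n)
      mu <- mean_mat[cbind(gene_col, rep(rep(seq_len(S), each = nr), n))]
      noise <- if (cfg$noise_sd > 0) {
        exp(stats::rnorm(rows, 0, cfg$noise_sd))
      } else {
        rep(1, rows)
      }
      tibble::tibble(
        gene_idx = gene_col, stage = stage_col,
        replicate = rep_col, value = mu * noise
      )
    }

    expr <- list()
    for (s in sp) {
      prof <- if (s == sp[["b"]]) perm_prof else base_prof
      e <- make_expr(prof)
      e$gene_id <- orthologs[[s]][e$gene_idx]
      expr[[s]] <- dplyr::select(e, "gene_id", "stage", "replicate", "value")
    }

    true_set <- apply(base_prof, 1L, function(p) {
      paste(cfg$stages[p / sum(p) >= 0.10], collapse = "")
    })

    truth <- tibble::tibble(
      ortholog_id = og,
      conservation_label = label,
      true_stage_set = true_set,
      category_term = category_term,
      planted_motif_id = planted_motif
    )

    list(expression = expr, orthologs = orthologs, truth = truth)
  })
}

#' Simulate toy genomes with gene models and conserved non-coding blocks
#'
#' Builds one chromosome per genome species (the first congener `g1s1`
#' and the outgroup `g2s1`): genes laid out sequentially with wide
#' intergenic gaps, each with three exons, two introns and terminal
#' UTRs; one conserved non-coding block upstream of each gene (within
#' `flank_length`) and one inside its first intron. Planted motif
#' consensus instances are written into the upstream blocks of category
#' genes at `planting_rate` (an exact count, the same gene subset in
#' both species), on a random strand. Each block also receives a mutated
#' partner-copy alignment so the windowed conservation caller can be
#' exercised on generator output.
#'
#' @param config A [sim_config()].
#' @param expr_world Output of [simulate_expression()] (supplies ortholog
#'   ids, category membership and planted-motif assignment).
#' @return A list with `genomes` (named list of [Biostrings::DNAStringSet]),
#'   `models` (named list of gene-model lists; see [gene_models()]),
#'   `conserved` (named list of block tibbles), `alignments` (tibble of
#'   per-block gapless alignment pairs), `motifs` (tibble of planted
#'   motif consensi) and `truth_sites` (tibble of planted site
#'   coordinates, 1-based closed).
#' @export
simulate_genomes <- function(config, expr_world) {
  validate_sim_config(config)
  cfg <- config
  sp <- sim_species()
  genome_sp <- c(sp[["a"]], sp[["c"]])
  orth <- expr_world$orthologs
  truth <- expr_world$truth

  with_seed(derive_seed(cfg$seed, "genomes"), {
    # Planted motif consensi: distinct random words, not self-reverse-
    # complementary, drawn once for the whole world.
    motif_ids <- sprintf("planted_%02d", seq_len(cfg$n_planted_motifs))
    consensus <- character(0)
    while (length(consensus) < cfg$n_planted_motifs) {
      cand <- random_dna(cfg$motif_width, 0.5)
      if (!cand %in% consensus && cand != revcomp(cand)) {
        consensus <- c(consensus, cand)
      }
    }
    motifs <- tibble::tibble(motif_id = motif_ids, consensus = consensus)

    # Exact planted-gene subset, shared across species.
    planted_idx <- integer(0)
    for (tm in unique(stats::na.omit(truth$category_term))) {
      idx <- which(truth$category_term == tm)
      k <- round(cfg$planting_rate * length(idx))
      if (k > 0L) planted_idx <- c(planted_idx, sort(sample(idx, k)))
    }
    planted_idx <- sort(planted_idx)

    worlds <- list(genomes = list(), models = list(), conserved = list())
    aln <- list()
    sites <- list()

    for (s in genome_sp) {
      n_genes <- cfg$n_genes_per_genome
      gene_ids <- c(
        orth[[s]],
        if (n_genes > nrow(orth)) {
          sprintf("%s_X%05d", toupper(s), seq_len(n_genes - nrow(orth)))
        }
      )

      gene_len <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2],
                         n_genes, replace = TRUE)
      gap <- sample((2L * cfg$flank_length + 200L):
                      (2L * cfg$flank_length + 1000L),
                    n_genes, replace = TRUE)
      start <- cfg$flank_length + 500L + cumsum(c(0L, gap[-n_genes])) +
        cumsum(c(0L, gene_len[-n_genes]))
      start <- as.integer(start + 1L)
      end <- as.integer(start + gene_len - 1L)
      strand <- sample(c("+", "-"), n_genes, replace = TRUE)
      chrom <- "chr1"
      chrom_len <- end[n_genes] + cfg$flank_length + 500L

      if (any(start[-1L] <= end[-n_genes])) {
        stop("internal error: simulated gene models overlap", call. = FALSE)
      }

      genes <- tibble::tibble(
        gene_id = gene_ids, seqnames = chrom,
        start = start, end = end, strand = strand
      )

      # Three exons, two introns, terminal UTRs (genomic orientation).
      feats <- vector("list", n_genes)
      intron1 <- matrix(0L, n_genes, 2L)
      for (i in seq_len(n_genes)) {
        L <- gene_len[i]
        i1 <- sample(120L:260L, 1L)
        i2 <- sample(80L:160L, 1L)
        coding <- L - i1 - i2
        e1 <- max(80L, round(coding * 0.3))
        e3 <- max(80L, round(coding * 0.25))
        e2 <- coding - e1 - e3
        b <- start[i]
        ex <- tibble::tibble(
          gene_id = gene_ids[i],
          type = c("five_prime_UTR", "exon", "exon", "exon",
                   "three_prime_UTR"),
          start = c(b, b, b + e1 + i1, b + e1 + i1 + e2 + i2,
                    end[i] - 39L),
          end = c(b + 39L, b + e1 - 1L, b + e1 + i1 + e2 - 1L, end[i],
                  end[i])
        )
        feats[[i]] <- ex
        intron1[i, ] <- c(b + e1, b + e1 + i1 - 1L)
      }
      features <- dplyr::bind_rows(feats)

      seq_chr <- random_dna(chrom_len, cfg$background_gc)

      # Conserved non-coding blocks: one upstream, one in intron 1.
      blk <- list()
      for (i in seq_len(n_genes)) {
        bl <- sample(cfg$block_length_range[1]:cfg$block_length_range[2], 1L)
        d <- sample(150L:(cfg$flank_length - bl - 50L), 1L)
        up_end <- start[i] - d
        up <- c(up_end - bl + 1L, up_end)
        ilen <- intron1[i, 2L] - intron1[i, 1L] + 1L
        bl2 <- min(sample(cfg$block_length_range[1]:
                            cfg$block_length_range[2], 1L), ilen - 20L)
        off <- sample(0L:(ilen - bl2 - 10L), 1L)
        inb <- c(intron1[i, 1L] + 5L + off,
                 intron1[i, 1L] + 5L + off + bl2 - 1L)
        blk[[i]] <- tibble::tibble(
          seqnames = chrom,
          start = c(up[1L], inb[1L]), end = c(up[2L], inb[2L]),
          block_id = sprintf("%s_blk%05d_%s", toupper(s), i,
                             c("up", "in")),
          gene_id = gene_ids[i], placement = c("upstream", "intron")
        )
      }
      conserved <- dplyr::bind_rows(blk)

      # Plant motif consensi into upstream blocks of planted genes.
      for (i in planted_idx) {
        mot <- truth$planted_motif_id[i]
        cons <- motifs$consensus[motifs$motif_id == mot]
        row <- conserved[conserved$gene_id == gene_ids[i] &
                           conserved$placement == "upstream", ]
        w <- cfg$motif_width
        pos <- row$start + sample(0L:(row$end - row$start + 1L - w), 1L)
        st <- sample(c("+", "-"), 1L)
        word <- if (st == "+") cons else revcomp(cons)
        substr(seq_chr, pos, pos + w - 1L) <- word
        sites[[length(sites) + 1L]] <- tibble::tibble(
          species = s, seqnames = chrom, start = pos,
          end = pos + w - 1L, strand = st, motif_id = mot,
          gene_id = gene_ids[i],
          ortholog_id = truth$ortholog_id[i],
          category_term = truth$category_term[i]
        )
      }

      # Mutated partner copy of every block (gapless alignment pair).
      bseq <- substring(seq_chr, conserved$start, conserved$end)
      mutate_copy <- function(x) {
        v <- strsplit(x, "")[[1]]
        hit <- stats::runif(length(v)) < cfg$paralog_divergence
        if (any(hit)) {
          v[hit] <- vapply(v[hit], function(b) {
            sample(setdiff(DNA_LETTERS, b), 1L)
          }, character(1))
        }
        paste(v, collapse = "")
      }
      aln[[s]] <- tibble::tibble(
        species = s, block_id = conserved$block_id,
        seq_a = bseq,
        seq_b = vapply(bseq, mutate_copy, character(1), USE.NAMES = FALSE)
      )

      genome <- Biostrings::DNAStringSet(stats::setNames(seq_chr, chrom))
      worlds$genomes[[s]] <- genome
      worlds$models[[s]] <- list(genes = genes, features = features)
      worlds$conserved[[s]] <- conserved
    }

    truth_sites <- if (length(sites)) {
      dplyr::bind_rows(sites)
    } else {
      tibble::tibble(
        species = character(), seqnames = character(), start = integer(),
        end = integer(), strand = character(), motif_id = character(),
        gene_id = character(), ortholog_id = character(),
        category_term = character()
      )
    }

    list(
      genomes = worlds$genomes, models = worlds$models,
      conserved = worlds$conserved,
      alignments = dplyr::bind_rows(aln),
      motifs = motifs, truth_sites = truth_sites
    )
  })
}

#' Simulate gene-to-GO annotations for the genome species
#'
#' Every annotated gene carries at least one term. Category terms are
#' assigned exactly to their designated gene sets (category genes are
#' always annotated); background terms are drawn at random, with the
#' per-gene background term count distributed as 1 + Poisson.
#'
#' @param config A [sim_config()].
#' @param genes Named list (per genome species) of gene-id character
#'   vectors.
#' @param truth Truth tibble from [simulate_expression()].
#' @param orthologs Ortholog table from [simulate_expression()].
#' @return Named list of annotation tibbles (`gene_id`, `term`).
#' @export
simulate_go <- function(config, genes, truth, orthologs) {
  validate_sim_config(config)
  cfg <- config
  if (cfg$n_go_terms < length(cfg$category_terms)) {
    stop("`n_go_terms` must be >= the number of category terms",
         call. = FALSE)
  }
  if (length(genes) == 0L || any(lengths(genes) == 0L)) {
    stop("`genes` must be non-empty for every species", call. = FALSE)
  }
  bg_terms <- if (cfg$n_go_terms > 0L) {
    sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  } else {
    character(0)
  }

  with_seed(derive_seed(cfg$seed, "go"), {
    out <- list()
    for (s in names(genes)) {
      ids <- genes[[s]]
      cat_genes <- character(0)
      cat_map <- list()
      if (s %in% names(orthologs)) {
        m <- match(truth$ortholog_id, orthologs$ortholog_id)
        gene_of <- orthologs[[s]][m]
        for (tm in unique(stats::na.omit(truth$category_term))) {
          g <- gene_of[!is.na(truth$category_term) &
                         truth$category_term == tm]
          g <- intersect(g, ids)
          cat_map[[tm]] <- g
          cat_genes <- union(cat_genes, g)
        }
      }
      n_ann <- round(cfg$annotated_frac * length(ids))
      ann_genes <- union(cat_genes,
                         sample(ids, min(n_ann, length(ids))))
      if (length(bg_terms) == 0L && length(cat_map) == 0L) {
        out[[s]] <- tibble::tibble(gene_id = character(),
                                   term = character())
        next
      }
      rows <- lapply(ann_genes, function(g) {
        k <- if (length(bg_terms)) {
          min(1L + stats::rpois(1L, cfg$mean_extra_terms),
              length(bg_terms))
        } else {
          0L
        }
        tms <- if (k > 0L) sample(bg_terms, k) else character(0)
        extra <- names(cat_map)[vapply(cat_map, function(v) g %in% v,
                                       logical(1))]
        tibble::tibble(gene_id = g, term = unique(c(extra, tms)))
      })
      out[[s]] <- dplyr::arrange(dplyr::bind_rows(rows), .data$gene_id,
                                 .data$term)
    }
    out
  })
}

#' Generate the full synthetic world
#'
#' Convenience wrapper chaining [simulate_expression()],
#' [simulate_genomes()] and [simulate_go()] into a single object
#' carrying every input the pipeline consumes plus the planted truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `crossnet_world`.
#' @export
#' @examples
#' \donttest{
#' w <- simulate_world(sim_config(n_orthologs = 40, category_size = 10,
#'                                seed = 2))
#' w
#' }
simulate_world <- function(config = sim_config()) {
  validate_sim_config(config)
  ew <- simulate_expression(config)
  gw <- simulate_genomes(config, ew)
  gene_lists <- lapply(gw$models, function(m) m$genes$gene_id)
  go <- simulate_go(config, gene_lists, ew$truth, ew$orthologs)
  world <- c(ew, gw, list(annotations = go, config = config))
  class(world) <- "crossnet_world"
  world
}

#' @export
print.crossnet_world <- function(x, ...) {
  cat("<crossnet_world>\n")
  cat(sprintf("  %d orthologs, %d species expression tables\n",
              nrow(x$orthologs), length(x$expression)))
  cat(sprintf("  genomes: %s\n", paste(names(x$genomes), collapse = ", ")))
  cat(sprintf("  %d planted motif(s), %d planted sites\n",
              nrow(x$motifs), nrow(x$truth_sites)))
  invisible(x)
}
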