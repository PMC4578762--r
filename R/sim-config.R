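#' Configuration for the synthetic world generator
#'
#' Bundles every tunable of the simulated study system: three species in
#' two genera (two congeners plus a distant outgroup), four developmental
#' stages (e embryonic, f first larval, i infective juvenile, a adult),
#' toy genomes with gene models and conserved non-coding blocks, planted
#' motif instances near genes of planted GO categories, and GO
#' annotations for both genome species.
#'
#' @param n_orthologs Number of 1:1:1 ortholog triples simulated.
#' @param stages Ordered developmental stage labels.
#' @param n_replicates RNA-seq replicates per stage.
#' @param frac_conserved Fraction of orthologs with conserved
#'   stage-specific expression across species; the remainder have their
#'   stage profile permuted in the second congener.
#' @param noise_sd Standard deviation, on the natural-log scale, of
#'   multiplicative lognormal expression noise.
#' @param n_genes_per_genome Genes per simulated genome. Must be at least
#'   `n_orthologs`; the default ties it to `n_orthologs`.
#' @param gene_length_range Length-2 numeric, min/max simulated gene
#'   span (bp).
#' @param flank_length Maximum distance (bp) from a gene at which its
#'   conserved non-coding blocks are placed.
#' @param motif_width Width (bp) of planted motif consensus sequences.
#' @param n_planted_motifs Number of distinct planted motifs; each is
#'   paired with one category term (recycled if fewer categories).
#' @param planting_rate Fraction of category genes that receive a planted
#'   site in each species.
#' @param background_gc GC fraction of background genomic sequence.
#'   Default 0.455, a realistic nematode genome-wide composition.
#' @param n_go_terms Number of background (non-category) GO terms.
#' @param category_terms Labels of the planted "neurogenesis-like"
#'   category terms.
#' @param category_size Genes per planted category.
#' @param annotated_frac Fraction of genes carrying any GO annotation.
#' @param mean_extra_terms Poisson mean of background terms per annotated
#'   gene beyond the guaranteed first.
#' @param block_length_range Length-2 numeric, min/max conserved
#'   non-coding block length (bp).
#' @param paralog_divergence Per-base substitution probability used when
#'   emitting the mutated partner copy of each conserved block (exercises
#'   the windowed conservation caller).
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_orthologs = 50, seed = 1)
#' cfg$frac_conserved
sim_config <- function(n_orthologs = 300L,
                       stages = c("e", "f", "i", "a"),
                       n_replicates = 2L,
                       frac_conserved = 0.5,
                       noise_sd = 0.05,
                       n_genes_per_genome = n_orthologs,
                       gene_length_range = c(600L, 1500L),
                       flank_length = 1000L,
                       motif_width = 8L,
                       n_planted_motifs = 2L,
                       planting_rate = 1.0,
                       background_gc = 0.455,
                       n_go_terms = 40L,
                       category_terms = c("GO:CAT0001", "GO:CAT0002"),
                       category_size = 50L,
                       annotated_frac = 0.9,
                       mean_extra_terms = 2,
                       block_length_range = c(60L, 150L),
                       paralog_divergence = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_orthologs = as.integer(n_orthologs),
    stages = as.character(stages),
    n_replicates = as.integer(n_replicates),
    frac_conserved = frac_conserved,
    noise_sd = noise_sd,
    n_genes_per_genome = as.integer(n_genes_per_genome),
    gene_length_range = as.integer(gene_length_range),
    flank_length = as.integer(flank_length),
    motif_width = as.integer(motif_width),
    n_planted_motifs = as.integer(n_planted_motifs),
    planting_rate = planting_rate,
    background_gc = background_gc,
    n_go_terms = as.integer(n_go_terms),
    category_terms = as.character(category_terms),
    category_size = as.integer(category_size),
    annotated_frac = annotated_frac,
    mean_extra_terms = mean_extra_terms,
    block_length_range = as.integer(block_length_range),
    paralog_divergence = paralog_divergence,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fr <- c("frac_conserved", "planting_rate", "background_gc",
          "annotated_frac")
  for (f in fr) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("`%s` must be a fraction in [0, 1]", f), call. = FALSE)
    }
  }
  cnt <- c("n_orthologs", "n_replicates", "n_genes_per_genome",
           "motif_width", "n_planted_motifs", "n_go_terms",
           "category_size")
  for (f in cnt) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      stop(sprintf("`%s` must be a non-negative count", f), call. = FALSE)
    }
  }
  if (length(cfg$stages) == 0L || anyDuplicated(cfg$stages)) {
    stop("`stages` must be non-empty and unique", call. = FALSE)
  }
  if (cfg$noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  if (cfg$n_genes_per_genome < cfg$n_orthologs) {
    stop("`n_genes_per_genome` must be >= `n_orthologs`", call. = FALSE)
  }
  if (cfg$n_planted_motifs > 0L &&
      cfg$n_planted_motifs * 0L + cfg$category_size *
        length(cfg$category_terms) > cfg$n_orthologs) {
    stop("category genes exceed `n_orthologs`; shrink `category_size`",
         call. = FALSE)
  }
  if (diff(cfg$gene_length_range) < 0 || cfg$gene_length_range[1] < 200L) {
    stop("`gene_length_range` must be increasing with min >= 200 bp",
         call. = FALSE)
  }
  if (cfg$block_length_range[1] <= cfg$motif_width + 4L) {
    stop("conserved blocks must be longer than the planted motif",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d orthologs across 3 species (2 genera), stages: %s\n",
              x$n_orthologs, paste(x$stages, collapse = "")))
  cat(sprintf("  frac_conserved = %.2f, noise_sd = %.3f, seed = %d\n",
              x$frac_conserved, x$noise_sd, x$seed))
  cat(sprintf("  %d genes/genome, %d planted motif(s), %d categories\n",
              x$n_genes_per_genome, x$n_planted_motifs,
              length(x$category_terms)))
  invisible(x)
}

# Species identifiers used throughout the synthetic world: two congeners
# in genus 1 (g1s1, g1s2) and one outgroup species in genus 2 (g2s1).
# Genomes are simulated for g1s1 and g2s1; expression for all three.
sim_species <- function() {
  c(a = "g1s1", b = "g1s2", c = "g2s1")
}
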