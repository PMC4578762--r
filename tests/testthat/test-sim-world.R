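test_that("conservation label counts are forced by the config", {
  w <- simulate_expression(sim_config(n_orthologs = 100,
                                      frac_conserved = 0.6,
                                      category_size = 20, seed = 9))
  expect_equal(sum(w$truth$conservation_label == "conserved"), 60)
  expect_equal(sum(w$truth$conservation_label == "divergent"), 40)
})

test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(n_orthologs = 30, category_size = 6, seed = 77)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1$expression, w2$expression)
  expect_identical(lapply(w1$genomes, as.character),
                   lapply(w2$genomes, as.character))
  expect_identical(w1$conserved, w2$conserved)
  expect_identical(w1$annotations, w2$annotations)
  expect_identical(w1$truth_sites, w2$truth_sites)
})

test_that("zero noise and full conservation give cosine exactly 1", {
  cfg <- sim_config(n_orthologs = 25, frac_conserved = 1, noise_sd = 0,
                    category_size = 5, seed = 3)
  w <- simulate_expression(cfg)
  cons <- cosine_conservation(w$expression$g1s1, w$expression$g1s2,
                              w$orthologs)
  expect_true(all(cons$similarity == 1))
  bin <- binary_conservation(w$expression$g1s1, w$expression$g1s2,
                             w$orthologs)
  assessed <- bin$call != "not_assessed"
  expect_true(all(bin$call[assessed] == "conserved"))
})

test_that("divergent orthologs are below the cosine threshold pre-noise", {
  cfg <- sim_config(n_orthologs = 60, frac_conserved = 0.4, noise_sd = 0,
                    category_size = 10, seed = 12)
  w <- simulate_expression(cfg)
  cons <- cosine_conservation(w$expression$g1s1, w$expression$g1s2,
                              w$orthologs)
  div <- w$truth$ortholog_id[w$truth$conservation_label == "divergent"]
  expect_true(all(cons$similarity[cons$ortholog_id %in% div] <= 0.95))
})

test_that("planted sites match the consensus and lie in conserved blocks", {
  w <- small_world()
  expect_equal(nrow(w$truth_sites),
               2L * sum(!is.na(w$truth$category_term)))
  for (i in seq_len(nrow(w$truth_sites))) {
    st <- w$truth_sites[i, ]
    sq <- as.character(Biostrings::subseq(
      w$genomes[[st$species]][[st$seqnames]], st$start, st$end))
    cons <- w$motifs$consensus[w$motifs$motif_id == st$motif_id]
    expect_equal(sq, if (st$strand == "+") cons else rc_chr(cons))
    blocks <- w$conserved[[st$species]]
    inside <- any(blocks$start <= st$start & blocks$end >= st$end)
    expect_true(inside)
  }
})

test_that("planting_rate scales the exact number of planted sites", {
  cfg <- sim_config(n_orthologs = 60, category_size = 10,
                    planting_rate = 0.5, frac_conserved = 0.8,
                    seed = 31)
  ew <- simulate_expression(cfg)
  gw <- simulate_genomes(cfg, ew)
  # 2 categories x 10 genes x rate 0.5 x 2 species = 20 sites
  expect_equal(nrow(gw$truth_sites), 20L)
})

test_that("emitted intervals are within sequence bounds", {
  w <- small_world()
  for (s in names(w$genomes)) {
    len <- Biostrings::width(w$genomes[[s]])[1]
    blocks <- w$conserved[[s]]
    expect_true(all(blocks$start >= 1 & blocks$start <= blocks$end &
                      blocks$end <= len))
    genes <- w$models[[s]]$genes
    expect_true(all(genes$start >= 1 & genes$end <= len))
    feats <- w$models[[s]]$features
    spans <- dplyr::left_join(feats, genes, by = "gene_id",
                              suffix = c("", "_g"))
    expect_true(all(spans$start >= spans$start_g &
                      spans$end <= spans$end_g))
  }
})

test_that("GFF3 and BED round-trip through the readers exactly", {
  w <- small_world()
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "g.gff3")
  write_gene_models(w$models$g1s1, gff)
  back <- read_gene_models(gff)
  srt <- function(m) {
    list(genes = dplyr::arrange(m$genes, seqnames, start,
                                end),
         features = dplyr::arrange(m$features, gene_id,
                                   start, end, type))
  }
  expect_equal(srt(back), srt(w$models$g1s1))

  bed <- file.path(dir, "c.bed")
  write_conserved_bed(w$conserved$g1s1, bed)
  back_bed <- read_conserved_bed(bed)
  orig <- w$conserved$g1s1[, c("seqnames", "start", "end", "block_id")]
  expect_equal(dplyr::arrange(back_bed, start),
               dplyr::arrange(orig, start))
})

test_that("the world writer emits every expected file", {
  w <- small_world()
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "expr_g1s1.tsv", "expr_g1s2.tsv", "expr_g2s1.tsv", "orthologs.tsv",
    "genome_g1s1.fa", "genes_g1s1.gff3", "conserved_g1s1.bed",
    "go_g1s1.tsv", "genome_g2s1.fa", "truth.json")))))
  back <- read_expression_tsv(file.path(dir, "expr_g1s1.tsv"))
  expect_equal(back, w$expression$g1s1, tolerance = 1e-8)
})

test_that("GO simulation plants category terms exactly and validates", {
  w <- small_world()
  cfg <- w$config
  for (s in names(w$annotations)) {
    ann <- w$annotations[[s]]
    expect_true(all(table(ann$gene_id) >= 1))
    for (tm in cfg$category_terms) {
      carriers <- unique(ann$gene_id[ann$term == tm])
      expect_equal(length(carriers), cfg$category_size)
    }
  }
  expect_error(
    simulate_go(sim_config(n_orthologs = 20, n_go_terms = 1,
                           category_size = 4, seed = 1),
                list(g1s1 = letters), w$truth, w$orthologs),
    "category terms"
  )
})

test_that("no categories and no terms give an empty annotation table", {
  cfg <- sim_config(n_orthologs = 20, n_go_terms = 0,
                    category_terms = character(0), n_planted_motifs = 0,
                    category_size = 0, seed = 2)
  ew <- simulate_expression(cfg)
  go <- simulate_go(cfg, list(g1s1 = ew$orthologs$g1s1), ew$truth,
                    ew$orthologs)
  expect_equal(nrow(go$g1s1), 0L)
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(frac_conserved = 1.2), "fraction")
  expect_error(sim_config(stages = c("e", "e")), "unique")
  expect_error(sim_config(n_orthologs = 10, n_genes_per_genome = 5),
               "n_genes_per_genome")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})
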