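# Oracle helpers for this file live in helper-fixtures.R.

test_that("identical sequences give one full-length element", {
  set.seed(2)
  a <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  el <- window_conservation(a, a)
  expect_equal(nrow(el), 1L)
  expect_equal(c(el$start, el$end), c(1L, 100L))
  expect_equal(el$mean_identity, 1)
})

test_that("alignments below the match threshold give no elements", {
  # alternate matching and mismatching: at most 15 matches per window
  a <- strrep("AC", 60)
  b <- strrep("AG", 60)
  expect_equal(nrow(window_conservation(a, b)), 0L)
})

test_that("a single passing window yields exactly that element", {
  # exactly 23 matches in one 30-column core, with matches at both core
  # ends so every shifted window drops to 22 matches: one passing window
  core_a <- paste0("G", strrep("A", 7), strrep("G", 22))
  core_b <- paste0("G", strrep("C", 7), strrep("G", 22))
  a <- paste0(strrep("A", 40), core_a, strrep("A", 40))
  b <- paste0(strrep("C", 40), core_b, strrep("C", 40))
  el <- window_conservation(a, b)
  expect_equal(nrow(el), 1L)
  expect_equal(c(el$start, el$end), c(41L, 70L))
})

test_that("the caller matches the brute-force oracle on random pairs", {
  for (seed in 1:8) {
    set.seed(seed)
    L <- sample(80:200, 1)
    a <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    b <- mutate_seq(a, runif(1, 0.05, 0.4), seed + 100)
    # sprinkle gaps into both rows at distinct columns
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    gap_a <- sample(L, round(L * 0.05))
    gap_b <- sample(setdiff(seq_len(L), gap_a), round(L * 0.05))
    av[gap_a] <- "-"
    bv[gap_b] <- "-"
    a <- paste(av, collapse = "")
    b <- paste(bv, collapse = "")
    got <- window_conservation(a, b)
    want <- oracle_elements(a, oracle_conserved_cols(a, b))
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start, sapply(want, `[`, 1))
      expect_equal(got$end, sapply(want, `[`, 2))
    }
  }
})

test_that("generator alignment pairs re-call their blocks", {
  w <- small_world()
  aln <- w$alignments[w$alignments$species == "g1s1", ][1:10, ]
  for (i in seq_len(nrow(aln))) {
    el <- window_conservation(aln$seq_a[i], aln$seq_b[i])
    # a 5%-diverged pair should be mostly recalled as conserved
    expect_gt(sum(el$end - el$start + 1), 0.5 * nchar(aln$seq_a[i]))
  }
})

test_that("unequal column counts are rejected", {
  expect_error(window_conservation("ACGT", "ACG"), "equal column")
})

test_that("partitioning splits elements at coding boundaries", {
  models <- list(
    genes = tibble::tibble(gene_id = "g1", seqnames = "chr1",
                           start = 101L, end = 400L, strand = "+"),
    features = tibble::tibble(gene_id = "g1", type = "exon",
                              start = 101L, end = 200L,
                              seqnames = "chr1")
  )
  elements <- tibble::tibble(
    seqnames = "chr1",
    start = c(120L, 500L, 191L),
    end = c(150L, 550L, 210L)
  )
  part <- partition_conserved(elements, models)
  # wholly exonic element -> coding; intergenic -> noncoding;
  # straddling 191-210 -> 10 bp coding (191-200) + 10 bp noncoding
  expect_true(any(part$coding$start == 120 & part$coding$end == 150))
  expect_true(any(part$noncoding$start == 500 & part$noncoding$end == 550))
  expect_true(any(part$coding$start == 191 & part$coding$end == 200))
  expect_true(any(part$noncoding$start == 201 & part$noncoding$end == 210))
})

test_that("the coding/noncoding partition conserves every base", {
  w <- small_world()
  el <- w$conserved$g1s1
  part <- partition_conserved(el, w$models$g1s1)
  merged <- GenomicRanges::reduce(GenomicRanges::GRanges(
    el$seqnames, IRanges::IRanges(el$start, el$end)))
  total <- sum(GenomicRanges::width(merged))
  n_cod <- sum(part$coding$end - part$coding$start + 1)
  n_non <- sum(part$noncoding$end - part$noncoding$start + 1)
  expect_equal(n_cod + n_non, total)
  # no overlap between the two classes
  ov <- GenomicRanges::intersect(
    GenomicRanges::GRanges(part$coding$seqnames,
                           IRanges::IRanges(part$coding$start,
                                            part$coding$end)),
    GenomicRanges::GRanges(part$noncoding$seqnames,
                           IRanges::IRanges(part$noncoding$start,
                                            part$noncoding$end)))
  expect_equal(length(ov), 0L)
})

test_that("region extraction respects the flank window and length filter", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 5000)))
  models <- list(
    genes = tibble::tibble(gene_id = "g1", seqnames = "chr1",
                           start = 8001L, end = 9000L, strand = "+"),
    features = tibble::tibble(gene_id = character(), type = character(),
                              start = integer(), end = integer(),
                              seqnames = character())
  )
  noncoding <- tibble::tibble(
    seqnames = "chr1",
    start = c(6001L, 4401L, 8101L),
    end = c(6100L, 4500L, 8108L)
  )
  reg <- extract_gene_set_regions("g1", models, noncoding, genome,
                                  flank = 3000L, min_len = 8L)
  # 2 kb upstream included; 3.5 kb upstream excluded; 8-bp piece excluded
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start, reg$end), c(6001L, 6100L))
  expect_equal(reg$gene_id, "g1")
  expect_equal(nchar(reg$seq), 100L)
})

test_that("region extraction is invariant to input order", {
  w <- small_world()
  part <- partition_conserved(w$conserved$g1s1, w$models$g1s1)
  genes <- w$models$g1s1$genes$gene_id[1:20]
  r1 <- extract_gene_set_regions(genes, w$models$g1s1, part$noncoding,
                                 w$genomes$g1s1)
  set.seed(1)
  r2 <- extract_gene_set_regions(sample(genes), w$models$g1s1,
                                 part$noncoding[sample(nrow(part$noncoding)), ],
                                 w$genomes$g1s1)
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("unknown genes land in the exclusion report", {
  w <- small_world()
  part <- partition_conserved(w$conserved$g1s1, w$models$g1s1)
  reg <- extract_gene_set_regions(c(w$models$g1s1$genes$gene_id[1],
                                    "NOT_A_GENE"),
                                  w$models$g1s1, part$noncoding,
                                  w$genomes$g1s1)
  expect_equal(attr(reg, "excluded"), "NOT_A_GENE")
})

test_that("every planted site lies inside an extracted region", {
  w <- small_world()
  part <- partition_conserved(w$conserved$g1s1, w$models$g1s1)
  sites <- w$truth_sites[w$truth_sites$species == "g1s1", ]
  reg <- extract_gene_set_regions(unique(sites$gene_id), w$models$g1s1,
                                  part$noncoding, w$genomes$g1s1)
  for (i in seq_len(nrow(sites))) {
    covered <- any(reg$start <= sites$start[i] & reg$end >= sites$end[i])
    expect_true(covered)
  }
})
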