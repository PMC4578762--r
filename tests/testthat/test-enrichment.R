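# Independent oracle: hypergeometric tail by explicit binomial-
# coefficient summation.
hyper_tail <- function(study_hits, pop_hits, pop_size, study_size) {
  ks <- study_hits:min(study_size, pop_hits)
  sum(choose(pop_hits, ks) *
        choose(pop_size - pop_hits, study_size - ks)) /
    choose(pop_size, study_size)
}

test_that("nearest-gene association handles distance and ties", {
  models <- list(genes = tibble::tibble(
    gene_id = c("gX", "gY"), seqnames = "chr1",
    start = c(1000L, 2001L), end = c(1200L, 2201L), strand = "+"
  ))
  hits <- tibble::tibble(
    motif_id = c("m_ov", "m_near", "m_tie"), seqnames = "chr1",
    start = c(1100L, 1300L, 1597L),
    end = c(1107L, 1307L, 1604L)
  )
  # 1100 overlaps gX; 1300-1307 is 99 bp from gX and ~700 from gY;
  # 1597-1604 is exactly 396 bp from both -> tie, both kept
  assoc <- associate_nearest(hits, models)
  expect_equal(assoc[assoc$motif_id == "m_ov", ]$gene_id, "gX")
  expect_equal(assoc[assoc$motif_id == "m_ov", ]$distance, 0L)
  expect_equal(assoc[assoc$motif_id == "m_near", ]$gene_id, "gX")
  tie <- assoc[assoc$motif_id == "m_tie", ]
  expect_setequal(tie$gene_id, c("gX", "gY"))
  expect_equal(tie$distance, c(396L, 396L))
  expect_error(associate_nearest(hits, list(genes = tibble::tibble())),
               "empty gene model")
})

test_that("enrichment p-values match the binomial-coefficient oracle", {
  # the worked example: 10-gene study, 8 with the term, population 100
  # with 10 term genes
  pop <- sprintf("g%03d", 1:100)
  term_genes <- pop[1:10]
  study <- c(pop[1:8], pop[51:52])
  ann <- tibble::tibble(gene_id = term_genes, term = "T1")
  res <- go_enrichment(study, pop, ann)
  expect_equal(res$p, hyper_tail(8, 10, 100, 10), tolerance = 1e-12)
  expect_equal(res$study_hits, 8L)
  expect_equal(res$pop_hits, 10L)
})

test_that("enrichment p-values match the oracle on random tables", {
  set.seed(31)
  for (k in 1:20) {
    pop_size <- sample(20:200, 1)
    pop <- sprintf("g%04d", seq_len(pop_size))
    study <- sample(pop, sample(5:min(50, pop_size), 1))
    ann <- tibble::tibble(
      gene_id = sample(pop, sample(10:pop_size, 1)),
      term = sample(c("T1", "T2", "T3"),
                    replace = TRUE,
                    size = sample(10:pop_size, 1))[1]
    )
    res <- go_enrichment(study, pop, ann)
    for (i in seq_len(nrow(res))) {
      expect_equal(
        res$p[i],
        hyper_tail(res$study_hits[i], res$pop_hits[i],
                   res$pop_size[i], res$study_size[i]),
        tolerance = 1e-10
      )
    }
  }
})

test_that("terms absent from the study set are not reported", {
  pop <- sprintf("g%02d", 1:20)
  ann <- tibble::tibble(gene_id = pop[11:20], term = "T_absent")
  res <- go_enrichment(pop[1:5], pop, ann)
  expect_equal(nrow(res), 0L)
})

test_that("study equal to population gives p = 1 for every term", {
  pop <- sprintf("g%02d", 1:30)
  ann <- tibble::tibble(gene_id = pop[1:12],
                        term = rep(c("T1", "T2"), 6))
  res <- go_enrichment(pop, pop, ann)
  expect_true(all(res$p == 1))
})

test_that("enrichment input contracts are enforced", {
  pop <- letters[1:10]
  ann <- tibble::tibble(gene_id = "a", term = "T1")
  expect_error(go_enrichment(character(0), pop, ann), "empty study")
  expect_error(go_enrichment("zz", pop, ann), "subset")
})

test_that("BH FDR within a motif's term list is monotone in p", {
  w <- small_world()
  ann <- w$annotations$g1s1
  pop <- unique(w$orthologs$g1s1)
  set.seed(3)
  study <- sample(pop, 40)
  res <- go_enrichment(study, pop, ann)
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12))
  expect_true(all(res$fdr >= res$p - 1e-12))
})

mk_mag_inputs <- function(genes_a, genes_b, term = "T1",
                          motif = "m1") {
  n <- max(length(genes_a), length(genes_b), 10)
  orth <- tibble::tibble(
    ortholog_id = sprintf("OG%02d", 1:n),
    gene_a = sprintf("A%02d", 1:n),
    gene_b = sprintf("B%02d", 1:n)
  )
  enr <- function(sp) tibble::tibble(motif_id = motif, term = term,
                                     fdr = 0.001)
  assoc_a <- tibble::tibble(motif_id = motif, gene_id = genes_a)
  assoc_b <- tibble::tibble(motif_id = motif, gene_id = genes_b)
  ann_a <- tibble::tibble(gene_id = genes_a, term = term)
  ann_b <- tibble::tibble(gene_id = genes_b, term = term)
  list(enr_a = enr("a"), enr_b = enr("b"), assoc_a = assoc_a,
       assoc_b = assoc_b, ann_a = ann_a, ann_b = ann_b, orth = orth)
}

test_that("fully orthologous MAG gene sets share 100%", {
  x <- mk_mag_inputs(sprintf("A%02d", 1:6), sprintf("B%02d", 1:6))
  m <- shared_mags(x$enr_a, x$enr_b, x$assoc_a, x$assoc_b, x$ann_a,
                   x$ann_b, x$orth)
  expect_equal(m$pct_shared, 1)
  expect_true(m$passes_overlap)
})

test_that("disjoint MAG gene sets share 0%", {
  x <- mk_mag_inputs(sprintf("A%02d", 1:5), sprintf("B%02d", 6:10))
  m <- shared_mags(x$enr_a, x$enr_b, x$assoc_a, x$assoc_b, x$ann_a,
                   x$ann_b, x$orth)
  expect_equal(m$pct_shared, 0)
  expect_false(m$passes_overlap)
})

test_that("a 30% directional overlap passes at the threshold", {
  # 3 of 10 A-side genes have orthologs in the B-side set, and the
  # B side is exactly those 3 genes' partners
  x <- mk_mag_inputs(sprintf("A%02d", 1:10), sprintf("B%02d", 1:3))
  m <- shared_mags(x$enr_a, x$enr_b, x$assoc_a, x$assoc_b, x$ann_a,
                   x$ann_b, x$orth)
  expect_equal(m$shared_ab, 0.3)
  expect_equal(m$shared_ba, 1)
  expect_equal(m$pct_shared, 0.3)
  expect_true(m$passes_overlap)
})

test_that("MAG pairs require significance in both species", {
  x <- mk_mag_inputs(sprintf("A%02d", 1:6), sprintf("B%02d", 1:6))
  enr_b_ns <- tibble::tibble(motif_id = "m1", term = "T1", fdr = 0.2)
  m <- shared_mags(x$enr_a, enr_b_ns, x$assoc_a, x$assoc_b, x$ann_a,
                   x$ann_b, x$orth)
  expect_equal(nrow(m), 0L)
})

test_that("a missing ortholog table leaves overlap fields unset", {
  x <- mk_mag_inputs(sprintf("A%02d", 1:6), sprintf("B%02d", 1:6))
  m <- shared_mags(x$enr_a, x$enr_b, x$assoc_a, x$assoc_b, x$ann_a,
                   x$ann_b, orthologs = NULL)
  expect_true(is.na(m$pct_shared))
  expect_false(m$passes_overlap)
})
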