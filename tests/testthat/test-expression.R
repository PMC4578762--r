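stages4 <- c("e", "f", "i", "a")

test_that("binary_stage_set applies the on-threshold rule", {
  expect_equal(binary_stage_set(c(12, 0, 0, 0), 10, stages4), "e")
  expect_equal(binary_stage_set(c(0, 0, 0, 0), 10, stages4),
               character(0))
  expect_equal(binary_stage_set(c(11, 11, 11, 11), 10, stages4), stages4)
  expect_equal(binary_stage_set(c(10, 9.999, 0, 0), 10, stages4), "e")
  expect_error(binary_stage_set(c(1, 2, 3), 10), "one value per stage")
})

test_that("binary conservation follows the 10/5 FPKM two-way rule", {
  thr <- conservation_thresholds()
  expect_equal(binary_conservation_call(c(12, 0, 0, 0), c(6, 0, 0, 0),
                                        thr, stages4), "conserved")
  expect_equal(binary_conservation_call(c(12, 0, 0, 0), c(4, 0, 0, 0),
                                        thr, stages4), "changed")
  expect_equal(binary_conservation_call(c(0, 0, 0, 0), c(0, 0, 0, 0),
                                        thr, stages4), "not_assessed")
  # symmetric: B on at f but A low there
  expect_equal(binary_conservation_call(c(12, 0, 0, 0), c(6, 11, 0, 0),
                                        thr, stages4), "changed")
  expect_error(binary_conservation_call(c(1, 2), c(1, 2, 3), thr),
               "stage alphabets")
})

test_that("binary call is monotone in the partner's expression", {
  thr <- conservation_thresholds()
  set.seed(5)
  for (k in 1:25) {
    a <- round(runif(4, 0, 30), 1)
    b <- round(runif(4, 0, 30), 1)
    base <- binary_conservation_call(a, b, thr, stages4)
    if (base != "conserved") next
    on_a <- which(a >= thr$on_fpkm)
    if (!length(on_a)) next
    b2 <- b
    b2[on_a] <- b2[on_a] + runif(length(on_a), 0, 10)
    expect_equal(binary_conservation_call(a, b2, thr, stages4),
                 "conserved")
  }
})

test_that("cosine similarity has its closed-form values", {
  expect_identical(cosine_similarity(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0, 0), c(0, 1, 0, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0, 0), c(0, 1, 1, 0)), 0.5)
  expect_true(is.na(cosine_similarity(c(0, 0, 0, 0), c(1, 1, 1, 1))))
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(cosine_similarity(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("cosine similarity is symmetric and scale-invariant", {
  set.seed(8)
  for (k in 1:30) {
    u <- rexp(4)
    v <- rexp(4)
    lam <- runif(1, 0.1, 50)
    expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
    expect_equal(cosine_similarity(lam * u, v), cosine_similarity(u, v),
                 tolerance = 1e-12)
  }
})

make_expr_pair <- function(mat_a, mat_b, stages = stages4) {
  n <- nrow(mat_a)
  ids_a <- sprintf("A%02d", seq_len(n))
  ids_b <- sprintf("B%02d", seq_len(n))
  long <- function(m, ids) {
    tidyr::expand_grid(gene_id = ids, stage = stages) %>%
      dplyr::mutate(replicate = 1L,
                    value = as.vector(t(m))[dplyr::row_number()])
  }
  list(a = long(mat_a, ids_a), b = long(mat_b, ids_b),
       orth = tibble::tibble(ortholog_id = sprintf("OG%02d", seq_len(n)),
                             gene_a = ids_a, gene_b = ids_b))
}

test_that("cosine conservation requires strict exceedance of the threshold", {
  u <- c(3, 4, 0, 0)
  v <- c(4, 3, 0, 0)
  sim <- cosine_similarity(u, v)  # 24/25
  ep <- make_expr_pair(rbind(u, u), rbind(v, u))
  thr <- conservation_thresholds(cosine_min = sim)
  cons <- cosine_conservation(ep$a, ep$b, ep$orth, thr)
  expect_equal(cons$call, c("changed", "conserved"))
  expect_equal(cons$similarity, c(sim, 1))
})

test_that("orthologs missing from a matrix go to the exclusion report", {
  ep <- make_expr_pair(rbind(c(1, 2, 3, 4)), rbind(c(1, 2, 3, 4)))
  orth2 <- dplyr::bind_rows(ep$orth,
                            tibble::tibble(ortholog_id = "OGxx",
                                           gene_a = "Amissing",
                                           gene_b = "B01"))
  cons <- cosine_conservation(ep$a, ep$b, orth2)
  expect_equal(nrow(cons), 1L)
  expect_equal(attr(cons, "excluded"), "OGxx")
})

test_that("stage-set labels follow the 10% contribution rule", {
  profs <- rbind(c(25, 25, 25, 25), c(91, 3, 3, 3), c(45, 45, 5, 5))
  ep <- make_expr_pair(profs, profs)
  cons <- tibble::tibble(ortholog_id = ep$orth$ortholog_id,
                         call = "conserved")
  sets <- stage_specific_sets(cons, ep$a, ep$b, ep$orth,
                              conservation_thresholds(min_set_size = 0L))
  expect_equal(sets$label, c("efia", "e", "ef"))
})

test_that("stage sets need strictly more than min_set_size genes to mine", {
  n <- 30
  profs <- matrix(rep(c(91, 3, 3, 3), each = n), nrow = n)
  ep <- make_expr_pair(profs, profs)
  cons <- tibble::tibble(ortholog_id = ep$orth$ortholog_id,
                         call = "conserved")
  thr <- conservation_thresholds(min_set_size = 30L)
  sets <- stage_specific_sets(cons, ep$a, ep$b, ep$orth, thr)
  expect_equal(unique(sets$set_size), 30L)
  expect_false(any(sets$mineable))
})

test_that("stage-set assignment partitions the conserved orthologs", {
  w <- small_world()
  cons <- cosine_conservation(w$expression$g1s1, w$expression$g1s2,
                              w$orthologs)
  sets <- stage_specific_sets(cons, w$expression$g1s1,
                              w$expression$g1s2, w$orthologs)
  expect_equal(anyDuplicated(sets$ortholog_id), 0L)
  expect_true(all(nchar(sets$label) >= 1))
  letters_used <- unique(unlist(strsplit(sets$label, "")))
  expect_true(all(letters_used %in% stages4))
})

test_that("binary conservation is invariant to replicate order", {
  set.seed(21)
  n <- 6
  expr <- tidyr::expand_grid(gene_id = sprintf("A%02d", 1:n),
                             stage = stages4, replicate = 1:3) %>%
    dplyr::mutate(value = rexp(dplyr::n(), 1 / 20))
  expr_b <- expr %>% dplyr::mutate(gene_id = sub("A", "B", gene_id))
  orth <- tibble::tibble(ortholog_id = sprintf("OG%02d", 1:n),
                         gene_a = sprintf("A%02d", 1:n),
                         gene_b = sprintf("B%02d", 1:n))
  shuffled <- expr[sample(nrow(expr)), ]
  c1 <- binary_conservation(expr, expr_b, orth)
  c2 <- binary_conservation(shuffled, expr_b, orth)
  expect_equal(c1, c2)
})
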