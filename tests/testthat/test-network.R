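mk_mags <- function(edges_per_motif) {
  # edges_per_motif: named list motif -> gene vector
  rows <- lapply(names(edges_per_motif), function(m) {
    tibble::tibble(
      motif_id = m, term = "GO:X", fdr_a = 0.001, fdr_b = 0.001,
      n_a = length(edges_per_motif[[m]]),
      n_b = length(edges_per_motif[[m]]),
      shared_ab = 1, shared_ba = 1, pct_shared = 1,
      passes_overlap = TRUE,
      genes_a = list(edges_per_motif[[m]]),
      genes_b = list(edges_per_motif[[m]]),
      shared_orthologs = list(edges_per_motif[[m]])
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mag_pairs", class(out))
  out
}

test_that("the degree filter is a single pass on original degrees", {
  genes <- sprintf("g%02d", 1:6)
  mags <- mk_mags(list(m1 = genes[1:5], m2 = genes[1:4],
                       m3 = genes[1:4], m4 = genes[1:4],
                       m5 = genes[1:5], m6 = "g06"))
  net <- build_category_network(mags, "GO:X", min_degree = 5)
  # m1 and m5 have degree 5; g01-g04 have degree 5; g05 degree 2;
  # m6 and g06 degree 1
  expect_true(all(c("m1", "m5") %in% net$nodes_filtered$node))
  expect_false("m6" %in% net$nodes_filtered$node)
  expect_false("g05" %in% net$nodes_filtered$node)
  expect_true("g05" %in% net$nodes$node)  # full export keeps it
  expect_true(all(net$nodes_filtered$degree >= 5))
  # filtered nodes are a subset of unfiltered nodes
  expect_true(all(net$nodes_filtered$node %in% net$nodes$node))
  # single pass: m1's filtered edges may now number fewer than 5,
  # yet m1 stays (original degree decides)
  expect_true("m1" %in% net$nodes_filtered$node)
})

test_that("an empty MAG list gives an empty network", {
  mags <- mk_mags(list(m1 = "g1"))[0, ]
  net <- build_category_network(mags, "GO:X")
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(net$nodes), 0L)
  expect_s3_class(autoplot(net), "ggplot")
})

test_that("network exports and tidiers work", {
  mags <- mk_mags(list(m1 = sprintf("g%02d", 1:5)))
  net <- build_category_network(mags, "GO:X", min_degree = 2)
  dir <- withr::local_tempdir()
  write_network(net, json_path = file.path(dir, "n.json"),
                graphml_path = file.path(dir, "n.graphml"))
  expect_true(file.exists(file.path(dir, "n.json")))
  expect_true(file.exists(file.path(dir, "n.graphml")))
  parsed <- jsonlite::read_json(file.path(dir, "n.json"))
  expect_equal(length(parsed$edges), nrow(net$edges))
  expect_equal(nrow(tidy(net)), 5L)
  expect_equal(glance(net)$n_genes, 5L)
})

test_that("motif arrangement classifies order and position", {
  a <- tibble::tibble(motif_id = c("m1", "m2", "m3"),
                      position = c(100, 500, 900))
  same <- tibble::tibble(motif_id = c("m1", "m2", "m3"),
                         position = c(150, 520, 880))
  expect_equal(motif_arrangement(a, same), "order+position")
  # two nearby motifs swap rank while every offset stays within
  # tolerance: position holds, order does not
  a2 <- tibble::tibble(motif_id = c("m1", "m2", "m3"),
                       position = c(100, 150, 900))
  swapped <- tibble::tibble(motif_id = c("m1", "m2", "m3"),
                            position = c(160, 90, 880))
  expect_equal(motif_arrangement(a2, swapped), "position_only")
  shifted <- tibble::tibble(motif_id = c("m1", "m2", "m3"),
                            position = c(100, 500, 1600))
  expect_equal(motif_arrangement(a, shifted), "order_only")
  both_bad <- tibble::tibble(motif_id = c("m1", "m2", "m3"),
                             position = c(2000, 150, 880))
  expect_equal(motif_arrangement(a, both_bad), "neither")
  one <- tibble::tibble(motif_id = "m1", position = 100)
  expect_equal(motif_arrangement(a, one), "not_applicable")
})

test_that("position_only requires offsets within tolerance", {
  a <- tibble::tibble(motif_id = c("m1", "m2"), position = c(100, 500))
  b <- tibble::tibble(motif_id = c("m1", "m2"), position = c(290, 520))
  expect_equal(motif_arrangement(a, b, tolerance_bp = 200),
               "order+position")
  expect_equal(motif_arrangement(a, b, tolerance_bp = 100),
               "order_only")
})

test_that("annotation shuffling preserves the term-set structure", {
  w <- small_world()
  ann <- w$annotations$g1s1
  set.seed(4)
  shuf <- shuffle_annotations(ann)
  expect_setequal(unique(shuf$gene_id), unique(ann$gene_id))
  sizes <- function(x) sort(table(x$gene_id) |> as.integer())
  expect_equal(sizes(shuf), sizes(ann))
  per_term <- function(x) dplyr::count(x, term) |> dplyr::arrange(term)
  expect_equal(per_term(shuf), per_term(ann))
})

test_that("the randomized control counts tests and recoveries", {
  w <- small_world()
  ann <- w$annotations$g1s1
  pop <- w$models$g1s1$genes$gene_id
  set.seed(9)
  assoc <- tibble::tibble(
    motif_id = rep(sprintf("m%d", 1:5), each = 12),
    gene_id = sample(pop, 60, replace = TRUE)
  )
  ctrl <- randomized_go_control(ann, assoc, pop,
                                w$config$category_terms, n_rand = 4,
                                seed = 2)
  expect_equal(ctrl$n_tests, 20L)
  expect_equal(nrow(ctrl$detail), 20L)
  expect_equal(ctrl$n_recovered, sum(ctrl$detail$recovered))
  zero <- randomized_go_control(ann, assoc, pop,
                                w$config$category_terms, n_rand = 0)
  expect_equal(zero$n_tests, 0L)
  expect_equal(zero$n_recovered, 0L)
  expect_error(randomized_go_control(ann, assoc, pop, "GO:X",
                                     n_rand = -1), "n_rand")
  expect_error(randomized_go_control(ann[0, ], assoc, pop, "GO:X"),
               "empty annotation")
})

test_that("the control is deterministic given its seed", {
  w <- small_world()
  ann <- w$annotations$g1s1
  pop <- w$models$g1s1$genes$gene_id
  set.seed(10)
  assoc <- tibble::tibble(motif_id = "m1",
                          gene_id = sample(pop, 25))
  c1 <- randomized_go_control(ann, assoc, pop,
                              w$config$category_terms, n_rand = 3,
                              seed = 5)
  c2 <- randomized_go_control(ann, assoc, pop,
                              w$config$category_terms, n_rand = 3,
                              seed = 5)
  expect_identical(c1$detail, c2$detail)
})
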