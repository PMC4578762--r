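#' Default thresholds for expression-conservation calling
#'
#' The binarization calls a stage "on" at `on_fpkm` (an averagely
#' expressed gene) and requires the partner species to reach
#' `relaxed_fpkm` at the same stages; cosine conservation requires
#' similarity strictly greater than `cosine_min`; stage-set assignment
#' requires a stage to contribute at least `contribution_min` of the
#' total profile; only stage sets with strictly more than `min_set_size`
#' genes are forwarded to motif mining.
#'
#' @param on_fpkm "On" threshold (FPKM/TPM).
#' @param relaxed_fpkm Partner-species relaxed threshold (FPKM/TPM).
#' @param cosine_min Cosine-similarity conservation threshold (strict).
#' @param contribution_min Minimum fractional stage contribution.
#' @param min_set_size Stage sets must exceed this size (strict) to be
#'   used for motif mining.
#' @return A list of class `crossnet_thresholds`.
#' @export
conservation_thresholds <- function(on_fpkm = 10, relaxed_fpkm = 5,
                                    cosine_min = 0.95,
                                    contribution_min = 0.10,
                                    min_set_size = 30L) {
  stopifnot(relaxed_fpkm <= on_fpkm, cosine_min > 0, cosine_min < 1,
            contribution_min > 0, contribution_min < 1)
  structure(list(on_fpkm = on_fpkm, relaxed_fpkm = relaxed_fpkm,
                 cosine_min = cosine_min,
                 contribution_min = contribution_min,
                 min_set_size = as.integer(min_set_size)),
            class = "crossnet_thresholds")
}

# Canonical stage ordering: the developmental order e, f, i, a when the
# data uses those labels, otherwise stable sorted order. Keeps results
# invariant to row order of the input tables.
canonical_stages <- function(x) {
  u <- unique(x)
  devo <- c("e", "f", "i", "a")
  if (all(u %in% devo)) devo[devo %in% u] else sort(u)
}

# Average replicates: long expression tibble -> gene x stage mean matrix.
stage_means <- function(expr, stages = NULL) {
  stopifnot(all(c("gene_id", "stage", "value") %in% names(expr)))
  if (any(expr$value < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  if (is.null(stages)) stages <- unique(expr$stage)
  wide <- expr %>%
    dplyr::group_by(.data$gene_id, .data$stage) %>%
    dplyr::summarise(value = mean(.data$value), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "stage", values_from = "value")
  missing <- setdiff(stages, names(wide))
  if (length(missing)) {
    stop("stages missing from expression table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(wide[, stages, drop = FALSE])
  rownames(m) <- wide$gene_id
  if (anyNA(m)) {
    stop("every gene must have a value for every stage", call. = FALSE)
  }
  m
}

#' Binarize a stage profile into its "on" stage set
#'
#' @param profile Named (or stage-ordered) non-negative numeric vector of
#'   per-stage mean expression.
#' @param on_threshold Stages with mean >= this value are "on".
#' @param stages Stage labels; defaults to `names(profile)`.
#' @return Character vector of "on" stage labels (possibly empty).
#' @export
#' @examples
#' binary_stage_set(c(e = 12, f = 0, i = 0, a = 0))
binary_stage_set <- function(profile, on_threshold = 10, stages = NULL) {
  stages <- stages %||% names(profile)
  if (is.null(stages) || length(stages) != length(profile)) {
    stop("`profile` needs one value per stage (supply names or `stages`)",
         call. = FALSE)
  }
  if (any(profile < 0)) stop("profile must be non-negative", call. = FALSE)
  stages[profile >= on_threshold]
}

#' Binarized conservation call for one ortholog pair
#'
#' An ortholog "on" (>= `on_fpkm`) in a set of stages in one species is
#' conserved if the partner reaches `relaxed_fpkm` in those same stages.
#' The rule is applied symmetrically in both directions; orthologs off
#' everywhere in both species are `not_assessed`.
#'
#' @param profile_a,profile_b Per-stage mean vectors over the same stage
#'   alphabet.
#' @param thresholds A [conservation_thresholds()].
#' @param stages Stage labels shared by both profiles.
#' @return One of `"conserved"`, `"changed"`, `"not_assessed"`.
#' @export
binary_conservation_call <- function(profile_a, profile_b,
                                     thresholds = conservation_thresholds(),
                                     stages = NULL) {
  stages <- stages %||% names(profile_a)
  if (!is.null(names(profile_a)) && !is.null(names(profile_b)) &&
      !identical(names(profile_a), names(profile_b))) {
    stop("profiles are over different stage alphabets", call. = FALSE)
  }
  if (length(profile_a) != length(profile_b)) {
    stop("profiles are over different stage alphabets", call. = FALSE)
  }
  on_a <- profile_a >= thresholds$on_fpkm
  on_b <- profile_b >= thresholds$on_fpkm
  if (!any(on_a) && !any(on_b)) {
    return("not_assessed")
  }
  ok_ab <- all(profile_b[on_a] >= thresholds$relaxed_fpkm)
  ok_ba <- all(profile_a[on_b] >= thresholds$relaxed_fpkm)
  if (ok_ab && ok_ba) "conserved" else "changed"
}

#' Cosine similarity between two non-negative expression vectors
#'
#' `dot(u, v) / (|u| |v|)`: 1 for proportional vectors, 0 for vectors
#' with disjoint support. Returns `NA` (the `not_assessed` signal) if
#' either vector is all zero.
#'
#' @param u,v Non-negative numeric vectors of equal length.
#' @return Similarity in `[0, 1]`, or `NA_real_` for a zero vector.
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 3, 4), c(2, 4, 6, 8))  # 1
#' cosine_similarity(c(1, 0, 0, 0), c(0, 1, 0, 0))  # 0
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (any(u < 0) || any(v < 0)) {
    stop("expression vectors must be non-negative", call. = FALSE)
  }
  s <- sum(u * v)
  s1 <- sum(u^2)
  s2 <- sum(v^2)
  if (s1 == 0 || s2 == 0) {
    return(NA_real_)
  }
  # Cauchy-Schwarz equality (proportional vectors) returns exactly 1;
  # comparing squared forms avoids sqrt() rounding at the boundary.
  if (s * s >= s1 * s2) {
    return(1)
  }
  s / (sqrt(s1) * sqrt(s2))
}

#' Binarized conservation calls for an ortholog table
#'
#' @param expr_a,expr_b Long expression tibbles (`gene_id`, `stage`,
#'   `replicate`, `value`) for the two species.
#' @param orthologs Tibble whose first column is `ortholog_id` and whose
#'   `gene_a`/`gene_b` columns (or columns named by `cols`) give the
#'   paired gene ids.
#' @param thresholds A [conservation_thresholds()].
#' @param cols Length-2 character: ortholog-table columns holding the
#'   species A and B gene ids. Defaults to columns 2 and 3.
#' @return Tibble with `ortholog_id`, `method`, `call`, `on_stages_a`,
#'   `on_stages_b`. Orthologs absent from a matrix are returned in the
#'   `"excluded"` attribute, not silently dropped.
#' @export
binary_conservation <- function(expr_a, expr_b, orthologs,
                                thresholds = conservation_thresholds(),
                                cols = NULL) {
  cols <- cols %||% names(orthologs)[2:3]
  stages <- canonical_stages(expr_a$stage)
  ma <- stage_means(expr_a, stages)
  mb <- stage_means(expr_b, stages)
  ga <- orthologs[[cols[1]]]
  gb <- orthologs[[cols[2]]]
  present <- ga %in% rownames(ma) & gb %in% rownames(mb)
  excluded <- orthologs$ortholog_id[!present]
  idx <- which(present)
  res <- lapply(idx, function(i) {
    pa <- ma[ga[i], ]
    pb <- mb[gb[i], ]
    tibble::tibble(
      ortholog_id = orthologs$ortholog_id[i],
      method = "binary",
      call = binary_conservation_call(pa, pb, thresholds, stages),
      on_stages_a = paste(binary_stage_set(pa, thresholds$on_fpkm, stages),
                          collapse = ""),
      on_stages_b = paste(binary_stage_set(pb, thresholds$on_fpkm, stages),
                          collapse = "")
    )
  })
  out <- dplyr::bind_rows(res)
  attr(out, "excluded") <- excluded
  out
}

#' Cosine-similarity conservation calls for an ortholog table
#'
#' Replicates are averaged to per-stage means, each ortholog's two stage
#' profiles are compared by cosine similarity, and the ortholog is
#' called conserved when similarity is strictly greater than
#' `thresholds$cosine_min`. The full similarity distribution is kept for
#' plotting.
#'
#' @inheritParams binary_conservation
#' @return Tibble of class `crossnet_conservation` with `ortholog_id`,
#'   `method`, `similarity`, `call`. Orthologs missing from a matrix are
#'   listed in the `"excluded"` attribute.
#' @export
cosine_conservation <- function(expr_a, expr_b, orthologs,
                                thresholds = conservation_thresholds(),
                                cols = NULL) {
  cols <- cols %||% names(orthologs)[2:3]
  stages <- canonical_stages(expr_a$stage)
  ma <- stage_means(expr_a, stages)
  mb <- stage_means(expr_b, stages)
  ga <- orthologs[[cols[1]]]
  gb <- orthologs[[cols[2]]]
  present <- ga %in% rownames(ma) & gb %in% rownames(mb)
  excluded <- orthologs$ortholog_id[!present]
  idx <- which(present)
  sim <- vapply(idx, function(i) {
    cosine_similarity(ma[ga[i], ], mb[gb[i], ])
  }, numeric(1))
  out <- tibble::tibble(
    ortholog_id = orthologs$ortholog_id[idx],
    method = "cosine",
    similarity = sim,
    call = dplyr::case_when(
      is.na(sim) ~ "not_assessed",
      sim > thresholds$cosine_min ~ "conserved",
      TRUE ~ "changed"
    )
  )
  class(out) <- c("crossnet_conservation", class(out))
  attr(out, "excluded") <- excluded
  attr(out, "cosine_min") <- thresholds$cosine_min
  out
}

#' Assign conserved orthologs to stage-specific sets
#'
#' Each conserved ortholog's combined profile (mean of the two species'
#' sum-normalized stage profiles) is labelled with the concatenation of
#' the stages contributing at least `contribution_min` of its total
#' (e.g. `"ef"`). Sets with strictly more than `min_set_size` members
#' are flagged for motif mining; smaller sets stay in the full report.
#'
#' @param conservation Conservation-call tibble (only rows with
#'   `call == "conserved"` are assigned).
#' @inheritParams binary_conservation
#' @return Tibble with `ortholog_id`, `label`, `set_size`, `mineable`.
#'   Orthologs with an all-zero combined profile are skipped with a
#'   warning.
#' @export
stage_specific_sets <- function(conservation, expr_a, expr_b, orthologs,
                                thresholds = conservation_thresholds(),
                                cols = NULL) {
  cols <- cols %||% names(orthologs)[2:3]
  stages <- canonical_stages(expr_a$stage)
  ma <- stage_means(expr_a, stages)
  mb <- stage_means(expr_b, stages)
  keep <- conservation$ortholog_id[conservation$call == "conserved"]
  orth <- orthologs[orthologs$ortholog_id %in% keep, ]
  labels <- character(nrow(orth))
  skipped <- character(0)
  for (i in seq_len(nrow(orth))) {
    pa <- ma[orth[[cols[1]]][i], ]
    pb <- mb[orth[[cols[2]]][i], ]
    ta <- sum(pa)
    tb <- sum(pb)
    if (ta == 0 && tb == 0) {
      skipped <- c(skipped, orth$ortholog_id[i])
      labels[i] <- NA_character_
      next
    }
    na_ <- if (ta > 0) pa / ta else rep(0, length(pa))
    nb_ <- if (tb > 0) pb / tb else rep(0, length(pb))
    comb <- (na_ + nb_) / 2
    labels[i] <- paste(stages[comb >= thresholds$contribution_min],
                       collapse = "")
  }
  if (length(skipped)) {
    warning(length(skipped), " ortholog(s) skipped: zero total expression",
            call. = FALSE)
  }
  out <- tibble::tibble(ortholog_id = orth$ortholog_id, label = labels)
  out <- out[!is.na(out$label) & out$label != "", ]
  out <- out %>%
    dplyr::add_count(.data$label, name = "set_size") %>%
    dplyr::mutate(mineable = .data$set_size > thresholds$min_set_size)
  out
}

#' @exportS3Method
#' @rdname cosine_conservation
#' @param x A `crossnet_conservation` tibble.
#' @param ... Unused.
glance.crossnet_conservation <- function(x, ...) {
  assessed <- x$call != "not_assessed"
  tibble::tibble(
    n = nrow(x),
    n_assessed = sum(assessed),
    n_conserved = sum(x$call == "conserved"),
    prop_conserved = sum(x$call == "conserved") / max(sum(assessed), 1L),
    cosine_min = attr(x, "cosine_min") %||% NA_real_
  )
}

#' Histogram of ortholog expression-profile similarities
#'
#' @param object A `crossnet_conservation` tibble from
#'   [cosine_conservation()].
#' @param binwidth Histogram bin width on the similarity axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.crossnet_conservation <- function(object, binwidth = 0.02, ...) {
  thr <- attr(object, "cosine_min") %||% 0.95
  df <- object[!is.na(object$similarity), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$similarity)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35") +
    ggplot2::geom_vline(xintercept = thr, linetype = 2, colour = "red") +
    ggplot2::labs(x = "cosine similarity of ortholog stage profiles",
                  y = "orthologs") +
    ggplot2::theme_minimal()
}
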