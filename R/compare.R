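# Motif-motif comparison (Pearson column correlation at
# the best ungapped offset/orientation, permutation null), redundancy
# filtering and database matching.

# Pearson correlation between two probability 4-vectors; columns with
# zero variance compare as 1 when identical, 0 otherwise.
column_pearson <- function(a, b) {
  sa <- stats::sd(a)
  sb <- stats::sd(b)
  if (sa == 0 || sb == 0) {
    return(if (isTRUE(all.equal(a, b))) 1 else 0)
  }
  stats::cor(a, b)
}

# All-pairs column correlation matrices between query and target (and
# the target's reverse complement).
pair_cor_matrices <- function(q, t) {
  wq <- nrow(q)
  wt <- nrow(t)
  trc <- revcomp_pwm(t)
  Rf <- matrix(0, wq, wt)
  Rr <- matrix(0, wq, wt)
  for (i in seq_len(wq)) {
    for (j in seq_len(wt)) {
      Rf[i, j] <- column_pearson(q[i, ], t[j, ])
      Rr[i, j] <- column_pearson(q[i, ], trc[j, ])
    }
  }
  list(f = Rf, r = Rr)
}

# Valid offsets (target start minus query start) with overlap >=
# min_overlap; returns a list of (offset, query cols, target cols).
offset_table <- function(wq, wt, min_overlap) {
  offs <- (-(wt - min_overlap)):(wq - min_overlap)
  lapply(offs, function(o) {
    qs <- max(1L, 1L + o)
    qe <- min(wq, wt + o)
    list(offset = o, q = qs:qe, t = (qs - o):(qe - o))
  })
}

# Best summed column correlation over offsets/orientations, given the
# correlation matrices and (optionally) a column permutation of the
# target.
best_match_score <- function(cm, offsets, revcomp = TRUE, perm = NULL) {
  best <- -Inf
  pick <- NULL
  for (ot in offsets) {
    tcols <- if (is.null(perm)) ot$t else perm[ot$t]
    sf <- sum(cm$f[cbind(ot$q, tcols)])
    if (sf > best) {
      best <- sf
      pick <- list(offset = ot$offset, orientation = "+",
                   overlap = length(ot$q))
    }
    if (revcomp) {
      sr <- sum(cm$r[cbind(ot$q, tcols)])
      if (sr > best) {
        best <- sr
        pick <- list(offset = ot$offset, orientation = "-",
                     overlap = length(ot$q))
      }
    }
  }
  c(pick, list(score = best))
}

#' Compare two PWMs by column-wise Pearson correlation
#'
#' Finds the ungapped offset and orientation maximizing the summed
#' column-wise Pearson correlation over at least `min_overlap`
#' overlapping columns; the p-value comes from a seeded permutation
#' null in which the target's columns are shuffled.
#'
#' @param query,target Probability matrices (width x 4).
#' @param min_overlap Minimum overlapping columns.
#' @param n_perm Permutations for the null.
#' @param seed RNG seed.
#' @param revcomp Also consider the target's reverse complement.
#' @return One-row tibble: `best_offset`, `orientation`, `overlap`,
#'   `r` (mean column correlation at the best alignment), `sum_r`,
#'   `p` (`(1 + #null >= observed) / (n_perm + 1)`).
#' @export
pwm_similarity <- function(query, target, min_overlap = 5L,
                           n_perm = 1000L, seed = 1L, revcomp = TRUE) {
  wq <- nrow(query)
  wt <- nrow(target)
  if (wq < min_overlap || wt < min_overlap) {
    stop("both motifs must be at least `min_overlap` columns wide",
         call. = FALSE)
  }
  cm <- pair_cor_matrices(query, target)
  offsets <- offset_table(wq, wt, min_overlap)
  obs <- best_match_score(cm, offsets, revcomp)
  null_ge <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      perm <- sample.int(wt)
      best_match_score(cm, offsets, revcomp, perm)$score >= obs$score
    }, logical(1))
  })
  tibble::tibble(
    best_offset = obs$offset,
    orientation = obs$orientation,
    overlap = obs$overlap,
    r = obs$score / obs$overlap,
    sum_r = obs$score,
    p = (1 + sum(null_ge)) / (n_perm + 1)
  )
}

# All unordered within-set matches below a p threshold.
self_matches <- function(motifs, min_overlap, n_perm, seed,
                         p_threshold) {
  n <- nrow(motifs)
  rows <- list()
  if (n < 2L) {
    return(tibble::tibble(query = character(), target = character(),
                          p = numeric()))
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- nrow(motifs$pwm[[i]]) >= min_overlap &&
        nrow(motifs$pwm[[j]]) >= min_overlap
      if (!ok) next
      m <- pwm_similarity(motifs$pwm[[i]], motifs$pwm[[j]],
                          min_overlap = min_overlap, n_perm = n_perm,
                          seed = derive_seed(seed, paste(i, j)))
      if (m$p < p_threshold) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          query = motifs$motif_id[i], target = motifs$motif_id[j],
          p = m$p
        )
      }
    }
  }
  if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(query = character(), target = character(),
                   p = numeric())
  }
}

#' Remove redundant motifs from a set
#'
#' Greedy: while any pair of motifs matches at `p < p_threshold`
#' (column-Pearson permutation test, [pwm_similarity()]), the member of
#' the pair with the worse (higher) significance score is removed; ties
#' break on motif id. Motifs narrower than `min_overlap` are excluded
#' with a warning. The result is idempotent.
#'
#' @param motifs A `motif_set` with significance scores.
#' @param p_threshold Match p-value threshold (default 0.05).
#' @param min_overlap,n_perm,seed Passed to [pwm_similarity()].
#' @return The non-redundant `motif_set`; removed ids are recorded in
#'   the `"removed"` attribute.
#' @export
remove_redundant <- function(motifs, p_threshold = 0.05,
                             min_overlap = 5L, n_perm = 1000L,
                             seed = 1L) {
  narrow <- motifs$width < min_overlap
  if (any(narrow)) {
    warning(sum(narrow), " motif(s) narrower than `min_overlap` excluded",
            call. = FALSE)
  }
  keep <- motifs[!narrow, ]
  matches <- self_matches(keep, min_overlap, n_perm, seed, p_threshold)
  matches <- dplyr::arrange(matches, .data$p, .data$query, .data$target)
  removed <- character(0)
  alive <- keep$motif_id
  score_of <- stats::setNames(keep$score, keep$motif_id)
  repeat {
    act <- matches[matches$query %in% alive & matches$target %in% alive, ]
    if (nrow(act) == 0L) break
    a <- act$query[1L]
    b <- act$target[1L]
    worse <- if (score_of[a] > score_of[b]) {
      a
    } else if (score_of[b] > score_of[a]) {
      b
    } else {
      max(a, b)
    }
    removed <- c(removed, worse)
    alive <- setdiff(alive, worse)
  }
  out <- keep[keep$motif_id %in% alive, ]
  out <- new_motif_set(out, background = motif_background(motifs),
                       provenance = attr(motifs, "provenance"))
  attr(out, "removed") <- c(motifs$motif_id[narrow], removed)
  out
}

#' Drop motifs that do not map to conserved regions in both species
#'
#' A motif is retained only if it has at least one q-value-passing hit
#' in each species (`require = "both"`, the default, as conserved
#' networks need associations in both genera) or in at least one
#' species (`require = "either"`).
#'
#' @param motifs A `motif_set`.
#' @param hits_a,hits_b `motif_hits` tibbles from [scan_motifs()] run on
#'   the two species' conserved non-coding regions.
#' @param require `"both"` or `"either"`.
#' @return The retained `motif_set`; dropped ids in the `"removed"`
#'   attribute.
#' @export
drop_unmappable <- function(motifs, hits_a, hits_b,
                            require = c("both", "either")) {
  require <- match.arg(require)
  in_a <- motifs$motif_id %in% hits_a$motif_id
  in_b <- motifs$motif_id %in% hits_b$motif_id
  keep <- if (require == "both") in_a & in_b else in_a | in_b
  out <- new_motif_set(motifs[keep, ],
                       background = motif_background(motifs),
                       provenance = attr(motifs, "provenance"))
  attr(out, "removed") <- motifs$motif_id[!keep]
  out
}

#' Match query motifs against a motif database
#'
#' For every query, the best database match (smallest p, then largest
#' summed correlation) passing `p < p_max` and `e < e_max` is reported,
#' with `e = p * database size`.
#'
#' @param motifs Query `motif_set`.
#' @param db Database `motif_set` (e.g. read with [read_meme()]).
#' @param p_max,e_max Reporting thresholds.
#' @param min_overlap,n_perm,seed Passed to [pwm_similarity()];
#'   `n_perm` defaults to 10^4 so p-values can resolve `p_max`.
#' @return Tibble with `query`, `target`, `best_offset`, `orientation`,
#'   `r`, `p`, `e`; zero rows (with a warning) for an empty database.
#' @export
match_motif_db <- function(motifs, db, p_max = 1e-4, e_max = 0.5,
                           min_overlap = 5L, n_perm = 10000L,
                           seed = 1L) {
  if (is.null(db) || nrow(db) == 0L) {
    warning("empty motif database: no matches", call. = FALSE)
    return(tibble::tibble(query = character(), target = character(),
                          best_offset = integer(),
                          orientation = character(), r = numeric(),
                          p = numeric(), e = numeric()))
  }
  n_db <- nrow(db)
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    best <- NULL
    for (j in seq_len(n_db)) {
      if (nrow(motifs$pwm[[i]]) < min_overlap ||
          nrow(db$pwm[[j]]) < min_overlap) next
      m <- pwm_similarity(motifs$pwm[[i]], db$pwm[[j]],
                          min_overlap = min_overlap, n_perm = n_perm,
                          seed = derive_seed(seed, paste(i, j)))
      m$target <- db$motif_id[j]
      if (is.null(best) || m$p < best$p ||
          (m$p == best$p && m$sum_r > best$sum_r)) {
        best <- m
      }
    }
    if (!is.null(best)) {
      e <- best$p * n_db
      if (best$p < p_max && e < e_max) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          query = motifs$motif_id[i], target = best$target,
          best_offset = best$best_offset,
          orientation = best$orientation, r = best$r, p = best$p,
          e = e
        )
      }
    }
  }
  if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(query = character(), target = character(),
                   best_offset = integer(), orientation = character(),
                   r = numeric(), p = numeric(), e = numeric())
  }
}
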