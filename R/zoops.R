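# ZOOPS (zero-or-one occurrence per sequence) expectation-maximization
# motif discovery.
#
# Model: each sequence independently contains a single motif site with
# probability gamma, placed uniformly over its eligible windows (both
# strands when revcomp = TRUE), or no site with probability 1 - gamma.
# Site columns follow the PWM, everything else the background. The
# E-step assigns each (window, strand) a responsibility; the M-step
# re-estimates gamma and the PWM with background-proportional
# pseudocounts (total mass 0.01 per row). The per-motif significance
# score is the negative log-likelihood ratio of the fitted ZOOPS model
# against the background-only model, penalized by log(number of seed
# starts) as an approximate Bonferroni correction; lower is better, and
# a motif is only reported while its score is negative.

# Build the window matrix for width w over encoded sequences, excluding
# windows that touch masked or ambiguous (non-ACGT) positions.
build_windows <- function(enc, w, mask) {
  rows <- list()
  win_seq <- list()
  win_pos <- list()
  for (i in seq_along(enc)) {
    x <- enc[[i]]
    L <- length(x)
    if (L < w) next
    n <- L - w + 1L
    idx <- outer(seq_len(n), 0L:(w - 1L), `+`)
    Wm <- matrix(x[idx], n, w)
    bad <- rowSums(is.na(Wm)) > 0L
    if (!is.null(mask[[i]])) {
      mcum <- cumsum(c(0L, as.integer(mask[[i]])))
      bad <- bad | (mcum[seq_len(n) + w] - mcum[seq_len(n)]) > 0L
    }
    keep <- which(!bad)
    if (!length(keep)) next
    rows[[length(rows) + 1L]] <- Wm[keep, , drop = FALSE]
    win_seq[[length(win_seq) + 1L]] <- rep(i, length(keep))
    win_pos[[length(win_pos) + 1L]] <- keep
  }
  if (!length(rows)) {
    return(NULL)
  }
  list(W = do.call(rbind, rows),
       win_seq = unlist(win_seq),
       win_pos = unlist(win_pos),
       n_seq = length(enc))
}

# Log likelihood-ratio scores of every window under log(pwm/bg) matrix R
# (w x 4).
window_scores <- function(W, R) {
  w <- ncol(W)
  R <- unname(R)
  s <- numeric(nrow(W))
  for (k in seq_len(w)) {
    s <- s + R[k, ][W[, k]]
  }
  s
}

# One EM pass; returns updated pwm, gamma and the data log-likelihood
# ratio (vs background-only) of the *incoming* parameters.
zoops_em_step <- function(pwm, gamma, win, bg, revcomp,
                          pseudo_mass = 0.01, ll_only = FALSE) {
  W <- win$W
  w <- ncol(W)
  R <- log(pwm) - matrix(log(bg), w, 4L, byrow = TRUE)
  lr_f <- exp(pmin(window_scores(W, R), 700))
  lr_r <- if (revcomp) {
    exp(pmin(window_scores(W, log(revcomp_pwm(pwm)) -
                             matrix(log(bg), w, 4L, byrow = TRUE)), 700))
  } else {
    NULL
  }
  gs <- as.integer(factor(win$win_seq, levels = seq_len(win$n_seq)))
  nwin <- tabulate(gs, nbins = win$n_seq)
  m_i <- nwin * (1L + as.integer(revcomp))
  sum_f <- rowsum(lr_f, gs, reorder = TRUE)[, 1L]
  by_seq <- numeric(win$n_seq)
  by_seq[sort(unique(gs))] <- sum_f
  if (revcomp) {
    sum_r <- rowsum(lr_r, gs, reorder = TRUE)[, 1L]
    tmp <- numeric(win$n_seq)
    tmp[sort(unique(gs))] <- sum_r
    by_seq <- by_seq + tmp
  }
  has_win <- m_i > 0L
  denom <- ifelse(has_win, (1 - gamma) + (gamma / pmax(m_i, 1L)) * by_seq, 1)
  ll <- sum(log(denom[has_win]))
  if (ll_only) {
    return(list(ll = ll))
  }

  # E-step responsibilities per window.
  z_f <- (gamma / m_i[gs]) * lr_f / denom[gs]
  z_r <- if (revcomp) (gamma / m_i[gs]) * lr_r / denom[gs] else NULL

  # M-step.
  q_i <- ifelse(has_win, 1 - (1 - gamma) / denom, 0)
  gamma_new <- min(max(mean(q_i[has_win]), 1e-4), 1 - 1e-4)
  counts <- matrix(0, w, 4L)
  for (k in seq_len(w)) {
    counts[k, ] <- counts[k, ] +
      vapply(1:4, function(l) sum(z_f[W[, k] == l]), numeric(1))
  }
  if (revcomp) {
    for (k in seq_len(w)) {
      kk <- w - k + 1L
      compW <- 5L - W[, kk]
      counts[k, ] <- counts[k, ] +
        vapply(1:4, function(l) sum(z_r[compW == l]), numeric(1))
    }
  }
  pc <- pseudo_mass * bg
  counts <- counts + matrix(pc, w, 4L, byrow = TRUE)
  pwm_new <- counts / rowSums(counts)
  colnames(pwm_new) <- DNA_LETTERS

  list(pwm = pwm_new, gamma = gamma_new, ll = ll,
       z_f = z_f, z_r = z_r)
}

seed_pwm <- function(word_codes, match = 0.7) {
  w <- length(word_codes)
  p <- matrix((1 - match) / 3, w, 4L, dimnames = list(NULL, DNA_LETTERS))
  p[cbind(seq_len(w), word_codes)] <- match
  p
}

# Full EM from one seed PWM.
run_em <- function(pwm0, win, bg, revcomp, max_iter, tol) {
  gamma <- 0.5
  pwm <- pwm0
  ll_prev <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    st <- zoops_em_step(pwm, gamma, win, bg, revcomp)
    trace <- c(trace, st$ll)
    if (is.finite(ll_prev) &&
        abs(st$ll - ll_prev) < tol * (abs(ll_prev) + 1e-8)) {
      pwm <- st$pwm
      gamma <- st$gamma
      ll_prev <- st$ll
      break
    }
    ll_prev <- st$ll
    pwm <- st$pwm
    gamma <- st$gamma
  }
  final <- zoops_em_step(pwm, gamma, win, bg, revcomp)
  list(pwm = pwm, gamma = gamma, ll = final$ll, z_f = final$z_f,
       z_r = final$z_r, ll_trace = c(trace, final$ll))
}

#' Significance score of a fitted ZOOPS motif
#'
#' `score = -(log-likelihood ratio of the ZOOPS model over the
#' background-only model) + log(n_starts)`, where `n_starts` is the
#' number of EM seed starts evaluated while searching for the motif
#' (approximate Bonferroni penalty). Lower is more significant; only
#' motifs with a negative score are treated as passing.
#'
#' @param pwm Width x 4 probability matrix.
#' @param sequences Character vector or `DNAStringSet`.
#' @param gamma Fitted site prior.
#' @param n_starts Seed starts evaluated.
#' @param background Background frequencies (default: observed
#'   mononucleotide frequencies of `sequences`).
#' @param revcomp Score both strands.
#' @return Numeric score (lower = more significant).
#' @export
motif_significance <- function(pwm, sequences, gamma, n_starts = 1L,
                               background = NULL, revcomp = TRUE) {
  seqs <- as_seq_chr(sequences)
  enc <- lapply(seqs, encode_dna)
  bg <- background %||% estimate_background(seqs)
  win <- build_windows(enc, nrow(pwm), vector("list", length(enc)))
  if (is.null(win)) {
    return(Inf)
  }
  st <- zoops_em_step(pwm, gamma, win, bg, revcomp)
  -st$ll + log(max(n_starts, 1L))
}

#' Mononucleotide background frequencies of a sequence set
#'
#' @param sequences Character vector or `DNAStringSet`.
#' @return Named frequency vector over A, C, G, T (floored away from 0).
#' @export
estimate_background <- function(sequences) {
  seqs <- as_seq_chr(sequences)
  tab <- table(factor(unlist(strsplit(paste(seqs, collapse = ""), "")),
                      levels = DNA_LETTERS))
  f <- as.numeric(tab)
  f <- pmax(f, 1)
  stats::setNames(f / sum(f), DNA_LETTERS)
}

#' Discover motifs by ZOOPS expectation-maximization
#'
#' For each width in `minw:maxw`, EM is started from PWMs seeded at
#' observed subsequences (subsampled to at most `n_seeds` per width with
#' a seeded RNG; seed words are drawn from the content-sorted sequence
#' set so results do not depend on input order). After a
#' single-iteration pre-screen, the `n_keep` best seeds per width get a
#' full EM run; the best-scoring fitted motif across widths is reported,
#' its sites (responsibility > 0.5) are masked out, and the search
#' repeats until `nmotifs` motifs are found or no candidate attains a
#' negative significance score.
#'
#' @param sequences Character vector or `DNAStringSet` (>= 2 sequences;
#'   sequences shorter than `minw` are skipped with a warning).
#' @param minw,maxw Motif width range (default 6-12).
#' @param nmotifs Maximum number of motifs to report (default 20).
#' @param revcomp Allow sites on either strand (default TRUE).
#' @param max_iter,tol EM convergence controls.
#' @param n_seeds Maximum seed starts per width.
#' @param n_keep Seeds surviving the pre-screen per width.
#' @param seed Integer RNG seed.
#' @param background Optional background frequencies; default estimated
#'   from the input.
#' @param motif_prefix Prefix for generated motif ids.
#' @return A `motif_set` tibble (ordered by significance score) with a
#'   `sites` attribute (tibble of reported site coordinates per motif)
#'   and per-motif EM log-likelihood traces in the `ll_trace` attribute.
#' @export
discover_motifs <- function(sequences, minw = 6L, maxw = 12L,
                            nmotifs = 20L, revcomp = TRUE,
                            max_iter = 100L, tol = 1e-4,
                            n_seeds = 2000L, n_keep = 10L, seed = 1L,
                            background = NULL, motif_prefix = "motif") {
  seqs <- as_seq_chr(sequences)
  if (length(seqs) == 0L) {
    stop("no input sequences", call. = FALSE)
  }
  short <- nchar(seqs) < minw
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than minw skipped",
            call. = FALSE)
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0L) {
    stop("all sequences are shorter than `minw`", call. = FALSE)
  }
  if (length(seqs) < 2L) {
    stop("need at least 2 sequences", call. = FALSE)
  }
  # Content-keyed ordering: results are invariant to input order.
  seqs <- seqs[order(unname(seqs), names(seqs))]
  enc <- lapply(seqs, encode_dna)
  bg <- background %||% estimate_background(seqs)
  mask <- lapply(enc, function(x) logical(length(x)))

  found <- list()
  sites_all <- list()
  traces <- list()

  for (round in seq_len(nmotifs)) {
    rng_seed <- derive_seed(seed, paste0("zoops_round_", round))
    cand <- NULL
    n_starts_total <- 0L
    for (w in minw:maxw) {
      win <- build_windows(enc, w, mask)
      if (is.null(win) || nrow(win$W) < 2L) next
      # Candidate seeds: distinct observed words, most frequent first
      # (recurring words are the point of motif discovery); ties broken
      # by a seeded draw so subsampling stays content-keyed.
      tab <- table(apply(win$W, 1L, paste, collapse = "."))
      words <- names(tab)[order(names(tab))]
      counts <- as.integer(tab[words])
      if (length(words) > n_seeds) {
        jitter <- with_seed(derive_seed(rng_seed, paste0("w", w)), {
          stats::runif(length(words))
        })
        words <- words[order(-counts, jitter)][seq_len(n_seeds)]
        words <- sort(words)
      }
      n_starts_total <- n_starts_total + length(words)
      # Single-iteration pre-screen.
      pre <- vapply(words, function(wd) {
        codes <- as.integer(strsplit(wd, ".", fixed = TRUE)[[1]])
        st <- zoops_em_step(seed_pwm(codes), 0.5, win, bg, revcomp,
                            ll_only = TRUE)
        st$ll
      }, numeric(1))
      top <- order(pre, decreasing = TRUE)[seq_len(min(n_keep,
                                                       length(pre)))]
      for (t in top) {
        codes <- as.integer(strsplit(words[t], ".", fixed = TRUE)[[1]])
        fit <- run_em(seed_pwm(codes), win, bg, revcomp, max_iter, tol)
        fit$width <- w
        fit$win <- win
        if (is.null(cand) || fit$ll > cand$ll) cand <- fit
      }
    }
    if (is.null(cand)) break
    score <- -cand$ll + log(max(n_starts_total, 1L))
    if (score >= 0) break

    # Reported sites: windows with combined (both-strand) responsibility
    # > 0.5; the strand is the larger contributor. Palindromic motifs
    # split their responsibility evenly across strands, so strands must
    # be pooled per window before thresholding.
    win <- cand$win
    zf <- cand$z_f
    zr <- if (revcomp && !is.null(cand$z_r)) cand$z_r else numeric(length(zf))
    zc <- zf + zr
    hit <- which(zc > 0.5)
    site_rows <- if (length(hit)) {
      tibble::tibble(
        seq_id = names(seqs)[win$win_seq[hit]],
        start = win$win_pos[hit],
        strand = ifelse(zf[hit] >= zr[hit], "+", "-"),
        z = zc[hit]
      )
    } else {
      NULL
    }
    if (is.null(site_rows) || nrow(site_rows) == 0L) break

    id <- sprintf("%s_%03d", motif_prefix, length(found) + 1L)
    found[[id]] <- tibble::tibble(
      motif_id = id, width = cand$width, nsites = nrow(site_rows),
      score = score, consensus = pwm_consensus(cand$pwm),
      pwm = list(cand$pwm)
    )
    site_rows$motif_id <- id
    site_rows$end <- site_rows$start + cand$width - 1L
    sites_all[[id]] <- site_rows
    traces[[id]] <- cand$ll_trace

    # Erase reported sites so later motifs cannot reuse them.
    for (r in seq_len(nrow(site_rows))) {
      i <- match(site_rows$seq_id[r], names(seqs))
      mask[[i]][site_rows$start[r]:site_rows$end[r]] <- TRUE
    }
  }

  df <- if (length(found)) {
    dplyr::arrange(dplyr::bind_rows(found), .data$score, .data$motif_id)
  } else {
    tibble::tibble(motif_id = character(), width = integer(),
                   nsites = integer(), score = numeric(),
                   consensus = character(), pwm = list())
  }
  out <- new_motif_set(df, background = bg,
                       provenance = list(minw = minw, maxw = maxw,
                                         nmotifs = nmotifs,
                                         revcomp = revcomp, seed = seed,
                                         n_seeds = n_seeds,
                                         n_keep = n_keep))
  attr(out, "sites") <- if (length(sites_all)) {
    dplyr::bind_rows(sites_all)
  } else {
    tibble::tibble(seq_id = character(), start = integer(),
                   strand = character(), z = numeric(),
                   motif_id = character(), end = integer())
  }
  attr(out, "ll_trace") <- traces
  out
}
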