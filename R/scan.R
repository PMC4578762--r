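# PWM scanning with exact p-values.
#
# Scores are log2 odds of the pseudocount-regularized PWM against the
# background; the null distribution of the total score of a random
# background word of the motif's width is computed exactly by
# dynamic-programming convolution over scores discretized at a fixed
# granularity, giving p(s) = P(score >= s).

#' Log-odds scoring matrix of a PWM
#'
#' Adds background-proportional pseudocounts of total mass
#' `pseudocount_mass` to each row (renormalized) and returns
#' `log2(p' / b)` in bits.
#'
#' @param pwm Width x 4 probability matrix (rows sum to 1).
#' @param background Background frequencies (all > 0).
#' @param pseudocount_mass Total pseudocount mass per row.
#' @return Width x 4 numeric matrix of scores in bits.
#' @export
#' @examples
#' log_odds_matrix(matrix(0.25, 4, 4), rep(0.25, 4))  # all zeros
log_odds_matrix <- function(pwm, background,
                            pseudocount_mass = 0.01) {
  if (any(background <= 0)) {
    stop("background must have strictly positive frequencies",
         call. = FALSE)
  }
  if (any(pwm < 0) || any(abs(rowSums(pwm) - 1) > 1e-6)) {
    stop("PWM rows must be non-negative and sum to 1", call. = FALSE)
  }
  bg <- background / sum(background)
  w <- nrow(pwm)
  padj <- (pwm + matrix(pseudocount_mass * bg, w, 4L, byrow = TRUE)) /
    (1 + pseudocount_mass)
  out <- log2(padj / matrix(bg, w, 4L, byrow = TRUE))
  colnames(out) <- DNA_LETTERS
  out
}

#' Exact null p-values for PWM scores
#'
#' Computes the exact distribution of the total log-odds score of a
#' random background sequence of the motif's width by dynamic
#' programming over scores discretized to `granularity` bits, and
#' returns a lookup function `p(s) = P(score >= s)`.
#'
#' @param score_matrix Width x 4 log-odds matrix from
#'   [log_odds_matrix()].
#' @param background Background frequencies.
#' @param granularity Score discretization step in bits.
#' @return A function mapping numeric score vectors to p-values; its
#'   `"support"` attribute holds the discretized score grid and tail
#'   probabilities.
#' @export
exact_score_pvalues <- function(score_matrix, background,
                                granularity = 1e-3) {
  if (granularity <= 0) {
    stop("`granularity` must be positive", call. = FALSE)
  }
  if (any(!is.finite(score_matrix))) {
    stop("scores must be finite", call. = FALSE)
  }
  bg <- background / sum(background)
  w <- nrow(score_matrix)
  si <- round(score_matrix / granularity)  # integer-valued, w x 4
  offset <- sum(apply(si, 1L, min))
  span <- sum(apply(si, 1L, max)) - offset
  pmf <- numeric(span + 1L)  # index k -> score (offset + k - 1)
  pmf[1L] <- 1
  cur_min <- 0L
  for (k in seq_len(w)) {
    mn <- min(si[k, ])
    new <- numeric(span + 1L)
    for (l in 1:4) {
      sh <- si[k, l] - mn
      n <- length(pmf) - sh
      if (n > 0L) {
        new[(sh + 1L):(sh + n)] <- new[(sh + 1L):(sh + n)] +
          bg[l] * pmf[seq_len(n)]
      }
    }
    pmf <- new
    cur_min <- cur_min + mn
  }
  grid <- (offset + seq_along(pmf) - 1L) * granularity
  tail_p <- rev(cumsum(rev(pmf)))
  tail_p <- pmin(tail_p, 1)
  f <- function(s) {
    # P(score >= s): observed scores are rounded onto the same grid the
    # null was built on, so ties land exactly on their grid point.
    # Observed scores sum unrounded cells, so they can land up to a few
    # grid steps past the DP support; clamp into the support so p stays
    # in (0, 1].
    k <- pmin(pmax(round(s / granularity) - offset + 1, 1),
              length(pmf))
    unname(tail_p[k])
  }
  attr(f, "support") <- list(score = grid, tail_p = tail_p, pmf = pmf)
  f
}

# Score every window of an encoded sequence with the log-odds matrix;
# ambiguous bases (N) contribute 0 bits.
scan_scores <- function(enc, lom) {
  w <- nrow(lom)
  L <- length(enc)
  if (L < w) {
    return(numeric(0))
  }
  lom5 <- unname(cbind(lom, 0))  # 5th column: N scores 0
  x <- enc
  x[is.na(x)] <- 5L
  n <- L - w + 1L
  s <- numeric(n)
  for (k in seq_len(w)) {
    s <- s + lom5[k, ][x[k:(k + n - 1L)]]
  }
  s
}

#' Scan a motif set over sequences with q-value thresholding
#'
#' Both strands of every sequence are scanned with each motif's
#' log-odds matrix; window p-values come from the exact DP null, and
#' Benjamini-Hochberg q-values are computed per motif across all
#' scanned positions (both strands of all sequences). Only hits with
#' `q <= q_threshold` are reported. Sequences shorter than a motif are
#' skipped for that motif. N positions score as background (0 bits).
#'
#' @param motifs A `motif_set`.
#' @param sequences Named character vector or `DNAStringSet`.
#' @param q_threshold Report hits with BH q-value at or below this
#'   (default 0.3).
#' @param background Optional background; default: the motif set's
#'   stored background if present, else estimated from `sequences`.
#' @param pseudocount_mass,granularity Passed to [log_odds_matrix()] and
#'   [exact_score_pvalues()].
#' @return Tibble of class `motif_hits`: `motif_id`, `seq_id`, `start`,
#'   `end`, `strand`, `score`, `p`, `q`.
#' @export
scan_motifs <- function(motifs, sequences, q_threshold = 0.3,
                        background = NULL, pseudocount_mass = 0.01,
                        granularity = 1e-3) {
  seqs <- as_seq_chr(sequences)
  bg <- background %||% motif_background(motifs)
  enc <- lapply(seqs, encode_dna)
  lens <- lengths(enc)
  res <- list()
  for (i in seq_len(nrow(motifs))) {
    pwm <- motifs$pwm[[i]]
    w <- nrow(pwm)
    lom <- log_odds_matrix(pwm, bg, pseudocount_mass)
    pfun <- exact_score_pvalues(lom, bg, granularity)
    lom_rc <- lom[rev(seq_len(w)), c(4L, 3L, 2L, 1L), drop = FALSE]
    rows <- list()
    for (j in seq_along(enc)) {
      if (lens[j] < w) next
      sf <- scan_scores(enc[[j]], lom)
      sr <- scan_scores(enc[[j]], lom_rc)
      n <- length(sf)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seq_id = names(seqs)[j],
        start = rep(seq_len(n), 2L),
        strand = rep(c("+", "-"), each = n),
        score = c(sf, sr)
      )
    }
    if (!length(rows)) next
    hits <- dplyr::bind_rows(rows)
    hits$p <- pfun(hits$score)
    hits$q <- stats::p.adjust(hits$p, method = "BH")
    hits <- hits[hits$q <= q_threshold, , drop = FALSE]
    if (nrow(hits)) {
      hits$motif_id <- motifs$motif_id[i]
      hits$end <- hits$start + w - 1L
      res[[length(res) + 1L]] <- hits
    }
  }
  out <- if (length(res)) {
    dplyr::bind_rows(res) %>%
      dplyr::select("motif_id", "seq_id", "start", "end", "strand",
                    "score", "p", "q") %>%
      dplyr::arrange(.data$motif_id, .data$seq_id, .data$start,
                     .data$strand)
  } else {
    tibble::tibble(motif_id = character(), seq_id = character(),
                   start = integer(), end = integer(),
                   strand = character(), score = numeric(),
                   p = numeric(), q = numeric())
  }
  class(out) <- c("motif_hits", class(out))
  out
}
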