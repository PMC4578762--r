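# Internal helpers shared across modules.

DNA_LETTERS <- c("A", "C", "G", "T")

#' Derive a reproducible child seed from a parent seed and a label
#'
#' All stochastic stages key their RNG off a single global seed plus a
#' stage label so stages can be re-run independently yet reproducibly.
#' The result is kept below 2^31 so it is a valid R integer.
#'
#' @param seed integer parent seed.
#' @param label character stage label.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- digest::digest(list(as.integer(seed), as.character(label)),
                      algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483647L)
}

# Run `expr` with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Encode a DNA string into integer codes A=1, C=2, G=3, T=4, other=NA.
encode_dna <- function(x) {
  m <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_LETTERS)
  m
}

decode_dna <- function(codes) {
  paste(DNA_LETTERS[codes], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Reverse complement of a w x 4 probability (or score) matrix.
revcomp_pwm <- function(pwm) {
  out <- pwm[rev(seq_len(nrow(pwm))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- colnames(pwm)
  out
}

pwm_consensus <- function(pwm) {
  paste(DNA_LETTERS[apply(pwm, 1L, which.max)], collapse = "")
}

# Random i.i.d. DNA with a given GC fraction (caller manages the RNG seed).
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_LETTERS, n, replace = TRUE, prob = p), collapse = "")
}

# One Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) {
    g <- rep(1, length(alpha))
  }
  g / sum(g)
}

# Accept a named character vector or DNAStringSet; return named character.
as_seq_chr <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
  } else if (is.character(sequences)) {
    out <- sequences
  } else {
    stop("`sequences` must be a character vector or a DNAStringSet",
         call. = FALSE)
  }
  if (is.null(names(out)) && length(out)) {
    names(out) <- paste0("seq", seq_along(out))
  }
  toupper(out)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
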