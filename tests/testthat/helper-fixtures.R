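# Shared fixtures, built in code and memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Random background sequences with one planted consensus site each.
planted_sequences <- function(n = 50, len = 200, consensus = "TGACGTCA",
                              seed = 1, revcomp_only = FALSE,
                              plant = TRUE) {
  set.seed(seed)
  w <- nchar(consensus)
  site <- if (revcomp_only) {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(consensus)))
  } else {
    consensus
  }
  out <- vapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    if (plant) {
      pos <- sample(len - w, 1)
      substr(s, pos, pos + w - 1) <- site
    }
    s
  }, character(1))
  names(out) <- sprintf("s%03d", seq_len(n))
  out
}

# A sharp PWM around a consensus word.
consensus_pwm <- function(consensus, major = 0.94) {
  letters4 <- c("A", "C", "G", "T")
  w <- nchar(consensus)
  m <- matrix((1 - major) / 3, w, 4, dimnames = list(NULL, letters4))
  for (i in seq_len(w)) {
    m[i, substr(consensus, i, i)] <- major
  }
  m
}

as_motif_set <- function(pwms, scores = NULL, background = rep(0.25, 4)) {
  ids <- if (is.null(names(pwms))) {
    sprintf("m%02d", seq_along(pwms))
  } else {
    names(pwms)
  }
  df <- tibble::tibble(
    motif_id = ids,
    width = unname(vapply(pwms, nrow, integer(1))),
    nsites = 10L,
    score = if (is.null(scores)) rep(-10, length(pwms)) else scores,
    consensus = unname(vapply(pwms, function(p) {
      paste(c("A", "C", "G", "T")[apply(p, 1, which.max)], collapse = "")
    }, character(1))),
    pwm = unname(pwms)
  )
  crossnet:::new_motif_set(df, background = background)
}

small_world <- function() {
  memo("small_world", simulate_world(
    sim_config(n_orthologs = 80, category_size = 20,
               frac_conserved = 0.7, seed = 421)
  ))
}

hamming_dist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Consensus recovered if within `d` mismatches of the target in either
# orientation.
consensus_close <- function(found, target, d = 1) {
  nchar(found) == nchar(target) &&
    min(hamming_dist(found, target), hamming_dist(found, rc_chr(target))) <= d
}

# Brute-force oracle for the windowed conservation caller: a column is
# conserved iff some length-`window` column window covering it has at
# least `min_matches` identical non-gap matches.
oracle_conserved_cols <- function(a, b, window = 30, min_matches = 23) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  L <- length(av)
  conserved <- logical(L)
  if (L >= window) {
    for (s in 1:(L - window + 1)) {
      cols <- s:(s + window - 1)
      m <- sum(av[cols] == bv[cols] & av[cols] != "-" & bv[cols] != "-")
      if (m >= min_matches) conserved[cols] <- TRUE
    }
  }
  conserved
}

# Convert oracle column flags to A-coordinate elements.
oracle_elements <- function(a, conserved) {
  av <- strsplit(a, "")[[1]]
  a_pos <- cumsum(av != "-")
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in which(r$values)) {
    cols <- starts[k]:ends[k]
    cols_a <- cols[av[cols] != "-"]
    if (length(cols_a)) {
      out[[length(out) + 1]] <- c(a_pos[cols_a[1]],
                                  a_pos[cols_a[length(cols_a)]])
    }
  }
  out
}

mutate_seq <- function(x, p, seed) {
  set.seed(seed)
  v <- strsplit(x, "")[[1]]
  hit <- runif(length(v)) < p
  v[hit] <- sapply(v[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  })
  paste(v, collapse = "")
}

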