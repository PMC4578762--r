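# MEME minimal motif format reader/writer.
#
# A motif set is represented as a tibble of class `motif_set` with
# columns: motif_id, width, nsites, score (significance; lower is
# better), consensus, pwm (list of width x 4 probability matrices with
# columns A, C, G, T). The set's background frequencies and provenance
# travel as attributes.

new_motif_set <- function(df, background = rep(0.25, 4),
                          provenance = list()) {
  stopifnot(all(c("motif_id", "width", "nsites", "score", "consensus",
                  "pwm") %in% names(df)))
  names(background) <- DNA_LETTERS
  out <- tibble::as_tibble(df)
  class(out) <- c("motif_set", class(out))
  attr(out, "background") <- background
  attr(out, "provenance") <- provenance
  out
}

#' Background frequencies of a motif set
#'
#' @param x A `motif_set`.
#' @return Named numeric vector over A, C, G, T.
#' @export
motif_background <- function(x) {
  attr(x, "background") %||% stats::setNames(rep(0.25, 4), DNA_LETTERS)
}

validate_motif_set <- function(x, tol = 1e-9) {
  for (i in seq_len(nrow(x))) {
    p <- x$pwm[[i]]
    if (any(p < 0) || any(abs(rowSums(p) - 1) > tol)) {
      stop("PWM rows must be non-negative and sum to 1 (motif ",
           x$motif_id[i], ")", call. = FALSE)
    }
  }
  bg <- motif_background(x)
  if (abs(sum(bg) - 1) > tol) {
    stop("background must sum to 1", call. = FALSE)
  }
  invisible(x)
}

#' Write a motif set in MEME minimal motif format
#'
#' @param motifs A `motif_set`.
#' @param path Output path.
#' @export
write_meme <- function(motifs, path) {
  bg <- motif_background(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
    ""
  ), con)
  for (i in seq_len(nrow(motifs))) {
    p <- motifs$pwm[[i]]
    writeLines(sprintf("MOTIF %s", motifs$motif_id[i]), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= %g",
      motifs$width[i], motifs$nsites[i], motifs$score[i]
    ), con)
    writeLines(apply(p, 1L, function(r) {
      sprintf(" %0.6f %0.6f %0.6f %0.6f", r[1], r[2], r[3], r[4])
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal motif format file
#'
#' @param path Input path.
#' @return A `motif_set` tibble.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bline <- grep("^Background letter frequencies", lines)
  if (length(bline) && bline[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bline[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    lv <- vals[!is.na(vals)]
    if (length(lv) >= 4L) bg <- lv[1:4]
  }
  starts <- grep("^MOTIF\\s", lines)
  rows <- lapply(starts, function(s) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- s + 1L
    while (h <= length(lines) &&
           !grepl("^letter-probability matrix", lines[h])) {
      h <- h + 1L
    }
    hdr <- lines[h]
    get_num <- function(key, default = NA_real_) {
      m <- regmatches(hdr, regexec(paste0(key, "=\\s*([0-9eE.+-]+)"), hdr))[[1]]
      if (length(m) == 2L) as.numeric(m[2]) else default
    }
    w <- as.integer(get_num("w"))
    nsites <- as.integer(get_num("nsites", 0))
    score <- get_num("E", NA_real_)
    mat <- matrix(NA_real_, w, 4L,
                  dimnames = list(NULL, DNA_LETTERS))
    for (j in seq_len(w)) {
      tok <- strsplit(trimws(lines[h + j]), "\\s+")[[1]]
      mat[j, ] <- as.numeric(tok[1:4])
    }
    tibble::tibble(motif_id = id, width = w, nsites = nsites,
                   score = score, consensus = pwm_consensus(mat),
                   pwm = list(mat))
  })
  new_motif_set(dplyr::bind_rows(rows), background = bg,
                provenance = list(source = path))
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set: %d motif(s)>\n", nrow(x)))
  NextMethod()
}

#' Tidy a motif set into a plain tibble (one row per motif)
#'
#' @param x A `motif_set`.
#' @param ... Unused.
#' @return A tibble without the list-column of matrices.
#' @exportS3Method
tidy.motif_set <- function(x, ...) {
  tibble::as_tibble(x[, c("motif_id", "width", "nsites", "score",
                          "consensus")])
}

#' @rdname tidy.motif_set
#' @exportS3Method
glance.motif_set <- function(x, ...) {
  tibble::tibble(
    n_motifs = nrow(x),
    min_width = if (nrow(x)) min(x$width) else NA_integer_,
    max_width = if (nrow(x)) max(x$width) else NA_integer_,
    best_score = if (nrow(x)) min(x$score) else NA_real_
  )
}

#' Information-content heat map of a motif set
#'
#' @param object A `motif_set`.
#' @param ... Unused.
#' @return A ggplot object: per-motif, per-position letter information
#'   content (bits).
#' @exportS3Method
autoplot.motif_set <- function(object, ...) {
  rows <- lapply(seq_len(nrow(object)), function(i) {
    p <- object$pwm[[i]]
    ic <- 2 + rowSums(ifelse(p > 0, p * log2(p), 0))
    tidyr::expand_grid(position = seq_len(nrow(p)),
                       letter = factor(DNA_LETTERS,
                                       levels = rev(DNA_LETTERS))) %>%
      dplyr::mutate(
        motif_id = object$motif_id[i],
        height = as.vector(t(p)) * rep(ic, each = 4L)
      )
  })
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$letter,
                                   fill = .data$height)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~motif_id, scales = "free_x") +
    ggplot2::scale_fill_viridis_c(name = "bits") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "motif position", y = NULL)
}
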