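#' Construct a frequency matrix
#'
#' A frequency matrix gives the per-position base distribution of a
#' transcription factor motif.  Rows are motif positions, columns are the
#' bases A, C, G, T.  Input rows may be probabilities or counts; a
#' pseudocount is added to every cell before renormalization so that all
#' entries stay strictly positive and log-odds scores stay finite.
#'
#' @param x numeric matrix (positions x 4) of probabilities or counts.
#' @param pseudocount mass added to each cell before normalization.
#' @param name optional label.
#' @return an object of class `freq_matrix` with elements `probs`
#'   (normalized positions x 4 matrix), `width`, `pseudocount` and `name`.
#' @export
freq_matrix <- function(x, pseudocount = 1e-4, name = "motif") {
  x <- as.matrix(x)
  if (ncol(x) != 4) stop("frequency matrix must have four columns (A C G T)")
  if (nrow(x) < 1 || nrow(x) > 30) stop("motif width must be between 1 and 30")
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("frequency matrix entries must be finite and non-negative")
  }
  rs <- rowSums(x)
  if (any(rs == 0)) stop("frequency matrix has a zero-sum row")
  x <- x + pseudocount
  probs <- x / rowSums(x)
  dimnames(probs) <- list(NULL, BASES)
  m <- list(probs = probs, width = nrow(probs), pseudocount = pseudocount,
            name = name)
  class(m) <- "freq_matrix"
  stopifnot(all(abs(rowSums(probs) - 1) < 1e-9), all(probs > 0))
  m
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("<freq_matrix '%s'> width %d, pseudocount %g\n",
              x$name, x$width, x$pseudocount))
  print(round(x$probs, 4))
  invisible(x)
}

#' Load a frequency matrix from a whitespace table
#'
#' Parses a plain text table with one row per motif position and four
#' whitespace-separated columns (A C G T; a header line is optional).  Rows
#' are auto-detected as probabilities (rows summing to ~1) or counts, and
#' are normalized after adding the pseudocount.
#'
#' @param file path to the table, or a character vector of lines via `text`.
#' @param text character vector of lines (alternative to `file`).
#' @inheritParams freq_matrix
#' @return a [freq_matrix()].
#' @export
load_frequency_matrix <- function(file = NULL, text = NULL,
                                  pseudocount = 1e-4, name = NULL) {
  if (is.null(text)) {
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(file))
    text <- readLines(file)
  }
  if (is.null(name)) name <- "motif"
  lines <- trimws(text)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^[ACGTacgt][ \t]", lines[[1]]) &&
      is.na(suppressWarnings(as.numeric(strsplit(lines[[1]],
                                                 "[ \t]+")[[1]][1])))) {
    lines <- lines[-1] # header row of base labels
  }
  if (!length(lines)) stop("no matrix rows found")
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "[ \t,]+")[[1]]
    f <- f[nzchar(f)]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != 4 || anyNA(v)) {
      stop(sprintf("matrix parse error at line %d: expected 4 numeric fields, got '%s'",
                   i, lines[[i]]))
    }
    if (any(v < 0)) {
      stop(sprintf("matrix parse error at line %d: negative entry", i))
    }
    if (sum(v) == 0) {
      stop(sprintf("matrix parse error at line %d: zero-sum row", i))
    }
    v
  })
  freq_matrix(do.call(rbind, rows), pseudocount = pseudocount, name = name)
}

#' GC-weighted iid background model
#'
#' @param gc GC fraction in `[0, 1]`; A and T each get `(1 - gc) / 2`,
#'   C and G each `gc / 2`.
#' @return an object of class `bg_model` with elements `gc` and `emission`.
#' @export
background_model <- function(gc = 0.38) {
  stopifnot(is.numeric(gc), length(gc) == 1, gc >= 0, gc <= 1)
  em <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  structure(list(gc = gc, emission = em), class = "bg_model")
}

#' @export
print.bg_model <- function(x, ...) {
  cat(sprintf("<bg_model> gc = %.3f\n", x$gc))
  invisible(x)
}

# positions x 4 matrix of log2(m/bg), and its reverse-complement-scan twin
log2_odds_matrix <- function(m, bg) {
  sweep(log2(m$probs), 2, log2(bg$emission))
}

log2_odds_matrix_rc <- function(m, bg) {
  lo <- log2_odds_matrix(m, bg)
  lo[rev(seq_len(nrow(lo))), c(4, 3, 2, 1), drop = FALSE]
}

#' Log-odds score of one subsequence
#'
#' Scores a subsequence of exactly the motif width against the matrix in
#' log2 units: `sum_i log2(m[i][base_i] / bg[base_i])`.  On the reverse
#' strand the reverse complement of the subsequence is scored against the
#' matrix.  Ambiguous bases (N) contribute zero, i.e. score as background.
#'
#' @param m a [freq_matrix()].
#' @param bg a [background_model()].
#' @param subseq character scalar of length `m$width`.
#' @param strand `"fwd"` or `"rev"`.
#' @return numeric score in log2 units.
#' @export
log_odds_score <- function(m, bg, subseq, strand = c("fwd", "rev")) {
  strand <- match.arg(strand)
  enc <- encode_seq(subseq)
  if (length(enc$codes) != m$width) {
    stop("subsequence length must equal the matrix width")
  }
  lo <- if (strand == "fwd") log2_odds_matrix(m, bg) else
    log2_odds_matrix_rc(m, bg)
  idx <- cbind(seq_len(m$width), enc$codes)
  vals <- ifelse(enc$codes == 0, 0, lo[idx])
  sum(vals)
}

#' Motif information content
#'
#' Kullback-Leibler divergence of the matrix from the background, summed
#' over positions: `sum_i sum_b m[i][b] * ln(m[i][b] / bg[b])`, in nats
#' (set `bits = TRUE` for bits).
#'
#' @inheritParams log_odds_score
#' @param bits report in bits instead of nats.
#' @return non-negative numeric.
#' @export
motif_information <- function(m, bg, bits = FALSE) {
  v <- sum(m$probs * log(sweep(m$probs, 2, bg$emission, "/")))
  v <- max(v, 0)
  if (bits) v / log(2) else v
}

#' Scan a sequence with a frequency matrix
#'
#' Computes log2 log-odds scores of every length-`w` window on both strands.
#' Ambiguous bases contribute zero to a window's score.
#'
#' @inheritParams log_odds_score
#' @param seq character scalar (length >= matrix width for a non-empty
#'   result).
#' @return matrix with `L - w + 1` rows and columns `fwd` and `rev`
#'   (zero rows when the sequence is shorter than the motif).
#' @export
scan_scores <- function(m, bg, seq) {
  enc <- encode_seq(seq)
  L <- length(enc$codes)
  w <- m$width
  if (L < w) {
    return(matrix(numeric(0), nrow = 0, ncol = 2,
                  dimnames = list(NULL, c("fwd", "rev"))))
  }
  lo <- log2_odds_matrix(m, bg)
  lorc <- log2_odds_matrix_rc(m, bg)
  n <- L - w + 1
  sf <- numeric(n)
  sr <- numeric(n)
  for (t in seq_len(w)) {
    code <- enc$codes[t:(t + n - 1)]
    keep <- code > 0L
    if (any(keep)) {
      idx <- cbind(t, code[keep])
      sf[keep] <- sf[keep] + lo[idx]
      sr[keep] <- sr[keep] + lorc[idx]
    }
  }
  cbind(fwd = sf, rev = sr)
}

#' Write a score track as a BED-like TSV
#'
#' One row per window and strand with columns promoter, start (0-based),
#' strand and score.
#'
#' @param tracks named list of matrices from [scan_scores()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_score_track <- function(tracks, path) {
  rows <- lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    if (nrow(tr) == 0) return(NULL)
    data.frame(promoter = id, start = rep(seq_len(nrow(tr)) - 1L, 2),
               strand = rep(c("+", "-"), each = nrow(tr)),
               score = c(tr[, "fwd"], tr[, "rev"]))
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
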