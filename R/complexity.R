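AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Compositional complexity of an amino-acid motif
#'
#' Computes the SEG-style compositional complexity of a sequence over the
#' 20-letter amino-acid alphabet: the Shannon entropy of its residue
#' composition in bits,
#' `K = -sum_i (n_i / L) * log2(n_i / L)`,
#' where `n_i` are the residue counts and `L` the length.  A homopolymer
#' scores exactly 0; the score is bounded by `log2(min(20, L))` and depends
#' only on the composition, never on residue order.  Sequences scoring
#' strictly above the threshold (default 2.5 bits) are classified
#' `"high"` complexity, all others `"low"`.
#'
#' @param sequence Single amino-acid string (canonical 20-letter alphabet,
#'   case-insensitive).
#' @param threshold Classification threshold, bits.
#' @param tolerate_x If `TRUE`, `X` (unknown residue) characters are dropped
#'   before scoring instead of raising an error.
#' @return List of class `complexity_result`: `sequence`, `length`,
#'   `score_bits` (unrounded), `score_display` (rounded to 2 decimals, the
#'   conventional reporting precision) and `classification`.
#' @export
complexity <- function(sequence, threshold = 2.5, tolerate_x = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (tolerate_x) chars <- chars[chars != "X"]
  if (!length(chars)) stop("empty sequence", call. = FALSE)
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("non-amino-acid character(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  counts <- table(chars)
  p <- as.numeric(counts) / length(chars)
  score <- -sum(p * log2(p))
  structure(list(sequence = paste(chars, collapse = ""),
                 length = length(chars),
                 score_bits = score,
                 score_display = round(score, 2),
                 classification = if (score > threshold) "high" else "low"),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("%s  (L = %d): complexity = %.2f bits, %s complexity\n",
              x$sequence, x$length, x$score_bits, x$classification))
  invisible(x)
}

#' Score a set of motifs
#'
#' @param sequences Named character vector of amino-acid motifs.
#' @param threshold,tolerate_x Passed to [complexity()].
#' @return Data frame: `name`, `sequence`, `length`, `score_bits`,
#'   `score_display`, `classification`.
#' @export
complexity_table <- function(sequences, threshold = 2.5,
                             tolerate_x = FALSE) {
  stopifnot(is.character(sequences))
  nm <- names(sequences) %||% as.character(seq_along(sequences))
  rows <- lapply(seq_along(sequences), function(i) {
    r <- complexity(sequences[[i]], threshold, tolerate_x)
    data.frame(name = nm[i], sequence = r$sequence, length = r$length,
               score_bits = r$score_bits, score_display = r$score_display,
               classification = r$classification)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sliding-window complexity profile
#'
#' Scores every length-`window_len` substring of `sequence`; positions are
#' 0-based, windows half-open `[start, start + window_len)`.
#'
#' @param sequence Amino-acid string.
#' @param window_len Window length (must not exceed the sequence length).
#' @param threshold,tolerate_x Passed to [complexity()].
#' @return Data frame: `start`, `end`, `window`, `score_bits`,
#'   `score_display`, `classification`.
#' @export
window_complexity <- function(sequence, window_len, threshold = 2.5,
                              tolerate_x = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (window_len > L) stop("window longer than sequence", call. = FALSE)
  starts <- 0:(L - window_len)
  rows <- lapply(starts, function(s) {
    win <- substr(sequence, s + 1L, s + window_len)
    r <- complexity(win, threshold, tolerate_x)
    data.frame(start = s, end = s + window_len, window = win,
               score_bits = r$score_bits, score_display = r$score_display,
               classification = r$classification)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read amino-acid motifs from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid motifs.
#' @return Named character vector of sequences.
#' @export
read_motifs <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  s <- Biostrings::readAAStringSet(path)
  setNames(as.character(s), names(s))
}
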