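# BLOSUM-style log-odds substitution matrix over the 20 structural states,
# estimated from structurally aligned, encoded residue pairs.

STATE_LETTERS <- LETTERS[1:20]

#' Count aligned state pairs
#'
#' Each observed pair (x, y) increments both `counts[x, y]` and
#' `counts[y, x]`; a matched pair on the diagonal is therefore incremented
#' twice, which keeps row marginals consistent with the symmetrized joint.
#' Pairs containing the unknown letter `"X"` are skipped.
#'
#' @param encoded_pairs Two-column character matrix (or data.frame) of
#'   structural-state letters.
#' @param letters State alphabet (default the 20 uppercase letters A-T).
#' @param pseudocount Added uniformly to every cell at estimation time.
#' @return An object of class `fs_subcounts`.
#' @export
count_substitutions <- function(encoded_pairs, letters = STATE_LETTERS,
                                pseudocount = 1) {
  m <- as.matrix(encoded_pairs)
  if (ncol(m) != 2) stop("encoded_pairs must have two columns")
  keep <- m[, 1] != "X" & m[, 2] != "X"
  m <- m[keep, , drop = FALSE]
  bad <- setdiff(unique(as.vector(m)), letters)
  if (length(bad)) stop("unknown letter(s): ", paste(bad, collapse = ", "))
  A <- length(letters)
  counts <- matrix(0, A, A, dimnames = list(letters, letters))
  if (nrow(m)) {
    x <- factor(m[, 1], levels = letters)
    y <- factor(m[, 2], levels = letters)
    tab <- table(x, y)
    counts <- unclass(tab) + unclass(t(tab))
    dimnames(counts) <- list(letters, letters)
  }
  structure(list(counts = counts, pseudocount = pseudocount,
                 letters = letters), class = "fs_subcounts")
}

#' Estimate the log-odds substitution matrix
#'
#' Scores are `2 * log2( p(x, y) / (p(x) p(y)) )` (half-bit-like units) where
#' `p(x, y)` is the pseudocount-smoothed, normalized joint frequency of
#' aligned states and `p(x)` its marginal. The integer matrix
#' (nearest-integer, ties to even) drives k-mer generation and alignment
#' scoring; the real-valued matrix is kept for diagnostics. The unknown
#' letter `"X"` scores 0 against everything.
#'
#' @param counts An `fs_subcounts` from [count_substitutions].
#' @return An object of class `fs_submat` with elements `scores`,
#'   `scores_int` (both with an `X` row/column), `background`, `letters`.
#' @export
estimate_matrix <- function(counts) {
  stopifnot(inherits(counts, "fs_subcounts"))
  cm <- counts$counts + counts$pseudocount
  if (sum(cm) <= 0) stop("total count must be positive")
  if (any(cm <= 0)) stop("zero cell after pseudocounts")
  p_xy <- cm / sum(cm)
  p_x <- rowSums(p_xy)
  scores <- 2 * log2(p_xy / outer(p_x, p_x))
  letters <- counts$letters
  full <- c(letters, "X")
  sc <- matrix(0, length(full), length(full), dimnames = list(full, full))
  sc[letters, letters] <- scores
  sci <- round(sc)  # round() rounds half to even
  structure(list(scores = sc, scores_int = sci, background = p_x,
                 letters = letters), class = "fs_submat")
}

#' @export
print.fs_submat <- function(x, ...) {
  cat(sprintf("<fs_submat: %d states, score range [%.1f, %.1f]>\n",
              length(x$letters), min(x$scores[x$letters, x$letters]),
              max(x$scores[x$letters, x$letters])))
  invisible(x)
}

#' Expected score under the background distribution
#'
#' For a well-formed log-odds matrix this is negative.
#' @param mat An `fs_submat`.
#' @export
expected_score <- function(mat) {
  l <- mat$letters
  p <- mat$background
  sum(outer(p, p) * mat$scores[l, l])
}

#' Write / read a substitution matrix in BLOSUM-style text format
#'
#' Whitespace-separated square matrix of integer scores with letter header
#' row/column; comment lines carry the background frequencies and the
#' real-valued scores are recoverable up to rounding only (the integer matrix
#' is the operational one).
#'
#' @param mat An `fs_submat`.
#' @param path File path.
#' @export
write_matrix <- function(mat, path) {
  l <- c(mat$letters, "X")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# structural-state substitution matrix (half-bit-like units)", con)
  writeLines(paste0("# background: ",
                    paste(sprintf("%s=%.6f", mat$letters, mat$background),
                          collapse = " ")), con)
  writeLines(paste(c(" ", l), collapse = "\t"), con)
  for (a in l)
    writeLines(paste(c(a, mat$scores_int[a, l]), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  bgline <- grep("^# background:", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  hdr <- strsplit(trimws(body[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(body[-1]), "\\s+")
  l <- hdr
  sci <- matrix(0, length(l), length(l), dimnames = list(l, l))
  for (r in rows) sci[r[1], ] <- as.numeric(r[-1])
  letters <- setdiff(l, "X")
  bg <- rep(1 / length(letters), length(letters))
  names(bg) <- letters
  if (length(bgline)) {
    kv <- strsplit(strsplit(sub("^# background: ", "", bgline[1]), " ")[[1]], "=")
    bg[vapply(kv, `[[`, "", 1)] <- as.numeric(vapply(kv, `[[`, "", 2))
  }
  structure(list(scores = sci, scores_int = sci, background = bg,
                 letters = letters), class = "fs_submat")
}

#' Amino-acid scoring matrix (BLOSUM62)
#'
#' BLOSUM62 (half-bit units, from Biostrings) restricted to the 20 standard
#' amino acids, with an all-zero `X` row/column so unknown residues score
#' neutrally.
#'
#' @return An `fs_submat` over the amino-acid alphabet.
#' @export
aa_matrix_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  full <- c(aas, "X")
  b <- matrix(0, 21, 21, dimnames = list(full, full))
  b[aas, aas] <- e$BLOSUM62[aas, aas]
  structure(list(scores = b, scores_int = b,
                 background = stats::setNames(rep(1 / 20, 20), aas),
                 letters = aas), class = "fs_submat")
}
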