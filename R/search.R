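# Candidate detection and alignment: similar-k-mer double-diagonal prefilter
# with an ungapped bit-score gate, then affine-gap Smith-Waterman over the
# weighted combination of amino-acid and structural-state substitution
# scores, with compositional bias correction and reversed-query score
# subtraction.

#' Prefilter parameters
#'
#' @param k Word length (6 or 7).
#' @param kmer_sim_delta Similar k-mers are those scoring within this many
#'   raw score units of the k-mer's self score (relative threshold).
#' @param kmer_sim_threshold Optional absolute score threshold overriding the
#'   relative rule.
#' @param ungapped_min_bits Minimum ungapped diagonal bit score for a hit to
#'   pass (default 15).
#' @param max_hits_per_query Cap on reported hits.
#' @export
prefilter_params <- function(k = 6, kmer_sim_delta = 6,
                             kmer_sim_threshold = NULL,
                             ungapped_min_bits = 15,
                             max_hits_per_query = 1000) {
  stopifnot(k %in% c(6, 7))
  structure(list(k = k, kmer_sim_delta = kmer_sim_delta,
                 kmer_sim_threshold = kmer_sim_threshold,
                 ungapped_min_bits = ungapped_min_bits,
                 max_hits_per_query = max_hits_per_query),
            class = "fs_prefilter_params")
}

#' Alignment parameters
#'
#' Amino-acid and structural-state scores are combined with weights 1.4 and
#' 2.1; gap penalties are in raw (half-bit) units, a gap of length g costing
#' `gap_open + (g - 1) * gap_extend`. Bit scores are raw / 2.
#'
#' @param w_aa,w_3di Score weights.
#' @param gap_open,gap_extend Affine gap penalties (raw units).
#' @param cbc_window Compositional-bias window (residues).
#' @param use_reverse_correction Subtract the reversed-query bit score.
#' @export
alignment_params <- function(w_aa = 1.4, w_3di = 2.1, gap_open = 11,
                             gap_extend = 1, cbc_window = 40,
                             use_reverse_correction = TRUE) {
  stopifnot(gap_extend <= gap_open)
  structure(list(w_aa = w_aa, w_3di = w_3di, gap_open = gap_open,
                 gap_extend = gap_extend, cbc_window = cbc_window,
                 use_reverse_correction = use_reverse_correction),
            class = "fs_alignment_params")
}

seq_chars <- function(s) strsplit(s, "")[[1]]

#' Build the k-mer index over a target database
#'
#' Indexes every length-`k` window of every target's structural-state
#' sequence (windows containing `"X"` are skipped) at its start position.
#'
#' @param targets List of [fs_entry] objects.
#' @param params A [prefilter_params].
#' @return An index object (list with `kmers`: environment mapping k-mer to
#'   a matrix of (target index, position), `targets`, `k`).
#' @export
build_kmer_index <- function(targets, params = prefilter_params()) {
  k <- params$k
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (ti in seq_along(targets)) {
    s <- seq_chars(targets[[ti]]$tdi_seq)
    L <- length(s)
    if (L < k) next
    hasx <- s == "X"
    for (p in seq_len(L - k + 1)) {
      if (any(hasx[p:(p + k - 1)])) next
      w <- paste(s[p:(p + k - 1)], collapse = "")
      env[[w]] <- rbind(env[[w]], c(ti, p))
    }
  }
  structure(list(kmers = env, targets = targets, k = k,
                 sim_cache = new.env(hash = TRUE, parent = emptyenv())),
            class = "fs_kmer_index")
}

#' Enumerate all k-mers similar to a given k-mer
#'
#' Returns every k-mer whose summed integer substitution score against the
#' input is at least `threshold`, found by depth-first branch-and-bound over
#' per-position score-sorted letters.
#'
#' @param kmer Structural-state k-mer (string, no `"X"`).
#' @param matrix An `fs_submat`.
#' @param threshold Minimum summed score.
#' @return Character vector of k-mers (always includes `kmer` when
#'   `threshold` is at most its self score).
#' @export
similar_kmers <- function(kmer, matrix, threshold) {
  letters <- matrix$letters
  q <- seq_chars(kmer)
  sc <- matrix$scores_int[letters, q, drop = FALSE]  # candidate letter x position
  ord <- apply(sc, 2, order, decreasing = TRUE)      # k columns of letter ranks
  hits <- enumerate_similar_kmers_cpp(sc, ord, threshold)
  if (nrow(hits) == 0) return(character(0))
  apply(hits, 1, function(r) paste(letters[r], collapse = ""))
}

kmer_threshold <- function(kmer, matrix, params) {
  if (!is.null(params$kmer_sim_threshold)) return(params$kmer_sim_threshold)
  q <- seq_chars(kmer)
  sum(matrix$scores_int[cbind(q, q)]) - params$kmer_sim_delta
}

#' Per-position compositional bias correction
#'
#' For each position p the correction is minus the mean substitution score of
#' the letter at p against the letters in a window of up to `window` residues
#' centered on p (p itself excluded, truncated at the sequence ends). Adding
#' these offsets discounts matches driven by locally biased composition.
#'
#' @param seq Sequence (string).
#' @param matrix An `fs_submat` (real-valued scores are used).
#' @param window Window size in residues.
#' @return Numeric vector of offsets, one per position.
#' @export
composition_bias_correction <- function(seq, matrix, window = 40) {
  s <- seq_chars(seq)
  L <- length(s)
  if (L == 0) stop("sequence must be non-empty")
  half <- window %/% 2
  letters <- colnames(matrix$scores)
  li <- match(s, letters)
  # windowed letter counts via cumulative sums, own position excluded
  ind <- matrix(0, L, length(letters))
  ind[cbind(seq_len(L), li)] <- 1
  cum <- rbind(0, apply(ind, 2, cumsum))
  lo <- pmax(1, seq_len(L) - half)
  hi <- pmin(L, seq_len(L) + half)
  W <- cum[hi + 1, , drop = FALSE] - cum[lo, , drop = FALSE] - ind
  nw <- hi - lo  # window size minus the excluded own position
  srow <- matrix$scores[li, , drop = FALSE]
  off <- -rowSums(W * srow) / pmax(nw, 1)
  off[nw == 0] <- 0
  unname(off)
}

# per-query compositional bias offsets for both score components
query_cbc <- function(query, matrices, params) {
  list(aa = composition_bias_correction(query$aa_seq, matrices$aa,
                                        params$cbc_window),
       tdi = composition_bias_correction(query$tdi_seq, matrices$tdi,
                                         params$cbc_window))
}

# combined per-position score matrix (query x target), real valued
combined_score_matrix <- function(query, target, matrices, params,
                                  cbc = NULL) {
  qa <- seq_chars(query$aa_seq); q3 <- seq_chars(query$tdi_seq)
  ta <- seq_chars(target$aa_seq); t3 <- seq_chars(target$tdi_seq)
  S_aa <- matrices$aa$scores[qa, ta, drop = FALSE]
  S_3di <- matrices$tdi$scores[q3, t3, drop = FALSE]
  if (is.null(cbc)) cbc <- query_cbc(query, matrices, params)
  params$w_aa * (S_aa + cbc$aa) + params$w_3di * (S_3di + cbc$tdi)
}

#' Prefilter a query against an indexed target database
#'
#' Finds target diagonals carrying at least two similar-k-mer matches (the
#' second at a later query position), scores an ungapped alignment along each
#' such diagonal with the combined, bias-corrected score, keeps the best
#' diagonal per target and returns targets whose ungapped bit score reaches
#' `ungapped_min_bits`, sorted by descending bits then target id.
#'
#' @param query An [fs_entry].
#' @param index An `fs_kmer_index` from [build_kmer_index].
#' @param matrices `list(tdi = , aa = )` of `fs_submat`.
#' @param params A [prefilter_params].
#' @param aln_params An [alignment_params] (weights and bias window for the
#'   ungapped diagonal score).
#' @return data.frame (target_id, diagonal, ungapped_bits).
#' @export
prefilter <- function(query, index, matrices, params = prefilter_params(),
                      aln_params = alignment_params()) {
  k <- index$k
  q3 <- seq_chars(query$tdi_seq)
  L <- length(q3)
  empty <- data.frame(target_id = character(0), diagonal = integer(0),
                      ungapped_bits = numeric(0))
  if (L < k) {
    warning("query shorter than k")
    return(empty)
  }
  hasx <- q3 == "X"
  # collect (target, diagonal, query position) triples of similar-kmer
  # matches; enumerated similar-kmer sets are cached on the index
  tgt <- dia <- qp <- integer(0)
  sim_cache <- index$sim_cache
  for (p in seq_len(L - k + 1)) {
    if (any(hasx[p:(p + k - 1)])) next
    w <- paste(q3[p:(p + k - 1)], collapse = "")
    sims <- sim_cache[[w]]
    if (is.null(sims)) {
      sims <- similar_kmers(w, matrices$tdi, kmer_threshold(w, matrices$tdi,
                                                            params))
      sim_cache[[w]] <- sims
    }
    for (s in sims) {
      hits <- index$kmers[[s]]
      if (is.null(hits)) next
      tgt <- c(tgt, hits[, 1])
      dia <- c(dia, p - hits[, 2])
      qp <- c(qp, rep.int(p, nrow(hits)))
    }
  }
  if (!length(tgt)) return(empty)
  df <- data.frame(tgt = tgt, dia = dia, qp = qp)
  df <- unique(df)
  key <- paste(df$tgt, df$dia)
  # double-match criterion: >=2 distinct query positions on one diagonal
  nqp <- tapply(df$qp, key, function(v) length(unique(v)))
  good <- names(nqp)[nqp >= 2]
  if (!length(good)) return(empty)
  parts <- strsplit(good, " ")
  cand <- data.frame(tgt = as.integer(vapply(parts, `[[`, "", 1)),
                     dia = as.integer(vapply(parts, `[[`, "", 2)))
  # ungapped score per candidate diagonal; best diagonal per target
  res <- empty
  cbc <- query_cbc(query, matrices, aln_params)
  for (ti in unique(cand$tgt)) {
    target <- index$targets[[ti]]
    S <- combined_score_matrix(query, target, matrices, aln_params, cbc)
    dias <- cand$dia[cand$tgt == ti]
    best <- -Inf; best_dia <- NA_integer_
    for (d in dias) {
      sc <- diagonal_best_segment(S, d)
      if (sc > best) { best <- sc; best_dia <- d }
    }
    bits <- best / 2
    if (bits >= params$ungapped_min_bits)
      res <- rbind(res, data.frame(target_id = target$entry_id,
                                   diagonal = best_dia,
                                   ungapped_bits = bits))
  }
  res <- res[order(-res$ungapped_bits, res$target_id), , drop = FALSE]
  if (nrow(res) > params$max_hits_per_query)
    res <- res[seq_len(params$max_hits_per_query), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# best contiguous segment sum along diagonal d (query index - target index)
diagonal_best_segment <- function(S, d) {
  n <- nrow(S); m <- ncol(S)
  i0 <- max(1, 1 + d); i1 <- min(n, m + d)
  if (i0 > i1) return(-Inf)
  v <- S[cbind(i0:i1, (i0:i1) - d)]
  cs <- cumsum(v)
  max(cs - cummin(c(0, cs[-length(cs)])))
}

#' Local alignment with combined structural and amino-acid scores
#'
#' Affine-gap Smith-Waterman maximizing the weighted sum of amino-acid and
#' structural-state substitution scores with per-query-position compositional
#' bias offsets. If `use_reverse_correction` the reversed query (both
#' strings) is aligned to the target and its bit score subtracted
#' (`corrected_bits = forward - reverse`), which suppresses high-scoring
#' false positives with biased composition.
#'
#' @param query,target [fs_entry] objects.
#' @param matrices `list(tdi = , aa = )` of `fs_submat`.
#' @param params An [alignment_params].
#' @param cbc Optional precomputed query bias offsets (reused across targets
#'   of the same query).
#' @return List of class `fs_alignment`: query_id, target_id, 1-based
#'   inclusive ranges `q_start/q_end/t_start/t_end`, `cigar`, `pairs`
#'   (2-column matrix of aligned residue indices), `raw_score`, `bit_score`,
#'   `corrected_bits`, `n_ident`, `aln_len`.
#' @export
align_local <- function(query, target, matrices, params = alignment_params(),
                        cbc = NULL) {
  if (nchar(query$aa_seq) == 0 || nchar(target$aa_seq) == 0)
    stop("empty sequence")
  if (is.null(cbc)) cbc <- query_cbc(query, matrices, params)
  S <- combined_score_matrix(query, target, matrices, params, cbc)
  r <- sw_align_cpp(S, params$gap_open, params$gap_extend, TRUE)
  bit <- r$score / 2
  corrected <- bit
  if (params$use_reverse_correction) {
    rev_entry <- fs_entry(query$entry_id,
                          reverse_string(query$aa_seq),
                          reverse_string(query$tdi_seq),
                          query$ca[rev(seq_len(nrow(query$ca))), , drop = FALSE])
    # the bias window is symmetric, so the reversed query's offsets are the
    # reversed offsets
    rcbc <- list(aa = rev(cbc$aa), tdi = rev(cbc$tdi))
    Sr <- combined_score_matrix(rev_entry, target, matrices, params, rcbc)
    rr <- sw_align_cpp(Sr, params$gap_open, params$gap_extend, FALSE)
    corrected <- bit - rr$score / 2
  }
  qa <- seq_chars(query$aa_seq); ta <- seq_chars(target$aa_seq)
  n_ident <- if (!is.null(r$pairs) && nrow(r$pairs))
    sum(qa[r$pairs[, 1]] == ta[r$pairs[, 2]]) else 0L
  aln_len <- if (is.na(r$cigar)) 0L else cigar_length(r$cigar)
  structure(list(query_id = query$entry_id, target_id = target$entry_id,
                 q_start = r$q_start, q_end = r$q_end,
                 t_start = r$t_start, t_end = r$t_end,
                 cigar = r$cigar, pairs = r$pairs,
                 raw_score = r$score, bit_score = bit,
                 corrected_bits = corrected,
                 n_ident = n_ident, aln_len = aln_len),
            class = "fs_alignment")
}

reverse_string <- function(s) paste(rev(seq_chars(s)), collapse = "")

cigar_length <- function(cigar) {
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  sum(n)
}

#' @export
print.fs_alignment <- function(x, ...) {
  cat(sprintf("<fs_alignment %s vs %s: bits %.1f (corrected %.1f), q %d-%d, t %d-%d, %s>\n",
              x$query_id, x$target_id, x$bit_score, x$corrected_bits,
              x$q_start, x$q_end, x$t_start, x$t_end, x$cigar))
  invisible(x)
}
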