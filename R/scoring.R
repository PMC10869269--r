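# Alignment quality scores: superposition-free LDDT over 15 A neighborhoods
# with spatial hashing, TM-score by iterative fragment-seeded Kabsch
# superposition on a fixed alignment, and the structural bit score used for
# ranking.

#' LDDT parameters
#'
#' @param radius Neighborhood radius (Angstrom).
#' @param thresholds Distance-difference thresholds (Angstrom, increasing).
#' @param denominator_mode `"aligned_neighbors"` divides each residue's score
#'   by the number of *aligned* neighbors within the radius;
#'   `"all_neighbors"` divides by the total number of neighbors (unaligned
#'   ones scoring zero), which penalizes non-compact models.
#' @export
lddt_params <- function(radius = 15, thresholds = c(0.5, 1, 2, 4),
                        denominator_mode = c("aligned_neighbors",
                                             "all_neighbors")) {
  stopifnot(all(diff(thresholds) > 0))
  structure(list(radius = radius, thresholds = thresholds,
                 denominator_mode = match.arg(denominator_mode)),
            class = "fs_lddt_params")
}

#' Per-pair LDDT contribution of a distance difference
#'
#' The four-threshold transform `0.25 * ((d < 0.5) + (d < 1) + (d < 2) +
#' (d < 4))`: a 3.0 Angstrom difference scores 0.25, a difference below 0.5
#' scores 1.
#'
#' @param d Absolute distance difference(s), Angstrom.
#' @param thresholds Thresholds (Angstrom).
#' @return Scores in `[0, 1]`.
#' @export
lddt_pair_score <- function(d, thresholds = c(0.5, 1, 2, 4)) {
  rowMeans(outer(d, thresholds, "<"))
}

#' Alignment LDDT with spatial hashing
#'
#' Query Calpha atoms are hashed into grid cells whose edge equals the
#' neighborhood radius; neighbors of each aligned residue are gathered from
#' the 27 adjacent cells. For each aligned query residue i and each aligned
#' neighbor j within the radius, the query and target inter-residue distances
#' are subtracted and the difference transformed with [lddt_pair_score]; the
#' per-residue score is the mean over neighbors and the alignment LDDT the
#' mean of these means. Residues with no neighbor in the radius are skipped.
#'
#' @param q_coords,t_coords Lx3 Calpha coordinate matrices.
#' @param alignment 2-column matrix of aligned (query, target) residue
#'   indices.
#' @param params An [lddt_params].
#' @return List with `per_residue` (named by query residue index) and `mean`.
#' @export
alignment_lddt <- function(q_coords, t_coords, alignment,
                           params = lddt_params()) {
  alignment <- as.matrix(alignment)
  if (nrow(alignment) == 0) stop("undefined-score error: empty alignment")
  qi <- alignment[, 1]
  ti <- alignment[, 2]
  r <- params$radius
  # integer cell ids on a shifted grid; neighbors gathered from the 27
  # adjacent cells via precomputed per-cell residue lists
  cells <- floor(q_coords / r)
  cmin <- apply(cells, 2, min)
  dims <- apply(cells, 2, max) - cmin + 3L
  cid <- (cells[, 1] - cmin[1] + 1) +
    dims[1] * (cells[, 2] - cmin[2] + 1) +
    dims[1] * dims[2] * (cells[, 3] - cmin[3] + 1)
  cellmap <- split(seq_len(nrow(q_coords)), cid)
  off3 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  oid <- off3[, 1] + dims[1] * off3[, 2] + dims[1] * dims[2] * off3[, 3]
  neigh_of_cell <- lapply(unique(cid), function(cc)
    unlist(cellmap[as.character(cc + oid)], use.names = FALSE))
  names(neigh_of_cell) <- unique(cid)
  t_of_q <- rep(NA_integer_, nrow(q_coords))
  t_of_q[qi] <- ti
  per <- rep(NA_real_, length(qi))
  for (ai in seq_along(qi)) {
    i <- qi[ai]
    neigh <- neigh_of_cell[[as.character(cid[i])]]
    neigh <- neigh[neigh != i]
    if (!length(neigh)) next
    dq <- sqrt(colSums((t(q_coords[neigh, , drop = FALSE]) - q_coords[i, ])^2))
    neigh <- neigh[dq <= r]
    dq <- dq[dq <= r]
    if (!length(neigh)) next
    aligned <- !is.na(t_of_q[neigh])
    n_all <- length(neigh)
    neigh_a <- neigh[aligned]
    if (!length(neigh_a)) {
      per[ai] <- if (params$denominator_mode == "all_neighbors") 0 else NA_real_
      next
    }
    dt <- sqrt(colSums((t(t_coords[t_of_q[neigh_a], , drop = FALSE]) -
                          t_coords[t_of_q[i], ])^2))
    s <- lddt_pair_score(abs(dq[aligned] - dt), params$thresholds)
    per[ai] <- if (params$denominator_mode == "all_neighbors")
      sum(s) / n_all else mean(s)
  }
  names(per) <- qi
  list(per_residue = per, mean = mean(per, na.rm = TRUE))
}

# d0 normalization of the TM-score, clamped below at 0.5
tm_d0 <- function(L) max(0.5, 1.24 * (max(L, 16) - 15)^(1 / 3) - 1.8)

#' TM-score of a fixed alignment
#'
#' Seeks the optimal superposition for the given residue alignment by Kabsch
#' superposition seeded from contiguous alignment fragments (lengths L, L/2,
#' L/4), each refined by iterating inclusion of pairs within a distance
#' cutoff (schedule 8, 6, 4.5, 3.5 Angstrom) to a fixed point; the best
#' resulting TM-score is kept. `TM = 1/L_norm * sum 1 / (1 + (d_i/d0)^2)`
#' over aligned pairs with `d0(L) = 1.24 (L - 15)^(1/3) - 1.8` (clamped at
#' 0.5), normalized by the query length, the target length, and their
#' average.
#'
#' @param q_coords,t_coords Calpha coordinate matrices of the two chains.
#' @param alignment 2-column matrix of aligned residue indices (>= 3 rows).
#' @return List `tm_query`, `tm_target`, `tm_avg`, plus the superposition
#'   (`R`, `t` mapping target onto query frame) and per-pair distances `d`.
#' @export
tm_score <- function(q_coords, t_coords, alignment) {
  alignment <- as.matrix(alignment)
  n <- nrow(alignment)
  if (n < 3) stop("need at least 3 aligned pairs")
  qa <- q_coords[alignment[, 1], , drop = FALSE]
  ta <- t_coords[alignment[, 2], , drop = FALSE]
  Lq <- nrow(q_coords)
  Lt <- nrow(t_coords)
  d0q <- tm_d0(Lq)
  seeds <- list()
  for (frac in c(1, 2, 4)) {
    len <- max(3, n %/% frac)
    starts <- unique(c(seq(1, n - len + 1, by = len), n - len + 1))
    for (s in starts) seeds[[length(seeds) + 1]] <- s:(s + len - 1)
  }
  best <- -Inf
  best_rt <- NULL
  for (seed in seeds) {
    rt <- kabsch(ta[seed, , drop = FALSE], qa[seed, , drop = FALSE])
    # refine through the cutoff schedule, each stage iterated to a fixed
    # point of the included-pair set
    prev <- integer(0)
    for (cutoff in c(8, 6, 4.5, 3.5)) {
      for (iter in 1:8) {
        d <- sqrt(rowSums((apply_rigid(ta, rt) - qa)^2))
        inc <- which(d < cutoff)
        if (length(inc) < 3 || identical(inc, prev)) break
        prev <- inc
        rt <- kabsch(ta[inc, , drop = FALSE], qa[inc, , drop = FALSE])
      }
      d <- sqrt(rowSums((apply_rigid(ta, rt) - qa)^2))
      tm <- sum(1 / (1 + (d / d0q)^2)) / Lq
      if (tm > best) { best <- tm; best_rt <- rt }
    }
    # remaining seeds cannot improve a near-perfect superposition
    if (best > 0.95) break
  }
  d <- sqrt(rowSums((apply_rigid(ta, best_rt) - qa)^2))
  tm_q <- sum(1 / (1 + (d / tm_d0(Lq))^2)) / Lq
  tm_t <- sum(1 / (1 + (d / tm_d0(Lt))^2)) / Lt
  list(tm_query = tm_q, tm_target = tm_t, tm_avg = (tm_q + tm_t) / 2,
       R = best_rt$R, t = best_rt$t, d = d)
}

#' Structural bit score
#'
#' The ranking statistic: the corrected alignment bit score multiplied by the
#' geometric mean of the alignment TM-score and the mean alignment LDDT.
#'
#' @param corrected_bits Reverse-corrected Smith-Waterman bit score.
#' @param tm_avg Alignment TM-score in `[0, 1]`.
#' @param lddt_mean Mean alignment LDDT in `[0, 1]`.
#' @export
structural_bit_score <- function(corrected_bits, tm_avg, lddt_mean) {
  if (tm_avg < 0 || lddt_mean < 0) stop("tm and lddt must be non-negative")
  corrected_bits * sqrt(tm_avg * lddt_mean)
}
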