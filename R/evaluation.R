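# Benchmark metrics: per-query sensitivity up to the first false positive
# (ROC1), group-size-weighted precision-recall, per-residue coverage for
# multi-domain sets, and reference-based / reference-free alignment quality.

level_cols <- c(family = "family", superfamily = "superfamily", fold = "fold")

# classify hits at a level: "tp", "fp" (different fold) or "ignore"
classify_hits <- function(qlab, tlabs, level) {
  tp <- switch(level,
    family = tlabs$family == qlab$family,
    superfamily = tlabs$superfamily == qlab$superfamily &
      tlabs$family != qlab$family,
    fold = tlabs$fold == qlab$fold & tlabs$superfamily != qlab$superfamily)
  fp <- tlabs$fold != qlab$fold
  ifelse(tp, "tp", ifelse(fp, "fp", "ignore"))
}

possible_tps <- function(qid, labels, level) {
  qlab <- labels[labels$entry_id == qid, ]
  others <- labels[labels$entry_id != qid, ]
  sum(classify_hits(qlab, others, level) == "tp")
}

sort_hits <- function(hits) {
  ord <- order(-hits$score,
               if (!is.null(hits$evalue)) hits$evalue else seq_len(nrow(hits)),
               hits$target_id)
  hits[ord, , drop = FALSE]
}

#' Per-query ROC1 sensitivity
#'
#' For each query, hits are sorted by score (descending; ties by E-value
#' then target id), self-hits removed, and the sensitivity computed as the
#' number of true positives before the first false positive divided by the
#' number of possible true positives at the level. True positives at the
#' family / superfamily / fold level are same-family, same-superfamily-but-
#' not-family and same-fold-but-not-superfamily targets; false positives are
#' different-fold targets; everything else is ignored. Queries with no
#' possible true positive at the level are excluded.
#'
#' @param hits data.frame with columns `query_id`, `target_id`, `score`
#'   (and optionally `evalue` for tie-breaks).
#' @param labels data.frame: `entry_id`, `family`, `superfamily`, `fold`.
#' @param level `"family"`, `"superfamily"` or `"fold"`.
#' @return List with `per_query` (named vector) and `mean`.
#' @export
roc1_sensitivity <- function(hits, labels, level = "family") {
  level <- match.arg(level, names(level_cols))
  queries <- unique(hits$query_id)
  missing <- setdiff(c(queries, hits$target_id), labels$entry_id)
  if (length(missing))
    stop("entries absent from labels: ", paste(missing, collapse = ", "))
  per <- numeric(0)
  for (qid in queries) {
    npos <- possible_tps(qid, labels, level)
    if (npos == 0) next
    h <- sort_hits(hits[hits$query_id == qid & hits$target_id != qid, ,
                        drop = FALSE])
    qlab <- labels[labels$entry_id == qid, ]
    tl <- labels[match(h$target_id, labels$entry_id), ]
    cls <- if (nrow(h)) classify_hits(qlab, tl, level) else character(0)
    ntp <- 0
    for (c_ in cls) {
      if (c_ == "fp") break
      if (c_ == "tp") ntp <- ntp + 1
    }
    per[qid] <- ntp / npos
  }
  list(per_query = per, mean = if (length(per)) mean(per) else NaN)
}

#' Group-size-weighted precision-recall curve
#'
#' Pooled hits are sorted by score; at each score threshold precision and
#' recall are computed with every TP, FP and FN count weighted by the
#' reciprocal of the query's group size at the level, so large families do
#' not dominate.
#'
#' @inheritParams roc1_sensitivity
#' @return data.frame with `score`, `precision`, `recall` (one row per
#'   distinct threshold, loosening downwards).
#' @export
weighted_precision_recall <- function(hits, labels, level = "family") {
  level <- match.arg(level, names(level_cols))
  lc <- level_cols[[level]]
  grp_size <- table(labels[[lc]])
  h <- hits[hits$query_id != hits$target_id, , drop = FALSE]
  h <- sort_hits(h)
  qlab <- labels[match(h$query_id, labels$entry_id), ]
  tlab <- labels[match(h$target_id, labels$entry_id), ]
  cls <- character(nrow(h))
  for (r in seq_len(nrow(h)))
    cls[r] <- classify_hits(qlab[r, ], tlab[r, ], level)
  w <- 1 / as.vector(grp_size[qlab[[lc]]])
  keep <- cls != "ignore"
  h <- h[keep, , drop = FALSE]
  cls <- cls[keep]
  w <- w[keep]
  # total weighted possible TPs (for recall denominator)
  total_w_tp <- 0
  for (qid in unique(hits$query_id)) {
    npos <- possible_tps(qid, labels, level)
    gsz <- grp_size[labels[[lc]][labels$entry_id == qid]]
    total_w_tp <- total_w_tp + npos / as.vector(gsz)
  }
  cw_tp <- cumsum(w * (cls == "tp"))
  cw_fp <- cumsum(w * (cls == "fp"))
  prec <- cw_tp / pmax(cw_tp + cw_fp, 1e-300)
  rec <- if (total_w_tp > 0) cw_tp / total_w_tp else rep(0, length(cw_tp))
  data.frame(score = h$score, precision = prec, recall = rec)
}

#' Per-residue query coverage
#'
#' Matches are labeled TP (alignment LDDT at least `tp_lddt`), FP (below
#' `fp_lddt`) or ignored. Per query the ranked match list is truncated at
#' the first FP; coverage at x is the fraction of query residues covered by
#' at least x of the remaining TP alignments.
#'
#' @param matches data.frame: `query_id`, `q_start`, `q_end` (1-based
#'   inclusive), `lddt`, `score`, and `query_length`.
#' @param x_max Largest coverage multiplicity reported.
#' @param tp_lddt,fp_lddt LDDT class thresholds.
#' @return data.frame `query_id`, `x`, `coverage`.
#' @export
per_residue_coverage <- function(matches, x_max = 5, tp_lddt = 0.6,
                                 fp_lddt = 0.25) {
  out <- NULL
  for (qid in unique(matches$query_id)) {
    m <- matches[matches$query_id == qid, , drop = FALSE]
    m <- m[order(-m$score), , drop = FALSE]
    L <- m$query_length[1]
    cover <- integer(L)
    for (r in seq_len(nrow(m))) {
      if (m$lddt[r] < fp_lddt) break
      if (m$lddt[r] < tp_lddt) next
      cover[m$q_start[r]:m$q_end[r]] <- cover[m$q_start[r]:m$q_end[r]] + 1L
    }
    for (x in seq_len(x_max))
      out <- rbind(out, data.frame(query_id = qid, x = x,
                                   coverage = mean(cover >= x)))
  }
  out
}

#' Alignment quality against a reference or reference-free
#'
#' Reference-based mode scores a predicted alignment against a curated
#' reference alignment: sensitivity is the fraction of reference residue
#' pairs correctly reproduced and precision the fraction of predicted pairs
#' present in the reference. Reference-free mode classifies aligned residues
#' by their residue-wise LDDT (TP at >= 0.6): sensitivity = TP residues /
#' query length, precision = TP residues / alignment length.
#'
#' @param alignment 2-column matrix of predicted aligned residue index pairs
#'   (`NULL` for a missing alignment, rated sensitivity 0).
#' @param mode `"reference_based"` or `"reference_free"`.
#' @param reference 2-column matrix of reference pairs (reference_based).
#' @param per_residue_lddt Residue-wise LDDT of the aligned query residues
#'   (reference_free).
#' @param query_length Query length (reference_free).
#' @param tp_lddt TP threshold on the residue-wise LDDT.
#' @return List of class `fs_quality`: `sensitivity`, `precision`, `f1`.
#' @export
alignment_quality <- function(alignment,
                              mode = c("reference_based", "reference_free"),
                              reference = NULL, per_residue_lddt = NULL,
                              query_length = NULL, tp_lddt = 0.6) {
  mode <- match.arg(mode)
  if (mode == "reference_based") {
    if (is.null(reference) || nrow(as.matrix(reference)) == 0)
      stop("empty reference")
    ref <- paste(reference[, 1], reference[, 2])
    if (is.null(alignment) || nrow(as.matrix(alignment)) == 0) {
      sens <- 0; prec <- 0
    } else {
      prd <- paste(alignment[, 1], alignment[, 2])
      ncorrect <- length(intersect(ref, prd))
      sens <- ncorrect / length(ref)
      prec <- ncorrect / length(prd)
    }
  } else {
    if (is.null(per_residue_lddt) || is.null(query_length))
      stop("reference_free mode needs per_residue_lddt and query_length")
    ntp <- sum(per_residue_lddt >= tp_lddt, na.rm = TRUE)
    sens <- ntp / query_length
    prec <- ntp / length(per_residue_lddt)
  }
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  structure(list(sensitivity = sens, precision = prec, f1 = f1),
            class = "fs_quality")
}
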