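# High-level driver: build a searchable database from chains or structure
# files, run the prefilter + alignment + scoring pipeline, and emit the
# tabular (BLAST m8-like) results.

#' Build database entries from chains or structure files
#'
#' Reconstructs missing Cbeta atoms, encodes every chain with the supplied
#' alphabet and returns the list of [fs_entry] records.
#'
#' @param x List of [fs_chain] objects, or character vector of PDB/mmCIF
#'   paths.
#' @param alphabet An `fs_alphabet`.
#' @param vc_params A [virtual_center_params].
#' @return List of [fs_entry].
#' @export
create_database <- function(x, alphabet,
                            vc_params = virtual_center_params()) {
  if (is.character(x)) {
    chains <- list()
    for (path in x) {
      parsed <- parse_structure(path)
      base <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                  ignore.case = TRUE)
      for (ch in parsed) {
        id <- if (length(parsed) > 1) paste0(base, "_", ch$chain_id) else base
        ch$chain_id <- id
        chains[[id]] <- ch
      }
    }
    x <- chains
  }
  entries <- vector("list", length(x))
  for (i in seq_along(x)) {
    ch <- reconstruct_cbeta(x[[i]])
    entries[[i]] <- fs_entry(ch$chain_id, paste(ch$aa, collapse = ""),
                             encode_structure(ch, alphabet, vc_params),
                             ch$ca)
  }
  entries
}

#' Search a query database against a target database
#'
#' Runs the similar-k-mer prefilter (optionally bypassed), computes local
#' combined-score alignments with reverse correction for the surviving
#' targets, scores each alignment with LDDT, TM-score and the structural bit
#' score, and (when models are supplied) appends E-values and TP
#' probabilities. Hits are ranked by structural bit score (ties by E-value,
#' then target id).
#'
#' @param queries,targets Lists of [fs_entry].
#' @param matrices `list(tdi = , aa = )` of `fs_submat` (`aa` defaults to
#'   BLOSUM62).
#' @param pf_params A [prefilter_params].
#' @param aln_params An [alignment_params].
#' @param lddt_par An [lddt_params].
#' @param evalue_model Optional `fs_evalue_model`.
#' @param mixtures Optional `fs_gamma_pair` for TP probabilities.
#' @param bypass_prefilter Align every query against every target.
#' @param max_evalue Drop hits with larger E-value (ignored without model).
#' @return data.frame with columns query, target, fident, alnlen, mismatch,
#'   gapopen, qstart, qend, tstart, tend, evalue, bits, lddt, qtmscore,
#'   ttmscore, prob, plus `score` (structural bits, the ranking key).
#' @export
search_database <- function(queries, targets, matrices,
                            pf_params = prefilter_params(),
                            aln_params = alignment_params(),
                            lddt_par = lddt_params(),
                            evalue_model = NULL, mixtures = NULL,
                            bypass_prefilter = FALSE, max_evalue = Inf) {
  if (is.null(matrices$aa)) matrices$aa <- aa_matrix_blosum62()
  index <- if (!bypass_prefilter) build_kmer_index(targets, pf_params)
  tmap <- stats::setNames(seq_along(targets),
                          vapply(targets, `[[`, "", "entry_id"))
  rows <- list()
  for (q in queries) {
    cand <- if (bypass_prefilter) names(tmap) else
      prefilter(q, index, matrices, pf_params, aln_params)$target_id
    feats <- if (!is.null(evalue_model)) evalue_features(q)
    cbc <- query_cbc(q, matrices, aln_params)
    for (tid in cand) {
      t <- targets[[tmap[[tid]]]]
      al <- align_local(q, t, matrices, aln_params, cbc = cbc)
      if (is.null(al$pairs) || nrow(al$pairs) < 3) next
      ld <- alignment_lddt(q$ca, t$ca, al$pairs, lddt_par)
      tm <- tm_score(q$ca, t$ca, al$pairs)
      sbits <- structural_bit_score(max(al$corrected_bits, 0), tm$tm_avg,
                                    ld$mean)
      ev <- if (!is.null(evalue_model))
        evalue(evalue_model, feats, al$corrected_bits, length(targets))
      else NA_real_
      if (!is.na(ev) && ev > max_evalue) next
      prob <- if (!is.null(mixtures)) p_tp(sbits, mixtures) else NA_real_
      rows[[length(rows) + 1]] <- list(
        query = q$entry_id, target = tid,
        fident = if (al$aln_len > 0) al$n_ident / al$aln_len else 0,
        alnlen = al$aln_len,
        mismatch = nrow(al$pairs) - al$n_ident,
        gapopen = count_gap_opens(al$cigar),
        qstart = al$q_start, qend = al$q_end,
        tstart = al$t_start, tend = al$t_end,
        evalue = ev, bits = al$corrected_bits,
        lddt = ld$mean, qtmscore = tm$tm_query, ttmscore = tm$tm_target,
        prob = prob, score = sbits)
    }
  }
  cols <- c("query", "target", "fident", "alnlen", "mismatch", "gapopen",
            "qstart", "qend", "tstart", "tend", "evalue", "bits", "lddt",
            "qtmscore", "ttmscore", "prob", "score")
  if (!length(rows)) {
    res <- as.data.frame(stats::setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 15)), cols))
    return(res)
  }
  res <- as.data.frame(stats::setNames(
    lapply(cols, function(cn) unlist(lapply(rows, `[[`, cn))), cols))
  ev_key <- ifelse(is.na(res$evalue), Inf, res$evalue)
  res[order(res$query, -res$score, ev_key, res$target), , drop = FALSE]
}

count_gap_opens <- function(cigar) {
  if (is.na(cigar)) return(0L)
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  sum(ops != "M")
}

#' Write search results as a tab-separated file
#'
#' @param results data.frame from [search_database].
#' @param path Output path.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
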