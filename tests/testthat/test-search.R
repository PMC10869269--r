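# Prefilter (k-mer index, similar-k-mer enumeration, double-diagonal rule,
# ungapped gate), compositional bias correction and local alignment.

mk_entry <- function(id, tdi, aa = NULL, L = nchar(tdi)) {
  if (is.null(aa)) aa <- strrep("A", L)
  fs_entry(id, aa, tdi, cbind(3.8 * seq_len(L), 0, 0))
}

random_entry <- function(id, L, seed) {
  set.seed(seed)
  mk_entry(id, paste(sample(LETTERS[1:20], L, TRUE), collapse = ""),
           paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], L, TRUE),
                 collapse = ""))
}

test_that("the k-mer index covers exactly the X-free windows", {
  idx <- build_kmer_index(list(mk_entry("t1", "AAAAAAA")),
                          prefilter_params(k = 6))
  expect_equal(nrow(idx$kmers[["AAAAAA"]]), 2)
  idx2 <- build_kmer_index(list(mk_entry("t2", "AAAA")),
                           prefilter_params(k = 6))
  expect_equal(length(ls(idx2$kmers)), 0)
  # every window of this sequence touches the X: nothing is indexed
  idx3 <- build_kmer_index(list(mk_entry("t3", "AAAXAAAAA")),
                           prefilter_params(k = 6))
  expect_equal(length(ls(idx3$kmers)), 0)
  # one residue longer: exactly the X-free window at positions 5..10
  idx4 <- build_kmer_index(list(mk_entry("t4", "AAAXAAAAAA")),
                           prefilter_params(k = 6))
  expect_equal(ls(idx4$kmers), "AAAAAA")
  expect_equal(idx4$kmers[["AAAAAA"]][1, ], c(1, 5))
})

test_that("similar k-mers always contain the k-mer at self threshold and
           the -Inf limit enumerates the whole space", {
  mat <- fx_tdi_matrix()
  km <- "ADFKLM"
  self <- sum(mat$scores_int[cbind(strsplit(km, "")[[1]],
                                   strsplit(km, "")[[1]])])
  s <- similar_kmers(km, mat, self)
  expect_true(km %in% s)
  expect_equal(length(similar_kmers("AB", mat, -Inf)), 400)
})

test_that("similar k-mer enumeration equals exhaustive search at k = 3", {
  mat <- fx_tdi_matrix()
  set.seed(5)
  all3 <- apply(expand.grid(LETTERS[1:20], LETTERS[1:20], LETTERS[1:20]),
                1, paste, collapse = "")
  for (case_ in 1:3) {
    km <- paste(sample(LETTERS[1:20], 3, TRUE), collapse = "")
    thr <- sum(mat$scores_int[cbind(strsplit(km, "")[[1]],
                                    strsplit(km, "")[[1]])]) - 6
    got <- sort(similar_kmers(km, mat, thr))
    q <- strsplit(km, "")[[1]]
    sc <- vapply(all3, function(w)
      sum(mat$scores_int[cbind(q, strsplit(w, "")[[1]])]), 0)
    expect_identical(got, sort(names(sc)[sc >= thr]))
  }
})

test_that("raising the similarity threshold shrinks the k-mer set", {
  mat <- fx_tdi_matrix()
  km <- "DDKKLL"
  thr0 <- sum(mat$scores_int[cbind(strsplit(km, "")[[1]],
                                   strsplit(km, "")[[1]])]) - 10
  prev <- similar_kmers(km, mat, thr0)
  for (d in c(6, 3, 0)) {
    cur <- similar_kmers(km, mat, thr0 + 10 - d)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("a query finds itself on diagonal 0 and an isolated single k-mer
           match is rejected by the double-match rule", {
  mat <- fx_tdi_matrix()
  matrices <- list(tdi = mat, aa = aa_matrix_blosum62())
  db <- fx_db()
  q <- db[[1]]
  idx <- build_kmer_index(list(q), prefilter_params())
  hits <- prefilter(q, idx, matrices)
  expect_equal(hits$target_id[1], q$entry_id)
  expect_equal(hits$diagonal[1], 0)
  # one shared k-mer inside an otherwise alien sequence: single match only
  core <- substr(q$tdi_seq, 3, 8)
  alien <- mk_entry("alien", paste0("XX", core, "XX"),
                    aa = strrep("G", nchar(core) + 4))
  idx2 <- build_kmer_index(list(alien),
                           prefilter_params(kmer_sim_threshold = 1e6))
  # absolute threshold so high that only exact self-matches qualify
  hits2 <- prefilter(q, idx2, matrices,
                     prefilter_params(kmer_sim_threshold =
                                        sum(mat$scores_int[cbind(
                                          strsplit(core, "")[[1]],
                                          strsplit(core, "")[[1]])])))
  expect_equal(nrow(hits2), 0)
})

test_that("prefilter equals a brute-force oracle on the fixture database", {
  mat <- fx_tdi_matrix()
  matrices <- list(tdi = mat, aa = aa_matrix_blosum62())
  db <- fx_db()
  pf <- prefilter_params()
  ap <- alignment_params()
  idx <- build_kmer_index(db, pf)
  for (qi in c(1, 33)) {
    q <- db[[qi]]
    got <- prefilter(q, idx, matrices, pf, ap)
    # oracle: enumerate every similar-k-mer match explicitly
    q3 <- strsplit(q$tdi_seq, "")[[1]]
    L <- length(q3)
    matches <- list()
    for (p in seq_len(L - pf$k + 1)) {
      w <- paste(q3[p:(p + pf$k - 1)], collapse = "")
      if (grepl("X", w)) next
      sims <- similar_kmers(w, mat, foldscan:::kmer_threshold(w, mat, pf))
      for (ti in seq_along(db)) {
        t3 <- strsplit(db[[ti]]$tdi_seq, "")[[1]]
        if (length(t3) < pf$k) next
        for (tp in seq_len(length(t3) - pf$k + 1)) {
          tw <- paste(t3[tp:(tp + pf$k - 1)], collapse = "")
          if (tw %in% sims)
            matches[[length(matches) + 1]] <- c(ti, p - tp, p)
        }
      }
    }
    mm <- unique(do.call(rbind, matches))
    keep <- NULL
    for (ti in unique(mm[, 1])) {
      sub <- mm[mm[, 1] == ti, , drop = FALSE]
      dias <- unique(sub[, 2])
      double <- dias[vapply(dias, function(d)
        length(unique(sub[sub[, 2] == d, 3])) >= 2, TRUE)]
      if (!length(double)) next
      cbc <- foldscan:::query_cbc(q, matrices, ap)
      S <- foldscan:::combined_score_matrix(q, db[[ti]], matrices, ap, cbc)
      sc <- vapply(double, function(d)
        foldscan:::diagonal_best_segment(S, d), 0)
      if (max(sc) / 2 >= pf$ungapped_min_bits)
        keep <- rbind(keep, data.frame(target_id = db[[ti]]$entry_id,
                                       ungapped_bits = max(sc) / 2))
    }
    keep <- keep[order(-keep$ungapped_bits, keep$target_id), , drop = FALSE]
    expect_equal(got$target_id, keep$target_id)
    expect_equal(got$ungapped_bits, keep$ungapped_bits, tolerance = 1e-9)
  }
})

test_that("compositional bias correction matches a windowed-mean oracle", {
  mat <- fx_tdi_matrix()
  # uniform sequence: offset is minus the self score everywhere
  off <- composition_bias_correction("DDDDDDDD", mat, window = 40)
  expect_equal(off, rep(-mat$scores["D", "D"], 8))
  # alternating letters vs direct computation
  s <- strsplit("ABABABABABAB", "")[[1]]
  off2 <- composition_bias_correction(paste(s, collapse = ""), mat,
                                      window = 4)
  want <- vapply(seq_along(s), function(p) {
    idx <- setdiff(max(1, p - 2):min(length(s), p + 2), p)
    -mean(mat$scores[s[p], s[idx]])
  }, 0)
  expect_equal(off2, want, tolerance = 1e-12)
  # window larger than the sequence: finite offsets
  off3 <- composition_bias_correction("ABC", mat, window = 400)
  expect_true(all(is.finite(off3)))
})

test_that("self alignment covers the full length and equals the direct sum
           of weighted, bias-corrected self scores", {
  db <- fx_db()
  matrices <- fx_matrices()
  ap <- alignment_params(use_reverse_correction = FALSE)
  q <- db[[5]]
  al <- align_local(q, q, matrices, ap)
  L <- nchar(q$aa_seq)
  expect_equal(al$q_start, 1)
  expect_equal(al$q_end, L)
  expect_equal(al$cigar, paste0(L, "M"))
  cbc <- foldscan:::query_cbc(q, matrices, ap)
  qa <- strsplit(q$aa_seq, "")[[1]]
  q3 <- strsplit(q$tdi_seq, "")[[1]]
  want <- sum(ap$w_aa * (matrices$aa$scores[cbind(qa, qa)] + cbc$aa) +
                ap$w_3di * (matrices$tdi$scores[cbind(q3, q3)] + cbc$tdi))
  expect_equal(al$raw_score, want, tolerance = 1e-9)
  expect_equal(al$bit_score, want / 2, tolerance = 1e-9)
  expect_equal(al$n_ident, L)
})

test_that("a palindromic query has zero reverse-corrected bits", {
  pal3 <- "ADKKDA"
  pala <- "GHLLHG"
  q <- mk_entry("pal", pal3, pala)
  t <- random_entry("t", 30, 4)
  al <- align_local(q, t, fx_matrices(), alignment_params())
  expect_equal(al$corrected_bits, 0, tolerance = 1e-9)
})

test_that("the alignment kernel matches a textbook affine-gap DP oracle on
           random pairs", {
  matrices <- fx_matrices()
  ap <- alignment_params(use_reverse_correction = FALSE)
  for (case_ in 1:30) {
    q <- random_entry(paste0("q", case_), sample(20:45, 1), 100 + case_)
    t <- random_entry(paste0("t", case_), sample(20:45, 1), 200 + case_)
    al <- align_local(q, t, matrices, ap)
    cbc <- foldscan:::query_cbc(q, matrices, ap)
    S <- foldscan:::combined_score_matrix(q, t, matrices, ap, cbc)
    expect_equal(al$raw_score, sw_oracle(S, ap$gap_open, ap$gap_extend),
                 tolerance = 1e-9)
    # the reported path attains the reported score
    if (!is.null(al$pairs) && nrow(al$pairs)) {
      path_score <- sum(S[al$pairs])
      gaps <- nrow(al$pairs)  # recompute gap cost from the cigar
      ops <- regmatches(al$cigar, gregexpr("[0-9]+[MID]", al$cigar))[[1]]
      gapcost <- 0
      for (op in ops) {
        n <- as.integer(sub("[MID]", "", op))
        if (grepl("[ID]", op))
          gapcost <- gapcost + ap$gap_open + (n - 1) * ap$gap_extend
      }
      expect_equal(path_score - gapcost, al$raw_score, tolerance = 1e-9)
    }
  }
})

test_that("alignment score is symmetric in query and target when the bias
           correction is disabled", {
  matrices <- fx_matrices()
  ap <- alignment_params(cbc_window = 0, use_reverse_correction = FALSE)
  for (case_ in 1:5) {
    q <- random_entry("q", 30, 300 + case_)
    t <- random_entry("t", 34, 400 + case_)
    a1 <- align_local(q, t, matrices, ap)
    a2 <- align_local(t, q, matrices, ap)
    expect_equal(a1$raw_score, a2$raw_score, tolerance = 1e-9)
  }
})

test_that("prefilter recovers high-scoring family hits", {
  db <- fx_db()
  matrices <- fx_matrices()
  labels <- fx_benchmark()$labels
  pf <- prefilter_params()
  idx <- build_kmer_index(db, pf)
  found <- total <- 0
  for (qi in seq(1, 40, by = 4)) {
    q <- db[[qi]]
    cand <- prefilter(q, idx, matrices, pf)$target_id
    for (t in db) {
      if (t$entry_id == q$entry_id) next
      al <- align_local(q, t, matrices)
      if (al$corrected_bits >= 30) {
        total <- total + 1
        if (t$entry_id %in% cand) found <- found + 1
      }
    }
  }
  expect_gt(total, 10)
  expect_gte(found / total, 0.9)
})
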