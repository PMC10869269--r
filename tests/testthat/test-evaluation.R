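# Benchmark metrics: ROC1 sensitivity, weighted precision-recall,
# per-residue coverage and alignment quality.

toy_labels <- data.frame(
  entry_id = c("q", paste0("t", 1:6)),
  family = c("f1", "f1", "f1", "f1", "f1", "g1", "h1"),
  superfamily = c("sf1", "sf1", "sf1", "sf1", "sf1", "sf2", "sf3"),
  fold = c("F1", "F1", "F1", "F1", "F1", "F2", "F3"))

test_that("ROC1 counts true positives up to the first false positive", {
  # ranking TP TP FP TP with 4 possible TPs -> 0.5
  hits <- data.frame(query_id = "q",
                     target_id = c("t1", "t2", "t5", "t3"),
                     score = c(40, 30, 20, 10))
  r <- roc1_sensitivity(hits, toy_labels, "family")
  expect_equal(unname(r$per_query["q"]), 0.5)
  # no FP in the list and all four TPs present -> 1
  hits2 <- data.frame(query_id = "q",
                      target_id = c("t1", "t2", "t3", "t4"),
                      score = c(40, 30, 20, 10))
  expect_equal(roc1_sensitivity(hits2, toy_labels, "family")$mean, 1)
  # self-hits are ignored
  hits3 <- rbind(data.frame(query_id = "q", target_id = "q", score = 99),
                 hits2)
  expect_equal(roc1_sensitivity(hits3, toy_labels, "family")$mean, 1)
  expect_error(roc1_sensitivity(
    data.frame(query_id = "nope", target_id = "t1", score = 1),
    toy_labels), "absent")
})

test_that("ROC1 equals a direct scan oracle on random rankings", {
  set.seed(8)
  labels <- data.frame(
    entry_id = paste0("e", 1:30),
    family = paste0("f", rep(1:6, each = 5)),
    superfamily = paste0("sf", rep(1:3, each = 10)),
    fold = paste0("F", rep(1:3, each = 10)))
  for (case_ in 1:100) {
    q <- sample(labels$entry_id, 1)
    tg <- sample(setdiff(labels$entry_id, q), 12)
    hits <- data.frame(query_id = q, target_id = tg,
                       score = runif(12))
    lvl <- sample(c("family", "superfamily", "fold"), 1)
    got <- roc1_sensitivity(hits, labels, lvl)
    # oracle: sort, scan
    ord <- tg[order(-hits$score, hits$target_id)]
    ql <- labels[labels$entry_id == q, ]
    ntp <- 0
    for (t in ord) {
      tl <- labels[labels$entry_id == t, ]
      is_tp <- switch(lvl,
        family = tl$family == ql$family,
        superfamily = tl$superfamily == ql$superfamily &
          tl$family != ql$family,
        fold = tl$fold == ql$fold & tl$superfamily != ql$superfamily)
      if (tl$fold != ql$fold) break
      if (is_tp) ntp <- ntp + 1
    }
    allt <- labels[labels$entry_id != q, ]
    npos <- sum(switch(lvl,
      family = allt$family == ql$family,
      superfamily = allt$superfamily == ql$superfamily &
        allt$family != ql$family,
      fold = allt$fold == ql$fold & allt$superfamily != ql$superfamily))
    if (npos == 0) {
      expect_false(q %in% names(got$per_query))
    } else {
      expect_equal(unname(got$per_query[q]), ntp / npos)
    }
  }
})

test_that("weighted precision-recall reduces to unweighted for singleton
           groups and matches a hand-computed weighted example", {
  labels1 <- data.frame(entry_id = c("q", "a", "b", "c"),
                        family = c("fq", "fq", "fb", "fc"),
                        superfamily = c("s1", "s1", "s2", "s3"),
                        fold = c("F1", "F1", "F2", "F3"))
  hits <- data.frame(query_id = "q", target_id = c("a", "b", "c"),
                     score = c(3, 2, 1))
  pr <- weighted_precision_recall(hits, labels1, "family")
  # groups fq has 2 members; the query weight is 1/2 for every count
  # unweighted precision would be 1, 1/2, 1/3; weights cancel within a
  # single query so precision is unchanged
  expect_equal(pr$precision, c(1, 1 / 2, 1 / 3))
  expect_equal(pr$recall[1], 1)  # the only possible TP (a) is found first
  # two queries from groups of different size: weighting equalizes them
  labels2 <- data.frame(
    entry_id = c(paste0("big", 1:10), "s1", "s2"),
    family = c(rep("fb", 10), "fs", "fs2"),
    superfamily = c(rep("sb", 10), "ss", "ss2"),
    fold = c(rep("FB", 10), "FS", "FS2"))
  hits2 <- data.frame(
    query_id = c("big1", "big1", "s1"),
    target_id = c("big2", "big3", "s2"),
    score = c(3, 2, 1))
  pr2 <- weighted_precision_recall(hits2, labels2, "family")
  # weighted TP increments: 1/10, 1/10, then FP 1/1 for the singleton query
  expect_equal(pr2$precision, c(1, 1, (0.2) / (0.2 + 1)), tolerance = 1e-12)
  # recall denominator: big1 has 9 possible TPs at weight 1/10, s1 none
  expect_equal(pr2$recall, c(0.1, 0.2, 0.2) / 0.9, tolerance = 1e-12)
})

test_that("recall reaches 1 exactly when every possible TP is reported", {
  labels <- data.frame(entry_id = c("q", "a", "b", "z"),
                       family = c("f", "f", "f", "zz"),
                       superfamily = c("s", "s", "s", "zs"),
                       fold = c("F", "F", "F", "ZF"))
  full <- data.frame(query_id = "q", target_id = c("a", "b"),
                     score = c(2, 1))
  pr <- weighted_precision_recall(full, labels, "family")
  expect_equal(max(pr$recall), 1)
  part <- full[1, ]
  pr2 <- weighted_precision_recall(part, labels, "family")
  expect_lt(max(pr2$recall), 1)
})

test_that("per-residue coverage handles single and disjoint matches and
           matches an interval-stabbing oracle", {
  m1 <- data.frame(query_id = "q", q_start = 1, q_end = 50, lddt = 0.9,
                   score = 10, query_length = 50)
  cov <- per_residue_coverage(m1, x_max = 2)
  expect_equal(cov$coverage[cov$x == 1], 1)
  expect_equal(cov$coverage[cov$x == 2], 0)
  m2 <- data.frame(query_id = "q", q_start = c(1, 26), q_end = c(25, 50),
                   lddt = 0.9, score = c(10, 9), query_length = 50)
  cov2 <- per_residue_coverage(m2, x_max = 2)
  expect_equal(cov2$coverage[cov2$x == 1], 1)
  expect_equal(cov2$coverage[cov2$x == 2], 0)
  # the first FP truncates; ignored-band hits are skipped
  m3 <- data.frame(query_id = "q",
                   q_start = c(1, 1, 1), q_end = c(50, 50, 50),
                   lddt = c(0.9, 0.1, 0.9),
                   score = c(10, 9, 8), query_length = 50)
  cov3 <- per_residue_coverage(m3, x_max = 2)
  expect_equal(cov3$coverage[cov3$x == 2], 0)
  m3$lddt[2] <- 0.4  # ignored, not FP: the third match now counts
  cov4 <- per_residue_coverage(m3, x_max = 2)
  expect_equal(cov4$coverage[cov4$x == 2], 1)
  # randomized intervals vs oracle
  set.seed(12)
  for (case_ in 1:20) {
    L <- 40
    n <- sample(1:6, 1)
    qs <- sample(1:30, n, TRUE)
    qe <- pmin(L, qs + sample(5:20, n, TRUE))
    lddt <- sample(c(0.9, 0.7, 0.4, 0.1), n, TRUE)
    mm <- data.frame(query_id = "q", q_start = qs, q_end = qe, lddt = lddt,
                     score = seq(n, 1), query_length = L)
    got <- per_residue_coverage(mm, x_max = 3)
    cover <- integer(L)
    for (r in seq_len(n)) {
      if (lddt[r] < 0.25) break
      if (lddt[r] < 0.6) next
      cover[qs[r]:qe[r]] <- cover[qs[r]:qe[r]] + 1L
    }
    for (x in 1:3)
      expect_equal(got$coverage[got$x == x], mean(cover >= x))
  }
})

test_that("alignment quality scores reference-based and reference-free
           modes", {
  ref <- cbind(1:20, 5:24)
  q1 <- alignment_quality(ref, "reference_based", reference = ref)
  expect_equal(q1$sensitivity, 1)
  expect_equal(q1$precision, 1)
  expect_equal(q1$f1, 1)
  shifted <- cbind(1:20, 6:25)
  q2 <- alignment_quality(shifted, "reference_based", reference = ref)
  expect_equal(q2$sensitivity, 0)
  expect_equal(q2$f1, 0)
  expect_error(alignment_quality(ref, "reference_based"), "empty reference")
  # missing alignment rates sensitivity 0
  q3 <- alignment_quality(NULL, "reference_based", reference = ref)
  expect_equal(q3$sensitivity, 0)
  # perturbed alignments equal a set-intersection oracle
  set.seed(5)
  for (case_ in 1:10) {
    pred <- ref
    flip <- sample(20, 8)
    pred[flip, 2] <- pred[flip, 2] + sample(c(-2, 1, 3), 8, TRUE)
    qx <- alignment_quality(pred, "reference_based", reference = ref)
    inter <- length(intersect(paste(ref[, 1], ref[, 2]),
                              paste(pred[, 1], pred[, 2])))
    expect_equal(qx$sensitivity, inter / 20)
    expect_equal(qx$precision, inter / 20)
  }
  # reference-free mode from residue-wise LDDT
  lddt <- c(0.9, 0.8, 0.5, 0.7, 0.3)
  q4 <- alignment_quality(NULL, "reference_free", per_residue_lddt = lddt,
                          query_length = 10)
  expect_equal(q4$sensitivity, 3 / 10)
  expect_equal(q4$precision, 3 / 5)
  expect_equal(q4$f1, 2 * 0.3 * 0.6 / 0.9)
})
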