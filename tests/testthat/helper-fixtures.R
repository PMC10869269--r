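# Shared fixtures, memoised across test files. Everything is generated in
# code; the only stored artifacts are the pre-trained synthetic alphabet and
# its substitution matrix shipped with the package.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_alphabet <- function() fx_memo("alphabet", load_alphabet(
  system.file("extdata", "alphabet_synthetic.json", package = "foldscan")))

fx_tdi_matrix <- function() fx_memo("tdi_matrix", read_matrix(
  system.file("extdata", "submat_3di_synthetic.txt", package = "foldscan")))

fx_matrices <- function() fx_memo("matrices",
  list(tdi = fx_tdi_matrix(), aa = aa_matrix_blosum62()))

# the default synthetic benchmark (8 families x 5 members + 10 decoys)
fx_benchmark <- function() fx_memo("benchmark",
  make_family(synthetic_family_spec(seed = 42)))

fx_db <- function() fx_memo("db",
  create_database(fx_benchmark()$chains, fx_alphabet()))

# a small three-element chain used by many geometry tests
fx_chain <- function(seed = 3) make_chain(
  list(list("helix", 12), list("coil", 4), list("strand", 10),
       list("coil", 4), list("helix", 10)), seed = seed)

# deterministic random Lx3 coordinates loosely packed like a compact globule
fx_random_coords <- function(L, seed = 1, scale = 8) {
  set.seed(seed)
  matrix(stats::rnorm(L * 3, 0, scale), L, 3)
}

# textbook affine-gap Smith-Waterman oracle, O(nm) with explicit 3-state DP;
# independent of the package's C++ kernel
sw_oracle <- function(S, gap_open, gap_extend) {
  n <- nrow(S); m <- ncol(S)
  H <- E <- F_ <- matrix(0, n + 1, m + 1)
  E[] <- -Inf; F_[] <- -Inf
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open, E[i, j - 1] - gap_extend)
      F_[i, j] <- max(H[i - 1, j] - gap_open, F_[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[i - 1, j - 1], E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# gridless O(L^2) LDDT oracle
lddt_oracle <- function(q, t, alignment, radius = 15,
                        thresholds = c(0.5, 1, 2, 4),
                        mode = "aligned_neighbors") {
  alignment <- as.matrix(alignment)
  t_of_q <- rep(NA_integer_, nrow(q))
  t_of_q[alignment[, 1]] <- alignment[, 2]
  per <- rep(NA_real_, nrow(alignment))
  for (ai in seq_len(nrow(alignment))) {
    i <- alignment[ai, 1]
    dq <- sqrt(rowSums((q - matrix(q[i, ], nrow(q), 3, byrow = TRUE))^2))
    neigh <- setdiff(which(dq <= radius), i)
    if (!length(neigh)) next
    al <- neigh[!is.na(t_of_q[neigh])]
    if (!length(al)) {
      per[ai] <- if (mode == "all_neighbors") 0 else NA_real_
      next
    }
    dt <- sqrt(rowSums((t[t_of_q[al], , drop = FALSE] -
                          matrix(t[t_of_q[i], ], length(al), 3,
                                 byrow = TRUE))^2))
    s <- sapply(abs(dq[al] - dt), function(d) mean(d < thresholds))
    per[ai] <- if (mode == "all_neighbors") sum(s) / length(neigh) else mean(s)
  }
  list(per_residue = per, mean = mean(per, na.rm = TRUE))
}

# random rotation + translation
fx_rigid <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3, 3)
  rot <- qr.Q(qr(m))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(R = rot, t = stats::runif(3, -30, 30))
}

fx_transform_chain <- function(ch, rt) {
  for (f in c("n", "ca", "c", "cb"))
    ch[[f]] <- ch[[f]] %*% rt$R + matrix(rt$t, nrow(ch[[f]]), 3, byrow = TRUE)
  ch
}

`%||%` <- function(a, b) if (is.null(a)) b else a
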