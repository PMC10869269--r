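#' Per-chain backbone record
#'
#' A chain holds the one-letter amino-acid sequence and the backbone
#' coordinates (N, Calpha, C, Cbeta) of one polymer chain. Missing atoms are
#' `NA` rows; every residue must have a Calpha. Residues are renumbered
#' consecutively 1..L after parsing, and sequence-distance features downstream
#' use this renumbering.
#'
#' @param chain_id Chain identifier (single string).
#' @param aa Character vector of one-letter amino acids (`"X"` for unknown).
#' @param ca,n,c,cb Lx3 coordinate matrices in Angstrom (`n`, `c`, `cb` may
#'   contain `NA` rows for absent atoms).
#' @return An object of class `fs_chain`.
#' @export
fs_chain <- function(chain_id, aa, ca, n = NULL, c = NULL, cb = NULL) {
  L <- length(aa)
  ca <- as_coord_matrix(ca, L)
  if (L < 1) stop("chain must have at least one residue")
  if (anyNA(ca)) stop("every residue must have a Calpha coordinate")
  blank <- matrix(NA_real_, L, 3)
  x <- list(
    chain_id = as.character(chain_id),
    aa = toupper(aa),
    n = if (is.null(n)) blank else as_coord_matrix(n, L),
    ca = ca,
    c = if (is.null(c)) blank else as_coord_matrix(c, L),
    cb = if (is.null(cb)) blank else as_coord_matrix(cb, L)
  )
  class(x) <- "fs_chain"
  x
}

as_coord_matrix <- function(m, L) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) != L || ncol(m) != 3)
    stop("coordinate matrix must be L x 3")
  dimnames(m) <- NULL
  m
}

#' @export
print.fs_chain <- function(x, ...) {
  cat(sprintf("<fs_chain %s: %d residues, %d with Cbeta>\n",
              x$chain_id, length(x$aa), sum(!is.na(x$cb[, 1]))))
  invisible(x)
}

#' @export
length.fs_chain <- function(x) length(x$aa)

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

#' Parse a structure file into per-chain backbone records
#'
#' Reads a PDB or mmCIF file and returns one [fs_chain] per polymer chain.
#' Only the first model of multi-model files is used. Alternate locations are
#' resolved to the highest-occupancy conformer (first on ties). Residues
#' without a Calpha atom are dropped with a warning; chains left empty are
#' dropped.
#'
#' @param source Path to a structure file, or a character string holding PDB
#'   text.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @return List of [fs_chain] objects.
#' @export
parse_structure <- function(source, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  path <- source
  if (length(source) == 1 && !file.exists(source) && grepl("\n", source)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(source, path)
    on.exit(unlink(path))
    if (format == "auto") format <- "pdb"
  }
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop("unparseable structure file: ", conditionMessage(e))
  )
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" | atoms$resid %in% names(AA3TO1), , drop = FALSE]
  if (nrow(atoms) == 0) stop("empty-structure error: no polymer atoms found")
  # resolve altloc: keep highest occupancy (first on tie) per atom site
  alt <- atoms$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
    occ <- atoms$o
    occ[is.na(occ)] <- 1
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
    ord <- order(key, -occ, seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                     atoms$elety)), , drop = FALSE]
  }
  chains <- list()
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    ins <- a$insert
    ins[is.na(ins)] <- ""
    reskey <- paste0(a$resno, "_", ins)
    # preserve file order of residues (honours insertion codes)
    resids <- unique(reskey)
    L <- length(resids)
    aa <- character(L)
    nm <- cam <- cm <- cbm <- matrix(NA_real_, L, 3)
    keep <- logical(L)
    for (ri in seq_len(L)) {
      r <- a[reskey == resids[ri], , drop = FALSE]
      aa1 <- AA3TO1[r$resid[1]]
      aa[ri] <- if (is.na(aa1)) "X" else aa1
      for (ety in c("N", "CA", "C", "CB")) {
        hit <- which(r$elety == ety)
        if (length(hit)) {
          xyz <- c(r$x[hit[1]], r$y[hit[1]], r$z[hit[1]])
          switch(ety, N = nm[ri, ] <- xyz, CA = cam[ri, ] <- xyz,
                 C = cm[ri, ] <- xyz, CB = cbm[ri, ] <- xyz)
        }
      }
      keep[ri] <- !is.na(cam[ri, 1])
    }
    if (any(!keep))
      warning(sprintf("chain %s: dropped %d residue(s) without Calpha",
                      ch, sum(!keep)))
    if (!any(keep)) next
    chains[[ch]] <- fs_chain(ch, aa[keep], cam[keep, , drop = FALSE],
                             nm[keep, , drop = FALSE], cm[keep, , drop = FALSE],
                             cbm[keep, , drop = FALSE])
  }
  if (length(chains) == 0)
    stop("empty-structure error: no chain with at least one Calpha")
  unname(chains)
}

# Tetrahedral Cbeta direction coefficients: the two free vertices of a regular
# tetrahedron whose other two vertices point along the N and C directions are
# dir = -cos(alpha) * bisector(u_N, u_C) +/- sin(alpha) * (u_N x u_C), with
# cos(alpha) = 1/sqrt(3). The sign is fixed to the L-configuration.
CB_BOND <- 1.53

#' Reconstruct missing Cbeta atoms
#'
#' Places a virtual Cbeta at the fourth vertex of a regular tetrahedron around
#' the Calpha, given the N and C directions, at a Calpha-Cbeta bond length of
#' 1.53 Angstrom (the L-amino-acid configuration). Existing Cbeta coordinates
#' are left untouched; residues lacking N or C keep an absent Cbeta and are
#' later encoded as the unknown structural state.
#'
#' @param chain An [fs_chain].
#' @return The chain with `cb` filled where reconstruction was possible.
#' @export
reconstruct_cbeta <- function(chain) {
  stopifnot(inherits(chain, "fs_chain"))
  need <- which(is.na(chain$cb[, 1]))
  for (i in need) {
    if (is.na(chain$n[i, 1]) || is.na(chain$c[i, 1])) next
    chain$cb[i, ] <- tetrahedral_cbeta(chain$n[i, ], chain$ca[i, ], chain$c[i, ])
  }
  chain
}

tetrahedral_cbeta <- function(n_xyz, ca_xyz, c_xyz) {
  u <- vunit(n_xyz - ca_xyz)
  v <- vunit(c_xyz - ca_xyz)
  bis <- vunit(u + v)
  perp <- vunit(vcross(u, v))
  dir <- -bis / sqrt(3) + perp * sqrt(2 / 3)
  ca_xyz + CB_BOND * dir
}

# ---------------------------------------------------------------------------
# database entries and on-disk format

#' Construct a database entry
#'
#' One entry stores the amino-acid sequence, the structural-alphabet sequence
#' and the Calpha trace of a single chain.
#'
#' @param entry_id Unique identifier.
#' @param aa_seq,tdi_seq Strings of equal length (`tdi_seq` over the 20
#'   structural-state letters plus `"X"`).
#' @param ca_coords Lx3 Calpha coordinate matrix.
#' @return An object of class `fs_entry`.
#' @export
fs_entry <- function(entry_id, aa_seq, tdi_seq, ca_coords) {
  L <- nchar(aa_seq)
  ca_coords <- as_coord_matrix(ca_coords, L)
  if (nchar(tdi_seq) != L)
    stop("aa_seq and tdi_seq must have equal length")
  structure(list(entry_id = as.character(entry_id), aa_seq = aa_seq,
                 tdi_seq = tdi_seq, ca = ca_coords),
            class = "fs_entry")
}

#' @export
print.fs_entry <- function(x, ...) {
  cat(sprintf("<fs_entry %s: %d residues>\n", x$entry_id, nchar(x$aa_seq)))
  invisible(x)
}

# fixed-point resolution of the 2-byte Calpha delta compression (Angstrom per
# unit). Declared in the database header; 0.01 A is below experimental
# coordinate precision and allows deltas up to +/-327 A.
CA_FIXED_POINT <- 0.01
DELTA_MAX <- 32767L

#' Write and read the structure database
#'
#' The database is stored as one binary data file plus a text index
#' (entry id, offset, length) and a lookup TSV. In compressed mode the first
#' Calpha is stored as three 4-byte floats and all subsequent coordinates as
#' 2-byte signed integer differences in fixed-point units of 0.01 Angstrom;
#' entries whose deltas overflow that range fall back to 4-byte floats.
#' Reading after writing is lossless up to the fixed-point resolution.
#'
#' @param entries List of [fs_entry] objects.
#' @param path Database path prefix (files `<path>`, `<path>.index`,
#'   `<path>.lookup` and `<path>.meta` are created).
#' @param compress Use delta compression for Calpha coordinates.
#' @param lookup Optional data.frame (entry_id, source, chain) written as the
#'   lookup TSV.
#' @return `write_database` returns `path` invisibly; `read_database` returns
#'   the list of entries.
#' @export
write_database <- function(entries, path, compress = TRUE, lookup = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  idx <- data.frame(entry_id = character(0), offset = integer(0),
                    length = integer(0), stringsAsFactors = FALSE)
  offset <- 0
  for (e in entries) {
    stopifnot(inherits(e, "fs_entry"))
    rec <- serialize_entry(e, compress)
    writeBin(rec, con)
    idx <- rbind(idx, data.frame(entry_id = e$entry_id, offset = offset,
                                 length = length(rec)))
    offset <- offset + length(rec)
  }
  utils::write.table(idx, paste0(path, ".index"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- c(format = "foldscan-db-1", fixed_point = CA_FIXED_POINT)
  writeLines(paste(names(meta), meta, sep = "\t"), paste0(path, ".meta"))
  if (is.null(lookup))
    lookup <- data.frame(entry_id = vapply(entries, `[[`, "", "entry_id"),
                         source = rep(NA_character_, length(entries)),
                         chain = rep(NA_character_, length(entries)))
  utils::write.table(lookup, paste0(path, ".lookup"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

serialize_entry <- function(e, compress) {
  L <- nchar(e$aa_seq)
  ca <- e$ca
  use_delta <- FALSE
  if (compress && L > 1) {
    deltas <- round(diff(ca) / CA_FIXED_POINT)
    use_delta <- all(abs(deltas) <= DELTA_MAX)
  }
  raw_head <- charToRaw(paste0(e$entry_id, "\n", e$aa_seq, "\n", e$tdi_seq, "\n"))
  con <- rawConnection(raw(0), "wb")
  writeBin(raw_head, con)
  writeBin(as.integer(c(L, if (use_delta) 1L else 0L)), con, size = 4)
  if (use_delta) {
    writeBin(as.numeric(ca[1, ]), con, size = 4)
    if (L > 1) {
      # quantize absolute positions then difference, so rounding does not
      # accumulate along the chain
      q <- round(sweep(ca, 2, ca[1, ]) / CA_FIXED_POINT)
      writeBin(as.integer(t(diff(q))), con, size = 2)
    }
  } else {
    writeBin(as.numeric(t(ca)), con, size = 4)
  }
  out <- rawConnectionValue(con)
  close(con)
  out
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  idx <- utils::read.table(paste0(path, ".index"), sep = "\t", header = TRUE,
                           colClasses = c("character", "integer", "integer"))
  if (nrow(idx) == 0) return(list())
  con <- file(path, "rb")
  on.exit(close(con))
  entries <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    seek(con, idx$offset[r])
    rec <- readBin(con, "raw", idx$length[r])
    entries[[r]] <- tryCatch(deserialize_entry(rec),
      error = function(e) stop("corrupt database entry '", idx$entry_id[r],
                               "': ", conditionMessage(e)))
  }
  entries
}

deserialize_entry <- function(rec) {
  nl <- which(rec == charToRaw("\n"))
  if (length(nl) < 3) stop("truncated header")
  entry_id <- rawToChar(rec[seq_len(nl[1] - 1)])
  aa_seq <- rawToChar(rec[(nl[1] + 1):(nl[2] - 1)])
  tdi_seq <- rawToChar(rec[(nl[2] + 1):(nl[3] - 1)])
  con <- rawConnection(rec[(nl[3] + 1):length(rec)])
  on.exit(close(con))
  hd <- readBin(con, "integer", 2, size = 4)
  L <- hd[1]
  if (L != nchar(aa_seq)) stop("length mismatch")
  if (hd[2] == 1L) {
    first <- readBin(con, "numeric", 3, size = 4)
    ca <- matrix(first, 1, 3)
    if (L > 1) {
      d <- readBin(con, "integer", 3 * (L - 1), size = 2, signed = TRUE)
      if (length(d) < 3 * (L - 1)) stop("truncated coordinates")
      steps <- matrix(d, ncol = 3, byrow = TRUE) * CA_FIXED_POINT
      cum <- apply(steps, 2, cumsum)
      if (L == 2) cum <- matrix(cum, 1, 3)
      ca <- rbind(ca, sweep(cum, 2, first, "+"))
    }
  } else {
    v <- readBin(con, "numeric", 3 * L, size = 4)
    if (length(v) < 3 * L) stop("truncated coordinates")
    ca <- matrix(v, ncol = 3, byrow = TRUE)
  }
  fs_entry(entry_id, aa_seq, tdi_seq, ca)
}
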