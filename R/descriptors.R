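# Tertiary-interaction descriptors: a virtual interaction center per residue,
# nearest-neighbor selection by virtual-center distance, and the 10-feature
# descriptor of the conformation of two three-residue backbone windows.

#' Virtual-center placement parameters
#'
#' The virtual center `V` of a residue is placed relative to its Calpha,
#' Cbeta and N atoms: `theta_deg` is the angle V-Calpha-Cbeta, `tau_deg` the
#' dihedral V-Calpha-Cbeta-N, and `l_factor` the length |V - Calpha| as a
#' multiple of the 1.53 Angstrom Calpha-Cbeta bond. The defaults (270, 0, 2)
#' favour long-range tertiary contacts over sequence neighbors.
#'
#' @param theta_deg,tau_deg,l_factor See description.
#' @return A list of class `fs_vc_params`.
#' @export
virtual_center_params <- function(theta_deg = 270, tau_deg = 0, l_factor = 2) {
  stopifnot(l_factor > 0)
  structure(list(theta_deg = theta_deg, tau_deg = tau_deg,
                 l_factor = l_factor), class = "fs_vc_params")
}

#' Compute the virtual interaction center of a residue
#'
#' @param n_xyz,ca_xyz,cb_xyz Backbone atom coordinates (length-3 vectors).
#' @param params A [virtual_center_params].
#' @return The position of `V` (length-3 vector) satisfying
#'   `angle(V, Ca, Cb) == theta_deg`, `dihedral(V, Ca, Cb, N) == tau_deg` and
#'   `|V - Ca| == l_factor * 1.53`.
#' @export
virtual_center <- function(n_xyz, ca_xyz, cb_xyz,
                           params = virtual_center_params()) {
  # dihedral(V, Ca, Cb, N) == dihedral(N, Cb, Ca, V): place V from the
  # reference atoms N -> Cb -> Ca by internal coordinates
  if (vnorm(vcross(n_xyz - ca_xyz, cb_xyz - ca_xyz)) < 1e-9)
    stop("undefined-dihedral error: N, Calpha, Cbeta are collinear")
  place_atom(n_xyz, cb_xyz, ca_xyz, params$l_factor * CB_BOND,
             params$theta_deg, params$tau_deg)
}

chain_virtual_centers <- function(chain, params = virtual_center_params()) {
  L <- length(chain$aa)
  vc <- matrix(NA_real_, L, 3)
  for (i in seq_len(L)) {
    if (anyNA(c(chain$n[i, ], chain$cb[i, ]))) next
    ok <- tryCatch({
      vc[i, ] <- virtual_center(chain$n[i, ], chain$ca[i, ], chain$cb[i, ],
                                params)
      TRUE
    }, error = function(e) FALSE)
  }
  vc
}

# residues with a full Calpha window (i-1, i, i+1)
valid_windows <- function(chain) {
  L <- length(chain$aa)
  ok <- !is.na(chain$ca[, 1])
  w <- logical(L)
  if (L >= 3)
    w[2:(L - 1)] <- ok[1:(L - 2)] & ok[2:(L - 1)] & ok[3:L]
  w
}

#' Select each residue's nearest neighbor by virtual-center distance
#'
#' For every residue `i` with a valid virtual center and descriptor window,
#' the partner `j != i` minimizing the distance between the two virtual
#' centers is chosen among residues that themselves have a valid window and
#' center. An exact all-pairs search is used; distances are quantized to
#' 1e-6 Angstrom and ties broken by the smaller residue index, which keeps
#' the selection stable under rigid-body motion (ideal helices have exactly
#' tied symmetric neighbors). Residues without a valid window or center get
#' `NA` (they are encoded as the unknown state downstream).
#'
#' @param chain An [fs_chain] (Cbeta reconstructed).
#' @param params A [virtual_center_params].
#' @return Integer vector of partner indices (`NA` where undefined).
#' @export
select_partners <- function(chain, params = virtual_center_params()) {
  L <- length(chain$aa)
  vc <- chain_virtual_centers(chain, params)
  win <- valid_windows(chain)
  cand <- which(win & !is.na(vc[, 1]))
  partner <- rep(NA_integer_, L)
  if (length(cand) < 2) return(partner)
  d <- round(as.matrix(stats::dist(vc[cand, , drop = FALSE])), 6)
  diag(d) <- Inf
  for (ii in seq_along(cand)) {
    i <- cand[ii]
    partner[i] <- cand[which.min(d[ii, ])]  # first minimum: smallest index
  }
  partner
}

#' Build the 10-feature tertiary-interaction descriptor
#'
#' Five unit vectors are built from the Calpha windows around residues `i`
#' and `j` (u1: i-1 to i, u2: i to i+1, u3: j-1 to j, u4: j to j+1, u5: i to
#' j). The descriptor is the seven angle cosines (u1u2, u3u4, u1u5, u3u5,
#' u1u4, u2u3, u1u3), the Calpha distance |i - j|, and the two
#' sequence-distance features `sign(i-j)*min(|i-j|,4)` and
#' `sign(i-j)*log(|i-j|+1)` (natural log).
#'
#' @param chain An [fs_chain].
#' @param i,j Residue indices (both need Calpha at positions -1, 0, +1).
#' @return Named numeric vector of length 10.
#' @export
compute_descriptor <- function(chain, i, j) {
  ca <- chain$ca
  L <- nrow(ca)
  idx <- c(i - 1, i, i + 1, j - 1, j, j + 1)
  if (any(idx < 1 | idx > L) || anyNA(ca[idx, 1]))
    stop("descriptor window out of range or missing Calpha")
  u1 <- vunit(ca[i, ] - ca[i - 1, ])
  u2 <- vunit(ca[i + 1, ] - ca[i, ])
  u3 <- vunit(ca[j, ] - ca[j - 1, ])
  u4 <- vunit(ca[j + 1, ] - ca[j, ])
  u5 <- vunit(ca[j, ] - ca[i, ])
  sd_ <- i - j
  c(cos_phi_12 = sum(u1 * u2), cos_phi_34 = sum(u3 * u4),
    cos_phi_15 = sum(u1 * u5), cos_phi_35 = sum(u3 * u5),
    cos_phi_14 = sum(u1 * u4), cos_phi_23 = sum(u2 * u3),
    cos_phi_13 = sum(u1 * u3),
    ca_dist = vnorm(ca[i, ] - ca[j, ]),
    seq_clip = sign(sd_) * min(abs(sd_), 4),
    seq_log = sign(sd_) * log(abs(sd_) + 1))
}

#' Descriptors for every residue of a chain
#'
#' @param chain An [fs_chain] (Cbeta reconstructed).
#' @param params A [virtual_center_params].
#' @return List with `partner` (integer vector) and `desc` (Lx10 matrix, NA
#'   rows where no valid descriptor exists).
#' @export
chain_descriptors <- function(chain, params = virtual_center_params()) {
  L <- length(chain$aa)
  partner <- select_partners(chain, params)
  desc <- matrix(NA_real_, L, 10)
  colnames(desc) <- names(compute_descriptor(helper_desc_names_chain(), 2, 3))
  for (i in seq_len(L)) {
    j <- partner[i]
    if (is.na(j)) next
    desc[i, ] <- compute_descriptor(chain, i, j)
  }
  list(partner = partner, desc = desc)
}

# tiny static chain used only to fetch descriptor column names
helper_desc_names_chain <- function() {
  ca <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0, 11.4, 0, 0), 4, 3, byrow = TRUE)
  fs_chain("tmp", rep("A", 4), ca)
}

#' Dump descriptors to a TSV for inspection
#'
#' @param chain An [fs_chain]; `entry` label written per row.
#' @param path Output TSV path.
#' @inheritParams chain_descriptors
#' @export
write_descriptor_tsv <- function(chain, path, entry = chain$chain_id,
                                 params = virtual_center_params()) {
  cd <- chain_descriptors(chain, params)
  ok <- which(!is.na(cd$partner))
  df <- data.frame(entry = entry, i = ok, j = cd$partner[ok],
                   cd$desc[ok, , drop = FALSE])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
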