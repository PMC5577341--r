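# Internal-coordinate chain building (natural extension reference frame).
# All distances nm, angles/torsions degrees. Backbone geometry uses standard
# ideal values (N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A, C=O 1.231 A).

BB_GEOM <- list(
  b_n_ca = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329, b_c_o = 0.1231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

#' Place an atom from three reference atoms and internal coordinates
#'
#' Returns the position `d` with `|d - c| = bond`, angle `b-c-d` equal to
#' `angle` and dihedral `a-b-c-d` equal to `torsion`.
#'
#' @param a,b,c Reference positions (length-3, nm).
#' @param bond Bond length nm; `angle`, `torsion` in degrees.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- vhat(c - b)
  n <- vhat(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Dihedral angle (degrees) of four positions
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vhat(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build full-atom coordinates for a topology from backbone dihedrals
#'
#' Chains the backbone N-CA-C trace with ideal bond geometry and the given
#' per-residue (phi, psi) torsions (omega fixed trans), places carbonyl O,
#' the backbone amide H (DSSP convention, along the previous C=O direction),
#' CB at ideal tetrahedral geometry, and remaining side-chain heavy atoms as
#' an extended zigzag from CB. Multi-chain topologies take per-chain
#' dihedral lists and an offset placing each later chain away from the
#' first.
#'
#' @param topology A `topology`.
#' @param phi,psi Numeric vectors (degrees), one value per residue (across
#'   all chains, in global residue order). `phi[1]` of each chain is unused.
#' @param chain_offsets Optional named list of length-3 translations (nm)
#'   applied to whole chains (default: chain k shifted by 1.5*(k-1) nm in z).
#' @return `n_atoms x 3` coordinate matrix (nm).
#' @export
build_peptide_coords <- function(topology, phi, psi, chain_offsets = NULL) {
  res <- topology$residues
  stopifnot(length(phi) == nrow(res), length(psi) == nrow(res))
  coords <- matrix(NA_real_, n_atoms(topology), 3)
  g <- BB_GEOM
  for (ci in seq_along(topology$chains)) {
    ch <- topology$chains[ci]
    rids <- res$residue[res$chain == ch]
    off <- if (!is.null(chain_offsets) && !is.null(chain_offsets[[ch]])) {
      chain_offsets[[ch]]
    } else {
      c(0, 0, 1.5 * (ci - 1))
    }
    bb <- matrix(NA_real_, length(rids), 9) # N, CA, C per residue
    for (k in seq_along(rids)) {
      if (k == 1) {
        n_pos <- c(0, 0, 0)
        ca_pos <- c(g$b_n_ca, 0, 0)
        ang <- g$a_n_ca_c * pi / 180
        c_pos <- ca_pos + g$b_ca_c * c(-cos(ang), sin(ang), 0)
      } else {
        pN <- bb[k - 1, 1:3]; pCA <- bb[k - 1, 4:6]; pC <- bb[k - 1, 7:9]
        n_pos <- place_atom(pN, pCA, pC, g$b_c_n, g$a_ca_c_n, psi[rids[k - 1]])
        ca_pos <- place_atom(pCA, pC, n_pos, g$b_n_ca, g$a_c_n_ca, 180)
        c_pos <- place_atom(pC, n_pos, ca_pos, g$b_ca_c, g$a_n_ca_c, phi[rids[k]])
      }
      bb[k, ] <- c(n_pos, ca_pos, c_pos)
    }
    for (k in seq_along(rids)) {
      r <- rids[k]
      n_pos <- bb[k, 1:3]; ca_pos <- bb[k, 4:6]; c_pos <- bb[k, 7:9]
      # carbonyl O: trans to the next N (defined by psi + 180)
      o_pos <- place_atom(n_pos, ca_pos, c_pos, g$b_c_o, g$a_ca_c_o,
                          psi[r] + 180)
      at <- coords_rows(topology, r)
      coords[at[["N"]], ] <- n_pos
      coords[at[["CA"]], ] <- ca_pos
      coords[at[["C"]], ] <- c_pos
      coords[at[["O"]], ] <- o_pos
      if (!is.na(at["H"])) {
        if (k > 1) {
          pc <- bb[k - 1, 7:9]
          po <- coords[coords_rows(topology, rids[k - 1])[["O"]], ]
          coords[at[["H"]], ] <- n_pos + 0.1 * vhat(pc - po)
        } else {
          coords[at[["H"]], ] <- n_pos + 0.1 * vhat(n_pos - ca_pos)
        }
      }
      coords <- place_sidechain(topology, coords, r, n_pos, ca_pos, c_pos)
    }
    rows <- which(topology$atoms$chain == ch)
    coords[rows, ] <- sweep(coords[rows, , drop = FALSE], 2, -off)
  }
  coords
}

# named atom-row lookup for one residue
coords_rows <- function(topology, residue) {
  rows <- which(topology$atoms$residue == residue)
  out <- stats::setNames(rows, topology$atoms$name[rows])
  full <- c("N", "H", "CA", "C", "O")
  miss <- setdiff(full, names(out))
  if (length(miss) > 0) out[miss] <- NA_integer_
  out
}

place_sidechain <- function(topology, coords, residue, n_pos, ca_pos, c_pos) {
  rows <- which(topology$atoms$residue == residue)
  nms <- topology$atoms$name[rows]
  side <- rows[!nms %in% c("N", "H", "CA", "C", "O", "OXT")]
  side_nms <- topology$atoms$name[side]
  if ("OXT" %in% nms) {
    oxt <- rows[nms == "OXT"]
    o_row <- rows[nms == "O"]
    coords[oxt, ] <- place_atom(n_pos, ca_pos, c_pos, BB_GEOM$b_c_o, 118,
                                dihedral_angle(n_pos, ca_pos, c_pos,
                                               coords[o_row, ]) + 180)
  }
  if (length(side) == 0) return(coords)
  # CB from ideal tetrahedral geometry (L-configuration)
  cb <- place_atom(c_pos, n_pos, ca_pos, 0.153, 110.5, 122.5)
  coords[side[1], ] <- cb
  if (length(side) > 1) {
    prev3 <- list(n_pos, ca_pos, cb)
    for (j in 2:length(side)) {
      tors <- c(180, 150, -150, 120)[(j %% 4) + 1]
      pos <- place_atom(prev3[[1]], prev3[[2]], prev3[[3]], 0.15, 112, tors)
      coords[side[j], ] <- pos
      prev3 <- list(prev3[[2]], prev3[[3]], pos)
    }
  }
  coords
}

#' Canonical backbone dihedrals for secondary-structure classes
#'
#' `"helix"`: (-57, -47); `"strand"`: (-139, 135); `"pp2"`-flavoured coil
#' draws from a small fixed set of extended/polyproline-like pairs.
#'
#' @param class Character vector of `"helix"`, `"strand"`, `"coil"`.
#' @param rng Optional function(n) returning uniform draws in (0,1) for coil
#'   variety; defaults to fixed mid-values.
#' @return List with numeric vectors `phi` and `psi` (degrees).
#' @export
class_dihedrals <- function(class, rng = NULL) {
  n <- length(class)
  phi <- numeric(n); psi <- numeric(n)
  coil_set <- matrix(c(-75, 145, -120, 130, -85, -10, -140, 160, -65, 140),
                     ncol = 2, byrow = TRUE)
  for (i in seq_len(n)) {
    if (class[i] == "helix") {
      phi[i] <- -57; psi[i] <- -47
    } else if (class[i] == "strand") {
      phi[i] <- -139; psi[i] <- 135
    } else {
      k <- if (is.null(rng)) 1L else 1L + floor(rng(1) * nrow(coil_set))
      k <- min(k, nrow(coil_set))
      phi[i] <- coil_set[k, 1]; psi[i] <- coil_set[k, 2]
    }
  }
  list(phi = phi, psi = psi)
}
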