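#' Residue heavy-atom templates
#'
#' Standard PDB heavy-atom names for the 20 amino acids. Templates carry
#' heavy atoms plus the backbone amide H (added at build time for non-proline
#' residues with a predecessor); side-chain hydrogens are never modelled —
#' every analysis in the package (contacts, SASA, energetics) is defined on
#' heavy atoms, and the amide H exists only for hydrogen-bond based
#' secondary-structure assignment.
#'
#' @keywords internal
#' @noRd
residue_heavy_atoms <- function() {
  list(
    ALA = c("N", "CA", "C", "O", "CB"),
    ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
    ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    CYS = c("N", "CA", "C", "O", "CB", "SG"),
    GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
    GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
    GLY = c("N", "CA", "C", "O"),
    HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
    LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
    LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
    MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
    PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
    SER = c("N", "CA", "C", "O", "CB", "OG"),
    THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
    TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
            "CE3", "CZ2", "CZ3", "CH2"),
    TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
            "CZ", "OH"),
    VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2")
  )
}

aa_three <- function() {
  c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
    E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
    M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
    Y = "TYR", V = "VAL")
}

aa_masses <- function() {
  # average atomic masses, amu
  c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)
}

#' Element from a PDB atom name
#' @keywords internal
#' @noRd
element_of <- function(atom_name) {
  substr(gsub("[0-9]", "", atom_name), 1, 1)
}

# Per-element nonbonded defaults: LJ sigma (nm), epsilon (kcal/mol),
# intrinsic Born radius (nm). Carbons and sulfurs are flagged hydrophobic.
element_params <- function() {
  tibble::tribble(
    ~element, ~sigma, ~epsilon, ~born, ~hydrophobic,
    "C", 0.340, 0.1094, 0.170, TRUE,
    "N", 0.325, 0.1700, 0.155, FALSE,
    "O", 0.296, 0.2100, 0.150, FALSE,
    "S", 0.356, 0.2500, 0.180, TRUE,
    "H", 0.107, 0.0157, 0.120, FALSE
  )
}

# HCT pairwise-descreening scale factors by element
hct_scale <- function(element) {
  s <- c(C = 0.72, N = 0.79, O = 0.85, S = 0.96, H = 0.85)
  unname(s[element])
}

# Side-chain partial charges for titratable/polar groups; every residue is
# brought to its integer net charge by an adjustment on CB (CA for glycine).
sidechain_charges <- function() {
  list(
    ASP = c(CG = 0.70, OD1 = -0.80, OD2 = -0.80),
    GLU = c(CD = 0.70, OE1 = -0.80, OE2 = -0.80),
    LYS = c(CE = 0.20, NZ = 0.40),
    ARG = c(NE = -0.50, CZ = 0.80, NH1 = 0.45, NH2 = 0.45),
    HIS = c(ND1 = -0.30, NE2 = -0.30, CE1 = 0.30, CD2 = 0.10, CG = 0.10),
    SER = c(OG = -0.40, CB = 0.40),
    THR = c(OG1 = -0.40),
    TYR = c(OH = -0.40, CZ = 0.40),
    ASN = c(CG = 0.55, OD1 = -0.55, ND2 = -0.60),
    GLN = c(CD = 0.55, OE1 = -0.55, NE2 = -0.60),
    TRP = c(NE1 = -0.30)
  )
}

residue_net_charge <- function(resid) {
  switch(resid, ASP = -1, GLU = -1, LYS = 1, ARG = 1, 0)
}
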