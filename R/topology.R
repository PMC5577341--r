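#' Build a peptide topology from a one-letter sequence
#'
#' Materializes the chain/residue/atom bookkeeping needed by every analysis:
#' heavy atoms follow the standard residue templates, a backbone amide H is
#' added for each non-proline residue that has a predecessor (used only by
#' the secondary-structure module), and per-atom nonbonded parameters
#' (partial charge, LJ sigma/epsilon, intrinsic Born radius, hydrophobic
#' flag) are filled from simple element-based defaults with integer residue
#' net charges (ASP/GLU -1, LYS/ARG +1, HIS neutral, neutral termini).
#'
#' @param sequence One-letter amino-acid string (standard 20 codes only).
#' @param chain_id Single-character chain identifier.
#' @param terminal_mode `"neutral"` (default) or `"oxt"`; with `"oxt"` a
#'   terminal carboxylate OXT heavy atom is appended to the last residue.
#' @return An object of class `topology`: a list with tibbles `atoms`
#'   (name, element, residue, resno, resid, chain, charge, sigma, epsilon,
#'   born, hydrophobic, mass) and `residues` (residue, resno, resid, chain),
#'   plus `chains`. `residue` is the global 1-based residue index; `resno`
#'   restarts at 1 per chain.
#' @examples
#' top <- build_topology("DAEFRH", chain_id = "B")
#' n_atoms(top)
#' @export
build_topology <- function(sequence, chain_id = "A", terminal_mode = c("neutral", "oxt")) {
  terminal_mode <- match.arg(terminal_mode)
  codes <- strsplit(toupper(sequence), "")[[1]]
  if (length(codes) == 0) stop("empty sequence")
  three <- aa_three()
  bad <- which(!codes %in% names(three))
  if (length(bad) > 0) {
    stop(sprintf("unknown residue code '%s' at position %d", codes[bad[1]], bad[1]))
  }
  resids <- unname(three[codes])
  templates <- residue_heavy_atoms()
  n_res <- length(resids)

  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    atoms <- templates[[resids[i]]]
    if (i > 1 && resids[i] != "PRO") {
      # amide H right after N, for DSSP-style assignment
      atoms <- append(atoms, "H", after = 1)
    }
    if (i == n_res && terminal_mode == "oxt") {
      atoms <- c(atoms, "OXT")
    }
    rows[[i]] <- tibble::tibble(
      name = atoms, residue = i, resno = i, resid = resids[i], chain = chain_id
    )
  }
  atoms <- dplyr::bind_rows(rows)
  atoms$element <- element_of(atoms$name)
  atoms <- assign_parameters(atoms)

  residues <- tibble::tibble(
    residue = seq_len(n_res), resno = seq_len(n_res),
    resid = resids, chain = chain_id
  )
  structure(
    list(atoms = atoms, residues = residues, chains = chain_id),
    class = "topology"
  )
}

assign_parameters <- function(atoms) {
  ep <- element_params()
  atoms <- dplyr::left_join(atoms, ep, by = "element")
  if (anyNA(atoms$sigma)) stop("unparameterized element in topology")
  atoms$mass <- unname(aa_masses()[atoms$element])
  atoms$charge <- 0
  # backbone partial charges
  bb <- c(N = -0.4157, H = 0.2719, CA = 0.0337, C = 0.5973, O = -0.5679, OXT = 0)
  hit <- atoms$name %in% names(bb)
  atoms$charge[hit] <- unname(bb[atoms$name[hit]])
  sc <- sidechain_charges()
  for (i in which(atoms$resid %in% names(sc))) {
    q <- sc[[atoms$resid[i]]]
    if (atoms$name[i] %in% names(q)) atoms$charge[i] <- unname(q[atoms$name[i]])
  }
  # bring each residue to its integer net charge via CB (CA for GLY)
  for (r in unique(atoms$residue)) {
    sel <- atoms$residue == r
    target <- residue_net_charge(atoms$resid[sel][1])
    adj_name <- if (atoms$resid[sel][1] == "GLY") "CA" else "CB"
    j <- which(sel & atoms$name == adj_name)[1]
    atoms$charge[j] <- atoms$charge[j] + (target - sum(atoms$charge[sel]))
  }
  atoms
}

#' Combine topologies into a multi-chain complex
#'
#' @param ... `topology` objects with distinct chain ids.
#' @return A `topology` whose global residue indices run over all chains;
#'   per-chain `resno` numbering is preserved.
#' @export
combine_topologies <- function(...) {
  tops <- list(...)
  stopifnot(length(tops) >= 1, all(vapply(tops, inherits, TRUE, "topology")))
  chains <- unlist(lapply(tops, `[[`, "chains"))
  if (anyDuplicated(chains)) stop("duplicate chain ids in combined topology")
  offset <- 0L
  atoms <- list(); residues <- list()
  for (tp in tops) {
    a <- tp$atoms; r <- tp$residues
    a$residue <- a$residue + offset
    r$residue <- r$residue + offset
    offset <- offset + nrow(tp$residues)
    atoms[[length(atoms) + 1]] <- a
    residues[[length(residues) + 1]] <- r
  }
  structure(
    list(atoms = dplyr::bind_rows(atoms), residues = dplyr::bind_rows(residues),
         chains = chains),
    class = "topology"
  )
}

#' Number of atoms / residues in a topology
#' @param topology A `topology`.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' @rdname n_atoms
#' @export
n_residues <- function(topology) nrow(topology$residues)

#' Indices of atoms matching a selection
#'
#' @param topology A `topology`.
#' @param name Optional atom-name filter (e.g. `"CA"`).
#' @param chain Optional chain filter.
#' @param residue Optional global residue-index filter.
#' @param heavy If `TRUE`, restrict to heavy (non-hydrogen) atoms.
#' @param hydrophobic If `TRUE`, restrict to hydrophobic-flagged atoms.
#' @return Integer vector of atom row indices.
#' @export
atom_select <- function(topology, name = NULL, chain = NULL, residue = NULL,
                        heavy = FALSE, hydrophobic = FALSE) {
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(residue)) keep <- keep & a$residue %in% residue
  if (heavy) keep <- keep & a$element != "H"
  if (hydrophobic) keep <- keep & a$hydrophobic
  which(keep)
}

validate_topology <- function(topology) {
  stopifnot(inherits(topology, "topology"))
  a <- topology$atoms; r <- topology$residues
  if (!all(a$residue %in% r$residue)) stop("atom maps to missing residue")
  for (ch in topology$chains) {
    rn <- r$resno[r$chain == ch]
    if (!identical(as.integer(rn), seq_len(length(rn)))) {
      stop("residue numbering not contiguous from 1 in chain ", ch)
    }
  }
  if (!all(is.finite(a$charge))) stop("non-finite charge")
  if (any(a$sigma < 0 | a$epsilon < 0 | a$born < 0)) stop("negative LJ/Born parameter")
  invisible(topology)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf(
    "topology: %d chain(s) [%s], %d residues, %d atoms (%d heavy)\n",
    length(x$chains), paste(x$chains, collapse = ","),
    n_residues(x), n_atoms(x), sum(x$atoms$element != "H")
  ))
  invisible(x)
}

#' Write / read a force-field parameter table
#'
#' Plain TSV with columns residue (global index), atom, charge, sigma,
#' epsilon, born_radius, hydrophobic — the interchange format for per-atom
#' nonbonded parameters.
#'
#' @param topology A `topology`.
#' @param path File path.
#' @export
write_parameters <- function(topology, path) {
  a <- topology$atoms
  out <- data.frame(
    residue = a$residue, atom = a$name, charge = a$charge, sigma = a$sigma,
    epsilon = a$epsilon, born_radius = a$born, hydrophobic = a$hydrophobic
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parameters
#' @param strict Error if the table does not cover every atom.
#' @return `read_parameters()` returns the `topology` with parameters replaced.
#' @export
read_parameters <- function(topology, path, strict = TRUE) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  key_top <- paste(topology$atoms$residue, topology$atoms$name)
  key_tab <- paste(tab$residue, tab$atom)
  idx <- match(key_top, key_tab)
  if (strict && anyNA(idx)) stop("parameter table does not cover all atoms")
  ok <- !is.na(idx)
  topology$atoms$charge[ok] <- tab$charge[idx[ok]]
  topology$atoms$sigma[ok] <- tab$sigma[idx[ok]]
  topology$atoms$epsilon[ok] <- tab$epsilon[idx[ok]]
  topology$atoms$born[ok] <- tab$born_radius[idx[ok]]
  topology$atoms$hydrophobic[ok] <- as.logical(tab$hydrophobic[idx[ok]])
  validate_topology(topology)
}
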