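#' Peptide sequences studied by the package
#'
#' The 42-residue amyloid-beta monomer and the three N-terminal hexapeptide
#' variants that differ only at position 2 (wild type alanine, the causative
#' A2V valine, and the protective A2T threonine).
#'
#' @return `sequence_library()` returns a named list with elements `ab42`
#'   (42-character string) and `hexapeptides` (named character vector with
#'   entries `WT`, `A2V`, `A2T`).
#' @examples
#' sequence_library()$hexapeptides
#' @export
sequence_library <- function() {
  lib <- list(
    ab42 = "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA",
    hexapeptides = c(WT = "DAEFRH", A2V = "DVEFRH", A2T = "DTEFRH")
  )
  stopifnot(nchar(lib$ab42) == 42L, all(nchar(lib$hexapeptides) == 6L))
  lib
}

#' Region scheme on the 42-mer
#'
#' Named residue-index ranges used for all regional analyses: the N-terminal
#' region (NTR, 1-16), the central hydrophobic core (CHC, 17-21), the turn
#' region (22-29) and the C-terminal region (CTR, 30-42). The derived preCHC
#' range (11-16) is a sub-range of the NTR. The four primary ranges partition
#' residues 1-42.
#'
#' @param ntr,chc,turn,ctr Integer vectors `c(first, last)` (1-based,
#'   inclusive) for the four primary regions.
#' @return An object of class `region_scheme`: a named list of integer
#'   ranges.
#' @examples
#' region_residues(region_scheme(), "CHC")
#' @export
region_scheme <- function(ntr = c(1L, 16L), chc = c(17L, 21L),
                          turn = c(22L, 29L), ctr = c(30L, 42L)) {
  regions <- list(NTR = ntr, CHC = chc, turn = turn, CTR = ctr)
  regions <- lapply(regions, function(r) as.integer(r))
  idx <- lapply(regions, function(r) seq.int(r[1], r[2]))
  all_idx <- sort(unname(unlist(idx)))
  if (anyDuplicated(all_idx)) {
    stop("primary regions overlap")
  }
  if (!identical(all_idx, seq.int(min(all_idx), max(all_idx)))) {
    stop("primary regions do not form a contiguous partition")
  }
  regions$preCHC <- c(max(regions$NTR[1], 11L), regions$NTR[2])
  structure(regions, class = "region_scheme")
}

#' Residues belonging to a named region
#'
#' @param scheme A [region_scheme()].
#' @param region Region name: one of `"NTR"`, `"CHC"`, `"turn"`, `"CTR"`,
#'   `"preCHC"`, or several names (their union, in index order).
#' @return Integer vector of 1-based residue indices.
#' @examples
#' region_residues(region_scheme(), c("CHC", "CTR"))
#' @export
region_residues <- function(scheme, region) {
  stopifnot(inherits(scheme, "region_scheme"))
  unknown <- setdiff(region, names(scheme))
  if (length(unknown) > 0) {
    stop("unknown region name(s): ", paste(unknown, collapse = ", "))
  }
  idx <- unlist(lapply(scheme[region], function(r) seq.int(r[1], r[2])))
  sort(unique(as.integer(idx)))
}

#' @export
print.region_scheme <- function(x, ...) {
  cat("Region scheme on the 42-mer:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-7s %d-%d\n", nm, x[[nm]][1], x[[nm]][2]))
  }
  invisible(x)
}
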