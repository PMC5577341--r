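#' Mass-weighted radius of gyration
#'
#' @param frame `n_atoms x 3` coordinate matrix (nm).
#' @param topology The matching `topology` (atom masses).
#' @param selection Atom row indices (default: all atoms).
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(frame, topology, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(n_atoms(topology))
  if (length(selection) == 0) stop("empty selection")
  m <- topology$atoms$mass[selection]
  x <- frame[selection, , drop = FALSE]
  com <- colSums(x * m) / sum(m)
  dx <- sweep(x, 2, com)
  sqrt(sum(m * rowSums(dx^2)) / sum(m))
}

#' Optimal-superposition (Kabsch) RMSD between two frames
#'
#' Least-squares rigid superposition (proper rotation enforced via the
#' determinant correction) followed by the root-mean-square deviation over
#' the selected atoms; `superpose = FALSE` gives the raw RMSD.
#'
#' @param frame_a,frame_b `n_atoms x 3` matrices (nm).
#' @param selection Atom indices (same in both frames); at least 3 for
#'   superposition.
#' @param superpose Superpose before measuring (default `TRUE`).
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(frame_a, frame_b, selection = NULL, superpose = TRUE) {
  if (is.null(selection)) selection <- seq_len(nrow(frame_a))
  a <- frame_a[selection, , drop = FALSE]
  b <- frame_b[selection, , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  if (superpose) {
    if (nrow(a) < 3) stop("superposition needs at least 3 atoms")
    b <- kabsch_fit(b, a)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Rigidly fit coordinates `x` onto reference `ref` (Kabsch)
#' @param x,ref `n x 3` matrices.
#' @return Transformed copy of `x`.
#' @keywords internal
#' @export
kabsch_fit <- function(x, ref) {
  cx <- colMeans(x); cr <- colMeans(ref)
  x0 <- sweep(x, 2, cx); r0 <- sweep(ref, 2, cr)
  s <- svd(crossprod(x0, r0))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  rot <- s$u %*% D %*% t(s$v)
  sweep(x0 %*% rot, 2, -cr)
}

#' Centered moving average with edge truncation
#'
#' @param values Numeric series.
#' @param window Odd-ish window length in points; at the edges the window is
#'   truncated to what fits.
#' @keywords internal
#' @export
moving_average <- function(values, window) {
  n <- length(values)
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(values[lo:hi])
  }, numeric(1))
}

#' Backbone RMSD time series with moving average
#'
#' Per-frame superposed RMSD to a reference frame over the selected atoms,
#' plus a centered moving average (window in ps, truncated at the series
#' edges) used for convergence plots.
#'
#' @param x An `ensemble` with time metadata.
#' @param reference `n_atoms x 3` reference coordinates (nm).
#' @param selection Atom indices used both for fitting and measurement.
#' @param ma_window Moving-average window in ps (e.g. 1000 for 1 ns);
#'   must be at least the sampling interval.
#' @return Tibble (class `scalar_series`): frame, time, replica, value
#'   (nm), ma (nm).
#' @export
rmsd_series <- function(x, reference, selection = NULL, ma_window = NULL) {
  nf <- n_frames(x)
  vals <- vapply(seq_len(nf), function(k) {
    kabsch_rmsd(frame_coords(x, k), reference, selection)
  }, numeric(1))
  out <- tibble::tibble(
    frame = x$frames$frame, time = x$frames$time, replica = x$frames$replica,
    value = vals
  )
  if (!is.null(ma_window)) {
    dt <- stats::median(diff(out$time), na.rm = TRUE)
    if (!is.finite(dt) || dt <= 0) dt <- 1
    if (ma_window < dt) stop("moving-average window smaller than sampling interval")
    out$ma <- moving_average(out$value, max(1, round(ma_window / dt)))
  } else {
    out$ma <- out$value
  }
  class(out) <- c("scalar_series", class(out))
  out
}

#' Radius-of-gyration series over an ensemble
#'
#' @inheritParams rmsd_series
#' @param topology_selection Atom indices for Rg (default all).
#' @return Tibble: frame, time, replica, value (nm).
#' @export
rg_series <- function(x, topology_selection = NULL) {
  vals <- vapply(seq_len(n_frames(x)), function(k) {
    radius_of_gyration(frame_coords(x, k), x$topology, topology_selection)
  }, numeric(1))
  out <- tibble::tibble(
    frame = x$frames$frame, time = x$frames$time, replica = x$frames$replica,
    value = vals, ma = vals
  )
  class(out) <- c("scalar_series", class(out))
  out
}

#' Shrake–Rupley solvent-accessible surface area
#'
#' Quadrature over a deterministic golden-section sphere of `n_points` test
#' points per atom; atom radii are the LJ minimum-energy radii
#' (`sigma * 2^(1/6) / 2`) plus the probe radius. The hydrophobic subset
#' sums the contributions of atoms flagged hydrophobic (C and S heavy
#' atoms). Hydrogens are excluded.
#'
#' @param frame `n_atoms x 3` matrix (nm).
#' @param topology The matching `topology`.
#' @param probe Probe radius in nm (default 0.14, water).
#' @param n_points Sphere points per atom (>= 60; default 240).
#' @param subset `"all"` or `"hydrophobic"` for the reported total.
#' @param selection Optional atom indices defining the molecule (default:
#'   all heavy atoms); occlusion is computed within the selection only.
#' @return List with `total` (Angstrom^2, for the requested subset) and
#'   `per_atom` tibble (atom row, area in Angstrom^2).
#' @export
sasa <- function(frame, topology, probe = 0.14, n_points = 240,
                 subset = c("all", "hydrophobic"), selection = NULL) {
  subset <- match.arg(subset)
  stopifnot(n_points >= 60)
  if (is.null(selection)) selection <- atom_select(topology, heavy = TRUE)
  a <- topology$atoms[selection, , drop = FALSE]
  radii <- a$sigma * 2^(1 / 6) / 2 + probe
  x <- frame[selection, , drop = FALSE]
  pts <- golden_sphere(n_points)
  n <- length(selection)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(x, 2, x[i, ])^2)
    cand <- d2 < (radii[i] + radii)^2
    cand[i] <- FALSE
    # exactly coincident duplicates: only the first keeps its surface
    cand[d2 <= 1e-12 & seq_len(n) > i] <- FALSE
    nb <- which(cand)
    sp <- sweep(pts * radii[i], 2, x[i, ], "+")
    if (length(nb) > 0) {
      free <- rep(TRUE, nrow(sp))
      for (j in nb) {
        dj2 <- rowSums(sweep(sp, 2, x[j, ])^2)
        # small slack so points exactly on a neighbor's surface count as
        # buried (exact ties arise for coincident duplicate atoms)
        free <- free & dj2 > radii[j]^2 * (1 + 1e-9)
        if (!any(free)) break
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    area[i] <- 4 * pi * (radii[i] * ANGSTROM_PER_NM)^2 * frac
  }
  keep <- if (subset == "hydrophobic") a$hydrophobic else rep(TRUE, n)
  list(
    total = sum(area[keep]),
    per_atom = tibble::tibble(atom = selection, name = a$name,
                              residue = a$residue, area = area,
                              hydrophobic = a$hydrophobic)
  )
}

# deterministic unit-sphere covering (golden spiral)
golden_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
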