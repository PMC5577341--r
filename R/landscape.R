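#' Block standard error of a time series
#'
#' Splits the series into `n_blocks` contiguous equal-length segments
#' (truncating any remainder at the end) and returns the sample standard
#' deviation of the block means divided by `sqrt(n_blocks)` — the
#' error protocol used for every ensemble average in the package (the
#' production analyses use four blocks, i.e. four 35 ns segments of the
#' 140 ns window).
#'
#' @param series Numeric vector, length >= `n_blocks`.
#' @param n_blocks Number of blocks (>= 2, default 4).
#' @return Standard error (same units as the series).
#' @export
block_standard_error <- function(series, n_blocks = 4) {
  if (n_blocks < 2) stop("n_blocks must be at least 2")
  if (length(series) < n_blocks) stop("series shorter than the number of blocks")
  bm <- block_means(series, n_blocks)
  stats::sd(bm) / sqrt(n_blocks)
}

#' 2D potential of mean force over the reaction coordinates
#'
#' Histogram of `(nbeta, ncontact)` on `[0, 1]^2`, converted to
#' `W = -kB T ln(P / P_max)` in kcal/mol so the most occupied bin sits at
#' exactly zero. Empty bins are `NA` (flagged, not zero).
#'
#' @param rc An [rc_series()] tibble (non-empty).
#' @param n_bins Bins per axis (>= 2, default 20).
#' @param temperature Temperature in K for kT (default 300).
#' @return Object of class `pmf_surface`: list with `w` and `counts`
#'   matrices (rows nbeta bins, columns ncontact bins), bin `edges`, and
#'   `temperature`.
#' @export
pmf2d <- function(rc, n_bins = 20, temperature = 300) {
  stopifnot(nrow(rc) > 0, n_bins >= 2, temperature > 0)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bx <- bin_index(rc$nbeta, edges)
  by <- bin_index(rc$ncontact, edges)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(bx)) {
    counts[bx[k], by[k]] <- counts[bx[k], by[k]] + 1L
  }
  p <- counts / sum(counts)
  w <- matrix(NA_real_, n_bins, n_bins)
  occ <- counts > 0
  w[occ] <- -KB_KCAL * temperature * log(p[occ] / max(p))
  structure(
    list(w = w, counts = counts, edges = edges, temperature = temperature,
         n_frames = nrow(rc)),
    class = "pmf_surface"
  )
}

# half-open bins [e_k, e_{k+1}), final edge closed
bin_index <- function(v, edges) {
  n <- length(edges) - 1
  idx <- findInterval(v, edges, rightmost.closed = TRUE, left.open = FALSE)
  pmin(pmax(idx, 1L), n)
}

#' @export
print.pmf_surface <- function(x, ...) {
  cat(sprintf("pmf_surface: %dx%d bins, T = %g K, %d frames, max W = %.2f kcal/mol\n",
              nrow(x$w), ncol(x$w), x$temperature, x$n_frames,
              max(x$w, na.rm = TRUE)))
  invisible(x)
}

#' Tidy a PMF surface (bin centers + free energy)
#' @param x A `pmf_surface`.
#' @param ... Unused.
#' @method tidy pmf_surface
#' @export
tidy.pmf_surface <- function(x, ...) {
  centers <- (x$edges[-1] + x$edges[-length(x$edges)]) / 2
  g <- expand.grid(i = seq_along(centers), j = seq_along(centers))
  tibble::tibble(
    nbeta = centers[g$i], ncontact = centers[g$j],
    w = x$w[cbind(g$i, g$j)], count = x$counts[cbind(g$i, g$j)]
  )
}

#' Rectangular conformational states on the landscape
#'
#' @param name State name (e.g. `"S6"`).
#' @param nbeta,ncontact Length-2 intervals within `[0, 1]`.
#' @return A `state_rectangle`.
#' @export
state_rectangle <- function(name, nbeta, ncontact) {
  stopifnot(length(nbeta) == 2, length(ncontact) == 2,
            all(c(nbeta, ncontact) >= 0), all(c(nbeta, ncontact) <= 1),
            nbeta[1] < nbeta[2], ncontact[1] < ncontact[2])
  structure(list(name = name, nbeta = nbeta, ncontact = ncontact),
            class = "state_rectangle")
}

#' Bundled default state layout
#'
#' Six pairwise-disjoint rectangles on the `(nbeta, ncontact)` plane used by
#' the synthetic validation suite. S6 occupies the high-nbeta/high-ncontact
#' corner — the CHC–CTR beta-hairpin-rich region; S1–S5 tile lower-order
#' parts of the plane. The exact boundaries are runtime configuration, not a
#' claim about any particular simulated system.
#'
#' @return Named list of [state_rectangle()]s.
#' @export
default_state_rectangles <- function() {
  list(
    S1 = state_rectangle("S1", c(0.0, 0.12), c(0.0, 0.08)),
    S2 = state_rectangle("S2", c(0.12, 0.35), c(0.0, 0.08)),
    S3 = state_rectangle("S3", c(0.0, 0.12), c(0.08, 0.30)),
    S4 = state_rectangle("S4", c(0.12, 0.35), c(0.08, 0.30)),
    S5 = state_rectangle("S5", c(0.35, 1.0), c(0.0, 0.08)),
    S6 = state_rectangle("S6", c(0.35, 1.0), c(0.08, 1.0))
  )
}

states_disjoint <- function(states) {
  overlap1d <- function(a, b) max(a[1], b[1]) < min(a[2], b[2])
  nm <- names(states)
  for (i in seq_along(states)) {
    for (j in seq_len(i - 1)) {
      if (overlap1d(states[[i]]$nbeta, states[[j]]$nbeta) &&
          overlap1d(states[[i]]$ncontact, states[[j]]$ncontact)) {
        stop("state rectangles overlap: ", nm[j], " and ", nm[i])
      }
    }
  }
  invisible(TRUE)
}

in_rectangle <- function(rc, rect) {
  inside1d <- function(v, iv) {
    if (iv[2] >= 1) v >= iv[1] & v <= 1 else v >= iv[1] & v < iv[2]
  }
  inside1d(rc$nbeta, rect$nbeta) & inside1d(rc$ncontact, rect$ncontact)
}

#' State populations with block errors
#'
#' Fraction of frames whose raw `(nbeta, ncontact)` falls in each rectangle
#' (closed-left, open-right intervals; the final edge at 1 closed), plus an
#' `Others` complement, with block SEs. Populations are computed on the raw
#' coordinates, never on PMF bins.
#'
#' @param rc An [rc_series()] tibble.
#' @param states Named list of [state_rectangle()]s (pairwise disjoint).
#' @param n_blocks Blocks for SEs (default 4).
#' @return Tibble (class `state_populations`): state, mean_pct, se_pct.
#'   Percentages (including Others) sum to 100.
#' @export
state_populations <- function(rc, states = default_state_rectangles(),
                              n_blocks = 4) {
  stopifnot(nrow(rc) >= n_blocks, n_blocks >= 2)
  states_disjoint(states)
  assigned <- rep(FALSE, nrow(rc))
  rows <- list()
  for (nm in names(states)) {
    ind <- in_rectangle(rc, states[[nm]])
    if (any(ind & assigned)) stop("frame assigned to two states: ", nm)
    assigned <- assigned | ind
    bm <- block_means(as.numeric(ind) * 100, n_blocks)
    rows[[nm]] <- tibble::tibble(
      state = nm, mean_pct = 100 * mean(ind),
      se_pct = stats::sd(bm) / sqrt(n_blocks)
    )
  }
  others <- !assigned
  bm <- block_means(as.numeric(others) * 100, n_blocks)
  rows[["Others"]] <- tibble::tibble(
    state = "Others", mean_pct = 100 * mean(others),
    se_pct = stats::sd(bm) / sqrt(n_blocks)
  )
  out <- dplyr::bind_rows(rows)
  stopifnot(abs(sum(out$mean_pct) - 100) < 1e-6)
  class(out) <- c("state_populations", class(out))
  out
}

#' Frames forming the hairpin-rich sub-population
#'
#' Retains frames with `nbeta` strictly greater than the threshold (the
#' hairpin filter: structures with a normalized CHC+CTR strand count above
#' 0.6 consistently carry the CHC–CTR hairpin motif).
#'
#' @param x The `ensemble` the series was computed from.
#' @param rc The aligned [rc_series()].
#' @param nbeta_threshold Strict lower bound on `nbeta` (default 0.6).
#' @return The filtered `ensemble`.
#' @export
hairpin_subset <- function(x, rc, nbeta_threshold = 0.6) {
  if (nrow(rc) != n_frames(x)) stop("series and ensemble frame counts differ")
  subset_frames(x, which(rc$nbeta > nbeta_threshold))
}
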