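#' Conformational ensembles
#'
#' An `ensemble` holds an ordered set of coordinate frames over one
#' `topology`: coordinates in nm as an `n_atoms x 3 x n_frames` array plus a
#' per-frame metadata tibble (time in ps, replica id, temperature in K).
#'
#' @param topology A [build_topology()] object.
#' @param coords Numeric array `n_atoms x 3 x n_frames` (nm), or a single
#'   `n_atoms x 3` matrix.
#' @param time,replica,temperature Optional per-frame metadata vectors
#'   (recycled); `NA` marks unset metadata.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(topology, coords, time = NA_real_, replica = NA_integer_,
                     temperature = NA_real_) {
  validate_topology(topology)
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != n_atoms(topology)) {
    stop(sprintf("coordinate atom count (%d) != topology atom count (%d)",
                 dim(coords)[1], n_atoms(topology)))
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  nf <- dim(coords)[3]
  frames <- tibble::tibble(
    frame = seq_len(nf),
    time = rep_len(as.numeric(time), nf),
    replica = rep_len(as.integer(replica), nf),
    temperature = rep_len(as.numeric(temperature), nf)
  )
  # times must be non-decreasing within each replica
  for (r in unique(frames$replica[!is.na(frames$replica)])) {
    tt <- frames$time[which(frames$replica == r)]
    tt <- tt[!is.na(tt)]
    if (is.unsorted(tt)) stop("times not non-decreasing within replica ", r)
  }
  structure(list(topology = topology, coords = coords, frames = frames),
            class = "ensemble")
}

#' @rdname ensemble
#' @param x An `ensemble`.
#' @export
n_frames <- function(x) dim(x$coords)[3]

#' Extract one frame's coordinate matrix (nm)
#' @param x An `ensemble`.
#' @param i Frame index.
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(x, i) x$coords[, , i, drop = TRUE]

#' Keep a subset of frames
#' @param x An `ensemble`.
#' @param idx Frame indices to retain (in the given order).
#' @export
subset_frames <- function(x, idx) {
  stopifnot(all(idx >= 1), all(idx <= n_frames(x)))
  x$coords <- x$coords[, , idx, drop = FALSE]
  x$frames <- x$frames[idx, ]
  x$frames$frame <- seq_len(nrow(x$frames))
  x
}

#' @export
print.ensemble <- function(x, ...) {
  tr <- x$frames$time
  cat(sprintf("ensemble: %d frames x %d atoms", n_frames(x), n_atoms(x$topology)))
  if (any(!is.na(tr))) {
    cat(sprintf(", t = %g..%g ps", min(tr, na.rm = TRUE), max(tr, na.rm = TRUE)))
  }
  nrep <- length(unique(x$frames$replica[!is.na(x$frames$replica)]))
  if (nrep > 0) cat(sprintf(", %d replica(s)", nrep))
  cat("\n")
  invisible(x)
}

#' Read an ensemble from disk
#'
#' Two formats are supported: standard multi-model PDB (`format = "pdb"`,
#' one frame per MODEL block, coordinates converted from Angstrom to nm;
#' replica/temperature metadata is left unset) and the package's internal
#' plain-text frame store (`format = "store"`), which round-trips metadata
#' exactly.
#'
#' @param topology The `topology` the file's atoms correspond to.
#' @param path File path.
#' @param format `"pdb"` or `"store"` (default guessed from extension).
#' @return An `ensemble`.
#' @export
read_ensemble <- function(topology, path, format = c("auto", "pdb", "store")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "store"
  }
  if (format == "pdb") read_ensemble_pdb(topology, path) else read_store(topology, path)
}

read_ensemble_pdb <- function(topology, path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  counts <- if (length(model_starts) == 0) {
    sum(grepl("^ATOM", lines))
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts)) stop("unbalanced MODEL/ENDMDL records")
    mapply(function(s, e) sum(grepl("^ATOM", lines[s:e])), model_starts, ends)
  }
  if (length(unique(counts)) > 1) {
    stop("inconsistent atom counts between models: ",
         paste(sort(unique(counts)), collapse = " vs "))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nat <- ncol(xyz) / 3
  if (nat != n_atoms(topology)) {
    stop(sprintf("PDB atom count (%d) != topology atom count (%d)",
                 nat, n_atoms(topology)))
  }
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nat, 3, nf))
  for (k in seq_len(nf)) {
    coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) * NM_PER_ANGSTROM
  }
  ensemble(topology, coords)
}

#' Write an ensemble to disk
#'
#' @param x An `ensemble` (non-empty).
#' @param path Output path.
#' @param format `"pdb"` (multi-model, MODEL/ENDMDL with TER records per
#'   chain, coordinates in Angstrom) or `"store"` (internal plain-text store
#'   preserving time/replica/temperature).
#' @export
write_ensemble <- function(x, path, format = c("auto", "pdb", "store")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ensemble"))
  if (n_frames(x) == 0) stop("cannot write an empty ensemble")
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "store"
  }
  if (format == "pdb") write_ensemble_pdb(x, path) else write_store(x, path)
}

write_ensemble_pdb <- function(x, path) {
  a <- x$topology$atoms
  r <- x$topology$residues
  con <- file(path, "w")
  on.exit(close(con))
  multi <- n_frames(x) > 1
  for (k in seq_len(n_frames(x))) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- frame_coords(x, k) * ANGSTROM_PER_NM
    serial <- 0L
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$name[i]
      # PDB alignment: 1-3 char names start in column 14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_fmt, a$resid[i], a$chain[i],
        r$resno[match(a$residue[i], r$residue)],
        xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, a$element[i]
      ), con)
      last_of_chain <- i == nrow(a) || a$chain[i + 1] != a$chain[i]
      if (last_of_chain) {
        serial <- serial + 1L
        writeLines(sprintf("TER   %5d      %3s %1s%4d", serial, a$resid[i],
                           a$chain[i], r$resno[match(a$residue[i], r$residue)]), con)
      }
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Internal frame store: plain text, one header line
# "REMSTORE <n_atoms> <n_frames>", then per frame a metadata line
# "FRAME <time> <replica> <temperature>" followed by n_atoms lines of
# "x y z" in nm at full precision.
write_store <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(x); nat <- n_atoms(x$topology)
  writeLines(sprintf("REMSTORE %d %d", nat, nf), con)
  f <- x$frames
  for (k in seq_len(nf)) {
    writeLines(sprintf("FRAME %.17g %s %.17g",
                       f$time[k],
                       ifelse(is.na(f$replica[k]), "NA", f$replica[k]),
                       f$temperature[k]), con)
    m <- frame_coords(x, k)
    writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

read_store <- function(topology, path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  if (hdr[1] != "REMSTORE") stop("not an internal frame store: ", path)
  nat <- as.integer(hdr[2]); nf <- as.integer(hdr[3])
  if (nat != n_atoms(topology)) stop("store atom count != topology atom count")
  coords <- array(NA_real_, c(nat, 3, nf))
  time <- numeric(nf); replica <- integer(nf); temp <- numeric(nf)
  pos <- 2L
  for (k in seq_len(nf)) {
    meta <- strsplit(lines[pos], " ")[[1]]
    stopifnot(meta[1] == "FRAME")
    time[k] <- as.numeric(meta[2])
    replica[k] <- suppressWarnings(as.integer(meta[3]))
    temp[k] <- as.numeric(meta[4])
    block <- lines[(pos + 1L):(pos + nat)]
    coords[, , k] <- matrix(scan(text = block, quiet = TRUE), ncol = 3, byrow = TRUE)
    pos <- pos + nat + 1L
  }
  ensemble(topology, coords, time = time, replica = replica, temperature = temp)
}

#' Select the production window of an ensemble
#'
#' Retains frames from the listed replicas whose times fall in the half-open
#' window `(start, end]` on the stride grid `start + k * stride`. With the
#' half-open convention a 60-200 ns window at 50 ps stride yields exactly
#' 2,800 frames per replica (33,600 over twelve replicas).
#'
#' @param x An `ensemble` with time (and optionally replica) metadata.
#' @param start,end Window bounds in ps, `start < end`.
#' @param stride Stride in ps (> 0); must be a multiple of the source
#'   sampling interval.
#' @param replica_ids Replicas to keep (default: all present).
#' @return The production `ensemble`; empty (with a warning) when the window
#'   misses the trajectory.
#' @export
select_production <- function(x, start, end, stride, replica_ids = NULL) {
  stopifnot(inherits(x, "ensemble"), start < end, stride > 0)
  f <- x$frames
  if (all(is.na(f$time))) stop("ensemble has no time metadata")
  if (is.null(replica_ids)) {
    replica_ids <- unique(f$replica)
  }
  keep_rep <- if (all(is.na(replica_ids))) is.na(f$replica) else f$replica %in% replica_ids
  # source sampling interval per replica
  dt <- unique(round(diff(sort(unique(f$time[keep_rep]))), 9))
  dt <- dt[dt > 0]
  if (length(dt) > 0) {
    base <- min(dt)
    if (abs(stride / base - round(stride / base)) > 1e-9) {
      stop(sprintf("stride %g ps is not a multiple of the source sampling interval %g ps",
                   stride, base))
    }
  }
  on_grid <- abs((f$time - start) / stride - round((f$time - start) / stride)) < 1e-9
  keep <- keep_rep & !is.na(f$time) & f$time > start & f$time <= end & on_grid
  if (!any(keep)) {
    warning("production window selects no frames")
    return(subset_frames(x, integer(0)))
  }
  idx <- which(keep)
  idx <- idx[order(f$replica[idx], f$time[idx])]
  subset_frames(x, idx)
}

#' Aggregate sampling bookkeeping for an REMD protocol
#'
#' @param n_replicas Number of replicas.
#' @param length_ns Per-replica trajectory length in ns.
#' @return One-row tibble with the aggregate sampling in ns and microseconds
#'   (e.g. 64 replicas x 200 ns = 12.8 us).
#' @export
aggregate_sampling <- function(n_replicas, length_ns) {
  stopifnot(n_replicas >= 1, length_ns > 0)
  total_ns <- n_replicas * length_ns
  tibble::tibble(
    n_replicas = as.integer(n_replicas), length_ns = length_ns,
    total_ns = total_ns, total_us = total_ns / 1000
  )
}
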