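## File formats: xvg-dialect work series, work-set manifests, trajectory
## text formats and sidecar masses.

#' Read a two-column xvg-style dH/dlambda file
#'
#' Whitespace-separated (lambda or time, dH/dlambda) pairs; '#' and '@'
#' comment/metadata lines are tolerated. When the first column is time it
#' is rescaled linearly onto lambda in [0, 1] (forward) or [1, 0]
#' (reverse).
#'
#' @param path File path.
#' @param direction "forward" (0 -> 1) or "reverse" (1 -> 0).
#' @return A [dhdl_series()].
#' @export
read_dhdl_xvg <- function(path, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop(sprintf("no data lines in '%s'", path))
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad))
    stop(sprintf("malformed data line in '%s' (line %d)", path,
                 which(keep)[bad[1]]))
  x <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 1L)))
  y <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  if (any(is.na(x)) || any(is.na(y)) || any(!is.finite(y)))
    stop(sprintf("non-numeric or non-finite values in '%s'", path))
  rng <- range(x)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9 || abs(rng[2] - rng[1] - 1) > 1e-6) {
    ## time axis: map linearly onto the lambda path
    if (rng[2] == rng[1]) stop(sprintf("degenerate abscissa in '%s'", path))
    lam <- (x - rng[1]) / (rng[2] - rng[1])
  } else lam <- x
  dhdl_series(lam, y, direction)
}

#' Write a dH/dlambda series as a two-column xvg file
#'
#' @param series A [dhdl_series()].
#' @param path Output path.
#' @param comment Optional header comment.
#' @export
write_dhdl_xvg <- function(series, path, comment = NULL) {
  lam <- series$lambda_values
  y <- series$dhdl_values
  if (series$direction == "reverse") { lam <- rev(lam); y <- rev(y) }
  hdr <- c(sprintf("# direction: %s", series$direction),
           if (!is.null(comment)) paste("#", comment),
           "@ xaxis label \"lambda\"",
           "@ yaxis label \"dH/dl (kJ/mol)\"")
  writeLines(c(hdr, sprintf("%.10g %.10g", lam, y)), path)
  invisible(path)
}

#' Read a work-set manifest
#'
#' CSV with columns `direction` (forward/reverse), `pose`, `repeat`,
#' `path`, plus optional grouping columns (`host`, `guest`, `forcefield`).
#' Paths are resolved relative to the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return data.frame with absolute `path` column.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("direction", "pose", "repeat", "path")
  if (!all(need %in% names(m)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (!all(m$direction %in% c("forward", "reverse")))
    stop("manifest direction must be 'forward' or 'reverse'")
  base <- dirname(normalizePath(path))
  abs <- file.path(base, m$path)
  abs[file.exists(m$path)] <- m$path[file.exists(m$path)]
  missing <- !file.exists(abs)
  if (any(missing))
    stop("manifest refers to missing files: ",
         paste(utils::head(m$path[missing], 5L), collapse = ", "))
  m$path <- abs
  m
}

#' Read a trajectory from long-format CSV
#'
#' Columns `frame`, `atom`, `x`, `y`, `z` (nm); frames and atoms 1-based.
#' Masses come from a sidecar CSV with columns `atom`, `mass`.
#'
#' @param path Trajectory CSV.
#' @param masses_path Sidecar CSV with per-atom masses (amu).
#' @param label Ensemble label.
#' @return A [trajectory_ensemble()].
#' @export
read_trajectory_csv <- function(path, masses_path, label = "") {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "atom", "x", "y", "z")
  if (!all(need %in% names(tr)))
    stop("trajectory needs columns: ", paste(need, collapse = ", "))
  ms <- utils::read.csv(masses_path, stringsAsFactors = FALSE)
  if (!all(c("atom", "mass") %in% names(ms)))
    stop("masses sidecar needs columns atom, mass")
  n_frames <- max(tr$frame); n_atoms <- max(tr$atom)
  if (nrow(tr) != n_frames * n_atoms)
    stop("trajectory is not a complete frames x atoms grid")
  coords <- array(NA_real_, c(n_frames, n_atoms, 3L))
  idx <- cbind(tr$frame, tr$atom)
  coords[cbind(idx, 1L)] <- tr$x
  coords[cbind(idx, 2L)] <- tr$y
  coords[cbind(idx, 3L)] <- tr$z
  if (any(is.na(coords))) stop("missing frame/atom combinations")
  ms <- ms[order(ms$atom), ]
  trajectory_ensemble(coords, ms$mass, label = label)
}

#' Write a trajectory ensemble to long-format CSV (plus masses sidecar)
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param path Trajectory CSV path.
#' @param masses_path Masses sidecar path.
#' @export
write_trajectory_csv <- function(ensemble, path, masses_path) {
  dm <- dim(ensemble$coordinates)
  grid <- expand.grid(atom = seq_len(dm[2]), frame = seq_len(dm[1]))
  df <- data.frame(frame = grid$frame, atom = grid$atom,
                   x = as.vector(t(ensemble$coordinates[, , 1])),
                   y = as.vector(t(ensemble$coordinates[, , 2])),
                   z = as.vector(t(ensemble$coordinates[, , 3])))
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(data.frame(atom = seq_len(dm[2]), mass = ensemble$masses),
                   masses_path, row.names = FALSE)
  invisible(path)
}
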