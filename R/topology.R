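## Molecular topologies: atoms (with charges) and dihedral assignments.
## Supports the three repair transforms for over-defined dihedrals and the
## side-chain charge scaling experiment.

#' Construct a topology
#'
#' @param atoms data.frame with columns `index` (1-based, contiguous),
#'   `type`, `name`, `charge` (e), `mass` (amu), `residue`.
#' @param dihedrals data.frame with columns `ai, aj, ak, al` (1-based atom
#'   indices) and optional inline parameter columns `barrier_kj`,
#'   `phase_deg`, `periodicity` (one row per term; multiple rows per
#'   quadruple = multiple terms).
#' @return A `topology` object.
#' @export
topology <- function(atoms, dihedrals = NULL) {
  atoms <- as.data.frame(atoms)
  need <- c("index", "type", "name", "charge", "mass", "residue")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns: ", paste(need, collapse = ", "))
  if (!identical(as.integer(atoms$index), seq_len(nrow(atoms))))
    stop("atom indices must be 1-based and contiguous")
  if (any(!is.finite(atoms$charge))) stop("charges must be finite")
  if (is.null(dihedrals)) {
    dihedrals <- data.frame(ai = integer(), aj = integer(), ak = integer(),
                            al = integer(), barrier_kj = numeric(),
                            phase_deg = numeric(), periodicity = integer())
  }
  dihedrals <- as.data.frame(dihedrals)
  for (col in c("ai", "aj", "ak", "al")) {
    if (any(dihedrals[[col]] < 1L | dihedrals[[col]] > nrow(atoms)))
      stop("dihedral atom index out of range")
  }
  structure(list(atoms = atoms, dihedrals = dihedrals), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d dihedral terms, net charge %+.4f e\n",
              nrow(x$atoms), nrow(x$dihedrals), sum(x$atoms$charge)))
  invisible(x)
}

#' Parse `[ atoms ]` and `[ dihedrals ]` sections of a GROMACS .top/.itp
#'
#' Reads the atom table (index, type, residue, name, charge, mass) and the
#' proper-dihedral assignments (function types 1 and 9; inline parameters
#' when present).
#'
#' @param text Character scalar or vector of lines.
#' @return A [topology()].
#' @export
parse_gromacs_topology <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else as.character(text)
  section <- ""
  atoms <- list(); dihs <- list()
  for (i in seq_along(lines)) {
    tr <- trimws(lines[i])
    if (tr == "" || grepl("^[;#]", tr)) next
    sec <- regmatches(tr, regexec("^\\[\\s*([a-z_]+)\\s*\\]", tr))[[1]]
    if (length(sec)) { section <- sec[2]; next }
    tok <- strsplit(tr, "[[:space:]]+")[[1]]
    cm <- which(tok == ";")
    if (length(cm)) tok <- tok[seq_len(cm[1] - 1L)]
    if (section == "atoms") {
      if (length(tok) < 8L)
        stop(sprintf("malformed [ atoms ] line %d: '%s'", i, lines[i]))
      atoms[[length(atoms) + 1L]] <- data.frame(
        index = as.integer(tok[1]), type = tok[2],
        residue = tok[4], name = tok[5],
        charge = as.numeric(tok[7]), mass = as.numeric(tok[8]),
        stringsAsFactors = FALSE)
    } else if (section == "dihedrals") {
      if (length(tok) < 5L)
        stop(sprintf("malformed [ dihedrals ] line %d: '%s'", i, lines[i]))
      funct <- as.integer(tok[5])
      if (!(funct %in% c(1L, 9L))) next   # propers only
      row <- data.frame(ai = as.integer(tok[1]), aj = as.integer(tok[2]),
                        ak = as.integer(tok[3]), al = as.integer(tok[4]),
                        barrier_kj = NA_real_, phase_deg = NA_real_,
                        periodicity = NA_integer_)
      if (length(tok) >= 8L) {
        row$phase_deg <- as.numeric(tok[6])
        row$barrier_kj <- as.numeric(tok[7])
        row$periodicity <- as.integer(tok[8])
      }
      dihs[[length(dihs) + 1L]] <- row
    }
  }
  if (length(atoms) == 0L) stop("no [ atoms ] section found")
  a <- do.call(rbind, atoms)
  a <- a[, c("index", "type", "name", "charge", "mass", "residue")]
  topology(a, if (length(dihs)) do.call(rbind, dihs) else NULL)
}

#' Write a topology as GROMACS `[ atoms ]` / `[ dihedrals ]` sections
#'
#' @param topo A [topology()].
#' @return Character scalar.
#' @export
write_gromacs_topology <- function(topo) {
  a <- topo$atoms
  al <- sprintf("%6d %6s %6d %6s %6s %6d %12.6f %10.4f",
                a$index, a$type, 1L, a$residue, a$name, a$index,
                a$charge, a$mass)
  d <- topo$dihedrals
  dl <- character(0)
  if (nrow(d)) {
    dl <- ifelse(is.na(d$barrier_kj),
      sprintf("%6d %6d %6d %6d %5d", d$ai, d$aj, d$ak, d$al, 9L),
      sprintf("%6d %6d %6d %6d %5d %10.3f %14.8f %4d",
              d$ai, d$aj, d$ak, d$al, 9L, d$phase_deg, d$barrier_kj,
              d$periodicity))
  }
  paste(c("[ atoms ]", al, "", "[ dihedrals ]", dl), collapse = "\n")
}

## Canonical type quadruple of a dihedral assignment row.
.assignment_canonical <- function(topo, row) {
  ty <- topo$atoms$type[c(row$ai, row$aj, row$ak, row$al)]
  .canonical_quad_str(paste(ty, collapse = "-"))
}

#' Resolve over-defined dihedral assignments in a topology
#'
#' For every dihedral assignment whose atom-type quadruple matches one of
#' the flagged over-definition groups, replaces the assignment's inline
#' parameter terms according to the chosen policy:
#' \describe{
#'   \item{first-match}{use the variant appearing earliest in the parameter
#'     file (what antechamber effectively does);}
#'   \item{preferred-variant}{use the variant selected by `preference`
#'     (default: highest force constant, i.e. the sugar-specific stiff set);}
#'   \item{all-variants}{emit one term per term of every variant
#'     simultaneously (the PrimaDORAC interpretation, over-defining the
#'     dihedral on purpose).}
#' }
#' The transform replaces (never appends to) the matched assignments'
#' terms, so applying it twice is a no-op. Assignment atom ordering is
#' preserved.
#'
#' @param topo A [topology()].
#' @param params Parsed parameter table ([parse_dihedral_params()]).
#' @param groups Output of [detect_overdefined()] on `params`.
#' @param policy "first-match", "preferred-variant" or "all-variants".
#' @param preference For "preferred-variant": either a function taking the
#'   list of variant data.frames and returning the index of exactly one, or
#'   an explicit variant index. Default picks the variant with the highest
#'   maximum barrier.
#' @return The transformed [topology()].
#' @export
apply_dihedral_policy <- function(topo, params, groups,
                                  policy = c("first-match",
                                             "preferred-variant",
                                             "all-variants"),
                                  preference = NULL) {
  policy <- match.arg(policy)
  if (nrow(groups) == 0L || nrow(topo$dihedrals) == 0L) return(topo)
  d <- topo$dihedrals
  canon <- vapply(seq_len(nrow(d)), function(i)
    .assignment_canonical(topo, d[i, ]), character(1))
  new_rows <- list()
  for (i in seq_len(nrow(d))) {
    cq <- canon[i]
    if (!(cq %in% groups$canonical)) {
      new_rows[[length(new_rows) + 1L]] <- d[i, ]
      next
    }
    variants <- group_variants(params, cq)
    chosen <- switch(policy,
      "first-match" = variants[1L],
      "preferred-variant" = {
        k <- if (is.null(preference)) {
          which.max(vapply(variants, function(v) max(v$barrier_kj),
                           numeric(1)))
        } else if (is.function(preference)) {
          preference(variants)
        } else as.integer(preference)
        if (length(k) != 1L || is.na(k) || k < 1L || k > length(variants))
          stop("preference must select exactly one variant")
        variants[k]
      },
      "all-variants" = variants)
    terms <- do.call(rbind, chosen)
    ## deduplicate identical terms so the transform is idempotent even if
    ## variants share a term
    key <- paste(terms$periodicity, signif(terms$barrier_kj, 12),
                 signif(terms$phase_deg, 12))
    terms <- terms[!duplicated(key), , drop = FALSE]
    rows <- d[rep(i, nrow(terms)), , drop = FALSE]
    rows$barrier_kj <- terms$barrier_kj
    rows$phase_deg <- terms$phase_deg
    rows$periodicity <- terms$periodicity
    new_rows[[length(new_rows) + 1L]] <- rows
  }
  ## collapse duplicate assignment rows produced by repeated application
  nd <- do.call(rbind, new_rows)
  key <- paste(nd$ai, nd$aj, nd$ak, nd$al, nd$periodicity,
               signif(nd$barrier_kj, 12), signif(nd$phase_deg, 12))
  nd <- nd[!duplicated(key), , drop = FALSE]
  rownames(nd) <- NULL
  topology(topo$atoms, nd)
}

#' Scale partial charges of selected atoms
#'
#' Multiplies the charges of the selected atoms by `factor` (e.g. 0.81 to
#' bring GAFF side-chain charges closer to CGenFF magnitudes); all other
#' fields are untouched. The induced net-charge change,
#' (factor - 1) * sum(selected charges), is attached as attribute
#' `net_charge_delta`.
#'
#' @param topo A [topology()].
#' @param selection Atom indices (1-based) to scale.
#' @param factor Dimensionless scaling factor.
#' @return The modified [topology()] with attribute `net_charge_delta`.
#' @export
scale_charges <- function(topo, selection, factor) {
  stopifnot_scalar(factor, "factor")
  selection <- as.integer(selection)
  if (length(selection) == 0L) {
    warning("empty selection: charges unchanged")
    attr(topo, "net_charge_delta") <- 0
    return(topo)
  }
  if (any(selection < 1L | selection > nrow(topo$atoms)))
    stop("selection indices out of range")
  delta <- (factor - 1) * sum(topo$atoms$charge[selection])
  topo$atoms$charge[selection] <- factor * topo$atoms$charge[selection]
  attr(topo, "net_charge_delta") <- delta
  topo
}
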