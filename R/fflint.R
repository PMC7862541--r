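## Force-field dihedral parameter linting.
##
## GAFF 2.x parameter files assign some atom-type-specific dihedral
## quadruples several distinct parameter sets with the same periodicity,
## entered non-sequentially (e.g. the sugar-ring c3-c3-os-c3 torsion, which
## has both a general-purpose and a stiffer sugar-specific set). Depending
## on which set the topology builder picks, the same molecule samples a
## different potential. This module parses dihedral blocks, detects the
## pathology and applies the repair policies.

#' Parse a dihedral parameter block
#'
#' Reads proper-dihedral parameter lines from AMBER parm .dat / .frcmod
#' DIHE sections or a GROMACS .itp `[ dihedraltypes ]` block. AMBER
#' multi-term entries (negative periodicity = continuation flag) are
#' grouped into one parameter set; barriers are converted to kJ/mol at
#' parse time (AMBER dialects are kcal/mol, GROMACS is kJ/mol already).
#'
#' @param text Character scalar (block with newlines) or vector of lines.
#' @param dialect "amber-dat", "amber-frcmod" or "gromacs-itp".
#' @return data.frame with one row per dihedral term: columns `a1..a4`
#'   (atom types), `quad`, `canonical` (direction-normalized quadruple),
#'   `divider`, `barrier_kj`, `phase_deg`, `periodicity` (absolute value),
#'   `continuation` (source periodicity was negative), `set_id` (parameter
#'   set the term belongs to: continuation lines share their predecessor's
#'   set), `source_line`, `wildcard`, `dialect`.
#' @export
parse_dihedral_params <- function(text,
                                  dialect = c("amber-dat", "amber-frcmod",
                                              "gromacs-itp")) {
  dialect <- match.arg(dialect)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else as.character(text)
  out <- list()
  set_id <- 0L
  prev_continuation <- FALSE
  prev_quad <- ""
  in_section <- dialect != "amber-frcmod" && dialect != "gromacs-itp"
  for (i in seq_along(lines)) {
    ln <- lines[i]
    trimmed <- trimws(ln)
    if (dialect == "amber-frcmod") {
      if (grepl("^DIHE", trimmed)) { in_section <- TRUE; next }
      if (in_section && (trimmed == "" ||
          grepl("^(MASS|BOND|ANGLE|IMPROPER|NONBON)", trimmed))) {
        in_section <- FALSE; next
      }
      if (!in_section) next
    }
    if (dialect == "gromacs-itp") {
      if (grepl("^\\[\\s*dihedraltypes\\s*\\]", trimmed)) {
        in_section <- TRUE; next
      }
      if (grepl("^\\[", trimmed)) { in_section <- FALSE; next }
      if (!in_section) next
    }
    if (trimmed == "" || grepl("^[;#!]", trimmed)) next

    if (dialect == "gromacs-itp") {
      tok <- strsplit(trimmed, "[[:space:]]+")[[1]]
      tok <- tok[tok != ""]
      cm <- which(tok == ";")
      if (length(cm)) tok <- tok[seq_len(cm[1] - 1L)]
      if (length(tok) < 8L)
        stop(sprintf("malformed gromacs dihedraltypes line %d: '%s'", i, ln))
      funct <- as.integer(tok[5])
      if (!(funct %in% c(1L, 4L, 9L))) next  # propers only
      if (funct == 4L) next                  # periodic improper: skip
      types <- tok[1:4]
      phase <- as.numeric(tok[6])
      barrier <- as.numeric(tok[7])          # kJ/mol
      pn <- as.numeric(tok[8])
      divider <- 1L
    } else {
      ## AMBER: "A -B -C -D  IDIVF  PK  PHASE  PN"; atom field is
      ## dash-separated, possibly with spaces around the dashes
      pat <- paste0("^([A-Za-z0-9*+]{1,2})\\s*-\\s*([A-Za-z0-9*+]{1,2})",
                    "\\s*-\\s*([A-Za-z0-9*+]{1,2})\\s*-\\s*",
                    "([A-Za-z0-9*+]{1,2})\\s+(.*)$")
      m <- regmatches(trimmed, regexec(pat, trimmed))[[1]]
      if (length(m) == 0L)
        stop(sprintf("malformed %s dihedral line %d: '%s'", dialect, i, ln))
      types <- m[2:5]
      rest <- strsplit(trimws(m[6]), "[[:space:]]+")[[1]]
      if (length(rest) < 4L)
        stop(sprintf("malformed %s dihedral line %d: '%s'", dialect, i, ln))
      divider <- as.integer(rest[1])
      barrier <- as.numeric(rest[2]) * .kcal_kJ   # kcal -> kJ
      phase <- as.numeric(rest[3])
      pn <- as.numeric(rest[4])
      if (any(is.na(c(divider, barrier, phase, pn))))
        stop(sprintf("malformed %s dihedral line %d: '%s'", dialect, i, ln))
    }
    continuation <- pn < 0
    quad <- paste(types, collapse = "-")
    same_set <- FALSE
    if (prev_continuation && quad == prev_quad) same_set <- TRUE
    if (!same_set) set_id <- set_id + 1L
    out[[length(out) + 1L]] <- data.frame(
      a1 = types[1], a2 = types[2], a3 = types[3], a4 = types[4],
      quad = quad,
      canonical = .canonical_quad_str(quad),
      divider = divider,
      barrier_kj = barrier,
      phase_deg = phase,
      periodicity = abs(as.integer(round(pn))),
      continuation = continuation,
      set_id = set_id,
      source_line = i,
      wildcard = any(types %in% c("X", "x", "*")),
      dialect = dialect,
      stringsAsFactors = FALSE)
    prev_continuation <- continuation
    prev_quad <- quad
  }
  if (length(out) == 0L) {
    return(data.frame(a1 = character(), a2 = character(), a3 = character(),
                      a4 = character(), quad = character(),
                      canonical = character(), divider = integer(),
                      barrier_kj = numeric(), phase_deg = numeric(),
                      periodicity = integer(), continuation = logical(),
                      set_id = integer(), source_line = integer(),
                      wildcard = logical(), dialect = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Write dihedral parameters back to a dialect
#'
#' Inverse of [parse_dihedral_params()] up to whitespace normalization:
#' parse -> write -> parse is a fixed point.
#'
#' @param params data.frame from [parse_dihedral_params()].
#' @param dialect Output dialect (default: the one recorded in `params`).
#' @return Character scalar with one line per term.
#' @export
write_dihedral_params <- function(params, dialect = NULL) {
  if (nrow(params) == 0L) return("")
  dialect <- dialect %||% params$dialect[1]
  params <- params[order(params$source_line), , drop = FALSE]
  lines <- character(nrow(params))
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    pn <- p$periodicity * if (p$continuation) -1 else 1
    if (dialect == "gromacs-itp") {
      lines[i] <- sprintf("%-4s %-4s %-4s %-4s %3d %10.3f %14.8f %4d",
                          p$a1, p$a2, p$a3, p$a4, 9L, p$phase_deg,
                          p$barrier_kj, pn)
    } else {
      lines[i] <- sprintf("%-2s-%-2s-%-2s-%-2s %4d %12.7f %10.3f %6.1f",
                          p$a1, p$a2, p$a3, p$a4, p$divider,
                          p$barrier_kj / .kcal_kJ, p$phase_deg, pn)
    }
  }
  if (dialect == "gromacs-itp")
    lines <- c("[ dihedraltypes ]", lines)
  if (dialect == "amber-frcmod")
    lines <- c("DIHE", lines, "")
  paste(lines, collapse = "\n")
}

## Split a parsed parameter table into parameter sets:
## list of data.frames, one per set_id, with attributes.
.param_sets <- function(params) {
  split(params, params$set_id)
}

#' Detect over-defined dihedral parameter groups
#'
#' Groups the parsed dihedral sets by their direction-normalized atom-type
#' quadruple (lexicographic minimum of forward and reversed order) and flags
#' a quadruple as over-defined iff all three conditions of the pathology
#' hold:
#' \enumerate{
#'   \item atom-type specific — no wildcard types in any member;
#'   \item at least two parameter sets share at least one periodicity while
#'     differing in barrier or phase at that periodicity (sets with fully
#'     disjoint periodicities are legitimate multi-term dihedrals);
#'   \item the sets are entered non-sequentially — separated by at least one
#'     unrelated line.
#' }
#'
#' @param params data.frame from [parse_dihedral_params()] (one file).
#' @return data.frame with one row per flagged group: `canonical`,
#'   `n_variants`, `periodicities` (shared, comma-joined), `barriers_kj`
#'   (per variant at the first shared periodicity, comma-joined),
#'   `first_lines` (comma-joined first source line of each variant),
#'   `non_sequential`. Ordered by first source line.
#' @export
detect_overdefined <- function(params) {
  empty <- data.frame(canonical = character(), n_variants = integer(),
                      periodicities = character(), barriers_kj = character(),
                      first_lines = character(), non_sequential = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(params) == 0L) return(empty)
  sets <- .param_sets(params)
  canon <- vapply(sets, function(s) s$canonical[1], character(1))
  groups <- split(seq_along(sets), canon)
  res <- list()
  for (cq in names(groups)) {
    idx <- groups[[cq]]
    if (length(idx) < 2L) next
    members <- sets[idx]
    if (any(vapply(members, function(s) any(s$wildcard), logical(1)))) next

    ## condition 2: some pair of sets shares a periodicity with different
    ## barrier/phase there
    shared_conflict <- FALSE
    shared_pn <- integer(0)
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (j <= i) next
        pi <- members[[i]]; pj <- members[[j]]
        common <- intersect(pi$periodicity, pj$periodicity)
        for (pn in common) {
          bi <- pi[pi$periodicity == pn, ]
          bj <- pj[pj$periodicity == pn, ]
          if (abs(bi$barrier_kj[1] - bj$barrier_kj[1]) > 1e-9 ||
              abs(bi$phase_deg[1] - bj$phase_deg[1]) > 1e-9) {
            shared_conflict <- TRUE
            shared_pn <- union(shared_pn, pn)
          }
        }
      }
    }
    if (!shared_conflict) next

    ## condition 3: non-sequential — at least one unrelated source line
    ## between consecutive variants
    lines_of <- lapply(members, function(s) range(s$source_line))
    ord <- order(vapply(lines_of, `[`, numeric(1), 1L))
    members <- members[ord]; lines_of <- lines_of[ord]
    non_seq <- FALSE
    group_lines <- sort(unlist(lapply(members, function(s) s$source_line)))
    other_lines <- setdiff(params$source_line, group_lines)
    for (k in seq_len(length(members) - 1L)) {
      gap <- other_lines > lines_of[[k]][2] & other_lines < lines_of[[k + 1L]][1]
      if (any(gap)) { non_seq <- TRUE; break }
    }
    if (!non_seq) next

    first_pn <- shared_pn[1]
    bar <- vapply(members, function(s) {
      b <- s$barrier_kj[s$periodicity == first_pn]
      if (length(b)) b[1] else NA_real_
    }, numeric(1))
    res[[length(res) + 1L]] <- data.frame(
      canonical = cq,
      n_variants = length(members),
      periodicities = paste(sort(shared_pn), collapse = ","),
      barriers_kj = paste(signif(bar, 10), collapse = ","),
      first_lines = paste(vapply(members, function(s)
        min(s$source_line), numeric(1)), collapse = ","),
      non_sequential = TRUE,
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(empty)
  df <- do.call(rbind, res)
  df <- df[order(as.numeric(vapply(strsplit(df$first_lines, ","),
                                   `[`, character(1), 1L))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Extract the variant parameter sets of one over-defined group
#'
#' @param params Parsed parameter table.
#' @param canonical Canonical quadruple of the group.
#' @return List of data.frames, one per variant set, ordered by source line.
#' @export
group_variants <- function(params, canonical) {
  sets <- .param_sets(params[params$canonical == canonical, , drop = FALSE])
  sets[order(vapply(sets, function(s) min(s$source_line), numeric(1)))]
}
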