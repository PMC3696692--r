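# Atom selection grammar: clauses joined by "and", e.g.
#   "chain A and resid 423-431 and name CA"
# Clause keys: chain (one or more chain ids), resid (numbers, ranges and
# comma lists), name (atom names), elty/element (element symbols).

#' Construct an atom selection
#'
#' @param indices 1-based atom indices into the ensemble atom table; must be
#'   non-empty and unique. Stored in increasing order.
#' @param label human-readable label.
#' @return an object of class `AtomSelection`.
#' @export
atom_selection <- function(indices, label = "selection") {
  indices <- as.integer(indices)
  if (length(indices) == 0) stop("empty atom selection '", label, "'")
  if (anyDuplicated(indices)) stop("duplicate indices in selection '", label, "'")
  structure(list(label = label, indices = sort(indices)), class = "AtomSelection")
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat(sprintf("AtomSelection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

#' @export
length.AtomSelection <- function(x) length(x$indices)

parse_resid_tokens <- function(txt) {
  toks <- unlist(strsplit(txt, "[,[:space:]]+"))
  toks <- toks[nzchar(toks)]
  out <- integer(0)
  for (tk in toks) {
    if (grepl("^-?[0-9]+--?[0-9]+$", tk) || grepl("^[0-9]+-[0-9]+$", tk)) {
      ab <- as.integer(strsplit(tk, "(?<=[0-9])-", perl = TRUE)[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", tk)) {
      out <- c(out, as.integer(tk))
    } else stop("cannot parse resid token '", tk, "'")
  }
  out
}

#' Resolve a selection expression against an ensemble
#'
#' The grammar is a conjunction of clauses joined by `and`:
#' `chain <id...>`, `resid <n|n-m|n,m,...>`, `name <atom names>`,
#' `element <symbols>`. Matching is case-sensitive for chains and
#' case-insensitive for atom names. An expression that matches no atoms is
#' an error, as is a referenced chain or residue absent from the structure.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param spec selection expression string, or an integer vector of atom
#'   indices taken verbatim.
#' @param label optional label; defaults to the expression itself.
#' @return an [atom_selection()].
#' @examples
#' helix <- make_ideal_helix(12)
#' resolve_selection(helix, "resid 2-5 and name CA")
#' @export
resolve_selection <- function(ensemble, spec, label = NULL) {
  at <- ensemble$atoms
  if (is.numeric(spec)) {
    return(atom_selection(spec, label %||% "indexed"))
  }
  keep <- rep(TRUE, nrow(at))
  clauses <- strsplit(spec, "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    cl <- trimws(cl)
    m <- regmatches(cl, regexec("^([a-zA-Z]+)\\s+(.+)$", cl))[[1]]
    if (length(m) != 3) stop("cannot parse selection clause '", cl, "'")
    key <- tolower(m[2]); val <- m[3]
    if (key == "chain") {
      want <- unlist(strsplit(val, "[,[:space:]]+"))
      missing <- setdiff(want, unique(at$chain))
      if (length(missing)) stop("unknown chain '", missing[1], "' in selection")
      keep <- keep & at$chain %in% want
    } else if (key == "resid") {
      want <- parse_resid_tokens(val)
      missing <- setdiff(want, unique(at$resid))
      if (length(missing) == length(want))
        stop("unknown resid '", missing[1], "' in selection")
      keep <- keep & at$resid %in% want
    } else if (key == "name") {
      want <- toupper(unlist(strsplit(val, "[,[:space:]]+")))
      keep <- keep & toupper(at$name) %in% want
    } else if (key %in% c("element", "elty")) {
      want <- toupper(unlist(strsplit(val, "[,[:space:]]+")))
      keep <- keep & toupper(at$element) %in% want
    } else stop("unknown selection key '", key, "'")
  }
  if (!any(keep)) stop("selection '", spec, "' matches no atoms")
  atom_selection(which(keep), label %||% spec)
}

#' Union of two atom selections
#' @param a,b `AtomSelection` objects on the same ensemble.
#' @param label label for the result.
#' @return an [atom_selection()] containing the union of indices.
#' @export
selection_union <- function(a, b, label = NULL) {
  atom_selection(union(a$indices, b$indices),
                 label %||% paste(a$label, "|", b$label))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
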