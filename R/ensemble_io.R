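# Ensemble, trace and alignment I/O. Everything downstream consumes only the
# containers defined here: StructureEnsemble, AtomSelection, DeerTrace,
# AlignmentBlock.

# Standard atomic masses (amu), IUPAC 2021 abridged. Unknown elements fall
# back to carbon with a warning (see element_mass()).
.ATOMIC_MASSES <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA_ = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45, K = 39.098,
  CA = 40.078, MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
  CU = 63.546, ZN = 65.38, SE = 78.971, BR = 79.904, I = 126.904
)

#' Look up atomic masses by element symbol
#'
#' Unknown symbols fall back to the mass of carbon with a warning, so that
#' exotic heteroatoms never abort an analysis.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA_"
  m <- .ATOMIC_MASSES[key]
  bad <- is.na(m)
  if (any(bad)) {
    warning("unknown element symbol(s) ", paste(unique(element[bad]), collapse = ", "),
            "; using carbon mass", call. = FALSE)
    m[bad] <- .ATOMIC_MASSES[["C"]]
  }
  unname(m)
}

# Infer element from a PDB atom name when columns 77-78 are blank:
# strip leading digits, take the first alphabetic character; keep two-letter
# symbols when the full stripped name matches a known element (FE, MG, ...).
infer_element <- function(name) {
  stripped <- toupper(gsub("^[0-9']+", "", trimws(name)))
  two <- substr(stripped, 1, 2)
  one <- substr(stripped, 1, 1)
  ifelse(two %in% names(.ATOMIC_MASSES), ifelse(nchar(stripped) == 2, two, one), one)
}

#' Construct a structure ensemble
#'
#' A `StructureEnsemble` is the package's stand-in for a molecular-dynamics
#' trajectory: a fixed atom table plus an `F x N x 3` coordinate array in
#' Angstrom, one slice per frame.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `resid`,
#'   `chain`, `element`, `mass` (mass filled from [element_mass()] when
#'   absent).
#' @param coords numeric array `F x N x 3` (Angstrom). A single `N x 3`
#'   matrix is promoted to one frame.
#' @param frame_times optional numeric vector of frame times in ns.
#' @return an object of class `StructureEnsemble`.
#' @export
structure_ensemble <- function(atoms, coords, frame_times = NULL) {
  stopifnot(is.data.frame(atoms))
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[2] != nrow(atoms))
    stop("coords has ", dim(coords)[2], " atoms but the atom table has ", nrow(atoms))
  if (!all(is.finite(coords))) stop("non-finite coordinates in ensemble")
  if (anyDuplicated(atoms$serial)) stop("duplicated atom serial numbers")
  if (is.null(atoms$element)) atoms$element <- infer_element(atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[1])
    stop("frame_times length does not match frame count")
  structure(list(atoms = atoms, coords = coords, frame_times = frame_times),
            class = "StructureEnsemble")
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  cat(sprintf("StructureEnsemble: %d frame(s) x %d atoms, %d chain(s)\n",
              n_frames(x), n_atoms(x), length(unique(x$atoms$chain))))
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ensemble a `StructureEnsemble`.
#' @return integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[2]

#' Extract one frame's coordinates as an N x 3 matrix
#' @param ensemble a `StructureEnsemble`.
#' @param frame 1-based frame index.
#' @return numeric `N x 3` matrix (Angstrom).
#' @export
frame_coords <- function(ensemble, frame) {
  stopifnot(frame >= 1, frame <= n_frames(ensemble))
  matrix(ensemble$coords[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a multi-MODEL PDB file as a structure ensemble
#'
#' Each MODEL becomes one frame; a file without MODEL records yields a
#' single-frame ensemble. ATOM and HETATM records are retained. The element
#' is taken from columns 77-78 when present, otherwise inferred from the
#' atom name.
#'
#' @param path path to a PDB file.
#' @return a [structure_ensemble()].
#' @details The file is validated before parsing: every MODEL must contain
#'   the same number of coordinate records (a mismatch is an error naming
#'   the offending MODEL) and every coordinate field must parse (an
#'   unparsable line is an error with its line number). Parsing itself is
#'   delegated to [bio3d::read.pdb()].
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_coord <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_coord)) stop("no ATOM/HETATM records in ", path)
  coord_idx <- which(is_coord)
  xyz_txt <- cbind(substr(lines[coord_idx], 31, 38),
                   substr(lines[coord_idx], 39, 46),
                   substr(lines[coord_idx], 47, 54))
  xyz <- suppressWarnings(matrix(as.numeric(xyz_txt), ncol = 3L))
  if (anyNA(xyz)) {
    bad <- coord_idx[which(rowSums(is.na(xyz)) > 0)[1]]
    stop("unparsable coordinate line ", bad, " in ", path, ": ", lines[bad])
  }
  model_starts <- which(rec == "MODEL ")
  multi <- length(model_starts) > 0
  if (multi) {
    # atoms per MODEL block: count coordinate records between MODEL/ENDMDL
    ends <- which(rec == "ENDMDL")
    if (length(ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    counts <- vapply(seq_along(model_starts), function(i)
      sum(is_coord[model_starts[i]:ends[i]]), integer(1))
    if (length(unique(counts)) > 1) {
      off <- which(counts != counts[1])[1]
      stop("MODEL ", trimws(substr(lines[model_starts[off]], 7, 14)),
           " has ", counts[off], " atoms; expected ", counts[1])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n <- if (multi) sum(is_coord[model_starts[1]:which(rec == "ENDMDL")[1]]) else nrow(at)
  at <- at[seq_len(n), , drop = FALSE]
  elem <- trimws(at$elesy)
  elem[is.na(elem) | elem == ""] <- infer_element(at$elety[is.na(elem) | elem == ""])
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      resname = trimws(at$resid), resid = at$resno,
                      chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
                      element = elem, stringsAsFactors = FALSE)
  atoms$mass <- element_mass(atoms$element)
  xyzm <- pdb$xyz
  if (is.vector(xyzm)) xyzm <- matrix(xyzm, nrow = 1L)
  f <- nrow(xyzm)
  coords <- array(0, c(f, n, 3L))
  for (i in seq_len(f)) coords[i, , ] <- matrix(xyzm[i, ], ncol = 3L, byrow = TRUE)
  structure_ensemble(atoms, coords)
}

#' Write a structure ensemble as a multi-MODEL PDB file
#'
#' @param ensemble a `StructureEnsemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  at <- ensemble$atoms
  nm <- ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(ensemble, f)
    writeLines(sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       "ATOM", at$serial, nm, at$resname, at$chain, at$resid,
                       xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Construct a DEER dipolar-evolution trace
#'
#' @param t times in microseconds, `t[1] = 0`, strictly increasing.
#' @param v real echo amplitudes; renormalized so `v[1] = 1` unless
#'   `normalize = FALSE`.
#' @param normalize renormalize to unit amplitude at zero time.
#' @return an object of class `DeerTrace`.
#' @export
deer_trace <- function(t, v, normalize = TRUE) {
  stopifnot(length(t) == length(v), all(is.finite(t)), all(is.finite(v)))
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (any(t < 0)) stop("negative times in trace")
  if (abs(t[1]) > 1e-9)
    stop("trace does not start at t = 0; zero-time correction is out of scope")
  t[1] <- 0
  if (normalize) v <- v / v[1]
  structure(list(t = t, v = v), class = "DeerTrace")
}

#' @export
print.DeerTrace <- function(x, ...) {
  cat(sprintf("DeerTrace: %d points, t in [0, %.3f] us\n", length(x$t), max(x$t)))
  invisible(x)
}

#' Read a two-column ASCII DEER trace
#'
#' Expects whitespace- or comma-delimited `time amplitude` rows; lines
#' starting with `#` are comments. A comment of the form `# units: ns` (or
#' `us`) declares the time unit; otherwise `time_unit` applies. Amplitudes
#' are renormalized to `v = 1` at `t = 0`.
#'
#' @param path input path.
#' @param time_unit `"us"` or `"ns"`; ignored when the file declares units.
#' @return a [deer_trace()].
#' @export
read_deer_trace <- function(path, time_unit = c("us", "ns")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  unit_line <- grep("units?\\s*[:=]", hdr, value = TRUE, ignore.case = TRUE)
  if (length(unit_line)) {
    if (grepl("\\bns\\b", unit_line[1], ignore.case = TRUE)) time_unit <- "ns"
    else if (grepl("\\b(us|µs)\\b", unit_line[1], ignore.case = TRUE)) time_unit <- "us"
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  body <- gsub(",", " ", body)
  fields <- strsplit(trimws(body), "\\s+")
  if (any(lengths(fields) < 2)) stop("malformed trace line in ", path)
  t <- as.numeric(vapply(fields, `[`, "", 1))
  v <- as.numeric(vapply(fields, `[`, "", 2))
  if (anyNA(t) || anyNA(v)) stop("non-numeric values in ", path)
  if (time_unit == "ns") t <- t / 1000
  deer_trace(t, v)
}

#' Write a DEER trace as two-column ASCII
#'
#' @param trace a `DeerTrace`.
#' @param path output path.
#' @param digits significant digits to print.
#' @return `path`, invisibly.
#' @export
write_deer_trace <- function(trace, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# DEER dipolar evolution trace", "# units: us"), con)
  writeLines(sprintf("%.*g %.*g", digits, trace$t, digits, trace$v), con)
  invisible(path)
}

#' Construct an alignment block
#'
#' @param ids sequence identifiers.
#' @param rows equal-length gapped sequences (gap character `-`).
#' @param region_spans named list of 0-based half-open column intervals
#'   `c(start, end)` marking e.g. transmembrane-domain segments. Defaults to
#'   one span covering the full alignment.
#' @return an object of class `AlignmentBlock`.
#' @export
alignment_block <- function(ids, rows, region_spans = NULL) {
  stopifnot(length(ids) == length(rows), length(rows) >= 1)
  rows <- unname(toupper(gsub("\\.", "-", rows)))
  w <- nchar(rows)
  if (length(unique(w)) > 1) {
    bad <- ids[which(w != w[1])[1]]
    stop("ragged alignment: sequence '", bad, "' has a different length")
  }
  nc <- w[1]
  if (is.null(region_spans)) region_spans <- list(full = c(0L, nc))
  for (nmr in names(region_spans)) {
    sp <- region_spans[[nmr]]
    if (sp[1] < 0 || sp[2] > nc || sp[1] > sp[2])
      stop("region span '", nmr, "' outside [0, ", nc, ")")
  }
  structure(list(ids = as.character(ids), rows = rows, region_spans = region_spans),
            class = "AlignmentBlock")
}

#' @export
print.AlignmentBlock <- function(x, ...) {
  cat(sprintf("AlignmentBlock: %d sequences x %d columns; regions: %s\n",
              length(x$ids), nchar(x$rows[1]),
              paste(names(x$region_spans), collapse = ", ")))
  invisible(x)
}

#' Read a sequence alignment (FASTA or Stockholm)
#'
#' Rows are uppercased and `.` gaps normalized to `-`. Ragged FASTA input is
#' an error listing the offending identifier.
#'
#' @param path input path.
#' @param format `"fasta"` or `"stockholm"`.
#' @param region_spans optional named list of 0-based half-open column
#'   spans; see [alignment_block()].
#' @return an [alignment_block()].
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm"), region_spans = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    if (length(ss) < 1) stop("no sequences in ", path)
    alignment_block(names(ss), as.character(ss), region_spans)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    rows <- as.character(aln)
    ids <- rownames(aln)
    if (is.null(ids)) ids <- names(rows)
    if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
    alignment_block(ids, rows, region_spans)
  }
}

#' Write an alignment block as FASTA
#' @param block an `AlignmentBlock`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(block, path) {
  writeLines(as.vector(rbind(paste0(">", block$ids), block$rows)), path)
  invisible(path)
}
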