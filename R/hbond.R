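# Backbone i -> i+4 hydrogen-bond occupancy and helical-defect calling.
#
# A helical defect marks a kink/unwinding hinge: the alpha-helical
# (i)C=O ... H-N(i+4) bond fails to persist in more than a threshold
# fraction of the frames (default 30%, strict inequality).

#' Hydrogen-bond geometric criterion
#'
#' Heavy-atom criterion by default: the bond is formed when
#' `d(N_{i+4}, O_i) <= d_NO_max` (inclusive). When `use_hydrogens` is TRUE
#' and the amide hydrogen is present, the N-H...O angle at the hydrogen
#' must additionally be at least `angle_min` degrees.
#'
#' @param d_NO_max maximum N...O distance in Angstrom.
#' @param angle_min minimum N-H...O angle in degrees.
#' @param use_hydrogens apply the angle condition when H atoms exist.
#' @return an object of class `HBondCriterion`.
#' @export
hbond_criterion <- function(d_NO_max = 3.5, angle_min = 120, use_hydrogens = FALSE) {
  stopifnot(d_NO_max > 0, angle_min >= 0, angle_min <= 180)
  structure(list(d_NO_max = d_NO_max, angle_min = angle_min,
                 use_hydrogens = use_hydrogens), class = "HBondCriterion")
}

# indices of a named backbone atom of (chain, resid); NA when absent
.backbone_idx <- function(atoms, chain, resid, name) {
  i <- which(atoms$chain == chain & atoms$resid == resid &
             toupper(atoms$name) == name)
  if (length(i) == 0) NA_integer_ else i[1]
}

#' Is the i -> i+4 backbone hydrogen bond formed in one frame?
#'
#' @param ensemble a `StructureEnsemble`.
#' @param frame 1-based frame index.
#' @param chain chain identifier.
#' @param resid_i acceptor residue i (its carbonyl O); the donor is the
#'   backbone N (and H) of residue i+4.
#' @param criterion an [hbond_criterion()].
#' @return `TRUE`/`FALSE`, or `NA` when a required backbone atom is missing
#'   (the pair is skipped with a warning by [occupancy_map()]).
#' @export
hbond_present <- function(ensemble, frame, chain, resid_i,
                          criterion = hbond_criterion()) {
  at <- ensemble$atoms
  iO <- .backbone_idx(at, chain, resid_i, "O")
  iN <- .backbone_idx(at, chain, resid_i + 4L, "N")
  if (is.na(iO) || is.na(iN)) return(NA)
  xyz <- frame_coords(ensemble, frame)
  dNO <- sqrt(sum((xyz[iN, ] - xyz[iO, ])^2))
  if (dNO > criterion$d_NO_max) return(FALSE)
  if (criterion$use_hydrogens) {
    iH <- .backbone_idx(at, chain, resid_i + 4L, "H")
    if (!is.na(iH)) {
      a <- xyz[iN, ] - xyz[iH, ]
      b <- xyz[iO, ] - xyz[iH, ]
      ang <- acos(pmin(1, pmax(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
      return(ang >= criterion$angle_min)
    }
  }
  TRUE
}

#' Backbone i -> i+4 hydrogen-bond occupancy over an ensemble
#'
#' For every residue i in `residue_range` with an i+4 partner in the same
#' chain, the fraction of frames in which the (i)C=O ... N(i+4) bond
#' satisfies the criterion.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param chain chain identifier.
#' @param residue_range integer vector of acceptor residues i to score.
#' @param criterion an [hbond_criterion()].
#' @return an `HBondOccupancyMap`: data.frame with `chain`, `resid`
#'   (acceptor i), `occupancy` in `[0, 1]`; pairs with missing backbone
#'   atoms are dropped with a warning. The criterion is stored as an
#'   attribute and echoed by writers.
#' @export
occupancy_map <- function(ensemble, chain, residue_range,
                          criterion = hbond_criterion()) {
  if (length(residue_range) == 0) stop("empty residue range")
  f <- n_frames(ensemble)
  res <- lapply(residue_range, function(i) {
    pres <- vapply(seq_len(f), function(fr)
      hbond_present(ensemble, fr, chain, i, criterion), NA)
    if (anyNA(pres)) return(NULL)
    data.frame(chain = chain, resid = i, occupancy = mean(pres))
  })
  skipped <- residue_range[vapply(res, is.null, logical(1))]
  if (length(skipped))
    warning("skipped residue(s) with missing backbone atoms: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no scorable (i, i+4) pairs in range")
  attr(out, "criterion") <- criterion
  class(out) <- c("HBondOccupancyMap", "data.frame")
  out
}

#' Call helical defects from an occupancy map
#'
#' A pair is defective when the bond is absent in strictly more than
#' `threshold_absent` of the frames, i.e. `(1 - occupancy) >
#' threshold_absent`. With the default 0.30, an occupancy of exactly 0.70
#' is *not* a defect. Set `strict_persistence = TRUE` for the alternative
#' reading in which a defect requires occupancy below `threshold_absent`
#' itself.
#'
#' @param map an `HBondOccupancyMap`.
#' @param threshold_absent absence fraction threshold (default 0.30).
#' @param strict_persistence alternative semantics: defect when
#'   `occupancy < threshold_absent`.
#' @return a `HelixDefectMap`: the map plus a logical `defect` column.
#' @export
call_defects <- function(map, threshold_absent = 0.30, strict_persistence = FALSE) {
  out <- as.data.frame(map)
  # occupancies are frame-count ratios; compare with an epsilon so that
  # e.g. 1 - 0.70 (= 0.30000000000000004 in floating point) is not > 0.30
  eps <- 1e-9
  out$defect <- if (strict_persistence) out$occupancy < threshold_absent - eps
                else (1 - out$occupancy) > threshold_absent + eps
  attr(out, "threshold_absent") <- threshold_absent
  attr(out, "criterion") <- attr(map, "criterion")
  class(out) <- c("HelixDefectMap", "data.frame")
  out
}

#' Per-residue defect aggregate for structure coloring
#'
#' Marks residue r defective when any pair with r as acceptor through r-4
#' as acceptor involves it, matching the residue-level coloring of defect
#' maps on structures.
#'
#' @param defects a `HelixDefectMap`.
#' @return data.frame with `chain`, `resid`, `defect` per residue covered
#'   by any scored pair.
#' @export
residue_defect_view <- function(defects) {
  rows <- list()
  for (k in seq_len(nrow(defects))) {
    i <- defects$resid[k]
    rows[[k]] <- data.frame(chain = defects$chain[k], resid = i:(i + 4L),
                            defect = defects$defect[k])
  }
  all <- do.call(rbind, rows)
  agg <- stats::aggregate(defect ~ chain + resid, data = all, FUN = any)
  agg[order(agg$chain, agg$resid), ]
}
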