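# Rigid-body superposition (Kabsch), r.m.s.f. and RMSD-to-template.

# Optimal rotation/translation mapping moving -> target (both M x 3),
# least-squares, no scaling. Returns list(R, t) with x_new = x %*% R + t.
kabsch_fit <- function(moving, target, weights = NULL) {
  stopifnot(nrow(moving) == nrow(target), nrow(moving) >= 3)
  w <- if (is.null(weights)) rep(1, nrow(moving)) else weights
  w <- w / sum(w)
  cm <- as.vector(crossprod(moving, w))
  ct <- as.vector(crossprod(target, w))
  A <- sweep(moving, 2, cm)
  B <- sweep(target, 2, ct)
  H <- crossprod(A * w, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  # degenerate (collinear) point sets leave the rotation underdetermined
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) fit set: rotation is not determined")
  list(R = R, t = ct - as.vector(cm %*% R))
}

apply_rigid <- function(xyz, fit) sweep(xyz %*% fit$R, 2, fit$t, "+")

#' Least-squares superposition of every frame onto a reference
#'
#' Rigid-body (rotation + translation, no scaling) Kabsch fit of each
#' frame's `fit_sel` atoms onto the reference; the transform is applied to
#' all atoms of the frame.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param fit_sel `AtomSelection` used for the fit (>= 3 non-collinear
#'   atoms). Defaults to all CA atoms.
#' @param reference `"mean"` (iterative mean structure, 2 passes: fit onto
#'   frame 1, recompute the mean, refit onto it), an integer frame index,
#'   or an external `M x 3` coordinate matrix matching `fit_sel`.
#' @return the superposed `StructureEnsemble`.
#' @export
superpose <- function(ensemble, fit_sel = NULL, reference = "mean") {
  if (is.null(fit_sel)) fit_sel <- resolve_selection(ensemble, "name CA", "all-CA")
  idx <- fit_sel$indices
  f <- n_frames(ensemble)
  fit_once <- function(ens, ref_xyz) {
    out <- ens$coords
    for (i in seq_len(f)) {
      xyz <- frame_coords(ens, i)
      fit <- kabsch_fit(xyz[idx, , drop = FALSE], ref_xyz)
      out[i, , ] <- apply_rigid(xyz, fit)
    }
    ens$coords <- out
    ens
  }
  if (is.character(reference) && reference == "mean") {
    ens <- fit_once(ensemble, frame_coords(ensemble, 1)[idx, , drop = FALSE])
    for (pass in 1:2) {
      mean_xyz <- apply(ens$coords, c(2, 3), mean)[idx, , drop = FALSE]
      ens <- fit_once(ens, mean_xyz)
    }
    ens
  } else if (is.numeric(reference) && length(reference) == 1) {
    fit_once(ensemble, frame_coords(ensemble, reference)[idx, , drop = FALSE])
  } else if (is.matrix(reference)) {
    stopifnot(nrow(reference) == length(idx), ncol(reference) == 3)
    fit_once(ensemble, reference)
  } else stop("invalid 'reference'")
}

#' Root-mean-square fluctuation per selected atom
#'
#' The 3-D displacement of each atom about its time-mean position,
#' `sqrt(mean_f |x_i(f) - <x_i>|^2)`. The ensemble must already be
#' superposed (see [superpose()]); the function does not refit.
#'
#' @param ensemble a superposed `StructureEnsemble` with >= 2 frames.
#' @param sel `AtomSelection`; defaults to all CA atoms.
#' @return an `RMSFProfile`: data.frame with `chain`, `resid`, `name`,
#'   `rmsf` (Angstrom), attribute `reference = "mean structure"`.
#' @export
rmsf <- function(ensemble, sel = NULL) {
  if (n_frames(ensemble) < 2) stop("r.m.s.f. needs at least 2 frames")
  if (is.null(sel)) sel <- resolve_selection(ensemble, "name CA", "all-CA")
  idx <- sel$indices
  sub <- ensemble$coords[, idx, , drop = FALSE]
  mu <- apply(sub, c(2, 3), mean)
  dev2 <- sweep(sub, c(2, 3), mu)^2
  msf <- apply(dev2, 2, sum) / dim(sub)[1]   # sums x,y,z and frames
  out <- ensemble$atoms[idx, c("chain", "resid", "name")]
  out$rmsf <- sqrt(msf)
  rownames(out) <- NULL
  attr(out, "reference") <- "mean structure"
  class(out) <- c("RMSFProfile", "data.frame")
  out
}

#' Per-frame minimal RMSD of a selection against template coordinates
#'
#' Each frame's selected atoms are optimally superposed (Kabsch) onto the
#' template before the RMSD is computed; atom correspondence is positional.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param sel `AtomSelection` of M >= 3 atoms.
#' @param template_coords `M x 3` matrix (Angstrom).
#' @return a [distance_trace()] of per-frame RMSD values (Angstrom).
#' @export
rmsd_to_template <- function(ensemble, sel, template_coords) {
  template_coords <- as.matrix(template_coords)
  if (nrow(template_coords) != length(sel))
    stop("template has ", nrow(template_coords), " atoms but selection has ", length(sel))
  f <- n_frames(ensemble)
  d <- vapply(seq_len(f), function(i) {
    xyz <- frame_coords(ensemble, i)[sel$indices, , drop = FALSE]
    fit <- kabsch_fit(xyz, template_coords)
    moved <- apply_rigid(xyz, fit)
    sqrt(mean(rowSums((moved - template_coords)^2)))
  }, numeric(1))
  distance_trace(d, sel$label, "template", time = ensemble$frame_times)
}
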