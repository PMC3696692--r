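# Distance, fluctuation and contact analytics over structure ensembles.

#' Center of mass of a selection in one frame
#'
#' @param ensemble a `StructureEnsemble`.
#' @param sel an `AtomSelection`.
#' @param frame 1-based frame index.
#' @param weighting `"mass"` (atomic-mass weighted, the default) or
#'   `"geometric"` (unweighted centroid). The weighting is exposed because
#'   published domain-distance analyses rarely state which was used.
#' @return numeric 3-vector (Angstrom).
#' @export
center_of_mass <- function(ensemble, sel, frame = 1, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  xyz <- frame_coords(ensemble, frame)[sel$indices, , drop = FALSE]
  w <- if (weighting == "mass") ensemble$atoms$mass[sel$indices] else rep(1, length(sel$indices))
  as.vector(crossprod(xyz, w) / sum(w))
}

#' Construct a per-frame distance trace
#' @param d distances per frame (Angstrom, non-negative).
#' @param label_a,label_b selection labels.
#' @param time optional frame times (ns).
#' @return an object of class `DistanceTrace`.
#' @export
distance_trace <- function(d, label_a = "a", label_b = "b", time = NULL) {
  stopifnot(all(is.finite(d)), all(d >= 0))
  structure(list(frame_index = seq_along(d), time = time, d = as.numeric(d),
                 label_a = label_a, label_b = label_b),
            class = "DistanceTrace")
}

#' @export
print.DistanceTrace <- function(x, ...) {
  cat(sprintf("DistanceTrace %s--%s: %d frames, mean %.2f A, range [%.2f, %.2f] A\n",
              x$label_a, x$label_b, length(x$d), mean(x$d), min(x$d), max(x$d)))
  invisible(x)
}

#' Center-of-mass distance trace between two selections
#'
#' The per-frame Euclidean distance between the centers of mass of two atom
#' groups, the standard readout for nucleotide-binding-domain separation in
#' ABC-transporter trajectories.
#'
#' @inheritParams center_of_mass
#' @param sel_a,sel_b `AtomSelection` objects (identical selections give a
#'   zero trace).
#' @return a [distance_trace()].
#' @export
com_distance_trace <- function(ensemble, sel_a, sel_b, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  f <- n_frames(ensemble)
  wa <- if (weighting == "mass") ensemble$atoms$mass[sel_a$indices] else rep(1, length(sel_a$indices))
  wb <- if (weighting == "mass") ensemble$atoms$mass[sel_b$indices] else rep(1, length(sel_b$indices))
  d <- vapply(seq_len(f), function(i) {
    xyz <- frame_coords(ensemble, i)
    ca <- crossprod(xyz[sel_a$indices, , drop = FALSE], wa) / sum(wa)
    cb <- crossprod(xyz[sel_b$indices, , drop = FALSE], wb) / sum(wb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  distance_trace(d, sel_a$label, sel_b$label, time = ensemble$frame_times)
}

#' Pool distance traces into a normalized population histogram
#'
#' Distances are grouped into uniform bins (default width 0.1 Angstrom)
#' anchored at integer multiples of the width; a sample falling exactly on
#' an edge goes to the upper bin. Probability mass sums to one and the
#' reported mean is the population average of the pooled samples.
#'
#' @param traces a `DistanceTrace` or list of them.
#' @param bin_width bin width in Angstrom.
#' @param discard_first number of leading frames dropped from every trace
#'   (equilibration exclusion); see [ns_to_frames()] to convert a time.
#' @return an object of class `DistanceHistogram` with fields `bin_edges`,
#'   `p`, `n_samples`, `mean`.
#' @export
pooled_histogram <- function(traces, bin_width = 0.1, discard_first = 0) {
  stopifnot(bin_width > 0, discard_first >= 0)
  if (inherits(traces, "DistanceTrace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  pooled <- unlist(lapply(traces, function(tr) {
    if (discard_first == 0) tr$d
    else if (discard_first >= length(tr$d)) numeric(0)
    else tr$d[-seq_len(discard_first)]
  }))
  if (length(pooled) == 0) stop("no samples left after discarding frames")
  idx <- floor(pooled / bin_width)            # edge samples go to the upper bin
  lo <- min(idx); hi <- max(idx)
  counts <- tabulate(idx - lo + 1L, nbins = hi - lo + 1L)
  structure(list(bin_edges = seq(lo, hi + 1L) * bin_width,
                 p = counts / length(pooled),
                 n_samples = length(pooled),
                 mean = mean(pooled)),
            class = "DistanceHistogram")
}

#' @export
print.DistanceHistogram <- function(x, ...) {
  cat(sprintf("DistanceHistogram: %d samples in [%.1f, %.1f] A, bin %.2g A, mean %.2f A\n",
              x$n_samples, min(x$bin_edges), max(x$bin_edges),
              diff(x$bin_edges[1:2]), x$mean))
  invisible(x)
}

#' Width of the occupied support of a distance histogram
#' @param hist a `DistanceHistogram`.
#' @return distance (Angstrom) between the outermost occupied bin edges.
#' @export
histogram_support_width <- function(hist) {
  occ <- which(hist$p > 0)
  hist$bin_edges[max(occ) + 1L] - hist$bin_edges[min(occ)]
}

#' Convert a time span to a frame count
#' @param ensemble a `StructureEnsemble` with `frame_times` (ns).
#' @param ns time span in ns.
#' @return number of leading frames with time < `ns`.
#' @export
ns_to_frames <- function(ensemble, ns) {
  if (is.null(ensemble$frame_times)) stop("ensemble has no frame_times")
  sum(ensemble$frame_times < ns)
}

#' Theoretical B-factors from an r.m.s.f. profile
#'
#' Applies the isotropic harmonic relationship `theta = (8 pi^2 / 3) *
#' rmsf^2` converting root-mean-square fluctuations (Angstrom) to
#' crystallographic temperature factors (Angstrom^2).
#'
#' @param profile an `RMSFProfile` from [rmsf()].
#' @return an object of class `TheoreticalBFactors`: data.frame with
#'   `chain`, `resid`, `name`, `theta`.
#' @export
rmsf_to_bfactor <- function(profile) {
  out <- profile[c("chain", "resid", "name")]
  out$theta <- (8 * pi^2 / 3) * profile$rmsf^2
  class(out) <- c("TheoreticalBFactors", "data.frame")
  out
}

#' Distance between two single atoms
#'
#' @param ensemble a `StructureEnsemble`.
#' @param spec_a,spec_b selection expressions each resolving to exactly one
#'   atom (see [resolve_selection()]).
#' @param frame 1-based frame index.
#' @return Euclidean distance in Angstrom.
#' @export
pair_distance <- function(ensemble, spec_a, spec_b, frame = 1) {
  sa <- resolve_selection(ensemble, spec_a)
  sb <- resolve_selection(ensemble, spec_b)
  if (length(sa) != 1) stop("'", spec_a, "' resolves to ", length(sa), " atoms, expected 1")
  if (length(sb) != 1) stop("'", spec_b, "' resolves to ", length(sb), " atoms, expected 1")
  xyz <- frame_coords(ensemble, frame)
  sqrt(sum((xyz[sa$indices, ] - xyz[sb$indices, ])^2))
}

#' Per-frame contact count between a probe and a site selection
#'
#' Counts probe atoms within `cutoff` of any site atom in each frame — the
#' readout used to follow e.g. a lipid acyl chain entering the lumen of a
#' transporter through a TMD portal.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param probe_sel,site_sel disjoint `AtomSelection` objects.
#' @param cutoff contact cutoff in Angstrom (heavy-atom convention).
#' @return an object of class `ContactCountTrace`: list with `frame_index`
#'   and integer `count` per frame.
#' @export
contact_count_trace <- function(ensemble, probe_sel, site_sel, cutoff = 4.0) {
  if (length(intersect(probe_sel$indices, site_sel$indices)))
    stop("probe and site selections must be disjoint")
  f <- n_frames(ensemble)
  cnt <- vapply(seq_len(f), function(i) {
    xyz <- frame_coords(ensemble, i)
    p <- xyz[probe_sel$indices, , drop = FALSE]
    s <- xyz[site_sel$indices, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(s^2), "+") - 2 * tcrossprod(p, s)
    sum(apply(d2 <= cutoff^2 + 1e-12, 1, any))
  }, numeric(1))
  structure(list(frame_index = seq_len(f), count = as.integer(cnt),
                 cutoff = cutoff), class = "ContactCountTrace")
}
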