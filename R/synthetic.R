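# Ground-truthed synthetic generators. Every generator returns the data
# object plus a machine-readable manifest recording the planted truth, so
# analyzer-versus-manifest closure can be tested end to end.

# Cylindrical placement of backbone atoms relative to the CA of the same
# residue, calibrated on an ideal (phi = -57, psi = -47) alpha-helix:
# radius (A), angular offset (deg) and axial offset (A).
.HELIX_ATOMS <- data.frame(
  name   = c("N", "CA", "C", "O", "H"),
  radius = c(1.5395, 2.2588, 1.6535, 1.9061, 1.5139),
  dphi   = c(-27.166, 0, 27.102, 20.549, -19.473),
  dz     = c(-0.9190, 0, 1.0693, 2.2566, -1.9077),
  element = c("N", "C", "C", "O", "H"),
  stringsAsFactors = FALSE
)

rot_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
  diag(3) * c_ + s * ux + (1 - c_) * outer(u, u)
}

#' Ideal alpha-helix backbone as a single-frame ensemble
#'
#' Backbone N, CA, C, O (optionally amide H) atoms are placed on a helical
#' wheel whose per-atom radial, angular and axial offsets were calibrated
#' on a (phi = -57, psi = -47) helix, so at the default geometry every
#' (i, i+4) carbonyl-amide pair satisfies the default hydrogen-bond
#' criterion (d(N,O) about 2.9-3.1 Angstrom, near-linear N-H...O).
#'
#' @param n_res number of residues (>= 5).
#' @param rise axial rise per residue, Angstrom.
#' @param twist rotation per residue, degrees.
#' @param radius CA helix radius, Angstrom.
#' @param chain chain identifier.
#' @param resid_start first residue number.
#' @param with_hydrogens include amide H atoms.
#' @param serial_start first atom serial number.
#' @return a single-frame [structure_ensemble()]; helix axis along z,
#'   first CA on the x axis.
#' @export
make_ideal_helix <- function(n_res, rise = 1.562, twist = 99.67, radius = 2.259,
                             chain = "H", resid_start = 1L,
                             with_hydrogens = FALSE, serial_start = 1L) {
  stopifnot(n_res >= 5)
  spec <- .HELIX_ATOMS
  if (!with_hydrogens) spec <- spec[spec$name != "H", ]
  # scale offsets with the requested geometry relative to the calibration
  rscale <- radius / 2.2588
  zscale <- rise / 1.562
  phscale <- twist / 99.67
  rows <- list(); xyz <- list()
  serial <- serial_start
  for (i in seq_len(n_res)) {
    phi0 <- (i - 1) * twist * pi / 180
    z0 <- (i - 1) * rise
    for (k in seq_len(nrow(spec))) {
      # first residue has no preceding carbonyl: skip H there
      if (spec$name[k] == "H" && i == 1) next
      ph <- phi0 + spec$dphi[k] * phscale * pi / 180
      rr <- spec$radius[k] * rscale
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = spec$name[k], resname = "ALA",
        resid = resid_start + i - 1L, chain = chain,
        element = spec$element[k], stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1]] <- c(rr * cos(ph), rr * sin(ph), z0 + spec$dz[k] * zscale)
      serial <- serial + 1L
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$mass <- element_mass(atoms$element)
  structure_ensemble(atoms, do.call(rbind, xyz))
}

#' Configuration for the hinged two-domain trajectory generator
#'
#' @param n_atoms_per_domain pseudo-atoms (CA-like) per rigid domain.
#' @param separation_base,separation_amplitude inter-domain center-of-mass
#'   separation follows `base + amplitude * sin(2 pi f / period)`
#'   (Angstrom). The default amplitude of 20 plants a wide hinge-bending
#'   signal of the kind seen in inward-facing transporter trajectories.
#' @param period_frames oscillation period in frames.
#' @param n_frames number of frames.
#' @param thermal_sigma per-coordinate Gaussian jitter of the domain atoms
#'   (Angstrom); linker atoms ride rigidly so planted hydrogen-bond breaks
#'   stay exact.
#' @param hinge_axis rotation axis of the hinge.
#' @param linker_len residues per linker helix.
#' @param broken_pairs data.frame with columns `resid`, `fraction`:
#'   (i, i+4) pairs of the first linker helix (chain "L") whose carbonyl O
#'   is displaced beyond the hydrogen-bond criterion in exactly
#'   `round(fraction * n_frames)` randomly chosen frames.
#' @param frame_dt_ns time between frames, ns.
#' @param seed integer seed (mandatory).
#' @return an object of class `HingedTrajectoryConfig`.
#' @export
hinged_config <- function(n_atoms_per_domain = 60, separation_base = 40,
                          separation_amplitude = 20, period_frames = 50,
                          n_frames = 100, thermal_sigma = 0.5,
                          hinge_axis = c(0, 0, 1), linker_len = 15,
                          broken_pairs = NULL, frame_dt_ns = 0.5, seed = 1) {
  stopifnot(separation_amplitude >= 0, thermal_sigma >= 0,
            separation_base > separation_amplitude, n_frames >= 2)
  if (!is.null(broken_pairs))
    stopifnot(all(broken_pairs$fraction >= 0), all(broken_pairs$fraction <= 1))
  structure(list(n_atoms_per_domain = n_atoms_per_domain,
                 separation_base = separation_base,
                 separation_amplitude = separation_amplitude,
                 period_frames = period_frames, n_frames = n_frames,
                 thermal_sigma = thermal_sigma, hinge_axis = hinge_axis,
                 linker_len = linker_len, broken_pairs = broken_pairs,
                 frame_dt_ns = frame_dt_ns, seed = seed),
            class = "HingedTrajectoryConfig")
}

#' Generate a hinged two-domain trajectory with known ground truth
#'
#' Two rigid pseudo-domains (chains "A" and "B") sit at the ends of two
#' arms meeting at a hinge; the hinge angle is driven so the inter-domain
#' center-of-mass separation follows the configured sinusoid — separation
#' arises from hinge bending, not translation. Two ideal helical linkers
#' (chains "L" and "M") ride the arms; designated (i, i+4) pairs of chain
#' "L" are geometrically broken (O displaced away from the partner N) in
#' exactly `round(fraction * n_frames)` seeded frames.
#'
#' @param cfg a [hinged_config()].
#' @return list with `ensemble` (a [structure_ensemble()]) and `manifest`:
#'   planted distance per frame, broken-pair table with exact break-frame
#'   lists and realized fractions, the seed and the full config.
#' @export
make_hinged_trajectory <- function(cfg = hinged_config()) {
  stopifnot(inherits(cfg, "HingedTrajectoryConfig"))
  with_seed(cfg$seed, {
    f <- cfg$n_frames
    n <- cfg$n_atoms_per_domain
    d_planted <- cfg$separation_base +
      cfg$separation_amplitude * sin(2 * pi * seq_len(f) / cfg$period_frames)
    arm <- cfg$separation_base + cfg$separation_amplitude  # hinge-to-domain-CoM
    # rigid domain template: centered Gaussian cloud, ~8 A radius
    dom_template <- matrix(rnorm(n * 3, 0, 5), ncol = 3)
    dom_template <- sweep(dom_template, 2, colMeans(dom_template))
    helixL <- make_ideal_helix(cfg$linker_len, chain = "L", serial_start = 1L)
    helixM <- make_ideal_helix(cfg$linker_len, chain = "M", serial_start = 1L)
    hx <- frame_coords(helixL, 1); hxM <- frame_coords(helixM, 1)
    # linker template: axis along +x, starting 5 A out from the hinge
    reorient <- function(h) {
      ax <- rot_about_axis(c(0, 1, 0), pi / 2)  # z -> x
      sweep(h %*% t(ax), 2, c(5, 0, 0), "+")
    }
    hx <- reorient(hx); hxM <- reorient(hxM)

    dom_atoms <- function(chain, serial0) data.frame(
      serial = serial0 + seq_len(n) - 1L, name = "CA", resname = "ALA",
      resid = seq_len(n), chain = chain, element = "C",
      stringsAsFactors = FALSE)
    meta_cols <- c("serial", "name", "resname", "resid", "chain", "element")
    atoms <- rbind(dom_atoms("A", 1L), dom_atoms("B", n + 1L),
                   transform(helixL$atoms, serial = serial + 2L * n)[meta_cols],
                   transform(helixM$atoms,
                             serial = serial + 2L * n + nrow(helixL$atoms))[meta_cols])
    atoms$mass <- element_mass(atoms$element)
    iA <- seq_len(n); iB <- n + seq_len(n)
    iL <- 2L * n + seq_len(nrow(hx)); iM <- max(iL) + seq_len(nrow(hxM))

    # planted breaks: which frames, per pair
    bp <- cfg$broken_pairs
    break_frames <- list()
    if (!is.null(bp)) for (k in seq_len(nrow(bp))) {
      nb <- round(bp$fraction[k] * f)
      break_frames[[k]] <- if (nb > 0) sort(sample.int(f, nb)) else integer(0)
    }

    coords <- array(0, c(f, nrow(atoms), 3L))
    for (fr in seq_len(f)) {
      theta <- 2 * asin(d_planted[fr] / (2 * arm))
      Rp <- rot_about_axis(cfg$hinge_axis, theta / 2)
      Rm <- rot_about_axis(cfg$hinge_axis, -theta / 2)
      cA <- as.vector(Rp %*% c(arm, 0, 0))
      cB <- as.vector(Rm %*% c(arm, 0, 0))
      domA <- sweep(dom_template %*% t(Rp), 2, cA, "+")
      domB <- sweep(dom_template %*% t(Rm), 2, cB, "+")
      if (cfg$thermal_sigma > 0) {
        domA <- domA + matrix(rnorm(n * 3, 0, cfg$thermal_sigma), ncol = 3)
        domB <- domB + matrix(rnorm(n * 3, 0, cfg$thermal_sigma), ncol = 3)
      }
      linkL <- hx %*% t(Rp)
      linkM <- hxM %*% t(Rm)
      # geometric breaks: displace O of pair i away from N of i+4 by 3 A
      if (!is.null(bp)) for (k in seq_len(nrow(bp))) {
        if (!(fr %in% break_frames[[k]])) next
        i <- bp$resid[k]
        la <- helixL$atoms
        iO <- which(la$resid == i & la$name == "O")
        iN <- which(la$resid == i + 4L & la$name == "N")
        dir <- linkL[iO, ] - linkL[iN, ]
        dir <- dir / sqrt(sum(dir^2))
        linkL[iO, ] <- linkL[iO, ] + 3.0 * dir
      }
      coords[fr, iA, ] <- domA
      coords[fr, iB, ] <- domB
      coords[fr, iL, ] <- linkL
      coords[fr, iM, ] <- linkM
    }
    ens <- structure_ensemble(atoms, coords,
                              frame_times = (seq_len(f) - 1) * cfg$frame_dt_ns)
    manifest <- list(
      seed = cfg$seed, config = unclass(cfg),
      planted_distance = d_planted,
      broken_pairs = if (is.null(bp)) NULL else
        data.frame(chain = "L", resid = bp$resid, fraction = bp$fraction,
                   realized_fraction = vapply(break_frames, length, 0L) / f),
      break_frames = break_frames,
      domain_selections = list(A = "chain A", B = "chain B"),
      linker_chain = "L")
    list(ensemble = ens, manifest = manifest)
  })
}

#' Configuration for the synthetic DEER generator
#'
#' The default single component (mean 5.8 nm, FWHM 2.0 nm) emulates a broad
#' inter-NBD label distribution of an inward-facing transporter.
#'
#' @param components data.frame with `mean` (nm), `sd` (nm), `weight`
#'   (weights must sum to 1).
#' @param t_max,n_t time axis: `n_t` points over `[0, t_max]` us.
#' @param lambda,bg_k,bg_dim signal model, see [deer_params()].
#' @param noise_sigma Gaussian noise SD; the implied signal-to-noise ratio
#'   is `lambda / noise_sigma`.
#' @param grid an [r_grid()].
#' @param seed integer seed.
#' @return an object of class `DeerSimConfig`.
#' @export
deer_sim_config <- function(components = data.frame(mean = 5.8, sd = 0.849, weight = 1),
                            t_max = 4, n_t = 250, lambda = 0.3, bg_k = 0.15,
                            bg_dim = 3, noise_sigma = 0.01, grid = r_grid(),
                            seed = 1) {
  stopifnot(abs(sum(components$weight) - 1) < 1e-9, all(components$sd > 0))
  structure(list(components = components, t_max = t_max, n_t = n_t,
                 lambda = lambda, bg_k = bg_k, bg_dim = bg_dim,
                 noise_sigma = noise_sigma, grid = grid, seed = seed),
            class = "DeerSimConfig")
}

#' Generate a synthetic DEER trace with known distance distribution
#'
#' @param cfg a [deer_sim_config()].
#' @return list with `trace` (a [deer_trace()]), `truth` (the
#'   Gaussian-mixture [distance_distribution()]) and `manifest` (config,
#'   seed, SNR).
#' @export
make_synthetic_deer <- function(cfg = deer_sim_config()) {
  stopifnot(inherits(cfg, "DeerSimConfig"))
  r <- cfg$grid$r
  dens <- rep(0, length(r))
  for (k in seq_len(nrow(cfg$components)))
    dens <- dens + cfg$components$weight[k] *
      dnorm(r, cfg$components$mean[k], cfg$components$sd[k])
  truth <- distance_distribution(cfg$grid, dens)
  t <- seq(0, cfg$t_max, length.out = cfg$n_t)
  trace <- simulate_deer(truth, t,
                         deer_params(cfg$lambda, cfg$bg_k, cfg$bg_dim),
                         noise_sigma = cfg$noise_sigma, seed = cfg$seed)
  list(trace = trace, truth = truth,
       manifest = list(seed = cfg$seed, config = unclass(cfg),
                       snr = if (cfg$noise_sigma > 0) cfg$lambda / cfg$noise_sigma else Inf))
}

#' Configuration for the synthetic sequence-set generator
#'
#' @param n_sequences,length set size and ungapped sequence length.
#' @param gly_freq,pro_freq per-site Gly and Pro probabilities (sum <= 1);
#'   the remaining mass is spread uniformly over the other 18 standard
#'   amino acids.
#' @param seed integer seed.
#' @return an object of class `SeqSetConfig`.
#' @export
seq_set_config <- function(n_sequences = 500, length = 200, gly_freq = 0.10,
                           pro_freq = 0.05, seed = 1) {
  stopifnot(gly_freq >= 0, pro_freq >= 0, gly_freq + pro_freq <= 1)
  structure(list(n_sequences = n_sequences, length = length,
                 gly_freq = gly_freq, pro_freq = pro_freq, seed = seed),
            class = "SeqSetConfig")
}

#' Generate an ungapped sequence set with controlled Gly/Pro frequencies
#'
#' Residues are drawn i.i.d. per site; the result carries one full-length
#' region span named `"full"`.
#'
#' @param cfg a [seq_set_config()].
#' @return list with `block` (an [alignment_block()]) and `manifest`.
#' @export
make_sequence_set <- function(cfg = seq_set_config()) {
  stopifnot(inherits(cfg, "SeqSetConfig"))
  others <- setdiff(c("A","C","D","E","F","H","I","K","L","M","N","Q","R",
                      "S","T","V","W","Y"), character(0))
  alphabet <- c("G", "P", others)
  pr <- c(cfg$gly_freq, cfg$pro_freq,
          rep((1 - cfg$gly_freq - cfg$pro_freq) / length(others), length(others)))
  rows <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_sequences), function(i)
      paste(sample(alphabet, cfg$length, replace = TRUE, prob = pr), collapse = ""),
      character(1))
  })
  ids <- sprintf("seq%04d", seq_len(cfg$n_sequences))
  block <- alignment_block(ids, rows)
  list(block = block,
       manifest = list(seed = cfg$seed, config = unclass(cfg), ids = ids))
}
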