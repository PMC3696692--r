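# Synthetic stand-ins for crystal-structure reference objects.
#
# Real crystal checks (label-site C-beta separation in an inward-facing
# transporter structure; protomer CoM separation in a closed NBD dimer)
# need the corresponding PDB entries, which the user can supply to
# read_pdb_ensemble() + pair_distance()/com_distance_trace(). The
# generators below build small SYNTHETIC structures whose construction
# embeds the published geometry, so the full machinery (PDB round-trip,
# selection grammar, distance code) can be exercised without external
# files. They are stand-ins, not the crystal structures.

#' Synthetic stand-in for a spin-label-site pair structure
#'
#' Two short helical segments carrying pseudo C-beta atoms at residues 613
#' and 1258 (the numbering of the classic symmetric NBD label pair),
#' placed so the 613-1258 C-beta separation equals `cb_distance` exactly —
#' by construction, mirroring the published inward-facing crystal geometry
#' of 48 Angstrom.
#'
#' @param cb_distance target C-beta separation in Angstrom.
#' @return a single-frame [structure_ensemble()], chains A and B.
#' @export
synthetic_label_site_structure <- function(cb_distance = 48.0) {
  add_cb <- function(ens) {
    at <- ens$atoms; xyz <- frame_coords(ens, 1)
    cb_rows <- list(); cb_xyz <- list()
    for (rs in unique(at$resid)) {
      ica <- which(at$resid == rs & at$name == "CA")
      ca <- xyz[ica, ]
      radial <- c(ca[1], ca[2], 0)
      radial <- radial / sqrt(sum(radial^2))
      cb_rows[[length(cb_rows) + 1]] <- data.frame(
        serial = 0L, name = "CB", resname = "ALA", resid = rs,
        chain = at$chain[ica], element = "C", stringsAsFactors = FALSE)
      cb_xyz[[length(cb_xyz) + 1]] <- ca + 1.53 * radial + c(0, 0, -0.5)
    }
    atoms <- rbind(at[, c("serial", "name", "resname", "resid", "chain", "element")],
                   do.call(rbind, cb_rows))
    atoms$serial <- seq_len(nrow(atoms))
    atoms$mass <- element_mass(atoms$element)
    structure_ensemble(atoms, rbind(xyz, do.call(rbind, cb_xyz)))
  }
  ha <- add_cb(make_ideal_helix(9, chain = "A", resid_start = 609L))
  hb <- add_cb(make_ideal_helix(9, chain = "B", resid_start = 1254L))
  xb <- frame_coords(hb, 1)
  xb <- xb %*% t(rot_about_axis(c(0, 0, 1), pi))       # face the partner
  xb <- sweep(xb, 2, c(40, 0, 0), "+")
  xa <- frame_coords(ha, 1)
  cb_a <- xa[ha$atoms$resid == 613 & ha$atoms$name == "CB", ]
  cb_b <- xb[hb$atoms$resid == 1258 & hb$atoms$name == "CB", ]
  u <- (cb_b - cb_a) / sqrt(sum((cb_b - cb_a)^2))
  xb <- sweep(xb, 2, (cb_distance - sqrt(sum((cb_b - cb_a)^2))) * u, "+")
  atoms <- rbind(ha$atoms, hb$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  structure_ensemble(atoms, rbind(xa, xb))
}

#' Synthetic stand-in for a closed NBD-dimer structure
#'
#' Two rigid pseudo-protomers (CA-like atom clouds, chains A and B) whose
#' centers of mass sit `com_distance` Angstrom apart — by construction
#' matching the 26.0-26.5 Angstrom protomer separation published for
#' closed ABC-exporter NBD dimers.
#'
#' @param com_distance planted protomer CoM separation, Angstrom.
#' @param n_atoms atoms per protomer.
#' @param seed integer seed for the cloud shape.
#' @return a single-frame [structure_ensemble()].
#' @export
synthetic_closed_nbd_dimer <- function(com_distance = 26.2, n_atoms = 120, seed = 42) {
  cloud <- with_seed(seed, matrix(rnorm(n_atoms * 3, 0, 7), ncol = 3))
  cloud <- sweep(cloud, 2, colMeans(cloud))            # exactly centered
  xa <- sweep(cloud, 2, c(-com_distance / 2, 0, 0), "+")
  xb <- sweep(cloud %*% t(rot_about_axis(c(0, 0, 1), pi)), 2,
              c(com_distance / 2, 0, 0), "+")
  mk <- function(chain, s0) data.frame(
    serial = s0 + seq_len(n_atoms) - 1L, name = "CA", resname = "GLY",
    resid = seq_len(n_atoms), chain = chain, element = "C",
    stringsAsFactors = FALSE)
  atoms <- rbind(mk("A", 1L), mk("B", n_atoms + 1L))
  atoms$mass <- element_mass(atoms$element)
  structure_ensemble(atoms, rbind(xa, xb))
}
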