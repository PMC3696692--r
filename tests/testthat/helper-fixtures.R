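# Shared fixtures and independent brute-force oracles.

# tiny single-frame ensemble from an explicit coordinate matrix
tiny_ensemble <- function(xyz, names = NULL, elements = NULL, chain = "A",
                          resids = NULL) {
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n),
    name = names %||% rep("CA", n),
    resname = "ALA",
    resid = resids %||% seq_len(n),
    chain = chain,
    element = elements %||% rep("C", n),
    stringsAsFactors = FALSE)
  structure_ensemble(atoms, xyz)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force center of mass
com_oracle <- function(xyz, m) colSums(xyz * m) / sum(m)

# brute-force Kabsch RMSD via explicit centered SVD, independent of the
# package's kabsch_fit code path
kabsch_rmsd_oracle <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  sv <- svd(crossprod(Ac, Bc))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sqrt(mean(rowSums((Ac %*% R - Bc)^2)))
}

# brute-force O(N^2) contact count
contact_oracle <- function(probe, site, cutoff) {
  cnt <- 0
  for (i in seq_len(nrow(probe))) {
    for (j in seq_len(nrow(site))) {
      if (sqrt(sum((probe[i, ] - site[j, ])^2)) <= cutoff) { cnt <- cnt + 1; break }
    }
  }
  cnt
}

# brute-force character scan for Gly/Pro counting
glypro_oracle <- function(row, span) {
  ch <- strsplit(toupper(row), "")[[1]]
  ch <- ch[(span[1] + 1):span[2]]
  ch <- ch[ch != "-"]
  c(gly = sum(ch == "G"), pro = sum(ch == "P"), n = length(ch))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
}
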