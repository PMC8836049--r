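# independent oracles and small fixture builders used across the suite

# all-pairs residue contact oracle (full distance matrix; no spatial grid)
brute_contact_pairs <- function(frame, topo, cutoff = 6.5, min_separation = 1L) {
  heavy <- select_atoms(topo, "heavy")
  xyz <- frame[heavy, , drop = FALSE]
  resid <- topo$atoms$resid[heavy]
  d <- as.matrix(stats::dist(xyz))
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  ri <- resid[hit[, 1]]; rj <- resid[hit[, 2]]
  keep <- abs(ri - rj) >= min_separation
  pr <- unique(cbind(pmin(ri, rj)[keep], pmax(ri, rj)[keep]))
  pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
}

rot_mat <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# minimal structure of single-atom (CA-only) residues at given coordinates
ca_structure <- function(xyz, resname = "GLY", resno = NULL) {
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                      resname = resname, chain = "A", resno = resno,
                      resid = seq_len(n), stringsAsFactors = FALSE)
  mdunfold:::new_structure(atoms, list(xyz))
}

# wrap a list of coordinate matrices into a trajectory on a given topology
make_traj <- function(struct, frames, dt = 1) {
  mdunfold:::as_trajectory(
    mdunfold:::new_structure(struct$atoms, frames), dt = dt)
}

# random "protein-like density" frame for a mainchain-only topology
random_frame <- function(n_atoms, box = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(box)) box <- (n_atoms / 0.012)^(1 / 3)  # ~ protein atom density
  matrix(stats::runif(n_atoms * 3, 0, box), n_atoms, 3)
}

# a mainchain-only topology of n_res 4-atom residues (names N/CA/C/O)
mainchain_topology <- function(n_res) {
  atoms <- data.frame(
    serial = seq_len(4L * n_res),
    name = rep(c("N", "CA", "C", "O"), n_res),
    element = rep(c("N", "C", "C", "O"), n_res),
    resname = "GLY", chain = "A",
    resno = rep(seq_len(n_res), each = 4L),
    resid = rep(seq_len(n_res), each = 4L),
    stringsAsFactors = FALSE)
  mdunfold:::new_structure(atoms, list(matrix(0, 4L * n_res, 3)))
}

synthetic_hgdc_path <- function() {
  system.file("extdata", "hgdc_ca_synthetic.pdb", package = "mdunfold")
}
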