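# Shared fixtures and independent oracles.

# Brute-force signed clearance: plain per-atom loop, written independently
# of the package's vectorized version.
oracle_clearance <- function(p, structure) {
  xyz <- coords(structure)
  r <- structure$vdw_radius
  best <- Inf
  for (i in seq_len(nrow(xyz))) {
    d <- sqrt((xyz[i, 1] - p[1])^2 + (xyz[i, 2] - p[2])^2 +
                (xyz[i, 3] - p[3])^2) - r[i]
    if (d < best) best <- d
  }
  best
}

# Dense-grid maximization of clearance over the disc of given radius
# orthogonal to `tangent` at `center` (independent oracle for refinement).
oracle_disc_max <- function(center, tangent, radius, structure,
                            spacing = 0.05) {
  w <- tangent / sqrt(sum(tangent^2))
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(w[2] * a[3] - w[3] * a[2], w[3] * a[1] - w[1] * a[3],
         w[1] * a[2] - w[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  g <- seq(-radius, radius, by = spacing)
  gg <- expand.grid(a = g, b = g)
  gg <- gg[gg$a^2 + gg$b^2 <= radius^2, ]
  pts <- cbind(center[1] + gg$a * u[1] + gg$b * v[1],
               center[2] + gg$a * u[2] + gg$b * v[2],
               center[3] + gg$a * u[3] + gg$b * v[3])
  xyz <- coords(structure)
  r <- structure$vdw_radius
  best <- -Inf
  for (i in seq_len(nrow(pts))) {
    cl <- min(sqrt((xyz[, 1] - pts[i, 1])^2 + (xyz[, 2] - pts[i, 2])^2 +
                     (xyz[, 3] - pts[i, 3])^2) - r)
    if (cl > best) best <- cl
  }
  best
}

# A tiny handwritten 3-atom PDB with known coordinates.
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A 775      11.104  13.207   9.004  1.00  0.00           C",
    "ATOM      2  N   ALA A 775      12.000 -13.500   0.250  1.00  0.00           N",
    "HETATM    3 MG    MG B   1       0.000   1.000   2.000  1.00  0.00          MG",
    "END"), path)
  path
}

# Minimal two-region graph with selections resolvable on a toy topology.
toy_two_region_graph <- function() {
  region_graph(list(
    macro_region("MR2", residue_selection(R = 1), "entry",
                 channels = "CH2"),
    macro_region("MR3", residue_selection(R = 2), "entry",
                 channels = "CH2")
  ), adjacency = list(c("MR2", "MR3")))
}

# Toy topology for the two-region graph: one carbon per region at a fixed
# anchor, plus `n_lig` single-atom CTP ligands.
toy_two_region_topology <- function(n_lig = 1) {
  anchors <- rbind(c(0, 0, 0), c(20, 0, 0))
  lig <- matrix(rep(c(100, 100, 100), n_lig), ncol = 3, byrow = TRUE)
  molecular_structure(
    atom_id = seq_len(2 + n_lig),
    element = c("C", "C", rep("P", n_lig)),
    atom_name = c("C", "C", rep("P", n_lig)),
    residue_name = c("MRX", "MRX", rep("CTP", n_lig)),
    residue_number = c(1, 2, seq_len(n_lig)),
    subunit_id = c("R", "R", rep("L", n_lig)),
    xyz = rbind(anchors, lig))
}
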