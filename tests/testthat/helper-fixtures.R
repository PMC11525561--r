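# shared fixture builders; everything is generated in code at test time

# trajectory with explicit coordinates for two CA pseudo-residues
# coords_a, coords_b: n x 3 matrices in Angstrom
make_pair_trajectory <- function(coords_a, coords_b, dt = 1) {
  atoms <- data.frame(chain = "A", resno = c(50L, 65L),
                      resname = c("CYS", "ASN"), atom = "CA",
                      stringsAsFactors = FALSE)
  n <- nrow(coords_a)
  coords <- array(0, dim = c(n, 2L, 3L))
  coords[, 1L, ] <- coords_a
  coords[, 2L, ] <- coords_b
  trajectory_frames(atoms, coords, times = (seq_len(n) - 1L) * dt)
}

# uniform random rotation (QR with positive diagonal, det forced to +1)
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid-body transform to every frame of a trajectory
rigid_transform <- function(frames, rotation, translation) {
  for (i in seq_len(n_frames(frames))) {
    xyz <- matrix(frames$coords[i, , ], ncol = 3L)
    frames$coords[i, , ] <- xyz %*% t(rotation) +
      matrix(translation, nrow(xyz), 3, byrow = TRUE)
  }
  frames
}

# a distance series built directly from values (times 0, 1, 2, ...)
series_from_values <- function(values, dt = 1, unit = "nm", rep_id = "") {
  distance_series_new(times = (seq_along(values) - 1) * dt, values = values,
                      unit = unit, replicate_id = rep_id)
}

# hand-written 2-model PDB text, 3 atoms per model, known coordinates
two_model_pdb_text <- function() {
  c("MODEL        1",
    "ATOM      1  N   CYS A  50      11.000  22.000  33.000  1.00  0.00",
    "ATOM      2  CA  CYS A  50       1.500   2.250   3.125  1.00  0.00",
    "ATOM      3  CA  ASN A  65       4.500   6.250   3.125  1.00  0.00",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   CYS A  50      11.000  22.000  33.000  1.00  0.00",
    "ATOM      2  CA  CYS A  50       1.600   2.350   3.225  1.00  0.00",
    "ATOM      3  CA  ASN A  65       4.600   6.350   3.225  1.00  0.00",
    "ENDMDL",
    "END")
}
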