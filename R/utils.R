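# Shared constants and small numeric helpers used across modules.

# 3-letter -> 1-letter amino acid codes; anything else maps to "X".
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_123 <- stats::setNames(names(AA_321), unname(AA_321))

AA1 <- unname(AA_321)

# Kyte-Doolittle hydropathy scale (kcal/mol-free units, higher = more hydrophobic).
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Amino-acid background frequencies derived from the BLOSUM62 alignment data
# (the background used by the Capra-Singh conservation scoring tradition).
BLOSUM62_BACKGROUND <- c(
  A = 0.078047, R = 0.051269, N = 0.044873, D = 0.053640, C = 0.024529,
  Q = 0.034040, E = 0.054328, G = 0.083252, H = 0.021992, I = 0.062341,
  L = 0.092375, K = 0.058186, M = 0.023213, F = 0.038542, P = 0.043852,
  S = 0.055951, T = 0.053287, W = 0.014512, Y = 0.032695, V = 0.064943
)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# All pairwise Euclidean distances between rows of a (n x 3) and b (m x 3).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

rmsd_coords <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# Dihedral angle (degrees, in (-180, 180]) defined by points p1-p2-p3-p4.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place a new atom D given three reference atoms A, B, C, a bond length |CD|,
# a bond angle B-C-D (degrees) and a dihedral A-B-C-D (degrees). NeRF scheme.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(dih), -sin(ang) * sin(dih))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  rot <- cbind(bc, m2, n)
  as.numeric(rot %*% d_local + c)
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)
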