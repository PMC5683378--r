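# Independent oracles used to cross-check the package's geometry and map
# arithmetic. Each is implemented from the defining formula, by a different
# route than the implementation it checks.

# Horn's quaternion method for optimal rigid superposition; returns the
# post-fit RMSD. Independent of the SVD/Kabsch route in the package.
quaternion_superpose_rmsd <- function(mobile, target) {
  P <- as.matrix(mobile); Q <- as.matrix(target)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- t(Pc) %*% Qc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  eig <- eigen(K, symmetric = TRUE)
  q <- eig$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  fitted <- Pc %*% t(R)
  sqrt(mean(rowSums((fitted - Qc)^2)))
}

# Brute-force all-pairs clash count.
bruteforce_clashes <- function(placed, context, cutoff) {
  P <- cs_xyz(placed); Q <- cs_xyz(context)
  n <- 0L
  for (i in seq_len(nrow(P))) {
    d2 <- (Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2 + (Q[, 3] - P[i, 3])^2
    n <- n + sum(d2 < cutoff^2)
  }
  n
}

# Direct-formula Pearson correlation (explicit sums, population form).
direct_pearson <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Direct-sum RMSD over explicit per-atom squared distances.
direct_rmsd <- function(X, Y) {
  s <- 0
  for (i in seq_len(nrow(X))) s <- s + sum((X[i, ] - Y[i, ])^2)
  sqrt(s / nrow(X))
}

# Direct-sum TM-score.
direct_tm <- function(X, Y, d0) {
  s <- 0
  for (i in seq_len(nrow(X))) {
    di2 <- sum((X[i, ] - Y[i, ])^2)
    s <- s + 1 / (1 + di2 / d0^2)
  }
  s / nrow(X)
}

# Four-point torsion via the atan2-free route: angle between plane normals,
# signed by the scalar triple product.
direct_torsion <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosv <- min(1, max(-1, cosv))
  ang <- acos(cosv) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# Random coordinate-set pair builders.
random_cs <- function(n, scale = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coord_set(rep("CA", n), seq_len(n), matrix(runif(3 * n, -scale, scale), ncol = 3))
}

random_rigid_motion <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, runif(3, -20, 20))
}

# Quantize values through float32 so MRC round trips are bit-exact.
quantize_f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric", n = length(x), size = 4L)
}

# A synthetic 3-residue fragment record whose terminal CA-CA distance is
# exactly `d` (coordinates chosen to be exactly representable).
fake_record_with_d <- function(d, id = sprintf("fake_d%g", d), sequence = "AGA") {
  xyz <- rbind(
    c(-1.5, 0.5, 0), c(0, 0, 0), c(1, 1, 0),        # res 1: N, CA, C
    c(d / 2 - 1, 3, 1), c(d / 2, 3.5, 1), c(d / 2 + 1, 3, 1),  # res 2
    c(d - 1.5, 0.5, 0), c(d, 0, 0), c(d + 1, -1, 0) # res 3
  )
  coords <- coord_set(rep(c("N", "CA", "C"), 3), rep(1:3, each = 3), xyz)
  new_fragment_record("fake", "A", 1L, sequence, coords, id = id)
}

# Small helper: per-candidate backbone RMSD to the gap's native interior.
fixture_rmsds <- function(fit) {
  nat <- fit$gap$native_interior
  vapply(fit$candidates, function(c) {
    kn <- paste(nat$resi, nat$elety)
    kp <- paste(c$placed$resi, c$placed$elety)
    common <- intersect(kn, kp)
    direct_rmsd(cs_xyz(nat)[match(common, kn), , drop = FALSE],
                cs_xyz(c$placed)[match(common, kp), , drop = FALSE])
  }, numeric(1))
}
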