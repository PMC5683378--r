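#' Geometric fingerprint of a stem pair
#'
#' Compact descriptor of the relative geometry of the two residues flanking
#' a gap (or of the terminal residues of a database fragment): the CA-CA
#' distance `d`, the angles `theta_n` (N-stem CA->C bond vs. the stem-stem
#' axis) and `theta_c` (C-stem CA->N bond vs. the reversed axis), and the
#' torsion `phi` over C(n)-CA(n)-CA(c)-N(c). All four are invariant under
#' rigid motion, which is what makes the fingerprint usable as a database
#' pre-filter.
#'
#' @param nstem_atoms,cstem_atoms [coord_set()]s carrying at least named
#'   N, CA and C atoms of each stem residue.
#' @return A `geometric_fingerprint` list with fields `d`, `theta_n`,
#'   `theta_c`, `phi` (Angstrom / degrees).
#' @export
compute_fingerprint <- function(nstem_atoms, cstem_atoms) {
  pick <- function(cs, name, which) {
    i <- match(name, cs$elety)
    if (is.na(i)) stopf("%s stem is missing atom %s", which, name)
    c(cs$x[i], cs$y[i], cs$z[i])
  }
  ca_n <- pick(nstem_atoms, "CA", "N")
  c_n <- pick(nstem_atoms, "C", "N")
  ca_c <- pick(cstem_atoms, "CA", "C")
  n_c <- pick(cstem_atoms, "N", "C")
  axis <- ca_c - ca_n
  d <- vnorm(axis)
  if (d < 1e-9) stopf("degenerate stem pair: coincident CA atoms")
  fp <- list(
    d = d,
    theta_n = vangle_deg(c_n - ca_n, axis),
    theta_c = vangle_deg(n_c - ca_c, -axis),
    phi = torsion_deg(c_n, ca_n, ca_c, n_c)
  )
  class(fp) <- "geometric_fingerprint"
  fp
}

# Smallest angular difference on the circle, degrees in [0, 180].
circ_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Deviation between two geometric fingerprints
#'
#' Unit-normalized sum of the four component deviations: `|delta d| / 0.75`
#' plus each angular deviation divided by 30 degrees (the torsion difference
#' is taken on the circle). The normalizers put the hard stage-1 distance
#' threshold at deviation 1, so all components share one scale.
#'
#' @param a,b `geometric_fingerprint`s.
#' @param d_scale,angle_scale normalizers (Angstrom, degrees).
#' @return Non-negative deviation; 0 iff the fingerprints are equal.
#' @export
fingerprint_deviation <- function(a, b, d_scale = 0.75, angle_scale = 30) {
  abs(a$d - b$d) / d_scale +
    abs(a$theta_n - b$theta_n) / angle_scale +
    abs(a$theta_c - b$theta_c) / angle_scale +
    circ_diff_deg(a$phi, b$phi) / angle_scale
}

#' Optimal rigid superposition of matched point sets
#'
#' Least-squares (Kabsch) fit of `mobile` onto `target` with a proper
#' rotation enforced. Used to place fragment terminal residues onto the
#' gap's stem residues.
#'
#' @param mobile,target [coord_set()]s or n x 3 matrices with matched rows
#'   (n >= 3, non-collinear).
#' @return list with `transform` (a [rigid_transform()]) and `stem_rmsd`,
#'   the post-fit RMSD in Angstrom.
#' @export
superpose_stems <- function(mobile, target) {
  M <- if (is.data.frame(mobile)) cs_xyz(mobile) else as.matrix(mobile)
  T_ <- if (is.data.frame(target)) cs_xyz(target) else as.matrix(target)
  if (nrow(M) != nrow(T_)) stopf("point counts differ (%d vs %d)", nrow(M), nrow(T_))
  if (nrow(M) < 3L) stopf("need at least 3 matched points")
  cm <- colMeans(M); ct <- colMeans(T_)
  Mc <- sweep(M, 2L, cm); Tc <- sweep(T_, 2L, ct)
  H <- t(Mc) %*% Tc
  s <- svd(H)
  if (s$d[2] < 1e-10) stopf("degenerate point set (collinear or coincident)")
  d_sign <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d_sign)) %*% t(s$u)
  t_vec <- ct - as.numeric(R %*% cm)
  tf <- rigid_transform(R, t_vec)
  fitted <- apply_transform(tf, M)
  rmsd <- sqrt(mean(rowSums((fitted - T_)^2)))
  list(transform = tf, stem_rmsd = rmsd)
}

# Stem-matched coordinate pair for a fragment vs. a gap: terminal-residue
# backbone atoms of the fragment matched by name to the gap stem atoms.
fragment_stem_pair <- function(fragment, gap) {
  fr <- fragment$coords
  term_n <- fr[fr$resi == 1L, , drop = FALSE]
  term_c <- fr[fr$resi == fragment$length, , drop = FALSE]
  gs <- gap$stem_fit_cs
  gn <- gs[gs$resi == 1L, , drop = FALSE]
  gc_ <- gs[gs$resi == 2L, , drop = FALSE]
  names_n <- intersect(gn$elety, term_n$elety)
  names_c <- intersect(gc_$elety, term_c$elety)
  if (length(names_n) < 3L || length(names_c) < 3L) {
    stopf("fragment terminals lack the backbone atoms needed for stem superposition")
  }
  mob <- rbind(cs_xyz(term_n[match(names_n, term_n$elety), ]),
               cs_xyz(term_c[match(names_c, term_c$elety), ]))
  tgt <- rbind(cs_xyz(gn[match(names_n, gn$elety), ]),
               cs_xyz(gc_[match(names_c, gc_$elety), ]))
  list(mobile = mob, target = tgt)
}

#' Graft a database fragment into a gap
#'
#' Superposes the fragment's terminal residues onto the gap's stem residues
#' and returns the placed coordinates of the interior residues (the modeled
#' segment). The fragment must be two residues longer than the gap sequence:
#' its terminals coincide with the stems and its interior fills the gap.
#'
#' @param fragment a fragment record (see [extract_fragments()]).
#' @param gap a `gap_spec` from [define_gap()].
#' @return list with `placed` (interior [coord_set()], `resi` 1..L),
#'   `stem_rmsd`, and the fitted `transform`.
#' @export
graft_fragment <- function(fragment, gap) {
  if (fragment$length != gap$L + 2L) {
    stopf("fragment length %d does not serve a gap of %d residues (need L+2 = %d)",
          fragment$length, gap$L, gap$L + 2L)
  }
  pair <- fragment_stem_pair(fragment, gap)
  fit <- superpose_stems(pair$mobile, pair$target)
  placed_all <- apply_transform(fit$transform, fragment$coords)
  interior <- placed_all[placed_all$resi >= 2L & placed_all$resi <= fragment$length - 1L, ,
                         drop = FALSE]
  interior$resi <- interior$resi - 1L
  rownames(interior) <- NULL
  list(placed = interior, stem_rmsd = fit$stem_rmsd, transform = fit$transform)
}

#' Count steric clashes between placed atoms and a structural context
#'
#' Counts atom pairs closer than `cutoff` between a placed fragment and the
#' context, using a uniform spatial grid (cell size = cutoff, 27-cell
#' neighborhood) so the result equals the all-pairs count at linear cost.
#'
#' @param placed [coord_set()] of placed fragment atoms.
#' @param context [coord_set()] of context atoms (stems and modeled span
#'   excluded by the caller), or `NULL` for no context.
#' @param cutoff clash distance in Angstrom (strict `<`).
#' @return integer clash-pair count.
#' @export
detect_clashes <- function(placed, context, cutoff = 2.0) {
  if (is.null(context) || nrow(context) == 0L) return(0L)
  P <- cs_xyz(placed); Q <- cs_xyz(context)
  cell <- pmax(cutoff, 1e-6)
  key_of <- function(M) {
    g <- floor(M / cell)
    paste(g[, 1], g[, 2], g[, 3], sep = "_")
  }
  gQ <- floor(Q / cell)
  buckets <- split(seq_len(nrow(Q)), paste(gQ[, 1], gQ[, 2], gQ[, 3], sep = "_"))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  gP <- floor(P / cell)
  n_clash <- 0L
  cutoff2 <- cutoff^2
  for (i in seq_len(nrow(P))) {
    cand <- integer(0)
    for (k in seq_len(27L)) {
      key <- paste(gP[i, 1] + offs[k, 1], gP[i, 2] + offs[k, 2], gP[i, 3] + offs[k, 3],
                   sep = "_")
      b <- buckets[[key]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    if (length(cand)) {
      d2 <- (Q[cand, 1] - P[i, 1])^2 + (Q[cand, 2] - P[i, 2])^2 + (Q[cand, 3] - P[i, 3])^2
      n_clash <- n_clash + sum(d2 < cutoff2)
    }
  }
  as.integer(n_clash)
}
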