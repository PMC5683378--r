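make_stem_pair <- function(seed = 1) {
  set.seed(seed)
  n <- coord_set(c("N", "CA", "C"), rep(1L, 3), matrix(rnorm(9, sd = 2), ncol = 3))
  c_ <- coord_set(c("N", "CA", "C"), rep(1L, 3),
                  matrix(rnorm(9, sd = 2), ncol = 3) + matrix(rep(c(9, 1, -2), each = 3), ncol = 3))
  list(n = n, c = c_)
}

test_that("fingerprint distance and torsion match direct formula oracles", {
  n <- coord_set(c("N", "CA", "C"), rep(1L, 3), rbind(c(-1, 1, 0), c(0, 0, 0), c(1, 1, 0)))
  c_ <- coord_set(c("N", "CA", "C"), rep(1L, 3), rbind(c(9, 1, 0), c(10, 0, 0), c(11, 1, 0)))
  fp <- compute_fingerprint(n, c_)
  expect_equal(fp$d, 10.0)
  for (seed in 1:50) {
    st <- make_stem_pair(seed)
    fp <- compute_fingerprint(st$n, st$c)
    ca_n <- cs_xyz(st$n)[2, ]; ca_c <- cs_xyz(st$c)[2, ]
    expect_equal(fp$d, sqrt(sum((ca_c - ca_n)^2)), tolerance = 1e-12)
    expect_equal(fp$phi,
                 direct_torsion(cs_xyz(st$n)[3, ], ca_n, ca_c, cs_xyz(st$c)[1, ]),
                 tolerance = 1e-9)
    expect_true(fp$theta_n >= 0 && fp$theta_n <= 180)
    expect_true(fp$theta_c >= 0 && fp$theta_c <= 180)
  }
})

test_that("fingerprint is invariant under rigid motion", {
  st <- make_stem_pair(42)
  fp0 <- compute_fingerprint(st$n, st$c)
  set.seed(7)
  for (i in 1:100) {
    tf <- random_rigid_motion()
    fp1 <- compute_fingerprint(apply_transform(tf, st$n), apply_transform(tf, st$c))
    expect_equal(fp1$d, fp0$d, tolerance = 1e-6)
    expect_equal(fp1$theta_n, fp0$theta_n, tolerance = 1e-6)
    expect_equal(fp1$theta_c, fp0$theta_c, tolerance = 1e-6)
    expect_equal(fp1$phi, fp0$phi, tolerance = 1e-6)
  }
})

test_that("fingerprint deviation is zero at identity, unit at the distance threshold, circular in phi", {
  st <- make_stem_pair(3)
  fp <- compute_fingerprint(st$n, st$c)
  expect_identical(fingerprint_deviation(fp, fp), 0)
  fp2 <- fp; fp2$d <- fp$d + 0.75
  expect_equal(fingerprint_deviation(fp, fp2), 1.0)
  fpa <- fp; fpa$phi <- 179
  fpb <- fp; fpb$phi <- -179
  expect_equal(fingerprint_deviation(fpa, fpb), 2 / 30, tolerance = 1e-12)
})

test_that("stem superposition matches the quaternion oracle and never increases RMSD", {
  set.seed(11)
  for (i in 1:200) {
    n <- 8L
    mob <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
    tgt <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
    fit <- superpose_stems(mob, tgt)
    expect_equal(fit$stem_rmsd, quaternion_superpose_rmsd(mob, tgt), tolerance = 1e-9)
    unfitted <- sqrt(mean(rowSums((mob - tgt)^2)))
    expect_lte(fit$stem_rmsd, unfitted + 1e-12)
  }
})

test_that("superposing a rigidly moved copy recovers zero RMSD", {
  set.seed(13)
  pts <- matrix(rnorm(24, sd = 5), ncol = 3)
  expect_equal(superpose_stems(pts, pts)$stem_rmsd, 0, tolerance = 1e-12)
  for (i in 1:20) {
    tf <- random_rigid_motion()
    moved <- apply_transform(tf, pts)
    fit <- superpose_stems(pts, moved)
    expect_lt(fit$stem_rmsd, 1e-9)
    # applying then inverting the recovered transform is the identity
    back <- apply_transform(invert_transform(fit$transform),
                            apply_transform(fit$transform, pts))
    expect_lt(max(abs(back - pts)), 1e-9)
  }
})

test_that("degenerate superposition inputs are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose_stems(line, line + 1), "degenerate|collinear")
  expect_error(superpose_stems(matrix(0, 2, 3), matrix(0, 2, 3)), "3 matched points")
})

test_that("grafting the native fragment reproduces the native segment", {
  fix <- make_gap_fixture("strand", 7, seed = 21, n_decoys = 0)
  nat_rec <- fix$db$records[[which(vapply(fix$db$records, `[[`, "", "id") == "native")]]
  g1 <- graft_fragment(nat_rec, fix$gap)
  expect_lt(g1$stem_rmsd, 1e-9)
  nat <- fix$gap$native_interior
  expect_lt(max(abs(cs_xyz(g1$placed) - cs_xyz(nat))), 1e-6)
  g2 <- graft_fragment(nat_rec, fix$gap)
  expect_identical(g1$placed, g2$placed)
})

test_that("graft rejects fragments of the wrong length", {
  fix <- make_gap_fixture("helix", 7, seed = 22, n_decoys = 0)
  rec <- fake_record_with_d(9)
  expect_error(graft_fragment(rec, fix$gap), "length")
})

test_that("perturbed-native graft RMSD equals the transform-then-RMSD oracle", {
  fix <- make_gap_fixture("loop", 9, seed = 23, n_decoys = 0)
  nat_rec <- fix$db$records[[which(vapply(fix$db$records, `[[`, "", "id") == "native")]]
  pert <- perturb_fragment(nat_rec$coords, sd = 0.8, seed = 99)
  rec <- new_fragment_record("t", "A", nat_rec$first_resno, nat_rec$sequence, pert, id = "pert")
  g <- graft_fragment(rec, fix$gap)
  # oracle: superpose terminal atoms independently, transform, measure RMSD
  last <- max(pert$resi)
  sel <- pert$resi %in% c(1L, last)
  fit <- superpose_stems(cs_xyz(pert[sel, ]), cs_xyz(nat_rec$coords[sel, ]))
  placed_oracle <- apply_transform(fit$transform,
                                   cs_xyz(pert[pert$resi > 1L & pert$resi < last, ]))
  nat <- fix$gap$native_interior
  expect_equal(direct_rmsd(cs_xyz(g$placed), cs_xyz(nat)),
               direct_rmsd(placed_oracle, cs_xyz(nat)), tolerance = 1e-9)
})

test_that("grid-based clash detection equals the all-pairs oracle", {
  set.seed(31)
  for (i in 1:20) {
    placed <- random_cs(50, scale = 8)
    context <- random_cs(200, scale = 8)
    cutoff <- runif(1, 1, 4)
    expect_identical(detect_clashes(placed, context, cutoff),
                     as.integer(bruteforce_clashes(placed, context, cutoff)))
  }
})

test_that("clash counting basics: near contact detected, empty context clean", {
  placed <- coord_set("CA", 1L, matrix(c(0, 0, 0), 1))
  context <- coord_set("CA", 1L, matrix(c(1.5, 0, 0), 1))
  expect_gte(detect_clashes(placed, context, 2.0), 1L)
  expect_identical(detect_clashes(placed, NULL, 2.0), 0L)
  far <- coord_set("CA", 1L, matrix(c(5, 0, 0), 1))
  expect_identical(detect_clashes(placed, far, 2.0), 0L)
})
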