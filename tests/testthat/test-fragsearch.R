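test_that("sequence similarity is 1 at identity, symmetric, and matches a table-lookup oracle", {
  expect_equal(sequence_similarity("QLFTW", "QLFTW"), 1.0)
  # independent oracle: explicit per-position BLOSUM62 lookups
  m <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  smin <- min(m[aas, aas])
  oracle <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    mean(vapply(seq_along(ca), function(i) {
      (m[ca[i], cb[i]] - smin) / (max(m[ca[i], ca[i]], m[cb[i], cb[i]]) - smin)
    }, numeric(1)))
  }
  set.seed(41)
  for (i in 1:100) {
    L <- sample(3:20, 1)
    a <- paste(sample(aas, L, replace = TRUE), collapse = "")
    b <- paste(sample(aas, L, replace = TRUE), collapse = "")
    expect_equal(sequence_similarity(a, b), oracle(a, b), tolerance = 1e-12)
    expect_equal(sequence_similarity(a, b), sequence_similarity(b, a), tolerance = 1e-15)
    expect_true(sequence_similarity(a, b) >= 0 && sequence_similarity(a, b) <= 1)
  }
  expect_error(sequence_similarity("AAA", "AAAA"), "mismatch")
})

test_that("only geometry-compatible fragments survive stage 1", {
  fix <- make_gap_fixture("helix", 7, seed = 51, n_decoys = 0)
  nat <- fragfitr:::native_fragment(fix$gap)
  # decoys whose stem distance is shifted by at least 1 A
  shifted <- lapply(1:10, function(i) {
    fake_record_with_d(fix$gap$fingerprint$d + 1 + 0.3 * i, id = sprintf("far%02d", i),
                       sequence = strrep("A", 3))
  })
  # fake records are length 3; embed the shift in records of the serving length
  shift_rec <- function(i) {
    co <- nat$coords
    last <- max(co$resi)
    sel <- co$resi == last
    xyz <- cs_xyz(co)
    axis <- xyz[match(TRUE, co$resi == last & co$elety == "CA"), ] -
      xyz[match(TRUE, co$resi == 1L & co$elety == "CA"), ]
    axis <- axis / sqrt(sum(axis^2))
    xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2, -(1 + 0.3 * i) * axis)
    new_fragment_record("far", "A", 1L, nat$sequence, fragfitr:::cs_set_xyz(co, xyz),
                        id = sprintf("far%02d", i))
  }
  db <- new_fragment_db(c(list(nat), lapply(1:10, shift_rec)))
  res <- run_fragsearch(fix$gap, db)
  expect_equal(stage_report(res)[["stage1"]], 1L)
  expect_equal(vapply(res$candidates, `[[`, "", "fragment_id"), "native")
})

test_that("duplicate records collapse under the redundancy rule", {
  fix <- make_gap_fixture("strand", 7, seed = 52, n_decoys = 0)
  nat <- fragfitr:::native_fragment(fix$gap)
  nat2 <- nat; nat2$id <- "native_copy"
  db <- new_fragment_db(list(nat, nat2))
  res <- run_fragsearch(fix$gap, db)
  rep_ <- stage_report(res)
  expect_equal(rep_[["stage1"]], 2L)
  expect_equal(rep_[["stage3"]], 1L)
  expect_length(res$candidates, 1L)
})

test_that("a candidate grafted through a context atom is excluded at stage 3", {
  fix <- make_gap_fixture("loop", 9, seed = 53, n_decoys = 1,
                          resolution = 8)
  decoy <- fix$db$records[[which(vapply(fix$db$records, `[[`, "", "id") == "decoy_001")]]
  decoy$coords <- perturb_fragment(fragfitr:::native_fragment(fix$gap)$coords, 2.2, seed = 9)
  decoy <- new_fragment_record("decoy", "A", decoy$first_resno, decoy$sequence,
                               decoy$coords, id = "clasher")
  g <- graft_fragment(decoy, fix$gap)
  nat <- fix$gap$native_interior
  # pick the decoy interior atom farthest from every native atom
  D <- as.matrix(dist(rbind(cs_xyz(g$placed), cs_xyz(nat))))
  np <- nrow(g$placed)
  mind <- apply(D[1:np, (np + 1):ncol(D), drop = FALSE], 1, min)
  target <- cs_xyz(g$placed)[which.max(mind), ]
  expect_gt(max(mind), 2.0)
  # plant a context atom 1.0 A away from that decoy atom
  st2 <- fix$structure
  st2$atom <- rbind(st2$atom, data.frame(
    type = "ATOM", elety = "CA", resid = "ALA", aa = "A", chain = "B",
    resno = 999L, insert = "", x = target[1] + 1.0, y = target[2], z = target[3],
    o = 1, b = 0
  ))
  gap2 <- define_gap(st2, "A", fix$gap$nstem_resno, fix$gap$cstem_resno, fix$gap$sequence)
  nat_rec <- fragfitr:::native_fragment(gap2)
  db <- new_fragment_db(list(nat_rec, decoy))
  res <- run_fragsearch(gap2, db)
  rep_ <- stage_report(res)
  expect_equal(rep_[["stage1"]], 2L)
  expect_equal(rep_[["stage3"]], rep_[["stage2"]] - 1L)
  expect_false("clasher" %in% vapply(res$candidates, `[[`, "", "fragment_id"))
})

test_that("the native ranks first when identity filtering is off", {
  for (seed in 1:5) {
    fix <- make_gap_fixture(c("helix", "strand", "loop")[1 + seed %% 3],
                            L = c(5, 9, 15)[1 + seed %% 3], seed = 60 + seed,
                            n_decoys = 12)
    res <- run_fragsearch(fix$gap, fix$db)
    expect_equal(res$candidates[[1]]$fragment_id, "native")
    expect_lt(res$candidates[[1]]$stem_rmsd, 1e-9)
    expect_equal(res$candidates[[1]]$seq_similarity, 1.0)
    expect_equal(res$candidates[[1]]$fp_deviation, 0)
  }
})

test_that("results are invariant to database record order", {
  fix <- make_gap_fixture("helix", 9, seed = 66, n_decoys = 15)
  ids0 <- vapply(run_fragsearch(fix$gap, fix$db)$candidates, `[[`, "", "fragment_id")
  set.seed(1)
  shuffled <- new_fragment_db(sample(fix$db$records))
  ids1 <- vapply(run_fragsearch(fix$gap, shuffled)$candidates, `[[`, "", "fragment_id")
  expect_identical(ids0, ids1)
})

test_that("stage counts are monotone and truncation caps are honored", {
  fix <- make_gap_fixture("loop", 7, seed = 67, n_decoys = 25)
  params <- search_params(pool_size = 20L, shortlist_size = 8L)
  res <- run_fragsearch(fix$gap, fix$db, params)
  cnt <- stage_report(res)
  expect_true(all(diff(cnt) <= 0))
  expect_lte(cnt[["stage2"]], 20L)
  expect_lte(length(res$candidates), 8L)
  empty <- run_fragsearch(fix$gap, new_fragment_db(list()))
  expect_identical(unname(stage_report(empty)), rep(0L, 4))
  expect_length(empty$candidates, 0)
})

test_that("benchmark mode removes near-identical sequences before ranking", {
  fix <- make_gap_fixture("helix", 9, seed = 68, n_decoys = 10)
  res <- run_fragsearch(fix$gap, fix$db, search_params(exclude_identity = TRUE))
  ids <- vapply(res$candidates, `[[`, "", "fragment_id")
  expect_false("native" %in% ids)
  expect_gt(length(ids), 0)
})
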