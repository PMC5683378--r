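# Ideal backbone internal coordinates (Angstrom / degrees).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.5

TORSIONS_HELIX <- c(phi = -57, psi = -47)
TORSIONS_STRAND <- c(phi = -139, psi = 135)

# Place atom D given A-B-C, bond |CD|, angle BCD and torsion ABCD (NeRF).
place_atom <- function(a, b, c_, bond, angle_deg, torsion_deg_) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg_ * pi / 180
  bc <- c_ - b
  bc <- bc / vnorm(bc)
  n <- cross3(b - a, bc)
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an ideal-geometry backbone (N, CA, C, O per residue) from phi/psi.
backbone_from_torsions <- function(phi, psi, omega = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 3L)
  omega <- omega %||% rep(180, n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  ang <- ANG_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_N, ANG_CA_C_N, psi[i])
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], BOND_N_CA, ANG_C_N_CA, omega[i])
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ], BOND_CA_C, ANG_N_CA_C,
                              phi[i + 1L])
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_O, ANG_CA_C_O, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

backbone_to_coord_set <- function(bb) {
  n <- nrow(bb$N)
  rows <- lapply(seq_len(n), function(i) {
    cbind(rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ]))
  })
  xyz <- do.call(rbind, rows)
  coord_set(rep(c("N", "CA", "C", "O"), n), rep(seq_len(n), each = 4L), xyz)
}

sample_loop_torsions <- function(n) {
  cbind(phi = stats::runif(n, -160, -50), psi = stats::runif(n, -60, 160))
}

# Minimum distance between atoms of residues at least `sep` residues apart.
min_nonbonded_dist <- function(cs, sep = 2L) {
  P <- cs_xyz(cs)
  resi <- cs$resi
  D <- as.matrix(stats::dist(P))
  mask <- abs(outer(resi, resi, `-`)) >= sep
  if (!any(mask)) return(Inf)
  min(D[mask])
}

#' Generate an ideal secondary-structure segment
#'
#' Builds an ideal-geometry backbone (N, CA, C, O per residue) from standard
#' internal coordinates: alpha-helical torsions (consecutive CA-CA 3.8 A,
#' ~1.5 A rise and ~100 degrees twist per residue), ideal extended-strand
#' torsions (~3.3 A rise), or a self-avoiding random-coil walk for loops.
#'
#' @param kind `"helix"`, `"strand"` or `"loop"`.
#' @param length number of residues (>= 3).
#' @param seed RNG seed (loops are stochastic; helices/strands are
#'   deterministic but accept a seed for a uniform interface).
#' @return backbone [coord_set()], `resi` 1..length.
#' @export
make_ideal_segment <- function(kind = c("helix", "strand", "loop"), length, seed = 1L) {
  kind <- match.arg(kind)
  if (length < 3L) stopf("segment length must be >= 3")
  with_seed(seed, {
    if (kind == "helix") {
      bb <- backbone_from_torsions(rep(TORSIONS_HELIX["phi"], length),
                                   rep(TORSIONS_HELIX["psi"], length))
      return(backbone_to_coord_set(bb))
    }
    if (kind == "strand") {
      bb <- backbone_from_torsions(rep(TORSIONS_STRAND["phi"], length),
                                   rep(TORSIONS_STRAND["psi"], length))
      return(backbone_to_coord_set(bb))
    }
    for (attempt in 1:200) {
      t <- sample_loop_torsions(length)
      cs <- backbone_to_coord_set(backbone_from_torsions(t[, "phi"], t[, "psi"]))
      ca <- cs[cs$elety == "CA", , drop = FALSE]
      if (min_nonbonded_dist(ca, 3L) >= 4.0 && min_nonbonded_dist(cs, 2L) >= 2.0) {
        return(cs)
      }
    }
    stopf("failed to build a self-avoiding loop of length %d", length)
  })
}

#' Perturb a fragment's interior coordinates
#'
#' Adds zero-mean isotropic Gaussian displacement of scale `sd` to every
#' atom of the interior residues; the terminal (stem) residues are kept
#' fixed bitwise, so the perturbed fragment retains the original stem
#' geometry. Bond lengths are not restored; decoys are deliberately
#' non-ideal.
#'
#' @param frag backbone [coord_set()].
#' @param sd per-coordinate displacement scale (Angstrom).
#' @param seed RNG seed.
#' @return perturbed [coord_set()].
#' @export
perturb_fragment <- function(frag, sd, seed = 1L) {
  if (sd < 0) stopf("sd must be >= 0")
  if (sd == 0) return(frag)
  last <- max(frag$resi)
  interior <- frag$resi > 1L & frag$resi < last
  with_seed(seed, {
    xyz <- cs_xyz(frag)
    xyz[interior, ] <- xyz[interior, ] + matrix(stats::rnorm(3 * sum(interior), 0, sd),
                                                ncol = 3)
    cs_set_xyz(frag, xyz)
  })
}

#' Specification for a synthetic fixture set
#'
#' @param seed master seed; the whole fixture set is a pure function of it.
#' @param layouts list of per-residue class strings (`H`/`E`/`L`), one per
#'   toy structure; default: three 40-residue chains mixing helix, strand
#'   and loop runs.
#' @param perturb_sd decoy interior displacement scale (Angstrom).
#' @param n_decoys decoys per gap in mini databases.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         layouts = NULL,
                         perturb_sd = 1.0, n_decoys = 20L) {
  layouts <- layouts %||% list(
    paste0(strrep("L", 4), strrep("H", 10), strrep("L", 4), strrep("E", 6),
           strrep("L", 4), strrep("H", 8), strrep("L", 4)),
    paste0(strrep("L", 5), strrep("E", 7), strrep("L", 5), strrep("H", 12),
           strrep("L", 5), strrep("E", 6)),
    paste0(strrep("L", 6), strrep("H", 14), strrep("L", 6), strrep("E", 8),
           strrep("L", 6))
  )
  structure(list(seed = as.integer(seed), layouts = layouts,
                 perturb_sd = perturb_sd, n_decoys = as.integer(n_decoys)),
            class = "fixture_spec")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

coord_set_to_structure <- function(cs, sequence, chain = "A") {
  seqc <- seq_chars(sequence)
  resid3 <- suppressWarnings(bio3d::aa123(seqc))
  resid3[is.na(resid3)] <- "UNK"
  protein_structure(data.frame(
    type = "ATOM", elety = cs$elety, resid = resid3[cs$resi], aa = seqc[cs$resi],
    chain = chain, resno = cs$resi, insert = "",
    x = cs$x, y = cs$y, z = cs$z, o = 1, b = 0, stringsAsFactors = FALSE
  ))
}

# Build one toy chain for a class layout; retries loop torsions until the
# chain is self-clash-free (non-bonded atoms >= 2 A apart).
gen_toy_structure <- function(layout, seed, chain = "A") {
  classes <- seq_chars(layout)
  n <- length(classes)
  if (n < 5L) stopf("layout too short")
  with_seed(seed, {
    sequence <- paste(sample(AA20, n, replace = TRUE), collapse = "")
    for (attempt in 1:100) {
      phi <- numeric(n); psi <- numeric(n)
      for (i in seq_len(n)) {
        if (classes[i] == "H") {
          phi[i] <- TORSIONS_HELIX["phi"]; psi[i] <- TORSIONS_HELIX["psi"]
        } else if (classes[i] == "E") {
          phi[i] <- TORSIONS_STRAND["phi"]; psi[i] <- TORSIONS_STRAND["psi"]
        } else {
          t <- sample_loop_torsions(1L)
          phi[i] <- t[1, "phi"]; psi[i] <- t[1, "psi"]
        }
      }
      cs <- backbone_to_coord_set(backbone_from_torsions(phi, psi))
      if (min_nonbonded_dist(cs, 2L) >= 2.0) {
        return(coord_set_to_structure(cs, sequence, chain))
      }
    }
    stopf("could not realize a clash-free chain for layout %s", layout)
  })
}

#' Build the toy protein set of a fixture specification
#'
#' Each structure realizes one class layout as an ideal-geometry chain with
#' complete N/CA/C/O backbone, a random sequence, and no two non-bonded
#' atoms closer than 2 A. Bit-reproducible from the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @return list of [protein_structure()]s.
#' @export
build_toy_protein_set <- function(spec = fixture_spec()) {
  lapply(seq_along(spec$layouts), function(i) {
    gen_toy_structure(spec$layouts[[i]], derive_seed(spec$seed, paste0("toy", i)))
  })
}

# The gap's native fragment (stems + original segment) as a fragment record.
native_fragment <- function(gap, id = "native") {
  res <- chain_residue_table(gap$structure, gap$chain)
  i1 <- match(gap$nstem, res$key)
  i2 <- match(gap$cstem, res$key)
  coords <- extract_backbone(gap$structure, gap$chain, res$resno[i1], res$resno[i2])
  new_fragment_record(source = "native", chain = gap$chain,
                      first_resno = res$resno[i1],
                      sequence = paste(res$aa[i1:i2], collapse = ""),
                      coords = coords, id = id)
}

mutate_sequence <- function(sequence, frac, preserve = integer(0)) {
  chars <- seq_chars(sequence)
  mutable <- setdiff(seq_along(chars), preserve)
  k <- max(1L, ceiling(frac * length(mutable)))
  pos <- sample(mutable, min(k, length(mutable)))
  for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Build a mini fragment database for one gap
#'
#' A desk-scale stand-in for a PDB-derived fragment library: background
#' fragments of the gap-serving length extracted from other toy structures,
#' optionally the gap's native fragment, and `n_decoys` decoys built by
#' perturbing the native interior (graded displacement scales) and mutating
#' its sequence. Decoy terminals equal the native stems, so every decoy
#' passes the stage-1 geometry filter and the density re-ranking becomes the
#' deciding stage.
#'
#' @param gap a `gap_spec` over a structure whose native segment is present.
#' @param background list of [protein_structure()]s mined for background
#'   fragments (may be empty).
#' @param include_native include the native fragment itself.
#' @param n_decoys number of perturbed-native decoys.
#' @param seed RNG seed.
#' @param decoy_sd_range range of interior displacement scales (Angstrom);
#'   decoys are spaced evenly across it.
#' @param decoy_mutation fraction of interior sequence positions mutated per
#'   decoy (keeps decoys below the benchmark identity cutoff).
#' @return A `fragment_db`.
#' @export
build_mini_db <- function(gap, background = list(), include_native = TRUE,
                          n_decoys = 20L, seed = 1L,
                          decoy_sd_range = c(0.35, 2.5), decoy_mutation = 0.4) {
  frag_len <- gap$L + 2L
  records <- list()
  for (i in seq_along(background)) {
    recs <- extract_fragments(background[[i]], frag_len, frag_len,
                              source_id = sprintf("bg%d", i))
    records <- c(records, recs)
  }
  nat <- native_fragment(gap)
  if (include_native) records <- c(records, list(nat))
  if (n_decoys > 0L) {
    sds <- seq(decoy_sd_range[1], decoy_sd_range[2], length.out = n_decoys)
    decoys <- with_seed(derive_seed(seed, "decoys"), {
      lapply(seq_len(n_decoys), function(i) {
        coords <- perturb_fragment(nat$coords, sds[i],
                                   seed = derive_seed(seed, paste0("decoy", i)))
        seq_i <- mutate_sequence(nat$sequence, decoy_mutation,
                                 preserve = c(1L, frag_len))
        new_fragment_record(source = "decoy", chain = gap$chain,
                            first_resno = nat$first_resno, sequence = seq_i,
                            coords = coords, id = sprintf("decoy_%03d", i))
      })
    })
    records <- c(records, decoys)
  }
  new_fragment_db(records)
}

#' Build a decoy database covering a sliding-window benchmark
#'
#' For every window the benchmark harness will visit (same enumeration:
#' interior start positions `2, 2+stride, ...` for each length), adds the
#' native fragment plus `n_decoys` perturbed-native decoys with mutated
#' sequences. Combined with the benchmark's identity filter this emulates a
#' library that contains plausible but non-identical candidates for every
#' gap.
#'
#' @param structure a [protein_structure()].
#' @param window_lengths segment lengths the benchmark will evaluate.
#' @param chain chain identifier (default: first chain).
#' @param stride,max_windows_per_length window enumeration, matching
#'   [benchmark_sliding_window()].
#' @param n_decoys decoys per window.
#' @param seed RNG seed.
#' @param decoy_sd_range,decoy_mutation decoy construction parameters.
#' @return A `fragment_db`.
#' @export
build_benchmark_db <- function(structure, window_lengths, chain = NULL,
                               stride = 1L, max_windows_per_length = Inf,
                               n_decoys = 16L, seed = 1L,
                               decoy_sd_range = c(0.35, 2.5), decoy_mutation = 0.4) {
  chain <- chain %||% structure$atom$chain[structure$atom$type == "ATOM"][1]
  res <- chain_residue_table(structure, chain)
  n <- nrow(res)
  records <- list()
  for (L in window_lengths) {
    starts <- seq(2L, n - L, by = stride)
    if (length(starts) > max_windows_per_length) starts <- starts[seq_len(max_windows_per_length)]
    for (j in starts) {
      seq_native <- paste(res$aa[j:(j + L - 1L)], collapse = "")
      gap <- define_gap(structure, chain, res$resno[j - 1L], res$resno[j + L], seq_native)
      sub <- build_mini_db(gap, include_native = TRUE, n_decoys = n_decoys,
                           seed = derive_seed(seed, sprintf("w%d_%d", L, j)),
                           decoy_sd_range = decoy_sd_range,
                           decoy_mutation = decoy_mutation)
      recs <- sub$records
      for (k in seq_along(recs)) {
        recs[[k]]$id <- sprintf("w%d_%d_%s", L, j, recs[[k]]$id)
      }
      records <- c(records, recs)
    }
  }
  new_fragment_db(records)
}

#' Simulate an "experimental" map of a structure, optionally with noise
#'
#' Simulates the full structure's density at the requested resolution and
#' adds i.i.d. Gaussian voxel noise at the given signal-to-noise ratio
#' (sd(signal)/sd(noise)). Real cryo-EM noise is structured; this fixture
#' noise is deliberately simple.
#'
#' @param structure a [protein_structure()].
#' @param resolution nominal resolution (Angstrom).
#' @param voxel_size grid spacing (Angstrom).
#' @param snr signal-to-noise ratio; `NULL` or `Inf` for a noise-free map.
#' @param seed RNG seed for the noise.
#' @return A [density_map()].
#' @export
simulate_experimental_map <- function(structure, resolution, voxel_size = 1.0,
                                      snr = NULL, seed = 1L) {
  at <- structure$atom[structure$atom$type == "ATOM", , drop = FALSE]
  coords <- coord_set(at$elety, seq_len(nrow(at)), as.matrix(at[, c("x", "y", "z")]))
  map <- simulate_map(coords, voxel_size, resolution)
  if (!is.null(snr) && is.finite(snr)) {
    stopifnot(snr > 0)
    noise_sd <- stats::sd(map$values) / snr
    map$values <- map$values + with_seed(derive_seed(seed, "mapnoise"),
                                         array(stats::rnorm(length(map$values), 0, noise_sd),
                                               dim = dim(map$values)))
  }
  map
}

#' Build a complete single-gap fixture
#'
#' Convenience wrapper used by the test harnesses: a toy protein with a
#' segment of the requested secondary-structure class embedded between loop
#' flanks, the gap over that segment, a simulated map, and a mini database.
#'
#' @param kind segment class of the modeled span.
#' @param L gap length (residues).
#' @param seed RNG seed.
#' @param resolution map resolution (Angstrom).
#' @param include_native,n_decoys passed to [build_mini_db()].
#' @param snr optional map noise level.
#' @param flank loop residues on each side of the segment.
#' @return list with `structure`, `gap`, `map`, `db`.
#' @export
make_gap_fixture <- function(kind = c("helix", "strand", "loop"), L = 9L, seed = 1L,
                             resolution = 8, include_native = TRUE, n_decoys = 20L,
                             snr = NULL, flank = 6L) {
  kind <- match.arg(kind)
  code <- c(helix = "H", strand = "E", loop = "L")[[kind]]
  layout <- paste0(strrep("L", flank), strrep(code, L), strrep("L", flank))
  st <- gen_toy_structure(layout, derive_seed(seed, paste0("gapfix", kind, L)))
  res <- chain_residue_table(st, "A")
  nstem <- res$resno[flank]
  cstem <- res$resno[flank + L + 1L]
  seq_native <- paste(res$aa[(flank + 1L):(flank + L)], collapse = "")
  gap <- define_gap(st, "A", nstem, cstem, seq_native)
  map <- simulate_experimental_map(st, resolution, snr = snr,
                                   seed = derive_seed(seed, "fixmap"))
  db <- build_mini_db(gap, include_native = include_native, n_decoys = n_decoys,
                      seed = derive_seed(seed, "fixdb"))
  list(structure = st, gap = gap, map = map, db = db)
}
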