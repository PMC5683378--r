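#' Backbone RMSD in a fixed frame
#'
#' Root-mean-square deviation over matched atoms,
#' `sqrt(mean_i |X_i - Y_i|^2)`. No fitting is performed here: the pipeline
#' fixes the frame by stem superposition, so predicted and native segments
#' are compared directly in world coordinates.
#'
#' @param x,y matched [coord_set()]s or n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(x, y) {
  X <- if (is.data.frame(x)) cs_xyz(x) else as.matrix(x)
  Y <- if (is.data.frame(y)) cs_xyz(y) else as.matrix(y)
  if (nrow(X) != nrow(Y)) stopf("coordinate sets differ in length (%d vs %d)", nrow(X), nrow(Y))
  if (nrow(X) == 0L) stopf("empty coordinate sets")
  sqrt(mean(rowSums((X - Y)^2)))
}

#' Length-dependent TM-score normalization distance
#'
#' The standard scaling `d0(L) = 1.24 * (L - 15)^(1/3) - 1.8`, floored at
#' 0.5 Angstrom so short segments remain well-defined.
#'
#' @param L segment length (residues).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L) {
  x <- L - 15
  d0 <- 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8
  max(d0, 0.5)
}

#' TM-score of a predicted segment (stem-aligned, equal lengths)
#'
#' Length-normalized topological similarity
#' `(1/L) * sum_i 1 / (1 + d_i^2 / d0^2)` over CA-CA distances `d_i`
#' computed in the frame fixed by stem superposition (no further
#' optimization). Values above 0.5 indicate the same fold.
#'
#' @param x,y CA [coord_set()]s (rows with `elety == "CA"` are used) or
#'   L x 3 matrices of CA positions, equal length.
#' @param d0 scaling distance; default [tm_d0()] of the length.
#' @return score in `[0, 1]`.
#' @export
tm_score <- function(x, y, d0 = NULL) {
  get_ca <- function(v) {
    if (is.data.frame(v)) {
      ca <- v[v$elety == "CA", , drop = FALSE]
      if (nrow(ca) == 0L) stopf("no CA atoms in coordinate set")
      cs_xyz(ca)
    } else {
      as.matrix(v)
    }
  }
  X <- get_ca(x); Y <- get_ca(y)
  if (nrow(X) != nrow(Y)) stopf("segment lengths differ (%d vs %d)", nrow(X), nrow(Y))
  L <- nrow(X)
  d0 <- d0 %||% tm_d0(L)
  stopifnot(d0 > 0)
  di2 <- rowSums((X - Y)^2)
  mean(1 / (1 + di2 / d0^2))
}

# Per-residue phi/psi torsions for a chain; NA at the termini.
chain_phi_psi <- function(structure, chain_id) {
  res <- chain_residue_table(structure, chain_id)
  n <- nrow(res)
  get <- function(i, a) {
    at <- residue_atoms(structure, chain_id, res$resno[i], res$insert[i], a)
    if (nrow(at)) c(at$x, at$y, at$z) else NULL
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      p <- list(get(i - 1L, "C"), get(i, "N"), get(i, "CA"), get(i, "C"))
      if (!any(vapply(p, is.null, logical(1)))) phi[i] <- torsion_deg(p[[1]], p[[2]], p[[3]], p[[4]])
    }
    if (i < n) {
      p <- list(get(i, "N"), get(i, "CA"), get(i, "C"), get(i + 1L, "N"))
      if (!any(vapply(p, is.null, logical(1)))) psi[i] <- torsion_deg(p[[1]], p[[2]], p[[3]], p[[4]])
    }
  }
  data.frame(resno = res$resno, insert = res$insert, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

#' Classify secondary structure from backbone dihedrals
#'
#' A deliberately simple, dependency-free phi/psi classifier used only to
#' label benchmark segments: helix for runs of at least 4 residues near
#' (-60, -45), strand for runs of at least 3 near (-120, 130); everything
#' else - including 3-10 helices, pi-bulges and kinks - is "loop". An
#' external DSSP assignment can be substituted wherever class labels are
#' accepted.
#'
#' @param structure a [protein_structure()].
#' @param chain_id chain identifier.
#' @return character vector of per-residue classes (`"H"`, `"E"`, `"L"`).
#' @export
classify_ss <- function(structure, chain_id) {
  tp <- chain_phi_psi(structure, chain_id)
  raw <- ifelse(!is.na(tp$phi) & !is.na(tp$psi) &
                  tp$phi > -100 & tp$phi < -30 & tp$psi > -80 & tp$psi < -5, "H",
                ifelse(!is.na(tp$phi) & !is.na(tp$psi) &
                         tp$phi > -180 & tp$phi < -90 & tp$psi > 90 & tp$psi < 180, "E", "L"))
  out <- rep("L", length(raw))
  r <- rle(raw)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == "H" && r$lengths[k] >= 4L) out[starts[k]:ends[k]] <- "H"
    if (r$values[k] == "E" && r$lengths[k] >= 3L) out[starts[k]:ends[k]] <- "E"
  }
  out
}

segment_class <- function(ss_vec) {
  tab <- table(factor(ss_vec, levels = c("H", "E", "L")))
  if (tab["H"] > length(ss_vec) / 2) return("helix")
  if (tab["E"] > length(ss_vec) / 2) return("sheet")
  "loop"
}

# Matched native/placed backbone pair on shared (residue, atom) labels.
matched_pair <- function(native, placed) {
  kn <- paste(native$resi, native$elety)
  kp <- paste(placed$resi, placed$elety)
  common <- intersect(kn, kp)
  if (!length(common)) stopf("no shared backbone atoms between native and placed segment")
  list(x = cs_xyz(native)[match(common, kn), , drop = FALSE],
       y = cs_xyz(placed)[match(common, kp), , drop = FALSE])
}

candidate_rmsd <- function(native, candidate) {
  p <- matched_pair(native, candidate$placed)
  backbone_rmsd(p$x, p$y)
}

#' Sliding-window benchmark of the full pipeline
#'
#' For every window of each requested length, defines the gap (stems =
#' residues flanking the window), deletes the native segment from the
#' context, runs the search plus density re-ranking against `map`, and
#' records the top-1 RMSD of both rankings, the best-of-top-5 RMSD, the
#' TM-score of the density top hit, and the native segment's
#' secondary-structure class. `delta_rmsd` is the search top-1 RMSD minus
#' the density top-1 RMSD: positive values mean the map improved the
#' prediction.
#'
#' @param structure a [protein_structure()].
#' @param map experimental (or simulated) [density_map()].
#' @param resolution nominal resolution (Angstrom).
#' @param db a `fragment_db`.
#' @param window_lengths integer vector of segment lengths to evaluate.
#' @param params a [search_params()]; benchmark runs typically enable
#'   `exclude_identity`.
#' @param chain chain to slide over (default: first chain).
#' @param stride step between window start positions.
#' @param max_windows_per_length optional cap per length.
#' @return data frame of benchmark rows (windows with no surviving
#'   candidates or incomplete backbone are skipped and counted in
#'   `attr(, "n_skipped")`).
#' @export
benchmark_sliding_window <- function(structure, map, resolution, db,
                                     window_lengths = 5:35,
                                     params = search_params(exclude_identity = TRUE),
                                     chain = NULL, stride = 1L,
                                     max_windows_per_length = Inf) {
  chain <- chain %||% structure$atom$chain[structure$atom$type == "ATOM"][1]
  res <- chain_residue_table(structure, chain)
  ss <- classify_ss(structure, chain)
  n <- nrow(res)
  rows <- list()
  n_skipped <- 0L
  for (L in window_lengths) {
    starts <- seq(2L, n - L, by = stride)   # interior start index; stems flank
    if (length(starts) > max_windows_per_length) {
      starts <- starts[seq_len(max_windows_per_length)]
    }
    for (j in starts) {
      ok <- tryCatch({
        seq_native <- paste(res$aa[j:(j + L - 1L)], collapse = "")
        gap <- define_gap(structure, chain, res$resno[j - 1L], res$resno[j + L], seq_native)
        if (is.null(gap$native_interior)) stop("incomplete native segment")
        fit <- run_fragfit(gap, db, map, resolution, params)
        if (!length(fit$candidates)) stop("no candidates")
        fit
      }, error = function(e) NULL)
      if (is.null(ok)) { n_skipped <- n_skipped + 1L; next }
      fit <- ok
      native <- fit$gap$native_interior
      cds <- fit$candidates
      fs_rank <- vapply(cds, `[[`, integer(1), "fragsearch_rank")
      top_fs <- cds[[which(fs_rank == 1L)]]
      rmsd_fs <- candidate_rmsd(native, top_fs)
      rmsd_ff <- candidate_rmsd(native, cds[[1L]])
      top5 <- cds[seq_len(min(5L, length(cds)))]
      rmsd_b5 <- min(vapply(top5, function(c) candidate_rmsd(native, c), numeric(1)))
      nat_ca <- native[native$elety == "CA", , drop = FALSE]
      cand_ca <- cds[[1L]]$placed[cds[[1L]]$placed$elety == "CA", , drop = FALSE]
      tm <- tm_score(nat_ca, cand_ca)
      rows[[length(rows) + 1L]] <- data.frame(
        gap_id = sprintf("%s_%d_%d", chain, res$resno[j], L),
        length = L,
        ss_class = segment_class(ss[j:(j + L - 1L)]),
        rmsd_fragsearch_top1 = rmsd_fs,
        rmsd_fragfit_top1 = rmsd_ff,
        rmsd_fragfit_best_of_5 = rmsd_b5,
        tm_score_top1 = tm,
        n_candidates = length(cds),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(out)) out$delta_rmsd <- out$rmsd_fragsearch_top1 - out$rmsd_fragfit_top1
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Resolution sweep of density-assisted prediction gain
#'
#' Simulates a map of the full structure at each requested resolution, runs
#' the sliding-window benchmark against it, and tabulates the mean
#' `delta_rmsd` per (resolution, length). Quantifies how the re-ranking
#' gain degrades as the map blurs.
#'
#' @param structure a [protein_structure()].
#' @param resolutions numeric vector of resolutions (Angstrom).
#' @param db a `fragment_db`.
#' @param window_lengths segment lengths to evaluate.
#' @param params a [search_params()].
#' @param voxel_size simulation voxel size (Angstrom).
#' @param chain,stride,max_windows_per_length passed to the benchmark.
#' @return list with `rows` (all benchmark rows, tagged by resolution) and
#'   `summary` (mean delta_rmsd per resolution x length).
#' @export
resolution_sweep <- function(structure, resolutions, db, window_lengths = c(5, 9),
                             params = search_params(exclude_identity = TRUE),
                             voxel_size = 1.0, chain = NULL, stride = 1L,
                             max_windows_per_length = Inf) {
  at <- structure$atom[structure$atom$type == "ATOM", , drop = FALSE]
  coords <- coord_set(at$elety, seq_len(nrow(at)), as.matrix(at[, c("x", "y", "z")]))
  all_rows <- list()
  for (r in resolutions) {
    map <- simulate_map(coords, voxel_size, r)
    bench <- benchmark_sliding_window(structure, map, r, db, window_lengths,
                                      params, chain, stride, max_windows_per_length)
    if (nrow(bench)) {
      bench$resolution <- r
      all_rows[[length(all_rows) + 1L]] <- bench
    }
  }
  rows <- if (length(all_rows)) do.call(rbind, all_rows) else data.frame()
  summary <- if (nrow(rows)) {
    stats::aggregate(delta_rmsd ~ resolution + length, data = rows, FUN = mean)
  } else {
    data.frame()
  }
  list(rows = rows, summary = summary)
}
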