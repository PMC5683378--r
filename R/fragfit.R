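#' Score shortlist candidates by density cross-correlation
#'
#' For each candidate, the placed interior coordinates are converted to a
#' simulated density on the residual box's own grid, low-pass filtered to
#' the map's nominal resolution, and compared to the residual by Pearson
#' cross-correlation. Candidates that fall entirely outside the box are
#' flagged and assigned a CCC of -1.
#'
#' @param candidates list of scored candidates (from [run_fragsearch()]).
#' @param residual_box residual [density_map()] from [subtract_context()].
#' @param resolution nominal resolution (Angstrom).
#' @param order Butterworth order.
#' @return the candidate list with `ccc` (and `outside_box` flag) set.
#' @export
score_candidates <- function(candidates, residual_box, resolution, order = 8L) {
  if (!length(candidates)) return(candidates)
  H <- bw_transfer(dim(residual_box$values), residual_box$voxel_size, resolution, order)
  ub <- map_upper_bound(residual_box)
  lapply(candidates, function(cd) {
    P <- cs_xyz(cd$placed)
    inside <- P[, 1] >= residual_box$origin[1] & P[, 1] <= ub[1] &
      P[, 2] >= residual_box$origin[2] & P[, 2] <= ub[2] &
      P[, 3] >= residual_box$origin[3] & P[, 3] <= ub[3]
    if (!any(inside)) {
      cd$ccc <- -1
      cd$outside_box <- TRUE
      return(cd)
    }
    sim <- simulate_map(P[inside, , drop = FALSE], residual_box$voxel_size,
                        resolution = NA_real_, box = residual_box, out_of_box = "clip")
    sim$values <- bw_apply(sim$values, H)
    if (stats::sd(sim$values) == 0) {
      cd$ccc <- -1
      cd$outside_box <- TRUE
      return(cd)
    }
    cd$ccc <- stats::cor(as.vector(sim$values), as.vector(residual_box$values))
    cd$outside_box <- FALSE
    cd
  })
}

#' Model a gap by fragment search plus density re-ranking
#'
#' The full pipeline: hierarchical fragment search, minimal-box extraction
#' around the gap, context-density subtraction, per-candidate density
#' scoring, and final re-ranking by descending CCC (ties: lower stem RMSD,
#' then fragment id). Re-ranking never changes the candidate set, only its
#' order; both ranks are kept per candidate.
#'
#' @param gap a `gap_spec`.
#' @param db a `fragment_db`.
#' @param exp_map experimental [density_map()].
#' @param resolution nominal map resolution (Angstrom).
#' @param params a [search_params()].
#' @param subtract score against the context-subtracted residual (default)
#'   or, for ablation, against the normalized unsubtracted box.
#' @param pad minimal-box padding (Angstrom); default = `resolution`.
#' @return A `fragfit_result` with ranked candidates, stage counts and box
#'   metadata.
#' @export
run_fragfit <- function(gap, db, exp_map, resolution, params = search_params(),
                        subtract = TRUE, pad = NULL) {
  search <- run_fragsearch(gap, db, params)
  if (!length(search$candidates)) {
    return(structure(list(gap = gap, candidates = list(), counts = search$counts,
                          resolution = resolution, box_dim = NULL),
                     class = "fragfit_result"))
  }
  exp_map$resolution <- resolution
  box <- minimal_box(gap, exp_map, pad = pad)
  residual <- if (subtract) {
    subtract_context(normalize_map(box), context_coords(gap), resolution)
  } else {
    normalize_map(box)
  }
  cands <- score_candidates(search$candidates, residual, resolution)
  ord <- order(-vapply(cands, `[[`, numeric(1), "ccc"),
               vapply(cands, `[[`, numeric(1), "stem_rmsd"),
               vapply(cands, `[[`, character(1), "fragment_id"))
  cands <- cands[ord]
  for (i in seq_along(cands)) cands[[i]]$fragfit_rank <- i
  structure(list(gap = gap, candidates = cands, counts = search$counts,
                 resolution = resolution, box_dim = dim(residual$values),
                 residual = residual),
            class = "fragfit_result")
}

#' @export
print.fragfit_result <- function(x, ...) {
  cat(sprintf("fragfit_result: %d ranked candidate(s), box %s @ %.1f A\n",
              length(x$candidates),
              if (is.null(x$box_dim)) "-" else paste(x$box_dim, collapse = "x"),
              x$resolution))
  invisible(x)
}

# Scores table of a result, in fragfit rank order.
result_table <- function(result) {
  cds <- result$candidates
  data.frame(
    fragfit_rank = vapply(cds, function(c) c$fragfit_rank %||% NA_integer_, integer(1)),
    fragsearch_rank = vapply(cds, function(c) c$fragsearch_rank %||% NA_integer_, integer(1)),
    fragment_id = vapply(cds, `[[`, character(1), "fragment_id"),
    ccc = vapply(cds, `[[`, numeric(1), "ccc"),
    stem_rmsd = vapply(cds, `[[`, numeric(1), "stem_rmsd"),
    seq_sim = vapply(cds, `[[`, numeric(1), "seq_similarity"),
    fp_dev = vapply(cds, `[[`, numeric(1), "fp_deviation"),
    combined_score = vapply(cds, `[[`, numeric(1), "combined_score"),
    stringsAsFactors = FALSE
  )
}

# Full structure with one candidate's interior grafted between the stems.
grafted_structure <- function(result, candidate) {
  gap <- result$gap
  ctx <- gap$context
  res <- chain_residue_table(gap$structure, gap$chain)
  i1 <- match(gap$nstem, res$key)
  placed <- candidate$placed
  L <- max(placed$resi)
  seqc <- seq_chars(gap$sequence)
  resid3 <- suppressWarnings(bio3d::aa123(seqc))
  resid3[is.na(resid3)] <- "UNK"
  new_rows <- data.frame(
    type = "ATOM", elety = placed$elety, resid = resid3[placed$resi],
    aa = seqc[placed$resi], chain = gap$chain,
    resno = gap$nstem_resno + placed$resi, insert = "",
    x = placed$x, y = placed$y, z = placed$z, o = 1, b = 0,
    stringsAsFactors = FALSE
  )
  in_chain <- ctx$chain == gap$chain & ctx$type == "ATOM"
  pos <- rep(NA_integer_, nrow(ctx))
  pos[in_chain] <- match(res_key(ctx$resno[in_chain], ctx$insert[in_chain]), res$key)
  before <- in_chain & !is.na(pos) & pos <= i1
  after <- in_chain & !is.na(pos) & pos > i1
  other <- !in_chain
  protein_structure(rbind(ctx[before, , drop = FALSE], new_rows,
                          ctx[after, , drop = FALSE], ctx[other, , drop = FALSE]))
}

#' Export top-ranked models and a score table
#'
#' Writes the top `k` candidates as PDB files of the full structure with the
#' fragment grafted between the stems, plus a TSV of all candidate scores.
#' Filenames encode the rank and fragment id. Inspecting the top five
#' placements visually is the intended selection aid.
#'
#' @param result a `fragfit_result`.
#' @param k number of models to export (default 5; `0` writes the TSV only).
#' @param out_dir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
export_models <- function(result, k = 5L, out_dir = ".") {
  if (!length(result$candidates)) stopf("result contains no candidates")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (k > length(result$candidates)) {
    warning(sprintf("only %d candidate(s) available; exporting all", length(result$candidates)))
    k <- length(result$candidates)
  }
  paths <- character(0)
  tab <- result_table(result)
  tsv <- file.path(out_dir, "fragfit_scores.tsv")
  utils::write.table(format(tab, digits = 12, trim = TRUE), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, tsv)
  for (i in seq_len(k)) {
    cd <- result$candidates[[i]]
    st <- grafted_structure(result, cd)
    p <- file.path(out_dir, sprintf("model_rank%02d_%s.pdb", i, cd$fragment_id))
    write_structure(st, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
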