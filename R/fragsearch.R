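#' Search parameters for the hierarchical fragment search
#'
#' @param delta_d stage-1 stem-distance half-window (Angstrom, strict).
#' @param redundancy_rmsd pairwise placed-backbone RMSD below which two
#'   candidates are considered the same fold (strict; the better stem fit
#'   survives).
#' @param clash_cutoff heavy-atom clash distance (Angstrom).
#' @param pool_size candidates kept after stem-RMSD ranking (top-1000 list).
#' @param shortlist_size candidates kept after re-ranking (top-100 list).
#' @param identity_cutoff benchmark-mode sequence-identity exclusion
#'   threshold (records strictly above it are removed).
#' @param exclude_identity enable the benchmark-mode identity filter.
#' @param w_seq,w_geo re-ranking weights for sequence similarity and
#'   normalized fingerprint deviation.
#' @return A `search_params` list.
#' @export
search_params <- function(delta_d = 0.75, redundancy_rmsd = 0.5, clash_cutoff = 2.0,
                          pool_size = 1000L, shortlist_size = 100L,
                          identity_cutoff = 0.90, exclude_identity = FALSE,
                          w_seq = 0.5, w_geo = 0.5) {
  stopifnot(delta_d > 0, redundancy_rmsd > 0, clash_cutoff > 0,
            pool_size >= 1L, shortlist_size >= 1L, shortlist_size <= pool_size)
  structure(list(delta_d = delta_d, redundancy_rmsd = redundancy_rmsd,
                 clash_cutoff = clash_cutoff, pool_size = as.integer(pool_size),
                 shortlist_size = as.integer(shortlist_size),
                 identity_cutoff = identity_cutoff,
                 exclude_identity = isTRUE(exclude_identity),
                 w_seq = w_seq, w_geo = w_geo),
            class = "search_params")
}

blosum_env <- new.env(parent = emptyenv())

get_blosum62 <- function() {
  if (is.null(blosum_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    blosum_env$mat <- m[aas, aas]
    blosum_env$min <- min(blosum_env$mat)
  }
  blosum_env$mat
}

#' Substitution-matrix sequence similarity
#'
#' Mean per-position BLOSUM62 score, min-max normalized at each position by
#' the larger of the two residues' self-scores (relative to the matrix
#' minimum). Identical sequences score exactly 1; the measure is symmetric.
#' Unknown residues (not one of the 20 standard amino acids) contribute 0.
#'
#' @param a,b equal-length one-letter sequences.
#' @return similarity in `[0, 1]`.
#' @export
sequence_similarity <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) stopf("sequence length mismatch (%d vs %d)", length(ca), length(cb))
  m <- get_blosum62()
  smin <- blosum_env$min
  vals <- vapply(seq_along(ca), function(i) {
    x <- ca[i]; y <- cb[i]
    if (!(x %in% rownames(m)) || !(y %in% rownames(m))) return(0)
    denom <- max(m[x, x], m[y, y]) - smin
    (m[x, y] - smin) / denom
  }, numeric(1))
  mean(pmin(1, pmax(0, vals)))
}

# Placed-interior backbone RMSD between two candidates on shared atom names.
placed_pair_rmsd <- function(a, b) {
  ka <- paste(a$resi, a$elety); kb <- paste(b$resi, b$elety)
  common <- intersect(ka, kb)
  xa <- cs_xyz(a)[match(common, ka), , drop = FALSE]
  xb <- cs_xyz(b)[match(common, kb), , drop = FALSE]
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Run the hierarchical fragment search
#'
#' Four stages produce the candidate shortlist:
#' 1. index query: fragments of length L+2 whose stem distance is strictly
#'    within `delta_d` of the gap's (benchmark mode additionally removes
#'    records above the identity cutoff);
#' 2. stem superposition: candidates ranked ascending by the RMSD of their
#'    terminal residues fitted onto the gap stems, truncated to `pool_size`;
#' 3. placement screening: grafted candidates clashing with the context are
#'    excluded, then redundant candidates (identical interior sequence, or
#'    pairwise placed-backbone RMSD strictly below `redundancy_rmsd`) are
#'    deleted, keeping the better stem fit;
#' 4. re-ranking by `w_seq * seq_similarity - w_geo * fp_deviation/4`,
#'    descending, truncated to `shortlist_size`.
#'
#' Ties break by (score, stem_rmsd, fragment id), so results do not depend
#' on database record order.
#'
#' @param gap a `gap_spec`.
#' @param db a `fragment_db`.
#' @param params a [search_params()].
#' @return A `fragsearch_result`: list of scored candidates plus per-stage
#'   diagnostic counts (see [stage_report()]).
#' @export
run_fragsearch <- function(gap, db, params = search_params()) {
  counts <- c(stage1 = 0L, stage2 = 0L, stage3 = 0L, stage4 = 0L)
  frag_len <- gap$L + 2L
  recs <- query_by_length_distance(db, frag_len, gap$fingerprint$d, params$delta_d)
  if (params$exclude_identity && length(recs)) {
    recs <- filter_identity(recs, gap$sequence, params$identity_cutoff)
  }
  counts["stage1"] <- length(recs)
  if (!length(recs)) {
    return(structure(list(candidates = list(), counts = counts, gap = gap),
                     class = "fragsearch_result"))
  }
  # stage 2: stem superposition
  cands <- lapply(seq_along(recs), function(i) {
    rec <- recs[[i]]
    gr <- graft_fragment(rec, gap)
    list(fragment_id = rec$id, record = rec, placed = gr$placed,
         stem_rmsd = gr$stem_rmsd,
         seq_similarity = NA_real_, fp_deviation = NA_real_,
         combined_score = NA_real_, ccc = NA_real_)
  })
  ord <- order(vapply(cands, `[[`, numeric(1), "stem_rmsd"),
               vapply(cands, `[[`, character(1), "fragment_id"))
  cands <- cands[ord][seq_len(min(length(cands), params$pool_size))]
  counts["stage2"] <- length(cands)
  # stage 3: clash exclusion, then redundancy deletion (keep better stem fit)
  ctx <- clash_context_coords(gap)
  cands <- Filter(function(cd) detect_clashes(cd$placed, ctx, params$clash_cutoff) == 0L, cands)
  kept <- list()
  for (cd in cands) {   # already in ascending stem_rmsd order
    redundant <- FALSE
    for (kc in kept) {
      if (identical(interior_sequence(cd$record), interior_sequence(kc$record)) ||
          placed_pair_rmsd(cd$placed, kc$placed) < params$redundancy_rmsd) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept[[length(kept) + 1L]] <- cd
  }
  cands <- kept
  counts["stage3"] <- length(cands)
  # stage 4: sequence similarity + fingerprint matching
  cands <- lapply(cands, function(cd) {
    cd$seq_similarity <- sequence_similarity(interior_sequence(cd$record), gap$sequence)
    cd$fp_deviation <- fingerprint_deviation(cd$record$fingerprint, gap$fingerprint,
                                             d_scale = params$delta_d)
    cd$combined_score <- params$w_seq * cd$seq_similarity -
      params$w_geo * cd$fp_deviation / 4
    cd
  })
  ord <- order(-vapply(cands, `[[`, numeric(1), "combined_score"),
               vapply(cands, `[[`, numeric(1), "stem_rmsd"),
               vapply(cands, `[[`, character(1), "fragment_id"))
  cands <- cands[ord][seq_len(min(length(cands), params$shortlist_size))]
  for (i in seq_along(cands)) cands[[i]]$fragsearch_rank <- i
  counts["stage4"] <- length(cands)
  structure(list(candidates = cands, counts = counts, gap = gap),
            class = "fragsearch_result")
}

#' Per-stage candidate counts of a search
#'
#' Counts surviving each of the four search stages; non-increasing by
#' construction.
#'
#' @param result a `fragsearch_result` (or a `fragfit_result`).
#' @return named integer vector `stage1..stage4`.
#' @export
stage_report <- function(result) {
  result$counts
}

#' @export
print.fragsearch_result <- function(x, ...) {
  cat(sprintf("fragsearch_result: %d candidate(s); stage counts %s\n",
              length(x$candidates), paste(x$counts, collapse = " -> ")))
  invisible(x)
}
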