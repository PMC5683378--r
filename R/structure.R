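BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Protein structure container
#'
#' A light wrapper around a per-atom data frame with columns `type`
#' (ATOM/HETATM), `elety`, `resid` (three-letter), `aa` (one-letter),
#' `chain`, `resno` (author numbering), `insert` (insertion code, `""` when
#' absent), `x`, `y`, `z`, `o` (occupancy), `b`. Residues within a chain are
#' ordered as in the file; the pipeline requires strictly increasing
#' (`resno`, `insert`) within each chain.
#'
#' @param atom per-atom data frame as described above.
#' @return A `protein_structure`.
#' @export
protein_structure <- function(atom) {
  need <- c("type", "elety", "resid", "aa", "chain", "resno", "insert",
            "x", "y", "z", "o", "b")
  miss <- setdiff(need, names(atom))
  if (length(miss)) stopf("atom table missing columns: %s", paste(miss, collapse = ", "))
  atom$insert[is.na(atom$insert)] <- ""
  structure(list(atom = atom), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  ch <- unique(x$atom$chain)
  cat(sprintf("protein_structure: %d atoms, %d chain(s) [%s]\n",
              nrow(x$atom), length(ch), paste(ch, collapse = ",")))
  invisible(x)
}

res_key <- function(resno, insert = "") paste0(resno, ifelse(insert == "" | is.na(insert), "", insert))

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d). Alternate locations are resolved
#' to the highest-occupancy conformer; hydrogens are dropped; multi-model
#' files yield the model selected by `model_index` (first by default).
#'
#' @param path path to a PDB-format text file.
#' @param model_index 1-based model to read from multi-model files.
#' @return A [protein_structure()].
#' @export
read_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  head_lines <- tryCatch(readLines(path, n = 50000L, warn = FALSE),
                         error = function(e) stopf("cannot read %s: not PDB text", path))
  if (!any(grepl("^(ATOM|HETATM)", head_lines))) {
    stopf("format error: %s contains no ATOM/HETATM records", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stopf("format error: failed to parse %s (%s)", path, conditionMessage(e))
  )
  at <- pdb$atom
  if (nrow(at) == 0L) stopf("empty model: %s", path)
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1L || model_index > n_models) {
    stopf("model_index %d out of range (file has %d model(s))", model_index, n_models)
  }
  if (model_index > 1L) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  # drop hydrogens/deuterium
  elesym <- at$elesy
  is_h <- (!is.na(elesym) & elesym %in% c("H", "D")) | grepl("^[0-9]*[HD]", at$elety)
  at <- at[!is_h, , drop = FALSE]
  if (nrow(at) == 0L) stopf("empty model after hydrogen removal: %s", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: keep highest occupancy per (chain, resno, insert, elety); ties -> first altloc
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno, at$insert,
                 match(at$elety, c(BACKBONE_ATOMS,
                                   sort(setdiff(unique(at$elety), BACKBONE_ATOMS))))), ,
           drop = FALSE]
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  aa1[is.na(aa1) | nchar(aa1) != 1L] <- "X"
  protein_structure(data.frame(
    type = at$type, elety = at$elety, resid = at$resid, aa = aa1,
    chain = at$chain, resno = at$resno, insert = at$insert,
    x = at$x, y = at$y, z = at$z, o = at$o, b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE
  ))
}

#' Write a protein structure to a PDB file
#'
#' Writes ATOM/HETATM records with sequential serials and the structure's
#' chain identifiers; coordinates are written at PDB precision (1e-3 A).
#'
#' @param structure a [protein_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atom
  xyz <- as.vector(t(cbind(at$x, at$y, at$z)))
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = xyz, type = at$type, resno = at$resno,
    resid = at$resid, eleno = seq_len(nrow(at)), elety = at$elety,
    chain = at$chain, insert = ifelse(at$insert == "", NA, at$insert),
    o = at$o, b = at$b
  ))
  invisible(path)
}

# Ordered residue table for one chain: one row per residue with completeness flags.
chain_residue_table <- function(structure, chain_id) {
  at <- structure$atom
  at <- at[at$chain == chain_id & at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stopf("chain %s not found or empty", chain_id)
  key <- paste(at$resno, at$insert, sep = "\r")
  idx <- !duplicated(key)
  res <- data.frame(
    resno = at$resno[idx], insert = at$insert[idx], aa = at$aa[idx],
    stringsAsFactors = FALSE
  )
  res$key <- res_key(res$resno, res$insert)
  for (a in BACKBONE_ATOMS) {
    res[[paste0("has_", a)]] <- vapply(seq_len(nrow(res)), function(i) {
      any(at$resno == res$resno[i] & at$insert == res$insert[i] & at$elety == a)
    }, logical(1))
  }
  res
}

residue_atoms <- function(structure, chain_id, resno, insert = "",
                          atoms = BACKBONE_ATOMS) {
  at <- structure$atom
  sel <- at$chain == chain_id & at$resno == resno & at$insert == insert &
    at$elety %in% atoms & at$type == "ATOM"
  out <- at[sel, , drop = FALSE]
  out[match(atoms[atoms %in% out$elety], out$elety), , drop = FALSE]
}

#' Extract backbone coordinates over a residue range
#'
#' Returns the N, CA, C (and O where present on every residue of the range)
#' atoms of a contiguous residue range, in residue order. Validation metrics
#' operate on these backbone coordinates only.
#'
#' @param structure a [protein_structure()].
#' @param chain_id chain identifier.
#' @param first,last author residue numbers bounding the range (inclusive).
#' @param require_o if `TRUE`, error when O is missing; by default O is
#'   included only when present on all residues of the range.
#' @return A [coord_set()] with `resi` numbering residues 1..k.
#' @export
extract_backbone <- function(structure, chain_id, first, last, require_o = FALSE) {
  res <- chain_residue_table(structure, chain_id)
  i1 <- match(res_key(first), res$key)
  i2 <- match(res_key(last), res$key)
  if (is.na(i1) || is.na(i2)) stopf("residue range %s..%s not found in chain %s", first, last, chain_id)
  if (i1 > i2) stopf("first residue follows last residue in chain order")
  rng <- res[i1:i2, , drop = FALSE]
  bad <- !(rng$has_N & rng$has_CA & rng$has_C)
  if (any(bad)) {
    stopf("incomplete residue(s) missing backbone atoms: %s",
          paste(rng$key[bad], collapse = ", "))
  }
  use_o <- all(rng$has_O)
  if (require_o && !use_o) {
    stopf("incomplete residue(s) missing O: %s", paste(rng$key[!rng$has_O], collapse = ", "))
  }
  atoms <- if (use_o) BACKBONE_ATOMS else c("N", "CA", "C")
  rows <- do.call(rbind, lapply(seq_len(nrow(rng)), function(i) {
    a <- residue_atoms(structure, chain_id, rng$resno[i], rng$insert[i], atoms)
    data.frame(elety = a$elety, resi = i, x = a$x, y = a$y, z = a$z,
               stringsAsFactors = FALSE)
  }))
  coord_set(rows$elety, rows$resi, as.matrix(rows[, c("x", "y", "z")]))
}

#' Define a modeling gap between two stem residues
#'
#' A gap is the modeling task: the structural context, the two stem residues
#' flanking the queried segment, and the segment's amino-acid sequence.
#' Residues strictly between the stems (the original segment, when present)
#' are removed from the context; when present they are also kept aside as
#' the native reference for benchmarking.
#'
#' @param structure a [protein_structure()].
#' @param chain_id chain holding the gap.
#' @param nstem,cstem author residue numbers of the N- and C-terminal stems.
#' @param sequence one-letter sequence of the queried segment (3-35 residues).
#' @return A `gap_spec` list with stem coordinate sets, context atoms, the
#'   gap fingerprint and, when available, the native interior backbone.
#' @export
define_gap <- function(structure, chain_id, nstem, cstem, sequence) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (L < 3L || L > 35L) {
    stopf("segment length %d outside supported range of 3-35 residues", L)
  }
  res <- chain_residue_table(structure, chain_id)
  i1 <- match(res_key(nstem), res$key)
  i2 <- match(res_key(cstem), res$key)
  if (is.na(i1)) stopf("N-stem residue %s not in chain %s", nstem, chain_id)
  if (is.na(i2)) stopf("C-stem residue %s not in chain %s", cstem, chain_id)
  if (i1 >= i2) stopf("stems are in the wrong order (N-stem must precede C-stem)")
  for (i in c(i1, i2)) {
    if (!(res$has_N[i] && res$has_CA[i] && res$has_C[i])) {
      stopf("stem residue %s lacks complete N/CA/C", res$key[i])
    }
  }
  stem_atoms <- function(i) {
    atoms <- if (res$has_O[i]) BACKBONE_ATOMS else c("N", "CA", "C")
    a <- residue_atoms(structure, chain_id, res$resno[i], res$insert[i], atoms)
    coord_set(a$elety, rep(1L, nrow(a)), as.matrix(a[, c("x", "y", "z")]))
  }
  ns <- stem_atoms(i1)
  cs <- stem_atoms(i2)
  # superposition uses O only when both stems carry it
  common <- intersect(ns$elety, cs$elety)
  ns_fit <- ns[match(common, ns$elety), , drop = FALSE]
  cs_fit <- cs[match(common, cs$elety), , drop = FALSE]
  between <- if (i2 > i1 + 1L) res[(i1 + 1L):(i2 - 1L), , drop = FALSE] else res[0, , drop = FALSE]
  at <- structure$atom
  in_between <- at$chain == chain_id &
    paste(at$resno, at$insert, sep = "\r") %in% paste(between$resno, between$insert, sep = "\r")
  context <- at[!in_between, , drop = FALSE]
  native <- NULL
  if (nrow(between) > 0L && all(between$has_N & between$has_CA & between$has_C)) {
    native <- extract_backbone(structure, chain_id, between$resno[1], between$resno[nrow(between)])
  }
  gap <- list(
    structure = structure, chain = chain_id,
    nstem = res$key[i1], cstem = res$key[i2],
    nstem_resno = res$resno[i1], cstem_resno = res$resno[i2],
    sequence = sequence, L = L,
    nstem_atoms = ns, cstem_atoms = cs,
    stem_fit_cs = coord_set(c(ns_fit$elety, cs_fit$elety),
                            c(rep(1L, nrow(ns_fit)), rep(2L, nrow(cs_fit))),
                            rbind(cs_xyz(ns_fit), cs_xyz(cs_fit))),
    context = context,
    native_interior = native,
    original_residue_count = nrow(between)
  )
  gap$fingerprint <- compute_fingerprint(ns, cs)
  class(gap) <- "gap_spec"
  gap
}

#' @export
print.gap_spec <- function(x, ...) {
  cat(sprintf("gap_spec: chain %s, stems %s..%s, L=%d, seq=%s\n",
              x$chain, x$nstem, x$cstem, x$L, x$sequence))
  invisible(x)
}

# Context atoms used for clash screening: the gap context minus the stem
# residues themselves (fragment terminals overlay the stems by construction).
clash_context_coords <- function(gap) {
  ctx <- gap$context
  keep <- !(ctx$chain == gap$chain &
              res_key(ctx$resno, ctx$insert) %in% c(gap$nstem, gap$cstem))
  ctx <- ctx[keep, , drop = FALSE]
  if (nrow(ctx) == 0L) return(NULL)
  coord_set(ctx$elety, seq_len(nrow(ctx)), as.matrix(ctx[, c("x", "y", "z")]))
}

# All context atom coordinates (for density subtraction).
context_coords <- function(gap) {
  ctx <- gap$context
  ctx <- ctx[ctx$type == "ATOM", , drop = FALSE]
  if (nrow(ctx) == 0L) return(NULL)
  coord_set(ctx$elety, seq_len(nrow(ctx)), as.matrix(ctx[, c("x", "y", "z")]))
}
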