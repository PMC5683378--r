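D_BUCKET_WIDTH <- 0.25

#' Extract all overlapping backbone fragments from a structure
#'
#' Slides windows of every length in `[min_len, max_len]` over each chain
#' and emits one fragment record per window. Windows containing a residue
#' with incomplete N/CA/C, or spanning a chain break (consecutive CA-CA
#' distance > 4.5 A or a jump in author numbering), are skipped and counted.
#'
#' Each record carries the window's one-letter sequence, source identifiers,
#' backbone coordinates (N/CA/C, plus O when present on every residue of the
#' window) and the geometric fingerprint of its terminal residues.
#'
#' @param structure a [protein_structure()].
#' @param min_len,max_len fragment length range (residues, default 3-35).
#' @param source_id identifier recorded as the fragment source (PDB id).
#' @return list of fragment records; attribute `n_skipped` counts windows
#'   dropped for incompleteness or chain breaks.
#' @export
extract_fragments <- function(structure, min_len = 3L, max_len = 35L,
                              source_id = "struct") {
  stopifnot(min_len >= 3L, max_len >= min_len)
  records <- list()
  n_skipped <- 0L
  for (ch in unique(structure$atom$chain[structure$atom$type == "ATOM"])) {
    n_before <- length(records)
    res <- chain_residue_table(structure, ch)
    complete <- res$has_N & res$has_CA & res$has_C
    n <- nrow(res)
    # total candidate windows (for skip accounting)
    total_windows <- sum(pmax(0L, n - seq(min_len, max_len) + 1L))
    # linkage between consecutive rows: peptide-plausible and numbering-contiguous
    linked <- rep(FALSE, max(0L, n - 1L))
    ca <- lapply(seq_len(n), function(i) {
      a <- residue_atoms(structure, ch, res$resno[i], res$insert[i], "CA")
      if (nrow(a)) c(a$x, a$y, a$z) else NULL
    })
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        if (!complete[i] || !complete[i + 1L]) next
        dr <- res$resno[i + 1L] - res$resno[i]
        contig <- (dr == 1L) || (dr == 0L && res$insert[i + 1L] != res$insert[i])
        if (contig && vnorm(ca[[i + 1L]] - ca[[i]]) <= 4.5) linked[i] <- TRUE
      }
    }
    # maximal runs of complete, linked residues
    runs <- list()
    i <- 1L
    while (i <= n) {
      if (!complete[i]) { i <- i + 1L; next }
      j <- i
      while (j < n && linked[j]) j <- j + 1L
      runs[[length(runs) + 1L]] <- i:j
      i <- j + 1L
    }
    # per-residue backbone atom cache for the chain
    bb <- lapply(seq_len(n), function(i) {
      if (!complete[i]) return(NULL)
      residue_atoms(structure, ch, res$resno[i], res$insert[i], BACKBONE_ATOMS)
    })
    for (run in runs) {
      m <- length(run)
      for (L in seq(min_len, max_len)) {
        if (m < L) next
        for (s in seq_len(m - L + 1L)) {
          idx <- run[s:(s + L - 1L)]
          use_o <- all(res$has_O[idx])
          atoms <- if (use_o) BACKBONE_ATOMS else c("N", "CA", "C")
          parts <- lapply(seq_along(idx), function(k) {
            a <- bb[[idx[k]]]
            a <- a[a$elety %in% atoms, , drop = FALSE]
            data.frame(elety = a$elety, resi = k, x = a$x, y = a$y, z = a$z,
                       stringsAsFactors = FALSE)
          })
          tab <- do.call(rbind, parts)
          coords <- coord_set(tab$elety, tab$resi, as.matrix(tab[, c("x", "y", "z")]))
          records[[length(records) + 1L]] <- new_fragment_record(
            source = source_id, chain = ch, first_resno = res$resno[idx[1]],
            sequence = paste(res$aa[idx], collapse = ""), coords = coords
          )
        }
      }
    }
    n_skipped <- n_skipped + max(0L, total_windows - (length(records) - n_before))
  }
  attr(records, "n_skipped") <- n_skipped
  records
}

#' Construct a single fragment record
#'
#' @param source,chain,first_resno source identifiers.
#' @param sequence one-letter sequence of the full fragment.
#' @param coords backbone [coord_set()] with `resi` 1..length.
#' @param id optional explicit fragment id.
#' @return A fragment record (list, class `fragment_record`).
#' @export
new_fragment_record <- function(source, chain, first_resno, sequence, coords,
                                id = NULL) {
  L <- nchar(sequence)
  if (length(unique(coords$resi)) != L) {
    stopf("coords cover %d residues but sequence has %d", length(unique(coords$resi)), L)
  }
  term_n <- coords[coords$resi == 1L, , drop = FALSE]
  term_c <- coords[coords$resi == L, , drop = FALSE]
  rec <- list(
    id = id %||% sprintf("%s_%s_%d_%d", source, chain, first_resno, L),
    source = source, chain = chain, first_resno = first_resno,
    length = L, sequence = toupper(sequence), coords = coords,
    has_o = all(vapply(split(coords$elety, coords$resi), function(e) "O" %in% e, logical(1))),
    fingerprint = compute_fingerprint(term_n, term_c)
  )
  class(rec) <- "fragment_record"
  rec
}

#' Assemble an indexed fragment database
#'
#' Builds the in-memory database object: the record list plus an index over
#' (length, stem-distance bucket) used by [query_by_length_distance()].
#' Bucket width is 0.25 A so a default query window of 0.75 A is always
#' covered by a contiguous bucket range before the exact refinement pass.
#'
#' @param records list of fragment records.
#' @param report optional build report to attach.
#' @return A `fragment_db`.
#' @export
new_fragment_db <- function(records, report = NULL) {
  records <- unname(records)
  idx <- if (length(records)) {
    data.frame(
      pos = seq_along(records),
      id = vapply(records, `[[`, character(1), "id"),
      length = vapply(records, `[[`, integer(1), "length"),
      d = vapply(records, function(r) r$fingerprint$d, numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(pos = integer(0), id = character(0), length = integer(0), d = numeric(0))
  }
  idx$bucket <- as.integer(floor(idx$d / D_BUCKET_WIDTH))
  db <- list(records = records, index = idx, report = report)
  class(db) <- "fragment_db"
  db
}

#' @export
print.fragment_db <- function(x, ...) {
  cat(sprintf("fragment_db: %d records, lengths %s\n", nrow(x$index),
              if (nrow(x$index)) paste(range(x$index$length), collapse = "-") else "-"))
  invisible(x)
}

#' Build a fragment database from structure files
#'
#' Reads each structure, extracts all overlapping fragments and assembles
#' the indexed database. Unreadable files are logged and skipped (counted in
#' the report's `n_warnings`). Duplicate input files yield duplicate
#' records; de-duplication is a search-stage concern.
#'
#' @param structure_paths character vector of PDB file paths.
#' @param db_path optional path; when given the database is persisted there
#'   with [write_fragment_db()].
#' @param min_len,max_len fragment length range.
#' @return A `fragment_db` whose `report` lists records per length, skipped
#'   windows and warnings.
#' @export
build_db <- function(structure_paths, db_path = NULL, min_len = 3L, max_len = 35L) {
  records <- list()
  n_warnings <- 0L
  n_skipped <- 0L
  for (p in structure_paths) {
    st <- tryCatch(read_structure(p), error = function(e) {
      message(sprintf("skipping %s: %s", p, conditionMessage(e)))
      NULL
    })
    if (is.null(st)) { n_warnings <- n_warnings + 1L; next }
    src <- sub("\\.pdb$", "", basename(p))
    recs <- extract_fragments(st, min_len, max_len, source_id = src)
    n_skipped <- n_skipped + attr(recs, "n_skipped")
    records <- c(records, recs)
  }
  lens <- vapply(records, `[[`, integer(1), "length")
  report <- list(
    n_records = length(records),
    records_per_length = if (length(lens)) table(lens) else table(integer(0)),
    n_skipped_windows = n_skipped,
    n_warnings = n_warnings,
    n_inputs = length(structure_paths)
  )
  db <- new_fragment_db(records, report = report)
  if (!is.null(db_path)) write_fragment_db(db, db_path)
  db
}

#' Persist / load a fragment database
#'
#' The store is a single serialized file holding the record list and its
#' index; portable and server-free.
#'
#' @param db a `fragment_db`.
#' @param path file path.
#' @return `read_fragment_db` returns the `fragment_db`.
#' @export
write_fragment_db <- function(db, path) {
  saveRDS(db, path)
  invisible(path)
}

#' @rdname write_fragment_db
#' @export
read_fragment_db <- function(path) {
  db <- readRDS(path)
  if (!inherits(db, "fragment_db")) stopf("%s is not a fragment database", path)
  db
}

#' Query fragments by length and stem distance
#'
#' Returns exactly the records with the requested length whose stem CA-CA
#' distance lies strictly within `delta_d` of `d` (`|d_rec - d| < delta_d`).
#' The bucket index narrows the scan; the final comparison is exact.
#'
#' @param db a `fragment_db`.
#' @param length fragment length (residues).
#' @param d target stem distance (Angstrom).
#' @param delta_d half-width of the strict acceptance window (Angstrom).
#' @return list of fragment records.
#' @export
query_by_length_distance <- function(db, length, d, delta_d = 0.75) {
  stopifnot(delta_d > 0)
  idx <- db$index
  if (nrow(idx) == 0L) return(list())
  b_lo <- as.integer(floor((d - delta_d) / D_BUCKET_WIDTH))
  b_hi <- as.integer(floor((d + delta_d) / D_BUCKET_WIDTH))
  sel <- idx$length == length & idx$bucket >= b_lo & idx$bucket <= b_hi &
    abs(idx$d - d) < delta_d
  db$records[idx$pos[sel]]
}

seq_chars <- function(s) strsplit(toupper(s), "")[[1]]

#' Position-wise sequence identity
#' @param a,b equal-length one-letter sequences.
#' @return fraction of identical positions in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) stopf("sequence length mismatch (%d vs %d)", length(ca), length(cb))
  mean(ca == cb)
}

#' Remove fragments nearly identical in sequence to the query
#'
#' Benchmark-mode filter: drops records whose position-wise identity to the
#' query exceeds `max_identity` strictly (a record at exactly the cutoff is
#' retained). Records two residues longer than the query are compared over
#' their interior (the stem-convention case); records of equal length are
#' compared directly.
#'
#' @param records list of fragment records.
#' @param query_sequence one-letter query sequence.
#' @param max_identity identity cutoff (default 0.90).
#' @return filtered record list.
#' @export
filter_identity <- function(records, query_sequence, max_identity = 0.90) {
  Lq <- nchar(query_sequence)
  keep <- vapply(records, function(r) {
    s <- r$sequence
    if (r$length == Lq + 2L) {
      s <- substr(s, 2L, r$length - 1L)
    } else if (r$length != Lq) {
      stopf("record length %d incomparable to query length %d", r$length, Lq)
    }
    sequence_identity(s, query_sequence) <= max_identity
  }, logical(1))
  records[keep]
}

# Interior sequence of a record under the L+2 stem convention.
interior_sequence <- function(record) {
  substr(record$sequence, 2L, record$length - 1L)
}
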