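#' Parse an MG-RAST-style similarity ("650") file
#'
#' The similarity stage stores local-alignment hits of reads (or cluster
#' representatives) against the M5nr protein database in the 12-column
#' BLAST tabular (m8) layout: query id, subject MD5, percent identity,
#' alignment length, mismatches, gap openings, query start/end
#' (nucleotide space), subject start/end (amino-acid space, 1-based
#' inclusive), e-value, bit score. Lines starting with `#` are comments.
#' Subject intervals reported end-before-start are normalized to
#' `s_start <= s_end` and flagged in the logical `s_reversed` column.
#' Gzip input is transparently decompressed.
#'
#' @param path similarity file (plain or `.gz`).
#' @return data.table with columns `query_id`, `subject_md5`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_openings`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`,
#'   `s_reversed`.
#' @export
read_similarity <- function(path) {
  lines <- read_lines_any(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]; lineno <- lineno[keep]
  what <- sprintf("read_similarity: %s", path)
  if (!length(lines)) return(empty_similarity())
  m <- split_tsv(lines, lineno, 12L, what)
  dt <- data.table(
    query_id     = m[, 1L],
    subject_md5  = m[, 2L],
    pct_identity = as_num_checked(m[, 3L], lineno, what, "pct_identity"),
    aln_length   = as_int_checked(m[, 4L], lineno, what, "aln_length"),
    mismatches   = as_int_checked(m[, 5L], lineno, what, "mismatches"),
    gap_openings = as_int_checked(m[, 6L], lineno, what, "gap_openings"),
    q_start      = as_int_checked(m[, 7L], lineno, what, "q_start"),
    q_end        = as_int_checked(m[, 8L], lineno, what, "q_end"),
    s_start      = as_int_checked(m[, 9L], lineno, what, "s_start"),
    s_end        = as_int_checked(m[, 10L], lineno, what, "s_end"),
    e_value      = as_num_checked(m[, 11L], lineno, what, "e_value"),
    bit_score    = as_num_checked(m[, 12L], lineno, what, "bit_score")
  )
  if (any(dt$s_start < 1L | dt$s_end < 1L)) {
    bad <- which(dt$s_start < 1L | dt$s_end < 1L)
    stop_("%s: line %d: subject coordinates must be positive",
          what, lineno[bad[1L]])
  }
  if (any(dt$e_value < 0)) {
    bad <- which(dt$e_value < 0)
    stop_("%s: line %d: negative e-value", what, lineno[bad[1L]])
  }
  dt[, s_reversed := s_start > s_end]
  rev <- dt$s_reversed
  if (any(rev)) {
    tmp <- dt$s_start[rev]
    dt[rev, s_start := dt$s_end[rev]]
    dt[rev, s_end := tmp]
  }
  dt[]
}

empty_similarity <- function() {
  data.table(query_id = character(), subject_md5 = character(),
             pct_identity = numeric(), aln_length = integer(),
             mismatches = integer(), gap_openings = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             e_value = numeric(), bit_score = numeric(),
             s_reversed = logical())
}

#' Write similarity records in the 12-column m8 layout
#'
#' Records flagged `s_reversed` are written with their original
#' end-before-start subject coordinates, so parse/write/parse is a fixed
#' point on canonical files.
#'
#' @param records data.table as returned by [read_similarity()].
#' @param path destination (`.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_similarity <- function(records, path) {
  r <- as.data.table(records)
  s1 <- r$s_start; s2 <- r$s_end
  if ("s_reversed" %in% names(r) && any(r$s_reversed)) {
    rev <- r$s_reversed
    tmp <- s1[rev]; s1[rev] <- s2[rev]; s2[rev] <- tmp
  }
  lines <- paste(r$query_id, r$subject_md5, num_chr(r$pct_identity),
                 r$aln_length, r$mismatches, r$gap_openings,
                 r$q_start, r$q_end, s1, s2,
                 num_chr(r$e_value), num_chr(r$bit_score), sep = "\t")
  write_lines_any(lines, path)
}

#' Parse an MG-RAST-style sequence-agglomeration ("330") file
#'
#' The agglomeration stage collapses near-identical reads under a
#' representative sequence. Each line holds: cluster id, representative
#' id, comma-separated member ids, and (optionally) comma-separated
#' percent identities. The multiplicity of a representative is 1 (itself)
#' plus its number of members; identifiers absent from the file have
#' multiplicity 1 on lookup (see [multiplicity_of()]).
#'
#' @param path cluster file (plain or `.gz`).
#' @return A `cluster_map` object (data.table with columns `cluster_id`,
#'   `query_id`, `members`, `identities`, `multiplicity`).
#' @export
read_clusters <- function(path) {
  lines <- read_lines_any(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]; lineno <- lineno[keep]
  what <- sprintf("read_clusters: %s", path)
  if (!length(lines)) {
    dt <- data.table(cluster_id = character(), query_id = character(),
                     members = character(), identities = character(),
                     multiplicity = integer())
    return(structure(dt, class = c("cluster_map", class(dt))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 3L | nf > 4L)
  if (length(bad))
    stop_("%s: line %d has %d fields, expected 3 or 4",
          what, lineno[bad[1L]], nf[bad[1L]])
  dt <- data.table(
    cluster_id = vapply(parts, `[`, "", 1L),
    query_id   = vapply(parts, `[`, "", 2L),
    members    = vapply(parts, `[`, "", 3L),
    identities = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else "",
                        "")
  )
  if (anyDuplicated(dt$query_id)) {
    dup <- dt$query_id[duplicated(dt$query_id)][1L]
    stop_("%s: duplicate representative id '%s'", what, dup)
  }
  n_memb <- vapply(strsplit(dt$members, ",", fixed = TRUE),
                   function(x) sum(nzchar(x)), 0L)
  dt[, multiplicity := 1L + n_memb]
  structure(dt, class = c("cluster_map", class(dt)))
}

#' Write a cluster map back to the "330" layout
#'
#' @param clusters a `cluster_map` from [read_clusters()].
#' @param path destination (`.gz` accepted).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  dt <- as.data.table(clusters)
  has_id <- nzchar(dt$identities)
  lines <- ifelse(has_id,
                  paste(dt$cluster_id, dt$query_id, dt$members,
                        dt$identities, sep = "\t"),
                  paste(dt$cluster_id, dt$query_id, dt$members, sep = "\t"))
  write_lines_any(as.character(lines), path)
}

#' Per-query multiplicity lookup
#'
#' @param clusters a `cluster_map`, or `NULL` (no agglomeration).
#' @param ids query identifiers.
#' @return integer vector: recorded multiplicity, defaulting to 1 for
#'   identifiers absent from the map.
#' @export
multiplicity_of <- function(clusters, ids) {
  if (is.null(clusters) || !nrow(clusters))
    return(rep.int(1L, length(ids)))
  idx <- match(ids, clusters$query_id)
  out <- clusters$multiplicity[idx]
  out[is.na(idx)] <- 1L
  out
}

#' Keep the best similarity hit per query
#'
#' Retains, for every query id, the record with the highest bit score;
#' ties are broken by lower e-value, then by lexicographically smallest
#' subject MD5 (with remaining fields as final arbiters, so selection is
#' a total order and invariant under input permutation). Best-hit
#' filtering before localization avoids counting one read toward several
#' proteins.
#'
#' @param records data.table from [read_similarity()].
#' @return data.table with one row per distinct `query_id`.
#' @export
best_hit_per_query <- function(records) {
  r <- as.data.table(records)
  if (!nrow(r)) return(r)
  setorder(r, query_id, -bit_score, e_value, subject_md5,
           s_start, s_end, pct_identity)
  r[, .SD[1L], by = query_id]
}

#' Download an MG-RAST pipeline stage file
#'
#' Retrieves the similarity ("650") or sequence-agglomeration ("330")
#' stage file for a metagenome accession through the MG-RAST download
#' API. The call is idempotent: if `dest` already exists and is
#' non-empty, no network request is made. Never required by any other
#' operation — all analyses run on local files.
#'
#' @param accession metagenome accession (e.g. `"mgm4714675.3"`).
#' @param stage `"650"` or `"330"`.
#' @param dest local destination path.
#' @param base_url API root.
#' @return `dest`, invisibly.
#' @export
fetch_mgrast <- function(accession, stage = c("650", "330"), dest,
                         base_url = "https://api.mg-rast.org") {
  stage <- match.arg(stage)
  if (!is.character(accession) || length(accession) != 1L ||
      !grepl("^mg[mp]", accession))
    stop_("accession must be a single MG-RAST identifier (mgm.../mgp...)")
  if (file.exists(dest) && file.size(dest) > 0)
    return(invisible(dest))
  url <- sprintf("%s/download/%s?file=%s.1", base_url, accession, stage)
  status <- utils::download.file(url, dest, mode = "wb", quiet = TRUE)
  if (status != 0L) stop_("download failed for %s (stage %s)",
                          accession, stage)
  invisible(dest)
}
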