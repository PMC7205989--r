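#' @import data.table
#' @importFrom stats cor.test lm coef hclust as.dist setNames
#' @importFrom utils download.file
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "md5", "domain", "env_start", "env_end", "length_aa",
  "query_id", "subject_md5", "s_start", "s_end", "s_reversed", "bit_score",
  "e_value", "ov", "hid", "a1", "a2", "cov_prev", "classification",
  "assigned_domain", "overlap_aa", "outside_aa", "ambiguous", "multiplicity",
  "n_members", "i.multiplicity", "placement", "true_domain", "cluster_id",
  "members", "identities", "pct_identity", "aln_length", "mismatches",
  "gap_openings", "q_start", "q_end", "n_over"
))

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# Read all lines from a plain or gzip-compressed text file.
# gzfile() reads uncompressed files transparently, so one path serves both.
read_lines_any <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_("file not found: %s", paste(path, collapse = ", "))
  con <- gzfile(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

write_lines_any <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# split tab-delimited lines into a character matrix, enforcing a fixed
# column count; `lineno` carries original file line numbers for messages
split_tsv <- function(lines, lineno, ncol, what) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != ncol)
  if (length(bad))
    stop_("%s: line %d has %d fields, expected %d",
          what, lineno[bad[1L]], nf[bad[1L]], ncol)
  matrix(unlist(parts, use.names = FALSE), ncol = ncol, byrow = TRUE)
}

# numeric conversion that names the offending line on failure
as_num_checked <- function(x, lineno, what, field) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop_("%s: line %d: non-numeric value '%s' in field '%s'",
          what, lineno[bad[1L]], x[bad[1L]], field)
  out
}

as_int_checked <- function(x, lineno, what, field) {
  out <- as_num_checked(x, lineno, what, field)
  if (any(out != floor(out), na.rm = TRUE)) {
    bad <- which(out != floor(out))
    stop_("%s: line %d: non-integer value '%s' in field '%s'",
          what, lineno[bad[1L]], x[bad[1L]], field)
  }
  as.integer(out)
}

# half-away-from-zero rounding (values here are non-negative)
round_half_up <- function(x) floor(x + 0.5)

# render doubles the way R prints them (so 92.3 -> "92.3", 1e-12 -> "1e-12")
num_chr <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, scientific = NA, digits = 15),
         character(1L))
}
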