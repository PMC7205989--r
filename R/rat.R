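#' Construct a reference annotation table (RAT)
#'
#' A RAT maps reference proteins, identified by their MD5 checksum, to the
#' Pfam-style domain envelopes they carry, and holds the canonical
#' (Pfam model) length of every domain family. Envelope coordinates are
#' 1-based inclusive amino-acid positions, following HMMER envelope
#' reporting. A single protein may carry several envelopes (multidomain
#' architectures) and envelopes of distinct families may overlap
#' (subdomains).
#'
#' @param envelopes data.frame with columns `md5`, `domain`, `env_start`,
#'   `env_end` (one row per domain occurrence). Extra columns (e.g. a
#'   protein length) are preserved but unused.
#' @param lengths data.frame with columns `domain`, `length_aa`: the
#'   canonical domain length in amino acids. Every domain referenced by an
#'   envelope must have an entry.
#' @return An object of class `rat` with elements `envelopes` and
#'   `lengths` (both data.tables).
#' @examples
#' rat <- rat_table(
#'   envelopes = data.frame(md5 = "abc123", domain = "GH13",
#'                          env_start = 98, env_end = 512),
#'   lengths   = data.frame(domain = "GH13", length_aa = 436)
#' )
#' domain_length(rat, "GH13")
#' @export
rat_table <- function(envelopes, lengths) {
  env <- as.data.table(envelopes)
  len <- as.data.table(lengths)
  req <- c("md5", "domain", "env_start", "env_end")
  if (!all(req %in% names(env)))
    stop_("envelope table must have columns: %s", paste(req, collapse = ", "))
  if (!all(c("domain", "length_aa") %in% names(len)))
    stop_("length table must have columns: domain, length_aa")
  env[, env_start := as.integer(env_start)]
  env[, env_end := as.integer(env_end)]
  len[, length_aa := as.integer(length_aa)]
  if (nrow(env)) {
    if (any(!nzchar(env$domain)))
      stop_("empty domain identifier in envelope table")
    if (any(env$env_start < 1L))
      stop_("envelope coordinates must be >= 1 (1-based inclusive)")
    if (any(env$env_start > env$env_end))
      stop_("envelope with env_start > env_end")
  }
  if (nrow(len) && any(len$length_aa < 1L))
    stop_("canonical domain lengths must be >= 1")
  if (anyDuplicated(len$domain))
    stop_("duplicate domain in length table: %s",
          len$domain[duplicated(len$domain)][1L])
  missing <- setdiff(unique(env$domain), len$domain)
  if (length(missing))
    stop_("envelope domain(s) missing from length table: %s",
          paste(missing, collapse = ", "))
  ndup <- anyDuplicated(env, by = req)
  if (ndup) {
    warning(sprintf("dropping %d duplicate envelope row(s)",
                    sum(duplicated(env, by = req))), call. = FALSE)
    env <- unique(env, by = req)
  }
  structure(list(envelopes = env[], lengths = len[]), class = "rat")
}

#' @export
print.rat <- function(x, ...) {
  cat(sprintf("<rat> %d envelope(s) on %d protein(s); %d domain famil%s\n",
              nrow(x$envelopes), uniqueN(x$envelopes$md5),
              nrow(x$lengths), if (nrow(x$lengths) == 1L) "y" else "ies"))
  invisible(x)
}

#' Read a reference annotation table from disk
#'
#' Two dialects are accepted: a 4-column envelope file
#' (`md5  domain  env_start  env_end`) with a companion 2-column length
#' table (`domain  length`), or a single 5-column file with a trailing
#' `length` column, which is split into envelopes and lengths on load.
#' All files are tab-delimited with a header line; gzip input is
#' transparently decompressed.
#'
#' @param path envelope file (4- or 5-column dialect).
#' @param lengths_path companion length table; required for the 4-column
#'   dialect, ignored for the 5-column dialect.
#' @return A [rat_table()] object.
#' @export
read_rat <- function(path, lengths_path = NULL) {
  lines <- read_lines_any(path)
  if (!length(lines)) stop_("read_rat: %s is empty (header expected)", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ncol <- length(header)
  if (ncol < 4L)
    stop_("read_rat: %s: expected >= 4 tab-delimited columns, found %d",
          path, ncol)
  need <- c("md5", "domain", "env_start", "env_end")
  if (!all(need %in% header))
    stop_("read_rat: %s: missing required column(s): %s", path,
          paste(setdiff(need, header), collapse = ", "))
  body <- lines[-1L]
  lineno <- seq_along(body) + 1L
  keep <- nzchar(body)
  body <- body[keep]; lineno <- lineno[keep]
  if (length(body)) {
    m <- split_tsv(body, lineno, ncol, sprintf("read_rat: %s", path))
    colnames(m) <- header
    env <- data.table(
      md5 = m[, "md5"],
      domain = m[, "domain"],
      env_start = as_int_checked(m[, "env_start"], lineno,
                                 sprintf("read_rat: %s", path), "env_start"),
      env_end = as_int_checked(m[, "env_end"], lineno,
                               sprintf("read_rat: %s", path), "env_end")
    )
    bad <- which(env$env_start > env$env_end)
    if (length(bad))
      stop_("read_rat: %s: line %d: env_start (%d) > env_end (%d)",
            path, lineno[bad[1L]], env$env_start[bad[1L]],
            env$env_end[bad[1L]])
    if (any(env$env_start < 1L)) {
      bad <- which(env$env_start < 1L)
      stop_("read_rat: %s: line %d: env_start must be >= 1",
            path, lineno[bad[1L]])
    }
  } else {
    env <- data.table(md5 = character(), domain = character(),
                      env_start = integer(), env_end = integer())
    m <- NULL
  }
  if ("length" %in% header) {
    # 5-column single-file variant: per-domain length repeated on each row
    if (length(body)) {
      lens <- unique(data.table(
        domain = m[, "domain"],
        length_aa = as_int_checked(m[, "length"], lineno,
                                   sprintf("read_rat: %s", path), "length")
      ))
      if (anyDuplicated(lens$domain))
        stop_("read_rat: %s: domain '%s' listed with conflicting lengths",
              path, lens$domain[duplicated(lens$domain)][1L])
    } else {
      lens <- data.table(domain = character(), length_aa = integer())
    }
  } else {
    if (is.null(lengths_path))
      stop_("read_rat: %s has no 'length' column; supply lengths_path", path)
    lens <- read_length_table(lengths_path)
  }
  rat_table(env, lens)
}

#' Read a canonical domain-length table
#'
#' Tab-delimited, header `domain  length`, one row per domain family with
#' its Pfam model length in amino acids.
#'
#' @param path file path (gzip accepted).
#' @return data.table with columns `domain`, `length_aa`.
#' @export
read_length_table <- function(path) {
  lines <- read_lines_any(path)
  if (!length(lines))
    stop_("read_length_table: %s is empty (header expected)", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!all(c("domain", "length") %in% header))
    stop_("read_length_table: %s: expected columns 'domain' and 'length'",
          path)
  body <- lines[-1L]
  lineno <- seq_along(body) + 1L
  keep <- nzchar(body)
  body <- body[keep]; lineno <- lineno[keep]
  if (!length(body))
    return(data.table(domain = character(), length_aa = integer()))
  m <- split_tsv(body, lineno, length(header),
                 sprintf("read_length_table: %s", path))
  colnames(m) <- header
  data.table(
    domain = m[, "domain"],
    length_aa = as_int_checked(m[, "length"], lineno,
                               sprintf("read_length_table: %s", path),
                               "length")
  )
}

#' Write a reference annotation table
#'
#' With `lengths_path` the two-file dialect is written (4-column envelope
#' file + 2-column length table); without it a single 5-column file with a
#' trailing `length` column is produced. Both round-trip through
#' [read_rat()] field-identically, preserving envelope order.
#'
#' @param rat a [rat_table()] object.
#' @param path destination for the envelope file.
#' @param lengths_path optional destination for the companion length table.
#' @return `path`, invisibly.
#' @export
write_rat <- function(rat, path, lengths_path = NULL) {
  stopifnot(inherits(rat, "rat"))
  env <- rat$envelopes
  if (is.null(lengths_path)) {
    lens <- setNames(rat$lengths$length_aa, rat$lengths$domain)
    lines <- c("md5\tdomain\tenv_start\tenv_end\tlength",
               if (nrow(env)) sprintf("%s\t%s\t%d\t%d\t%d", env$md5,
                                      env$domain, env$env_start, env$env_end,
                                      lens[env$domain]))
  } else {
    lines <- c("md5\tdomain\tenv_start\tenv_end",
               if (nrow(env)) sprintf("%s\t%s\t%d\t%d", env$md5, env$domain,
                                      env$env_start, env$env_end))
    write_lines_any(c("domain\tlength",
                      if (nrow(rat$lengths))
                        sprintf("%s\t%d", rat$lengths$domain,
                                rat$lengths$length_aa)),
                    lengths_path)
  }
  write_lines_any(lines, path)
}

#' Canonical length of a domain family
#'
#' Looks up the Pfam-model length (amino acids) recorded for a domain in
#' the RAT's length table, e.g. 805 for the reference glycoside hydrolase
#' family GH70.
#'
#' @param rat a [rat_table()] object.
#' @param domain_id domain family label.
#' @return integer vector of lengths, same length as `domain_id`.
#' @export
domain_length <- function(rat, domain_id) {
  stopifnot(inherits(rat, "rat"))
  idx <- match(domain_id, rat$lengths$domain)
  if (anyNA(idx))
    stop_("unknown domain(s): %s",
          paste(domain_id[is.na(idx)], collapse = ", "))
  rat$lengths$length_aa[idx]
}

#' All envelopes recorded for a protein
#'
#' @param rat a [rat_table()] object.
#' @param md5 protein identifier(s).
#' @return data.table of envelopes (possibly zero rows).
#' @export
envelopes_for <- function(rat, md5) {
  stopifnot(inherits(rat, "rat"))
  rat$envelopes[md5, on = "md5", nomatch = NULL]
}
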