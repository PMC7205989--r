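#' Count tables
#'
#' A count table is a samples x features numeric matrix (row names =
#' sample ids, column names = domain or taxon ids) tagged with a `kind`:
#' `"raw"` (integer localized-hit counts), `"normalized"` (real-valued,
#' after length normalization) or `"rarefied"` (integer, equal row sums).
#'
#' @param values numeric matrix with dimnames.
#' @param kind one of `"raw"`, `"normalized"`, `"rarefied"`.
#' @return A `count_table` (matrix with a `kind` attribute).
#' @export
count_table <- function(values, kind = c("raw", "normalized", "rarefied")) {
  kind <- match.arg(kind)
  m <- as.matrix(values)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_("count_table needs sample row names and feature column names")
  if (any(m < 0)) stop_("count table values must be >= 0")
  structure(m, kind = kind, class = c("count_table", class(m)))
}

#' @export
as.matrix.count_table <- function(x, ...) {
  m <- unclass(x)
  attr(m, "kind") <- NULL
  m
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table [%s]> %d sample(s) x %d feature(s)\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(5L, nrow(x))),
                   seq_len(min(8L, ncol(x))), drop = FALSE])
  invisible(x)
}

table_kind <- function(x) attr(x, "kind") %||% "raw"

#' Expand localized hits into a one-sample raw count row
#'
#' Each `IN_DOMAIN` result contributes the multiplicity of its query id
#' (the number of reads agglomerated under that representative in the
#' "330" file; 1 when absent) to its assigned domain. `OUT_OF_DOMAIN`
#' and `UNCLASSIFIED` results are excluded.
#'
#' @param localization a `localization` from [localize_all()] (or its
#'   `results` data.table).
#' @param clusters a `cluster_map` from [read_clusters()], or `NULL`.
#' @param sample_id row label for the resulting table.
#' @param features optional character vector fixing the column universe
#'   (zero-filled); defaults to the sorted assigned domains observed.
#' @return A one-row `count_table` of kind `"raw"`.
#' @export
expand_counts <- function(localization, clusters = NULL,
                          sample_id = "sample", features = NULL) {
  res <- if (inherits(localization, "localization")) localization$results
         else as.data.table(localization)
  hits <- res[classification == "IN_DOMAIN",
              .(query_id, domain = assigned_domain)]
  hits[, multiplicity := multiplicity_of(clusters, query_id)]
  counts <- hits[, .(n = sum(multiplicity)), by = domain]
  feats <- features %||% sort(counts$domain)
  v <- setNames(rep.int(0, length(feats)), feats)
  known <- counts$domain %in% feats
  if (any(!known))
    warning(sprintf("dropping %d domain(s) outside the feature universe",
                    sum(!known)), call. = FALSE)
  v[counts$domain[known]] <- counts$n[known]
  count_table(matrix(v, nrow = 1L,
                     dimnames = list(sample_id, feats)), "raw")
}

#' Stack one-row count tables into a multi-sample table
#'
#' @param ... `count_table` rows sharing a kind; feature universes are
#'   unioned and zero-filled.
#' @return A `count_table`.
#' @export
bind_counts <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) &&
      !inherits(tabs[[1L]], "count_table"))
    tabs <- tabs[[1L]]
  kinds <- unique(vapply(tabs, table_kind, ""))
  if (length(kinds) != 1L) stop_("cannot bind tables of different kinds")
  feats <- sort(unique(unlist(lapply(tabs, colnames))))
  rows <- lapply(tabs, function(t) {
    v <- matrix(0, nrow(t), length(feats),
                dimnames = list(rownames(t), feats))
    v[, colnames(t)] <- unclass(t)
    v
  })
  count_table(do.call(rbind, rows), kinds)
}

#' Length-normalize a raw count table
#'
#' Multiplies each domain's localized-hit count by
#' `reference_length / length(domain)`, the canonical correction for the
#' fact that longer domains recruit proportionally more short-read hits.
#' The default reference is the longest domain present in the table (805
#' AA for GH70 in the stock glycoside hydrolase annotation), so the
#' longest domain's factor is exactly 1 and every other count is scaled
#' up.
#'
#' @param table a raw `count_table`.
#' @param lengths a domain-length table ([read_length_table()] layout:
#'   columns `domain`, `length_aa`) or a [rat_table()].
#' @param reference_length reference length in AA; default
#'   `max(length)` over the table's features.
#' @return A `count_table` of kind `"normalized"`.
#' @export
normalize_counts <- function(table, lengths, reference_length = NULL) {
  if (inherits(lengths, "rat")) lengths <- lengths$lengths
  lengths <- as.data.table(lengths)
  feats <- colnames(table)
  idx <- match(feats, lengths$domain)
  if (anyNA(idx))
    stop_("no canonical length for feature(s): %s",
          paste(feats[is.na(idx)], collapse = ", "))
  len <- as.numeric(lengths$length_aa[idx])
  ref <- as.numeric(reference_length %||% max(len))
  if (ref <= 0) stop_("reference_length must be > 0")
  out <- sweep(unclass(table), 2L, ref / len, `*`)
  count_table(out, "normalized")
}

#' Rarefy a count table to a fixed depth
#'
#' Draws `depth` reads per sample without replacement from the
#' feature-labelled count multiset (a multivariate hypergeometric draw),
#' equalizing sampling effort across samples. Normalized (real-valued)
#' tables are first rounded half-away-from-zero to integers, with a
#' message. Samples whose total is below `depth` are dropped with a
#' warning rather than up-sampled. With the same `seed` the draw is
#' reproducible; the caller's RNG state is left untouched.
#'
#' @param table a `count_table` (raw or normalized).
#' @param depth target row sum (positive integer), e.g. 99922 in the
#'   stock mouse-gut profile.
#' @param seed integer seed for the draw.
#' @return A `count_table` of kind `"rarefied"` whose rows each sum to
#'   exactly `depth`.
#' @export
rarefy_counts <- function(table, depth, seed = 1L) {
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0 ||
      depth != floor(depth))
    stop_("depth must be a single positive integer")
  m <- unclass(table)
  if (table_kind(table) == "normalized") {
    message("rounding normalized counts half-away-from-zero before ",
            "rarefaction")
    m <- round_half_up(m)
  }
  if (any(m != floor(m)))
    stop_("rarefaction needs integer counts; normalize or round first")
  storage.mode(m) <- "double"
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) with fewer than %d counts: %s",
                    sum(!keep), depth,
                    paste(rownames(m)[!keep], collapse = ", ")),
            call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  if (!nrow(m)) stop_("no sample reaches the rarefaction depth")
  # vegan::rrarefy heuristically warns when the smallest count exceeds 1
  # ("should be used for observed counts"); rounded normalized counts are
  # a legitimate multiset here, so that advisory is muffled
  out <- withr::with_seed(as.integer(seed), withCallingHandlers(
    vegan::rrarefy(m, sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  count_table(out, "rarefied")
}

#' Diagnose length bias in a count table
#'
#' Correlates per-domain total counts with canonical domain lengths
#' (Pearson and Spearman, with p-values). On raw tables from
#' uniform-coverage data the counts track domain length; after
#' [normalize_counts()] the association should vanish — the before/after
#' pair is the standard check that the normalization removed the length
#' bias.
#'
#' @param table a `count_table` with at least 3 features.
#' @param lengths domain-length table or [rat_table()].
#' @return list with `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n_features`, `degenerate` (TRUE when a zero-variance
#'   side forced the coefficients to 0 with NA p-values).
#' @export
length_bias_diagnostic <- function(table, lengths) {
  if (inherits(lengths, "rat")) lengths <- lengths$lengths
  lengths <- as.data.table(lengths)
  feats <- colnames(table)
  if (length(feats) < 3L)
    stop_("length-bias diagnostic needs >= 3 features")
  idx <- match(feats, lengths$domain)
  if (anyNA(idx))
    stop_("no canonical length for feature(s): %s",
          paste(feats[is.na(idx)], collapse = ", "))
  totals <- colSums(unclass(table))
  len <- as.numeric(lengths$length_aa[idx])
  if (stats::sd(totals) == 0 || stats::sd(len) == 0) {
    return(list(pearson_r = 0, pearson_p = NA_real_,
                spearman_rho = 0, spearman_p = NA_real_,
                n_features = length(feats), degenerate = TRUE))
  }
  pe <- stats::cor.test(totals, len, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(totals, len, method = "spearman", exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n_features = length(feats), degenerate = FALSE)
}

#' Read / write count tables
#'
#' TSV with the sample id in the first column (`sample`) and one column
#' per feature. `kind` is not stored in the file; supply it on read.
#'
#' @param path file path.
#' @param kind kind tag to attach on read.
#' @return [read_count_table()]: a `count_table`.
#' @export
read_count_table <- function(path, kind = "raw") {
  dt <- fread(path, sep = "\t", header = TRUE, data.table = TRUE)
  if (names(dt)[1L] != "sample")
    stop_("count table must have 'sample' as its first column")
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- dt[[1L]]
  count_table(m, kind)
}

#' @param table a `count_table`.
#' @rdname read_count_table
#' @export
write_count_table <- function(table, path) {
  dt <- data.table(sample = rownames(table))
  dt <- cbind(dt, as.data.table(unclass(table)))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
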