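#' Overlap between an alignment and a domain envelope, in amino acids
#'
#' Both intervals are 1-based inclusive amino-acid positions on the same
#' protein. The overlap is the number of shared residues:
#' `max(0, min(a_end, e_end) - max(a_start, e_start) + 1)`. Vectorized.
#'
#' @param a_start,a_end alignment interval on the subject protein.
#' @param e_start,e_end domain envelope interval.
#' @return integer vector of overlap sizes (>= 0).
#' @export
overlap_aa <- function(a_start, a_end, e_start, e_end) {
  a_start <- as.integer(a_start); a_end <- as.integer(a_end)
  e_start <- as.integer(e_start); e_end <- as.integer(e_end)
  if (any(a_start > a_end)) stop_("inverted alignment interval")
  if (any(e_start > e_end)) stop_("inverted envelope interval")
  pmax(0L, pmin(a_end, e_end) - pmax(a_start, e_start) + 1L)
}

#' Overlap cutoff for annotation transfer
#'
#' A hit is localized inside a domain when its envelope overlap exceeds
#' the cutoff (strictly greater by default, so the stock 20-AA rule
#' transfers the annotation at 21 aligned residues or more). The same
#' cutoff, with the same comparison, governs the negative call: a hit is
#' outside the domains of interest when more than `cutoff` aligned
#' residues fall in regions covered by no envelope (linkers, accessory
#' domains, signal peptides). Set `strict = FALSE` for a
#' greater-or-equal comparison.
#'
#' @param cutoff minimum overlap in amino acids (default 20).
#' @param strict logical; `TRUE` compares with `>`, `FALSE` with `>=`.
#' @return An `overlap_cutoff` object.
#' @export
overlap_cutoff <- function(cutoff = 20, strict = TRUE) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0)
    stop_("cutoff must be a single number >= 0")
  structure(list(cutoff = as.numeric(cutoff), strict = isTRUE(strict)),
            class = "overlap_cutoff")
}

as_cutoff <- function(x) {
  if (inherits(x, "overlap_cutoff")) x else overlap_cutoff(x)
}

exceeds <- function(x, co) if (co$strict) x > co$cutoff else x >= co$cutoff

# vectorized core shared by classify_hit() and localize_all():
# hits: data.table(query_id, subject_md5, s_start, s_end); env: envelope
# table. Returns one row per hit, in input order. The hot path is plain
# O(n) vector arithmetic (hits x envelopes expansion by index, per-group
# maxima via an offset cummax on group-ascending vectors) so that
# million-hit similarity files localize in seconds.
localize_core <- function(hits, env, co) {
  n <- nrow(hits)
  a1 <- as.integer(hits$s_start)
  a2 <- as.integer(hits$s_end)
  # envelopes grouped by protein (stable order within a protein is
  # irrelevant: the tie-break below is a total order on (overlap, domain))
  eo <- order(env$md5, method = "radix")
  emd5 <- env$md5[eo]
  es <- as.integer(env$env_start[eo])
  ee <- as.integer(env$env_end[eo])
  edom <- env$domain[eo]
  um <- unique(emd5)  # sorted, since emd5 is sorted
  cnt_all <- tabulate(match(emd5, um), nbins = length(um))
  first_all <- cumsum(c(1L, cnt_all))[seq_along(cnt_all)]
  fi <- match(hits$subject_md5, um)
  cnt <- integer(n)
  cnt[!is.na(fi)] <- cnt_all[fi[!is.na(fi)]]
  # hits x envelopes expansion: row i repeated once per envelope
  hid <- rep.int(seq_len(n), cnt)
  off <- integer(n)
  off[!is.na(fi)] <- first_all[fi[!is.na(fi)]] - 1L
  erow <- sequence(cnt) + rep.int(off, cnt)
  has_env <- cnt > 0L
  hw <- which(has_env)                    # hits with >= 1 envelope
  gidx <- rep.int(seq_along(hw), cnt[hw]) # compact group id, ascending
  A1 <- a1[hid]; A2 <- a2[hid]
  E1 <- es[erow]; E2 <- ee[erow]
  ov <- pmax(0L, pmin(A2, E2) - pmax(A1, E1) + 1L)
  doms <- sort(unique(edom))
  R <- length(doms) + 1L
  drank <- match(edom[erow], doms)
  overlap <- integer(n)
  assigned <- character(n)
  nover <- integer(n)
  covered <- integer(n)
  if (length(gidx)) {
    ends <- cumsum(cnt[hw])
    # best (overlap desc, domain asc) per hit: encode both in one score,
    # take the per-group running max with a group-offset cummax
    score <- as.numeric(ov) * R + (R - drank)
    M <- max(score) + 1
    runmax <- cummax(score + gidx * M) - gidx * M
    gmax <- runmax[ends]
    ib <- which(score == gmax[gidx])
    firsts <- ib[!duplicated(gidx[ib])]
    overlap[hw] <- ov[firsts]
    assigned[hw] <- edom[erow[firsts]]
    # distinct domains exceeding the cutoff, per hit
    exc <- which(exceeds(ov, co))
    if (length(exc)) {
      key <- unique(gidx[exc] * R + drank[exc])
      nover[hw] <- tabulate(key %/% R, nbins = length(hw))
    }
    # union of clipped envelope intervals per hit (set-based, so stacked
    # subdomain envelopes are not double-counted)
    pos <- which(ov > 0L)
    if (length(pos)) {
      g <- gidx[pos]
      s <- pmax(A1[pos], E1[pos])
      e <- pmin(A2[pos], E2[pos])
      o2 <- order(g, s, method = "radix")
      g <- g[o2]; s <- s[o2]; e <- e[o2]
      M2 <- max(e) + 1
      ce <- cummax(e + g * M2) - g * M2
      len <- length(g)
      prev <- c(0, ce[-len])
      prev[g != c(-1L, g[-len])] <- 0
      contrib <- pmax(0, e - pmax(s, prev + 1) + 1)
      cs <- cumsum(contrib)
      gend <- which(g != c(g[-1L], -1L))
      covered[hw[g[gend]]] <- as.integer(diff(c(0, cs[gend])))
    }
  }
  outside <- (a2 - a1 + 1L) - covered
  inside <- exceeds(overlap, co)
  classification <- rep("UNCLASSIFIED", n)
  classification[inside] <- "IN_DOMAIN"
  classification[!inside & exceeds(outside, co)] <- "OUT_OF_DOMAIN"
  assigned[!inside] <- ""
  data.table(query_id = hits$query_id, subject_md5 = hits$subject_md5,
             classification = classification, assigned_domain = assigned,
             overlap_aa = overlap, outside_aa = outside,
             ambiguous = nover >= 2L)
}

#' Classify a single similarity hit against the envelopes of its protein
#'
#' Computes the envelope overlap for every domain occurrence on the
#' subject protein. If the largest overlap exceeds the cutoff the hit is
#' `IN_DOMAIN` and that domain's annotation is transferred (ties go to
#' the lexicographically smallest domain id; `ambiguous` is set when two
#' or more distinct domains exceed the cutoff). Otherwise, if more than
#' `cutoff` aligned residues fall outside every envelope, the hit is
#' `OUT_OF_DOMAIN`; hits clearing neither bar are `UNCLASSIFIED`.
#'
#' @param record a single similarity record (one-row data.frame or list
#'   with `query_id`, `subject_md5`, `s_start`, `s_end`).
#' @param envelopes envelopes of `record$subject_md5` (data.table with
#'   `md5`, `domain`, `env_start`, `env_end`).
#' @param cutoff numeric or [overlap_cutoff()] (default 20, strict).
#' @return one-row data.table: `query_id`, `subject_md5`,
#'   `classification`, `assigned_domain`, `overlap_aa`, `outside_aa`,
#'   `ambiguous`.
#' @export
classify_hit <- function(record, envelopes, cutoff = 20) {
  co <- as_cutoff(cutoff)
  rec <- as.data.table(as.list(record)[c("query_id", "subject_md5",
                                         "s_start", "s_end")])
  env <- as.data.table(envelopes)
  if (nrow(env) && any(env$md5 != rec$subject_md5))
    stop_("envelope md5 does not match record subject_md5")
  if (rec$s_start > rec$s_end) stop_("inverted subject interval")
  localize_core(rec, env, co)
}

#' Localize every similarity hit against a reference annotation table
#'
#' Runs the domain-transfer rule over a full set of similarity records.
#' Records whose subject MD5 is absent from the RAT are skipped and
#' tallied separately; each RAT-matching record receives exactly one
#' classification.
#'
#' @param records similarity records ([read_similarity()] layout).
#' @param rat a [rat_table()].
#' @param cutoff numeric or [overlap_cutoff()] (default 20, strict).
#' @return A `localization` object: list with `results` (one row per
#'   RAT-matching record) and `summary` (`n_input`, `n_skipped`,
#'   `n_matching`, `n_in_domain`, `n_out`, `n_unclassified`,
#'   `fraction_in_domain`).
#' @export
localize_all <- function(records, rat, cutoff = 20) {
  stopifnot(inherits(rat, "rat"))
  co <- as_cutoff(cutoff)
  r <- as.data.table(records)
  known <- r$subject_md5 %chin% unique(rat$envelopes$md5)
  matching <- r[known]
  results <- if (nrow(matching)) {
    localize_core(matching, rat$envelopes, co)
  } else {
    data.table(query_id = character(), subject_md5 = character(),
               classification = character(), assigned_domain = character(),
               overlap_aa = integer(), outside_aa = integer(),
               ambiguous = logical())
  }
  n_matching <- nrow(results)
  n_in <- sum(results$classification == "IN_DOMAIN")
  n_out <- sum(results$classification == "OUT_OF_DOMAIN")
  n_unc <- sum(results$classification == "UNCLASSIFIED")
  if (n_matching == 0L) {
    warning("no records matched the RAT; fraction_in_domain is undefined",
            call. = FALSE)
    frac <- NaN
  } else {
    frac <- n_in / n_matching
  }
  structure(list(
    results = results,
    summary = list(n_input = nrow(r), n_skipped = sum(!known),
                   n_matching = n_matching, n_in_domain = n_in,
                   n_out = n_out, n_unclassified = n_unc,
                   fraction_in_domain = frac)
  ), class = "localization")
}

#' @export
print.localization <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<localization> %d record(s): %d matched the RAT ",
                     "(%d skipped)\n  IN_DOMAIN %d | OUT_OF_DOMAIN %d | ",
                     "UNCLASSIFIED %d | fraction in-domain %.4f\n"),
              s$n_input, s$n_matching, s$n_skipped, s$n_in_domain,
              s$n_out, s$n_unclassified, s$fraction_in_domain))
  invisible(x)
}
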