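#' Configuration for the synthetic benchmark generator
#'
#' Defines the statistical regime of a fully synthetic benchmark:
#' a reference annotation table over `n_domains` families with canonical
#' lengths spanning `length_range` (default 50-805 AA, the realistic
#' span of glycoside hydrolase domains up to GH70), proteins mixing
#' mono- and multidomain architectures, and short reads whose translated
#' footprint on the subject protein is `read_span_aa` residues (default
#' 33 AA, i.e. a 100-nt read). Reads are placed constructively: exactly
#' `round(target_in_fraction * n_reads)` fall fully inside an envelope
#' and the rest fully in linkers/flanks, both with at least
#' `cutoff + margin` residues of classification slack, so ground-truth
#' labels are exact rather than sampled.
#'
#' @param n_domains number of domain families.
#' @param length_range canonical length range (min, max) in AA.
#' @param n_proteins number of reference proteins.
#' @param domains_per_protein named numeric vector of probabilities over
#'   architecture sizes (names `"1"`, `"2"`, `"3"`).
#' @param linker_length AA of linker between envelopes and of each flank.
#' @param n_reads number of reads to emit.
#' @param read_span_aa subject-space footprint of one read, in AA.
#' @param target_in_fraction proportion of reads placed inside envelopes.
#' @param cluster_rate fraction of reads given a cluster entry in the
#'   "330" file.
#' @param cluster_lambda Poisson rate for extra cluster members (each
#'   clustered representative gets `1 + rpois(lambda)` members).
#' @param cutoff overlap cutoff the fixture is built to separate.
#' @param margin extra AA of slack beyond the cutoff.
#' @param seed integer seed; all draws are reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_domains = 30L,
                         length_range = c(50L, 805L),
                         n_proteins = 200L,
                         domains_per_protein = c("1" = 0.5, "2" = 0.3,
                                                 "3" = 0.2),
                         linker_length = 50L,
                         n_reads = 10000L,
                         read_span_aa = 33L,
                         target_in_fraction = 0.4,
                         cluster_rate = 0.2,
                         cluster_lambda = 1.5,
                         cutoff = 20L,
                         margin = 5L,
                         seed = 1L) {
  cfg <- list(n_domains = as.integer(n_domains),
              length_range = as.integer(length_range),
              n_proteins = as.integer(n_proteins),
              domains_per_protein = domains_per_protein /
                sum(domains_per_protein),
              linker_length = as.integer(linker_length),
              n_reads = as.integer(n_reads),
              read_span_aa = as.integer(read_span_aa),
              target_in_fraction = target_in_fraction,
              cluster_rate = cluster_rate,
              cluster_lambda = cluster_lambda,
              cutoff = as.integer(cutoff),
              margin = as.integer(margin),
              seed = as.integer(seed))
  if (cfg$target_in_fraction < 0 || cfg$target_in_fraction > 1)
    stop_("target_in_fraction must be in [0, 1]")
  if (any(cfg$length_range < 1L) ||
      cfg$length_range[1L] > cfg$length_range[2L])
    stop_("invalid length_range")
  if (cfg$read_span_aa < 1L || cfg$n_domains < 1L || cfg$n_proteins < 1L)
    stop_("counts must be positive")
  structure(cfg, class = "synth_config")
}

# deterministic pseudo-MD5 identifiers (32 hex digits)
synth_md5 <- function(n) {
  hex <- c(0:9, letters[1:6])
  vapply(seq_len(n), function(i)
    paste(sample(hex, 32L, replace = TRUE), collapse = ""), "")
}

#' Generate a synthetic reference annotation table
#'
#' Draws `n_domains` families with canonical lengths uniform on
#' `length_range`, then builds `n_proteins` proteins whose architectures
#' (1-3 domains) follow `domains_per_protein`. Every family is dealt to
#' at least one protein before the remaining slots are filled at random,
#' so no family is silently absent. Envelopes span the full canonical
#' length and are separated (and flanked) by `linker_length` residues;
#' envelopes of distinct proteins never overlap, so constructive ground
#' truth stays unambiguous. Deterministic under `seed`.
#'
#' @param config a [synth_config()].
#' @return A [rat_table()].
#' @export
generate_rat <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    dom_ids <- sprintf("DOM%03d", seq_len(config$n_domains))
    # sample.int keeps a degenerate (lo == hi) range degenerate
    lens <- config$length_range[1L] - 1L +
      sample.int(config$length_range[2L] - config$length_range[1L] + 1L,
                 config$n_domains, replace = TRUE)
    md5s <- synth_md5(config$n_proteins)
    k <- sample(as.integer(names(config$domains_per_protein)),
                config$n_proteins, replace = TRUE,
                prob = config$domains_per_protein)
    # deal each family once (proteins permit), then fill randomly
    slots <- sum(k)
    if (slots < config$n_domains)
      stop_("infeasible geometry: fewer architecture slots (%d) than domains (%d); raise n_proteins",
            slots, config$n_domains)
    env <- vector("list", config$n_proteins)
    pending <- sample(dom_ids)  # families still owed a first occurrence
    for (p in seq_len(config$n_proteins)) {
      npd <- k[p]
      take <- character(0)
      if (length(pending)) {
        take <- pending[seq_len(min(npd, length(pending)))]
        pending <- setdiff(pending, take)
      }
      if (length(take) < npd) {
        pool <- setdiff(dom_ids, take)
        take <- c(take, sample(pool, npd - length(take)))
      }
      take <- sample(take)  # shuffle order within the protein
      pos <- config$linker_length
      rows <- lapply(take, function(d) {
        L <- lens[match(d, dom_ids)]
        r <- data.table(md5 = md5s[p], domain = d,
                        env_start = pos + 1L, env_end = pos + L)
        pos <<- pos + L + config$linker_length
        r
      })
      env[[p]] <- rbindlist(rows)
    }
    if (length(pending))
      stop_("infeasible geometry: could not place families: %s",
            paste(pending, collapse = ", "))
    rat_table(rbindlist(env),
              data.table(domain = dom_ids, length_aa = lens))
  })
}

# m8 filler columns (identity, e-value, bit score): plausible values,
# never consulted by the localizer; tests must not depend on them
synth_filler <- function(n, span) {
  data.table(
    pct_identity = round(stats::runif(n, 60, 100), 1L),
    aln_length = rep.int(span, n),
    mismatches = as.integer(stats::rbinom(n, span, 0.1)),
    gap_openings = 0L,
    q_start = 1L,
    q_end = span * 3L,
    e_value = 10^stats::runif(n, -30, -5),
    bit_score = round(stats::runif(n, 40, 200), 1L)
  )
}

# eligible outside regions (flanks + linkers) per protein, wide enough
# for a full read placement
outside_regions <- function(rat, config) {
  span <- config$read_span_aa
  env <- copy(rat$envelopes)
  setorder(env, md5, env_start)
  regs <- env[, {
    starts <- c(1L, env_end + 1L)
    ends <- c(env_start - 1L, env_end[.N] + config$linker_length)
    .(r_start = starts, r_end = ends)
  }, by = md5]
  regs[r_end - r_start + 1L >= span]
}

utils::globalVariables(c("r_start", "r_end"))

#' Generate synthetic reads with constructive ground truth
#'
#' Emits a similarity table ("650" layout), a cluster map ("330"
#' layout) and a ground-truth table. Exactly
#' `round(target_in_fraction * n_reads)` reads are placed fully inside a
#' uniformly chosen envelope (so their in-envelope overlap equals the
#' full read span, comfortably above the cutoff); the rest are placed
#' fully within linker/flank regions (so their outside span equals the
#' read span). A `cluster_rate` fraction of reads receive an
#' agglomeration entry with `1 + rpois(cluster_lambda)` members.
#' Deterministic under the config seed; when `dir` is given the three
#' files (`sample.650.tsv`, `sample.330.tsv`, `truth.tsv`) are written
#' there as well.
#'
#' @param config a [synth_config()].
#' @param rat RAT from [generate_rat()] (same config).
#' @param dir optional output directory for the fixture files.
#' @return list with `similarity` (data.table in [read_similarity()]
#'   layout), `clusters` (a `cluster_map`), `truth` (data.table:
#'   `query_id`, `placement` in {IN, OUT}, `true_domain`,
#'   `multiplicity`), and `files` (paths, when `dir` was given).
#' @export
generate_reads <- function(config, rat, dir = NULL) {
  stopifnot(inherits(config, "synth_config"), inherits(rat, "rat"))
  span <- config$read_span_aa
  slack <- config$cutoff + config$margin
  if (span < slack)
    stop_("read_span_aa (%d) must be >= cutoff + margin (%d) for unambiguous ground truth",
          span, slack)
  env <- rat$envelopes
  if (any(env$env_end - env$env_start + 1L < span))
    stop_("envelope shorter than read_span_aa: cannot place in-domain reads fully inside")
  regs <- outside_regions(rat, config)
  n_in <- as.integer(round(config$target_in_fraction * config$n_reads))
  n_out <- config$n_reads - n_in
  if (n_out > 0L && !nrow(regs))
    stop_("no linker/flank region can hold a read of %d AA", span)
  withr::with_seed(config$seed + 1L, {
    ids <- sprintf("read%06d", seq_len(config$n_reads))
    # in-domain placements: envelope uniform, start uniform inside
    ei <- sample.int(nrow(env), n_in, replace = TRUE)
    in_start <- env$env_start[ei] +
      as.integer(floor(stats::runif(n_in) *
                         (env$env_end[ei] - env$env_start[ei] - span + 2L)))
    # outside placements: region uniform, start uniform inside
    ri <- sample.int(nrow(regs), n_out, replace = TRUE)
    out_start <- regs$r_start[ri] +
      as.integer(floor(stats::runif(n_out) *
                         (regs$r_end[ri] - regs$r_start[ri] - span + 2L)))
    placement <- sample(rep(c("IN", "OUT"), c(n_in, n_out)))
    s_start <- integer(config$n_reads)
    md5 <- character(config$n_reads)
    true_domain <- rep("", config$n_reads)
    is_in <- placement == "IN"
    s_start[is_in] <- in_start
    md5[is_in] <- env$md5[ei]
    true_domain[is_in] <- env$domain[ei]
    s_start[!is_in] <- out_start
    md5[!is_in] <- regs$md5[ri]
    sim <- data.table(query_id = ids, subject_md5 = md5,
                      synth_filler(config$n_reads, span),
                      s_start = s_start, s_end = s_start + span - 1L,
                      s_reversed = FALSE)
    setcolorder(sim, names(empty_similarity()))
    # cluster file: a fraction of reads become representatives
    n_cl <- as.integer(round(config$cluster_rate * config$n_reads))
    reps <- sort(sample(ids, n_cl))
    n_memb <- 1L + stats::rpois(n_cl, config$cluster_lambda)
    members <- vapply(seq_len(n_cl), function(i)
      paste(sprintf("%s_m%02d", reps[i], seq_len(n_memb[i])),
            collapse = ","), "")
    idents <- vapply(n_memb, function(k)
      paste(sprintf("%.1f", stats::runif(k, 90, 100)), collapse = ","), "")
    cl <- data.table(cluster_id = sprintf("aa%05d", seq_len(n_cl)),
                     query_id = reps, members = members,
                     identities = idents,
                     multiplicity = 1L + n_memb)
    clusters <- structure(cl, class = c("cluster_map", class(cl)))
    truth <- data.table(query_id = ids, placement = placement,
                        true_domain = true_domain,
                        multiplicity = multiplicity_of(clusters, ids))
  })
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      rat = file.path(dir, "rat.tsv"),
      lengths = file.path(dir, "lengths.tsv"),
      similarity = file.path(dir, "sample.650.tsv"),
      clusters = file.path(dir, "sample.330.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_rat(rat, files$rat, files$lengths)
    write_similarity(sim, files$similarity)
    write_clusters(clusters, files$clusters)
    fwrite(truth, files$truth, sep = "\t")
  }
  list(similarity = sim, clusters = clusters, truth = truth, files = files)
}

#' Generate boundary-overlap reads for cutoff semantics checks
#'
#' Emits reads straddling an envelope start so that exactly `k` aligned
#' residues fall inside the envelope, for each `k` in `overlaps`
#' (default: one batch at 20 AA and one at 21 AA, bracketing the stock
#' cutoff). At the default strict-greater rule the 20-AA reads must
#' never be localized and the 21-AA reads always are.
#'
#' @param config a [synth_config()].
#' @param rat RAT from [generate_rat()].
#' @param overlaps integer vector of exact in-envelope overlaps.
#' @param n_per_overlap reads per overlap value.
#' @return list with `similarity` and `truth` (`query_id`,
#'   `true_overlap`, `true_domain`).
#' @export
generate_boundary_reads <- function(config, rat, overlaps = c(20L, 21L),
                                    n_per_overlap = 50L) {
  stopifnot(inherits(config, "synth_config"), inherits(rat, "rat"))
  span <- config$read_span_aa
  if (any(overlaps < 1L) || any(overlaps > span))
    stop_("overlaps must be within [1, read_span_aa]")
  env <- rat$envelopes
  # need linker_length flank before the envelope to hold span - k residues
  ok <- env$env_start > span
  if (!any(ok)) stop_("no envelope deep enough for boundary placement")
  env <- env[ok]
  withr::with_seed(config$seed + 2L, {
    rows <- lapply(overlaps, function(k) {
      ei <- sample.int(nrow(env), n_per_overlap, replace = TRUE)
      s_start <- env$env_start[ei] - (span - k)
      data.table(query_id = sprintf("bnd%02d_%04d", k,
                                    seq_len(n_per_overlap)),
                 subject_md5 = env$md5[ei],
                 s_start = s_start, s_end = s_start + span - 1L,
                 true_overlap = k, true_domain = env$domain[ei])
    })
    all <- rbindlist(rows)
    sim <- data.table(query_id = all$query_id,
                      subject_md5 = all$subject_md5,
                      synth_filler(nrow(all), span),
                      s_start = all$s_start, s_end = all$s_end,
                      s_reversed = FALSE)
    setcolorder(sim, names(empty_similarity()))
  })
  list(similarity = sim,
       truth = all[, .(query_id, true_overlap, true_domain)])
}

utils::globalVariables(c("true_overlap"))

#' Generate reads with uniform residue coverage over all envelopes
#'
#' Places every read fully inside an envelope, choosing the envelope
#' with probability proportional to its length, so the expected
#' per-domain read count is proportional to that domain's envelope
#' residues. This is the regime in which raw counts correlate with
#' domain length and length-normalized counts do not — the fixture for
#' the length-bias diagnostic.
#'
#' @param config a [synth_config()].
#' @param rat RAT from [generate_rat()].
#' @param seed optional seed override (defaults to `config$seed + 3`).
#' @return list with `similarity` and `truth` (`query_id`,
#'   `true_domain`).
#' @export
generate_uniform_coverage <- function(config, rat, seed = NULL) {
  stopifnot(inherits(config, "synth_config"), inherits(rat, "rat"))
  span <- config$read_span_aa
  env <- rat$envelopes
  if (!nrow(env)) stop_("RAT has no envelopes")
  if (any(env$env_end - env$env_start + 1L < span))
    stop_("envelope shorter than read_span_aa")
  n <- config$n_reads
  if (n == 0L)
    return(list(similarity = empty_similarity(),
                truth = data.table(query_id = character(),
                                   true_domain = character())))
  wt <- as.numeric(env$env_end - env$env_start + 1L)
  withr::with_seed(as.integer(seed %||% (config$seed + 3L)), {
    ei <- sample.int(nrow(env), n, replace = TRUE, prob = wt)
    s_start <- env$env_start[ei] +
      as.integer(floor(stats::runif(n) *
                         (env$env_end[ei] - env$env_start[ei] - span + 2L)))
    sim <- data.table(query_id = sprintf("ucov%06d", seq_len(n)),
                      subject_md5 = env$md5[ei],
                      synth_filler(n, span),
                      s_start = s_start, s_end = s_start + span - 1L,
                      s_reversed = FALSE)
    setcolorder(sim, names(empty_similarity()))
  })
  list(similarity = sim,
       truth = data.table(query_id = sim$query_id,
                          true_domain = env$domain[ei]))
}
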