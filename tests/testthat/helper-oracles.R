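# Independent oracles: explicit residue-set arithmetic and literal
# formula transcriptions, kept free of the package's code paths.

oracle_overlap <- function(a1, a2, e1, e2) {
  length(intersect(seq(a1, a2), seq(e1, e2)))
}

oracle_outside <- function(a1, a2, env) {
  cov <- unlist(mapply(seq, env$env_start, env$env_end, SIMPLIFY = FALSE))
  length(setdiff(seq(a1, a2), cov))
}

oracle_bray_curtis <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# a hand-checkable RAT: two proteins, three domain families, one
# multidomain architecture with a subdomain-style overlap on protB
tiny_rat <- function() {
  rat_table(
    envelopes = data.frame(
      md5 = c("protA", "protA", "protB", "protB"),
      domain = c("GH13", "CBM48", "GH3", "GH3C"),
      env_start = c(100L, 400L, 50L, 240L),
      env_end = c(300L, 520L, 260L, 400L)
    ),
    lengths = data.frame(
      domain = c("GH13", "CBM48", "GH3", "GH3C"),
      length_aa = c(201L, 121L, 211L, 161L)
    )
  )
}

# minimal similarity record with filler m8 columns
sim_record <- function(query_id, md5, s_start, s_end, bit = 88.2,
                       evalue = 1e-12) {
  data.frame(query_id = query_id, subject_md5 = md5,
             pct_identity = 92.3, aln_length = abs(s_end - s_start) + 1L,
             mismatches = 3L, gap_openings = 0L, q_start = 1L,
             q_end = 120L, s_start = s_start, s_end = s_end,
             e_value = evalue, bit_score = bit,
             s_reversed = FALSE)
}

sim_records <- function(...) do.call(rbind, list(...))
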