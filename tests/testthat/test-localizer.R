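test_that("overlap_aa equals residue-set intersection cardinality", {
  expect_identical(overlap_aa(280, 350, 100, 300),
                   oracle_overlap(280, 350, 100, 300))  # 21
  expect_identical(overlap_aa(100, 300, 100, 300), 201L)
  expect_identical(overlap_aa(301, 350, 100, 300), 0L)
  expect_error(overlap_aa(350, 280, 100, 300), "inverted")
  expect_error(overlap_aa(280, 350, 300, 100), "inverted")

  set.seed(11)
  for (i in 1:300) {
    a <- sort(sample(1:1000, 2)); e <- sort(sample(1:1000, 2))
    expect_identical(overlap_aa(a[1], a[2], e[1], e[2]),
                     oracle_overlap(a[1], a[2], e[1], e[2]))
  }
})

test_that("classify_hit applies the >cutoff transfer and negative rules", {
  env <- data.frame(md5 = "p1", domain = "GH13",
                    env_start = 100L, env_end = 300L)
  hit <- function(s1, s2) list(query_id = "r1", subject_md5 = "p1",
                               s_start = s1, s_end = s2)
  # 21 in-domain residues: annotation transferred
  r <- classify_hit(hit(280, 350), env, 20)
  expect_equal(r$classification, "IN_DOMAIN")
  expect_equal(r$assigned_domain, "GH13")
  expect_equal(r$overlap_aa, 21L)
  # 20 in-domain residues is not >20; 50 outside -> negative
  r <- classify_hit(hit(281, 350), env, 20)
  expect_equal(r$classification, "OUT_OF_DOMAIN")
  expect_equal(r$assigned_domain, "")
  expect_equal(r$overlap_aa, 20L)
  expect_equal(r$outside_aa, 50L)
  # neither portion exceeds the cutoff
  r <- classify_hit(hit(290, 310), env, 20)
  expect_equal(r$classification, "UNCLASSIFIED")
  expect_equal(c(r$overlap_aa, r$outside_aa), c(11L, 10L))
  # md5 mismatch is an argument error
  expect_error(
    classify_hit(list(query_id = "r1", subject_md5 = "pX",
                      s_start = 1, s_end = 50), env),
    "md5")
})

test_that("in-domain transfer takes precedence over the negative rule", {
  env <- data.frame(md5 = "p1", domain = "GH13",
                    env_start = 100L, env_end = 150L)
  r <- classify_hit(list(query_id = "r1", subject_md5 = "p1",
                         s_start = 80, s_end = 200), env, 20)
  expect_equal(r$classification, "IN_DOMAIN")  # 51 inside AND 70 outside
  expect_equal(r$overlap_aa, 51L)
  expect_equal(r$outside_aa, 70L)
})

test_that("multi-domain hits resolve to the largest overlap with ties and
           ambiguity handled deterministically", {
  env <- data.frame(md5 = "p1", domain = c("GH3", "GH3C"),
                    env_start = c(50L, 240L), env_end = c(260L, 400L))
  # 21 residues in GH3 [240,260] overlap zone, 61 in GH3C
  r <- classify_hit(list(query_id = "r1", subject_md5 = "p1",
                         s_start = 240, s_end = 300), env, 20)
  expect_equal(r$assigned_domain, "GH3C")
  expect_true(r$ambiguous)
  # symmetric overlap -> lexicographically smallest domain id
  env2 <- data.frame(md5 = "p1", domain = c("GHB", "GHA"),
                     env_start = c(100L, 200L), env_end = c(149L, 249L))
  r <- classify_hit(list(query_id = "r1", subject_md5 = "p1",
                         s_start = 125, s_end = 224), env2, 20)
  expect_equal(r$assigned_domain, "GHA")
  expect_true(r$ambiguous)
  # outside_aa is set-based over overlapping envelopes (no double count)
  r <- classify_hit(list(query_id = "r1", subject_md5 = "p1",
                         s_start = 40, s_end = 410),
                    data.frame(md5 = "p1", domain = c("GH3", "GH3C"),
                               env_start = c(50L, 240L),
                               env_end = c(260L, 400L)), 20)
  expect_equal(r$outside_aa, oracle_outside(40, 410,
               data.frame(env_start = c(50, 240), env_end = c(260, 400))))
})

test_that("the cutoff comparison is strict by default and configurable", {
  env <- data.frame(md5 = "p1", domain = "GH13",
                    env_start = 100L, env_end = 300L)
  hit <- list(query_id = "r1", subject_md5 = "p1",
              s_start = 281, s_end = 350)  # exactly 20 inside
  expect_equal(classify_hit(hit, env, overlap_cutoff(20))$classification,
               "OUT_OF_DOMAIN")
  expect_equal(
    classify_hit(hit, env, overlap_cutoff(20, strict = FALSE))$classification,
    "IN_DOMAIN")
  expect_error(overlap_cutoff(-1), ">= 0")
})

test_that("localize_all partitions RAT-matching records and tallies them", {
  rat <- tiny_rat()
  recs <- sim_records(
    sim_record("r1", "protA", 280, 350),   # 21 AA in GH13 -> IN
    sim_record("r2", "protA", 310, 390),   # outside both -> OUT
    sim_record("r3", "protB", 240, 300),   # GH3/GH3C ambiguity -> IN
    sim_record("r4", "unknown", 1, 80),    # not in RAT -> skipped
    sim_record("r5", "protA", 290, 310)    # 11 in / 10 out -> UNCLASSIFIED
  )
  loc <- localize_all(recs, rat, 20)
  s <- loc$summary
  expect_equal(s$n_input, 5L)
  expect_equal(s$n_skipped, 1L)
  expect_equal(s$n_matching, 4L)
  expect_equal(s$n_in_domain + s$n_out + s$n_unclassified, s$n_matching)
  expect_equal(s$fraction_in_domain, 2 / 4)
  expect_equal(nrow(loc$results), 4L)

  # all-unknown input: zero matches, NaN fraction, with a warning
  expect_warning(loc0 <- localize_all(sim_record("r", "zzz", 1, 50), rat),
                 "undefined")
  expect_equal(loc0$summary$n_skipped, 1L)
  expect_true(is.nan(loc0$summary$fraction_in_domain))
  expect_warning(locE <- localize_all(recs[0, ], rat), "undefined")
  expect_equal(locE$summary$n_matching, 0L)
})

test_that("localization is invariant under record and envelope order", {
  rat <- tiny_rat()
  set.seed(21)
  recs <- do.call(rbind, lapply(1:60, function(i) {
    s1 <- sample(1:500, 1)
    sim_record(sprintf("r%02d", i), sample(c("protA", "protB"), 1),
               s1, s1 + sample(10:120, 1))
  }))
  ref <- localize_all(recs, rat, 20)$results
  shuf_env <- rat_table(rat$envelopes[sample(nrow(rat$envelopes))],
                        rat$lengths)
  perm <- sample(nrow(recs))
  out <- localize_all(recs[perm, ], shuf_env, 20)$results
  expect_equal(as.data.frame(out[order(query_id)]),
               as.data.frame(ref[order(query_id)]))
})

test_that("raising the cutoff never creates new in-domain calls", {
  rat <- tiny_rat()
  set.seed(31)
  recs <- do.call(rbind, lapply(1:80, function(i) {
    s1 <- sample(1:500, 1)
    sim_record(sprintf("r%02d", i), sample(c("protA", "protB"), 1),
               s1, s1 + sample(5:150, 1))
  }))
  cuts <- seq(0, 50, by = 5)
  n_in <- vapply(cuts, function(co)
    localize_all(recs, rat, co)$summary$n_in_domain, 0L)
  expect_true(all(diff(n_in) <= 0))
  # per-record: an IN call at a higher cutoff implies IN at every lower one
  lo <- localize_all(recs, rat, 10)$results
  hi <- localize_all(recs, rat, 30)$results
  expect_true(all(lo$classification[hi$classification == "IN_DOMAIN"] ==
                    "IN_DOMAIN"))
})
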