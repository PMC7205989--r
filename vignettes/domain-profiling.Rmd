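---
title: "Domain-level profiling of short-read metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-level profiling of short-read metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainprofiler)
```

## The problem

Most published metagenomes are unassembled short reads, annotated by
local alignment against a pre-annotated protein database. A local match
to a protein, however, says little about *where* on that protein the
read landed. Many protein families — glycoside hydrolases (GHs) are the
motivating example — have complex multidomain architectures: a read
matching a GH13-containing amylase may in fact align to a starch-binding
CBM48 module, a linker, or a signal peptide. Counting every such match as
"GH13" systematically overestimates the functional signal, and the
overestimate grows with domain and protein length.

This package addresses both problems for MG-RAST-style annotated
datasets. It consumes a precomputed **reference annotation table (RAT)**
that maps each reference protein (keyed by its MD5 checksum, the
identifier scheme of the M5nr database) to the amino-acid envelopes of
the domains it carries, plus the canonical (Pfam model) length of each
domain family. Building the RAT itself — scanning the protein database
with domain HMMs — is out of scope here; the package consumes the table.

## The localization rule

For each similarity record (12-column BLAST tabular layout; subject
coordinates in amino-acid space), the overlap between the alignment
interval $[a_1, a_2]$ and each envelope $[e_1, e_2]$ of the subject
protein is the shared residue count

$$\mathrm{ov} = \max\bigl(0,\; \min(a_2, e_2) - \max(a_1, e_1) + 1\bigr),$$

with all coordinates 1-based inclusive (the HMMER envelope convention the
RAT derives from). Classification of a hit is then:

* **IN_DOMAIN** if the largest envelope overlap exceeds the cutoff
  (default 20 AA, strict `>`); the annotation of the argmax domain is
  transferred to the read.
* **OUT_OF_DOMAIN** otherwise, if more than `cutoff` aligned residues
  are covered by *no* envelope of that protein (linker, flank,
  accessory region). The uncovered count is set-based, so stacked
  subdomain envelopes are not double-counted.
* **UNCLASSIFIED** when neither portion clears the cutoff (short or
  boundary-straddling alignments).

Three decisions here were genuinely open and are resolved as follows:

* **Strict comparison.** "More than 20 AA" is implemented as `> 20`,
  i.e. transfer at 21 residues and never at 20. `overlap_cutoff(k,
  strict = FALSE)` switches to `>=` for users who read the rule
  inclusively; the comparison lives in exactly one place.
* **Precedence.** A long alignment can exceed the cutoff both inside
  and outside a domain. IN_DOMAIN wins: the method exists to transfer
  domain annotations, and the negative rule is read as applying to reads
  lacking sufficient in-domain overlap.
* **Multi-domain overlap.** A read overlapping two domains above the
  cutoff is assigned to the single largest-overlap domain (ties to the
  lexicographically smallest domain id, making the output independent of
  record and envelope order), and flagged `ambiguous`. Double-assignment
  would double-count a single read; silent dropping would hide real
  subdomain structure. The flag lets users filter either way.

Hits whose subject MD5 is absent from the RAT are skipped and tallied
separately — the RAT is comprehensive only for the families it was built
for.

By default the pipeline keeps one best hit per query (highest bit score,
then lowest e-value, then smallest subject MD5) before localization, so
one read counts toward at most one protein; `--all-hits` disables this.

## From hits to profiles

**Multiplicity expansion.** MG-RAST collapses near-identical reads under
representative sequences; the agglomeration ("330") file records the
members. A representative's multiplicity is 1 (itself) plus its member
count, and identifiers absent from the file count 1. Each IN_DOMAIN hit
contributes its multiplicity to its assigned domain.

**Length normalization.** The expected number of reads landing in a
domain scales with the domain's length, so raw counts overestimate long
domains. Each domain's count is multiplied by
$L_\mathrm{ref} / L_d$, where $L_d$ is the family's canonical Pfam
length and $L_\mathrm{ref}$ defaults to the longest domain present in
the table (805 AA, the GH70 length, in the stock GH annotation — its
factor is exactly 1). The normalization is linear, so it commutes with
scaling a sample's sequencing depth. `length_bias_diagnostic()` reports
Pearson and Spearman correlations of per-domain totals against length
before and after normalization; zero-variance inputs are reported as
coefficient 0 with `degenerate = TRUE` rather than an error, since
constant rows arise naturally in truncated fixtures.

**Rarefaction.** Rows are subsampled without replacement to a fixed
depth (a multivariate hypergeometric draw, via `vegan::rrarefy`),
equalizing sampling effort before dissimilarity analysis. Normalized
tables are real-valued; they are rounded half-away-from-zero first (the
rounding error is at most 0.5 per cell, negligible at profiling depths)
so the draw remains a true without-replacement draw. Samples below the
target depth are dropped with a warning, never up-sampled. A single
explicit seed drives the draw and the caller's RNG state is restored
afterwards.

**Profile analytics.** Bray–Curtis dissimilarity
($1 - 2\sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)$),
complete-linkage clustering (via `hclust`; merge heights are
non-decreasing by construction), Shannon diversity in natural-log units,
and a structure-vs-function comparison that correlates, within each
sample group, the taxonomic and the domain-profile Bray–Curtis values of
all within-group sample pairs (groups need at least three samples — one
pair supports no correlation — and are otherwise skipped with a
warning; pairs are pooled within a group, not per individual).

## The synthetic generator

Every analysis step is testable offline against
constructive ground truth. `generate_rat()` draws domain families with
canonical lengths uniform on 50–805 AA — the realistic span of GH
domains up to GH70 — and assembles proteins whose architectures mix 1, 2
and 3 domains with probabilities 0.5/0.3/0.2, reflecting that a
substantial fraction of GH proteins (for instance most GH13 amylases)
are multidomain. Envelopes are separated and flanked by 50-AA linkers.
Each family is dealt to at least one protein before remaining slots are
filled at random, so no family is silently absent.

`generate_reads()` places reads *constructively*: exactly
`round(target_in_fraction × n_reads)` reads fall fully inside a
uniformly chosen envelope and the rest fully inside linkers/flanks. The
read footprint is 33 AA (a 100-nt read translated), which exceeds the
default cutoff by 13 residues, so every placement is unambiguous and
label totals are exact rather than sampled — fraction-recovery tests
assert equality, not approximation. `generate_boundary_reads()`
deliberately emits exact 20- and 21-AA overlaps for cutoff-semantics
tests. `generate_uniform_coverage()` picks envelopes with probability
proportional to their length, the regime in which raw counts correlate
with domain length and normalized counts do not. The m8 filler columns
(identity, e-value, bit score) are drawn from plausible ranges and are
never consulted by the localizer; tests must not depend on them.

What the generator does **not** emulate: sequencing error and chimeras,
frameshifts, alignment boundary noise (real local alignments do not stop
cleanly at envelope edges), spurious homology, variable read lengths,
and realistic taxon-correlated domain abundances. Passing tests
therefore demonstrate the correctness of the interval arithmetic,
counting, normalization and subsampling — not the biological accuracy of
any particular RAT or upstream aligner.

## Problem sizes and numerical choices

The shipped test suite exercises the pipeline at the scales it is
designed for while staying quick: localization ground-truth recovery on
10,000 reads at a 0.40 in-domain fraction; the length-bias contrast on
30 mono-domain families × 100,000 uniform-coverage reads, repeated over
50 seeds (the normalized-count correlation test is expected
non-significant at α = 0.01 in at least 48 of 50); rarefaction checked
against the hypergeometric expectation over 200 seeds; and 1,000 random
interval pairs against an explicit residue-set oracle. The localizer's
hot path is plain vectorized arithmetic (hits × envelope expansion by
index, per-group maxima via an offset running-max), so a 10^5-hit file
localizes in well under a second and full-size MG-RAST similarity files
remain tractable.

Other numerical conventions: reversed subject intervals in similarity
files are normalized to `start <= end` with the orientation recorded,
not rejected; duplicate identical RAT rows are deduplicated with a
warning; parse errors name the offending line; all tie-breaks
(best-hit selection, domain assignment, linkage merges) are total
orders, so results are independent of input order.

## Limitations

* The RAT is trusted as given; envelope quality bounds annotation
  quality, and families absent from the RAT are invisible.
* Comprehensive identification only holds for the domains the RAT
  targets; accessory domains surface only when they are themselves
  listed.
* Rarefaction of rounded normalized counts is a pragmatic convention;
  depth choice is the user's (the stock mouse-gut profile used 99,922).
* Bespoke inferential statistics on the resulting profiles (two-way
  ANOVA per family, PERMANOVA, NMDS) are deliberately not
  re-implemented; profiles are exported in tidy form for standard tools.
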