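#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`, the abundance-based
#' dissimilarity in `[0, 1]` used throughout the sample comparisons.
#' Identical profiles give 0, disjoint supports give 1; the value is
#' invariant under joint rescaling of both vectors by the same positive
#' factor (but not under rescaling one of them).
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop_("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop_("abundances must be >= 0")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop_("both vectors are all-zero")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' All pairwise Bray-Curtis dissimilarities of a count table
#'
#' @param table a `count_table` (rarefied, by convention, so sampling
#'   effort is equal across rows) with >= 2 samples.
#' @return a `dist` object over the sample labels.
#' @export
bray_curtis_matrix <- function(table) {
  m <- unclass(table)
  if (nrow(m) < 2L) stop_("need >= 2 samples for a distance matrix")
  if (any(rowSums(m) == 0)) stop_("all-zero sample row")
  vegan::vegdist(m, method = "bray")
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering in which the distance between clusters is
#' the maximum pairwise dissimilarity; merge heights are therefore
#' non-decreasing. Input is typically [bray_curtis_matrix()] output.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @return an `hclust` tree.
#' @export
complete_linkage <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  stats::hclust(d, method = "complete")
}

#' Serialize a dendrogram as a Newick tree
#'
#' @param hc an `hclust` from [complete_linkage()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Shannon alpha-diversity
#'
#' `H = -sum(p_i * log(p_i))` in natural-log units over the relative
#' abundances `p_i = x_i / sum(x)`, with `0 * log(0) = 0`. Bounded by
#' `log(k)` for `k` features, attained at the uniform profile.
#'
#' @param x non-negative abundance vector (or a `count_table`, giving
#'   one value per sample).
#' @return numeric diversity value(s).
#' @export
shannon_diversity <- function(x) {
  if (inherits(x, "count_table")) x <- unclass(x)
  if (is.matrix(x)) {
    if (any(rowSums(x) == 0)) stop_("all-zero sample row")
    return(vegan::diversity(x, index = "shannon"))
  }
  if (sum(x) == 0) stop_("all-zero abundance vector")
  unname(vegan::diversity(x, index = "shannon"))
}

#' Correlate structural and functional dissimilarity within groups
#'
#' For each sample group (e.g. gut location), collects all within-group
#' sample pairs, computes the Bray-Curtis dissimilarity of each pair in
#' the taxonomic table ("structure") and in the domain table
#' ("function"), and reports the Pearson correlation between the two
#' together with the fitted regression line. A positive correlation
#' means compositional shifts track shifts in functional potential.
#' Groups with fewer than 3 samples (i.e. at most one pair) are skipped
#' with a warning.
#'
#' @param taxa,domains `count_table`s over the same samples.
#' @param grouping named character vector: sample id -> group label.
#' @return data.table: `group`, `n_samples`, `n_pairs`, `pearson_r`,
#'   `p_value`, `slope`, `intercept`.
#' @export
structure_function_correlation <- function(taxa, domains, grouping) {
  if (!setequal(rownames(taxa), rownames(domains)))
    stop_("taxa and domain tables cover different samples")
  samples <- rownames(taxa)
  if (!all(samples %in% names(grouping)))
    stop_("grouping is missing sample(s): %s",
          paste(setdiff(samples, names(grouping)), collapse = ", "))
  dom <- unclass(domains)[samples, , drop = FALSE]
  tax <- unclass(taxa)
  out <- lapply(unique(grouping[samples]), function(g) {
    ids <- samples[grouping[samples] == g]
    if (length(ids) < 3L) {
      warning(sprintf("group '%s' has %d sample(s); need >= 3 for a ",
                      g, length(ids)), "correlation - skipped",
              call. = FALSE)
      return(NULL)
    }
    pairs <- utils::combn(ids, 2L)
    bc_t <- apply(pairs, 2L, function(p) bray_curtis(tax[p[1L], ],
                                                     tax[p[2L], ]))
    bc_f <- apply(pairs, 2L, function(p) bray_curtis(dom[p[1L], ],
                                                     dom[p[2L], ]))
    ct <- stats::cor.test(bc_t, bc_f, method = "pearson")
    fit <- stats::coef(stats::lm(bc_f ~ bc_t))
    data.table(group = g, n_samples = length(ids), n_pairs = ncol(pairs),
               pearson_r = unname(ct$estimate), p_value = ct$p.value,
               slope = unname(fit[2L]), intercept = unname(fit[1L]))
  })
  rbindlist(out)
}
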