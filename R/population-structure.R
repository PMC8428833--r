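#' PAV-based accession distances
#'
#' Pairwise distances between accessions computed from the binary PAV
#' matrix. *Simple matching* (default) is the fraction of genes whose
#' presence state differs between two accessions; *Jaccard* is one minus the
#' intersection-over-union of the two present-gene sets.
#'
#' @param matrix A [pav_matrix()] (or coercible).
#' @param metric `"simple_matching"` or `"jaccard"`.
#' @param gene_subset Optional character vector of gene ids to restrict the
#'   computation to (e.g. variable genes only).
#' @return Symmetric numeric matrix with zero diagonal and accession labels.
#' @export
pav_distance <- function(matrix, metric = c("simple_matching", "jaccard"),
                         gene_subset = NULL) {
  metric <- match.arg(metric)
  m <- unclass(as_pav_matrix(matrix))
  if (ncol(m) < 2L) abort("Need at least 2 accessions.")
  if (!is.null(gene_subset)) {
    if (length(gene_subset) == 0L) abort("Empty gene subset.")
    m <- m[rownames(m) %in% gene_subset, , drop = FALSE]
    if (nrow(m) == 0L) abort("Empty gene subset.")
  }
  ones <- colSums(m)
  both <- crossprod(m)              # genes present in both
  if (metric == "simple_matching") {
    # mismatches = present in exactly one of the two accessions
    d <- (outer(ones, ones, "+") - 2 * both) / nrow(m)
  } else {
    un <- outer(ones, ones, "+") - both
    d <- 1 - both / un
    d[un == 0] <- 0                 # two empty accessions: identical
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' PCA of the PAV matrix
#'
#' Principal component analysis of accessions on binary gene presence:
#' columns (genes) are centered but not scaled, the convention of genotype
#' PCA. Component signs follow a deterministic convention (the
#' largest-magnitude loading of each component is positive).
#'
#' @param matrix A [pav_matrix()] (or coercible).
#' @param n_components Number of components to return (truncated to the
#'   matrix rank with a warning if larger).
#' @return A `pav_pca` list: `scores` (tibble `accession_id`, `PC1`, ...),
#'   `explained` (tibble `component`, `variance`, `prop_variance`).
#' @export
pav_pca <- function(matrix, n_components = 2L) {
  m <- unclass(as_pav_matrix(matrix))
  if (ncol(m) < 2L) abort("Need at least 2 accessions.")
  x <- t(m)                          # accessions x genes
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(p$sdev > .Machine$double.eps^0.5 * p$sdev[1])
  if (n_components > rank) {
    warn(sprintf("Requested %d components but rank is %d; truncating.",
                 n_components, rank))
    n_components <- rank
  }
  k <- seq_len(n_components)
  # Deterministic sign: flip each PC so its largest-|loading| gene is positive.
  for (j in k) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  scores <- tibble::as_tibble(p$x[, k, drop = FALSE])
  scores <- dplyr::bind_cols(tibble(accession_id = colnames(m)), scores)
  vars <- p$sdev^2
  structure(list(
    scores = scores,
    explained = tibble(component = paste0("PC", k), variance = vars[k],
                       prop_variance = vars[k] / sum(vars))
  ), class = "pav_pca")
}

#' @export
print.pav_pca <- function(x, ...) {
  cat(sprintf("<pav_pca> %d accessions, %d components (%.1f%% variance)\n",
              nrow(x$scores), nrow(x$explained),
              100 * sum(x$explained$prop_variance)))
  invisible(x)
}

#' @describeIn pav_pca accession scores joined with explained variance.
#' @param x A `pav_pca`.
#' @param ... Unused.
#' @export
tidy.pav_pca <- function(x, ...) x$scores

#' @describeIn pav_pca one-row summary of explained variance.
#' @export
glance.pav_pca <- function(x, ...) {
  tibble(n_components = nrow(x$explained),
         prop_variance_total = sum(x$explained$prop_variance))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining ([ape::nj()]) with two post-processing
#' guarantees: taxa are presented to the algorithm in label order (so ties
#' break deterministically), and negative branch lengths are clamped to zero
#' with the negative excess transferred to the sister branch, preserving
#' tip-to-tip path lengths through the parent node.
#'
#' @param d Symmetric distance matrix with labels (at least 3 taxa).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  if (any(!is.finite(d))) abort("Non-finite distances.")
  if (nrow(d) < 3L) abort("Need at least 3 taxa.")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tr)
}

clamp_negative_branches <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    excess <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sisters <- which(tr$edge[, 1] == parent)
    sisters <- setdiff(sisters, e)
    tr$edge.length[e] <- 0
    if (length(sisters) > 0L) {
      tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] + excess
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Split a tree into its two basal clades
#'
#' Clade assignment for downstream contrasts (e.g. per-clade gene loss): each
#' internal edge of the unrooted tree induces a bipartition of the tips; the
#' chosen split is the one maximizing the separation of the underlying
#' distances (mean between-clade minus mean within-clade distance), with both
#' sides holding at least `min_clade` tips. Without a distance matrix the
#' longest internal edge is used instead.
#'
#' @param tree An [ape::phylo] tree.
#' @param d Optional distance matrix over the tip labels used to score
#'   candidate bipartitions (recommended; the edge-length heuristic is easily
#'   dominated by a single long terminal-side edge).
#' @param min_clade Minimum tips per side when scoring with `d` (default 2).
#' @return Tibble `accession_id`, `clade` (`"I"`/`"II"`; clade I holds the
#'   first tip label).
#' @export
tree_bipartition <- function(tree, d = NULL, min_clade = 2L) {
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > ntip)
  if (length(internal) == 0L) abort("Tree has no internal edge to split on.")
  side_of <- function(e) {
    inside <- phangorn_free_descendants(tree, tree$edge[e, 2])
    tree$tip.label %in% tree$tip.label[inside]
  }
  if (is.null(d)) {
    e <- internal[which.max(tree$edge.length[internal])]
    side <- side_of(e)
  } else {
    d <- d[tree$tip.label, tree$tip.label]
    best <- -Inf
    side <- NULL
    for (e in internal) {
      s <- side_of(e)
      k <- sum(s)
      if (k < min_clade || ntip - k < min_clade) next
      between <- mean(d[s, !s])
      within <- (sum(d[s, s]) + sum(d[!s, !s])) /
        (k * (k - 1) + (ntip - k) * (ntip - k - 1))
      score <- between - within
      if (score > best) {
        best <- score
        side <- s
      }
    }
    if (is.null(side)) abort("No bipartition satisfies the size constraint.")
  }
  # Clade I = the side containing the first tip label.
  if (!side[1]) side <- !side
  tibble(accession_id = tree$tip.label,
         clade = ifelse(side, "I", "II"))
}

# Tip indices below `node` (iterative DFS; avoids a phangorn dependency).
phangorn_free_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  stack <- node
  tips <- integer()
  while (length(stack) > 0L) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    tips <- c(tips, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  tips
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with significance from
#' simultaneous row/column permutations of the second matrix. The p-value is
#' `(1 + #{permuted r at least as extreme}) / (1 + n_perm)`.
#'
#' @param d1,d2 Symmetric distance matrices over the same labels in the same
#'   order.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional seed.
#' @param alternative `"greater"` (default: positive association claimed) or
#'   `"two.sided"`.
#' @param exact If `TRUE`, enumerate all `n!` label permutations (at most 7
#'   labels) instead of sampling; the p-value is then the exact proportion of
#'   permutations (identity included) at least as extreme as observed.
#' @return A `mantel_test` list: `statistic` (r), `p_value`, `n_perm`,
#'   `alternative`, `n`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999L, seed = NULL,
                        alternative = c("greater", "two.sided"),
                        exact = FALSE) {
  alternative <- match.arg(alternative)
  if (!identical(dim(d1), dim(d2))) abort("Distance matrices differ in size.")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    abort("Distance matrices must share labels in the same order.")
  }
  n <- nrow(d1)
  off <- upper.tri(d1)
  v1 <- d1[off]
  if (stats::sd(v1) == 0 || stats::sd(d2[off]) == 0) {
    abort("Constant distance matrix: Mantel correlation undefined.")
  }
  r_obs <- stats::cor(v1, d2[off])
  if (exact) {
    if (n > 7L) abort("`exact = TRUE` supports at most 7 labels.")
    perms <- all_permutations(seq_len(n))
    r_all <- apply(perms, 1, function(p) stats::cor(v1, d2[p, p][off]))
    hit <- if (alternative == "greater") r_all >= r_obs - 1e-12
           else abs(r_all) >= abs(r_obs) - 1e-12
    return(structure(list(statistic = r_obs, p_value = mean(hit),
                          n_perm = nrow(perms), alternative = alternative,
                          n = n),
                     class = "mantel_test"))
  }
  with_local_seed(seed, {
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      r_p <- stats::cor(v1, d2[p, p][off])
      hit <- if (alternative == "greater") r_p >= r_obs
             else abs(r_p) >= abs(r_obs)
      if (hit) exceed <- exceed + 1L
    }
    structure(list(statistic = r_obs,
                   p_value = (1 + exceed) / (1 + n_perm),
                   n_perm = as.integer(n_perm),
                   alternative = alternative, n = n),
              class = "mantel_test")
  })
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations, n = %d)\n",
              x$statistic, x$p_value, x$alternative, x$n_perm, x$n))
  invisible(x)
}

#' @describeIn mantel_test one-row tibble of the test result.
#' @param x A `mantel_test`.
#' @param ... Unused.
#' @export
tidy.mantel_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_perm = x$n_perm, alternative = x$alternative, n = x$n)
}

#' Welch two-sample t-test on count samples
#'
#' Thin tidy wrapper around [stats::t.test()] (unequal variances,
#' Welch–Satterthwaite degrees of freedom, two-sided by default); used for
#' the per-clade gene-loss contrast.
#'
#' @param a,b Numeric samples (each of length at least 2, nonzero variance in
#'   at least one).
#' @param alternative Passed to [stats::t.test()].
#' @return Tibble `estimate_a`, `estimate_b`, `t`, `df`, `p_value`.
#' @export
welch_t <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L) abort("Each sample needs n >= 2.")
  if (var(a) == 0 && var(b) == 0) {
    abort("Both samples have zero variance; Welch t undefined.")
  }
  ht <- t.test(a, b, var.equal = FALSE, alternative = alternative)
  tibble(estimate_a = mean(a), estimate_b = mean(b),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Per-clade gene-loss contrast
#'
#' Splits accessions into two clades (from labels or the NJ tree's basal
#' bipartition) and compares per-accession gene-loss counts with a Welch
#' two-sample t-test.
#'
#' @param matrix A [pav_matrix()] (or coercible).
#' @param clades Optional tibble `accession_id`, `clade`; when `NULL`, clades
#'   come from [tree_bipartition()] of the NJ tree on simple-matching PAV
#'   distances.
#' @return A list: `clades` (the assignment used), `loss` (per-accession
#'   counts with clade), `test` (the [welch_t()] tibble with per-clade means).
#' @export
clade_gene_loss <- function(matrix, clades = NULL) {
  m <- as_pav_matrix(matrix)
  if (is.null(clades)) {
    d <- pav_distance(m)
    clades <- tree_bipartition(nj_tree(d), d = d)
  }
  loss <- left_join(gene_loss_counts(m), clades, by = "accession_id")
  if (anyNA(loss$clade)) abort("Clade labels missing for some accessions.")
  a <- loss$n_lost[loss$clade == "I"]
  b <- loss$n_lost[loss$clade == "II"]
  list(clades = clades, loss = loss, test = welch_t(a, b))
}
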