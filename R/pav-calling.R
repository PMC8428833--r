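#' The map-to-pan presence rule
#'
#' A gene is called present in an accession when short-read alignment covers
#' at least `min_gene_body_cov` of its gene-body positions and at least
#' `min_cds_cov` of its CDS positions (breadth of coverage at read depth of at
#' least the profile's `depth_min`). Both thresholds are inclusive.
#'
#' @param min_gene_body_cov Minimum gene-body breadth of coverage (default
#'   0.75).
#' @param min_cds_cov Minimum CDS breadth of coverage (default 0.95).
#' @return A `presence_rule` list.
#' @export
presence_rule <- function(min_gene_body_cov = 0.75, min_cds_cov = 0.95) {
  stopifnot(min_gene_body_cov > 0, min_gene_body_cov <= 1,
            min_cds_cov > 0, min_cds_cov <= 1)
  structure(list(min_gene_body_cov = min_gene_body_cov,
                 min_cds_cov = min_cds_cov),
            class = "presence_rule")
}

#' Breadth of coverage of a region
#'
#' Fraction of the positions in `region` (union of its intervals) that fall
#' inside the covered intervals of a single-accession coverage profile.
#'
#' @param region Tibble with columns `seq_id`, `start`, `end` (0-based
#'   half-open); multiple rows form one region (e.g. the CDS parts of a gene).
#' @param profile Coverage profile tibble (`seq_id`, `start`, `end`), e.g.
#'   from [read_depth_table()].
#' @return A fraction in `[0, 1]`.
#' @export
covered_fraction <- function(region, profile) {
  width <- sum(region$end - region$start)
  if (width <= 0) abort("Region has zero-length union.")
  regions <- mutate(region, group = "r")
  cov_bp <- regions_covered_bp(regions, profile)
  if (nrow(cov_bp) == 0L) return(0)
  cov_bp$covered_bp[1] / width
}

# Per gene x accession body/CDS covered fractions.
# genes: gene-models tibble; coverage: tibble with accession_id column.
coverage_fractions_one <- function(genes, coverage_one) {
  bodies <- genes %>%
    select(group = "gene_id", "seq_id", "start", "end")
  cds <- genes %>%
    select("gene_id", "seq_id", "cds") %>%
    tidyr::unnest("cds") %>%
    select(group = "gene_id", "seq_id", "start", "end")
  body_w <- setNames(genes$end - genes$start, genes$gene_id)
  cds_w <- cds %>%
    group_by(.data$group) %>%
    summarise(w = sum(.data$end - .data$start), .groups = "drop")
  cds_w <- setNames(cds_w$w, cds_w$group)

  body_bp <- regions_covered_bp(bodies, coverage_one)
  cds_bp <- regions_covered_bp(cds, coverage_one)
  tibble(
    gene_id = genes$gene_id,
    body_cov = unname(setNames(body_bp$covered_bp,
                               body_bp$group)[genes$gene_id] /
                        body_w[genes$gene_id]),
    cds_cov = unname(setNames(cds_bp$covered_bp,
                              cds_bp$group)[genes$gene_id] /
                       cds_w[genes$gene_id])
  )
}

#' Gene-body and CDS covered fractions for every gene and accession
#'
#' @param genes Gene-models tibble from [read_gff3()] (or the synthetic
#'   generator).
#' @param coverage Coverage tibble with columns `accession_id`, `seq_id`,
#'   `start`, `end`; may hold any number of accessions.
#' @return Tibble `gene_id`, `accession_id`, `body_cov`, `cds_cov`.
#' @export
coverage_fractions <- function(genes, coverage) {
  accs <- unique(coverage$accession_id)
  purrr::map_dfr(accs, function(a) {
    coverage_fractions_one(genes,
                           coverage[coverage$accession_id == a, ,
                                    drop = FALSE]) %>%
      mutate(accession_id = a, .after = "gene_id")
  })
}

#' Call presence of one gene in one accession
#'
#' @param gene One row of a gene-models tibble.
#' @param profile Single-accession coverage profile tibble.
#' @param rule A [presence_rule()].
#' @return One-row tibble `gene_id`, `body_cov`, `cds_cov`, `present`
#'   (integer 0/1). If the gene's sequence does not appear in the profile at
#'   all, the gene is called absent with a warning (no coverage evidence).
#' @export
call_presence <- function(gene, profile, rule = presence_rule()) {
  stopifnot(nrow(gene) == 1L)
  if (!gene$seq_id %in% profile$seq_id) {
    warn(sprintf(
      "Sequence '%s' of gene '%s' absent from the coverage profile; calling absent.",
      gene$seq_id, gene$gene_id))
  }
  fr <- coverage_fractions_one(gene, profile)
  mutate(fr, present = as.integer(
    .data$body_cov >= rule$min_gene_body_cov &
      .data$cds_cov >= rule$min_cds_cov))
}

#' Build the genic PAV matrix from coverage evidence
#'
#' Applies the map-to-pan presence rule to every gene x accession pair. Gene
#' order follows `genes`; accession order follows first appearance in
#' `coverage`.
#'
#' @inheritParams coverage_fractions
#' @param rule A [presence_rule()].
#' @param fractions If `TRUE`, attach the per-call fraction table as attribute
#'   `"fractions"`.
#' @return A [pav_matrix()].
#' @export
build_pav_matrix <- function(genes, coverage, rule = presence_rule(),
                             fractions = FALSE) {
  if (is.list(coverage) && !is.data.frame(coverage)) {
    ids <- purrr::map_chr(coverage, ~ .x$accession_id[1])
    if (anyDuplicated(ids)) abort("Duplicate accession ids in coverage profiles.")
    coverage <- bind_rows(coverage)
  }
  if (nrow(genes) == 0L || nrow(coverage) == 0L) {
    abort("Need at least one gene and one coverage interval.")
  }
  fr <- coverage_fractions(genes, coverage)
  fr <- mutate(fr, present = as.integer(
    .data$body_cov >= rule$min_gene_body_cov &
      .data$cds_cov >= rule$min_cds_cov))
  accs <- unique(coverage$accession_id)
  m <- matrix(0L, nrow(genes), length(accs),
              dimnames = list(genes$gene_id, accs))
  m[cbind(match(fr$gene_id, genes$gene_id),
          match(fr$accession_id, accs))] <- fr$present
  out <- pav_matrix(m)
  if (fractions) attr(out, "fractions") <- fr
  out
}
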