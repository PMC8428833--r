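#' Support of short-read absence calls by long-read deletions
#'
#' A gene called absent from short-read coverage is *supported* when a
#' long-read deletion on the same sequence overlaps its gene body by at least
#' `min_overlap_bp` (partial or complete overlap; no reciprocal-overlap
#' requirement). Reports the per-gene flags and, per accession, the support
#' rate = supported / absent; plus the pooled rate over all accessions and
#' the unweighted mean of per-accession rates (two natural aggregations of a
#' multi-accession validation).
#'
#' @param absent_genes Tibble `accession_id`, `gene_id`, `seq_id`, `start`,
#'   `end`: gene-body intervals of genes called absent per accession (e.g.
#'   built from a [pav_matrix()] and gene models via [absent_gene_intervals()]).
#' @param deletions Tibble `accession_id`, `seq_id`, `start`, `end` of
#'   long-read deletion calls (e.g. `sv$deletions` from
#'   [simulate_sv_calls()], or [read_deletions_bed()]).
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return A list: `per_gene` (input plus `supported`), `per_accession`
#'   (tibble `accession_id`, `n_absent`, `n_supported`, `support_rate`;
#'   rate is `NA` for accessions with no absent genes), `pooled_rate`,
#'   `mean_rate`.
#' @export
deletion_support <- function(absent_genes, deletions, min_overlap_bp = 1L) {
  stopifnot(min_overlap_bp >= 1L)
  supported <- logical(nrow(absent_genes))
  if (nrow(absent_genes) > 0L && nrow(deletions) > 0L) {
    key_g <- paste(absent_genes$accession_id, absent_genes$seq_id, sep = "\r")
    key_d <- paste(deletions$accession_id, deletions$seq_id, sep = "\r")
    for (k in intersect(unique(key_g), unique(key_d))) {
      gi <- which(key_g == k)
      di <- which(key_d == k)
      g_ir <- ir0(absent_genes$start[gi], absent_genes$end[gi])
      d_ir <- ir0(deletions$start[di], deletions$end[di])
      hits <- IRanges::findOverlaps(g_ir, d_ir,
                                    minoverlap = as.integer(min_overlap_bp))
      supported[gi[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
  }
  per_gene <- mutate(absent_genes, supported = supported)
  per_accession <- per_gene %>%
    group_by(.data$accession_id) %>%
    summarise(n_absent = n(), n_supported = sum(.data$supported),
              .groups = "drop") %>%
    mutate(support_rate = ifelse(.data$n_absent > 0,
                                 .data$n_supported / .data$n_absent,
                                 NA_real_))
  pooled <- if (nrow(per_gene) > 0L) mean(per_gene$supported) else NA_real_
  list(per_gene = per_gene,
       per_accession = per_accession,
       pooled_rate = pooled,
       mean_rate = mean(per_accession$support_rate, na.rm = TRUE))
}

#' Gene-body intervals of absent genes
#'
#' Convenience builder for [deletion_support()]: joins a PAV matrix with gene
#' models and returns one row per (accession, absent gene).
#'
#' @param matrix A [pav_matrix()] (or coercible).
#' @param genes Gene-models tibble.
#' @param accessions Accessions to include (default all).
#' @return Tibble `accession_id`, `gene_id`, `seq_id`, `start`, `end`.
#' @export
absent_gene_intervals <- function(matrix, genes,
                                  accessions = colnames(as_pav_matrix(matrix))) {
  m <- unclass(as_pav_matrix(matrix))
  purrr::map_dfr(accessions, function(a) {
    g <- genes[m[genes$gene_id, a] == 0L, , drop = FALSE]
    tibble(accession_id = a, gene_id = g$gene_id, seq_id = g$seq_id,
           start = g$start, end = g$end)
  })
}

# Canonical k-mers of a set of sequences: each k-mer and its reverse
# complement are represented by the lexicographically smaller of the two.
canonical_kmers <- function(seqs, k) {
  seqs <- toupper(seqs)
  kms <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }))
  if (length(kms) == 0L) return(character())
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kms)))
  unique(pmin(kms, rc))
}

#' Recovery of novel sequences within long-read insertions
#'
#' A novel (nonreference) sequence is *recovered* when at least
#' `min_containment` of its canonical k-mers occur among the canonical k-mers
#' of the insertion sequences — an aligner-free stand-in for remapping the
#' previously unaligned reads onto the insertion catalogue. Sequences shorter
#' than `k` fall back to exact substring search (on either strand).
#'
#' @param novel_sequences Tibble `name`, `sequence`.
#' @param insertions Tibble with a `sequence` column (e.g. `sv$insertions`
#'   from [simulate_sv_calls()]), or a character vector of sequences.
#' @param k k-mer size (default 31).
#' @param min_containment Containment fraction required for recovery
#'   (default 0.8).
#' @return A list: `per_sequence` (tibble `name`, `length`, `containment`,
#'   `recovered`), `recovered_bp_fraction` (recovered bp / total bp) and
#'   `recovered_fraction` (sequences recovered / sequences).
#' @export
insertion_recovery <- function(novel_sequences, insertions, k = 31L,
                               min_containment = 0.8) {
  ins_seqs <- if (is.data.frame(insertions)) insertions$sequence
              else as.character(insertions)
  pool <- canonical_kmers(ins_seqs, k)
  per <- purrr::pmap_dfr(novel_sequences[, c("name", "sequence")],
                         function(name, sequence) {
    len <- nchar(sequence)
    if (len < k) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sequence)))
      hit <- any(vapply(ins_seqs, function(s) {
        grepl(sequence, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE)
      }, logical(1)))
      return(tibble(name = name, length = len,
                    containment = as.numeric(hit), recovered = hit))
    }
    kms <- canonical_kmers(sequence, k)
    cont <- if (length(kms) == 0L) 0 else mean(kms %in% pool)
    tibble(name = name, length = len, containment = cont,
           recovered = cont >= min_containment)
  })
  list(
    per_sequence = per,
    recovered_bp_fraction = sum(per$length[per$recovered]) / sum(per$length),
    recovered_fraction = mean(per$recovered)
  )
}
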