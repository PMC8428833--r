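#' Extraction thresholds for nonreference sequence
#'
#' Defaults follow the canonical novel-sequence workflow: only contigs of at
#' least 500 bp are considered; unaligned fragments must be strictly longer
#' than 450 bp to be excised; sequences are treated as redundant at 90%
#' identity (the CD-HIT `-c 0.9` convention; set `redundancy_identity = 0.95`
#' for the stricter published redundancy figure — the two thresholds coexist
#' in the literature and both are exposed here).
#'
#' @param min_contig_bp Minimum contig length considered.
#' @param min_unaligned_fragment_bp Minimum (strict) unaligned fragment
#'   length.
#' @param identity_max_to_reference Maximum identity to the reference for a
#'   sequence to count as novel.
#' @param redundancy_identity Identity threshold for redundancy clustering.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(min_contig_bp = 500L,
                              min_unaligned_fragment_bp = 450L,
                              identity_max_to_reference = 0.90,
                              redundancy_identity = 0.90) {
  stopifnot(min_contig_bp > 0, min_unaligned_fragment_bp > 0,
            identity_max_to_reference > 0, identity_max_to_reference <= 1,
            redundancy_identity > 0, redundancy_identity <= 1)
  structure(list(min_contig_bp = as.integer(min_contig_bp),
                 min_unaligned_fragment_bp = as.integer(min_unaligned_fragment_bp),
                 identity_max_to_reference = identity_max_to_reference,
                 redundancy_identity = redundancy_identity),
            class = "extraction_config")
}

#' Read contig alignment summaries
#'
#' Tab-separated: `contig_id`, `length`, `aln_start`, `aln_end` (0-based
#' half-open alignment intervals on the contig), one row per aligned
#' interval. Contigs with no alignment carry a single row with empty
#' alignment fields.
#'
#' @param path File path (no header).
#' @return Tibble `contig_id`, `length`, `aln_start`, `aln_end` (`NA` for
#'   unaligned contigs).
#' @export
read_alignment_summary <- function(path) {
  readr::read_tsv(path, col_names = c("contig_id", "length", "aln_start",
                                      "aln_end"),
                  col_types = "ciii", progress = FALSE)
}

#' Classify contigs against a reference alignment summary
#'
#' Partitions contigs into `too_short` (below the minimum length),
#' `fully_unaligned` (no alignment to the reference), `partially_unaligned`
#' (at least one alignment and at least one unaligned fragment strictly
#' longer than the fragment threshold) and `aligned` (everything else).
#' Overlapping aligned intervals are merged with a warning.
#'
#' @param summary Tibble as from [read_alignment_summary()]; one row per
#'   aligned interval, `NA` intervals for unaligned contigs.
#' @param cfg An [extraction_config()].
#' @return Tibble `contig_id`, `length`, `class`, `fragments` (list-column of
#'   tibbles `start`, `end`: the whole contig for `fully_unaligned`, the
#'   qualifying complement intervals for `partially_unaligned`, empty
#'   otherwise).
#' @export
classify_contigs <- function(summary, cfg = extraction_config()) {
  stopifnot(all(c("contig_id", "length") %in% names(summary)))
  per <- summary %>%
    group_by(.data$contig_id, .data$length) %>%
    summarise(aln = {
      s <- .data$aln_start; e <- .data$aln_end
      list(tibble(start = s[!is.na(s)], end = e[!is.na(e)]))
    }, .groups = "drop")
  overlapped <- FALSE
  res <- purrr::pmap(per, function(contig_id, length, aln) {
    if (length < cfg$min_contig_bp) {
      return(list(class = "too_short",
                  fragments = tibble(start = integer(), end = integer())))
    }
    if (nrow(aln) == 0L) {
      return(list(class = "fully_unaligned",
                  fragments = tibble(start = 0L, end = as.integer(length))))
    }
    merged <- merge_intervals(aln$start, aln$end)
    if (nrow(merged) < nrow(aln)) overlapped <<- TRUE
    frags <- complement_intervals(merged$start, merged$end, length)
    frags <- frags[frags$end - frags$start > cfg$min_unaligned_fragment_bp, ,
                   drop = FALSE]
    if (nrow(frags) > 0L) {
      list(class = "partially_unaligned", fragments = frags)
    } else {
      list(class = "aligned",
           fragments = tibble(start = integer(), end = integer()))
    }
  })
  if (overlapped) warn("Overlapping aligned intervals were merged.")
  per %>%
    mutate(class = purrr::map_chr(res, "class"),
           fragments = purrr::map(res, "fragments")) %>%
    select("contig_id", "length", "class", "fragments")
}

#' Excise unaligned fragments from a contig sequence
#'
#' @param contig_sequence Single DNA string.
#' @param fragments Tibble `start`, `end` (0-based half-open, within the
#'   sequence).
#' @param contig_id Name used to label fragments (`contig_id:start-end`).
#' @return Tibble `name`, `sequence`, `length`, in contig order.
#' @export
excise_fragments <- function(contig_sequence, fragments,
                             contig_id = "contig") {
  len <- nchar(contig_sequence)
  if (nrow(fragments) == 0L) {
    return(tibble(name = character(), sequence = character(),
                  length = integer()))
  }
  if (any(fragments$start < 0 | fragments$end > len |
          fragments$start >= fragments$end)) {
    abort("Fragment interval out of bounds.")
  }
  fragments <- arrange(fragments, .data$start)
  tibble(
    name = sprintf("%s:%d-%d", contig_id, fragments$start, fragments$end),
    sequence = substring(contig_sequence, fragments$start + 1L,
                         fragments$end),
    length = as.integer(fragments$end - fragments$start)
  )
}

# Pairwise identity between two sequences: identical matches in the best
# local alignment divided by the shorter sequence length (the CD-HIT
# convention; a raw matches/alignment-length ratio would call any two
# sequences sharing a short exact word identical). When lengths differ more
# than 2x, approximated by k-mer containment of the shorter in the longer.
pair_identity <- function(s1, s2, word_k = 12L) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  shorter <- min(n1, n2)
  if (shorter == 0L) return(0)
  if (max(n1, n2) > 2L * shorter) {
    sh <- if (n1 <= n2) s1 else s2
    lo <- if (n1 <= n2) s2 else s1
    k <- min(word_k, nchar(sh))
    km_sh <- unique(substring(sh, seq_len(nchar(sh) - k + 1L),
                              seq_len(nchar(sh) - k + 1L) + k - 1L))
    km_lo <- unique(substring(lo, seq_len(nchar(lo) - k + 1L),
                              seq_len(nchar(lo) - k + 1L) + k - 1L))
    return(mean(km_sh %in% km_lo))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(s1, s2, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 2)
  Biostrings::nmatch(aln) / shorter
}

#' Remove redundant sequences by greedy identity clustering
#'
#' CD-HIT-style greedy clustering: sequences are visited longest first (ties
#' broken by name); a sequence joins the first existing representative it
#' matches at `identity_threshold` or better, otherwise it founds a new
#' cluster. Identity is computed from the best local alignment (see
#' Details in [extraction_config()]); for sequence pairs differing more than
#' two-fold in length a shared-k-mer containment approximation is used.
#'
#' @param sequences Tibble `name`, `sequence`.
#' @param identity_threshold Clustering identity threshold (default 0.9).
#' @param word_k k-mer size for the containment approximation.
#' @return A list: `representatives` (tibble `name`, `sequence`, `length`)
#'   and `membership` (tibble `name`, `representative`). Cluster union equals
#'   the input set; representative order is deterministic (length descending,
#'   then name).
#' @export
remove_redundancy <- function(sequences, identity_threshold = 0.90,
                              word_k = 12L) {
  if (nrow(sequences) == 0L) {
    return(list(representatives = tibble(name = character(),
                                         sequence = character(),
                                         length = integer()),
                membership = tibble(name = character(),
                                    representative = character())))
  }
  sequences <- sequences %>%
    mutate(length = nchar(.data$sequence)) %>%
    arrange(dplyr::desc(.data$length), .data$name)
  reps <- integer()
  member_of <- character(nrow(sequences))
  for (i in seq_len(nrow(sequences))) {
    assigned <- FALSE
    for (r in reps) {
      idt <- pair_identity(sequences$sequence[i], sequences$sequence[r],
                           word_k)
      if (idt >= identity_threshold) {
        member_of[i] <- sequences$name[r]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      member_of[i] <- sequences$name[i]
    }
  }
  list(
    representatives = sequences[reps, c("name", "sequence", "length")],
    membership = tibble(name = sequences$name, representative = member_of)
  )
}

#' Filter contaminant contigs from taxon-labelled hit tables
#'
#' A contig is removed when its best hit (minimum e-value; ties broken by
#' contaminant-class priority organellar > microbial > non_viridiplantae,
#' then by lower identity) is anything but nuclear plant sequence. Contigs
#' with no hits are retained (no evidence of contamination).
#'
#' @param contig_ids Character vector of contig ids under consideration.
#' @param hits Tibble `contig_id`, `subject_taxon_class` (one of
#'   `viridiplantae_nuclear`, `organellar`, `microbial`,
#'   `non_viridiplantae`), `e_value`, `identity`.
#' @return Tibble `contig_id`, `best_class` (`NA` when no hits), `retained`.
#' @export
filter_contaminants <- function(contig_ids, hits) {
  classes <- c("organellar", "microbial", "non_viridiplantae",
               "viridiplantae_nuclear")
  if (nrow(hits) > 0L && !all(hits$subject_taxon_class %in% classes)) {
    abort("Unknown subject_taxon_class in hits.")
  }
  best <- hits %>%
    filter(.data$contig_id %in% contig_ids) %>%
    mutate(.priority = match(.data$subject_taxon_class, classes)) %>%
    group_by(.data$contig_id) %>%
    arrange(.data$e_value, .data$.priority, .data$identity,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("contig_id", best_class = "subject_taxon_class")
  tibble(contig_id = contig_ids) %>%
    left_join(best, by = "contig_id") %>%
    mutate(retained = is.na(.data$best_class) |
             .data$best_class == "viridiplantae_nuclear")
}

#' Accumulation curve of novel sequence
#'
#' Cumulative nonreference sequence length (bp of the union of representative
#' sequences) over incremental random subsets of accessions: for each of
#' `n_orders` random accession orders, the union length is evaluated at
#' subset sizes `step, 2*step, ..., N` (N always included), and per-size
#' mean/min/max are reported. The curve is non-decreasing within every order
#' and its final value is the total union length regardless of order.
#'
#' @param per_accession_novel Tibble `accession_id`, `rep_id`, `length`:
#'   which representative sequences each accession contributed (lengths are a
#'   property of the representative and must agree across accessions).
#' @param step Subset-size increment (default 20). A step larger than the
#'   number of accessions yields the single size N.
#' @param n_orders Number of random orders (default 100).
#' @param seed Optional seed.
#' @param exhaustive If `TRUE`, enumerate all accession orders (at most 7
#'   accessions); means are then exact.
#' @return Tibble `size`, `mean_bp`, `min_bp`, `max_bp`.
#' @export
accumulation_curve <- function(per_accession_novel, step = 20L,
                               n_orders = 100L, seed = NULL,
                               exhaustive = FALSE) {
  accs <- unique(per_accession_novel$accession_id)
  N <- length(accs)
  perms <- NULL
  if (exhaustive) {
    if (N > 7L) abort("`exhaustive = TRUE` supports at most 7 accessions.")
    perms <- all_permutations(seq_len(N))
    n_orders <- nrow(perms)
  }
  reps <- distinct(per_accession_novel, .data$rep_id, .data$length)
  if (anyDuplicated(reps$rep_id)) {
    abort("Representative lengths disagree across accessions.")
  }
  sizes <- unique(c(seq(min(step, N), N, by = step), N))
  # accession x representative incidence
  inc <- matrix(FALSE, N, nrow(reps),
                dimnames = list(accs, reps$rep_id))
  inc[cbind(match(per_accession_novel$accession_id, accs),
            match(per_accession_novel$rep_id, reps$rep_id))] <- TRUE
  with_local_seed(seed, {
    cum <- matrix(0, n_orders, length(sizes))
    for (o in seq_len(n_orders)) {
      perm <- if (exhaustive) perms[o, ] else sample.int(N)
      # First order position at which each representative appears.
      first <- apply(inc[perm, , drop = FALSE], 2, function(v) {
        w <- which(v)
        if (length(w) == 0L) NA_integer_ else w[1]
      })
      newbp <- rowsum_safe(reps$length[!is.na(first)], first[!is.na(first)], N)
      cum[o, ] <- cumsum(newbp)[sizes]
    }
    tibble(size = sizes,
           mean_bp = colMeans(cum),
           min_bp = apply(cum, 2, min),
           max_bp = apply(cum, 2, max))
  })
}
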