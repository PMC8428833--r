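#' Frequency-band configuration for gene categories
#'
#' Presence-frequency bands follow the pan-genome convention: *hardcore*
#' genes are present in more than 99% of accessions, *softcore* in more than
#' 95% up to 99%, *shell* in 5% to 95%, and *cloud* in fewer than 5%. The
#' two superclasses are *core* = hardcore + softcore (loss rate below 0.05)
#' and *variable* = shell + cloud (loss rate of 0.05 or more). Boundary
#' semantics: cloud `[0, 0.05)`, shell `[0.05, 0.95]`, softcore
#' `(0.95, 0.99]`, hardcore `(0.99, 1]` — the only partition consistent with
#' a strict ">99%" hardcore bound, a strict "<5%" cloud bound, and a gene at
#' exactly 5% loss being variable.
#'
#' @param hardcore_min_excl Exclusive lower frequency bound for hardcore.
#' @param softcore_min_excl Exclusive lower bound for softcore (also the
#'   core/variable boundary).
#' @param cloud_max_excl Exclusive upper bound for cloud.
#' @return A `classification_config` list.
#' @export
classification_config <- function(hardcore_min_excl = 0.99,
                                  softcore_min_excl = 0.95,
                                  cloud_max_excl = 0.05) {
  stopifnot(0 < cloud_max_excl, cloud_max_excl < softcore_min_excl,
            softcore_min_excl < hardcore_min_excl, hardcore_min_excl < 1)
  structure(list(hardcore_min_excl = hardcore_min_excl,
                 softcore_min_excl = softcore_min_excl,
                 cloud_max_excl = cloud_max_excl),
            class = "classification_config")
}

#' Per-gene presence counts and frequencies
#'
#' @param matrix A [pav_matrix()] (or coercible data frame / matrix).
#' @return Tibble `gene_id`, `presence_count`, `frequency` where
#'   `frequency = presence_count / n_accessions` exactly.
#' @export
presence_frequency <- function(matrix) {
  m <- as_pav_matrix(matrix)
  if (ncol(m) < 1L) abort("Need at least one accession.")
  cnt <- as.integer(rowSums(m))
  tibble(gene_id = rownames(m), presence_count = cnt,
         frequency = cnt / ncol(m))
}

# Category from presence count and accession total. Boundary comparisons are
# done on integer counts (count vs threshold * n) to dodge floating-point
# misclassification at exact band edges.
category_from_count <- function(count, n, cfg = classification_config()) {
  eps <- 1e-9
  f <- count / n
  dplyr::case_when(
    count < n * cfg$cloud_max_excl - eps ~ "cloud",
    count <= n * cfg$softcore_min_excl + eps ~ "shell",
    count <= n * cfg$hardcore_min_excl + eps ~ "softcore",
    TRUE ~ "hardcore"
  )
}

#' Assign hardcore/softcore/shell/cloud categories
#'
#' @param matrix A [pav_matrix()] (or coercible). Alternatively a tibble from
#'   [presence_frequency()] plus `n_accessions`.
#' @param cfg A [classification_config()].
#' @param n_accessions Required only when `matrix` is a frequency tibble.
#' @return A *gene category table*: tibble `gene_id`, `presence_count`,
#'   `frequency`, `category` (factor hardcore/softcore/shell/cloud) and
#'   `superclass` (factor core/variable). Genes present in no accession are
#'   classified cloud and flagged with a warning (they should not occur in a
#'   map-to-pan matrix, whose genes all exist somewhere).
#' @export
categorize_genes <- function(matrix, cfg = classification_config(),
                             n_accessions = NULL) {
  if (is.data.frame(matrix) && all(c("gene_id", "frequency") %in% names(matrix)) &&
      !is.null(n_accessions)) {
    freq <- matrix
    if (!"presence_count" %in% names(freq)) {
      freq$presence_count <- as.integer(round(freq$frequency * n_accessions))
    }
    n <- n_accessions
  } else {
    m <- as_pav_matrix(matrix)
    freq <- presence_frequency(m)
    n <- ncol(m)
  }
  if (any(freq$frequency < 0 | freq$frequency > 1)) {
    abort("Presence frequency outside [0, 1].")
  }
  if (any(freq$presence_count == 0L)) {
    warn(sprintf("%d gene(s) present in no accession (frequency 0).",
                 sum(freq$presence_count == 0L)))
  }
  cat_levels <- c("hardcore", "softcore", "shell", "cloud")
  freq %>%
    mutate(
      category = factor(category_from_count(.data$presence_count, n, cfg),
                        levels = cat_levels),
      superclass = factor(
        ifelse(.data$category %in% c("hardcore", "softcore"),
               "core", "variable"),
        levels = c("core", "variable"))
    )
}

#' Category counts and percentages
#'
#' @param category_table Output of [categorize_genes()].
#' @return Tibble `category`, `n`, `pct` (per cent of all genes), covering all
#'   four categories (zero-filled).
#' @export
classification_summary <- function(category_table) {
  category_table %>%
    count(.data$category, .drop = FALSE) %>%
    mutate(pct = 100 * .data$n / sum(.data$n))
}

#' Per-accession core/variable composition
#'
#' Two statistics per accession, mirroring the two natural readings of
#' "contains X% of core genes": (1) of the genes *present in the accession*,
#' the percentage that are core vs variable (`pct_of_present_core`,
#' `pct_of_present_variable`; they sum to 100); (2) the percentage *of the
#' core (resp. variable) gene set* that the accession carries
#' (`pct_core_set_present`, `pct_variable_set_present`).
#'
#' @param matrix A [pav_matrix()] (or coercible).
#' @param category_table Gene category table computed from the same matrix.
#' @return Tibble with one row per accession.
#' @export
per_accession_composition <- function(matrix, category_table) {
  m <- as_pav_matrix(matrix)
  ct <- category_table[match(rownames(m), category_table$gene_id), ]
  is_core <- ct$superclass == "core"
  present_core <- colSums(m[is_core, , drop = FALSE])
  present_var <- colSums(m[!is_core, , drop = FALSE])
  present_all <- present_core + present_var
  tibble(
    accession_id = colnames(m),
    n_present = as.integer(present_all),
    pct_of_present_core = unname(100 * present_core / present_all),
    pct_of_present_variable = unname(100 * present_var / present_all),
    pct_core_set_present = unname(100 * present_core / max(sum(is_core), 1L)),
    pct_variable_set_present = unname(100 * present_var /
                                        max(sum(!is_core), 1L))
  )
}

#' Per-accession gene-loss counts
#'
#' Number of pan-genome genes absent from each accession (column-wise zero
#' counts) — the quantity contrasted between population clades.
#'
#' @param matrix A [pav_matrix()] (or coercible).
#' @return Tibble `accession_id`, `n_lost`.
#' @export
gene_loss_counts <- function(matrix) {
  m <- as_pav_matrix(matrix)
  tibble(accession_id = colnames(m),
         n_lost = as.integer(nrow(m) - colSums(m)))
}
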