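# Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction, standard genetic
# code. Conventions: substitutions creating a stop codon count as
# nonsynonymous in the site counts; mutational pathways passing through a
# stop codon are excluded from the pathway average unless every pathway does.

BASES <- c("A", "C", "G", "T")

codon_translate <- local({
  tab <- NULL
  function(codon) {
    if (is.null(tab)) tab <<- as.list(Biostrings::GENETIC_CODE)
    aa <- tab[[codon]]
    if (is.null(aa)) NA_character_ else aa
  }
})

# Synonymous site count of one codon: over the 9 single-nucleotide mutations,
# the fraction that preserve the amino acid, summed over the 3 positions.
# Mutations to stop codons are nonsynonymous. Returns NA for stop codons or
# codons with ambiguity characters.
codon_syn_sites <- function(codon) {
  aa <- codon_translate(codon)
  if (is.na(aa) || aa == "*") return(NA_real_)
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- b
      if (codon_translate(paste(mut, collapse = "")) == aa) s <- s + 1 / 3
    }
  }
  s
}

# Synonymous/nonsynonymous differences between two codons, averaged over all
# minimal mutational pathways (orderings of the differing positions).
codon_differences <- function(c1, c2) {
  chars1 <- strsplit(c1, "")[[1]]
  chars2 <- strsplit(c2, "")[[1]]
  diffpos <- which(chars1 != chars2)
  nd <- length(diffpos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- all_permutations(diffpos)
  paths <- list()
  for (p in seq_len(nrow(perms))) {
    cur <- chars1
    steps <- character(0)
    through_stop <- FALSE
    syn <- 0; nonsyn <- 0
    for (pos in perms[p, ]) {
      prev <- paste(cur, collapse = "")
      cur[pos] <- chars2[pos]
      nxt <- paste(cur, collapse = "")
      aa1 <- codon_translate(prev)
      aa2 <- codon_translate(nxt)
      if (aa2 == "*" || aa1 == "*") through_stop <- TRUE
      if (aa1 == aa2) syn <- syn + 1 else nonsyn <- nonsyn + 1
    }
    paths[[p]] <- c(sd = syn, nd = nonsyn, stop = through_stop)
  }
  pm <- do.call(rbind, paths)
  keep <- pm[, "stop"] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(pm))
  c(sd = mean(pm[keep, "sd"]), nd = mean(pm[keep, "nd"]))
}

all_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- all_permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Nei-Gojobori (NG86) dN/dS for a pairwise codon alignment
#'
#' Classic NG86: per-codon synonymous (S) and nonsynonymous (N) site counts
#' are averaged over the two sequences (S + N equals the sequence length in
#' nucleotides); observed synonymous/nonsynonymous differences are averaged
#' over all minimal mutational pathways between differing codons; the
#' difference proportions are Jukes-Cantor corrected,
#' `d = -(3/4) * log(1 - (4/3) * p)`. The ratio is `NA` when `dS = 0`
#' (undefined), and a proportion of 3/4 or more makes the correction
#' undefined (reported as `NA` with a warning). Codon pairs containing
#' ambiguity characters are skipped; an internal stop codon is an error.
#'
#' @param seq1,seq2 Equal-length gap-free nucleotide strings, length
#'   divisible by 3.
#' @return One-row tibble: `n_codons`, `S`, `N` (site counts), `Sd`, `Nd`
#'   (difference counts), `pS`, `pN`, `dS`, `dN`, `dnds`.
#' @export
ng86_dnds <- function(seq1, seq2) {
  seq1 <- toupper(gsub("U", "T", seq1))
  seq2 <- toupper(gsub("U", "T", seq2))
  if (nchar(seq1) != nchar(seq2)) abort("Sequences differ in length.")
  if (nchar(seq1) %% 3 != 0) abort("Length not divisible by 3.")
  if (nchar(seq1) < 3) abort("Need at least one codon.")
  n_cod <- nchar(seq1) %/% 3
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  cods1 <- substring(seq1, starts, starts + 2L)
  cods2 <- substring(seq2, starts, starts + 2L)

  clean <- grepl("^[ACGT]{3}$", cods1) & grepl("^[ACGT]{3}$", cods2)
  cods1 <- cods1[clean]; cods2 <- cods2[clean]
  if (length(cods1) == 0L) abort("No unambiguous codon pairs.")
  aa1 <- vapply(cods1, codon_translate, character(1))
  aa2 <- vapply(cods2, codon_translate, character(1))
  if (any(aa1 == "*") || any(aa2 == "*")) {
    abort("Internal stop codon in codon alignment.")
  }

  s1 <- vapply(cods1, codon_syn_sites, numeric(1))
  s2 <- vapply(cods2, codon_syn_sites, numeric(1))
  S <- (sum(s1) + sum(s2)) / 2
  N <- 3 * length(cods1) - S

  diffs <- mapply(codon_differences, cods1, cods2)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])

  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 3 / 4) {
      warn(sprintf("Proportion %.3f >= 3/4: Jukes-Cantor correction undefined.",
                   p))
      return(NA_real_)
    }
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  ratio <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  tibble(n_codons = length(cods1), S = S, N = N, Sd = Sd, Nd = Nd,
         pS = pS, pN = pN, dS = dS, dN = dN, dnds = ratio)
}

#' dN/dS for a table of sequence pairs
#'
#' @param pairs Tibble `gene_id`, `seq1`, `seq2` (pairwise codon alignments).
#' @return Tibble with one [ng86_dnds()] row per gene.
#' @export
dnds_table <- function(pairs) {
  purrr::pmap_dfr(pairs[, c("gene_id", "seq1", "seq2")],
                  function(gene_id, seq1, seq2) {
    mutate(ng86_dnds(seq1, seq2), gene_id = gene_id, .before = 1)
  })
}

#' Core-vs-variable dN/dS contrast
#'
#' Welch two-sample t-test of per-gene dN/dS between core and variable genes.
#'
#' @param dnds Tibble from [dnds_table()].
#' @param category_table Gene category table from [categorize_genes()].
#' @return A list: `by_superclass` (tibble of per-class means) and `test`
#'   (the [welch_t()] tibble, core vs variable).
#' @export
dnds_contrast <- function(dnds, category_table) {
  joined <- dnds %>%
    left_join(select(category_table, "gene_id", "superclass"),
              by = "gene_id") %>%
    filter(!is.na(.data$dnds), !is.na(.data$superclass))
  by_class <- joined %>%
    group_by(.data$superclass) %>%
    summarise(n = n(), mean_dnds = mean(.data$dnds), .groups = "drop")
  test <- welch_t(joined$dnds[joined$superclass == "core"],
                  joined$dnds[joined$superclass == "variable"])
  list(by_superclass = by_class, test = test)
}
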