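# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# A tiny gene-models tibble: genes of length `len` spaced on one sequence,
# each with a single centered CDS covering `cds_frac` of the body.
toy_genes <- function(n = 3, len = 100L, cds_frac = 0.5, seq_id = "chr1",
                      gap = 50L) {
  start <- gap + (seq_len(n) - 1L) * (len + gap)
  cds_len <- as.integer(round(cds_frac * len))
  cds_off <- as.integer((len - cds_len) %/% 2L)
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    seq_id = seq_id,
    strand = "+",
    start = as.integer(start),
    end = as.integer(start + len),
    cds = lapply(start, function(s) {
      tibble::tibble(start = as.integer(s + cds_off),
                     end = as.integer(s + cds_off + cds_len))
    })
  )
}

# Coverage tibble covering given fractions of one toy gene: `body_frac` of
# the gene body with `cds_frac` of the CDS (CDS prefix first, then left
# flank, then right flank), mirroring how real breadth evidence looks.
toy_coverage <- function(gene, body_frac, cds_frac, accession_id = "a1") {
  L <- gene$end - gene$start
  cds <- gene$cds[[1]]
  C <- cds$end - cds$start
  m_c <- round(cds_frac * C)
  m_f <- max(0, round(body_frac * L) - m_c)
  left_len <- cds$start - gene$start
  left_cov <- min(m_f, left_len)
  right_cov <- min(max(m_f - left_len, 0), L - C - left_len)
  out <- tibble::tibble(
    accession_id = accession_id,
    seq_id = gene$seq_id,
    start = c(cds$start, gene$start, cds$end),
    end = c(cds$start + m_c, gene$start + left_cov, cds$end + right_cov)
  )
  out[out$end > out$start, , drop = FALSE]
}

# A random binary pav_matrix.
random_pav <- function(n_genes, n_accessions, p = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rbinom(n_genes * n_accessions, 1, p), n_genes, n_accessions)
  panpav::pav_matrix(m,
                     gene_ids = sprintf("g%03d", seq_len(n_genes)),
                     accession_ids = sprintf("a%03d", seq_len(n_accessions)))
}

# Write a small GFF3 file and return its path.
write_toy_gff3 <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

# Brute-force covered fraction by per-position membership.
oracle_covered_fraction <- function(region, cover) {
  pos <- unlist(mapply(function(s, e) seq(s, e - 1L), region$start,
                       region$end, SIMPLIFY = FALSE))
  cov_pos <- unlist(mapply(function(s, e) seq(s, e - 1L), cover$start,
                           cover$end, SIMPLIFY = FALSE))
  mean(pos %in% cov_pos)
}

# Brute-force category assignment from a presence count.
oracle_category <- function(count, n) {
  f <- count / n
  if (count < n * 0.05) "cloud"
  else if (count <= n * 0.95) "shell"
  else if (count <= n * 0.99) "softcore"
  else "hardcore"
}

# Brute-force pan/core subset means by enumerating all C(N, n) subsets.
oracle_pan_core <- function(m, n) {
  subsets <- utils::combn(ncol(m), n, simplify = FALSE)
  pan <- vapply(subsets, function(s) {
    sum(rowSums(m[, s, drop = FALSE]) > 0)
  }, numeric(1))
  core <- vapply(subsets, function(s) {
    sum(rowSums(m[, s, drop = FALSE]) == n)
  }, numeric(1))
  c(pan = mean(pan), core = mean(core))
}

# Standard genetic code lookup for oracle-side NG86 computations.
oracle_translate <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[[codon]])
}

# Independent brute-force NG86 oracle: enumerates the 9 single-nucleotide
# mutations per codon for site counts, and all orderings of differing
# positions for pathway averaging (paths through stop codons excluded unless
# all are).
oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- oracle_translate(codon)
  syn <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
    mut <- ch; mut[pos] <- b
    if (oracle_translate(paste(mut, collapse = "")) == aa) syn <- syn + 1
  }
  syn / 3
}

oracle_pair <- function(s1, s2) {
  n <- nchar(s1) / 3
  cods1 <- substring(s1, 3 * (1:n) - 2, 3 * (1:n))
  cods2 <- substring(s2, 3 * (1:n) - 2, 3 * (1:n))
  S <- (sum(vapply(cods1, oracle_syn_sites, 0)) +
          sum(vapply(cods2, oracle_syn_sites, 0))) / 2
  Sd <- 0; Nd <- 0
  for (i in seq_len(n)) {
    a <- strsplit(cods1[i], "")[[1]]; b <- strsplit(cods2[i], "")[[1]]
    dp <- which(a != b)
    if (length(dp) == 0) next
    perms <- if (length(dp) == 1) list(dp) else {
      if (length(dp) == 2) list(dp, rev(dp)) else {
        do.call(c, lapply(1:3, function(i1) {
          lapply(setdiff(1:3, i1), function(i2) {
            dp[c(i1, i2, setdiff(1:3, c(i1, i2)))]
          })
        }))
      }
    }
    paths <- lapply(perms, function(p) {
      cur <- a; syn <- 0; nonsyn <- 0; stopped <- FALSE
      for (pos in p) {
        aa_from <- oracle_translate(paste(cur, collapse = ""))
        cur[pos] <- b[pos]
        aa_to <- oracle_translate(paste(cur, collapse = ""))
        if (aa_from == "*" || aa_to == "*") stopped <- TRUE
        if (aa_from == aa_to) syn <- syn + 1 else nonsyn <- nonsyn + 1
      }
      c(syn, nonsyn, stopped)
    })
    pm <- do.call(rbind, paths)
    keep <- pm[, 3] == 0
    if (!any(keep)) keep <- rep(TRUE, nrow(pm))
    Sd <- Sd + mean(pm[keep, 1]); Nd <- Nd + mean(pm[keep, 2])
  }
  list(S = S, N = 3 * n - S, Sd = Sd, Nd = Nd)
}

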