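# Ground-truthed synthetic pan-genomes: gene models on a small multi-sequence
# genome, a truth PAV matrix with a realistic presence-frequency spectrum and
# two-clade structure, coverage evidence consistent with the presence rule,
# long-read SV calls, and an SNP distance matrix correlated with PAV distances.

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Configuration of the synthetic pan-genome generator
#'
#' Defaults reproduce the conditions of a cultivated-soybean-scale
#' map-to-pan study: 204 accessions, 54,531 genes, and category fractions
#' equal to the observed hardcore/softcore/shell/cloud proportions
#' (49,431 / 1,401 / 3,402 / 297 of 54,531). Category fractions must sum to 1.
#'
#' @param n_accessions Number of accessions.
#' @param n_genes Number of pan-genome genes.
#' @param frac_hardcore,frac_softcore,frac_shell,frac_cloud Category
#'   fractions; must sum to 1 within 1e-9.
#' @param coverage_noise Probability that a gene-accession pair's coverage is
#'   drawn from the opposite regime (present vs absent), i.e. the expected
#'   PAV-call error rate.
#' @param clade_split Fraction of accessions assigned to clade II.
#' @param clade_bias Presence-frequency gap between clades for
#'   clade-informative shell genes (clade I gets the extra absence).
#' @param clade_informative_frac Fraction of shell genes that are
#'   clade-informative.
#' @param n_seqs Number of pan-genome sequences (chromosomes/scaffolds).
#' @param gene_length Gene-body length in bp.
#' @param cds_fraction Fraction of the gene body that is CDS (one centered
#'   CDS interval).
#' @param intergenic_bp Gap between consecutive genes in bp.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_accessions = 204L,
                       n_genes = 54531L,
                       frac_hardcore = 49431 / 54531,
                       frac_softcore = 1401 / 54531,
                       frac_shell = 3402 / 54531,
                       frac_cloud = 297 / 54531,
                       coverage_noise = 0,
                       clade_split = 0.5,
                       clade_bias = 0.22,
                       clade_informative_frac = 0.5,
                       n_seqs = 20L,
                       gene_length = 3000L,
                       cds_fraction = 0.4,
                       intergenic_bp = 1000L,
                       seed = 1L) {
  fr <- c(frac_hardcore, frac_softcore, frac_shell, frac_cloud)
  if (any(fr < 0 | fr > 1)) abort("Category fractions must lie in [0, 1].")
  if (abs(sum(fr) - 1) > 1e-9) {
    abort(sprintf("Category fractions must sum to 1 (got %.12f).", sum(fr)))
  }
  stopifnot(n_accessions >= 1, n_genes >= 1,
            coverage_noise >= 0, coverage_noise < 1,
            clade_split >= 0, clade_split <= 1,
            cds_fraction > 0, cds_fraction < 1)
  structure(list(
    n_accessions = as.integer(n_accessions), n_genes = as.integer(n_genes),
    frac_hardcore = frac_hardcore, frac_softcore = frac_softcore,
    frac_shell = frac_shell, frac_cloud = frac_cloud,
    coverage_noise = coverage_noise, clade_split = clade_split,
    clade_bias = clade_bias, clade_informative_frac = clade_informative_frac,
    n_seqs = as.integer(n_seqs), gene_length = as.integer(gene_length),
    cds_fraction = cds_fraction, intergenic_bp = as.integer(intergenic_bp),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Largest-remainder apportionment of n_genes into the four categories so the
# realized proportions match the config fractions exactly up to integrality.
category_counts <- function(config) {
  fr <- c(hardcore = config$frac_hardcore, softcore = config$frac_softcore,
          shell = config$frac_shell, cloud = config$frac_cloud)
  raw <- fr * config$n_genes
  base <- floor(raw)
  rem <- config$n_genes - sum(base)
  if (rem > 0) {
    up <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[up] <- base[up] + 1
  }
  as.integer(base)
}

#' Simulate a ground-truthed pan-genome
#'
#' Genes are assigned to categories deterministically by count (largest
#' remainder), then given a truth presence frequency: hardcore exactly 1.0,
#' softcore uniform on (0.955, 0.99), shell uniform on (0.06, 0.94), cloud
#' uniform on (max(1/n, 0.044 lower guard), 0.045). The guard margins keep
#' sampled frequencies inside their category bands at realistic accession
#' counts, so category recovery is sharp. Presence is sampled independently
#' Bernoulli per accession, except clade-informative shell genes whose
#' frequency differs between the two clades by `clade_bias`. Genes sampled
#' absent everywhere are resampled (a pan-genome gene exists in at least one
#' accession).
#'
#' @param config A [sim_config()].
#' @return A `simulated_pangenome` list: `genes` (gene-models tibble),
#'   `truth` (tibble `gene_id`, `category`, `truth_frequency`,
#'   `clade_informative`, `freq_clade1`, `freq_clade2`), `truth_matrix`
#'   ([pav_matrix()]), `clades` (tibble `accession_id`, `clade`), `config`.
#' @export
simulate_pangenome <- function(config = sim_config()) {
  with_local_seed(config$seed, {
    G <- config$n_genes
    N <- config$n_accessions
    counts <- category_counts(config)
    category <- rep(c("hardcore", "softcore", "shell", "cloud"), counts)

    freq <- numeric(G)
    freq[category == "hardcore"] <- 1
    freq[category == "softcore"] <- runif(counts[2], 0.955, 0.99)
    freq[category == "shell"] <- runif(counts[3], 0.06, 0.94)
    cloud_lo <- min(1 / N, 0.044)
    freq[category == "cloud"] <- runif(counts[4], cloud_lo, 0.045)

    n2 <- round(config$clade_split * N)
    clade <- rep(c("I", "II"), c(N - n2, n2))
    acc_ids <- sprintf("acc%03d", seq_len(N))

    shell_idx <- which(category == "shell")
    n_inf <- round(config$clade_informative_frac * length(shell_idx))
    informative <- logical(G)
    informative[shell_idx[seq_len(n_inf)]] <- TRUE
    f1 <- ifelse(informative, pmin(pmax(freq - config$clade_bias / 2, 0.01), 0.99),
                 freq)
    f2 <- ifelse(informative, pmin(pmax(freq + config$clade_bias / 2, 0.01), 0.99),
                 freq)

    p <- matrix(0, G, N)
    p[, clade == "I"] <- f1
    p[, clade == "II"] <- f2
    m <- matrix(as.integer(runif(G * N) < p), G, N)
    # Resample rows sampled absent everywhere.
    for (i in 1:100) {
      z <- which(rowSums(m) == 0L)
      if (length(z) == 0L) break
      m[z, ] <- matrix(as.integer(runif(length(z) * N) < p[z, , drop = FALSE]),
                       length(z), N)
    }
    z <- which(rowSums(m) == 0L)
    if (length(z) > 0L) m[z, which.max(colSums(p))] <- 1L

    gene_ids <- sprintf("g%06d", seq_len(G))
    genes <- layout_genes(gene_ids, config)
    truth_matrix <- pav_matrix(m, gene_ids = gene_ids, accession_ids = acc_ids)

    structure(list(
      genes = genes,
      truth = tibble(gene_id = gene_ids, category = category,
                     truth_frequency = freq, clade_informative = informative,
                     freq_clade1 = f1, freq_clade2 = f2),
      truth_matrix = truth_matrix,
      clades = tibble(accession_id = acc_ids, clade = clade),
      config = config
    ), class = "simulated_pangenome")
  })
}

# Place genes sequentially on n_seqs sequences with intergenic gaps; one
# centered CDS interval per gene.
layout_genes <- function(gene_ids, config) {
  G <- length(gene_ids)
  per_seq <- ceiling(G / config$n_seqs)
  seq_idx <- ((seq_len(G) - 1L) %/% per_seq) + 1L
  pos_idx <- ((seq_len(G) - 1L) %% per_seq)
  L <- config$gene_length
  gap <- config$intergenic_bp
  start <- gap + pos_idx * (L + gap)
  cds_len <- max(3L, as.integer(round(config$cds_fraction * L)))
  cds_off <- as.integer((L - cds_len) %/% 2L)
  tibble(
    gene_id = gene_ids,
    seq_id = sprintf("chr%02d", seq_idx),
    strand = "+",
    start = as.integer(start),
    end = as.integer(start + L),
    cds = purrr::map(start, ~ tibble(start = as.integer(.x + cds_off),
                                     end = as.integer(.x + cds_off + cds_len)))
  )
}

#' Simulate breadth-of-coverage evidence
#'
#' For each gene x accession pair, draws a gene-body and a CDS covered
#' fraction from the regime matching the truth matrix — present: body >= 0.9,
#' CDS >= 0.97; absent: body <= 0.4, CDS <= 0.5 — and realizes them as covered
#' intervals inside the gene (CDS prefix first, then flanks). With probability
#' `coverage_noise` a pair is drawn from the opposite regime, so downstream
#' presence calls err at exactly that expected rate; with zero noise the
#' called matrix reproduces the truth matrix exactly.
#'
#' @param sim A [simulate_pangenome()] result.
#' @param coverage_noise Mislabel-injection probability; defaults to the
#'   value in `sim$config`.
#' @param accessions Accession ids to simulate (default all).
#' @param seed Optional seed (default: continue the current RNG stream).
#' @return Coverage tibble `accession_id`, `seq_id`, `start`, `end`.
#' @export
simulate_coverage <- function(sim, coverage_noise = sim$config$coverage_noise,
                              accessions = colnames(sim$truth_matrix),
                              seed = NULL) {
  with_local_seed(seed, {
    genes <- sim$genes
    m <- unclass(sim$truth_matrix)[, accessions, drop = FALSE]
    G <- nrow(m); N <- ncol(m)
    cds_start <- purrr::map_int(genes$cds, ~ .x$start[1])
    cds_end <- purrr::map_int(genes$cds, ~ .x$end[1])
    L <- genes$end - genes$start
    C <- cds_end - cds_start

    present <- as.logical(m)
    flip <- runif(G * N) < coverage_noise
    regime <- xor(present, flip)
    fb <- ifelse(regime, runif(G * N, 0.90, 1), runif(G * N, 0, 0.40))
    fc <- ifelse(regime, runif(G * N, 0.97, 1), runif(G * N, 0, 0.50))

    Lv <- rep(L, times = N); Cv <- rep(C, times = N)
    startv <- rep(genes$start, times = N)
    cds_sv <- rep(cds_start, times = N); cds_ev <- rep(cds_end, times = N)
    seqv <- rep(genes$seq_id, times = N)
    accv <- rep(accessions, each = G)

    m_c <- round(fc * Cv)
    m_f <- pmax(0, round(fb * Lv) - m_c)
    left_len <- cds_sv - startv
    left_cov <- pmin(m_f, left_len)
    right_cov <- pmin(pmax(m_f - left_len, 0), Lv - Cv - left_len)

    out <- tibble(
      accession_id = rep(accv, 3),
      seq_id = rep(seqv, 3),
      start = c(cds_sv, startv, cds_ev),
      end = c(cds_sv + m_c, startv + left_cov, cds_ev + right_cov)
    )
    out <- out[out$end > out$start, , drop = FALSE]
    out %>% arrange(.data$accession_id, .data$seq_id, .data$start)
  })
}

#' Simulate long-read structural-variant calls for one accession
#'
#' Every gene absent from the accession yields a deletion interval spanning
#' its gene body with endpoints jittered by up to `jitter_bp`, and omitted
#' with probability `dropout` (long-read calling misses a fraction of true
#' deletions; the default 0.057 yields a deletion support rate of about
#' 94.3%). Insertions are built from `novel_sequences` (point-mutated at
#' `mutation_rate`) or generated at random.
#'
#' @param sim A [simulate_pangenome()] result.
#' @param accession_id One accession present in the truth matrix.
#' @param jitter_bp Maximum breakpoint jitter in bp (default 50).
#' @param dropout Probability a true deletion is missing from the call set.
#' @param novel_sequences Optional tibble (`name`, `sequence`) used as
#'   insertion sequences after mutation.
#' @param n_insertions Number of random insertions when `novel_sequences` is
#'   `NULL`.
#' @param mutation_rate Per-base substitution rate applied to insertion
#'   sequences.
#' @param seed Optional seed.
#' @return An `sv_call_set` list with tibbles `deletions` (`accession_id`,
#'   `seq_id`, `start`, `end`, `length`) and `insertions` (`accession_id`,
#'   `seq_id`, `pos`, `length`, `sequence`).
#' @export
simulate_sv_calls <- function(sim, accession_id, jitter_bp = 50L,
                              dropout = 0.057, novel_sequences = NULL,
                              n_insertions = 5L, mutation_rate = 0.01,
                              seed = NULL) {
  if (!accession_id %in% colnames(sim$truth_matrix)) {
    abort(sprintf("Unknown accession '%s'.", accession_id))
  }
  with_local_seed(seed, {
    absent <- sim$genes[unclass(sim$truth_matrix)[, accession_id] == 0L, ,
                        drop = FALSE]
    keep <- runif(nrow(absent)) >= dropout
    absent <- absent[keep, , drop = FALSE]
    j1 <- if (jitter_bp > 0) sample(-jitter_bp:jitter_bp, nrow(absent), TRUE)
          else integer(nrow(absent))
    j2 <- if (jitter_bp > 0) sample(-jitter_bp:jitter_bp, nrow(absent), TRUE)
          else integer(nrow(absent))
    dstart <- pmax(0L, absent$start + j1)
    dend <- pmax(dstart + 1L, absent$end + j2)
    deletions <- tibble(accession_id = accession_id, seq_id = absent$seq_id,
                        start = dstart, end = dend, length = dend - dstart)

    if (is.null(novel_sequences)) {
      novel_sequences <- tibble(
        name = sprintf("ins%03d", seq_len(n_insertions)),
        sequence = purrr::map_chr(seq_len(n_insertions), ~ random_dna(500L))
      )
    }
    ins_seq <- purrr::map_chr(novel_sequences$sequence, mutate_dna,
                              rate = mutation_rate)
    insertions <- tibble(
      accession_id = accession_id,
      seq_id = novel_sequences$name,
      pos = 0L,
      length = nchar(ins_seq),
      sequence = ins_seq
    )
    structure(list(deletions = deletions, insertions = insertions),
              class = "sv_call_set")
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    subs <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    chars[hit] <- subs
  }
  paste(chars, collapse = "")
}

#' Simulate an SNP distance matrix correlated with PAV distances
#'
#' Returns `mixing * D_pav + (1 - mixing) * noise`, where `D_pav` is the
#' simple-matching PAV distance of the truth matrix and `noise` is a random
#' symmetric zero-diagonal matrix rescaled to the spread of `D_pav`. The
#' Mantel correlation between the result and `D_pav` increases monotonically
#' with `mixing` (1 at `mixing = 1`, near 0 at `mixing = 0`).
#'
#' @param sim A [simulate_pangenome()] result (or a [pav_matrix()]).
#' @param mixing Mixing weight in `[0, 1]` (default 0.6).
#' @param seed Optional seed for the noise matrix.
#' @return A symmetric numeric distance matrix with accession labels.
#' @export
simulate_snp_distance <- function(sim, mixing = 0.6, seed = NULL) {
  stopifnot(mixing >= 0, mixing <= 1)
  m <- if (inherits(sim, "simulated_pangenome")) sim$truth_matrix
       else as_pav_matrix(sim)
  d_pav <- pav_distance(m)
  with_local_seed(seed, {
    n <- ncol(m)
    a <- matrix(runif(n * n), n, n)
    noise <- (a + t(a)) / 2
    diag(noise) <- 0
    off <- upper.tri(noise)
    scale <- stats::sd(d_pav[off]) / stats::sd(noise[off])
    noise <- noise * scale
    out <- mixing * d_pav + (1 - mixing) * noise
    out <- (out + t(out)) / 2
    diag(out) <- 0
    dimnames(out) <- dimnames(d_pav)
    out
  })
}

#' Calibrate the SNP-distance mixing weight to a target Mantel correlation
#'
#' Bisection on `mixing` against the Mantel statistic between the simulated
#' SNP distances and the PAV distances, using one fixed noise realization
#' (so the response is deterministic and monotone).
#'
#' @param sim A [simulate_pangenome()] result.
#' @param target_r Target Mantel correlation.
#' @param seed Seed for the noise realization.
#' @param tol Bisection tolerance on the correlation.
#' @return The calibrated mixing weight (scalar).
#' @export
calibrate_snp_mixing <- function(sim, target_r = 0.49, seed = 1L,
                                 tol = 0.005) {
  d_pav <- pav_distance(sim$truth_matrix)
  off <- upper.tri(d_pav)
  r_of <- function(mix) {
    d_snp <- simulate_snp_distance(sim, mixing = mix, seed = seed)
    stats::cor(d_pav[off], d_snp[off])
  }
  lo <- 0; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    r <- r_of(mid)
    if (abs(r - target_r) < tol) return(mid)
    if (r < target_r) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
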