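test_that("a deletion spanning the gene supports its absence", {
  absent <- tibble::tibble(accession_id = "a1", gene_id = "g1",
                           seq_id = "chr3", start = 1000L, end = 4000L)
  spanning <- tibble::tibble(accession_id = "a1", seq_id = "chr3",
                             start = 500L, end = 7300L)  # contains the gene
  res <- deletion_support(absent, spanning)
  expect_true(res$per_gene$supported)
  expect_equal(res$pooled_rate, 1)

  none <- deletion_support(absent, spanning[0, ])
  expect_false(none$per_gene$supported)
  expect_equal(none$pooled_rate, 0)
})

test_that("overlap flags equal a brute-force all-pairs scan", {
  set.seed(14)
  absent <- tibble::tibble(
    accession_id = "a1", gene_id = sprintf("g%02d", 1:30),
    seq_id = sample(c("c1", "c2"), 30, TRUE),
    start = sample(0:5000, 30))
  absent$end <- absent$start + sample(100:500, 30, TRUE)
  dels <- tibble::tibble(
    accession_id = "a1",
    seq_id = sample(c("c1", "c2"), 15, TRUE),
    start = sample(0:5000, 15))
  dels$end <- dels$start + sample(50:2000, 15, TRUE)

  for (minov in c(1L, 50L, 200L)) {
    res <- deletion_support(absent, dels, min_overlap_bp = minov)
    oracle <- vapply(seq_len(nrow(absent)), function(i) {
      any(vapply(seq_len(nrow(dels)), function(j) {
        dels$seq_id[j] == absent$seq_id[i] &&
          min(dels$end[j], absent$end[i]) -
            max(dels$start[j], absent$start[i]) >= minov
      }, logical(1)))
    }, logical(1))
    expect_equal(res$per_gene$supported, oracle)
  }
})

test_that("support rate never rises as the overlap threshold grows", {
  set.seed(15)
  absent <- tibble::tibble(
    accession_id = "a1", gene_id = sprintf("g%02d", 1:40),
    seq_id = "c1", start = sample(0:20000, 40))
  absent$end <- absent$start + 300L
  dels <- tibble::tibble(accession_id = "a1", seq_id = "c1",
                         start = sample(0:20000, 25))
  dels$end <- dels$start + sample(100:1000, 25, TRUE)
  rates <- vapply(c(1L, 10L, 100L, 250L), function(mo) {
    deletion_support(absent, dels, min_overlap_bp = mo)$pooled_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("deletions across accessions never support each other's genes", {
  absent <- tibble::tibble(accession_id = c("a1", "a2"),
                           gene_id = c("g1", "g1"), seq_id = "c1",
                           start = 100L, end = 200L)
  dels <- tibble::tibble(accession_id = "a1", seq_id = "c1",
                         start = 0L, end = 500L)
  res <- deletion_support(absent, dels)
  expect_equal(res$per_gene$supported, c(TRUE, FALSE))
  pa <- res$per_accession
  expect_equal(pa$support_rate[pa$accession_id == "a1"], 1)
  expect_equal(pa$support_rate[pa$accession_id == "a2"], 0)
})

test_that("noise-free simulation yields a support rate of exactly 1", {
  sim <- simulate_pangenome(sim_config(
    n_accessions = 8, n_genes = 150, frac_hardcore = 0.5, frac_softcore = 0,
    frac_shell = 0.5, frac_cloud = 0, seed = 19))
  ag <- absent_gene_intervals(sim$truth_matrix, sim$genes, "acc002")
  sv <- simulate_sv_calls(sim, "acc002", jitter_bp = 40, dropout = 0,
                          seed = 20)
  res <- deletion_support(ag, sv$deletions)
  expect_equal(res$pooled_rate, 1.0)
})

test_that("novel substrings of insertions are recovered, noise is not", {
  set.seed(41)
  ins <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  novel <- tibble::tibble(
    name = c("hit", "miss"),
    sequence = c(substr(ins, 501, 1500),
                 paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                       collapse = "")))
  res <- insertion_recovery(novel, ins, k = 31)
  per <- res$per_sequence
  expect_equal(per$containment[per$name == "hit"], 1.0)
  expect_true(per$recovered[per$name == "hit"])
  expect_lt(per$containment[per$name == "miss"], 0.05)
  expect_false(per$recovered[per$name == "miss"])
  expect_equal(res$recovered_bp_fraction, 0.5)
})

test_that("recovery is invariant to the strand of the insertion", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  novel <- tibble::tibble(name = "n1", sequence = substr(s, 101, 500))
  fwd <- insertion_recovery(novel, s, k = 31)
  rev <- insertion_recovery(novel, rc, k = 31)
  expect_equal(fwd$per_sequence$containment, rev$per_sequence$containment)
  expect_true(rev$per_sequence$recovered)
})

test_that("short novel sequences fall back to substring search", {
  ins <- "ACGTACGTACGTACGTACGTACGT"
  novel <- tibble::tibble(name = c("sub", "abs"),
                          sequence = c("GTACGTACG", "TTTTTTTTT"))
  res <- insertion_recovery(novel, ins, k = 31)
  expect_equal(res$per_sequence$recovered, c(TRUE, FALSE))
})

test_that("mutated insertions still recover most novel sequence at k = 31", {
  sim <- simulate_pangenome(sim_config(n_accessions = 5, n_genes = 40,
                                       seed = 29))
  set.seed(30)
  novel <- tibble::tibble(
    name = sprintf("nov%02d", 1:12),
    sequence = replicate(12, paste(sample(c("A", "C", "G", "T"), 1500, TRUE),
                                   collapse = "")))
  sv <- simulate_sv_calls(sim, "acc001", novel_sequences = novel,
                          mutation_rate = 0.01, seed = 31)
  res <- insertion_recovery(novel, sv$insertions, k = 31,
                            min_containment = 0.5)
  expect_gte(res$recovered_bp_fraction, 0.95)
})
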