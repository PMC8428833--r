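mk_summary <- function(contig_id, length, intervals = NULL) {
  if (is.null(intervals)) {
    tibble::tibble(contig_id = contig_id, length = length,
                   aln_start = NA_integer_, aln_end = NA_integer_)
  } else {
    tibble::tibble(contig_id = contig_id, length = length,
                   aln_start = intervals[, 1], aln_end = intervals[, 2])
  }
}

test_that("contig classification follows the 500/450 bp rules", {
  s <- dplyr::bind_rows(
    mk_summary("short", 400L),
    mk_summary("full", 1000L),
    mk_summary("partial", 1000L, cbind(0L, 400L)),
    mk_summary("resid", 1000L, cbind(0L, 600L)),       # residual 400 <= 450
    mk_summary("edge", 951L, cbind(0L, 500L))          # residual 451 > 450
  )
  cl <- classify_contigs(s)
  got <- setNames(cl$class, cl$contig_id)
  expect_equal(got[["short"]], "too_short")
  expect_equal(got[["full"]], "fully_unaligned")
  expect_equal(got[["partial"]], "partially_unaligned")
  expect_equal(got[["resid"]], "aligned")
  expect_equal(got[["edge"]], "partially_unaligned")

  frag <- cl$fragments[[which(cl$contig_id == "full")]]
  expect_equal(frag, tibble::tibble(start = 0L, end = 1000L))
  frag_p <- cl$fragments[[which(cl$contig_id == "partial")]]
  expect_equal(frag_p$start, 400L)
  expect_equal(frag_p$end, 1000L)

  # Exactly one label per contig, fragments all strictly > 450 bp.
  expect_equal(nrow(cl), 5L)
  lens <- unlist(lapply(cl$fragments, function(f) f$end - f$start))
  expect_true(all(lens > 450L))
})

test_that("overlapping aligned intervals are merged with a warning", {
  s <- mk_summary("ovl", 2000L, cbind(c(0L, 300L), c(500L, 800L)))
  expect_warning(cl <- classify_contigs(s), "merged")
  expect_equal(cl$class, "partially_unaligned")
  expect_equal(cl$fragments[[1]]$start, 800L)
  expect_equal(cl$fragments[[1]]$end, 2000L)
})

test_that("fragment excision slices the contig exactly", {
  seq <- paste(rep(c("ACGT"), 25), collapse = "")  # 100 bp
  whole <- excise_fragments(seq, tibble::tibble(start = 0L, end = 100L), "c1")
  expect_equal(whole$sequence, seq)
  expect_equal(whole$name, "c1:0-100")

  none <- excise_fragments(seq, tibble::tibble(start = integer(),
                                               end = integer()), "c1")
  expect_equal(nrow(none), 0L)

  two <- excise_fragments(seq, tibble::tibble(start = c(0L, 50L),
                                              end = c(10L, 60L)), "c1")
  expect_equal(two$sequence, c(substr(seq, 1, 10), substr(seq, 51, 60)))

  expect_error(excise_fragments(seq, tibble::tibble(start = 90L, end = 110L)),
               "out of bounds")
})

test_that("redundancy clustering merges near-identical sequences only", {
  set.seed(123)
  base <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  mutate_at_rate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                      character(1))
    paste(ch, collapse = "")
  }

  s1 <- base(1000)
  s2 <- mutate_at_rate(s1, 0.05)   # ~95% identical to s1
  s3 <- base(1000)                 # unrelated
  seqs <- tibble::tibble(name = c("s1", "s2", "s3"),
                         sequence = c(s1, s2, s3))
  res <- remove_redundancy(seqs, identity_threshold = 0.90)
  expect_equal(sort(res$representatives$name), c("s1", "s3"))
  expect_equal(res$membership$representative[res$membership$name == "s2"],
               "s1")
  # Union of clusters is the input set.
  expect_setequal(res$membership$name, seqs$name)

  two_same <- tibble::tibble(name = c("a", "b"), sequence = c(s1, s1))
  res2 <- remove_redundancy(two_same)
  expect_equal(nrow(res2$representatives), 1L)

  unrelated <- tibble::tibble(name = c("u1", "u2"),
                              sequence = c(base(1000), base(1000)))
  expect_equal(nrow(remove_redundancy(unrelated)$representatives), 2L)
})

test_that("greedy clusters match a brute-force all-pairs oracle", {
  set.seed(7)
  base <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  mutate_at_rate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                      character(1))
    paste(ch, collapse = "")
  }
  roots <- replicate(4, base(600))
  seqs <- tibble::tibble(
    name = sprintf("q%02d", 1:10),
    sequence = c(roots,
                 vapply(roots[1:3], mutate_at_rate, character(1), rate = 0.05),
                 vapply(roots[1:3], mutate_at_rate, character(1), rate = 0.04))
  )
  res <- remove_redundancy(seqs, identity_threshold = 0.90)

  # Oracle: pairwise identity matrix by local alignment, then the same greedy
  # longest-first scan done independently.
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  ident <- function(x, y) {
    aln <- Biostrings::pairwiseAlignment(x, y, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 4, gapExtension = 2)
    Biostrings::nmatch(aln) / min(nchar(x), nchar(y))
  }
  ord <- order(-nchar(seqs$sequence), seqs$name)
  reps <- integer(); member <- character(nrow(seqs))
  for (i in ord) {
    hit <- FALSE
    for (r in reps) {
      if (ident(seqs$sequence[i], seqs$sequence[r]) >= 0.90) {
        member[i] <- seqs$name[r]; hit <- TRUE; break
      }
    }
    if (!hit) { reps <- c(reps, i); member[i] <- seqs$name[i] }
  }
  oracle <- tibble::tibble(name = seqs$name, representative = member)
  got <- res$membership[match(seqs$name, res$membership$name), ]
  expect_equal(got$representative, oracle$representative)
})

test_that("contaminant filtering keeps nuclear-plant and hitless contigs", {
  ids <- c("c1", "c2", "c3", "c4")
  hits <- tibble::tibble(
    contig_id = c("c2", "c2", "c3", "c4", "c4"),
    subject_taxon_class = c("organellar", "viridiplantae_nuclear",
                            "viridiplantae_nuclear", "microbial",
                            "non_viridiplantae"),
    e_value = c(1e-50, 1e-10, 1e-20, 1e-5, 1e-8),
    identity = c(0.99, 0.95, 0.97, 0.88, 0.92)
  )
  res <- filter_contaminants(ids, hits)
  expect_true(res$retained[res$contig_id == "c1"])   # no hits
  expect_false(res$retained[res$contig_id == "c2"])  # organellar best
  expect_true(res$retained[res$contig_id == "c3"])
  expect_false(res$retained[res$contig_id == "c4"])  # non_viridiplantae best

  # Oracle: per-contig argmin scan.
  for (cid in c("c2", "c3", "c4")) {
    h <- hits[hits$contig_id == cid, ]
    best <- h$subject_taxon_class[which.min(h$e_value)]
    expect_equal(res$retained[res$contig_id == cid],
                 best == "viridiplantae_nuclear")
  }

  all_kept <- filter_contaminants(ids, hits[0, ])
  expect_true(all(all_kept$retained))
})

test_that("accumulation curves are exact for N = 4 and order-independent at N", {
  novel <- tibble::tibble(
    accession_id = c("a1", "a1", "a2", "a2", "a3", "a4"),
    rep_id = c("r1", "r2", "r2", "r3", "r1", "r4"),
    length = c(100L, 200L, 200L, 300L, 100L, 50L)
  )
  cur <- accumulation_curve(novel, step = 1, exhaustive = TRUE)

  # Oracle: exhaustive enumeration over all 4! accession orders.
  accs <- c("a1", "a2", "a3", "a4")
  sets <- split(novel[, c("rep_id", "length")], novel$accession_id)
  perms <- expand.grid(1:4, 1:4, 1:4, 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  cum_all <- t(apply(perms, 1, function(p) {
    seen <- character(); out <- numeric(4)
    for (i in 1:4) {
      s <- sets[[accs[p[i]]]]
      seen <- union(seen, s$rep_id)
      lens <- unique(novel[novel$rep_id %in% seen, c("rep_id", "length")])
      out[i] <- sum(lens$length)
    }
    out
  }))
  expect_equal(cur$mean_bp, colMeans(cum_all))
  expect_equal(cur$min_bp, apply(cum_all, 2, min))
  expect_equal(cur$max_bp, apply(cum_all, 2, max))
  # Final value is the total union length for every order.
  expect_equal(cur$min_bp[4], cur$max_bp[4])
  expect_equal(cur$mean_bp[4], 100 + 200 + 300 + 50)

  single <- accumulation_curve(
    tibble::tibble(accession_id = "only", rep_id = c("r1", "r2"),
                   length = c(10L, 20L)), step = 20, n_orders = 3, seed = 1)
  expect_equal(single$size, 1L)
  expect_equal(single$mean_bp, 30)

  disjoint <- tibble::tibble(
    accession_id = rep(c("a1", "a2", "a3"), each = 1),
    rep_id = c("x1", "x2", "x3"), length = c(100L, 100L, 100L))
  lin <- accumulation_curve(disjoint, step = 1, n_orders = 10, seed = 3)
  expect_equal(lin$mean_bp, c(100, 200, 300))
})
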