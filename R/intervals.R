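# Internal interval helpers. All package-internal coordinates are 0-based
# half-open [start, end); IRanges (1-based closed) only at the boundary of
# each helper. External GFF3/depth coordinates are converted on read/write.

ir0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

ir0_to_tbl <- function(ir) {
  tibble::tibble(
    start = IRanges::start(ir) - 1L,
    end   = IRanges::end(ir)
  )
}

# Merge a set of 0-based half-open intervals (single coordinate space) into
# maximal disjoint sorted intervals. Adjacent intervals are fused.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  ir0_to_tbl(IRanges::reduce(ir0(start, end)))
}

# Total width of the union of 0-based half-open intervals.
union_width <- function(start, end) {
  if (length(start) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(ir0(start, end))))
}

# Complement of intervals within [0, len): the unaligned fragments of a contig.
complement_intervals <- function(start, end, len) {
  if (length(start) == 0L) {
    return(tibble::tibble(start = 0L, end = as.integer(len)))
  }
  gaps <- IRanges::gaps(IRanges::reduce(ir0(start, end)),
                        start = 1L, end = as.integer(len))
  ir0_to_tbl(gaps)
}

# Overlap width between each region (grouped by `group`) and the union of a
# cover, per seq_id. `regions`: tibble(group, seq_id, start, end);
# `cover`: tibble(seq_id, start, end). Returns tibble(group, covered_bp).
# Regions belonging to one group may span several intervals (e.g. CDS parts).
regions_covered_bp <- function(regions, cover) {
  if (nrow(regions) == 0L) {
    return(tibble::tibble(group = character(), covered_bp = integer()))
  }
  out <- numeric(nrow(regions))
  for (sid in unique(regions$seq_id)) {
    ri <- which(regions$seq_id == sid)
    cv <- cover[cover$seq_id == sid, , drop = FALSE]
    if (nrow(cv) == 0L) next
    reg_ir <- ir0(regions$start[ri], regions$end[ri])
    cov_ir <- IRanges::reduce(ir0(cv$start, cv$end))
    hits <- IRanges::findOverlaps(reg_ir, cov_ir)
    if (length(hits) == 0L) next
    w <- IRanges::width(IRanges::pintersect(
      reg_ir[S4Vectors::queryHits(hits)],
      cov_ir[S4Vectors::subjectHits(hits)]
    ))
    out[ri] <- out[ri] + as.numeric(rowsum_safe(w, S4Vectors::queryHits(hits),
                                                length(ri)))
  }
  regions %>%
    mutate(.covered = out) %>%
    group_by(group = .data$group) %>%
    summarise(covered_bp = sum(.data$.covered), .groups = "drop")
}

rowsum_safe <- function(x, index, n) {
  v <- numeric(n)
  agg <- rowsum(x, index)
  v[as.integer(rownames(agg))] <- agg[, 1]
  v
}
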