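#' Read gene models from a GFF3 annotation
#'
#' Parses `gene` and `CDS` features and links them through the `ID`/`Parent`
#' attribute chain (CDS may be attached to the gene directly or through an
#' mRNA/transcript feature). GFF3 coordinates are 1-based inclusive; all
#' returned coordinates are 0-based half-open, the convention used throughout
#' the package. CDS intervals of a gene are unioned (overlapping transcript
#' isoforms collapse to one interval set).
#'
#' CDS records falling outside their parent gene are dropped with a warning;
#' genes that end up with no CDS are excluded with a warning, since the
#' presence rule needs both a gene-body and a CDS region.
#'
#' @param path Path to a GFF3 file.
#' @return A *gene models* tibble with columns `gene_id`, `seq_id`, `strand`,
#'   `start`, `end` (gene body, 0-based half-open) and `cds`, a list-column of
#'   tibbles (`start`, `end`) holding the per-gene unioned CDS intervals.
#' @seealso [build_pav_matrix()], which consumes gene models.
#' @export
read_gff3 <- function(path) {
  empty <- tibble(
    gene_id = character(), seq_id = character(), strand = character(),
    start = integer(), end = integer(), cds = list()
  )
  lines <- readr::read_lines(path, progress = FALSE)
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) return(empty)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  md$ID <- as.character(md$ID)
  parent1 <- vapply(md$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  id2type <- setNames(as.character(md$type), md$ID)
  id2parent <- setNames(parent1, md$ID)

  genes <- md[md$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) return(empty)

  # Resolve each CDS to its ancestral gene (at most a few hops).
  cds <- md[md$type == "CDS", , drop = FALSE]
  resolve_gene <- function(pid) {
    for (i in 1:5) {
      if (is.na(pid) || is.na(id2type[pid])) return(NA_character_)
      if (id2type[pid] == "gene") return(pid)
      pid <- id2parent[pid]
    }
    NA_character_
  }
  cds$gene_id <- vapply(parent1[md$type == "CDS"], resolve_gene, character(1))

  gene_tbl <- tibble(
    gene_id = genes$ID,
    seq_id = as.character(genes$seqnames),
    strand = as.character(genes$strand),
    start = genes$start - 1L,   # 1-based inclusive -> 0-based half-open
    end = genes$end
  )

  cds_tbl <- tibble(
    gene_id = cds$gene_id,
    seq_id = as.character(cds$seqnames),
    start = cds$start - 1L,
    end = cds$end
  )
  # Reject CDS outside the parent gene body.
  cds_tbl <- left_join(cds_tbl, gene_tbl,
                       by = c("gene_id", "seq_id"), suffix = c("", ".gene"))
  outside <- is.na(cds_tbl$start.gene) |
    cds_tbl$start < cds_tbl$start.gene | cds_tbl$end > cds_tbl$end.gene
  if (any(outside)) {
    warn(sprintf("%d CDS record(s) outside their parent gene were dropped.",
                 sum(outside)))
    cds_tbl <- cds_tbl[!outside, , drop = FALSE]
  }
  cds_by_gene <- cds_tbl %>%
    group_by(.data$gene_id) %>%
    summarise(cds = list(merge_intervals(.data$start, .data$end)),
              .groups = "drop")

  out <- left_join(gene_tbl, cds_by_gene, by = "gene_id")
  no_cds <- vapply(out$cds, is.null, logical(1))
  if (any(no_cds)) {
    warn(sprintf("%d gene(s) without CDS were excluded: %s",
                 sum(no_cds),
                 paste(utils::head(out$gene_id[no_cds], 5), collapse = ", ")))
    out <- out[!no_cds, , drop = FALSE]
  }
  out
}

#' Read a per-base depth table into a coverage profile
#'
#' Consumes `samtools depth`-style text: three tab-separated columns
#' (`seq_id`, 1-based position, depth), position-sorted within each sequence.
#' Positions with depth at or above `depth_min` are merged into maximal
#' intervals — the breadth-of-coverage evidence behind the presence rule.
#'
#' @param path Path to the depth table (no header).
#' @param accession_id Accession label to attach to the profile.
#' @param depth_min Minimum read depth for a position to count as covered.
#'   Defaults to 1: presence evidence is breadth of coverage at any depth.
#' @return A *coverage profile* tibble: `accession_id`, `seq_id`, `start`,
#'   `end` (0-based half-open covered intervals, sorted and disjoint), with
#'   the depth threshold in attribute `depth_min`.
#' @export
read_depth_table <- function(path, accession_id = basename(path),
                             depth_min = 1L) {
  stopifnot(depth_min >= 1L)
  tb <- readr::read_tsv(path,
                        col_names = c("seq_id", "pos", "depth"),
                        col_types = "cii", progress = FALSE)
  if (nrow(tb) > 1L) {
    same <- tb$seq_id[-1] == tb$seq_id[-nrow(tb)]
    bad <- which(same & tb$pos[-1] <= tb$pos[-nrow(tb)])
    if (length(bad) > 0L) {
      abort(sprintf(
        "Depth table not position-sorted: line %d (%s:%d) follows %s:%d.",
        bad[1] + 1L, tb$seq_id[bad[1] + 1L], tb$pos[bad[1] + 1L],
        tb$seq_id[bad[1]], tb$pos[bad[1]]))
    }
  }
  tb <- tb[tb$depth >= depth_min, , drop = FALSE]
  prof <- tb %>%
    group_by(.data$seq_id) %>%
    dplyr::reframe(merge_intervals(.data$pos - 1L, .data$pos)) %>%
    mutate(accession_id = accession_id, .before = 1)
  attr(prof, "depth_min") <- as.integer(depth_min)
  prof
}

#' Read and write deletion calls as BED
#'
#' Deletions are exchanged as three-column BED (`seq_id`, `start`, `end`,
#' 0-based half-open), the natural interchange for structural-variant
#' intervals called from long reads.
#'
#' @param path File path.
#' @param accession_id Accession label to attach.
#' @param deletions Tibble with columns `seq_id`, `start`, `end`.
#' @return `read_deletions_bed()` returns a tibble `accession_id`, `seq_id`,
#'   `start`, `end`, `length`.
#' @export
read_deletions_bed <- function(path, accession_id = basename(path)) {
  tb <- readr::read_tsv(path, col_names = c("seq_id", "start", "end"),
                        col_types = "cii", progress = FALSE)
  tibble(accession_id = accession_id, seq_id = tb$seq_id,
         start = tb$start, end = tb$end, length = tb$end - tb$start)
}

#' @rdname read_deletions_bed
#' @export
write_deletions_bed <- function(deletions, path) {
  readr::write_tsv(deletions[, c("seq_id", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write square labelled distance matrices
#'
#' Tab-separated dialect: header row of labels, first column of the same
#' labels, numeric cells. Used for PAV and SNP distance matrices.
#'
#' @param path File path.
#' @param d A square numeric matrix with identical row and column names.
#' @return `read_distance_matrix()` returns a numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(), readr::col_character()
  ), progress = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- as.character(tb[[1]])
  if (!identical(rownames(m), colnames(m))) {
    abort("Distance matrix row labels do not match column labels.")
  }
  m
}

#' @rdname read_distance_matrix
#' @export
write_distance_matrix <- function(d, path) {
  tb <- dplyr::bind_cols(tibble(label = rownames(d)),
                         tibble::as_tibble(d, .name_repair = "minimal"))
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Read/write FASTA as a tibble of sequences
#'
#' Thin tabular veneer over [Biostrings::readDNAStringSet()] so sequence sets
#' flow through the pipeline as data frames.
#'
#' @param path File path.
#' @param sequences Tibble with columns `name`, `sequence`.
#' @return `read_fasta_tbl()` returns a tibble `name`, `sequence`, `length`.
#' @export
read_fasta_tbl <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(name = names(ss), sequence = unname(as.character(ss)),
         length = Biostrings::width(ss))
}

#' @rdname read_fasta_tbl
#' @export
write_fasta_tbl <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences$sequence)
  names(ss) <- sequences$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
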