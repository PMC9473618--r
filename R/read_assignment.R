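#' Minimal deterministic read assigner
#'
#' Enumerates candidate locations by exact k-mer seeding (tiled seed
#' offsets, both strands), scores ungapped full-length extension (+1 match,
#' -2 mismatch), and reports the single best location per read as its
#' primary record. `n_cooptimal` counts locations with the best score;
#' `is_unique` is `TRUE` when the best score exceeds the second best by more
#' than `margin`. Ties are broken deterministically by (reference name,
#' start, strand) lexicographic order. Reads shorter than `k` are skipped and
#' tallied; reads whose best placement has more than `max_mismatches`
#' mismatches (or more than `max_mismatch_frac` of their length) are dropped
#' as unmapped and tallied.
#'
#' @param reads character vector of read sequences, or a `read_set`
#'   (both mates aligned, `mate` column set)
#' @param references named character vector of reference sequences
#' @param k exact seed length
#' @param max_mismatches maximum mismatches at the best placement (-1 for
#'   unlimited)
#' @param max_mismatch_frac maximum mismatch fraction of the read length
#' @param margin score margin for uniqueness
#' @param read_ids optional read identifiers (defaults to indices)
#' @param mate optional mate numbers (1 or 2) per read
#' @return data.frame of alignment records with columns `read_id`, `mate`,
#'   `ref`, `start`, `end` (0-based half-open), `strand`, `score`,
#'   `n_cooptimal`, `mismatches`, `is_primary`, `is_unique`; attributes
#'   `n_skipped`, `n_unmapped`, `n_input`
#' @export
align_minimal <- function(reads, references, k = 20L, max_mismatches = 5L,
                          max_mismatch_frac = 1.0, margin = 0L,
                          read_ids = NULL, mate = NULL) {
  if (inherits(reads, "read_set")) {
    rs <- reads
    n <- length(rs$r1)
    reads <- c(rs$r1, rs$r2)
    read_ids <- c(rs$id, rs$id)
    mate <- rep(c(1L, 2L), each = n)
  }
  if (length(references) == 0) stopf("references must be non-empty")
  if (is.null(names(references))) stopf("references must be named")
  references <- references[order(names(references))]
  if (is.null(read_ids)) read_ids <- as.character(seq_along(reads))
  if (is.null(mate)) mate <- rep(1L, length(reads))

  res <- cpp_align(as.character(reads), as.character(references),
                   as.integer(k), as.integer(max_mismatches),
                   as.numeric(max_mismatch_frac), as.integer(margin))
  out <- data.frame(
    read_id = read_ids[res$read_idx],
    mate = mate[res$read_idx],
    ref = names(references)[res$ref_idx],
    start = res$start, end = res$end,
    strand = ifelse(res$strand == 0L, "+", "-"),
    score = res$score, n_cooptimal = res$n_cooptimal,
    mismatches = res$mismatches,
    is_primary = rep(TRUE, length(res$start)),
    is_unique = res$is_unique == 1L,
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- res$n_skipped
  attr(out, "n_unmapped") <- res$n_unmapped
  attr(out, "n_input") <- length(reads)
  out
}

#' Write alignment records as minimal plain SAM
#'
#' Mandatory fields only; MAPQ is written as 30 for unique records and 0
#' otherwise, CIGAR as full-length match, SEQ/QUAL as `*`.
#' @param alignments alignment record data.frame (as from [align_minimal()])
#' @param ref_lengths named integer vector of reference lengths
#' @param path output SAM path
#' @export
write_sam <- function(alignments, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  a <- alignments
  flag <- ifelse(a$strand == "-", 16L, 0L)
  if (!is.null(a$mate))
    flag <- flag + 1L + ifelse(a$mate == 2L, 128L, 64L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                 a$read_id, flag, a$ref, a$start + 1L,
                 ifelse(a$is_unique, 30L, 0L), a$end - a$start)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

# reference-consumed length of a CIGAR string
cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    m <- gregexpr("(\\d+)([MIDNSHP=X])", cg)[[1]]
    if (m[1] == -1) return(NA_integer_)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    op <- substring(toks, nchar(toks))
    len <- as.integer(substring(toks, 1, nchar(toks) - 1))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignment records from a plain SAM file
#'
#' Secondary (0x100) and supplementary (0x800) records are dropped; unmapped
#' records (0x4) are dropped and tallied. Coordinates are converted from SAM
#' 1-based to 0-based half-open (end from the CIGAR reference length). A
#' record is unique when MAPQ >= `mapq_threshold` (inclusive, mirroring the
#' `samtools -q 10` convention).
#'
#' @param path SAM path
#' @param mapq_threshold MAPQ cutoff for uniqueness (default 10)
#' @return alignment record data.frame (columns as [align_minimal()], with
#'   `mapq` instead of `n_cooptimal`/`mismatches`); attribute `n_unmapped`
#' @export
read_sam <- function(path, mapq_threshold = 10L) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  if (!any(is_hdr))
    stopf("format error: missing SAM header in %s", path)
  body_idx <- which(!is_hdr)
  n_unmapped <- 0L
  rows <- vector("list", length(body_idx))
  j <- 0L
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stopf("format error at line %d: %d fields (11 required)", i, length(f))
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    mapq <- suppressWarnings(as.integer(f[5]))
    if (is.na(flag) || is.na(pos) || is.na(mapq))
      stopf("format error at line %d: malformed mandatory field", i)
    if (bitwAnd(flag, 256L) > 0 || bitwAnd(flag, 2048L) > 0) next
    if (bitwAnd(flag, 4L) > 0) { n_unmapped <- n_unmapped + 1L; next }
    rlen <- cigar_ref_length(f[6])
    if (is.na(rlen))
      stopf("format error at line %d: malformed CIGAR '%s'", i, f[6])
    mate <- if (bitwAnd(flag, 1L) > 0 && bitwAnd(flag, 128L) > 0) 2L else 1L
    j <- j + 1L
    rows[[j]] <- data.frame(
      read_id = f[1], mate = mate, ref = f[3], start = pos - 1L,
      end = pos - 1L + rlen, strand = if (bitwAnd(flag, 16L) > 0) "-" else "+",
      mapq = mapq, is_primary = TRUE,
      is_unique = mapq >= mapq_threshold, stringsAsFactors = FALSE)
  }
  out <- if (j == 0) data.frame(
    read_id = character(0), mate = integer(0), ref = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    mapq = integer(0), is_primary = logical(0), is_unique = logical(0),
    stringsAsFactors = FALSE) else do.call(rbind, rows[seq_len(j)])
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Count primary mapped mates per repeat family
#'
#' Each primary mapped mate contributes exactly one count to the family
#' containing its alignment start position (genome mode, via the annotation)
#' or to its reference name (consensus mode). Multi-mapped reads are included
#' by default (all-mapped policy); `unique_only = TRUE` restricts to unique
#' records. Alignments starting outside any annotated interval are assigned
#' to the reserved family `background`.
#'
#' @param alignments alignment record data.frame
#' @param annotation annotation data.frame (`start`, `end`, `family`,
#'   non-overlapping) for genome mode; `NULL` for consensus mode
#' @param unique_only count only uniquely mapped records
#' @param sample_label,replicate_id labels attached to the output rows
#' @return data.frame with columns `sample`, `replicate`, `family`, `count`,
#'   `total_mapped`
#' @export
count_by_family <- function(alignments, annotation = NULL,
                            unique_only = FALSE, sample_label = "sample",
                            replicate_id = "rep1") {
  a <- alignments[alignments$is_primary, , drop = FALSE]
  total_mapped <- nrow(a)
  if (unique_only) a <- a[a$is_unique, , drop = FALSE]
  if (is.null(annotation)) {
    fam <- a$ref
  } else {
    ann <- annotation[order(annotation$start), , drop = FALSE]
    idx <- findInterval(a$start, ann$start)
    inside <- idx > 0 & a$start < ann$end[pmax(idx, 1L)]
    fam <- ifelse(inside, ann$family[pmax(idx, 1L)], "background")
  }
  tab <- table(fam)
  data.frame(sample = sample_label, replicate = replicate_id,
             family = names(tab), count = as.integer(tab),
             total_mapped = total_mapped, stringsAsFactors = FALSE,
             row.names = NULL)
}
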