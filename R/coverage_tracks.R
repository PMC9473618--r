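#' Fragment intervals from paired alignment records
#'
#' Mates of a pair mapped to the same reference yield one fragment interval
#' `[min(start), max(end))`; improper pairs (mates on different references)
#' and single mapped mates fall back to per-mate intervals and are tallied.
#' A fragment is uniquely mapped only if every contributing mate is.
#'
#' @param alignments alignment record data.frame (primary records; columns
#'   `read_id`, `mate`, `ref`, `start`, `end`, `is_unique`)
#' @return data.frame with columns `ref`, `start`, `end`, `is_unique`;
#'   attribute `n_improper`
#' @export
fragment_intervals <- function(alignments) {
  a <- alignments[alignments$is_primary, , drop = FALSE]
  m1 <- a[a$mate == 1L, , drop = FALSE]
  m2 <- a[a$mate == 2L, , drop = FALSE]
  i2 <- match(m1$read_id, m2$read_id)
  paired <- !is.na(i2) & m1$ref == m2$ref[pmax(i2, 1L)]
  frag <- data.frame(
    ref = m1$ref[paired],
    start = pmin(m1$start[paired], m2$start[i2[paired]]),
    end = pmax(m1$end[paired], m2$end[i2[paired]]),
    is_unique = m1$is_unique[paired] & m2$is_unique[i2[paired]],
    stringsAsFactors = FALSE)
  # fall back to per-mate intervals for everything unpaired
  lone1 <- m1[!paired, , drop = FALSE]
  lone2 <- m2[!(m2$read_id %in% m1$read_id[paired]), , drop = FALSE]
  lone <- rbind(lone1[, c("ref", "start", "end", "is_unique")],
                lone2[, c("ref", "start", "end", "is_unique")])
  out <- rbind(frag, lone)
  rownames(out) <- NULL
  attr(out, "n_improper") <- nrow(lone)
  out
}

#' Binned RPM coverage track
#'
#' Bins tile each chromosome; a fragment increments every bin it overlaps
#' (genome-browser coverage semantics), and bin values are normalized to
#' RPM: overlapping fragments x 1e6 / total_mapped.
#'
#' @param fragments fragment data.frame from [fragment_intervals()] (columns
#'   `ref`, `start`, `end`)
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param bin_size bin width (bp, >= 1)
#' @param total_mapped RPM denominator (> 0)
#' @param unique_only restrict to uniquely mapped fragments (requires an
#'   `is_unique` column)
#' @return data.frame with columns `chrom`, `start`, `end`, `value`
#' @export
binned_rpm <- function(fragments, chrom_lengths, bin_size = 100L,
                       total_mapped, unique_only = FALSE) {
  if (bin_size < 1) stopf("bin_size must be >= 1")
  if (total_mapped <= 0) stopf("total_mapped must be > 0")
  if (unique_only) fragments <- fragments[fragments$is_unique, , drop = FALSE]
  out <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    starts <- seq.int(0L, len - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    fr <- fragments[fragments$ref == chrom, , drop = FALSE]
    bins <- IRanges::IRanges(start = starts + 1L, end = ends)
    frs <- IRanges::IRanges(start = fr$start + 1L, end = fr$end)
    hits <- IRanges::countOverlaps(bins, frs)
    data.frame(chrom = chrom, start = starts, end = ends,
               value = hits * 1e6 / total_mapped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Coverage layers split by mapping uniqueness
#'
#' Convenience wrapper producing the two track layers of the repeat-region
#' views: all mapped fragments, and uniquely mapped fragments only.
#' @inheritParams binned_rpm
#' @return named list of two track data.frames: `all` and `unique`
#' @export
coverage_layers <- function(fragments, chrom_lengths, bin_size = 100L,
                            total_mapped) {
  list(all = binned_rpm(fragments, chrom_lengths, bin_size, total_mapped,
                        unique_only = FALSE),
       unique = binned_rpm(fragments, chrom_lengths, bin_size, total_mapped,
                           unique_only = TRUE))
}

#' Mean track signal over named regions
#'
#' @param tracks named list of track data.frames (layers), as from
#'   [coverage_layers()]
#' @param regions data.frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open)
#' @return data.frame with columns `region`, `layer`, `mean_rpm`
#' @export
region_report <- function(tracks, regions) {
  if (nrow(regions) == 0)
    return(data.frame(region = character(0), layer = character(0),
                      mean_rpm = numeric(0), stringsAsFactors = FALSE))
  out <- list()
  for (layer in names(tracks)) {
    tr <- tracks[[layer]]
    for (i in seq_len(nrow(regions))) {
      sel <- tr$chrom == regions$chrom[i] & tr$start < regions$end[i] &
        tr$end > regions$start[i]
      if (!any(tr$chrom == regions$chrom[i]) ||
          regions$end[i] > max(tr$end[tr$chrom == regions$chrom[i]]) ||
          regions$start[i] < 0)
        stopf("region %s outside the assembly", regions$name[i])
      out[[length(out) + 1L]] <- data.frame(
        region = regions$name[i], layer = layer,
        mean_rpm = mean(tr$value[sel]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a coverage track as bedGraph
#'
#' 0-based half-open per the standard; zero-valued bins are omitted; values
#' are written with 4 fractional digits.
#' @param track track data.frame (columns `chrom`, `start`, `end`, `value`)
#' @param path output path
#' @export
write_bedgraph <- function(track, path) {
  tr <- track[track$value != 0, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%.4f", tr$chrom, tr$start, tr$end,
                     tr$value), path)
  invisible(path)
}

#' Read a bedGraph file
#' @param path bedGraph path
#' @return track data.frame (columns `chrom`, `start`, `end`, `value`)
#' @export
read_bedgraph <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "value"))
  df
}
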