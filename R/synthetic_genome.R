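#' Configuration for a synthetic repeat-rich toy genome
#'
#' The defaults describe a 200 kb chromosome emulating the repeat structure
#' the analysis targets: a terminal head-to-tail array of three telomeric
#' retrotransposon-like families (copies independently 5'-truncated, as is
#' typical for target-primed reverse transcription), a centromeric island of
#' two distinct complex repeat families, scattered background complex
#' repeats, and interstitial satellite (simple tandem repeat) tracts.
#'
#' @param chrom_name chromosome name
#' @param chrom_length chromosome length (bp)
#' @param telomeric_families named integer vector: copies per telomeric family
#' @param telomeric_consensus_length consensus length (bp) of telomeric
#'   families
#' @param centromeric_families named integer vector: copies per centromeric
#'   island family
#' @param centromeric_consensus_length consensus length (bp)
#' @param background_families named integer vector: copies per background
#'   complex-repeat family (scattered, not arrayed)
#' @param background_consensus_length consensus length (bp)
#' @param simple_repeats named integer vector: tandem unit copies per
#'   satellite unit (names are the unit sequences, e.g. `c(AACAC = 1000)`)
#' @param truncation_prob probability that a telomeric copy is 5'-truncated
#' @param truncation_fraction fraction of the copy removed from the 5' end
#'   when truncated
#' @param mutation_rate per-base substitution rate applied to each complex
#'   repeat copy (divergence from consensus)
#' @param seed integer seed; the whole genome is deterministic given the seed
#' @return a list of class `toy_genome_config`
#' @export
toy_genome_config <- function(chrom_name = "chr_toy",
                              chrom_length = 200000L,
                              telomeric_families = c(telA = 30L, telB = 30L,
                                                     telC = 30L),
                              telomeric_consensus_length = 750L,
                              centromeric_families = c(cenA = 20L,
                                                       cenB = 20L),
                              centromeric_consensus_length = 400L,
                              background_families = c(bgA = 6L, bgB = 6L,
                                                      bgC = 6L),
                              background_consensus_length = 600L,
                              simple_repeats = c(AACAC = 1000L, AATAT = 600L,
                                                 AG = 1000L),
                              truncation_prob = 0.7,
                              truncation_fraction = 0.5,
                              mutation_rate = 0.02,
                              seed = 1L) {
  cfg <- list(chrom_name = chrom_name, chrom_length = as.integer(chrom_length),
              telomeric_families = telomeric_families,
              telomeric_consensus_length = as.integer(telomeric_consensus_length),
              centromeric_families = centromeric_families,
              centromeric_consensus_length = as.integer(centromeric_consensus_length),
              background_families = background_families,
              background_consensus_length = as.integer(background_consensus_length),
              simple_repeats = simple_repeats,
              truncation_prob = truncation_prob,
              truncation_fraction = truncation_fraction,
              mutation_rate = mutation_rate,
              seed = as.integer(seed))
  class(cfg) <- "toy_genome_config"
  cfg
}

# family label used for a satellite tract of the given unit
simple_family <- function(unit) paste0("simple_", unit)

#' Is an annotation class a complex repeat family?
#'
#' Reserved classes (`background`, `centromere_island`, and per-unit
#' simple-repeat classes `simple_<UNIT>`) are not complex repeat families.
#' @param family character vector of class labels
#' @return logical vector
#' @export
is_complex_family <- function(family) {
  !(family %in% c("background", "simple_repeat", "centromere_island")) &
    !startsWith(family, "simple_")
}

#' Build a synthetic repeat-rich genome
#'
#' Generates a random consensus library, assembles the chromosome
#' (terminal telomeric array, central centromeric island, scattered
#' background complex repeats and satellite tracts, random background
#' elsewhere) and the matching annotation. Every complex-repeat copy carries
#' independent point mutations at `mutation_rate`; telomeric copies are
#' independently 5'-truncated with `truncation_prob` (truncation removes the
#' 5' `truncation_fraction` of the copy). Deterministic given `config$seed`.
#'
#' @param config a [toy_genome_config()]
#' @return an object of class `toy_genome`: list with `chrom_name`,
#'   `sequence` (character), `annotation` (data.frame with 0-based half-open
#'   `start`, `end`, plus `family`, `copy_id`, `truncated_5p`), `library`
#'   (a [repeat_library()]) and `config`
#' @export
build_toy_genome <- function(config) {
  cfg <- config
  if (cfg$truncation_prob < 0 || cfg$truncation_prob > 1)
    stopf("truncation_prob must be in [0, 1]")
  if (cfg$chrom_length <= 0) stopf("chrom_length must be > 0")
  set.seed(cfg$seed)

  # consensus library (random consensus per subfamily; identity map)
  fam_lengths <- c(
    setNames(rep(cfg$telomeric_consensus_length,
                 length(cfg$telomeric_families)),
             names(cfg$telomeric_families)),
    setNames(rep(cfg$centromeric_consensus_length,
                 length(cfg$centromeric_families)),
             names(cfg$centromeric_families)),
    setNames(rep(cfg$background_consensus_length,
                 length(cfg$background_families)),
             names(cfg$background_families)))
  consensus <- vapply(fam_lengths, random_dna, character(1))
  library <- repeat_library(consensus)

  make_copy <- function(family, truncated) {
    s <- consensus[[family]]
    if (truncated) {
      cut <- floor(nchar(s) * cfg$truncation_fraction)
      s <- substring(s, cut + 1L, nchar(s))
    }
    mutate_sequences(s, cfg$mutation_rate)
  }

  # --- telomeric terminal array (interleaved, head-to-tail) ---
  tel_order <- sample(rep(names(cfg$telomeric_families),
                          cfg$telomeric_families))
  tel_trunc <- runif(length(tel_order)) < cfg$truncation_prob
  tel_seqs <- character(length(tel_order))
  for (i in seq_along(tel_order))
    tel_seqs[i] <- make_copy(tel_order[i], tel_trunc[i])
  tel_len <- sum(nchar(tel_seqs))
  tel_start <- cfg$chrom_length - tel_len

  # --- centromeric island (tandem copies, centered) ---
  cen_order <- sample(rep(names(cfg$centromeric_families),
                          cfg$centromeric_families))
  cen_seqs <- vapply(cen_order, function(f) make_copy(f, FALSE), character(1))
  cen_len <- sum(nchar(cen_seqs))
  cen_start <- as.integer(floor(cfg$chrom_length / 2 - cen_len / 2))
  if (cen_start < 0 || cen_start + cen_len > tel_start)
    stopf("configuration error: repeat content does not fit the chromosome")

  # --- scattered features: background complex copies + satellite tracts ---
  feats <- list()
  for (f in names(cfg$background_families)) {
    for (i in seq_len(cfg$background_families[[f]])) {
      feats[[length(feats) + 1L]] <-
        list(family = f, seq = make_copy(f, FALSE))
    }
  }
  for (unit in names(cfg$simple_repeats)) {
    feats[[length(feats) + 1L]] <-
      list(family = simple_family(unit),
           seq = strrep(unit, cfg$simple_repeats[[unit]]))
  }
  feats <- feats[sample(length(feats))]

  # free gaps between the fixed blocks
  gaps <- data.frame(start = c(0L, cen_start + cen_len),
                     end = c(cen_start, tel_start))
  placed <- data.frame(start = integer(0), end = integer(0),
                       family = character(0), seq = character(0),
                       stringsAsFactors = FALSE)
  for (ft in feats) {
    w <- nchar(ft$seq)
    room <- pmax(0L, gaps$end - gaps$start - w + 1L)
    if (sum(room) == 0)
      stopf("configuration error: feature of width %d does not fit", w)
    g <- sample.int(nrow(gaps), 1L, prob = room)
    off <- floor(runif(1) * room[g])
    s <- gaps$start[g] + off
    placed <- rbind(placed, data.frame(start = s, end = s + w,
                                       family = ft$family, seq = ft$seq,
                                       stringsAsFactors = FALSE))
    # split the gap
    gaps <- rbind(gaps[-g, , drop = FALSE],
                  data.frame(start = c(gaps$start[g], s + w),
                             end = c(s, gaps$end[g])))
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
  }

  # --- assemble annotation ---
  ann <- data.frame(start = integer(0), end = integer(0),
                    family = character(0), copy_id = integer(0),
                    truncated_5p = logical(0), seq = character(0),
                    stringsAsFactors = FALSE)
  pos <- tel_start
  for (i in seq_along(tel_order)) {
    w <- nchar(tel_seqs[i])
    ann <- rbind(ann, data.frame(start = pos, end = pos + w,
                                 family = tel_order[i], copy_id = 0L,
                                 truncated_5p = tel_trunc[i],
                                 seq = tel_seqs[i], stringsAsFactors = FALSE))
    pos <- pos + w
  }
  pos <- cen_start
  for (i in seq_along(cen_order)) {
    w <- nchar(cen_seqs[i])
    ann <- rbind(ann, data.frame(start = pos, end = pos + w,
                                 family = cen_order[i], copy_id = 0L,
                                 truncated_5p = FALSE,
                                 seq = cen_seqs[i], stringsAsFactors = FALSE))
    pos <- pos + w
  }
  if (nrow(placed) > 0) {
    ann <- rbind(ann, data.frame(start = placed$start, end = placed$end,
                                 family = placed$family, copy_id = 0L,
                                 truncated_5p = FALSE, seq = placed$seq,
                                 stringsAsFactors = FALSE))
  }
  ann <- ann[order(ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  for (f in unique(ann$family)) {
    idx <- which(ann$family == f)
    ann$copy_id[idx] <- seq_along(idx)
  }

  # --- assemble sequence: random background between annotated intervals ---
  chunks <- character(0)
  cursor <- 0L
  for (i in seq_len(nrow(ann))) {
    if (ann$start[i] > cursor)
      chunks <- c(chunks, random_dna(ann$start[i] - cursor))
    chunks <- c(chunks, ann$seq[i])
    cursor <- ann$end[i]
  }
  if (cursor < cfg$chrom_length)
    chunks <- c(chunks, random_dna(cfg$chrom_length - cursor))
  sequence <- paste(chunks, collapse = "")

  ann$seq <- NULL
  genome <- structure(list(chrom_name = cfg$chrom_name, sequence = sequence,
                           annotation = ann, library = library,
                           config = cfg),
                      class = "toy_genome")
  validate_toy_genome(genome)
  genome
}

#' Validate a toy genome's internal consistency
#'
#' Checks that annotation intervals lie within the chromosome, are mutually
#' non-overlapping, and that every family label is either in the consensus
#' library or a reserved class.
#' @param genome a `toy_genome`
#' @return the genome, invisibly; errors on violation
#' @export
validate_toy_genome <- function(genome) {
  ann <- genome$annotation
  n <- nchar(genome$sequence)
  if (nrow(ann) > 0) {
    if (any(ann$start < 0) || any(ann$end > n) || any(ann$start >= ann$end))
      stopf("annotation interval outside [0, %d) or empty", n)
    o <- order(ann$start)
    if (any(ann$start[o][-1] < ann$end[o][-length(o)]))
      stopf("annotation intervals overlap")
    known <- names(genome$library$consensus)
    ok <- ann$family %in% known |
      ann$family %in% c("background", "simple_repeat", "centromere_island") |
      startsWith(ann$family, "simple_")
    if (!all(ok))
      stopf("unknown family label: %s",
            paste(unique(ann$family[!ok]), collapse = ", "))
    for (f in unique(ann$family)) {
      ids <- ann$copy_id[ann$family == f]
      if (anyDuplicated(ids)) stopf("duplicate copy_id within family %s", f)
    }
  }
  invisible(genome)
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome %s: %d bp, %d annotated intervals, %d classes\n",
              x$chrom_name, nchar(x$sequence), nrow(x$annotation),
              length(unique(x$annotation$family))))
  invisible(x)
}

#' Write a toy genome to FASTA + BED + library files
#'
#' The BED is 0-based half-open with columns chrom, start, end, name
#' (family), score (copy_id), strand, and an extra `truncated_5p` column
#' (0/1).
#'
#' @param genome a `toy_genome`
#' @param dir output directory (created if missing)
#' @return named character vector of written paths
#' @export
write_toy_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "genome.fa")
  bed <- file.path(dir, "annotation.bed")
  lib_fa <- file.path(dir, "library.fa")
  lib_map <- file.path(dir, "subfamilies.tsv")
  seqs <- Biostrings::DNAStringSet(setNames(genome$sequence,
                                            genome$chrom_name))
  Biostrings::writeXStringSet(seqs, fasta)
  ann <- genome$annotation
  bed_df <- data.frame(chrom = genome$chrom_name, start = ann$start,
                       end = ann$end, name = ann$family,
                       score = ann$copy_id, strand = "+",
                       truncated_5p = as.integer(ann$truncated_5p))
  write.table(bed_df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write_repeat_library(genome$library, lib_fa, lib_map)
  c(genome = fasta, annotation = bed, library = lib_fa, subfamilies = lib_map)
}

#' Read a toy genome back from FASTA + BED + library files
#' @param dir directory written by [write_toy_genome()]
#' @return a `toy_genome` (without the generating config)
#' @export
read_toy_genome <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  bed <- read.table(file.path(dir, "annotation.bed"), sep = "\t",
                    stringsAsFactors = FALSE)
  colnames(bed) <- c("chrom", "start", "end", "family", "copy_id", "strand",
                     "truncated_5p")
  ann <- data.frame(start = bed$start, end = bed$end, family = bed$family,
                    copy_id = bed$copy_id,
                    truncated_5p = bed$truncated_5p == 1L,
                    stringsAsFactors = FALSE)
  library <- read_repeat_library(file.path(dir, "library.fa"),
                                 file.path(dir, "subfamilies.tsv"))
  structure(list(chrom_name = names(seqs)[1],
                 sequence = as.character(seqs[[1]]),
                 annotation = ann, library = library, config = NULL),
            class = "toy_genome")
}

# class lengths over annotation classes plus pooled background
class_lengths <- function(genome) {
  ann <- genome$annotation
  widths <- tapply(ann$end - ann$start, ann$family, sum)
  lens <- setNames(as.numeric(widths), names(widths))
  bg <- nchar(genome$sequence) - sum(ann$end - ann$start)
  c(lens, background = bg)
}
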