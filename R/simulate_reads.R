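#' Sampling profile for simulated sequencing reads
#'
#' Encodes the generative assumption of tethered-nuclease enrichment: reads
#' are sampled from annotation classes with probability proportional to
#' weight x class length. A uniform profile (all weights 1) models the
#' no-tag / whole-genome controls; raising the weight of telomeric families
#' models IP enrichment at those elements.
#'
#' @param weights named numeric vector of non-negative per-class sampling
#'   weights; classes absent from the vector default to weight 1. Class
#'   labels are annotation families plus `background`.
#' @param error_rate per-base substitution probability in [0, 0.2]
#' @param fragment_length_mean,fragment_length_sd fragment length (bp),
#'   normal, truncated at the read length
#' @param read_length read length (bp)
#' @param seed integer seed; all draws for a sample flow from this one seed
#' @return list of class `enrichment_profile`
#' @export
enrichment_profile <- function(weights = numeric(0), error_rate = 0.001,
                               fragment_length_mean = 200,
                               fragment_length_sd = 40,
                               read_length = 50L, seed = 1L) {
  if (error_rate < 0 || error_rate > 0.2)
    stopf("error_rate must be in [0, 0.2]")
  if (read_length > fragment_length_mean + 4 * fragment_length_sd)
    stopf("read_length exceeds fragment mean + 4 sd")
  if (length(weights) > 0) {
    if (any(weights < 0)) stopf("weights must be non-negative")
    if (is.null(names(weights))) stopf("weights must be named by class")
  }
  structure(list(weights = weights, error_rate = error_rate,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "enrichment_profile")
}

#' Simulate paired-end reads from a toy genome
#'
#' Fragment midpoints are sampled from annotation classes with probability
#' proportional to weight x class length, then uniformly within a class
#' interval (so a fragment's truth label is the class of its midpoint).
#' Proper FR read pairs are emitted from a random strand, with independent
#' per-base substitution errors. Deterministic given `profile$seed`.
#'
#' @param genome a `toy_genome`
#' @param profile an [enrichment_profile()]
#' @param n_pairs number of read pairs (>= 0)
#' @param sample_label one of `IP`, `no_tag`, `whole_genome`
#' @param target_name profiled factor name (metadata)
#' @param replicate_id replicate label (metadata)
#' @return a `read_set`: list with `r1`, `r2` (character vectors), `id`,
#'   `meta` (per-pair truth: class, fragment start/end, strand) and `truth`
#'   (list with `expected_fractions`, `realized_counts`, `seed`)
#' @export
simulate_reads <- function(genome, profile, n_pairs,
                           sample_label = c("IP", "no_tag", "whole_genome"),
                           target_name = "target", replicate_id = "rep1") {
  sample_label <- match.arg(sample_label)
  if (n_pairs < 0) stopf("n_pairs must be >= 0")
  chrom_len <- nchar(genome$sequence)
  max_frag <- ceiling(profile$fragment_length_mean +
                        4 * profile$fragment_length_sd)
  if (chrom_len < max_frag)
    stopf("configuration error: genome shorter than fragment length")
  set.seed(profile$seed)

  lens <- class_lengths(genome)
  classes <- names(lens)
  w <- rep(1, length(classes))
  names(w) <- classes
  known <- names(profile$weights) %in% classes
  w[names(profile$weights)[known]] <- profile$weights[known]
  if (all(w * lens == 0)) stopf("at least one class weight must be positive")
  probs <- w * lens / sum(w * lens)

  truth <- list(expected_fractions = probs,
                realized_counts = setNames(rep(0L, length(classes)), classes),
                seed = profile$seed)
  empty <- function() {
    structure(list(sample_label = sample_label, target_name = target_name,
                   replicate_id = replicate_id, id = character(0),
                   r1 = character(0), r2 = character(0),
                   meta = data.frame(class = character(0),
                                     frag_start = integer(0),
                                     frag_end = integer(0),
                                     strand = character(0)),
                   truth = truth, profile = profile),
              class = "read_set")
  }
  if (n_pairs == 0) return(empty())

  # per-class interval table (background = complement of the annotation)
  ann <- genome$annotation
  gaps_start <- c(0L, ann$end)
  gaps_end <- c(ann$start, chrom_len)
  keep <- gaps_end > gaps_start
  itab <- rbind(
    data.frame(class = ann$family, start = ann$start, end = ann$end,
               stringsAsFactors = FALSE),
    data.frame(class = "background", start = gaps_start[keep],
               end = gaps_end[keep], stringsAsFactors = FALSE))
  itab$width <- itab$end - itab$start

  cls <- sample(classes, n_pairs, replace = TRUE, prob = probs)
  mid <- integer(n_pairs)
  for (cl in unique(cls)) {
    sel <- which(cls == cl)
    rows <- which(itab$class == cl)
    iv <- if (length(rows) == 1) rep(rows, length(sel)) else
      sample(rows, length(sel), replace = TRUE, prob = itab$width[rows])
    mid[sel] <- itab$start[iv] + as.integer(floor(runif(length(sel)) *
                                                    itab$width[iv]))
  }

  rl <- profile$read_length
  frag <- pmin(pmax(rl, round(rnorm(n_pairs, profile$fragment_length_mean,
                                    profile$fragment_length_sd))), max_frag)
  fs <- pmin(pmax(0L, as.integer(mid - frag %/% 2)), chrom_len - frag)
  fe <- fs + as.integer(frag)

  fwd5 <- substring(genome$sequence, fs + 1L, fs + rl)
  rev5 <- revcomp(substring(genome$sequence, fe - rl + 1L, fe))
  minus <- runif(n_pairs) < 0.5
  r1 <- ifelse(minus, rev5, fwd5)
  r2 <- ifelse(minus, fwd5, rev5)
  r1 <- mutate_sequences(r1, profile$error_rate)
  r2 <- mutate_sequences(r2, profile$error_rate)

  counts <- table(factor(cls, levels = classes))
  truth$realized_counts <- setNames(as.integer(counts), classes)

  structure(list(sample_label = sample_label, target_name = target_name,
                 replicate_id = replicate_id,
                 id = sprintf("%s_%s_%07d", sample_label, replicate_id,
                              seq_len(n_pairs)),
                 r1 = r1, r2 = r2,
                 meta = data.frame(class = cls, frag_start = fs,
                                   frag_end = fe,
                                   strand = ifelse(minus, "-", "+"),
                                   stringsAsFactors = FALSE),
                 truth = truth, profile = profile),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set %s/%s (%s): %d pairs, read length %d\n",
              x$sample_label, x$replicate_id, x$target_name, length(x$r1),
              x$profile$read_length))
  invisible(x)
}

#' Write a read set as paired FASTQ plus a truth TSV
#'
#' Base qualities are written as fixed Phred 'I'; quality is never used
#' downstream.
#' @param reads a `read_set`
#' @param prefix output path prefix; writes `<prefix>_R1.fastq`,
#'   `<prefix>_R2.fastq`, `<prefix>_truth.tsv`
#' @return named character vector of written paths
#' @export
write_read_set <- function(reads, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(r1 = paste0(prefix, "_R1.fastq"),
             r2 = paste0(prefix, "_R2.fastq"),
             truth = paste0(prefix, "_truth.tsv"))
  fq <- function(ids, seqs, path) {
    if (length(seqs) == 0) {
      file.create(path)
      return(invisible())
    }
    qual <- strrep("I", nchar(seqs))
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  }
  fq(paste0(reads$id, "/1"), reads$r1, paths[["r1"]])
  fq(paste0(reads$id, "/2"), reads$r2, paths[["r2"]])
  truth_df <- cbind(data.frame(read_id = reads$id), reads$meta)
  write.table(truth_df, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read paired FASTQ files into a read set
#' @param r1_path,r2_path FASTQ paths
#' @param sample_label,target_name,replicate_id sample metadata
#' @return a `read_set` (without simulation truth)
#' @export
read_fastq_pair <- function(r1_path, r2_path, sample_label = "IP",
                            target_name = "target", replicate_id = "rep1") {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  ids <- sub("/1$", "", sub(" .*", "", names(r1)))
  structure(list(sample_label = sample_label, target_name = target_name,
                 replicate_id = replicate_id, id = ids,
                 r1 = unname(as.character(r1)),
                 r2 = unname(as.character(r2)),
                 meta = NULL, truth = NULL, profile = NULL),
            class = "read_set")
}
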