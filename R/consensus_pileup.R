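#' Consensus dimer
#'
#' A repeat consensus concatenated to itself, so that reads spanning the
#' junction between adjacent copies of a head-to-tail tandem array align
#' contiguously.
#' @param consensus DNA string
#' @return the consensus concatenated with itself (length 2L)
#' @export
build_dimer <- function(consensus) {
  if (nchar(consensus) == 0) stopf("consensus must be non-empty")
  paste0(consensus, consensus)
}

#' Fold a dimer interval onto monomer coordinates
#'
#' Each covered dimer position p contributes one unit at monomer position
#' p mod L. Placements must start in the first monomer (start < L): a dimer
#' admits duplicate placements offset by L, and restricting starts makes
#' folding a bijection on placements.
#'
#' @param start,end 0-based half-open interval on the dimer; `start < L`,
#'   `end <= 2L`
#' @param L monomer consensus length
#' @return integer vector of 0-based monomer positions, one per covered base
#' @export
fold_coordinates <- function(start, end, L) {
  if (start < 0 || start >= L)
    stopf("redundant placement: start must be in [0, L)")
  if (end <= start || end > 2 * L) stopf("end must be in (start, 2L]")
  (start:(end - 1L)) %% L
}

# fold a set of accepted dimer placements into a length-L coverage vector
fold_coverage <- function(starts, ends, L) {
  cov2 <- numeric(2L * L)
  if (length(starts) > 0) {
    # difference-array accumulation over the dimer, then fold the two halves
    d <- numeric(2L * L + 1L)
    tab_s <- tabulate(starts + 1L, nbins = 2L * L)
    tab_e <- tabulate(ends + 1L, nbins = 2L * L + 1L)
    d[seq_len(2L * L)] <- tab_s
    d <- d - tab_e
    cov2 <- cumsum(d[seq_len(2L * L)])
  }
  cov2[seq_len(L)] + cov2[L + seq_len(L)]
}

#' Read pileup profiles along repeat consensus sequences
#'
#' Each read is aligned to every family's consensus dimer with the built-in
#' assigner; the single best-scoring family wins (cross-family score ties
#' are dropped and tallied), placements are restricted to start < L, and the
#' covered dimer positions are folded onto the monomer. Coverage is
#' normalized to RPM using the total mapped reads of the whole sample (not
#' only consensus-matching reads), consistent with the RPM definition used
#' for family counts.
#'
#' @param reads character vector of read sequences, or a `read_set`
#' @param library a [repeat_library()]
#' @param total_mapped total primary mapped mates of the sample (> 0)
#' @param families subfamilies to profile (default: all in the library)
#' @param min_identity minimum identity of an accepted placement
#' @param k seed length passed to the assigner
#' @param sample_label,replicate_id metadata attached to the profiles
#' @return named list of `pileup_profile` objects: each a list with
#'   `family`, `L`, `counts` (per-position folded coverage), `rpm`,
#'   `n_reads`, `sample_label`, `replicate_id`; attribute `n_ambiguous`
#'   (reads dropped for cross-family ties)
#' @export
consensus_pileup <- function(reads, library, total_mapped,
                             families = NULL, min_identity = 0.9, k = 20L,
                             sample_label = "sample", replicate_id = "rep1") {
  if (inherits(reads, "read_set")) {
    sample_label <- reads$sample_label
    replicate_id <- reads$replicate_id
    reads <- c(reads$r1, reads$r2)
  }
  if (length(library$consensus) == 0)
    stopf("configuration error: empty library")
  if (total_mapped <= 0) stopf("total_mapped must be > 0")
  fams <- families %||% names(library$consensus)
  n <- length(reads)

  score <- matrix(-Inf, nrow = n, ncol = length(fams),
                  dimnames = list(NULL, fams))
  starts <- ends <- matrix(NA_integer_, nrow = n, ncol = length(fams))
  for (j in seq_along(fams)) {
    f <- fams[j]
    dimer <- setNames(build_dimer(library$consensus[[f]]), f)
    aln <- align_minimal(reads, dimer, k = k, max_mismatches = -1L,
                         max_mismatch_frac = 1 - min_identity)
    idx <- as.integer(aln$read_id)
    score[idx, j] <- aln$score
    starts[idx, j] <- aln$start
    ends[idx, j] <- aln$end
  }

  best <- score[, 1]
  for (j in seq_len(ncol(score))[-1]) best <- pmax(best, score[, j])
  hit <- which(is.finite(best))
  n_best <- rowSums(score[hit, , drop = FALSE] == best[hit])
  accepted <- hit[n_best == 1]
  n_ambiguous <- sum(n_best > 1)
  best_fam <- max.col(score[accepted, , drop = FALSE], ties.method = "first")

  profiles <- vector("list", length(fams))
  names(profiles) <- fams
  for (j in seq_along(fams)) {
    L <- nchar(library$consensus[[fams[j]]])
    sel <- accepted[best_fam == j]
    s <- starts[cbind(sel, j)]
    e <- ends[cbind(sel, j)]
    keep <- s < L   # duplicate dimer placements (start >= L) are redundant
    counts <- fold_coverage(s[keep], e[keep], L)
    profiles[[j]] <- structure(
      list(family = fams[j], L = L, counts = counts,
           rpm = counts * 1e6 / total_mapped, n_reads = sum(keep),
           sample_label = sample_label, replicate_id = replicate_id),
      class = "pileup_profile")
  }
  attr(profiles, "n_ambiguous") <- n_ambiguous
  profiles
}

#' Replicate-mean IP-over-control enrichment profile
#'
#' Per position: the mean over replicates of IP RPM, and the enrichment
#' ratio (mean IP RPM + eps) / (control RPM + eps). Both the IP RPM and the
#' ratio are reported.
#'
#' @param ip_profiles list of `pileup_profile`s (or bare RPM vectors), one
#'   per replicate, for one family
#' @param ctrl_profile control `pileup_profile` (or RPM vector) of matching
#'   length
#' @param eps pseudocount (RPM)
#' @return list with `family`, `L`, `mean_ip_rpm`, `ctrl_rpm`, `enrichment`
#'   (per-position vectors)
#' @export
profile_enrichment <- function(ip_profiles, ctrl_profile, eps = 0.01) {
  if (length(ip_profiles) < 1) stopf("at least one IP replicate required")
  as_rpm <- function(p) if (inherits(p, "pileup_profile")) p$rpm else p
  fam <- if (inherits(ip_profiles[[1]], "pileup_profile"))
    ip_profiles[[1]]$family else NA_character_
  ip <- lapply(ip_profiles, as_rpm)
  ctrl <- as_rpm(ctrl_profile)
  L <- length(ctrl)
  if (any(vapply(ip, length, integer(1)) != L))
    stopf("mismatched profile lengths")
  mean_ip <- Reduce(`+`, ip) / length(ip)
  list(family = fam, L = L, mean_ip_rpm = mean_ip, ctrl_rpm = ctrl,
       enrichment = (mean_ip + eps) / (ctrl + eps))
}

#' Write pileup profiles as TSV (positions 1-based in output)
#' @param profiles named list of per-replicate profile lists, shape
#'   `profiles[[replicate]]` = `pileup_profile`, all for one family
#' @param ctrl_profile control `pileup_profile` for the same family
#' @param path output TSV path
#' @param eps pseudocount for the enrichment column
#' @export
write_profile_tsv <- function(profiles, ctrl_profile, path, eps = 0.01) {
  enr <- profile_enrichment(profiles, ctrl_profile, eps)
  df <- data.frame(position = seq_len(enr$L))
  for (i in seq_along(profiles))
    df[[paste0("ip_rpm_", profiles[[i]]$replicate_id)]] <-
      round(profiles[[i]]$rpm, 4)
  df$mean_ip_rpm <- round(enr$mean_ip_rpm, 4)
  df$ctrl_rpm <- round(enr$ctrl_rpm, 4)
  df$enrichment <- round(enr$enrichment, 4)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
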