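# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the package implementation.

oracle_revcomp <- function(x) {
  vapply(x, function(s)
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
}

oracle_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force circular-offset pileup: score every read at every circular
# offset of the monomer on both strands (+1 match / -2 mismatch over the
# full read), accept the best placement if identity >= min_identity, break
# ties by (smaller offset, '+' before '-'), and accumulate per-position
# coverage.
oracle_circular_pileup <- function(reads, monomer, min_identity = 0.9) {
  L <- nchar(monomer)
  m <- utf8ToInt(monomer)
  idx_mat <- outer(0:(L - 1), 0:(max(nchar(reads)) - 1),
                   function(o, j) (o + j) %% L + 1)
  counts <- numeric(L)
  score_vec <- function(q, rl) {
    qi <- utf8ToInt(q)
    mm <- matrix(m[idx_mat[, seq_len(rl)]], nrow = L)
    sc <- rowSums(mm == matrix(qi, nrow = L, ncol = rl, byrow = TRUE))
    sc - 2 * (rl - sc)
  }
  for (rd in reads) {
    rl <- nchar(rd)
    # rows: '+' then '-' within each offset column, so that which() on the
    # matrix (column-major) realizes the (start, strand) tie order
    allsc <- rbind(score_vec(rd, rl), score_vec(oracle_revcomp(rd), rl))
    best <- max(allsc)
    matches <- (best + 2 * rl) / 3
    if (matches < min_identity * rl) next
    first <- which(allsc == best)[1]
    best_o <- (first - 1L) %/% 2L
    pos <- (best_o + 0:(rl - 1)) %% L + 1
    counts[pos] <- counts[pos] + 1
  }
  counts
}

oracle_canonical_unit <- function(unit) {
  k <- nchar(unit)
  rots <- function(u) vapply(0:(k - 1), function(r)
    paste0(substring(u, r + 1, k), substring(u, 1, r)), character(1))
  min(c(rots(unit), rots(oracle_revcomp(unit))))
}

# Naive tandem detection: every unit length k <= k_max, every phase, with an
# explicit primitivity check; maximal-coverage run wins, ties by smaller k
# then lexicographically smaller canonical unit.
oracle_detect_tandem <- function(read, k_max = 20, min_copies = 3,
                                 min_fraction = 0.5) {
  n <- nchar(read)
  best <- NULL
  for (k in seq_len(min(k_max, n))) {
    for (st in 0:(n - k)) {
      unit <- substring(read, st + 1, st + k)
      prim <- TRUE
      if (k > 1) {
        for (d in seq_len(k - 1)) {
          if (k %% d == 0 &&
              strrep(substring(unit, 1, d), k / d) == unit) {
            prim <- FALSE
            break
          }
        }
      }
      if (!prim) next
      cc <- 1L
      while (st + (cc + 1L) * k <= n &&
             substring(read, st + cc * k + 1, st + (cc + 1) * k) == unit)
        cc <- cc + 1L
      if (cc < min_copies || cc * k < min_fraction * n) next
      cand <- list(cov = cc * k, k = k,
                   canon = oracle_canonical_unit(unit), copies = cc)
      if (is.null(best) || cand$cov > best$cov ||
          (cand$cov == best$cov &&
             (cand$k < best$k ||
                (cand$k == best$k && cand$canon < best$canon))))
        best <- cand
    }
  }
  best
}

# small genome used by several unit tests (fast to build)
small_genome <- function(seed = 1L) {
  build_toy_genome(toy_genome_config(
    chrom_length = 60000L,
    telomeric_families = c(telA = 10L, telB = 10L, telC = 10L),
    telomeric_consensus_length = 600L,
    centromeric_families = c(cenA = 8L, cenB = 8L),
    centromeric_consensus_length = 300L,
    background_families = c(bgA = 3L, bgB = 3L, bgC = 3L),
    background_consensus_length = 500L,
    simple_repeats = c(AACAC = 400L, AATAT = 250L, AG = 300L),
    seed = seed))
}

# simulate + align + count for one sample against a genome
sim_sample <- function(genome, weights, n_pairs, seed, label = "IP",
                       rep_id = "rep1") {
  prof <- enrichment_profile(weights = weights, seed = seed)
  rs <- simulate_reads(genome, prof, n_pairs, label, replicate_id = rep_id)
  refs <- setNames(genome$sequence, genome$chrom_name)
  aln <- align_minimal(rs, refs)
  ct <- count_by_family(aln, genome$annotation, sample_label = label,
                        replicate_id = rep_id)
  list(rs = rs, aln = aln, ct = ct, total_mapped = nrow(aln))
}
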