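test_that("a unique verbatim substring maps uniquely with full score", {
  set.seed(42)
  ref <- c(chrA = oracle_random_dna(500))
  read <- substring(ref, 101, 150)
  aln <- align_minimal(read, ref)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$start, 100L)
  expect_equal(aln$end, 150L)
  expect_equal(aln$strand, "+")
  expect_equal(aln$score, 50L)
  expect_equal(aln$n_cooptimal, 1L)
  expect_true(aln$is_unique)
})

test_that("a read present at two locations is primary at the first, non-unique", {
  set.seed(43)
  core <- oracle_random_dna(60)
  ref <- c(chrA = paste0(oracle_random_dna(100), core, oracle_random_dna(100),
                         core, oracle_random_dna(100)))
  read <- substring(core, 6, 55)
  aln <- align_minimal(read, ref)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$start, 105L)          # lexicographically first location
  expect_equal(aln$n_cooptimal, 2L)
  expect_false(aln$is_unique)
  # reverse-complement read maps to the same first location on '-'
  aln_rc <- align_minimal(oracle_revcomp(read), ref)
  expect_equal(aln_rc$start, 105L)
  expect_equal(aln_rc$strand, "-")
})

test_that("error-free simulated reads are recovered at their true coordinates", {
  set.seed(44)
  ref <- c(chrA = oracle_random_dna(5000))
  starts <- sample(0:4950, 100)
  fwd <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  reads <- substring(ref, starts + 1, starts + 50)
  reads[!fwd] <- oracle_revcomp(reads[!fwd])
  aln <- align_minimal(reads, ref)
  expect_equal(nrow(aln), 100L)
  expect_equal(aln$start[order(as.integer(aln$read_id))], starts)
  expect_equal(aln$strand[order(as.integer(aln$read_id))],
               ifelse(fwd, "+", "-"))
})

test_that("short reads are skipped and unmappable reads tallied", {
  set.seed(45)
  ref <- c(chrA = oracle_random_dna(300))
  aln <- align_minimal(c("ACGT", oracle_random_dna(50)), ref)
  expect_equal(attr(aln, "n_skipped"), 1L)
  expect_equal(nrow(aln) + attr(aln, "n_unmapped"), 1L)
})

test_that("SAM ingestion applies flag, coordinate and MAPQ conventions", {
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:chrA\tLN:2000",
           "r1\t0\tchrA\t1001\t10\t100M\t*\t0\t0\t*\t*",
           "r2\t16\tchrA\t51\t9\t50M\t*\t0\t0\t*\t*",
           "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
           "r4\t256\tchrA\t1\t30\t50M\t*\t0\t0\t*\t*",
           "r5\t0\tchrA\t201\t30\t20M5D10M3I17M\t*\t0\t0\t*\t*")
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  aln <- read_sam(path, mapq_threshold = 10)
  expect_equal(aln$read_id, c("r1", "r2", "r5"))   # unmapped + secondary gone
  expect_equal(attr(aln, "n_unmapped"), 1L)
  expect_equal(aln$start[1], 1000L)                # POS 1001 -> 0-based 1000
  expect_equal(aln$end[1], 1100L)
  expect_true(aln$is_unique[1])                    # MAPQ 10 inclusive
  expect_false(aln$is_unique[2])                   # MAPQ 9 below threshold
  expect_equal(aln$strand[2], "-")
  expect_equal(aln$end[3] - aln$start[3], 20L + 5L + 10L + 17L)  # I: no ref
})

test_that("malformed SAM raises a format error naming the line", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("r1\t0\tchrA\t100\t30\t50M\t*\t0\t0\t*\t*"), path)
  expect_error(read_sam(path), "missing SAM header")
  writeLines(c("@HD\tVN:1.6", "r1\t0\tchrA\t100"), path)
  expect_error(read_sam(path), "line 2")
})

test_that("SAM write -> read is the identity on coordinates and uniqueness", {
  set.seed(46)
  ref <- c(chrA = oracle_random_dna(3000))
  core <- substring(ref, 501, 560)
  ref <- c(chrA = paste0(ref, core))  # duplicate region -> multi-mapped reads
  starts <- sample(0:2950, 60)
  reads <- substring(ref, starts + 1, starts + 50)
  reads[31:60] <- oracle_revcomp(reads[31:60])
  aln <- align_minimal(reads, ref, read_ids = sprintf("rd%02d", 1:60),
                       mate = rep(c(1L, 2L), 30))
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, c(chrA = nchar(ref)), path)
  back <- read_sam(path, mapq_threshold = 10)
  cols <- c("read_id", "mate", "ref", "start", "end", "strand", "is_unique")
  expect_identical(back[cols], aln[cols])
})

test_that("counting follows the start-position rule and the all-mapped policy", {
  ann <- data.frame(start = c(100L, 200L), end = c(200L, 300L),
                    family = c("A", "B"))
  aln <- data.frame(
    read_id = sprintf("r%d", 1:6), mate = 1L, ref = "chrA",
    start = c(110L, 150L, 190L, 250L, 400L, 205L),
    end = c(160L, 200L, 240L, 300L, 450L, 255L),
    strand = "+", is_primary = TRUE,
    is_unique = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  ct <- count_by_family(aln, ann)
  cnt <- setNames(ct$count, ct$family)
  expect_equal(cnt[["A"]], 3L)            # r3 starts in A, overhangs into B
  expect_equal(cnt[["B"]], 2L)
  expect_equal(cnt[["background"]], 1L)
  expect_equal(ct$total_mapped[1], 6L)
  expect_equal(sum(ct$count), ct$total_mapped[1])  # every mate counted once
  cu <- count_by_family(aln, ann, unique_only = TRUE)
  expect_equal(sum(cu$count), 4L)
})

test_that("per-family counts match simulation truth for clean reads", {
  g <- small_genome(seed = 5L)
  prof <- enrichment_profile(error_rate = 0, seed = 31L)
  rs <- simulate_reads(g, prof, 3000)
  aln <- align_minimal(rs, setNames(g$sequence, g$chrom_name))
  ct <- count_by_family(aln, g$annotation)
  truth <- rs$truth$realized_counts
  # fragments spanning class borders put some mates in the neighbour class;
  # telomeric copies are contiguous so family totals should agree closely
  for (f in c("cenA", "cenB", "bgA")) {
    expect_equal(ct$count[ct$family == f] / 2, unname(truth[f]),
                 tolerance = 0.12, label = f)
  }
  expect_equal(sum(ct$count), nrow(aln))
})
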