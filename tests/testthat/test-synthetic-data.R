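test_that("noise-free genome is a verbatim concatenation of consensus copies", {
  cfg <- toy_genome_config(
    chrom_length = 20000L,
    telomeric_families = c(telA = 5L), telomeric_consensus_length = 400L,
    centromeric_families = c(cenA = 2L), centromeric_consensus_length = 300L,
    background_families = c(bgA = 1L), background_consensus_length = 300L,
    simple_repeats = c(AG = 50L),
    truncation_prob = 0, mutation_rate = 0, seed = 3L)
  g <- build_toy_genome(cfg)
  tel <- g$annotation[g$annotation$family == "telA", ]
  expect_equal(nrow(tel), 5L)
  expect_true(all(tel$end - tel$start == 400L))
  expect_false(any(tel$truncated_5p))
  # copies are exact consensus text, laid head-to-tail at the chromosome end
  cons <- g$library$consensus[["telA"]]
  for (i in seq_len(nrow(tel)))
    expect_identical(substring(g$sequence, tel$start[i] + 1, tel$end[i]), cons)
  expect_equal(max(tel$end), nchar(g$sequence))
  expect_equal(diff(tel$start), rep(400L, 4L))
})

test_that("forced truncation halves every telomeric copy", {
  cfg <- toy_genome_config(
    chrom_length = 20000L,
    telomeric_families = c(telA = 8L), telomeric_consensus_length = 400L,
    centromeric_families = c(cenA = 2L), centromeric_consensus_length = 300L,
    background_families = c(bgA = 1L), background_consensus_length = 300L,
    simple_repeats = c(AG = 50L),
    truncation_prob = 1, mutation_rate = 0, seed = 4L)
  g <- build_toy_genome(cfg)
  tel <- g$annotation[g$annotation$family == "telA", ]
  expect_true(all(tel$truncated_5p))
  expect_true(all(tel$end - tel$start == 200L))
  # truncated copies carry the 3' half of the consensus
  half <- substring(g$library$consensus[["telA"]], 201, 400)
  expect_identical(substring(g$sequence, tel$start[1] + 1, tel$end[1]), half)
})

test_that("truncation draws are seeded, reproducible and binomial", {
  cfg <- toy_genome_config(
    chrom_length = 200000L,
    telomeric_families = c(telA = 200L), telomeric_consensus_length = 400L,
    centromeric_families = c(cenA = 2L), centromeric_consensus_length = 300L,
    background_families = c(bgA = 1L), background_consensus_length = 300L,
    simple_repeats = c(AG = 50L),
    truncation_prob = 0.7, mutation_rate = 0, seed = 11L)
  g1 <- build_toy_genome(cfg)
  g2 <- build_toy_genome(cfg)
  n1 <- sum(g1$annotation$truncated_5p)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(n1, sum(g2$annotation$truncated_5p))
  sigma <- sqrt(200 * 0.7 * 0.3)
  expect_lt(abs(n1 - 140), 3 * sigma)
})

test_that("genome and read outputs are byte-identical across reruns", {
  cfg <- toy_genome_config(chrom_length = 30000L,
                           telomeric_families = c(telA = 5L, telB = 5L),
                           telomeric_consensus_length = 400L,
                           centromeric_families = c(cenA = 4L),
                           centromeric_consensus_length = 300L,
                           background_families = c(bgA = 2L),
                           background_consensus_length = 400L,
                           simple_repeats = c(AACAC = 100L),
                           seed = 7L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    g <- build_toy_genome(cfg)
    write_toy_genome(g, d)
    rs <- simulate_reads(g, enrichment_profile(seed = 9L), 500)
    write_read_set(rs, file.path(d, "reads"))
  }
  for (f in c("genome.fa", "annotation.bed", "library.fa",
              "reads_R1.fastq", "reads_R2.fastq", "reads_truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("zero pairs yield an empty read set with zero truth counts", {
  g <- small_genome()
  rs <- simulate_reads(g, enrichment_profile(seed = 1L), 0)
  expect_length(rs$r1, 0)
  expect_true(all(rs$truth$realized_counts == 0L))
  expect_equal(sum(rs$truth$expected_fractions), 1, tolerance = 1e-9)
})

test_that("class read fractions track weight x length (binomial oracle)", {
  g <- small_genome(seed = 2L)
  lens <- repeatcnr:::class_lengths(g)
  tel_names <- c("telA", "telB", "telC")
  f_tel <- sum(lens[tel_names]) / sum(lens)

  # uniform weights: telomere fraction ~ its length fraction
  rs <- simulate_reads(g, enrichment_profile(seed = 5L), 10000)
  got <- sum(rs$truth$realized_counts[tel_names]) / 10000
  sigma <- sqrt(f_tel * (1 - f_tel) / 10000)
  expect_lt(abs(got - f_tel), 3 * sigma)

  # telomere weight 10: closed-form weight normalization
  rs10 <- simulate_reads(g, enrichment_profile(
    weights = setNames(rep(10, 3), tel_names), seed = 6L), 10000, "IP")
  exp10 <- 10 * f_tel / (10 * f_tel + (1 - f_tel))
  got10 <- sum(rs10$truth$realized_counts[tel_names]) / 10000
  sigma10 <- sqrt(exp10 * (1 - exp10) / 10000)
  expect_equal(sum(rs10$truth$expected_fractions[tel_names]), exp10,
               tolerance = 1e-9)
  expect_lt(abs(got10 - exp10), 3 * sigma10)
})

test_that("truth counts equal annotation class of emitted fragment midpoints", {
  g <- small_genome(seed = 3L)
  rs <- simulate_reads(g, enrichment_profile(seed = 8L), 2000)
  ann <- g$annotation
  mid <- (rs$meta$frag_start + rs$meta$frag_end) %/% 2
  idx <- findInterval(mid, ann$start)
  cls <- ifelse(idx > 0 & mid < ann$end[pmax(idx, 1L)],
                ann$family[pmax(idx, 1L)], "background")
  recount <- table(factor(cls, levels = names(rs$truth$realized_counts)))
  expect_equal(as.integer(recount), unname(rs$truth$realized_counts))
})

test_that("non-truncated copies match their consensus at ~1 - mutation_rate", {
  mu <- 0.02
  g <- small_genome(seed = 4L)
  ann <- g$annotation
  full <- ann[ann$family == "telB" & !ann$truncated_5p, ][1, ]
  copy <- substring(g$sequence, full$start + 1, full$end)
  cons <- g$library$consensus[["telB"]]
  ident <- mean(utf8ToInt(copy) == utf8ToInt(cons))
  expect_gte(ident, 1 - mu - 0.03)
})

test_that("inconsistent genome specs and profiles are rejected", {
  expect_error(build_toy_genome(toy_genome_config(chrom_length = 5000L)),
               "configuration error")
  expect_error(enrichment_profile(error_rate = 0.5), "error_rate")
  expect_error(enrichment_profile(read_length = 1000L), "fragment")
  g <- small_genome()
  expect_error(simulate_reads(g, enrichment_profile(
    weights = c(background = 0, telA = 0), seed = 1L), 10),
    NA)  # unlisted classes default to weight 1, so this is still valid
})
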