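make_counts <- function(counts, total) {
  data.frame(sample = "s", replicate = "rep1", family = names(counts),
             count = unname(counts), total_mapped = total,
             stringsAsFactors = FALSE)
}

test_that("RPM normalization is exact and scale invariant", {
  ct <- make_counts(c(A = 5L), 1000000L)
  expect_equal(rpm_normalize(ct)$rpm, 5.0)
  ct2 <- make_counts(c(A = 250L, B = 750L), 500000L)
  expect_equal(rpm_normalize(ct2)$rpm, c(500.0, 1500.0))
  doubled <- make_counts(c(A = 500L, B = 1500L), 1000000L)
  expect_equal(rpm_normalize(doubled)$rpm, rpm_normalize(ct2)$rpm)
  expect_error(rpm_normalize(make_counts(c(A = 1L), 0L)), "normalization")
})

test_that("summed family RPM never exceeds one million", {
  g <- small_genome(seed = 6L)
  s <- sim_sample(g, numeric(0), 2000, seed = 61L)
  rpm <- rpm_normalize(s$ct)
  expect_lte(sum(rpm$rpm), 1e6 + 1e-6)
  # every mate is family-assigned (background included), so equality holds
  expect_equal(sum(rpm$rpm), 1e6)
})

test_that("enrichment ratio applies the pseudocount convention", {
  tab <- function(ip, ctrl) enrichment_ratio(
    data.frame(family = "A", rpm = ip),
    data.frame(family = "A", rpm = ctrl), eps = 0.01)
  expect_equal(tab(10, 5)$e, 10.01 / 5.01)
  expect_equal(tab(0, 0)$e, 1.0)
  expect_equal(tab(20, 0)$e, 2001.0)
  expect_error(enrichment_ratio(data.frame(family = "A", rpm = 1),
                                data.frame(family = "A", rpm = 1), eps = 0),
               "configuration error")
  # missing families are treated as RPM 0
  et <- enrichment_ratio(data.frame(family = c("A", "B"), rpm = c(1, 2)),
                         data.frame(family = "A", rpm = 1))
  expect_equal(et$ctrl_rpm[et$family == "B"], 0)
})

test_that("dual quantile filter reproduces the brute-force intersection", {
  et <- data.frame(family = paste0("f", 1:10), ip_rpm = (1:10) * 100,
                   e = c(rep(1, 8), 4, 5), ctrl_rpm = 0)
  out <- dual_quantile_filter(et, theta = 0.2)
  expect_equal(out$family[out$pass], c("f9", "f10"))
  # brute-force reconstruction: intersection of the two axis memberships
  thr_ip <- quantile(et$ip_rpm, 0.8, names = FALSE)
  thr_e <- quantile(et$e, 0.8, names = FALSE)
  expect_equal(out$pass, et$ip_rpm >= thr_ip & et$e >= thr_e)
})

test_that("quantile filter tie and degenerate conventions", {
  # all families identical on both axes: everything passes
  et <- data.frame(family = paste0("f", 1:5), ip_rpm = 7, e = 2)
  expect_true(all(dual_quantile_filter(et)$pass))
  # a single family with ip_rpm > 0 passes
  et1 <- data.frame(family = "f1", ip_rpm = 3, e = 0.5)
  expect_true(dual_quantile_filter(et1)$pass)
  # zero-RPM families are excluded from the universe and never pass
  et0 <- data.frame(family = c("f1", "f2"), ip_rpm = c(5, 0), e = c(2, 9))
  out0 <- dual_quantile_filter(et0)
  expect_equal(out0$pass, c(TRUE, FALSE))
  expect_warning(dual_quantile_filter(
    data.frame(family = "f1", ip_rpm = 0, e = 1)), "empty")
})

test_that("pass flags are invariant under rescaling of IP counts", {
  g <- small_genome(seed = 7L)
  ip <- sim_sample(g, c(telA = 10, telB = 10, telC = 10), 5000, seed = 71L)
  ctrl <- sim_sample(g, numeric(0), 5000, seed = 72L, label = "no_tag")
  base <- repeat_enrichment(list(ip$ct), list(ctrl$ct))
  scaled_ct <- ip$ct
  scaled_ct$count <- scaled_ct$count * 13L
  scaled_ct$total_mapped <- scaled_ct$total_mapped * 13L
  scaled <- repeat_enrichment(list(scaled_ct), list(ctrl$ct))
  expect_equal(scaled$pass, base$pass)
  expect_equal(scaled$ip_rpm, base$ip_rpm)
})

test_that("subfamily merging sums counts and recomputes RPM from sums", {
  map <- data.frame(subfamily = c("HeTA_1D", "HeTA_2", "TARTA"),
                    family = c("HeTA", "HeTA", "TARTA"))
  ct <- make_counts(c(HeTA_1D = 30L, HeTA_2 = 70L, TARTA = 50L), 200000L)
  merged <- merge_subfamilies(ct, map)
  expect_equal(merged$count[merged$family == "HeTA"], 100L)
  # merged RPM = RPM of summed counts, not the mean of subfamily RPMs
  expect_equal(merged$rpm[merged$family == "HeTA"], 100 * 1e6 / 200000)
  sub_rpms <- rpm_normalize(ct)$rpm[1:2]
  expect_false(isTRUE(all.equal(merged$rpm[merged$family == "HeTA"],
                                mean(sub_rpms))))
  # identity map leaves the table unchanged
  idmap <- data.frame(subfamily = c("A", "B"), family = c("A", "B"))
  ct2 <- make_counts(c(A = 10L, B = 20L), 1000L)
  m2 <- merge_subfamilies(ct2, idmap)
  expect_equal(setNames(m2$count, m2$family), c(A = 10L, B = 20L))
  expect_error(merge_subfamilies(make_counts(c(zzz = 1L), 10L), idmap),
               "mapping error.*zzz")
})

test_that("replicate concordance matches the rank-formula oracle", {
  rpm <- function(v) data.frame(family = paste0("f", seq_along(v)), rpm = v)
  expect_equal(replicate_concordance(rpm(c(1, 5, 9, 2, 4)),
                                     rpm(c(1, 5, 9, 2, 4))), 1.0)
  expect_equal(replicate_concordance(rpm(1:5), rpm(5:1)), -1.0)
  # 8 families, one adjacent pair swapped: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  a <- c(10, 20, 30, 40, 50, 60, 70, 80)
  b <- c(10, 20, 40, 30, 50, 60, 70, 80)
  d2 <- sum((rank(a) - rank(b))^2)
  expect_equal(replicate_concordance(rpm(a), rpm(b)),
               1 - 6 * d2 / (8 * (8^2 - 1)))
  expect_error(replicate_concordance(rpm(1:2), rpm(1:2)), "fewer than 3")
})

test_that("per-replicate mode requires a family to pass in every replicate", {
  tab <- function(tel_count) {
    fams <- c("tel", paste0("f", 1:9))
    make_counts(setNames(c(tel_count, (1:9) * 10L), fams), 100000L)
  }
  ip1 <- tab(5000L)   # tel dominant in rep1
  ip2 <- tab(50L)     # tel unremarkable in rep2
  ctrl <- tab(50L)
  res <- repeat_enrichment(list(ip1, ip2), list(ctrl, ctrl))
  expect_false(res$pass[res$family == "tel"])
  res_both <- repeat_enrichment(list(ip1, ip1), list(ctrl, ctrl))
  expect_true(res_both$pass[res_both$family == "tel"])
})
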