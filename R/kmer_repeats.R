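#' Canonical tandem repeat unit
#'
#' The lexicographically smallest string among all rotations of the unit and
#' all rotations of its reverse complement, so that e.g. GA/AG/TC/CT tandems
#' collapse onto a single record ("AG"). Idempotent.
#' @param unit character vector of DNA units over A/C/G/T
#' @return character vector of canonical units
#' @export
canonical_unit <- function(unit) {
  unit <- toupper(unit)
  if (any(nchar(unit) < 1)) stopf("unit must have length >= 1")
  if (any(grepl("[^ACGT]", unit)))
    stopf("input error: unit contains non-ACGT characters")
  cpp_canonical_unit(unit)
}

#' Detect a tandem simple-repeat unit in a read
#'
#' Finds unit lengths k <= `k_max` for which some phase yields at least
#' `min_copies` consecutive exact copies covering at least `min_fraction` of
#' the read. The maximal-coverage run wins; ties are broken by smaller k,
#' then by lexicographically smaller canonical unit. The reported unit is
#' primitive (a run of a non-primitive unit is always dominated by its
#' primitive root at equal coverage and smaller k).
#'
#' @param reads character vector of read sequences
#' @param k_max maximum unit length
#' @param min_copies minimum consecutive exact copies
#' @param min_fraction minimum fraction of the read covered by the run
#' @return data.frame with columns `unit` (canonical; `NA` when no candidate
#'   qualifies) and `copies` (maximal consecutive copy number)
#' @export
detect_tandem <- function(reads, k_max = 20L, min_copies = 3L,
                          min_fraction = 0.5) {
  res <- cpp_detect_tandem(toupper(as.character(reads)), as.integer(k_max),
                           as.integer(min_copies), as.numeric(min_fraction))
  data.frame(unit = res$unit, copies = res$copies, stringsAsFactors = FALSE)
}

#' Tandem k-mer count table for one sample
#'
#' One record per canonical unit; `count` is the number of reads whose
#' detected tandem unit is that unit, and RPM is normalized to the number of
#' reads mapped to the assembly (not the tandem-read count).
#'
#' @param reads character vector of read sequences, or a `read_set` (both
#'   mates used)
#' @param total_mapped reads mapped to the assembly (> 0), the RPM
#'   denominator
#' @param k_max,min_copies,min_fraction see [detect_tandem()]
#' @return data.frame with columns `unit`, `k`, `count`, `rpm`
#' @export
kmer_table <- function(reads, total_mapped, k_max = 20L, min_copies = 3L,
                       min_fraction = 0.5) {
  if (total_mapped <= 0)
    stopf("normalization error: total_mapped must be > 0")
  if (inherits(reads, "read_set")) reads <- c(reads$r1, reads$r2)
  det <- detect_tandem(reads, k_max, min_copies, min_fraction)
  units <- det$unit[!is.na(det$unit)]
  if (length(units) == 0)
    return(data.frame(unit = character(0), k = integer(0),
                      count = integer(0), rpm = numeric(0),
                      stringsAsFactors = FALSE))
  tab <- table(units)
  data.frame(unit = names(tab), k = nchar(names(tab)),
             count = as.integer(tab),
             rpm = as.integer(tab) * 1e6 / total_mapped,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simple-repeat enrichment rule over replicates
#'
#' A canonical unit passes when, in every IP replicate, its RPM exceeds
#' `rpm_min` and its enrichment E = (ip_rpm + eps) / (ctrl_rpm + eps)
#' exceeds `e_min` (strict inequalities; default thresholds RPM > 10 and
#' E > 1 in both replicates).
#'
#' @param ip_tables list of [kmer_table()]s, one per IP replicate
#' @param ctrl_tables list of control [kmer_table()]s (recycled to the
#'   number of IP replicates); a single table may be given directly
#' @param eps pseudocount (RPM)
#' @param rpm_min RPM threshold (strict)
#' @param e_min enrichment threshold (strict)
#' @return data.frame with `unit`, `k`, per-replicate `rpm_*` and `e_*`
#'   columns, and `pass`
#' @export
kmer_enrichment_filter <- function(ip_tables, ctrl_tables, eps = 0.01,
                                   rpm_min = 10, e_min = 1) {
  if (is.data.frame(ip_tables)) ip_tables <- list(ip_tables)
  if (is.data.frame(ctrl_tables)) ctrl_tables <- list(ctrl_tables)
  n_rep <- length(ip_tables)
  if (n_rep < 2)
    warning("fewer than 2 replicates: the both-replicates rule degenerates")
  if (length(ctrl_tables) < n_rep)
    ctrl_tables <- rep(ctrl_tables, length.out = n_rep)
  units <- sort(unique(unlist(lapply(ip_tables, `[[`, "unit"))))
  out <- data.frame(unit = units, k = nchar(units), stringsAsFactors = FALSE)
  pass <- rep(TRUE, length(units))
  for (r in seq_len(n_rep)) {
    ipr <- setNames(rep(0, length(units)), units)
    m <- match(ip_tables[[r]]$unit, units)
    ipr[m[!is.na(m)]] <- ip_tables[[r]]$rpm[!is.na(m)]
    ctr <- setNames(rep(0, length(units)), units)
    m <- match(ctrl_tables[[r]]$unit, units)
    ctr[m[!is.na(m)]] <- ctrl_tables[[r]]$rpm[!is.na(m)]
    e <- (ipr + eps) / (ctr + eps)
    out[[paste0("rpm_rep", r)]] <- unname(ipr)
    out[[paste0("e_rep", r)]] <- unname(e)
    pass <- pass & ipr > rpm_min & e > e_min
  }
  out$pass <- pass
  out
}
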