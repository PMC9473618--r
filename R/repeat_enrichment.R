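#' RPM-normalize a count table
#'
#' RPM (reads per million mapped reads) = count x 1e6 / total_mapped,
#' per sample.
#' @param counts count table as from [count_by_family()] (columns `family`,
#'   `count`, `total_mapped`, plus optional labels)
#' @return the table with an `rpm` column added
#' @export
rpm_normalize <- function(counts) {
  if (any(counts$total_mapped <= 0))
    stopf("normalization error: total_mapped must be > 0")
  counts$rpm <- counts$count * 1e6 / counts$total_mapped
  counts
}

#' IP over control enrichment ratio per family
#'
#' E = (ip_rpm + eps) / (ctrl_rpm + eps). The pseudocount keeps the ratio
#' defined for families absent from the control; families missing from
#' either table are treated as RPM 0.
#'
#' @param ip,ctrl RPM tables (columns `family`, `rpm`)
#' @param eps pseudocount in RPM units (> 0)
#' @return data.frame with columns `family`, `ip_rpm`, `ctrl_rpm`, `e`
#' @export
enrichment_ratio <- function(ip, ctrl, eps = 0.01) {
  if (eps <= 0) stopf("configuration error: eps must be > 0")
  fams <- sort(union(ip$family, ctrl$family))
  ip_rpm <- setNames(rep(0, length(fams)), fams)
  ctrl_rpm <- ip_rpm
  ip_rpm[ip$family] <- ip$rpm
  ctrl_rpm[ctrl$family] <- ctrl$rpm
  data.frame(family = fams, ip_rpm = unname(ip_rpm),
             ctrl_rpm = unname(ctrl_rpm),
             e = unname((ip_rpm + eps) / (ctrl_rpm + eps)),
             stringsAsFactors = FALSE)
}

#' Dual top-quantile enrichment filter
#'
#' A family passes when it lies in the top `theta` fraction of IP RPM *and*
#' the top `theta` fraction of IP/control enrichment (default: the published
#' dual top-20% rule). The quantile universe is restricted to families with
#' `ip_rpm > 0`; thresholds are the empirical (1 - theta) quantiles
#' (`stats::quantile`, type 7) and membership is inclusive (>=), so ties at
#' the threshold all pass that axis.
#'
#' @param etab enrichment table from [enrichment_ratio()]
#' @param theta top-quantile fraction in (0, 1]
#' @return `etab` with a logical `pass` column; attributes `ip_threshold`
#'   and `e_threshold`
#' @export
dual_quantile_filter <- function(etab, theta = 0.2) {
  if (theta <= 0 || theta > 1) stopf("theta must be in (0, 1]")
  u <- etab$ip_rpm > 0
  if (!any(u)) {
    warning("empty quantile universe (no family with ip_rpm > 0)")
    etab$pass <- rep(FALSE, nrow(etab))
    return(etab)
  }
  thr_ip <- quantile(etab$ip_rpm[u], 1 - theta, names = FALSE, type = 7)
  thr_e <- quantile(etab$e[u], 1 - theta, names = FALSE, type = 7)
  etab$pass <- u & etab$ip_rpm >= thr_ip & etab$e >= thr_e
  attr(etab, "ip_threshold") <- thr_ip
  attr(etab, "e_threshold") <- thr_e
  etab
}

#' Merge subfamily counts onto families
#'
#' Counts are summed over subfamilies and RPM is recomputed from the merged
#' counts (never averaged over subfamily RPMs).
#' @param counts count table (columns `family` holding subfamily labels,
#'   `count`, `total_mapped`, optional `sample`/`replicate`)
#' @param map data.frame with columns `subfamily`, `family`; must cover
#'   every subfamily present. Labels absent from the map raise an error,
#'   except reserved classes (`background`, `simple_*`,
#'   `centromere_island`), which pass through unchanged.
#' @return merged count table with `rpm` recomputed
#' @export
merge_subfamilies <- function(counts, map) {
  reserved <- counts$family %in% c("background", "centromere_island") |
    startsWith(counts$family, "simple_")
  idx <- match(counts$family, map$subfamily)
  unknown <- is.na(idx) & !reserved
  if (any(unknown))
    stopf("mapping error: subfamily not in map: %s",
          paste(unique(counts$family[unknown]), collapse = ", "))
  fam <- ifelse(is.na(idx), counts$family, map$family[idx])
  key_cols <- intersect(c("sample", "replicate"), colnames(counts))
  key <- if (length(key_cols)) do.call(paste, c(counts[key_cols], sep = "\r"))
         else rep("", nrow(counts))
  agg <- aggregate(counts$count, by = list(key = key, family = fam), FUN = sum)
  first <- match(paste(agg$key, agg$family, sep = "\r"),
                 paste(key, fam, sep = "\r"))
  out <- counts[first, setdiff(colnames(counts), c("family", "count", "rpm")),
                drop = FALSE]
  out$family <- agg$family
  out$count <- agg$x
  rownames(out) <- NULL
  out <- out[order(out$family), , drop = FALSE]
  if ("total_mapped" %in% colnames(out)) out <- rpm_normalize(out)
  rownames(out) <- NULL
  out
}

#' Replicate concordance (Spearman rank correlation)
#'
#' Spearman rank correlation of per-family RPM between two replicates, over
#' the shared family universe, with average-rank tie handling.
#' @param rpm_a,rpm_b RPM tables (columns `family`, `rpm`)
#' @return Spearman's rho
#' @export
replicate_concordance <- function(rpm_a, rpm_b) {
  shared <- intersect(rpm_a$family, rpm_b$family)
  if (length(shared) < 3)
    stopf("replicate concordance undefined: fewer than 3 shared families")
  a <- rpm_a$rpm[match(shared, rpm_a$family)]
  b <- rpm_b$rpm[match(shared, rpm_b$family)]
  cor(a, b, method = "spearman")
}

#' Per-replicate dual-filter enrichment analysis
#'
#' Computes the enrichment table and dual top-quantile pass flags per
#' replicate and combines them: in `per_replicate` mode a family passes only
#' if it passes in every replicate; in `pooled` mode replicate counts are
#' summed before a single filter. Reported `ip_rpm`/`ctrl_rpm`/`e` are means
#' over replicates (per_replicate mode) or pooled values.
#'
#' @param ip_counts list of count tables, one per IP replicate
#' @param ctrl_counts list of count tables, one per control replicate
#'   (recycled if shorter than `ip_counts`)
#' @param theta top-quantile fraction
#' @param eps pseudocount (RPM)
#' @param mode `"per_replicate"` (default) or `"pooled"`
#' @return enrichment table with `pass` column
#' @export
repeat_enrichment <- function(ip_counts, ctrl_counts, theta = 0.2,
                              eps = 0.01,
                              mode = c("per_replicate", "pooled")) {
  mode <- match.arg(mode)
  n_rep <- length(ip_counts)
  if (length(ctrl_counts) < n_rep)
    ctrl_counts <- rep(ctrl_counts, length.out = n_rep)
  if (mode == "pooled") {
    pool <- function(lst) {
      fam <- sort(unique(unlist(lapply(lst, `[[`, "family"))))
      cnt <- rep(0L, length(fam))
      tot <- 0L
      for (x in lst) {
        cnt <- cnt + ifelse(is.na(match(fam, x$family)), 0L,
                            x$count[match(fam, x$family)])
        tot <- tot + x$total_mapped[1]
      }
      data.frame(family = fam, count = cnt, total_mapped = tot,
                 stringsAsFactors = FALSE)
    }
    etab <- enrichment_ratio(rpm_normalize(pool(ip_counts)),
                             rpm_normalize(pool(ctrl_counts)), eps)
    return(dual_quantile_filter(etab, theta))
  }
  per_rep <- lapply(seq_len(n_rep), function(r) {
    etab <- enrichment_ratio(rpm_normalize(ip_counts[[r]]),
                             rpm_normalize(ctrl_counts[[r]]), eps)
    dual_quantile_filter(etab, theta)
  })
  fams <- sort(unique(unlist(lapply(per_rep, `[[`, "family"))))
  get <- function(etab, col) {
    v <- rep(0, length(fams))
    v[match(etab$family, fams)] <- etab[[col]]
    v
  }
  out <- data.frame(
    family = fams,
    ip_rpm = rowMeans(sapply(per_rep, get, "ip_rpm")),
    ctrl_rpm = rowMeans(sapply(per_rep, get, "ctrl_rpm")),
    e = rowMeans(sapply(per_rep, get, "e")),
    pass = apply(sapply(per_rep, function(x) {
      p <- rep(FALSE, length(fams))
      p[match(x$family, fams)] <- x$pass
      p
    }), 1, all),
    stringsAsFactors = FALSE)
  attr(out, "per_replicate") <- per_rep
  out
}
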