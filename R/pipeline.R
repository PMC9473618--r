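#' Validate a pipeline configuration
#'
#' A configuration is a list (typically from YAML) with components `genome`
#' (toy-genome settings or paths to existing files), `samples` (list of
#' sample descriptions: `sample_label` in IP/no_tag/whole_genome,
#' `target_name`, `replicate_id`, and either `n_pairs` + optional `weights`
#' for simulation or `r1`/`r2` FASTQ paths), and `params` (theta, eps, mapq,
#' bin_size, k_max, min_copies, min_fraction, read_length,
#' fragment_length_mean, fragment_length_sd, error_rate).
#'
#' @param config configuration list or YAML path
#' @return the normalized configuration list; errors on invalid input
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$samples) || length(config$samples) == 0)
    stopf("validation error: no samples in config")
  labs <- vapply(config$samples, function(s) s$sample_label %||% "",
                 character(1))
  bad <- !labs %in% c("IP", "no_tag", "whole_genome")
  if (any(bad))
    stopf("validation error: invalid sample_label '%s'", labs[bad][1])
  if (any(labs == "IP") && !any(labs == "no_tag"))
    stopf("validation error: IP samples present but no no_tag control sample")
  key <- vapply(config$samples, function(s)
    paste(s$sample_label %||% "", s$target_name %||% "",
          s$replicate_id %||% ""), character(1))
  if (anyDuplicated(key))
    stopf("validation error: duplicate (sample_label, target, replicate)")
  for (s in config$samples) {
    if (is.null(s$n_pairs) && (is.null(s$r1) || is.null(s$r2)))
      stopf("validation error: sample without n_pairs or FASTQ paths")
    if (!is.null(s$r1) && !file.exists(s$r1))
      stopf("validation error: missing file %s", s$r1)
    if (!is.null(s$r2) && !file.exists(s$r2))
      stopf("validation error: missing file %s", s$r2)
  }
  config$params <- config$params %||% list()
  config
}

pipeline_params <- function(config) {
  p <- config$params %||% list()
  list(theta = p$theta %||% 0.2, eps = p$eps %||% 0.01,
       mapq = p$mapq %||% 10L, bin_size = p$bin_size %||% 100L,
       k_max = p$k_max %||% 20L, min_copies = p$min_copies %||% 3L,
       min_fraction = p$min_fraction %||% 0.5,
       read_length = p$read_length %||% 50L,
       fragment_length_mean = p$fragment_length_mean %||% 200,
       fragment_length_sd = p$fragment_length_sd %||% 40,
       error_rate = p$error_rate %||% 0.001,
       seed_k = p$seed_k %||% 20L,
       max_mismatches = p$max_mismatches %||% 5L,
       min_identity = p$min_identity %||% 0.9,
       pileup_families = p$pileup_families)
}

# genome settings from config, with toy_genome_config defaults
config_genome <- function(config, seed) {
  g <- config$genome %||% list()
  defaults <- toy_genome_config(seed = seed)
  for (nm in names(g)) {
    v <- g[[nm]]
    if (nm %in% c("telomeric_families", "centromeric_families",
                  "background_families", "simple_repeats"))
      v <- unlist(v)
    defaults[[nm]] <- v
  }
  defaults$seed <- as.integer(g$seed %||% seed)
  defaults
}

#' Run the repeat-centric analysis pipeline end-to-end
#'
#' Executes simulate (or FASTQ ingest) -> align -> count -> enrich ->
#' pileup -> kmers -> tracks, writing every stage's outputs under `out_dir`
#' and a machine-readable `summary.json` with parameters and per-sample
#' metrics (total reads, mapped reads, assigned reads). Deterministic given
#' `seed`. With `resume = TRUE`, previously written genome/read files under
#' `out_dir` are reloaded instead of regenerated (simulation is the only
#' stochastic stage, so downstream outputs are identical).
#'
#' @param config configuration list or YAML path (see [validate_config()])
#' @param out_dir output directory
#' @param seed integer seed for all stochastic stages
#' @param resume reuse existing simulate-stage outputs under `out_dir`
#' @return (invisibly) a list with the main in-memory results: `genome`,
#'   `counts`, `enrichment`, `kmers`, `metrics`, `region_report`
#' @export
run_pipeline <- function(config, out_dir, seed = 1L, resume = FALSE) {
  config <- validate_config(config)
  par <- pipeline_params(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gdir <- file.path(out_dir, "genome")
  rdir <- file.path(out_dir, "reads")
  adir <- file.path(out_dir, "alignments")
  pdir <- file.path(out_dir, "pileup")
  tdir <- file.path(out_dir, "tracks")
  for (d in c(gdir, rdir, adir, pdir, tdir))
    dir.create(d, showWarnings = FALSE)

  # --- stage: simulate (or ingest) ---
  gcfg <- config_genome(config, seed)
  if (resume && file.exists(file.path(gdir, "genome.fa"))) {
    genome <- read_toy_genome(gdir)
  } else {
    genome <- build_toy_genome(gcfg)
    write_toy_genome(genome, gdir)
  }
  tel_families <- names(gcfg$telomeric_families)

  read_sets <- list()
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    tag <- paste(s$sample_label %||% "IP", s$target_name %||% "target",
                 s$replicate_id %||% "rep1", sep = "_")
    prefix <- file.path(rdir, tag)
    if (!is.null(s$r1)) {
      rs <- read_fastq_pair(s$r1, s$r2, s$sample_label,
                            s$target_name %||% "target",
                            s$replicate_id %||% "rep1")
    } else if (resume && file.exists(paste0(prefix, "_R1.fastq"))) {
      rs <- read_fastq_pair(paste0(prefix, "_R1.fastq"),
                            paste0(prefix, "_R2.fastq"), s$sample_label,
                            s$target_name %||% "target",
                            s$replicate_id %||% "rep1")
    } else {
      prof <- enrichment_profile(
        weights = unlist(s$weights) %||% numeric(0),
        error_rate = par$error_rate,
        fragment_length_mean = par$fragment_length_mean,
        fragment_length_sd = par$fragment_length_sd,
        read_length = par$read_length, seed = seed + i)
      rs <- simulate_reads(genome, prof, s$n_pairs, s$sample_label,
                           s$target_name %||% "target",
                           s$replicate_id %||% "rep1")
      write_read_set(rs, prefix)
    }
    read_sets[[tag]] <- rs
  }

  # --- stage: align + count ---
  refs <- setNames(genome$sequence, genome$chrom_name)
  ref_lengths <- setNames(nchar(genome$sequence), genome$chrom_name)
  alns <- list()
  counts <- list()
  metrics <- list()
  for (tag in names(read_sets)) {
    rs <- read_sets[[tag]]
    aln <- align_minimal(rs, refs, k = par$seed_k,
                         max_mismatches = par$max_mismatches)
    write_sam(aln, ref_lengths, file.path(adir, paste0(tag, ".sam")))
    ct <- count_by_family(aln, genome$annotation,
                          sample_label = rs$sample_label,
                          replicate_id = rs$replicate_id)
    ct$target <- rs$target_name
    alns[[tag]] <- aln
    counts[[tag]] <- ct
    metrics[[tag]] <- list(sample = tag,
                           total_reads = attr(aln, "n_input"),
                           mapped_reads = nrow(aln),
                           assigned_reads = sum(ct$count))
  }
  count_table <- do.call(rbind, c(counts, make.row.names = FALSE))
  rpm_table <- rpm_normalize(count_table)
  write.table(rpm_table, file.path(out_dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- stage: enrich (per IP target, per-replicate dual filter) ---
  is_ip <- vapply(read_sets, function(r) r$sample_label == "IP", logical(1))
  is_ctrl <- vapply(read_sets, function(r) r$sample_label == "no_tag",
                    logical(1))
  enrichment <- NULL
  if (any(is_ip) && any(is_ctrl)) {
    ord <- function(x) x[order(vapply(x, function(ct) ct$replicate[1],
                                      character(1)))]
    ip_counts <- ord(counts[is_ip])
    ctrl_counts <- ord(counts[is_ctrl])
    enrichment <- repeat_enrichment(ip_counts, ctrl_counts,
                                    theta = par$theta, eps = par$eps)
    write.table(enrichment, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # --- stage: pileup (telomeric consensus profiles) ---
  pf <- par$pileup_families %||% tel_families
  pf <- intersect(pf, names(genome$library$consensus))
  if (length(pf) > 0 && any(is_ip) && any(is_ctrl)) {
    ip_tags <- names(read_sets)[is_ip]
    ctrl_tag <- names(read_sets)[is_ctrl][1]
    ip_piles <- lapply(ip_tags, function(tag)
      consensus_pileup(read_sets[[tag]], genome$library,
                       total_mapped = metrics[[tag]]$mapped_reads,
                       families = pf, min_identity = par$min_identity,
                       k = par$seed_k))
    ctrl_pile <- consensus_pileup(read_sets[[ctrl_tag]], genome$library,
                                  total_mapped =
                                    metrics[[ctrl_tag]]$mapped_reads,
                                  families = pf,
                                  min_identity = par$min_identity,
                                  k = par$seed_k)
    for (f in pf) {
      write_profile_tsv(lapply(ip_piles, `[[`, f), ctrl_pile[[f]],
                        file.path(pdir, paste0(f, ".tsv")), eps = par$eps)
    }
  }

  # --- stage: kmers ---
  ktabs <- lapply(names(read_sets), function(tag)
    kmer_table(read_sets[[tag]], metrics[[tag]]$mapped_reads,
               k_max = par$k_max, min_copies = par$min_copies,
               min_fraction = par$min_fraction))
  names(ktabs) <- names(read_sets)
  kmers <- NULL
  if (any(is_ip) && any(is_ctrl)) {
    ord_k <- function(x, sel) {
      x <- x[sel]
      x[order(vapply(names(x), function(tag)
        read_sets[[tag]]$replicate_id, character(1)))]
    }
    kmers <- kmer_enrichment_filter(unname(ord_k(ktabs, is_ip)),
                                    unname(ord_k(ktabs, is_ctrl)),
                                    eps = par$eps)
    write.table(kmers, file.path(out_dir, "kmers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # --- stage: tracks + region report ---
  ann <- genome$annotation
  regions <- data.frame(name = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        stringsAsFactors = FALSE)
  tel_ann <- ann[ann$family %in% tel_families, , drop = FALSE]
  if (nrow(tel_ann) > 0)
    regions <- rbind(regions, data.frame(
      name = "telomere", chrom = genome$chrom_name,
      start = min(tel_ann$start), end = max(tel_ann$end)))
  cen_ann <- ann[ann$family %in% names(gcfg$centromeric_families), ,
                 drop = FALSE]
  if (nrow(cen_ann) > 0)
    regions <- rbind(regions, data.frame(
      name = "centromere", chrom = genome$chrom_name,
      start = min(cen_ann$start), end = max(cen_ann$end)))
  reg_reports <- list()
  for (tag in names(read_sets)) {
    frags <- fragment_intervals(alns[[tag]])
    layers <- coverage_layers(frags, ref_lengths, par$bin_size,
                              metrics[[tag]]$mapped_reads)
    write_bedgraph(layers$all, file.path(tdir, paste0(tag, "_all.bedgraph")))
    write_bedgraph(layers$unique,
                   file.path(tdir, paste0(tag, "_unique.bedgraph")))
    if (nrow(regions) > 0) {
      rr <- region_report(layers, regions)
      rr$sample <- tag
      reg_reports[[tag]] <- rr
    }
  }
  region_tab <- if (length(reg_reports))
    do.call(rbind, c(reg_reports, make.row.names = FALSE)) else NULL
  if (!is.null(region_tab))
    write.table(region_tab, file.path(out_dir, "regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  summary <- list(
    package = "repeatcnr",
    version = as.character(utils::packageVersion("repeatcnr")),
    seed = seed, parameters = par,
    metrics = unname(metrics))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(genome = genome, counts = rpm_table,
                 enrichment = enrichment, kmers = kmers,
                 metrics = metrics, region_report = region_tab))
}
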