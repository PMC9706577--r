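#' Build a benchmark set for one sample
#'
#' The end-to-end engine: computes per-callset callable regions from depth
#' tracks (HiFi union semantics, linked-read haplotype-XOR subtraction,
#' plain depth thresholds for short-read callsets), builds the
#' difficult-region exclusion stack (many-copy segmental duplications,
#' coverage-outlier and dual-technology CNV evidence, assembly
#' multi-contig regions, SV regions, long tandem repeats, fixed tracks)
#' with progressive accounting, arbitrates calls across callsets, and
#' composes the final benchmark VCF + BED.
#'
#' @param sites_by_callset named list of [variant_sites()] tables.
#' @param technologies named character vector: callset label -> technology
#'   class token.
#' @param annotation_only named logical vector per callset.
#' @param depth_tracks named list per technology role: `hifi` and `tenx`
#'   entries are lists with `unsplit`, `hap1`, `hap2` [depth_track()]s;
#'   `short` has `unsplit`.  Short-read callsets use `short`.
#' @param windows a [coverage_windows()] table (HiFi + ONT depths).
#' @param tracks a [repeat_class_tracks()] bundle.
#' @param segdup_records segdup record table for [filter_segdups()].
#' @param fixed_sets named list of always-excluded [region_set()]s placed
#'   at the top of the ledger (e.g. centromere/heterochromatin, VDJ, KIR).
#' @param sv_regions SV benchmark [region_set()] (expanded 25% each side).
#' @param tr_gt10k tandem repeats longer than 10 kb.
#' @param external_cnv external CNV calls intersected with the
#'   dual-technology high-coverage windows.
#' @param assemblies optional list for [assembly_multicontig()].
#' @param genome a [genome_file()].
#' @param cfg a [callable_config()].
#' @param min_support minimum agreeing callsets (default 2).
#' @return A list: `benchmark` ([benchmark_set()]), `ledger`, `callable`
#'   (per-callset), `conflict`, `accepted`, `counts` (per-stage counts).
#' @export
run_sample_benchmark <- function(sites_by_callset, technologies,
                                 annotation_only, depth_tracks, windows,
                                 tracks, segdup_records,
                                 fixed_sets = list(),
                                 sv_regions = region_set(),
                                 tr_gt10k = region_set(),
                                 external_cnv = NULL, assemblies = NULL,
                                 genome = NULL, cfg = callable_config(),
                                 min_support = 2) {
  labs <- names(sites_by_callset)
  callable <- list()
  kept_sites <- sites_by_callset
  for (l in labs) {
    if (annotation_only[[l]]) { callable[l] <- list(NULL); next }
    tech <- technologies[[l]]
    s <- sites_by_callset[[l]]
    if (grepl("^hifi", tech)) {
      mk <- hifi_vcf_mask(s)
      kept_sites[[l]] <- mk$sites
      tr <- depth_tracks$hifi
      callable[[l]] <- hifi_callable(tr$unsplit, tr$hap1, tr$hap2, cfg,
                                     mask = mk$mask, sites = mk$sites)
    } else if (tech == "tenx") {
      mk <- filtered_indel_mask(s)
      kept_sites[[l]] <- mk$sites
      tr <- depth_tracks$tenx
      callable[[l]] <- linkedread_callable(tr$unsplit, tr$hap1, tr$hap2, cfg,
                                           filtered_indel_mask = mk$mask,
                                           sites = mk$sites)
    } else {
      tr <- depth_tracks$short$unsplit
      med <- median_depth(tr, s, cfg)
      callable[[l]] <- callable_from_depth(tr, cfg$min_depth_unsplit,
                                           cfg$max_depth_unsplit_factor * med)
    }
  }

  ell <- elliptical_outliers(windows)
  dual <- dual_tech_high_coverage(windows, external_cnv = external_cnv)
  multi <- if (!is.null(assemblies)) assembly_multicontig(assemblies)
           else region_set()
  cnv_excl <- union_regions(list(ell$regions, dual, multi))
  segdup_excl <- filter_segdups(segdup_records)
  sv_excl <- if (nrow(sv_regions))
    sv_exclusion(sv_regions, mode = "benchmark_bed", genome = genome)
  else region_set()
  excl_sets <- c(fixed_sets,
                 list(segdup_highcopy = segdup_excl,
                      cnv_coverage = cnv_excl,
                      sv_expanded = sv_excl,
                      tr_gt10k = normalize_regions(tr_gt10k)))
  ledger <- compose_exclusions(excl_sets, genome = genome)

  profiles <- lapply(stats::setNames(labs, labs), function(l)
    callset_profile(l, technologies[[l]], callable = callable[[l]],
                    annotation_only = annotation_only[[l]]))
  arb <- arbitrate(kept_sites, profiles, tracks, min_support = min_support)
  bench <- build_benchmark(arb$accepted, profiles, tracks, ledger,
                           conflict = arb$conflict, genome = genome,
                           min_support = min_support)
  counts <- list(
    input_sites = vapply(sites_by_callset, nrow, integer(1)),
    callable_bp = vapply(callable, function(x) if (is.null(x)) NA_real_
                         else region_bp(x), numeric(1)),
    excluded_bp = region_bp(attr(ledger, "total")),
    conflict_bp = region_bp(arb$conflict),
    accepted = nrow(arb$accepted),
    benchmark_variants = nrow(bench$variants),
    benchmark_bp = region_bp(bench$regions))
  list(benchmark = bench, ledger = ledger, callable = callable,
       conflict = arb$conflict, accepted = arb$accepted, counts = counts)
}

#' Run the benchmark pipeline on a synthetic fixture bundle
#'
#' Convenience wrapper wiring a [make_fixtures()] bundle into
#' [run_sample_benchmark()] for one trio member.
#'
#' @param fx output of [make_fixtures()].
#' @param member `"son"`, `"father"` or `"mother"`.
#' @param min_support minimum agreeing callsets.
#' @return See [run_sample_benchmark()].
#' @export
run_fixture_pipeline <- function(fx, member = "son", min_support = 2) {
  cs <- fx$callsets[[member]]
  gen <- fx$genome
  run_sample_benchmark(
    sites_by_callset = cs$sites,
    technologies = cs$technologies,
    annotation_only = cs$annotation_only,
    depth_tracks = fx$coverage$tracks,
    windows = fx$coverage$windows,
    tracks = gen$tracks,
    segdup_records = gen$segdup_records,
    fixed_sets = list(centromere_heterochromatin = gen$features$centromere,
                      vdj = gen$features$vdj),
    sv_regions = gen$features$sv,
    tr_gt10k = gen$features$tr_gt10k,
    external_cnv = fx$coverage$external_cnv,
    assemblies = fx$coverage$assemblies,
    genome = gen$genome,
    min_support = min_support)
}

validate_config <- function(config) {
  required <- c("genome", "callsets", "tracks", "out_dir")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("config validation error: missing key(s): ", paste(miss, collapse = ", "))
  known <- c(required, "fixed_tracks", "sv_bed", "tr_gt10k_bed", "segdups",
             "external_cnv_bed", "windows_hifi", "windows_ont", "depth",
             "min_support", "thresholds", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("config validation error: unknown key(s): ", paste(unknown, collapse = ", "))
  for (cs in config$callsets) {
    if (is.null(cs$label) || is.null(cs$vcf) || is.null(cs$technology))
      stop("config validation error: each callset needs label, vcf, technology")
    if (!file.exists(cs$vcf)) stop("config validation error: missing file ", cs$vcf)
  }
  invisible(TRUE)
}

#' Run the full pipeline from a YAML config of file paths
#'
#' Reads a config listing the genome file, per-callset VCFs (with
#' technology class and depth-track paths), annotation tracks and
#' thresholds; runs [run_sample_benchmark()]; writes the benchmark VCF,
#' BED, the exclusion ledger TSV, and a JSON run log with parameters and
#' per-stage counts.  The pipeline is a pure function of (config, inputs).
#'
#' @param config path to a YAML config, or an equivalent named list.
#' @return Invisibly, the [run_sample_benchmark()] result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  genome <- read_genome_file(config$genome)
  sites <- list(); technologies <- character(); annotation_only <- logical()
  for (cs in config$callsets) {
    sites[[cs$label]] <- read_vcf(cs$vcf, callset = cs$label)
    technologies[cs$label] <- cs$technology
    annotation_only[cs$label] <- isTRUE(cs$annotation_only)
  }
  read_track <- function(path) if (is.null(path)) region_set() else
    read_bed(path, genome = genome)
  tr_names <- c("tr_lt51", "tr_51_200", "tr_200_10k", "homopolymer_gt6",
                "imperfect_homopolymer_gt10", "low_mappability",
                "line_l1hs_gt500", "segdup")
  tracks <- do.call(repeat_class_tracks,
                    lapply(stats::setNames(tr_names, tr_names),
                           function(n) read_track(config$tracks[[n]])))
  fixed_sets <- lapply(config$fixed_tracks, read_track)
  depth_tracks <- lapply(config$depth, function(d)
    lapply(d, function(p) read_bedgraph(p)))
  wh <- read_bedgraph(config$windows_hifi)
  wo <- read_bedgraph(config$windows_ont)
  windows <- coverage_windows(wh$chrom, wh$start, wh$end, wh$depth, wo$depth)
  segdups <- utils::read.table(config$segdups, sep = "\t",
                               col.names = c("chrom", "start", "end", "identity"))
  res <- run_sample_benchmark(
    sites_by_callset = sites, technologies = technologies,
    annotation_only = annotation_only, depth_tracks = depth_tracks,
    windows = windows, tracks = tracks, segdup_records = segdups,
    fixed_sets = fixed_sets,
    sv_regions = read_track(config$sv_bed),
    tr_gt10k = read_track(config$tr_gt10k_bed),
    external_cnv = if (is.null(config$external_cnv_bed)) NULL
                   else read_track(config$external_cnv_bed),
    genome = genome,
    min_support = if (is.null(config$min_support)) 2 else config$min_support)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_benchmark(res$benchmark, file.path(config$out_dir, "benchmark.vcf"),
                  file.path(config$out_dir, "benchmark.bed"), genome = genome)
  utils::write.table(as.data.frame(res$ledger),
                     file.path(config$out_dir, "exclusion_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(parameters = config[setdiff(names(config), "callsets")],
         counts = res$counts),
    file.path(config$out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
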