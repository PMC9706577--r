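#' Coverage window table
#'
#' Fixed-width windows (1,000 bp by default; the final window of a
#' chromosome may be shorter) carrying mean HiFi and ONT depth, the joint
#' evidence for copy-number exclusion.
#'
#' @param chrom,start,end window coordinates (0-based half-open).
#' @param hifi_depth,ont_depth mean read depth per window (>= 0).
#' @return A `coverage_windows` data frame.
#' @export
coverage_windows <- function(chrom, start, end, hifi_depth, ont_depth) {
  if (any(hifi_depth < 0) || any(ont_depth < 0)) stop("depths must be >= 0")
  df <- region_set(chrom, start, end)
  df$hifi_depth <- as.numeric(hifi_depth)
  df$ont_depth <- as.numeric(ont_depth)
  class(df) <- c("coverage_windows", "data.frame")
  df
}

#' Elliptical coverage-outlier statistic
#'
#' Flags candidate duplications as windows whose joint median-normalized
#' HiFi/ONT depth is an outlier.  Each window's value is
#' `sqrt(((hifi/median_hifi)^2 + (ont/median_ont)^2) / 2)` (so a window at
#' exactly median depth in both technologies scores 1, and a window at
#' twice the median in both scores 2); a window is flagged when its value
#' strictly exceeds `Q3 + 1.5 * IQR` of all values.  Quartiles use linear
#' interpolation (R quantile type 7).
#'
#' The `form = "sum_sqrt"` variant omits the /2, i.e. the plain root of the
#' summed squares; the flagging rank threshold is not invariant under this
#' nonlinear change, so both forms are exposed.
#'
#' @param tbl a [coverage_windows()] table.
#' @param form `"sqrt_mean_sq"` (default) or `"sum_sqrt"`.
#' @return A list with `stat` (medians, per-window `values`, `threshold`)
#'   and `regions` (normalized [region_set()] of flagged windows).
#' @export
elliptical_outliers <- function(tbl, form = c("sqrt_mean_sq", "sum_sqrt")) {
  form <- match.arg(form)
  mh <- stats::median(tbl$hifi_depth)
  mo <- stats::median(tbl$ont_depth)
  if (mh <= 0 || mo <= 0) stop("degenerate track: median depth is 0")
  ss <- (tbl$hifi_depth / mh)^2 + (tbl$ont_depth / mo)^2
  values <- if (form == "sqrt_mean_sq") sqrt(ss / 2) else sqrt(ss)
  q3 <- stats::quantile(values, 0.75, type = 7, names = FALSE)
  iqr <- q3 - stats::quantile(values, 0.25, type = 7, names = FALSE)
  thr <- q3 + 1.5 * iqr
  flag <- values > thr
  regions <- if (any(flag))
    normalize_regions(region_set(tbl$chrom[flag], tbl$start[flag], tbl$end[flag]))
  else region_set()
  list(stat = list(median_hifi = mh, median_ont = mo, values = values,
                   threshold = thr, flagged = flag),
       regions = regions)
}

#' High-coverage windows supported by both long-read technologies
#'
#' Windows whose HiFi depth and ONT depth both strictly exceed
#' `multiplier` times that technology's mean window depth, intersected with
#' an external CNV call set.  The default multiplier 1.25 reads
#' "mean / 2 * 2.5" left to right.
#'
#' @param tbl a [coverage_windows()] table.
#' @param multiplier positive multiple of the mean (default 1.25).
#' @param external_cnv [region_set()] of CNV calls to intersect with.
#' @return A normalized [region_set()].
#' @export
dual_tech_high_coverage <- function(tbl, multiplier = 1.25,
                                    external_cnv = NULL) {
  stopifnot(multiplier > 0)
  keep <- tbl$hifi_depth > multiplier * mean(tbl$hifi_depth) &
    tbl$ont_depth > multiplier * mean(tbl$ont_depth)
  hi <- if (any(keep))
    normalize_regions(region_set(tbl$chrom[keep], tbl$start[keep], tbl$end[keep]))
  else region_set()
  if (is.null(external_cnv)) hi else intersect_regions(hi, external_cnv)
}

#' Regions covered by two or more assembly contigs, in every assembly
#'
#' For each assembly (a list with maternal and paternal contig-coverage
#' bedGraphs), finds reference bases covered by `min_coverage` or more
#' contigs of a single haplotype -- the signature of a duplication in the
#' sample attracting extra contigs -- taking the union over the
#' haplotypes; intersects across assemblies; keeps merged intervals
#' strictly longer than `min_bp`.  (Coverage is per haplotype, not summed
#' across haplotypes: a complete diploid assembly covers every base once
#' per haplotype, so the summed coverage is 2 genome-wide and carries no
#' signal.)
#'
#' @param assemblies list of assemblies, each a list of one or more
#'   [depth_track()] contig-coverage bedGraphs (typically maternal and
#'   paternal).
#' @param min_coverage per-haplotype contig coverage threshold (default 2,
#'   >=).
#' @param min_bp keep merged intervals strictly longer than this (default
#'   10000).
#' @return A normalized [region_set()].
#' @export
assembly_multicontig <- function(assemblies, min_coverage = 2, min_bp = 10000) {
  if (!length(assemblies)) stop("at least one assembly is required")
  per_asm <- lapply(assemblies, function(tracks) {
    if (inherits(tracks, "data.frame")) tracks <- list(tracks)
    per_hap <- lapply(tracks, function(t)
      pileup_regions(t$chrom, t$start, t$end, t$depth, min_coverage,
                     strict = FALSE))
    union_regions(per_hap)
  })
  inter <- Reduce(intersect_regions, per_asm)
  filter_by_length(normalize_regions(inter), min_bp = min_bp)
}

#' Many-copy, high-identity segmental duplication exclusion
#'
#' From a genomicSuperDups-like record table, keeps duplications strictly
#' longer than 10 kb with identity strictly greater than 99%, then returns
#' bases where the pile-up depth of the kept records is strictly greater
#' than 5 (i.e. more than 5 stacked copies).  Identity columns given as
#' percentages (values > 1.5 observed) are auto-detected and rescaled.
#'
#' @param records data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `identity`.
#' @param min_len strict length threshold in bp (default 10000).
#' @param min_identity strict fractional identity threshold (default 0.99).
#' @param min_depth strict stacking-depth threshold (default 5).
#' @return A normalized [region_set()].
#' @export
filter_segdups <- function(records, min_len = 10000, min_identity = 0.99,
                           min_depth = 5) {
  identity <- records$identity
  if (length(identity) && any(identity > 1.5, na.rm = TRUE)) {
    message("segdup identity column looks like percentages; rescaling by 1/100")
    identity <- identity / 100
  }
  if (length(identity) && any(identity < 0 | identity > 1, na.rm = TRUE))
    stop("segdup identity out of [0, 1]")
  keep <- (records$end - records$start) > min_len & identity > min_identity
  kept <- records[keep, , drop = FALSE]
  if (!nrow(kept)) return(region_set())
  stack_depth_filter(region_set(kept$chrom, kept$start, kept$end), min_depth)
}

## KIR locus, 1-based inclusive source coordinates converted to 0-based
## half-open: GRCh38 chr19:54716689-54871732, GRCh37 19:55228188-55383188.
kir_region <- function(build) {
  switch(build,
         GRCh38 = region_set("chr19", 54716688, 54871732),
         GRCh37 = region_set("19", 55228187, 55383188),
         stop("unknown build: ", build))
}

#' Fixed exclusion tracks for a reference build
#'
#' Assembles the build-specific labelled exclusion sets: the KIR locus from
#' built-in coordinates; the VDJ somatic-recombination regions restricted
#' to chromosomes 2, 14 and 22; for GRCh38, the modeled centromere and
#' heterochromatin track; for GRCh37, the collapsed/expanded-region track.
#'
#' @param tracks named list of [region_set()]s; requires `vdj`, plus
#'   `centromere_heterochromatin` (GRCh38) or `collapsed_expanded` (GRCh37).
#' @param build `"GRCh37"` or `"GRCh38"`.
#' @return Named list of [region_set()]s.
#' @export
fixed_exclusions <- function(tracks, build = c("GRCh38", "GRCh37")) {
  build <- match.arg(build)
  need <- c("vdj", if (build == "GRCh38") "centromere_heterochromatin"
            else "collapsed_expanded")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) stop("missing mandatory track(s): ", paste(miss, collapse = ", "))
  vdj_chroms <- c("2", "14", "22", "chr2", "chr14", "chr22")
  vdj <- tracks$vdj[tracks$vdj$chrom %in% vdj_chroms, , drop = FALSE]
  class(vdj) <- c("region_set", "data.frame")
  out <- list(kir = kir_region(build), vdj = normalize_regions(vdj))
  if (build == "GRCh38")
    out$centromere_heterochromatin <- normalize_regions(tracks$centromere_heterochromatin)
  else
    out$collapsed_expanded <- normalize_regions(tracks$collapsed_expanded)
  out
}

#' Structural-variant exclusion regions
#'
#' `benchmark_bed` mode expands an SV benchmark BED by 25% of each region's
#' size on each side (regions become 150% of their length before merging).
#' `call_expand` mode first widens each SV to the span of itself plus every
#' overlapping repeat interval, then applies the same 25% expansion.
#'
#' @param sv_regions [region_set()] of SV calls or SV benchmark regions.
#' @param repeats [region_set()] of tandem repeats/homopolymers (required
#'   for `call_expand`).
#' @param mode `"benchmark_bed"` or `"call_expand"`.
#' @param genome optional [genome_file()] for clipping.
#' @return A normalized [region_set()].
#' @export
sv_exclusion <- function(sv_regions, repeats = NULL,
                         mode = c("benchmark_bed", "call_expand"),
                         genome = NULL) {
  mode <- match.arg(mode)
  if (mode == "benchmark_bed")
    return(slop_regions(sv_regions, "pct", 0.25, genome = genome))
  if (is.null(repeats)) stop("call_expand mode requires a repeat track")
  if (!nrow(sv_regions)) return(region_set(genome = genome))
  hull <- overlap_hull(sv_regions$chrom, sv_regions$start, sv_regions$end,
                       repeats)
  start <- pmin(sv_regions$start, hull$start, na.rm = TRUE)
  end <- pmax(sv_regions$end, hull$end, na.rm = TRUE)
  widened <- region_set(sv_regions$chrom, start, end)
  slop_regions(widened, "pct", 0.25, genome = genome)
}

#' Compose exclusion classes with progressive-subtraction accounting
#'
#' Given an ordered, labelled list of exclusion region sets, produces a
#' ledger in which each row reports the base pairs a class contributes
#' after subtracting every class above it, so the rows sum exactly to the
#' base pairs of the union of all classes.
#'
#' @param sets ordered named list of [region_set()]s.
#' @param genome optional [genome_file()].
#' @return An `exclusion_ledger`: data frame with `label`, `bp_raw`,
#'   `bp_progressive`; the union of all classes is in attribute `total`.
#' @export
compose_exclusions <- function(sets, genome = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  cum <- region_set(genome = genome)
  rows <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    rows[[i]] <- data.frame(label = names(sets)[i],
                            bp_raw = region_bp(s),
                            bp_progressive = region_bp(subtract_regions(s, cum)),
                            stringsAsFactors = FALSE)
    cum <- union_regions(list(cum, s))
  }
  ledger <- do.call(rbind, rows)
  class(ledger) <- c("exclusion_ledger", "data.frame")
  attr(ledger, "total") <- cum
  ledger
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Exclusion ledger (progressive subtraction):\n")
  print.data.frame(x)
  cat("Total excluded bp:", format(region_bp(attr(x, "total")), big.mark = ","), "\n")
  invisible(x)
}
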