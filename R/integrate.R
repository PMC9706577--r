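## Per-technology repeat-class exclusion matrix.  For each repeat class,
## the technology classes that are *exempt* (the class is excluded from all
## other technologies' callable regions):
##   - tandem repeats < 51 bp:        Illumina PCR-free GATK, Complete
##                                    Genomics, HiFi DeepVariant
##   - tandem repeats 51-200 bp:      Illumina PCR-free GATK, HiFi DeepVariant
##   - tandem repeats 200 bp - 10 kb: HiFi DeepVariant
##   - homopolymers > 6 bp:           Illumina PCR-free GATK, Complete
##                                    Genomics, Ion exome, HiFi DeepVariant
##   - imperfect homopolymers > 10 bp: Illumina PCR-free GATK
##   - low-mappability regions:       10x Genomics, HiFi (both callers)
##   - LINE L1Hs > 500 bp:            Illumina mate-pair, 10x, HiFi (both)
##   - segmental duplications:        10x, HiFi (both)
.tech_classes <- c("illumina_pcrfree_gatk", "illumina_pcrfree_other",
                   "illumina_matepair", "complete_genomics", "ion_exome",
                   "tenx", "hifi_deepvariant", "hifi_gatk", "solid", "other")

.repeat_exemptions <- list(
  tr_lt51 = c("illumina_pcrfree_gatk", "complete_genomics", "hifi_deepvariant"),
  tr_51_200 = c("illumina_pcrfree_gatk", "hifi_deepvariant"),
  tr_200_10k = "hifi_deepvariant",
  homopolymer_gt6 = c("illumina_pcrfree_gatk", "complete_genomics",
                      "ion_exome", "hifi_deepvariant"),
  imperfect_homopolymer_gt10 = "illumina_pcrfree_gatk",
  low_mappability = c("tenx", "hifi_deepvariant", "hifi_gatk"),
  line_l1hs_gt500 = c("illumina_matepair", "tenx", "hifi_deepvariant", "hifi_gatk"),
  segdup = c("tenx", "hifi_deepvariant", "hifi_gatk"))

#' Repeat-class tracks for technology-specific exclusion
#'
#' Bundles the eight repeat-class region sets used by the per-technology
#' exclusion matrix.  Classes may overlap one another.
#'
#' @param tr_lt51,tr_51_200,tr_200_10k tandem repeats by length class.
#' @param homopolymer_gt6 perfect homopolymers longer than 6 bp.
#' @param imperfect_homopolymer_gt10 imperfect homopolymers longer than 10 bp.
#' @param low_mappability short-read low-mappability regions.
#' @param line_l1hs_gt500 LINE L1Hs elements longer than 500 bp.
#' @param segdup segmental duplications.
#' @return A named list of [region_set()]s with class `repeat_class_tracks`.
#' @export
repeat_class_tracks <- function(tr_lt51 = region_set(), tr_51_200 = region_set(),
                                tr_200_10k = region_set(),
                                homopolymer_gt6 = region_set(),
                                imperfect_homopolymer_gt10 = region_set(),
                                low_mappability = region_set(),
                                line_l1hs_gt500 = region_set(),
                                segdup = region_set()) {
  structure(list(tr_lt51 = tr_lt51, tr_51_200 = tr_51_200,
                 tr_200_10k = tr_200_10k, homopolymer_gt6 = homopolymer_gt6,
                 imperfect_homopolymer_gt10 = imperfect_homopolymer_gt10,
                 low_mappability = low_mappability,
                 line_l1hs_gt500 = line_l1hs_gt500, segdup = segdup),
            class = "repeat_class_tracks")
}

#' Callset profile
#'
#' Identity and integration behaviour of one input callset: its technology
#' class (which row of the repeat-exclusion matrix applies), its callable
#' regions, and whether it participates only as annotation (no callable
#' regions, never supports or vetoes a call -- used for Ion Torrent and
#' SOLiD callsets).
#'
#' @param label callset name.
#' @param technology one of the ten technology-class tokens (see
#'   [tech_exclusion()]).
#' @param callable [region_set()] of callable regions, or NULL.
#' @param annotation_only logical; annotation-only callsets must have no
#'   callable regions.
#' @param excluded_repeat_classes optional manual override of the repeat
#'   classes excluded for this callset (character vector of track names).
#' @return A `callset_profile` list.
#' @export
callset_profile <- function(label, technology, callable = NULL,
                            annotation_only = FALSE,
                            excluded_repeat_classes = NULL) {
  if (!technology %in% .tech_classes)
    stop("unknown technology class: ", technology)
  if (annotation_only && !is.null(callable))
    stop("annotation-only callsets cannot have callable regions")
  if (is.null(excluded_repeat_classes))
    excluded_repeat_classes <- names(.repeat_exemptions)[
      !vapply(.repeat_exemptions, function(ex) technology %in% ex, logical(1))]
  structure(list(label = label, technology = technology, callable = callable,
                 annotation_only = annotation_only,
                 excluded_repeat_classes = excluded_repeat_classes),
            class = "callset_profile")
}

#' Technology-specific exclusion regions for a callset
#'
#' Union of the repeat-class tracks excluded for the callset's technology
#' class under the exclusion matrix (tandem repeats approximately longer
#' than the technology's read length, homopolymers, low-mappability
#' regions, LINEs and segmental duplications, each with its own exemption
#' list).
#'
#' @param profile a [callset_profile()].
#' @param tracks a [repeat_class_tracks()] bundle.
#' @return A normalized [region_set()].
#' @export
tech_exclusion <- function(profile, tracks) {
  cls <- profile$excluded_repeat_classes
  if (!length(cls)) return(region_set())
  union_regions(tracks[cls])
}

#' Effective callable regions of a callset
#'
#' The callset's callable regions minus its technology-specific exclusions.
#'
#' @inheritParams tech_exclusion
#' @return A normalized [region_set()].
#' @export
effective_callable <- function(profile, tracks) {
  if (profile$annotation_only)
    stop("annotation-only callset '", profile$label, "' has no callable semantics")
  if (is.null(profile$callable))
    stop("callset '", profile$label, "' has no callable regions")
  subtract_regions(profile$callable, tech_exclusion(profile, tracks))
}

## canonical genotype string: unphased, allele indices sorted
gt_key <- function(a1, a2) {
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  ifelse(is.na(a1) | is.na(a2), "./.", paste0(lo, "/", hi))
}

#' Arbitrate variant calls across callsets
#'
#' A site is accepted when at least `min_support` callsets whose effective
#' callable regions cover its position report an identical
#' (chrom, pos, ref, alt, genotype) record, and no covering callset reports
#' a conflicting allele or genotype at that locus.  Loci where covering
#' callsets disagree are emitted as conflict regions padded by `pad` bp on
#' each side.  Annotation-only callsets never support, veto, or exclude.
#'
#' @param sites_by_callset named list of normalized [variant_sites()]
#'   tables, one per callset label.
#' @param profiles named list of [callset_profile()]s (same labels).
#' @param tracks a [repeat_class_tracks()] bundle.
#' @param min_support minimum number of agreeing, covering callsets (>= 1).
#' @param pad conflict-region padding in bp (default 50).
#' @return A list with `accepted` (a [variant_sites()] table with columns
#'   `n_support` and `platforms`) and `conflict` (a [region_set()]).
#' @export
arbitrate <- function(sites_by_callset, profiles, tracks,
                      min_support = 2, pad = 50) {
  stopifnot(min_support >= 1)
  labs <- names(sites_by_callset)
  active <- labs[!vapply(profiles[labs], `[[`, logical(1), "annotation_only")]
  if (!length(active)) stop("no non-annotation callsets supplied")
  eff <- lapply(profiles[active], effective_callable, tracks = tracks)

  all <- do.call(rbind, lapply(active, function(l) {
    s <- sites_by_callset[[l]]
    if (!nrow(s)) return(NULL)
    s$callset <- l
    as.data.frame(s)
  }))
  if (is.null(all) || !nrow(all))
    return(list(accepted = variant_sites(), conflict = region_set()))

  ## covering = callset's effective callable contains the site position
  covered <- logical(nrow(all))
  for (l in active) {
    idx <- which(all$callset == l)
    if (!length(idx)) next
    d <- in_regions(all$chrom[idx], all$pos[idx], eff[[l]])
    covered[idx] <- d
  }
  all <- all[covered, , drop = FALSE]
  if (!nrow(all))
    return(list(accepted = variant_sites(), conflict = region_set()))

  locus <- paste(all$chrom, all$pos)
  rec <- paste(all$chrom, all$pos, all$ref, all$alt, gt_key(all$a1, all$a2))
  n_rec_per_locus <- tapply(rec, locus, function(r) length(unique(r)))
  conflicted <- names(n_rec_per_locus)[n_rec_per_locus > 1]
  ok <- !(locus %in% conflicted)

  support <- table(rec[ok])
  first <- !duplicated(rec) & ok
  acc <- all[first & support[rec] >= min_support, , drop = FALSE]
  if (nrow(acc)) {
    acc$n_support <- as.integer(support[paste(acc$chrom, acc$pos, acc$ref,
                                              acc$alt, gt_key(acc$a1, acc$a2))])
    acc$platforms <- vapply(paste(acc$chrom, acc$pos, acc$ref, acc$alt,
                                  gt_key(acc$a1, acc$a2)),
                            function(k) paste(sort(unique(all$callset[rec == k])),
                                              collapse = ","), "")
    acc <- acc[order(acc$chrom, acc$pos), , drop = FALSE]
    rownames(acc) <- NULL
  } else {
    acc$n_support <- integer(); acc$platforms <- character()
  }
  class(acc) <- c("variant_sites", "data.frame")

  conf_sites <- all[locus %in% conflicted & !duplicated(locus), , drop = FALSE]
  conflict <- pad_site_spans(conf_sites, pad)
  list(accepted = acc, conflict = conflict)
}

#' Benchmark set
#'
#' The paired deliverable of the pipeline: trusted variants plus the
#' regions in which all true variants are asserted to be in the VCF.
#'
#' @param variants a [variant_sites()] table.
#' @param regions a [region_set()]; every variant must lie inside it.
#' @param ledger optional [compose_exclusions()] ledger (provenance).
#' @return A `benchmark_set` list.
#' @export
benchmark_set <- function(variants, regions, ledger = NULL) {
  if (nrow(variants)) {
    inside <- in_regions(variants$chrom, variants$pos, regions)
    if (!all(inside)) stop("variant(s) outside benchmark regions")
    key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
    if (anyDuplicated(key)) stop("duplicate (chrom,pos,ref,alt) in benchmark variants")
  }
  structure(list(variants = variants, regions = regions, ledger = ledger),
            class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf("benchmark_set: %d variant(s) in %d region(s) (%s bp)\n",
              nrow(x$variants), nrow(x$regions),
              format(region_bp(x$regions), big.mark = ",")))
  invisible(x)
}

#' Build the final benchmark VCF + BED
#'
#' Composes the benchmark regions as the bases where at least
#' `min_support` callsets are effectively callable (a base where the
#' support threshold can never be met must not assert hom-ref), minus the
#' global exclusion stack and the arbitration conflict regions, then
#' removes every tandem repeat or homopolymer only partially covered
#' (full-containment-or-absence).  The benchmark variants are the accepted
#' sites lying entirely inside the final regions.
#'
#' @param accepted accepted [variant_sites()] from [arbitrate()].
#' @param profiles named list of [callset_profile()]s.
#' @param tracks a [repeat_class_tracks()] bundle.
#' @param exclusions an exclusion ledger from [compose_exclusions()], or a
#'   [region_set()] of excluded bases.
#' @param conflict conflict [region_set()] from [arbitrate()].
#' @param genome a [genome_file()].
#' @param min_support minimum number of effectively callable callsets for
#'   a base to enter the benchmark regions (default 2; must match the
#'   [arbitrate()] threshold).
#' @return A [benchmark_set()].
#' @export
build_benchmark <- function(accepted, profiles, tracks, exclusions,
                            conflict = region_set(), genome = NULL,
                            min_support = 2) {
  active <- Filter(function(p) !p$annotation_only, profiles)
  if (!length(active)) stop("no non-annotation callsets supplied")
  eff <- lapply(active, effective_callable, tracks = tracks)
  callable_union <- if (min_support <= 1) union_regions(eff) else
    stack_depth_filter(do.call(rbind, lapply(eff, function(e)
      as.data.frame(e)[c("chrom", "start", "end")])), min_support - 1)
  excl_set <- if (inherits(exclusions, "exclusion_ledger"))
    attr(exclusions, "total") else exclusions
  regions <- subtract_regions(subtract_regions(callable_union, excl_set),
                              conflict)
  repeats <- union_regions(tracks[c("tr_lt51", "tr_51_200", "tr_200_10k",
                                    "homopolymer_gt6",
                                    "imperfect_homopolymer_gt10")])
  regions <- remove_partial_repeats(regions, repeats)
  if (!is.null(genome)) attr(regions, "genome") <- genome
  if (nrow(accepted)) {
    keep <- span_in_regions(accepted$chrom, accepted$pos - 1,
                            accepted$pos - 1 + nchar(accepted$ref),
                            regions, mode = "within")
    accepted <- accepted[keep, , drop = FALSE]
    rownames(accepted) <- NULL
    class(accepted) <- c("variant_sites", "data.frame")
  }
  benchmark_set(accepted, regions,
                ledger = if (inherits(exclusions, "exclusion_ledger")) exclusions)
}

#' Write a benchmark set to disk
#'
#' Emits the benchmark VCF (with `callsets=` and `platforms=` INFO keys)
#' and the benchmark-region BED.
#'
#' @param bench a [benchmark_set()].
#' @param vcf_path,bed_path output paths.
#' @param sample sample name for the VCF genotype column.
#' @param genome optional [genome_file()] for VCF contig headers.
#' @export
write_benchmark <- function(bench, vcf_path, bed_path, sample = "SAMPLE",
                            genome = NULL) {
  v <- bench$variants
  info <- if (nrow(v) && !is.null(v$n_support))
    sprintf("callsets=%d;platforms=%s", v$n_support, v$platforms)
  else NULL
  write_vcf(v, vcf_path, sample = sample, genome = genome, info = info)
  write_bed(bench$regions, bed_path)
  invisible(list(vcf = vcf_path, bed = bed_path))
}
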