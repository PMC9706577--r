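#' Callable-region configuration
#'
#' Depth thresholds for classifying windows of a depth track as callable.
#' For the unsplit (all-reads) track the defaults are a minimum depth of 20
#' and a maximum of 2x the median coverage; for each haplotype-split track,
#' a minimum of 5 and a maximum of 1x the median.  The median is taken over
#' depths at the callset's variant positions by default (`vcf_positions`),
#' or length-weighted over the whole track (`genome_wide`).
#'
#' @param min_depth_unsplit,min_depth_hap minimum callable depth (reads).
#' @param max_depth_unsplit_factor,max_depth_hap_factor maximum callable
#'   depth as a multiple of the median coverage.
#' @param median_source `"vcf_positions"` or `"genome_wide"`.
#' @return A `callable_config` list.
#' @export
callable_config <- function(min_depth_unsplit = 20, max_depth_unsplit_factor = 2,
                            min_depth_hap = 5, max_depth_hap_factor = 1,
                            median_source = c("vcf_positions", "genome_wide")) {
  stopifnot(min_depth_unsplit >= 0, min_depth_hap >= 0,
            max_depth_unsplit_factor > 0, max_depth_hap_factor > 0)
  structure(list(min_depth_unsplit = min_depth_unsplit,
                 max_depth_unsplit_factor = max_depth_unsplit_factor,
                 min_depth_hap = min_depth_hap,
                 max_depth_hap_factor = max_depth_hap_factor,
                 median_source = match.arg(median_source)),
            class = "callable_config")
}

#' Median coverage of a depth track
#'
#' With `median_source = "vcf_positions"` (the default), returns the median
#' of the track depth at each variant position in `sites`; with
#' `"genome_wide"`, the length-weighted median over all windows.
#'
#' @param track a [depth_track()].
#' @param sites a [variant_sites()] table, required for `vcf_positions`.
#' @param cfg a [callable_config()].
#' @return A single depth value.
#' @export
median_depth <- function(track, sites = NULL, cfg = callable_config()) {
  if (!nrow(track)) stop("empty depth track")
  if (cfg$median_source == "vcf_positions") {
    if (is.null(sites) || !nrow(sites))
      stop("median_source = 'vcf_positions' requires variant sites")
    d <- depth_at(track, sites$chrom, sites$pos)
    d <- d[!is.na(d)]
    if (!length(d)) stop("no variant site overlaps the depth track")
    return(stats::median(d))
  }
  weighted_median(track$depth, track$end - track$start)
}

## depth of the window containing each 1-based position (NA when uncovered)
depth_at <- function(track, chrom, pos) {
  n <- length(pos)
  out <- rep(NA_real_, n)
  o <- order(track$chrom, track$start)
  tch <- track$chrom[o]; ts <- track$start[o]; te <- track$end[o]
  td <- track$depth[o]
  idx_t <- split(seq_along(ts), tch)
  idx_q <- split(seq_len(n), chrom)
  p0 <- pos - 1
  for (ch in names(idx_q)) {
    it <- idx_t[[ch]]
    if (is.null(it)) next
    iq <- idx_q[[ch]]
    i <- findInterval(p0[iq], ts[it])
    hit <- i > 0 & p0[iq] < te[it][pmax(i, 1)]
    out[iq[hit]] <- td[it][i[hit]]
  }
  out
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  # standard weighted median: smallest x with cumulative weight >= 0.5,
  # averaging with the next value on an exact 0.5 boundary
  i <- which(cw >= 0.5)[1]
  if (isTRUE(all.equal(cw[i], 0.5)) && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

#' Callable regions of a depth track
#'
#' Bases whose window depth d satisfies `min_depth <= d <= max_depth`.
#'
#' @param track a [depth_track()].
#' @param min_depth,max_depth inclusive depth bounds.
#' @return A normalized [region_set()].
#' @export
callable_from_depth <- function(track, min_depth, max_depth) {
  stopifnot(min_depth <= max_depth)
  keep <- track$depth >= min_depth & track$depth <= max_depth
  if (!any(keep)) return(region_set())
  normalize_regions(region_set(track$chrom[keep], track$start[keep], track$end[keep]))
}

#' HiFi VCF preprocessing mask
#'
#' Removes multi-allelic entries, and RefCall entries with QUAL strictly
#' below 40, from a HiFi callset; each removed entry contributes its
#' reference span padded by 50 bp on each side to the returned mask.
#'
#' @param sites a [variant_sites()] table, position-sorted.
#' @param pad padding in bp on each side of a removed entry (default 50).
#' @param min_refcall_qual RefCall entries strictly below this QUAL are
#'   removed (default 40).
#' @return A list with `sites` (kept sites) and `mask` (a [region_set()]).
#' @export
hifi_vcf_mask <- function(sites, pad = 50, min_refcall_qual = 40) {
  multi <- grepl(",", sites$alt, fixed = TRUE)
  refcall <- grepl("RefCall", sites$filter) & !is.na(sites$qual) &
    sites$qual < min_refcall_qual
  drop <- multi | refcall
  list(sites = sites[!drop, , drop = FALSE],
       mask = pad_site_spans(sites[drop, , drop = FALSE], pad))
}

#' Filtered-indel mask for linked-read callsets
#'
#' Removes indel entries whose FILTER is not PASS/"." and returns their
#' padded spans as a mask, mirroring the HiFi preprocessing convention.
#'
#' @inheritParams hifi_vcf_mask
#' @return A list with `sites` (kept sites) and `mask` (a [region_set()]).
#' @export
filtered_indel_mask <- function(sites, pad = 50) {
  alt1 <- vapply(strsplit(sites$alt, ",", fixed = TRUE),
                 function(a) max(nchar(a)), numeric(1))
  indel <- nchar(sites$ref) != 1 | alt1 != 1
  filtered <- !(sites$filter %in% c("PASS", "."))
  drop <- indel & filtered
  list(sites = sites[!drop, , drop = FALSE],
       mask = pad_site_spans(sites[drop, , drop = FALSE], pad))
}

## variant reference span in 0-based half-open coords, padded both sides
pad_site_spans <- function(sites, pad) {
  if (!nrow(sites)) return(region_set())
  start <- pmax(sites$pos - 1 - pad, 0)
  end <- sites$pos - 1 + nchar(sites$ref) + pad
  normalize_regions(region_set(sites$chrom, start, end))
}

per_track_callable <- function(track, cfg, sites, role) {
  med <- median_depth(track, sites, cfg)
  if (role == "unsplit") {
    min_d <- cfg$min_depth_unsplit
    max_d <- cfg$max_depth_unsplit_factor * med
  } else {
    min_d <- cfg$min_depth_hap
    max_d <- cfg$max_depth_hap_factor * med
  }
  # zero/low-coverage tracks (e.g. an unphased haplotype) are simply
  # not-callable, not an error
  if (max_d < min_d) return(region_set())
  callable_from_depth(track, min_d, max_d)
}

#' Callable regions for a HiFi callset
#'
#' Computes callable regions independently for the unsplit track and each
#' haplotype-split track, takes the union of the three, and subtracts the
#' VCF preprocessing mask.  A base callable on either haplotype alone is
#' callable (union semantics).  Missing haplotype tracks fall back to the
#' unsplit track only, with a warning.
#'
#' @param unsplit,hap1,hap2 [depth_track()]s from one dataset (`hap1`/`hap2`
#'   may be NULL).
#' @param cfg a [callable_config()].
#' @param mask [region_set()] to subtract (e.g. from [hifi_vcf_mask()]).
#' @param sites [variant_sites()] used for the per-track median when
#'   `cfg$median_source == "vcf_positions"`.
#' @return A normalized [region_set()].
#' @export
hifi_callable <- function(unsplit, hap1 = NULL, hap2 = NULL,
                          cfg = callable_config(), mask = region_set(),
                          sites = NULL) {
  sets <- list(per_track_callable(unsplit, cfg, sites, "unsplit"))
  if (is.null(hap1) || is.null(hap2)) {
    warning("missing haplotype track(s): falling back to the unsplit track only")
  } else {
    sets <- c(sets, list(per_track_callable(hap1, cfg, sites, "hap"),
                         per_track_callable(hap2, cfg, sites, "hap")))
  }
  subtract_regions(union_regions(sets), mask)
}

#' Callable regions for a linked-read callset
#'
#' As [hifi_callable()], but additionally subtracts regions callable on one
#' haplotype and not the other (haplotype-XOR), plus a filtered-indel mask.
#'
#' @inheritParams hifi_callable
#' @param filtered_indel_mask [region_set()] of padded filtered indels.
#' @return A normalized [region_set()].
#' @export
linkedread_callable <- function(unsplit, hap1 = NULL, hap2 = NULL,
                                cfg = callable_config(),
                                filtered_indel_mask = region_set(),
                                sites = NULL) {
  if (is.null(hap1) || is.null(hap2)) {
    warning("missing haplotype track(s): falling back to the unsplit track only")
    base <- per_track_callable(unsplit, cfg, sites, "unsplit")
    return(subtract_regions(base, filtered_indel_mask))
  }
  c0 <- per_track_callable(unsplit, cfg, sites, "unsplit")
  c1 <- per_track_callable(hap1, cfg, sites, "hap")
  c2 <- per_track_callable(hap2, cfg, sites, "hap")
  xor <- union_regions(list(subtract_regions(c1, c2), subtract_regions(c2, c1)))
  subtract_regions(subtract_regions(union_regions(list(c0, c1, c2)), xor),
                   filtered_indel_mask)
}
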