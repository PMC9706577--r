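#' Genomic region sets
#'
#' A `region_set` is the package's universal currency for callable, excluded
#' and benchmark regions: a set of 0-based half-open intervals on named
#' chromosomes, optionally bound to a genome (chromosome lengths).  It is a
#' plain data frame with columns `chrom`, `start`, `end` (extra columns are
#' carried along opaquely) and, when bound, a `genome` attribute.
#'
#' The interval algebra is implemented natively on sorted endpoints so that
#' its dialect is fully pinned: intervals are 0-based half-open, book-ended
#' intervals merge on normalization, threshold comparisons are strict where
#' documented, and percentage slop rounds half away from zero.  VCF
#' positions are 1-based and converted exactly once, at VCF ingestion.
#'
#' @param chrom character vector of chromosome names (recycled if scalar).
#' @param start,end numeric vectors of 0-based half-open interval bounds.
#' @param genome optional [genome_file()] binding chromosome lengths.
#' @param extra optional data frame of extra BED columns, carried opaquely.
#' @return A `region_set` data frame.
#' @examples
#' rs <- region_set("chr1", c(10, 15), c(20, 30))
#' normalize_regions(rs)
#' @export
region_set <- function(chrom = character(), start = numeric(), end = numeric(),
                       genome = NULL, extra = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(start) == 1) start <- rep(start, n)
  if (length(end) == 1) end <- rep(end, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop("invalid interval(s) at index ", paste(bad, collapse = ", "),
         ": need 0 <= start < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(extra) && nrow(df)) df <- cbind(df, extra)
  if (!is.null(genome)) {
    check_in_genome(df, genome)
    attr(df, "genome") <- genome
  }
  class(df) <- c("region_set", "data.frame")
  df
}

#' @export
print.region_set <- function(x, ...) {
  g <- attr(x, "genome")
  cat(sprintf("region_set: %d interval(s), %s bp%s\n", nrow(x),
              format(region_bp(x), big.mark = ","),
              if (is.null(g)) "" else sprintf(" on %d-chromosome genome", nrow(g))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more)\n", sep = "")
  invisible(x)
}

#' Genome file (chromosome lengths)
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length positive chromosome lengths in bp.
#' @return A `genome_file` data frame with columns `chrom` and `length`.
#' @examples
#' genome_file(c("chr1", "chr2"), c(1e6, 1e6))
#' @export
genome_file <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("duplicate chromosome names in genome file")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  g <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(g) <- c("genome_file", "data.frame")
  g
}

check_in_genome <- function(df, genome) {
  m <- match(df$chrom, genome$chrom)
  if (anyNA(m))
    stop("chromosome(s) not in genome file: ",
         paste(unique(df$chrom[is.na(m)]), collapse = ", "))
  over <- which(df$end > genome$length[m])
  if (length(over))
    stop("interval(s) beyond chromosome length at index ",
         paste(over, collapse = ", "))
  invisible(TRUE)
}

rs_genome <- function(...) {
  for (x in list(...)) {
    g <- attr(x, "genome")
    if (!is.null(g)) return(g)
  }
  NULL
}

as_region_set <- function(chrom, start, end, genome = NULL) {
  # internal fast path: trusted, already-validated components
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  class(df) <- c("region_set", "data.frame")
  attr(df, "genome") <- genome
  df
}

sort_rs <- function(rs, genome = NULL) {
  if (!is.null(genome)) {
    o <- order(match(rs$chrom, genome$chrom), rs$start, rs$end)
  } else {
    o <- order(rs$chrom, rs$start, rs$end)
  }
  out <- rs[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  attr(out, "genome") <- genome
  out
}

#' Normalize a region set
#'
#' Sorts intervals and fuses any that overlap or abut (book-ended intervals
#' merge), so that afterwards no two intervals on a chromosome overlap or
#' touch.  The set of covered bases is unchanged.
#'
#' @param rs a [region_set()].
#' @return A normalized `region_set`.
#' @export
normalize_regions <- function(rs) {
  g <- rs_genome(rs)
  n <- nrow(rs)
  if (!n) return(region_set(genome = g))
  o <- order(rs$chrom, rs$start, rs$end)
  ch <- rs$chrom[o]; s <- rs$start[o]; e <- rs$end[o]
  run_new <- c(TRUE, ch[-1] != ch[-n])
  run_id <- cumsum(run_new)
  cme <- unlist(lapply(split(e, run_id), cummax), use.names = FALSE)
  new_grp <- c(TRUE, run_new[-1] | s[-1] > cme[-n])
  first_idx <- which(new_grp)
  last_idx <- c(first_idx[-1] - 1L, n)
  as_region_set(ch[first_idx], s[first_idx], cme[last_idx], genome = g)
}

#' Union of several region sets
#'
#' A base is covered in the result iff it is covered in at least one input.
#'
#' @param sets a list of [region_set()] objects.
#' @return A normalized `region_set`; empty when `sets` is empty.
#' @export
union_regions <- function(sets) {
  if (!length(sets)) return(region_set())
  g <- do.call(rs_genome, sets)
  all <- do.call(rbind, lapply(sets, function(s)
    as.data.frame(s)[c("chrom", "start", "end")]))
  normalize_regions(as_region_set(all$chrom, all$start, all$end, genome = g))
}

## For each interval of normalized `a`, the index range [lo, hi] of
## intervals of normalized `b` (same chromosome vectors) that overlap it;
## lo > hi means no overlap.  Both inputs must be normalized and sorted.
overlap_ranges <- function(a_ch, a_s, a_e, b_ch, b_s, b_e) {
  lo <- integer(length(a_s)); hi <- integer(length(a_s))
  idx_b <- split(seq_along(b_s), b_ch)
  idx_a <- split(seq_along(a_s), a_ch)
  for (ch in names(idx_a)) {
    ia <- idx_a[[ch]]; ib <- idx_b[[ch]]
    if (is.null(ib)) { lo[ia] <- 1L; hi[ia] <- 0L; next }
    bs <- b_s[ib]; be <- b_e[ib]
    l <- findInterval(a_s[ia], be) + 1L        # skip b ending at/before start
    h <- findInterval(a_e[ia] - 0.5, bs)       # b starting before end
    lo[ia] <- ib[1] - 1L + l
    hi[ia] <- ib[1] - 1L + h
  }
  list(lo = lo, hi = hi)
}

#' Subtract one region set from another
#'
#' A base is covered in the result iff it is covered by `a` and not by `b`.
#'
#' @param a,b [region_set()] objects.
#' @return A normalized `region_set`.
#' @export
subtract_regions <- function(a, b) {
  g <- rs_genome(a, b)
  a <- normalize_regions(a)
  if (!nrow(a)) return(region_set(genome = g))
  b <- normalize_regions(b)
  if (!nrow(b)) { attr(a, "genome") <- g; return(a) }
  ov <- overlap_ranges(a$chrom, a$start, a$end, b$chrom, b$start, b$end)
  k <- pmax(ov$hi - ov$lo + 1L, 0L)
  plain <- which(k == 0L)
  cut <- which(k > 0L)
  out_ch <- a$chrom[plain]; out_s <- a$start[plain]; out_e <- a$end[plain]
  if (length(cut)) {
    reps <- k[cut] + 1L
    ai <- rep(cut, reps)
    t <- sequence(reps)
    is_first <- t == 1L
    is_last <- t == rep(reps, reps)
    bj <- ov$lo[ai] + t - 2L          # b index supplying the fragment start
    fs <- ifelse(is_first, a$start[ai], b$end[pmax(bj, 1L)])
    fe <- ifelse(is_last, a$end[ai], b$start[bj + 1L])
    fs <- pmax(fs, a$start[ai]); fe <- pmin(fe, a$end[ai])
    keep <- fs < fe
    out_ch <- c(out_ch, a$chrom[ai][keep])
    out_s <- c(out_s, fs[keep]); out_e <- c(out_e, fe[keep])
  }
  if (!length(out_s)) return(region_set(genome = g))
  o <- order(out_ch, out_s)
  as_region_set(out_ch[o], out_s[o], out_e[o], genome = g)
}

#' Intersect two region sets
#'
#' @param a,b [region_set()] objects.
#' @return A normalized `region_set` covering bases in both `a` and `b`.
#' @export
intersect_regions <- function(a, b) {
  g <- rs_genome(a, b)
  a <- normalize_regions(a); b <- normalize_regions(b)
  if (!nrow(a) || !nrow(b)) return(region_set(genome = g))
  ov <- overlap_ranges(a$chrom, a$start, a$end, b$chrom, b$start, b$end)
  k <- pmax(ov$hi - ov$lo + 1L, 0L)
  cut <- which(k > 0L)
  if (!length(cut)) return(region_set(genome = g))
  reps <- k[cut]
  ai <- rep(cut, reps)
  bj <- ov$lo[ai] + sequence(reps) - 1L
  ps <- pmax(a$start[ai], b$start[bj])
  pe <- pmin(a$end[ai], b$end[bj])
  keep <- ps < pe
  out <- as_region_set(a$chrom[ai][keep], ps[keep], pe[keep], genome = g)
  o <- order(out$chrom, out$start)
  as_region_set(out$chrom[o], out$start[o], out$end[o], genome = g)
}

#' Complement of a region set within a genome
#'
#' @param a a [region_set()].
#' @param genome a [genome_file()]; every interval of `a` must lie within it.
#' @return A normalized `region_set` of all genome bases not covered by `a`.
#' @export
complement_regions <- function(a, genome) {
  stopifnot(inherits(genome, "genome_file"))
  check_in_genome(a, genome)
  whole <- as_region_set(genome$chrom, rep(0, nrow(genome)), genome$length,
                         genome = genome)
  subtract_regions(whole, a)
}

#' Extend (slop) intervals symmetrically
#'
#' Each interval of length L is extended on both sides by `amount` bp
#' (`mode = "fixed_bp"`) or by `round(amount * L)` bp (`mode = "pct"`,
#' rounding half away from zero), clipped to chromosome bounds when a genome
#' is supplied, then normalized.  `mode = "pct", amount = 0.25` grows each
#' interval to 150% of its length before merging.
#'
#' @param a a [region_set()].
#' @param mode `"fixed_bp"` or `"pct"`.
#' @param amount non-negative extension (bp, or fraction of interval length).
#' @param genome optional [genome_file()] used for clipping; without it,
#'   `pct` mode warns that no clipping is applied.
#' @return A normalized `region_set`.
#' @export
slop_regions <- function(a, mode = c("fixed_bp", "pct"), amount, genome = NULL) {
  mode <- match.arg(mode)
  stopifnot(amount >= 0)
  if (is.null(genome)) genome <- rs_genome(a)
  if (is.null(genome) && mode == "pct")
    warning("slop pct without a genome: intervals are not clipped")
  if (!nrow(a)) return(region_set(genome = genome))
  len <- a$end - a$start
  ext <- if (mode == "fixed_bp") rep(amount, nrow(a)) else floor(amount * len + 0.5)
  start <- pmax(a$start - ext, 0)
  end <- a$end + ext
  if (!is.null(genome)) {
    m <- match(a$chrom, genome$chrom)
    if (anyNA(m)) stop("chromosome(s) not in genome file")
    end <- pmin(end, genome$length[m])
  }
  normalize_regions(as_region_set(a$chrom, start, end, genome = genome))
}

## weighted pile-up: bases where the summed weight of covering intervals
## satisfies `depth > threshold` (strict) or `depth >= threshold`
pileup_regions <- function(chrom, start, end, weight, threshold,
                           strict = TRUE, genome = NULL) {
  out_ch <- character(); out_s <- numeric(); out_e <- numeric()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos <- c(start[sel], end[sel])
    delta <- c(weight[sel], -weight[sel])
    o <- order(pos)
    pos <- pos[o]; delta <- delta[o]
    lastof <- c(diff(pos) > 0, TRUE)
    u <- pos[lastof]
    depth <- cumsum(delta)[lastof]
    m <- length(u)
    if (m < 2) next
    seg_ok <- if (strict) depth[-m] > threshold else depth[-m] >= threshold
    if (!any(seg_ok)) next
    r <- rle(seg_ok)
    endpos <- cumsum(r$lengths)
    startpos <- endpos - r$lengths + 1
    kept <- which(r$values)
    out_ch <- c(out_ch, rep(ch, length(kept)))
    out_s <- c(out_s, u[startpos[kept]])
    out_e <- c(out_e, u[endpos[kept] + 1])
  }
  if (!length(out_s)) return(region_set(genome = genome))
  o <- order(out_ch, out_s)
  as_region_set(out_ch[o], out_s[o], out_e[o], genome = genome)
}

#' Bases covered by strictly more than `min_depth` intervals
#'
#' Treats the input as a multiset of (possibly overlapping) intervals --
#' overlaps are the signal, so the input is deliberately not normalized
#' first -- and returns the bases covered by more than `min_depth` of them.
#' This mirrors stacking a BED on itself and thresholding the pile-up depth,
#' as done for many-copy segmental duplications.
#'
#' @param a a [region_set()] (not normalized; duplicates allowed).
#' @param min_depth keep bases covered by strictly more than this many
#'   intervals (>= 1).
#' @return A normalized `region_set`.
#' @export
stack_depth_filter <- function(a, min_depth) {
  stopifnot(min_depth >= 1)
  g <- rs_genome(a)
  if (!nrow(a)) return(region_set(genome = g))
  pileup_regions(a$chrom, a$start, a$end, rep(1, nrow(a)), min_depth,
                 strict = TRUE, genome = g)
}

#' Filter intervals by length
#'
#' Keeps intervals whose length is strictly greater than `min_bp` and/or
#' strictly less than `max_bp`.  Intervals are not merged beforehand.
#'
#' @param a a [region_set()].
#' @param min_bp,max_bp strict bounds on interval length in bp; at least one
#'   must be non-NULL.
#' @return A `region_set` (same intervals, filtered; not re-normalized).
#' @export
filter_by_length <- function(a, min_bp = NULL, max_bp = NULL) {
  if (is.null(min_bp) && is.null(max_bp))
    stop("at least one of min_bp, max_bp must be set")
  len <- a$end - a$start
  keep <- rep(TRUE, nrow(a))
  if (!is.null(min_bp)) keep <- keep & len > min_bp
  if (!is.null(max_bp)) keep <- keep & len < max_bp
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  attr(out, "genome") <- rs_genome(a)
  out
}

## are 1-based positions covered by the region set?
in_regions <- function(chrom, pos, rs) {
  span_in_regions(chrom, pos - 1, pos, rs, mode = "overlap")
}

## query spans [s0, e0) against a region set; mode "overlap" tests any
## overlap, "within" tests full containment in one normalized interval
span_in_regions <- function(chrom, s0, e0, rs, mode = c("overlap", "within")) {
  mode <- match.arg(mode)
  n <- length(chrom)
  if (!n) return(logical(0))
  if (!nrow(rs)) return(rep(FALSE, n))
  rs <- normalize_regions(rs)
  out <- logical(n)
  idx_r <- split(seq_len(nrow(rs)), rs$chrom)
  idx_q <- split(seq_len(n), chrom)
  for (ch in names(idx_q)) {
    ir <- idx_r[[ch]]
    if (is.null(ir)) next
    iq <- idx_q[[ch]]
    bs <- rs$start[ir]; be <- rs$end[ir]
    if (mode == "within") {
      i <- findInterval(s0[iq], bs)
      ok <- i > 0
      ok[ok] <- e0[iq][ok] <= be[i[ok]]
      out[iq] <- ok
    } else {
      lo <- findInterval(s0[iq], be) + 1
      hi <- findInterval(e0[iq] - 0.5, bs)
      out[iq] <- lo <= hi
    }
  }
  out
}

## per query span, the hull (min start / max end) of overlapping intervals
## of a normalized region set; NA when none overlap
overlap_hull <- function(chrom, s0, e0, rs) {
  rs <- normalize_regions(rs)
  n <- length(chrom)
  hs <- rep(NA_real_, n); he <- rep(NA_real_, n)
  if (!nrow(rs)) return(list(start = hs, end = he))
  idx_r <- split(seq_len(nrow(rs)), rs$chrom)
  idx_q <- split(seq_len(n), chrom)
  for (ch in names(idx_q)) {
    ir <- idx_r[[ch]]
    if (is.null(ir)) next
    iq <- idx_q[[ch]]
    bs <- rs$start[ir]; be <- rs$end[ir]
    lo <- findInterval(s0[iq], be) + 1
    hi <- findInterval(e0[iq] - 0.5, bs)
    ok <- lo <= hi
    hs[iq[ok]] <- bs[lo[ok]]
    he[iq[ok]] <- be[hi[ok]]
  }
  list(start = hs, end = he)
}

#' Remove partially covered repeats from a benchmark region set
#'
#' Benchmark regions must fully contain or fully exclude every repeat:
#' for every repeat interval not fully contained in `bench`, the entire
#' repeat interval is subtracted from `bench`; fully contained repeats are
#' untouched.  Idempotent.
#'
#' @param bench benchmark [region_set()].
#' @param repeats normalized repeat [region_set()].
#' @return A normalized `region_set`.
#' @export
remove_partial_repeats <- function(bench, repeats) {
  bench <- normalize_regions(bench)
  if (!nrow(repeats) || !nrow(bench)) return(bench)
  contained <- span_in_regions(repeats$chrom, repeats$start, repeats$end,
                               bench, mode = "within")
  partial <- repeats[!contained, , drop = FALSE]
  class(partial) <- c("region_set", "data.frame")
  subtract_regions(bench, partial)
}

#' Total covered base pairs of a region set (after normalization)
#' @param a a [region_set()].
#' @return Numeric bp count.
#' @export
region_bp <- function(a) {
  if (!nrow(a)) return(0)
  n <- normalize_regions(a)
  sum(n$end - n$start)
}

#' Summary statistics of a region set
#'
#' Reports the interval count, covered bp, fraction of the genome covered,
#' and NG50: the interval length at which intervals sorted by decreasing
#' length first cumulatively cover at least 50% of the genome length
#' (NA when they never do).
#'
#' @param a a [region_set()] (normalized internally).
#' @param genome a [genome_file()].
#' @return A list with `n_intervals`, `total_bp`, `genome_fraction`, `ng50`.
#' @export
region_stats <- function(a, genome) {
  stopifnot(inherits(genome, "genome_file"))
  a <- normalize_regions(a)
  gsize <- sum(genome$length)
  if (!nrow(a))
    return(list(n_intervals = 0L, total_bp = 0, genome_fraction = 0,
                ng50 = NA_real_))
  len <- sort(a$end - a$start, decreasing = TRUE)
  cum <- cumsum(len)
  hit <- which(cum >= gsize / 2)
  list(n_intervals = nrow(a),
       total_bp = sum(len),
       genome_fraction = sum(len) / gsize,
       ng50 = if (length(hit)) len[hit[1]] else NA_real_)
}
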