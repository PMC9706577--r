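#' Normalize variant representations
#'
#' Decomposes multi-allelic sites into biallelic records (with genotype
#' bookkeeping: the decomposed record's genotype counts only the focal
#' alternate allele), trims shared prefix/suffix bases parsimoniously and
#' left-aligns indels against the reference sequence.  Idempotent.
#'
#' @param sites a [variant_sites()] table.
#' @param genome_seq named `Biostrings::DNAStringSet` (or named character
#'   vector) of chromosome sequences.
#' @return A normalized, position-sorted [variant_sites()] table.
#' @export
normalize_variants <- function(sites, genome_seq) {
  if (!nrow(sites)) return(sites)
  if (is.character(genome_seq)) genome_seq <- Biostrings::DNAStringSet(genome_seq)
  ## decompose multi-allelics
  alts <- strsplit(sites$alt, ",", fixed = TRUE)
  n <- lengths(alts)
  idx <- rep(seq_len(nrow(sites)), n)
  out <- as.data.frame(sites)[idx, , drop = FALSE]
  out$alt <- unlist(alts)
  which_alt <- unlist(lapply(n, seq_len))
  out$a1 <- ifelse(is.na(out$a1), NA_integer_, as.integer(out$a1 == which_alt))
  out$a2 <- ifelse(is.na(out$a2), NA_integer_, as.integer(out$a2 == which_alt))
  ## drop decomposed records carrying no copy of the focal allele at a
  ## multi-allelic site (pure bookkeeping rows)
  keep <- n[idx] == 1 | (!is.na(out$a1) & (out$a1 + out$a2) > 0) | is.na(out$a1)
  out <- out[keep, , drop = FALSE]

  chrseq <- function(chrom) {
    if (!chrom %in% names(genome_seq))
      stop("chromosome not in reference: ", chrom)
    genome_seq[[chrom]]
  }
  for (i in seq_len(nrow(out))) {
    pos <- out$pos[i]; ref <- out$ref[i]; alt <- out$alt[i]
    seq <- chrseq(out$chrom[i])
    if (as.character(Biostrings::subseq(seq, pos, pos + nchar(ref) - 1)) != ref)
      stop(sprintf("reference mismatch at %s:%d (%s)", out$chrom[i], pos, ref))
    repeat {
      if (substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
        if (nchar(ref) > 1 && nchar(alt) > 1) {
          ref <- substr(ref, 1, nchar(ref) - 1)
          alt <- substr(alt, 1, nchar(alt) - 1)
        } else if (pos > 1) {
          prev <- as.character(Biostrings::subseq(seq, pos - 1, pos - 1))
          ref <- paste0(prev, substr(ref, 1, nchar(ref) - 1))
          alt <- paste0(prev, substr(alt, 1, nchar(alt) - 1))
          pos <- pos - 1
        } else break
      } else break
    }
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref))
      alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1
    }
    out$pos[i] <- pos; out$ref[i] <- ref; out$alt[i] <- alt
  }
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_sites", "data.frame")
  out
}

#' Compare a query callset against a truth benchmark set
#'
#' Exact comparison of normalized records confined to the truth regions:
#' a true positive is an exact (chrom, pos, ref, alt, genotype) match; a
#' query-only record inside the regions is a false positive (counted
#' separately as `filtered_fp` when its FILTER is neither PASS nor ".");
#' a truth-only record is a false negative.  Query records outside the
#' truth regions are ignored.  A genotype mismatch at a matching allele
#' counts as an FP + FN pair, or as a separate `genotype_error` class when
#' `genotype_error_class = TRUE`.
#'
#' @param query a normalized [variant_sites()] table.
#' @param truth a [benchmark_set()] (normalized variants + regions).
#' @param genotype_error_class logical; see above.
#' @return A `benchmark_comparison` list with per-class site tables
#'   (`tp`, `fp`, `filtered_fp`, `fn`, `genotype_error`) and a `summary`
#'   of counts, precision and recall split by SNV/indel.
#' @export
compare_benchmark <- function(query, truth, genotype_error_class = FALSE) {
  regions <- truth$regions
  tv <- as.data.frame(truth$variants)
  qv <- as.data.frame(query)
  if (nrow(qv)) qv <- qv[in_regions(qv$chrom, qv$pos, regions), , drop = FALSE]
  if (nrow(tv)) tv <- tv[in_regions(tv$chrom, tv$pos, regions), , drop = FALSE]

  kq <- paste(qv$chrom, qv$pos, qv$ref, qv$alt, gt_key(qv$a1, qv$a2))
  kt <- paste(tv$chrom, tv$pos, tv$ref, tv$alt, gt_key(tv$a1, tv$a2))
  tp <- qv[kq %in% kt, , drop = FALSE]
  q_rest <- qv[!(kq %in% kt), , drop = FALSE]
  t_rest <- tv[!(kt %in% kq), , drop = FALSE]

  gterr <- q_rest[0, , drop = FALSE]
  if (genotype_error_class && nrow(q_rest) && nrow(t_rest)) {
    aq <- paste(q_rest$chrom, q_rest$pos, q_rest$ref, q_rest$alt)
    at <- paste(t_rest$chrom, t_rest$pos, t_rest$ref, t_rest$alt)
    gterr <- q_rest[aq %in% at, , drop = FALSE]
    q_rest <- q_rest[!(aq %in% at), , drop = FALSE]
    t_rest <- t_rest[!(at %in% aq), , drop = FALSE]
  }
  filtered <- !(q_rest$filter %in% c("PASS", "."))
  res <- list(tp = tp,
              fp = q_rest[!filtered, , drop = FALSE],
              filtered_fp = q_rest[filtered, , drop = FALSE],
              fn = t_rest,
              genotype_error = gterr)
  res$summary <- comparison_summary(res)
  class(res) <- "benchmark_comparison"
  res
}

count_by_type <- function(df) {
  if (is.null(df) || !nrow(df)) return(c(snv = 0L, indel = 0L))
  snv <- is_snv_site(df$ref, df$alt)
  c(snv = sum(snv), indel = sum(!snv))
}

comparison_summary <- function(res) {
  tp <- count_by_type(res$tp); fp <- count_by_type(res$fp)
  fn <- count_by_type(res$fn); ffp <- count_by_type(res$filtered_fp)
  out <- data.frame(
    type = c("snv", "indel"),
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    filtered_fp = as.integer(ffp),
    stringsAsFactors = FALSE)
  out$precision <- ifelse(out$tp + out$fp > 0, out$tp / (out$tp + out$fp), NA)
  out$recall <- ifelse(out$tp + out$fn > 0, out$tp / (out$tp + out$fn), NA)
  out
}

#' @export
print.benchmark_comparison <- function(x, ...) {
  cat("benchmark comparison:\n")
  print.data.frame(x$summary)
  invisible(x)
}

#' Stratified precision/recall report
#'
#' Assigns TP and FN by the truth variant's position and FP by the query
#' variant's position to each stratum; strata with fewer than `min_truth`
#' truth variants are dropped; output is sorted by (precision - recall),
#' descending.
#'
#' @param cmp a `benchmark_comparison` from [compare_benchmark()].
#' @param strata named list of [region_set()]s.
#' @param min_truth minimum truth variants for a stratum to be reported.
#' @return A data frame with one row per stratum and per variant type
#'   (`snv`, `indel`, `all`): counts, precision and recall.
#' @export
stratify_comparison <- function(cmp, strata, min_truth = 1000) {
  rows <- lapply(names(strata), function(lab) {
    rs <- strata[[lab]]
    sub <- function(df) {
      if (is.null(df) || !nrow(df)) return(df)
      df[in_regions(df$chrom, df$pos, rs), , drop = FALSE]
    }
    tp <- count_by_type(sub(cmp$tp)); fp <- count_by_type(sub(cmp$fp))
    fn <- count_by_type(sub(cmp$fn))
    n_truth <- sum(tp) + sum(fn)
    if (n_truth < min_truth) return(NULL)
    data.frame(stratum = lab, type = c("snv", "indel", "all"),
               tp = c(tp, sum(tp)), fp = c(fp, sum(fp)), fn = c(fn, sum(fn)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(stratum = character(), type = character(),
                      tp = integer(), fp = integer(), fn = integer(),
                      precision = numeric(), recall = numeric(),
                      stringsAsFactors = FALSE))
  }
  out$precision <- ifelse(out$tp + out$fp > 0, out$tp / (out$tp + out$fp), NA)
  out$recall <- ifelse(out$tp + out$fn > 0, out$tp / (out$tp + out$fn), NA)
  allrows <- out[out$type == "all", ]
  ord <- allrows$stratum[order(allrows$precision - allrows$recall,
                               decreasing = TRUE)]
  out <- out[order(match(out$stratum, ord)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene benchmark inclusion
#'
#' Fraction of each gene's span covered by the benchmark regions, plus the
#' number of genes covered above a threshold.
#'
#' @param genes data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `name`.
#' @param bench_regions a [region_set()].
#' @param threshold inclusion threshold (default 0.90, strict).
#' @return A data frame with `name`, `bp`, `bp_included`, `fraction`;
#'   attribute `n_above` is the count with fraction > threshold.
#' @export
gene_inclusion <- function(genes, bench_regions, threshold = 0.90) {
  if (any(genes$end <= genes$start)) stop("zero- or negative-length gene")
  frac <- numeric(nrow(genes))
  bpin <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- region_set(genes$chrom[i], genes$start[i], genes$end[i])
    bpin[i] <- region_bp(intersect_regions(g, bench_regions))
    frac[i] <- bpin[i] / (genes$end[i] - genes$start[i])
  }
  out <- data.frame(name = genes$name, bp = genes$end - genes$start,
                    bp_included = bpin, fraction = frac,
                    stringsAsFactors = FALSE)
  attr(out, "n_above") <- sum(frac > threshold)
  out
}
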