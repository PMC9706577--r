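#' Intersection of trio benchmark regions
#'
#' @param son,father,mother [benchmark_set()]s (or [region_set()]s).
#' @return A normalized [region_set()] covered by all three.
#' @export
trio_regions <- function(son, father, mother) {
  reg <- lapply(list(son, father, mother), function(x)
    if (inherits(x, "benchmark_set")) x$regions else x)
  Reduce(intersect_regions, reg)
}

#' Classify a trio genotype pattern
#'
#' A site is `consistent` when the son's two alleles can be partitioned
#' with one inherited from the father and one from the mother;
#' `potential_de_novo` when inconsistent but the son is heterozygous 0/1
#' and both parents are homozygous reference (the one biologically
#' plausible violation); anything else is `violation_other`.  A missing
#' genotype makes the site untestable and it is classified `consistent`
#' by convention.
#'
#' @param gt_son,gt_father,gt_mother diploid genotypes as length-2 integer
#'   vectors of allele indices (0 = reference); NA for missing.
#' @return One of `"consistent"`, `"potential_de_novo"`, `"violation_other"`.
#' @export
classify_trio_site <- function(gt_son, gt_father, gt_mother) {
  for (g in list(gt_son, gt_father, gt_mother))
    if (length(g) != 2) stop("genotypes must be diploid (length 2)")
  if (anyNA(c(gt_son, gt_father, gt_mother))) return("consistent")
  s <- sort(gt_son)
  ok <- (gt_son[1] %in% gt_father && gt_son[2] %in% gt_mother) ||
    (gt_son[2] %in% gt_father && gt_son[1] %in% gt_mother)
  if (ok) return("consistent")
  if (identical(s, c(0L, 1L)) && all(gt_father == 0L) && all(gt_mother == 0L))
    return("potential_de_novo")
  "violation_other"
}

is_snv_site <- function(ref, alt) {
  nchar(ref) == 1 & !grepl(",", alt, fixed = TRUE) & nchar(alt) == 1
}

#' Mendelian-consistency report for a trio
#'
#' Matches sites across the three members by (chrom, pos, ref, alt) inside
#' the joint regions; a member with no call at a matched site inside the
#' regions is imputed homozygous reference (benchmark semantics: the
#' regions assert hom-ref where no variant is listed).  Sites outside the
#' joint regions are ignored.
#'
#' @param son,father,mother [variant_sites()] tables or [benchmark_set()]s.
#' @param regions joint [region_set()]; defaults to [trio_regions()] when
#'   benchmark sets are given.
#' @return A list with `summary` (counts: sites tested, consistent,
#'   potential de novo SNVs/indels, other violations) and `sites`
#'   (per-site table with a `classification` column).
#' @export
mendelian_report <- function(son, father, mother, regions = NULL) {
  get_sites <- function(x) if (inherits(x, "benchmark_set")) x$variants else x
  if (is.null(regions)) {
    if (!inherits(son, "benchmark_set"))
      stop("regions must be supplied when inputs are plain site tables")
    regions <- trio_regions(son, father, mother)
  }
  members <- lapply(list(son = son, father = father, mother = mother), get_sites)
  members <- lapply(members, function(s) {
    if (!nrow(s)) return(s)
    s[in_regions(s$chrom, s$pos, regions), , drop = FALSE]
  })
  keys <- unique(do.call(rbind, lapply(members, function(s)
    data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
               stringsAsFactors = FALSE))))
  if (is.null(keys) || !nrow(keys)) {
    return(list(summary = list(n_sites = 0L, n_consistent = 0L,
                               n_de_novo_snv = 0L, n_de_novo_indel = 0L,
                               n_violation_other = 0L),
                sites = NULL))
  }
  keys <- keys[order(keys$chrom, keys$pos, keys$ref, keys$alt), , drop = FALSE]
  kk <- paste(keys$chrom, keys$pos, keys$ref, keys$alt)
  gts <- lapply(members, function(s) {
    m <- match(kk, paste(s$chrom, s$pos, s$ref, s$alt))
    cbind(ifelse(is.na(m), 0L, s$a1[m]), ifelse(is.na(m), 0L, s$a2[m]))
  })
  cls <- vapply(seq_len(nrow(keys)), function(i)
    classify_trio_site(gts$son[i, ], gts$father[i, ], gts$mother[i, ]),
    character(1))
  keys$gt_son <- gt_key(gts$son[, 1], gts$son[, 2])
  keys$gt_father <- gt_key(gts$father[, 1], gts$father[, 2])
  keys$gt_mother <- gt_key(gts$mother[, 1], gts$mother[, 2])
  keys$classification <- cls
  snv <- is_snv_site(keys$ref, keys$alt)
  list(summary = list(
    n_sites = nrow(keys),
    n_consistent = sum(cls == "consistent"),
    n_de_novo_snv = sum(cls == "potential_de_novo" & snv),
    n_de_novo_indel = sum(cls == "potential_de_novo" & !snv),
    n_violation_other = sum(cls == "violation_other")),
    sites = keys)
}

#' Exclude non-biological Mendelian violations from trio benchmarks
#'
#' Subtracts each `violation_other` locus, padded by `pad` bp on each side,
#' from the benchmark regions of all three members; potential de novo
#' sites are retained.  Re-running [mendelian_report()] afterwards yields
#' zero `violation_other` sites.
#'
#' @param son,father,mother [benchmark_set()]s.
#' @param violations per-site table from [mendelian_report()] (rows with
#'   other classifications are ignored) or a [variant_sites()]-like table.
#' @param pad padding in bp (default 50).
#' @return A named list of the three updated [benchmark_set()]s.
#' @export
exclude_violations <- function(son, father, mother, violations, pad = 50) {
  v <- violations
  if (!is.null(v$classification))
    v <- v[v$classification == "violation_other", , drop = FALSE]
  mask <- pad_site_spans(v, pad)
  fix <- function(b) {
    regions <- subtract_regions(b$regions, mask)
    vars <- b$variants
    if (nrow(vars)) {
      vars <- vars[in_regions(vars$chrom, vars$pos, regions), , drop = FALSE]
      rownames(vars) <- NULL
      class(vars) <- c("variant_sites", "data.frame")
    }
    benchmark_set(vars, regions, ledger = b$ledger)
  }
  list(son = fix(son), father = fix(father), mother = fix(mother))
}
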