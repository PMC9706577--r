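# Independent per-base oracles: a region set on a small genome is a list of
# logical vectors (one element per base), so every interval operation can be
# checked against plain boolean algebra.

mask_genome <- function(chroms = c("chr1", "chr2"), len = 1000) {
  genome_file(chroms, rep(len, length(chroms)))
}

rs_to_mask <- function(rs, genome) {
  m <- lapply(stats::setNames(genome$length, genome$chrom),
              function(n) logical(n))
  for (i in seq_len(nrow(rs))) {
    ch <- rs$chrom[i]
    m[[ch]][(rs$start[i] + 1):rs$end[i]] <- TRUE
  }
  m
}

mask_to_bp <- function(m) sum(vapply(m, sum, numeric(1)))

expect_same_bases <- function(rs, mask, genome) {
  expect_identical(rs_to_mask(normalize_regions(rs), genome), mask)
}

random_rs <- function(genome, n = 20, max_len = 120) {
  chrom <- sample(genome$chrom, n, replace = TRUE)
  len <- genome$length[match(chrom, genome$chrom)]
  start <- floor(stats::runif(n) * (len - max_len))
  width <- 1 + floor(stats::runif(n) * max_len)
  region_set(chrom, start, pmin(start + width, len))
}

# per-base interval stacking depth (counting oracle)
depth_mask <- function(rs, genome) {
  m <- lapply(stats::setNames(genome$length, genome$chrom),
              function(n) integer(n))
  for (i in seq_len(nrow(rs))) {
    ch <- rs$chrom[i]
    idx <- (rs$start[i] + 1):rs$end[i]
    m[[ch]][idx] <- m[[ch]][idx] + 1L
  }
  m
}

# exhaustive parental-transmission oracle: a trio genotype is consistent iff
# some choice of one paternal and one maternal allele reproduces the son
transmission_oracle <- function(gt_son, gt_father, gt_mother) {
  for (f in gt_father) for (m in gt_mother) {
    if (setequal_multiset(c(f, m), gt_son)) return(TRUE)
  }
  FALSE
}

setequal_multiset <- function(a, b) identical(sort(a), sort(b))

gt_sort_key <- function(d) {
  paste(d$chrom, d$pos, d$ref, d$alt, pmin(d$a1, d$a2), pmax(d$a1, d$a2))
}

# the seeded fixture bundle and per-member pipeline runs are expensive;
# build them once per test session
fx_cache <- new.env(parent = emptyenv())

get_fx42 <- function() {
  if (is.null(fx_cache$fx)) fx_cache$fx <- make_fixtures(fixture_config(seed = 42))
  fx_cache$fx
}

get_pipeline42 <- function(member = "son") {
  key <- paste0("pipe_", member)
  if (is.null(fx_cache[[key]]))
    fx_cache[[key]] <- run_fixture_pipeline(get_fx42(), member)
  fx_cache[[key]]
}
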