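#' Synthetic-fixture configuration
#'
#' Parameters of the toy diploid trio world: a small multi-chromosome
#' genome with planted segmental duplications, tandem repeats,
#' homopolymers, LINE-like elements, a centromere-like block and a sample
#' duplication (CNV); trio truth variants with planted de novo mutations;
#' per-technology coverage tracks; and per-technology callsets with
#' planted error structure (paralog false positives inside the many-copy
#' segmental duplication, haplotype-dropout genotype errors in LINEs,
#' homopolymer indel errors) mimicking the failure modes of short reads.
#'
#' With a fixed seed all outputs are byte-identical across runs.  Each
#' sub-generator (genome, trio, coverage, callsets) uses its own RNG
#' stream seeded at `seed + 1 .. seed + 4`, so changing one profile does
#' not reshuffle the others.
#'
#' @param seed integer RNG seed.
#' @param n_chroms,chrom_size genome shape (default 2 chromosomes x 1 Mb,
#'   enough for >500 coverage windows and every repeat class).
#' @param window coverage window width in bp.
#' @param segdup_len,segdup_copies,segdup_identity the many-copy
#'   duplication family (the 2-copy control family uses the same length
#'   and identity).
#' @param snv_rate,indel_rate per-bp truth variant rates.
#' @param maf alternate-allele frequency on parental haplotypes.
#' @param de_novo_snvs,de_novo_indels planted de novo counts (son 0/1,
#'   parents 0/0).
#' @param depth_hifi,depth_ont,depth_short,depth_tenx mean window depths.
#' @param cnv_len,cnv_fold sample duplication length and coverage fold.
#' @param segdup_fp_per_copy short-read paralog FPs planted per duplicated
#'   copy.
#' @param line_cluster_sites heterozygous sites planted inside the first
#'   LINE element (substrate for short-read haplotype-dropout errors).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 42, n_chroms = 2, chrom_size = 1e6,
                           window = 1000,
                           segdup_len = 12000, segdup_copies = 6,
                           segdup_identity = 0.995,
                           snv_rate = 1e-3, indel_rate = 1e-4, maf = 0.35,
                           de_novo_snvs = 7, de_novo_indels = 3,
                           depth_hifi = 35, depth_ont = 45,
                           depth_short = 50, depth_tenx = 40,
                           cnv_len = 10000, cnv_fold = 2,
                           segdup_fp_per_copy = 2, line_cluster_sites = 3) {
  stopifnot(seed == floor(seed), n_chroms >= 1, chrom_size >= 1e6,
            snv_rate >= 0, snv_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            maf >= 0, maf <= 1)
  structure(as.list(environment()), class = "fixture_config")
}

.bases <- c("A", "C", "G", "T")

rand_seq <- function(n) sample(.bases, n, replace = TRUE)

mutate_seq <- function(x, rate) {
  k <- max(1L, round(rate * length(x)))
  at <- sample(length(x), k)
  x[at] <- vapply(x[at], function(b) sample(setdiff(.bases, b), 1), "")
  x
}

## Fixed feature layout per chromosome (coordinates are 0-based half-open).
fixture_layout <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  sd_starts <- c(100000 + (0:4) * 20000, 100000)  # copy 6 goes on chr2
  sd_chrom <- c(rep(chroms[1], 5), chroms[min(2, cfg$n_chroms)])
  n <- cfg$segdup_copies
  list(
    chroms = chroms,
    tr30 = c(20000, 22000, 24000),
    tr100 = c(30000, 32000),
    tr1000 = 40000,
    homopolymer = c(50000, 50500, 51000),
    imperfect_homopolymer = 52000,
    line = c(60000, 62000), line_len = 800,
    segdup_main = data.frame(chrom = sd_chrom[seq_len(min(n, 6))],
                             start = sd_starts[seq_len(min(n, 6))],
                             stringsAsFactors = FALSE),
    segdup_minor = data.frame(chrom = chroms[c(1, min(2, cfg$n_chroms))],
                              start = c(220000, 220000),
                              stringsAsFactors = FALSE),
    lowmap = c(300000, 320000),
    tenx_dropout = list(chrom = chroms[min(2, cfg$n_chroms)],
                        start = 350000, end = 352000),
    centromere = c(480000, 500000),
    tr_gt10k = list(chrom = chroms[1], start = 600000, len = 12000),
    sv = list(chrom = chroms[min(2, cfg$n_chroms)], start = 620000, end = 621000),
    cnv = list(chrom = chroms[1], start = 700000),
    vdj = list(chrom = chroms[min(2, cfg$n_chroms)], start = 780000, end = 781000),
    easy = c(820000, 960000),
    de_novo_snv_start = 850000, de_novo_indel_start = 858000,
    segdup_fp_offsets = c(500, 1500, 2500, 3500),
    line_sites = c(60100, 60300, 60500),
    homopolymer_fp_pos = 50003,
    hifi_refcall_pos = 900000, hifi_multiallelic_pos = 905000
  )
}

#' Generate the toy genome, annotation tracks and segdup records
#'
#' Plants, at fixed coordinates on each chromosome: tandem repeats of each
#' length class, perfect and imperfect homopolymers, two copies of a
#' LINE-like element, a low-complexity centromere block, a dedicated
#' low-mappability block, and two segmental-duplication families (one with
#' `segdup_copies` copies that must trigger the many-copy exclusion, one
#' 2-copy control that must not).  The annotation tracks exactly describe
#' the planted features; segdup records list each aligned pair in both
#' orientations, as duplication annotation tracks do, so a family of N
#' copies stacks 2(N-1) records on each copy.
#'
#' @param cfg a [fixture_config()].
#' @return A list with `seq` (named `DNAStringSet`), `genome`
#'   ([genome_file()]), `tracks` ([repeat_class_tracks()]), `segdup_records`
#'   and `features` (named list of planted-feature [region_set()]s).
#' @export
make_genome <- function(cfg = fixture_config()) {
  set.seed(cfg$seed + 1)
  lay <- fixture_layout(cfg)
  size <- cfg$chrom_size
  chroms <- lay$chroms
  seqs <- lapply(chroms, function(ch) rand_seq(size))
  names(seqs) <- chroms

  plant <- function(chrom, start, bases) {
    stopifnot(start + length(bases) <= size)
    seqs[[chrom]][(start + 1):(start + length(bases))] <<- bases
  }
  rs <- function(chrom, start, end) region_set(chrom, start, end)

  tr30_unit <- rep(c("A", "C", "G"), 10)
  tr100_unit <- rep(c("A", "C", "G", "T", "G"), 20)
  tr1000_unit <- rep(strsplit("ACGTGATCGG", "")[[1]], 100)
  trbig_unit <- rep(strsplit("ACGTGA", "")[[1]], lay$tr_gt10k$len / 6)
  hp <- rep("A", 10)
  ihp <- c(rep("A", 7), "C", rep("A", 7))
  cen <- rep(c("A", "T"), (lay$centromere[2] - lay$centromere[1]) / 2)
  line_motif <- rand_seq(lay$line_len)

  feats <- list()
  add_feat <- function(name, chrom, start, end) {
    feats[[name]] <<- rbind(feats[[name]],
                            data.frame(chrom = chrom, start = start, end = end,
                                       stringsAsFactors = FALSE))
  }
  for (ch in chroms) {
    for (p in lay$tr30) { plant(ch, p, tr30_unit); add_feat("tr_lt51", ch, p, p + 30) }
    for (p in lay$tr100) { plant(ch, p, tr100_unit); add_feat("tr_51_200", ch, p, p + 100) }
    plant(ch, lay$tr1000, tr1000_unit); add_feat("tr_200_10k", ch, lay$tr1000, lay$tr1000 + 1000)
    for (p in lay$homopolymer) { plant(ch, p, hp); add_feat("homopolymer_gt6", ch, p, p + 10) }
    plant(ch, lay$imperfect_homopolymer, ihp)
    add_feat("imperfect_homopolymer_gt10", ch, lay$imperfect_homopolymer,
             lay$imperfect_homopolymer + 15)
    for (p in lay$line) { plant(ch, p, line_motif); add_feat("line", ch, p, p + lay$line_len) }
    plant(ch, lay$centromere[1], cen)
    add_feat("centromere", ch, lay$centromere[1], lay$centromere[2])
    add_feat("lowmap_block", ch, lay$lowmap[1], lay$lowmap[2])
  }
  plant(lay$tr_gt10k$chrom, lay$tr_gt10k$start, trbig_unit)
  feats$tr_gt10k <- data.frame(chrom = lay$tr_gt10k$chrom,
                               start = lay$tr_gt10k$start,
                               end = lay$tr_gt10k$start + lay$tr_gt10k$len)

  ## segdup families: mutate each copy of a common source at 1 - identity
  plant_family <- function(copies_df, len, identity) {
    src <- rand_seq(len)
    for (i in seq_len(nrow(copies_df))) {
      copy <- if (i == 1) src else mutate_seq(src, 1 - identity)
      plant(copies_df$chrom[i], copies_df$start[i], copy)
    }
    data.frame(chrom = copies_df$chrom, start = copies_df$start,
               end = copies_df$start + len, stringsAsFactors = FALSE)
  }
  main <- plant_family(lay$segdup_main, cfg$segdup_len, cfg$segdup_identity)
  minor <- plant_family(lay$segdup_minor, cfg$segdup_len, cfg$segdup_identity)

  pair_records <- function(fam, identity) {
    n <- nrow(fam)
    if (n < 2) return(NULL)
    idx <- rep(seq_len(n), each = 2 * (n - 1))
    data.frame(chrom = fam$chrom[idx], start = fam$start[idx],
               end = fam$end[idx], identity = identity,
               stringsAsFactors = FALSE)
  }
  segdup_records <- rbind(pair_records(main, cfg$segdup_identity),
                          pair_records(minor, cfg$segdup_identity))

  feats$segdup_main <- main
  feats$segdup_minor <- minor
  feats$cnv <- data.frame(chrom = lay$cnv$chrom, start = lay$cnv$start,
                          end = lay$cnv$start + cfg$cnv_len)
  feats$vdj <- data.frame(chrom = lay$vdj$chrom, start = lay$vdj$start, end = lay$vdj$end)
  feats$sv <- data.frame(chrom = lay$sv$chrom, start = lay$sv$start, end = lay$sv$end)
  feats$tenx_dropout <- data.frame(chrom = lay$tenx_dropout$chrom,
                                   start = lay$tenx_dropout$start,
                                   end = lay$tenx_dropout$end)

  genome <- genome_file(chroms, rep(size, length(chroms)))
  to_rs <- function(df) region_set(df$chrom, df$start, df$end, genome = genome)
  features <- lapply(feats, to_rs)

  tracks <- repeat_class_tracks(
    tr_lt51 = features$tr_lt51,
    tr_51_200 = features$tr_51_200,
    tr_200_10k = features$tr_200_10k,
    homopolymer_gt6 = features$homopolymer_gt6,
    imperfect_homopolymer_gt10 = features$imperfect_homopolymer_gt10,
    low_mappability = union_regions(list(features$lowmap_block, features$segdup_main)),
    line_l1hs_gt500 = features$line,
    segdup = union_regions(list(features$segdup_main, features$segdup_minor)))

  dna <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(dna) <- chroms
  list(seq = dna, genome = genome, tracks = tracks,
       segdup_records = segdup_records, features = features, layout = lay)
}

ref_at <- function(seq, chrom, pos, len = 1) {
  as.character(Biostrings::subseq(seq[[chrom]], pos, pos + len - 1))
}

#' Generate trio truth variants
#'
#' Parental haplotypes carry population alternate alleles independently at
#' frequency `maf`; the son inherits one haplotype from each parent.
#' Planted on top are `de_novo_snvs` + `de_novo_indels` de novo sites
#' (son 0/1, both parents 0/0) at fixed positions in an easy region, and a
#' small cluster of heterozygous sites inside the first LINE element (the
#' substrate for the short-read haplotype-dropout error profile).
#'
#' @param cfg a [fixture_config()].
#' @param gen output of [make_genome()].
#' @return A list with `manifest` (all truth sites with the three
#'   genotypes, `de_novo` and `line_cluster` flags), per-member
#'   [variant_sites()] tables (`son`, `father`, `mother`), and `cnv_bed`.
#' @export
make_trio_truth <- function(cfg, gen) {
  set.seed(cfg$seed + 2)
  lay <- gen$layout
  size <- cfg$chrom_size
  reserved <- c(lay$line_sites,
                outer(lay$segdup_fp_offsets, gen$features$segdup_main$start, "+"),
                lay$homopolymer_fp_pos, lay$hifi_refcall_pos,
                lay$hifi_multiallelic_pos,
                lay$de_novo_snv_start + (0:19) * 500,
                lay$de_novo_indel_start + (0:19) * 500)

  rows <- list()
  for (ch in lay$chroms) {
    n_snv <- round(cfg$snv_rate * size)
    n_indel <- round(cfg$indel_rate * size)
    pos <- sort(sample(100:(size - 200), (n_snv + n_indel) * 2))
    pos <- pos[c(TRUE, diff(pos) >= 20)]
    pos <- pos[!(pos %in% as.vector(outer(-25:25, reserved, "+")))]
    pos <- pos[seq_len(min(length(pos), n_snv + n_indel))]
    is_snv <- rep(FALSE, length(pos))
    is_snv[sample(length(pos), min(n_snv, length(pos)))] <- TRUE
    for (i in seq_along(pos)) {
      p <- pos[i]
      if (is_snv[i]) {
        ref <- ref_at(gen$seq, ch, p)
        alt <- sample(setdiff(.bases, ref), 1)
      } else if (stats::runif(1) < 0.5) {    # deletion of 1-2 bp
        del <- sample(1:2, 1)
        ref <- ref_at(gen$seq, ch, p, del + 1)
        alt <- substr(ref, 1, 1)
      } else {                               # insertion of 1-2 bp
        ref <- ref_at(gen$seq, ch, p)
        alt <- paste0(ref, paste(sample(.bases, sample(1:2, 1), TRUE), collapse = ""))
      }
      hap <- stats::rbinom(4, 1, cfg$maf)    # father h1 h2, mother h1 h2
      f <- hap[1:2]; m <- hap[3:4]
      s <- c(f[sample(2, 1)], m[sample(2, 1)])
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, pos = p, ref = ref, alt = alt,
        s1 = s[1], s2 = s[2], f1 = f[1], f2 = f[2], m1 = m[1], m2 = m[2],
        de_novo = FALSE, line_cluster = FALSE, stringsAsFactors = FALSE)
    }
  }
  ## LINE cluster: het in all members (consistent transmission)
  for (p in lay$line_sites[seq_len(cfg$line_cluster_sites)]) {
    ref <- ref_at(gen$seq, lay$chroms[1], p)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = lay$chroms[1], pos = p, ref = ref,
      alt = sample(setdiff(.bases, ref), 1),
      s1 = 0, s2 = 1, f1 = 0, f2 = 1, m1 = 0, m2 = 1,
      de_novo = FALSE, line_cluster = TRUE, stringsAsFactors = FALSE)
  }
  ## de novo sites: son het, parents hom-ref
  dn_pos_snv <- lay$de_novo_snv_start + seq_len(cfg$de_novo_snvs) * 500 - 500
  for (p in dn_pos_snv) {
    ref <- ref_at(gen$seq, lay$chroms[1], p)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = lay$chroms[1], pos = p, ref = ref,
      alt = sample(setdiff(.bases, ref), 1),
      s1 = 0, s2 = 1, f1 = 0, f2 = 0, m1 = 0, m2 = 0,
      de_novo = TRUE, line_cluster = FALSE, stringsAsFactors = FALSE)
  }
  dn_pos_ind <- lay$de_novo_indel_start + seq_len(cfg$de_novo_indels) * 500 - 500
  for (p in dn_pos_ind) {
    ref <- ref_at(gen$seq, lay$chroms[1], p, 2)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = lay$chroms[1], pos = p, ref = ref, alt = substr(ref, 1, 1),
      s1 = 0, s2 = 1, f1 = 0, f2 = 0, m1 = 0, m2 = 0,
      de_novo = TRUE, line_cluster = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    rows <- list(data.frame(chrom = character(), pos = numeric(),
                            ref = character(), alt = character(),
                            s1 = integer(), s2 = integer(), f1 = integer(),
                            f2 = integer(), m1 = integer(), m2 = integer(),
                            de_novo = logical(), line_cluster = logical(),
                            stringsAsFactors = FALSE))
  manifest <- do.call(rbind, rows)
  manifest <- manifest[!(manifest$s1 + manifest$s2 + manifest$f1 + manifest$f2 +
                           manifest$m1 + manifest$m2 == 0), , drop = FALSE]
  manifest <- manifest[order(manifest$chrom, manifest$pos), , drop = FALSE]
  rownames(manifest) <- NULL

  member_sites <- function(a1c, a2c) {
    keep <- manifest[[a1c]] + manifest[[a2c]] > 0
    m <- manifest[keep, , drop = FALSE]
    variant_sites(m$chrom, m$pos, m$ref, m$alt, m[[a1c]], m[[a2c]],
                  qual = 50, filter = "PASS", callset = "truth")
  }
  list(manifest = manifest,
       son = member_sites("s1", "s2"),
       father = member_sites("f1", "f2"),
       mother = member_sites("m1", "m2"),
       cnv_bed = gen$features$cnv)
}

#' Generate per-technology coverage tracks and the coverage window table
#'
#' Window depths are Poisson around each technology's configured mean,
#' doubled (by `cnv_fold`) over the planted sample duplication, near zero
#' over the centromere for every technology, and near zero over
#' low-mappability blocks and the many-copy segmental duplication for
#' short reads (high-MQ depth collapses where reads multi-map).
#' Haplotype-split HiFi and linked-read tracks binomially halve the
#' unsplit depth, except in the linked-read allele-dropout zone where one
#' haplotype gets everything.  Also returns three synthetic assembly
#' contig-coverage bedGraph pairs (contig coverage 2 spanning the
#' duplication) and an external CNV call track.
#'
#' @param cfg a [fixture_config()].
#' @param gen output of [make_genome()].
#' @return A list with `tracks` (per technology: `unsplit` and, for hifi
#'   and tenx, `hap1`/`hap2` [depth_track()]s), `windows`
#'   (a [coverage_windows()] table), `assemblies`, `external_cnv`.
#' @export
make_coverage <- function(cfg, gen) {
  set.seed(cfg$seed + 3)
  lay <- gen$layout
  size <- cfg$chrom_size
  win <- cfg$window
  chrom <- rep(lay$chroms, each = ceiling(size / win))
  start <- rep(seq(0, size - 1, by = win), length(lay$chroms))
  end <- pmin(start + win, size)
  wr <- region_set(chrom, start, end)
  over <- function(feature_rs)
    span_in_regions(wr$chrom, wr$start, wr$end, feature_rs, mode = "overlap")
  in_cnv <- over(gen$features$cnv)
  in_cen <- over(gen$features$centromere)
  in_lowmap <- over(union_regions(list(gen$features$lowmap_block,
                                       gen$features$segdup_main)))
  in_dropout <- over(gen$features$tenx_dropout)

  lambda_for <- function(mean_depth, short_read = FALSE) {
    lam <- rep(mean_depth, nrow(wr))
    lam[in_cnv] <- lam[in_cnv] * cfg$cnv_fold
    if (short_read) lam[in_lowmap] <- 1
    lam[in_cen] <- 0.2
    lam
  }
  mk <- function(depth, label, haplotype = "unsplit")
    depth_track(chrom, start, end, depth, label = label, haplotype = haplotype)
  split_haps <- function(depth, label, dropout = NULL) {
    h1 <- stats::rbinom(length(depth), depth, 0.5)
    h2 <- depth - h1
    if (!is.null(dropout)) { h1[dropout] <- depth[dropout]; h2[dropout] <- 0 }
    list(hap1 = mk(h1, label, "hap1"), hap2 = mk(h2, label, "hap2"))
  }
  hifi_d <- stats::rpois(nrow(wr), lambda_for(cfg$depth_hifi))
  ont_d <- stats::rpois(nrow(wr), lambda_for(cfg$depth_ont))
  short_d <- stats::rpois(nrow(wr), lambda_for(cfg$depth_short, short_read = TRUE))
  tenx_d <- stats::rpois(nrow(wr), lambda_for(cfg$depth_tenx))

  tracks <- list(
    hifi = c(list(unsplit = mk(hifi_d, "hifi")), split_haps(hifi_d, "hifi")),
    ont = list(unsplit = mk(ont_d, "ont")),
    short = list(unsplit = mk(short_d, "short")),
    tenx = c(list(unsplit = mk(tenx_d, "tenx")),
             split_haps(tenx_d, "tenx", dropout = in_dropout)))

  windows <- coverage_windows(chrom, start, end, hifi_d, ont_d)

  cnv <- gen$features$cnv
  asm_pair <- function() {
    nchr <- nrow(gen$genome)
    base <- depth_track(gen$genome$chrom, rep(0, nchr), gen$genome$length,
                        rep(1, nchr), label = "asm")
    mat <- rbind(as.data.frame(base),
                 data.frame(chrom = cnv$chrom, start = pmax(cnv$start - 1000, 0),
                            end = cnv$end + 1000, depth = 1))
    mat <- depth_track(mat$chrom, mat$start, mat$end, mat$depth, label = "asm-mat")
    list(mat = mat, pat = base)
  }
  assemblies <- list(asm_pair(), asm_pair(), asm_pair())
  external_cnv <- slop_regions(cnv, "fixed_bp", 2000, genome = gen$genome)
  list(tracks = tracks, windows = windows, assemblies = assemblies,
       external_cnv = external_cnv)
}

#' Generate per-technology callsets for one trio member
#'
#' Each callset reports the member's truth variants restricted to where
#' its technology can see them, plus its planted error structure:
#' short-read callsets drop sites in low-mappability blocks and the
#' many-copy duplication, carry agreeing paralog false positives inside
#' the duplicated copies, genotype the LINE-cluster heterozygous sites as
#' homozygous (haplotype dropout), and add an agreed homopolymer indel
#' false positive; the HiFi callset is error-free but includes a low-QUAL
#' RefCall entry and a multi-allelic entry (exercising VCF preprocessing);
#' the linked-read callset misses sites in its allele-dropout zone; the
#' Ion callset participates as annotation only.
#'
#' @param cfg a [fixture_config()].
#' @param gen output of [make_genome()].
#' @param truth output of [make_trio_truth()].
#' @param member `"son"`, `"father"` or `"mother"`.
#' @return A list with `sites` (named list of [variant_sites()]),
#'   `technologies` (named character vector of technology classes) and
#'   `annotation_only` (named logical vector).
#' @export
make_callsets <- function(cfg, gen, truth, member = "son") {
  midx <- match(member, c("son", "father", "mother"))
  set.seed(cfg$seed + 4 + midx)
  lay <- gen$layout
  base <- truth[[member]]
  drop_in <- function(s, rs) s[!in_regions(s$chrom, s$pos, rs), , drop = FALSE]
  keep_class <- function(s) { class(s) <- c("variant_sites", "data.frame"); s }

  cen <- gen$features$centromere
  short_blind <- union_regions(list(gen$features$lowmap_block,
                                    gen$features$segdup_main, cen))
  line_pos <- lay$line_sites

  short_sites <- keep_class(drop_in(base, short_blind))
  flip <- short_sites$chrom == lay$chroms[1] & short_sites$pos %in% line_pos
  short_sites$a1[flip] <- 1L; short_sites$a2[flip] <- 1L   # haplotype dropout

  fp_pos <- as.vector(outer(lay$segdup_fp_offsets[seq_len(cfg$segdup_fp_per_copy)],
                            gen$features$segdup_main$start, "+"))
  fp_chrom <- rep(gen$features$segdup_main$chrom, each = cfg$segdup_fp_per_copy)
  fp_ref <- mapply(function(ch, p) ref_at(gen$seq, ch, p), fp_chrom, fp_pos)
  fp_alt <- vapply(fp_ref, function(r) sample(setdiff(.bases, r), 1), "")
  segdup_fps <- variant_sites(fp_chrom, fp_pos, fp_ref, fp_alt, 0L, 1L,
                              qual = 45, filter = "PASS", callset = "fp")
  hp_ref <- ref_at(gen$seq, lay$chroms[1], lay$homopolymer_fp_pos)
  hp_fp <- variant_sites(lay$chroms[1], lay$homopolymer_fp_pos, hp_ref,
                         paste0(hp_ref, "A"), 0L, 1L, qual = 38,
                         filter = "PASS", callset = "fp")
  with_errors <- function(s, label) {
    out <- rbind(as.data.frame(s), as.data.frame(segdup_fps), as.data.frame(hp_fp))
    out$callset <- label
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    keep_class(out)
  }

  hifi_extra <- variant_sites(
    rep(lay$chroms[1], 2),
    c(lay$hifi_refcall_pos, lay$hifi_multiallelic_pos),
    c(ref_at(gen$seq, lay$chroms[1], lay$hifi_refcall_pos),
      ref_at(gen$seq, lay$chroms[1], lay$hifi_multiallelic_pos)),
    c(".", paste(sample(.bases, 2), collapse = ",")),
    c(0L, 1L), c(0L, 2L), qual = c(30, 50),
    filter = c("RefCall", "PASS"), callset = "hifi_dv")
  ## keep the multi-allelic ALT distinct from REF
  ma_ref <- hifi_extra$ref[2]
  alts <- setdiff(.bases, ma_ref)[1:2]
  hifi_extra$alt[2] <- paste(alts, collapse = ",")

  hifi_sites <- keep_class(drop_in(base, cen))
  hifi_sites <- keep_class(rbind(as.data.frame(hifi_sites), as.data.frame(hifi_extra)))
  hifi_sites$callset <- "hifi_dv"
  hifi_sites <- keep_class(hifi_sites[order(hifi_sites$chrom, hifi_sites$pos), ])

  tenx_sites <- keep_class(drop_in(drop_in(base, cen), gen$features$tenx_dropout))
  tenx_sites$callset <- "tenx"

  ion_sites <- keep_class(drop_in(base, cen))
  ion_sites$callset <- "ion"

  list(sites = list(ill_gatk = with_errors(short_sites, "ill_gatk"),
                    ill_fb = with_errors(short_sites, "ill_fb"),
                    hifi_dv = hifi_sites,
                    tenx = tenx_sites,
                    ion = ion_sites),
       technologies = c(ill_gatk = "illumina_pcrfree_gatk",
                        ill_fb = "illumina_pcrfree_other",
                        hifi_dv = "hifi_deepvariant",
                        tenx = "tenx",
                        ion = "ion_exome"),
       annotation_only = c(ill_gatk = FALSE, ill_fb = FALSE, hifi_dv = FALSE,
                           tenx = FALSE, ion = TRUE))
}

#' Generate the complete fixture bundle
#'
#' Runs all four sub-generators; with a fixed seed the result is
#' deterministic.
#'
#' @param cfg a [fixture_config()].
#' @param members trio members to build callsets for.
#' @return A list with `config`, `genome` (the [make_genome()] bundle),
#'   `truth`, `coverage` and per-member `callsets`.
#' @export
make_fixtures <- function(cfg = fixture_config(),
                          members = c("son", "father", "mother")) {
  gen <- make_genome(cfg)
  truth <- make_trio_truth(cfg, gen)
  coverage <- make_coverage(cfg, gen)
  callsets <- lapply(stats::setNames(members, members),
                     function(m) make_callsets(cfg, gen, truth, m))
  list(config = cfg, genome = gen, truth = truth, coverage = coverage,
       callsets = callsets)
}

#' Write a fixture bundle to a directory
#'
#' Emits the FASTA, genome file, annotation BEDs, coverage bedGraphs,
#' per-callset VCFs and the truth manifest TSV.
#'
#' @param fx output of [make_fixtures()].
#' @param dir output directory (created if needed).
#' @export
write_fixtures <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(fx$genome$seq, p("genome.fa"))
  write_genome_file(fx$genome$genome, p("genome.txt"))
  for (nm in names(fx$genome$tracks))
    write_bed(fx$genome$tracks[[nm]], p(paste0("track_", nm, ".bed")))
  for (nm in names(fx$genome$features))
    write_bed(fx$genome$features[[nm]], p(paste0("feature_", nm, ".bed")))
  sd <- fx$genome$segdup_records
  utils::write.table(sd, p("segdups.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (tech in names(fx$coverage$tracks))
    for (hap in names(fx$coverage$tracks[[tech]]))
      write_bedgraph(fx$coverage$tracks[[tech]][[hap]],
                     p(sprintf("cov_%s_%s.bedgraph", tech, hap)))
  utils::write.table(fx$truth$manifest, p("truth_manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (m in names(fx$callsets)) {
    write_vcf(fx$truth[[m]], p(sprintf("truth_%s.vcf", m)), sample = m,
              genome = fx$genome$genome)
    for (cs in names(fx$callsets[[m]]$sites))
      write_vcf(fx$callsets[[m]]$sites[[cs]],
                p(sprintf("callset_%s_%s.vcf", m, cs)), sample = m,
                genome = fx$genome$genome)
  }
  invisible(dir)
}
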