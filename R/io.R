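#' Read a BED3+ file into a region_set
#'
#' BED is 0-based half-open, tab-separated.  Columns beyond the third are
#' preserved opaquely as extra columns and written back on output.
#'
#' @param path path to a BED file.
#' @param genome optional [genome_file()]; when bound, chromosomes must be
#'   known and intervals within bounds.
#' @return A [region_set()].
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(region_set(genome = genome))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3))
    stop("malformed BED line ", which(nfield < 3)[1], " in ", path,
         ": fewer than 3 fields")
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, ": non-integer coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, ": start >= end")
  extra <- NULL
  if (max(nfield) > 3) {
    k <- max(nfield) - 3
    extra <- as.data.frame(do.call(rbind, lapply(parts, function(p) {
      c(p[-(1:3)], rep(NA_character_, k - (length(p) - 3)))
    })), stringsAsFactors = FALSE)
    names(extra) <- paste0("V", seq_len(k) + 3)
  }
  region_set(chrom, start, end, genome = genome, extra = extra)
}

#' Write a region_set as BED
#'
#' Output is tab-separated BED, sorted by genome-file chromosome order when
#' a genome is bound (lexicographic otherwise).  Extra columns are written
#' back as-is.
#'
#' @param rs a [region_set()].
#' @param path output path.
#' @export
write_bed <- function(rs, path) {
  rs <- sort_rs(rs, rs_genome(rs))
  df <- as.data.frame(rs)
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome file (two columns: chromosome, length)
#' @param path path to a "chrom<TAB>length" file.
#' @return A [genome_file()].
#' @export
read_genome_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_file(df$chrom, df$length)
}

#' @rdname read_genome_file
#' @param genome a [genome_file()] to write.
#' @export
write_genome_file <- function(genome, path) {
  utils::write.table(data.frame(genome$chrom,
                                format(genome$length, scientific = FALSE, trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Depth tracks
#'
#' A depth track holds per-window mean read depth in the windowed-bedGraph
#' dialect ("chrom start end depth", 0-based half-open windows), with a
#' dataset label and a haplotype tag (`unsplit`, `hap1` or `hap2`).
#'
#' @param chrom,start,end window coordinates (0-based half-open).
#' @param depth mean read depth per window (>= 0).
#' @param label dataset name.
#' @param haplotype one of `"unsplit"`, `"hap1"`, `"hap2"`.
#' @return A `depth_track` data frame.
#' @export
depth_track <- function(chrom, start, end, depth, label = "track",
                        haplotype = c("unsplit", "hap1", "hap2")) {
  haplotype <- match.arg(haplotype)
  if (any(depth < 0)) stop("depth must be >= 0")
  df <- region_set(chrom, start, end)
  df$depth <- as.numeric(depth)
  class(df) <- c("depth_track", "data.frame")
  attr(df, "label") <- label
  attr(df, "haplotype") <- haplotype
  df
}

#' Read a bedGraph / windowed depth BED into a depth_track
#' @param path bedGraph path ("chrom\\tstart\\tend\\tdepth").
#' @inheritParams depth_track
#' @return A `depth_track`.
#' @export
read_bedgraph <- function(path, label = basename(path), haplotype = "unsplit") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  depth_track(df[[1]], df[[2]], df[[3]], df[[4]], label = label,
              haplotype = haplotype)
}

#' @rdname read_bedgraph
#' @param track a `depth_track` to write.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(data.frame(track$chrom,
                                format(track$start, scientific = FALSE, trim = TRUE),
                                format(track$end, scientific = FALSE, trim = TRUE),
                                track$depth),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Variant site tables
#'
#' Variant sites are normalized records with 1-based positions (converted
#' from/to VCF exactly once, here), a diploid genotype as allele indices,
#' and callset provenance.
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions.
#' @param ref reference alleles (A/C/G/T/N strings).
#' @param alt alternate alleles; multi-allelic sites comma-separated.
#' @param a1,a2 genotype allele indices (0 = ref); NA for missing.
#' @param phased logical, genotype phased flag.
#' @param qual Phred-scaled quality (NA allowed).
#' @param filter FILTER string ("PASS", "." or semicolon-joined tokens).
#' @param callset provenance label.
#' @return A `variant_sites` data frame.
#' @export
variant_sites <- function(chrom = character(), pos = numeric(),
                          ref = character(), alt = character(),
                          a1 = integer(), a2 = integer(),
                          phased = FALSE, qual = NA_real_, filter = "PASS",
                          callset = NA_character_) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   a1 = as.integer(a1), a2 = as.integer(a2),
                   phased = rep_len(as.logical(phased), n),
                   qual = rep_len(as.numeric(qual), n),
                   filter = rep_len(as.character(filter), n),
                   callset = rep_len(as.character(callset), n),
                   stringsAsFactors = FALSE)
  if (n && any(!grepl("^[ACGTN]+$", df$ref)))
    stop("ref alleles must be non-empty over {A,C,G,T,N}")
  nalt <- if (n) lengths(strsplit(df$alt, ",", fixed = TRUE)) else integer()
  if (n && any(stats::na.omit(df$a1) > nalt[!is.na(df$a1)] |
               stats::na.omit(df$a2) > nalt[!is.na(df$a2)]))
    stop("genotype allele index exceeds number of alleles")
  class(df) <- c("variant_sites", "data.frame")
  df
}

parse_gt <- function(gt) {
  gt <- sub(":.*", "", gt)
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")))
  list(a1 = a1, a2 = a2, phased = phased)
}

#' Read a single-sample VCF into a variant_sites table
#'
#' Uses VCF 4.2 via `vcfR`; the 1-based VCF position is kept as `pos`.
#'
#' @param path VCF path (plain or bgzipped).
#' @param callset provenance label recorded on every site.
#' @return A `variant_sites` data frame.
#' @export
read_vcf <- function(path, callset = basename(path)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx)) || nrow(fx) == 0)
    return(variant_sites(callset = callset))
  gt_raw <- if (!is.null(v@gt) && ncol(v@gt) >= 2) v@gt[, 2] else rep("./.", nrow(fx))
  gt <- parse_gt(gt_raw)
  qual <- suppressWarnings(as.numeric(fx[, "QUAL"]))
  filt <- fx[, "FILTER"]
  filt[is.na(filt)] <- "."
  variant_sites(fx[, "CHROM"], as.numeric(fx[, "POS"]), fx[, "REF"], fx[, "ALT"],
                gt$a1, gt$a2, phased = gt$phased, qual = qual, filter = filt,
                callset = callset)
}

#' Write a variant_sites table as a single-sample VCF 4.2 file
#'
#' @param sites a `variant_sites` data frame.
#' @param path output path (plain text).
#' @param sample sample name for the genotype column.
#' @param genome optional [genome_file()] for contig header lines.
#' @param info optional character vector of INFO strings, one per site.
#' @export
write_vcf <- function(sites, path, sample = "SAMPLE", genome = NULL,
                      info = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=benchforge",
           if (!is.null(genome))
             sprintf("##contig=<ID=%s,length=%d>", genome$chrom, as.integer(genome$length)),
           "##INFO=<ID=callsets,Number=1,Type=Integer,Description=\"Number of supporting callsets\">",
           "##INFO=<ID=platforms,Number=.,Type=String,Description=\"Supporting callset labels\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sample, sep = "\t"))
  if (nrow(sites)) {
    o <- if (!is.null(genome)) order(match(sites$chrom, genome$chrom), sites$pos)
         else order(sites$chrom, sites$pos)
    sites <- sites[o, , drop = FALSE]
    if (!is.null(info)) info <- info[o]
    sep <- ifelse(sites$phased, "|", "/")
    gt <- ifelse(is.na(sites$a1) | is.na(sites$a2), "./.",
                 paste0(sites$a1, sep, sites$a2))
    body <- paste(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
                  ".", sites$ref, sites$alt,
                  ifelse(is.na(sites$qual), ".", format(sites$qual, trim = TRUE)),
                  ifelse(is.na(sites$filter) | sites$filter == "", ".", sites$filter),
                  if (is.null(info)) "." else info,
                  "GT", gt, sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
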