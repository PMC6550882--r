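# Readers and writers for the on-disk formats: counts TSV, allele-count TSV,
# VCF genotypes, BED/GTF transcript models, sample tables, YAML config.
# All readers reject malformed input rather than silently coercing.

#' Read a transcripts x samples count matrix from TSV
#'
#' First column holds transcript IDs (must be unique), remaining columns one
#' sample each. Values must be non-negative numbers.
#'
#' @param path TSV file path.
#' @return Numeric matrix with transcript rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts file needs an ID column plus >= 1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate transcript IDs in ", path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric counts in ", path)
  if (anyNA(mat)) stop("missing values in counts (ragged rows?) in ", path)
  if (any(mat < 0)) stop("negative counts in ", path)
  rownames(mat) <- ids
  mat
}

#' @rdname read_counts
#' @param counts Matrix to write.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-SNP allele-count table from TSV
#'
#' Expected columns: `contig`/`chrom`, `position`/`pos` (1-based),
#' `refAllele`, `altAllele`, `sample`, `refCount`, `altCount`.
#'
#' @param path TSV file path.
#' @param samples Optional sample table; unknown sample IDs are an error.
#' @return Data frame with columns chrom, pos, refAllele, altAllele, sample,
#'   refCount, altCount.
#' @export
read_allele_counts <- function(path, samples = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "contig"] <- "chrom"
  names(df)[names(df) == "position"] <- "pos"
  need <- c("chrom", "pos", "refAllele", "altAllele", "sample",
            "refCount", "altCount")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("allele-count table missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[need]
  if (anyNA(df)) stop("missing values in allele-count table")
  if (any(df$pos < 1)) stop("positions must be 1-based (>= 1)")
  if (any(df$refAllele == df$altAllele)) stop("refAllele == altAllele at some SNPs")
  if (any(df$refCount < 0 | df$altCount < 0)) stop("negative allele counts")
  if (!is.null(samples)) {
    bad <- setdiff(unique(df$sample), samples$sample_id)
    if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' @rdname read_allele_counts
#' @param allele_counts Table to write.
#' @export
write_allele_counts <- function(allele_counts, path) {
  utils::write.table(allele_counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read diploid genotypes from a VCF
#'
#' Parses a VCF (v4.x) with \pkg{vcfR}, keeping biallelic SNPs only;
#' multi-allelic and indel records are skipped with a message reporting the
#' count. Genotypes are coded as alternate-allele dosage 0/1/2, `NA` for
#' missing.
#'
#' @param vcf_path VCF file path (plain text or gzipped).
#' @param samples Optional character vector of sample IDs to extract; an
#'   absent sample is an error.
#' @return List with `geno` (sites x individuals integer matrix) and `sites`
#'   (chrom, pos, ref, alt data frame).
#' @export
read_genotypes <- function(vcf_path, samples = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message("read_genotypes: skipped ", n_skip, " multi-allelic/indel record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (!is.null(samples)) {
    absent <- setdiff(samples, colnames(gt))
    if (length(absent)) stop("sample(s) absent from VCF: ",
                             paste(absent, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  geno <- apply(gt, 2L, code)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(gt),
                                         dimnames = list(NULL, colnames(gt)))
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  list(geno = geno, sites = sites)
}

#' Write a minimal VCF v4.2 with GT genotypes
#'
#' @param geno Sites x individuals matrix of 0/1/2/NA dosages.
#' @param sites Data frame with chrom, pos, ref, alt.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, sites, path) {
  stopifnot(nrow(geno) == nrow(sites))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow(geno),
                   dimnames = dimnames(geno))
  gt_str[is.na(gt_str)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT",
                apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read transcript models and TSSs from BED6 or GTF
#'
#' For BED, the interval is the transcript span and the TSS is the start on
#' the plus strand, the end on the minus strand. For GTF, exon records are
#' grouped by `transcript_id`.
#'
#' @param path BED or GTF file.
#' @return Data frame with transcript_id, locus_id, chrom, strand, start,
#'   end, tss (1-based coordinates).
#' @export
read_tss <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e)))
  if (grepl("\\.g[tf]f[0-9]?(\\.gz)?$", path, ignore.case = TRUE)) {
    md <- S4Vectors::mcols(gr)
    if (!"transcript_id" %in% names(md)) stop("GTF lacks transcript_id")
    keep <- if ("type" %in% names(md)) md$type %in% c("exon", "transcript") else TRUE
    gr <- gr[keep]
    sp <- split(gr, S4Vectors::mcols(gr)$transcript_id)
    rng <- unlist(range(sp))
    ids <- names(rng)
    gene <- vapply(split(as.character(S4Vectors::mcols(gr)$gene_id %||%
                                        S4Vectors::mcols(gr)$transcript_id),
                         S4Vectors::mcols(gr)$transcript_id),
                   function(x) x[[1L]], "")
    out <- data.frame(
      transcript_id = ids, locus_id = gene[ids],
      chrom = as.character(GenomicRanges::seqnames(rng)),
      strand = as.character(GenomicRanges::strand(rng)),
      start = GenomicRanges::start(rng), end = GenomicRanges::end(rng),
      stringsAsFactors = FALSE)
  } else {
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm)) stop("BED file lacks a name column (need BED6)")
    out <- data.frame(
      transcript_id = nm, locus_id = nm,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
  }
  if (any(out$strand == "*")) out$strand[out$strand == "*"] <- "+"
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out
}

#' Write transcript models as BED6
#'
#' @param transcripts Data frame with transcript_id, chrom, strand, start, end.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(transcripts, path) {
  bed <- data.frame(transcripts$chrom, transcripts$start - 1L, transcripts$end,
                    transcripts$transcript_id, 0L, transcripts$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert transcript models to GRanges
#'
#' @param transcripts Data frame as returned by [read_tss()].
#' @return A `GRanges` with transcript_id metadata.
#' @export
transcripts_to_granges <- function(transcripts) {
  gr <- GenomicRanges::GRanges(
    seqnames = transcripts$chrom,
    ranges = IRanges::IRanges(start = transcripts$start, end = transcripts$end),
    strand = transcripts$strand)
  S4Vectors::mcols(gr)$transcript_id <- transcripts$transcript_id
  names(gr) <- transcripts$transcript_id
  gr
}

#' Build and validate a sample table
#'
#' @param sample_id Unique sample identifiers.
#' @param river River system of origin.
#' @param ecotype One of marine, freshwater, hybrid.
#' @param sex Optional sex.
#' @param role parent, F1 or pure.
#' @param family Cross/family identifier (F1s must reference a family with
#'   exactly two parents when parents are present).
#' @param salinity Optional acclimation salinity (ppt).
#' @return Validated data frame.
#' @export
sample_table <- function(sample_id, river = NA, ecotype = NA, sex = NA,
                         role = NA, family = NA, salinity = NA) {
  df <- data.frame(sample_id = as.character(sample_id), river = river,
                   ecotype = ecotype, sex = sex, role = role, family = family,
                   salinity = salinity, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("sample IDs must be unique")
  bad_eco <- !is.na(df$ecotype) &
    !df$ecotype %in% c("marine", "freshwater", "hybrid")
  if (any(bad_eco)) stop("ecotype must be marine, freshwater or hybrid")
  f1s <- df[!is.na(df$role) & df$role == "F1", ]
  for (fam in unique(stats::na.omit(f1s$family))) {
    n_par <- sum(!is.na(df$role) & df$role == "parent" &
                   !is.na(df$family) & df$family == fam)
    if (n_par > 0 && n_par != 2L)
      stop("family ", fam, " must have exactly 2 parents, found ", n_par)
  }
  df
}

#' Write a JSON run summary
#'
#' Records package version, seed, and arbitrary counters (e.g. filter tallies)
#' for a pipeline step.
#'
#' @param path Output JSON path.
#' @param step Step name.
#' @param seed Seed used (or NA).
#' @param ... Further scalar fields to record.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(path, step, seed = NA, ...) {
  info <- c(list(step = step,
                 package_version = as.character(utils::packageVersion("paracis")),
                 seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            list(...))
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
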