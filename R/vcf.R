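#' Specify biallelic variants by genomic coordinates
#'
#' Builds a variant panel keyed by `chrom:pos:ref>alt` (1-based VCF
#' coordinates, GRCh38 or whatever build the VCF uses — no liftover is
#' attempted). Matching against a VCF is strict on all four fields; alleles
#' are never flipped or strand-complemented, because a silent mismatch is
#' worse than an explicit error.
#'
#' @param chrom Chromosome labels.
#' @param pos 1-based positions.
#' @param ref,alt Reference / alternate allele strings (`ref != alt`).
#' @param rsid Optional dbSNP IDs.
#' @param gene Optional gene symbols (used only for feature labelling).
#' @return A data frame of class `variant_spec` with a `key` column
#'   rendering as `chrom:pos:ref>alt`. Duplicate coordinates are collapsed
#'   to one row; their gene labels are concatenated with `/`.
#' @export
variant_spec <- function(chrom, pos, ref, alt, rsid = NA_character_,
                         gene = NA_character_) {
  pos <- as.integer(pos)
  if (any(pos < 1)) stop("pos must be >= 1", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt alleles must differ", call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), pos = pos,
                   ref = as.character(ref), alt = as.character(alt),
                   rsid = rsid, gene = gene, stringsAsFactors = FALSE)
  df$key <- sprintf("%s:%d:%s>%s", df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(df$key)) {
    # same variant listed under several gene labels: keep one row, all labels
    key_order <- unique(df$key)
    df <- do.call(rbind, lapply(split(df, df$key), function(g) {
      g$gene[1] <- paste(unique(stats::na.omit(g$gene)), collapse = "/")
      g[1, , drop = FALSE]
    }))
    df <- df[match(key_order, df$key), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("variant_spec", "data.frame")
  df
}

#' @export
format.variant_spec <- function(x, ...) x$key

#' Extract genotype calls for a variant panel from a VCF file
#'
#' Reads a VCF (v4.x, plain or bgzipped) and returns alternate-allele
#' dosages for each requested variant, matched strictly on
#' (chrom, pos, ref, alt). Multiallelic records match when the requested
#' alt appears among the record's comma-separated alternates; the dosage
#' then counts that allele only.
#'
#' @param vcf_path Path to the VCF file.
#' @param variants A [variant_spec] panel.
#' @param unmatched What to do when a requested variant has no matching
#'   record: `"error"` (default) or `"all_missing"` (dosage `NA` for every
#'   subject).
#' @return Integer matrix, subjects x variants (columns named by variant
#'   key), of alt-allele dosages 0/1/2 with `NA` for missing calls. Feed to
#'   [encode_snp_indicators()] to obtain model features.
#' @export
extract_variants_vcf <- function(vcf_path, variants,
                                 unmatched = c("error", "all_missing")) {
  unmatched <- match.arg(unmatched)
  stopifnot(inherits(variants, "variant_spec"))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  out <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(variants),
                dimnames = list(samples, variants$key))
  for (v in seq_len(nrow(variants))) {
    hit <- which(fix[, "CHROM"] == variants$chrom[v] &
                   as.integer(fix[, "POS"]) == variants$pos[v] &
                   fix[, "REF"] == variants$ref[v])
    alt_idx <- NA_integer_
    rec <- NA_integer_
    for (h in hit) {
      alts <- strsplit(fix[h, "ALT"], ",", fixed = TRUE)[[1]]
      j <- match(variants$alt[v], alts)
      if (!is.na(j)) { rec <- h; alt_idx <- j; break }
    }
    if (is.na(rec)) {
      if (unmatched == "error") {
        stop(sprintf("variant %s not found in %s (strict chrom/pos/ref/alt match)",
                     variants$key[v], vcf_path), call. = FALSE)
      }
      next
    }
    out[, v] <- parse_gt_dosage(gt[rec, ], alt_idx)
  }
  out
}

# GT strings like "0/1", "1|1", "./." -> count of the requested alt index.
parse_gt_dosage <- function(gt_row, alt_idx) {
  vapply(gt_row, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(as.integer(alleles) == alt_idx)
  }, integer(1), USE.NAMES = FALSE)
}
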