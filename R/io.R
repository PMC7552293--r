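# Readers and writers: genotype/trait CSV, minimal single-locus VCF, and
# TSV result tables. Genotype strings II/ID/DD (case-insensitive) and
# numeric 0/1/2 codes are both accepted; internally genotypes are 0/1/2
# copies of the deletion (minor) allele.

parse_genotype_codes <- function(x) {
  s <- toupper(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[s %in% c("II", "0")] <- 0L
  out[s %in% c("ID", "DI", "1")] <- 1L
  out[s %in% c("DD", "2")] <- 2L
  out[s %in% c("", "NA", "./.", ".")] <- NA_integer_
  bad <- !(s %in% c("II", "ID", "DI", "DD", "0", "1", "2", "", "NA", "./.", "."))
  attr(out, "bad_rows") <- which(bad)
  out
}

#' Read a genotype table from CSV
#'
#' Expects a header with at least `id` and `genotype` columns (additional
#' genotype columns may carry further loci); `breed` and `sex` are carried
#' through when present. Genotypes may be `II`/`ID`/`DD` strings or 0/1/2.
#'
#' @param path CSV file path.
#' @param genotype_cols columns to decode as genotypes (default: every
#'   column whose name starts with `genotype` or `locus`).
#' @return data.frame of validated records with integer genotype codes.
#' @export
read_genotype_csv <- function(path, genotype_cols = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_input("no records in %s", path)
  if (!("id" %in% names(df))) stop_input("missing id column in %s", path)
  if (anyDuplicated(df$id)) {
    stop_input("duplicate individual ID(s): %s",
               paste(utils::head(unique(df$id[duplicated(df$id)]), 5),
                     collapse = ", "))
  }
  if (is.null(genotype_cols)) {
    genotype_cols <- grep("^(genotype|locus)", names(df), value = TRUE)
  }
  if (!length(genotype_cols)) stop_input("no genotype column found in %s", path)
  for (col in genotype_cols) {
    g <- parse_genotype_codes(df[[col]])
    if (length(attr(g, "bad_rows"))) {
      stop_input("malformed genotype in column %s, row(s) %s of %s", col,
                 paste(utils::head(attr(g, "bad_rows"), 5), collapse = ", "),
                 path)
    }
    df[[col]] <- as.integer(g)
  }
  df
}

#' Write a genotype table to CSV
#'
#' @param records data.frame with an `id` and genotype column(s).
#' @param path output path.
#' @param string_codes write genotypes as `II`/`ID`/`DD` (default) rather
#'   than 0/1/2.
#' @export
write_genotype_csv <- function(records, path, string_codes = TRUE) {
  out <- records
  if (string_codes) {
    cols <- grep("^(genotype|locus)", names(out), value = TRUE)
    for (col in cols) out[[col]] <- GENOTYPE_LEVELS[out[[col]] + 1L]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes from a minimal VCF
#'
#' Accepts a VCF 4.2 with GT fields; biallelic records only (multi-allelic
#' sites are skipped with a warning). GT `0/0`, `0/1`, `1/1` map to 0, 1, 2
#' copies of the ALT allele; `./.` is recorded as missing. The VCF's 1-based
#' POS is preserved in the per-locus metadata, alongside a 0-based half-open
#' internal interval.
#'
#' @param path VCF file path.
#' @return data.frame: `id` (sample), one `locus_<ID>` column per retained
#'   site; attribute `loci` holds per-site metadata (`chrom`, `pos`,
#'   `start0`, `end0`, `ref`, `alt`, `variant_id`).
#' @export
read_minimal_vcf <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  # v@fix stays a matrix even for a single site (getFIX drops dimensions)
  fix <- as.data.frame(v@fix[, 1:7, drop = FALSE], stringsAsFactors = FALSE)
  names(fix) <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  }
  keep <- !grepl(",", fix$ALT)
  if (any(!keep)) {
    warning(sum(!keep), " multi-allelic site(s) skipped")
  }
  samples <- colnames(gt)
  out <- data.frame(id = samples, stringsAsFactors = FALSE)
  loci <- list()
  for (i in which(keep)) {
    gts <- gsub("\\|", "/", gt[i, ])
    code <- rep(NA_integer_, length(gts))
    code[gts == "0/0"] <- 0L
    code[gts %in% c("0/1", "1/0")] <- 1L
    code[gts == "1/1"] <- 2L
    vid <- if (is.na(fix$ID[i]) || fix$ID[i] == ".") {
      paste0("site", i)
    } else fix$ID[i]
    col <- paste0("locus_", vid)
    out[[col]] <- unname(code)
    pos <- as.integer(fix$POS[i])
    loci[[col]] <- data.frame(
      chrom = fix$CHROM[i], pos = pos,
      start0 = pos - 1L, end0 = pos - 1L + nchar(fix$REF[i]),
      ref = fix$REF[i], alt = fix$ALT[i], variant_id = vid,
      stringsAsFactors = FALSE)
  }
  if (ncol(out) < 2) stop_input("no usable biallelic site in %s", path)
  attr(out, "loci") <- do.call(rbind, loci)
  out
}

#' Write a single-locus genotype table as a minimal VCF 4.2
#'
#' @param records data.frame with `id` and `genotype` (0/1/2 or NA).
#' @param path output path.
#' @param chrom,pos,ref,alt,variant_id site description; defaults describe
#'   an 8-bp deletion as REF/ALT alleles at a placeholder coordinate.
#' @export
write_minimal_vcf <- function(records, path,
                              chrom = "NC_040260.1", pos = 36219993,
                              ref = "CGTTACAAG", alt = "C",
                              variant_id = "rs593501397") {
  gt_str <- c("0/0", "0/1", "1/1")[records$genotype + 1L]
  gt_str[is.na(gt_str)] <- "./."
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", records$id), collapse = "\t"),
    paste(c(chrom, pos, variant_id, ref, alt, ".", ".", ".", "GT", gt_str),
          collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param table data.frame.
#' @param path output path.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
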