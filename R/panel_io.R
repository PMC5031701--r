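#' SNP panel input/output
#'
#' A panel is a set of biallelic SNP loci at which a two-contributor
#' mixture is interrogated. Internally positions are 1-based (the pileup
#' convention) and chromosome names are normalized by stripping any "chr"
#' prefix. Allele order (allele_a/allele_b) carries no reference/alternate
#' meaning: the recipient allele is determined from the read data, never
#' from the panel, which is what makes the method genotyping-free.
#'
#' @name panel_io
NULL

.BASES <- c("A", "C", "G", "T")

.norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

.is_autosomal <- function(chrom) .norm_chrom(chrom) %in% as.character(1:22)

#' Construct a panel of biallelic SNP loci
#'
#' Low-level constructor used by the readers and the simulator. Validates
#' the panel invariants: distinct single-nucleotide alleles, positive
#' 1-based positions, unique locus identifiers.
#'
#' @param locus_id character vector of unique locus identifiers (e.g. rsIDs).
#' @param chrom chromosome names; "chr1" and "1" are equivalent.
#' @param pos integer vector of 1-based positions.
#' @param allele_a,allele_b the two panel alleles, each one of A/C/G/T.
#' @return A `data.frame` of class `panel_loci` with columns `locus_id`,
#'   `chrom`, `pos`, `allele_a`, `allele_b`, `is_autosomal`.
#' @export
panel_loci <- function(locus_id, chrom, pos, allele_a, allele_b) {
  locus_id <- as.character(locus_id)
  chrom <- .norm_chrom(chrom)
  pos <- as.integer(pos)
  allele_a <- toupper(as.character(allele_a))
  allele_b <- toupper(as.character(allele_b))
  n <- length(locus_id)
  if (!all(lengths(list(chrom, pos, allele_a, allele_b)) == n))
    stop("panel_loci: field lengths differ", call. = FALSE)
  if (n == 0L)
    stop("empty panel: no usable loci", call. = FALSE)
  if (anyDuplicated(locus_id))
    stop("panel_loci: duplicated locus_id: ",
         paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "),
         call. = FALSE)
  if (!all(allele_a %in% .BASES) || !all(allele_b %in% .BASES))
    stop("panel_loci: alleles must be one of A/C/G/T", call. = FALSE)
  if (any(allele_a == allele_b))
    stop("panel_loci: allele_a must differ from allele_b", call. = FALSE)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("panel_loci: positions must be integers >= 1", call. = FALSE)
  out <- data.frame(
    locus_id = locus_id, chrom = chrom, pos = pos,
    allele_a = allele_a, allele_b = allele_b,
    is_autosomal = .is_autosomal(chrom),
    stringsAsFactors = FALSE
  )
  class(out) <- c("panel_loci", "data.frame")
  out
}

#' Read a SNP panel from a VCF file
#'
#' Retains biallelic single-nucleotide records only. Records with
#' multi-allelic ALT fields or with REF/ALT longer than one base (indels)
#' are skipped with a warning. INFO and sample columns are ignored: the
#' VCF is used purely as a locus list, not as genotype evidence.
#'
#' @param path path to a VCF (4.x) file.
#' @return A [panel_loci] data frame.
#' @export
read_panel_vcf <- function(path) {
  if (!file.exists(path))
    stop("panel file not found: ", path, call. = FALSE)
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    stop("empty panel: VCF '", path, "' has no records", call. = FALSE)
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  usable <- !is.na(ref) & !is.na(alt) &
    ref %in% .BASES & alt %in% .BASES
  if (any(!usable)) {
    warning(sum(!usable), " VCF record(s) skipped (multi-allelic or indel)",
            call. = FALSE)
  }
  if (!any(usable))
    stop("empty panel: no usable biallelic SNP records in '", path, "'",
         call. = FALSE)
  fix <- fix[usable, , drop = FALSE]
  ref <- ref[usable]
  alt <- alt[usable]
  id <- fix$ID
  missing_id <- is.na(id) | id == "." | id == ""
  id[missing_id] <- paste0(.norm_chrom(fix$CHROM[missing_id]), ":",
                           fix$POS[missing_id])
  panel_loci(id, fix$CHROM, as.integer(fix$POS), ref, alt)
}

#' Read a SNP panel from a BED file
#'
#' Expects a five-column BED dialect: chrom, 0-based start, end, locus_id,
#' alleles as "A/G". Intervals must have width 1 (one SNP per line);
#' positions are converted to 1-based on read.
#'
#' @param path path to the BED file.
#' @return A [panel_loci] data frame.
#' @export
read_panel_bed <- function(path) {
  if (!file.exists(path))
    stop("panel file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("empty panel: BED '", path, "' has no records", call. = FALSE)
  fields <- strsplit(lines, "\t| +")
  nfield <- lengths(fields)
  if (any(nfield < 5L))
    stop("malformed BED line ", which(nfield < 5L)[1],
         ": need >= 5 columns (chrom, start, end, locus_id, alleles)",
         call. = FALSE)
  mat <- t(vapply(fields, function(f) f[1:5], character(5)))
  start <- suppressWarnings(as.integer(mat[, 2]))
  end <- suppressWarnings(as.integer(mat[, 3]))
  if (any(is.na(start)) || any(is.na(end)))
    stop("malformed BED: non-integer coordinates at line ",
         which(is.na(start) | is.na(end))[1], call. = FALSE)
  width <- end - start
  if (any(width != 1L))
    stop("BED interval width != 1 at line ", which(width != 1L)[1],
         " (one SNP per line required)", call. = FALSE)
  alleles <- mat[, 5]
  ok <- grepl("^[ACGTacgt]/[ACGTacgt]$", alleles)
  if (any(!ok))
    stop("BED allele field must be like 'A/G' (got '", alleles[!ok][1],
         "' at line ", which(!ok)[1], ")", call. = FALSE)
  a <- toupper(substr(alleles, 1, 1))
  b <- toupper(substr(alleles, 3, 3))
  if (any(a == b))
    stop("BED allele field with identical alleles at line ",
         which(a == b)[1], call. = FALSE)
  panel_loci(mat[, 4], mat[, 1], start + 1L, a, b)
}

#' Write a SNP panel to BED
#'
#' Emits the same five-column dialect [read_panel_bed()] reads, so that
#' write-then-read round-trips to an identical panel.
#'
#' @param panel a [panel_loci] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "panel_loci"))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s/%s",
                   panel$chrom, panel$pos - 1L, panel$pos,
                   panel$locus_id, panel$allele_a, panel$allele_b)
  writeLines(lines, path)
  invisible(path)
}
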