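#' Quality-filtered per-base counts at panel loci
#'
#' Counts are kept in mutually exclusive buckets per locus: reads calling
#' one of the two panel alleles go to that base's column (`n_A` ... `n_T`),
#' and quality-passing reads calling N or any base that is not a panel
#' allele go to `n_ambiguous`. At a biallelic SNP a third allele is
#' uninformative for the two-contributor model and most plausibly a
#' sequencing error, so it is pooled with N calls rather than treated as
#' signal. `depth_qualified` is the total of all quality-passing calls.
#' Counting is strand-agnostic.
#'
#' @name allele_counting
NULL

#' Phred quality score to error probability
#'
#' @param q Phred quality score(s).
#' @return `10^(-q/10)`, the base-call error probability; Q30 gives 0.001.
#' @export
phred_to_error_prob <- function(q) 10^(-q / 10)

.counts_df <- function(locus_id, n_A, n_C, n_G, n_T, n_ambiguous,
                       absent = FALSE) {
  out <- data.frame(
    locus_id = as.character(locus_id),
    n_A = as.integer(n_A), n_C = as.integer(n_C),
    n_G = as.integer(n_G), n_T = as.integer(n_T),
    n_ambiguous = as.integer(n_ambiguous),
    stringsAsFactors = FALSE
  )
  out$depth_qualified <- out$n_A + out$n_C + out$n_G + out$n_T + out$n_ambiguous
  out$absent <- as.logical(absent)
  class(out) <- c("locus_counts", "data.frame")
  out
}

# Strip mpileup read-base markup, leaving one call character per base with
# a quality character. Handles ^X (read start + mapping quality), $ (read
# end), +n/-n indel insertions, and * / < / > placeholders (deleted base,
# reference skip) which carry a quality but are not base calls.
.parse_pileup_bases <- function(bases, ref, line_no) {
  chars <- strsplit(bases, "")[[1]]
  calls <- character(0)
  is_call <- logical(0)  # does this position consume a quality char?
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L  # caret plus mapping-quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- suppressWarnings(as.integer(paste(chars[(i + 1L):(j - 1L)],
                                               collapse = "")))
      if (is.na(len))
        stop("malformed pileup indel markup at line ", line_no, call. = FALSE)
      i <- j + len
    } else if (ch %in% c("*", "<", ">")) {
      calls <- c(calls, NA_character_)  # consumes a quality, not a base call
      is_call <- c(is_call, TRUE)
      i <- i + 1L
    } else if (ch %in% c(".", ",")) {
      calls <- c(calls, toupper(ref))
      is_call <- c(is_call, TRUE)
      i <- i + 1L
    } else if (grepl("[ACGTNacgtn]", ch)) {
      calls <- c(calls, toupper(ch))
      is_call <- c(is_call, TRUE)
      i <- i + 1L
    } else {
      stop("malformed pileup read-base string at line ", line_no,
           " (unexpected '", ch, "')", call. = FALSE)
    }
  }
  calls
}

#' Count panel-allele reads from a samtools-mpileup text pileup
#'
#' Parses the 6-column mpileup text format (chrom, 1-based position,
#' reference base, depth, read bases, base qualities) and tallies, at each
#' panel locus, the quality-passing calls of the two panel alleles and of
#' ambiguous bases (N or a non-panel base). Match/mismatch symbols (`.`
#' and `,`) are resolved against the pileup reference column; read
#' start/end and indel markup is skipped. Only bases with Phred quality
#' `>= min_base_quality` (qualities decoded as Phred+33) are counted.
#'
#' Panel loci absent from the pileup are returned with zero counts and
#' `absent = TRUE`.
#'
#' @param pileup path to a samtools-mpileup text file.
#' @param panel a [panel_loci] data frame.
#' @param min_base_quality minimum Phred base quality (default 30).
#' @return A `locus_counts` data frame, one row per panel locus, in panel
#'   order.
#' @export
count_from_pileup <- function(pileup, panel, min_base_quality = 30) {
  stopifnot(inherits(panel, "panel_loci"))
  if (!file.exists(pileup))
    stop("pileup file not found: ", pileup, call. = FALSE)
  lines <- readLines(pileup)
  lines <- lines[nzchar(trimws(lines))]
  key <- paste(panel$chrom, panel$pos, sep = ":")
  res <- matrix(0L, nrow = nrow(panel), ncol = 5,
                dimnames = list(NULL, c("A", "C", "G", "T", "amb")))
  seen <- logical(nrow(panel))
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t")[[1]]
    if (length(f) < 6L) {
      # depth-0 lines may omit base/quality columns
      if (length(f) >= 4L && suppressWarnings(as.integer(f[4])) == 0L) next
      stop("malformed pileup line ", ln, ": expected 6 columns", call. = FALSE)
    }
    k <- paste(.norm_chrom(f[1]), f[2], sep = ":")
    idx <- match(k, key)
    if (is.na(idx)) next
    calls <- .parse_pileup_bases(f[5], f[3], ln)
    quals <- utf8ToInt(f[6]) - 33L
    if (length(calls) != length(quals))
      stop("pileup base/quality length mismatch at line ", ln,
           " (", length(calls), " calls vs ", length(quals), " qualities)",
           call. = FALSE)
    keep <- quals >= min_base_quality & !is.na(calls)
    calls <- calls[keep]
    a <- panel$allele_a[idx]
    b <- panel$allele_b[idx]
    res[idx, a] <- res[idx, a] + sum(calls == a)
    res[idx, b] <- res[idx, b] + sum(calls == b)
    res[idx, "amb"] <- res[idx, "amb"] + sum(calls != a & calls != b)
    seen[idx] <- TRUE
  }
  if (any(!seen))
    message(sum(!seen), " panel locus/loci absent from pileup; ",
            "reported with zero counts")
  .counts_df(panel$locus_id, res[, "A"], res[, "C"], res[, "G"], res[, "T"],
             res[, "amb"], absent = !seen)
}

#' Load a per-locus counts table
#'
#' Reads a TSV with header `locus_id n_A n_C n_G n_T n_ambiguous` and
#' validates it against the panel: every locus_id must be a panel locus,
#' appear at most once, and carry non-negative counts.
#'
#' @param path path to the TSV file.
#' @param panel a [panel_loci] data frame.
#' @return A `locus_counts` data frame, one row per panel locus, in panel
#'   order; panel loci missing from the table get zero counts and
#'   `absent = TRUE`.
#' @export
load_counts_table <- function(path, panel) {
  stopifnot(inherits(panel, "panel_loci"))
  if (!file.exists(path))
    stop("counts file not found: ", path, call. = FALSE)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("locus_id", "n_A", "n_C", "n_G", "n_T", "n_ambiguous")
  if (!all(req %in% names(tab)))
    stop("counts table must have columns: ", paste(req, collapse = " "),
         call. = FALSE)
  tab$locus_id <- as.character(tab$locus_id)
  unknown <- setdiff(tab$locus_id, panel$locus_id)
  if (length(unknown) > 0L)
    stop("counts table has locus_id not in panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$locus_id))
    stop("counts table has duplicated locus_id: ",
         paste(unique(tab$locus_id[duplicated(tab$locus_id)]),
               collapse = ", "), call. = FALSE)
  cnt <- as.matrix(tab[, req[-1]])
  if (any(is.na(cnt)) || any(cnt < 0))
    stop("counts table has negative or missing counts", call. = FALSE)
  idx <- match(panel$locus_id, tab$locus_id)
  absent <- is.na(idx)
  get <- function(col) ifelse(absent, 0L, as.integer(tab[[col]][idx]))
  .counts_df(panel$locus_id, get("n_A"), get("n_C"), get("n_G"), get("n_T"),
             get("n_ambiguous"), absent = absent)
}

#' Write a per-locus counts table
#'
#' Fixed column order (`locus_id n_A n_C n_G n_T n_ambiguous`) so that
#' outputs diff bit-exactly across runs.
#'
#' @param counts a `locus_counts` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  stopifnot(inherits(counts, "locus_counts"))
  out <- counts[, c("locus_id", "n_A", "n_C", "n_G", "n_T", "n_ambiguous")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
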