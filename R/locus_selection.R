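#' Selection of recipient-homozygous informative loci
#'
#' At a biallelic SNP where the recipient is homozygous, every read of the
#' other panel allele comes from donor DNA or sequencing error, so the
#' minor-allele fraction at such loci carries the donor signal. Selection
#' keeps autosomal loci that pass an ambiguity filter and a hard
#' homozygosity call, then computes the donor-signal fraction over the two
#' panel alleles only.
#'
#' @name locus_selection
NULL

#' Classify a locus as recipient-homozygous
#'
#' A locus is called homozygous for a panel allele when that allele's
#' quality-passing count strictly exceeds `homozygosity_threshold` times
#' the total quality-passing depth (all calls, including ambiguous ones —
#' the conservative denominator). The strict inequality means a locus at
#' exactly the threshold is not called.
#'
#' @param counts one row of a `locus_counts` data frame.
#' @param locus the matching row of a [panel_loci] data frame.
#' @param homozygosity_threshold fraction of reads the major allele must
#'   exceed (default 0.86).
#' @return The recipient allele as a single character, or `NA_character_`
#'   if no allele qualifies (heterozygous or uncallable). Zero-depth loci
#'   return `NA` with a message, not an error.
#' @export
classify_homozygous <- function(counts, locus, homozygosity_threshold = 0.86) {
  stopifnot(counts$locus_id == locus$locus_id)
  depth <- counts$depth_qualified
  if (depth <= 0) {
    message("locus ", locus$locus_id, " skipped: zero qualified depth")
    return(NA_character_)
  }
  n_a <- counts[[paste0("n_", locus$allele_a)]]
  n_b <- counts[[paste0("n_", locus$allele_b)]]
  if (n_a > homozygosity_threshold * depth) return(locus$allele_a)
  if (n_b > homozygosity_threshold * depth) return(locus$allele_b)
  NA_character_
}

#' Ambiguity filter
#'
#' A locus passes when its fraction of ambiguous calls (N or non-panel
#' bases) among all quality-passing calls is at most
#' `max_ambiguous_fraction`; strictly more is excluded, so a locus at
#' exactly the threshold is retained.
#'
#' @param counts one row of a `locus_counts` data frame.
#' @param max_ambiguous_fraction maximum tolerated ambiguous fraction
#'   (default 0.05).
#' @return `TRUE` or `FALSE` (zero depth fails).
#' @export
passes_ambiguity_filter <- function(counts, max_ambiguous_fraction = 0.05) {
  depth <- counts$depth_qualified
  if (depth <= 0) return(FALSE)
  counts$n_ambiguous / depth <= max_ambiguous_fraction
}

#' Default selection thresholds
#'
#' @param homozygosity_threshold major-allele fraction that must be
#'   exceeded for a homozygous call (default 0.86).
#' @param max_ambiguous_fraction maximum ambiguous-call fraction
#'   (default 0.05).
#' @param min_depth minimum qualified depth; shallower loci are dropped
#'   with a warning because their minor-allele fractions are too noisy to
#'   enter the mixture (default 100).
#' @return A named list of thresholds.
#' @export
selection_config <- function(homozygosity_threshold = 0.86,
                             max_ambiguous_fraction = 0.05,
                             min_depth = 100) {
  stopifnot(homozygosity_threshold > 0, homozygosity_threshold < 1,
            max_ambiguous_fraction >= 0, max_ambiguous_fraction < 1,
            min_depth >= 0)
  list(homozygosity_threshold = homozygosity_threshold,
       max_ambiguous_fraction = max_ambiguous_fraction,
       min_depth = min_depth)
}

#' Select recipient-homozygous loci and compute donor-signal fractions
#'
#' Applies, in order: autosomal filter, presence/minimum-depth filter,
#' ambiguity filter, homozygosity call. For each surviving locus the
#' donor-signal fraction is the count of the non-recipient panel allele
#' divided by the total count of the two panel alleles (ambiguous calls
#' excluded from this denominator: the mixture's three signal classes are
#' defined over the panel alleles).
#'
#' @param all_counts a `locus_counts` data frame covering the panel.
#' @param panel a [panel_loci] data frame.
#' @param config a [selection_config()] list.
#' @return A `selected_loci` data frame with columns `locus_id`,
#'   `recipient_allele`, `donor_signal_fraction`, `depth` (panel-allele
#'   depth). Attributes: `drop_counts` (named integer vector of loci
#'   dropped per stage) and `report` (per-locus stage table).
#' @export
select_loci <- function(all_counts, panel, config = selection_config()) {
  stopifnot(inherits(all_counts, "locus_counts"), inherits(panel, "panel_loci"))
  idx <- match(panel$locus_id, all_counts$locus_id)
  if (any(is.na(idx)))
    stop("counts missing for panel loci: ",
         paste(panel$locus_id[is.na(idx)], collapse = ", "), call. = FALSE)
  counts <- all_counts[idx, , drop = FALSE]

  n <- nrow(panel)
  stage <- rep("selected", n)
  recipient <- rep(NA_character_, n)
  frac <- rep(NA_real_, n)
  depth_panel <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    ci <- counts[i, , drop = FALSE]
    li <- panel[i, , drop = FALSE]
    if (!li$is_autosomal) { stage[i] <- "non_autosomal"; next }
    if (ci$depth_qualified < config$min_depth || isTRUE(ci$absent)) {
      stage[i] <- "low_depth"
      next
    }
    if (!passes_ambiguity_filter(ci, config$max_ambiguous_fraction)) {
      stage[i] <- "ambiguous"
      next
    }
    allele <- suppressMessages(
      classify_homozygous(ci, li, config$homozygosity_threshold))
    if (is.na(allele)) { stage[i] <- "not_homozygous"; next }
    other <- if (allele == li$allele_a) li$allele_b else li$allele_a
    n_rec <- ci[[paste0("n_", allele)]]
    n_oth <- ci[[paste0("n_", other)]]
    dp <- n_rec + n_oth
    if (dp <= 0) { stage[i] <- "low_depth"; next }
    recipient[i] <- allele
    frac[i] <- n_oth / dp
    depth_panel[i] <- dp
  }

  n_low <- sum(stage == "low_depth")
  if (n_low > 0)
    warning(n_low, " locus/loci dropped below minimum depth ",
            config$min_depth, call. = FALSE)

  keep <- stage == "selected"
  if (!any(keep))
    stop("no loci selected: all ", n, " panel loci were dropped ",
         "(check depth, sample quality, and that the sample is the major ",
         "contributor)", call. = FALSE)

  drop_counts <- c(
    non_autosomal = sum(stage == "non_autosomal"),
    low_depth = n_low,
    ambiguous = sum(stage == "ambiguous"),
    not_homozygous = sum(stage == "not_homozygous"),
    selected = sum(keep)
  )
  out <- data.frame(
    locus_id = panel$locus_id[keep],
    recipient_allele = recipient[keep],
    donor_signal_fraction = frac[keep],
    depth = depth_panel[keep],
    stringsAsFactors = FALSE
  )
  class(out) <- c("selected_loci", "data.frame")
  attr(out, "drop_counts") <- drop_counts
  attr(out, "report") <- data.frame(
    locus_id = panel$locus_id, stage = stage,
    recipient_allele = recipient, donor_signal_fraction = frac,
    depth = depth_panel, stringsAsFactors = FALSE
  )
  out
}

#' Write the per-locus selection report
#'
#' One row per panel locus: the stage at which it was dropped (or
#' "selected"), and for selected loci the recipient allele, donor-signal
#' fraction and panel-allele depth.
#'
#' @param selected a `selected_loci` data frame from [select_loci()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selected, path) {
  rep <- attr(selected, "report")
  stopifnot(is.data.frame(rep))
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
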