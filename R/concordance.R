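## Tissue-vs-eDNA concordance: the call-rate statistic.
##
## For one eDNA sample (individual x dilution scheme) the call rate is the
## proportion of its replicate reactions, across all scored assays, whose
## genotype call matches the tissue-derived reference. Replicate reactions
## are independent and no-calls stay in the denominator: a NOCALL can never
## match, which is the only reading under which observed call rates can
## drop as low as ~19%.

#' Tissue reference genotypes for one sample x scheme
#'
#' One reference call per assay: the majority call of that assay's tissue
#' reactions after excluding NOCALLs. Assays whose tissue reference is
#' all-NOCALL or tied between genotypes cannot anchor a comparison and are
#' dropped (with a warning naming them).
#'
#' @param tissue_records tissue reactions of one sample x scheme, calls set.
#' @return named character vector (assay id -> `AA`/`AB`/`BB`).
#' @export
reference_genotypes <- function(tissue_records) {
  tis <- tissue_records[tissue_records$sample_type == "tissue", ,
                        drop = FALSE]
  if (!nrow(tis)) stop("no tissue records supplied", call. = FALSE)
  refs <- vapply(split(tis$call, tis$assay_id), function(calls) {
    calls <- calls[calls != "NOCALL"]
    if (!length(calls)) return(NA_character_)
    tab <- table(calls)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) NA_character_ else top
  }, character(1L))
  dropped <- names(refs)[is.na(refs)]
  if (length(dropped)) {
    warning("assay(s) without a usable tissue reference excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  refs[!is.na(refs)]
}

#' Call rate of one eDNA sample against its tissue reference
#'
#' Counts every eDNA reaction on a scored assay: a match if its call equals
#' the reference, a NOCALL into the denominator as non-matching, anything
#' else a mismatch. `call_rate = n_match / n_reactions`.
#'
#' @param edna_records eDNA reactions of one sample x scheme, calls set.
#' @param reference named reference vector from [reference_genotypes()].
#' @param unscored_assays how to treat reactions on assays absent from the
#'   reference: `"exclude"` (default) drops them; `"count_as_mismatch"`
#'   keeps them in the denominator as mismatches (the reading under which
#'   all assays, even failed ones, count).
#' @return one-row data.frame: `sample_id`, `scheme_id`, `n_reactions`,
#'   `n_match`, `n_mismatch`, `n_nocall`, `call_rate`. With zero scored
#'   reactions `call_rate` is `NA` (flagged, never silently 0).
#' @export
call_rate <- function(edna_records, reference,
                      unscored_assays = c("exclude", "count_as_mismatch")) {
  unscored_assays <- match.arg(unscored_assays)
  if (!length(reference)) stop("empty reference", call. = FALSE)
  ed <- edna_records[edna_records$sample_type == "edna", , drop = FALSE]
  scored <- ed$assay_id %in% names(reference)
  if (unscored_assays == "exclude") ed <- ed[scored, , drop = FALSE]
  ref <- unname(reference[ed$assay_id])   # NA on unscored assays
  n <- nrow(ed)
  n_nocall <- sum(ed$call == "NOCALL")
  n_match <- sum(!is.na(ref) & ed$call == ref)
  data.frame(
    sample_id = if (n) ed$sample_id[1L] else edna_records$sample_id[1L],
    scheme_id = if (n) ed$scheme_id[1L] else edna_records$scheme_id[1L],
    n_reactions = n,
    n_match = n_match,
    n_mismatch = n - n_match - n_nocall,
    n_nocall = n_nocall,
    call_rate = if (n) n_match / n else NA_real_,
    stringsAsFactors = FALSE)
}

#' Concordance table across all samples and schemes
#'
#' Applies [reference_genotypes()] and [call_rate()] to every individual x
#' dilution-scheme cell of a called reaction table. Water samples from
#' different extraction methods belong to different schemes, so each
#' extraction is scored as its own result.
#'
#' @param records called reaction data.frame (tissue + eDNA rows).
#' @inheritParams call_rate
#' @return data.frame, one row per sample x scheme with a defined cell.
#' @export
concordance_table <- function(records, unscored_assays = "exclude") {
  cells <- unique(records[records$sample_type == "edna",
                          c("sample_id", "scheme_id")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- records[records$sample_id == cells$sample_id[i] &
                     records$scheme_id == cells$scheme_id[i] &
                     records$sample_type == "edna", , drop = FALSE]
    tis <- records[records$sample_id == cells$sample_id[i] &
                     records$scheme_id == cells$scheme_id[i] &
                     records$sample_type == "tissue", , drop = FALSE]
    if (!nrow(tis)) {
      warning("no tissue reference for sample ", cells$sample_id[i],
              " scheme ", cells$scheme_id[i], "; skipped", call. = FALSE)
      return(NULL)
    }
    ref <- suppressWarnings(reference_genotypes(tis))
    if (!length(ref)) return(NULL)
    call_rate(sub, ref, unscored_assays = unscored_assays)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize call rates across samples
#'
#' Unweighted mean and sample standard deviation (n - 1 denominator) of the
#' per-sample call rates, with min and max, reported as percentages. With a
#' single sample the SD is undefined and reported as `NA`.
#'
#' @param results data.frame from [concordance_table()] (needs a
#'   `call_rate` column); rows with undefined call rate are dropped.
#' @return one-row data.frame: `n`, `mean_pct`, `sd_pct`, `min_pct`,
#'   `max_pct`.
#' @export
summarize_call_rates <- function(results) {
  rates <- results$call_rate
  rates <- rates[!is.na(rates)]
  if (!length(rates)) {
    stop("no results with a defined call rate", call. = FALSE)
  }
  data.frame(
    n = length(rates),
    mean_pct = 100 * mean(rates),
    sd_pct = if (length(rates) > 1L) 100 * stats::sd(rates) else NA_real_,
    min_pct = 100 * min(rates),
    max_pct = 100 * max(rates))
}
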