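#' Mean minor allele frequency of candidate SNPs
#'
#' Candidates are held in a wide data.frame: a `snp_id` column plus one
#' numeric column of minor allele frequencies per discovery population.
#' The ranking statistic is the unweighted arithmetic mean across
#' populations.
#'
#' @param candidates data.frame with column `snp_id` and one MAF column per
#'   population; all frequencies in \[0, 0.5\].
#' @return named numeric vector of mean MAFs, one per candidate.
#' @export
#' @examples
#' cand <- data.frame(snp_id = c("s1", "s2"), popA = c(0.2, 0.1),
#'                    popB = c(0.4, 0.3))
#' mean_maf(cand)
mean_maf <- function(candidates) {
  cols <- validate_candidates(candidates)
  m <- as.matrix(candidates[cols])
  stats::setNames(rowMeans(m), candidates$snp_id)
}

validate_candidates <- function(candidates) {
  if (!is.data.frame(candidates) || !"snp_id" %in% names(candidates)) {
    stop("candidates must be a data.frame with a snp_id column",
         call. = FALSE)
  }
  if (anyDuplicated(candidates$snp_id)) {
    stop("duplicate snp_ids in candidate table", call. = FALSE)
  }
  cols <- setdiff(names(candidates), "snp_id")
  if (!length(cols)) {
    stop("candidate table has no population MAF columns", call. = FALSE)
  }
  m <- as.matrix(candidates[cols])
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m > 0.5)) {
    stop("population MAFs must be numeric in [0, 0.5]", call. = FALSE)
  }
  cols
}

#' Select the top-k panel by mean minor allele frequency
#'
#' Ranks candidates by mean MAF across discovery populations and keeps the
#' `k` largest, in descending order (ties broken lexicographically by
#' `snp_id`, so the selection is invariant to input order). High-MAF SNPs
#' discriminate best between individuals in parentage assignment; each
#' selected SNP is annotated with whether it exceeds the conventional 0.2
#' informativeness guideline (an annotation, not a filter).
#'
#' @inheritParams mean_maf
#' @param k panel size; must not exceed the number of candidates.
#' @return a [panel_spec()] whose `maf_per_snp` are the mean MAFs, with an
#'   additional logical attribute `exceeds_guideline` (mean MAF > 0.2),
#'   named by SNP.
#' @export
select_top_panel <- function(candidates, k) {
  mm <- mean_maf(candidates)
  if (k < 1 || k > length(mm)) {
    stop("k must be between 1 and the number of candidates (", length(mm),
         ")", call. = FALSE)
  }
  ord <- order(-mm, names(mm))
  keep <- ord[seq_len(k)]
  panel <- panel_spec(unname(mm[keep]), snp_ids = names(mm)[keep])
  attr(panel, "exceeds_guideline") <-
    stats::setNames(mm[keep] > 0.2, names(mm)[keep])
  panel
}

#' Read / write candidate and panel tables
#'
#' `read_candidates()` reads a candidate CSV (`snp_id` + one MAF column per
#' population). `write_panel()` writes a selected panel as a CSV with
#' columns `snp_id`, `mean_maf`, `exceeds_guideline`.
#'
#' @param path file path.
#' @export
read_candidates <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_candidates(x)
  x
}

#' @rdname read_candidates
#' @param panel a [panel_spec()] from [select_top_panel()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_spec"))
  flag <- attr(panel, "exceeds_guideline") %||% (panel$maf_per_snp > 0.2)
  utils::write.csv(
    data.frame(snp_id = panel$snp_ids,
               mean_maf = unname(panel$maf_per_snp),
               exceeds_guideline = unname(flag)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
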