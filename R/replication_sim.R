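## Replicate-subsampling consensus simulation.
##
## Question: how many replicate eDNA reactions are needed per genotype for
## a reliable consensus call? From the full set of replicate reactions per
## genotype (individual x SNP), r replicates are drawn without replacement,
## the majority genotype (excluding no-calls) is formed, and compared to
## the tissue-derived genotype. Equal-frequency conflicts -- and subsamples
## with no callable genotype at all -- score as incorrect. A Monte-Carlo
## estimator (scenarios) runs alongside an exact enumeration over all
## C(n, r) subsets, which is the expectation the scenarios estimate.

#' Simulation configuration
#'
#' @param replicate_levels replication levels r to simulate (default 1:3).
#' @param n_scenarios random scenarios per scheme x level (default 100).
#' @param seed master integer seed; every scenario gets a deterministic
#'   counter-derived sub-seed and is independently reproducible.
#' @param source_replicates replicate reactions available per genotype
#'   (default 6).
#' @param shared_subset if `TRUE`, a scenario draws one subset of replicate
#'   indices shared across all genotypes; default `FALSE` draws
#'   independently per genotype.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(replicate_levels = 1:3, n_scenarios = 100L,
                              seed = 1L, source_replicates = 6L,
                              shared_subset = FALSE) {
  replicate_levels <- sort(unique(as.integer(replicate_levels)))
  stopifnot(n_scenarios >= 1, source_replicates >= 1,
            all(replicate_levels >= 1),
            all(replicate_levels <= source_replicates))
  structure(list(replicate_levels = replicate_levels,
                 n_scenarios = as.integer(n_scenarios),
                 seed = as.integer(seed),
                 source_replicates = as.integer(source_replicates),
                 shared_subset = isTRUE(shared_subset)),
            class = "simulation_config")
}

#' Majority-vote consensus of replicate genotype calls
#'
#' Drops NOCALLs, then returns the strictly most frequent genotype. When
#' two or more genotypes tie for the maximum -- or nothing callable remains
#' -- the result is `"TIE"`, which downstream scoring counts as incorrect.
#'
#' @param calls character vector of calls (`AA`/`AB`/`BB`/`NOCALL`).
#' @return one of `"AA"`, `"AB"`, `"BB"`, `"TIE"`.
#' @export
#' @examples
#' consensus_call(c("AA", "AA", "NOCALL"))  # "AA"
#' consensus_call(c("AA", "BB"))            # "TIE"
consensus_call <- function(calls) {
  if (!length(calls)) stop("empty subsample", call. = FALSE)
  counts <- tabulate(match(calls, GENOTYPES), nbins = 3L)
  m <- max(counts)
  if (m == 0L || sum(counts == m) > 1L) "TIE" else GENOTYPES[which.max(counts)]
}

check_pools <- function(pools, references, r, n_source) {
  stopifnot(length(pools) == length(references), length(pools) >= 1L)
  sizes <- lengths(pools)
  if (any(sizes != n_source)) {
    stop("every genotype needs exactly ", n_source, " replicate calls",
         call. = FALSE)
  }
  if (r < 1L || r > n_source) {
    stop("replication level r must be in 1..", n_source, call. = FALSE)
  }
}

#' Score one random replication scenario
#'
#' For each genotype, draws `r` of its replicate calls without replacement
#' (a scenario simulates having run only r physical reactions), forms the
#' consensus, and scores it correct iff it equals the tissue reference
#' (`TIE` is incorrect). Uses the ambient RNG stream; seed before calling
#' for reproducibility.
#'
#' @param pools list of character vectors, one per genotype (individual x
#'   SNP), each holding that genotype's replicate eDNA calls.
#' @param references character vector of tissue reference genotypes,
#'   parallel to `pools`.
#' @param r replication level.
#' @return proportion of genotypes called correctly, in \[0, 1\].
#' @export
score_scenario <- function(pools, references, r) {
  n_source <- length(pools[[1L]])
  check_pools(pools, references, r, n_source)
  correct <- vapply(seq_along(pools), function(g) {
    sub <- pools[[g]][sample.int(n_source, r)]
    consensus_call(sub) == references[[g]]
  }, logical(1L))
  mean(correct)
}

#' Exact consensus accuracy by subset enumeration
#'
#' Enumerates all `choose(n, r)` replicate subsets of every genotype,
#' applies [consensus_call()] to each, and averages correctness exactly:
#' the expectation that [score_scenario()] estimates. At `r = n` there is a
#' single subset and the value equals the direct consensus correctness.
#'
#' @inheritParams score_scenario
#' @return exact expected proportion of correct consensus calls.
#' @export
exact_consensus_accuracy <- function(pools, references, r) {
  n_source <- length(pools[[1L]])
  check_pools(pools, references, r, n_source)
  subsets <- utils::combn(n_source, r)
  per_genotype <- vapply(seq_along(pools), function(g) {
    hits <- apply(subsets, 2L, function(idx)
      consensus_call(pools[[g]][idx]) == references[[g]])
    mean(hits)
  }, numeric(1L))
  mean(per_genotype)
}

## Per-genotype correctness over every C(n, r) subset: G x n_subsets
## logical matrix. Sampling a uniform subset column is equivalent to
## drawing r replicates without replacement.
subset_correct_matrix <- function(pools, references, r, n_source) {
  subsets <- utils::combn(n_source, r)
  m <- vapply(seq_along(pools), function(g) {
    apply(subsets, 2L, function(idx)
      consensus_call(pools[[g]][idx]) == references[[g]])
  }, logical(ncol(subsets)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)  # single subset at r = n
  t(m)
}

## Extract per-scheme call pools and tissue references from a called
## reaction table. Genotypes (individual x assay) with a replicate count
## different from source_replicates are dropped with a warning.
scheme_call_pools <- function(records, scheme, source_replicates) {
  sub <- records[records$scheme_id == scheme, , drop = FALSE]
  ed <- sub[sub$sample_type == "edna", , drop = FALSE]
  pools <- list()
  refs <- character()
  for (sample in unique(ed$sample_id)) {
    tis <- sub[sub$sample_type == "tissue" & sub$sample_id == sample, ,
               drop = FALSE]
    if (!nrow(tis)) next
    ref <- suppressWarnings(reference_genotypes(tis))
    es <- ed[ed$sample_id == sample, , drop = FALSE]
    for (assay in intersect(unique(es$assay_id), names(ref))) {
      calls <- es$call[es$assay_id == assay]
      key <- paste(sample, assay, sep = ".")
      if (length(calls) != source_replicates) {
        warning("genotype ", key, " in scheme ", scheme, " has ",
                length(calls), " replicates (expected ", source_replicates,
                "); dropped", call. = FALSE)
        next
      }
      pools[[key]] <- calls
      refs[key] <- ref[[assay]]
    }
  }
  list(pools = pools, references = refs)
}

#' Run the replication-level simulation
#'
#' For every dilution scheme and replication level, runs `n_scenarios`
#' Monte-Carlo scenarios (each scenario draws, independently for every
#' genotype, one of the `choose(n, r)` replicate subsets uniformly at
#' random under a counter-derived sub-seed -- equivalent to sampling r
#' reactions without replacement) and computes the exact enumeration
#' accuracy alongside. Accuracy is pooled over all individual x SNP
#' genotypes of a scheme.
#'
#' @param records called reaction data.frame with tissue and eDNA rows
#'   (e.g. the `records` of [call_dataset()] or a platform export read by
#'   [read_reactions()]).
#' @param config a [simulation_config()].
#' @return object of class `replication_sim`: a list with `scenarios`
#'   (scheme_id, replicate_level, scenario, accuracy) and `summary`
#'   (scheme_id, replicate_level, n_genotypes, mean_accuracy,
#'   exact_accuracy).
#' @export
run_simulation <- function(records, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  schemes <- unique(records$scheme_id[records$sample_type == "edna"])
  scen_rows <- list()
  sum_rows <- list()
  for (scheme in schemes) {
    cp <- scheme_call_pools(records, scheme, config$source_replicates)
    if (!length(cp$pools)) {
      warning("scheme ", scheme, " has no scorable genotypes; skipped",
              call. = FALSE)
      next
    }
    g_n <- length(cp$pools)
    for (r in config$replicate_levels) {
      correct <- subset_correct_matrix(cp$pools, cp$references, r,
                                       config$source_replicates)
      n_sub <- ncol(correct)
      acc <- vapply(seq_len(config$n_scenarios), function(s) {
        with_seed(mix_seed(config$seed, "scenario", scheme, r, s), {
          idx <- if (config$shared_subset) {
            rep(sample.int(n_sub, 1L), g_n)
          } else {
            sample.int(n_sub, g_n, replace = TRUE)
          }
          mean(correct[cbind(seq_len(g_n), idx)])
        })
      }, numeric(1L))
      scen_rows[[paste(scheme, r)]] <- data.frame(
        scheme_id = scheme, replicate_level = r,
        scenario = seq_len(config$n_scenarios), accuracy = acc,
        stringsAsFactors = FALSE)
      sum_rows[[paste(scheme, r)]] <- data.frame(
        scheme_id = scheme, replicate_level = r, n_genotypes = g_n,
        mean_accuracy = mean(acc),
        exact_accuracy = mean(rowMeans(correct)),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    scenarios = do.call(rbind, c(scen_rows, make.row.names = FALSE)),
    summary = do.call(rbind, c(sum_rows, make.row.names = FALSE)),
    config = config), class = "replication_sim")
}
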