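#' Define a SNP genotyping panel
#'
#' A panel is the set of assays carried on the genotyping chip: one
#' bi-allelic SNP per assay, each with a (mean) minor allele frequency used
#' by the Hardy-Weinberg genotype generator.
#'
#' @param maf numeric vector of minor allele frequencies, each in \[0, 0.5\].
#' @param snp_ids unique assay labels; defaults to `SNP01`, `SNP02`, ...
#' @return an object of class `panel_spec` with fields `n_snps`,
#'   `maf_per_snp` (named by SNP) and `snp_ids`.
#' @export
#' @examples
#' panel_spec(c(0.5, 0.3, 0.1))
panel_spec <- function(maf, snp_ids = sprintf("SNP%02d", seq_along(maf))) {
  maf <- as.numeric(maf)
  if (length(maf) < 1L) stop("panel needs at least one SNP", call. = FALSE)
  bad <- which(!is.finite(maf) | maf < 0 | maf > 0.5)
  if (length(bad)) {
    stop("invalid MAF (must be in [0, 0.5]) for SNP(s): ",
         paste(snp_ids[bad], collapse = ", "), call. = FALSE)
  }
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != length(maf)) {
    stop("snp_ids and maf must have equal length", call. = FALSE)
  }
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique", call. = FALSE)
  structure(
    list(n_snps = length(maf),
         maf_per_snp = stats::setNames(maf, snp_ids),
         snp_ids = snp_ids),
    class = "panel_spec")
}

#' Default 16-assay panel
#'
#' Sixteen SNPs with mean MAF descending from 0.50 to 0.24, emulating a
#' parentage panel picked as the top of a MAF-ranked candidate list (high
#' MAF, mostly above the 0.2 informativeness guideline).
#'
#' @param n_snps number of assays (default 16).
#' @return a [panel_spec()].
#' @export
default_panel <- function(n_snps = 16L) {
  panel_spec(round(seq(0.50, 0.24, length.out = n_snps), 3))
}

#' Phenomenological reaction error model
#'
#' Per-reaction error behaviour of one dilution scheme: a reaction is a
#' no-call with probability `p_nocall`; a called reaction differs from the
#' true genotype with probability `p_miscall` (uniform over the two wrong
#' genotypes). Simulated fluorescence clusters are placed
#' `intensity_separation` apart with isotropic Gaussian noise
#' `intensity_noise_sd`, so `intensity_separation / intensity_noise_sd` is
#' the cluster signal-to-noise ratio.
#'
#' @param p_nocall,p_miscall probabilities in \[0, 1\].
#' @param intensity_separation,intensity_noise_sd strictly positive reals
#'   (arbitrary fluorescence units).
#' @return an object of class `error_model`.
#' @export
error_model <- function(p_nocall = 0, p_miscall = 0,
                        intensity_separation = 10, intensity_noise_sd = 1) {
  stopifnot(p_nocall >= 0, p_nocall <= 1, p_miscall >= 0, p_miscall <= 1,
            intensity_separation > 0, intensity_noise_sd > 0)
  structure(list(p_nocall = p_nocall, p_miscall = p_miscall,
                 intensity_separation = intensity_separation,
                 intensity_noise_sd = intensity_noise_sd),
            class = "error_model")
}

#' Dilution schemes of the study design
#'
#' A dilution scheme is a labelled combination of extraction method and
#' pre-/post-STA (Specific Target Amplification) dilution factors. The
#' default table carries four column-extraction schemes (`D1`-`D4`) and four
#' crude Chelex lysis schemes (`C1`-`C4`); the factors are illustrative
#' labels for the strata and do not enter any computation.
#'
#' @param scheme_id character vector of unique labels.
#' @param extraction `"column"` or `"chelex"`, recycled.
#' @param pre_sta_dilution,post_sta_dilution dilution factors, `1` = neat.
#' @return data.frame with one row per scheme.
#' @export
dilution_schemes <- function(scheme_id,
                             extraction,
                             pre_sta_dilution = 1,
                             post_sta_dilution = 1) {
  scheme_id <- as.character(scheme_id)
  if (anyDuplicated(scheme_id)) stop("scheme_id must be unique", call. = FALSE)
  extraction <- rep_len(as.character(extraction), length(scheme_id))
  if (!all(extraction %in% EXTRACTIONS)) {
    stop("extraction must be one of: ", paste(EXTRACTIONS, collapse = ", "),
         call. = FALSE)
  }
  pre <- rep_len(as.numeric(pre_sta_dilution), length(scheme_id))
  post <- rep_len(as.numeric(post_sta_dilution), length(scheme_id))
  if (any(pre < 1) || any(post < 1)) {
    stop("dilution factors must be >= 1 (1 = neat)", call. = FALSE)
  }
  data.frame(scheme_id = scheme_id, extraction = extraction,
             pre_sta_dilution = pre, post_sta_dilution = post,
             stringsAsFactors = FALSE)
}

#' @rdname dilution_schemes
#' @export
default_dilution_schemes <- function() {
  dilution_schemes(
    scheme_id = c("D1", "D2", "D3", "D4", "C1", "C2", "C3", "C4"),
    extraction = rep(c("column", "chelex"), each = 4L),
    pre_sta_dilution  = c(1, 1, 10, 10, 1, 1, 10, 10),
    post_sta_dilution = c(1, 10, 1, 10, 1, 10, 1, 10))
}

#' Default per-scheme error models
#'
#' Illustrative per-dilution error rates. The per-replicate probability of a
#' correct call is `(1 - p_nocall) * (1 - p_miscall)`; for the two
#' best-performing schemes it is anchored at the observed single-replicate
#' consensus accuracies (D2 about 0.994, C1 about 0.958), the remaining
#' schemes span the wide degradation seen across dilutions (all other
#' Chelex schemes below 0.90, worst around 0.20).
#'
#' @return named list of [error_model()] objects, one per default scheme.
#' @export
default_error_models <- function() {
  list(
    D1 = error_model(0.100, 0.056, intensity_separation = 8),
    D2 = error_model(0.004, 0.002, intensity_separation = 12),
    D3 = error_model(0.170, 0.096, intensity_separation = 7),
    D4 = error_model(0.280, 0.167, intensity_separation = 6),
    C1 = error_model(0.030, 0.013, intensity_separation = 10),
    C2 = error_model(0.220, 0.167, intensity_separation = 7),
    C3 = error_model(0.380, 0.274, intensity_separation = 6),
    C4 = error_model(0.600, 0.500, intensity_separation = 5))
}

#' Study design for the synthetic data generator
#'
#' Defaults mirror the tank experiment the generator emulates: 6 individuals
#' genotyped at 16 SNPs, 6 replicate eDNA reactions per SNP per sample, and
#' 8 dilution schemes across 2 extraction methods, with tissue reference
#' reactions run alongside every scheme.
#'
#' @param n_individuals number of animals.
#' @param n_replicates eDNA reactions per individual x SNP x scheme.
#' @param n_tissue_replicates tissue reactions per individual x SNP x scheme.
#' @param schemes a data.frame from [dilution_schemes()].
#' @param error_models named list of [error_model()], one per scheme id.
#' @param tissue_error_model [error_model()] for tissue reactions
#'   (near-perfect by default: tissue is the ground truth).
#' @param n_controls no-template control reactions per assay x scheme.
#' @param seed master integer seed; expands into per-stage substreams.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_individuals = 6L,
                         n_replicates = 6L,
                         n_tissue_replicates = 3L,
                         schemes = default_dilution_schemes(),
                         error_models = default_error_models(),
                         tissue_error_model = error_model(
                           0.002, 0.001, intensity_separation = 12),
                         n_controls = 1L,
                         seed = 1L) {
  stopifnot(n_individuals >= 1, n_replicates >= 1, n_tissue_replicates >= 1,
            n_controls >= 0, is.data.frame(schemes))
  missing <- setdiff(schemes$scheme_id, names(error_models))
  if (length(missing)) {
    stop("no error model for scheme(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_replicates = as.integer(n_replicates),
         n_tissue_replicates = as.integer(n_tissue_replicates),
         schemes = schemes,
         error_models = error_models[schemes$scheme_id],
         tissue_error_model = tissue_error_model,
         n_controls = as.integer(n_controls),
         seed = as.integer(seed)),
    class = "study_design")
}

#' Draw true genotypes under Hardy-Weinberg equilibrium
#'
#' For a SNP with minor allele frequency `q`, genotypes are drawn
#' independently with P(AA) = (1-q)^2, P(AB) = 2q(1-q), P(BB) = q^2.
#'
#' @param panel a [panel_spec()].
#' @param n_individuals number of individuals to draw.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return character matrix (individuals x SNPs) over `AA`/`AB`/`BB`, with
#'   row names `IND1`, ... and column names the panel's SNP ids.
#' @export
simulate_true_genotypes <- function(panel, n_individuals, seed = 1L) {
  stopifnot(inherits(panel, "panel_spec"), n_individuals >= 1)
  with_seed(mix_seed(seed, "true_genotypes"), {
    g <- vapply(panel$maf_per_snp, function(q) {
      probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
      sample(GENOTYPES, n_individuals, replace = TRUE, prob = probs)
    }, character(n_individuals))
    g <- matrix(g, nrow = n_individuals, ncol = panel$n_snps,
                dimnames = list(paste0("IND", seq_len(n_individuals)),
                                panel$snp_ids))
    g
  })
}

## Cluster centroid for a call, in raw fluorescence units.
## AA loads on the allele-1 axis, BB on allele-2, AB intermediate,
## NOCALL (no amplification) near the origin.
call_centroid <- function(call, separation) {
  switch(call,
         AA = c(separation, 0),
         AB = c(0.55 * separation, 0.55 * separation),
         BB = c(0, separation),
         NOCALL = c(0, 0),
         stop("unknown call: ", call))
}

## Emit calls for one batch of reactions under an error model.
draw_calls <- function(truth_calls, model) {
  n <- length(truth_calls)
  out <- truth_calls
  u <- stats::runif(n)
  nocall <- u < model$p_nocall
  mis <- !nocall & stats::runif(n) < model$p_miscall
  out[nocall] <- "NOCALL"
  if (any(mis)) {
    out[mis] <- vapply(truth_calls[mis], function(g) {
      sample(setdiff(GENOTYPES, g), 1L)
    }, character(1L))
  }
  out
}

## Intensities around the emitted call's centroid, truncated at zero.
draw_intensities <- function(calls, model) {
  cen <- t(vapply(calls, call_centroid, numeric(2L),
                  separation = model$intensity_separation))
  n <- length(calls)
  cbind(pmax(0, cen[, 1] + stats::rnorm(n, sd = model$intensity_noise_sd)),
        pmax(0, cen[, 2] + stats::rnorm(n, sd = model$intensity_noise_sd)))
}

#' Simulate the full reaction table of a study
#'
#' Emits, for every individual x SNP x dilution scheme, `n_replicates` eDNA
#' reactions under the scheme's error model and `n_tissue_replicates` tissue
#' reactions under the tissue error model, plus `n_controls` no-template
#' control reactions per assay x scheme. Each reaction carries a generated
#' call (truth perturbed by the error model) and fluorescence intensities
#' drawn around the emitted call's cluster centroid.
#'
#' @param truth genotype matrix from [simulate_true_genotypes()] (or any
#'   character matrix over `AA`/`AB`/`BB` with individual row names and SNP
#'   column names covering the panel).
#' @param design a [study_design()].
#' @param panel a [panel_spec()]; its SNP ids must all be columns of `truth`.
#' @return a reaction data.frame (see [read_reactions()] for the column
#'   schema) with `nrow = n_individuals * n_snps * n_schemes *
#'   (n_replicates + n_tissue_replicates) + n_snps * n_schemes * n_controls`.
#' @export
simulate_reactions <- function(truth, design, panel) {
  stopifnot(inherits(design, "study_design"), inherits(panel, "panel_spec"))
  if (!all(panel$snp_ids %in% colnames(truth))) {
    stop("truth matrix does not cover all panel SNPs", call. = FALSE)
  }
  if (nrow(truth) < design$n_individuals) {
    stop("truth matrix does not cover all individuals", call. = FALSE)
  }
  individuals <- rownames(truth)[seq_len(design$n_individuals)]
  schemes <- design$schemes

  blocks <- vector("list", nrow(schemes) * 3L)
  bi <- 0L
  for (si in seq_len(nrow(schemes))) {
    sid <- schemes$scheme_id[si]
    extr <- schemes$extraction[si]
    em <- design$error_models[[sid]]
    seed_s <- mix_seed(design$seed, "reactions", sid)

    grid <- expand.grid(sample_id = individuals, assay_id = panel$snp_ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth_calls <- truth[cbind(grid$sample_id, grid$assay_id)]

    edna <- with_seed(seed_s, {
      g <- grid[rep(seq_len(nrow(grid)), each = design$n_replicates), ]
      tc <- rep(truth_calls, each = design$n_replicates)
      calls <- draw_calls(tc, em)
      ints <- draw_intensities(calls, em)
      data.frame(sample_id = g$sample_id, sample_type = "edna",
                 extraction = extr, scheme_id = sid, assay_id = g$assay_id,
                 replicate = rep(seq_len(design$n_replicates), nrow(grid)),
                 intensity_a = ints[, 1], intensity_b = ints[, 2],
                 call = calls, stringsAsFactors = FALSE)
    })

    tissue <- with_seed(mix_seed(design$seed, "tissue", sid), {
      g <- grid[rep(seq_len(nrow(grid)), each = design$n_tissue_replicates), ]
      tc <- rep(truth_calls, each = design$n_tissue_replicates)
      calls <- draw_calls(tc, design$tissue_error_model)
      ints <- draw_intensities(calls, design$tissue_error_model)
      data.frame(sample_id = g$sample_id, sample_type = "tissue",
                 extraction = "column", scheme_id = sid,
                 assay_id = g$assay_id,
                 replicate = rep(seq_len(design$n_tissue_replicates),
                                 nrow(grid)),
                 intensity_a = ints[, 1], intensity_b = ints[, 2],
                 call = calls, stringsAsFactors = FALSE)
    })

    blocks[[bi <- bi + 1L]] <- edna
    blocks[[bi <- bi + 1L]] <- tissue

    if (design$n_controls > 0L) {
      blocks[[bi <- bi + 1L]] <- with_seed(mix_seed(design$seed, "ntc", sid), {
        calls <- rep("NOCALL", panel$n_snps * design$n_controls)
        ints <- draw_intensities(calls, em)
        data.frame(sample_id = "NTC", sample_type = "control",
                   extraction = "none", scheme_id = sid,
                   assay_id = rep(panel$snp_ids, each = design$n_controls),
                   replicate = rep(seq_len(design$n_controls), panel$n_snps),
                   intensity_a = ints[, 1], intensity_b = ints[, 2],
                   call = calls, stringsAsFactors = FALSE)
      })
    }
  }
  out <- do.call(rbind, blocks[seq_len(bi)])
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study dataset
#'
#' Convenience wrapper: draws true genotypes under Hardy-Weinberg
#' equilibrium at the panel MAFs, then simulates the full reaction table.
#'
#' @inheritParams simulate_reactions
#' @return list with elements `truth` (genotype matrix), `reactions`
#'   (reaction data.frame), `panel` and `design`.
#' @export
simulate_study <- function(design = study_design(), panel = default_panel()) {
  truth <- simulate_true_genotypes(panel, design$n_individuals, design$seed)
  list(truth = truth,
       reactions = simulate_reactions(truth, design, panel),
       panel = panel, design = design)
}
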