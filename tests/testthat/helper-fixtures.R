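# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Minimal reaction rows with sensible defaults.
rx <- function(sample_id = "IND1", sample_type = "edna",
               extraction = "column", scheme_id = "S1", assay_id = "A1",
               replicate = 1L, intensity_a = NA_real_,
               intensity_b = NA_real_, call = NA_character_) {
  data.frame(sample_id = sample_id, sample_type = sample_type,
             extraction = extraction, scheme_id = scheme_id,
             assay_id = assay_id, replicate = replicate,
             intensity_a = intensity_a, intensity_b = intensity_b,
             call = call, stringsAsFactors = FALSE)
}

# A reaction table carrying pre-made calls only: per sample x assay,
# one block of eDNA replicate calls plus tissue reference reactions.
calls_table <- function(pools, references, scheme_id = "S1",
                        n_tissue = 2L) {
  stopifnot(length(pools) == length(references))
  blocks <- lapply(seq_along(pools), function(i) {
    key <- strsplit(names(pools)[i], "\\.")[[1]]
    rbind(
      rx(sample_id = key[1], assay_id = key[2], scheme_id = scheme_id,
         sample_type = "edna", replicate = seq_along(pools[[i]]),
         call = pools[[i]]),
      rx(sample_id = key[1], assay_id = key[2], scheme_id = scheme_id,
         sample_type = "tissue", replicate = seq_len(n_tissue),
         call = references[[i]]))
  })
  do.call(rbind, c(blocks, make.row.names = FALSE))
}

# Random replicate-call pools: each genotype gets n_source calls drawn so a
# replicate is NOCALL with prob z, else the reference with prob p, else a
# uniformly wrong genotype.
random_pools <- function(n_genotypes, n_source = 6L, p = 0.8, z = 0,
                         samples = NULL) {
  samples <- samples %||% paste0("IND", seq_len(n_genotypes))
  refs <- sample(c("AA", "AB", "BB"), n_genotypes, replace = TRUE)
  pools <- lapply(seq_len(n_genotypes), function(i) {
    vapply(seq_len(n_source), function(j) {
      if (runif(1) < z) return("NOCALL")
      if (runif(1) < p) refs[i] else sample(setdiff(c("AA", "AB", "BB"),
                                                    refs[i]), 1L)
    }, character(1L))
  })
  names(pools) <- paste0(samples, ".A1")
  names(refs) <- names(pools)
  list(pools = pools, references = refs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A truth matrix in which every SNP segregates all three genotypes
# across the individuals (two of each, shuffled deterministically).
balanced_truth <- function(n_individuals = 6L, snp_ids, seed = 1L) {
  stopifnot(n_individuals %% 3L == 0L)
  m <- ednasnp:::with_seed(seed, {
    vapply(seq_along(snp_ids), function(j)
      sample(rep(c("AA", "AB", "BB"), n_individuals / 3L)),
      character(n_individuals))
  })
  dimnames(m) <- list(paste0("IND", seq_len(n_individuals)), snp_ids)
  m
}
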