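# Builders for normalized intensity strata.
stratum <- function(a, b, type = "edna", call = NA_character_,
                    sample_id = "IND1") {
  rx(sample_id = sample_id, sample_type = type, intensity_a = a,
     intensity_b = b, call = call, replicate = seq_along(a))
}

test_that("min-max normalization matches a direct oracle per stratum", {
  s <- stratum(c(2, 4, 6), c(10, 20, 15))
  n <- normalize_intensities(s)
  expect_equal(n$intensity_a, c(0, 0.5, 1))
  expect_equal(n$intensity_b, c(0, 1, 0.5))

  # idempotence on input already spanning [0, 1]
  expect_equal(normalize_intensities(n)$intensity_a, n$intensity_a)

  # random stratum against the (x - min) / (max - min) oracle
  set.seed(41)
  a <- runif(30, 5, 500); b <- runif(30, 1, 80)
  n2 <- normalize_intensities(stratum(a, b))
  expect_equal(n2$intensity_a, (a - min(a)) / (max(a) - min(a)),
               tolerance = 1e-12)
  expect_equal(n2$intensity_b, (b - min(b)) / (max(b) - min(b)),
               tolerance = 1e-12)

  # two strata are rescaled independently
  two <- rbind(stratum(c(2, 4), c(1, 2)),
               rx(assay_id = "A2", intensity_a = c(100, 300),
                  intensity_b = c(7, 9), replicate = 1:2))
  nt <- normalize_intensities(two)
  expect_equal(nt$intensity_a, c(0, 1, 0, 1))

  # degenerate axis: left at 0 with a QC flag
  d <- normalize_intensities(stratum(c(3, 3, 3), c(1, 2, 3)))
  expect_equal(d$intensity_a, c(0, 0, 0))
  expect_match(attr(d, "qc")$flag, "degenerate axis intensity_a")
})

test_that("cluster fitting recovers well-separated blobs and flags failures", {
  set.seed(42)
  means <- list(AA = c(0.9, 0.05), AB = c(0.5, 0.5), BB = c(0.05, 0.9))
  a <- unlist(lapply(means, function(m) rnorm(15, m[1], 0.02)))
  b <- unlist(lapply(means, function(m) rnorm(15, m[2], 0.02)))
  model <- fit_clusters(stratum(a, b), seed = 1)
  expect_identical(model$k, 3L)
  # each generating mean has a centroid within a few noise SDs
  d <- ednasnp:::point_centroid_dist(do.call(rbind, means), model$centroids)
  expect_true(all(apply(d, 1, min) < 0.02 * 4))

  # all records at one point: k = 1, centroid at that point, no flag
  m1 <- fit_clusters(stratum(rep(0.4, 5), rep(0.6, 5)), seed = 1)
  expect_identical(m1$k, 1L)
  expect_equal(unname(m1$centroids[1, ]), c(0.4, 0.6))
  expect_length(m1$qc_flags, 0)

  # one diffuse overlapping cloud: no identifiable clusters
  set.seed(43)
  diffuse <- fit_clusters(stratum(runif(60), runif(60)), seed = 1)
  expect_identical(diffuse$k, 1L)
  expect_true("no identifiable clusters" %in% diffuse$qc_flags)

  # determinism under the seed
  expect_identical(fit_clusters(stratum(a, b), seed = 7),
                   fit_clusters(stratum(a, b), seed = 7))
})

test_that("tissue references label centroids; geometry fills the gaps", {
  set.seed(44)
  pts <- function(m, n, type, call) {
    stratum(rnorm(n, m[1], 0.02), rnorm(n, m[2], 0.02), type = type,
            call = call)
  }
  means <- list(AA = c(0.9, 0.05), AB = c(0.5, 0.5), BB = c(0.05, 0.9))
  full <- rbind(pts(means$AA, 10, "edna", NA), pts(means$AB, 10, "edna", NA),
                pts(means$BB, 10, "edna", NA),
                pts(means$AA, 3, "tissue", "AA"),
                pts(means$AB, 3, "tissue", "AB"),
                pts(means$BB, 3, "tissue", "BB"))
  model <- fit_clusters(full, seed = 1)
  labelled <- label_clusters(model, full)
  # full tissue coverage: all three labels, zero geometry fallbacks
  expect_setequal(labelled$labels, c("AA", "AB", "BB"))
  expect_false(any(grepl("geometry", labelled$qc_flags)))
  # the AA tissue blob's nearest centroid carries the AA label
  dn <- ednasnp:::point_centroid_dist(matrix(means$AA, 1), model$centroids)
  expect_identical(labelled$labels[which.min(dn)], "AA")

  # tissue covering only AA and BB: middle centroid becomes AB by geometry
  partial <- rbind(pts(means$AA, 10, "edna", NA),
                   pts(means$AB, 10, "edna", NA),
                   pts(means$BB, 10, "edna", NA),
                   pts(means$AA, 3, "tissue", "AA"),
                   pts(means$BB, 3, "tissue", "BB"))
  model2 <- label_clusters(fit_clusters(partial, seed = 1), partial)
  mid <- which.min(ednasnp:::point_centroid_dist(matrix(means$AB, 1),
                                                 model2$centroids))
  expect_identical(model2$labels[mid], "AB")
  expect_true(any(grepl("geometry", model2$qc_flags)))

  # no tissue at all: prominent flag, pure geometry labelling
  edna_only <- rbind(pts(means$AA, 10, "edna", NA),
                     pts(means$BB, 10, "edna", NA))
  m3 <- label_clusters(fit_clusters(edna_only, seed = 1), edna_only[0, ])
  expect_true(any(grepl("NO TISSUE", m3$qc_flags)))
  expect_false(anyNA(m3$labels))
})

test_that("nearest-centroid calling respects the no-call radius", {
  model <- structure(
    list(assay_id = "A1", scheme_id = "S1", k = 3L,
         centroids = rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.1, 0.9)),
         labels = c("AA", "AB", "BB"), nocall_radius = 0.15,
         qc_flags = character()),
    class = "cluster_model")
  recs <- stratum(c(0.9, 0.52, 0.02, 0.5), c(0.1, 0.48, 0.02, 0.2))
  called <- call_genotypes(recs, model)
  # at a centroid -> its genotype; near one -> same; far from all -> NOCALL
  expect_identical(called$call, c("AA", "AB", "NOCALL", "NOCALL"))

  # a control landing inside a genotype cluster raises a QC flag
  ctrl <- rbind(recs, stratum(0.9, 0.1, type = "control"))
  expect_match(attr(call_genotypes(ctrl, model), "qc"), "control")

  # unlabelled model is rejected
  model$labels <- rep(NA_character_, 3)
  expect_error(call_genotypes(recs, model), "unlabelled")
})

test_that("end-to-end calling recovers generated calls on clean data", {
  panel <- panel_spec(c(0.5, 0.4, 0.35, 0.3))
  truth <- balanced_truth(6, panel$snp_ids, seed = 9)
  design <- study_design(
    n_individuals = 6, n_replicates = 6, n_tissue_replicates = 3,
    schemes = dilution_schemes("S1", "column"),
    error_models = list(S1 = error_model(0, 0, intensity_separation = 10,
                                         intensity_noise_sd = 1)),
    tissue_error_model = error_model(0, 0, 10, 1),
    n_controls = 1, seed = 9)
  recs <- simulate_reactions(truth, design, panel)
  generated <- recs$call
  called <- call_dataset(recs, seed = 9)
  # record count and order conserved; every record has exactly one call
  expect_identical(nrow(called$records), nrow(recs))
  expect_identical(called$records$assay_id, recs$assay_id)
  expect_true(all(called$records$call %in% c("AA", "AB", "BB", "NOCALL")))
  # noiseless limit: 100% of non-control calls match the generating truth
  keep <- recs$sample_type != "control"
  expect_identical(called$records$call[keep], generated[keep])
})

test_that("calling is deterministic given records and seed", {
  panel <- panel_spec(c(0.5, 0.3))
  truth <- balanced_truth(6, panel$snp_ids, seed = 2)
  design <- study_design(
    n_individuals = 6, n_replicates = 4, n_tissue_replicates = 2,
    schemes = dilution_schemes("S1", "chelex"),
    error_models = list(S1 = error_model(0.2, 0.1, 6, 1)),
    n_controls = 0, seed = 2)
  recs <- simulate_reactions(truth, design, panel)
  expect_identical(call_dataset(recs, seed = 5)$records,
                   call_dataset(recs, seed = 5)$records)
})
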