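## Genotype calling from bi-allelic fluorescence intensities.
##
## Reactions are clustered within assay x dilution-scheme strata (dilution
## changes the intensity distribution, so clustering across dilutions mixes
## incompatible scales). Cluster number is chosen by average silhouette
## width, clusters are labelled from the tissue reference reactions of the
## same stratum, and reactions too far from every centroid are NOCALL.

stratum_key <- function(records) {
  paste(records$assay_id, records$scheme_id, sep = "\r")
}

#' Normalize fluorescence intensities within assay x scheme strata
#'
#' Rescales each intensity axis to \[0, 1\] by min-max over the records of
#' each assay x dilution-scheme stratum. Record order is preserved. An axis
#' that is constant within a stratum cannot be rescaled; it is set to 0 and
#' the stratum is QC-flagged.
#'
#' @param records reaction data.frame (see [read_reactions()]).
#' @return the records with `intensity_a`/`intensity_b` rescaled, carrying a
#'   `qc` attribute (data.frame of stratum flags, zero rows if clean).
#' @export
normalize_intensities <- function(records) {
  flags <- list()
  for (key in unique(stratum_key(records))) {
    idx <- which(stratum_key(records) == key)
    for (col in c("intensity_a", "intensity_b")) {
      v <- records[[col]][idx]
      rng <- range(v)
      if (diff(rng) == 0) {
        records[[col]][idx] <- 0
        flags[[length(flags) + 1L]] <- data.frame(
          assay_id = records$assay_id[idx[1L]],
          scheme_id = records$scheme_id[idx[1L]],
          flag = paste0("degenerate axis ", col, ": all values identical"),
          stringsAsFactors = FALSE)
      } else {
        records[[col]][idx] <- (v - rng[1L]) / diff(rng)
      }
    }
  }
  attr(records, "qc") <- if (length(flags)) do.call(rbind, flags) else
    data.frame(assay_id = character(), scheme_id = character(),
               flag = character(), stringsAsFactors = FALSE)
  records
}

## Average silhouette width of a k-means partition; NA when undefined.
avg_silhouette <- function(clusters, dmat) {
  if (length(unique(clusters)) < 2L) return(NA_real_)
  mean(cluster::silhouette(clusters, dmat)[, "sil_width"])
}

#' Fit a cluster model to one assay x scheme stratum
#'
#' Runs k-means for k = 1..`k_max` on the stratum's non-control records and
#' selects k by average silhouette width, falling back to k = 1 when the
#' silhouette is undefined or every candidate falls below `sil_floor`.
#' A k = 1 winner with high within-cluster dispersion gets the
#' `"no identifiable clusters"` QC flag (the automated analogue of a
#' manually rejected assay).
#'
#' @param records normalized reactions of a single assay x scheme stratum.
#' @param k_max maximum number of clusters (3 genotype clusters for a
#'   bi-allelic SNP).
#' @param seed integer seed; restarts use deterministic sub-seeds.
#' @param sil_floor minimum acceptable average silhouette width.
#' @return an object of class `cluster_model`: unlabelled centroids plus QC
#'   flags. Label with [label_clusters()] before calling genotypes.
#' @export
fit_clusters <- function(records, k_max = 3L, seed = 1L, sil_floor = 0.5) {
  stopifnot(length(unique(stratum_key(records))) == 1L)
  fit <- records[records$sample_type != "control", , drop = FALSE]
  if (nrow(fit) < 2L) {
    stop("need at least 2 non-control records to fit clusters",
         call. = FALSE)
  }
  x <- cbind(fit$intensity_a, fit$intensity_b)
  n_distinct <- nrow(unique(x))
  k_max <- min(k_max, n_distinct)
  qc <- character()

  best_k <- 1L
  best_fit <- NULL
  if (k_max >= 2L) {
    dmat <- stats::dist(x)
    best_sil <- -Inf
    for (k in 2:k_max) {
      km <- with_seed(mix_seed(seed, "kmeans", k),
                      stats::kmeans(x, centers = k, nstart = 10L,
                                    iter.max = 50L))
      sil <- avg_silhouette(km$cluster, dmat)
      if (!is.na(sil) && sil > best_sil) {
        best_sil <- sil
        best_k <- k
        best_fit <- km
      }
    }
    if (!is.finite(best_sil) || best_sil < sil_floor) {
      best_k <- 1L
      best_fit <- NULL
    }
  }

  if (best_k == 1L) {
    centroids <- matrix(colMeans(x), nrow = 1L)
    dispersion <- mean(sqrt(rowSums(sweep(x, 2, centroids[1L, ])^2)))
    if (dispersion > 0.2) qc <- c(qc, "no identifiable clusters")
  } else {
    centroids <- unname(best_fit$centers)
  }

  structure(
    list(assay_id = records$assay_id[1L],
         scheme_id = records$scheme_id[1L],
         k = nrow(centroids),
         centroids = centroids,
         labels = rep(NA_character_, nrow(centroids)),
         nocall_radius = NA_real_,
         qc_flags = qc),
    class = "cluster_model")
}

## Geometry convention for centroids no tissue record labels: the highest
## allele-1 signal is AA, the highest allele-2 signal is BB, the rest AB.
## Centroids sitting near the origin are the no-template cluster, never a
## genotype.
geometry_labels <- function(centroids, unlabelled, unused) {
  labels <- rep(NA_character_, nrow(centroids))
  near_origin <- sqrt(rowSums(centroids^2)) < 0.25
  for (i in unlabelled[near_origin[unlabelled]]) labels[i] <- "NOCALL"
  pool <- setdiff(unlabelled, which(near_origin))
  if ("AA" %in% unused && length(pool)) {
    i <- pool[which.max(centroids[pool, 1L])]
    labels[i] <- "AA"
    pool <- setdiff(pool, i)
    unused <- setdiff(unused, "AA")
  }
  if ("BB" %in% unused && length(pool)) {
    i <- pool[which.max(centroids[pool, 2L])]
    labels[i] <- "BB"
    pool <- setdiff(pool, i)
    unused <- setdiff(unused, "BB")
  }
  if ("AB" %in% unused && length(pool)) {
    labels[pool[1L]] <- "AB"
    pool <- pool[-1L]
  }
  labels[pool] <- "NOCALL"
  labels
}

#' Label fitted clusters from tissue reference reactions
#'
#' Each centroid takes the majority reference call of the tissue reactions
#' nearest to it. Centroids that capture no tissue reaction are labelled by
#' intensity geometry (highest allele-1 signal AA, highest allele-2 signal
#' BB, remainder AB), except near-origin centroids, which are the
#' no-template cluster and are labelled NOCALL. Conflicts and fallbacks are
#' QC-flagged. Also sets the model's no-call radius: 3x the median distance
#' of tissue reactions to their nearest centroid, but never below half the
#' minimum inter-centroid gap (a smaller radius would no-call reactions
#' unambiguously nearest one cluster).
#'
#' @param model a [fit_clusters()] model.
#' @param tissue_records normalized tissue reactions of the same stratum,
#'   with reference calls in `call`.
#' @param radius_multiplier multiplier on the median tissue distance.
#' @return the model with `labels` and `nocall_radius` set.
#' @export
label_clusters <- function(model, tissue_records, radius_multiplier = 3) {
  stopifnot(inherits(model, "cluster_model"))
  k <- model$k
  labels <- rep(NA_character_, k)
  qc <- model$qc_flags

  tis <- tissue_records[tissue_records$sample_type == "tissue" &
                          !is.na(tissue_records$call) &
                          tissue_records$call != "NOCALL", , drop = FALSE]
  tissue_dists <- numeric()
  if (nrow(tis)) {
    d <- point_centroid_dist(cbind(tis$intensity_a, tis$intensity_b),
                             model$centroids)
    nearest <- max.col(-d)
    tissue_dists <- d[cbind(seq_len(nrow(d)), nearest)]
    for (i in seq_len(k)) {
      votes <- table(tis$call[nearest == i])
      if (!length(votes)) next
      top <- names(votes)[votes == max(votes)]
      if (length(top) > 1L) {
        qc <- c(qc, sprintf(
          "centroid %d: tied tissue labels (%s); left to geometry", i,
          paste(top, collapse = "/")))
        next
      }
      labels[i] <- top
    }
    ## two centroids claiming the same genotype: keep the better-supported
    for (g in unique(stats::na.omit(labels))) {
      claim <- which(labels == g)
      if (length(claim) > 1L) {
        support <- vapply(claim, function(i) sum(tis$call[nearest == i] == g),
                          numeric(1L))
        lose <- claim[-which.max(support)]
        labels[lose] <- NA_character_
        qc <- c(qc, sprintf(
          "conflicting tissue label %s on centroids %s; kept best-supported",
          g, paste(claim, collapse = ",")))
      }
    }
  } else {
    qc <- c(qc, "NO TISSUE REFERENCE: all centroids labelled by geometry")
  }

  unlabelled <- which(is.na(labels))
  if (length(unlabelled)) {
    geo <- geometry_labels(model$centroids, unlabelled,
                           unused = setdiff(GENOTYPES, labels))
    labels[unlabelled] <- geo[unlabelled]
    if (nrow(tis)) {
      qc <- c(qc, sprintf("centroid %d labelled %s by geometry fallback",
                          unlabelled, labels[unlabelled]))
    }
  }

  half_gap <- if (k >= 2L) min(stats::dist(model$centroids)) / 2 else Inf
  med <- if (length(tissue_dists)) stats::median(tissue_dists) else 0.05
  model$nocall_radius <- max(radius_multiplier * med,
                             min(half_gap, 0.5), 0.05)
  model$labels <- labels
  model$qc_flags <- qc
  model
}

#' Call genotypes from a labelled cluster model
#'
#' Each non-control reaction takes the genotype label of its nearest
#' centroid if within the model's no-call radius, else NOCALL (as it does
#' when the nearest centroid is the no-template cluster). Controls are run
#' through the same rule and QC-flagged if they produce a genotype call.
#'
#' @param records normalized reactions of the model's stratum.
#' @param model a labelled [cluster_model][label_clusters()].
#' @return the records with `call` set, carrying a `qc` attribute.
#' @export
call_genotypes <- function(records, model) {
  stopifnot(inherits(model, "cluster_model"))
  if (anyNA(model$labels) || is.na(model$nocall_radius)) {
    stop("cluster model is unlabelled; run label_clusters() first",
         call. = FALSE)
  }
  d <- point_centroid_dist(cbind(records$intensity_a, records$intensity_b),
                           model$centroids)
  nearest <- max.col(-d)
  nearest_d <- d[cbind(seq_len(nrow(d)), nearest)]
  call <- model$labels[nearest]
  call[nearest_d > model$nocall_radius] <- "NOCALL"
  records$call <- call
  qc <- character()
  ctrl <- records$sample_type == "control" & call != "NOCALL"
  if (any(ctrl)) {
    qc <- sprintf("control reaction called %s (possible contamination)",
                  call[ctrl])
  }
  attr(records, "qc") <- qc
  records
}

#' Call genotypes across a whole reaction table
#'
#' Splits the table into assay x dilution-scheme strata and, per stratum:
#' min-max normalizes intensities, fits a k-means cluster model, labels its
#' centroids from the stratum's tissue reactions (their incoming `call`
#' values are the reference), and calls every reaction from the labelled
#' model. Record count and order are preserved.
#'
#' @param records reaction data.frame with intensities; tissue rows must
#'   carry reference calls.
#' @param k_max,sil_floor,radius_multiplier see [fit_clusters()] and
#'   [label_clusters()].
#' @param nocall_radius optional fixed no-call radius (normalized units)
#'   overriding the per-stratum rule.
#' @param normalize set `FALSE` to cluster raw intensities.
#' @param seed integer seed for the (restart-level) randomness of k-means.
#' @return list of class `called_dataset`: `records` (calls filled in),
#'   `models` (per-stratum labelled cluster models) and `qc` (data.frame of
#'   all flags).
#' @export
call_dataset <- function(records, k_max = 3L, sil_floor = 0.5,
                         radius_multiplier = 3, nocall_radius = NULL,
                         normalize = TRUE, seed = 1L) {
  records$.row <- seq_len(nrow(records))
  if (normalize) {
    records <- normalize_intensities(records)
    qc_norm <- attr(records, "qc")
  } else {
    qc_norm <- NULL
  }
  keys <- stratum_key(records)
  out <- vector("list", length(unique(keys)))
  models <- list()
  qc <- list()
  for (key in unique(keys)) {
    stratum <- records[keys == key, , drop = FALSE]
    id <- paste0(stratum$assay_id[1L], "/", stratum$scheme_id[1L])
    model <- fit_clusters(stratum, k_max = k_max, seed = seed,
                          sil_floor = sil_floor)
    model <- label_clusters(model, stratum[stratum$sample_type == "tissue", ,
                                           drop = FALSE],
                            radius_multiplier = radius_multiplier)
    if (!is.null(nocall_radius)) model$nocall_radius <- nocall_radius
    stratum <- call_genotypes(stratum, model)
    if (length(model$qc_flags) || length(attr(stratum, "qc"))) {
      qc[[id]] <- data.frame(
        assay_id = model$assay_id, scheme_id = model$scheme_id,
        flag = c(model$qc_flags, attr(stratum, "qc")),
        stringsAsFactors = FALSE)
    }
    models[[id]] <- model
    out[[key]] <- stratum
  }
  res <- do.call(rbind, out)
  res <- res[order(res$.row), , drop = FALSE]
  res$.row <- NULL
  rownames(res) <- NULL
  qc <- if (length(qc)) do.call(rbind, c(qc, make.row.names = FALSE)) else
    data.frame(assay_id = character(), scheme_id = character(),
               flag = character(), stringsAsFactors = FALSE)
  if (!is.null(qc_norm) && nrow(qc_norm)) qc <- rbind(qc_norm, qc)
  structure(list(records = res, models = models, qc = qc),
            class = "called_dataset")
}

#' Serialize cluster models to a text audit file
#'
#' Writes per-stratum centroids, labels, no-call radii and QC flags as YAML
#' so calling decisions can be audited.
#'
#' @param models the `models` element of a [call_dataset()] result.
#' @param path output file.
#' @export
write_cluster_models <- function(models, path) {
  ser <- lapply(models, function(m) {
    list(assay_id = m$assay_id, scheme_id = m$scheme_id, k = m$k,
         centroids = lapply(seq_len(m$k), function(i)
           list(label = m$labels[i],
                intensity_a = round(m$centroids[i, 1L], 6),
                intensity_b = round(m$centroids[i, 2L], 6))),
         nocall_radius = round(m$nocall_radius, 6),
         qc_flags = as.list(m$qc_flags))
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}
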