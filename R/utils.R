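#' @keywords internal
"_PACKAGE"

## Genotype vocabulary used throughout: the three bi-allelic genotypes plus
## the no-call state. "TIE" is only ever produced by consensus_call(); it is
## not a valid reaction-level call.
GENOTYPES <- c("AA", "AB", "BB")
CALL_LEVELS <- c(GENOTYPES, "NOCALL")

SAMPLE_TYPES <- c("tissue", "edna", "control")
EXTRACTIONS <- c("column", "chelex", "none")

#' Parse genotype call strings
#'
#' Maps platform-export spellings onto the canonical call vocabulary.
#' Parsing is case-insensitive; `"No Call"`, `"NTC"`, `NA` and the empty
#' string all map to `"NOCALL"`.
#'
#' @param x character vector of raw call strings.
#' @return character vector over `AA`, `AB`, `BB`, `NOCALL`.
#' @export
parse_genotype <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[is.na(x) | x == "" | x == "NTC" | gsub("[ _]", "", x) == "NOCALL"] <- "NOCALL"
  bad <- !(x %in% CALL_LEVELS)
  if (any(bad)) {
    stop("unrecognised genotype call(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

## Deterministic substream seeds: one global integer seed expands into
## per-stage / per-counter seeds so stages can be rerun in isolation.
## Multiplicative string hash over a Mersenne prime keeps values < 2^31.
mix_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (part in c(...)) {
    for (ch in utf8ToInt(as.character(part))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

## with_seed: evaluate expr under a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Euclidean distances from points (n x 2 matrix) to centroids (k x 2).
point_centroid_dist <- function(points, centroids) {
  points <- matrix(as.numeric(points), ncol = 2)
  centroids <- matrix(as.numeric(centroids), ncol = 2)
  da <- outer(points[, 1], centroids[, 1], "-")
  db <- outer(points[, 2], centroids[, 2], "-")
  sqrt(da^2 + db^2)
}
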