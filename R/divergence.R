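# Pairwise plumage distances, uncorrected molecular p-distances, and the
# descriptive plumage-vs-molecular regression.

#' Plumage distance between two taxa
#'
#' Number of plumage characters whose states differ; missing cells (`"?"`)
#' are skipped pairwise.
#'
#' @param a,b named character vectors of states over the same character set.
#' @return integer count with attribute `n_compared`.
#' @export
plumage_distance <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (!length(common)) stop("profiles share no characters")
  a <- a[common]; b <- b[common]
  ok <- a != MISSING_TOKEN & b != MISSING_TOKEN & !is.na(a) & !is.na(b)
  structure(sum(a[ok] != b[ok]), n_compared = sum(ok))
}

#' All pairwise plumage distances for a character matrix
#'
#' @param matrix a `"character_matrix"`.
#' @param include,exclude optional taxon filters.
#' @return symmetric integer matrix with attribute `kind = "plumage"`.
#' @export
plumage_distance_matrix <- function(matrix, include = NULL, exclude = NULL) {
  m <- as.matrix(matrix)
  taxa <- rownames(m)
  if (!is.null(include)) taxa <- intersect(taxa, include)
  if (!is.null(exclude)) taxa <- setdiff(taxa, exclude)
  m <- m[taxa, , drop = FALSE]
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- as.integer(plumage_distance(m[i, ], m[j, ]))
  }
  structure(d, kind = "plumage")
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among sites where both sequences carry an
#' unambiguous base (A/C/G/T); gaps and ambiguity codes are excluded
#' pairwise.
#'
#' @param a,b equal-length character vectors of bases.
#' @return p-distance in [0, 1], with attribute `n_sites` (comparable sites).
#' @export
p_distance <- function(a, b) {
  if (length(a) != length(b)) stop("sequences not aligned (unequal lengths)")
  bases <- c("A", "C", "G", "T")
  ok <- toupper(a) %in% bases & toupper(b) %in% bases
  if (!any(ok)) stop("no comparable sites between the two sequences")
  structure(sum(toupper(a)[ok] != toupper(b)[ok]) / sum(ok), n_sites = sum(ok))
}

#' All pairwise uncorrected p-distances for an alignment
#'
#' Computed on the concatenation of all partitions with pairwise deletion of
#' gaps/ambiguities.
#'
#' @param alignment a `"dna_alignment"`.
#' @param include,exclude optional taxon filters.
#' @return symmetric numeric matrix with attribute `kind = "p_distance"`.
#' @export
p_distance_matrix <- function(alignment, include = NULL, exclude = NULL) {
  m <- as.matrix(alignment)
  taxa <- rownames(m)
  if (!is.null(include)) taxa <- intersect(taxa, include)
  if (!is.null(exclude)) taxa <- setdiff(taxa, exclude)
  m <- m[taxa, , drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- as.numeric(p_distance(m[i, ], m[j, ]))
  structure(d, kind = "p_distance")
}

# shared container for simple / through-origin regression summaries
regression_result <- function(slope, intercept, r_squared, f, df1, df2, p, n) {
  structure(list(slope = slope, intercept = intercept, r_squared = r_squared,
                 f = f, df1 = df1, df2 = df2, p = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("slope %.4g, intercept %s, R^2 = %.4g, F(%d,%d) = %.4g, p = %.4g, n = %d\n",
              x$slope,
              if (is.na(x$intercept)) "(through origin)" else sprintf("%.4g", x$intercept),
              x$r_squared, x$df1, x$df2, x$f, x$p, x$n))
  invisible(x)
}

#' Plumage distance as a function of molecular divergence
#'
#' Ordinary least squares of plumage distance on molecular p-distance over
#' all unordered taxon pairs (the upper triangle of both matrices). The
#' pairs are not phylogenetically independent, so the fit is descriptive: it
#' summarises whether plumage differences accumulate with genetic distance,
#' not a hypothesis test corrected for shared history.
#'
#' @param x molecular distances: symmetric matrix or vector of pair values.
#' @param y plumage distances matching `x` (same taxon ordering).
#' @return a `"regression_result"` (slope, intercept, R^2, F with df
#'   (1, n-2), p, n = number of pairs).
#' @export
divergence_regression <- function(x, y) {
  if (is.matrix(x)) {
    if (!identical(dim(x), dim(y)))
      stop("distance matrices have different dimensions")
    if (!is.null(rownames(x)) && !is.null(rownames(y))) {
      if (!setequal(rownames(x), rownames(y)))
        stop("distance matrices cover different taxa")
      y <- y[rownames(x), rownames(x)]
    }
    ut <- upper.tri(x)
    x <- x[ut]; y <- y[ut]
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs for regression")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  regression_result(slope = unname(coef(fit)[2]),
                    intercept = unname(coef(fit)[1]),
                    r_squared = sm$r.squared,
                    f = unname(sm$fstatistic[1]),
                    df1 = 1L, df2 = n - 2L,
                    p = pf(sm$fstatistic[1], 1, n - 2, lower.tail = FALSE),
                    n = n)
}

#' Pairwise divergence table for a study bundle
#'
#' One row per taxon pair: molecular p-distance plus male and female plumage
#' distances, the input to the divergence regressions.
#'
#' @param bundle a `"study_bundle"` with an alignment.
#' @param include,exclude optional taxon filters applied to every component.
#' @return data.frame (taxonA, taxonB, p_dist, plumage_dist_male,
#'   plumage_dist_female).
#' @export
divergence_table <- function(bundle, include = NULL, exclude = NULL) {
  if (is.null(bundle$alignment)) stop("bundle has no alignment")
  pd <- p_distance_matrix(bundle$alignment, include, exclude)
  taxa <- rownames(pd)
  dm <- plumage_distance_matrix(bundle$male, include = taxa)[taxa, taxa]
  df_ <- plumage_distance_matrix(bundle$female, include = taxa)[taxa, taxa]
  pairs <- which(upper.tri(pd), arr.ind = TRUE)
  data.frame(taxonA = taxa[pairs[, 1]], taxonB = taxa[pairs[, 2]],
             p_dist = pd[pairs], plumage_dist_male = dm[pairs],
             plumage_dist_female = df_[pairs])
}
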