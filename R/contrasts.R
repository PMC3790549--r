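# Dichromatism scores, latitude summaries, Felsenstein's independent
# contrasts with the branch-length adequacy diagnostic, and regression
# through the origin.

#' Sexual dichromatism of one taxon
#'
#' Percentage of plumage characters whose states differ between the male
#' and female profiles; missing cells are skipped pairwise.
#'
#' @param male,female named state vectors over the same character set.
#' @return list: `n_diff`, `n_compared`, `D` (percentage in [0, 100]).
#' @export
dichromatism <- function(male, female) {
  if (!setequal(names(male), names(female)))
    stop("male and female profiles cover different characters")
  d <- plumage_distance(male, female)
  n <- attr(d, "n_compared")
  list(n_diff = as.integer(d), n_compared = n, D = 100 * as.integer(d) / n)
}

#' Per-taxon dichromatism table
#'
#' @param male,female character matrices with matching characters.
#' @param taxa taxa to score (default: taxa present in both matrices).
#' @return data.frame (taxon, n_diff, n_compared, D).
#' @export
dichromatism_scores <- function(male, female, taxa = NULL) {
  if (is.null(taxa)) taxa <- intersect(rownames(male), rownames(female))
  rows <- lapply(taxa, function(tx)
    dichromatism(as.matrix(male)[tx, ], as.matrix(female)[tx, ]))
  data.frame(taxon = taxa,
             n_diff = vapply(rows, `[[`, 1L, "n_diff"),
             n_compared = vapply(rows, `[[`, 1L, "n_compared"),
             D = vapply(rows, `[[`, 1, "D"))
}

#' Latitude summaries per taxon
#'
#' Mean breeding latitude (midpoint of the northern and southern range
#' limits) and the southern (lower) limit, in degrees south (positive
#' southward).
#'
#' @param meta metadata with columns `taxon`, `lat_north`, `lat_south`.
#' @return data.frame (taxon, midpoint, southern).
#' @export
latitude_summary <- function(meta) {
  validate_taxon_meta(meta)
  data.frame(taxon = meta$taxon,
             midpoint = (meta$lat_north + meta$lat_south) / 2,
             southern = meta$lat_south)
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's recursion: at each internal node the two daughter values
#' are differenced and standardized by the square root of the summed branch
#' lengths (daughter branches lengthened by the variance of their imputed
#' values); the node is imputed the precision-weighted average. On a
#' bifurcating tree with `n` tips this yields `n - 1` contrasts that are
#' independent and identically distributed under Brownian motion.
#' Polytomies are resolved arbitrarily with zero-length branches (with a
#' warning).
#'
#' @param tree a `"phylo"`.
#' @param x named trait vector over the tips.
#' @return a `"contrast_set"` data.frame: `node`, `contrast` (standardized),
#'   `sd` (its standard deviation, sqrt of summed variances), `node_value`,
#'   `lengthened_branch` (branch above the node after lengthening; `NA` at
#'   the root).
#' @export
pic_contrasts <- function(tree, x) {
  if (!ape::is.binary(tree)) {
    warning("polytomies resolved arbitrarily with zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("trait values missing for some tips")
  nt <- length(tree$tip.label)
  ntot <- nt + tree$Nnode
  val <- c(as.numeric(x), rep(NA_real_, tree$Nnode))
  extra <- numeric(ntot)                       # variance added by imputation
  blen <- rep(NA_real_, ntot)
  blen[tree$edge[, 2]] <- tree$edge.length
  ord <- ape::reorder.phylo(tree, "postorder")
  out <- vector("list", tree$Nnode)
  j <- 0L
  for (node in unique(ord$edge[, 1])) {
    ch <- ord$edge[ord$edge[, 1] == node, 2]
    v <- blen[ch] + extra[ch]
    if (sum(v) <= 0)
      stop("zero combined branch length at node ", node,
           ": contrast variance undefined")
    j <- j + 1L
    contrast <- (val[ch[1]] - val[ch[2]]) / sqrt(sum(v))
    w <- 1 / v; w[!is.finite(w)] <- .Machine$double.xmax
    val[node] <- sum(w * val[ch]) / sum(w)
    extra[node] <- prod(v) / sum(v)
    out[[j]] <- data.frame(node = node, contrast = contrast,
                           sd = sqrt(sum(v)), node_value = val[node],
                           lengthened_branch =
                             if (is.na(blen[node])) NA_real_
                             else blen[node] + extra[node])
  }
  res <- do.call(rbind, out)
  class(res) <- c("contrast_set", "data.frame")
  res
}

#' Branch-length adequacy diagnostic for contrasts
#'
#' OLS of the absolute standardized contrasts on their standard deviations.
#' A slope indistinguishable from zero indicates the branch lengths
#' adequately standardize the contrasts; a positive slope indicates
#' under-standardization of deep contrasts.
#'
#' @param contrasts a `"contrast_set"`.
#' @return a `"regression_result"` with df (1, n - 2), n = number of
#'   contrasts.
#' @export
adequacy_diagnostic <- function(contrasts) {
  n <- nrow(contrasts)
  if (n < 3) stop("need at least 3 contrasts")
  if (var(contrasts$sd) == 0) stop("contrast standard deviations are constant")
  divergence_regression(contrasts$sd, abs(contrasts$contrast))
}

#' Regression of contrasts through the origin
#'
#' Contrasts have an arbitrary sign, so each pair is oriented so the
#' predictor contrast is non-negative and the regression is forced through
#' the origin: slope = sum(cx cy) / sum(cx^2), R^2 = slope^2 sum(cx^2) /
#' sum(cy^2), F on (1, n - 1) degrees of freedom.
#'
#' @param cx,cy `"contrast_set"`s (matched by node) or plain numeric vectors
#'   of paired contrasts.
#' @return a `"regression_result"` (intercept is `NA`: through the origin).
#' @export
origin_regression <- function(cx, cy) {
  if (inherits(cx, "contrast_set") && inherits(cy, "contrast_set")) {
    if (!identical(cx$node, cy$node))
      stop("contrast sets computed on different nodes")
    cx <- cx$contrast; cy <- cy$contrast
  }
  if (length(cx) != length(cy)) stop("unequal numbers of contrasts")
  flip <- cx < 0
  cx[flip] <- -cx[flip]; cy[flip] <- -cy[flip]
  sxx <- sum(cx^2)
  if (sxx == 0) stop("all predictor contrasts are zero")
  n <- length(cx)
  slope <- sum(cx * cy) / sxx
  r2 <- sum(cx * cy)^2 / (sxx * sum(cy^2))
  f <- (n - 1) * r2 / (1 - r2)
  regression_result(slope = slope, intercept = NA_real_, r_squared = r2,
                    f = f, df1 = 1L, df2 = n - 1L,
                    p = pf(f, 1, n - 1, lower.tail = FALSE), n = n)
}

#' Dichromatism-versus-latitude contrasts analysis
#'
#' Scores dichromatism, summarises latitude both ways (midpoint and
#' southern limit), computes independent contrasts of each variable, runs
#' the adequacy diagnostic on each, and regresses dichromatism contrasts on
#' latitude contrasts through the origin.
#'
#' @param tree a `"phylo"` restricted to the analysis taxa.
#' @param male,female character matrices.
#' @param meta metadata with latitudinal limits.
#' @param latitude which latitude covariates to use (default: both).
#' @return list with the per-taxon `scores` table, per-variant contrast
#'   sets, adequacy diagnostics, and origin regressions.
#' @export
dichromatism_latitude_analysis <- function(tree, male, female, meta,
                                           latitude = c("midpoint", "southern")) {
  latitude <- match.arg(latitude, several.ok = TRUE)
  ds <- dichromatism_scores(male, female, taxa = tree$tip.label)
  lat <- latitude_summary(meta)
  tab <- merge(ds, lat, by = "taxon")
  d_tr <- setNames(tab$D, tab$taxon)
  cd <- pic_contrasts(tree, d_tr)
  out <- list(scores = tab, contrasts_dichromatism = cd,
              adequacy_dichromatism = adequacy_diagnostic(cd))
  for (v in latitude) {
    x_tr <- setNames(tab[[v]], tab$taxon)
    cl <- pic_contrasts(tree, x_tr)
    out[[paste0("contrasts_", v)]] <- cl
    out[[paste0("adequacy_", v)]] <- adequacy_diagnostic(cl)
    out[[paste0("regression_", v)]] <- origin_regression(cl, cd)
  }
  out
}
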