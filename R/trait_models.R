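# Continuous plumage score (principal coordinates of the plumage distance
# matrix) and maximum-likelihood fitting of Brownian-motion and
# single/multi-optimum Ornstein-Uhlenbeck (Hansen) models.
#
# Parameterisation: alpha is the strength of attraction toward the optimum
# (per unit branch length), sigma2 the Brownian diffusion rate, theta the
# regime optima. For OU models the root value z0 is tied to the root
# regime's optimum, so parameter counts are k = 2 (BM: sigma2, z0),
# 3 (OU1: alpha, sigma2, theta), 2 + r for r regimes.

#' Principal-coordinates plumage score
#'
#' Classical metric multidimensional scaling (Gower double-centering +
#' eigendecomposition) of a plumage distance matrix; the requested axis is
#' returned as the continuous trait used for evolutionary model fitting.
#' Scores are centered; the sign is fixed so the largest-magnitude score is
#' positive.
#'
#' @param dist symmetric distance matrix with taxon dimnames.
#' @param axis which principal coordinate to return (default 1).
#' @return list of class `"ordination_scores"`: `trait` (named vector on the
#'   chosen axis), `scores` (all axes), `eigenvalues`, `axis`.
#' @export
pcoa_trait <- function(dist, axis = 1L) {
  d <- as.matrix(dist)
  if (all(d == 0)) stop("all distances are zero: ordination undefined")
  k <- nrow(d) - 1L
  # Hamming distances are typically non-Euclidean, so trailing eigenvalues
  # can be negative; only the leading axes are meaningful and cmdscale's
  # warning about dropped axes is expected
  mds <- suppressWarnings(cmdscale(d, k = k, eig = TRUE))
  ev <- mds$eig
  sc <- mds$points
  if (axis > ncol(sc)) stop("axis ", axis, " not available")
  tr <- sc[, axis]
  if (abs(min(tr)) > abs(max(tr))) {            # sign convention
    tr <- -tr
    sc[, axis] <- tr
  }
  structure(list(trait = setNames(tr, rownames(d)), scores = sc,
                 eigenvalues = ev, axis = axis),
            class = "ordination_scores")
}

# ---- regime paintings -------------------------------------------------------

#' Paint every branch of a tree with a selective regime
#'
#' @param tree a `"phylo"`.
#' @param edge_regimes character vector, one regime label per row of
#'   `tree$edge`.
#' @param regimes the regime set (defaults to the labels present).
#' @param root_regime regime assumed at the root (the OU root state is tied
#'   to this regime's optimum). Defaults to the modal regime among the
#'   root's child edges.
#' @return a `"regime_painting"` list.
#' @export
regime_painting <- function(tree, edge_regimes, regimes = NULL,
                            root_regime = NULL) {
  if (length(edge_regimes) != nrow(tree$edge))
    stop("need one regime per branch (", nrow(tree$edge), ")")
  if (anyNA(edge_regimes)) stop("unlabelled branch(es) in painting")
  if (is.null(regimes)) regimes <- sort(unique(edge_regimes))
  if (!all(edge_regimes %in% regimes))
    stop("edge regime outside declared regime set")
  if (is.null(root_regime)) {
    root <- length(tree$tip.label) + 1L
    at_root <- edge_regimes[tree$edge[, 1] == root]
    root_regime <- names(sort(table(at_root), decreasing = TRUE))[1]
  }
  stopifnot(root_regime %in% regimes)
  structure(list(tree = tree, edge_regimes = edge_regimes, regimes = regimes,
                 root_regime = root_regime),
            class = "regime_painting")
}

#' @export
single_regime_painting <- function(tree, label = "all") {
  regime_painting(tree, rep(label, nrow(tree$edge)), regimes = label,
                  root_regime = label)
}

# ---- tree precomputations ---------------------------------------------------

# node depths from the root, tip depths, and the tip MRCA-depth matrix
# (= shared root-to-MRCA path length, the BM vcv)
phylo_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::vcv.phylo(tree)           # shared path lengths, tip order
  list(depth = depth, T = depth[seq_along(tree$tip.label)], M = M)
}

# OU covariance with unit sigma2:
# V_ij = exp(-alpha d_ij) (1 - exp(-2 alpha t_a)) / (2 alpha)
ou_vcv_unit <- function(H, alpha) {
  Tt <- H$T
  D <- outer(Tt, Tt, "+") - 2 * H$M
  exp(-alpha * D) * (-expm1(-2 * alpha * H$M)) / (2 * alpha)
}

# per-tip regime weights: mean(y_i) = W %*% theta once z0 is tied to the
# root regime (the root term exp(-alpha T_i) loads on the root regime);
# each epoch (edge) on the root-to-tip path contributes
# exp(-alpha (T_i - t_end)) - exp(-alpha (T_i - t_start)) to its regime.
# single preorder pass: with B[v, r] the regime-r epoch weight measured at
# node v's own height, B[child] = B[parent] e^(-a dt) + (1 - e^(-a dt)) on
# the edge's regime (every term stays in [0, 1], stable for any alpha)
ou_mean_weights <- function(painting, alpha, H = NULL) {
  tree <- painting$tree
  if (is.null(H)) H <- phylo_heights(tree)
  nt <- length(tree$tip.label)
  reg <- painting$regimes
  B <- matrix(0, nt + tree$Nnode, length(reg))
  colnames(B) <- reg
  ord <- ape::reorder.phylo(tree, "postorder")
  ekey <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  for (i in rev(seq_len(nrow(ord$edge)))) {    # preorder
    p <- ord$edge[i, 1]; ch <- ord$edge[i, 2]
    decay <- exp(-alpha * (H$depth[ch] - H$depth[p]))
    B[ch, ] <- B[p, ] * decay
    r <- painting$edge_regimes[ekey[i]]
    B[ch, r] <- B[ch, r] + (1 - decay)
  }
  W <- B[seq_len(nt), , drop = FALSE]
  W[, painting$root_regime] <- W[, painting$root_regime] + exp(-alpha * H$T)
  rownames(W) <- tree$tip.label
  W
}

# log multivariate normal density via Cholesky
ldmvnorm <- function(y, mu, S) {
  R <- tryCatch(chol(S), error = function(e)
    stop("singular trait covariance (zero-length cherries?); ",
         "enforce a minimum branch length"))
  z <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# ---- likelihoods ------------------------------------------------------------

#' Brownian-motion log-likelihood
#'
#' Multivariate normal log-density of tip values with mean `z0` and
#' covariance `sigma2 * C`, where `C_ij` is the shared root-to-MRCA path
#' length.
#'
#' @param tree a `"phylo"`.
#' @param y named trait vector over the tips.
#' @param sigma2 diffusion rate (> 0).
#' @param z0 root value.
#' @return log-likelihood.
#' @export
bm_loglik <- function(tree, y, sigma2, z0) {
  stopifnot(sigma2 > 0)
  y <- y[tree$tip.label]
  if (anyNA(y)) stop("trait values missing for some tips")
  C <- ape::vcv.phylo(tree)
  ldmvnorm(as.numeric(y), rep(z0, length(y)), sigma2 * C)
}

#' Multi-regime Ornstein-Uhlenbeck (Hansen) log-likelihood
#'
#' Expected tip values follow the painted regime optima along each
#' root-to-tip path,
#' `E[y_i] = z0 e^(-alpha T_i) + sum_epochs theta_r (e^(-alpha(T_i - t_end)) - e^(-alpha(T_i - t_start)))`,
#' and `Cov(y_i, y_j) = sigma2/(2 alpha) e^(-alpha d_ij) (1 - e^(-2 alpha t_a))`
#' with `t_a` the root-to-MRCA height and `d_ij` the patristic distance
#' (valid for non-ultrametric trees). A single-regime painting gives the
#' single-optimum OU model.
#'
#' @param tree a `"phylo"`.
#' @param y named trait vector.
#' @param painting a `"regime_painting"` on `tree`.
#' @param alpha attraction strength (> 0; use [bm_loglik()] for the limit).
#' @param sigma2 diffusion rate (> 0).
#' @param theta named vector of optima, one per regime in the painting.
#' @param z0 root value; default ties it to the root regime's optimum.
#' @return log-likelihood.
#' @export
ou_loglik <- function(tree, y, painting, alpha, sigma2, theta, z0 = NULL) {
  if (alpha <= 0) stop("alpha must be > 0; use bm_loglik for the BM limit")
  stopifnot(sigma2 > 0)
  if (is.null(names(theta)) && length(theta) == length(painting$regimes))
    names(theta) <- painting$regimes
  if (!all(painting$regimes %in% names(theta)))
    stop("theta must cover every regime in the painting")
  y <- y[tree$tip.label]
  H <- phylo_heights(tree)
  W <- ou_mean_weights(painting, alpha, H)
  mu <- as.numeric(W %*% theta[painting$regimes])
  if (!is.null(z0)) {
    decay <- exp(-alpha * H$T)
    mu <- mu + decay * (z0 - theta[painting$root_regime])
  }
  V <- ou_vcv_unit(H, alpha)
  ldmvnorm(as.numeric(y), mu, sigma2 * V)
}

# ---- fitting ----------------------------------------------------------------

# profile lnL for mean design X and unit covariance V: GLS beta, ML sigma2
profile_gls <- function(y, X, V) {
  R <- chol(V)
  b <- backsolve(R, y, transpose = TRUE)
  A <- backsolve(R, X, transpose = TRUE)
  qa <- qr(A)
  beta <- qr.coef(qa, b)
  beta[is.na(beta)] <- 0                      # unidentified regime: no data on it
  r <- b - A %*% beta
  n <- length(y)
  rss <- sum(r^2)
  sigma2 <- rss / n
  lnL <- -0.5 * n * log(2 * pi) - 0.5 * n * log(sigma2) -
    sum(log(diag(R))) - 0.5 * n
  list(beta = as.numeric(beta), sigma2 = sigma2, lnL = lnL)
}

#' Fit an evolutionary model to a continuous trait by maximum likelihood
#'
#' Models: `"BM"` (random walk; k = 2), `"OU1"` (single optimum; k = 3),
#' `"OUM2"`/`"OUM4"` (Hansen models with regime optima painted on the tree;
#' k = 4/6). For OU models the optimisation is a bounded search over
#' log(alpha) on `alpha in [1e-9, 1e3] / tree height`, restarted on five
#' subintervals; at each alpha the optima (and the root value, tied to the
#' root regime) are profiled by GLS and sigma2 by its analytic ML value, so
#' no further numerical search is needed.
#'
#' @param tree a `"phylo"`.
#' @param y named trait vector over the tips.
#' @param model one of `"BM"`, `"OU1"`, `"OUM2"`, `"OUM4"`.
#' @param painting a `"regime_painting"`, required for `"OUM2"`/`"OUM4"`
#'   (with 2/4 regimes); ignored for `"BM"`, optional single-regime for
#'   `"OU1"`.
#' @return an `"ou_model_fit"` list: `model`, `alpha`, `sigma2`, `theta`
#'   (named optima; `NA` for BM), `z0`, `lnL`, `k`, `n`, `convergence`
#'   (including an alpha-at-bound flag).
#' @export
fit_trait_model <- function(tree, y, model = c("BM", "OU1", "OUM2", "OUM4"),
                            painting = NULL) {
  model <- match.arg(model)
  y <- y[tree$tip.label]
  if (anyNA(y)) stop("trait values missing for some tips")
  y <- as.numeric(y)
  n <- length(y)
  H <- phylo_heights(tree)
  if (model == "BM") {
    V <- H$M
    pr <- profile_gls(y, matrix(1, n, 1), V)
    return(structure(list(model = "BM", alpha = 0, sigma2 = pr$sigma2,
                          theta = NA_real_, z0 = pr$beta[1], lnL = pr$lnL,
                          k = 2L, n = n,
                          convergence = list(ok = TRUE, alpha_at_bound = FALSE)),
                     class = "ou_model_fit"))
  }
  if (model == "OU1") {
    if (is.null(painting)) painting <- single_regime_painting(tree)
    if (length(painting$regimes) != 1) stop("OU1 needs a single-regime painting")
  } else {
    need <- if (model == "OUM2") 2L else 4L
    if (is.null(painting)) stop(model, " requires a regime painting")
    if (length(painting$regimes) != need)
      stop(model, " needs exactly ", need, " regimes; painting has ",
           length(painting$regimes))
  }
  h <- max(H$T)
  lo <- log(1e-9 / h); hi <- log(1e3 / h)
  obj <- function(la) {
    a <- exp(la)
    W <- ou_mean_weights(painting, a, H)
    V <- ou_vcv_unit(H, a)
    -profile_gls(y, W, V)$lnL
  }
  cuts <- seq(lo, hi, length.out = 6)
  best <- NULL
  for (i in seq_len(5)) {
    o <- optimize(obj, c(cuts[i], cuts[i + 1]), tol = 1e-9)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  for (la in c(lo, hi)) {                      # guard the interval edges
    v <- obj(la)
    if (v < best$objective) best <- list(minimum = la, objective = v)
  }
  a <- exp(best$minimum)
  W <- ou_mean_weights(painting, a, H)
  V <- ou_vcv_unit(H, a)
  pr <- profile_gls(y, W, V)
  theta <- setNames(pr$beta, painting$regimes)
  at_bound <- best$minimum > hi - 1e-3
  if (at_bound) warning("alpha estimate at the upper search bound")
  structure(list(model = model, alpha = a, sigma2 = pr$sigma2, theta = theta,
                 z0 = unname(theta[painting$root_regime]), lnL = pr$lnL,
                 k = 2L + length(painting$regimes), n = n,
                 convergence = list(ok = is.finite(pr$lnL),
                                    alpha_at_bound = at_bound)),
            class = "ou_model_fit")
}

#' @export
print.ou_model_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): lnL = %.4f, k = %d\n", x$model, x$n, x$lnL, x$k))
  cat(sprintf("  alpha = %.4g, sigma2 = %.4g, z0 = %.4g\n",
              x$alpha, x$sigma2, x$z0))
  if (!all(is.na(x$theta)))
    cat("  theta:", paste(sprintf("%s = %.4g", names(x$theta), x$theta),
                          collapse = ", "), "\n")
  invisible(x)
}

# shared AICc machinery (also behind table1_check)
aicc_table <- function(lnL, k, n, models = names(lnL)) {
  if (is.null(models)) models <- paste0("model", seq_along(lnL))
  if (any(n - k - 1 <= 0))
    stop("AICc undefined: need n > k + 1 for every model")
  aicc <- -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2); w <- w / sum(w)
  data.frame(model = models, lnL = lnL, k = k, n = n, AICc = aicc,
             delta_AICc = delta, weight = w,
             best = delta == 0 & vapply(seq_along(delta), function(i)
               all(delta[-i] >= 2), TRUE),
             row.names = NULL)
}

#' AICc model-selection table
#'
#' Small-sample AIC (`AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`), differences to
#' the best model, and Akaike weights. The `best` flag marks a model at
#' delta = 0 that is two or more points below every other model (the
#' substantial-support convention of Burnham & Anderson).
#'
#' @param fits list of `"ou_model_fit"` objects on identical data.
#' @param n number of taxa; defaults to the common `n` of the fits.
#' @return data.frame with columns model, lnL, k, n, AICc, delta_AICc,
#'   weight, best.
#' @export
model_table <- function(fits, n = NULL) {
  ns <- vapply(fits, `[[`, 1, "n")
  if (length(unique(ns)) != 1) stop("fits computed on different n")
  if (is.null(n)) n <- ns[1]
  aicc_table(vapply(fits, `[[`, 1, "lnL"),
             vapply(fits, function(f) as.numeric(f$k), 1),
             n, models = vapply(fits, `[[`, "", "model"))
}
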