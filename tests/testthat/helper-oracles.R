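# Independent brute-force / closed-form oracles used across the suite.
# These deliberately avoid the package's own DP and pruning code paths.

# exhaustive parsimony: enumerate every assignment of states to internal
# nodes (and missing tips), score each by counting state changes on edges
brute_parsimony <- function(tree, states) {
  x <- states[tree$tip.label]
  obs <- sort(unique(x[x != "?"]))
  if (!length(obs)) obs <- "0"
  nt <- length(tree$tip.label)
  ntot <- nt + tree$Nnode
  free <- c(which(x == "?"), (nt + 1L):ntot)
  k <- length(obs)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  asn <- matrix(NA_integer_, nrow(grid), ntot)
  asn[, free] <- grid
  for (i in setdiff(seq_len(nt), free)) asn[, i] <- match(x[i], obs)
  cost <- rowSums(matrix(vapply(seq_len(nrow(tree$edge)), function(e)
    asn[, tree$edge[e, 1]] != asn[, tree$edge[e, 2]],
    logical(nrow(asn))), nrow = nrow(asn)))
  s <- min(cost)
  opt <- asn[cost == s, , drop = FALSE]
  unamb <- vapply(seq_len(nrow(tree$edge)), function(e)
    all(opt[, tree$edge[e, 1]] != opt[, tree$edge[e, 2]]), TRUE)
  list(steps = s, unambiguous = unamb, n_mpr = nrow(opt))
}

# random unordered character on a tree's tips
random_character <- function(tree, n_states = 2, p_missing = 0) {
  s <- sample(as.character(seq_len(n_states)), length(tree$tip.label),
              replace = TRUE)
  if (p_missing > 0) s[runif(length(s)) < p_missing] <- "?"
  stats::setNames(s, tree$tip.label)
}

# path epochs (t0, t1, regime) from the root for one tip
tip_epochs <- function(tree, painting, tip) {
  depth <- ape::node.depth.edgelength(tree)
  parent <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  eidx <- parent
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  eidx[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  node <- tip
  out <- NULL
  while (!is.na(parent[node])) {
    out <- rbind(data.frame(t0 = depth[parent[node]], t1 = depth[node],
                            regime = painting$edge_regimes[eidx[node]]), out)
    node <- parent[node]
  }
  out
}

# Hansen-model mean and covariance by numerical quadrature along paths,
# then the multivariate normal density assembled by hand
ou_oracle_loglik <- function(tree, y, painting, alpha, sigma2, theta, z0) {
  nt <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  Tt <- depth[seq_len(nt)]
  M <- ape::vcv.phylo(tree)
  mu <- numeric(nt)
  for (i in seq_len(nt)) {
    ep <- tip_epochs(tree, painting, i)
    m <- z0 * exp(-alpha * Tt[i])
    for (r in seq_len(nrow(ep))) {
      th <- theta[[ep$regime[r]]]
      if (ep$t1[r] > ep$t0[r])
        m <- m + stats::integrate(function(s)
          alpha * th * exp(-alpha * (Tt[i] - s)),
          ep$t0[r], ep$t1[r], rel.tol = 1e-12, abs.tol = 1e-14)$value
    }
    mu[i] <- m
  }
  S <- matrix(0, nt, nt)
  for (i in seq_len(nt)) for (j in i:nt) {
    ta <- M[i, j]
    v <- if (ta > 0)
      stats::integrate(function(s)
        sigma2 * exp(-alpha * (Tt[i] - s)) * exp(-alpha * (Tt[j] - s)),
        0, ta, rel.tol = 1e-12, abs.tol = 1e-14)$value
    else 0
    S[i, j] <- S[j, i] <- v
  }
  yv <- as.numeric(y[tree$tip.label])
  R <- chol(S)
  z <- backsolve(R, yv - mu, transpose = TRUE)
  -0.5 * nt * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# Mk likelihood and node marginals by explicit summation over all internal
# state assignments
mk_brute <- function(tree, states, q, state_set) {
  k <- length(state_set)
  nt <- length(tree$tip.label)
  ntot <- nt + tree$Nnode
  x <- match(states[tree$tip.label], state_set)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  asn <- cbind(matrix(x, nrow(grid), nt, byrow = TRUE), grid)
  ps <- function(t) 1 / k + (1 - 1 / k) * exp(-k * q * t)
  pd <- function(t) 1 / k - (1 / k) * exp(-k * q * t)
  pr <- rep(1 / k, nrow(asn))
  for (e in seq_len(nrow(tree$edge))) {
    same <- asn[, tree$edge[e, 1]] == asn[, tree$edge[e, 2]]
    t_ <- tree$edge.length[e]
    pr <- pr * ifelse(same, ps(t_), pd(t_))
  }
  marg <- t(vapply((nt + 1L):ntot, function(v)
    vapply(seq_len(k), function(s) sum(pr[asn[, v] == s]), 1), numeric(k)))
  marg <- marg / rowSums(marg)
  dimnames(marg) <- list(paste0("node", (nt + 1L):ntot), state_set)
  list(lnL = log(sum(pr)), marginals = marg)
}

# GLS slope of y on x with intercept under BM tip covariance
gls_slope_bm <- function(tree, x, y) {
  C <- ape::vcv.phylo(tree)
  Ci <- solve(C)
  X <- cbind(1, as.numeric(x[tree$tip.label]))
  b <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% as.numeric(y[tree$tip.label]))
  b[2]
}

# deterministic two-regime painting by basal split (larger clade = "S")
basal_split_painting <- function(tree) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  lab <- rep("S", nt + tree$Nnode)
  sizes <- vapply(kids, function(kk)
    if (kk <= nt) 1L else length(unlist(phangorn::Descendants(tree, kk, "tips"))),
    1L)
  small <- kids[-which.max(sizes)]
  for (kk in small) {
    below <- kk
    if (kk > nt) below <- c(below, unlist(phangorn::Descendants(tree, kk, "all")))
    lab[below] <- "N"
  }
  regime_painting(tree, lab[tree$edge[, 2]], regimes = c("N", "S"),
                  root_regime = "S")
}

# small helper: build a character_matrix from a named state vector
one_char_matrix <- function(states, name = "c1") {
  character_matrix(matrix(states, ncol = 1,
                          dimnames = list(names(states), name)))
}
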