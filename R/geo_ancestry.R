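# Equal-rates Mk maximum likelihood for discrete geographic states:
# pruning likelihood, 1-D ML of the transition rate, marginal ancestral
# probabilities at every node, and the bridge to OU regime paintings.
#
# Under the equal-rates model with k states and rate q per state pair,
# P(same, t) = 1/k + (1 - 1/k) e^(-k q t) and
# P(diff, t) = 1/k - (1/k) e^(-k q t); the root prior is flat (1/k).

mk_p_same <- function(q, t, k) 1 / k + (1 - 1 / k) * exp(-k * q * t)
mk_p_diff <- function(q, t, k) 1 / k - (1 / k) * exp(-k * q * t)

# downpass conditional likelihoods, scaled per node; returns matrix
# ((ntip+nnode) x k), per-node log scaling factors, and the total lnL
mk_down <- function(tree, sets, q) {
  nt <- nrow(sets); k <- ncol(sets)
  ntot <- nt + tree$Nnode
  D <- matrix(1, ntot, k)
  D[seq_len(nt), ] <- ifelse(sets, 1, 0)
  logscale <- numeric(ntot)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    t_ <- ord$edge.length[e]
    ps <- mk_p_same(q, t_, k); pd <- mk_p_diff(q, t_, k)
    contrib <- pd * sum(D[ch, ]) + (ps - pd) * D[ch, ]
    D[p, ] <- D[p, ] * contrib
    logscale[p] <- logscale[p] + logscale[ch]
    m <- max(D[p, ])
    if (m > 0 && (m < 1e-100 || m > 1e100)) {
      D[p, ] <- D[p, ] / m
      logscale[p] <- logscale[p] + log(m)
    }
  }
  root <- nt + 1L
  lnL <- log(sum(D[root, ] / k)) + logscale[root]
  list(D = D, logscale = logscale, lnL = lnL, root = root, k = k)
}

mk_tip_sets <- function(tree, states, state_set = NULL) {
  x <- states[tree$tip.label]
  if (anyNA(x))
    stop("tip(s) without a state: ",
         paste(setdiff(tree$tip.label, names(states)), collapse = ", "))
  if (is.null(state_set)) state_set <- sort(unique(x[x != MISSING_TOKEN]))
  if (!all(x[x != MISSING_TOKEN] %in% state_set))
    stop("unknown tip state(s): ",
         paste(setdiff(x, c(state_set, MISSING_TOKEN)), collapse = ", "))
  sets <- matrix(FALSE, length(x), length(state_set),
                 dimnames = list(tree$tip.label, state_set))
  for (i in seq_along(x)) {
    if (x[i] == MISSING_TOKEN) sets[i, ] <- TRUE else sets[i, x[i]] <- TRUE
  }
  sets
}

#' Equal-rates Mk log-likelihood
#'
#' Felsenstein pruning with the closed-form equal-rates transition
#' probabilities and a flat root prior.
#'
#' @param tree a `"phylo"`.
#' @param states named character vector of tip states.
#' @param q transition rate per state pair (> 0), per unit branch length.
#' @param state_set optional state alphabet (defaults to observed states);
#'   its size is the Mk `k`.
#' @return log-likelihood.
#' @export
mk_loglik <- function(tree, states, q, state_set = NULL) {
  stopifnot(q > 0)
  sets <- mk_tip_sets(tree, states, state_set)
  mk_down(tree, sets, q)$lnL
}

#' Maximum-likelihood fit of the equal-rates Mk model
#'
#' Bounded 1-D search over log(q). Monomorphic tip states leave q
#' unidentifiable; the fit is then flagged degenerate with q at the lower
#' search bound.
#'
#' @inheritParams mk_loglik
#' @return an `"mk_fit"` list: `q`, `lnL`, `k`, `state_set`, `degenerate`,
#'   plus the tree and tip states for downstream marginal reconstruction.
#' @export
fit_mk <- function(tree, states, state_set = NULL) {
  sets <- mk_tip_sets(tree, states, state_set)
  k <- ncol(sets)
  h <- max(ape::node.depth.edgelength(tree))
  lo <- log(1e-8 / h); hi <- log(1e3 / h)
  monomorphic <- length(unique(states[tree$tip.label][
    states[tree$tip.label] != MISSING_TOKEN])) < 2
  if (monomorphic) {
    q <- exp(lo)
    return(structure(list(tree = tree, states = states, state_set = colnames(sets),
                          k = k, q = q, lnL = mk_down(tree, sets, q)$lnL,
                          degenerate = TRUE),
                     class = "mk_fit"))
  }
  obj <- function(lq) -mk_down(tree, sets, exp(lq))$lnL
  cuts <- seq(lo, hi, length.out = 6)
  best <- NULL
  for (i in seq_len(5)) {
    o <- optimize(obj, c(cuts[i], cuts[i + 1]), tol = 1e-10)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  q <- exp(best$minimum)
  structure(list(tree = tree, states = states, state_set = colnames(sets),
                 k = k, q = q, lnL = -best$objective, degenerate = FALSE),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk fit: %d states, q = %.4g, lnL = %.4f%s\n", x$k, x$q, x$lnL,
              if (x$degenerate) " (degenerate: monomorphic tips)" else ""))
  invisible(x)
}

#' Marginal ancestral state probabilities at every node
#'
#' Inside-outside computation at the fitted rate: the marginal probability
#' of each state at each internal node given all tip states (equivalent to
#' re-rooting at each node under the reversible equal-rates model). The
#' root row is the headline "ancestral point of radiation" probability
#' vector.
#'
#' @param fit an `"mk_fit"`.
#' @return matrix (internal nodes x states) of probabilities summing to one
#'   per row, rownames `node<id>`, with attribute `root` (the root node's
#'   row).
#' @export
marginal_ancestral <- function(fit) {
  tree <- fit$tree
  sets <- mk_tip_sets(tree, fit$states, fit$state_set)
  k <- ncol(sets); q <- fit$q
  dn <- mk_down(tree, sets, q)
  nt <- nrow(sets); ntot <- nt + tree$Nnode
  up <- matrix(0, ntot, k)
  up[dn$root, ] <- 1 / k
  ord <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(ord$edge)))
  for (i in pre) {
    p <- ord$edge[i, 1]; ch <- ord$edge[i, 2]
    t_ <- ord$edge.length[i]
    ps <- mk_p_same(q, t_, k); pd <- mk_p_diff(q, t_, k)
    contrib <- pd * sum(dn$D[ch, ]) + (ps - pd) * dn$D[ch, ]
    g <- up[p, ] * dn$D[p, ] / contrib       # parent term excluding this child
    u <- pd * sum(g) + (ps - pd) * g
    up[ch, ] <- u / sum(u)
  }
  marg <- up * dn$D
  marg <- marg / rowSums(marg)
  internal <- (nt + 1L):ntot
  m <- marg[internal, , drop = FALSE]
  dimnames(m) <- list(paste0("node", internal), colnames(sets))
  attr(m, "root") <- m[1, ]
  m
}

#' Regime painting from marginal ancestral states
#'
#' Labels every branch with its child node's most probable state (observed
#' states at tips); ties are broken toward the parent's label, then
#' lexicographically. The root regime is the root's most probable state.
#'
#' @param fit an `"mk_fit"`.
#' @param marginals optional precomputed [marginal_ancestral()] matrix.
#' @return a `"regime_painting"`.
#' @export
painting_from_marginals <- function(fit, marginals = NULL) {
  tree <- fit$tree
  if (is.null(marginals)) marginals <- marginal_ancestral(fit)
  nt <- length(tree$tip.label)
  ntot <- nt + tree$Nnode
  states <- fit$state_set
  lab <- character(ntot)
  parent <- rep(NA_integer_, ntot)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  pick <- function(pvec, parent_lab) {
    top <- which(pvec >= max(pvec) - 1e-12)
    cand <- states[top]
    if (!is.na(parent_lab) && parent_lab %in% cand) return(parent_lab)
    sort(cand)[1]
  }
  root <- nt + 1L
  lab[root] <- pick(marginals[paste0("node", root), ], NA)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(ord$edge)))) {      # preorder
    ch <- ord$edge[i, 2]
    if (ch <= nt) {
      s <- fit$states[tree$tip.label[ch]]
      lab[ch] <- if (s == MISSING_TOKEN) lab[ord$edge[i, 1]] else s
    } else {
      lab[ch] <- pick(marginals[paste0("node", ch), ], lab[ord$edge[i, 1]])
    }
  }
  regime_painting(tree, lab[tree$edge[, 2]], regimes = states,
                  root_regime = lab[root])
}
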