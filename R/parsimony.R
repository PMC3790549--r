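# Unordered (Fitch/Sankoff) parsimony with exact MPR handling.
#
# All characters are unordered and unit cost. Polytomies are treated as hard
# (the Sankoff recursion runs over all children). A missing cell ("?") is
# treated as the full state set, i.e. the tip's state is free to vary across
# most-parsimonious reconstructions.

# tip state sets as a (tips x states) logical matrix over the character's
# working alphabet (observed states; missing tips allow everything)
tip_state_sets <- function(tree, states) {
  if (!all(tree$tip.label %in% names(states)))
    stop("tip(s) absent from character column: ",
         paste(setdiff(tree$tip.label, names(states)), collapse = ", "))
  x <- states[tree$tip.label]
  obs <- sort(unique(x[x != MISSING_TOKEN & !is.na(x)]))
  if (!length(obs)) obs <- "0"   # fully missing character: any single state
  sets <- matrix(FALSE, length(x), length(obs),
                 dimnames = list(tree$tip.label, obs))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || x[i] == MISSING_TOKEN) sets[i, ] <- TRUE
    else sets[i, x[i]] <- TRUE
  }
  sets
}

# Sankoff downpass. Returns node cost matrix ((Ntip+Nnode) x k), the working
# alphabet, and per-edge child transfer costs W[e, a] = min_b(cost[c,b] + a!=b).
sankoff_down <- function(tree, sets) {
  nt <- length(tree$tip.label); nn <- tree$Nnode; k <- ncol(sets)
  ord <- ape::reorder.phylo(tree, "postorder")
  cost <- matrix(0, nt + nn, k)
  cost[seq_len(nt), ] <- ifelse(sets, 0, Inf)
  W <- matrix(NA_real_, nrow(ord$edge), k)
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    v <- cost[ch, ]
    w <- pmin(v, min(v) + 1)
    W[e, ] <- w
    cost[p, ] <- cost[p, ] + w
  }
  # map W rows back to the tree's own edge order
  key <- paste(ord$edge[, 1], ord$edge[, 2])
  W <- W[match(paste(tree$edge[, 1], tree$edge[, 2]), key), , drop = FALSE]
  list(cost = cost, alphabet = colnames(sets), W = W,
       root = nt + 1L, ntip = nt)
}

#' Minimum number of unordered-parsimony steps for one character
#'
#' Sankoff dynamic programme with unit off-diagonal costs, which equals the
#' Fitch count on binary trees and generalises it to polytomies. Missing
#' tips (`"?"`) contribute the full state set.
#'
#' @param tree a `"phylo"`.
#' @param states named character vector of tip states (names = tip labels).
#' @return integer minimum step count.
#' @export
fitch_steps <- function(tree, states) {
  sk <- sankoff_down(tree, tip_state_sets(tree, states))
  as.integer(min(sk$cost[sk$root, ]))
}

#' Enumerate all most-parsimonious reconstructions of one character
#'
#' Exact backtracking over the Sankoff tableau: every assignment of states to
#' internal nodes (and to missing tips) whose total cost equals the minimum
#' step count is produced. This is the oracle definition behind
#' "unambiguous" change counting; a guard caps the enumeration size.
#'
#' @inheritParams fitch_steps
#' @param cap maximum number of reconstructions to enumerate before erroring.
#' @return character matrix, one row per MPR, one column per node
#'   (tips then internal nodes, in ape node order), entries are states.
#' @export
enumerate_mprs <- function(tree, states, cap = 100000L) {
  sets <- tip_state_sets(tree, states)
  sk <- sankoff_down(tree, sets)
  k <- length(sk$alphabet)
  nt <- sk$ntip; ntot <- nt + tree$Nnode
  s <- min(sk$cost[sk$root, ])
  # preorder edge list
  ord <- ape::reorder.phylo(tree, "postorder")
  pre <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  Wkey <- match(paste(pre[, 1], pre[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  root_states <- which(sk$cost[sk$root, ] == s)
  asn <- matrix(NA_integer_, length(root_states), ntot)
  asn[, sk$root] <- root_states
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1]; ch <- pre[i, 2]
    need <- sk$W[Wkey[i], ]                      # W_c(a)
    out <- vector("list", nrow(asn))
    for (r in seq_len(nrow(asn))) {
      a <- asn[r, p]
      allowed <- which(sk$cost[ch, ] + (seq_len(k) != a) == need[a])
      rows <- matrix(rep(asn[r, ], length(allowed)), nrow = length(allowed),
                     byrow = TRUE)
      rows[, ch] <- allowed
      out[[r]] <- rows
    }
    asn <- do.call(rbind, out)
    if (nrow(asn) > cap)
      stop("MPR enumeration exceeds cap (", cap, "); raise `cap` if intended")
  }
  m <- matrix(sk$alphabet[asn], nrow(asn), ntot)
  colnames(m) <- c(tree$tip.label, paste0("node", (nt + 1L):ntot))
  m
}

# per-edge unambiguous-change indicator for one character via inside-outside
# DP: a change on edge (p,c) is in every MPR iff no minimum-cost assignment
# gives p and c the same state.
unambiguous_edges_dp <- function(tree, states) {
  sets <- tip_state_sets(tree, states)
  sk <- sankoff_down(tree, sets)
  k <- length(sk$alphabet)
  nt <- sk$ntip
  s <- min(sk$cost[sk$root, ])
  ne <- nrow(tree$edge)
  # outside costs per node (cost of the rest of the tree given node state)
  out <- matrix(NA_real_, nt + tree$Nnode, k)
  out[sk$root, ] <- 0
  ord <- ape::reorder.phylo(tree, "postorder")
  pre_idx <- rev(seq_len(nrow(ord$edge)))
  Wkey <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  # sum of child transfer costs per parent, in tree edge indexing
  sumW <- matrix(0, nt + tree$Nnode, k)
  for (e in seq_len(ne))
    sumW[tree$edge[e, 1], ] <- sumW[tree$edge[e, 1], ] + sk$W[e, ]
  unamb <- logical(ne)
  for (i in pre_idx) {
    e <- Wkey[i]
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    base <- out[p, ] + sumW[p, ] - sk$W[e, ]     # everything except c's subtree
    out[ch, ] <- pmin(base, min(base) + 1)
    best_same <- min(base + sk$cost[ch, ])       # best cost with p == c
    unamb[e] <- best_same > s + 1e-9
  }
  list(unambiguous = unamb, steps = as.integer(s))
}

#' Per-branch unambiguous character changes
#'
#' For every branch and character, a change is counted iff the parent and
#' child states differ in every most-parsimonious reconstruction of that
#' character ("unequivocal" changes; ambiguous cases, where the change can
#' float between branches, are ignored). Per-branch totals are sums over
#' characters; these are the numbers conventionally printed above branches
#' on the tree.
#'
#' @param tree a `"phylo"`.
#' @param matrix a `"character_matrix"` (or plain matrix) of tip states.
#' @param method `"dp"` (inside-outside dynamic programme, exact) or
#'   `"enumeration"` (explicit intersection over all enumerated MPRs; the
#'   oracle definition, exponential worst case).
#' @param cap enumeration guard passed to [enumerate_mprs()].
#' @return a `"parsimony_result"` list: per-character `steps` (s), `min_steps`
#'   (m, observed states minus one), `max_steps` (g, scored taxa minus modal
#'   state frequency), 0/1 `branch_changes` (edges x characters),
#'   `branch_totals` named by child node, and `total_changes`.
#' @export
unambiguous_changes <- function(tree, matrix, method = c("dp", "enumeration"),
                                cap = 100000L) {
  method <- match.arg(method)
  matrix <- as.matrix(matrix)
  if (!all(tree$tip.label %in% rownames(matrix)))
    stop("matrix lacks tree tip(s): ",
         paste(setdiff(tree$tip.label, rownames(matrix)), collapse = ", "))
  ne <- nrow(tree$edge)
  nc <- ncol(matrix)
  chg <- matrix(0L, ne, nc, dimnames = list(NULL, colnames(matrix)))
  steps <- integer(nc); m <- integer(nc); g <- integer(nc)
  for (j in seq_len(nc)) {
    col <- setNames(matrix[, j], rownames(matrix))
    obs <- col[names(col) %in% tree$tip.label]
    scored <- obs[obs != MISSING_TOKEN & !is.na(obs)]
    m[j] <- max(0L, length(unique(scored)) - 1L)
    g[j] <- if (length(scored)) length(scored) - max(table(scored)) else 0L
    if (method == "dp") {
      r <- unambiguous_edges_dp(tree, col)
      steps[j] <- r$steps
      chg[, j] <- as.integer(r$unambiguous)
    } else {
      mprs <- enumerate_mprs(tree, col, cap = cap)
      steps[j] <- fitch_steps(tree, col)
      for (e in seq_len(ne)) {
        ps <- mprs[, tree$edge[e, 1]]
        cs <- mprs[, tree$edge[e, 2]]
        chg[e, j] <- as.integer(all(ps != cs))
      }
    }
  }
  nt <- length(tree$tip.label)
  branch_id <- ifelse(tree$edge[, 2] <= nt, tree$tip.label[tree$edge[, 2]],
                      paste0("node", tree$edge[, 2]))
  totals <- setNames(rowSums(chg), branch_id)
  structure(list(tree = tree, steps = setNames(steps, colnames(matrix)),
                 min_steps = setNames(m, colnames(matrix)),
                 max_steps = setNames(g, colnames(matrix)),
                 branch_changes = chg, branch_totals = totals,
                 total_changes = sum(chg), method = method),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("parsimony reconstruction: %d characters, %d branches\n",
              length(x$steps), length(x$branch_totals)))
  cat(sprintf("  total steps %d, total unambiguous changes %d\n",
              sum(x$steps), x$total_changes))
  cat(sprintf("  ensemble CI %.3f, RI %s\n", consistency_index(x),
              tryCatch(sprintf("%.3f", retention_index(x)),
                       error = function(e) "undefined")))
  invisible(x)
}

#' Ensemble consistency index
#'
#' CI = sum(m_i) / sum(s_i) over variable characters (characters with zero
#' steps are excluded from both sums); 1 means no homoplasy.
#'
#' @param result a `"parsimony_result"`.
#' @return CI in (0, 1].
#' @export
consistency_index <- function(result) {
  keep <- result$steps > 0
  if (!any(keep)) stop("all characters invariant on the tree: CI undefined")
  sum(result$min_steps[keep]) / sum(result$steps[keep])
}

#' Ensemble retention index
#'
#' RI = (sum(g_i) - sum(s_i)) / (sum(g_i) - sum(m_i)) over variable
#' characters; 1 means all similarity is retained synapomorphy, 0 means the
#' characters fit the tree no better than the worst case.
#'
#' @param result a `"parsimony_result"`.
#' @return RI in [0, 1].
#' @export
retention_index <- function(result) {
  keep <- result$steps > 0
  G <- sum(result$max_steps[keep]); M <- sum(result$min_steps[keep])
  S <- sum(result$steps[keep])
  if (!any(keep) || G <= M)
    stop("retention index undefined (sum g must exceed sum m)")
  (G - S) / (G - M)
}

#' Per-branch change table for both sexes
#'
#' Runs [unambiguous_changes()] on the male and female matrices through the
#' identical code path and tabulates per-branch counts side by side, the
#' layout used to annotate the tree.
#'
#' @param tree a `"phylo"`.
#' @param male,female character matrices.
#' @param ... passed to [unambiguous_changes()].
#' @return list with `table` (data.frame branch, male, female), the two
#'   `"parsimony_result"` objects, and an annotated newick string with
#'   "male/female" branch labels.
#' @export
branch_change_table <- function(tree, male, female, ...) {
  rm_ <- unambiguous_changes(tree, male, ...)
  rf_ <- unambiguous_changes(tree, female, ...)
  tab <- data.frame(branch = names(rm_$branch_totals),
                    male = as.integer(rm_$branch_totals),
                    female = as.integer(rf_$branch_totals))
  ann <- tree
  lab <- sprintf("%d/%d", tab$male, tab$female)
  nt <- length(tree$tip.label)
  node_lab <- rep("", tree$Nnode)
  int <- tree$edge[, 2] > nt
  node_lab[tree$edge[int, 2] - nt] <- lab[int]
  ann$node.label <- node_lab
  list(table = tab, male = rm_, female = rf_,
       annotated_newick = ape::write.tree(ann))
}
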