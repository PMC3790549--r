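# Synthetic study fixtures: pure-birth trees, Mk-evolved sex-specific
# plumage matrices, regime paintings, OU/BM continuous traits, Jukes-Cantor
# sequences, and latitude metadata with the statistical structure the
# analysis assumes. All randomness flows from one master seed through named
# substreams so each component regenerates independently and bundles are
# byte-identical under (spec, seed).

#' Fixture specification
#'
#' Defaults emulate the study design: 22 taxa, 25 six-state colour patches
#' plus 5 presence/absence traits, a two-region geography (southern/arid vs
#' northern/tropical) evolving on the tree as a dispersal process and
#' refined by a second environmental axis into four interleaved radiations,
#' a seven-locus alignment, latitudes in degrees south tracking region, and
#' a female plumage process whose regime-dependent state biases make female
#' ordination scores track geography while male characters evolve steadily.
#'
#' @param seed master seed (mandatory).
#' @param n_taxa,birth_rate tips and pure-birth rate of the simulated tree.
#' @param n_color,n_pa numbers of colour-patch and presence/absence
#'   characters; `color_alphabet`/`pa_alphabet` their state sets.
#' @param male_rate equal-rates Mk rate per state pair for male characters
#'   (per unit branch length); also the female baseline.
#' @param dispersal_rate rate of the 2-state geographic dispersal process
#'   painted on the tree (transitions per unit branch length; the default
#'   yields a handful of region changes, as repeated land-bridge crossings
#'   would).
#' @param female_noise per-cell probability that a female state deviates
#'   from the male state irrespective of regime (baseline dichromatism).
#' @param female_bias per-cell probability that, in the southern regime, a
#'   female state is replaced by that character's regime target state (the
#'   dichromatism/regime effect size).
#' @param seq_lengths named locus lengths for the alignment; `seq_rate`
#'   Jukes-Cantor substitution rate (expected substitutions per site per
#'   unit branch length).
#' @param lat latitude model: regime means (degrees south), s.d. of range
#'   midpoints, and uniform range-width limits.
#' @param ou_male,ou_female parameters of the auxiliary continuous traits
#'   attached to the bundle (male: Brownian motion; female: two-optimum OU
#'   tracking the basal regimes).
#' @return list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed,
                         n_taxa = 22L, birth_rate = 1,
                         n_color = 25L, n_pa = 5L,
                         color_alphabet = c("C", "B", "N", "D", "L", "W"),
                         pa_alphabet = c("P", "A"),
                         male_rate = 0.015,
                         dispersal_rate = 0.5,
                         female_noise = 0.05,
                         female_bias = 0.6,
                         seq_lengths = c(ND2 = 1041, ND3 = 351, CO1 = 651,
                                         ATP6 = 684, FIB5 = 550, LDH = 500,
                                         GAPDH = 450),
                         seq_rate = 0.02,
                         lat = list(north_mean = 5, south_mean = 30, sd = 2.5,
                                    width_min = 4, width_max = 12),
                         ou_male = list(alpha = 0, sigma2 = 1),
                         ou_female = list(alpha = 2, sigma2 = 1,
                                          theta = c(Australia = 5, NewGuinea = 0))) {
  if (missing(seed)) stop("fixture_spec requires a seed")
  stopifnot(n_taxa >= 3, birth_rate > 0, male_rate > 0, seq_rate > 0,
            female_noise >= 0, female_noise <= 1,
            female_bias >= 0, female_bias <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

# derive named substream seeds from the master seed
substreams <- function(seed) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 7),
           c("tree", "regimes", "chars", "female", "seqs", "latitude", "traits"))
}

#' Simulate a pure-birth (Yule) tree
#'
#' Exponential waiting times between birth events, conditioned on the tip
#' count; the resulting tree is ultrametric.
#'
#' @param n number of tips (>= 3).
#' @param birth_rate birth rate per lineage.
#' @param seed RNG seed.
#' @return an ultrametric `"phylo"` with tips `t1..tn`.
#' @export
simulate_tree <- function(n, birth_rate = 1, seed) {
  stopifnot(n >= 3)
  set.seed(seed)
  tr <- ape::rphylo(n, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

#' Simulate discrete characters under the equal-rates Mk model
#'
#' Each character evolves independently from a uniformly drawn root state;
#' along a branch of length t the state is retained with probability
#' `1/k + (1 - 1/k) exp(-k q t)` and otherwise replaced uniformly by one of
#' the other states.
#'
#' @param tree a `"phylo"`.
#' @param n_chars number of characters.
#' @param alphabet state alphabet (k = its length).
#' @param rate Mk rate q per state pair.
#' @param seed RNG seed.
#' @param prefix character-name prefix.
#' @return a `"character_matrix"` (tips x characters).
#' @export
simulate_mk_characters <- function(tree, n_chars, alphabet, rate, seed,
                                   prefix = "char") {
  stopifnot(rate > 0)
  set.seed(seed)
  k <- length(alphabet)
  nt <- length(tree$tip.label)
  ntot <- nt + tree$Nnode
  st <- matrix(NA_integer_, ntot, n_chars)
  st[nt + 1L, ] <- sample.int(k, n_chars, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(ord$edge)))) {    # preorder
    p <- ord$edge[i, 1]; ch <- ord$edge[i, 2]
    psame <- 1 / k + (1 - 1 / k) * exp(-k * rate * ord$edge.length[i])
    stay <- runif(n_chars) < psame
    new <- st[p, ]
    nc <- sum(!stay)
    if (nc) {
      shift <- sample.int(k - 1L, nc, replace = TRUE)
      new[!stay] <- ((st[p, !stay] - 1L + shift) %% k) + 1L
    }
    st[ch, ] <- new
  }
  m <- matrix(alphabet[st[seq_len(nt), ]], nt, n_chars,
              dimnames = list(tree$tip.label,
                              sprintf("%s%02d", prefix, seq_len(n_chars))))
  character_matrix(m, alphabets = alphabet)
}

#' Simulate a continuous trait under multi-regime OU (or BM)
#'
#' Preorder recursion: along a branch of length t painted with regime r,
#' `child ~ Normal(parent e^(-alpha t) + theta_r (1 - e^(-alpha t)),
#' sigma2 (1 - e^(-2 alpha t)) / (2 alpha))`; with `alpha = 0` the Brownian
#' recursion `child ~ Normal(parent, sigma2 t)` is used and `theta` is
#' ignored.
#'
#' @param tree a `"phylo"`.
#' @param painting a `"regime_painting"` (ignored when `alpha = 0`).
#' @param alpha attraction strength (>= 0).
#' @param sigma2 diffusion rate.
#' @param theta named optima per regime.
#' @param z0 root value; defaults to the root regime's optimum (0 for BM).
#' @param seed RNG seed.
#' @return named trait vector over the tips.
#' @export
simulate_ou_trait <- function(tree, painting = NULL, alpha, sigma2, theta = NULL,
                              z0 = NULL, seed) {
  stopifnot(alpha >= 0, sigma2 > 0)
  set.seed(seed)
  nt <- length(tree$tip.label)
  val <- numeric(nt + tree$Nnode)
  if (is.null(z0))
    z0 <- if (alpha > 0) unname(theta[painting$root_regime]) else 0
  val[nt + 1L] <- z0
  ord <- ape::reorder.phylo(tree, "postorder")
  ekey <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  for (i in rev(seq_len(nrow(ord$edge)))) {
    p <- ord$edge[i, 1]; ch <- ord$edge[i, 2]
    t_ <- ord$edge.length[i]
    if (alpha > 0) {
      th <- theta[painting$edge_regimes[ekey[i]]]
      m <- val[p] * exp(-alpha * t_) + th * (1 - exp(-alpha * t_))
      v <- sigma2 * (-expm1(-2 * alpha * t_)) / (2 * alpha)
    } else {
      m <- val[p]; v <- sigma2 * t_
    }
    val[ch] <- rnorm(1, m, sqrt(v))
  }
  setNames(val[seq_len(nt)], tree$tip.label)
}

#' Simulate a partitioned alignment under Jukes-Cantor
#'
#' All loci share the tree and rate; the expected p-distance between tips
#' at patristic distance d is `(3/4)(1 - exp(-4 r d / 3))`.
#'
#' @param tree a `"phylo"`.
#' @param lengths named vector of locus lengths.
#' @param rate substitutions per site per unit branch length.
#' @param seed RNG seed.
#' @return a `"dna_alignment"` with one partition per locus.
#' @export
simulate_sequences <- function(tree, lengths, rate, seed) {
  stopifnot(all(lengths >= 1), rate > 0)
  set.seed(seed)
  total <- sum(lengths)
  sim <- phangorn::simSeq(tree, l = total, type = "DNA", rate = rate)
  mat <- toupper(as.character(sim))
  rownames(mat) <- names(sim)
  ends <- as.integer(cumsum(lengths))
  parts <- data.frame(gene = names(lengths),
                      start = c(1L, head(ends, -1) + 1L), end = ends)
  dna_alignment(mat[tree$tip.label, , drop = FALSE], parts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evolve a single 2-state geographic character down the tree from a fixed
# root state, returning the state of every node (tips + internal)
simulate_dispersal <- function(tree, rate, seed,
                               states = c("Australia", "NewGuinea"),
                               root_state = states[1]) {
  set.seed(seed)
  k <- length(states)
  nt <- length(tree$tip.label)
  st <- integer(nt + tree$Nnode)
  st[nt + 1L] <- match(root_state, states)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(ord$edge)))) {
    p <- ord$edge[i, 1]; ch <- ord$edge[i, 2]
    psame <- 1 / k + (1 - 1 / k) * exp(-k * rate * ord$edge.length[i])
    st[ch] <- if (runif(1) < psame) st[p]
              else ((st[p] - 1L + sample.int(k - 1L, 1)) %% k) + 1L
  }
  setNames(states[st], c(tree$tip.label, paste0("node", nt + seq_len(tree$Nnode))))
}

# painting from per-node regime labels: each edge takes its child's label
painting_from_node_states <- function(tree, node_states, regimes = NULL,
                                      root_regime = NULL) {
  nt <- length(tree$tip.label)
  regime_painting(tree, node_states[tree$edge[, 2]],
                  regimes = regimes %||% sort(unique(node_states)),
                  root_regime = root_regime %||% node_states[nt + 1L])
}

#' Build a complete synthetic study bundle
#'
#' Assembles tree, regime assignments (basal split for two regimes, refined
#' at the oldest divergences for four), male and female character matrices,
#' a partitioned alignment, latitudes drawn per regime, and auxiliary
#' continuous traits. The female matrix is the male matrix perturbed by
#' baseline noise everywhere plus a per-character regime target state
#' applied with probability `female_bias` in the southern regime, so
#' dichromatism increases southward and female ordination scores track the
#' basal regimes by construction.
#'
#' @param spec a `"fixture_spec"`.
#' @return a `"study_bundle"` whose extra elements `painting2`,
#'   `painting4` (the generating paintings), `traits` (auxiliary continuous
#'   traits), and `spec` support testing.
#' @export
make_study_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  ss <- substreams(spec$seed)
  tree <- simulate_tree(spec$n_taxa, spec$birth_rate, ss["tree"])
  nt <- length(tree$tip.label)

  # geography evolves as a 2-state dispersal process from an Australian
  # root, giving interleaved regimes (repeated movements between regions);
  # a second, independent binary axis (habitat era) refines it into four
  # interleaved radiations. Redraw with perturbed substreams until both
  # regions hold enough taxa and all four radiations are represented.
  node_r2 <- node_hab <- NULL
  for (try in 0:49) {
    s1 <- (ss["regimes"] %% 1000000000L) + try * 2000003L
    cand <- simulate_dispersal(tree, spec$dispersal_rate, s1)
    hab <- simulate_dispersal(tree, spec$dispersal_rate, s1 + 1000001L,
                              states = c("a", "b"), root_state = "a")
    tip_r2 <- cand[seq_len(nt)]
    combos <- table(factor(tip_r2, c("Australia", "NewGuinea")),
                    factor(hab[seq_len(nt)], c("a", "b")))
    if (min(rowSums(combos)) >= 5 && all(combos >= 1)) {
      node_r2 <- cand; node_hab <- hab
      break
    }
  }
  if (is.null(node_r2))
    stop("could not draw a dispersal history with all radiations represented; ",
         "check dispersal_rate")
  regime2 <- node_r2[seq_len(nt)]
  painting2 <- painting_from_node_states(tree, node_r2,
                                         regimes = c("Australia", "NewGuinea"),
                                         root_regime = "Australia")

  # four radiations = region crossed with the habitat axis
  node_r4 <- setNames(paste0(node_r2, node_hab), names(node_r2))
  regime4 <- node_r4[seq_len(nt)]
  painting4 <- painting_from_node_states(tree, node_r4)

  # male characters: steady Mk evolution
  male_col <- simulate_mk_characters(tree, spec$n_color, spec$color_alphabet,
                                     spec$male_rate, ss["chars"], prefix = "patch")
  male_pa <- simulate_mk_characters(tree, spec$n_pa, spec$pa_alphabet,
                                    spec$male_rate, ss["chars"] %% 2147483646L + 1L,
                                    prefix = "trait")
  male <- character_matrix(cbind(unclass(male_col), unclass(male_pa)),
                           alphabets = c(attr(male_col, "alphabets"),
                                         attr(male_pa, "alphabets")))

  # female characters: male states + baseline noise + southern regime bias
  set.seed(ss["female"])
  fem <- unclass(male)
  alphs <- attr(male, "alphabets")
  south <- regime2[rownames(fem)] == "Australia"
  targets <- vapply(alphs, function(a) sample(a, 1), "")
  for (j in seq_len(ncol(fem))) {
    a <- alphs[[j]]
    flip <- runif(nrow(fem)) < spec$female_noise
    if (any(flip)) {
      cur <- match(fem[flip, j], a)
      shift <- sample.int(length(a) - 1L, sum(flip), replace = TRUE)
      fem[flip, j] <- a[((cur - 1L + shift) %% length(a)) + 1L]
    }
    hit <- south & runif(nrow(fem)) < spec$female_bias
    fem[hit, j] <- targets[j]
  }
  female <- character_matrix(fem, alphabets = alphs)

  aln <- simulate_sequences(tree, spec$seq_lengths, spec$seq_rate, ss["seqs"])

  # latitudes (degrees south): southern regime deep in Australia, northern
  # regime tropical
  set.seed(ss["latitude"])
  mid <- ifelse(south, rnorm(nt, spec$lat$south_mean, spec$lat$sd),
                rnorm(nt, spec$lat$north_mean, spec$lat$sd))
  width <- runif(nt, spec$lat$width_min, spec$lat$width_max)
  meta <- data.frame(taxon = rownames(fem),
                     regime2 = unname(regime2[rownames(fem)]),
                     regime4 = unname(regime4[rownames(fem)]),
                     lat_north = mid - width / 2,
                     lat_south = mid + width / 2, row.names = NULL)

  # auxiliary continuous traits
  traits <- list(
    male = simulate_ou_trait(tree, alpha = spec$ou_male$alpha,
                             sigma2 = spec$ou_male$sigma2, z0 = 0,
                             seed = ss["traits"]),
    female = simulate_ou_trait(tree, painting2, alpha = spec$ou_female$alpha,
                               sigma2 = spec$ou_female$sigma2,
                               theta = spec$ou_female$theta,
                               seed = ss["traits"] %% 2147483646L + 1L))

  b <- study_bundle(tree, male, female, meta, alignment = aln,
                    config = list(regime_scheme = "two", seed = spec$seed))
  b$painting2 <- painting2
  b$painting4 <- painting4
  b$traits <- traits
  b$spec <- spec
  b
}

#' Write a study bundle to disk in the formats the readers accept
#'
#' @param bundle a `"study_bundle"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tree(bundle$tree, file.path(dir, "tree.nwk"))
  write_character_matrix(bundle$male, file.path(dir, "male.csv"))
  write_character_matrix(bundle$female, file.path(dir, "female.csv"))
  write.csv(bundle$meta, file.path(dir, "meta.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(bundle$alignment))
    write_alignment(bundle$alignment, file.path(dir, "alignment.fasta"))
  invisible(dir)
}
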