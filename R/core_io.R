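#' @keywords internal
"_PACKAGE"

#' @importFrom stats cmdscale coef dexp lm optimize pf rexp rnorm runif
#'   setNames var sd pt qnorm complete.cases
#' @importFrom utils read.table write.csv head combn
NULL

# ---- trees ------------------------------------------------------------------

#' Read a rooted phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream analyses rely on: unique tip labels, non-negative branch
#' lengths, branch lengths present on every edge. Quoted labels and square
#' bracket comments are handled by the ape parser; polytomies are allowed
#' and treated as hard downstream.
#'
#' @param path path to a newick file, or a literal newick string via `text`.
#' @param text optional newick string (exclusive with `path`).
#' @return an object of class `"phylo"`.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr)) stop("malformed newick: could not parse ",
                        if (is.null(text)) path else "input string")
  validate_tree(tr)
  tr
}

#' Write a phylogeny to newick
#'
#' @param tree a `"phylo"` object.
#' @param path output file; if `NULL` the newick string is returned.
#' @param digits significant digits for branch lengths (default keeps full
#'   double precision so read/write round-trips are exact).
#' @return the newick string, invisibly when written to file.
#' @export
write_tree <- function(tree, path = NULL, digits = 17) {
  validate_tree(tree)
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) present")
  invisible(tree)
}

# ---- character matrices -----------------------------------------------------

MISSING_TOKEN <- "?"

#' Construct a validated plumage character matrix
#'
#' A character matrix is a taxa-by-characters matrix of single-symbol discrete
#' states. Each character carries its own alphabet (a colour patch never
#' shares states with a presence/absence trait); `"?"` marks missing data and
#' is skipped pairwise in distances and expanded to the full state set in
#' parsimony.
#'
#' @param x a character matrix with taxon rownames and character colnames.
#' @param alphabets either a single character vector used as the alphabet for
#'   every character, or a named list with one alphabet per character. When
#'   `NULL` the per-character alphabet is the set of observed states.
#' @return the matrix with class `"character_matrix"` and an `"alphabets"`
#'   attribute (named list).
#' @export
character_matrix <- function(x, alphabets = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "character"
  if (is.null(rownames(x))) stop("character matrix needs taxon rownames")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("char", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate taxon labels")
  if (is.null(alphabets)) {
    alphabets <- lapply(seq_len(ncol(x)), function(j)
      sort(unique(x[, j][x[, j] != MISSING_TOKEN & !is.na(x[, j])])))
  } else if (!is.list(alphabets)) {
    alphabets <- rep(list(alphabets), ncol(x))
  }
  names(alphabets) <- colnames(x)
  for (j in seq_len(ncol(x))) {
    bad <- which(!is.na(x[, j]) & x[, j] != MISSING_TOKEN &
                   !(x[, j] %in% alphabets[[j]]))
    if (length(bad))
      stop(sprintf("state '%s' for taxon '%s' not in alphabet of character '%s'",
                   x[bad[1], j], rownames(x)[bad[1]], colnames(x)[j]))
  }
  x[is.na(x)] <- MISSING_TOKEN
  structure(x, alphabets = alphabets, class = c("character_matrix", "matrix"))
}

#' Read a plumage character matrix from a delimited file
#'
#' Expects a header row of character names and a first column of taxon
#' labels; the separator is inferred from the extension (`.csv` vs `.tsv`).
#'
#' @param path file path.
#' @param alphabets passed to [character_matrix()]; a global alphabet or a
#'   per-character list. States found in the file that are absent from the
#'   declared alphabet raise an error naming taxon and character.
#' @param sep field separator; inferred from extension when `NULL`.
#' @return a `"character_matrix"`.
#' @export
read_character_matrix <- function(path, alphabets = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   colClasses = "character", check.names = FALSE,
                   na.strings = character())
  character_matrix(as.matrix(df), alphabets = alphabets)
}

#' @export
write_character_matrix <- function(x, path) {
  df <- data.frame(taxon = rownames(x), unclass(x), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- alignments -------------------------------------------------------------

#' Read a multiple sequence alignment from FASTA
#'
#' Sequences are uppercased on read and must be equal length. An optional
#' partition table assigns gene names to disjoint, covering site ranges.
#'
#' @param path FASTA file.
#' @param partitions optional `data.frame(gene, start, end)` (1-based,
#'   inclusive) covering the alignment with disjoint ranges.
#' @return a character matrix (taxa x sites) of class `"dna_alignment"` with
#'   a `"partitions"` attribute.
#' @export
read_alignment <- function(path, partitions = NULL) {
  recs <- as.character(ape::read.FASTA(path))
  lens <- vapply(recs, length, 1L)
  if (length(unique(lens)) > 1L)
    stop("unequal sequence lengths: ",
         paste(sprintf("%s (%d)", names(lens), lens), collapse = ", "))
  mat <- toupper(do.call(rbind, recs))
  rownames(mat) <- names(recs)
  dna_alignment(mat, partitions)
}

#' @export
dna_alignment <- function(mat, partitions = NULL) {
  mat <- toupper(as.matrix(mat))
  if (is.null(partitions))
    partitions <- data.frame(gene = "all", start = 1L, end = ncol(mat))
  stopifnot(all(c("gene", "start", "end") %in% names(partitions)))
  o <- order(partitions$start)
  p <- partitions[o, , drop = FALSE]
  if (p$start[1] != 1L || p$end[nrow(p)] != ncol(mat) ||
      (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)] + 1L)))
    stop("partitions must be disjoint and cover all ", ncol(mat), " sites")
  structure(mat, partitions = p, class = c("dna_alignment", "matrix"))
}

#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln)))
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  invisible(path)
}

# ---- metadata ---------------------------------------------------------------

#' Read per-taxon metadata
#'
#' Columns: `taxon`, geographic regime columns (e.g. `regime2`, `regime4`),
#' and latitudinal range limits in degrees south (`lat_north`, `lat_south`,
#' with `lat_south >= lat_north` since degrees south increase southward).
#'
#' @param path CSV/TSV path.
#' @param sep separator, inferred from extension when `NULL`.
#' @return a `data.frame`.
#' @export
read_taxon_meta <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  validate_taxon_meta(df)
  df
}

validate_taxon_meta <- function(df) {
  stopifnot("taxon" %in% names(df))
  if (all(c("lat_north", "lat_south") %in% names(df))) {
    bad <- which(df$lat_south < df$lat_north)
    if (length(bad))
      stop("southern latitudinal limit (degrees south) below northern limit for: ",
           paste(df$taxon[bad], collapse = ", "))
  }
  invisible(df)
}

# ---- study bundle -----------------------------------------------------------

#' Assemble a study bundle
#'
#' Bundles the tree, per-sex character matrices, metadata and (optionally)
#' the alignment, together with the configuration that downstream stages
#' consult: which regime scheme to use and which taxa to include or exclude
#' at each stage. The study design keeps the malurid outgroup in the
#' parsimony reconstruction while the non-malurid outgroup enters only the
#' pairwise-distance stage, so include/exclude lists are per stage.
#'
#' @param tree a `"phylo"`.
#' @param male,female `"character_matrix"` objects sharing the character set.
#' @param meta per-taxon metadata `data.frame` (see [read_taxon_meta()]).
#' @param alignment optional `"dna_alignment"`.
#' @param config list; recognised entries `regime_scheme` (`"two"` or
#'   `"four"`), and per-stage `exclude` lists such as
#'   `exclude = list(parsimony = "Honeyeater_out")`.
#' @return a list of class `"study_bundle"`.
#' @export
study_bundle <- function(tree, male, female, meta, alignment = NULL,
                         config = list()) {
  b <- structure(list(tree = tree, male = male, female = female, meta = meta,
                      alignment = alignment, config = config),
                 class = "study_bundle")
  b
}

#' Validate cross-component agreement of a study bundle
#'
#' Cross-checks taxon label sets across tree tips, both character matrices,
#' metadata and alignment (after declared exclusions) and regime labels
#' against the declared regime set. Issues are reported, never thrown.
#'
#' @param bundle a `"study_bundle"`.
#' @param regime_levels optional named list of allowed regime labels per
#'   regime column, e.g. `list(regime2 = c("Australia", "NewGuinea"))`.
#' @return character vector of issues (length zero when fully consistent),
#'   class `"bundle_validation"`.
#' @export
validate_bundle <- function(bundle, regime_levels = NULL) {
  issues <- character()
  tips <- bundle$tree$tip.label
  comp <- list(male_matrix = rownames(bundle$male),
               female_matrix = rownames(bundle$female),
               metadata = bundle$meta$taxon)
  if (!is.null(bundle$alignment)) comp$alignment <- rownames(bundle$alignment)
  for (nm in names(comp)) {
    miss <- setdiff(tips, comp[[nm]])
    extra <- setdiff(comp[[nm]], tips)
    if (length(miss))
      issues <- c(issues, sprintf("tree tip(s) missing from %s: %s", nm,
                                  paste(miss, collapse = ", ")))
    if (length(extra))
      issues <- c(issues, sprintf("taxa in %s absent from tree: %s", nm,
                                  paste(extra, collapse = ", ")))
  }
  if (!identical(colnames(bundle$male), colnames(bundle$female)))
    issues <- c(issues, "male and female matrices have different character sets")
  if (!is.null(regime_levels)) {
    for (col in names(regime_levels)) {
      if (!col %in% names(bundle$meta)) {
        issues <- c(issues, sprintf("metadata lacks regime column '%s'", col))
        next
      }
      bad <- setdiff(unique(bundle$meta[[col]]), regime_levels[[col]])
      if (length(bad))
        issues <- c(issues, sprintf("regime value(s) in '%s' outside declared set: %s",
                                    col, paste(bad, collapse = ", ")))
    }
  }
  structure(issues, class = "bundle_validation")
}

#' @export
print.bundle_validation <- function(x, ...) {
  if (!length(x)) cat("study bundle consistent: no issues\n")
  else cat(sprintf("%d issue(s):\n%s\n", length(x),
                   paste("-", unclass(x), collapse = "\n")))
  invisible(x)
}

# restrict a tree + companions to an include list / minus an exclude list
keep_taxa <- function(tree, include = NULL, exclude = NULL) {
  keep <- tree$tip.label
  if (!is.null(include)) keep <- intersect(keep, include)
  if (!is.null(exclude)) keep <- setdiff(keep, exclude)
  if (length(keep) < 3) stop("fewer than 3 taxa retained")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::drop.tip(tree, setdiff(tree$tip.label, keep))
}
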