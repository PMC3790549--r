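# Orchestration: run every stage of the comparative analysis on a study
# bundle, collect a run report, and (optionally) write CSV outputs plus a
# JSON manifest.

#' Recompute an AICc model table from log-likelihoods
#'
#' Standalone utility for checking a published model-selection table: given
#' per-model log-likelihoods and parameter counts it recomputes AICc,
#' differences to the best model, and Akaike weights. The default
#' parameter counts are those of the BM / single-optimum OU / two-optimum
#' OU / four-optimum OU model family (sigma2 and root state; plus alpha and
#' the optima, the root state being tied to the root regime's optimum).
#'
#' @param lnL numeric vector of log-likelihoods (optionally named).
#' @param k parameter counts, same length.
#' @param n number of taxa.
#' @param models model names.
#' @return data.frame as from [model_table()].
#' @export
table1_check <- function(lnL, k = c(2L, 3L, 4L, 6L), n = 22L,
                         models = c("BM", "OU1", "OUM2", "OUM4")[seq_along(lnL)]) {
  if (length(lnL) != length(k)) stop("lnL and k lengths differ")
  aicc_table(lnL, k, n, models = models)
}

run_stage <- function(report, name, stages, expr) {
  if (!name %in% stages) {
    report[[name]] <- structure(list(reason = "not requested"),
                                class = "skipped_stage")
    return(report)
  }
  t0 <- proc.time()[["elapsed"]]
  report[[name]] <- expr
  report$manifest$timings[[name]] <- proc.time()[["elapsed"]] - t0
  report
}

#' Run the full comparative analysis on a study bundle
#'
#' Stage order: ancestral geography (its ML paintings feed the
#' multi-optimum OU fits), parsimony reconstruction of plumage changes for
#' each sex, plumage-vs-molecular divergence, evolutionary model selection
#' on the per-sex ordination scores, and the dichromatism-latitude
#' contrasts analysis. Any stage can be skipped; skipped stages are marked
#' explicitly in the report.
#'
#' @param bundle a `"study_bundle"` (e.g. from [make_study_fixture()]).
#' @param stages which stages to run.
#' @param outdir optional directory for CSV outputs and `manifest.json`.
#' @return a `"run_report"` list with one element per stage plus a
#'   `manifest` (seed, package version, timings).
#' @export
run_all <- function(bundle,
                    stages = c("geo_ancestry", "parsimony", "divergence",
                               "trait_models", "contrasts"),
                    outdir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  issues <- validate_bundle(bundle)
  if (length(issues))
    stop("bundle validation failed:\n", paste("-", issues, collapse = "\n"))
  report <- list(manifest = list(
    seed = bundle$config$seed,
    package_version = as.character(utils::packageVersion("plumevol")),
    r_version = R.version.string,
    timings = list()))
  tree <- bundle$tree
  excl <- bundle$config$exclude %||% list()

  report <- run_stage(report, "geo_ancestry", stages, {
    out <- list()
    for (col in intersect(c("regime2", "regime4"), names(bundle$meta))) {
      st <- setNames(bundle$meta[[col]], bundle$meta$taxon)
      fit <- fit_mk(tree, st)
      marg <- marginal_ancestral(fit)
      out[[col]] <- list(fit = fit, marginals = marg,
                         root_probabilities = attr(marg, "root"),
                         painting = painting_from_marginals(fit, marg))
    }
    out
  })

  report <- run_stage(report, "parsimony", stages, {
    ptree <- keep_taxa(tree, exclude = excl$parsimony)
    res <- branch_change_table(ptree, bundle$male, bundle$female)
    res$summary <- data.frame(
      sex = c("male", "female"),
      total_changes = c(res$male$total_changes, res$female$total_changes),
      total_steps = c(sum(res$male$steps), sum(res$female$steps)),
      CI = c(consistency_index(res$male), consistency_index(res$female)),
      RI = c(retention_index(res$male), retention_index(res$female)))
    res
  })

  report <- run_stage(report, "divergence", stages, {
    if (is.null(bundle$alignment)) {
      structure(list(reason = "no alignment in bundle"), class = "skipped_stage")
    } else {
      tab <- divergence_table(bundle, exclude = excl$divergence)
      list(pairs = tab,
           regression_male = divergence_regression(tab$p_dist,
                                                   tab$plumage_dist_male),
           regression_female = divergence_regression(tab$p_dist,
                                                     tab$plumage_dist_female))
    }
  })

  report <- run_stage(report, "trait_models", stages, {
    if (!"geo_ancestry" %in% stages)
      stop("trait_models needs the geo_ancestry paintings; include that stage")
    p2 <- report$geo_ancestry$regime2$painting
    p4 <- report$geo_ancestry$regime4$painting
    mtree <- keep_taxa(tree, exclude = excl$trait_models)
    out <- list()
    for (sex in c("male", "female")) {
      D <- plumage_distance_matrix(bundle[[sex]], include = mtree$tip.label)
      trait <- pcoa_trait(D)$trait
      fits <- list(fit_trait_model(mtree, trait, "BM"),
                   fit_trait_model(mtree, trait, "OU1"))
      if (!is.null(p2)) fits <- c(fits, list(
        fit_trait_model(mtree, trait, "OUM2", painting = p2)))
      if (!is.null(p4)) fits <- c(fits, list(
        fit_trait_model(mtree, trait, "OUM4", painting = p4)))
      out[[sex]] <- list(trait = trait, fits = fits, table = model_table(fits))
    }
    out
  })

  report <- run_stage(report, "contrasts", stages, {
    ctree <- keep_taxa(tree, exclude = excl$contrasts)
    dichromatism_latitude_analysis(ctree, bundle$male, bundle$female,
                                   bundle$meta)
  })

  class(report) <- "run_report"
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run report; stages:\n")
  for (nm in setdiff(names(x), "manifest")) {
    if (inherits(x[[nm]], "skipped_stage"))
      cat(sprintf("  %s: skipped (%s)\n", nm, x[[nm]]$reason))
    else cat(sprintf("  %s: done\n", nm))
  }
  invisible(x)
}

#' Write a run report to CSV files plus a JSON manifest
#'
#' @param report a `"run_report"`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) write.csv(df, file.path(outdir, f), row.names = FALSE)
  if (!inherits(report$parsimony, c("skipped_stage", "NULL"))) {
    w(report$parsimony$table, "branch_changes.csv")
    w(report$parsimony$summary, "parsimony_summary.csv")
    writeLines(report$parsimony$annotated_newick,
               file.path(outdir, "branch_changes.nwk"))
  }
  if (!inherits(report$divergence, c("skipped_stage", "NULL")))
    w(report$divergence$pairs, "divergence_pairs.csv")
  if (!inherits(report$trait_models, c("skipped_stage", "NULL"))) {
    w(report$trait_models$male$table, "model_table_male.csv")
    w(report$trait_models$female$table, "model_table_female.csv")
  }
  if (!inherits(report$geo_ancestry, c("skipped_stage", "NULL"))) {
    for (col in names(report$geo_ancestry)) {
      m <- report$geo_ancestry[[col]]$marginals
      w(data.frame(node = rownames(m), as.data.frame(unclass(m))),
        sprintf("geo_marginals_%s.csv", col))
    }
  }
  if (!inherits(report$contrasts, c("skipped_stage", "NULL"))) {
    w(report$contrasts$scores, "dichromatism_latitude.csv")
    w(as.data.frame(report$contrasts$contrasts_dichromatism),
      "contrasts_dichromatism.csv")
  }
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
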