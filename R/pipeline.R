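#' Analysis configuration
#'
#' Bundles the settings of a full comparative run. The reference group must
#' be consistent with the analysis set: `terrestrial` for all-species
#' analyses, `surface-foraging` for aquatic-only analyses (where dive-score
#' models join the candidate set).
#'
#' @param analysis_set `"all_species"` or `"aquatic_only"`.
#' @param reference_group factor reference level; defaults to the
#'   convention for the chosen analysis set.
#' @param traits trait columns to analyse; `NULL` means every available
#'   continuous measure.
#' @param mcmc list with `chains`, `iterations`, `seed` for the ordinal
#'   models.
#' @param ppca_mode `"cov"` or `"cor"`.
#' @param ppca_lambda lambda applied inside the pPCA.
#' @param output_dir optional directory; when set, result tables are
#'   written as TSV.
#' @return List of class `"ear_config"`.
#' @export
analysis_config <- function(analysis_set = c("all_species", "aquatic_only"),
                            reference_group = NULL, traits = NULL,
                            mcmc = list(chains = 2L, iterations = 6000L,
                                        seed = 1L),
                            ppca_mode = "cov", ppca_lambda = 1,
                            output_dir = NULL) {
  analysis_set <- match.arg(analysis_set)
  default_ref <- if (analysis_set == "all_species") "terrestrial"
                 else "surface-foraging"
  if (is.null(reference_group)) reference_group <- default_ref
  if (reference_group != default_ref)
    stop(sprintf("reference group for %s analyses must be '%s'",
                 analysis_set, default_ref), call. = FALSE)
  mcmc <- modifyList(list(chains = 2L, iterations = 6000L, seed = 1L), mcmc)
  structure(list(analysis_set = analysis_set,
                 reference_group = reference_group, traits = traits,
                 mcmc = mcmc, ppca_mode = ppca_mode,
                 ppca_lambda = ppca_lambda, output_dir = output_dir),
            class = "ear_config")
}

# candidate predictor sets per analysis type
.candidates <- function(analysis_set) {
  if (analysis_set == "all_species") c("HM", "HM+GROUP", "HMxGROUP")
  else c("HM", "HM+GROUP", "HMxGROUP", "HM+DIVE", "HMxDIVE")
}

.trait_columns <- function(table, traits) {
  if (!is.null(traits)) return(traits)
  out <- intersect(.ear_measures, names(table))
  if (length(out)) return(out)
  # fall back to any numeric column that is not metadata
  meta <- c("species", "head_mass", "group", "max_depth_m", "dive_score",
            "n_specimens", "IAC", "IBP")
  nm <- setdiff(names(table), meta)
  nm[vapply(table[nm], is.numeric, logical(1))]
}

# align table rows to the pruned tree; hard error before any fitting
.align_inputs <- function(tree, table, substitutions = NULL) {
  mt <- match_tips(tree, table$species, substitutions)
  table <- table[match(mt$tree$tip.label, table$species), , drop = FALSE]
  rownames(table) <- NULL
  list(tree = mt$tree, table = table, C = phylo_covariance(mt$tree))
}

# one trait: fit candidate set, select, test coefficients
.analyse_trait <- function(table, C, trait, analysis_set, reference_group) {
  y <- log(table[[trait]])
  if (any(!is.finite(y)))
    stop(sprintf("trait '%s' has non-positive or missing values", trait),
         call. = FALSE)
  fits <- lapply(.candidates(analysis_set), function(pr) {
    sp <- model_spec(trait, pr, reference_group)
    fit_pgls(y, design_matrix(table, sp), C, spec = sp)
  })
  sel <- select_model(fits)
  list(selection = sel, coef = coef_tests(sel$fits[[sel$chosen]]),
       hm_fit = fits[[1L]])   # head-mass-only fit feeds the pPCA
}

.run_pipeline <- function(tree, table, config, substitutions = NULL,
                          connectivity = NULL) {
  stopifnot(inherits(config, "ear_config"))
  table <- validate_groups(table)
  al <- .align_inputs(tree, table, substitutions)
  table <- al$table; C <- al$C
  traits <- .trait_columns(table, config$traits)
  if (!length(traits)) stop("no trait columns to analyse", call. = FALSE)
  per_trait <- lapply(traits, function(tr)
    .analyse_trait(table, C, tr, config$analysis_set,
                   config$reference_group))
  names(per_trait) <- traits
  # residual matrix: head-mass-only PGLS residuals per trait, by design
  resid_mat <- vapply(per_trait, function(x) pgls_residuals(x$hm_fit),
                      numeric(nrow(table)))
  rownames(resid_mat) <- table$species
  pp <- ppca(resid_mat, C, lambda = config$ppca_lambda,
             mode = config$ppca_mode)
  ordinal <- NULL
  if (!is.null(connectivity)) {
    Xo <- design_matrix(table, model_spec(traits[1], "HM+GROUP",
                                          config$reference_group))
    Xo <- Xo[, grep("^group", colnames(Xo)), drop = FALSE]
    ordinal <- lapply(connectivity, function(yv) {
      yv <- yv[table$species]
      fit_phylo_ordinal(yv, Xo, C, chains = config$mcmc$chains,
                        iterations = config$mcmc$iterations,
                        seed = config$mcmc$seed)
    })
  }
  sel_tab <- do.call(rbind, lapply(traits, function(tr) {
    s <- per_trait[[tr]]$selection
    ch <- s$table[s$table$chosen, , drop = FALSE]
    data.frame(trait = tr, model = ch$model, r2_adj = ch$r2_adj,
               lambda = ch$lambda, aicc = ch$aicc,
               stringsAsFactors = FALSE)
  }))
  coef_tab <- do.call(rbind, lapply(traits, function(tr)
    cbind(trait = tr, per_trait[[tr]]$coef)))
  res <- structure(list(config = config, table = table, tree = al$tree,
                        per_trait = per_trait, selection_table = sel_tab,
                        coefficient_table = coef_tab,
                        residual_matrix = resid_mat, ppca = pp,
                        ordinal = ordinal),
                   class = "ear_analysis")
  if (!is.null(config$output_dir)) write_results(res, config$output_dir)
  res
}

#' Run the all-species comparative analysis
#'
#' For each trait, fits the three candidate PGLS models (head mass alone,
#' plus ecological group, and their interaction) with terrestrial as the
#' reference group, applies the AICc parsimony rule, and tests the chosen
#' model's coefficients. Head-mass-only residuals per trait feed a
#' phylogenetic PCA, and (when connectivity states are supplied) Bayesian
#' phylogenetic ordinal regressions are fitted for each structure.
#'
#' @param tree a `phylo` object.
#' @param table trait table: `species`, `head_mass`, `group`, optional
#'   `max_depth_m`/`dive_score`, and trait columns (raw scale; logged
#'   internally).
#' @param config an [analysis_config()] with `analysis_set = "all_species"`.
#' @param substitutions optional tip-substitution map (see [match_tips()]).
#' @param connectivity optional named list (e.g. `IAC`, `IBP`) of integer
#'   vectors (1..3, named by species) of connectivity states.
#' @return Object of class `"ear_analysis"`.
#' @export
run_all_species <- function(tree, table, config = analysis_config(),
                            substitutions = NULL, connectivity = NULL) {
  if (config$analysis_set != "all_species")
    stop("config is not an all-species configuration", call. = FALSE)
  .run_pipeline(tree, table, config, substitutions, connectivity)
}

#' Run the aquatic-only comparative analysis
#'
#' As [run_all_species()], but restricted to the three aquatic groups with
#' surface-foraging as the reference and two additional dive-score models
#' (head mass + dive score, head mass x dive score) in the candidate set.
#' Terrestrial rows in the table are an error: filter first.
#'
#' @inheritParams run_all_species
#' @param config an [analysis_config()] with `analysis_set = "aquatic_only"`.
#' @return Object of class `"ear_analysis"`.
#' @export
run_aquatic_only <- function(tree, table,
                             config = analysis_config("aquatic_only"),
                             substitutions = NULL, connectivity = NULL) {
  if (config$analysis_set != "aquatic_only")
    stop("config is not an aquatic-only configuration", call. = FALSE)
  table <- validate_groups(table)
  if (any(table$group == "terrestrial"))
    stop("terrestrial rows present in an aquatic-only analysis",
         call. = FALSE)
  if (!"dive_score" %in% names(table) || anyNA(table$dive_score))
    stop("aquatic-only analyses need a complete dive_score column",
         call. = FALSE)
  .run_pipeline(tree, table, config, substitutions, connectivity)
}

#' @export
print.ear_analysis <- function(x, ...) {
  cat(sprintf("Comparative ear analysis (%s): %d species, %d traits\n",
              x$config$analysis_set, nrow(x$table),
              nrow(x$selection_table)))
  print(transform(x$selection_table, r2_adj = round(r2_adj, 3),
                  lambda = round(lambda, 4), aicc = round(aicc, 2)))
  vp <- round(100 * x$ppca$variance_proportion[1:2], 1)
  cat(sprintf("  pPC1/pPC2 variance: %s%% / %s%%\n", vp[1], vp[2]))
  invisible(x)
}

#' Write analysis result tables as TSV
#'
#' Writes the model-selection table, coefficient table, residual matrix,
#' pPCA scores and loadings, and (if present) ordinal posterior summaries.
#'
#' @param res an `"ear_analysis"` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(res, dir) {
  stopifnot(inherits(res, "ear_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(obj, name, rn = FALSE) {
    f <- file.path(dir, name)
    write.table(obj, f, sep = "\t", quote = FALSE, row.names = rn,
                col.names = TRUE)
    f
  }
  files <- c(wt(res$selection_table, "model_selection.tsv"),
             wt(res$coefficient_table, "coefficients.tsv"),
             wt(res$residual_matrix, "pgls_residuals.tsv", rn = TRUE),
             wt(res$ppca$scores, "ppca_scores.tsv", rn = TRUE),
             wt(res$ppca$loadings, "ppca_loadings.tsv", rn = TRUE))
  if (!is.null(res$ordinal))
    for (nm in names(res$ordinal))
      files <- c(files, wt(res$ordinal[[nm]]$summary,
                           sprintf("ordinal_%s.tsv", nm)))
  invisible(files)
}

#' Read a species trait table CSV
#'
#' @param path CSV with `species`, `head_mass`, `group` and trait columns.
#' @return Data frame with canonical group labels.
#' @export
read_trait_table <- function(path) {
  validate_groups(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a species trait table CSV
#'
#' @param table trait table data frame.
#' @param path output path.
#' @export
write_trait_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
}
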