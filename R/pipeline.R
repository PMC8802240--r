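## characters analysed by the standard pipeline, with their codings
.pipeline_characters <- function() {
  list(
    sperm_location_bin = list(column = "sperm_location", coding = "binary"),
    sperm_location_tri = list(column = "sperm_location", coding = "trinary"),
    bristle_state_bin = list(column = "bristle_state", coding = "binary"),
    bristle_state_tri = list(column = "bristle_state", coding = "trinary"),
    antrum_state_bin = list(column = "antrum_state", coding = "binary"),
    syndrome_bin = list(column = "syndrome", coding = "binary"),
    syndrome_tri = list(column = "syndrome", coding = "trinary")
  )
}

.code_character <- function(records, column, coding) {
  scheme <- if (column == "syndrome") "syndrome" else column
  v <- if (coding == "binary") recode_binary(records[[column]], scheme)
       else recode_trinary(records[[column]], scheme)
  stats::setNames(v, records$species)
}

#' Run the full mating-syndrome comparative pipeline
#'
#' Orchestrates the analysis sequence on one dataset: syndrome
#' classification, binary/trinary recoding, Mk model comparison per
#' character, stochastic character mapping for every model with AICc weight
#' above `map_threshold`, lower-bound origin counts, Pagel correlated-
#' evolution tests for the three binary trait pairs, a phylogenetic PCA of
#' the quantitative traits, a PGLS suite for sperm length against each
#' binary indicator (with and without body size), and the stylet-antrum
#' coevolution analysis. Every stochastic stage derives its seed from
#' `seed`; rerunning with the same seed reproduces the report exactly.
#'
#' @param dataset A `synthetic_dataset` from [generate_study_like()], or
#'   `NULL` if `tree`, `records` and `quant` are given directly.
#' @param tree,records,quant Alternative direct inputs: a `phylo`, the
#'   categorical species table, and a list with `values`/`n` matrices of
#'   transformed quantitative species means.
#' @param profile `"fast"` (short chains for interactive use and continuous
#'   testing) or `"paper"` (10,000-iteration burn-in and sampling with
#'   thinning 10, 1000 retained histories, 50 stepping stones).
#' @param seed Master seed.
#' @param characters Subset of characters to model (default: all binary;
#'   names as in the report). Trinary codings are included when
#'   `trinary = TRUE`.
#' @param trinary Also fit the trinary codings (slower).
#' @param map_threshold AICc-weight cutoff for stochastic mapping.
#' @param origin_threshold Posterior-probability cutoff of the lower-bound
#'   origin rule.
#' @param out_dir If non-NULL, write CSV tables and a JSON log there.
#' @return A list of class `pipeline_report` with elements `classification`,
#'   `model_tables`, `mappings`, `origins`, `pagel`, `ppca`, `pgls_sperm`,
#'   `coevolution`, `log`.
#' @export
run_all <- function(dataset = NULL, tree = NULL, records = NULL,
                    quant = NULL, profile = c("fast", "paper"), seed = 1,
                    characters = NULL, trinary = FALSE,
                    map_threshold = 0.15, origin_threshold = 0.95,
                    out_dir = NULL) {
  profile <- match.arg(profile)
  if (!is.null(dataset)) {
    tree <- dataset$tree
    records <- dataset$records
    quant <- dataset$quant
  }
  stopifnot(inherits(tree, "phylo"), is.data.frame(records))
  mc <- if (profile == "paper") {
    list(n_burnin = 10000, n_iter = 10000, n_thin = 10, n_stones = 50,
         iters_per_stone = 2000)
  } else {
    list(n_burnin = 1000, n_iter = 1000, n_thin = 10, n_stones = 8,
         iters_per_stone = 150)
  }
  log <- list(seed = seed, profile = profile,
              package_version = as.character(utils::packageVersion(
                "phylosyndrome")),
              n_species = ape::Ntip(tree))

  ## 1. classification
  cls <- classify_syndrome(records)
  records$syndrome <- cls$syndrome

  ## 2-4. per-character Mk comparison + mapping + origins
  chars <- .pipeline_characters()
  if (!trinary) chars <- chars[!grepl("_tri$", names(chars))]
  if (!is.null(characters)) chars <- chars[characters]
  model_tables <- list()
  mappings <- list()
  origins <- list()
  for (nm in names(chars)) {
    states <- .code_character(records, chars[[nm]]$column,
                              chars[[nm]]$coding)
    states <- states[!is.na(states)]
    if (length(states) < 4L || length(unique(states)) < 2L) next
    tr <- prune_to(tree, names(states))
    models <- if (chars[[nm]]$coding == "binary") c("ER", "Dollo", "ARD")
              else c("ER", "SYM", "ORD-Dollo", "Dollo", "ORD", "ARD")
    cmp <- compare_models(tr, states, models, n_starts = 3,
                          seed = seed, map_threshold = map_threshold)
    model_tables[[nm]] <- cmp$table
    for (model in cmp$table$model[cmp$table$map]) {
      key <- paste(nm, model, sep = ".")
      n_states <- max(states) + 1L
      mp <- map_character(tr, states, build_template(model, n_states),
                          n_burnin = mc$n_burnin, n_iter = mc$n_iter,
                          n_thin = mc$n_thin, seed = seed)
      sm <- summarize_maps(mp$histories)
      mappings[[key]] <- sm
      ancestral <- n_states - 1L
      origins[[key]] <- lower_bound_origins(sm, tr, derived = 0L,
                                            ancestral = ancestral,
                                            threshold = origin_threshold)
    }
  }

  ## 5. Pagel tests on the three binary pairs
  pairs <- list(c("sperm_location", "bristle_state"),
                c("sperm_location", "antrum_state"),
                c("bristle_state", "antrum_state"))
  pagel <- list()
  for (pr in pairs) {
    x <- .code_character(records, pr[1L], "binary")
    y <- .code_character(records, pr[2L], "binary")
    keep <- names(x)[!is.na(x) & !is.na(y)]
    if (length(keep) < 8L) next
    tr <- prune_to(tree, keep)
    key <- paste(pr, collapse = "_x_")
    zi <- stepping_stone_logZ(tr, x[keep], y[keep], "independent",
                              n_stones = mc$n_stones,
                              iters_per_stone = mc$iters_per_stone,
                              seed = seed)
    zd <- stepping_stone_logZ(tr, x[keep], y[keep], "dependent",
                              n_stones = mc$n_stones,
                              iters_per_stone = mc$iters_per_stone,
                              seed = seed)
    pagel[[key]] <- list(logZ_independent = zi, logZ_dependent = zd,
                         BF = bayes_factor(zd, zi), n = length(keep))
  }

  ## 6. pPCA of the quantitative traits
  ppca_res <- NULL
  if (!is.null(quant)) {
    Xc <- quant$values[stats::complete.cases(quant$values), , drop = FALSE]
    if (nrow(Xc) >= 3L) ppca_res <- ppca(Xc, tree)
  }

  ## 7. PGLS suite: sperm length vs each binary indicator
  pgls_sperm <- list()
  if (!is.null(quant) && "sperm_length" %in% colnames(quant$values)) {
    sl <- quant$values[, "sperm_length"]
    wn <- quant$n[, "sperm_length"]
    body <- if ("body_area" %in% colnames(quant$values)) {
      quant$values[, "body_area"]
    } else NULL
    for (pred_name in c("sperm_location", "bristle_state", "antrum_state",
                        "syndrome")) {
      xb <- .code_character(records, pred_name, "binary")
      keep <- names(xb)[!is.na(xb) & !is.na(sl[names(xb)])]
      if (length(keep) < 8L) next
      tr <- prune_to(tree, keep)
      pred <- cbind(indicator = xb[keep])
      rownames(pred) <- keep
      cmpst <- pgls_compare_structures(sl[keep], pred, tr,
                                       weights = wn[keep])
      best <- cmpst$fits[[cmpst$table$structure[1L]]]
      null_plain <- pgls_fit(sl[keep], NULL, tr, structure = "none")
      null_phylo <- pgls_fit(sl[keep], NULL, tr,
                             structure = best$structure)
      res <- list(fit = best, structure_table = cmpst$table,
                  r2_pred = r2_pred(best, null_plain),
                  r2_pred_phylo = r2_pred(best, null_phylo))
      if (!is.null(body)) {
        pred2 <- cbind(indicator = xb[keep], body_size = body[keep])
        rownames(pred2) <- keep
        res$fit_with_body <- pgls_fit(sl[keep], pred2, tr,
                                      structure = best$structure,
                                      weights = wn[keep])
      }
      pgls_sperm[[pred_name]] <- res
    }
  }

  ## 8. stylet-antrum coevolution
  coev <- NULL
  stylet_cols <- c("stylet_length", "stylet_curviness",
                   "proximal_opening_width", "distal_opening_width",
                   "distal_asymmetry")
  antrum_cols <- c("antrum_thickness", "cellular_valve",
                   "chamber_complexity", "n_genital_openings")
  if (!is.null(quant) && all(stylet_cols %in% colnames(quant$values)) &&
      all(antrum_cols %in% names(records))) {
    A <- as.matrix(data.frame(lapply(records[antrum_cols], function(v) {
      as.numeric(as.character(v))
    }), row.names = records$species))
    hyp <- records$species[records$syndrome == "hypodermic"]
    coev <- tryCatch(
      coevolution_analysis(quant$values[, stylet_cols, drop = FALSE], A,
                           tree, exclude_species = hyp),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "pipeline_failure"))
  }

  report <- structure(list(classification = cls,
                           model_tables = model_tables,
                           mappings = mappings, origins = origins,
                           pagel = pagel, ppca = ppca_res,
                           pgls_sperm = pgls_sperm, coevolution = coev,
                           log = log),
                      class = "pipeline_report")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$log$seed, ", profile", x$log$profile,
      ")\n")
  cat("  syndromes:", paste(names(table(x$classification$syndrome)),
                            table(x$classification$syndrome),
                            collapse = ", "), "\n")
  cat("  characters modelled:", length(x$model_tables),
      " mapped:", length(x$mappings), "\n")
  for (nm in names(x$origins)) {
    cat("  origins [", nm, "]:", x$origins[[nm]]$count, "\n")
  }
  for (nm in names(x$pagel)) {
    cat("  Pagel BF [", nm, "]:", round(x$pagel[[nm]]$BF, 1), "\n")
  }
  invisible(x)
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$classification,
                   file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  for (nm in names(report$model_tables)) {
    utils::write.csv(report$model_tables[[nm]],
                     file.path(out_dir, paste0("models_", nm, ".csv")),
                     row.names = FALSE)
  }
  summary_lines <- c(
    sprintf("seed: %s", report$log$seed),
    sprintf("profile: %s", report$log$profile),
    sprintf("package_version: %s", report$log$package_version),
    sprintf("n_species: %s", report$log$n_species),
    vapply(names(report$origins), function(nm) {
      sprintf("origins %s: %d", nm, report$origins[[nm]]$count)
    }, character(1L)),
    vapply(names(report$pagel), function(nm) {
      sprintf("pagel_BF %s: %.3f", nm, report$pagel[[nm]]$BF)
    }, character(1L)))
  writeLines(summary_lines, file.path(out_dir, "report_log.txt"))
  invisible(NULL)
}
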