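## tiny FNV-1a over a deparsed object; good enough to fingerprint a
## config in the provenance block without external dependencies
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), as.integer(b %% 256))
    ## 32-bit modular multiply by the FNV prime 16777619, split into
    ## 16-bit halves to stay inside exact double-integer range
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.log_msg <- function(level, ..., log_file = NULL) {
  line <- paste0("[", level, "] ", paste0(..., collapse = ""))
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE,
                              sep = "")
  invisible(line)
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis.  Defaults follow the
#' conventional settings of the method: 5000 permutations, 5000
#' bootstraps, alpha 0.05, Benjamini-Hochberg FDR with one joint family
#' for the maturity-memory tests, stretched-beta prior width 1 for Bayes
#' factors, and an age-group cutoff of 7 years.
#'
#' @param cohort Path to a cohort file, or a \code{"cohort"} data.frame.
#' @param metrics Path to a metrics file, or a \code{"tract_metrics"}
#'   data.frame.
#' @param tracts Tracts to analyze (default: all four canonical tracts
#'   present in the metrics table).
#' @param n_perm,n_boot Resampling effort per latent-variable test.
#' @param alpha Significance level used throughout.
#' @param kappa Bayes-factor prior width.
#' @param fdr_family \code{"joint"} or \code{"per_tract"}.
#' @param age_cutoff Age-group boundary for interaction models.
#' @param seed Root seed; child seeds for every stochastic stage are
#'   derived from it.
#' @param out_dir Optional output directory; when set,
#'   \code{\link{run_pipeline}} writes report files there.
#' @param delim Delimiter of the input files.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(cohort, metrics, tracts = NULL, n_perm = 5000L,
                       n_boot = 5000L, alpha = 0.05, kappa = 1,
                       fdr_family = "joint", age_cutoff = 7, seed = 1L,
                       out_dir = NULL, delim = ",") {
  structure(
    list(cohort = cohort, metrics = metrics, tracts = tracts,
         n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
         alpha = alpha, kappa = kappa, fdr_family = fdr_family,
         age_cutoff = age_cutoff, seed = as.integer(seed),
         out_dir = out_dir, delim = delim),
    class = "run_config"
  )
}

.stage <- function(name, expr, log_file = NULL) {
  .log_msg("INFO", "stage: ", name, log_file = log_file)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their canonical order: (1) univariate age
#' effects of recall scores and diffusion metrics with FDR; (2) per-tract
#' PLSC of diffusion metrics against the recall scores, with permutation
#' significance, bootstrap ratios and behavior weights; (3) per-tract
#' diffusion-by-age PLSC yielding maturity scores; (4) maturity-memory
#' correlations with FDR and Bayes factors plus the discrimination
#' specificity panel - tracts whose age latent variable is not
#' significant are reported but excluded from this stage; (5) age-group
#' interaction models for the included tracts.
#'
#' When \code{config$out_dir} is set the report is serialized as
#' \code{report.json} together with \code{table2_analog.tsv},
#' \code{associations.tsv}, \code{maturity_scores.tsv}, one
#' \code{plsc_<tract>.tsv} per analyzed tract, and \code{run.log}.
#' Outputs contain no timestamps: a rerun with the same config, inputs
#' and seed is byte-identical.
#'
#' @param config A \code{\link{run_config}}.
#' @return An \code{"analysis_report"} list; see the JSON schema shipped
#'   in \code{inst/schema/report.schema.json}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_file <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    log_file <- file.path(config$out_dir, "run.log")
    cat("", file = log_file)  # truncate
  }
  cohort <- .stage("load-cohort", {
    if (is.character(config$cohort))
      load_cohort(config$cohort, config$delim)
    else as_cohort(as.data.frame(config$cohort))
  }, log_file)
  metrics <- .stage("load-metrics", {
    if (is.character(config$metrics))
      load_tract_metrics(config$metrics, config$delim)
    else as_tract_metrics(as.data.frame(config$metrics))
  }, log_file)
  tracts <- config$tracts
  if (is.null(tracts)) tracts <- intersect(TRACTS, unique(metrics$tract))

  set.seed(config$seed)
  seeds <- matrix(sample.int(2147483646L, 2L * length(tracts)), ncol = 2,
                  dimnames = list(tracts, c("em", "age")))
  .log_msg("INFO", "root seed ", config$seed, "; per-tract stage seeds ",
           "drawn for ", length(tracts), " tract(s)", log_file = log_file)

  em_age <- .stage("univariate-age-effects", {
    regs <- lapply(EM_SCORES, function(sc)
      regress_on_age(cohort[[sc]], cohort$age, outcome = sc))
    names(regs) <- EM_SCORES
    p_fdr <- fdr_adjust(vapply(regs, `[[`, numeric(1), "p"))
    for (i in seq_along(regs)) regs[[i]]$p_fdr <- p_fdr[i]
    regs
  }, log_file)
  table2 <- .stage("metric-age-correlations",
                   correlate_with_age(metrics, cohort), log_file)

  em_plsc <- list()
  maturity <- list()
  for (tr in tracts) {
    em_plsc[[tr]] <- .stage(paste0("em-plsc-", tr), {
      am <- build_analysis_matrix(cohort, metrics, tr, "em_scores")
      .log_msg("DEBUG", tr, ": em-plsc seed ", seeds[tr, "em"],
               log_file = log_file)
      fit <- plsc_decompose(am$X, am$Y)
      set.seed(seeds[tr, "em"])
      child <- sample.int(2147483646L, 2L)
      perm <- permutation_test(am$X, am$Y, 1L, config$n_perm, child[1])
      boot <- bootstrap_ratios(am$X, am$Y, 1L, config$n_boot, child[2])
      weights <- behavior_weights(am$Y, fit$Lx[, 1], config$alpha)
      list(tract = tr, n = length(am$subject_ids), dropped = am$dropped,
           singular_values = fit$S, lv_p_value = perm$p_value,
           bootstrap = boot, behavior_weights = weights,
           significant = perm$p_value <= config$alpha)
    }, log_file)
    maturity[[tr]] <- .stage(paste0("age-plsc-", tr), {
      am <- build_analysis_matrix(cohort, metrics, tr, "age")
      .log_msg("DEBUG", tr, ": age-plsc seed ", seeds[tr, "age"],
               log_file = log_file)
      suppressMessages(
        maturity_scores(am, n_perm = config$n_perm,
                        n_boot = config$n_boot, seed = seeds[tr, "age"],
                        alpha = config$alpha, force = TRUE))
    }, log_file)
  }

  sig_tracts <- names(maturity)[vapply(maturity, `[[`, logical(1),
                                       "significant")]
  excluded <- setdiff(tracts, sig_tracts)
  if (length(excluded))
    .log_msg("WARN", "tract(s) excluded from the maturity-memory stage ",
             "(non-significant age latent variable): ",
             paste(excluded, collapse = ", "), log_file = log_file)

  associations <- NULL
  interactions <- list()
  if (length(sig_tracts)) {
    associations <- .stage("maturity-memory-association",
      suppressWarnings(
        maturity_em_association(maturity[sig_tracts], cohort,
                                alpha = config$alpha,
                                kappa = config$kappa,
                                fdr_family = config$fdr_family)),
      log_file)
    interactions <- .stage("age-group-interactions", {
      res <- list()
      ages <- stats::setNames(cohort$age, cohort$subject_id)
      for (tr in sig_tracts) {
        ms <- maturity[[tr]]
        for (sc in EM_SCORES) {
          em <- stats::setNames(cohort[[sc]], cohort$subject_id)
          res[[paste(tr, sc, sep = ".")]] <-
            age_group_interaction(ms$score, em[ms$subject_ids],
                                  ages[ms$subject_ids],
                                  cutoff = config$age_cutoff)
        }
      }
      res
    }, log_file)
  } else {
    .log_msg("WARN", "no tract passed the age latent-variable test; ",
             "association and interaction stages skipped",
             log_file = log_file)
  }

  cfg_echo <- config[c("tracts", "n_perm", "n_boot", "alpha", "kappa",
                       "fdr_family", "age_cutoff", "seed")]
  report <- structure(
    list(provenance = list(
           package = "tractmaturity",
           version = as.character(utils::packageVersion("tractmaturity")),
           seed = config$seed,
           config = cfg_echo,
           config_hash = .fnv1a(cfg_echo)),
         em_age_regressions = em_age,
         metric_age_correlations = table2,
         em_plsc = em_plsc,
         maturity = maturity,
         excluded_tracts = excluded,
         associations = associations,
         interactions = interactions),
    class = "analysis_report"
  )
  if (!is.null(config$out_dir))
    .write_report_files(report, config$out_dir, log_file)
  report
}

.tsv <- function(df, path) {
  out <- as.data.frame(df)
  num <- vapply(out, is.numeric, logical(1))
  for (nm in names(out)[num]) out[[nm]] <- .fmt_num(out[[nm]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.report_as_list <- function(report) {
  mat_list <- lapply(report$maturity, function(ms) {
    list(tract = ms$tract, n = ms$n, lv_p_value = ms$lv_p_value,
         significant = ms$significant, sign_flipped = ms$sign_flipped,
         age_correlation = ms$age_correlation,
         singular_value = ms$singular_value,
         salience = as.list(stats::setNames(as.numeric(ms$salience),
                                            names(ms$salience))),
         bootstrap = as.data.frame(ms$bootstrap),
         subject_ids = ms$subject_ids,
         score = if (is.null(ms$score)) NULL else as.numeric(ms$score))
  })
  em_list <- lapply(report$em_plsc, function(e) {
    e$bootstrap <- as.data.frame(e$bootstrap)
    e
  })
  int_list <- lapply(report$interactions, unclass)
  list(provenance = report$provenance,
       em_age_regressions = lapply(report$em_age_regressions, unclass),
       metric_age_correlations =
         as.data.frame(report$metric_age_correlations),
       em_plsc = em_list,
       maturity = mat_list,
       excluded_tracts = as.list(report$excluded_tracts),
       associations = if (is.null(report$associations)) NULL
                      else as.data.frame(report$associations),
       interactions = int_list)
}

.write_report_files <- function(report, out_dir, log_file = NULL) {
  jsonlite::write_json(.report_as_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  .tsv(report$metric_age_correlations,
       file.path(out_dir, "table2_analog.tsv"))
  if (!is.null(report$associations))
    .tsv(report$associations, file.path(out_dir, "associations.tsv"))
  ms_rows <- do.call(rbind, lapply(report$maturity, function(ms) {
    if (is.null(ms$score)) return(NULL)
    data.frame(tract = ms$tract, subject_id = ms$subject_ids,
               maturity_score = as.numeric(ms$score),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ms_rows))
    .tsv(ms_rows, file.path(out_dir, "maturity_scores.tsv"))
  for (tr in names(report$em_plsc)) {
    e <- report$em_plsc[[tr]]
    boot <- as.data.frame(e$bootstrap)
    boot$section <- "bootstrap_ratio"
    w <- e$behavior_weights
    w <- data.frame(variable = w$variable, salience = NA_real_,
                    se = NA_real_, bootstrap_ratio = NA_real_,
                    reliable = NA, section = "behavior_weight",
                    weight = w$weight, p_value = w$p_value)
    boot$weight <- NA_real_
    boot$p_value <- NA_real_
    .tsv(rbind(boot, w), file.path(out_dir, paste0("plsc_", tr, ".tsv")))
  }
  .log_msg("INFO", "report files written", log_file = log_file)
  invisible(out_dir)
}

#' Simulate a cohort and write its input files
#'
#' Wraps \code{\link{generate_cohort}} and writes \code{cohort.csv},
#' \code{metrics.csv} and the ground truth \code{truth.json} into a
#' directory, producing exactly the file dialects the loaders read.
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Output directory (created if needed).
#' @param seed Optional root seed overriding \code{config$seed}.
#' @param delim Delimiter for the written tables.
#' @return Invisibly, a list with the file paths and the \code{truth}
#'   object.
#' @export
simulate_cohort <- function(config = sim_config(), dir, seed = NULL,
                            delim = ",") {
  sim <- generate_cohort(config, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(dir, "cohort.csv")
  metrics_path <- file.path(dir, "metrics.csv")
  write_cohort(sim$cohort, cohort_path, delim)
  write_tract_metrics(sim$metrics, metrics_path, delim)
  truth <- sim$truth
  truth_list <- list(
    seed = truth$seed,
    age_loadings = truth$age_loadings,
    maturation_age_cor = as.list(truth$maturation_age_cor),
    em_beta = as.list(truth$em_beta),
    em_tract_coupling = truth$em_tract_coupling,
    realized = list(
      metric_age_cor = truth$realized$metric_age_cor,
      em_age_r2 = as.list(truth$realized$em_age_r2),
      maturation_age_cor = as.list(truth$realized$maturation_age_cor)),
    failed_subjects = truth$failed_subjects)
  jsonlite::write_json(truth_list, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort_path, metrics = metrics_path,
                 truth_file = file.path(dir, "truth.json"),
                 truth = truth))
}

#' Structural validation of a serialized report
#'
#' Checks a parsed \code{report.json} against the JSON schema shipped
#' with the package (\code{inst/schema/report.schema.json}): every
#' property listed as required at each level of the schema must be
#' present.  This is a structural check of presence and nesting, not a
#' full JSON-Schema validator.
#'
#' @param report A list as returned by \code{jsonlite::read_json}, or an
#'   \code{"analysis_report"}.
#' @param schema_path Path to the schema (defaults to the installed one).
#' @return TRUE invisibly, or an error naming the first missing field.
#' @export
validate_report <- function(report,
                            schema_path = system.file(
                              "schema", "report.schema.json",
                              package = "tractmaturity")) {
  if (inherits(report, "analysis_report"))
    report <- .report_as_list(report)
  schema <- jsonlite::read_json(schema_path)
  check <- function(node, sch, path) {
    req <- unlist(sch$required)
    for (r in req)
      if (!(r %in% names(node)))
        stop("report is missing required field: ",
             paste(c(path, r), collapse = "."), call. = FALSE)
    for (pn in names(sch$properties)) {
      child <- sch$properties[[pn]]
      if (!is.null(child$required) && pn %in% names(node) &&
          !is.null(node[[pn]]))
        check(node[[pn]], child, c(path, pn))
    }
  }
  check(report, schema, character(0))
  invisible(TRUE)
}
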