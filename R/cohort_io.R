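## canonical vocabularies used across the package
TRACTS <- c("uncinate_fasciculus", "dorsal_cingulum", "ventral_cingulum",
            "fornix")
HEMISPHERES <- c("left", "right")
METRICS <- c("fa", "rd", "ad")
EM_SCORES <- c("sdfr", "ldfr", "ldcr")
CVLT_MAX <- 15  # list length of the verbal learning task

## fixed predictor-column order: left FA, left RD, left AD, right FA,
## right RD, right AD - so saliences are comparable across runs
X_COLUMNS <- as.vector(t(outer(HEMISPHERES, METRICS, paste, sep = "_")))

.read_delim <- function(path, delim) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    fileEncoding = "UTF-8")
}

.require_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("format error: ", what, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

.fmt_num <- function(x) {
  ## full double precision so a write/read round trip is bit-exact
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Load a cohort table
#'
#' Reads a delimited text file with one row per subject and columns
#' \code{subject_id, age, sex, sdfr, ldfr, ldcr} and optionally
#' \code{discrimination}.  \code{sdfr}, \code{ldfr} and \code{ldcr} are the
#' short-delay free, long-delay free and long-delay cued recall scores of
#' the children's verbal learning task (out of a 15-word list);
#' \code{discrimination} is an unconstrained real memory-discrimination
#' score used for specificity checks.
#'
#' Structural problems (missing required columns, duplicated subject ids)
#' abort with an error.  Malformed rows - non-positive or non-numeric age,
#' recall scores outside [0, 15], sex outside {F, M} - are dropped with a
#' warning that reports their file line numbers; the dropped rows are kept
#' in the \code{"rejected"} attribute.  Fractional recall values are
#' accepted (simulated or averaged scores are continuous).
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter: \code{","} (default) or \code{"\t"}.
#' @return A data.frame of class \code{"cohort"} with attribute
#'   \code{"rejected"} (data.frame of \code{line}, \code{subject_id},
#'   \code{reason}).
#' @export
load_cohort <- function(path, delim = ",") {
  df <- .read_delim(path, delim)
  .require_columns(df, c("subject_id", "age", "sex", EM_SCORES), "cohort")
  df$subject_id <- as.character(df$subject_id)
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup))
    stop("integrity error: duplicated subject_id: ",
         paste(dup, collapse = ", "), call. = FALSE)
  as_cohort(df, .lines = seq_len(nrow(df)) + 1L)
}

#' Validate a data.frame as a cohort
#'
#' Applies the row-level checks of \code{\link{load_cohort}} to an
#' in-memory data.frame.
#'
#' @param df A data.frame with the cohort columns.
#' @param .lines Internal: file line numbers used in rejection reports.
#' @return A \code{"cohort"} data.frame.
#' @export
as_cohort <- function(df, .lines = seq_len(nrow(df)) + 1L) {
  .require_columns(df, c("subject_id", "age", "sex", EM_SCORES), "cohort")
  df$subject_id <- as.character(df$subject_id)
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup))
    stop("integrity error: duplicated subject_id: ",
         paste(dup, collapse = ", "), call. = FALSE)
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  age <- suppressWarnings(as.numeric(df$age))
  flag(is.na(age) | age <= 0, "age must be a positive number")
  flag(!(df$sex %in% c("F", "M")), "sex must be F or M")
  for (sc in EM_SCORES) {
    v <- suppressWarnings(as.numeric(df[[sc]]))
    flag(is.na(v) | v < 0 | v > CVLT_MAX,
         sprintf("%s outside recall range [0, %d]", sc, CVLT_MAX))
    df[[sc]] <- v
  }
  df$age <- age
  if ("discrimination" %in% names(df))
    df$discrimination <- suppressWarnings(as.numeric(df$discrimination))
  rejected <- data.frame(
    line = .lines[!is.na(reason)],
    subject_id = df$subject_id[!is.na(reason)],
    reason = reason[!is.na(reason)],
    stringsAsFactors = FALSE
  )
  if (nrow(rejected))
    warning("rejected ", nrow(rejected), " malformed cohort row(s) at line(s) ",
            paste(rejected$line, collapse = ", "), call. = FALSE)
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write a cohort table
#'
#' Inverse of \code{\link{load_cohort}}; numeric columns are written with
#' full double precision so that write-then-read reproduces values
#' bit-exactly.
#'
#' @param cohort A cohort data.frame.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  out <- as.data.frame(cohort)
  for (nm in intersect(c("age", EM_SCORES, "discrimination"), names(out)))
    out[[nm]] <- .fmt_num(out[[nm]])
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a tract-metrics table
#'
#' Reads a delimited file with one row per (subject, tract, hemisphere)
#' and columns \code{subject_id, tract, hemisphere, fa, rd, ad}.
#' \code{tract} must be one of \code{uncinate_fasciculus, dorsal_cingulum,
#' ventral_cingulum, fornix}; \code{hemisphere} one of \code{left, right};
#' \code{fa} lies in [0, 1]; \code{rd} and \code{ad} are positive
#' diffusivities.  Any consistent diffusivity unit is accepted (mm^2/s or
#' 1e-3 mm^2/s): downstream standardization makes all results
#' scale-invariant, so no conversion is applied.  Missing rows (failed
#' tract reconstructions) are allowed; duplicated (subject, tract,
#' hemisphere) triples are an integrity error.  Malformed rows are dropped
#' with a warning, as in \code{\link{load_cohort}}.
#'
#' @inheritParams load_cohort
#' @return A data.frame of class \code{"tract_metrics"} with attribute
#'   \code{"rejected"}.
#' @export
load_tract_metrics <- function(path, delim = ",") {
  df <- .read_delim(path, delim)
  as_tract_metrics(df, .lines = seq_len(nrow(df)) + 1L)
}

#' Validate a data.frame as a tract-metrics table
#' @param df A data.frame with the metric columns.
#' @param .lines Internal: file line numbers used in rejection reports.
#' @return A \code{"tract_metrics"} data.frame.
#' @export
as_tract_metrics <- function(df, .lines = seq_len(nrow(df)) + 1L) {
  .require_columns(df, c("subject_id", "tract", "hemisphere", METRICS),
                   "tract metrics")
  df$subject_id <- as.character(df$subject_id)
  key <- paste(df$subject_id, df$tract, df$hemisphere)
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop("integrity error: duplicated (subject, tract, hemisphere) row(s): ",
         paste(dup, collapse = "; "), call. = FALSE)
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  flag(!(df$tract %in% TRACTS),
       paste("tract must be one of:", paste(TRACTS, collapse = ", ")))
  flag(!(df$hemisphere %in% HEMISPHERES), "hemisphere must be left or right")
  for (m in METRICS) df[[m]] <- suppressWarnings(as.numeric(df[[m]]))
  flag(is.na(df$fa) | df$fa < 0 | df$fa > 1, "fa must lie in [0, 1]")
  flag(is.na(df$rd) | df$rd <= 0, "rd must be a positive diffusivity")
  flag(is.na(df$ad) | df$ad <= 0, "ad must be a positive diffusivity")
  rejected <- data.frame(
    line = .lines[!is.na(reason)],
    subject_id = df$subject_id[!is.na(reason)],
    reason = reason[!is.na(reason)],
    stringsAsFactors = FALSE
  )
  if (nrow(rejected))
    warning("rejected ", nrow(rejected), " malformed metric row(s) at line(s) ",
            paste(rejected$line, collapse = ", "), call. = FALSE)
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("tract_metrics", "data.frame")
  out
}

#' Write a tract-metrics table
#' @param metrics A tract_metrics data.frame.
#' @inheritParams write_cohort
#' @export
write_tract_metrics <- function(metrics, path, delim = ",") {
  out <- as.data.frame(metrics)
  for (m in METRICS) out[[m]] <- .fmt_num(out[[m]])
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Two-stage streamline-to-tract metric aggregation
#'
#' A tract-level diffusion metric is the mean over streamlines of the
#' per-streamline means of the sampled values: every streamline
#' contributes equally regardless of how many points were sampled along
#' it.  This is deliberately \emph{not} the pooled mean over all samples,
#' which would weight streamlines by their sample counts.
#'
#' @param samples Either a list of numeric vectors (one per streamline) or
#'   a data.frame with columns \code{streamline_id} and \code{value}.
#' @return The tract-mean metric (a single number).
#' @examples
#' aggregate_streamline_metrics(list(c(0, 2), 4))  # 2.5, not the pooled 2
#' @export
aggregate_streamline_metrics <- function(samples) {
  if (is.data.frame(samples)) {
    .require_columns(samples, c("streamline_id", "value"),
                     "streamline samples")
    samples <- split(samples$value, samples$streamline_id)
  }
  if (!is.list(samples)) samples <- list(samples)
  if (length(samples) == 0L)
    stop("no streamlines to aggregate", call. = FALSE)
  ok <- vapply(samples, function(v) length(v) >= 1L && is.numeric(v) &&
                 all(is.finite(v)), logical(1))
  if (!all(ok))
    stop("every streamline needs at least one finite sample", call. = FALSE)
  mean(vapply(samples, mean, numeric(1)))
}

#' Load per-streamline metric samples
#'
#' Reads one CSV per tract with columns \code{streamline_id},
#' \code{position_index}, \code{value} (samples along each streamline,
#' ordered by position) into the list form accepted by
#' \code{\link{aggregate_streamline_metrics}}.
#'
#' @inheritParams load_cohort
#' @return A named list of numeric vectors, one per streamline.
#' @export
load_streamline_samples <- function(path, delim = ",") {
  df <- .read_delim(path, delim)
  .require_columns(df, c("streamline_id", "position_index", "value"),
                   "streamline samples")
  df <- df[order(df$streamline_id, df$position_index), ]
  split(df$value, df$streamline_id)
}

#' Assemble the per-tract analysis matrix
#'
#' Builds the listwise-complete blocks for one tract: \code{X} holds the
#' six diffusion metrics (columns in the fixed order left FA, left RD,
#' left AD, right FA, right RD, right AD) and \code{Y} holds either the
#' three recall scores or age.  Subjects missing either hemisphere of the
#' tract, or any Y variable, are dropped listwise (no imputation);
#' the dropped ids are reported in the \code{dropped} element.  Rows are
#' ordered by sorted subject id regardless of input order.
#'
#' @param cohort A \code{"cohort"} data.frame.
#' @param metrics A \code{"tract_metrics"} data.frame.
#' @param tract Tract identifier (one of the four canonical tracts).
#' @param y_spec \code{"em_scores"} (default) or \code{"age"}.
#' @return An object of class \code{"analysis_matrix"}: list with
#'   \code{subject_ids}, \code{X}, \code{x_names}, \code{Y},
#'   \code{y_names}, \code{tract}, \code{y_spec}, \code{dropped}.
#' @export
build_analysis_matrix <- function(cohort, metrics, tract,
                                  y_spec = c("em_scores", "age")) {
  y_spec <- match.arg(y_spec)
  tract <- match.arg(tract, TRACTS)
  if (!any(metrics$tract == tract))
    stop("tract '", tract, "' not present in the metrics table",
         call. = FALSE)
  sub <- metrics[metrics$tract == tract, , drop = FALSE]
  ids <- sort(unique(cohort$subject_id))
  p <- length(X_COLUMNS)
  X <- matrix(NA_real_, length(ids), p,
              dimnames = list(ids, X_COLUMNS))
  for (h in HEMISPHERES) {
    hs <- sub[sub$hemisphere == h, , drop = FALSE]
    keep <- hs$subject_id %in% ids
    for (m in METRICS)
      X[hs$subject_id[keep], paste(h, m, sep = "_")] <- hs[[m]][keep]
  }
  ci <- match(ids, cohort$subject_id)
  if (y_spec == "em_scores") {
    Y <- as.matrix(cohort[ci, EM_SCORES, drop = FALSE])
    colnames(Y) <- EM_SCORES
  } else {
    Y <- matrix(cohort$age[ci], ncol = 1, dimnames = list(NULL, "age"))
  }
  rownames(Y) <- ids
  complete <- stats::complete.cases(X) & stats::complete.cases(Y)
  dropped <- ids[!complete]
  if (length(dropped))
    message("dropped ", length(dropped), " subject(s) for tract '", tract,
            "': ", paste(dropped, collapse = ", "))
  n <- sum(complete)
  if (n < p + 2L)
    stop("insufficient data for tract '", tract, "': n = ", n,
         " after listwise deletion but at least ", p + 2L, " subjects ",
         "are required", call. = FALSE)
  structure(
    list(subject_ids = ids[complete],
         X = X[complete, , drop = FALSE],
         x_names = X_COLUMNS,
         Y = Y[complete, , drop = FALSE],
         y_names = colnames(Y),
         tract = tract,
         y_spec = y_spec,
         dropped = dropped),
    class = "analysis_matrix"
  )
}

#' @export
print.analysis_matrix <- function(x, ...) {
  cat("Analysis matrix for tract '", x$tract, "' (Y = ", x$y_spec, "): n = ",
      length(x$subject_ids), ", p = ", ncol(x$X), ", q = ", ncol(x$Y),
      "\n", sep = "")
  if (length(x$dropped))
    cat("Dropped subjects:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
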