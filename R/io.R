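#' Read a scan configuration from a YAML file
#'
#' The schema is a flat key-value document:
#' \preformatted{
#' pairing: homologous          # or complementary
#' polarity: parallel           # or antiparallel
#' alphabet: binary             # binary | rna | explicit symbol string
#' L: 4
#' n_pairs: 2
#' sample_size: null            # null = exhaustive
#' replicates: 1
#' seed: 1
#' elongation_mean: 1.0
#' elongation_width: 0.0
#' influx_mean: 1.0
#' influx_width: 0.0
#' monomer_decay_mean: 1.0
#' monomer_decay_width: 0.0
#' intermediate_decay_mean: 0.01
#' intermediate_decay_width: 0.1
#' }
#' Missing rate keys fall back to the [rate_distribution()] defaults.
#'
#' @param path path to the YAML file.
#' @return A [survey_config()].
#' @export
read_survey_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- function(key) {
    if (is.null(cfg[[key]]))
      stop("config field '", key, "' is required (", path, ")")
    cfg[[key]]
  }
  alphabet <- switch(as.character(cfg$alphabet %||% "binary"),
    binary = binary_alphabet(),
    rna = rna_alphabet(),
    monomer_alphabet(seq_chars(as.character(cfg$alphabet))))
  dist_keys <- c("elongation_mean", "elongation_width", "influx_mean",
                 "influx_width", "monomer_decay_mean", "monomer_decay_width",
                 "intermediate_decay_mean", "intermediate_decay_width")
  dist_args <- cfg[intersect(dist_keys, names(cfg))]
  survey_config(
    scheme = pairing_scheme(need("pairing"), need("polarity")),
    alphabet = alphabet,
    L = need("L"),
    n_pairs = cfg$n_pairs %||% 2L,
    sample_size = cfg$sample_size,
    replicates = cfg$replicates %||% 1L,
    dist = do.call(rate_distribution, dist_args),
    seed = cfg$seed %||% 1L
  )
}

#' Write the per-cell table and summary of a scan to CSV
#'
#' The summary row mirrors the structure of the published scan tables
#' (group size or length, scanned count, coexistence fraction, mean leading
#' eigenvalue); the per-cell table follows below the summary file.
#'
#' @param survey a `replicator_survey` result.
#' @param path output file; a companion `<path>_cells.csv` receives the
#'   per-cell records.
#' @return Invisibly, the summary data frame.
#' @export
write_survey_csv <- function(survey, path) {
  stopifnot(inherits(survey, "replicator_survey"))
  summary_df <- data.frame(
    n_pairs = survey$config$n_pairs,
    L = survey$config$L,
    n_scanned = survey$n_scanned,
    n_runs = survey$n_runs,
    fraction_coexisting = survey$fraction_coexisting,
    mean_leading_eigenvalue = survey$mean_leading_eigenvalue,
    n_unconverged = survey$n_unconverged,
    seed = survey$config$seed
  )
  utils::write.csv(summary_df, path, row.names = FALSE)
  cells_path <- sub("(\\.csv)?$", "_cells.csv", path)
  utils::write.csv(survey$cells, cells_path, row.names = FALSE)
  invisible(summary_df)
}

#' Export a coexistence matrix as CSV
#'
#' Writes the outcome matrix with the axis ordering recorded in the header
#' comment; for the ode engine the split-plot convention is applied to a
#' second value matrix: outcomes fill the lower triangle and leading
#' eigenvalues (or replicate coexistence probabilities) the upper triangle.
#'
#' @param mat a [coexistence_matrix()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_matrix_csv <- function(mat, path) {
  stopifnot(inherits(mat, "coexistence_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# axis ordering: ", mat$order,
                    "; engine: ", mat$engine), con)
  utils::write.csv(mat$outcome, con)
  if (mat$engine == "ode") {
    vals <- if (!is.null(mat$probability)) mat$probability else mat$eigenvalue
    split <- matrix(NA, nrow(vals), ncol(vals), dimnames = dimnames(vals))
    split[lower.tri(split, diag = TRUE)] <-
      mat$outcome[lower.tri(split, diag = TRUE)]
    split[upper.tri(split)] <- vals[upper.tri(vals)]
    writeLines("# split plot: lower triangle outcomes, upper triangle values",
               con)
    utils::write.csv(split, con)
  }
  invisible(path)
}

#' JSON run manifest
#'
#' Records the configuration, seeds, package version and outcome summary of
#' a scan or single run, sufficient to re-execute it bit-identically with
#' the same solver version.
#'
#' @param object a `replicator_survey`, `competition_run` or
#'   [coexistence_matrix()].
#' @param path optional file to write; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to file.
#' @export
run_manifest <- function(object, path = NULL) {
  describe_config <- function(cfg) list(
    pairing = cfg$scheme$pairing, polarity = cfg$scheme$polarity,
    alphabet = paste(cfg$alphabet$symbols, collapse = ""),
    L = cfg$L, n_pairs = cfg$n_pairs,
    sample_size = cfg$sample_size, replicates = cfg$replicates,
    seed = cfg$seed, dist = unclass(cfg$dist)
  )
  body <- if (inherits(object, "replicator_survey")) {
    list(kind = "survey", config = describe_config(object$config),
         fraction_coexisting = object$fraction_coexisting,
         mean_leading_eigenvalue = object$mean_leading_eigenvalue,
         n_scanned = object$n_scanned, n_runs = object$n_runs,
         n_unconverged = object$n_unconverged)
  } else if (inherits(object, "coexistence_matrix")) {
    list(kind = "matrix", engine = object$engine, order = object$order,
         config = describe_config(object$config),
         n_sequences = length(object$sequences))
  } else if (inherits(object, "competition_run")) {
    list(kind = "simulation",
         sequences = object$system$pairs$plus,
         pairing = object$system$scheme$pairing,
         polarity = object$system$scheme$polarity,
         outcome = object$outcome,
         converged = object$steady_state$converged,
         leading_eigenvalue =
           if (is.null(object$stability)) NULL
           else object$stability$leading_eigenvalue)
  } else stop("unsupported object for a run manifest")
  body$tool_version <- as.character(utils::packageVersion("replicoex"))
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
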