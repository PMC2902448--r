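# Delimited-matrix I/O and the end-to-end run driver behind the
# command-line interface.

#' Read a samples x variables matrix from delimited text
#'
#' Expects a header row of variable names; a first column of
#' non-numeric sample identifiers is detected and used as row labels.
#' The delimiter (tab or comma) is sniffed from the header line.
#' Missing or non-numeric cells are rejected with their coordinates.
#'
#' @param path File path (TSV or CSV).
#' @param transpose If `TRUE` the file stores variables in rows (the
#'   common expression-matrix layout) and is transposed after reading.
#' @return Numeric matrix with `dimnames`.
#' @export
read_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 0 || nrow(df) == 0)
    stop("empty table: ", path, call. = FALSE)
  row_labels <- NULL
  if (!is.numeric(df[[1]]) &&
      suppressWarnings(any(is.na(as.numeric(as.character(df[[1]])))))) {
    row_labels <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  M <- as.matrix(df)
  suppressWarnings(storage.mode(M) <- "double")
  if (any(!is.finite(M))) {
    bad <- which(!is.finite(M), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric or missing value at row %d, column '%s'",
      bad[1], colnames(M)[bad[2]]), call. = FALSE)
  }
  rownames(M) <- row_labels
  if (transpose) M <- t(M)
  M
}

#' Run configuration for the command-line driver
#'
#' @param input_path Path to the input matrix (TSV/CSV).
#' @param method `"pca"`, `"spca"` or `"sspca"` (`sspca` enables
#'   condition-number shrinkage).
#' @param penalty Penalty family for the sparse methods (`"hl"`,
#'   `"lasso"`, `"scad"`, `"en"`).
#' @param w Gamma variance for the HL penalty.
#' @param k Component count, or `"auto"` for permutation selection.
#' @param cv_folds CV folds for tuning.
#' @param permutations,alpha Permutation-test controls (used when
#'   `k = "auto"`; at least 100 permutations are required then).
#' @param transpose Transpose the input after reading?
#' @param output_dir Directory for result files.
#' @param seed Integer seed.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input_path, method = c("pca", "spca", "sspca"),
                       penalty = c("hl", "lasso", "scad", "en"),
                       w = 30, k = 1L, cv_folds = 5L,
                       permutations = 1000L, alpha = 0.001,
                       transpose = FALSE,
                       output_dir = "sspca_out", seed = 1L) {
  method <- match.arg(method)
  penalty <- match.arg(penalty)
  auto_k <- identical(k, "auto")
  if (!auto_k) {
    k <- as.integer(k)
    if (is.na(k) || k < 1) stop("k must be a positive integer or 'auto'",
                                call. = FALSE)
  }
  if (auto_k && permutations < 100)
    stop("k = 'auto' requires at least 100 permutations", call. = FALSE)
  structure(list(input_path = input_path, method = method,
                 penalty = penalty, w = w, k = k, auto_k = auto_k,
                 cv_folds = as.integer(cv_folds),
                 permutations = as.integer(permutations), alpha = alpha,
                 transpose = transpose, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Execute a configured analysis and write result files
#'
#' Reads the matrix, centers it, optionally selects the number of
#' components by permutation, fits the requested method, and writes:
#' `loadings.tsv` (full-precision loadings plus a sparsity mask using
#' the 5e-5 reporting threshold), `scores.tsv`, `summary.tsv`
#' (singular values, nonzero counts, adjusted and cumulative adjusted
#' variance), `permutation.tsv` (when `k = "auto"`), and
#' `manifest.json` recording the seed and tuning choices.  On error,
#' partial outputs are removed.
#'
#' @param config A [run_config()].
#' @return The fitted `"sspca_fit"` object, invisibly.
#' @export
sspca_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("run failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    M <- read_matrix(config$input_path, transpose = config$transpose)
    Xc <- center_columns(M)
    set.seed(config$seed)
    perm <- NULL
    k <- config$k
    if (config$auto_k) {
      perm <- permutation_component_count(Xc, P = config$permutations,
                                          alpha = config$alpha,
                                          seed = config$seed)
      k <- max(perm$k0, 1L)
    }
    spec <- if (config$method == "pca") penalty_spec("NONE")
            else penalty_spec(toupper(config$penalty),
                              lambda = NA_real_, w = config$w)
    fit <- sspca_fit(Xc, k = k, spec = spec,
                     shrink = (config$method == "sspca"),
                     tuning = tuning_config(K = config$cv_folds,
                                            seed = config$seed))

    od <- config$output_dir
    f <- function(name) { p <- file.path(od, name)
                          written <<- c(written, p); p }
    L <- fit$loadings
    var_names <- if (!is.null(Xc$col_labels)) Xc$col_labels
                 else paste0("V", seq_len(ncol(Xc$values)))
    ld <- data.frame(variable = var_names, L, check.names = FALSE)
    colnames(ld)[-1] <- paste0("PC", seq_len(k))
    mask <- (abs(L) >= spec$zero_threshold) * 1L
    colnames(mask) <- paste0("nonzero_PC", seq_len(k))
    write_tsv(cbind(ld, mask), f("loadings.tsv"))
    sc <- data.frame(
      sample = if (!is.null(Xc$row_labels)) Xc$row_labels
               else paste0("S", seq_len(nrow(Xc$values))),
      fit$scores, check.names = FALSE)
    colnames(sc)[-1] <- paste0("PC", seq_len(k))
    write_tsv(sc, f("scores.tsv"))
    write_tsv(data.frame(
      component = seq_len(k),
      singular_value = fit$singular_values,
      nonzero_loadings = fit$nonzero_counts,
      lambda = fit$lambdas,
      adjusted_variance_pct = fit$adjusted_variance,
      cumulative_adjusted_variance_pct =
        fit$cumulative_adjusted_variance),
      f("summary.tsv"))
    if (!is.null(perm))
      write_tsv(data.frame(component = seq_along(perm$p_values),
                           d_observed = perm$d_observed,
                           p_value = perm$p_values),
                f("permutation.tsv"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("sspca")),
      r_version = R.version.string,
      input_path = config$input_path, method = config$method,
      penalty = if (config$method == "pca") NULL else config$penalty,
      w = config$w, k = k, auto_k = config$auto_k,
      k0 = if (!is.null(perm)) perm$k0 else NULL,
      cv_folds = config$cv_folds, seed = config$seed,
      kappa_max = fit$kappa_max, theta = fit$theta,
      lambdas = fit$lambdas,
      zero_threshold = spec$zero_threshold)
    jsonlite::write_json(manifest, f("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    invisible(fit)
  }, error = on_fail)
}
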