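#' Write a cohort to CSV with a JSON sidecar
#'
#' The CSV has columns `oxi_1..oxi_p1`, `meta_1..meta_p2`, `label` (shared
#' covariates appear in both blocks). If the cohort carries a generating
#' spec, it is stored — true parameters, seed and all — in a `.json`
#' sidecar next to the CSV so the generating process travels with the data.
#'
#' @param cohort an `hs_cohort` (or any list with `X_oxi`, `X_meta`, `y`).
#' @param path output CSV path.
#' @param spec_path sidecar path; defaults to `path` with `.json` appended.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, spec_path = paste0(path, ".json")) {
  p1 <- ncol(cohort$X_oxi); p2 <- ncol(cohort$X_meta)
  df <- data.frame(cohort$X_oxi, cohort$X_meta, label = cohort$y)
  names(df) <- c(paste0("oxi_", seq_len(p1)), paste0("meta_", seq_len(p2)),
                 "label")
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(cohort$spec) && !is.null(spec_path)) {
    sp <- unclass(cohort$spec)
    jsonlite::write_json(sp, spec_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Columns are selected by name, so file column order is irrelevant. Rows
#' with missing values in the mapped columns are dropped with a warning
#' giving the count; the label column must be integer-valued. A category
#' census is reported via `message()`. If a generating-spec sidecar exists
#' next to the file it is reattached.
#'
#' @param path CSV path with a header row.
#' @param oxi_cols,meta_cols character vectors naming the covariate columns
#'   of each axis; by default all columns matching `^oxi_` / `^meta_`.
#' @param label_col name of the ordinal label column (default `"label"`).
#' @return an `hs_cohort`.
#' @export
read_cohort <- function(path, oxi_cols = NULL, meta_cols = NULL,
                        label_col = "label") {
  df <- utils::read.csv(path, check.names = FALSE)
  detect <- function(prefix) {
    found <- grep(paste0("^", prefix), names(df), value = TRUE)
    # canonical order by numeric suffix, independent of file column order
    found[order(suppressWarnings(
      as.numeric(sub(paste0("^", prefix), "", found))), found)]
  }
  if (is.null(oxi_cols)) oxi_cols <- detect("oxi_")
  if (is.null(meta_cols)) meta_cols <- detect("meta_")
  missing_cols <- setdiff(c(oxi_cols, meta_cols, label_col), names(df))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (!length(oxi_cols) || !length(meta_cols))
    stop("oxi and meta column sets must be non-empty")
  if (label_col %in% c(oxi_cols, meta_cols))
    stop("label column must be distinct from covariate columns")
  used <- df[, c(oxi_cols, meta_cols, label_col)]
  keep <- stats::complete.cases(used)
  if (any(!keep)) {
    warning(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    used <- used[keep, , drop = FALSE]
  }
  y <- used[[label_col]]
  if (!is.numeric(y) || any(y != floor(y))) {
    bad <- which(!is.numeric(y) | y != floor(y))[1L]
    stop(sprintf("non-integer label at row %d", bad))
  }
  y <- as.integer(y)
  census <- table(y)
  message("label census: ",
          paste(sprintf("%s:%d", names(census), census), collapse = "  "))
  spec <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sp <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    spec <- try(do.call(cohort_spec, sp[c(
      "n_samples", "n_categories", "seed", "alpha_true", "beta_oxi_true",
      "beta_meta_true", "nonlinearity", "nonlin_coef", "noise_scale")]),
      silent = TRUE)
    if (inherits(spec, "try-error")) spec <- NULL
  }
  structure(list(
    X_oxi = as_num_matrix(used[, oxi_cols, drop = FALSE], "oxi columns"),
    X_meta = as_num_matrix(used[, meta_cols, drop = FALSE], "meta columns"),
    y = y, spec = spec), class = "hs_cohort")
}

#' Write health-space scores to CSV
#' @param hs a [health_space()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(hs, path) {
  df <- data.frame(sample_id = seq_along(hs$labels),
                   raw_oxi = hs$raw_oxi, raw_meta = hs$raw_meta,
                   norm_oxi = hs$norm_oxi, norm_meta = hs$norm_meta,
                   label = hs$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize an HSI result to JSON
#' @param x an `hsi_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_hsi <- function(x, path) {
  jsonlite::write_json(list(level = x$level, method = x$method,
                            average = x$average, pairs = x$pairs),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Save and load fitted axis models as JSON
#'
#' All parameters — layer weights, shared coefficients, threshold
#' intercepts, standardization constants and training configuration — are
#' stored as plain JSON so fits round-trip between sessions and machines.
#'
#' @param model a fitted `donn`, `binary_dnn` or `pom`.
#' @param path JSON file path.
#' @return `save_hs_model()` returns `path` invisibly; `load_hs_model()`
#'   the reconstructed model.
#' @export
save_hs_model <- function(model, path) {
  if (inherits(model, "donn")) {
    obj <- list(type = if (inherits(model, "binary_dnn")) "binary_dnn" else "donn",
                mode = model$mode, hidden = model$hidden, J = model$J,
                p = model$p, center = model$center, scale = model$scale,
                standardize = model$standardize,
                W = model$params$W, b = model$params$b,
                beta = model$params$beta, alpha = model$params$alpha,
                best_epoch = model$best_epoch,
                alpha_ordered = model$alpha_ordered, config = model$config)
  } else if (inherits(model, "pom")) {
    obj <- list(type = "pom", J = model$J, p = model$p,
                alpha = model$alpha, beta = model$beta,
                logLik = model$logLik, n = model$n)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_hs_model
#' @export
load_hs_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "pom") {
    return(structure(list(alpha = obj$alpha, beta = obj$beta, J = obj$J,
                          p = obj$p, logLik = obj$logLik, n = obj$n),
                     class = "pom"))
  }
  W <- lapply(obj$W, function(w) {
    m <- as.matrix(w); storage.mode(m) <- "double"; m
  })
  b <- lapply(obj$b, as.numeric)
  model <- structure(list(
    params = list(W = W, b = b, beta = as.numeric(obj$beta),
                  alpha = as.numeric(obj$alpha)),
    J = obj$J, p = obj$p, hidden = as.integer(obj$hidden %||% integer(0)),
    center = as.numeric(obj$center), scale = as.numeric(obj$scale),
    standardize = obj$standardize,
    train_log = data.frame(), best_epoch = obj$best_epoch,
    alpha_ordered = obj$alpha_ordered, config = obj$config,
    mode = obj$mode),
    class = "donn")
  if (identical(obj$type, "binary_dnn"))
    class(model) <- c("binary_dnn", "donn")
  model
}
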