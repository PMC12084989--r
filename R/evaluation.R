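#' Names of the six health-space models
#'
#' One deep ordinal network, four binary DNN variants and the proportional
#' odds baseline, in the order they are reported.
#' @export
hs_model_names <- function() {
  c("DONN", "BinaryDNN_0v3", "BinaryDNN_0v123", "BinaryDNN_01v23",
    "BinaryDNN_012v3", "POM")
}

binary_mode_for <- function(name) {
  switch(name,
         BinaryDNN_0v3 = "zero_vs_three",
         BinaryDNN_0v123 = "zero_vs_rest",
         BinaryDNN_01v23 = "low_vs_high",
         BinaryDNN_012v3 = "rest_vs_three",
         stop("unknown binary model name: ", name))
}

# Fit one named model on one covariate block.
fit_axis_model <- function(name, x, y, J, fit_args) {
  tryCatch({
    if (name == "DONN") {
      do.call(donn, c(list(x = x, y = y, J = J), fit_args))
    } else if (name == "POM") {
      pom(x, y, J = J)
    } else {
      do.call(binary_dnn, c(list(x = x, y = y, mode = binary_mode_for(name),
                                 J = J), fit_args))
    }
  }, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

# Fit both axes of one named model and return its training health space.
fit_hs_model <- function(name, cohort, J, fit_args, normalizer) {
  m_oxi <- fit_axis_model(name, cohort$X_oxi, cohort$y, J, fit_args)
  fit_args_meta <- fit_args
  if (!is.null(fit_args_meta$seed)) fit_args_meta$seed <- fit_args_meta$seed + 1L
  m_meta <- fit_axis_model(name, cohort$X_meta, cohort$y, J, fit_args_meta)
  health_space(m_oxi, m_meta, cohort$X_oxi, cohort$X_meta, cohort$y,
               normalizer = normalizer)
}

hs_metrics_row <- function(hs, level, hsi_method, resolution, n_points, seed) {
  hsi <- pairwise_hsi(hs, level = level, method = hsi_method,
                      resolution = resolution, n_points = n_points,
                      seed = seed)
  cm <- cluster_metrics(hs)
  data.frame(avg_hsi = hsi$average, silhouette = cm$silhouette,
             davies_bouldin = cm$davies_bouldin,
             calinski_harabasz = cm$calinski_harabasz,
             n = length(hs$labels))
}

#' Fit and compare the six health-space models
#'
#' Fits each requested model once per axis on the training cohort, then for
#' the training cohort and every external cohort computes the average
#' Health Space Index and the three clustering indices on the 2-D scores.
#' External cohorts are scored with the frozen axis models and
#' normalization constants — they never enter training.
#'
#' @param train a cohort (as from [generate_cohort()] or [read_cohort()])
#'   containing all ordinal categories.
#' @param eval_sets named list of external cohorts to score (optional).
#' @param models subset of [hs_model_names()] to fit.
#' @param J number of ordinal categories.
#' @param fit_args list of arguments passed to the network fits (`hidden`,
#'   `epochs`, `batch_size`, `seed`, ...); POM takes none.
#' @param normalizer score normalizer, see [health_space()].
#' @param level,hsi_method,resolution,n_points,hsi_seed HSI settings, see
#'   [pairwise_hsi()].
#' @return an object of class `hs_evaluation`: a data frame with one row
#'   per (model, dataset) holding the four measures, with the fitted health
#'   spaces in `attr(, "spaces")`.
#' @export
evaluate_models <- function(train, eval_sets = list(),
                            models = hs_model_names(), J = 4L,
                            fit_args = list(), normalizer = "minmax",
                            level = 0.95, hsi_method = "grid",
                            resolution = 512L, n_points = 2e5,
                            hsi_seed = 1L) {
  stopifnot(all(models %in% hs_model_names()))
  if (length(setdiff(0:(J - 1L), unique(train$y))))
    stop("training cohort must contain all ordinal categories")
  if (length(eval_sets) && is.null(names(eval_sets)))
    names(eval_sets) <- paste0("eval", seq_along(eval_sets))
  rows <- list(); spaces <- list()
  for (name in models) {
    hs_train <- fit_hs_model(name, train, J, fit_args, normalizer)
    spaces[[name]] <- hs_train
    r <- hs_metrics_row(hs_train, level, hsi_method, resolution, n_points,
                        hsi_seed)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(model = name, dataset = "train"), r)
    for (ds in names(eval_sets)) {
      ev <- eval_sets[[ds]]
      hs_ev <- predict(hs_train, ev$X_oxi, ev$X_meta, ev$y)
      r <- hs_metrics_row(hs_ev, level, hsi_method, resolution, n_points,
                          hsi_seed)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(model = name, dataset = ds), r)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, spaces = spaces, class = c("hs_evaluation", "data.frame"))
}

#' @export
print.hs_evaluation <- function(x, digits = 4, ...) {
  cat("Health-space model comparison\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bootstrap the average Health Space Index of one model
#'
#' Quantifies the sampling variability of a model's average HSI. For each of
#' `B` replicates the training cohort is resampled with replacement, the
#' model is refitted on both axes (`refit = TRUE`, the default) or the
#' fitted scores are resampled without refitting (`refit = FALSE`), and the
#' average HSI is recomputed — on the replicate itself by default, or on the
#' out-of-bag rows with `oob = TRUE`. The summary is the replicate mean with
#' a 95 percent percentile interval. Replicates missing an ordinal category
#' (or, for the 0-vs-3 model, an extreme category) are redrawn up to 10
#' times.
#'
#' @param train training cohort.
#' @param model one of [hs_model_names()].
#' @param B number of bootstrap replicates (>= 20; 200 in a full run).
#' @param seed RNG seed; the whole procedure is reproducible given it.
#' @param refit refit the model on every replicate (default) or resample
#'   fitted scores only.
#' @param oob evaluate each replicate's HSI on its out-of-bag rows.
#' @param J,fit_args,normalizer,level,hsi_method,resolution,n_points as in
#'   [evaluate_models()].
#' @return an object of class `hs_bootstrap`: `estimate` (full-data average
#'   HSI), `replicates`, `boot_mean`, `ci_low`, `ci_high`.
#' @export
bootstrap_hsi <- function(train, model = "DONN", B = 200L, seed = 1L,
                          refit = TRUE, oob = FALSE, J = 4L,
                          fit_args = list(), normalizer = "minmax",
                          level = 0.95, hsi_method = "grid",
                          resolution = 512L, n_points = 2e5) {
  stopifnot(model %in% hs_model_names())
  B <- as.integer(B)
  if (B < 20L) stop("B must be >= 20")
  n <- length(train$y)
  hsi_of <- function(hs) pairwise_hsi(hs, level = level, method = hsi_method,
                                      resolution = resolution,
                                      n_points = n_points,
                                      seed = seed)$average
  full_hs <- fit_hs_model(model, train, J, fit_args, normalizer)
  estimate <- hsi_of(full_hs)

  needed <- if (model == "BinaryDNN_0v3") c(0L, J - 1L) else 0:(J - 1L)
  reps <- numeric(B)
  with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
    for (b in seq_len(B)) {
      idx <- NULL
      for (try in 1:10) {
        cand <- sample.int(n, n, replace = TRUE)
        if (all(needed %in% unique(train$y[cand]))) { idx <- cand; break }
      }
      if (is.null(idx))
        stop(sprintf("replicate %d missing a category after 10 redraws", b))
      boot <- list(X_oxi = train$X_oxi[idx, , drop = FALSE],
                   X_meta = train$X_meta[idx, , drop = FALSE],
                   y = train$y[idx])
      if (refit) {
        fa <- fit_args
        fa$seed <- rep_seeds[b]
        hs_b <- fit_hs_model(model, boot, J, fa, normalizer)
        target <- if (oob) {
          out_rows <- setdiff(seq_len(n), unique(idx))
          predict(hs_b, train$X_oxi[out_rows, , drop = FALSE],
                  train$X_meta[out_rows, , drop = FALSE],
                  train$y[out_rows])
        } else hs_b
      } else {
        target <- full_hs
        target$raw_oxi <- full_hs$raw_oxi[idx]
        target$raw_meta <- full_hs$raw_meta[idx]
        target$norm_oxi <- full_hs$norm_oxi[idx]
        target$norm_meta <- full_hs$norm_meta[idx]
        target$labels <- full_hs$labels[idx]
      }
      reps[b] <- hsi_of(target)
    }
  })
  ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  structure(list(model = model, B = B, estimate = estimate,
                 replicates = reps, boot_mean = mean(reps),
                 ci_low = ci[1L], ci_high = ci[2L],
                 refit = refit, oob = oob, seed = seed),
            class = "hs_bootstrap")
}

#' @export
print.hs_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap average HSI for %s (B = %d, %s)\n", x$model, x$B,
              if (x$refit) "refit per replicate" else "score resampling"))
  cat(sprintf("  point estimate %.4f, bootstrap mean %.4f, 95%% CI (%.4f, %.4f)\n",
              x$estimate, x$boot_mean, x$ci_low, x$ci_high))
  invisible(x)
}
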