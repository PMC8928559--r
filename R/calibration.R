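#' Binarize Disease Severity Ratings at a distribution quantile
#'
#' Accessions in the first decile of the DSr distribution (by default) are
#' labelled resistant: the threshold is the empirical quantile of `dsr` at
#' `quantile` (type-7, linear interpolation), and a record is resistant iff
#' its DSr is strictly below it. The strict inequality excludes boundary
#' ties from the resistant class, keeping the label reserved for maximal
#' resistance.
#'
#' @param records Tibble with a `dsr` column (0-100, low = resistant).
#' @param quantile Quantile defining the resistant class (default 0.10, the
#'   first decile; alternative cutoffs such as 0.17, 0.35 or 0.50 can be
#'   explored for hard-to-model traits).
#' @param type Quantile estimator type passed to [stats::quantile()].
#' @return The records with a logical `resistant` column; the threshold and
#'   class counts are attached as attributes `threshold`, `n_resistant`,
#'   `n_sensitive`.
#' @export
binarize_dsr <- function(records, quantile = 0.10, type = 7) {
  records <- as_tibble(records)
  assert_columns(records, "dsr", "records")
  dsr <- records$dsr[!is.na(records$dsr)]
  if (length(dsr) < 10) {
    abort("need at least 10 DSr values", class = "predchar_spec_error")
  }
  if (diff(range(dsr)) == 0) {
    abort("DSr distribution is degenerate (all values identical)",
      class = "predchar_domain_error"
    )
  }
  q <- stats::quantile(dsr, probs = quantile, type = type, names = FALSE)
  records$resistant <- !is.na(records$dsr) & records$dsr < q
  attr(records, "threshold") <- q
  attr(records, "n_resistant") <- sum(records$resistant)
  attr(records, "n_sensitive") <- sum(!records$resistant & !is.na(records$dsr))
  records
}

#' True Skill Statistic
#'
#' `TSS = sensitivity + specificity - 1 = tp/(tp+fn) + tn/(tn+fp) - 1`,
#' a prevalence-independent accuracy measure for presence/absence models,
#' ranging from -1 to 1 (1 = perfect, 0 = no better than chance).
#'
#' @param tp,fn,tn,fp Confusion-table cell counts (vectorized).
#' @return Numeric TSS values.
#' @examples
#' tss(3, 1, 4, 2) # 0.75 + 2/3 - 1
#' @export
tss <- function(tp, fn, tn, fp) {
  if (any(tp + fn == 0) || any(tn + fp == 0)) {
    abort("TSS undefined when a class is empty", class = "predchar_domain_error")
  }
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Model-performance class of a mean TSS
#'
#' Bins mean TSS into the conventional five performance classes:
#' Fail `[-1,0.2)`, Poor `[0.2,0.4)`, Fair `[0.4,0.6)`, Good `[0.6,0.8)`,
#' Excellent `[0.8,1]`.
#'
#' @param mean_tss Numeric vector of mean TSS values.
#' @return An ordered factor of performance classes.
#' @export
classify_performance <- function(mean_tss) {
  cut(mean_tss,
    breaks = c(-1, 0.2, 0.4, 0.6, 0.8, 1), right = FALSE,
    labels = c("Fail", "Poor", "Fair", "Good", "Excellent"),
    include.lowest = TRUE, ordered_result = TRUE
  ) -> out
  out[!is.na(mean_tss) & mean_tss >= 1] <- "Excellent"
  out
}

#' Surface range envelope predictor
#'
#' A Bioclim-style envelope: the per-variable quantile interval
#' (2.5th-97.5th percentile by default) of the training presences. A point's
#' suitability is the fraction of variables lying inside their envelope; it
#' predicts presence only when every variable is inside.
#'
#' @param presences Data frame of presence-site predictor values (>= 2
#'   rows).
#' @param quantile_pair Lower and upper envelope quantiles.
#' @return An object of class `pc_sre` with a `predict()` method returning
#'   suitability in [0, 1].
#' @export
sre_envelope <- function(presences, quantile_pair = c(0.025, 0.975)) {
  presences <- as.data.frame(presences)
  if (nrow(presences) < 2) {
    abort("need at least 2 presences for an envelope", class = "predchar_domain_error")
  }
  bounds <- lapply(presences, function(x) {
    stats::quantile(x, probs = quantile_pair, na.rm = TRUE, names = FALSE)
  })
  structure(list(bounds = bounds), class = "pc_sre")
}

#' @export
predict.pc_sre <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[names(object$bounds)]
  inside <- sapply(names(object$bounds), function(v) {
    b <- object$bounds[[v]]
    as.numeric(newdata[[v]] >= b[1] & newdata[[v]] <= b[2])
  })
  if (is.null(dim(inside))) inside <- matrix(inside, nrow = nrow(newdata))
  rowMeans(inside)
}

# ---- algorithm suite -------------------------------------------------------

suite_algorithms <- function() {
  c("GLM", "GAM", "GBM", "CTA", "ANN", "FDA", "MARS", "RF", "SRE")
}

# Equal total weight per class regardless of prevalence.
class_weights <- function(y) {
  w <- ifelse(y == 1, 0.5 / sum(y == 1), 0.5 / sum(y == 0))
  w * length(y) # normalized so weights average 1
}

# Fit one algorithm; returns an object with a unified predict_prob().
# Hyperparameters follow common species-distribution-modeling defaults and
# are collected here so they are auditable in one place.
fit_algorithm <- function(algorithm, x, y, params = list()) {
  x <- as.data.frame(x)
  w <- class_weights(y)
  vars <- names(x)
  dat <- cbind(x, .y = y)
  model <- switch(algorithm,
    GLM = {
      f <- stats::as.formula(paste(".y ~", paste(vars, collapse = " + ")))
      suppressWarnings(glm(f, data = dat, family = binomial("logit"), weights = w))
    },
    GAM = {
      terms <- vapply(vars, function(v) {
        k <- min(params$gam_k %||% 4, length(unique(x[[v]])) - 1L)
        if (k >= 3) sprintf("s(%s, k = %d)", v, k) else v
      }, character(1))
      f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
      suppressWarnings(mgcv::gam(f, data = dat, family = binomial("logit"), weights = w))
    },
    GBM = {
      xgboost::xgboost(
        x = as.matrix(x), y = factor(y, levels = c(0, 1)),
        weights = w,
        nrounds = params$gbm_nrounds %||% 50,
        learning_rate = params$gbm_eta %||% 0.1,
        max_depth = params$gbm_depth %||% 3,
        nthreads = 1, verbosity = 0
      )
    },
    CTA = {
      f <- stats::as.formula(paste("factor(.y) ~", paste(vars, collapse = " + ")))
      rpart::rpart(f, data = dat, weights = w, method = "class",
        control = rpart::rpart.control(cp = params$cta_cp %||% 0.01, xval = 0)
      )
    },
    ANN = {
      ctr <- scale(as.matrix(x))
      fit <- nnet::nnet(ctr, y,
        size = params$ann_size %||% 5, decay = params$ann_decay %||% 0.01,
        maxit = params$ann_maxit %||% 200, weights = w,
        entropy = TRUE, trace = FALSE
      )
      list(fit = fit, center = attr(ctr, "scaled:center"), scale = attr(ctr, "scaled:scale"))
    },
    FDA = {
      # flexible discriminant: LDA on a natural-spline basis expansion
      basis <- fda_basis(x, df = params$fda_df %||% 3)
      keep <- apply(basis$mat, 2, function(col) sd(col) > 1e-10)
      fit <- MASS::lda(basis$mat[, keep, drop = FALSE], grouping = factor(y),
        prior = c(0.5, 0.5)
      )
      list(fit = fit, basis = basis, keep = keep)
    },
    MARS = mars_fit(x, y, w,
      max_terms = params$mars_max_terms %||% 15,
      n_knots = params$mars_knots %||% 5
    ),
    RF = {
      suppressWarnings(randomForest::randomForest(
        x = x, y = factor(y, levels = c(0, 1)),
        ntree = params$rf_ntree %||% 500,
        classwt = c("0" = 0.5, "1" = 0.5)
      ))
    },
    SRE = sre_envelope(x[y == 1, , drop = FALSE],
      quantile_pair = params$sre_quantiles %||% c(0.025, 0.975)
    ),
    abort(paste0("unknown algorithm: ", algorithm), class = "predchar_spec_error")
  )
  structure(list(algorithm = algorithm, model = model, vars = vars),
    class = "pc_model"
  )
}

fda_basis <- function(x, df = 3, knots = NULL) {
  if (is.null(knots)) {
    knots <- lapply(x, function(v) {
      stats::quantile(v, probs = seq(0, 1, length.out = df + 1), names = FALSE)
    })
  }
  cols <- lapply(names(x), function(v) {
    b <- splines::ns(x[[v]],
      knots = knots[[v]][-c(1, length(knots[[v]]))],
      Boundary.knots = knots[[v]][c(1, length(knots[[v]]))]
    )
    colnames(b) <- paste0(v, "_ns", seq_len(ncol(b)))
    b
  })
  list(mat = do.call(cbind, cols), knots = knots, df = df)
}

# Minimal multivariate-adaptive-regression-splines-style fit: forward
# selection over hinge bases with a generalized-cross-validation stop,
# weighted least squares on the 0/1 response, predictions clipped to [0,1].
mars_fit <- function(x, y, w, max_terms = 15, n_knots = 5) {
  n <- length(y)
  candidates <- list()
  for (v in names(x)) {
    ks <- unique(stats::quantile(x[[v]],
      probs = seq_len(n_knots) / (n_knots + 1), names = FALSE
    ))
    for (k in ks) {
      candidates[[length(candidates) + 1]] <- list(var = v, knot = k, dir = 1)
      candidates[[length(candidates) + 1]] <- list(var = v, knot = k, dir = -1)
    }
  }
  hinge <- function(term, xd) pmax(0, term$dir * (xd[[term$var]] - term$knot))
  basis <- matrix(1, n, 1)
  terms <- list()
  gcv <- function(rss, m) rss / (n * (1 - min(0.999, (m + 2 * m) / n))^2)
  fit_ls <- function(B) {
    fit <- stats::lm.wfit(B, y, w)
    list(coef = fit$coefficients, rss = sum(w * fit$residuals^2))
  }
  current <- fit_ls(basis)
  best_gcv <- gcv(current$rss, 1)
  while (length(terms) < max_terms) {
    best <- NULL
    for (cand in candidates) {
      B <- cbind(basis, hinge(cand, x))
      f <- fit_ls(B)
      g <- gcv(f$rss, ncol(B))
      if (is.null(best) || g < best$gcv) best <- list(cand = cand, gcv = g)
    }
    if (is.null(best) || best$gcv >= best_gcv * 0.999) break
    terms[[length(terms) + 1]] <- best$cand
    basis <- cbind(basis, hinge(best$cand, x))
    best_gcv <- best$gcv
  }
  final <- fit_ls(basis)
  structure(
    list(terms = terms, coef = final$coef, hinge = hinge),
    class = "pc_mars"
  )
}

#' @export
predict.pc_mars <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  B <- matrix(1, nrow(newdata), 1)
  for (term in object$terms) B <- cbind(B, object$hinge(term, newdata))
  coef <- ifelse(is.na(object$coef), 0, object$coef)
  pmin(pmax(as.numeric(B %*% coef), 0), 1)
}

predict_prob <- function(model, newdata) {
  newdata <- as.data.frame(newdata)[model$vars]
  m <- model$model
  p <- switch(model$algorithm,
    GLM = predict(m, newdata = newdata, type = "response"),
    GAM = as.numeric(predict(m, newdata = newdata, type = "response")),
    GBM = as.numeric(predict(m, as.matrix(newdata))),
    CTA = predict(m, newdata = newdata, type = "prob")[, "1"],
    ANN = {
      z <- scale(as.matrix(newdata), center = m$center, scale = m$scale)
      as.numeric(predict(m$fit, z))
    },
    FDA = {
      basis <- fda_basis(newdata, df = m$basis$df, knots = m$basis$knots)
      predict(m$fit, basis$mat[, m$keep, drop = FALSE])$posterior[, "1"]
    },
    MARS = predict(m, newdata),
    RF = predict(m, newdata = newdata, type = "prob")[, "1"],
    SRE = predict(m, newdata)
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

# TSS-maximizing threshold on (prob, label); candidates are midpoints of
# consecutive distinct predictions. Ties resolved toward the lowest
# threshold. Returns the threshold; labels are positive when prob is
# strictly above it.
tss_cutoff <- function(prob, y) {
  u <- sort(unique(prob))
  cand <- if (length(u) == 1) {
    u - 0.5
  } else {
    c(u[1] - 0.5, (u[-1] + u[-length(u)]) / 2, u[length(u)])
  }
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  scores <- vapply(cand, function(th) {
    pred <- prob > th
    sum(pred & y == 1) / n_pos + sum(!pred & y == 0) / n_neg - 1
  }, numeric(1))
  cand[which.max(scores)]
}

confusion_tss <- function(prob, y, cutoff) {
  pred <- prob > cutoff
  tp <- sum(pred & y == 1)
  fn <- sum(!pred & y == 1)
  tn <- sum(!pred & y == 0)
  fp <- sum(pred & y == 0)
  tss(tp, fn, tn, fp)
}

#' Train and evaluate the presence/absence algorithm suite
#'
#' For each algorithm and each of `n_runs` runs: draw a (by default
#' class-stratified) 75/25 train/test split, fit on the training portion
#' with both classes weighted equally regardless of prevalence, choose the
#' suitability cutoff maximizing TSS on the training predictions, and score
#' TSS on the held-out 25% at that cutoff. Runs where an algorithm fails to
#' fit are recorded as failed and excluded from the mean with a count. All
#' randomness derives from `seed`; every run is refittable from its recorded
#' substream (see [refit_run()]).
#'
#' @param records Tibble with a logical `resistant` column (from
#'   [binarize_dsr()]) and the predictor columns.
#' @param predictors Character vector of predictor column names (>= 2).
#' @param algorithms Algorithms to run (default all nine: GLM, GAM, GBM,
#'   CTA, ANN, FDA, MARS, RF, SRE).
#' @param n_runs Runs per algorithm (default 100).
#' @param train_frac Training fraction (default 0.75).
#' @param stratify Stratify the split by class (default TRUE; an
#'   unstratified split can leave the rare class empty).
#' @param params Named list of hyperparameter overrides (see source of
#'   `fit_algorithm`).
#' @param seed Master seed.
#' @return A `pc_runs` object: `runs` (tibble: algorithm, run, tss, cutoff,
#'   failed), `summary` (per-algorithm mean TSS, performance class, failure
#'   count), plus the data needed to refit any run.
#' @export
train_suite <- function(records, predictors, algorithms = suite_algorithms(),
                        n_runs = 100, train_frac = 0.75, stratify = TRUE,
                        params = list(), seed = 1L) {
  records <- as_tibble(records)
  assert_columns(records, c("resistant", predictors), "records")
  if (length(predictors) < 2) {
    abort("need at least two predictors", class = "predchar_spec_error")
  }
  keep <- complete.cases(records[c("resistant", predictors)])
  records <- records[keep, ]
  y <- as.integer(records$resistant)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    abort("both classes need at least two records", class = "predchar_spec_error")
  }
  x <- records[predictors]
  runs <- list()
  for (a_i in seq_along(algorithms)) {
    algo <- algorithms[[a_i]]
    for (r in seq_len(n_runs)) {
      run_seed <- derive_seed(seed, paste0("run_", algo), r)
      split <- split_indices(y, train_frac, stratify, run_seed)
      res <- tryCatch(
        {
          model <- with_seed(run_seed, fit_algorithm(algo, x[split$train, ], y[split$train], params))
          p_train <- predict_prob(model, x[split$train, ])
          cutoff <- tss_cutoff(p_train, y[split$train])
          p_test <- predict_prob(model, x[split$test, ])
          list(tss = confusion_tss(p_test, y[split$test], cutoff), cutoff = cutoff)
        },
        error = function(e) NULL
      )
      runs[[length(runs) + 1]] <- tibble(
        algorithm = algo, run = r, seed = run_seed,
        tss = if (is.null(res)) NA_real_ else res$tss,
        cutoff = if (is.null(res)) NA_real_ else res$cutoff * 1000,
        failed = is.null(res)
      )
    }
  }
  runs <- bind_rows(runs)
  summary <- runs |>
    group_by(.data$algorithm) |>
    summarise(
      mean_tss = mean(.data$tss[!.data$failed]),
      sd_tss = sd(.data$tss[!.data$failed]),
      n_failed = sum(.data$failed),
      .groups = "drop"
    ) |>
    mutate(performance = classify_performance(.data$mean_tss)) |>
    arrange(desc(.data$mean_tss))
  structure(
    list(
      runs = runs, summary = summary,
      data = x, y = y, predictors = predictors,
      train_frac = train_frac, stratify = stratify,
      params = params, seed = seed
    ),
    class = "pc_runs"
  )
}

split_indices <- function(y, train_frac, stratify, run_seed) {
  with_seed(run_seed, {
    n <- length(y)
    if (stratify) {
      train <- unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(train_frac * length(idx))))
      }))
    } else {
      train <- sample.int(n, max(2L, round(train_frac * n)))
    }
    list(train = sort(train), test = setdiff(seq_len(n), train))
  })
}

#' @export
print.pc_runs <- function(x, ...) {
  ok <- x$runs[!x$runs$failed, ]
  cat(sprintf(
    "<pc_runs> %d algorithms x %d runs (%d failed); best mean TSS %.3f (%s)\n",
    length(unique(x$runs$algorithm)), max(x$runs$run), sum(x$runs$failed),
    x$summary$mean_tss[1], x$summary$algorithm[1]
  ))
  invisible(x)
}

#' Refit one recorded run of a trained suite
#'
#' Runs are stored as (algorithm, run, substream seed) rather than as model
#' objects; this refits the identical model deterministically.
#'
#' @param suite A `pc_runs`.
#' @param algorithm,run Which run to refit.
#' @return A list: `model` (`pc_model`), `cutoff` (0-1000 scale), `tss`,
#'   `train`, `test` indices.
#' @export
refit_run <- function(suite, algorithm, run) {
  stopifnot(inherits(suite, "pc_runs"))
  rec <- suite$runs[suite$runs$algorithm == algorithm & suite$runs$run == run, ]
  if (nrow(rec) != 1 || rec$failed) {
    abort("no such successful run", class = "predchar_spec_error")
  }
  split <- split_indices(suite$y, suite$train_frac, suite$stratify, rec$seed)
  model <- with_seed(
    rec$seed,
    fit_algorithm(algorithm, suite$data[split$train, ], suite$y[split$train], suite$params)
  )
  list(
    model = model, cutoff = rec$cutoff, tss = rec$tss,
    train = split$train, test = split$test
  )
}

#' Permutation variable importance
#'
#' For each predictor: the predictor's column is shuffled `n_perm` times,
#' predictions are averaged over the shuffles, and importance is one minus
#' the Pearson correlation between the intact-data predictions and that
#' average, clipped to [0, 1] (0 = no influence, 1 = total influence). A
#' model with constant predictions gets importance 0 everywhere.
#'
#' @param model A `pc_model` (e.g. `refit_run(...)$model`).
#' @param data Data frame of predictor values to permute over.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @return A named numeric vector of importances in [0, 1].
#' @export
permutation_importance <- function(model, data, n_perm = 100, seed = 1L) {
  data <- as.data.frame(data)[model$vars]
  p0 <- predict_prob(model, data)
  out <- setNames(numeric(length(model$vars)), model$vars)
  if (sd(p0) < 1e-12) {
    return(out)
  }
  for (v in model$vars) {
    mean_perm <- numeric(nrow(data))
    for (i in seq_len(n_perm)) {
      shuffled <- data
      shuffled[[v]] <- with_seed(
        derive_seed(seed, paste0("perm_", v), i),
        sample(data[[v]])
      )
      mean_perm <- mean_perm + predict_prob(model, shuffled)
    }
    mean_perm <- mean_perm / n_perm
    r <- if (sd(mean_perm) < 1e-12) 1 else suppressWarnings(cor(p0, mean_perm))
    if (is.na(r)) r <- 1
    out[v] <- min(max(1 - r, 0), 1)
  }
  out
}

#' Select the best model and project suitability onto populations
#'
#' Ranks algorithms by mean TSS and reports the top three with permutation
#' importance tables for their best runs, supporting a judicious choice
#' rather than silent automation: `choose` overrides the default
#' highest-mean-TSS pick, and `exclude_variables` discards from
#' consideration any top algorithm whose best run is dominated by one of the
#' listed variables (useful when a variable, e.g. longitude, is not
#' biologically meaningful as a lone mechanism). The chosen algorithm's
#' highest-TSS run is refitted and projected: suitability is the predicted
#' probability scaled to 0-1000, and populations strictly above the run's
#' cutoff are labelled resistant. If every algorithm's mean TSS is below 0.2
#' (performance "Fail") the trait is declared unmodelable and no projection
#' is made.
#'
#' @param suite A `pc_runs` from [train_suite()].
#' @param populations Tibble of populations with the predictor columns.
#' @param top_n Size of the final candidate subset (default 30).
#' @param choose Optional algorithm name overriding the automatic pick.
#' @param exclude_variables Variables that must not dominate the chosen
#'   model (importance share > `dominance`).
#' @param dominance Importance share above which a model counts as
#'   dominated by a single variable (default 0.5).
#' @param n_perm Permutations for the importance tables.
#' @return A `pc_calibration` object: `verdict` (`"ok"` or
#'   `"unmodelable"`), `summary`, `top3` (importance tables), `algorithm`,
#'   `run`, `tss`, `cutoff`, `projections` (tibble with `suitability` and
#'   `label`), `top_subset`.
#' @export
select_and_project <- function(suite, populations, top_n = 30, choose = NULL,
                               exclude_variables = character(0),
                               dominance = 0.5, n_perm = 100) {
  stopifnot(inherits(suite, "pc_runs"))
  ok_runs <- suite$runs[!suite$runs$failed, ]
  if (nrow(ok_runs) == 0) {
    abort("no successful runs", class = "predchar_pipeline_error")
  }
  summary <- suite$summary
  if (all(summary$mean_tss < 0.2, na.rm = TRUE)) {
    return(structure(
      list(
        verdict = "unmodelable", summary = summary, top3 = list(),
        algorithm = NA_character_, run = NA_integer_, tss = NA_real_,
        cutoff = NA_real_,
        projections = tibble(), top_subset = tibble()
      ),
      class = "pc_calibration"
    ))
  }
  top3 <- head(summary$algorithm[!is.na(summary$mean_tss)], 3)
  importance <- list()
  dominated <- character(0)
  for (algo in top3) {
    best <- best_run_of(ok_runs, algo)
    refit <- refit_run(suite, algo, best$run)
    imp <- permutation_importance(refit$model, suite$data,
      n_perm = n_perm, seed = derive_seed(suite$seed, paste0("imp_", algo))
    )
    importance[[algo]] <- tibble(
      variable = names(imp), importance = unname(imp),
      best_run_tss = best$tss
    ) |> arrange(desc(.data$importance))
    share <- imp / max(sum(imp), 1e-12)
    top_var <- names(which.max(imp))
    if (length(exclude_variables) > 0 && top_var %in% exclude_variables &&
      share[top_var] > dominance) {
      dominated <- c(dominated, algo)
    }
  }
  pickable <- setdiff(top3, dominated)
  if (!is.null(choose)) {
    if (!choose %in% summary$algorithm) {
      abort(paste0("unknown algorithm: ", choose), class = "predchar_spec_error")
    }
    chosen <- choose
  } else {
    if (length(pickable) == 0) {
      abort("all top algorithms are dominated by excluded variables; pass `choose`",
        class = "predchar_pipeline_error"
      )
    }
    chosen <- pickable[1]
  }
  best <- best_run_of(ok_runs, chosen)
  refit <- refit_run(suite, chosen, best$run)
  populations <- as_tibble(populations)
  assert_columns(populations, suite$predictors, "populations")
  if (!"pop_id" %in% names(populations)) {
    populations$pop_id <- sprintf("P_%05d", seq_len(nrow(populations)))
  }
  cc <- complete.cases(populations[suite$predictors])
  suit <- rep(NA_real_, nrow(populations))
  suit[cc] <- round(predict_prob(refit$model, populations[cc, suite$predictors]) * 1000)
  projections <- populations
  projections$suitability <- suit
  projections$label <- ifelse(
    is.na(suit), NA_character_,
    ifelse(suit > refit$cutoff, "resistant", "sensitive")
  )
  top_subset <- projections |>
    filter(!is.na(.data$label), .data$label == "resistant") |>
    arrange(desc(.data$suitability), .data$pop_id) |>
    head(top_n)
  structure(
    list(
      verdict = "ok", summary = summary, top3 = importance,
      dominated = dominated,
      algorithm = chosen, run = best$run, tss = best$tss,
      cutoff = refit$cutoff,
      projections = projections, top_subset = top_subset
    ),
    class = "pc_calibration"
  )
}

best_run_of <- function(ok_runs, algo) {
  rr <- ok_runs[ok_runs$algorithm == algo, ]
  rr[order(-rr$tss, rr$run), ][1, ]
}

#' @export
print.pc_calibration <- function(x, ...) {
  if (x$verdict == "unmodelable") {
    cat("<pc_calibration> unmodelable: every algorithm's mean TSS < 0.2; no projection\n")
  } else {
    cat(sprintf(
      "<pc_calibration> %s best run %d (TSS %.3f, cutoff %.0f): %d resistant of %d projected; top subset %d\n",
      x$algorithm, x$run, x$tss, x$cutoff,
      sum(x$projections$label == "resistant", na.rm = TRUE),
      sum(!is.na(x$projections$label)), nrow(x$top_subset)
    ))
  }
  invisible(x)
}
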