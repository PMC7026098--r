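#' Clinical preprocessing: category derivation, filtering, imputation
#'
#' @name clinical
NULL

#' Derive clinical categories from raw scores
#'
#' ADOS severity (1-10) collapses to Non-spectrum (1-3), ASD (4-5), Autism
#' (6-10).  VABS subscale scores <= 70 are "dysfunctional", otherwise
#' "normal".  Performance IQ maps to severe intellectual disability below
#' `iq_boundaries[1]`, mild below `iq_boundaries[2]`, normal at or above it
#' (the conventional closed-above reading of the strict published cut-offs;
#' the boundaries are configurable).
#'
#' @param table Clinical data.frame (post-imputation, or with NAs which
#'   yield NA categories).
#' @param iq_boundaries Numeric length-2: severe/mild and mild/normal
#'   cut-offs, default `c(50, 70)`.
#' @return `table` with `ados_category`, `vabs_*_category` and
#'   `iq_category` columns appended (character, NA where inputs missing).
#' @export
derive_categories <- function(table, iq_boundaries = c(50, 70)) {
  sev <- table$ados_severity
  bad <- !is.na(sev) & (sev < 1 | sev > 10)
  if (any(bad))
    stop("ados_severity outside 1-10 for: ",
         paste(table$individual_id[bad], collapse = ", "))
  table$ados_category <- ifelse(is.na(sev), NA_character_,
                         ifelse(sev >= 6, "Autism",
                         ifelse(sev >= 4, "ASD", "Non-spectrum")))
  for (s in c("communication", "daily_living", "socialization")) {
    x <- table[[paste0("vabs_", s)]]
    table[[paste0("vabs_", s, "_category")]] <-
      ifelse(is.na(x), NA_character_, ifelse(x <= 70, "dysfunctional", "normal"))
  }
  iq <- table$performance_iq
  table$iq_category <- ifelse(is.na(iq), NA_character_,
                       ifelse(iq < iq_boundaries[1], "severe_ID",
                       ifelse(iq < iq_boundaries[2], "mild_ID", "normal")))
  table
}

#' Filter the cohort on module and missingness rules
#'
#' Three exclusion rules, applied in order: (1) individuals assessed with
#' ADOS module 4 are dropped (no severity metric exists for module 4);
#' (2) clinical features observed in at most 70% of the remaining
#' individuals are dropped (strictly more than `completeness_threshold`
#' information is required to retain a feature); (3) individuals missing
#' more than `max_missing_features` of the retained features are dropped.
#'
#' @param table Raw clinical data.frame.
#' @param completeness_threshold Retention threshold on per-feature
#'   completeness (strict `>`), default 0.70.
#' @param max_missing_features Maximum missing retained features an
#'   individual may have, default 2.
#' @return List with `table` (filtered, non-retained feature columns
#'   removed), `features` (retained feature names), and `log` (data.frame
#'   of every exclusion with its reason).
#' @export
filter_cohort <- function(table, completeness_threshold = 0.70,
                          max_missing_features = 2L) {
  log <- data.frame(entity = character(), id = character(),
                    reason = character(), stringsAsFactors = FALSE)
  add <- function(entity, id, reason)
    rbind(log, data.frame(entity = entity, id = id, reason = reason,
                          stringsAsFactors = FALSE))
  mod4 <- !is.na(table$ados_module) & table$ados_module == 4L
  if (any(mod4))
    log <- add("individual", table$individual_id[mod4], "ADOS module 4")
  table <- table[!mod4, , drop = FALSE]

  feats <- intersect(clinical_feature_columns(), names(table))
  completeness <- vapply(feats, function(f) mean(!is.na(table[[f]])), numeric(1))
  keep <- completeness > completeness_threshold
  if (any(!keep))
    log <- add("feature", feats[!keep],
               sprintf("completeness %.3f <= %.2f",
                       completeness[!keep], completeness_threshold))
  retained <- feats[keep]
  table <- table[, setdiff(names(table), feats[!keep]), drop = FALSE]

  n_missing <- rowSums(is.na(table[retained]))
  drop_ind <- n_missing > max_missing_features
  if (any(drop_ind))
    log <- add("individual", table$individual_id[drop_ind],
               sprintf("missing %d retained features", n_missing[drop_ind]))
  table <- table[!drop_ind, , drop = FALSE]
  if (nrow(table) == 0L) warning("cohort empty after filtering")
  rownames(table) <- NULL
  list(table = table, features = retained,
       completeness = completeness, log = log)
}

#' Iterative random-forest imputation (missForest scheme)
#'
#' Missing cells are initialised with the feature mode (categorical) or
#' median (numeric).  Features are then visited in order of increasing
#' missingness; for each, a random forest is fit on the rows observed for
#' that feature (all other features as predictors, current completions
#' used) and the missing rows are predicted.  After each sweep the change
#' relative to the previous sweep is measured (normalised RMS for numeric
#' features, disagreement fraction for categorical ones); the loop stops
#' the first time either criterion increases, returning the previous
#' sweep's values, or at `max_iter`.
#'
#' @param table Filtered clinical data.frame.
#' @param features Feature columns to impute over (default: the clinical
#'   feature columns present).
#' @param n_trees Trees per forest.
#' @param max_iter Maximum sweeps.
#' @param seed Integer seed.
#' @return List with `table` (completed) and `report` (n_iterations,
#'   per-feature completeness, converged flag).
#' @export
impute_missforest <- function(table, features = NULL, n_trees = 100L,
                              max_iter = 10L, seed = 1L) {
  if (is.null(features))
    features <- intersect(clinical_feature_columns(), names(table))
  x <- table[features]
  categorical <- vapply(x, function(col) is.character(col) || is.factor(col),
                        logical(1))
  for (f in features[categorical]) x[[f]] <- factor(x[[f]])
  na0 <- is.na(x)
  completeness <- 1 - colMeans(na0)
  if (any(completeness == 0))
    stop("feature(s) with zero observed values: ",
         paste(features[completeness == 0], collapse = ", "))
  if (!any(na0)) {
    report <- list(n_iterations = 0L, completeness = completeness,
                   converged = TRUE)
    return(list(table = table, report = report))
  }
  # mode / median initialisation
  for (f in features) {
    miss <- na0[, f]
    if (!any(miss)) next
    x[[f]][miss] <- if (categorical[[f]]) stat_mode(x[[f]])
                    else stats::median(x[[f]], na.rm = TRUE)
  }
  visit <- features[order(colMeans(na0)[features])]
  visit <- visit[colSums(na0[, visit, drop = FALSE]) > 0]
  num_feats <- features[!categorical]
  cat_feats <- features[categorical]
  change <- function(cur, prev) {
    dn <- if (length(num_feats)) {
      num_cur <- as.matrix(cur[num_feats]); num_prev <- as.matrix(prev[num_feats])
      sum((num_cur - num_prev)^2) / max(sum(num_cur^2), .Machine$double.eps)
    } else 0
    dc <- if (length(cat_feats)) {
      n_cat_na <- sum(na0[, cat_feats, drop = FALSE])
      if (n_cat_na == 0) 0 else {
        dis <- 0
        for (f in cat_feats) dis <- dis + sum(cur[[f]][na0[, f]] != prev[[f]][na0[, f]])
        dis / n_cat_na
      }
    } else 0
    c(numeric = dn, categorical = dc)
  }
  best <- x
  prev_change <- c(numeric = Inf, categorical = Inf)
  iters <- 0L
  converged <- FALSE
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      prev <- x
      for (f in visit) {
        miss <- na0[, f]
        obs <- !miss
        preds <- setdiff(features, f)
        # near-constant numeric features are legitimate here; silence the
        # base learner's few-unique-values regression warning only
        fit <- withCallingHandlers(
          randomForest::randomForest(
            x = x[obs, preds, drop = FALSE], y = x[[f]][obs],
            ntree = n_trees),
          warning = function(w) {
            if (grepl("five or fewer unique values", conditionMessage(w)))
              invokeRestart("muffleWarning")
          })
        x[[f]][miss] <- stats::predict(fit, x[miss, preds, drop = FALSE])
      }
      iters <- it
      d <- change(x, prev)
      if (it > 1 && (d["numeric"] > prev_change["numeric"] ||
                     d["categorical"] > prev_change["categorical"])) {
        x <- prev          # error criterion rose: keep previous sweep
        converged <- TRUE
        break
      }
      prev_change <- d
      best <- x
      if (all(d < 1e-8)) { converged <- TRUE; break }
    }
  })
  for (f in features) {
    table[[f]] <- if (categorical[[f]]) as.character(x[[f]]) else x[[f]]
  }
  report <- list(n_iterations = iters, completeness = completeness,
                 converged = converged)
  list(table = table, report = report)
}

#' Proportion of falsely classified imputed cells
#'
#' Among masked categorical cells, the fraction where the imputed value
#' disagrees with the held-out truth.
#'
#' @param truth Complete data.frame (pre-masking).
#' @param imputed Completed data.frame, same rows/columns.
#' @param mask Logical matrix (rows x clinical features) as returned by
#'   [inject_missingness()].
#' @param categorical Character vector of categorical feature names
#'   (default: character/factor columns among the mask's columns).
#' @return Fraction in [0, 1].
#' @export
pfc <- function(truth, imputed, mask,
                categorical = NULL) {
  cols <- colnames(mask)
  if (is.null(categorical))
    categorical <- cols[vapply(truth[cols], function(x)
      is.character(x) || is.factor(x), logical(1))]
  categorical <- intersect(categorical, cols)
  total <- sum(mask[, categorical, drop = FALSE])
  if (total == 0) stop("no masked categorical cells")
  wrong <- 0
  for (f in categorical) {
    m <- mask[, f]
    wrong <- wrong + sum(as.character(imputed[[f]][m]) != as.character(truth[[f]][m]))
  }
  wrong / total
}

#' Normalised RMSE of numeric imputation
#'
#' Companion diagnostic to [pfc()] for numeric features; not used for any
#' gating decision.
#'
#' @inheritParams pfc
#' @param numeric Character vector of numeric feature names.
#' @return sqrt(mean squared error / variance of truth) over masked cells.
#' @export
nrmse <- function(truth, imputed, mask, numeric = NULL) {
  cols <- colnames(mask)
  if (is.null(numeric))
    numeric <- cols[vapply(truth[cols], is.numeric, logical(1))]
  numeric <- intersect(numeric, cols)
  err <- truevals <- numeric(0)
  for (f in numeric) {
    m <- mask[, f]
    err <- c(err, imputed[[f]][m] - truth[[f]][m])
    truevals <- c(truevals, truth[[f]][m])
  }
  if (!length(err)) stop("no masked numeric cells")
  sqrt(mean(err^2) / stats::var(truevals))
}
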