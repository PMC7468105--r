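# Factorial experiment harness: the 16-cell design crossing training/test
# cohort (in-set vs out-of-set), data portion (100% vs 10%) and background
# masking, with fourfold cross-validation for in-set cells and replicated
# runs for out-of-set cells; aggregation of replicate F1 scores; and
# reference-cell ANOVA giving baseline-relative factor effects.

experiment_id <- function(train_source, test_source, portion, masking) {
  tag <- function(src) sprintf("%s_%d,%s", src, portion, if (masking) "+" else "-")
  paste(tag(train_source), tag(test_source), sep = "|")
}

#' Build the 16-cell factorial experiment design
#'
#' Crosses the two cohorts (in-set and both out-of-set directions), the
#' data portion (100\% vs 10\%) and background masking. In-set cells use
#' fourfold cross-validation; out-of-set cells use 3 replicates at full
#' portion and 5 replicates at 10\% portion. Batch size follows the
#' portion (32 at 100\%, 8 at 10\%). Optionally prepends the pooled
#' both-cohort cell with the 72/18/10 split.
#'
#' @param cohorts length-2 character vector of distinct cohort ids.
#' @param include_pooled if `TRUE`, add the merged-cohort unmasked cell
#'   (scheme `pooled`) before the 16 factorial rows.
#' @return data frame with one row per experiment: `row`, `experiment`,
#'   `train_source`, `test_source`, `portion`, `masking`, `scheme`,
#'   `replicates`, `batch_size`.
#' @export
build_design <- function(cohorts = c("A", "B"), include_pooled = FALSE) {
  stopifnot(length(cohorts) == 2)
  if (cohorts[1] == cohorts[2]) stop("cohorts must be distinct")
  a <- cohorts[1]; b <- cohorts[2]
  cell <- function(tr, te, portion, masking) {
    oos <- tr != te
    data.frame(train_source = tr, test_source = te, portion = portion,
               masking = masking,
               scheme = if (!oos) "cv4" else if (portion == 100) "oos3" else "oos10pct5",
               replicates = if (!oos) 4L else if (portion == 100) 3L else 5L,
               batch_size = if (portion == 100) 32L else 8L,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    cell(a, a, 100, FALSE), cell(b, b, 100, FALSE),
    cell(a, a, 100, TRUE),  cell(b, b, 100, TRUE),
    cell(a, a, 10, FALSE),  cell(b, b, 10, FALSE),
    cell(a, a, 10, TRUE),   cell(b, b, 10, TRUE),
    cell(a, b, 100, FALSE), cell(b, a, 100, FALSE),
    cell(a, b, 100, TRUE),  cell(b, a, 100, TRUE),
    cell(a, b, 10, FALSE),  cell(b, a, 10, FALSE),
    cell(a, b, 10, TRUE),   cell(b, a, 10, TRUE))
  if (include_pooled) {
    pooled <- data.frame(train_source = paste0(a, b), test_source = paste0(a, b),
                         portion = 100, masking = FALSE, scheme = "pooled",
                         replicates = 1L, batch_size = 32L,
                         stringsAsFactors = FALSE)
    rows <- rbind(pooled, rows)
  }
  rows$experiment <- mapply(experiment_id, rows$train_source, rows$test_source,
                            rows$portion, rows$masking)
  rows$row <- seq_len(nrow(rows))
  rows[, c("row", "experiment", "train_source", "test_source", "portion",
           "masking", "scheme", "replicates", "batch_size")]
}

#' Group cut-outs into a class -> item-id map
#'
#' Item identity is the `slide_id/annotation_id` pair; the result feeds
#' the split constructors directly.
#'
#' @param cutouts list of labelled `cutout` objects.
#' @return named list mapping class to a character vector of item ids.
#' @export
items_by_class_of <- function(cutouts) {
  ids <- vapply(cutouts, function(co)
    paste(co$source$slide_id, co$source$annotation_id, sep = "/"), "")
  labs <- vapply(cutouts, function(co) as.character(co$label), "")
  split(ids, labs)
}

#' Assemble a two-cohort cut-out data source for the experiment runner
#'
#' Extracts both the raw and the background-masked variant of every
#' annotated object of a cohort pair (as produced by
#' [generate_cohort_pair()]), resolving labels with the senior-wins
#' policy and dropping skip decisions.
#'
#' @param pair list with per-cohort slide lists, as returned by
#'   [generate_cohort_pair()].
#' @param margin_px cut-out margin, see [extract_cutout()].
#' @param transition_width_px masking transition width, see
#'   [mask_background()].
#' @return nested list `source[[cohort]][[variant]]`, variant `"raw"` or
#'   `"masked"`, each a list of labelled cut-outs.
#' @export
assemble_dataset <- function(pair, margin_px = 10L, transition_width_px = 5) {
  out <- lapply(pair, function(slides) {
    raw <- list()
    for (s in slides) {
      for (rec in s$annotations) {
        lab <- resolve_gold_label(rec)
        if (is.na(lab)) next
        raw[[length(raw) + 1L]] <- extract_cutout(s$slide, rec, margin_px, label = lab)
      }
    }
    masked <- lapply(raw, mask_background,
                     transition_width_px = transition_width_px)
    list(raw = raw, masked = masked)
  })
  names(out) <- names(pair)
  out
}

#' Name a cut-out list by item id for id-based subsetting
#'
#' @param cutouts list of `cutout` objects.
#' @return the same list named by `slide_id/annotation_id`, so that
#'   `lookup[plan$train]` picks the training cut-outs of a split plan.
#' @export
cutout_lookup <- function(cutouts) {
  ids <- vapply(cutouts, function(co)
    paste(co$source$slide_id, co$source$annotation_id, sep = "/"), "")
  stats::setNames(cutouts, ids)
}

#' Run (part of) the factorial design on a data source
#'
#' For every design row: takes the portion subset (redrawn per replicate
#' for 10\% cells), builds the scheme's split plans (fourfold CV, pooled
#' 72/18/10, or out-of-set 80/20), trains the classifier on the training
#' split and scores the test split with micro and macro F1. A run whose
#' training split misses a class is skipped with a diagnostic message.
#'
#' @param design data frame from [build_design()] (any subset of rows).
#' @param dataset data source from [assemble_dataset()].
#' @param cspec_fn function(n_classes) returning a [classifier_spec()];
#'   lets the caller fix backbone/head while the class count follows the
#'   data.
#' @param aconfig,tconfig augmentation and training configuration; the
#'   design row's `batch_size` overrides `tconfig$batch_size`.
#' @param seed base seed; every (row, replicate) derives its own stream.
#' @param epochs optional override of `tconfig$epochs`.
#' @return data frame of result rows: `experiment`, `replicate`,
#'   `f1_micro`, `f1_macro`, `seed`.
#' @export
run_design <- function(design, dataset, cspec_fn,
                       aconfig = augmentation_config(),
                       tconfig = train_config(), seed = 1L, epochs = NULL) {
  if (!is.null(epochs)) tconfig$epochs <- as.integer(epochs)
  results <- list()
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    variant <- if (row$masking) "masked" else "raw"
    pooled <- identical(row$scheme, "pooled")
    tr_ids <- if (pooled) strsplit(row$train_source, "")[[1]] else row$train_source
    te_ids <- if (pooled) strsplit(row$test_source, "")[[1]] else row$test_source
    train_cuts <- do.call(c, lapply(tr_ids, function(cc) dataset[[cc]][[variant]]))
    test_cuts <- do.call(c, lapply(te_ids, function(cc) dataset[[cc]][[variant]]))
    lookup <- cutout_lookup(c(train_cuts, test_cuts))  # name lookup takes the first match
    tr_by_class <- items_by_class_of(train_cuts)
    te_by_class <- items_by_class_of(test_cuts)
    classes <- sort(names(tr_by_class))

    rep_plans <- function(rep_seed) {
      tr <- tr_by_class; te <- te_by_class
      if (row$portion < 100) {
        frac <- row$portion / 100
        tr <- subset_fraction(tr, frac, seed = rep_seed)
        te <- if (row$train_source == row$test_source) tr else
          subset_fraction(te, frac, seed = child_seed(rep_seed, 7L))
      }
      if (row$scheme == "cv4") {
        cv_folds(tr, k = 4L, seed = rep_seed)
      } else if (pooled) {
        list(pooled_split(tr, seed = rep_seed))
      } else {
        list(out_of_set_plan(tr, te, val_frac = 0.2, seed = rep_seed))
      }
    }

    run_one <- function(plan, rep_idx, rep_seed) {
      present <- unique(vapply(lookup[plan$train], function(co)
        as.character(co$label), ""))
      if (!setequal(present, classes)) {
        message(sprintf("skipping %s replicate %d: class(es) %s absent from training",
                        row$experiment, rep_idx,
                        paste(setdiff(classes, present), collapse = ", ")))
        return(NULL)
      }
      cs <- cspec_fn(length(classes))
      tc <- tconfig
      tc$batch_size <- row$batch_size
      tc$seed <- as.integer(rep_seed)
      model <- train_classifier(lookup[plan$train], lookup[plan$validation],
                                cs, aconfig, tc)
      pred <- predict(model, lookup[plan$test])
      cm <- confusion_counts(pred$true_label, pred$predicted, model$classes)
      rep_report <- metrics_report(cm)
      data.frame(experiment = row$experiment, replicate = rep_idx,
                 f1_micro = rep_report$f1_micro,
                 f1_macro = rep_report$f1_macro,
                 seed = as.integer(rep_seed), stringsAsFactors = FALSE)
    }

    if (row$scheme %in% c("cv4", "pooled")) {
      rep_seed <- child_seed(seed, 100L * i)
      plans <- rep_plans(rep_seed)
      for (f in seq_along(plans)) {
        results[[length(results) + 1L]] <- run_one(plans[[f]], f,
                                                   child_seed(rep_seed, f))
      }
    } else {
      for (r in seq_len(row$replicates)) {
        rep_seed <- child_seed(seed, 100L * i + r)
        plan <- rep_plans(rep_seed)[[1]]
        results[[length(results) + 1L]] <- run_one(plan, r, rep_seed)
      }
    }
  }
  out <- do.call(rbind, results)
  if (is.null(out)) {
    out <- data.frame(experiment = character(), replicate = integer(),
                      f1_micro = numeric(), f1_macro = numeric(),
                      seed = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Average replicate results per experiment
#'
#' @param rows result rows from [run_design()] (or simulated rows with the
#'   same columns).
#' @return data frame with per-experiment mean `f1_micro`/`f1_macro`,
#'   replicate count, and `is_max`/`is_min` flags on the micro score
#'   (the table's bold-marking convention).
#' @export
summarize_results <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  agg <- stats::aggregate(cbind(f1_micro, f1_macro) ~ experiment, data = rows,
                          FUN = mean)
  n <- stats::aggregate(replicate ~ experiment, data = rows, FUN = length)
  names(n)[2] <- "n"
  agg <- merge(agg, n, by = "experiment", sort = FALSE)
  # preserve first-appearance order of experiments
  agg <- agg[match(unique(rows$experiment), agg$experiment), ]
  rownames(agg) <- NULL
  agg$is_max <- agg$f1_micro == max(agg$f1_micro)
  agg$is_min <- agg$f1_micro == min(agg$f1_micro)
  agg
}

significance_code <- function(p) {
  out <- ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*",
                              ifelse(p < 0.1, ".", ""))))
  out[is.na(p)] <- ""
  out
}

design_factors <- function(design) {
  data.frame(experiment = design$experiment,
             portion10 = design$portion == 10,
             masked = design$masking,
             oos = design$train_source != design$test_source,
             stringsAsFactors = FALSE)
}

#' Estimate baseline-relative factor effects by ANOVA
#'
#' Fits an ordinary least-squares linear model of F1 on the factor
#' combination of each run (one cell per combination of portion-10,
#' background-masked and out-of-set), parameterised with the
#' full-data + masked + in-set cell as the reference. The intercept is the
#' absolute baseline; every other coefficient is that combination's delta
#' relative to baseline, with a p-value mapped to significance codes
#' (`***` p < 0.001, `**` < 0.01, `*` < 0.05, `.` < 0.1). Fitted
#' separately for micro and macro F1. With `full_only = TRUE` the 10\%
#' cells are dropped and the model reduces to the masked x out-of-set
#' combinations.
#'
#' @param rows result rows (experiment, replicate, f1_micro, f1_macro).
#' @param design the design the rows came from ([build_design()] output),
#'   used to map experiments to factor levels.
#' @param full_only restrict to the full-portion cells.
#' @return object of class `effect_table`: a data frame with one baseline
#'   row (absolute values) and one row per factor combination
#'   (`delta_f1_micro`, `delta_f1_macro`, p-values and significance
#'   codes).
#' @export
estimate_effects <- function(rows, design, full_only = FALSE) {
  fac <- design_factors(design)
  dat <- merge(rows, fac, by = "experiment")
  if (nrow(dat) < nrow(rows)) stop("some rows have no design entry")
  if (full_only) dat <- dat[!dat$portion10, ]
  use_portion <- !full_only
  combo_of <- function(p10, m, o) {
    parts <- c(if (use_portion) (if (p10) "portion10" else "portion100"),
               if (m) "masked" else "unmasked",
               if (o) "oos" else "inset")
    paste(parts, collapse = ".")
  }
  dat$combo <- mapply(combo_of, dat$portion10, dat$masked, dat$oos)
  ref <- combo_of(FALSE, TRUE, FALSE)
  if (!ref %in% dat$combo) {
    stop("reference cell (full data, masked, in-set) missing from rows")
  }
  dat$combo <- stats::relevel(factor(dat$combo), ref = ref)
  fit_one <- function(response) {
    fit <- stats::lm(stats::reformulate("combo", response), data = dat)
    sm <- suppressWarnings(summary(fit))
    co <- sm$coefficients
    # a (numerically) perfect fit has no residual scale; p-values are
    # meaningless there
    if (sm$sigma < 1e-10 * max(1, mean(abs(dat[[response]])))) {
      co[, "Pr(>|t|)"] <- NA_real_
    }
    co
  }
  sm_mi <- fit_one("f1_micro")
  sm_ma <- fit_one("f1_macro")
  combos <- levels(dat$combo)
  term_of <- c("(Intercept)", paste0("combo", combos[-1]))
  tab <- data.frame(
    combination = c("baseline", combos[-1]),
    f1_micro = sm_mi[term_of, "Estimate"],
    se_micro = sm_mi[term_of, "Std. Error"],
    p_micro = sm_mi[term_of, "Pr(>|t|)"],
    f1_macro = sm_ma[term_of, "Estimate"],
    se_macro = sm_ma[term_of, "Std. Error"],
    p_macro = sm_ma[term_of, "Pr(>|t|)"],
    stringsAsFactors = FALSE)
  tab$sig_micro <- significance_code(tab$p_micro)
  tab$sig_macro <- significance_code(tab$p_macro)
  tab$p_micro[1] <- NA; tab$p_macro[1] <- NA
  tab$sig_micro[1] <- ""; tab$sig_macro[1] <- ""
  rownames(tab) <- NULL
  structure(tab, class = c("effect_table", "data.frame"))
}

#' @export
print.effect_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  class(y) <- "data.frame"
  for (col in intersect(c("f1_micro", "f1_macro"), names(y))) {
    y[[col]] <- round(y[[col]], digits)
  }
  for (col in intersect(c("p_micro", "p_macro"), names(y))) {
    y[[col]] <- signif(y[[col]], 2)
  }
  print(y)
  invisible(x)
}

#' Compare classifier models against the best performer
#'
#' Reports the best model (by mean micro F1) with absolute values and
#' every other model as a delta relative to it, using the same
#' reference-cell linear-model machinery and significance codes as
#' [estimate_effects()].
#'
#' @param rows result rows with an additional `model` column.
#' @return data frame: one absolute row for the best model, delta rows for
#'   the others.
#' @export
model_comparison <- function(rows) {
  stopifnot("model" %in% names(rows))
  means <- stats::aggregate(f1_micro ~ model, data = rows, FUN = mean)
  best <- means$model[which.max(means$f1_micro)]
  rows$model <- stats::relevel(factor(rows$model), ref = best)
  if (nlevels(rows$model) == 1) {
    return(data.frame(model = best, reference = TRUE,
                      f1_micro = mean(rows$f1_micro),
                      f1_macro = mean(rows$f1_macro),
                      p_micro = NA, p_macro = NA,
                      sig_micro = "", sig_macro = "",
                      stringsAsFactors = FALSE))
  }
  fit_model <- function(response) {
    sm <- suppressWarnings(summary(
      stats::lm(stats::reformulate("model", response), data = rows)))
    co <- sm$coefficients
    if (sm$sigma < 1e-10 * max(1, mean(abs(rows[[response]])))) {
      co[, "Pr(>|t|)"] <- NA_real_
    }
    co
  }
  sm_mi <- fit_model("f1_micro")
  sm_ma <- fit_model("f1_macro")
  lev <- levels(rows$model)
  terms <- c("(Intercept)", paste0("model", lev[-1]))
  tab <- data.frame(model = lev, reference = lev == best,
                    f1_micro = sm_mi[terms, "Estimate"],
                    p_micro = sm_mi[terms, "Pr(>|t|)"],
                    f1_macro = sm_ma[terms, "Estimate"],
                    p_macro = sm_ma[terms, "Pr(>|t|)"],
                    stringsAsFactors = FALSE)
  tab$sig_micro <- significance_code(tab$p_micro)
  tab$sig_macro <- significance_code(tab$p_macro)
  tab$p_micro[1] <- NA; tab$p_macro[1] <- NA
  tab$sig_micro[1] <- ""; tab$sig_macro[1] <- ""
  rownames(tab) <- NULL
  tab
}

#' Simulate replicate F1 tables with injected factor effects
#'
#' Generates result rows for the full factorial design with a known
#' baseline, additive per-factor effects and Gaussian noise — the ground
#' truth for parameter-recovery checks of [estimate_effects()].
#'
#' @param design design from [build_design()].
#' @param baseline absolute baseline F1 (applies to both responses).
#' @param effects named list with numeric `portion10`, `masked_off`,
#'   `oos`, each either one value (applied to both responses) or
#'   `c(micro, macro)`.
#' @param sd noise standard deviation.
#' @param reps replicates per design cell.
#' @param seed integer seed.
#' @return result rows as from [run_design()] (without `seed` column),
#'   plus the per-row true means `mu_micro`/`mu_macro`.
#' @export
simulate_f1_rows <- function(design, baseline = 0.98,
                             effects = list(portion10 = c(-0.06, -0.12),
                                            masked_off = -0.02,
                                            oos = -0.02),
                             sd = 0.005, reps = 20L, seed = 1L) {
  fac <- design_factors(design)
  both <- function(e) if (length(e) == 1) c(e, e) else e
  ef <- lapply(effects, both)
  mu <- function(i, which) {
    baseline +
      (if (fac$portion10[i]) ef$portion10[which] else 0) +
      (if (!fac$masked[i]) ef$masked_off[which] else 0) +
      (if (fac$oos[i]) ef$oos[which] else 0)
  }
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      m_mi <- mu(i, 1); m_ma <- mu(i, 2)
      data.frame(experiment = design$experiment[i],
                 replicate = seq_len(reps),
                 f1_micro = m_mi + stats::rnorm(reps, 0, sd),
                 f1_macro = m_ma + stats::rnorm(reps, 0, sd),
                 mu_micro = m_mi, mu_macro = m_ma,
                 stringsAsFactors = FALSE)
    }))
  })
}
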