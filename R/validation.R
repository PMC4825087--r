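# Sire-blocked cross-validation of predictive ability: adjusted
# phenotypes, balanced sire folds, test-set prediction rules and
# PB -> CB cross-prediction.

#' Adjust phenotypes for the systematic (fixed) effects of a fit
#'
#' `y_adj = y - (fixed-effect part of the linear predictor)` using the
#' BLUP solutions of a full-data fit (the study uses the GEN model's
#' solutions, computed once). Pen effects are random, not systematic, and
#' are NOT removed. Adjusted values are invariant to the reference-coding
#' choice of the factors because the intercept absorbs the difference.
#'
#' @param data trait table.
#' @param fit a [solve_blup()] result whose design covered all factor
#'   levels present in `data`.
#' @return `data` with the trait column replaced by its adjusted value.
#' @export
adjust_phenotypes <- function(data, fit) {
  spec <- fit$spec
  rec <- spec$recipe
  trait <- spec$trait
  validate_trait_table(data, trait)
  design <- fit$mme$design
  out <- data
  for (tag in c("A", "C")) {
    sel <- if (tag == "A") data$breed_type == "PB" else data$breed_type == "CB"
    sel <- sel & !is.na(data[[trait]])
    if (!any(sel)) next
    fx <- if (tag == "A") design$fxA else design$fxC
    if (!length(fx$names)) {
      stop_tc("fit has no fixed-effect block for breed type ",
              if (tag == "A") "PB" else "CB")
    }
    sols <- fit_effect(fit, paste0("fixed", tag))
    pred <- rep(sols[["(Intercept)"]], sum(sel))
    dat <- data[sel, , drop = FALSE]
    for (f in rec$factors) {
      ls <- fx$factor_levels[[f]]
      v <- as.character(dat[[f]])
      unseen <- setdiff(unique(v), ls)
      if (length(unseen)) {
        stop_tc("unseen level(s) of ", f, " in data: ",
                paste(unseen, collapse = ", "))
      }
      if (length(ls) > 1) {
        eff <- setNames(c(0, sols[paste0(f, "=", ls[-1])]), ls)
        pred <- pred + unname(eff[v])
      }
    }
    for (cv in rec$covariates) {
      pred <- pred + sols[[paste0("cov:", cv)]] * (dat[[cv]] - fx$centers[[cv]])
    }
    out[[trait]][sel] <- data[[trait]][sel] - pred
  }
  out
}

#' Random balanced sire folds
#'
#' Sires are split into `k` subsets whose sizes differ by at most one;
#' all records of a sire's offspring follow the sire.
#'
#' @param sires sire ids.
#' @param k number of folds (default 6).
#' @param seed integer seed.
#' @return Named integer vector: fold per sire.
#' @export
make_folds <- function(sires, k = 6, seed = 1) {
  sires <- unique(as.character(sires))
  if (k < 2) stop_tc("k must be >= 2")
  if (length(sires) < k) stop_tc("need at least k sires (", k, ")")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  perm <- sample(sires)
  fold <- rep(seq_len(k), length.out = length(sires))
  setNames(fold[order(match(sires, perm))], sires)
}

#' Predict test-set (adjusted) phenotypes from a training fit
#'
#' A purebred test record is predicted by the animal's own `u_AA` from the
#' training fit; a crossbred record by the gametic sum
#' `u_AC(sire) + u_BC(dam)` (matching the unit incidence coding), or by
#' the sire term alone with `dam_term = FALSE`. Cross-prediction mode uses
#' the sire's `u_AA` (its PB breeding value) in place of `u_AC`.
#'
#' @param fit training-fold [solve_blup()] result.
#' @param test test-fold trait table rows.
#' @param cross_prediction logical: predict CB records from the sire's PB
#'   breeding value (requires a fit with a `u_AA` block).
#' @param dam_term include the dam gametic contribution (default TRUE).
#' @return Numeric predictions aligned with `test` rows.
#' @export
predict_testset <- function(fit, test, cross_prediction = FALSE,
                            dam_term = TRUE) {
  uAA <- tryCatch(fit_effect(fit, "uAA"), error = function(e) numeric(0))
  uAC <- tryCatch(fit_effect(fit, "uAC"), error = function(e) numeric(0))
  uBC <- tryCatch(fit_effect(fit, "uBC"), error = function(e) numeric(0))
  pred <- numeric(nrow(test))
  for (r in seq_len(nrow(test))) {
    if (test$breed_type[r] == "PB") {
      if (!(test$animal[r] %in% names(uAA))) {
        stop_tc("test animal not in pedigree: ", test$animal[r])
      }
      pred[r] <- uAA[[test$animal[r]]]
    } else {
      s <- test$sire[r]; d <- test$dam[r]
      sire_part <- if (cross_prediction) {
        if (!(s %in% names(uAA))) stop_tc("test sire not in pedigree: ", s)
        uAA[[s]]
      } else {
        if (!(s %in% names(uAC))) stop_tc("test sire not in pedigree: ", s)
        uAC[[s]]
      }
      dam_part <- if (dam_term && length(uBC) && d %in% names(uBC)) {
        uBC[[d]]
      } else 0
      pred[r] <- sire_part + dam_part
    }
  }
  pred
}

#' Per-fold predictive ability (Pearson correlations)
#'
#' Per-fold correlation between observed and predicted values over
#' non-missing pairs; folds with fewer than 3 pairs (or zero variance)
#' are reported missing and excluded from the unweighted mean.
#'
#' @param observed,predicted aligned numeric vectors.
#' @param folds integer fold label per element.
#' @return data.frame (class `tc_cv_result`): fold, n, r, with an
#'   `"average"` row.
#' @export
predictive_ability <- function(observed, predicted, folds) {
  stopifnot(length(observed) == length(predicted),
            length(observed) == length(folds))
  out <- lapply(sort(unique(folds)), function(f) {
    sel <- folds == f & !is.na(observed) & !is.na(predicted)
    n <- sum(sel)
    r <- if (n < 3 || stats::sd(observed[sel]) == 0 ||
             stats::sd(predicted[sel]) == 0) {
      warning("fold ", f, " has fewer than 3 usable pairs or zero variance; ",
              "reported missing")
      NA_real_
    } else stats::cor(observed[sel], predicted[sel])
    data.frame(fold = as.character(f), n = n, r = r)
  })
  res <- do.call(rbind, out)
  res <- rbind(res, data.frame(fold = "average", n = sum(res$n),
                               r = mean(res$r, na.rm = TRUE)))
  class(res) <- c("tc_cv_result", "data.frame")
  res
}

#' Sire-blocked k-fold cross-validation of a terminal-cross model
#'
#' The study's two-stage protocol: (1) phenotypes are adjusted once for
#' the systematic effects of a full-data fit (`adjust_fit`, typically the
#' GEN model — a deliberate, documented leakage of fixed effects);
#' (2) sires are randomly split into `k` balanced subsets, all offspring
#' records following their sire; (3) for each fold the model is re-solved
#' on the training records only (animals stay in the pedigree and genotype
#' panel) with variance components fixed at `vc`, and the test fold's
#' adjusted phenotypes are predicted by the rules of [predict_testset()].
#'
#' @param data trait table.
#' @param spec a [model_spec()] for the model under evaluation.
#' @param kinship kinship list for `spec` (see [assemble_mme()]).
#' @param vc variance components, fixed across folds.
#' @param ped_A,ped_B pedigrees.
#' @param adjust_fit full-data fit used for adjustment (default: fit
#'   `spec` itself on the full data).
#' @param k folds (default 6).
#' @param seed fold-assignment seed.
#' @param cross_prediction,dam_term passed to [predict_testset()].
#' @return List with `folds`, and per-performance `tc_cv_result` tables
#'   `PB` and `CB` (NULL when the model kind has no such records).
#' @export
run_cv <- function(data, spec, kinship, vc, ped_A, ped_B = NULL,
                   adjust_fit = NULL, k = 6, seed = 1,
                   cross_prediction = FALSE, dam_term = TRUE) {
  validate_trait_table(data, spec$trait)
  if (is.null(adjust_fit)) {
    des <- build_design(data, spec, ped_A, ped_B)
    adjust_fit <- solve_blup(assemble_mme(des, vc, kinship))
  }
  adj <- adjust_phenotypes(data, adjust_fit)
  sires <- sort(unique(adj$sire[!is.na(adj[[spec$trait]])]))
  folds <- make_folds(sires, k = k, seed = seed)
  rec_fold <- unname(folds[adj$sire])

  used <- if (spec$kind == "GEN_UNI_PB") adj$breed_type == "PB" else
          if (spec$kind == "GEN_UNI_CB") adj$breed_type == "CB" else
          rep(TRUE, nrow(adj))
  pred <- rep(NA_real_, nrow(adj))
  for (f in seq_len(k)) {
    train <- adj[rec_fold != f & used, , drop = FALSE]
    test <- adj[rec_fold == f & used, , drop = FALSE]
    if (!nrow(test)) next
    fit_spec <- if (cross_prediction) {
      model_spec("GEN_UNI_PB", spec$trait, spec$recipe, spec$genotyped)
    } else spec
    train_used <- if (cross_prediction) {
      train[train$breed_type == "PB", , drop = FALSE]
    } else train
    des_f <- build_design(train_used, fit_spec, ped_A, ped_B)
    fit_f <- solve_blup(assemble_mme(des_f, vc, kinship))
    pred[which(rec_fold == f & used)] <-
      predict_testset(fit_f, test, cross_prediction = cross_prediction,
                      dam_term = dam_term)
  }
  obs <- adj[[spec$trait]]
  res <- list(folds = folds)
  for (perf in c("PB", "CB")) {
    sel <- used & adj$breed_type == perf & !is.na(pred)
    res[[perf]] <- if (any(sel)) {
      predictive_ability(obs[sel], pred[sel], rec_fold[sel])
    } else NULL
  }
  res
}

#' Flatten cross-validation results to a report table
#' @param cv a [run_cv()] result.
#' @param model,trait labels for the report.
#' @return data.frame: model, trait, performance, fold, n, r.
#' @export
cv_report <- function(cv, model = "", trait = "") {
  out <- list()
  for (perf in c("PB", "CB")) {
    if (is.null(cv[[perf]])) next
    tb <- as.data.frame(cv[[perf]])
    out[[perf]] <- data.frame(model = model, trait = trait,
                              performance = perf, tb)
  }
  do.call(rbind, out)
}
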