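# End-to-end calibration and evaluation.
#
# Calibration: filter bank -> per-band CSP -> log-variance features -> MIBIF
# selection -> LDA, retaining the per-band class covariances for later
# alignment.  Evaluation: trial-by-trial, optionally recomputing the per-band
# alignment transforms from a bounded buffer of recent labeled trials before
# classifying each new trial.

#' Calibrate a subject-specific decoding model
#'
#' Runs the full training pipeline on a labeled session.  If the epoch extent
#' is wider than the configured analysis window, the window is cut first.
#' The per-band class covariances of the calibration session are stored in
#' the model; they are the reference distributions for adaptation.
#'
#' @param es a validated, roughly class-balanced two-class `epoch_set`.
#' @param cfg a [pipeline_config()].
#' @return object of class `calibration_model`.
#' @export
calibrate <- function(es, cfg = pipeline_config()) {
  validate_epoch_set(es)
  if (!isTRUE(all.equal(es$window, cfg$window))) {
    es <- extract_window(es, cfg$window[1], cfg$window[2])
  }
  be <- apply_filter_bank(es, cfg)
  nb <- nrow(cfg$bands)
  calib_cov <- vector("list", nb)
  csp_models <- vector("list", nb)
  for (b in seq_len(nb)) {
    calib_cov[[b]] <- class_covariances(be, b)
    csp_models[[b]] <- fit_csp(calib_cov[[b]], cfg$m)
  }
  fm <- extract_features(be, csp_models)
  sel <- select_features(fm, cfg$k_select, estimator = cfg$features$mi_estimator)
  lda <- fit_lda(fm$values[, sel$selected, drop = FALSE], fm$labels)
  structure(list(cfg = cfg, csp_models = csp_models, selection = sel,
                 selection_bands = fm$band_of_feature[sel$selected],
                 lda = lda, calib_cov = calib_cov,
                 channels = es$channels, fs = es$fs,
                 train_accuracy_pct = 100 * mean(
                   predict(lda, fm$values[, sel$selected, drop = FALSE])$class == fm$labels)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> ", length(x$channels), " channels, ",
      nrow(x$cfg$bands), " bands; selected columns: ",
      paste(x$selection$selected, collapse = ", "),
      " (bands ", paste(sort(unique(x$selection_bands)), collapse = ", "), ")\n",
      "  training resubstitution accuracy: ",
      format(x$train_accuracy_pct, digits = 4), " %\n", sep = "")
  invisible(x)
}

# features of ONE banded trial under the model, with optional per-band
# transforms (V = NULL means identity everywhere)
trial_features <- function(model, banded_trial, V = NULL) {
  sel <- model$selection$selected
  p_band <- 2L * model$cfg$m
  f <- numeric(length(sel))
  for (k in seq_along(sel)) {
    b <- model$selection_bands[k]
    x <- banded_trial[[b]]
    if (!is.null(V)) x <- apply_transform(V[[b]], x)
    mod <- model$csp_models[[b]]
    Wr <- mod$W[mod$retained, , drop = FALSE]
    v <- rowSums((Wr %*% x)^2)
    row <- (sel[k] - 1L) %% p_band + 1L
    f[k] <- log(v[row] / sum(v))
  }
  f
}

# shared preparation: cut the window and run the filter bank of the model.
# A banded_epochs (already filtered, e.g. once before several evaluation
# protocols) is passed through after a layout check.
prepare_eval <- function(model, es) {
  if (inherits(es, "banded_epochs")) {
    if (!identical(es$channels, model$channels)) {
      stop("channel layout of the evaluation set does not match the model")
    }
    return(es)
  }
  validate_epoch_set(es)
  if (!identical(es$channels, model$channels)) {
    stop("channel layout of the evaluation set does not match the model")
  }
  if (!isTRUE(all.equal(es$window, model$cfg$window))) {
    es <- extract_window(es, model$cfg$window[1], model$cfg$window[2])
  }
  apply_filter_bank(es, model$cfg)
}

result_from_records <- function(true, pred, scored) {
  acc <- 100 * mean(pred[scored] == true[scored])
  structure(list(trials = data.frame(true = true, pred = pred, scored = scored),
                 accuracy_pct = acc, n_scored = sum(scored),
                 n_adaptation_only = sum(!scored)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> ", format(x$accuracy_pct, digits = 4), " % correct on ",
      x$n_scored, " scored trials (", x$n_adaptation_only, " adaptation-only)\n",
      sep = "")
  invisible(x)
}

#' Evaluate a model without adaptation
#'
#' Classifies every trial with the identity transform.  By default the first
#' `cfg$buffer_size` trials are still excluded from scoring so that the
#' static and adaptive protocols are compared on exactly the same trials.
#'
#' @param model a `calibration_model`.
#' @param es evaluation `epoch_set` with matching channel layout (or an
#'   already filtered `banded_epochs`, e.g. when several protocols are run on
#'   one session).
#' @param skip_first number of leading trials excluded from scoring.
#' @return an `evaluation_result`.
#' @export
evaluate_static <- function(model, es, skip_first = model$cfg$buffer_size) {
  be <- prepare_eval(model, es)
  N <- length(be$labels)
  fm <- extract_features(be, model$csp_models)
  pred <- predict(model$lda,
                  fm$values[, model$selection$selected, drop = FALSE])$class
  result_from_records(be$labels, pred, seq_len(N) > skip_first)
}

#' Evaluate a model with buffer-based adaptation
#'
#' Trials are processed in arrival order.  For each trial the per-band
#' alignment transforms are recomputed from the current buffer
#' ([compute_band_transforms()]; identity while a class is still empty), the
#' trial is transformed, classified, and then pushed into the buffer with its
#' adaptation label (the true label under the offline protocol, the
#' prediction if `dsa_label_source = "predicted"`).  Before the buffer is
#' full, transforms use all trials seen so far (ramp-up); the first
#' `skip_first` trials are excluded from scoring.  `buffer_size = 0` disables
#' adaptation entirely and reproduces the static protocol.
#'
#' @param model a `calibration_model`.
#' @param es evaluation `epoch_set`.
#' @param buffer_size total buffer capacity in trials (even; half per class).
#' @param skip_first trials excluded from scoring (defaults to `buffer_size`).
#' @return an `evaluation_result`.
#' @export
evaluate_adaptive <- function(model, es, buffer_size = model$cfg$buffer_size,
                              skip_first = buffer_size) {
  stopifnot(buffer_size >= 0, buffer_size %% 2 == 0)
  be <- prepare_eval(model, es)
  N <- length(be$labels)
  nb <- length(be$data)
  use_true <- !identical(model$cfg$dsa$label_source, "predicted")
  # per-trial, per-band unit-trace covariances (buffer payload)
  covs <- lapply(seq_len(N), function(i) {
    lapply(seq_len(nb), function(b) trial_covariance(be$data[[b]][, , i]))
  })
  buf <- adaptation_buffer(capacity = buffer_size %/% 2L)
  pred <- integer(N)
  for (i in seq_len(N)) {
    V <- NULL
    if (buffer_size > 0 && length(buf$class_1) >= 1 && length(buf$class_2) >= 1) {
      V <- compute_band_transforms(buf, model)$V
    }
    banded_trial <- lapply(seq_len(nb), function(b) be$data[[b]][, , i])
    f <- trial_features(model, banded_trial, V)
    pred[i] <- predict(model$lda, f)$class
    if (buffer_size > 0) {
      lab <- if (use_true) be$labels[i] else pred[i]
      buf <- update_buffer(buf, list(cov = covs[[i]]), lab)
    }
  }
  result_from_records(be$labels, pred, seq_len(N) > skip_first)
}

#' Sweep the adaptation-buffer size
#'
#' Runs [evaluate_adaptive()] for each requested buffer size, scoring only
#' trials after the first `max(sizes)` so that every size is compared on the
#' same trials (size 0 is the static protocol).
#'
#' @param model a `calibration_model`.
#' @param es evaluation `epoch_set`.
#' @param sizes even buffer sizes, each <= 30 by protocol convention.
#' @return named numeric vector of accuracies (percent), one per size.
#' @export
buffer_sweep <- function(model, es, sizes = seq(0, 30, by = 2)) {
  stopifnot(all(sizes %% 2 == 0), all(sizes >= 0))
  skip <- max(sizes)
  out <- vapply(sizes, function(sz) {
    evaluate_adaptive(model, es, buffer_size = sz, skip_first = skip)$accuracy_pct
  }, 0)
  stats::setNames(out, as.character(sizes))
}

#' Chance-level screening by repeated stratified cross-validation
#'
#' 10 repetitions of stratified 10-fold cross-validation of the full pipeline
#' (CSP, feature selection and LDA refit inside every fold; the per-epoch
#' band-pass filtering is trial-wise and therefore computed once).  A session
#' whose mean accuracy falls inside the chance band (43-57 percent by
#' default, from the binomial chance-level convention) fails the screen: its
#' data are not usable for calibration.
#'
#' @param es a labeled `epoch_set`.
#' @param cfg a [pipeline_config()]; `cfg$seed` seeds the fold assignment.
#' @param n_repeats,n_folds cross-validation layout (default 10 x 10).
#' @return list with `mean_accuracy_pct`, `pass` (TRUE iff outside the chance
#'   band), `per_repeat` accuracies, `chance_band`.
#' @export
crossval_screen <- function(es, cfg = pipeline_config(), n_repeats = 10L,
                            n_folds = 10L) {
  validate_epoch_set(es)
  if (min(table(es$labels)) < n_folds) {
    stop("need at least ", n_folds, " trials per class for ", n_folds, "-fold CV")
  }
  if (!isTRUE(all.equal(es$window, cfg$window))) {
    es <- extract_window(es, cfg$window[1], cfg$window[2])
  }
  be <- apply_filter_bank(es, cfg)
  nb <- nrow(cfg$bands)
  d <- dim(be$data[[1]])
  n <- d[1]; s <- d[2]; N <- d[3]
  labels <- be$labels
  # precompute per-trial covariances and flat band matrices once
  covs <- lapply(seq_len(nb), function(b) {
    lapply(seq_len(N), function(i) trial_covariance(be$data[[b]][, , i]))
  })
  flat <- lapply(be$data, function(a) { dim(a) <- c(n, s * N); a })
  grp <- rep(seq_len(N), each = s)
  p_band <- 2L * cfg$m
  fold_acc <- matrix(NA_real_, n_repeats, n_folds)
  withr::with_seed(cfg$seed, {
    for (r in seq_len(n_repeats)) {
      fold_id <- integer(N)
      for (j in 1:2) {
        idx <- sample(which(labels == j))
        fold_id[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      for (fold in seq_len(n_folds)) {
        test <- which(fold_id == fold)
        train <- setdiff(seq_len(N), test)
        vals <- matrix(NA_real_, N, nb * p_band)
        for (b in seq_len(nb)) {
          sig1 <- Reduce(`+`, covs[[b]][intersect(train, which(labels == 1L))])
          sig2 <- Reduce(`+`, covs[[b]][intersect(train, which(labels == 2L))])
          cc <- class_covariances_obj(sig1 / sum(labels[train] == 1L),
                                      sig2 / sum(labels[train] == 2L))
          mod <- fit_csp(cc, cfg$m)
          Wr <- mod$W[mod$retained, , drop = FALSE]
          v <- rowsum(t((Wr %*% flat[[b]])^2), grp)
          vals[, (b - 1L) * p_band + seq_len(p_band)] <- log(v / rowSums(v))
        }
        fm_train <- structure(list(values = vals[train, , drop = FALSE],
                                   band_of_feature = rep(seq_len(nb), each = p_band),
                                   row_of_feature = rep(seq_len(p_band), nb),
                                   labels = labels[train]),
                              class = "feature_matrix")
        sel <- select_features(fm_train, cfg$k_select,
                               estimator = cfg$features$mi_estimator)
        lda <- fit_lda(vals[train, sel$selected, drop = FALSE], labels[train])
        pred <- predict(lda, vals[test, sel$selected, drop = FALSE])$class
        fold_acc[r, fold] <- mean(pred == labels[test])
      }
    }
  })
  mean_acc <- 100 * mean(fold_acc)
  list(mean_accuracy_pct = mean_acc,
       pass = !(mean_acc >= cfg$chance_band[1] && mean_acc <= cfg$chance_band[2]),
       per_repeat = 100 * rowMeans(fold_acc),
       chance_band = cfg$chance_band)
}

#' Covariance disparity between two recordings
#'
#' Measures how differently two sessions (e.g. a passive-movement calibration
#' run and a motor-imagery run) are distributed in the model's most
#' discriminative frequency band: the band whose top selected feature has
#' maximal mutual information.  Both sets are band-pass filtered in that
#' band, optionally restricted to a channel subset (e.g. the six motor
#' channels), and the zero-mean Gaussian KL divergence between their average
#' class covariances is summed over classes, with `es_b` as the reference.
#'
#' @param es_a,es_b `epoch_set`s sharing at least the requested channels.
#' @param model a `calibration_model` (defines the band and the MI ranking).
#' @param channels `"all"` or a character vector of channel names
#'   (e.g. [motor_channels()]).
#' @return scalar disparity (>= 0; 0 when the sets are identical).
#' @export
kl_disparity <- function(es_a, es_b, model, channels = "all") {
  sel <- model$selection$selected
  best_band <- model$selection_bands[which.max(model$selection$mi_scores[sel])]
  cfg1 <- model$cfg
  cfg1$bands <- cfg1$bands[best_band, , drop = FALSE]
  chans <- if (identical(channels, "all")) es_a$channels else channels
  per_set <- function(es) {
    idx <- match(chans, es$channels)
    if (anyNA(idx)) {
      stop("channels not present: ", paste(chans[is.na(idx)], collapse = ", "))
    }
    if (!isTRUE(all.equal(es$window, cfg1$window))) {
      es <- extract_window(es, cfg1$window[1], cfg1$window[2])
    }
    be <- apply_filter_bank(es, cfg1)
    arr <- be$data[[1]][idx, , , drop = FALSE]
    lapply(1:2, function(j) {
      ids <- which(be$labels == j)
      Reduce(`+`, lapply(ids, function(i) trial_covariance(arr[, , i]))) / length(ids)
    })
  }
  sa <- per_set(es_a)
  sb <- per_set(es_b)
  gaussian_kl(sa[[1]], sb[[1]]) + gaussian_kl(sa[[2]], sb[[2]])
}

#' Aggregate per-subject accuracies into a results table
#'
#' @param per_subject either a named list (subject -> named numeric vector of
#'   condition accuracies) or a data.frame with columns `subject`,
#'   `condition`, `accuracy_pct`.
#' @return object of class `results_table`: a condition x subject matrix with
#'   a final `Mean` column (arithmetic row mean, reported to 2 decimals).
#' @export
aggregate_results <- function(per_subject) {
  if (is.data.frame(per_subject)) {
    df <- per_subject
    subjects <- unique(df$subject)
    conditions <- unique(df$condition)
    M <- matrix(NA_real_, length(conditions), length(subjects),
                dimnames = list(conditions, subjects))
    for (k in seq_len(nrow(df))) {
      M[as.character(df$condition[k]), as.character(df$subject[k])] <- df$accuracy_pct[k]
    }
  } else {
    subjects <- names(per_subject)
    conditions <- names(per_subject[[1]])
    M <- vapply(per_subject, function(v) as.numeric(v[conditions]),
                numeric(length(conditions)))
    M <- matrix(M, nrow = length(conditions), dimnames = list(conditions, subjects))
  }
  if (anyNA(M)) stop("every condition must be present for every subject")
  structure(list(accuracies = M, mean = round(rowMeans(M), 2)),
            class = "results_table")
}

#' @export
print.results_table <- function(x, ...) {
  out <- cbind(x$accuracies, Mean = x$mean)
  print(round(out, 2))
  invisible(x)
}

#' Bundled reference per-subject accuracies
#'
#' Per-subject classification accuracies (percent) for two cohorts (16
#' healthy subjects, 6 stroke patients) under four calibration/adaptation
#' conditions of the passive-movement-calibration evaluation study this
#' package models: motor-imagery-calibrated and passive-movement-calibrated
#' models, each with and without buffer-based alignment.  Used to validate
#' [aggregate_results()] against the study's published row means.
#'
#' @return data.frame with columns `cohort`, `subject`, `condition`,
#'   `accuracy_pct`.
#' @export
reference_accuracies <- function() {
  path <- system.file("extdata", "reference_accuracies.csv", package = "fbdsa",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
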