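#' Patient-grouped fold assignment for cross-validation
#'
#' Shuffles patients (seeded), stratified by patient label, and deals them
#' into `k` folds so fold sizes and class composition stay balanced. All
#' eyes of a patient share the patient's fold, so train/validation/test
#' patient sets are always disjoint. Fold roles rotate cyclically: for test
#' fold `f` the validation fold is `f %% k + 1` and the remaining folds
#' train, giving each eye exactly one appearance in validation and one in
#' test across the `k` rotations (a 60/20/20 split at `k = 5`).
#'
#' @param manifest Data frame with columns `patient_id` and `label` (one
#'   label per patient).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the patient shuffle.
#' @return A tibble of class `split_plan` with columns `patient_id`,
#'   `label`, `fold` and attribute `k`.
#' @export
make_patient_grouped_folds <- function(manifest, k = 5, seed = 1L) {
  stopifnot(all(c("patient_id", "label") %in% names(manifest)))
  patients <- dplyr::distinct(tibble::as_tibble(manifest),
                              .data$patient_id, .data$label)
  if (anyDuplicated(patients$patient_id))
    stop("a patient carries more than one label", call. = FALSE)
  if (nrow(patients) < k)
    stop("fewer patients than folds", call. = FALSE)
  plan <- with_seed(seed, {
    offset <- 0L
    parts <- lapply(split(patients, patients$label), function(d) {
      d <- d[sample.int(nrow(d)), ]
      d$fold <- ((seq_len(nrow(d)) - 1L + offset) %% k) + 1L
      offset <<- (offset + nrow(d)) %% k
      d
    })
    dplyr::arrange(dplyr::bind_rows(parts), .data$patient_id)
  })
  structure(plan, k = as.integer(k), class = c("split_plan", class(plan)))
}

# Patient sets playing train/validation/test for one rotation.
fold_roles <- function(plan, fold) {
  k <- attr(plan, "k")
  stopifnot(fold >= 1, fold <= k)
  val <- (fold %% k) + 1L
  list(
    test = plan$patient_id[plan$fold == fold],
    validation = plan$patient_id[plan$fold == val],
    train = plan$patient_id[!plan$fold %in% c(fold, val)]
  )
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted one half; computed from midranks. Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels: logical, 0/1 numeric, or a factor/character
#'   where `"glaucoma"` (or the second factor level) is positive.
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' auroc(c(1, 3, 2, 4), c(0, 1, 0, 1))
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y))
    stop("scores and labels differ in length", call. = FALSE)
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    pos <- if ("glaucoma" %in% lv) "glaucoma" else lv[length(lv)]
    return(as.integer(labels == pos))
  }
  stop("unsupported label type", call. = FALSE)
}

#' F1 score for the positive class
#'
#' Harmonic mean of precision and recall, `2 TP / (2 TP + FP + FN)`; defined
#' as 0 when the denominator vanishes (no positives and no positive
#' predictions).
#'
#' @param predictions Predicted binary labels (same encodings as [auroc()]).
#' @param labels True binary labels.
#' @return Scalar in \[0, 1\].
#' @export
f1_score <- function(predictions, labels) {
  p <- as_binary_labels(predictions)
  y <- as_binary_labels(labels)
  if (length(p) != length(y))
    stop("predictions and labels differ in length", call. = FALSE)
  tp <- sum(p == 1 & y == 1)
  fp <- sum(p == 1 & y == 0)
  fn <- sum(p == 0 & y == 1)
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

#' SVM hyperparameter grid
#'
#' The grid searched per fold: linear and RBF kernels, cost in
#' {0.1, 1, 10, 100}, and for the RBF kernel gamma in {scale heuristic,
#' 0.01, 0.1, 1}, where the scale heuristic is `1 / (p * var(X_train))`.
#' Order is fixed so validation ties resolve deterministically to the first
#' grid point.
#'
#' @return A tibble with columns `kernel`, `cost`, `gamma` (`NA` = linear or
#'   scale heuristic).
#' @export
svm_grid <- function() {
  costs <- c(0.1, 1, 10, 100)
  dplyr::bind_rows(
    tibble::tibble(kernel = "linear", cost = costs, gamma = NA_real_),
    tidyr::expand_grid(kernel = "radial", cost = costs,
                       gamma = c(NA_real_, 0.01, 0.1, 1))
  )
}

# Wide feature matrix (rows = eyes) for one method, plus labels/patients.
features_to_matrix <- function(features, method) {
  f <- dplyr::filter(features, .data$method == !!method)
  if (nrow(f) == 0) stop("no rows for method ", method, call. = FALSE)
  wide <- tidyr::pivot_wider(
    dplyr::select(f, "image_id", "patient_id", "label", "feature", "value"),
    names_from = "feature", values_from = "value"
  )
  x <- as.matrix(wide[, setdiff(names(wide),
                                c("image_id", "patient_id", "label"))])
  list(x = x, image_id = wide$image_id, patient_id = wide$patient_id,
       label = as_binary_labels(wide$label))
}

fit_svm_scores <- function(x_train, y_train, x_new, kernel, cost, gamma) {
  y <- factor(ifelse(y_train == 1, "pos", "neg"), levels = c("neg", "pos"))
  args <- list(x = x_train, y = y, kernel = kernel, cost = cost,
               scale = FALSE, probability = FALSE)
  if (kernel == "radial" && !is.na(gamma)) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  pred <- predict(fit, x_new, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm's decision value is positive for the class named first in the
  # column label; orient it so larger = more "pos".
  sign <- if (startsWith(colnames(dv)[1], "pos")) 1 else -1
  list(scores = as.numeric(dv) * sign,
       predictions = as.integer(pred == "pos"))
}

#' Train and evaluate one cross-validation rotation
#'
#' For one method and one fold rotation: features are standardised with the
#' training set's mean and standard deviation, an SVM is fitted per grid
#' point on the training patients, the grid point with the highest
#' validation AUROC is selected (ties: first in grid order), and that model
#' is scored on the test patients — AUROC from decision-function margins,
#' F1 from hard predictions.
#'
#' @param features Long feature tibble from [extract_features()].
#' @param plan A [make_patient_grouped_folds()] plan.
#' @param fold Rotation index in `1..k`.
#' @param method One of `"VD"`, `"GPDP"`, `"IA"`, `"PD"`, `"PDA"`.
#' @param grid Hyperparameter grid, see [svm_grid()].
#' @return One-row tibble: `method`, `fold`, `auroc`, `f1`, `kernel`,
#'   `cost`, `gamma`, `n_train`, `n_test`.
#' @export
train_eval_fold <- function(features, plan, fold, method,
                            grid = svm_grid()) {
  fm <- features_to_matrix(features, method)
  roles <- fold_roles(plan, fold)
  idx <- function(pats) fm$patient_id %in% pats
  tr <- idx(roles$train); va <- idx(roles$validation); te <- idx(roles$test)
  for (nm in c("validation", "test")) {
    sel <- if (nm == "validation") va else te
    if (length(unique(fm$label[sel])) < 2)
      stop("fold ", fold, ": ", nm, " set is single-class", call. = FALSE)
  }
  mu <- colMeans(fm$x[tr, , drop = FALSE])
  sdv <- apply(fm$x[tr, , drop = FALSE], 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  z <- sweep(sweep(fm$x, 2, mu), 2, sdv, "/")
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- fit_svm_scores(z[tr, , drop = FALSE], fm$label[tr],
                          z[va, , drop = FALSE],
                          g$kernel, g$cost, g$gamma)
    val_auc <- auroc(res$scores, fm$label[va])
    if (is.null(best) || val_auc > best$val_auc)
      best <- list(val_auc = val_auc, g = g)
  }
  res <- fit_svm_scores(z[tr, , drop = FALSE], fm$label[tr],
                        z[te, , drop = FALSE],
                        best$g$kernel, best$g$cost, best$g$gamma)
  tibble::tibble(
    method = method, fold = as.integer(fold),
    auroc = auroc(res$scores, fm$label[te]),
    f1 = f1_score(res$predictions, fm$label[te]),
    kernel = best$g$kernel, cost = best$g$cost, gamma = best$g$gamma,
    n_train = sum(tr), n_test = sum(te)
  )
}

#' Patient-grouped k-fold cross-validation over methods
#'
#' Runs [train_eval_fold()] for every method and fold rotation on one shared
#' patient-grouped split plan (and separately per plexus when the feature
#' table carries more than one).
#'
#' @param features Long feature tibble from [extract_features()], optionally
#'   with a `plexus` column.
#' @param methods Methods to evaluate; default all present.
#' @param k Number of folds.
#' @param seed Seed for the patient shuffle.
#' @param grid Hyperparameter grid.
#' @return A tibble of class `octa_cv` with one row per (plexus, method,
#'   fold). Use [tidy()] for per-fold rows, [glance()] for per-method means
#'   sorted by mean AUROC, [autoplot()] for a fold-level plot.
#' @export
cross_validate <- function(features, methods = NULL, k = 5, seed = 1L,
                           grid = svm_grid()) {
  features <- tibble::as_tibble(features)
  if (!"plexus" %in% names(features)) features$plexus <- "Retina"
  methods <- methods %||% unique(features$method)
  out <- dplyr::bind_rows(lapply(
    split(features, features$plexus), function(fp) {
      plan <- make_patient_grouped_folds(fp, k = k, seed = seed)
      dplyr::bind_rows(lapply(methods, function(m) {
        dplyr::bind_rows(lapply(seq_len(k), function(f) {
          train_eval_fold(fp, plan, f, m, grid)
        }))
      })) |>
        dplyr::mutate(plexus = fp$plexus[1], .before = 1)
    }))
  structure(out, class = c("octa_cv", class(out)),
            k = as.integer(k), seed = as.integer(seed))
}

#' @export
tidy.octa_cv <- function(x, ...) {
  class(x) <- setdiff(class(x), "octa_cv")
  tibble::as_tibble(x)
}

#' Per-method summary of a cross-validation run
#'
#' @param x An `octa_cv` result.
#' @param ... Unused.
#' @return Tibble with one row per (plexus, method): `mean_auroc`,
#'   `mean_f1`, `n_folds`, sorted by descending mean AUROC within plexus.
#' @export
glance.octa_cv <- function(x, ...) {
  tidy(x) |>
    dplyr::group_by(.data$plexus, .data$method) |>
    dplyr::summarise(mean_auroc = mean(.data$auroc),
                     mean_f1 = mean(.data$f1),
                     n_folds = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$plexus, dplyr::desc(.data$mean_auroc))
}

#' @rdname glance.octa_cv
#' @param object An `octa_cv` result.
#' @export
autoplot.octa_cv <- function(object, ...) {
  d <- tidy(object)
  ord <- glance(object)
  d$method <- factor(d$method, levels = rev(unique(ord$method)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$auroc, y = .data$method)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          size = 4, colour = "red3") +
    ggplot2::facet_wrap(ggplot2::vars(.data$plexus)) +
    ggplot2::labs(x = "test AUROC (per fold; diamond = mean)",
                  y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
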