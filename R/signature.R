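# Radiomic signature: Z-score -> Spearman redundancy pruning -> univariate
# AUC filter -> SMOTE -> LASSO -> cubic-kernel SVM -> ROC threshold.
# fit_signature() composes the stages and freezes every parameter; applying
# the model to new patients uses the frozen parameters only.

#' Z-score normalisation fitted on the training set
#'
#' `zscore_fit()` estimates per-feature means and standard deviations on the
#' training matrix (dropping zero-variance columns); `zscore_apply()`
#' transforms any matrix with those frozen parameters, so test patients are
#' normalised with training statistics only.
#'
#' @param train numeric matrix, training patients x features (>= 2 rows).
#' @return `zscore_fit()`: list with `mean`, `sd` (named) and `dropped`
#'   (zero-variance feature names).
#' @export
zscore_fit <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need >= 2 training patients")
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  dropped <- colnames(train)[sdv == 0 | !is.finite(sdv)]
  if (length(dropped))
    rs_log("dropping zero-variance features: ", length(dropped))
  keep <- setdiff(colnames(train), dropped)
  list(mean = mu[keep], sd = sdv[keep], dropped = dropped)
}

#' @rdname zscore_fit
#' @param params a fitted normalisation from `zscore_fit()`.
#' @param x matrix to transform (must contain the fitted features).
#' @export
zscore_apply <- function(params, x) {
  x <- as.matrix(x)
  missing <- setdiff(names(params$mean), colnames(x))
  if (length(missing))
    stop("matrix lacks fitted features: ", paste(missing, collapse = ", "))
  x <- x[, names(params$mean), drop = FALSE]
  scale(x, center = params$mean, scale = params$sd)[, , drop = FALSE]
}

# Spearman correlation matrix via ranked columns (average ranks for ties)
spearman_matrix <- function(x) {
  r <- apply(x, 2, rank)
  stats::cor(r)
}

#' Prune redundant features by pairwise Spearman correlation
#'
#' Among each pair with |Spearman rho| above the threshold (default 0.85),
#' only one member is kept: the one with the lower mean absolute correlation
#' with all other currently retained features (the pair partners excluded).
#' Offending pairs are visited in decreasing |rho| order, which makes the
#' outcome deterministic; exact mean-correlation ties drop the
#' lexicographically later name.
#'
#' @param x numeric matrix, patients x features (>= 3 features).
#' @param threshold absolute Spearman correlation above which a pair is
#'   redundant.
#' @return character vector of retained feature names (original order).
#' @export
prune_redundant <- function(x, threshold = 0.85) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 3) stop("redundancy pruning needs >= 3 features")
  nm <- colnames(x)
  rho <- abs(spearman_matrix(x))
  diag(rho) <- 0
  pairs <- which(upper.tri(rho) & rho > threshold, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(nm)
  ord <- order(rho[pairs], decreasing = TRUE)
  pairs <- pairs[ord, , drop = FALSE]
  retained <- rep(TRUE, p)
  for (q in seq_len(nrow(pairs))) {
    a <- pairs[q, 1]; b <- pairs[q, 2]
    if (!retained[a] || !retained[b]) next
    others <- which(retained); others <- setdiff(others, c(a, b))
    ma <- if (length(others)) mean(rho[a, others]) else 0
    mb <- if (length(others)) mean(rho[b, others]) else 0
    drop <- if (ma > mb) a else if (mb > ma) b
      else c(a, b)[which.max(rank(nm[c(a, b)]))]  # tie: later name goes
    retained[drop] <- FALSE
  }
  nm[retained]
}

# rank-sum AUC of x as a score for labels (ties get half credit)
rank_auc <- function(x, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(x)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Univariate AUC filter
#'
#' Scores every feature by its rank-sum AUC against the binary label,
#' orientation-corrected as `max(AUC, 1 - AUC)` (a feature that orders the
#' classes perfectly in either direction is maximally informative), and
#' keeps features strictly above the threshold (default 0.7).
#'
#' @param x numeric matrix, patients x features.
#' @param labels binary labels (0/1), both classes present.
#' @param threshold AUC threshold; features with oriented AUC > threshold
#'   are kept.
#' @return character vector of retained feature names; attribute `"auc"`
#'   carries the oriented AUC of every candidate.
#' @export
auc_filter <- function(x, labels, threshold = 0.7) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  aucs <- apply(x, 2, rank_auc, labels = labels)
  oriented <- pmax(aucs, 1 - aucs)
  keep <- colnames(x)[oriented > threshold]
  if (length(keep) == 0)
    stop("no feature exceeds AUC ", threshold,
         "; with synthetic cohorts, increase the planted effect size")
  structure(keep, auc = oriented)
}

#' SMOTE class balancing
#'
#' Synthetic Minority Oversampling: new minority samples are drawn as
#' `x_i + u (x_nn - x_i)` with `u ~ Uniform(0,1)` and `x_nn` one of the
#' `k_neighbors` nearest minority neighbours of `x_i`, until the classes are
#' exactly balanced. Uses the caller's RNG stream. If the minority class has
#' fewer than `k_neighbors + 1` members, `k` is reduced (with a log entry).
#'
#' @param x numeric matrix, patients x features.
#' @param labels binary labels (0/1); minority class size >= 2.
#' @param k_neighbors number of nearest neighbours (default 5).
#' @return list with the augmented `x` and `labels` (originals first,
#'   synthetic rows appended).
#' @export
smote <- function(x, labels, k_neighbors = 5) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0, 1)))
  if (tab[1] == tab[2]) return(list(x = x, labels = labels))
  minority <- as.integer(names(which.min(tab)))
  idx <- which(labels == minority)
  n_min <- length(idx)
  if (n_min < 2) stop("SMOTE needs at least 2 minority samples")
  n_syn <- abs(tab[1] - tab[2])
  k <- k_neighbors
  if (n_min < k + 1) {
    k <- n_min - 1
    rs_log("SMOTE: minority class of ", n_min,
           " samples, reducing k_neighbors to ", k)
  }
  xm <- x[idx, , drop = FALSE]
  dd <- as.matrix(dist(xm))
  diag(dd) <- Inf
  nn_idx <- matrix(apply(dd, 1, function(row) order(row)[seq_len(k)]),
                   ncol = n_min)
  nn_idx <- t(nn_idx)                     # rows = minority points, k columns
  syn <- matrix(NA_real_, n_syn, ncol(x), dimnames = list(NULL, colnames(x)))
  for (s in seq_len(n_syn)) {
    i <- sample.int(n_min, 1)
    j <- nn_idx[i, sample.int(k, 1)]
    u <- runif(1)
    syn[s, ] <- xm[i, ] + u * (xm[j, ] - xm[i, ])
  }
  list(x = rbind(x, syn), labels = c(labels, rep(minority, n_syn)))
}

#' LASSO feature selection with internal cross-validation
#'
#' L1-penalised logistic regression over a log-spaced lambda grid; the
#' penalty is chosen to maximise the mean cross-validated AUC over
#' stratified folds, restricted to lambdas whose solution retains at least
#' one feature. Selected features are those with non-zero coefficients at
#' the chosen lambda. Fold assignment uses the caller's RNG stream.
#'
#' @param x numeric matrix, patients x features (>= 2 * n_folds rows).
#' @param labels binary labels (0/1).
#' @param n_folds number of CV folds (default 5).
#' @param n_lambda grid size (default 50).
#' @return list with `features`, `lambda`, `coefficients` (named, non-zero,
#'   plus `(Intercept)`), `lambda_grid`, `cv_auc` and `n_nonzero` per grid
#'   point.
#' @export
lasso_select <- function(x, labels, n_folds = 5, n_lambda = 50) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (nrow(x) < 2 * n_folds) stop("need >= 2 patients per fold")
  if (ncol(x) == 1) {
    # nothing to select: unpenalised logistic coefficient for the record
    co <- coef(stats::glm(labels ~ x[, 1], family = stats::binomial()))
    rs_log("LASSO skipped: a single candidate feature remains")
    return(list(features = colnames(x), lambda = 0,
                coefficients = setNames(as.numeric(co),
                                        c("(Intercept)", colnames(x))),
                lambda_grid = 0, cv_auc = NA_real_, n_nonzero = 1L))
  }
  fit0 <- glmnet::glmnet(x, labels, family = "binomial", alpha = 1,
                         nlambda = n_lambda)
  grid <- fit0$lambda
  # stratified fold assignment
  foldid <- integer(nrow(x))
  for (cl in c(0, 1)) {
    i <- which(labels == cl)
    foldid[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  # cross-validated AUC per lambda, computed explicitly so the criterion
  # never silently changes with the fold size
  fold_auc <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    hold <- foldid == f
    if (length(unique(labels[hold])) < 2) next
    ff <- glmnet::glmnet(x[!hold, , drop = FALSE], labels[!hold],
                         family = "binomial", alpha = 1, lambda = grid)
    lp <- predict(ff, x[hold, , drop = FALSE], s = grid, type = "link")
    fold_auc[f, ] <- apply(lp, 2, function(s) {
      if (length(unique(s)) == 1) 0.5 else rank_auc(s, labels[hold])
    })
  }
  cv_auc <- colMeans(fold_auc, na.rm = TRUE)
  nz <- fit0$df
  ok <- which(nz > 0)
  if (length(ok) == 0)
    stop("LASSO selected zero features at every lambda")
  best <- ok[which.max(cv_auc[ok])]
  lambda <- grid[best]
  co <- coef(fit0, s = lambda, exact = FALSE)
  co <- setNames(as.numeric(co), rownames(co))
  sel <- setdiff(names(co)[co != 0], "(Intercept)")
  list(features = sel, lambda = lambda,
       coefficients = co[co != 0],
       lambda_grid = grid, cv_auc = cv_auc, n_nonzero = nz)
}

#' Cubic-kernel support vector machine
#'
#' Trains an SVM with polynomial kernel of degree 3,
#' `K(u, v) = (gamma u.v + coef0)^3`, keeping the continuous decision value
#' as the signature score. The score is oriented so that higher values
#' indicate the positive class (label 1). Kernel scale defaults to
#' `1 / (n_features * var(x))`.
#'
#' @param x numeric matrix (typically normalised, LASSO-selected features).
#' @param labels binary labels (0/1), both classes present.
#' @param C regularisation cost (default 1).
#' @param degree polynomial degree (default 3, the cubic kernel).
#' @param gamma kernel scale; `NULL` for the default above.
#' @param coef0 kernel offset (default 0).
#' @return list with support vectors, their coefficients, `rho`, kernel
#'   parameters and the orientation sign; `svm_decision()` evaluates the
#'   frozen score on new rows.
#' @export
train_svm <- function(x, labels, C = 1, degree = 3, gamma = NULL,
                      coef0 = 0) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (is.null(gamma)) {
    v <- var(as.vector(x))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  fit <- e1071::svm(x, factor(labels, levels = c(0, 1)), scale = FALSE,
                    kernel = "polynomial", degree = degree, gamma = gamma,
                    coef0 = coef0, cost = C)
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  # e1071 orients decision values toward the first label of the colname pair
  pos_first <- strsplit(colnames(dv), "/")[[1]][1] == "1"
  sign_ <- if (pos_first) 1 else -1
  model <- list(sv = unname(as.matrix(fit$SV)), coefs = as.numeric(fit$coefs),
                rho = as.numeric(fit$rho), gamma = gamma, coef0 = coef0,
                degree = degree, C = C, sign = sign_,
                features = colnames(x))
  # sanity: frozen evaluator reproduces the library's decision values
  ours <- svm_decision(model, x)
  if (max(abs(ours - sign_ * as.numeric(dv))) > 1e-8)
    stop("internal error: decision-value mismatch")
  model
}

#' @rdname train_svm
#' @param model a fitted SVM component.
#' @param newx matrix of rows to score (columns = model features).
#' @export
svm_decision <- function(model, newx) {
  newx <- as.matrix(newx)
  K <- (model$gamma * (newx %*% t(model$sv)) + model$coef0)^model$degree
  as.numeric(model$sign * (K %*% model$coefs - model$rho))
}

#' ROC-optimal classification threshold
#'
#' Chooses the score threshold whose ROC operating point minimises the
#' Euclidean distance to the ideal corner (sensitivity 100%, false-positive
#' rate 0%); ties are broken toward higher specificity. Candidate
#' thresholds are midpoints between consecutive unique scores plus
#' sentinels below and above the score range; a patient is called high-risk
#' when `score > threshold`.
#'
#' @param scores numeric signature scores.
#' @param labels binary labels (0/1), both classes present.
#' @return the threshold (numeric scalar).
#' @export
choose_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) == 1) {
    warning("degenerate single-valued scores; returning midpoint threshold")
    return(u)
  }
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  sens <- vapply(cand, function(t) mean(pos > t), 0)
  fpr <- vapply(cand, function(t) mean(neg > t), 0)
  d <- sqrt((1 - sens)^2 + fpr^2)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.min(fpr[best])]  # higher specificity
  cand[best]
}

#' Default signature-training settings
#'
#' @param spearman_threshold redundancy threshold on |Spearman rho|.
#' @param auc_threshold univariate AUC filter threshold.
#' @param n_folds,n_lambda LASSO cross-validation settings.
#' @param smote_k SMOTE neighbour count.
#' @param svm_C,svm_degree,svm_coef0,svm_gamma cubic-SVM settings
#'   (`svm_gamma = NULL` uses `1/(n_features * var)`).
#' @param auc_fallback if no feature passes the AUC filter, retain the
#'   single best-AUC feature instead of failing (keeps no-signal
#'   calibration runs well defined); logged when triggered.
#' @return list of settings for [fit_signature()].
#' @export
signature_config <- function(spearman_threshold = 0.85, auc_threshold = 0.7,
                             n_folds = 5, n_lambda = 50, smote_k = 5,
                             svm_C = 1, svm_degree = 3, svm_coef0 = 0,
                             svm_gamma = NULL, auc_fallback = TRUE) {
  as.list(environment())
}

#' Fit the radiomic signature
#'
#' Composes the training pipeline in its reference order on the training
#' matrix: Z-score normalisation (parameters frozen), Spearman redundancy
#' pruning, univariate AUC filtering, SMOTE balancing, LASSO selection with
#' internal cross-validation, cubic-kernel SVM, and ROC-based threshold
#' selection on the training scores of the original (non-synthetic)
#' patients. No statistic of any test set enters the fit.
#'
#' @param x numeric matrix, training patients x features — typically the
#'   stability-selected columns (see [select_stable()]); row names are
#'   patient ids.
#' @param labels binary training labels (1 = short survivor).
#' @param config settings from [signature_config()].
#' @param seed integer seed governing SMOTE draws and CV fold assignment.
#' @return An object of class `radiomic_signature` with frozen
#'   normalisation parameters, the four nested feature lists
#'   (`stable_features` ⊇ `pruned_features` ⊇ `auc_features` ⊇
#'   `lasso_features`), LASSO penalty and coefficients, SVM parameters and
#'   the classification threshold. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`.
#' @seealso [predict.radiomic_signature()], [signature_to_json()]
#' @export
fit_signature <- function(x, labels, config = signature_config(), seed = 1) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels))
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  with_seed(seed, {
    norm <- zscore_fit(x)
    xs <- zscore_apply(norm, x)
    stable <- colnames(xs)

    pruned <- if (ncol(xs) >= 3)
      prune_redundant(xs, config$spearman_threshold) else colnames(xs)
    xp <- xs[, pruned, drop = FALSE]

    kept <- tryCatch(auc_filter(xp, labels, config$auc_threshold),
                     error = function(e) e)
    if (inherits(kept, "error")) {
      if (!isTRUE(config$auc_fallback)) stop(kept)
      aucs <- apply(xp, 2, rank_auc, labels = labels)
      oriented <- pmax(aucs, 1 - aucs)
      kept <- pruned[which.max(oriented)]
      rs_log("AUC filter empty; falling back to best single feature ", kept)
    }
    auc_feats <- as.character(kept)
    xa <- xp[, auc_feats, drop = FALSE]

    bal <- smote(xa, labels, config$smote_k)

    las <- lasso_select(bal$x, bal$labels, config$n_folds, config$n_lambda)
    if (length(las$features) == 0)
      stop("LASSO retained no features")
    xl <- bal$x[, las$features, drop = FALSE]

    svm_ <- train_svm(xl, bal$labels, C = config$svm_C,
                      degree = config$svm_degree, gamma = config$svm_gamma,
                      coef0 = config$svm_coef0)

    train_scores <- svm_decision(svm_, xa[, las$features, drop = FALSE])
    thr <- choose_threshold(train_scores, labels)

    structure(list(
      normalization = norm,
      stable_features = stable, pruned_features = pruned,
      auc_features = auc_feats, lasso_features = las$features,
      lasso_lambda = las$lambda, lasso_coefficients = las$coefficients,
      svm = svm_, threshold = thr, seed = as.integer(seed),
      config = config,
      train = list(scores = train_scores, labels = labels,
                   ids = rownames(x))),
      class = "radiomic_signature")
  })
}

#' Apply a fitted signature to new patients
#'
#' Normalises the supplied features with the frozen training parameters,
#' evaluates the frozen SVM decision value and thresholds it: patients with
#' `score > threshold` are called high-risk (`HR`), the rest low-risk
#' (`LR`).
#'
#' @param object a fitted `radiomic_signature`.
#' @param newdata matrix or data frame of features (must contain all model
#'   features; extra columns are ignored).
#' @param ... unused.
#' @return data frame with `patient_id` (row names of `newdata`), `score`
#'   and `call` (`"HR"`/`"LR"`).
#' @export
predict.radiomic_signature <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$lasso_features, colnames(newdata))
  if (length(missing))
    stop("newdata lacks model features: ", paste(missing, collapse = ", "))
  xs <- zscore_apply(object$normalization,
                     newdata[, object$stable_features, drop = FALSE])
  scores <- svm_decision(object$svm,
                         xs[, object$lasso_features, drop = FALSE])
  data.frame(
    patient_id = if (!is.null(rownames(newdata))) rownames(newdata)
                 else paste0("row", seq_len(nrow(newdata))),
    score = scores,
    call = ifelse(scores > object$threshold, "HR", "LR"),
    stringsAsFactors = FALSE)
}

#' @export
print.radiomic_signature <- function(x, ...) {
  cat("Radiomic signature (cubic-kernel SVM)\n")
  cat("  features: ", length(x$stable_features), " stable -> ",
      length(x$pruned_features), " non-redundant -> ",
      length(x$auc_features), " AUC-filtered -> ",
      length(x$lasso_features), " in model\n", sep = "")
  cat("  lasso lambda: ", signif(x$lasso_lambda, 4),
      "; threshold: ", signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.radiomic_signature <- function(object, ...) {
  tr_auc <- rank_auc(object$train$scores, object$train$labels)
  cat("Radiomic signature\n")
  cat("  model features:\n")
  for (f in object$lasso_features) cat("    - ", f, "\n", sep = "")
  cat("  LASSO lambda: ", signif(object$lasso_lambda, 4), "\n", sep = "")
  cat("  SVM: degree ", object$svm$degree, ", C ", object$svm$C,
      ", gamma ", signif(object$svm$gamma, 4), "\n", sep = "")
  cat("  threshold: ", signif(object$threshold, 4),
      " (HR if score > threshold)\n", sep = "")
  cat("  training AUC: ", round(tr_auc, 3), "\n", sep = "")
  invisible(object)
}

#' @export
coef.radiomic_signature <- function(object, ...) {
  object$lasso_coefficients
}

#' @export
plot.radiomic_signature <- function(x, ...) {
  roc <- roc_auc(x$train$scores, x$train$labels)
  plot(roc$roc$fpr, roc$roc$sens, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "Sensitivity",
       main = sprintf("Training ROC (AUC = %.2f)", roc$auc), ...)
  abline(0, 1, lty = 3)
  sel <- x$train$scores > x$threshold
  points(mean(x$train$scores[x$train$labels == 0] > x$threshold),
         mean(x$train$scores[x$train$labels == 1] > x$threshold),
         pch = 19, col = "red")
  invisible(x)
}

#' Serialize a signature to JSON and back
#'
#' The JSON document stores every frozen parameter (feature lists,
#' normalisation, LASSO penalty and coefficients, SVM support vectors and
#' kernel parameters, threshold, seed) at full floating-point precision;
#' reloading reproduces identical predictions.
#'
#' @param model a `radiomic_signature`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return `signature_to_json()`: the JSON string (invisibly if written to
#'   a file); `signature_from_json()`: the restored `radiomic_signature`.
#' @export
signature_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "radiomic_signature"))
  payload <- unclass(model)
  payload$config$svm_gamma <- model$svm$gamma
  payload$normalization <- list(
    feature = names(model$normalization$mean),
    mean = unname(model$normalization$mean),
    sd = unname(model$normalization$sd),
    dropped = model$normalization$dropped)
  payload$lasso_coefficients <- list(
    name = names(model$lasso_coefficients),
    value = unname(model$lasso_coefficients))
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                         null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname signature_to_json
#' @param json a JSON string or path produced by `signature_to_json()`.
#' @export
signature_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  obj$normalization <- list(
    mean = setNames(obj$normalization$mean, obj$normalization$feature),
    sd = setNames(obj$normalization$sd, obj$normalization$feature),
    dropped = obj$normalization$dropped %||% character(0))
  obj$lasso_coefficients <- setNames(obj$lasso_coefficients$value,
                                     obj$lasso_coefficients$name)
  if (!is.matrix(obj$svm$sv))
    obj$svm$sv <- matrix(obj$svm$sv, nrow = 1)
  obj$svm$coefs <- as.numeric(obj$svm$coefs)
  structure(obj, class = "radiomic_signature")
}
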