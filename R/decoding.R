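#' Build the trial x 100-bin population feature matrix
#'
#' For each session, every unit's single-trial binned rates are normalized
#' against the unit's own baseline (z against the mean/SD of its single-trial
#' pre-cue baseline-bin rates pooled over trials; units with zero baseline
#' spread are dropped with a warning, and with `normalization = "raw"` rates
#' are used as-is). The per-trial feature vector is the mean of those
#' normalized rates across the session's simultaneously recorded units; one
#' row per trial, stacked across sessions/animals. Labels are 1 for DS+ and
#' 0 for DS-.
#'
#' @param bundles list of [session_bundle()] objects belonging to one
#'   (area, group, session) cell.
#' @param config an [analysis_config()].
#' @param normalization `"baseline_z"` (default) or `"raw"`.
#' @return list with `x` (trials x 100 matrix), `y` (0/1 labels) and
#'   `session` (per-row session index).
#' @export
build_feature_matrix <- function(bundles, config = analysis_config(),
                                 normalization = c("baseline_z", "raw")) {
  normalization <- match.arg(normalization)
  if (inherits(bundles, "session_bundle")) bundles <- list(bundles)
  bl_bins <- bins_in_interval(config$grid, -1, 0)
  xs <- list(); ys <- list(); ss <- list()
  for (k in seq_along(bundles)) {
    tensor <- align_and_bin(bundles[[k]], config)
    uids <- dimnames(tensor$counts)[[1]]
    if (!length(uids)) {
      warning("session ", k, " has no units; excluded")
      next
    }
    mats <- list()
    for (u in uids) {
      rates <- unit_rates(tensor, u)
      if (normalization == "baseline_z") {
        bl <- as.vector(rates[, bl_bins])
        mu <- mean(bl); sigma <- stats::sd(bl)
        if (!(sigma > 0)) {
          warning("unit ", u, " has zero baseline spread; excluded from features")
          next
        }
        rates <- (rates - mu) / sigma
      }
      mats[[u]] <- rates
    }
    if (!length(mats)) {
      warning("session ", k, " has no usable units; excluded")
      next
    }
    xs[[k]] <- Reduce(`+`, mats) / length(mats)
    ys[[k]] <- as.integer(tensor$trials$cue_type == "DSplus")
    ss[[k]] <- rep(k, nrow(tensor$trials))
  }
  if (!length(xs)) stop("no usable sessions")
  list(x = do.call(rbind, xs), y = unlist(ys), session = unlist(ss))
}

# stratified train/test partition; returns list(train, test) of row indices
.stratified_split <- function(y, train_frac) {
  idx <- seq_along(y)
  tr <- unlist(lapply(unique(y), function(cl) {
    cand <- idx[y == cl]
    sample(cand, max(1L, round(length(cand) * train_frac)))
  }))
  list(train = sort(tr), test = setdiff(idx, tr))
}

# stratified fold ids 1..n_folds
.stratified_folds <- function(y, n_folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    f[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  f
}

.standardize <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sigma <- apply(xtr, 2, stats::sd)
  sigma[!(sigma > 0)] <- 1
  list(train = sweep(sweep(xtr, 2, mu), 2, sigma, "/"),
       test = sweep(sweep(xte, 2, mu), 2, sigma, "/"))
}

#' One repeated-split LASSO decoding run
#'
#' Draws a stratified train/test split (80/20 by default), standardizes
#' features on the training split only, chooses the L1 penalty from a
#' 30-value log-spaced path by stratified 5-fold cross-validated accuracy
#' within the training set (ties broken toward the stronger penalty),
#' refits on the full training set at the chosen penalty, and reports the
#' held-out accuracy together with the nonzero-coefficient features. A
#' degenerate (single-class) split is resampled with the next seed.
#'
#' @param x trials x features matrix (see [build_feature_matrix()]).
#' @param y 0/1 labels.
#' @param config an [analysis_config()] (decoder settings are read from
#'   `config$decoder`).
#' @param seed random seed of the split.
#' @return list with `seed`, `lambda`, `accuracy`, `selected` (feature
#'   indices), `train`, `test` (row indices).
#' @export
decode_once <- function(x, y, config = analysis_config(), seed = 1L) {
  dec <- config$decoder
  for (attempt in 0:20) {
    set.seed(seed + attempt)
    sp <- .stratified_split(y, dec$train_frac)
    ok <- length(unique(y[sp$train])) == 2 && length(unique(y[sp$test])) == 2
    if (ok) break
    message("degenerate split at seed ", seed + attempt, "; resampling")
  }
  if (!ok) stop("could not produce a two-class split")
  std <- .standardize(x[sp$train, , drop = FALSE], x[sp$test, , drop = FALSE])
  ytr <- y[sp$train]
  path <- suppressWarnings(
    glmnet::glmnet(std$train, ytr, family = "binomial",
                   standardize = FALSE, nlambda = dec$n_lambda))
  grid <- path$lambda
  folds <- .stratified_folds(ytr, dec$n_folds)
  acc <- matrix(NA_real_, dec$n_folds, length(grid))
  for (f in seq_len(dec$n_folds)) {
    hold <- folds == f
    fit <- suppressWarnings(
      glmnet::glmnet(std$train[!hold, , drop = FALSE], ytr[!hold],
                     family = "binomial", standardize = FALSE,
                     lambda = grid))
    pr <- stats::predict(fit, std$train[hold, , drop = FALSE], type = "class")
    acc[f, seq_len(ncol(pr))] <- colMeans(pr == ytr[hold])
  }
  cv <- colMeans(acc, na.rm = TRUE)
  # parsimony under ties: take the strongest penalty whose CV accuracy is
  # within one fold-SE of the maximum (with noisy CV curves a strict
  # argmax never ties; this is the standard one-SE rule)
  best_ix <- which.max(cv)
  se_best <- stats::sd(acc[, best_ix], na.rm = TRUE) / sqrt(dec$n_folds)
  lambda <- grid[which(cv >= max(cv, na.rm = TRUE) - se_best)[1]]
  co <- stats::coef(path, s = lambda, exact = FALSE)
  selected <- which(as.numeric(co)[-1] != 0)
  pred <- stats::predict(path, std$test, s = lambda, type = "class")
  list(seed = seed, lambda = lambda,
       accuracy = mean(as.numeric(pred) == y[sp$test]),
       selected = selected, train = sp$train, test = sp$test)
}

# refit a plain logistic model on a feature subset; test accuracy.
# An empty feature set falls back to the intercept-only model (majority
# class), the natural chance-level reference.
.restricted_accuracy <- function(x, y, train, test, features) {
  if (!length(features)) {
    pred <- as.integer(mean(y[train]) > 0.5)
    return(mean(pred == y[test]))
  }
  std <- .standardize(x[train, features, drop = FALSE],
                      x[test, features, drop = FALSE])
  d <- data.frame(y = y[train], std$train)
  fit <- suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
  pr <- suppressWarnings(
    stats::predict(fit, newdata = data.frame(std$test), type = "response"))
  mean(as.integer(pr > 0.5) == y[test])
}

#' Repeated-split LASSO decoding with per-epoch accuracies
#'
#' Runs [decode_once()] over `n_repeats` (default 100) derived seeds and
#' tallies how often each of the 100 bin features receives a nonzero
#' coefficient. Epoch accuracies depend on `accuracy_mode`:
#'
#' * `"epoch"` (default): the repeated LASSO is additionally run with the
#'   feature set restricted to each epoch's mask (Tone: post-cue tone bins;
#'   Lever: post-lever bins), using the same splits. Per-repeat held-out
#'   accuracies of those epoch decoders are reported, and the `top_k` (10)
#'   most frequently selected features within each mask are recorded. All
#'   feature selection happens inside training splits, so label-permuted
#'   data decodes at chance.
#' * `"top_k_refit"`: a plain logistic model restricted to the `top_k` most
#'   frequently selected features of the mask (tallied over all repeats) is
#'   refit on every repeat's training split. Because the tally sees every
#'   split, this mode is optimistically biased under the null; it is kept
#'   for comparison, not inference.
#' * `"global"`: the unrestricted per-repeat LASSO accuracies are reported
#'   for both epochs.
#'
#' @inheritParams decode_once
#' @return An object of class `decode_result`: list with `repeats`
#'   (data.frame seed/lambda/accuracy/n_selected), `frequency` (length-100
#'   selection counts from the unrestricted model), `top_features` (list
#'   Tone/Lever), `epoch_accuracy` (n_repeats x 2 matrix),
#'   `mean_epoch_accuracy` (named vector) and `config` snapshot of decoder
#'   settings.
#' @export
repeated_decoding <- function(x, y, config = analysis_config()) {
  dec <- config$decoder
  seeds <- config$seed * 1000L + seq_len(dec$n_repeats)
  runs <- lapply(seeds, function(s) decode_once(x, y, config, seed = s))
  freq <- tabulate(unlist(lapply(runs, `[[`, "selected")), nbins = ncol(x))
  masks <- list(Tone = dec$tone_bins, Lever = dec$lever_bins)
  top_of <- function(f, m) {
    cand <- m[f[m] > 0]
    if (length(cand) < dec$top_k)
      message("fewer than top_k ever-selected features in mask; using ",
              length(cand))
    cand[order(-f[cand], cand)][seq_len(min(dec$top_k, length(cand)))]
  }
  ea <- matrix(NA_real_, dec$n_repeats, 2,
               dimnames = list(NULL, names(masks)))
  top <- lapply(masks, function(m) top_of(freq, m))
  if (dec$accuracy_mode == "epoch") {
    for (e in names(masks)) {
      m <- masks[[e]]
      eruns <- lapply(seeds, function(s)
        decode_once(x[, m, drop = FALSE], y, config, seed = s))
      ea[, e] <- vapply(eruns, `[[`, numeric(1), "accuracy")
      efreq <- numeric(ncol(x))
      efreq[m] <- tabulate(unlist(lapply(eruns, `[[`, "selected")),
                           nbins = length(m))
      top[[e]] <- top_of(efreq, m)
    }
  } else if (dec$accuracy_mode == "top_k_refit") {
    for (i in seq_along(runs)) for (e in names(masks))
      ea[i, e] <- .restricted_accuracy(x, y, runs[[i]]$train,
                                       runs[[i]]$test, top[[e]])
  } else {
    for (e in names(masks))
      ea[, e] <- vapply(runs, `[[`, numeric(1), "accuracy")
  }
  structure(
    list(repeats = data.frame(
           seed = seeds,
           lambda = vapply(runs, `[[`, numeric(1), "lambda"),
           accuracy = vapply(runs, `[[`, numeric(1), "accuracy"),
           n_selected = vapply(runs, function(r) length(r$selected),
                               integer(1))),
         selected = lapply(runs, `[[`, "selected"),
         frequency = freq, top_features = top, epoch_accuracy = ea,
         mean_epoch_accuracy = colMeans(ea), config = dec),
    class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf(
    "<decode_result> %d repeats; mean accuracy Tone %.3f, Lever %.3f\n",
    nrow(x$repeats), x$mean_epoch_accuracy["Tone"],
    x$mean_epoch_accuracy["Lever"]))
  invisible(x)
}

#' Compare two groups' decoding accuracies
#'
#' Independent two-sample t test (pooled variance, df = 2 x n_repeats - 2)
#' on the per-repeat epoch accuracies of two [repeated_decoding()] results,
#' with Cohen's d.
#'
#' @param result_a,result_b `decode_result` objects with equal repeat
#'   counts.
#' @return data.frame with one row per epoch: `epoch`, `mean_a`, `mean_b`,
#'   `t`, `df`, `p`, `cohens_d`.
#' @export
compare_groups <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "decode_result"),
            inherits(result_b, "decode_result"))
  if (nrow(result_a$repeats) != nrow(result_b$repeats))
    stop("groups must have equal numbers of repeats")
  rows <- lapply(colnames(result_a$epoch_accuracy), function(e) {
    a <- result_a$epoch_accuracy[, e]; b <- result_b$epoch_accuracy[, e]
    tt <- t_tests(a, b, mode = "independent")
    data.frame(epoch = e, mean_a = mean(a), mean_b = mean(b),
               t = tt$t, df = tt$df, p = tt$p, cohens_d = tt$cohens_d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
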