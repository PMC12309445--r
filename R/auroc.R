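#' Binwise auROC between two firing-rate distributions
#'
#' Area under the ROC curve for discriminating DS+ from DS- single-trial
#' firing rates in one time bin, computed as the normalized Mann-Whitney
#' pair statistic: the fraction of (DS+, DS-) trial pairs in which the DS+
#' rate exceeds the DS- rate, with ties credited 0.5. Equal distributions
#' give exactly 0.5; complete separation gives 0 or 1.
#'
#' @param dsplus numeric vector of per-trial rates under DS+.
#' @param dsminus numeric vector of per-trial rates under DS-.
#' @return auROC in [0, 1].
#' @examples
#' binwise_auroc(c(2, 3, 4), c(1, 2, 3))  # 7/9
#' @export
binwise_auroc <- function(dsplus, dsminus) {
  n1 <- length(dsplus); n2 <- length(dsminus)
  if (n1 < 1 || n2 < 1) stop("both trial classes must be non-empty")
  r <- rank(c(dsplus, dsminus))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Binwise auROC profile with epoch selectivity of one unit
#'
#' Computes the DS+ vs DS- auROC in every 50 ms bin, then for each epoch
#' forms the epoch mean auROC, the baseline mean \eqn{\mu_a} and SD
#' \eqn{\sigma_a} over the epoch's baseline bins, the increase
#' \eqn{\Delta = } epoch mean \eqn{- \mu_a}, and flags the unit selective
#' when \eqn{|\Delta|/\sigma_a} exceeds the z threshold. `ToneR`/`ToneS`
#' use the pre-cue baseline bins, `Lever` the 2--3 s bins, mirroring the
#' z-score convention. A zero baseline spread yields a degenerate
#' (non-selective) epoch entry.
#'
#' @param tensor an [align_and_bin()] result.
#' @param unit_id unit identifier.
#' @param config an [analysis_config()].
#' @param trial_labels optional replacement cue-label vector (used by
#'   [shuffle_null()]); defaults to the tensor's own labels.
#' @return An object of class `auroc_profile`: list with `auroc` (per-bin
#'   values) and `epochs`, a data.frame with one row per epoch: `epoch`,
#'   `epoch_mean`, `baseline_mean`, `baseline_sd`, `delta_auroc`, `z`,
#'   `selective`, `degenerate`.
#' @export
auroc_profile <- function(tensor, unit_id, config = analysis_config(),
                          trial_labels = NULL) {
  labs <- trial_labels %||% tensor$trials$cue_type
  rates <- unit_rates(tensor, unit_id)
  ip <- labs == "DSplus"; im <- labs == "DSminus"
  if (!any(ip) || !any(im)) stop("both trial classes must be present")
  au <- vapply(seq_len(ncol(rates)), function(b)
    binwise_auroc(rates[ip, b], rates[im, b]), numeric(1))
  structure(list(unit_id = unit_id, auroc = au,
                 epochs = epoch_selectivity(au, config)),
            class = "auroc_profile")
}

#' Epoch selectivity statistics from a binwise auROC trace
#'
#' For each epoch: epoch mean auROC, baseline mean/SD over the epoch's
#' baseline bins, \eqn{\Delta} auROC (epoch mean minus baseline mean), the
#' z value \eqn{\Delta/\sigma_a} and the selectivity flag
#' (\eqn{|z| >} threshold). Exposed separately from [auroc_profile()] so
#' the arithmetic can be applied to any auROC trace.
#'
#' @param auroc numeric vector of per-bin auROC values (length =
#'   `config$grid$n_bins`).
#' @param config an [analysis_config()].
#' @return data.frame with one row per epoch: `epoch`, `epoch_mean`,
#'   `baseline_mean`, `baseline_sd`, `delta_auroc`, `z`, `selective`,
#'   `degenerate`.
#' @export
epoch_selectivity <- function(auroc, config = analysis_config()) {
  stopifnot(length(auroc) == config$grid$n_bins)
  rows <- lapply(config$epochs, function(ep) {
    bl <- bins_in_interval(config$grid, ep$baseline[1], ep$baseline[2])
    an <- bins_in_interval(config$grid, ep$analysis[1], ep$analysis[2])
    mu <- mean(auroc[bl])
    sigma <- .spread(auroc[bl], config$sd_type)
    em <- mean(auroc[an])
    degen <- !(sigma > 0)
    z <- if (degen) NA_real_ else (em - mu) / sigma
    data.frame(epoch = ep$name, epoch_mean = em, baseline_mean = mu,
               baseline_sd = sigma, delta_auroc = em - mu, z = z,
               selective = !degen && abs(z) > config$z_threshold,
               degenerate = degen, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Selectivity table for a session
#'
#' Runs [auroc_profile()] for every unit and stacks the per-epoch results.
#'
#' @inheritParams auroc_profile
#' @return data.frame with one row per unit x epoch (columns as in
#'   `auroc_profile()$epochs`, plus `unit_id`).
#' @export
selectivity_table <- function(tensor, config = analysis_config(),
                              trial_labels = NULL) {
  uids <- dimnames(tensor$counts)[[1]]
  res <- lapply(uids, function(u) {
    e <- auroc_profile(tensor, u, config, trial_labels)$epochs
    cbind(unit_id = u, e, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Trial-shuffle null for selective-unit proportions
#'
#' Permutes the DS+/DS- labels across trials (class sizes preserved),
#' re-runs the full auROC selectivity pipeline, and tallies the proportion
#' of selective units per epoch in each of `n_shuffles` replicates (10 by
#' default). The mean shuffled proportion is the null against which the
#' observed proportion of selective units is compared (see
#' [compare_selectivity_to_null()]).
#'
#' @param tensor an [align_and_bin()] result.
#' @param config an [analysis_config()].
#' @param n_shuffles number of label permutations.
#' @param seed random seed (shuffles are deterministic given it).
#' @return list with `per_shuffle` (n_shuffles x epochs matrix of selective
#'   proportions), `mean_proportion` (named per-epoch vector), and
#'   `n_units`.
#' @export
shuffle_null <- function(tensor, config = analysis_config(),
                         n_shuffles = config$n_shuffles,
                         seed = config$seed) {
  labs <- tensor$trials$cue_type
  ep_names <- vapply(config$epochs, `[[`, "", "name")
  n_units <- dim(tensor$counts)[1]
  set.seed(seed)
  per <- matrix(NA_real_, n_shuffles, length(ep_names),
                dimnames = list(NULL, ep_names))
  for (s in seq_len(n_shuffles)) {
    st <- selectivity_table(tensor, config, trial_labels = sample(labs))
    agg <- tapply(st$selective, st$epoch, mean)
    per[s, ] <- agg[ep_names]
  }
  list(per_shuffle = per, mean_proportion = colMeans(per), n_units = n_units)
}

#' Compare observed selective-unit counts with the shuffle null
#'
#' Chi-square (or, when any expected count is below 5, Fisher's exact) test
#' of the 2x2 table observed-selective vs mean-shuffled-selective counts.
#'
#' @param observed_selective number of selective units observed.
#' @param null_proportion mean selective proportion under the shuffle null.
#' @param n_units number of units.
#' @return data.frame row: counts, test used, statistic (NA for Fisher) and
#'   p value.
#' @export
compare_selectivity_to_null <- function(observed_selective, null_proportion,
                                        n_units) {
  null_sel <- round(null_proportion * n_units)
  tab <- matrix(c(observed_selective, n_units - observed_selective,
                  null_sel, n_units - null_sel), nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("counts must be nonnegative")
  small <- any(tab < 5)
  if (small) {
    p <- fisher_exact(tab)$p.value
    data.frame(n_selective = observed_selective, n_null = null_sel,
               n_units = n_units, test = "fisher", statistic = NA_real_,
               p = p, stringsAsFactors = FALSE)
  } else {
    r <- chi_square(tab)
    data.frame(n_selective = observed_selective, n_null = null_sel,
               n_units = n_units, test = "chi_square", statistic = r$statistic,
               p = r$p.value, stringsAsFactors = FALSE)
  }
}
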