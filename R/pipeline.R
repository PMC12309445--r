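#' Run the full analysis pipeline on a set of session bundles
#'
#' Executes every stage in order on one or more groups of sessions:
#' alignment and binning, responsiveness classification and proportion
#' tables, basal rates and (for VTA) putative-DA cell typing, auROC
#' selectivity with the trial-shuffle null, LASSO population decoding per
#' group, and the group statistics (chi-square on responsive proportions,
#' t tests on epoch population activity, decoder comparisons when exactly
#' two groups are present). All tables are written as TSV plus a JSON
#' manifest; the run is deterministic given `seed`.
#'
#' @param bundles either a list of [session_bundle()] objects or a named
#'   list of such lists (one element per group, e.g.
#'   `list(control = ..., stress = ...)`).
#' @param out_dir output directory.
#' @param config an [analysis_config()].
#' @param seed master seed for the stochastic stages (shuffle null,
#'   decoder splits); defaults to `config$seed`.
#' @param decode run the decoding stage (default TRUE).
#' @return list with all result tables and the manifest, invisibly.
#' @export
run_pipeline <- function(bundles, out_dir, config = analysis_config(),
                         seed = config$seed, decode = TRUE) {
  if (inherits(bundles, "session_bundle")) bundles <- list(bundles)
  if (!length(bundles)) stop("no input sessions")
  grouped <- !inherits(bundles[[1]], "session_bundle")
  groups <- if (grouped) bundles else list(all = bundles)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))

  labels <- list(); celltypes <- list(); basal <- list()
  select <- list(); null_prop <- list()
  for (g in names(groups)) {
    for (k in seq_along(groups[[g]])) {
      b <- groups[[g]][[k]]
      tensor <- align_and_bin(b, config)
      lab <- classify_responses(tensor, config)
      lab$run_group <- g
      labels[[paste(g, k)]] <- lab
      br <- basal_rate(tensor)
      br$run_group <- g
      br$animal_id <- b$metadata$animal_id %||% NA_character_
      basal[[paste(g, k)]] <- br
      ct <- cell_type_table(tensor, config)
      ct$run_group <- g
      celltypes[[paste(g, k)]] <- ct
      st <- selectivity_table(tensor, config)
      st$run_group <- g
      select[[paste(g, k)]] <- st
      nn <- shuffle_null(tensor, config, seed = seed + 17L * k)
      null_prop[[paste(g, k)]] <- data.frame(
        run_group = g, session_idx = k,
        epoch = names(nn$mean_proportion),
        null_proportion = unname(nn$mean_proportion),
        n_units = nn$n_units, stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, c(labels, list(make.row.names = FALSE)))
  basal <- do.call(rbind, c(basal, list(make.row.names = FALSE)))
  celltypes <- do.call(rbind, c(celltypes, list(make.row.names = FALSE)))
  select <- do.call(rbind, c(select, list(make.row.names = FALSE)))
  null_prop <- do.call(rbind, c(null_prop, list(make.row.names = FALSE)))
  props <- proportion_summary(labels,
                              by = c("run_group", "area", "cue_type", "epoch"))

  # selective-unit proportions vs their shuffle null, pooled per group/epoch
  sel_sum <- list()
  for (g in unique(select$run_group)) for (e in unique(select$epoch)) {
    s <- select[select$run_group == g & select$epoch == e, ]
    np <- null_prop[null_prop$run_group == g & null_prop$epoch == e, ]
    n_units <- sum(np$n_units)
    obs <- sum(s$selective)
    nullp <- stats::weighted.mean(np$null_proportion, np$n_units)
    cmp <- compare_selectivity_to_null(obs, nullp, n_units)
    sel_sum[[paste(g, e)]] <- cbind(run_group = g, epoch = e, cmp,
                                    stringsAsFactors = FALSE)
  }
  sel_sum <- do.call(rbind, c(sel_sum, list(make.row.names = FALSE)))

  # group statistics on proportions and population activity (2 groups)
  stats_rows <- list()
  gnames <- names(groups)
  if (length(gnames) == 2) {
    for (e in c("ToneR", "ToneS", "Lever")) {
      sub <- labels[labels$epoch == e & labels$cue_type == "DSplus", ]
      tab <- t(vapply(gnames, function(g) {
        d <- sub[sub$run_group == g, ]
        c(activated = sum(d$label == "activated"),
          inhibited = sum(d$label == "inhibited"),
          none = sum(!d$label %in% c("activated", "inhibited")))
      }, numeric(3)))
      use_fisher <- any(tab[, c("activated", "inhibited")] < 5)
      if (use_fisher) {
        resp <- cbind(tab[, "activated"] + tab[, "inhibited"], tab[, "none"])
        p <- fisher_exact(resp)$p.value
        stats_rows[[paste("prop", e)]] <- data.frame(
          comparison = paste0("proportion_", e), test = "fisher",
          statistic = NA_real_, df = NA_real_, p = p,
          effect_size = NA_real_, stringsAsFactors = FALSE)
      } else {
        cs <- chi_square(tab)
        stats_rows[[paste("prop", e)]] <- data.frame(
          comparison = paste0("proportion_", e), test = "chi_square",
          statistic = cs$statistic, df = cs$df, p = cs$p.value,
          effect_size = phi_effect(cs), stringsAsFactors = FALSE)
      }
      act <- lapply(gnames, function(g) {
        d <- sub[sub$run_group == g, ]
        d$mean_z[!is.na(d$mean_z)]
      })
      if (all(lengths(act) >= 2)) {
        mode <- if (length(act[[1]]) == length(act[[2]])) "independent" else "welch"
        tt <- t_tests(act[[1]], act[[2]], mode = mode)
        stats_rows[[paste("act", e)]] <- data.frame(
          comparison = paste0("population_activity_", e), test = tt$mode,
          statistic = tt$t, df = tt$df, p = tt$p, effect_size = tt$cohens_d,
          stringsAsFactors = FALSE)
      }
    }
  }
  group_tests <- if (length(stats_rows))
    do.call(rbind, c(stats_rows, list(make.row.names = FALSE))) else
    data.frame()

  decode_tables <- list()
  if (decode) {
    dec_res <- list()
    for (g in gnames) {
      cfg_g <- config
      cfg_g$seed <- seed + match(g, gnames)
      fm <- build_feature_matrix(groups[[g]], cfg_g)
      dec_res[[g]] <- repeated_decoding(fm$x, fm$y, cfg_g)
    }
    acc <- do.call(rbind, lapply(gnames, function(g) {
      ea <- dec_res[[g]]$epoch_accuracy
      data.frame(run_group = g, epoch = rep(colnames(ea), each = nrow(ea)),
                 repeat_idx = rep(seq_len(nrow(ea)), times = ncol(ea)),
                 accuracy = c(ea), stringsAsFactors = FALSE)
    }))
    freq <- do.call(rbind, lapply(gnames, function(g)
      data.frame(run_group = g, bin = seq_along(dec_res[[g]]$frequency),
                 frequency = dec_res[[g]]$frequency,
                 stringsAsFactors = FALSE)))
    decode_tables <- list(decode_accuracy = acc, feature_frequency = freq)
    if (length(gnames) == 2) {
      cmp <- compare_groups(dec_res[[1]], dec_res[[2]])
      cmp <- data.frame(comparison = paste0("decoding_", cmp$epoch),
                        test = "independent", statistic = cmp$t, df = cmp$df,
                        p = cmp$p, effect_size = cmp$cohens_d,
                        stringsAsFactors = FALSE)
      group_tests <- rbind(group_tests, cmp)
    }
  }

  tables <- c(list(labels = labels, proportions = props, basal_rates = basal,
                   celltypes = celltypes, selectivity = select,
                   shuffle_null = null_prop, selectivity_vs_null = sel_sum,
                   group_tests = group_tests),
              decode_tables)
  tables <- Filter(function(t) is.data.frame(t) && nrow(t) > 0, tables)
  manifest <- write_results(tables, out_dir, config = config, seed = seed)
  invisible(c(tables, list(manifest = manifest)))
}

#' Render a plain-text summary report from pipeline output
#'
#' Reads the TSV tables written by [run_pipeline()] from `out_dir` and
#' formats a markdown summary: responsive-unit proportions, selectivity vs
#' shuffle null, decoding accuracies and group tests. Every number is taken
#' from the written tables; nothing is recomputed, so the report is
#' byte-identical for identical manifests.
#'
#' @param out_dir directory holding a pipeline run.
#' @param file optional path to also write the report to.
#' @return character vector of report lines, invisibly printed.
#' @export
report_pipeline <- function(out_dir, file = NULL) {
  rd <- function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    if (!file.exists(p)) stop("missing pipeline output: ", nm, ".tsv")
    utils::read.delim(p, stringsAsFactors = FALSE)
  }
  lines <- c("# DS-task pipeline summary", "")
  pr <- rd("proportions")
  lines <- c(lines, "## Responsive-unit proportions (% activated / inhibited)", "")
  for (i in seq_len(nrow(pr)))
    lines <- c(lines, sprintf("- %s %s %s %s: %d%% (%d%%) of %d units",
                              pr$run_group[i], pr$area[i], pr$cue_type[i],
                              pr$epoch[i], pr$pct_activated[i],
                              pr$pct_inhibited[i], pr$n_total[i]))
  sv <- rd("selectivity_vs_null")
  lines <- c(lines, "", "## Selective units vs shuffle null", "")
  for (i in seq_len(nrow(sv)))
    lines <- c(lines, sprintf("- %s %s: %d/%d selective (null %d), %s p = %.4g",
                              sv$run_group[i], sv$epoch[i], sv$n_selective[i],
                              sv$n_units[i], sv$n_null[i], sv$test[i], sv$p[i]))
  da <- file.path(out_dir, "decode_accuracy.tsv")
  if (file.exists(da)) {
    ac <- utils::read.delim(da, stringsAsFactors = FALSE)
    lines <- c(lines, "", "## Decoding accuracy (mean over repeats)", "")
    agg <- stats::aggregate(accuracy ~ run_group + epoch, ac, mean)
    for (i in seq_len(nrow(agg)))
      lines <- c(lines, sprintf("- %s %s: %.1f%%", agg$run_group[i],
                                agg$epoch[i], 100 * agg$accuracy[i]))
  }
  gt <- file.path(out_dir, "group_tests.tsv")
  if (file.exists(gt)) {
    g <- utils::read.delim(gt, stringsAsFactors = FALSE)
    lines <- c(lines, "", "## Group statistics", "")
    for (i in seq_len(nrow(g)))
      lines <- c(lines, sprintf("- %s [%s]: statistic = %s, df = %s, p = %.4g",
                                g$comparison[i], g$test[i],
                                format(g$statistic[i], digits = 4),
                                format(g$df[i], digits = 4), g$p[i]))
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
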