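# Replicated benchmark driver: runs every method on every scenario with
# paired replicate seeds, computes selection and prediction metrics, and
# aggregates stability profiles and cross-scenario ranks.

#' The thirteen benchmarked selectors
#'
#' Returns the registry of method wrappers used by [benchmark_methods()].
#' Each entry fits one selector on a standardized dataset and returns an
#' `sb_fit` carrying its declared selection rule. Three methods receive the
#' oracle calibration the evaluation protocol grants them: SSVS gets the
#' true sparsity as its prior inclusion probability, the regularized
#' horseshoe gets the true active count as its expected model size, and
#' SuSiE gets the true active count as `L`.
#'
#' @return Named list of fitting functions `f(x, y, seed, opts)` where
#'   `opts` carries `k_true`, `s_true` and the `mcmc` settings.
#' @export
method_registry <- function() {
  list(
    lasso = function(x, y, seed, opts) fit_lasso(x, y, seed = seed),
    enet = function(x, y, seed, opts) {
      fit_elastic_net(x, y, alpha = 0.5, seed = seed)
    },
    alasso = function(x, y, seed, opts) fit_alasso(x, y, seed = seed),
    blasso = function(x, y, seed, opts) {
      fit_blasso(x, y, mcmc = opts_mcmc(opts, seed))
    },
    hs = function(x, y, seed, opts) {
      fit_horseshoe(x, y, mcmc = opts_mcmc(opts, seed))
    },
    hsp = function(x, y, seed, opts) {
      fit_horseshoe_plus(x, y, mcmc = opts_mcmc(opts, seed))
    },
    rhs = function(x, y, seed, opts) {
      fit_reg_horseshoe(x, y, mcmc = opts_mcmc(opts, seed),
                        p0 = max(1, opts$k_true))
    },
    sn = function(x, y, seed, opts) {
      fit_ssvs(x, y, cfg = spike_slab_config(omega = opts$s_true),
               mcmc = opts_mcmc(opts, seed))
    },
    sl = function(x, y, seed, opts) fit_sslasso(x, y),
    susie = function(x, y, seed, opts) {
      fit_susie(x, y, L = max(1, opts$k_true))
    },
    rf = function(x, y, seed, opts) fit_rf(x, y, seed = seed),
    sisl = function(x, y, seed, opts) fit_sisl(x, y, seed = seed),
    rfsfs = function(x, y, seed, opts) fit_rfsfs(x, y, seed = seed)
  )
}

opts_mcmc <- function(opts, seed) {
  m <- opts$mcmc
  mcmc_config(m$n_iter, m$burn_in, m$thin, seed = seed)
}

#' Run a replicated benchmark
#'
#' For each scenario and replicate, generates a dataset (seeded so every
#' method sees the identical dataset: a paired design), standardizes it,
#' fits every requested method, applies its selection rule and records
#' FDR, FNR, F-score, in- and out-of-sample MSPE and runtime. A method
#' failure on a replicate yields a record with missing metrics and the run
#' continues.
#'
#' @param scenarios A [sim_config()] or named list of them.
#' @param methods Character vector of registry names (default all 13).
#' @param reps Replicates per scenario.
#' @param base_seed Base seed; replicate seeds are derived from it.
#' @param mcmc An [mcmc_config()] shared by the samplers (its seed field is
#'   replaced by replicate-specific seeds).
#' @param fix_coef If `TRUE`, the true coefficients are drawn once per
#'   scenario and held fixed across replicates (the selection-stability
#'   design); otherwise every replicate draws its own support.
#' @param pip_threshold Threshold for PIP-based selection (default 0.5).
#' @param quiet Suppress per-failure messages.
#' @return A `benchmark_result`: list with `records` (tibble, one row per
#'   method x scenario x replicate), `selections` (per scenario/method a
#'   reps x p binary matrix), `supports`, and `configs`.
#' @export
benchmark_methods <- function(scenarios, methods = names(method_registry()),
                              reps = 10, base_seed = 1L,
                              mcmc = mcmc_config(n_iter = 2000,
                                                 burn_in = 500),
                              fix_coef = FALSE, pip_threshold = 0.5,
                              quiet = FALSE) {
  if (inherits(scenarios, "sim_config")) {
    scenarios <- list(scenario_1 = scenarios)
  }
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  }
  registry <- method_registry()
  unknown <- setdiff(methods, names(registry))
  if (length(unknown)) {
    stopf("unknown methods: %s", paste(unknown, collapse = ", "))
  }
  if (reps < 1) stopf("`reps` must be at least 1")
  records <- list()
  selections <- list()
  supports <- list()
  for (si in seq_along(scenarios)) {
    scen_name <- names(scenarios)[si]
    cfg <- scenarios[[si]]
    fixed_coef <- if (fix_coef) {
      with_local_seed(child_seed(base_seed, si, 0L), make_coefficients(cfg))
    } else {
      NULL
    }
    sel_mats <- lapply(methods, function(m) {
      matrix(NA_integer_, reps, cfg$p)
    })
    names(sel_mats) <- methods
    supp_list <- vector("list", reps)
    for (r in seq_len(reps)) {
      cfg_r <- cfg
      cfg_r$seed <- child_seed(base_seed, si, r)
      data <- standardize_dataset(generate_dataset(cfg_r, coef = fixed_coef))
      support <- data$coef$support
      supp_list[[r]] <- support
      k_true <- length(support)
      opts <- list(k_true = k_true,
                   s_true = max(k_true / cfg$p, 1e-6), mcmc = mcmc)
      for (mi in seq_along(methods)) {
        m <- methods[mi]
        fit_seed <- child_seed(base_seed, si, r, mi)
        fit <- tryCatch(
          registry[[m]](data$x_train, data$y_train, fit_seed, opts),
          error = function(e) e
        )
        if (inherits(fit, "error")) {
          if (!quiet) {
            message(sprintf("[%s | rep %d] %s failed: %s",
                            scen_name, r, m, conditionMessage(fit)))
          }
          records[[length(records) + 1]] <- tibble::tibble(
            method = m, scenario = scen_name, replicate = r,
            tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
            fdr = NA_real_, fnr = NA_real_, fscore = NA_real_,
            mspe_in = NA_real_, mspe_out = NA_real_,
            runtime_s = NA_real_, degenerate = NA, failed = TRUE)
          next
        }
        sel <- select_features(fit, pip_threshold = pip_threshold,
                               seed = fit_seed)
        sel_mats[[m]][r, ] <- sel$selected
        cc <- confusion_counts(sel, support, cfg$p)
        f <- fscore(cc)
        records[[length(records) + 1]] <- tibble::tibble(
          method = m, scenario = scen_name, replicate = r,
          tp = cc$tp, fp = cc$fp, fn = cc$fn,
          fdr = fdr(cc), fnr = fnr(cc), fscore = as.numeric(f),
          mspe_in = mspe(fit$beta_hat, data$x_train, data$y_train),
          mspe_out = mspe(fit$beta_hat, data$x_test, data$y_test),
          runtime_s = fit$runtime_s,
          degenerate = attr(f, "degenerate"), failed = FALSE)
      }
    }
    selections[[scen_name]] <- sel_mats
    supports[[scen_name]] <- supp_list
  }
  structure(
    list(records = dplyr::bind_rows(records), selections = selections,
         supports = supports, configs = scenarios,
         base_seed = base_seed, reps = reps),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "<benchmark_result> %d scenarios x %d replicates, %d method records (%d failed)\n",
    length(x$configs), x$reps, nrow(x$records), sum(x$records$failed)))
  invisible(x)
}

#' Per-feature selection probabilities across replicates
#'
#' The proportion of replicates in which each feature was selected, split
#' into important (truly active) and non-important features. Meaningful
#' when the benchmark was run with `fix_coef = TRUE` so the true support is
#' the same in every replicate; otherwise features are labelled important
#' when active in at least half the replicates, with a warning.
#'
#' @param result A `benchmark_result` with at least 2 replicates.
#' @return A tibble with `scenario`, `method`, `feature`, `p_select`,
#'   `important`.
#' @export
selection_stability <- function(result) {
  stopifnot(inherits(result, "benchmark_result"))
  if (result$reps < 2) stopf("stability needs at least 2 replicates")
  out <- list()
  for (scen in names(result$selections)) {
    supps <- result$supports[[scen]]
    constant <- all(vapply(supps, identical, logical(1), supps[[1]]))
    if (!constant) {
      warning("true support varies across replicates; labelling features ",
              "important when active in at least half of them",
              call. = FALSE)
    }
    p <- result$configs[[scen]]$p
    freq <- tabulate(unlist(supps), nbins = p) / length(supps)
    important <- if (constant) {
      seq_len(p) %in% supps[[1]]
    } else {
      freq >= 0.5
    }
    for (m in names(result$selections[[scen]])) {
      mat <- result$selections[[scen]][[m]]
      ok <- stats::complete.cases(mat)
      if (!any(ok)) next
      pj <- colMeans(mat[ok, , drop = FALSE])
      out[[length(out) + 1]] <- tibble::tibble(
        scenario = scen, method = m, feature = seq_len(p),
        p_select = pj, important = important)
    }
  }
  dplyr::bind_rows(out)
}

#' Group medians of selection probabilities
#'
#' @param stability Output of [selection_stability()].
#' @return Tibble with the median selection probability per scenario,
#'   method and importance group.
#' @export
stability_summary <- function(stability) {
  dplyr::summarise(
    dplyr::group_by(stability, .data$scenario, .data$method,
                    .data$important),
    median_p = median(.data$p_select), .groups = "drop")
}

#' Cross-scenario rank aggregation
#'
#' Within each scenario and metric, methods are ranked on their mean metric
#' across replicates (ascending for FDR, FNR, MSPE and runtime; descending
#' for F-score), with midranks for ties. Methods that miss the entire true
#' support in every replicate of a scenario are left unranked there, as are
#' methods whose fits all failed. Ranks are then averaged across scenarios.
#'
#' @param result A `benchmark_result` or its `records` tibble.
#' @param metrics Metrics to rank (default all five plus runtime).
#' @return A `rank_table` tibble: `method`, `metric`, `m` (average rank),
#'   `m_med` (median rank), `n_scenarios`.
#' @export
rank_methods <- function(result,
                         metrics = c("fdr", "fnr", "fscore", "mspe_in",
                                     "mspe_out", "runtime_s")) {
  records <- if (inherits(result, "benchmark_result")) {
    result$records
  } else {
    result
  }
  ranked <- list()
  for (scen in unique(records$scenario)) {
    rs <- records[records$scenario == scen & !records$failed, ]
    if (nrow(rs) == 0) next
    excl <- dplyr::summarise(dplyr::group_by(rs, .data$method),
                             all_degen = all(.data$degenerate),
                             .groups = "drop")
    keep <- excl$method[!excl$all_degen]
    rs <- rs[rs$method %in% keep, ]
    means <- dplyr::summarise(
      dplyr::group_by(rs, .data$method),
      dplyr::across(dplyr::all_of(metrics), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")
    for (metric in metrics) {
      v <- means[[metric]]
      if (metric == "fscore") v <- -v
      ranked[[length(ranked) + 1]] <- tibble::tibble(
        scenario = scen, method = means$method, metric = metric,
        rank = rank(v, ties.method = "average"))
    }
  }
  per_scen <- dplyr::bind_rows(ranked)
  out <- dplyr::summarise(
    dplyr::group_by(per_scen, .data$method, .data$metric),
    m = mean(.data$rank), m_med = median(.data$rank),
    n_scenarios = dplyr::n(), .groups = "drop")
  class(out) <- c("rank_table", class(out))
  attr(out, "per_scenario") <- per_scen
  out
}
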