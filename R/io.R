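# Plain-text serialization: CSV matrices with a JSON sidecar for datasets,
# JSON (sparse-encoded coefficients) for method results.

#' Write a simulated dataset to a directory
#'
#' Writes `x_train.csv`, `y_train.csv`, `x_test.csv`, `y_test.csv` and a
#' `dataset.json` sidecar holding the configuration, seed, true
#' coefficients, support and realized noise scale.
#'
#' @param data A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data$x_train, file.path(dir, "x_train.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(data$x_test, file.path(dir, "x_test.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  writeLines(format(data$y_train, digits = 17), file.path(dir, "y_train.csv"))
  writeLines(format(data$y_test, digits = 17), file.path(dir, "y_test.csv"))
  sidecar <- list(
    config = unclass(data$config), beta = data$coef$beta,
    support = data$coef$support, sigma = data$sigma,
    standardized = isTRUE(data$standardized))
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the CSV files and JSON sidecar.
#' @return A `sim_dataset`.
#' @export
read_dataset <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  cfg_fields <- side$config
  cfg <- sim_config(
    n = cfg_fields$n, p = cfg_fields$p, n_test = cfg_fields$n_test,
    sparsity = cfg_fields$sparsity, snr = cfg_fields$snr,
    sigma_fixed = cfg_fields$sigma_fixed, design = cfg_fields$design,
    error = cfg_fields$error, coef_regime = cfg_fields$coef_regime,
    rho1 = cfg_fields$rho1, rho2 = cfg_fields$rho2, rho3 = cfg_fields$rho3,
    seed = cfg_fields$seed)
  structure(
    list(
      x_train = as.matrix(utils::read.table(file.path(dir, "x_train.csv"),
                                            sep = ",")),
      y_train = as.numeric(readLines(file.path(dir, "y_train.csv"))),
      x_test = as.matrix(utils::read.table(file.path(dir, "x_test.csv"),
                                           sep = ",")),
      y_test = as.numeric(readLines(file.path(dir, "y_test.csv"))),
      coef = list(beta = side$beta, support = side$support),
      sigma = side$sigma, config = cfg,
      standardized = isTRUE(side$standardized)),
    class = "sim_dataset"
  )
}

#' Write a fitted method result as JSON
#'
#' Coefficients are sparse-encoded as index/value pairs; PIPs and posterior
#' means, when present, are written densely.
#'
#' @param fit An `sb_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_method_result <- function(fit, path) {
  stopifnot(inherits(fit, "sb_fit"))
  nz <- which(fit$beta_hat != 0)
  out <- list(
    method = fit$method, p = length(fit$beta_hat),
    beta_index = nz, beta_value = fit$beta_hat[nz],
    pip = fit$pip, posterior_mean = fit$posterior_mean,
    hyperparams = fit$hyperparams, runtime_s = fit$runtime_s,
    selection_rule = fit$selection_rule)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a method result written by [write_method_result()]
#'
#' @param path JSON file path.
#' @return An `sb_fit`.
#' @export
read_method_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- numeric(obj$p)
  if (length(obj$beta_index)) beta[obj$beta_index] <- obj$beta_value
  new_sb_fit(obj$method, beta, pip = obj$pip,
             posterior_mean = obj$posterior_mean,
             hyperparams = as.list(obj$hyperparams),
             runtime_s = obj$runtime_s %||% NA_real_,
             selection_rule = obj$selection_rule)
}

#' Read a simulation configuration from a flat key-value JSON file
#'
#' @param path JSON file with fields mirroring [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  kv <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- kv[intersect(names(kv), names(formals(sim_config)))]
  do.call(sim_config, args)
}
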