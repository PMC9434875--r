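#' Cross-validated benchmark of the SAE against classical methods
#'
#' The benchmark protocol: the data are divided into `n_folds` stratified
#' folds, each method is trained on every combination of all-but-one folds and
#' scored on the remaining fold, and the whole procedure is repeated for each
#' seed, so `n_folds x length(seeds)` train/test splits per method (12 with
#' the defaults). All methods see identical splits, and preprocessing
#' statistics are fitted inside each training fold only. Reported metrics are
#' the means over splits of accuracy, AUC and support-weighted F1.
#'
#' The two SAE columns correspond to the reconstruction loss: `sae_huber`
#' (smooth l1, robust to outlier samples) and `sae_l2` (squared error).
#'
#' @param data Data frame with feature columns and a label column.
#' @param label Name of the label column.
#' @param config [sae_config()] driving the SAE/NN fits.
#' @param n_folds Number of folds per seed (default 4).
#' @param seeds Integer vector of fold/training seeds (default `c(0, 1, 2)`).
#' @param methods Methods to run; any of `"sae_huber"`, `"sae_l2"`,
#'   `"plsda"`, `"rf"`, `"svm"`, `"nn"`.
#' @param stratified Stratify the folds by class (default `TRUE`).
#' @return An object of class `sae_cv`: list with `results` (one row per
#'   split per method), `folds` (fold assignments per seed), plus the call
#'   settings. `tidy()` returns the per-split rows, `glance()` the per-method
#'   aggregate means, `autoplot()` a comparison figure.
#' @export
#' @examples
#' sim <- generate_metabolomics(synthetic_preset("tiny"))
#' cv <- cross_validate(sim, config = sae_config(eta = 10, epochs = 5),
#'                      methods = c("sae_huber", "plsda"), seeds = 0)
#' glance(cv)
cross_validate <- function(data, label = "label", config = sae_config(),
                           n_folds = 4, seeds = c(0, 1, 2),
                           methods = c("sae_huber", "sae_l2", "plsda",
                                       "rf", "svm", "nn"),
                           stratified = TRUE) {
  data <- tibble::as_tibble(data)
  methods <- match.arg(methods, several.ok = TRUE)
  fold_list <- lapply(seeds, function(s) {
    make_folds(data, label, n_folds = n_folds, seed = s, stratified = stratified)
  })
  names(fold_list) <- as.character(seeds)
  results <- purrr::map_dfr(seq_along(seeds), function(i) {
    purrr::map_dfr(methods, function(mth) {
      run_baseline(data, label, mth, fold_list[[i]], seed = seeds[i],
                   config = config)
    })
  })
  structure(
    list(results = results, folds = fold_list, config = config,
         label = label, n_folds = n_folds, seeds = seeds, methods = methods),
    class = "sae_cv"
  )
}

#' @export
print.sae_cv <- function(x, ...) {
  cat(sprintf("<sae_cv> %d folds x %d seeds = %d splits per method\n",
              x$n_folds, length(x$seeds), x$n_folds * length(x$seeds)))
  print(generics::glance(x))
  invisible(x)
}
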