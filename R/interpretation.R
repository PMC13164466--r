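#' @title Multi-run mechanistic interpretation
#' @description Because the optimization is stochastic, an attribute whose
#'   correlation weight keeps the same sign across independent runs carries
#'   a stable structural signal: permanently positive weights mark
#'   promoters of endpoint increase, permanently negative ones promoters of
#'   decrease.
#' @name interpretation
NULL

#' Run the optimizer several times with different seeds
#'
#' @param ds Dataset data.frame.
#' @param split Split data.frame (shared by all runs).
#' @param config [optimizer_config()]; its seed is replaced per run.
#' @param seeds Integer vector of at least two distinct seeds.
#' @param X Optional precomputed [attribute_matrix()].
#' @return List of `cw_model`, in seed order.
#' @export
multi_run <- function(ds, split, config = optimizer_config(), seeds,
                      X = NULL) {
  if (length(seeds) < 2L) stop("need at least 2 runs for interpretation")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  if (is.null(X)) X <- attribute_matrix(ds)
  lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    mc_optimize(ds, split, cfg, X = X)
  })
}

#' Classify attributes as promoters of increase or decrease
#'
#' An attribute is a promoter of increase when its correlation weight is
#' strictly positive in every run (beyond `min_abs`), of decrease when
#' strictly negative in every run; mixed signs (or any |weight| <=
#' `min_abs`) leave it undefined. Records carry the A/P/C frequencies and
#' the statistical defect and are sorted by active-training frequency,
#' descending.
#'
#' @param models List of `cw_model` from [multi_run()] (same active set).
#' @param stats [attribute_stats()] data.frame for the same split.
#' @param min_abs Minimum |weight| for a run to count toward a sign
#'   (default 0).
#' @return Data.frame: `code`, one `cw_run<i>` column per run,
#'   `classification`, `freq_a`, `freq_p`, `freq_c`, `defect`.
#' @export
classify_promoters <- function(models, stats, min_abs = 0) {
  if (length(models) < 2L) stop("need at least 2 models")
  active <- names(models[[1L]]$weights)
  for (m in models) {
    if (!identical(sort(names(m$weights)), sort(active))) {
      stop("models disagree on the active attribute set")
    }
  }
  W <- vapply(models, function(m) m$weights[active],
              numeric(length(active)))
  W <- matrix(W, nrow = length(active),
              dimnames = list(active, paste0("cw_run", seq_along(models))))
  classification <- apply(W, 1L, function(w) {
    if (all(w > min_abs)) "increase"
    else if (all(w < -min_abs)) "decrease"
    else "undefined"
  })
  stats$defect <- attribute_defect(stats$freq_a, stats$freq_p, stats$freq_c,
                                   stats$size_a, stats$size_p, stats$size_c)
  idx <- match(active, stats$code)
  out <- data.frame(code = active, W, classification = classification,
                    freq_a = stats$freq_a[idx], freq_p = stats$freq_p[idx],
                    freq_c = stats$freq_c[idx], defect = stats$defect[idx],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$freq_a, out$code), , drop = FALSE]
}

#' Planted-signal recovery check for the promoter classification
#'
#' Generates a synthetic dataset whose endpoint is driven by attributes of
#' known sign, runs the optimizer with several seeds, classifies promoters
#' and reports whether each planted attribute recovered its sign.
#'
#' @param config [generator_config()] with non-empty `true_weights`.
#' @param split_seed Seed for the four-way split.
#' @param run_seeds Optimizer seeds (default three).
#' @param opt_config [optimizer_config()].
#' @return List: `promoters` (full classification) and `planted`
#'   (data.frame `code`, `true_sign`, `classification`, `correct`).
#' @export
planted_signal_check <- function(config, split_seed = 1L,
                                 run_seeds = c(11L, 12L, 13L),
                                 opt_config = optimizer_config()) {
  ds <- gen_dataset(config)
  split <- random_split(ds$id, seed = split_seed)
  X <- attribute_matrix(ds)
  models <- multi_run(ds, split, opt_config, seeds = run_seeds, X = X)
  prom <- classify_promoters(models, attribute_stats(X, split))
  truth <- config$true_weights
  planted <- data.frame(code = names(truth),
                        true_sign = ifelse(truth > 0, "increase",
                                           "decrease"),
                        stringsAsFactors = FALSE)
  planted$classification <- prom$classification[match(planted$code,
                                                      prom$code)]
  planted$classification[is.na(planted$classification)] <- "blocked"
  planted$correct <- planted$classification == planted$true_sign
  list(promoters = prom, planted = planted)
}
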