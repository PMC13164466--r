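#' @title Monte Carlo optimization of correlation weights
#' @description The model is `log(S) = C0 + C1 * DCW(T, N)`, where the
#'   optimal descriptor DCW is the sum of correlation weights of a
#'   compound's active (non-rare) attributes. Weights are optimized by
#'   greedy coordinate ascent on a target function that combines the active
#'   and passive training R2 with the calibration-set IIC or CII.
#' @name optimizer
NULL

#' Optimizer configuration
#'
#' @param threshold_T Rarity threshold: attributes contained in fewer than
#'   `threshold_T` active-training compounds are blocked (default 3).
#' @param epochs_N Number of optimization epochs, each one full pass over
#'   the active attributes in fresh random order (default 15).
#' @param tf_kind Calibration index in the target function: `"CII"` or
#'   `"IIC"`.
#' @param tf_coefficient Weight of the calibration index (default 0.3).
#' @param step Weight perturbation magnitude per move (default 0.1).
#' @param init_low,init_high Range of the seeded uniform weight
#'   initialization (default 0.5-1.5), chosen so that independent runs start
#'   from different tables — the multi-run promoter interpretation depends
#'   on that.
#' @param count_mode How attribute frequency is counted for the T rule:
#'   `"compounds"` (number of active-training compounds containing the
#'   attribute, the default) or `"occurrences"` (total count).
#' @param seed Integer seed for initialization and visit order.
#' @return List of class `optimizer_config`.
#' @export
optimizer_config <- function(threshold_T = 3L, epochs_N = 15L,
                             tf_kind = c("CII", "IIC"),
                             tf_coefficient = 0.3, step = 0.1,
                             init_low = 0.5, init_high = 1.5,
                             count_mode = c("compounds", "occurrences"),
                             seed = 1L) {
  tf_kind <- match.arg(tf_kind)
  count_mode <- match.arg(count_mode)
  if (threshold_T < 1L) stop("threshold_T must be >= 1")
  if (epochs_N < 1L) stop("epochs_N must be >= 1")
  if (step <= 0) stop("step must be positive")
  structure(list(threshold_T = as.integer(threshold_T),
                 epochs_N = as.integer(epochs_N), tf_kind = tf_kind,
                 tf_coefficient = tf_coefficient, step = step,
                 init_low = init_low, init_high = init_high,
                 count_mode = count_mode, seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Classify attributes as active or rare
#'
#' An attribute is active when its frequency in the active training set
#' reaches the threshold T; rarer attributes — and attributes absent from
#' the active training set entirely — are blocked (correlation weight
#' pinned to 0).
#'
#' @param X Attribute count matrix from [attribute_matrix()] (rownames are
#'   compound ids).
#' @param split Split data.frame.
#' @param threshold_T Rarity threshold.
#' @param count_mode `"compounds"` or `"occurrences"` (see
#'   [optimizer_config()]).
#' @return List with character vectors `active` and `blocked`.
#' @export
classify_attributes <- function(X, split, threshold_T = 3L,
                                count_mode = "compounds") {
  a_ids <- .split_ids(split, "A")
  if (length(a_ids) == 0L) stop("empty active training set")
  XA <- X[rownames(X) %in% a_ids, , drop = FALSE]
  freq <- if (count_mode == "compounds") colSums(XA > 0) else colSums(XA)
  list(active = colnames(X)[freq >= threshold_T],
       blocked = colnames(X)[freq < threshold_T])
}

#' Optimal descriptor DCW
#'
#' Sum over a compound's attribute multiset of count times correlation
#' weight; blocked and unseen attributes contribute 0.
#'
#' @param attrs Attribute multiset from [featurize()].
#' @param weights Named numeric vector of correlation weights (active
#'   attributes only).
#' @return The descriptor value.
#' @export
dcw <- function(attrs, weights) {
  if (length(attrs) == 0L) return(0)
  hit <- names(attrs) %in% names(weights)
  if (!any(hit)) return(0)
  sum(attrs[hit] * weights[names(attrs)[hit]])
}

#' Least-squares line fit of endpoint on descriptor
#'
#' Ordinary least squares of `y` on `x` over the active training set;
#' closed-form univariate normal equations.
#'
#' @param y Endpoints.
#' @param x Descriptor values.
#' @return Named vector `c0` (intercept), `c1` (slope).
#' @export
fit_line <- function(y, x) {
  .check_pairs(y, x)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate descriptor: zero DCW variance")
  c1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(c0 = mean(y) - c1 * mean(x), c1 = c1)
}

# Target function for a candidate weight state given precomputed descriptor
# vectors; -Inf marks a degenerate state the search must reject.
.tf_eval <- function(dcw_a, dcw_p, dcw_c, y_a, y_p, y_c, cfg) {
  sxx <- sum((dcw_a - mean(dcw_a))^2)
  if (sxx == 0) return(list(tf = -Inf, c0 = NA_real_, c1 = NA_real_))
  c1 <- sum((dcw_a - mean(dcw_a)) * (y_a - mean(y_a))) / sxx
  c0 <- mean(y_a) - c1 * mean(dcw_a)
  r2_a <- .safe_r2(y_a, dcw_a)
  r2_p <- .safe_r2(y_p, dcw_p)
  pred_c <- c0 + c1 * dcw_c
  idx <- if (cfg$tf_kind == "CII") .safe_cii(y_c, pred_c)
         else .safe_iic(y_c, pred_c)
  list(tf = target_function(r2_a, r2_p, idx, cfg$tf_coefficient),
       c0 = c0, c1 = c1)
}

#' Train a correlation-weight model
#'
#' Runs the Monte Carlo optimization: active attributes get seeded uniform
#' initial weights; over `epochs_N` epochs each active attribute is visited
#' in fresh random order and its weight moved by +step / -step when that
#' improves the target function (with `c0`, `c1` refit on the active
#' training set at every evaluation). The returned model is the best-TF
#' state seen over the whole trajectory. The validation set never enters
#' any evaluation.
#'
#' @param ds Dataset data.frame.
#' @param split Split data.frame with non-empty A, P and C sets.
#' @param config [optimizer_config()].
#' @param X Optional precomputed [attribute_matrix()] for `ds` (saves
#'   refeaturizing in multi-run experiments).
#' @return Object of class `cw_model`: correlation weights, blocked
#'   attributes, `c0`, `c1`, config, split fingerprint and the per-epoch
#'   trace of the best TF.
#' @export
mc_optimize <- function(ds, split, config = optimizer_config(), X = NULL) {
  stopifnot(inherits(config, "optimizer_config"))
  .check_split(split)
  for (role in c("A", "P", "C")) {
    if (!any(split$role == role)) stop("empty ", role, " set")
  }
  if (is.null(X)) X <- attribute_matrix(ds)
  cls <- classify_attributes(X, split, config$threshold_T,
                             config$count_mode)
  if (length(cls$active) == 0L) {
    stop("no active attributes at T = ", config$threshold_T)
  }
  rows <- function(role) {
    which(rownames(X) %in% .split_ids(split, role))
  }
  ia <- rows("A"); ip <- rows("P"); ic <- rows("C")
  XA <- X[ia, cls$active, drop = FALSE]
  XP <- X[ip, cls$active, drop = FALSE]
  XC <- X[ic, cls$active, drop = FALSE]
  y_a <- ds$endpoint[match(rownames(X)[ia], ds$id)]
  y_p <- ds$endpoint[match(rownames(X)[ip], ds$id)]
  y_c <- ds$endpoint[match(rownames(X)[ic], ds$id)]
  k <- length(cls$active)
  step <- config$step

  run <- function() {
    w <- stats::runif(k, config$init_low, config$init_high)
    dcw_a <- drop(XA %*% w); dcw_p <- drop(XP %*% w); dcw_c <- drop(XC %*% w)
    cur <- .tf_eval(dcw_a, dcw_p, dcw_c, y_a, y_p, y_c, config)
    if (!is.finite(cur$tf)) {
      stop("degenerate descriptor: zero DCW variance at initialization")
    }
    best <- list(w = w, c0 = cur$c0, c1 = cur$c1, tf = cur$tf)
    trace <- numeric(config$epochs_N)
    for (epoch in seq_len(config$epochs_N)) {
      for (j in sample.int(k)) {
        best_delta <- 0
        best_local <- cur
        for (delta in c(step, -step)) {
          cand <- .tf_eval(dcw_a + delta * XA[, j],
                           dcw_p + delta * XP[, j],
                           dcw_c + delta * XC[, j],
                           y_a, y_p, y_c, config)
          if (cand$tf > best_local$tf) {
            best_local <- cand
            best_delta <- delta
          }
        }
        if (best_delta != 0) {
          w[j] <- w[j] + best_delta
          dcw_a <- dcw_a + best_delta * XA[, j]
          dcw_p <- dcw_p + best_delta * XP[, j]
          dcw_c <- dcw_c + best_delta * XC[, j]
          cur <- best_local
          if (cur$tf > best$tf) {
            best <- list(w = w, c0 = cur$c0, c1 = cur$c1, tf = cur$tf)
          }
        }
      }
      trace[epoch] <- best$tf
    }
    list(best = best, trace = trace)
  }
  res <- withr::with_seed(config$seed, run())
  # Canonical sign: negating c1 and every weight leaves all predictions
  # unchanged, so fix c1 >= 0 — weight signs then read directly as
  # endpoint-increasing or -decreasing, which the promoter interpretation
  # relies on.
  if (res$best$c1 < 0) {
    res$best$w <- -res$best$w
    res$best$c1 <- -res$best$c1
  }

  structure(list(weights = structure(res$best$w, names = cls$active),
                 blocked = cls$blocked,
                 c0 = unname(res$best$c0), c1 = unname(res$best$c1),
                 tf_best = res$best$tf, tf_trace = res$trace,
                 n_active = k, config = config,
                 split_fingerprint = .split_fingerprint(split)),
            class = "cw_model")
}

#' Predict endpoints with a trained model
#'
#' `c0 + c1 * DCW` per compound; attributes unseen in training (including
#' blocked ones) contribute 0, so prediction never fails on new chemistry.
#'
#' @param object A `cw_model`.
#' @param newdata Dataset data.frame or character vector of SMILES.
#' @param ... Unused.
#' @return Numeric vector of predicted endpoints.
#' @export
predict.cw_model <- function(object, newdata, ...) {
  smiles <- if (is.character(newdata)) newdata else newdata$smiles
  vapply(smiles, function(s) {
    object$c0 + object$c1 * dcw(featurize(s), object$weights)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' @export
print.cw_model <- function(x, ...) {
  cat("Correlation-weight model  log(S) = C0 + C1 * DCW(T, N)\n")
  cat(sprintf("  C0 = %.4f, C1 = %.4f\n", x$c0, x$c1))
  cat(sprintf("  T = %d, N = %d, TF_%s (coefficient %.2f)\n",
              x$config$threshold_T, x$config$epochs_N, x$config$tf_kind,
              x$config$tf_coefficient))
  cat(sprintf("  %d active attributes, %d blocked; best TF = %.4f\n",
              x$n_active, length(x$blocked), x$tf_best))
  invisible(x)
}

#' Serialize / deserialize a model as JSON
#'
#' Round-trips bit-exactly: numeric fields are written at full precision.
#'
#' @param model A `cw_model`.
#' @param path File path.
#' @return `read_model` returns the `cw_model`; `write_model` the path,
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cw_model"))
  obj <- list(c0 = model$c0, c1 = model$c1,
              T = model$config$threshold_T, N = model$config$epochs_N,
              tf_kind = model$config$tf_kind,
              tf_coefficient = model$config$tf_coefficient,
              step = model$config$step,
              init_low = model$config$init_low,
              init_high = model$config$init_high,
              count_mode = model$config$count_mode,
              seed = model$config$seed,
              weights = as.list(model$weights),
              blocked = model$blocked,
              tf_best = model$tf_best, tf_trace = model$tf_trace,
              n_active = model$n_active,
              split_fingerprint = model$split_fingerprint)
  # 17 significant digits: the shortest width that round-trips every double
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- optimizer_config(threshold_T = obj$T, epochs_N = obj$N,
                          tf_kind = obj$tf_kind,
                          tf_coefficient = obj$tf_coefficient,
                          step = obj$step, init_low = obj$init_low,
                          init_high = obj$init_high,
                          count_mode = obj$count_mode, seed = obj$seed)
  structure(list(weights = unlist(obj$weights),
                 blocked = as.character(obj$blocked),
                 c0 = obj$c0, c1 = obj$c1,
                 tf_best = obj$tf_best, tf_trace = obj$tf_trace,
                 n_active = obj$n_active, config = cfg,
                 split_fingerprint = obj$split_fingerprint),
            class = "cw_model")
}

#' Per-set metric report for a trained model
#'
#' Evaluates the model on each role of the split and assembles the full
#' statistics row: n, R2, IIC, CII, Q2, Q2F1-3, averaged rm2, MAE, F and
#' the number of active attributes. The Q2F family is referenced to the
#' active-training endpoints and reported for the calibration and
#' validation sets.
#'
#' @param model A `cw_model`.
#' @param ds Dataset data.frame.
#' @param split Split data.frame.
#' @return Data.frame with one row per role A, P, C, V.
#' @export
evaluate_model <- function(model, ds, split) {
  .check_split(split)
  y_train <- ds$endpoint[ds$id %in% .split_ids(split, "A")]
  out <- lapply(.roles, function(role) {
    sub <- ds[ds$id %in% .split_ids(split, role), , drop = FALSE]
    obs <- sub$endpoint
    calc <- predict(model, sub)
    x <- (calc - model$c0) / if (model$c1 != 0) model$c1 else 1
    external <- role %in% c("C", "V")
    q2f <- if (external) q2f_family(obs, calc, y_train)
           else c(q2f1 = NA_real_, q2f2 = NA_real_, q2f3 = NA_real_)
    data.frame(role = role, n = length(obs),
               r2 = .safe_r2(obs, calc),
               iic = .safe_iic(obs, calc),
               cii = if (length(obs) >= 3L) .safe_cii(obs, calc)
                     else NA_real_,
               q2 = tryCatch(q2_loo(obs, x), error = function(e) NA_real_),
               q2f1 = q2f[["q2f1"]], q2f2 = q2f[["q2f2"]],
               q2f3 = q2f[["q2f3"]],
               rm2_avg = if (external) rm2_average(obs, calc) else NA_real_,
               mae = mae(obs, calc),
               f = tryCatch(f_ratio(obs, calc), error = function(e) NA_real_),
               na_active = model$n_active,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
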