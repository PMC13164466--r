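test_that("attribute rarity classification follows the T rule", {
  ds <- tiny_dataset()
  X <- attribute_matrix(ds)
  split <- data.frame(id = ds$id,
                      role = c("A", "A", "A", "P", "C", "V"))
  # "C..........." occurs in all 3 A compounds; threshold 3 keeps it active
  cls3 <- classify_attributes(X, split, threshold_T = 3L)
  expect_true(sk_code("C") %in% cls3$active)
  # "=..........." occurs in only 1 A compound -> blocked at T = 3
  expect_true(sk_code("=") %in% cls3$blocked)
  # T = 1: everything present in A is active
  cls1 <- classify_attributes(X, split, threshold_T = 1L)
  present_in_A <- colnames(X)[colSums(X[1:3, , drop = FALSE] > 0) > 0]
  expect_true(all(present_in_A %in% cls1$active))
  # attributes absent from A (e.g. sulfur ones) stay blocked at any T
  expect_true(sk_code("S") %in% cls1$blocked)

  expect_error(classify_attributes(X, data.frame(id = ds$id,
                                                 role = rep("P", 6)), 3L),
               "empty active training set")
})

test_that("the descriptor is the weighted attribute sum and is linear", {
  ms <- featurize("C=O")
  w1 <- structure(rep(1, length(ms)), names = names(ms))
  expect_equal(dcw(ms, w1), 7)
  expect_equal(dcw(ms, structure(numeric(0), names = character(0))), 0)
  expect_equal(dcw(ms, w1 * 2), 2 * dcw(ms, w1))
  # unknown attributes contribute nothing
  expect_equal(dcw(ms, c("ZZZ........." = 5)), 0)
})

test_that("line fit is exact least squares with degenerate guards", {
  cf <- fit_line(c(1, 3), c(0, 1))
  expect_equal(unname(cf), c(1, 2))
  cf2 <- fit_line(rep(2.5, 4), c(1, 2, 3, 4))
  expect_equal(unname(cf2), c(2.5, 0))
  withr::with_seed(8L, {
    x <- rnorm(40)
    y <- 0.4 + 0.2 * x
    expect_equal(unname(fit_line(y, x)), c(0.4, 0.2), tolerance = 1e-12)
  })
  expect_error(fit_line(c(1, 2, 3), rep(1, 3)), "degenerate descriptor")
})

test_that("optimization recovers a planted single-token signal", {
  # endpoint = 0.5 + 0.1 * (number of C tokens), zero noise
  cfg_gen <- generator_config(n_compounds = 200L, noise_sd = 0,
                              true_weights = c("C" = 1),
                              true_c0 = 0.5, true_c1 = 0.1, seed = 31L)
  ds <- gen_dataset(cfg_gen)
  split <- random_split(ds$id, seed = 31L)
  m <- mc_optimize(ds, split, optimizer_config(tf_kind = "CII", seed = 31L))
  ev <- evaluate_model(m, ds, split)
  expect_gte(ev$r2[ev$role == "A"], 0.9)
})

test_that("optimizer is deterministic, greedy-safe, and validation-blind", {
  ds <- small_corpus(n = 48L, seed = 13L)
  split <- random_split(ds$id, seed = 13L)
  cfg <- optimizer_config(threshold_T = 2L, epochs_N = 4L, tf_kind = "CII",
                          seed = 77L)
  m1 <- mc_optimize(ds, split, cfg)
  m2 <- mc_optimize(ds, split, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$c0, m2$c0)

  # the running-best TF trace never decreases
  expect_true(all(diff(m1$tf_trace) >= 0))
  expect_identical(m1$tf_best, max(m1$tf_trace))

  # permuting validation endpoints changes nothing about training
  ds_perm <- ds
  v_ids <- split$id[split$role == "V"]
  v_rows <- ds_perm$id %in% v_ids
  ds_perm$endpoint[v_rows] <- rev(ds_perm$endpoint[v_rows])
  m3 <- mc_optimize(ds_perm, split, cfg)
  expect_identical(m1$weights, m3$weights)

  expect_error(optimizer_config(epochs_N = 0L), "epochs_N")
  expect_error(optimizer_config(threshold_T = 0L), "threshold_T")
  expect_error(optimizer_config(step = 0), "step")
})

test_that("blocked attributes never receive weight", {
  ds <- small_corpus(n = 48L, seed = 14L)
  split <- random_split(ds$id, seed = 14L)
  m <- mc_optimize(ds, split,
                   optimizer_config(threshold_T = 5L, epochs_N = 2L))
  expect_length(intersect(names(m$weights), m$blocked), 0L)
  # blocked attributes contribute 0 to any prediction: a compound made
  # only of blocked attributes predicts the intercept-at-zero-descriptor
  expect_equal(dcw(structure(3L, names = m$blocked[1]), m$weights), 0)
})

test_that("prediction composes the descriptor with the fitted line", {
  ms <- featurize("C=O")
  model <- structure(list(
    weights = structure(rep(0.5, length(ms)), names = names(ms)),
    blocked = character(0), c0 = 1, c1 = 2,
    tf_best = NA_real_, tf_trace = NA_real_, n_active = length(ms),
    config = optimizer_config(), split_fingerprint = ""),
    class = "cw_model")
  # DCW = 7 * 0.5 = 3.5 ; prediction = 1 + 2 * 3.5 = 8
  expect_equal(predict(model, "C=O"), 8)
  # zero weights -> every prediction is c0
  model$weights[] <- 0
  expect_equal(predict(model, c("C=O", "CCO", "SCCN")), rep(1, 3))
})

test_that("OLS predictions preserve the active-set endpoint mean", {
  ds <- small_corpus(n = 48L, seed = 15L)
  split <- random_split(ds$id, seed = 15L)
  m <- mc_optimize(ds, split,
                   optimizer_config(threshold_T = 2L, epochs_N = 2L))
  a_rows <- ds$id %in% split$id[split$role == "A"]
  expect_equal(mean(predict(m, ds[a_rows, ])),
               mean(ds$endpoint[a_rows]), tolerance = 1e-10)
})

test_that("model JSON serialization round-trips bit-exactly", {
  ds <- small_corpus(n = 48L, seed = 16L)
  split <- random_split(ds$id, seed = 16L)
  m <- mc_optimize(ds, split,
                   optimizer_config(threshold_T = 2L, epochs_N = 2L,
                                    seed = 9L))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$c0, m$c0)
  expect_identical(m2$c1, m$c1)
  expect_identical(m2$blocked, m$blocked)
  expect_identical(m2$config$tf_kind, m$config$tf_kind)
  expect_identical(predict(m2, ds), predict(m, ds))
})
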