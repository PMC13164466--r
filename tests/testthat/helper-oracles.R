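# Independent brute-force oracles, coded directly from the defining
# formulas and kept deliberately naive; the package implementations are
# checked against these, never the other way round.

# IIC: r scaled by min/max of the side-wise mean absolute residuals.
iic_brute <- function(obs, calc) {
  r <- cor(obs, calc)
  d <- obs - calc
  neg <- d[d < 0]
  pos <- d[d >= 0]
  mae_neg <- if (length(neg)) sum(abs(neg)) / length(neg) else 0
  mae_pos <- if (length(pos)) sum(abs(pos)) / length(pos) else 0
  if (max(mae_neg, mae_pos) == 0) return(r)
  r * min(mae_neg, mae_pos) / max(mae_neg, mae_pos)
}

# CII: explicit leave-one-out loop recomputing the squared correlation.
cii_brute <- function(obs, calc) {
  n <- length(obs)
  r2_full <- cor(obs, calc)^2
  protest <- 0
  for (k in seq_len(n)) {
    o <- obs[-k]; c_ <- calc[-k]
    if (var(o) == 0 || var(c_) == 0) next
    r2_k <- cor(o, c_)^2
    if (r2_k - r2_full > 0) protest <- protest + (r2_k - r2_full)
  }
  1 - protest
}

# Statistical defect of one attribute, term by term.
defect_brute <- function(fa, fp, fc, sa, sp, sc) {
  pa <- fa / sa; pp <- fp / sp; pc <- fc / sc
  t1 <- if (fa + fp > 0) abs(pa - pp) / (fa + fp) else 0
  t2 <- if (fa + fc > 0) abs(pa - pc) / (fa + fc) else 0
  t3 <- if (fp + fc > 0) abs(pp - pc) / (fp + fc) else 0
  t1 + t2 + t3
}

# Leave-one-out Q2 by explicit refitting (no hat-matrix shortcut).
q2_loo_refit <- function(y, x) {
  n <- length(y)
  press <- 0
  for (k in seq_len(n)) {
    fit <- lm(y[-k] ~ x[-k])
    pred <- unname(coef(fit)[1] + coef(fit)[2] * x[k])
    press <- press + (y[k] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Small fixed dataset with hand-checkable structures.
tiny_dataset <- function() {
  new_dataset(id = c("fa", "et", "cp", "am", "ke", "th"),
              smiles = c("C=O", "CCO", "C1CC1", "NCC", "CC(=O)C", "SCC"),
              endpoint = c(0.1, 0.2, 0.3, 0.8, 0.4, 0.15))
}

# A synthetic corpus big enough to train on, small enough for fast tests.
small_corpus <- function(n = 60L, seed = 42L, noise_sd = 0.05) {
  gen_dataset(generator_config(n_compounds = n, noise_sd = noise_sd,
                               seed = seed))
}
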