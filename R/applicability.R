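#' @title Statistical-defect applicability domain
#' @description An attribute whose prevalence differs between the active
#'   training, passive training and calibration sets is statistically
#'   "defective"; compounds accumulating too much defect fall outside the
#'   domain where the model's statistics are trustworthy.
#' @name applicability
NULL

#' Per-attribute prevalence statistics across A, P and C
#'
#' For every attribute: the number of compounds containing it in each of
#' the active training, passive training and calibration sets, the set
#' sizes, and the resulting probabilities (frequency / set size).
#'
#' @param X Attribute count matrix from [attribute_matrix()].
#' @param split Split data.frame.
#' @return Data.frame: `code`, `freq_a`, `freq_p`, `freq_c`, `size_a`,
#'   `size_p`, `size_c`, `prob_a`, `prob_p`, `prob_c`.
#' @export
attribute_stats <- function(X, split) {
  .check_split(split)
  sub <- function(role) X[rownames(X) %in% .split_ids(split, role), ,
                          drop = FALSE]
  XA <- sub("A"); XP <- sub("P"); XC <- sub("C")
  data.frame(code = colnames(X),
             freq_a = colSums(XA > 0), freq_p = colSums(XP > 0),
             freq_c = colSums(XC > 0),
             size_a = nrow(XA), size_p = nrow(XP), size_c = nrow(XC),
             prob_a = colSums(XA > 0) / nrow(XA),
             prob_p = colSums(XP > 0) / nrow(XP),
             prob_c = colSums(XC > 0) / nrow(XC),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Statistical defect of an attribute
#'
#' `d_k = |P - P'| / (N + N') + |P - P''| / (N + N'') +
#' |P' - P''| / (N' + N'')`, where P, P', P'' are the attribute's
#' probabilities in the active training, passive training and calibration
#' sets and N, N', N'' its compound frequencies there. A pairwise term with
#' zero frequency sum contributes 0. Vectorized over attributes.
#'
#' @param freq_a,freq_p,freq_c Compound frequencies in A, P, C.
#' @param size_a,size_p,size_c Set sizes.
#' @return Defect value(s) `d_k >= 0`.
#' @examples
#' attribute_defect(70, 71, 70, 72, 73, 72) # rounds to 0.0000
#' @export
attribute_defect <- function(freq_a, freq_p, freq_c,
                             size_a, size_p, size_c) {
  if (any(freq_a > size_a | freq_p > size_p | freq_c > size_c) ||
      any(c(freq_a, freq_p, freq_c) < 0)) {
    stop("frequencies must lie in [0, set size]")
  }
  p_a <- freq_a / size_a; p_p <- freq_p / size_p; p_c <- freq_c / size_c
  term <- function(pi, pj, ni, nj) {
    den <- ni + nj
    ifelse(den == 0, 0, abs(pi - pj) / den)
  }
  term(p_a, p_p, freq_a, freq_p) +
    term(p_a, p_c, freq_a, freq_c) +
    term(p_p, p_c, freq_p, freq_c)
}

#' Statistical defect of a compound
#'
#' Sum of the attribute defects over the compound's distinct non-blocked
#' attributes. A compound whose every attribute is blocked gets defect 0
#' and is flagged.
#'
#' @param attrs Attribute multiset from [featurize()].
#' @param defects Named numeric vector: attribute code -> `d_k`.
#' @param blocked Character vector of blocked attribute codes.
#' @return Numeric defect with attribute `all_blocked` (logical).
#' @export
compound_defect <- function(attrs, defects, blocked = character(0L)) {
  codes <- setdiff(names(attrs), blocked)
  all_blocked <- length(attrs) > 0L && length(codes) == 0L
  known <- intersect(codes, names(defects))
  structure(sum(defects[known]), all_blocked = all_blocked)
}

#' Applicability-domain mask
#'
#' A query compound is inside the domain when its defect is below twice the
#' mean defect of the reference population. By the Markov inequality at
#' least half of any reference population is always in-domain.
#'
#' @param reference_dj Defects of the reference population (non-empty).
#' @param query_dj Defects of the query compounds (defaults to the
#'   reference itself).
#' @return List: `d_bar` (reference mean), `cutoff` (2 * d_bar) and
#'   `report` (data.frame `d_j`, `in_domain`).
#' @export
domain_mask <- function(reference_dj, query_dj = reference_dj) {
  if (length(reference_dj) == 0L) stop("empty reference population")
  d_bar <- mean(reference_dj)
  list(d_bar = d_bar, cutoff = 2 * d_bar,
       report = data.frame(d_j = query_dj,
                           in_domain = query_dj < 2 * d_bar))
}

#' Full applicability-domain report for a dataset and split
#'
#' Computes attribute defects from the A/P/C prevalences, sums them into
#' per-compound defects (blocked attributes excluded), takes the reference
#' population to be the union of the A, P and C sets, and classifies every
#' compound — validation compounds are queries against the training-side
#' cutoff.
#'
#' @param ds Dataset data.frame.
#' @param split Split data.frame.
#' @param blocked Blocked attribute codes (take them from a trained model
#'   so the domain matches what the model actually uses).
#' @param X Optional precomputed [attribute_matrix()].
#' @return List: `d_bar`, `cutoff`, `attribute_defects` (data.frame) and
#'   `compounds` (data.frame `id`, `role`, `d_j`, `in_domain`,
#'   `all_blocked`).
#' @export
domain_report <- function(ds, split, blocked = character(0L), X = NULL) {
  if (is.null(X)) X <- attribute_matrix(ds)
  st <- attribute_stats(X, split)
  st$defect <- attribute_defect(st$freq_a, st$freq_p, st$freq_c,
                                st$size_a, st$size_p, st$size_c)
  defects <- structure(st$defect, names = st$code)
  role <- split$role[match(rownames(X), split$id)]
  per <- lapply(seq_len(nrow(X)), function(i) {
    present <- colnames(X)[X[i, ] > 0]
    d <- compound_defect(structure(rep(1L, length(present)),
                                   names = present),
                         defects, blocked)
    data.frame(id = rownames(X)[i], role = role[i], d_j = as.numeric(d),
               all_blocked = attr(d, "all_blocked"),
               stringsAsFactors = FALSE)
  })
  cmp <- do.call(rbind, per)
  ref <- cmp$d_j[cmp$role %in% c("A", "P", "C")]
  msk <- domain_mask(ref, cmp$d_j)
  cmp$in_domain <- msk$report$in_domain
  list(d_bar = msk$d_bar, cutoff = msk$cutoff,
       attribute_defects = st, compounds = cmp)
}
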