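#' Shannon entropy of a column profile
#'
#' Variability of a residue-type distribution in nats:
#' \eqn{H = -\sum_\alpha f_\alpha \ln f_\alpha}, with the
#' \eqn{0 \ln 0 = 0} convention. Ranges from 0 (single type) to
#' \eqn{\ln 20} (uniform).
#'
#' @param profile length-20 frequency vector, or a list with a `freq` field.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(profile) {
  f <- if (is.list(profile)) profile$freq else profile
  if (sum(f) <= 0) stop("empty profile has no entropy", call. = FALSE)
  -sum(.xlogx(f))
}

#' Min-max rescale raw scores within one group
#'
#' Affine map of per-position raw scores onto \[0, 1\]: the group minimum
#' maps to 0, the maximum to 1. A degenerate (constant) score vector maps
#' to all zeros. All conservation variants are rescaled this way so their
#' scales — and the logarithm base — become irrelevant downstream.
#'
#' @param values numeric vector of raw per-position scores for one group
#'   (NAs preserved).
#' @return Vector of the same length with finite values in \[0, 1\].
#' @export
rescale_within_group <- function(values) {
  fin <- is.finite(values)
  if (!any(fin)) stop("no finite values to rescale", call. = FALSE)
  lo <- min(values[fin]); hi <- max(values[fin])
  out <- values
  if (hi - lo <= 0) {
    out[fin] <- 0
  } else {
    out[fin] <- (values[fin] - lo) / (hi - lo)
  }
  out
}

#' Expected entropy of a freely evolving position
#'
#' Entropy of the free-evolution distribution rooted at `ancestral` after
#' time `t`: 0 at t = 0, approaching the entropy of the stationary
#' distribution as t grows. Types with high exchangeability (isoleucine)
#' accumulate entropy faster than slow-mutating ones (tryptophan).
#'
#' @param model a `rate_model`.
#' @param ancestral type index or letter.
#' @param t time (expected substitutions per site).
#' @return Expected entropy in nats.
#' @export
expected_entropy <- function(model, ancestral, t) {
  shannon_entropy(free_distribution(model, ancestral, t)$p)
}

#' Exchangeability-corrected entropy score
#'
#' Observed-minus-expected conservation score: the observed column entropy
#' minus the entropy the column would have if it had evolved free of
#' constraints from its ancestral type for the family's effective time.
#' Negative values mean the column is more conserved than free evolution
#' predicts; a fully conserved rare-to-mutate type (tryptophan) is penalized
#' less than a fully conserved mutable type (isoleucine), which encodes the
#' intuition that absent "easy" variability signals strong constraint.
#'
#' @param profile length-20 frequency vector or list with `freq`.
#' @param model a `rate_model`.
#' @param ancestral ancestral type (index or letter); typically
#'   [ancestral_type()] of the same profile.
#' @param t_eff family-wide effective time from [effective_time()].
#' @return Score in nats (may be negative).
#' @export
corrected_entropy <- function(profile, model, ancestral, t_eff) {
  shannon_entropy(profile) - expected_entropy(model, ancestral, t_eff)
}

#' Kullback-Leibler divergence from the stationary distribution
#'
#' \eqn{\sum_\alpha f_\alpha \ln(f_\alpha/\pi_\alpha)}. Zero iff the profile
#' equals the background; large for profiles concentrated on rare types.
#' Note the counterintuitive direction: a conserved rare type (tryptophan)
#' scores higher than a conserved common, highly mutable one (isoleucine).
#'
#' @param profile length-20 frequency vector or list with `freq`.
#' @param pi strictly positive background distribution (e.g.
#'   [stationary_distribution()]).
#' @return Divergence in nats (>= 0).
#' @export
kl_from_stationary <- function(profile, pi) {
  f <- if (is.list(profile)) profile$freq else profile
  stopifnot(all(pi > 0))
  sum(.xlogxy(f, pi))
}

#' Jensen-Shannon divergence from the stationary distribution
#'
#' Symmetrized, smoothed relative entropy between the column profile and the
#' background: \eqn{JS(f,\pi) = \frac12 KL(f\|m) + \frac12 KL(\pi\|m)} with
#' \eqn{m = (f+\pi)/2}. Bounded by \eqn{\ln 2}; conservation id `j`.
#'
#' @inheritParams kl_from_stationary
#' @return Divergence in nats, in \[0, ln 2\].
#' @export
js_from_stationary <- function(profile, pi) {
  f <- if (is.list(profile)) profile$freq else profile
  js_divergence(f, pi)
}

# plain Jensen-Shannon divergence between two distributions (equal weights)
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  0.5 * sum(.xlogxy(p, m)) + 0.5 * sum(.xlogxy(q, m))
}

#' Per-group conservation matrix for a whole alignment
#'
#' Applies one conservation method to every (position, group) profile, then
#' min-max rescales the raw values within each group and orients the result
#' so that 1 = fully conserved. Method ids follow the scorer grammar:
#' `e` plain entropy, `r` exchangeability-corrected entropy, `j`
#' Jensen-Shannon divergence from the stationary distribution, `0` no
#' conservation information (constant 1/2).
#'
#' @param profiles a `column_profiles` object.
#' @param model a `rate_model` (needed for `r` and `j`).
#' @param method_id one of `"e"`, `"r"`, `"j"`, `"0"`.
#' @param t_eff an `effective_time` object or a single time value (needed
#'   for `r`).
#' @return List with `conservation` (positions x groups matrix in \[0, 1\],
#'   NA for empty profiles), `raw` (unrescaled scores), `method_id`.
#' @export
conservation_matrix <- function(profiles, model = NULL,
                                method_id = c("e", "r", "j", "0"),
                                t_eff = NULL) {
  method_id <- match.arg(method_id)
  L <- dim(profiles$freq)[1]
  G <- dim(profiles$freq)[2]
  raw <- matrix(NA_real_, L, G)
  if (method_id == "0") {
    cons <- matrix(ifelse(profiles$empty, NA_real_, 0.5), L, G)
    return(list(conservation = cons, raw = cons, method_id = method_id))
  }
  if (method_id %in% c("r", "j") && is.null(model)) {
    stop("method '", method_id, "' needs a rate model", call. = FALSE)
  }
  if (method_id == "r") {
    if (inherits(t_eff, "effective_time")) {
      anc <- t_eff$ancestral
      t_val <- t_eff$t_eff
    } else if (is.numeric(t_eff) && length(t_eff) == 1) {
      anc <- ancestral_matrix(profiles, model)
      t_val <- t_eff
    } else {
      te <- effective_time(profiles, model)
      anc <- te$ancestral
      t_val <- te$t_eff
    }
    # expected entropies depend only on the ancestral type: cache all 20
    P <- transition_matrix(model, t_val)
    h_exp <- apply(P, 1, function(p) -sum(.xlogx(p)))
  }
  for (g in seq_len(G)) {
    for (i in seq_len(L)) {
      if (profiles$empty[i, g]) next
      f <- profiles$freq[i, g, ]
      raw[i, g] <- switch(method_id,
        e = -sum(.xlogx(f)),
        r = -sum(.xlogx(f)) - h_exp[anc[i, g]],
        j = js_divergence(f, model$pi))
    }
  }
  rescaled <- apply(raw, 2, rescale_within_group)
  # e, r measure variability (high = variable); j measures conservation
  cons <- if (method_id == "j") rescaled else 1 - rescaled
  list(conservation = cons, raw = raw, method_id = method_id)
}
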