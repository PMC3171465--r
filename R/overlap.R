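#' Overlap of two normalized residue-type distributions
#'
#' The package's preferred overlap measure (id `o`): the inner product of
#' the two frequency vectors normalized by their Euclidean norms,
#' \eqn{o(p,q) = p^\top q / (\|p\|\,\|q\|)}. Equals 1 exactly when the two
#' distributions are identical — irrespective of their variability — and 0
#' exactly when their supports are disjoint, which is what keeps the
#' conservation and overlap information separated.
#'
#' @param p,q length-20 frequency vectors (must each sum to 1).
#' @return Overlap in \[0, 1\].
#' @export
#' @examples
#' p <- q <- numeric(20); p[1:2] <- 0.5; q[2:3] <- 0.5
#' overlap_o(p, q)   # 0.5
overlap_o <- function(p, q) {
  .check_distribution(p, "p"); .check_distribution(q, "q")
  sum(p * q) / sqrt(sum(p * p) * sum(q * q))
}

#' Unnormalized distribution overlap
#'
#' The raw inner product \eqn{p^\top q}: 0 for distributions with no common
#' element, but the value assigned to identical distributions depends on
#' their spread (1 for matching single types, 1/k for matching uniforms over
#' k types), so conservation leaks into the overlap score.
#'
#' @inheritParams overlap_o
#' @return Overlap in \[0, 1\].
#' @export
overlap_eq9 <- function(p, q) {
  .check_distribution(p, "p"); .check_distribution(q, "q")
  sum(p * q)
}

#' Sum of squared frequency differences
#'
#' \eqn{\sum_\alpha (p_\alpha - q_\alpha)^2} (overlap id `f`; the distance
#' used by GroupSim). Zero iff the distributions are identical; maximal (2)
#' for disjoint single types, while the disjoint-support value in general
#' depends on the variability of the two columns.
#'
#' @inheritParams overlap_o
#' @return Value in \[0, 2\]; larger = more diverged.
#' @export
squared_difference <- function(p, q) {
  .check_distribution(p, "p"); .check_distribution(q, "q")
  sum((p - q)^2)
}

#' Kullback-Leibler divergence between two group distributions
#'
#' \eqn{\sum_\alpha p_\alpha \ln(p_\alpha/q_\alpha)} ("relative entropy
#' between groups"). To keep the value finite where p has mass and q none,
#' q is floored at 1e-6 and renormalized. Asymmetric in its arguments.
#'
#' @inheritParams overlap_o
#' @param floor lower bound applied to q before renormalization.
#' @return Divergence in nats (>= 0 up to the floor's perturbation).
#' @export
kl_between_groups <- function(p, q, floor = 1e-6) {
  .check_distribution(p, "p"); .check_distribution(q, "q")
  qf <- pmax(q, floor)
  qf <- qf / sum(qf)
  sum(.xlogxy(p, qf))
}

#' Sequence-harmony overlap (Jensen-Shannon between groups)
#'
#' The symmetrized, smoothed counterpart of [kl_between_groups()]:
#' \eqn{JS(p,q)} with the equal-weight mixture \eqn{m=(p+q)/2}. Universally
#' 0 for identical distributions and bounded by \eqn{\ln 2}, attained
#' whenever the supports are disjoint.
#'
#' @inheritParams overlap_o
#' @return Divergence in nats, in \[0, ln 2\]; larger = more diverged.
#' @export
sequence_harmony <- function(p, q) {
  .check_distribution(p, "p"); .check_distribution(q, "q")
  js_divergence(p, q)
}

#' Mutual information between residue type and group membership
#'
#' How precisely residue types assort into the functional groups at one
#' position: \eqn{MI = \sum_{\alpha,S} f(\alpha,S)
#' \ln\frac{f(\alpha,S)}{f(\alpha) w(S)}}, the KL divergence of the joint
#' type-by-group table from the product of its marginals. The group marginal
#' `w(S)` uses counted (non-gap) residues, so gapped columns do not fake
#' assortment signal. Zero iff type and grouping are independent; the
#' ultimate discriminant-model measure.
#'
#' @param counts 20 x G matrix of residue counts (types in canonical order,
#'   one column per group), or a `column_profiles` object together with
#'   `position`.
#' @param position 1-based position, required when `counts` is a
#'   `column_profiles` object.
#' @return Mutual information in nats (>= 0).
#' @export
mutual_information <- function(counts, position = NULL) {
  if (inherits(counts, "column_profiles")) {
    stopifnot(!is.null(position))
    counts <- t(counts$counts[position, , ])
  }
  counts <- as.matrix(counts)
  n <- sum(counts)
  if (n == 0) stop("all group columns empty at this position", call. = FALSE)
  if (ncol(counts) < 2) stop("need at least 2 groups", call. = FALSE)
  joint <- counts / n
  type_marg <- rowSums(joint)
  grp_marg <- colSums(joint)
  expected <- outer(type_marg, grp_marg)
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / expected[pos]))
}

#' Pairwise mutual information between two groups
#'
#' [mutual_information()] restricted to two groups (overlap id `m`). High
#' values mean low overlap, so downstream the score is negated and rescaled
#' before entering a combined scorer.
#'
#' @param p_counts,q_counts length-20 residue count vectors for the two
#'   groups at one position.
#' @return Mutual information in nats.
#' @export
pairwise_mi <- function(p_counts, q_counts) {
  mutual_information(cbind(p_counts, q_counts))
}

#' Exchangeability-corrected overlap
#'
#' Observed-minus-expected overlap (id `r`): [overlap_o()] of the two
#' observed distributions minus the overlap of the free-evolution
#' distributions rooted at the two groups' ancestral types after the
#' family's effective time,
#' \eqn{o^r = o(p, q) - o(P(t)^\top e_{a_1}, P(t)^\top e_{a_2})}.
#' Zero when both observed profiles equal their free expectations; positive
#' when the groups overlap more than free drift predicts. Two groups
#' conserved as different but highly exchangeable types are judged less
#' diverged than two conserved non-exchangeable types.
#'
#' @inheritParams overlap_o
#' @param model a `rate_model`.
#' @param ancestral_p,ancestral_q ancestral type (index or letter) of each
#'   group's profile.
#' @param t_eff family-wide effective time.
#' @return Corrected overlap in \[-1, 1\].
#' @export
corrected_overlap <- function(p, q, model, ancestral_p, ancestral_q, t_eff) {
  P <- transition_matrix(model, t_eff)
  pe <- P[.resolve_type(ancestral_p), ]
  qe <- P[.resolve_type(ancestral_q), ]
  overlap_o(p, q) - overlap_o(pe, qe)
}

# ---- whole-alignment overlap machinery ------------------------------------

# unordered group pairs of a profiles object, as a 2-column index matrix
.group_pairs <- function(G) {
  if (G < 2) stop("need at least 2 groups", call. = FALSE)
  t(utils::combn(G, 2))
}

#' Pairwise overlap matrix for a whole alignment
#'
#' Applies one overlap method to every position and unordered group pair,
#' then orients and rescales the values to \[0, 1\] with 1 = identical
#' distributions, 0 = most diverged observed in the family:
#' `o` passes through unchanged; `r` (corrected overlap) and `eq9` are
#' min-max rescaled; `f`, `m`, `klg`, `sh` measure divergence and are
#' negated before rescaling.
#'
#' @param profiles a `column_profiles` object.
#' @param method_id one of `"o"`, `"f"`, `"r"`, `"m"`, `"eq9"`, `"klg"`,
#'   `"sh"`.
#' @param model a `rate_model` (needed for `r`).
#' @param t_eff an `effective_time` object or single time value (for `r`).
#' @return List with `overlap` (positions x pairs matrix in \[0, 1\]), `raw`
#'   (method's natural scale), `pairs` (2-column matrix of group indices),
#'   `method_id`.
#' @export
overlap_matrix <- function(profiles,
                           method_id = c("o", "f", "r", "m", "eq9", "klg",
                                         "sh"),
                           model = NULL, t_eff = NULL) {
  method_id <- match.arg(method_id)
  L <- dim(profiles$freq)[1]
  G <- dim(profiles$freq)[2]
  pairs <- .group_pairs(G)
  raw <- matrix(NA_real_, L, nrow(pairs))
  if (method_id == "r") {
    if (is.null(model)) stop("method 'r' needs a rate model", call. = FALSE)
    if (inherits(t_eff, "effective_time")) {
      anc <- t_eff$ancestral; t_val <- t_eff$t_eff
    } else if (is.numeric(t_eff) && length(t_eff) == 1) {
      anc <- ancestral_matrix(profiles, model); t_val <- t_eff
    } else {
      te <- effective_time(profiles, model)
      anc <- te$ancestral; t_val <- te$t_eff
    }
    P <- transition_matrix(model, t_val)
    # expected overlap depends only on the two ancestral types: cache 20x20
    exp_ov <- matrix(NA_real_, 20, 20)
    for (a in 1:20) for (b in a:20) {
      exp_ov[a, b] <- exp_ov[b, a] <- overlap_o(P[a, ], P[b, ])
    }
  }
  for (k in seq_len(nrow(pairs))) {
    g1 <- pairs[k, 1]; g2 <- pairs[k, 2]
    ok <- !profiles$empty[, g1] & !profiles$empty[, g2]
    for (i in which(ok)) {
      p <- profiles$freq[i, g1, ]
      q <- profiles$freq[i, g2, ]
      raw[i, k] <- switch(method_id,
        o   = overlap_o(p, q),
        f   = squared_difference(p, q),
        r   = overlap_o(p, q) - exp_ov[anc[i, g1], anc[i, g2]],
        m   = mutual_information(cbind(profiles$counts[i, g1, ],
                                       profiles$counts[i, g2, ])),
        eq9 = overlap_eq9(p, q),
        klg = kl_between_groups(p, q),
        sh  = sequence_harmony(p, q))
    }
  }
  oriented <- switch(method_id,
    o   = raw,
    r   = apply(raw, 2, rescale_within_group),
    eq9 = apply(raw, 2, rescale_within_group),
    apply(-raw, 2, rescale_within_group))
  if (is.null(dim(oriented))) oriented <- matrix(oriented, nrow = L)
  list(overlap = oriented, raw = raw, pairs = pairs, method_id = method_id)
}
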