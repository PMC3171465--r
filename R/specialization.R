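#' Parse a scorer identifier
#'
#' Scorer identifiers are three characters: conservation id (`e` entropy,
#' `r` exchangeability-corrected entropy, `j` Jensen-Shannon from the
#' stationary distribution, `0` none), overlap id (`o` normalized overlap,
#' `f` squared difference, `r` expectation-corrected overlap, `m` pairwise
#' mutual information), and combiner (`e` Euclidean, `l` linear) — e.g.
#' `"eoe"`, `"rol"`, `"jfl"`, `"0me"`.
#'
#' @param id three-character scorer identifier.
#' @return List with `conservation_id`, `overlap_id`, `combiner`.
#' @export
parse_scorer <- function(id) {
  if (!is.character(id) || length(id) != 1 || nchar(id) != 3) {
    stop("scorer identifier must be a 3-character string, e.g. 'rol'",
         call. = FALSE)
  }
  ch <- strsplit(id, "")[[1]]
  if (!ch[1] %in% c("e", "r", "j", "0")) {
    stop("unknown conservation id '", ch[1], "' (use e, r, j or 0)",
         call. = FALSE)
  }
  if (!ch[2] %in% c("o", "f", "r", "m")) {
    stop("unknown overlap id '", ch[2], "' (use o, f, r or m)",
         call. = FALSE)
  }
  if (!ch[3] %in% c("e", "l")) {
    stop("unknown combiner '", ch[3], "' (use e or l)", call. = FALSE)
  }
  list(conservation_id = ch[1], overlap_id = ch[2], combiner = ch[3])
}

#' Per-position score triplets
#'
#' Assigns to each alignment column its coordinates in the
#' conservation/overlap cube: one conservation value per group (1 = fully
#' conserved) and one overlap value per unordered group pair (1 = identical
#' distributions). These are the coordinates every combined scorer works
#' from.
#'
#' @param profiles a `column_profiles` object.
#' @param conservation_id,overlap_id method ids (see [parse_scorer()]).
#' @param model a `rate_model` (needed for ids `r`, `j`).
#' @param t_eff an `effective_time` object or single time (for ids `r`).
#' @return Object of class `score_triplets`: list with `conservation`
#'   (positions x groups), `overlap` (positions x pairs), `pairs`, `groups`,
#'   plus the ids used.
#' @export
score_triplets <- function(profiles, conservation_id = "e", overlap_id = "o",
                           model = NULL, t_eff = NULL) {
  cm <- conservation_matrix(profiles, model, conservation_id, t_eff)
  om <- overlap_matrix(profiles, overlap_id, model, t_eff)
  structure(list(conservation = cm$conservation, overlap = om$overlap,
                 pairs = om$pairs, groups = profiles$groups,
                 conservation_id = conservation_id, overlap_id = overlap_id,
                 raw_conservation = cm$raw, raw_overlap = om$raw),
            class = "score_triplets")
}

# combine a matrix of penalty terms (rows = positions) into one score/row
.combine <- function(terms, combiner) {
  if (combiner == "e") {
    sqrt(rowMeans(terms^2))
  } else {
    rowMeans(terms)
  }
}

#' Conservation-only score
#'
#' Distance from the all-conserved corner of the cube over all groups,
#' normalized to \[0, 1\]: \eqn{\sqrt{\sum_g (1-C_g)^2 / G}}. The smallest
#' distance indicates the highest family-wide conservation.
#'
#' @param triplets a `score_triplets` object.
#' @return Numeric vector, one score per position (smaller = more
#'   conserved).
#' @export
conservation_only_score <- function(triplets) {
  sqrt(rowMeans((1 - triplets$conservation)^2))
}

#' Discriminant specialization score
#'
#' Seeks positions conserved within every group but different between
#' groups: penalty terms are \eqn{1-C_g} for every group and the overlap of
#' every group pair. Euclidean combiner: root-mean-square of the terms;
#' linear: their mean. Both lie in \[0, 1\]; smaller = more discriminant.
#' The ranking, not the absolute value, is the meaningful output.
#'
#' @param triplets a `score_triplets` object.
#' @param combiner `"e"` (Euclidean) or `"l"` (linear).
#' @return Numeric vector of per-position scores.
#' @export
discriminant_score <- function(triplets, combiner = c("e", "l")) {
  combiner <- match.arg(combiner)
  terms <- cbind(1 - triplets$conservation, triplets$overlap)
  .combine(terms, combiner)
}

#' Determinant specialization score
#'
#' Seeks positions conserved in the target group while making no assumption
#' about the other groups: penalty terms are \eqn{1-C_T} for the target
#' group and the overlap of every pair involving the target. Conservation
#' of non-target groups and overlaps between non-target pairs do not enter
#' the score at all. Smaller = more determinant of the target group.
#'
#' @param triplets a `score_triplets` object.
#' @param target_group group label (or index) whose determinants are sought.
#' @param combiner `"e"` (Euclidean) or `"l"` (linear).
#' @return Numeric vector of per-position scores.
#' @export
determinant_score <- function(triplets, target_group,
                              combiner = c("e", "l")) {
  combiner <- match.arg(combiner)
  tg <- if (is.character(target_group)) {
    match(target_group, triplets$groups)
  } else {
    as.integer(target_group)
  }
  if (is.na(tg) || tg < 1 || tg > length(triplets$groups)) {
    stop("unknown target group: ", target_group, call. = FALSE)
  }
  involves <- triplets$pairs[, 1] == tg | triplets$pairs[, 2] == tg
  terms <- cbind(1 - triplets$conservation[, tg],
                 triplets$overlap[, involves, drop = FALSE])
  .combine(terms, combiner)
}

#' Non-conserved, non-overlapping score
#'
#' Distance from the fully variable, fully non-overlapping corner of the
#' cube: penalty terms are \eqn{C_g} for every group and every pairwise
#' overlap. Included for completeness; positions of this kind do not
#' typically determine functional divergence.
#'
#' @inheritParams discriminant_score
#' @return Numeric vector of per-position scores.
#' @export
nonconserved_nonoverlap_score <- function(triplets, combiner = c("e", "l")) {
  combiner <- match.arg(combiner)
  terms <- cbind(triplets$conservation, triplets$overlap)
  .combine(terms, combiner)
}

#' Rank alignment positions by a specialization scorer
#'
#' Runs the full per-position pipeline: column profiles, effective time
#' (when an exchangeability-corrected method is requested), triplets, and
#' the combined score, then ranks positions ascending (smallest score = most
#' specific). Ties are broken by position index.
#'
#' @param ga a `grouped_alignment`.
#' @param scorer 3-character scorer identifier (see [parse_scorer()]).
#' @param model evolutionary model: `"determinant"`, `"discriminant"`,
#'   `"conservation_only"`, `"nonconserved_nonoverlap"`, or
#'   `"mutual_information"` (multi-group MI of the position, ranked
#'   descending; scorer ids are ignored).
#' @param target_group required when `model = "determinant"`.
#' @param rate_model a `rate_model`; loaded WAG by default when needed.
#' @param t_eff optional precomputed `effective_time` or numeric value.
#' @param profiles optional precomputed `column_profiles`.
#' @return A data.frame of class `sdp_ranking` with columns `position`
#'   (1-based), `score`, `rank`, `high_gap`, ordered by rank, with
#'   attributes `scorer`, `model`, `target_group`, `t_eff`.
#' @export
rank_positions <- function(ga, scorer = "eoe",
                           model = c("determinant", "discriminant",
                                     "conservation_only",
                                     "nonconserved_nonoverlap",
                                     "mutual_information"),
                           target_group = NULL, rate_model = NULL,
                           t_eff = NULL, profiles = NULL) {
  model <- match.arg(model)
  if (is.null(profiles)) profiles <- column_profiles(ga)
  L <- dim(profiles$freq)[1]
  if (model == "mutual_information") {
    mi <- vapply(seq_len(L), function(i) {
      cnt <- t(profiles$counts[i, , ])
      if (sum(cnt) == 0) return(NA_real_)
      mutual_information(cnt)
    }, numeric(1))
    score <- -mi  # high MI = high assortment = more specific
    t_used <- NA_real_
  } else {
    sp <- parse_scorer(scorer)
    needs_model <- sp$conservation_id %in% c("r", "j") || sp$overlap_id == "r"
    if (needs_model && is.null(rate_model)) rate_model <- load_rate_matrix()
    if (is.null(t_eff) &&
        (sp$conservation_id == "r" || sp$overlap_id == "r")) {
      t_eff <- effective_time(profiles, rate_model)
    }
    tr <- score_triplets(profiles, sp$conservation_id, sp$overlap_id,
                         rate_model, t_eff)
    score <- switch(model,
      determinant = {
        if (is.null(target_group)) {
          stop("determinant model needs a target group", call. = FALSE)
        }
        determinant_score(tr, target_group, sp$combiner)
      },
      discriminant = discriminant_score(tr, sp$combiner),
      conservation_only = conservation_only_score(tr),
      nonconserved_nonoverlap = nonconserved_nonoverlap_score(tr,
                                                              sp$combiner))
    t_used <- if (inherits(t_eff, "effective_time")) t_eff$t_eff
              else if (is.numeric(t_eff)) t_eff else NA_real_
  }
  ord <- order(score, seq_len(L), na.last = TRUE)
  out <- data.frame(position = ord, score = score[ord],
                    rank = seq_len(L), high_gap = profiles$high_gap[ord])
  attr(out, "scorer") <- if (model == "mutual_information") "mi" else scorer
  attr(out, "model") <- model
  attr(out, "target_group") <- target_group
  attr(out, "t_eff") <- t_used
  class(out) <- c("sdp_ranking", "data.frame")
  out
}
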