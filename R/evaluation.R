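#' ROC curve of a ranking against residue annotation
#'
#' Sweeps a threshold down the ranked position list; at each distinct score
#' value the true-positive rate is plotted against either the fraction of
#' all non-positive residues above threshold (`mode = "non_positive"`, the
#' convention for scans where untested residues dominate) or the fraction
#' of experimentally confirmed negatives above threshold
#' (`mode = "confirmed_negative"`, the standard false-positive rate).
#' Tied scores are processed as a single threshold step.
#'
#' @param ranking an `sdp_ranking` from [rank_positions()], or a data.frame
#'   with `position` and `score` columns (smaller score = more specific).
#' @param annotation a `residue_annotation`.
#' @param mode x-axis convention, see above.
#' @return Object of class `roc_result`: list with `points` (data.frame
#'   `x`, `y` from (0,0) to (1,1)), `auc`, `mode`.
#' @export
roc_curve <- function(ranking, annotation,
                      mode = c("non_positive", "confirmed_negative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(annotation, "residue_annotation"))
  pos_set <- annotation$positives
  if (length(pos_set) == 0) {
    stop("annotation has no positive positions", call. = FALSE)
  }
  universe <- annotation$universe
  if (!all(universe %in% ranking$position)) {
    stop("ranking does not cover the annotation universe", call. = FALSE)
  }
  keep <- ranking$position %in% universe
  position <- ranking$position[keep]
  score <- ranking$score[keep]
  if (mode == "confirmed_negative") {
    neg_set <- annotation$negatives
    if (length(neg_set) == 0) {
      stop("confirmed_negative mode needs a non-empty negative set",
           call. = FALSE)
    }
  } else {
    neg_set <- setdiff(universe, pos_set)
  }
  ord <- order(score, position)
  score <- score[ord]; position <- position[ord]
  is_pos <- position %in% pos_set
  is_neg <- position %in% neg_set
  # one step per distinct score value
  last_of_tie <- c(score[-1] != score[-length(score)], TRUE)
  steps <- which(last_of_tie)
  tp <- cumsum(is_pos)[steps] / length(pos_set)
  fp <- cumsum(is_neg)[steps] / sum(is_neg)
  pts <- data.frame(x = c(0, fp), y = c(0, tp))
  structure(list(points = pts,
                 auc = .trapezoid(pts$x, pts$y),
                 mode = mode),
            class = "roc_result")
}

.trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Area under a ROC curve
#'
#' Trapezoidal integral of the curve; with the step-per-distinct-score
#' construction this equals the probability that a uniformly chosen positive
#' outranks a uniformly chosen negative, with ties counted half.
#'
#' @param roc a `roc_result` from [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  roc$auc
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result (%s mode): %d points, AUC = %.4f\n",
              x$mode, nrow(x$points), x$auc))
  invisible(x)
}

#' Sweep a grid of scorers and rank them by AUC
#'
#' Evaluates every combination of conservation id, overlap id, combiner and
#' evolutionary model on one annotated alignment, and returns the table
#' sorted by decreasing area under the ROC curve. Column profiles and the
#' effective time are computed once and shared across the grid.
#'
#' @param ga a `grouped_alignment`.
#' @param annotation a `residue_annotation`.
#' @param target_group target for the determinant model (default: first
#'   group).
#' @param conservation_ids,overlap_ids,combiners,models the grid (defaults:
#'   `{e,r,j,0} x {o,f,r,m} x {e,l} x {determinant, discriminant}`).
#' @param mode ROC x-axis convention, see [roc_curve()].
#' @param rate_model a `rate_model` (WAG loaded on demand).
#' @return data.frame with columns `scorer`, `model`, `auc`, sorted by
#'   decreasing `auc`.
#' @export
method_sweep <- function(ga, annotation, target_group = NULL,
                         conservation_ids = c("e", "r", "j", "0"),
                         overlap_ids = c("o", "f", "r", "m"),
                         combiners = c("e", "l"),
                         models = c("determinant", "discriminant"),
                         mode = "non_positive", rate_model = NULL) {
  if (is.null(target_group)) target_group <- ga$groups[1]
  if (is.null(rate_model)) rate_model <- load_rate_matrix()
  profiles <- column_profiles(ga)
  t_eff <- effective_time(profiles, rate_model)
  grid <- expand.grid(cons = conservation_ids, ovl = overlap_ids,
                      comb = combiners, model = models,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    id <- paste0(grid$cons[k], grid$ovl[k], grid$comb[k])
    rk <- rank_positions(ga, scorer = id, model = grid$model[k],
                         target_group = target_group,
                         rate_model = rate_model, t_eff = t_eff,
                         profiles = profiles)
    data.frame(scorer = id, model = grid$model[k],
               auc = roc_curve(rk, annotation, mode = mode)$auc)
  })
  out <- do.call(rbind, res)
  out[order(-out$auc, out$scorer, out$model), , drop = FALSE]
}
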