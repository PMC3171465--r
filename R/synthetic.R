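#' Simulate a grouped alignment with planted column classes
#'
#' Generates a family of G orthologous groups on a star phylogeny, one
#' independent column at a time, under the free-evolution model. Each
#' column is assigned a class:
#' \describe{
#'   \item{conserved_all}{every sequence carries the column's ancestral
#'     type (drawn from the stationary distribution)}
#'   \item{determinant}{the target group is fixed at the ancestral type;
#'     every other group's residues are drawn i.i.d. from the
#'     free-evolution distribution at `t_free`}
#'   \item{discriminant}{each group is fixed at its own type; the types are
#'     distinct, the first being the ancestral type and the rest drawn
#'     uniformly without replacement}
#'   \item{free}{all residues drawn i.i.d. from the free-evolution
#'     distribution at `t_free`}
#' }
#' Column classes are assigned to shuffled positions, so classes are not
#' positional blocks.
#'
#' @param G number of groups (>= 2).
#' @param n_per_group sequences per group (>= 2); scalar or length-G.
#' @param L alignment length in columns.
#' @param class_mixture named integer vector of column counts; names from
#'   `conserved_all`, `determinant`, `discriminant`, `free`; must sum to L.
#' @param t_free divergence time of unconstrained residues (> 0).
#' @param seed integer seed; the simulation is bit-reproducible under it.
#' @param model a `rate_model` (bundled WAG by default).
#' @param det_target group index whose determinants are planted (default 1).
#' @return Object of class `synthetic_family`: list with `ga` (a
#'   `grouped_alignment`), `truth` (data.frame `position`, `kind`,
#'   `target`), and `params`.
#' @export
#' @examples
#' fam <- simulate_family(G = 2, n_per_group = 4, L = 10,
#'                        class_mixture = c(conserved_all = 5, free = 5),
#'                        t_free = 1, seed = 1)
#' table(fam$truth$kind)
simulate_family <- function(G = 2, n_per_group = 40, L = 200,
                            class_mixture = c(determinant = 20,
                                              discriminant = 20,
                                              free = 80,
                                              conserved_all = 80),
                            t_free = 2.0, seed = 1, model = NULL,
                            det_target = 1) {
  if (G < 2) stop("need at least 2 groups", call. = FALSE)
  n_per_group <- rep(as.integer(n_per_group), length.out = G)
  if (any(n_per_group < 2)) {
    stop("need at least 2 sequences per group", call. = FALSE)
  }
  if (t_free <= 0) stop("'t_free' must be positive", call. = FALSE)
  kinds <- c("conserved_all", "determinant", "discriminant", "free")
  if (is.null(names(class_mixture)) ||
      !all(names(class_mixture) %in% kinds)) {
    stop("class_mixture names must be among: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  if (sum(class_mixture) != L) {
    stop("class_mixture counts must sum to L = ", L, call. = FALSE)
  }
  if (is.null(model)) model <- load_rate_matrix()
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)

  P_free <- transition_matrix(model, t_free)
  pi <- model$pi
  n_total <- sum(n_per_group)
  group_labels <- paste0("g", seq_len(G))
  seq_group <- rep(seq_len(G), times = n_per_group)
  mat <- matrix(NA_character_, n_total, L)

  class_of <- rep(names(class_mixture), times = class_mixture)
  class_of <- class_of[sample.int(L)]
  target_of <- ifelse(class_of == "determinant", det_target, NA_integer_)

  for (i in seq_len(L)) {
    anc <- sample.int(20, 1, prob = pi)
    col <- switch(class_of[i],
      conserved_all = rep.int(anc, n_total),
      determinant = {
        res <- integer(n_total)
        fixed <- seq_group == det_target
        res[fixed] <- anc
        res[!fixed] <- sample.int(20, sum(!fixed), replace = TRUE,
                                  prob = P_free[anc, ])
        res
      },
      discriminant = {
        types <- c(anc, sample(setdiff(seq_len(20), anc), G - 1))
        types[seq_group]
      },
      free = sample.int(20, n_total, replace = TRUE, prob = P_free[anc, ]))
    mat[, i] <- AA_ALPHABET[col]
  }

  ids <- sprintf("%s_s%02d", group_labels[seq_group],
                 unlist(lapply(n_per_group, seq_len)))
  aln <- structure(list(ids = ids,
                        rows = apply(mat, 1, paste, collapse = "")),
                   class = "raw_alignment")
  ga <- assign_groups(aln, stats::setNames(group_labels[seq_group], ids))
  truth <- data.frame(position = seq_len(L), kind = class_of,
                      target = target_of)
  structure(list(ga = ga, truth = truth,
                 params = list(G = G, n_per_group = n_per_group, L = L,
                               class_mixture = class_mixture,
                               t_free = t_free, seed = seed,
                               model = model$name,
                               det_target = det_target)),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat("synthetic_family:", x$params$L, "columns,", x$params$G, "groups x",
      paste(x$params$n_per_group, collapse = "/"), "sequences; t_free =",
      x$params$t_free, "\n")
  print(table(x$truth$kind))
  invisible(x)
}

#' Convert planted truth into a residue annotation
#'
#' Positives are the columns of the requested class; negatives are the free
#' and fully conserved columns. Fully conserved columns can never be
#' positives; columns of other planted classes are neither positive nor
#' negative.
#'
#' @param family a `synthetic_family`.
#' @param positive_kind `"determinant"` or `"discriminant"`.
#' @return A `residue_annotation`.
#' @export
planted_truth_to_annotation <- function(family,
                                        positive_kind = c("determinant",
                                                          "discriminant")) {
  positive_kind <- match.arg(positive_kind)
  truth <- family$truth
  if (!any(truth$kind == positive_kind)) {
    stop("no planted columns of class '", positive_kind, "'", call. = FALSE)
  }
  residue_annotation(
    positives = truth$position[truth$kind == positive_kind],
    negatives = truth$position[truth$kind %in% c("free", "conserved_all")],
    universe = truth$position)
}

#' Write a synthetic family to disk
#'
#' Writes the alignment as FASTA, the group assignment and the planted
#' truth as TSV.
#'
#' @param family a `synthetic_family`.
#' @param prefix output path prefix; creates `<prefix>.fasta`,
#'   `<prefix>_groups.tsv`, `<prefix>_truth.tsv`.
#' @return Invisibly, the three file paths.
#' @export
write_family <- function(family, prefix) {
  ga <- family$ga
  fa <- paste0(prefix, ".fasta")
  gr <- paste0(prefix, "_groups.tsv")
  tr <- paste0(prefix, "_truth.tsv")
  writeLines(paste0(">", ga$ids, "\n",
                    apply(ga$mat, 1, paste, collapse = "")), fa)
  utils::write.table(data.frame(id = ga$ids, group = unname(ga$group_of)),
                     gr, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(family$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fa, gr, tr))
}
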