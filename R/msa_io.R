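#' Read a protein multiple sequence alignment
#'
#' Reads a FASTA or Stockholm alignment into a raw alignment object. Rows are
#' uppercased, the `.` gap character is normalized to `-`, and any letter
#' outside the canonical 20-letter alphabet (e.g. B, Z, J, U, O) is mapped to
#' the unknown character `X` with a warning.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return An object of class `raw_alignment`: a list with `ids` (unique
#'   sequence identifiers) and `rows` (character vector of aligned sequences,
#'   all the same length).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACD-E", ">s2", "acdke"), fa)
#' aln <- read_alignment(fa)
#' aln$rows
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("alignment file not found: ", path, call. = FALSE)
  }
  if (format == "fasta") {
    seqs <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) stop("malformed FASTA file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    ids <- names(seqs)
    rows <- as.character(seqs)
  } else {
    msa <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "stockholm"),
      error = function(e) stop("malformed Stockholm file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    rows <- as.character(msa)
    ids <- names(rows)
  }
  if (length(rows) == 0) {
    stop("empty alignment file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", ids)  # keep first token of FASTA headers
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: sequence lengths differ (",
         paste(range(widths), collapse = "-"), ")", call. = FALSE)
  }
  rows <- toupper(rows)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  bad <- setdiff(unique(strsplit(paste(rows, collapse = ""), "")[[1]]),
                 c(AA_ALPHABET, .gap_char, .unknown_char))
  if (length(bad)) {
    warning("non-canonical characters mapped to 'X': ",
            paste(bad, collapse = " "), call. = FALSE)
    rows <- chartr(paste(bad, collapse = ""),
                   strrep(.unknown_char, length(bad)), rows)
  }
  structure(list(ids = unname(ids), rows = unname(rows)),
            class = "raw_alignment")
}

#' Read a sequence-to-group assignment table
#'
#' @param path two-column TSV without header: `sequence_id <TAB> group_label`.
#' @return Named character vector mapping sequence id to group label.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) {
    stop("group file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "")
  if (ncol(tab) < 2) {
    stop("group file must have two tab-separated columns: ", path,
         call. = FALSE)
  }
  if (anyDuplicated(tab[[1]])) {
    stop("duplicate sequence ids in group file: ", path, call. = FALSE)
  }
  stats::setNames(tab[[2]], tab[[1]])
}

#' Attach group labels to a raw alignment
#'
#' Builds the grouped alignment that all scores are computed relative to.
#' Groups are ordered by first appearance in the alignment; ids present in
#' `group_map` but absent from the alignment are silently ignored.
#'
#' @param aln a `raw_alignment` from [read_alignment()], or a list with
#'   `ids` and `rows`.
#' @param group_map named character vector id -> group label (see
#'   [read_group_map()]).
#' @return An object of class `grouped_alignment`: list with `ids`, `mat`
#'   (character matrix, sequences x positions), `group_of`, `groups`,
#'   `n_positions`.
#' @export
assign_groups <- function(aln, group_map) {
  ids <- aln$ids
  rows <- aln$rows
  missing <- setdiff(ids, names(group_map))
  if (length(missing)) {
    stop("sequence ids missing from group map: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  }
  group_of <- group_map[ids]
  groups <- unique(unname(group_of))
  sizes <- table(factor(group_of, levels = groups))
  if (any(sizes < 2)) {
    stop("every group needs at least 2 sequences; singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat, group_of = group_of,
                 groups = groups, n_positions = ncol(mat)),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat("grouped_alignment:", length(x$ids), "sequences x", x$n_positions,
      "positions;", length(x$groups), "groups (",
      paste(x$groups, collapse = ", "), ")\n")
  invisible(x)
}

#' Per-position, per-group residue frequency profiles
#'
#' For every alignment column and group, counts the canonical residues
#' (gaps and `X` excluded) and renormalizes to relative frequencies.
#' Columns where any group has a gap/unknown fraction above `gap_threshold`
#' are flagged as unreliable but still scored.
#'
#' @param ga a `grouped_alignment`.
#' @param gap_policy only `"exclude_renormalize"` is implemented: gaps and
#'   unknowns are dropped from the counts and the remainder renormalized.
#' @param gap_threshold flag positions whose gap fraction in any group
#'   exceeds this value (default 0.5).
#' @return An object of class `column_profiles`: list with
#'   \describe{
#'   \item{freq}{array `n_positions x n_groups x 20` of relative frequencies}
#'   \item{counts}{array of raw residue counts, same shape}
#'   \item{n_counted}{matrix `n_positions x n_groups` of counted residues}
#'   \item{empty}{logical matrix, `TRUE` where a group column had no
#'     countable residue (excluded from scoring)}
#'   \item{high_gap}{logical vector flagging unreliable positions}
#'   \item{groups}{group labels}
#'   }
#' @export
column_profiles <- function(ga, gap_policy = "exclude_renormalize",
                            gap_threshold = 0.5) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(ga, "grouped_alignment"))
  L <- ga$n_positions
  G <- length(ga$groups)
  A <- length(AA_ALPHABET)
  counts <- array(0L, dim = c(L, G, A),
                  dimnames = list(NULL, ga$groups, AA_ALPHABET))
  n_members <- integer(G)
  for (g in seq_len(G)) {
    sub <- ga$mat[ga$group_of == ga$groups[g], , drop = FALSE]
    n_members[g] <- nrow(sub)
    for (a in seq_len(A)) {
      counts[, g, a] <- colSums(sub == AA_ALPHABET[a])
    }
  }
  n_counted <- apply(counts, c(1, 2), sum)
  freq <- counts
  for (g in seq_len(G)) {
    nz <- n_counted[, g] > 0
    freq[nz, g, ] <- counts[nz, g, , drop = FALSE] / n_counted[nz, g]
    freq[!nz, g, ] <- 0
  }
  gap_frac <- 1 - sweep(n_counted, 2, n_members, "/")
  structure(list(freq = freq, counts = counts, n_counted = n_counted,
                 empty = n_counted == 0,
                 high_gap = apply(gap_frac > gap_threshold, 1, any),
                 groups = ga$groups, n_members = n_members),
            class = "column_profiles")
}

#' Extract one column profile
#'
#' @param profiles a `column_profiles` object.
#' @param position 1-based column index.
#' @param group group label or index.
#' @return List with `position`, `group`, `freq` (length-20), `n_counted`,
#'   `empty`.
#' @export
column_profile <- function(profiles, position, group) {
  g <- if (is.character(group)) match(group, profiles$groups) else group
  if (is.na(g)) stop("unknown group: ", group, call. = FALSE)
  list(position = position, group = profiles$groups[g],
       freq = profiles$freq[position, g, ],
       n_counted = unname(profiles$n_counted[position, g]),
       empty = unname(profiles$empty[position, g]))
}

#' Read a residue annotation table
#'
#' @param path TSV without header: `position <TAB> label`, positions 1-based,
#'   labels `positive` or `negative`.
#' @param universe integer vector of all scored (1-based) positions.
#' @param ga optional `grouped_alignment`; when supplied, positions fully
#'   conserved across all groups are removed from the positive set.
#' @return A `residue_annotation` object (see [residue_annotation()]).
#' @export
read_annotation <- function(path, universe, ga = NULL) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", quote = "")
  pos <- as.integer(tab[[1]])
  lab <- tolower(as.character(tab[[2]]))
  if (!all(lab %in% c("positive", "negative"))) {
    stop("annotation labels must be 'positive' or 'negative'", call. = FALSE)
  }
  residue_annotation(positives = pos[lab == "positive"],
                     negatives = pos[lab == "negative"],
                     universe = universe, ga = ga)
}

#' Construct a residue annotation
#'
#' Positions fully conserved across all groups are never counted as
#' positives: when an alignment is supplied they are dropped from the
#' positive set at construction time.
#'
#' @param positives integer positions experimentally confirmed specific.
#' @param negatives integer positions confirmed non-specific.
#' @param universe all scored positions.
#' @param ga optional `grouped_alignment` used to identify fully conserved
#'   columns.
#' @return Object of class `residue_annotation` with fields `positives`,
#'   `negatives`, `universe`.
#' @export
residue_annotation <- function(positives, negatives = integer(0), universe,
                               ga = NULL) {
  positives <- unique(as.integer(positives))
  negatives <- unique(as.integer(negatives))
  universe <- unique(as.integer(universe))
  if (length(intersect(positives, negatives))) {
    stop("positives and negatives overlap", call. = FALSE)
  }
  if (!all(positives %in% universe) || !all(negatives %in% universe)) {
    stop("annotated positions outside the scored universe", call. = FALSE)
  }
  if (!is.null(ga)) {
    cons <- fully_conserved_positions(ga)
    positives <- setdiff(positives, cons)
  }
  structure(list(positives = sort(positives), negatives = sort(negatives),
                 universe = sort(universe)),
            class = "residue_annotation")
}

#' Positions fully conserved across every group
#'
#' A position is fully conserved when all countable (non-gap, non-`X`)
#' residues in the whole family are the same type.
#'
#' @param ga a `grouped_alignment`.
#' @return Integer vector of 1-based positions.
#' @export
fully_conserved_positions <- function(ga) {
  which(apply(ga$mat, 2, function(col) {
    res <- col[col %in% AA_ALPHABET]
    length(res) > 0 && length(unique(res)) == 1
  }))
}
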