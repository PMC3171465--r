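# shared fixtures: tiny alignments, distributions, toy rate models

# indicator distribution on a single amino-acid letter
indicator <- function(letter) {
  v <- numeric(20)
  v[match(letter, AA_ALPHABET)] <- 1
  v
}

# uniform distribution over a set of letters
uniform_on <- function(letters) {
  v <- numeric(20)
  v[match(letters, AA_ALPHABET)] <- 1 / length(letters)
  v
}

# random distribution with a random support size
random_distribution <- function(max_support = 20) {
  k <- sample.int(max_support, 1)
  idx <- sample.int(20, k)
  v <- numeric(20)
  v[idx] <- stats::rexp(k)
  v / sum(v)
}

# write a FASTA file from named sequences, return the path
write_fasta <- function(seqs, ids = names(seqs)) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# grouped alignment straight from per-group row vectors
make_ga <- function(...) {
  groups <- list(...)
  rows <- unlist(groups)
  labels <- rep(names(groups), lengths(groups))
  ids <- sprintf("s%02d", seq_along(rows))
  assign_groups(structure(list(ids = ids, rows = rows),
                          class = "raw_alignment"),
                stats::setNames(labels, ids))
}

# toy uniform-exchangeability, uniform-frequency PAML file
write_uniform_paml <- function() {
  path <- withr::local_tempfile(fileext = ".paml",
                                .local_envir = parent.frame())
  rows <- vapply(1:19, function(i) paste(rep("1.0", i), collapse = " "),
                 character(1))
  writeLines(c(rows, "", paste(rep("0.05", 20), collapse = " ")), path)
  path
}

# cached WAG model for the whole test run
wag_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) model <<- load_rate_matrix("wag")
    model
  }
})

# the shared acceptance-scale synthetic family (spec-fixed conditions)
planted_family <- local({
  fam <- NULL
  function() {
    if (is.null(fam)) {
      fam <<- simulate_family(
        G = 2, n_per_group = 40, L = 200,
        class_mixture = c(determinant = 20, discriminant = 20,
                          free = 80, conserved_all = 80),
        t_free = 2.0, seed = 7, model = wag_model())
    }
    fam
  }
})
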