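#' Load an amino-acid replacement rate model
#'
#' Builds a continuous-time Markov model of amino-acid substitution from a
#' PAML-dialect matrix file: 19 rows of lower-triangular exchangeabilities
#' \eqn{s_{ij}} followed by a line of 20 equilibrium frequencies \eqn{\pi}.
#' The generator is assembled as \eqn{Q_{ij} = s_{ij}\pi_j} (off-diagonal),
#' diagonals set so rows sum to zero, and the whole matrix rescaled so that
#' \eqn{-\sum_i \pi_i Q_{ii} = 1}, i.e. time is measured in expected
#' substitutions per site.
#'
#' @param source path to a PAML-dialect file, or the builtin name `"wag"`
#'   (the bundled WAG matrix of Whelan & Goldman 2001).
#' @return An object of class `rate_model` with fields `name`, `Q`
#'   (20x20 generator), `pi` (stationary distribution), `s`
#'   (symmetric exchangeabilities), `normalized`, and a cached spectral
#'   decomposition used by [transition_matrix()].
#' @export
#' @examples
#' m <- load_rate_matrix("wag")
#' range(rowSums(m$Q))            # ~0
#' -sum(m$pi * diag(m$Q))         # 1
load_rate_matrix <- function(source = "wag") {
  if (tolower(source) %in% c("wag")) {
    path <- system.file("extdata", paste0(tolower(source), ".paml"),
                        package = "sdpscan", mustWork = TRUE)
    name <- toupper(source)
  } else {
    path <- source
    name <- basename(source)
    if (!file.exists(path)) {
      stop("rate matrix file not found: ", path, call. = FALSE)
    }
  }
  parsed <- parse_paml_matrix(path)
  build_rate_model(parsed$s, parsed$pi, name = name)
}

#' Parse a PAML-dialect rate matrix file
#'
#' @param path file with 19 lower-triangular exchangeability rows followed by
#'   a frequency line; `#` comments and blank lines are ignored.
#' @return List with `s` (20x20 symmetric exchangeability matrix, zero
#'   diagonal) and `pi` (length-20 frequencies summing to 1).
#' @export
parse_paml_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  tokens <- scan(text = paste(lines, collapse = "\n"), what = numeric(),
                 quiet = TRUE)
  A <- length(AA_ALPHABET)
  need <- A * (A - 1) / 2 + A
  if (length(tokens) < need) {
    stop("malformed PAML matrix file '", path, "': expected at least ", need,
         " numbers, found ", length(tokens), call. = FALSE)
  }
  ex <- tokens[seq_len(A * (A - 1) / 2)]
  pi <- tokens[A * (A - 1) / 2 + seq_len(A)]
  if (any(ex < 0)) stop("negative exchangeability in ", path, call. = FALSE)
  if (any(pi <= 0)) {
    stop("equilibrium frequencies must be strictly positive in ", path,
         call. = FALSE)
  }
  s <- matrix(0, A, A, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  k <- 0
  for (i in 2:A) {            # PAML row-major lower triangle
    s[i, seq_len(i - 1)] <- ex[k + seq_len(i - 1)]
    k <- k + i - 1
  }
  s <- s + t(s)
  list(s = s, pi = pi / sum(pi))
}

#' Assemble a rate model from exchangeabilities and frequencies
#'
#' @param s symmetric 20x20 exchangeability matrix (diagonal ignored).
#' @param pi length-20 stationary frequencies, strictly positive.
#' @param name model label.
#' @return A `rate_model` object (see [load_rate_matrix()]).
#' @export
build_rate_model <- function(s, pi, name = "custom") {
  A <- length(AA_ALPHABET)
  stopifnot(is.matrix(s), all(dim(s) == A), length(pi) == A, all(pi > 0))
  pi <- pi / sum(pi)
  Q <- s %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (rate <= 0) stop("degenerate rate matrix: zero total rate", call. = FALSE)
  Q <- Q / rate
  dimnames(Q) <- list(AA_ALPHABET, AA_ALPHABET)
  # reversible-model spectral decomposition: B = D^{1/2} Q D^{-1/2} symmetric
  sq <- sqrt(pi)
  B <- (Q * rep(sq, times = A)) * rep(1 / sq, each = A)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(name = name, Q = Q, pi = stats::setNames(pi, AA_ALPHABET),
                 s = s, normalized = TRUE,
                 evals = eig$values,
                 U = eig$vectors * rep(1 / sq, times = A),     # D^{-1/2} V
                 Uinv = t(eig$vectors) * rep(sq, each = A)),   # V' D^{1/2}
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("rate_model:", x$name, "(20x20, time unit = expected subst/site)\n")
  invisible(x)
}

#' Transition-probability matrix P(t) = exp(Qt)
#'
#' @param model a `rate_model`.
#' @param t divergence time, expected substitutions per site (>= 0).
#' @return 20x20 row-stochastic matrix; entry (i, j) is the probability of
#'   type i being replaced by type j after time t.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "rate_model"))
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    stop("'t' must be a single non-negative number", call. = FALSE)
  }
  P <- model$U %*% (exp(model$evals * t) * model$Uinv)
  P[P < 0] <- 0                       # clip eigen-roundoff
  P <- P / rowSums(P)
  dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
  P
}

#' Stationary distribution of the model
#'
#' The long-time limit every residue-type distribution drifts to when free
#' of constraints; the model's background distribution.
#'
#' @param model a `rate_model`.
#' @return Named length-20 probability vector.
#' @export
stationary_distribution <- function(model) {
  model$pi
}

#' Free-evolution distribution from a single ancestral type
#'
#' The expected residue-type distribution of a position that started as
#' `ancestral` and evolved for time `t` free of any constraint: the
#' `ancestral` row of P(t).
#'
#' @param model a `rate_model`.
#' @param ancestral type index (1..20) or single letter.
#' @param t time (expected substitutions per site).
#' @return Object of class `free_distribution`: list with `ancestral`, `t`,
#'   `p` (length-20 probability vector).
#' @export
free_distribution <- function(model, ancestral, t) {
  a <- .resolve_type(ancestral)
  p <- transition_matrix(model, t)[a, ]
  structure(list(ancestral = a, t = t, p = p), class = "free_distribution")
}

.resolve_type <- function(ancestral) {
  if (is.character(ancestral)) {
    a <- aa_index(ancestral)
    if (is.na(a)) stop("unknown amino-acid type: ", ancestral, call. = FALSE)
  } else {
    a <- as.integer(ancestral)
    if (is.na(a) || a < 1 || a > length(AA_ALPHABET)) {
      stop("ancestral type index out of range: ", ancestral, call. = FALSE)
    }
  }
  a
}

# default time grid for effective-time search: {0} plus 64 log-spaced points
.default_t_grid <- function() {
  c(0, exp(seq(log(1e-3), log(20), length.out = 64)))
}

# rows of P(t) for the whole grid, cached as a list of matrices
.grid_transitions <- function(model, t_grid) {
  lapply(t_grid, function(t) transition_matrix(model, t))
}

#' Ancestral residue type of a column profile
#'
#' The majority type of the profile. Ties among the top frequency are broken
#' in favour of the type whose free-evolution distribution, maximized over
#' the time grid, overlaps the observed profile most; remaining exact ties
#' fall back to canonical alphabet order.
#'
#' @param profile length-20 frequency vector or a list with a `freq` field.
#' @param model a `rate_model`.
#' @param t_grid time grid used for the tie-break search.
#' @param overlap_fn two-distribution overlap used in the tie-break
#'   (default [overlap_o()]).
#' @return Type index in 1..20.
#' @export
ancestral_type <- function(profile, model, t_grid = .default_t_grid(),
                           overlap_fn = overlap_o) {
  f <- if (is.list(profile)) profile$freq else profile
  if (sum(f) <= 0) stop("empty profile has no ancestral type", call. = FALSE)
  top <- which(f >= max(f) - 1e-12)
  if (length(top) == 1) return(top)
  Pg <- .grid_transitions(model, t_grid)
  best <- vapply(top, function(a) {
    max(vapply(Pg, function(P) overlap_fn(P[a, ], f), numeric(1)))
  }, numeric(1))
  top[which.max(best)]  # which.max takes the first (canonical order) on ties
}

#' Family-wide effective divergence time
#'
#' For every non-empty (position, group) profile, finds the time at which a
#' freely evolving distribution rooted at the profile's ancestral type
#' overlaps the observed distribution most (grid search over
#' `t_grid`, golden-section refinement to |dt| < 1e-3), then returns the
#' unweighted mean of those per-profile optima. This single family-wide
#' estimate feeds the expected-value corrections of the conservation and
#' overlap scores.
#'
#' @param profiles a `column_profiles` object.
#' @param model a `rate_model`.
#' @param overlap_fn two-distribution overlap maximized per profile
#'   (default [overlap_o()]).
#' @param t_grid search grid; default `{0}` plus 64 log-spaced points in
#'   `[1e-3, 20]`.
#' @return List of class `effective_time`: `t_eff` (the mean), `t_star`
#'   (matrix of per-profile optima, NA where empty), `ancestral` (matrix of
#'   per-profile ancestral type indices).
#' @export
effective_time <- function(profiles, model, overlap_fn = overlap_o,
                           t_grid = .default_t_grid()) {
  stopifnot(inherits(profiles, "column_profiles"))
  if (all(profiles$empty)) {
    stop("all profiles are empty; cannot estimate effective time",
         call. = FALSE)
  }
  Pg <- .grid_transitions(model, t_grid)
  attr(Pg, "model") <- model
  L <- dim(profiles$freq)[1]
  G <- dim(profiles$freq)[2]
  t_star <- matrix(NA_real_, L, G)
  anc <- matrix(NA_integer_, L, G)
  for (i in seq_len(L)) {
    for (g in seq_len(G)) {
      if (profiles$empty[i, g]) next
      f <- profiles$freq[i, g, ]
      a <- .ancestral_from_grid(f, Pg, overlap_fn)
      anc[i, g] <- a
      t_star[i, g] <- .golden_refine(f, a, Pg, t_grid, overlap_fn, model)
    }
  }
  structure(list(t_eff = mean(t_star, na.rm = TRUE), t_star = t_star,
                 ancestral = anc, t_grid = t_grid),
            class = "effective_time")
}

#' Ancestral types for every (position, group) profile
#'
#' @param profiles a `column_profiles` object.
#' @param model a `rate_model`.
#' @param t_grid tie-break search grid.
#' @return Integer matrix positions x groups (NA where empty).
#' @export
ancestral_matrix <- function(profiles, model, t_grid = .default_t_grid()) {
  L <- dim(profiles$freq)[1]
  G <- dim(profiles$freq)[2]
  anc <- matrix(NA_integer_, L, G)
  Pg <- NULL  # built lazily: ties are rare
  for (i in seq_len(L)) {
    for (g in seq_len(G)) {
      if (profiles$empty[i, g]) next
      f <- profiles$freq[i, g, ]
      top <- which(f >= max(f) - 1e-12)
      if (length(top) == 1) {
        anc[i, g] <- top
      } else {
        if (is.null(Pg)) Pg <- .grid_transitions(model, t_grid)
        anc[i, g] <- .ancestral_from_grid(f, Pg, overlap_o)
      }
    }
  }
  anc
}

# ancestral type with grid-overlap tie-break, reusing precomputed Pg
.ancestral_from_grid <- function(f, Pg, overlap_fn) {
  top <- which(f >= max(f) - 1e-12)
  if (length(top) == 1) return(top)
  best <- vapply(top, function(a) {
    max(vapply(Pg, function(P) overlap_fn(P[a, ], f), numeric(1)))
  }, numeric(1))
  top[which.max(best)]
}

# grid search + golden-section refinement of the per-profile optimum
.golden_refine <- function(f, anc, Pg, t_grid, overlap_fn, model,
                           tol = 1e-3) {
  ov <- vapply(Pg, function(P) overlap_fn(P[anc, ], f), numeric(1))
  k <- which.max(ov)
  if (k == 1 || k == length(t_grid)) return(t_grid[k])
  lo <- t_grid[k - 1]; hi <- t_grid[k + 1]
  phi <- (sqrt(5) - 1) / 2
  h <- function(t) overlap_fn(transition_matrix(model, t)[anc, ], f)
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  h1 <- h(x1); h2 <- h(x2)
  while (hi - lo > tol) {
    if (h1 < h2) {
      lo <- x1; x1 <- x2; h1 <- h2
      x2 <- lo + phi * (hi - lo); h2 <- h(x2)
    } else {
      hi <- x2; x2 <- x1; h2 <- h1
      x1 <- hi - phi * (hi - lo); h1 <- h(x1)
    }
  }
  (lo + hi) / 2
}
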