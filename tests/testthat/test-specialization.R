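# random triplets object for G groups (valid score_triplets surrogate)
random_triplets <- function(n, G = 3) {
  pairs <- t(utils::combn(G, 2))
  structure(list(conservation = matrix(stats::runif(n * G), n, G),
                 overlap = matrix(stats::runif(n * nrow(pairs)), n,
                                  nrow(pairs)),
                 pairs = pairs, groups = paste0("g", seq_len(G)),
                 conservation_id = "e", overlap_id = "o"),
            class = "score_triplets")
}

triplet_row <- function(cons, ovl, G = length(cons)) {
  pairs <- t(utils::combn(G, 2))
  structure(list(conservation = matrix(cons, 1), overlap = matrix(ovl, 1),
                 pairs = pairs, groups = paste0("g", seq_len(G)),
                 conservation_id = "e", overlap_id = "o"),
            class = "score_triplets")
}

test_that("the scorer grammar parses and rejects correctly", {
  sp <- parse_scorer("rol")
  expect_equal(sp, list(conservation_id = "r", overlap_id = "o",
                        combiner = "l"))
  expect_equal(parse_scorer("0me")$conservation_id, "0")
  expect_error(parse_scorer("xol"), "conservation")
  expect_error(parse_scorer("exl"), "overlap")
  expect_error(parse_scorer("eox"), "combiner")
  expect_error(parse_scorer("eo"), "3-character")
})

test_that("score triplets land on the cube corners for archetype columns", {
  ga <- make_ga(A = rep("AAA", 4), B = c("ACA", "ACC", "ACD", "ACE"))
  # col 1: same conserved type; col 2: conserved but different; col 3: mixed B
  tr <- score_triplets(column_profiles(ga), "e", "o")
  expect_equal(tr$conservation[1, ], c(1, 1))
  expect_equal(tr$overlap[1, 1], 1)
  expect_equal(tr$conservation[2, ], c(1, 1))
  expect_equal(tr$overlap[2, 1], 0)
  expect_equal(tr$conservation[3, 1], 1)
  expect_lt(tr$conservation[3, 2], 1)
})

test_that("conservation-only score is the normalized corner distance", {
  expect_equal(conservation_only_score(triplet_row(c(1, 1), 1)), 0)
  expect_equal(conservation_only_score(triplet_row(c(0, 0), 1)), 1)
  expect_equal(conservation_only_score(triplet_row(c(1, 0), 0)),
               1 / sqrt(2))
})

test_that("discriminant score matches the decided normalization", {
  expect_equal(discriminant_score(triplet_row(c(1, 1), 0), "e"), 0)
  expect_equal(discriminant_score(triplet_row(c(0, 0), 1), "e"), 1)
  expect_equal(discriminant_score(triplet_row(c(1, 0), 0), "l"), 1 / 3)
  expect_equal(discriminant_score(triplet_row(c(1, 0), 0), "e"),
               sqrt(1 / 3))
  # permutation invariance over group labels
  withr::local_seed(20)
  for (k in 1:20) {
    tr <- random_triplets(5, G = 3)
    perm <- sample.int(3)
    pairs <- tr$pairs
    # reindex pairwise overlaps under the permutation
    key <- function(p) paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
    new_pairs <- cbind(perm[pairs[, 1]], perm[pairs[, 2]])
    tr2 <- tr
    tr2$conservation <- tr$conservation[, order(perm), drop = FALSE]
    tr2$overlap <- tr$overlap[, match(key(pairs), key(new_pairs)),
                              drop = FALSE]
    for (comb in c("e", "l")) {
      expect_equal(discriminant_score(tr2, comb),
                   discriminant_score(tr, comb))
    }
  }
})

test_that("determinant score ignores everything not involving the target", {
  tr <- triplet_row(c(1, 0.2, 0.9), c(0, 0, 0.4))  # pairs 12, 13, 23
  for (comb in c("e", "l")) {
    base <- determinant_score(tr, 1, comb)
    # corner: conserved target, zero target overlaps -> 0
    expect_equal(base, 0)
    # perturbing non-target conservation and the 2-3 overlap: bit-identical
    tr2 <- tr
    tr2$conservation[1, 2:3] <- c(0.5, 0.1)
    tr2$overlap[1, 3] <- 0.99
    expect_identical(determinant_score(tr2, 1, comb), base)
  }
  expect_error(determinant_score(tr, "nope"), "unknown target")
  # monotonicity in the target-pair overlap
  lo <- triplet_row(c(1, 1), 0); hi <- triplet_row(c(1, 1), 1)
  expect_lt(determinant_score(lo, 1, "l"), determinant_score(hi, 1, "l"))
})

test_that("determinant independence holds over 1000 random triplets", {
  withr::local_seed(21)
  for (k in 1:1000) {
    G <- sample(2:4, 1)
    tr <- random_triplets(1, G = G)
    target <- sample.int(G, 1)
    comb <- sample(c("e", "l"), 1)
    base <- determinant_score(tr, target, comb)
    tr2 <- tr
    tr2$conservation[, -target] <- stats::runif(G - 1)
    off <- !(tr$pairs[, 1] == target | tr$pairs[, 2] == target)
    if (any(off)) tr2$overlap[, off] <- stats::runif(sum(off))
    expect_identical(determinant_score(tr2, target, comb), base)
  }
})

test_that("for two groups determinant and discriminant differ only by the
           non-target conservation term", {
  withr::local_seed(22)
  for (k in 1:100) {
    tr <- random_triplets(1, G = 2)
    det <- determinant_score(tr, 1, "l")
    dis <- discriminant_score(tr, "l")
    # linear forms: mean of 2 vs mean of 3 terms sharing all but 1 - C_2
    expect_equal(dis, (2 * det + (1 - tr$conservation[1, 2])) / 3)
  }
})

test_that("Euclidean and linear combiners agree at corners, not inside", {
  corners <- expand.grid(c1 = c(0, 1), c2 = c(0, 1), ov = c(0, 1))
  e_scores <- apply(corners, 1, function(r) {
    discriminant_score(triplet_row(c(r[1], r[2]), r[3]), "e")
  })
  l_scores <- apply(corners, 1, function(r) {
    discriminant_score(triplet_row(c(r[1], r[2]), r[3]), "l")
  })
  expect_equal(order(e_scores), order(l_scores))
  # interior witness where the two combiners disagree on ranking
  a <- triplet_row(c(1, 1), 0.6)        # one big penalty term
  b <- triplet_row(c(0.7, 0.7), 0.35)   # three moderate terms
  expect_true((discriminant_score(a, "e") - discriminant_score(b, "e")) *
                (discriminant_score(a, "l") - discriminant_score(b, "l")) <
                0)
})

test_that("rank_positions runs the toy pipeline to the hand-computed order", {
  ga <- make_ga(A = rep("AAA", 4), B = c("ACA", "ACC", "ACD", "ACE"))
  # columns: 1 conserved-same, 2 discriminant (A|C), 3 determinant-of-A
  # hand evaluation of "eoe" determinant(A):
  #   col1 terms (0, 1) -> sqrt(1/2); col2 (0, 0) -> 0;
  #   col3 overlap = cos(indicator, uniform4) = 1/2 -> sqrt((0+0.25)/2)
  rk <- rank_positions(ga, "eoe", model = "determinant", target_group = "A")
  expect_equal(rk$position, c(2, 3, 1))
  expect_equal(rk$score, c(0, sqrt(0.125), sqrt(0.5)))
  expect_equal(rk$rank, 1:3)
})

test_that("rankings are invariant under positive affine score transforms", {
  withr::local_seed(23)
  fam <- simulate_family(G = 2, n_per_group = 6, L = 30,
                         class_mixture = c(determinant = 5, free = 15,
                                           conserved_all = 10),
                         t_free = 1.5, seed = 3, model = wag_model())
  rk <- rank_positions(fam$ga, "eol", model = "determinant",
                       target_group = "g1", rate_model = wag_model())
  rk2 <- rk
  rk2$score <- 3.7 * rk2$score + 1.2
  ann <- planted_truth_to_annotation(fam, "determinant")
  expect_equal(roc_curve(rk, ann)$points, roc_curve(rk2, ann)$points)
  # planted determinant columns outrank planted free columns
  det_pos <- fam$truth$position[fam$truth$kind == "determinant"]
  free_pos <- fam$truth$position[fam$truth$kind == "free"]
  mean_rank <- function(p) mean(match(p, rk$position))
  expect_lt(mean_rank(det_pos), mean_rank(free_pos))
})
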