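test_that("normalized overlap has exact identity and disjointness extremes", {
  expect_equal(overlap_o(indicator("A"), indicator("A")), 1)
  expect_equal(overlap_o(indicator("A"), indicator("C")), 0)
  # 1 for identical distributions irrespective of their variability
  for (supp in list("A", c("A", "C"), c("A", "C", "D", "E"))) {
    expect_equal(overlap_o(uniform_on(supp), uniform_on(supp)), 1)
  }
  # hand evaluation: uniform{A,C} vs uniform{C,D} -> 0.25 / (0.7071^2)
  expect_equal(overlap_o(uniform_on(c("A", "C")), uniform_on(c("C", "D"))),
               0.5)
  expect_error(overlap_o(rep(0.1, 20), indicator("A")), "sum to 1")
})

test_that("normalized overlap behaves over 1000 random distribution pairs", {
  withr::local_seed(10)
  for (k in 1:1000) {
    p <- random_distribution(8)
    q <- if (k %% 3 == 0) p else random_distribution(8)
    v <- overlap_o(p, q)
    expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
    expect_equal(v, overlap_o(q, p))
    if (max(abs(p - q)) < 1e-12) expect_equal(v, 1)
    if (v == 1) expect_lt(max(abs(p - q)), 1e-12)
    disjoint <- all(p * q == 0)
    expect_equal(v == 0, disjoint)
  }
})

test_that("unnormalized overlap is spread-dependent at identity, 0 disjoint", {
  expect_equal(overlap_eq9(indicator("A"), indicator("C")), 0)
  expect_equal(overlap_eq9(uniform_on(c("A", "C", "D")),
                           uniform_on(c("E", "F", "G"))), 0)
  # identical distributions score differently depending on their spread
  expect_equal(overlap_eq9(indicator("A"), indicator("A")), 1)
  expect_equal(overlap_eq9(uniform_on(c("A", "C", "D", "E")),
                           uniform_on(c("A", "C", "D", "E"))), 0.25)
  withr::local_seed(11)
  for (k in 1:50) {
    p <- random_distribution(); q <- random_distribution()
    expect_equal(overlap_eq9(p, q), sum(p * q))  # element-wise oracle
  }
})

test_that("squared difference matches closed forms and is spread-dependent
           for disjoint supports", {
  expect_equal(squared_difference(indicator("A"), indicator("A")), 0)
  expect_equal(squared_difference(indicator("A"), indicator("C")), 2)
  expect_equal(squared_difference(uniform_on(c("A", "C")),
                                  uniform_on(c("C", "D"))), 0.5)
  # disjoint indicators vs disjoint two-type uniforms: different values
  expect_equal(squared_difference(uniform_on(c("A", "C")),
                                  uniform_on(c("D", "E"))), 1)
})

test_that("between-group KL is asymmetric, floored, zero at identity", {
  expect_equal(kl_between_groups(indicator("A"), indicator("A")), 0,
               tolerance = 1e-4)
  p <- uniform_on(c("A", "C"))
  q <- numeric(20); q[match(c("A", "C"), AA_ALPHABET)] <- c(0.9, 0.1)
  expect_equal(kl_between_groups(p, q),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-3)
  expect_gt(abs(kl_between_groups(p, q) - kl_between_groups(q, p)), 0.01)
  # mass where the reference has none stays finite thanks to the floor
  expect_true(is.finite(kl_between_groups(indicator("A"), indicator("C"))))
})

test_that("sequence harmony is symmetric, 0 at identity, ln 2 disjoint", {
  expect_equal(sequence_harmony(indicator("A"), indicator("A")), 0)
  p <- uniform_on(c("A", "C", "W"))
  expect_equal(sequence_harmony(p, p), 0)
  expect_equal(sequence_harmony(indicator("A"), indicator("C")), log(2))
  withr::local_seed(12)
  for (k in 1:50) {
    p <- random_distribution(); q <- random_distribution()
    v <- sequence_harmony(p, q)
    expect_equal(v, sequence_harmony(q, p))
    mx <- (p + q) / 2
    brute <- sum(ifelse(p > 0, p * log(p / mx), 0)) / 2 +
      sum(ifelse(q > 0, q * log(q / mx), 0)) / 2
    expect_equal(v, brute)
    expect_gte(v, 0); expect_lte(v, log(2) + 1e-12)
  }
})

test_that("mutual information matches the joint-table KL oracle", {
  # identical compositions: independence, MI = 0
  expect_equal(mutual_information(cbind(c(rep(5, 2), rep(0, 18)),
                                        c(rep(5, 2), rep(0, 18)))), 0)
  # perfectly assorting equal groups: MI = ln 2
  a <- numeric(20); a[1] <- 10
  c_ <- numeric(20); c_[5] <- 10
  expect_equal(mutual_information(cbind(a, c_)), log(2))
  expect_equal(pairwise_mi(a, c_), log(2))
  expect_equal(pairwise_mi(a, c_), pairwise_mi(c_, a))  # group-swap symmetry
  withr::local_seed(13)
  for (k in 1:30) {
    G <- sample(2:4, 1)
    counts <- matrix(stats::rpois(20 * G, 1.2), 20, G)
    if (sum(counts) == 0) counts[1, 1] <- 1
    v <- mutual_information(counts)
    # independent brute force over the 20 x G joint table
    joint <- counts / sum(counts)
    brute <- 0
    for (i in 1:20) for (g in 1:G) {
      pj <- joint[i, g]
      if (pj > 0) {
        brute <- brute + pj * log(pj / (sum(joint[i, ]) * sum(joint[, g])))
      }
    }
    expect_equal(v, brute)
    expect_gte(v, -1e-12)
  }
  expect_error(mutual_information(matrix(0, 20, 2)), "empty")
})

test_that("corrected overlap is observed minus expected", {
  m <- wag_model()
  withr::local_seed(14)
  for (k in 1:10) {
    a1 <- sample.int(20, 1); a2 <- sample.int(20, 1)
    t <- stats::runif(1, 0.1, 3)
    p <- free_distribution(m, a1, t)$p
    q <- free_distribution(m, a2, t)$p
    # both observed profiles equal their free expectations -> 0
    expect_equal(corrected_overlap(p, q, m, a1, a2, t), 0)
  }
  expect_equal(corrected_overlap(indicator("A"), indicator("A"), m,
                                 "A", "A", 0), 0)
  # observed-minus-expected direction: groups conserved as different but
  # highly exchangeable types (I/V) forgo a large expected overlap, so the
  # absence of "easy" overlap signals stronger divergence than conserved
  # non-exchangeable types (W/D), whose free expectation is near zero anyway
  iv <- corrected_overlap(indicator("I"), indicator("V"), m, "I", "V", 1)
  wd <- corrected_overlap(indicator("W"), indicator("D"), m, "W", "D", 1)
  expect_lt(iv, wd)
  # the gap is driven by the expected term alone (observed overlaps tie at 0)
  P <- transition_matrix(m, 1)
  expect_gt(overlap_o(P[match("I", AA_ALPHABET), ],
                      P[match("V", AA_ALPHABET), ]),
            overlap_o(P[match("W", AA_ALPHABET), ],
                      P[match("D", AA_ALPHABET), ]))
  # with everything else fixed it is overlap_o minus a constant
  const <- overlap_o(free_distribution(m, 1, 0.7)$p,
                     free_distribution(m, 2, 0.7)$p)
  p <- random_distribution(); q <- random_distribution()
  expect_equal(corrected_overlap(p, q, m, 1, 2, 0.7),
               overlap_o(p, q) - const)
})

test_that("overlap matrices are oriented to [0,1] with 1 = identical", {
  m <- wag_model()
  ga <- make_ga(A = c("AAAC", "AAAC", "AADC"), B = c("ACWC", "ACWD", "ACWC"))
  pr <- column_profiles(ga)
  for (id in c("o", "f", "r", "m", "eq9", "klg", "sh")) {
    om <- overlap_matrix(pr, id, model = m, t_eff = 0.4)
    expect_true(all(om$overlap >= 0 & om$overlap <= 1, na.rm = TRUE))
  }
  # orientation: the identical column (1) must not score below the
  # disjoint column (3) under any method
  for (id in c("o", "f", "m", "eq9", "klg", "sh")) {
    om <- overlap_matrix(pr, id, model = m)
    expect_gte(om$overlap[1, 1], om$overlap[3, 1])
  }
})
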