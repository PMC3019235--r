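# expression: constitutive exons, counting, accounting, quantile
# normalization, NB exact test, pre-mRNA model

test_that("constitutive exons are the isoform intersection, minus cross-gene overlaps", {
  m <- toy_models(list(
    gA = list(t1 = rbind(c(100, 200), c(300, 400), c(500, 600)),
              t2 = rbind(c(100, 200), c(500, 600))),
    gB = list(t1 = rbind(c(1000, 1100)))))
  ce <- derive_constitutive_exons(m)
  expect_equal(start(ce[["gA"]]) - 1L, c(100L, 500L))   # {e1, e3}
  expect_equal(end(ce[["gA"]]), c(200L, 600L))
  # single-isoform gene, no neighbours: all exons
  expect_equal(start(ce[["gB"]]) - 1L, 1000L)
  # a 1-bp overlap from a neighbour removes the whole interval
  m2 <- toy_models(list(
    gA = list(t1 = rbind(c(100, 200), c(500, 600))),
    gC = list(t1 = rbind(c(599, 700)))))
  ce2 <- derive_constitutive_exons(m2)
  expect_equal(start(ce2[["gA"]]) - 1L, 100L)           # e2 removed entirely
  expect_length(ce2[["gC"]], 0L)                        # and vice versa
})

test_that("partial isoform overlap intersects at base level into maximal intervals", {
  m <- toy_models(list(
    g = list(t1 = rbind(c(100, 300)), t2 = rbind(c(150, 250)))))
  ce <- derive_constitutive_exons(m)
  expect_equal(start(ce[["g"]]) - 1L, 150L)
  expect_equal(end(ce[["g"]]), 250L)
})

test_that("fragment counting requires full containment in one gene's constitutive bases", {
  m <- toy_models(list(
    g = list(t1 = rbind(c(1000, 1200), c(2000, 2200)))))
  ce <- derive_constitutive_exons(m)
  fr <- toy_frags(list(
    rbind(c(1010, 1060), c(1100, 1150)),     # both mates in one exon -> +1
    rbind(c(1150, 1250)),                    # straddles exon/intron -> 0
    rbind(c(1150, 1200), c(2000, 2050)),     # spliced, all bases exonic -> +1
    rbind(c(500, 560))))                     # intergenic -> 0
  cnt <- count_constitutive_fragments(fr, ce, samples = "S")
  expect_equal(unname(cnt["g", "S"]), 2L)
  # non-unique fragments are excluded
  fr2 <- toy_frags(list(rbind(c(1010, 1060))), unique = FALSE)
  expect_equal(unname(count_constitutive_fragments(fr2, ce, samples = "S")["g", "S"]),
               0L)
})

test_that("accounting identities reproduce the printed two-sample values", {
  # blastocyst column: exonic + intronic -> genic and the 0.1%-rounded fraction
  b <- intronic_fraction(11596019, 2525630)
  expect_identical(b$genic, 14121649)
  expect_identical(b$fraction_pct, 17.9)
  d <- intronic_fraction(7103823, 3644395)
  expect_identical(d$genic, 10748218)
  expect_identical(d$fraction_pct, 33.9)
})

test_that("genic accounting classifies fragments exhaustively and exclusively", {
  m <- toy_models(list(
    g = list(t1 = rbind(c(1000, 1200), c(2000, 2200)))))
  fr <- toy_frags(list(
    rbind(c(1010, 1110)),                    # exonic
    rbind(c(1150, 1300)),                    # intron-overlapping
    rbind(c(1400, 1500)),                    # wholly intronic
    rbind(c(5000, 5100))))                   # intergenic
  acc <- genic_accounting(fr, m, samples = "S")
  expect_equal(acc$exonic, 1L)
  expect_equal(acc$intronic, 2L)
  expect_equal(acc$intergenic, 1L)
  expect_equal(acc$genic, acc$exonic + acc$intronic)
  expect_equal(acc$total, acc$genic + acc$intergenic)
  expect_equal(acc$intronic_fraction, 2 / 3)
  # zero intronic -> fraction 0; zero genic -> fraction missing
  acc0 <- genic_accounting(toy_frags(list(rbind(c(1010, 1110)))), m, samples = "S")
  expect_equal(acc0$intronic_fraction, 0)
  accNA <- genic_accounting(toy_frags(list(rbind(c(5000, 5100)))), m, samples = "S")
  expect_true(is.na(accNA$intronic_fraction))
})

test_that("constitutive counts never exceed the exonic accounting count", {
  sim <- small_sim()
  ce <- derive_constitutive_exons(sim$models)
  cnt <- count_constitutive_fragments(sim$frags, ce,
                                      samples = sim$config$samples)
  acc <- genic_accounting(sim$frags, sim$models,
                          samples = sim$config$samples)
  expect_true(all(colSums(cnt) <= acc$exonic))
})

test_that("quantile normalization matches the rank-mean oracle, with ties averaged", {
  # identical columns unchanged
  m <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(quantile_normalize(m), m)
  # aligned ranks: both columns become the row-wise means of the sorted values
  m2 <- cbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(quantile_normalize(m2)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # tie-average oracle on a 4x2 matrix, brute force:
  # sorted refs rowMeans([1,2,2,5],[3,4,5,6]) = (2,3,3.5,5.5); the tied pair
  # in column 1 (ranks 2 and 3) receives mean(3, 3.5) = 3.25
  m3 <- cbind(c(1, 2, 2, 5), c(3, 4, 5, 6))
  n3 <- quantile_normalize(m3)
  expect_equal(unname(n3[, 1L]), c(2, 3.25, 3.25, 5.5))
  expect_equal(unname(n3[, 2L]), c(2, 3, 3.5, 5.5))
  expect_equal(n3[2L, 1L], n3[3L, 1L])      # tied entries equal
  # multiset identity and idempotence are exact on tie-free data; with ties
  # the tie-averaging contract perturbs both slightly (no tie rule can
  # satisfy tie-means, multiset identity and idempotence simultaneously)
  set.seed(3)
  m5 <- matrix(sample(10000L, 120L), ncol = 2L)  # tie-free
  n5 <- quantile_normalize(m5)
  expect_equal(sort(n5[, 1L]), sort(n5[, 2L]))
  expect_equal(quantile_normalize(n5), n5)
  m4 <- matrix(rpois(200, 40), ncol = 2L)        # heavily tied
  n4 <- quantile_normalize(m4)
  expect_equal(sort(n4[, 1L]), sort(n4[, 2L]), tolerance = 0.02)
  expect_equal(quantile_normalize(n4), n4, tolerance = 0.02)
  expect_warning(quantile_normalize(m4[, 1L, drop = FALSE]), "single sample")
})

# independent enumeration oracle for the conditional split p-value
nb_split_oracle <- function(kA, kB, alpha) {
  s <- kA + kB
  pr <- if (alpha > 0) dnbinom(0:s, size = 1 / alpha, mu = s / 2)
        else dpois(0:s, s / 2)
  joint <- pr * rev(pr)
  obs <- pr[kA + 1L] * pr[kB + 1L]
  sum(joint[joint <= obs * (1 + 1e-10)]) / sum(joint)
}

test_that("NB exact test: equal counts give p = 1; Poisson limit matches enumeration", {
  res <- nb_exact_test(cbind(c(7, 30), c(7, 30)), alpha = 0.1)
  expect_equal(res$p, c(1, 1))
  # kA = 0, kB = 10 in the Poisson limit equals the two-sided conditional
  # binomial tail by full enumeration
  res <- nb_exact_test(cbind(0, 10), alpha = 0)
  expect_equal(res$p, nb_split_oracle(0, 10, 0), tolerance = 1e-12)
  expect_equal(res$p, 2 * dbinom(0, 10, 0.5), tolerance = 1e-10)
  # general agreement with the oracle across random splits and dispersions
  set.seed(9)
  for (i in 1:25) {
    kA <- rpois(1, 60); kB <- rpois(1, 60); a <- runif(1, 0, 0.3)
    expect_equal(nb_exact_test(cbind(kA, kB), alpha = a)$p,
                 nb_split_oracle(kA, kB, a), tolerance = 1e-9)
  }
})

test_that("NB exact test is invariant under sample-label swap and excludes zero rows", {
  set.seed(12)
  k <- matrix(rnbinom(200, mu = 50, size = 5), ncol = 2L)
  k[1L, ] <- 0L
  r1 <- nb_exact_test(k)
  r2 <- nb_exact_test(k[, 2:1])
  expect_equal(r1$p, r2$p)
  expect_true(is.na(r1$p[1L]))
  # BH runs over testable features only
  expect_equal(r1$q[-1L], p.adjust(r1$p[-1L], "BH"))
  expect_true(all(r1$q >= r1$p, na.rm = TRUE))
})

test_that("the pre-mRNA model follows its closed form and grows disproportionally", {
  expect_equal(premrna_intronic_model(0), 0)
  expect_equal(premrna_intronic_model(1, 1 / 20), 0.95)
  expect_equal(premrna_intronic_model(0.05, 1 / 20), 0.0475 / 0.0975)
  expect_equal(premrna_intronic_model(0, 0), 0)
  # strictly increasing in p
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(premrna_intronic_model(p, 1 / 20)) > 0))
  # derivative at 0 is (1 - e) / e = 19 for e = 1/20: the "faster rate"
  h <- 1e-6
  expect_equal(premrna_intronic_model(h, 1 / 20) / h, 19, tolerance = 1e-3)
  # inverse round-trips
  expect_equal(premrna_intronic_model(premrna_fraction_for(0.179)), 0.179)
  expect_equal(premrna_intronic_model(premrna_fraction_for(0.339)), 0.339)
})

test_that("log-scale correlation utility uses jointly nonzero features", {
  x <- c(0, 2, 4, 8); y <- c(1, 4, 8, 0)
  expect_equal(log_expression_cor(x, y), cor(log2(c(2, 4)), log2(c(4, 8))))
})
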