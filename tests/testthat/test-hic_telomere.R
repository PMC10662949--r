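test_that("vc_sqrt matches hand-computed oracles", {
  chroms <- data.frame(name = "c1", length = 30000)
  m3 <- contact_matrix(matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3), 10000,
                       chromosomes = chroms)
  vc <- vc_sqrt_normalize(m3)
  expect_equal(vc$matrix, matrix(c(.5, .25, .25, .25, .5, .25,
                                   .25, .25, .5), 3, 3))
  # constant matrix -> 1/n everywhere
  mc <- contact_matrix(matrix(7, 3, 3), 10000, chromosomes = chroms)
  expect_equal(vc_sqrt_normalize(mc)$matrix, matrix(1 / 3, 3, 3))
  # explicit brute force on a random instance
  rm_ <- random_contact_matrix(c(4, 3), seed = 5)
  got <- vc_sqrt_normalize(rm_)$matrix
  M <- rm_$matrix
  r <- rowSums(M)
  brute <- M
  for (i in 1:7) for (j in 1:7) brute[i, j] <- M[i, j] / sqrt(r[i] * r[j])
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("vc_sqrt is scale invariant and masks zero-marginal rows", {
  for (seed in 1:25) {
    m <- random_contact_matrix(c(5, 4), seed = seed)
    k <- stats::runif(1, 0.1, 50)
    m2 <- m; m2$matrix <- m$matrix * k
    expect_equal(vc_sqrt_normalize(m2)$matrix, vc_sqrt_normalize(m)$matrix,
                 tolerance = 1e-10)
  }
  m <- random_contact_matrix(c(3, 2), seed = 1)
  m$matrix[2, ] <- 0; m$matrix[, 2] <- 0
  vc <- vc_sqrt_normalize(m)
  expect_true(all(is.na(vc$matrix[2, ])))
  expect_true(all(is.na(vc$matrix[, 2])))
  expect_false(anyNA(vc$matrix[-2, -2]))
  # asymmetric input rejected
  bad <- random_contact_matrix(c(3, 2), seed = 2)
  expect_error(contact_matrix(bad$matrix + diag(5) %*%
                                matrix(stats::runif(25), 5, 5),
                              10000, chromosomes = bad$chromosomes),
               "symmetric")
})

test_that("observed/expected matches a brute-force per-diagonal oracle", {
  m <- random_contact_matrix(c(4, 3), seed = 7)
  m$matrix[2, 5] <- m$matrix[5, 2] <- NA  # masking respected
  oe <- observed_over_expected(m)
  M <- m$matrix
  chrom <- m$bins$chromosome
  brute <- matrix(NA_real_, 7, 7)
  for (i in 1:7) for (j in 1:7) {
    if (chrom[i] == chrom[j]) {
      d <- abs(i - j)
      pool <- c()
      for (a in 1:7) for (b in 1:7)
        if (chrom[a] == chrom[b] && abs(a - b) == d)
          pool <- c(pool, M[a, b])
      brute[i, j] <- M[i, j] / mean(pool, na.rm = TRUE)
    } else {
      brute[i, j] <- M[i, j] / mean(M[chrom[row(M)] != chrom[col(M)]],
                                    na.rm = TRUE)
    }
  }
  expect_equal(oe$matrix, brute, tolerance = 1e-12)
  expect_true(is.na(oe$matrix[2, 5]) && is.na(oe$matrix[5, 2]))

  # matrix constant per diagonal -> O/E exactly 1 intra-chromosomally
  n <- 6
  Mc <- outer(1:n, 1:n, function(i, j) 10 / (1 + abs(i - j)))
  mc <- contact_matrix(Mc, 5000,
                       chromosomes = data.frame(name = "c1",
                                                length = n * 5000))
  expect_equal(observed_over_expected(mc)$matrix,
               matrix(1, n, n), tolerance = 1e-12)
})

test_that("distance decay recovers a planted exponent", {
  g <- build_toy_genome()
  m <- simulate_hic(g$target,
                    hic_sim_params(exponent = -1, intra_telomere_gain = 1,
                                   inter_telomere_gain = 1,
                                   centromere_gain = 1, noise = "none"),
                    seed = 1)
  # on the raw expectation matrix the planted decay is strictly monotone
  raw_dc <- distance_decay_curve(m)
  expect_true(all(diff(raw_dc$prob) <= 1e-12))
  dc <- distance_decay_curve(vc_sqrt_normalize(m))
  expect_equal(sum(dc$prob), 1)
  mid <- dc[dc$distance >= 10000 & dc$distance <= 150000, ]
  slope <- unname(stats::coef(stats::lm(log(prob) ~ log(distance),
                                        mid))[2])
  expect_gt(slope, -1.1)
  expect_lt(slope, -0.9)
  # all-equal matrix -> flat series
  flat <- contact_matrix(matrix(2, 5, 5), 1000,
                         chromosomes = data.frame(name = "c", length = 5000))
  expect_true(all(abs(diff(distance_decay_curve(flat)$prob)) < 1e-12))
})

test_that("differential map equals hand-computed log2 ratios", {
  chroms <- data.frame(name = "c1", length = 40000)
  A <- matrix(c(4, 2, 1, 0,
                2, 8, 3, 1,
                1, 3, 2, 2,
                0, 1, 2, 6), 4, 4)
  B <- matrix(c(2, 1, 1, 1,
                1, 4, 1, 3,
                1, 1, 1, 1,
                1, 3, 1, 2), 4, 4)
  ma <- contact_matrix(A, 10000, chromosomes = chroms)
  mb <- contact_matrix(B, 10000, chromosomes = chroms)
  d1 <- differential_map(ma, mb, eps = 1)
  expect_equal(d1$matrix, log2((A + 1) / (B + 1)))
  # a = b -> zeros; a = 2b with eps 0 -> ones
  expect_true(all(differential_map(mb, mb, eps = 0)$matrix == 0))
  m2b <- contact_matrix(2 * B, 10000, chromosomes = chroms)
  expect_true(all(differential_map(m2b, mb, eps = 0)$matrix == 1))
  # geometry mismatch rejected
  expect_error(differential_map(ma, random_contact_matrix(c(3, 2))),
               "mismatch")
})

test_that("rank quantization follows mid-rank scaling and rank invariance", {
  expect_equal(rank_quantize(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(rank_quantize(matrix(c(5, 9, 5, 1), 2, 2)),
               matrix(c(0.5, 1, 0.5, 0), 2, 2))
  for (seed in 1:20) {
    set.seed(seed)
    w <- matrix(stats::rnorm(21 * 21), 21, 21)
    expect_equal(rank_quantize(exp(w)), rank_quantize(w))
    expect_equal(rank_quantize(w * 3 + 17), rank_quantize(w))
    q <- rank_quantize(w)
    expect_true(all(q >= 0 & q <= 1))
  }
  expect_true(all(rank_quantize(matrix(4, 3, 3)) == 0.5))
  allna <- matrix(NA_real_, 2, 2)
  expect_true(all(is.na(rank_quantize(allna))))
  # partial NA preserved
  q <- rank_quantize(c(3, NA, 1, 2))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3, 4)], c(1, 0, 0.5))
})

test_that("telomere aggregation geometry and tie handling are exact", {
  g <- build_toy_genome()
  n <- 180
  const <- contact_matrix(matrix(5, n, n), 5000, genome = g$target)
  st <- telomere_aggregate(const, g$target)
  # (30 - 21 + 1)^2 = 100 frames per pair
  expect_equal(st$intra$n_windows, 3 * 100)
  expect_equal(st$inter$n_windows, 12 * 100)
  expect_equal(st$intra$n_pairs, 3)
  # constant input: raw aggregate constant, quantized uniformly 0.5
  expect_true(all(st$intra$aggregate_raw == 5))
  expect_true(all(st$inter$aggregate_quantized == 0.5))
  expect_true(all(dim(st$intra$aggregate_quantized) == c(21, 21)))
  # window larger than the region is rejected
  expect_error(telomere_aggregate(const, g$target, region_bp = 50000,
                                  window = 21), "fewer bins")
})

test_that("planted corner signal localizes at the repeat-proximal corner", {
  g <- build_toy_genome()
  # strong planted end-end clustering (mutant-like preset); under the
  # wild-type preset the centromere corner of the 150-kb window dominates
  hits <- 0L
  for (seed in 1:10) {
    m <- simulate_hic(g$target, cut14_like_params(), seed = 700 + seed)
    st <- telomere_aggregate(vc_sqrt_normalize(m), g$target)
    ag <- st$inter$aggregate_quantized
    top <- which(ag == max(ag), arr.ind = TRUE)[1, ]
    if (all(top == c(1, 1))) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("aggregation is invariant to stored chromosome orientation", {
  g <- build_toy_genome()
  m <- simulate_hic(g$target, hic_sim_params(total_pairs = 500000),
                    seed = 12)
  vc <- vc_sqrt_normalize(m)
  # mirror chrT1: reverse its bins in the matrix and its feature coords
  idx <- telodisjoin:::.chrom_bin_idx(m, "chrT1")
  perm <- seq_len(nrow(m$matrix))
  perm[idx] <- rev(idx)
  m2 <- vc
  m2$matrix <- vc$matrix[perm, perm]
  g2 <- g$target
  L <- chrom_lengths(g$target)[["chrT1"]]
  sel <- g2$features$chromosome == "chrT1"
  s <- g2$features$start[sel]; e <- g2$features$end[sel]
  g2$features$start[sel] <- L - e
  g2$features$end[sel] <- L - s
  st1 <- telomere_aggregate(vc, g$target)
  st2 <- telomere_aggregate(m2, g2)
  expect_equal(sort(st1$inter$window_scores_quantized),
               sort(st2$inter$window_scores_quantized), tolerance = 1e-12)
  expect_equal(mean(st1$intra$window_scores_raw),
               mean(st2$intra$window_scores_raw), tolerance = 1e-12)
})

test_that("condition comparison reports both variants with sane p-values", {
  g <- build_toy_genome()
  m <- simulate_hic(g$target, hic_sim_params(total_pairs = 500000),
                    seed = 13)
  st <- telomere_aggregate(vc_sqrt_normalize(m), g$target)
  self <- compare_conditions(st, st)
  expect_equal(nrow(self), 4)  # 2 classes x 2 variants
  expect_true(all(self$p.value == 1))  # identical stacks, symmetric U
  expect_true(all(!self$significant))

  # all-greater separation attains the enumeration minimum
  sa <- st; sb <- st
  sa$intra$window_scores_quantized <- 101:104
  sa$intra$window_scores_raw <- 101:104
  sb$intra$window_scores_quantized <- 1:4
  sb$intra$window_scores_raw <- 1:4
  sa$inter <- sa$intra; sb$inter <- sb$intra
  cmp <- compare_conditions(sa, sb, alpha = 0.05)
  oracle <- brute_mw(101:104, 1:4)
  expect_equal(cmp$p.value[1], oracle$p)
  expect_equal(cmp$p.value[1], 2 / choose(8, 4))
})

test_that("contact matrix TSV round-trips", {
  m <- random_contact_matrix(c(4, 3), seed = 9)
  m$condition <- "wt"
  path <- tempfile(fileext = ".tsv")
  write_contact_tsv(m, path)
  back <- read_contact_tsv(path)
  expect_equal(back$matrix, m$matrix, tolerance = 1e-12)
  expect_equal(back$resolution, m$resolution)
  expect_equal(back$chromosomes, m$chromosomes)
  expect_equal(back$condition, "wt")
})
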