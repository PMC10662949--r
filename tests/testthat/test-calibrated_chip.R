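tg <- tiny_genome()

test_that("coverage counts fragment overlaps, matching a brute-force oracle", {
  frag1 <- data.frame(chromosome = "chr1", start = 10, end = 20)
  cov <- coverage_from_fragments(frag1, tg, "IP")
  v <- cov$counts$chr1
  expect_equal(v[11:20], rep(1L, 10))   # 0-based [10,20) -> R index 11:20
  expect_equal(sum(v), 10)

  empty <- coverage_from_fragments(frag1[0, ], tg, "Total")
  expect_equal(track_total(empty), 0)

  set.seed(42)
  frags <- data.frame(chromosome = "chr1",
                      start = s <- sample(0:45, 12, replace = TRUE),
                      end = s + sample(3:10, 12, replace = TRUE))
  small <- genome_model("target", data.frame(name = "chr1", length = 60),
                        data.frame(chromosome = "chr1", start = 10,
                                   end = 20, strand = "+", class = "gene",
                                   name = "g1"))
  got <- coverage_from_fragments(frags, small, "IP")$counts$chr1
  expect_equal(as.numeric(got), brute_coverage(frags, 60))

  # binned counts are overlap counts, not per-base sums
  binned <- coverage_from_fragments(frags, small, "IP", bin_size = 20)
  expect_equal(as.numeric(binned$counts$chr1),
               vapply(c(0, 20, 40), function(b)
                 sum(frags$start < b + 20 & frags$end > b), numeric(1)))

  expect_error(coverage_from_fragments(
    data.frame(chromosome = "chr1", start = -5, end = 10), tg, "IP"),
    "row")
})

test_that("calibration factor is Total/IP on the spike-in", {
  gsp <- genome_model("spikein", data.frame(name = "s1", length = 1000),
                      data.frame(chromosome = "s1", start = 100, end = 200,
                                 strand = ".", class = "control_locus",
                                 name = "ctl"))
  mk <- function(n) data.frame(chromosome = rep("s1", n),
                               start = rep(0, n), end = rep(50, n))
  ip <- coverage_from_fragments(mk(1000), gsp, "IP")
  tot <- coverage_from_fragments(mk(2000), gsp, "Total")
  expect_equal(calibration_factor(ip, tot), 2.0)
  expect_equal(calibration_factor(ip, ip), 1.0)
  expect_error(calibration_factor(coverage_from_fragments(mk(0), gsp, "IP"),
                                  tot), "zero spike-in IP")
  # target tracks are rejected
  tt <- coverage_from_fragments(
    data.frame(chromosome = "chr1", start = 0, end = 10), tg, "IP")
  expect_error(calibration_factor(tt, tot), "spike-in")
})

test_that("calibrated ratio formula, floor and masking behave", {
  frag <- data.frame(chromosome = "chr1",
                     start = rep(seq(0, 49900, by = 100), each = 10),
                     end = rep(seq(0, 49900, by = 100), each = 10) + 100)
  ip <- coverage_from_fragments(frag, tg, "IP")
  tot <- coverage_from_fragments(frag, tg, "Total")
  r <- calibrated_ratio(ip, tot, alpha = 1, pseudocount = 7)
  expect_true(all(abs(r$ratios$chr1 - 1) < 1e-12))  # IP == Total -> R = 1

  # all-zero IP with pseudocount 1: R = 1/(T+1) <= 1
  ip0 <- coverage_from_fragments(frag[0, ], tg, "IP")
  r0 <- calibrated_ratio(ip0, tot, alpha = 1, pseudocount = 1)
  ok <- !is.na(r0$ratios$chr1)
  expect_true(all(r0$ratios$chr1[ok] <= 1))
  expect_equal(r0$ratios$chr1[ok],
               1 / (tot$counts$chr1[ok] + 1))

  # low-coverage floor masks, never zeroes
  rf <- calibrated_ratio(ip, tot, alpha = 1, total_floor = 1e6)
  expect_true(all(is.na(rf$ratios$chr1)))

  # scale invariance: common factor cancels exactly at pseudocount 0
  frag2 <- rbind(frag, frag, frag)
  ip2 <- coverage_from_fragments(frag2, tg, "IP")
  tot2 <- coverage_from_fragments(frag2, tg, "Total")
  ra <- calibrated_ratio(ip, tot, alpha = 1.7, pseudocount = 0)
  rb <- calibrated_ratio(ip2, tot2, alpha = 1.7, pseudocount = 0)
  expect_equal(ra$ratios$chr1, rb$ratios$chr1)

  expect_error(calibrated_ratio(ip, coverage_from_fragments(
    frag, tg, "Total", bin_size = 10), alpha = 1), "geometries")
})

test_that("masked positions never contribute to summaries", {
  frag <- data.frame(chromosome = "chr1",
                     start = rep(seq(0, 49900, by = 100), each = 10),
                     end = rep(seq(0, 49900, by = 100), each = 10) + 100)
  ip <- coverage_from_fragments(frag, tg, "IP")
  tot <- coverage_from_fragments(frag, tg, "Total")
  mask <- telomere_mask(tg, data.frame(chromosome = "chr1", side = "right",
                                       boundary = 48500))
  r <- calibrated_ratio(ip, tot, alpha = 1, mask = mask)
  # sentinel injection: poison the masked region of the IP counts instead
  ip_poison <- ip
  ip_poison$counts$chr1[48501:50000] <- 1e9
  rp <- calibrated_ratio(ip_poison, tot, alpha = 1, mask = mask)
  expect_equal(feature_class_means(rp, tg), feature_class_means(r, tg))
  mg <- metagene_profile(r, tg$features)
  mgp <- metagene_profile(rp, tg$features)
  expect_equal(mgp$mean, mg$mean)
  expect_true(all(is.na(rp$ratios$chr1[48501:50000])))
})

test_that("spike-in calibration cancels a global IP-efficiency change", {
  genomes <- build_toy_genome()
  run_one <- function(eff) {
    prof <- enrichment_profile(ip_depth = 120000, total_depth = 120000,
                               ip_efficiency = eff)
    sim <- simulate_chip(genomes, prof, seed = 31)
    ip_t <- coverage_from_fragments(sim$ip_target, genomes$target, "IP")
    tot_t <- coverage_from_fragments(sim$total_target, genomes$target,
                                     "Total")
    ip_s <- coverage_from_fragments(sim$ip_spike, genomes$spikein, "IP")
    tot_s <- coverage_from_fragments(sim$total_spike, genomes$spikein,
                                     "Total")
    a <- calibration_factor(ip_s, tot_s)
    rt <- calibrated_ratio(ip_t, tot_t, a, pseudocount = 0)
    fc <- feature_class_means(rt, genomes$target)
    # uncalibrated counterpart: alpha forced to 1
    ru <- calibrated_ratio(ip_t, tot_t, 1, pseudocount = 0)
    fu <- feature_class_means(ru, genomes$target)
    list(alpha = a, cal = fc[["telomere_repeat"]],
         uncal = fu[["telomere_repeat"]])
  }
  full <- run_one(1)
  half <- run_one(0.5)
  expect_equal(half$alpha / full$alpha, 2, tolerance = 0.05)
  expect_equal(half$cal / full$cal, 1, tolerance = 0.05)
  expect_equal(half$uncal / full$uncal, 0.5, tolerance = 0.05)
})

test_that("qPCR normalization divides by the control and summarizes", {
  rec <- data.frame(
    locus = rep("telo", 3), percent_ip = c(0.04, 0.05, 0.03),
    control_percent_ip = c(0.02, 0.02, 0.02),
    condition = "wt", replicate = 1:3)
  out <- qpcr_normalize(rec)
  expect_equal(out$per_replicate$normalized, c(2.0, 2.5, 1.5))
  expect_equal(out$summary$mean, 2.0)
  expect_equal(out$summary$sd, 0.5)   # n-1 sample SD, hand-computed
  expect_equal(out$summary$n, 3)

  # locus equal to control
  rec1 <- data.frame(locus = "x", percent_ip = 0.02,
                     control_percent_ip = 0.02, condition = "wt",
                     replicate = 1)
  expect_equal(qpcr_normalize(rec1)$per_replicate$normalized, 1.0)

  # unit invariance
  rec_scaled <- rec
  rec_scaled$percent_ip <- rec$percent_ip * 100
  rec_scaled$control_percent_ip <- rec$control_percent_ip * 100
  expect_equal(qpcr_normalize(rec_scaled)$summary,
               qpcr_normalize(rec)$summary)

  # zero control excluded with a warning
  rec_bad <- rbind(rec, data.frame(locus = "telo", percent_ip = 0.04,
                                   control_percent_ip = 0, condition = "wt",
                                   replicate = 4))
  expect_warning(out2 <- qpcr_normalize(rec_bad), "excluded")
  expect_equal(nrow(out2$per_replicate), 3)
})

test_that("metagene profile matches a brute-force per-gene rescaler", {
  L <- 4000
  g <- genome_model("target", data.frame(name = "chr1", length = L),
                    data.frame(chromosome = "chr1",
                               start = c(1000, 2400),
                               end = c(1600, 3000),
                               strand = c("+", "-"),
                               class = "gene", name = c("gp", "gm")))
  # step track: value = floor(position / 100)
  vals <- floor((seq_len(L) - 1) / 100)
  rt <- structure(list(species = "target",
                       ratios = list(chr1 = as.numeric(vals)),
                       bin_size = 1L, alpha = 1, pseudocount = 0,
                       total_floor = 0, n_masked = 0),
                  class = "ratio_track")
  body_bins <- 6; flank_bp <- 200; flank_bins <- 4
  prof <- metagene_profile(rt, g$features, body_bins, flank_bp, flank_bins)

  brute_gene <- function(s, e, strand) {
    v <- rt$ratios$chr1
    fw <- flank_bp / flank_bins
    bin_mean <- function(a, b) mean(v[(floor(a) + 1):ceiling(b)])
    up <- sapply(0:(flank_bins - 1), function(k)
      bin_mean(s - flank_bp + k * fw, s - flank_bp + (k + 1) * fw))
    bd <- sapply(0:(body_bins - 1), function(k)
      bin_mean(s + k * (e - s) / body_bins,
               s + (k + 1) * (e - s) / body_bins))
    dn <- sapply(0:(flank_bins - 1), function(k)
      bin_mean(e + k * fw, e + (k + 1) * fw))
    out <- c(up, bd, dn)
    if (strand == "-") rev(out) else out
  }
  expected <- colMeans(rbind(brute_gene(1000, 1600, "+"),
                             brute_gene(2400, 3000, "-")))
  expect_equal(prof$mean, expected)

  # constant track gives a flat profile; strand orientation symmetric
  rt$ratios$chr1 <- rep(3.7, L)
  flat <- metagene_profile(rt, g$features, body_bins, flank_bp, flank_bins)
  expect_true(all(abs(flat$mean - 3.7) < 1e-12))
})

test_that("bedGraph writer merges runs and omits masked positions", {
  rt <- structure(list(species = "target",
                       ratios = list(chr1 = c(1, 1, NA, 2, 2, 2)),
                       bin_size = 1L, alpha = 1, pseudocount = 0,
                       total_floor = 0, n_masked = 1),
                  class = "ratio_track")
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(rt, path)
  expect_equal(readLines(path), c("chr1\t0\t2\t1", "chr1\t3\t6\t2"))
})
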