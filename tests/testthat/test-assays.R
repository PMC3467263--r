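ct_table <- function(samples, groups, target_ct, hk_ct,
                     target = "NDRG2", hk = "TBP") {
  rbind(data.frame(sample_id = samples, group = groups, gene = target, ct = target_ct),
        data.frame(sample_id = samples, group = groups, gene = hk, ct = hk_ct))
}

test_that("ddct_fold implements 2^-(dCt - mean control dCt)", {
  # identical Cts everywhere -> all folds 1
  tab <- ct_table(paste0("s", 1:6), rep(c("DMSO", "PX"), each = 3), 25, 20)
  r <- ddct_fold(tab, "NDRG2", "TBP", control_group = "DMSO")
  expect_equal(r$samples$fold, rep(1, 6))
  expect_equal(r$groups$mean_fold, c(1, 1))

  # treated target exactly 1 cycle lower, housekeeping equal -> fold 2
  tab2 <- ct_table(paste0("s", 1:6), rep(c("DMSO", "PX"), each = 3),
                   c(25, 25, 25, 24, 24, 24), 20)
  r2 <- ddct_fold(tab2, "NDRG2", "TBP", control_group = "DMSO")
  expect_equal(r2$groups$mean_fold[r2$groups$group == "PX"], 2)
  expect_equal(r2$groups$mean_fold[r2$groups$group == "DMSO"], 1)
})

test_that("ddct_fold matches a spreadsheet-style oracle on randomised tables", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    samples <- paste0("s", 1:n)
    groups <- sample(c("ctl", "trt"), n, replace = TRUE)
    groups[1:2] <- c("ctl", "trt")  # both groups nonempty
    tct <- runif(n, 18, 30); hct <- runif(n, 15, 22)
    r <- ddct_fold(ct_table(samples, groups, tct, hct), "NDRG2", "TBP", "ctl")
    # independent arithmetic
    dct <- tct - hct
    fold <- 2^(-(dct - mean(dct[groups == "ctl"])))
    expect_equal(r$samples$fold[match(samples, r$samples$sample_id)], fold,
                 tolerance = 1e-12)
    sem <- tapply(fold, groups, function(x) sd(x) / sqrt(length(x)))
    expect_equal(r$groups$sem[match(names(sem), r$groups$group)], as.numeric(sem),
                 tolerance = 1e-12)
  }
})

test_that("ddct_fold is invariant to a per-sample shift of both Cts", {
  set.seed(62)
  samples <- paste0("s", 1:6); groups <- rep(c("ctl", "trt"), 3)
  tct <- runif(6, 20, 28); hct <- runif(6, 16, 20); shift <- runif(6, -3, 3)
  r0 <- ddct_fold(ct_table(samples, groups, tct, hct), "NDRG2", "TBP", "ctl")
  r1 <- ddct_fold(ct_table(samples, groups, tct + shift, hct + shift),
                  "NDRG2", "TBP", "ctl")
  expect_equal(r0$samples$fold, r1$samples$fold, tolerance = 1e-12)
})

test_that("ddct_fold names the sample missing its housekeeping Ct", {
  tab <- ct_table(paste0("s", 1:4), rep(c("ctl", "trt"), 2), 25, 20)
  tab <- tab[!(tab$sample_id == "s3" & tab$gene == "TBP"), ]
  expect_error(ddct_fold(tab, "NDRG2", "TBP", "ctl"), "s3")
})

test_that("rla_fold is the ratio of mean firefly/Renilla ratios", {
  wells <- data.frame(well_id = paste0("w", 1:6),
                      condition = rep(c("DMSO", "PX"), each = 3),
                      firefly = c(100, 110, 90, 100, 110, 90),
                      renilla = c(10, 11, 9, 10, 11, 9))
  expect_equal(rla_fold(wells, "PX", "DMSO")$fold, 1)

  wells$firefly[4:6] <- wells$firefly[4:6] * 3
  expect_equal(rla_fold(wells, "PX", "DMSO")$fold, 3)

  # unbalanced replicate counts against an independent oracle
  set.seed(63)
  w2 <- data.frame(well_id = paste0("w", 1:7),
                   condition = c(rep("DMSO", 4), rep("PX", 3)),
                   firefly = runif(7, 50, 500), renilla = runif(7, 5, 50))
  got <- rla_fold(w2, "PX", "DMSO")$fold
  want <- mean(w2$firefly[5:7] / w2$renilla[5:7]) / mean(w2$firefly[1:4] / w2$renilla[1:4])
  expect_equal(got, want, tolerance = 1e-12)

  # common per-condition scale factors cancel
  w3 <- w2
  w3[w3$condition == "PX", c("firefly", "renilla")] <-
    w3[w3$condition == "PX", c("firefly", "renilla")] * 7.5
  expect_equal(rla_fold(w3, "PX", "DMSO")$fold, got, tolerance = 1e-12)

  w2$renilla[1] <- 0
  expect_error(rla_fold(w2, "PX", "DMSO"), "positive")
})

test_that("insilico_pcr sizes products from exact primer footprints", {
  f <- "GAACTGATGCCCTTGTAGCC"; r <- "CAACGAGGTGAATGACATGG"
  tpl <- paste0(f, strrep("A", 10), revcomp(r))
  p <- insilico_pcr(tpl, f, r)
  expect_equal(p$length, nchar(f) + 10L + nchar(r))

  expect_equal(nrow(insilico_pcr(strrep("ACGT", 30), f, r)), 0L)
  expect_equal(nrow(insilico_pcr(paste0(f, strrep("A", 30)), f, r)), 0L)

  # two reverse sites -> two products with arithmetic lengths
  tpl2 <- paste0(f, strrep("C", 8), revcomp(r), strrep("T", 5), revcomp(r))
  p2 <- insilico_pcr(tpl2, f, r)
  expect_equal(p2$length, c(20L + 8L + 20L, 20L + 8L + 20L + 5L + 20L))

  # product length invariant under flanking sequence without primer sites
  p3 <- insilico_pcr(paste0(strrep("G", 40), tpl, strrep("G", 25)), f, r)
  expect_equal(p3$length, p$length)
})

test_that("unpaired_t matches the closed-form pooled statistic", {
  a <- c(1.1, 2.3, 3.7, 2.9); b <- c(4.0, 5.2, 6.1)
  got <- unpaired_t(a, b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_hand <- 2 * pt(-abs(t_hand), df = length(a) + length(b) - 2)
  expect_equal(got$statistic, t_hand, tolerance = 1e-9)
  expect_equal(got$p_value, p_hand, tolerance = 1e-9)

  # identical groups
  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")

  # a large shift is highly significant
  expect_equal(unpaired_t(c(1, 2, 3), c(1, 2, 3) + 100)$stars, "***")

  # symmetry: swapping groups negates t, preserves p
  swapped <- unpaired_t(b, a)
  expect_equal(swapped$statistic, -got$statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)

  expect_error(unpaired_t(c(1, 1, 1), c(2, 2, 2)), "undefined")
  expect_error(unpaired_t(1, c(1, 2)))

  welch <- unpaired_t(a, b, welch = TRUE)
  expect_equal(welch$statistic, unname(t.test(a, b)$statistic), tolerance = 1e-12)
})

test_that("significance stars follow the 0.05/0.01/0.001 convention", {
  expect_equal(significance_stars(c(0.2, 0.049, 0.009, 0.0009)),
               c("ns", "*", "**", "***"))
  expect_equal(significance_stars(c(0.05, 0.01, 0.001)), c("ns", "*", "**"))
})
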