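test_that("orthogonal causal variants keep marginal betas under conditioning", {
  pan <- orthogonal_panel()
  y <- 0.4 * pan$dosages[, "s1"] - 0.3 * pan$dosages[, "s2"]  # noiseless
  ss <- sumstats_of(pan, y)
  ss$p <- pmax(ss$p, 1e-300)
  sel <- cojo_select(ss, pan, p_threshold = 1e-4)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$bC, sel$beta, tolerance = 1e-6)
  expect_equal(sel$bJ, sel$beta, tolerance = 1e-6)
})

test_that("perfect-LD duplicates trigger the collinearity exclusion", {
  withr::local_seed(31)
  g <- rbinom(400, 2, 0.3)
  pan <- as_ld_panel(cbind(d1 = g, d2 = g, ind = rbinom(400, 2, 0.3)),
                     tibble::tibble(marker = c("d1", "d2", "ind"), chr = "1",
                                    pos = c(1e6, 1.001e6, 1.002e6)))
  y <- 0.5 * g + rnorm(400, 0, 0.5)
  ss <- sumstats_of(pan, y)
  sel <- cojo_select(ss, pan, p_threshold = 1e-4)
  expect_equal(sum(sel$marker %in% c("d1", "d2")), 1)
})

test_that("joint estimates equal exact multiple-regression OLS on the sample", {
  pan <- simulate_ld_panel(2000, ld_blocks(80, 0.1, 0.5, 0.9), seed = 32)
  y <- simulate_phenotype(pan, betas = c(var000020 = 0.3, var000060 = 0.25),
                          seed = 33)
  ss <- sumstats_of(pan, y)
  sel <- cojo_select(ss, pan)
  expect_equal(nrow(sel), 2)
  ols <- coef(lm(y ~ pan$dosages[, sel$marker]))[-1]
  expect_lt(max(abs(sel$bJ - ols)), 1e-6)
})

test_that("selection respects the signal cap and is order-invariant", {
  pan <- simulate_ld_panel(3000, ld_blocks(60, 0.1, 0.5, 0.5), seed = 34)
  betas <- setNames(c(0.3, 0.28, 0.26, 0.24, 0.22),
                    pan$variants$marker[c(5, 15, 25, 35, 45)])
  y <- simulate_phenotype(pan, betas = betas, seed = 35)
  ss <- sumstats_of(pan, y)
  sel <- cojo_select(ss, pan, max_signals = 3)
  expect_lte(nrow(sel), 3)
  shuf <- cojo_select(ss[sample(nrow(ss)), ], pan, max_signals = 3)
  expect_identical(sel$marker, shuf$marker)
  expect_equal(sel$bJ, shuf$bJ, tolerance = 1e-12)
})

test_that("no-significant-variant windows return an empty signal set", {
  pan <- simulate_ld_panel(500, ld_blocks(20, 0.1, 0.5, 0), seed = 36)
  y <- simulate_phenotype(pan, seed = 37)
  sel <- cojo_select(sumstats_of(pan, y), pan)
  expect_equal(nrow(sel), 0)
})

test_that("single planted causal yields exactly one signal almost always", {
  # beta 0.3 at MAF >= 0.3 and n = 2,000 puts the causal z around 8.7, so
  # planted power exceeds 0.999; selection should find one and only one signal
  pan <- simulate_ld_panel(600, ld_blocks(30, 0.30, 0.45, 0.8), seed = 38)
  withr::local_seed(39)
  n_sig <- replicate(200, {
    coh <- regenerate_panel(pan, 2000)
    y <- simulate_phenotype(coh, betas = c(var000015 = 0.3))
    nrow(cojo_select(sumstats_of(coh, y), coh))
  })
  expect_gte(mean(n_sig == 1), 0.95)
})

test_that("conditional p of the primary equals marginal p when alone", {
  pan <- simulate_ld_panel(2000, ld_blocks(40, 0.2, 0.4, 0.8), seed = 40)
  y <- simulate_phenotype(pan, betas = c(var000020 = 0.25), seed = 41)
  ss <- sumstats_of(pan, y)
  sel <- cojo_select(ss, pan)
  expect_equal(nrow(sel), 1)
  expect_identical(sel$pC, sel$p)
  expect_identical(sel$bC, sel$beta)
})

test_that("consensus requires two panels and groups proxies", {
  sig <- function(marker, pC, panel) {
    tibble::tibble(marker = marker, chr = "1", pos = 1e6, ea = "G", nea = "A",
                   eaf = 0.3, beta = 0.1, se = 0.01, p = pC,
                   bJ = 0.1, bJ_se = 0.01, pJ = pC,
                   bC = 0.1, bC_se = 0.01, pC = pC,
                   ld_with_primary = 1, step = 1L, panel = panel)
  }
  withr::local_seed(42)
  g <- rbinom(500, 2, 0.4)
  flip <- rbinom(500, 1, 0.02)
  g2 <- ifelse(flip == 1, sample(0:2, 500, TRUE), g)        # r2 ~ 0.95
  g3 <- rbinom(500, 2, 0.4)                                  # independent
  pan <- as_ld_panel(cbind(p1 = g, p2 = as.integer(g2), q1 = g3),
                     tibble::tibble(marker = c("p1", "p2", "q1"), chr = "1",
                                    pos = c(1e6, 1.01e6, 1.02e6)))
  expect_gt(panel_r2(pan, "p1", "p2"), 0.8)

  per_panel <- list(
    A = dplyr::bind_rows(sig("p1", 1e-10, "A"), sig("q1", 1e-9, "A")),
    B = sig("p2", 1e-12, "B"),
    C = sig("p1", 1e-11, "C"))
  cons <- consensus_signals(per_panel, pan)
  expect_equal(nrow(cons), 1)                   # q1 seen in one panel only
  expect_identical(cons$marker, "p2")           # smallest conditional p
  expect_setequal(cons$panel_support[[1]], c("A", "B", "C"))
  rej <- attr(cons, "rejected")
  expect_identical(rej$marker, "q1")
})

test_that("many-signal panels collapse to few consensus groups", {
  # one strong locus: the three panels report 5, 7, and 9 signals, but only
  # proxies of three true signals recur across panels; the rest are
  # panel-private noise picks, so consensus keeps exactly three groups
  withr::local_seed(43)
  n <- 600
  truth <- sapply(1:3, function(i) rbinom(n, 2, 0.4))
  copies <- truth  # r2 = 1 proxies of the true signals, different markers
  noise <- sapply(1:12, function(i) rbinom(n, 2, 0.4))
  dos <- cbind(truth, copies, noise)
  mk <- c(sprintf("t%d", 1:3), sprintf("t%db", 1:3), sprintf("x%02d", 1:12))
  colnames(dos) <- mk
  pan <- as_ld_panel(dos, tibble::tibble(marker = mk, chr = "1",
                                         pos = seq(1e6, by = 1e4,
                                                   length.out = length(mk))))
  sig_row <- function(marker, pC, panel) {
    tibble::tibble(marker = marker, pC = pC, panel = panel)
  }
  per_panel <- list(
    A = dplyr::bind_rows(purrr::map2(
      c("t1", "t2", "t3", "x01", "x02"), 1e-9, sig_row, panel = "A")),
    B = dplyr::bind_rows(purrr::map2(
      c("t1b", "t2b", "t3b", "x03", "x04", "x05", "x06"), 1e-10, sig_row,
      panel = "B")),
    C = dplyr::bind_rows(purrr::map2(
      c("t1", "t2", "t3", "x07", "x08", "x09", "x10", "x11", "x12"), 1e-9,
      sig_row, panel = "C")))
  cons <- consensus_signals(per_panel, pan)
  expect_equal(nrow(cons), 3)
  expect_setequal(cons$marker, c("t1b", "t2b", "t3b"))  # smallest pC members
})

test_that("MAF-consistency screen matches its examples", {
  mk_panel <- function(freq, marker = "m") {
    as_ld_panel(matrix(rbinom(4000, 2, freq), ncol = 1,
                       dimnames = list(NULL, marker)),
                tibble::tibble(marker = marker, chr = "1", pos = 1e6))
  }
  withr::local_seed(45)
  sig <- tibble::tibble(marker = "m", eaf = 0.12)
  low <- list(a = mk_panel(0.008), b = mk_panel(0.009))
  expect_false(maf_consistency(sig, low)$keep)

  consistent <- tibble::tibble(marker = "m", eaf = 0.30)
  near <- list(a = mk_panel(0.29), b = mk_panel(0.31), c = mk_panel(0.30))
  expect_true(maf_consistency(consistent, near)$keep)

  single <- list(a = mk_panel(0.10))
  expect_true(maf_consistency(sig, single)$keep)

  absent <- maf_consistency(sig, list(a = mk_panel(0.3, marker = "other")))
  expect_false(absent$keep)
  expect_identical(absent$reason, "no panel frequency")
})
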