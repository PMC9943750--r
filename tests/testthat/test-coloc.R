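# shared fixtures: two expression/trait cohorts drawn from one population
coloc_cohorts <- local({
  pop <- NULL
  function() {
    if (is.null(pop)) {
      pop <<- simulate_ld_panel(400, ld_blocks(60, 0.2, 0.45, 0.9), seed = 61)
    }
    pop
  }
})

trait_pair <- function(pop, causal_a, causal_b, beta = 0.35, n = 2000) {
  bts <- function(cv) if (is.null(cv)) NULL else setNames(beta, cv)
  ca <- regenerate_panel(pop, n)
  cb <- regenerate_panel(pop, n)
  ya <- simulate_phenotype(ca, betas = bts(causal_a))
  yb <- simulate_phenotype(cb, betas = bts(causal_b))
  list(a = sumstats_of(ca, ya), b = sumstats_of(cb, yb))
}

test_that("Wakefield ABF matches direct evaluation and limits", {
  # high-precision direct evaluation of the closed form
  beta <- 0.1; se <- 0.02; W <- 0.15^2
  expect_equal(trait_abf(beta, se, 0.15),
               0.5 * (log(se^2 / (se^2 + W)) +
                        W * (beta / se)^2 / (se^2 + W)),
               tolerance = 1e-15)
  # null variant is disfavoured; degenerate prior gives no evidence
  expect_lt(trait_abf(0, 0.1, 0.15), 0)
  expect_equal(trait_abf(0.3, 0.1, 1e-12), 0, tolerance = 1e-6)
  expect_error(trait_abf(0.1, 0), "> 0")
})

test_that("pairwise posteriors equal the brute-force enumeration oracle", {
  withr::local_seed(62)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    a <- tibble::tibble(marker = sprintf("v%03d", 1:n),
                        beta = rnorm(n, 0, 0.2), se = runif(n, 0.02, 0.2))
    b <- tibble::tibble(marker = a$marker,
                        beta = rnorm(n, 0, 0.2), se = runif(n, 0.02, 0.2))
    res <- suppressWarnings(coloc_pair(a, b))
    oracle <- coloc_bruteforce(trait_abf(a$beta, a$se),
                               trait_abf(b$beta, b$se),
                               p1 = 1e-4, p2 = 1e-4, p12 = 1e-5)
    got <- unlist(res[1, c("pp0", "pp1", "pp2", "pp3", "pp4")])
    expect_lt(max(abs(got - oracle)), 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-10)
  }
})

test_that("null traits concentrate on H0", {
  withr::local_seed(63)
  a <- tibble::tibble(marker = sprintf("v%03d", 1:100),
                      beta = rnorm(100, 0, 0.01), se = 0.05)
  b <- dplyr::mutate(a, beta = rnorm(100, 0, 0.01))
  res <- coloc_pair(a, b)
  expect_gt(res$pp0, 0.9)
})

test_that("shared vs distinct causal variants are separated reliably", {
  pop <- coloc_cohorts()
  withr::local_seed(64)
  shared <- replicate(100, {
    tp <- trait_pair(pop, "var000030", "var000030")
    suppressWarnings(coloc_pair(tp$a, tp$b))$pp4
  })
  expect_gte(mean(shared > 0.95), 0.9)

  distinct <- replicate(100, {
    # causal variants at opposite ends of the block: r2 well under 0.05
    tp <- trait_pair(pop, "var000005", "var000055")
    res <- suppressWarnings(coloc_pair(tp$a, tp$b))
    res$pp3 > res$pp4
  })
  expect_gte(mean(distinct), 0.9)
})

test_that("PP4 is non-decreasing in the colocalization prior", {
  pop <- coloc_cohorts()
  withr::local_seed(65)
  tp <- trait_pair(pop, "var000030", "var000030")
  grid <- 10^seq(-8, -4, length.out = 100)
  pp4 <- sapply(grid, function(p12) {
    suppressWarnings(coloc_pair(tp$a, tp$b, p12 = p12))$pp4
  })
  expect_true(all(diff(pp4) >= -1e-12))
})

test_that("multi-trait colocalization matches pairwise calls and truth", {
  pop <- coloc_cohorts()
  withr::local_seed(66)
  # cross-method concordance over loci spanning shared/distinct/null truths
  agree <- replicate(70, {
    kind <- sample(c("shared", "distinct", "null"), 1)
    tp <- switch(kind,
      shared = trait_pair(pop, "var000030", "var000030"),
      distinct = trait_pair(pop, "var000005", "var000055"),
      null = trait_pair(pop, NULL, NULL))
    pair_call <- suppressWarnings(coloc_pair(tp$a, tp$b))$pp4 > 0.6
    mc <- multi_coloc(list(A = tp$a, B = tp$b))
    multi_call <- any(mc$selected & mc$n_traits == 2)
    pair_call == multi_call
  })
  expect_gte(mean(agree), 0.95)

  # three traits sharing one causal variant form a full cluster
  three <- replicate(30, {
    tp <- trait_pair(pop, "var000030", "var000030")
    cc <- regenerate_panel(pop, 2000)
    yc <- simulate_phenotype(cc, betas = c(var000030 = 0.35))
    mc <- multi_coloc(list(A = tp$a, B = tp$b, C = sumstats_of(cc, yc)))
    full <- mc[mc$n_traits == 3, ]
    full$selected & full$ppfc > 0.6
  })
  expect_gte(mean(three), 0.9)

  # distinct causal variants: no full-cluster colocalization
  none <- replicate(30, {
    tp <- trait_pair(pop, "var000005", "var000055")
    mc <- multi_coloc(list(A = tp$a, B = tp$b))
    !any(mc$selected)
  })
  expect_gte(mean(none), 0.9)

  expect_error(multi_coloc(list(A = tibble::tibble(marker = "x", beta = 1,
                                                   se = 1))), ">= 2")
})

test_that("sensitivity score is the passing fraction of the grid", {
  pop <- coloc_cohorts()
  withr::local_seed(67)
  tp <- trait_pair(pop, "var000030", "var000030", beta = 0.5)
  s <- sensitivity_score(list(tp$a, tp$b), engine = "pair")
  expect_equal(as.numeric(s), 1)
  runs <- attr(s, "runs")
  expect_equal(nrow(runs), 100)
  expect_equal(as.numeric(s), mean(runs$pass))

  tp0 <- trait_pair(pop, NULL, NULL)
  expect_equal(as.numeric(sensitivity_score(list(tp0$a, tp0$b),
                                            engine = "pair")), 0)

  sm <- sensitivity_score(list(A = tp$a, B = tp$b), engine = "multi")
  expect_equal(nrow(attr(sm, "runs")), 64)
  expect_gte(as.numeric(sm), 0.9)
})

test_that("composite decision rule boundary cases", {
  expect_true(coloc_decision(0.7, 0.5, 0.3))          # sensitivity branch
  expect_false(coloc_decision(0.5, 1.0, 0.95))        # pp gate fails
  expect_true(coloc_decision(0.9, 0.2, 0.85))         # LD branch
  expect_false(coloc_decision(0.9, 0.2, 0.8))         # r2 strictly > 0.8
  expect_false(coloc_decision(0.6, 1.0, 1.0))         # pp strictly > 0.6
  expect_false(coloc_decision(0.9, 0.4, 0.5))         # sens strictly > 0.4
  expect_message(out <- coloc_decision(0.9, 0.5, NA), "treated as 0")
  expect_true(out)
})

test_that("direction-of-effect consensus rules", {
  lk <- function(...) {
    tibble::tibble(trait = c("T2D", "FG", "FI", "HbA1c", "2hGlu"), ...)
  }
  # primary: T2D association sets the sign
  expect_identical(
    classify_direction(lk(beta = c(0.2, 0, 0, 0, 0),
                          p = c(1e-6, 0.5, 0.5, 0.5, 0.5)))$direction,
    "higher")
  # nothing qualifies
  res <- classify_direction(lk(beta = rep(0.1, 5), p = rep(0.5, 5)))
  expect_identical(res$direction, "unclassified")
  expect_identical(res$rule, "none")
  # fallback: two lenient outcomes sharing a sign
  fb <- classify_direction(lk(beta = c(0, 0, 0.1, 0.2, 0),
                              p = c(0.9, 0.9, 0.005, 0.008, 0.9)))
  expect_identical(fb$direction, "higher")
  expect_identical(fb$rule, "fallback")
  # conflicting primary signs
  cf <- classify_direction(lk(beta = c(0.2, -0.3, 0, 0, 0),
                              p = c(1e-6, 1e-7, 0.5, 0.5, 0.5)))
  expect_identical(cf$direction, "unclassified")
  expect_true(cf$conflict)
  # a single lenient outcome is not enough
  one <- classify_direction(lk(beta = c(0, 0, -0.1, 0, 0),
                               p = c(0.9, 0.9, 0.005, 0.9, 0.9)))
  expect_identical(one$direction, "unclassified")
})

test_that("planted half/half split reproduces the direction table", {
  # ten loci: five with glucose-raising/proinsulin-raising alleles, five
  # opposite; the consensus classifier recovers the 5/5 split
  withr::local_seed(68)
  out <- purrr::map_chr(1:10, function(i) {
    sign <- if (i <= 5) 1 else -1
    lk <- tibble::tibble(trait = c("T2D", "FG", "FI", "HbA1c", "2hGlu"),
                         beta = c(0.1, sign * 0.1, 0, 0, 0),
                         p = c(0.5, 1e-6, 0.5, 0.5, 0.5))
    classify_direction(lk)$direction
  })
  expect_equal(sum(out == "higher"), 5)
  expect_equal(sum(out == "lower"), 5)
})
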