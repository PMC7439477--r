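# Competitive indices, Dunnett comparisons, passage trajectory summaries.

mkTable <- function(gutCounts, inocCounts, flask = "F1") {
  gut <- data.frame(flask_id = flask, gut_id = seq_len(nrow(gutCounts)),
                    count_comp1 = gutCounts[, 1],
                    count_comp2 = gutCounts[, 2],
                    inoc_rep = NA_integer_, inoc_count_comp1 = NA_real_,
                    inoc_count_comp2 = NA_real_, dilution = 1)
  inoc <- data.frame(flask_id = flask, gut_id = NA_integer_,
                     count_comp1 = NA_real_, count_comp2 = NA_real_,
                     inoc_rep = seq_len(nrow(inocCounts)),
                     inoc_count_comp1 = inocCounts[, 1],
                     inoc_count_comp2 = inocCounts[, 2], dilution = 1)
  rbind(gut, inoc)
}

test_that("competitive index follows the mean-inoculum-ratio formula", {
  t1 <- mkTable(cbind(100, 100), cbind(c(50, 50, 50), c(50, 50, 50)))
  expect_equal(competitiveIndex(t1)$ci, 1.0)
  t2 <- mkTable(cbind(200, 50), cbind(c(40, 50, 60), c(40, 50, 60)))
  expect_equal(competitiveIndex(t2)$ci, 4.0)
  # inoculum triplicate ratios {1.0, 1.25, 0.75}, mean 1.0; gut 30:60
  t3 <- mkTable(cbind(30, 60), cbind(c(40, 50, 30), c(40, 40, 40)))
  expect_equal(competitiveIndex(t3)$ci, 0.5)
})

test_that("swapping competitors inverts the competitive index", {
  tbl <- simulateCompetition(trueLogCI = 0.4, nFlasks = 3, gutsPerFlask = 5,
                             seed = 6)
  swap <- tbl
  swap$count_comp1 <- tbl$count_comp2
  swap$count_comp2 <- tbl$count_comp1
  swap$inoc_count_comp1 <- tbl$inoc_count_comp2
  swap$inoc_count_comp2 <- tbl$inoc_count_comp1
  a <- competitiveIndex(tbl)
  b <- competitiveIndex(swap)
  ok <- !a$censored & !b$censored
  # exact algebra: the product deviates from 1 only through the
  # mean-of-ratios asymmetry of the inoculum estimate (Jensen gap)
  inocA <- tapply(tbl$inoc_count_comp1 / tbl$inoc_count_comp2,
                  tbl$flask_id, mean, na.rm = TRUE)
  inocB <- tapply(swap$inoc_count_comp1 / swap$inoc_count_comp2,
                  swap$flask_id, mean, na.rm = TRUE)
  gap <- (inocA * inocB)[as.character(a$flask_id)]
  expect_equal(a$ci[ok] * b$ci[ok], as.numeric(1 / gap[ok]), tolerance = 1e-9)
  # and reciprocity holds up to that small gap
  expect_equal(a$log10_ci[ok] + b$log10_ci[ok],
               rep(0, sum(ok)), tolerance = 0.05)
})

test_that("zero gut counts trigger the pseudocount rule and censoring", {
  tbl <- mkTable(cbind(c(100, 0, 0), c(0, 100, 0)),
                 cbind(c(50, 50, 50), c(50, 50, 50)))
  expect_warning(ci <- competitiveIndex(tbl), "both counts zero")
  expect_equal(ci$ci[1], 100 / 0.5)
  expect_equal(ci$ci[2], 0.5 / 100)
  expect_true(all(ci$censored[1:2]))
  expect_true(is.na(ci$ci[3]))
})

test_that("degenerate inoculum triplicates are rejected", {
  tbl <- mkTable(cbind(10, 10), cbind(c(0, 0, 0), c(5, 5, 5)))
  expect_error(competitiveIndex(tbl), "degenerate")
})

test_that("rich-medium CI divides final by initial mean ratios", {
  same <- data.frame(count_comp1 = c(50, 60, 70), count_comp2 = c(50, 60, 70))
  expect_equal(richMediumCI(same, same)$ci, 1.0)
  init <- data.frame(count_comp1 = c(50, 50, 50), count_comp2 = c(50, 50, 50))
  fin <- data.frame(count_comp1 = c(90, 75, 60), count_comp2 = c(30, 25, 20))
  expect_equal(richMediumCI(init, fin)$ci, 3.0)
  # initial ratios {0.9, 1.0, 1.1}, final {1.8, 2.0, 2.2} -> CI 2.0
  init2 <- data.frame(count_comp1 = c(90, 100, 110),
                      count_comp2 = c(100, 100, 100))
  fin2 <- data.frame(count_comp1 = c(180, 200, 220),
                     count_comp2 = c(100, 100, 100))
  expect_equal(richMediumCI(init2, fin2)$ci, 2.0)
})

test_that("identical groups with identical flask means give p = 1", {
  cis <- data.frame(group = rep(c("anc", "A", "B"), each = 4),
                    flask_id = rep(sprintf("F%d", 1:6), each = 2),
                    log10_ci = 0.3)
  expect_warning(res <- dunnettVsControl(cis, control = "anc"),
                 "zero residual variance")
  expect_equal(res$estimate, c(0, 0))
  expect_equal(res$p_adj, c(1, 1))
})

test_that("adjusted p-values are no smaller than unadjusted ones", {
  set.seed(12)
  cis <- do.call(rbind, lapply(c("anc", "A", "B", "C"), function(g) {
    tbl <- simulateCompetition(trueLogCI = if (g == "B") 0.8 else 0,
                               nFlasks = 3, gutsPerFlask = 8,
                               seed = sample.int(1e6, 1))
    ci <- competitiveIndex(tbl)
    ci$group <- g
    ci$flask_id <- paste(g, ci$flask_id)
    ci
  }))
  res <- dunnettVsControl(cis, control = "anc")
  dfres <- sum(table(unique(cis[, c("group", "flask_id")])$group)) - 4
  pUnadj <- 2 * pt(-abs(res$t_value), df = dfres)
  expect_true(all(res$p_adj >= pUnadj - 1e-9))
  expect_true(all(res$p_adj >= 0 & res$p_adj <= 1))
})

test_that("missing control and single-flask groups are handled", {
  cis <- data.frame(group = rep(c("anc", "A"), c(6, 2)),
                    flask_id = c(rep(c("F1", "F2", "F3"), 2), "G1", "G1"),
                    log10_ci = rnorm(8))
  expect_error(dunnettVsControl(cis, control = "missing"), "not present")
  cis2 <- rbind(cis, data.frame(group = "B",
                                flask_id = rep(c("H1", "H2"), 2),
                                log10_ci = rnorm(4)))
  expect_warning(res <- dunnettVsControl(cis2, control = "anc"),
                 "single flask")
  expect_equal(res$group, "B")
})

test_that("group estimates converge to the true log CI with more flasks", {
  biasAt <- function(nf, reps = 60) {
    errs <- vapply(seq_len(reps), function(r) {
      tbl <- simulateCompetition(trueLogCI = log(10) * 0.5, nFlasks = nf,
                                 gutsPerFlask = 5, seed = 7000 + nf * 100 + r)
      ci <- competitiveIndex(tbl)
      mean(tapply(ci$log10_ci, ci$flask_id, mean)) - 0.5
    }, numeric(1))
    c(bias = mean(errs), se = sd(errs) / sqrt(reps))
  }
  b3 <- biasAt(3); b30 <- biasAt(30)
  expect_lt(abs(b30["bias"]), 3 * b30["se"] + 0.02)
  expect_lt(abs(b30["bias"]), abs(b3["bias"]) + 2 * (b3["se"] + b30["se"]))
})

test_that("constant tag counts give flat frequencies and no sweep", {
  counts <- data.frame(passage = 0:20, count_dtomato = 50, count_gfp = 50)
  res <- tagTrajectorySummary(counts)
  expect_equal(res$trajectory$freq_dtomato, rep(0.5, 21))
  expect_false(any(res$sweeps$flagged))
})

test_that("a monotone 40-point rise is flagged as a sweep", {
  fd <- c(rep(0.5, 5), seq(0.5, 0.9, length.out = 6), rep(0.9, 10))
  counts <- data.frame(passage = 0:20,
                       count_dtomato = round(1000 * fd),
                       count_gfp = 1000 - round(1000 * fd))
  res <- tagTrajectorySummary(counts)
  sw <- res$sweeps
  expect_true(sw$flagged[sw$tag == "dTomato"])
  expect_false(sw$flagged[sw$tag == "gfp"])
  expect_gte(sw$delta[sw$tag == "dTomato"], 0.30)
})

test_that("zero-count passages break monotone windows", {
  counts <- data.frame(passage = 0:6,
                       count_dtomato = c(10, 12, 0, 30, 35, 40, 45),
                       count_gfp = c(90, 88, 0, 20, 15, 10, 5))
  res <- tagTrajectorySummary(counts)
  expect_true(is.na(res$trajectory$freq_dtomato[3]))
  # the rise must be re-measured from after the gap
  expect_equal(res$sweeps$start[res$sweeps$tag == "dTomato"], 3)
})

test_that("sweeps are flagged more often under selection than drift", {
  flagRate <- function(s) {
    mean(vapply(1:100, function(r) {
      tr <- simulatePassages(s = s, tMut = 1, bottleneckSize = 1e4,
                             seed = 5000 + r)
      any(tagTrajectorySummary(tr)$sweeps$flagged)
    }, logical(1)))
  }
  expect_gt(flagRate(0.5), flagRate(0))
})
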