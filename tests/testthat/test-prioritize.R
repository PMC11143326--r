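# Consensus rule, exclusivity classification, summed pair scores, ranking.

test_that("consensus rule follows the >=5/6 significance pattern", {
  # 5 significant: enriched, representative = most significant of them
  c1 <- consensus_call(c(1e-6, 1e-5, 1e-4, 1e-3, 0.04, 0.2))
  expect_identical(c1$n_significant, 5L)
  expect_true(c1$enriched)
  expect_equal(c1$rep_p, 1e-6)

  # 3 significant: not enriched, representative = most significant
  # NON-significant p
  c2 <- consensus_call(c(1e-6, 1e-5, 1e-4, 0.06, 0.2, 0.9))
  expect_identical(c2$n_significant, 3L)
  expect_false(c2$enriched)
  expect_equal(c2$rep_p, 0.06)

  # all six equal, just under alpha
  c3 <- consensus_call(rep(0.04, 6))
  expect_true(c3$enriched)
  expect_equal(c3$rep_log2p, -log2(0.04), tolerance = 1e-12)

  expect_error(consensus_call(rep(0.01, 5)), "six")
})

test_that("all 64 significance patterns produce the correct call", {
  sig_p <- log(0.001)
  ns_p <- log(0.5)
  for (mask in 0:63) {
    bits <- as.logical(bitwAnd(mask, 2^(0:5)))
    lp <- ifelse(bits, sig_p, ns_p)
    # make minima identifiable: perturb each entry slightly
    lp <- lp - seq(0.01, 0.06, by = 0.01)
    cc <- consensus_call(lp, log_p = TRUE)
    expect_identical(cc$n_significant, sum(bits))
    expect_identical(cc$enriched, sum(bits) >= 5L)
    expected_rep <- if (sum(bits) >= 5L) min(lp[bits]) else min(lp[!bits])
    expect_identical(cc$log_rep_p, expected_rep)
    expect_equal(cc$rep_log2p, -expected_rep / log(2))
  }
})

test_that("all 16 enrichment-flag patterns map onto the documented partition", {
  expected <- function(fo, fc, lo, lc) {
    if (fo && lc && !lo && !fc) "hunger_pair_exclusive"
    else if (fo && !fc && !lo && !lc) "hunger_single_exclusive"
    else if (lo && fc && !fo && !lc) "satiety_pair_exclusive"
    else if (lo && !fo && !fc && !lc) "satiety_single_exclusive"
    else if (fo || fc || lo || lc) "mixed"
    else "none"
  }
  cats <- character(0)
  for (mask in 0:15) {
    fl <- as.logical(bitwAnd(mask, 2^(0:3)))
    names(fl) <- c("fasted_opened", "fasted_closed", "leptin_opened",
                   "leptin_closed")
    got <- classify_tf_category(fl)
    expect_identical(got, expected(fl[1], fl[2], fl[3], fl[4]),
                     info = paste(fl, collapse = ","))
    cats <- c(cats, got)
  }
  # spot checks straight from the truth table
  expect_identical(classify_tf_category(
    c(fasted_opened = TRUE, fasted_closed = FALSE, leptin_opened = FALSE,
      leptin_closed = TRUE)), "hunger_pair_exclusive")
  expect_identical(classify_tf_category(
    c(fasted_opened = TRUE, fasted_closed = FALSE, leptin_opened = FALSE,
      leptin_closed = FALSE)), "hunger_single_exclusive")
  expect_identical(classify_tf_category(
    c(fasted_opened = TRUE, fasted_closed = TRUE, leptin_opened = TRUE,
      leptin_closed = TRUE)), "mixed")
  # each flag pattern lands in exactly one category (partition)
  expect_identical(length(cats), 16L)
  expect_true(all(cats %in% c("hunger_pair_exclusive",
                              "hunger_single_exclusive",
                              "satiety_pair_exclusive",
                              "satiety_single_exclusive", "mixed", "none")))
})

mk_cons <- function(enriched, rep_log2p) {
  list(enriched = enriched, rep_log2p = rep_log2p,
       log_rep_p = -rep_log2p * log(2), rep_p = 2^(-rep_log2p),
       n_significant = if (enriched) 6L else 0L)
}

test_that("summed pair scores require both members and are symmetric", {
  cons <- list(fasted_opened = mk_cons(TRUE, 30),
               fasted_closed = mk_cons(FALSE, 2),
               leptin_opened = mk_cons(FALSE, 1),
               leptin_closed = mk_cons(TRUE, 20))
  expect_identical(summed_pair_score(cons, "hunger"), 50)
  expect_true(is.na(summed_pair_score(cons, "satiety")))
  # swapping the two members leaves the sum unchanged
  cons2 <- cons
  cons2$fasted_opened <- mk_cons(TRUE, 20)
  cons2$leptin_closed <- mk_cons(TRUE, 30)
  expect_identical(summed_pair_score(cons2, "hunger"), 50)
  # one member missing -> undefined, not 0
  cons3 <- cons
  cons3$leptin_closed <- mk_cons(FALSE, 20)
  expect_true(is.na(summed_pair_score(cons3, "hunger")))
})

# Build a synthetic enrichment table for prioritize_tfs.
mk_enrichment <- function(spec_list, alpha = 0.05) {
  conds <- c("fasted_opened", "fasted_closed", "leptin_opened",
             "leptin_closed")
  rows <- list()
  for (m in names(spec_list)) {
    for (cond in conds) {
      lp <- spec_list[[m]][[cond]]
      rows[[length(rows) + 1]] <- data.frame(
        motif_id = m, condition = cond,
        background_label = paste0("bg", 1:6), log_p_adj = lp,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

sig6 <- function(strength) rep(-strength * log(2), 6)  # all six significant
ns6 <- rep(log(0.5), 6)

test_that("prioritize_tfs + rank_and_export order motifs as documented", {
  enr <- mk_enrichment(list(
    STRONG = list(fasted_opened = sig6(30), fasted_closed = ns6,
                  leptin_opened = ns6, leptin_closed = sig6(20)),
    WEAK = list(fasted_opened = sig6(25), fasted_closed = ns6,
                leptin_opened = ns6, leptin_closed = sig6(15)),
    TIED = list(fasted_opened = sig6(30), fasted_closed = ns6,
                leptin_opened = ns6, leptin_closed = sig6(20)),
    SOLO = list(fasted_opened = sig6(12), fasted_closed = ns6,
                leptin_opened = ns6, leptin_closed = ns6),
    EVERY = list(fasted_opened = sig6(9), fasted_closed = sig6(9),
                 leptin_opened = sig6(9), leptin_closed = sig6(9)),
    QUIET = list(fasted_opened = ns6, fasted_closed = ns6,
                 leptin_opened = ns6, leptin_closed = ns6)))
  pr <- prioritize_tfs(enr)
  expect_setequal(pr$motif_id[pr$category == "hunger_pair_exclusive"],
                  c("STRONG", "WEAK", "TIED"))
  expect_identical(pr$category[pr$motif_id == "SOLO"],
                   "hunger_single_exclusive")
  expect_identical(pr$category[pr$motif_id == "EVERY"], "mixed")
  expect_identical(pr$category[pr$motif_id == "QUIET"], "none")
  # every motif receives exactly one category
  expect_identical(nrow(pr), 6L)

  rk <- rank_and_export(pr)
  # 50, 50, 40: lexicographic tie-break between STRONG and TIED
  expect_identical(rk$hunger_pair$motif_id, c("STRONG", "TIED", "WEAK"))
  expect_identical(rk$hunger_pair$rank, 1:3)
  expect_identical(rk$hunger_single$motif_id, "SOLO")
  # undefined sums stay NA
  expect_true(is.na(pr$summed_score_hunger[pr$motif_id == "SOLO"]))
  # radar floors non-informative axes at 0 and keeps 4 axes per motif
  expect_identical(ncol(rk$radar), 5L)
  expect_true(all(rk$radar$fasted_closed >= 0))
})

test_that("uniformly more significant p-values never lower rep_log2p", {
  # entries are kept clearly on one side of alpha so the significance
  # pattern is stable under shrinking (crossing alpha can change which
  # subset the representative is drawn from)
  set.seed(8)
  for (i in 1:25) {
    strong <- -stats::rexp(6, 1 / 3) - 5          # well below log(0.05)
    weak <- stats::runif(6, log(0.5), log(0.9))   # stays non-significant
    lp <- ifelse(stats::runif(6) < 0.5, strong, weak)
    a <- consensus_call(lp, log_p = TRUE)
    b <- consensus_call(lp * 1.5, log_p = TRUE)   # every p shrinks
    expect_gte(b$rep_log2p, a$rep_log2p - 1e-12)
  }
})

test_that("the clamp fallback caps rep_log2p at -log2(exp(-300))", {
  lp <- rep(-921, 6)                       # p ~ 1e-400
  exact <- consensus_call(lp, log_p = TRUE)
  clamped <- consensus_call(lp, log_p = TRUE, clamp_log = TRUE)
  expect_gt(exact$rep_log2p, 1300)
  expect_equal(clamped$rep_log2p, 300 / log(2))
})

test_that("radar JSON export carries four axes per motif", {
  enr <- mk_enrichment(list(
    ONLY = list(fasted_opened = sig6(10), fasted_closed = ns6,
                leptin_opened = ns6, leptin_closed = sig6(4))))
  pr <- prioritize_tfs(enr)
  f <- withr::local_tempfile(fileext = ".json")
  write_radar_json(pr, f, meta = list(seed = 1))
  parsed <- jsonlite::read_json(f)
  expect_identical(parsed$metadata$n_axes, 4L)
  expect_length(parsed$motifs[[1]]$axes, 4L)
  expect_equal(parsed$motifs[[1]]$axes$fasted_opened, 10)
})
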