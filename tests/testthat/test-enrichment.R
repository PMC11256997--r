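# small hand-built table: 2 ASVs, 3 fractions per treatment
tiny_table <- function() {
  m <- rbind(ASV_a = c(0.10, 0.20, 0.30, 0.05, 0.05, 0.40),
             ASV_b = c(0.90, 0.80, 0.70, 0.95, 0.95, 0.60))
  colnames(m) <- c("12C_1", "12C_2", "12C_3", "13C_1", "13C_2", "13C_3")
  asv_table(m)
}

tiny_fractions <- function() {
  rbind(gradient_run("12C", 1:3, c(1.706, 1.737, 1.739), rep(1, 3)),
        gradient_run("13C", 1:3, c(1.706, 1.737, 1.739), rep(1, 3)))
}

test_that("window aggregation is the unweighted mean over window fractions", {
  agg <- aggregate_window_abundance(tiny_table(), fraction_windows(),
                                    tiny_fractions())
  a <- agg[agg$asv_id == "ASV_a", ]
  # single light fraction: mean of one
  expect_equal(a$A12_light, 0.10)
  expect_equal(a$A13_light, 0.05)
  # two heavy fractions 0.20 and 0.30 -> 0.25; 0.05 and 0.40 -> 0.225
  expect_equal(a$A12_heavy, 0.25)
  expect_equal(a$A13_heavy, 0.225)
})

test_that("aggregation matches an explicit-loop re-implementation", {
  sim <- simulate_gradient_experiment(paper_mimic_gradient_config(seed = 8))
  w <- fraction_windows()
  agg <- aggregate_window_abundance(sim$asv_table, w, sim$fractions)
  oracle <- oracle_aggregate(sim$asv_table, w, sim$fractions)
  for (col in c("A13_heavy", "A13_light", "A12_heavy", "A12_light")) {
    expect_equal(agg[[col]], oracle[[col]])
  }
})

test_that("an empty window is rejected with the window named", {
  fr <- rbind(gradient_run("12C", 1:2, c(1.706, 1.737), c(1, 1)),
              gradient_run("13C", 1:2, c(1.706, 1.720), c(1, 1)))
  m <- rbind(ASV_a = c(0.4, 0.6, 0.5, 0.5), ASV_b = c(0.6, 0.4, 0.5, 0.5))
  colnames(m) <- c("12C_1", "12C_2", "13C_1", "13C_2")
  expect_error(aggregate_window_abundance(asv_table(m), fraction_windows(), fr),
               "13C.*heavy")
})

test_that("REF reproduces the printed worked examples exactly", {
  expect_identical(compute_ref(0.309, 0.100, 0.050, 0.050, pseudocount = 0),
                   3.09)
  expect_identical(compute_ref(0.334, 0.100, 0.080, 0.080, pseudocount = 0),
                   3.34)
})

test_that("REF null case and zero handling", {
  expect_equal(compute_ref(0.3, 0.3, 0.07, 0.07, pseudocount = 0), 1.0)
  expect_error(compute_ref(0, 0, 0, 0, pseudocount = 0), "undefined")
  # pseudocount keeps zeros finite and leaves positive inputs untouched
  expect_true(is.finite(compute_ref(0.3, 0, 0.1, 0.1)))
  expect_identical(compute_ref(c(0.309, 0.3), c(0.1, 0), c(0.05, 0.1),
                               c(0.05, 0.1))[1], 3.09)
  expect_error(compute_ref(-0.1, 0.1, 0.1, 0.1), "non-negative")
})

test_that("REF is scale-invariant within each treatment pair", {
  set.seed(42)
  for (i in 1:25) {
    a <- runif(4, 0.01, 1)
    c13 <- runif(1, 0.1, 10)
    c12 <- runif(1, 0.1, 10)
    r0 <- compute_ref(a[1], a[2], a[3], a[4], pseudocount = 0)
    expect_equal(compute_ref(c13 * a[1], c13 * a[2], a[3], a[4],
                             pseudocount = 0), r0)
    expect_equal(compute_ref(a[1], a[2], c12 * a[3], c12 * a[4],
                             pseudocount = 0), r0)
  }
})

test_that("swapping the treatment pairs inverts REF", {
  set.seed(43)
  for (i in 1:25) {
    a <- runif(4, 0.01, 1)
    r <- compute_ref(a[1], a[2], a[3], a[4], pseudocount = 0)
    r_swapped <- compute_ref(a[3], a[4], a[1], a[2], pseudocount = 0)
    expect_equal(r_swapped, 1 / r)
  }
})

test_that("calling on the paper-mimic experiment recovers the labelled taxa", {
  sim <- simulate_gradient_experiment(paper_mimic_gradient_config(seed = 1))
  w <- identify_windows(sim$run_12C, sim$run_13C)
  calls <- call_active_degraders(sim$asv_table, w, sim$fractions)
  expect_setequal(calls$asv_id[calls$active], c("ASV_029", "ASV_037"))
  # output is sorted by REF descending
  expect_true(all(diff(calls$REF) <= 0))
})

test_that("no taxon is active when all REF values are 1", {
  m <- matrix(rep(c(0.2, 0.3, 0.5), 4), nrow = 3,
              dimnames = list(c("ASV_a", "ASV_b", "ASV_c"),
                              c("12C_1", "12C_2", "13C_1", "13C_2")))
  fr <- rbind(gradient_run("12C", 1:2, c(1.706, 1.737), c(1, 1)),
              gradient_run("13C", 1:2, c(1.706, 1.737), c(1, 1)))
  expect_warning(
    calls <- call_active_degraders(asv_table(m), fraction_windows(), fr),
    "top_n")
  expect_equal(calls$REF, rep(1, 3))
  expect_false(any(calls$active))
})

test_that("REF exactly at the threshold is not active (strict inequality)", {
  # A13 2:1, A12 1:1 -> REF exactly 2.0
  m <- rbind(ASV_a = c(0.25, 0.25, 0.40, 0.20),
             ASV_b = c(0.75, 0.75, 0.60, 0.80))
  colnames(m) <- c("12C_1", "12C_2", "13C_1", "13C_2")
  fr <- rbind(gradient_run("12C", 1:2, c(1.737, 1.706), c(1, 1)),
              gradient_run("13C", 1:2, c(1.737, 1.706), c(1, 1)))
  suppressWarnings(
    calls <- call_active_degraders(asv_table(m), fraction_windows(), fr,
                                   calling_params(top_n = 2)))
  expect_equal(calls$REF[calls$asv_id == "ASV_a"], 2.0)
  expect_false(calls$active[calls$asv_id == "ASV_a"])
})

test_that("calling matches an exhaustive re-computation on a small table", {
  sim <- simulate_gradient_experiment(
    sim_gradient_config(seed = 17, n_taxa = 15,
                        labelled_taxa = c(ASV_003 = 1)))
  w <- fraction_windows()
  suppressWarnings(
    calls <- call_active_degraders(sim$asv_table, w, sim$fractions,
                                   calling_params(top_n = 10)))
  # oracle: explicit per-ASV recomputation
  agg <- oracle_aggregate(sim$asv_table, w, sim$fractions)
  cls <- classify_fraction(sim$fractions$buoyant_density, w)
  keys <- paste(sim$fractions$treatment, sim$fractions$fraction_number,
                sep = "_")[cls != "neither"]
  mean_ab <- rowMeans(sim$asv_table$abundance[, keys])
  ord <- order(-mean_ab, names(mean_ab))
  rank <- integer(15); rank[ord] <- 1:15
  names(rank) <- names(mean_ab)
  for (i in seq_len(nrow(calls))) {
    id <- calls$asv_id[i]
    j <- which(agg$asv_id == id)
    ref <- (agg$A13_heavy[j] / agg$A13_light[j]) /
      (agg$A12_heavy[j] / agg$A12_light[j])
    expect_equal(calls$REF[i], ref)
    expect_equal(calls$rank[i], unname(rank[id]))
    expect_identical(calls$active[i], unname(rank[id] <= 10 && ref > 2))
  }
})
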